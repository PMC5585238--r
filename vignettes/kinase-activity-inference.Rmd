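---
title: "Inferring active kinases from TMT phosphoproteomics: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring active kinases from TMT phosphoproteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphokin)
```

# The problem

Cancer cell lines that resist a targeted drug (here, colorectal lines that
keep proliferating under the anti-EGFR antibody cetuximab) often do so
because alternative kinases stay active and sustain proliferative
signaling. Deep quantitative phosphoproteomics can expose those kinases:
if a kinase is active in the resistant line, its substrates — and usually
its own activation-loop phosphosite — show elevated phosphorylation
relative to drug-sensitive lines. `phosphokin` implements the complete
computational path from multiplexed (TMT) phosphosite quantification
tables to a ranked set of active-kinase candidates and the curated
kinase–kinase phosphorylation network connecting them.

The pipeline has six computational stages, each exposed as ordinary
functions and orchestrated by `run_pipeline()`:

1. **Identification filtering** (`filter_class1`): keep confidently
   identified, confidently localized phosphosites.
2. **Normalization** (`to_log2_with_missing`, `median_center`,
   `reference_bridge`): reporter intensities to comparable log2 ratios.
3. **Error calibration** (`reference_fold_sd`, `fold_change_cutoff`): a
   fold-change significance cutoff derived from duplicate reference
   channels.
4. **Differential statistics** (`welch_test`, `permutation_q`,
   `classify_sites`): per-site two-group tests with a permutation FDR.
5. **Kinase activity** (`regulatory_evidence`, `ksea_scores`,
   `merge_activity`): two independent evidence routes, merged.
6. **Network reconstruction** (`build_network`, `export_network`).

# Data model and quality filtering

The site table is MaxQuant-Phospho(STY)Sites-like: one row per site with
reporter-ion intensities per TMT channel, expanded on reading into one
quantitative feature per *multiplicity* (number of phosphogroups on the
underlying peptides), keyed `(protein, position, residue, multiplicity)`.
The leading protein accession is the site's protein id. Downstream
annotation joins (regulatory sites, kinase–substrate relations) ignore
multiplicity and join on `(protein, position, residue)`, averaging the
fold changes of a site's multiplicity features — the conventional
Perseus-style treatment that loses no quantitative information while
keeping site identity biological rather than technical.

Class-1 filtering keeps records with Andromeda score ≥ 40, delta score
≥ 8 and localization probability ≥ 0.75 — all boundaries inclusive — and
drops contaminant/reverse hits at this stage (they are retained, flagged,
by the reader so the decision is visible). The completeness filter
(`replicate_complete_filter`) then requires a site to be quantified in
every sample of a chosen scope; `run_pipeline()` applies it per contrast,
i.e. across the nine samples actually compared, reading the requirement
of detection "in all replicate experiments" as completeness within the
compared triplicates.

# Normalization and the bridging operator

Intensities of exactly 0 are missing values, never zeros on the log
scale. After `log2`, each sample column is median-centered, which removes
channel loading differences. TMT sets are then bridged: for each site and
set, the mean of that set's reference-channel values is subtracted from
all of the set's samples, so values become log2 ratios to the common
pooled reference and any per-site, per-set additive offset cancels
exactly (this offset-invariance is tested property-style). The order —
center, then bridge — is enforced by provenance flags on the matrix; the
reference difference used by the calibration below is invariant to both
operations, so calibration may run at any stage after log2. When one of
the two reference channels is missing for a site in a set, the available
one is used; when both are missing, the site's values in that set become
missing.

# Calibrating the fold-change cutoff

The two reference channels of every set carry the same pooled sample, so
the SD over sites of their log2 difference measures pure technical error.
The calibration computes this sample SD (n−1 denominator) per set on
complete pairs, averages the per-set SDs, doubles the average (the 2-SD
rule), and exponentiates: `linear_cutoff = 2^(2·mean_sd)`. Full precision
is carried end to end; rounding happens only in reports. For two-SD
values of 0.989 and 0.556 — typical of deep global (pSTY) and
phosphotyrosine (pY) TMT experiments respectively — the rule yields
linear cutoffs of 1.985 and 1.470. With more than two reference channels,
the first two configured channels are compared (configurable), matching
the conventional 126/127N bridge design.

# Differential statistics

Per site, the resistant line's replicates (n = 3) are tested against the
pooled sensitive group (n = 6) with a two-tailed Welch unequal-variance
t-test (Welch–Satterthwaite degrees of freedom), requiring at least two
usable values per side; sites below that are reported untested. Two
degenerate conventions: both groups constant and equal gives p = 1; both
constant and unequal gives p = 0, flagged.

The q-value is a SAM/Perseus-style permutation FDR: group labels are
relabeled over the contrast's nine samples preserving group sizes; for
each observed p, the raw q is the mean count of permutation p-values at
or below it divided by the count of observed p-values at or below it,
clipped to [0, 1] and monotonized non-decreasing in p. With 3-vs-6
groups all C(9,3) = 84 relabelings are enumerated, making q exact and
seed-independent; sampling (default 1000 relabelings, seeded) is used
only when enumeration would exceed 5000 relabelings. A consequence worth
knowing: with 84 relabelings the smallest achievable q for a uniquely
most-extreme site is 1/84 ≈ 0.0119, so single-site significance at
q < 0.05 demands a clearly extreme statistic — the permutation FDR is
discrete, and power per site is modest at these group sizes. A site is
called `increased` when q < 0.05 **and** its log2 fold change reaches the
calibrated cutoff (`decreased` symmetrically).

The viability-screen statistics (`sirna_screen_test`) are separate:
paired two-tailed t-tests of perturbation versus matched control wells,
Benjamini–Hochberg-adjusted across perturbations.

# Kinase activity: two evidence routes

**Regulatory-site evidence.** Kinase activity is frequently governed by
phosphorylation of the kinase itself (activation-loop
autophosphorylation being the canonical case). Given an annotation of
kinase-regulatory phosphosites classed `activity_up`, `activity_down` or
`other`, a kinase is called active when at least one of its
`activity_up` sites is classified `increased`. Increases on
`activity_down` sites are reported but never generate a call.

**KSEA.** Kinase–substrate enrichment analysis scores each kinase with at
least `min_substrates` (default 3) quantified substrates among predicted
kinase–substrate relations:

$$z = \frac{(\bar m_S - \bar m_P)\sqrt{m}}{\delta}$$

with $\bar m_S$ the mean log2 fold change of the kinase's substrates,
$\bar m_P$ and $\delta$ the mean and SD over all tested sites, and $m$
the substrate count; p is the two-tailed normal tail and q the BH
adjustment across scored kinases. "Activated" requires z > 0 and
q < 0.05. This is the canonical z-score form of KSEA; the substrate
minimum and an optional prediction-score threshold are configurable
because no single convention dominates practice.

`merge_activity()` takes the union, labelling kinases found by both
routes `both` — the strongest candidates, combining the kinase's own
phosphorylation state with the behavior of its substrates.

# Network reconstruction

Called kinases become nodes (classed by evidence route). A directed edge
A→B, annotated with the substrate site, is drawn when both are called and
an experimentally curated KSR "A phosphorylates B at site" exists.
Additionally, for each called kinase's increased regulatory site, curated
upstream kinases phosphorylating **exactly that site** are wired in, as
`upstream_only` nodes when not themselves called; a site-agnostic
fallback is deliberately absent, since the point of these edges is to
explain the observed activating phosphorylation. Autophosphorylation
edges (self-loops) are retained and flagged — self-activation is itself a
mechanism of constitutive signaling, not an artifact. Exports (SIF,
GraphML, TSV) are sorted and deterministic.

# The synthetic-data generator

`sim_design()`/`simulate_experiment()` emulate the full study design so
every stage is testable without raw MS data. Defaults encode the study
conditions: three 10-plex TMT sets, channels 126 and 127N carrying the
pooled reference in every set, and the remaining eight channels one
replicate of each cell line × treatment (two sensitive lines, two
resistant lines, ± drug), so each contrast compares n = 3 resistant
against n = 6 pooled sensitive values in triplicate. Log2 reporter
values are baseline Uniform(20, 30) plus a site×set batch effect
(SD 0.5, removed exactly by bridging), a per-channel loading offset
(SD 0.3, removed exactly by median centering), planted effects, and
Normal measurement noise (`sigma_meas`, default 0.2 — a tight but
realistic reporter-ion CV). Reference channels share the site's
baseline+batch value, each perturbed with SD `sigma_ref`; the default
0.349 = 0.494/√2 makes the reference fold-change SD ≈ 0.494, the
technical-error scale of a deep global phosphoproteome arm (0.277/√2 ≈
0.196 is the pY-arm equivalent). Ground truth records every planted
differential site and kinase program. Identification metadata are drawn
so a configurable fraction fails exactly one class-1 criterion; 2% of
sites are contaminants; missingness is independent site×channel
Bernoulli (2%); 10% of sites carry a second multiplicity.

What the generator does **not** emulate: ratio compression from
co-isolation, intensity-dependent variance and missingness,
peptide-level structure beneath sites, correlated regulation outside the
planted programs. Passing tests therefore demonstrate correctness of the
statistical machinery under a clean generative model, not robustness to
every artifact of real TMT data.

# Numerical and design choices

- SDs use the n−1 denominator throughout.
- Class-1 thresholds are inclusive (≥), the Perseus convention.
- Median centering precedes bridging; provenance flags prevent reordering
  or re-application.
- Permutation q-values monotonize step-up from the largest p (the same
  scheme BH uses), guaranteeing q non-decreasing in p.
- The two proteomic arms (pSTY, pY) are calibrated separately — their
  technical error differs by ~2× — and their classified sites are pooled
  per contrast before kinase-activity inference, since both arms
  contribute substrate and regulatory-site evidence.
- Minimum non-missing values per contrast side is 2; the KSEA substrate
  minimum is 3.
- Test and acceptance simulations use 300–5000 sites, 10–20 seeds, and
  planted effects of 1–3 log2 units over 10–12 substrates: sizes at
  which calibration recovery sits within 5%, null false-call fractions
  are estimated on ≥ 20 000 site tests, and KSEA recovery of planted
  kinases is essentially deterministic.

# Limitations

Per-site power at n = 3 vs 6 with an 84-relabeling permutation FDR is
limited; single-site calls need large shifts, which is why the KSEA
route (aggregating ≥ 3 substrates) carries much of the detection burden.
The KSEA normal approximation assumes substrate fold changes are draws
from the global distribution; correlated substrates (shared peptides,
co-regulation) inflate z. Regulatory-site evidence inherits the
completeness of the annotation: an active kinase with no annotated
`activity_up` site can only ever be found by KSEA. Network edges are
bounded by curated-KSR coverage and say nothing about edges absent from
curation.
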