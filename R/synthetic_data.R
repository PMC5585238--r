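# Synthetic TMT phosphoproteomics experiments with known ground truth:
# planted differential sites, planted active-kinase programs that shift
# their substrates' fold changes, reference-channel replication noise, and
# matching kinase-substrate / regulatory-site annotation tables in the same
# file dialects the pipeline reads.

#' Define a simulated TMT experiment
#'
#' The default design mirrors a triplicate 10-plex layout: each TMT set
#' carries two reference channels (126, 127N) labelled with a common pooled
#' sample, plus one replicate of each cell line x treatment combination
#' (two cetuximab-sensitive lines, two resistant lines, with and without
#' drug), so three sets give the sensitive group n = 6 and each resistant
#' line n = 3 per treatment state.
#'
#' Log2 reporter values are generated as baseline (Uniform 20-30) plus a
#' site-by-set batch effect, a channel loading offset, planted group/kinase
#' effects, and Normal(0, `sigma_meas`) measurement noise; the two
#' reference channels of a set share the site's baseline + batch value,
#' each perturbed independently with SD `sigma_ref`. The default
#' `sigma_ref` of 0.349 reproduces a reference-channel fold-change SD of
#' about 0.494 (0.349 * sqrt(2)), the technical-error scale of a deep
#' global phosphoproteome TMT run; 0.196 is the phosphotyrosine-arm
#' equivalent (SD about 0.277).
#'
#' @param n_sets Number of TMT sets (replicates of the full layout).
#' @param channels Channel labels per set.
#' @param reference_channels Labels of the pooled-reference channels.
#' @param sensitive_lines,resistant_lines,treatments Sample-group layout;
#'   their combinations must fill the non-reference channels exactly.
#' @param n_sites Number of generic phosphosites (kinase-regulatory sites
#'   of programs are appended beyond these).
#' @param frac_pY Fraction of tyrosine sites among generic sites.
#' @param sigma_meas Per-channel measurement SD, log2 scale.
#' @param sigma_ref Reference-channel replication SD, log2 scale.
#' @param sigma_channel SD of per-channel loading offsets (removed by
#'   median centering).
#' @param sigma_batch SD of site-by-set batch effects (removed by
#'   reference bridging).
#' @param kinase_programs List of [kinase_program()] objects.
#' @param n_planted_diff Number of non-kinase-driven differential sites.
#' @param effect_diff Their absolute log2 effect (signs alternate).
#' @param frac_missing Site-by-channel independent missingness rate.
#' @param frac_fail_class1 Fraction of sites drawn to fail one class-1
#'   identification criterion.
#' @param frac_multi Fraction of sites carrying a second multiplicity.
#' @param frac_contaminant Fraction of sites flagged as contaminants.
#' @param n_proteins Number of generic proteins the sites are spread over.
#' @param seed Integer RNG seed; identical designs give byte-identical
#'   simulated tables.
#' @return A `sim_design` object.
#' @export
sim_design <- function(n_sets = 3,
                       channels = c("126", "127N", "127C", "128N", "128C",
                                    "129N", "129C", "130N", "130C", "131"),
                       reference_channels = c("126", "127N"),
                       sensitive_lines = c("DLD1", "LIM1215"),
                       resistant_lines = c("HCT116", "HT29"),
                       treatments = c("none", "drug"),
                       n_sites = 2000,
                       frac_pY = 0.1,
                       sigma_meas = 0.2,
                       sigma_ref = 0.494 / sqrt(2),
                       sigma_channel = 0.3,
                       sigma_batch = 0.5,
                       kinase_programs = list(),
                       n_planted_diff = 0,
                       effect_diff = 1,
                       frac_missing = 0.02,
                       frac_fail_class1 = 0.1,
                       frac_multi = 0.1,
                       frac_contaminant = 0.02,
                       n_proteins = NULL,
                       seed = 1L) {
  if (is.null(n_proteins)) n_proteins <- max(50, n_sites %/% 5)
  d <- structure(as.list(environment()), class = "sim_design")
  validate_sim_design(d)
  d
}

validate_sim_design <- function(d) {
  stopifnot(d$n_sets >= 1, d$n_sites >= 1)
  if (anyDuplicated(d$channels)) stop_fmt("duplicate channel labels")
  if (!all(d$reference_channels %in% d$channels))
    stop_fmt("reference channels must be a subset of the channel labels")
  if (d$sigma_meas < 0 || d$sigma_ref < 0 || d$sigma_channel < 0 ||
      d$sigma_batch < 0)
    stop_fmt("noise SDs must be non-negative")
  for (f in c("frac_pY", "frac_missing", "frac_fail_class1", "frac_multi",
              "frac_contaminant")) {
    if (d[[f]] < 0 || d[[f]] > 1) stop_fmt("%s must lie in [0, 1]", f)
  }
  n_cond <- length(c(d$sensitive_lines, d$resistant_lines)) * length(d$treatments)
  n_free <- length(d$channels) - length(d$reference_channels)
  if (n_cond != n_free)
    stop_fmt("layout mismatch: %d cell line x treatment conditions but %d non-reference channels per set",
             n_cond, n_free)
  ids <- vapply(d$kinase_programs, `[[`, "", "kinase_id")
  if (anyDuplicated(ids)) stop_fmt("duplicate kinase program id(s)")
  for (pr in d$kinase_programs) {
    stopifnot(inherits(pr, "kinase_program"))
    bad <- pr$substrate_sites[pr$substrate_sites < 1 |
                                pr$substrate_sites > d$n_sites]
    if (length(bad) > 0)
      stop_fmt("program %s references unknown substrate site id(s): %s",
               pr$kinase_id, paste(bad, collapse = ", "))
    if (!pr$target_line %in% d$resistant_lines)
      stop_fmt("program %s targets unknown resistant line '%s'",
               pr$kinase_id, pr$target_line)
    if (!all(pr$treatments %in% d$treatments))
      stop_fmt("program %s names unknown treatment(s)", pr$kinase_id)
  }
  invisible(d)
}

#' Define a planted active-kinase program
#'
#' A program plants one "active kinase": all its substrate sites (and its
#' own activation-loop regulatory site) are shifted by `effect` log2 units
#' in the targeted resistant cell line.
#'
#' @param kinase_id Kinase name (also its protein accession in the
#'   simulated world).
#' @param substrate_sites Integer indices (into the design's generic sites)
#'   of the kinase's substrates.
#' @param effect Log2 effect size added in the target line.
#' @param target_line Resistant cell line carrying the activation.
#' @param treatments Treatment states in which the program is active.
#' @param reg_position Protein position of the kinase's activation-loop
#'   tyrosine.
#' @return A `kinase_program` object.
#' @export
kinase_program <- function(kinase_id, substrate_sites, effect, target_line,
                           treatments = c("none", "drug"),
                           reg_position = 400) {
  structure(list(kinase_id = kinase_id,
                 substrate_sites = as.integer(substrate_sites),
                 effect = effect, target_line = target_line,
                 treatments = treatments,
                 reg_position = as.integer(reg_position)),
            class = "kinase_program")
}

# deterministic design table for a sim_design
sim_design_table <- function(d) {
  conds <- expand.grid(cell_line = c(d$sensitive_lines, d$resistant_lines),
                       treatment = d$treatments,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- list()
  for (s in seq_len(d$n_sets)) {
    set_id <- paste0("set", s)
    free <- setdiff(d$channels, d$reference_channels)
    for (ch in d$reference_channels) {
      rows[[length(rows) + 1]] <- data.frame(
        set_id = set_id, channel = ch,
        sample_id = paste0(set_id, ".ref.", ch),
        cell_line = "pooled_reference", group = "reference",
        treatment = "none", replicate = s, is_reference = TRUE,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(conds))) {
      rows[[length(rows) + 1]] <- data.frame(
        set_id = set_id, channel = free[i],
        sample_id = paste0(conds$cell_line[i], "_", conds$treatment[i], "_R", s),
        cell_line = conds$cell_line[i],
        group = if (conds$cell_line[i] %in% d$resistant_lines) "resistant"
                else "sensitive",
        treatment = conds$treatment[i], replicate = s, is_reference = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  design <- do.call(rbind, rows)
  validate_design(design)
  design
}

#' Simulate a TMT phosphoproteomics experiment
#'
#' Generates a site table (in the internal representation of
#' [read_site_table()]), the matching sample-design table, and the planted
#' ground truth, all deterministically from the design's seed.
#'
#' @param design A [sim_design()].
#' @return A `sim_experiment` list: `sites` (site table), `design_table`,
#'   `truth` (planted differential sites per contrast, active kinases,
#'   `sigma_ref`), `site_assignment` (site index to protein/position/
#'   residue map), and the `design`.
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  validate_sim_design(design)
  d <- design
  with_seed(d$seed, {
    n_prog <- length(d$kinase_programs)
    N <- d$n_sites + n_prog

    # --- site -> protein assignment ---------------------------------------
    protein <- character(N); position <- integer(N); residue <- character(N)
    gi <- seq_len(d$n_sites)
    protein[gi] <- sprintf("P%05d", ((gi - 1) %% d$n_proteins) + 1)
    position[gi] <- 10L + 7L * ((gi - 1) %/% d$n_proteins)
    r <- stats::runif(d$n_sites)
    residue[gi] <- ifelse(r < d$frac_pY, "Y",
                          ifelse(r < d$frac_pY + (1 - d$frac_pY) / 2, "S", "T"))
    for (j in seq_along(d$kinase_programs)) {
      pr <- d$kinase_programs[[j]]
      i <- d$n_sites + j
      protein[i] <- pr$kinase_id
      position[i] <- pr$reg_position
      residue[i] <- "Y"
    }

    design_table <- sim_design_table(d)
    nonref <- design_table[!design_table$is_reference, , drop = FALSE]

    # --- planted effects (site x non-reference sample) --------------------
    E <- matrix(0, N, nrow(nonref), dimnames = list(NULL, nonref$sample_id))
    truth_rows <- list()
    for (j in seq_along(d$kinase_programs)) {
      pr <- d$kinase_programs[[j]]
      rows <- c(pr$substrate_sites, d$n_sites + j)
      cols <- nonref$cell_line == pr$target_line &
        nonref$treatment %in% pr$treatments
      E[rows, cols] <- E[rows, cols] + pr$effect
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        site_index = rows, effect = pr$effect, target_line = pr$target_line,
        treatments = paste(pr$treatments, collapse = ";"),
        source = paste0("program:", pr$kinase_id), stringsAsFactors = FALSE)
    }
    prog_sites <- unlist(lapply(d$kinase_programs, `[[`, "substrate_sites"))
    if (d$n_planted_diff > 0) {
      cand <- setdiff(seq_len(d$n_sites), prog_sites)
      if (length(cand) < d$n_planted_diff)
        stop_fmt("not enough free sites for %d planted differentials",
                 d$n_planted_diff)
      idx <- sort(sample(cand, d$n_planted_diff))
      lines <- rep_len(d$resistant_lines, d$n_planted_diff)
      signs <- rep_len(c(1, -1), d$n_planted_diff)
      for (k in seq_len(d$n_planted_diff)) {
        cols <- nonref$cell_line == lines[k]
        E[idx[k], cols] <- E[idx[k], cols] + signs[k] * d$effect_diff
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          site_index = idx[k], effect = signs[k] * d$effect_diff,
          target_line = lines[k],
          treatments = paste(d$treatments, collapse = ";"),
          source = "planted", stringsAsFactors = FALSE)
      }
    }

    # --- identification metadata (per parent site) ------------------------
    locprob <- stats::runif(N, 0.75, 1)
    score <- stats::runif(N, 40, 200)
    delta <- stats::runif(N, 8, 80)
    fails <- stats::runif(N) < d$frac_fail_class1
    which_fail <- sample(3, N, replace = TRUE)
    u <- stats::runif(N)
    locprob[fails & which_fail == 1] <- (0.74 * u)[fails & which_fail == 1]
    score[fails & which_fail == 2] <- (10 + 29 * u)[fails & which_fail == 2]
    delta[fails & which_fail == 3] <- (7.5 * u)[fails & which_fail == 3]
    contaminant <- stats::runif(N) < d$frac_contaminant

    # --- feature expansion (multiplicity) ---------------------------------
    multi <- stats::runif(N) < d$frac_multi
    parent <- c(seq_len(N), which(multi))
    mult <- c(rep(1L, N), rep(2L, sum(multi)))
    ord <- order(parent, mult)
    parent <- parent[ord]; mult <- mult[ord]
    FN <- length(parent)

    # --- log2 values ------------------------------------------------------
    baseline <- stats::runif(N, 20, 30)
    batch <- matrix(stats::rnorm(N * d$n_sets, 0, d$sigma_batch), N, d$n_sets)
    base_f <- baseline[parent] - (mult - 1)   # second multiplicity dimmer
    set_idx <- match(design_table$set_id, unique(design_table$set_id))
    V <- matrix(NA_real_, FN, nrow(design_table))
    for (cidx in seq_len(nrow(design_table))) {
      chan_offset <- stats::rnorm(1, 0, d$sigma_channel)
      common <- base_f + batch[parent, set_idx[cidx]] + chan_offset
      if (design_table$is_reference[cidx]) {
        V[, cidx] <- common + stats::rnorm(FN, 0, d$sigma_ref)
      } else {
        V[, cidx] <- common + E[parent, design_table$sample_id[cidx]] +
          stats::rnorm(FN, 0, d$sigma_meas)
      }
    }
    intens <- 2^V
    intens[matrix(stats::runif(FN * ncol(V)) < d$frac_missing, FN)] <- 0

    # --- assemble the site table ------------------------------------------
    channel_map <- data.frame(set_id = design_table$set_id,
                              channel = design_table$channel,
                              stringsAsFactors = FALSE)
    channel_map$col <- paste0("I.", channel_map$set_id, ".", channel_map$channel)
    sites <- data.frame(
      protein_id = protein[parent],
      proteins = protein[parent],
      gene_symbol = protein[parent],
      position = position[parent],
      residue = residue[parent],
      multiplicity = mult,
      localization_prob = locprob[parent],
      score = score[parent],
      delta_score = delta[parent],
      contaminant = contaminant[parent],
      reverse = FALSE,
      stringsAsFactors = FALSE)
    colnames(intens) <- channel_map$col
    sites <- cbind(sites, as.data.frame(intens))
    sites <- validate_site_table(sites, channel_map)

    site_assignment <- data.frame(site_index = seq_len(N), protein_id = protein,
                                  position = position, residue = residue,
                                  stringsAsFactors = FALSE)

    truth_sites <- if (length(truth_rows) > 0) do.call(rbind, truth_rows) else
      data.frame(site_index = integer(), effect = numeric(),
                 target_line = character(), treatments = character(),
                 source = character(), stringsAsFactors = FALSE)
    truth_sites$protein_id <- protein[truth_sites$site_index]
    truth_sites$position <- position[truth_sites$site_index]
    truth_sites$residue <- residue[truth_sites$site_index]
    truth <- list(
      diff_sites = truth_sites,
      active_kinases = data.frame(
        kinase_id = vapply(d$kinase_programs, `[[`, "", "kinase_id"),
        target_line = vapply(d$kinase_programs, `[[`, "", "target_line"),
        effect = vapply(d$kinase_programs, function(p) p$effect, 0),
        n_substrates = vapply(d$kinase_programs,
                              function(p) length(p$substrate_sites), 0L),
        reg_site = vapply(d$kinase_programs,
                          function(p) paste0("Y", p$reg_position), ""),
        stringsAsFactors = FALSE),
      sigma_ref = d$sigma_ref)

    structure(list(sites = sites, design_table = design_table, truth = truth,
                   site_assignment = site_assignment, design = d),
              class = "sim_experiment")
  })
}

#' Matching annotation tables for a simulated experiment
#'
#' Builds the predicted kinase-substrate table (every program kinase with
#' all of its substrates, plus decoy kinases with random substrates), the
#' curated KSR table (each program kinase's activation-loop
#' autophosphorylation, a chain of curated edges between consecutive
#' program kinases, and one upstream-only decoy kinase), and the
#' regulatory-site annotation marking each program kinase's activation-loop
#' site as `activity_up`. Deterministic given the design seed.
#'
#' @param sim A `sim_experiment` from [simulate_experiment()].
#' @param n_decoy_kinases Number of decoy predicted kinases.
#' @param decoy_substrates Substrates per decoy kinase.
#' @return List `predicted`, `curated`, `regulatory`.
#' @export
annotation_tables <- function(sim, n_decoy_kinases = 3, decoy_substrates = 8) {
  stopifnot(inherits(sim, "sim_experiment"))
  d <- sim$design
  sa <- sim$site_assignment
  with_seed(d$seed + 7919L, {
    pred <- list(); cur <- list(); reg <- list()
    progs <- d$kinase_programs
    for (j in seq_along(progs)) {
      pr <- progs[[j]]
      sub <- sa[pr$substrate_sites, , drop = FALSE]
      pred[[length(pred) + 1]] <- data.frame(
        kinase_id = pr$kinase_id, substrate_protein_id = sub$protein_id,
        substrate_position = sub$position, substrate_residue = sub$residue,
        source = "predicted",
        score = round(stats::runif(nrow(sub), 1, 5), 3),
        stringsAsFactors = FALSE)
      # activation-loop autophosphorylation, curated
      cur[[length(cur) + 1]] <- data.frame(
        kinase_id = pr$kinase_id, substrate_protein_id = pr$kinase_id,
        substrate_position = pr$reg_position, substrate_residue = "Y",
        source = "curated", score = NA_real_, stringsAsFactors = FALSE)
      if (j < length(progs)) {
        nxt <- progs[[j + 1]]
        cur[[length(cur) + 1]] <- data.frame(
          kinase_id = pr$kinase_id, substrate_protein_id = nxt$kinase_id,
          substrate_position = nxt$reg_position, substrate_residue = "Y",
          source = "curated", score = NA_real_, stringsAsFactors = FALSE)
      }
      reg[[length(reg) + 1]] <- data.frame(
        kinase_id = pr$kinase_id, position = pr$reg_position, residue = "Y",
        function_class = "activity_up", stringsAsFactors = FALSE)
    }
    if (length(progs) > 0) {
      # an upstream kinase never itself called: curated edge onto program 1
      cur[[length(cur) + 1]] <- data.frame(
        kinase_id = "UPSTREAM1", substrate_protein_id = progs[[1]]$kinase_id,
        substrate_position = progs[[1]]$reg_position, substrate_residue = "Y",
        source = "curated", score = NA_real_, stringsAsFactors = FALSE)
    }
    for (k in seq_len(n_decoy_kinases)) {
      idx <- sample(d$n_sites, min(decoy_substrates, d$n_sites))
      sub <- sa[idx, , drop = FALSE]
      pred[[length(pred) + 1]] <- data.frame(
        kinase_id = sprintf("DECOY%d", k), substrate_protein_id = sub$protein_id,
        substrate_position = sub$position, substrate_residue = sub$residue,
        source = "predicted",
        score = round(stats::runif(nrow(sub), 1, 5), 3),
        stringsAsFactors = FALSE)
      reg[[length(reg) + 1]] <- data.frame(
        kinase_id = sprintf("DECOY%d", k), position = 100L, residue = "S",
        function_class = "other", stringsAsFactors = FALSE)
    }
    empty_ksr <- data.frame(
      kinase_id = character(), substrate_protein_id = character(),
      substrate_position = integer(), substrate_residue = character(),
      source = character(), score = numeric(), stringsAsFactors = FALSE)
    empty_reg <- data.frame(
      kinase_id = character(), position = integer(), residue = character(),
      function_class = character(), stringsAsFactors = FALSE)
    dedup <- function(x, keys, empty) {
      if (length(x) == 0) return(empty)
      x <- do.call(rbind, x)
      x <- x[!duplicated(x[, keys]), , drop = FALSE]
      rownames(x) <- NULL
      x
    }
    ksr_keys <- c("kinase_id", "substrate_protein_id", "substrate_position",
                  "substrate_residue")
    list(predicted = dedup(pred, ksr_keys, empty_ksr),
         curated = dedup(cur, ksr_keys, empty_ksr),
         regulatory = dedup(reg, c("kinase_id", "position", "residue"),
                            empty_reg))
  })
}

#' Write a simulated experiment to disk
#'
#' Emits `site_table.tsv` (MaxQuant-like dialect), `design.tsv`, and
#' `ground_truth.json` into `out_dir`.
#'
#' @param sim A `sim_experiment`.
#' @param out_dir Output directory (created if absent).
#' @return Named list of file paths, invisibly.
#' @export
write_experiment <- function(sim, out_dir) {
  stopifnot(inherits(sim, "sim_experiment"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    site_table = file.path(out_dir, "site_table.tsv"),
    design = file.path(out_dir, "design.tsv"),
    truth = file.path(out_dir, "ground_truth.json"))
  write_site_table(sim$sites, paths$site_table)
  write_design_table(sim$design_table, paths$design)
  jsonlite::write_json(sim$truth, paths$truth, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write annotation fixture files for a simulated experiment
#'
#' Writes the [annotation_tables()] of the simulation in the dialects the
#' msio readers consume: a NetworKIN-like predicted KSR TSV, a
#' PhosphositePlus-like curated KSR TSV, and the regulatory-site TSV.
#'
#' @param sim A `sim_experiment` (or a [sim_design()], which is simulated
#'   first).
#' @param out_dir Output directory (created if absent).
#' @inheritParams annotation_tables
#' @return Named list of file paths (`predicted_ksr`, `curated_ksr`,
#'   `regulatory_sites`), invisibly.
#' @export
write_annotation_fixtures <- function(sim, out_dir, n_decoy_kinases = 3,
                                      decoy_substrates = 8) {
  if (inherits(sim, "sim_design")) sim <- simulate_experiment(sim)
  tabs <- annotation_tables(sim, n_decoy_kinases, decoy_substrates)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    predicted_ksr = file.path(out_dir, "predicted_ksr.tsv"),
    curated_ksr = file.path(out_dir, "curated_ksr.tsv"),
    regulatory_sites = file.path(out_dir, "regulatory_sites.tsv"))
  write_ksr_table(tabs$predicted, paths$predicted_ksr, source = "predicted")
  write_ksr_table(tabs$curated, paths$curated_ksr, source = "curated")
  write_regulatory_sites(tabs$regulatory, paths$regulatory_sites)
  invisible(paths)
}
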