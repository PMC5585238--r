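# Per-site two-group statistics: vectorized Welch tests, permutation-based
# q-values (SAM/Perseus-style relabeling FDR), volcano classification, and
# the paired-t + BH statistics used for viability screens.

#' Define a two-group contrast
#'
#' A contrast compares a resistant cell line's replicates against the pooled
#' sensitive-group replicates (conventionally n = 3 vs n = 6) at one
#' treatment state.
#'
#' @param name Contrast label, e.g. `"HCT116_none"`.
#' @param resistant_samples,sensitive_samples Disjoint character vectors of
#'   sample ids.
#' @return A `contrast` object.
#' @export
make_contrast <- function(name, resistant_samples, sensitive_samples) {
  if (length(intersect(resistant_samples, sensitive_samples)) > 0)
    stop_fmt("contrast '%s': the two sample sets overlap", name)
  if (length(resistant_samples) < 2 || length(sensitive_samples) < 2)
    stop_fmt("contrast '%s': each side needs at least 2 samples", name)
  structure(list(name = name, resistant_samples = resistant_samples,
                 sensitive_samples = sensitive_samples),
            class = "contrast")
}

#' Derive the standard contrasts from a design table
#'
#' One contrast per resistant cell line and treatment state: that line's
#' replicates versus all sensitive-group replicates at the same treatment.
#'
#' @param design Design data.frame.
#' @return Named list of [make_contrast()] objects.
#' @export
contrasts_from_design <- function(design) {
  validate_design(design)
  d <- design[!design$is_reference, , drop = FALSE]
  res_lines <- sort(unique(d$cell_line[d$group == "resistant"]))
  out <- list()
  for (line in res_lines) {
    for (trt in sort(unique(d$treatment[d$cell_line == line]))) {
      res <- d$sample_id[d$cell_line == line & d$treatment == trt]
      sen <- d$sample_id[d$group == "sensitive" & d$treatment == trt]
      nm <- paste(line, trt, sep = "_")
      out[[nm]] <- make_contrast(nm, res, sen)
    }
  }
  out
}

# core vectorized Welch machinery shared by the observed test and the
# permutation null; X is the log2 matrix, idx1/idx2 column indices
welch_stats <- function(X, idx1, idx2, min_per_group = 2) {
  x1 <- X[, idx1, drop = FALSE]
  x2 <- X[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- rowSums((x1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((x2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  tested <- n1 >= min_per_group & n2 >= min_per_group
  se2 <- v1 / n1 + v2 / n2
  fc <- m1 - m2
  t <- fc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / pmax(n1 - 1, 1) + (v2 / n2)^2 / pmax(n2 - 1, 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- tested & se2 == 0
  # both sides constant: equal means -> p = 1 by convention, else p -> 0
  zero_eq <- degenerate & fc == 0
  p[zero_eq] <- 1; t[zero_eq] <- 0
  p[degenerate & fc != 0] <- 0
  p[!tested] <- NA_real_
  list(log2fc = fc, t = t, df = df, p = p, n1 = n1, n2 = n2,
       tested = tested, degenerate = degenerate)
}

#' Welch's t-test per phosphosite
#'
#' Two-tailed Welch unequal-variance test of resistant versus sensitive
#' samples for every site, with the Welch-Satterthwaite degrees of freedom.
#' Sites with fewer than `min_per_group` non-missing values on either side
#' are marked untested (`NA` statistics). When both groups have zero
#' variance, p is 1 if the means agree and 0 (flagged `degenerate`)
#' otherwise.
#'
#' @param qm A normalized [quant_matrix()].
#' @param contrast A [make_contrast()] object.
#' @param min_per_group Minimum usable values per side (default 2).
#' @return Data.frame: `site_id`, `log2fc` (mean resistant - mean
#'   sensitive), `t`, `df`, `p`, `n_res`, `n_sen`, `tested`, `degenerate`.
#' @export
welch_test <- function(qm, contrast, min_per_group = 2) {
  stopifnot(inherits(qm, "quant_matrix"), inherits(contrast, "contrast"))
  missing_s <- setdiff(c(contrast$resistant_samples, contrast$sensitive_samples),
                       colnames(qm$values))
  if (length(missing_s) > 0)
    stop_fmt("contrast sample(s) not in matrix: %s", paste(missing_s, collapse = ", "))
  st <- welch_stats(qm$values,
                    match(contrast$resistant_samples, colnames(qm$values)),
                    match(contrast$sensitive_samples, colnames(qm$values)),
                    min_per_group)
  data.frame(site_id = rownames(qm$values),
             log2fc = ifelse(st$tested, st$log2fc, NA_real_),
             t = ifelse(st$tested, st$t, NA_real_),
             df = ifelse(st$tested, st$df, NA_real_),
             p = st$p, n_res = st$n1, n_sen = st$n2,
             tested = st$tested, degenerate = st$degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Permutation-based q-values for the site tests
#'
#' SAM/Perseus-style permutation FDR. Group labels are permuted over the
#' contrast's samples preserving group sizes; for each observed p the raw q
#' is the mean number of permutation p-values at or below it, divided by
#' the number of observed p-values at or below it, clipped to \[0, 1\] and
#' then monotonized to be non-decreasing in p. All distinct relabelings are
#' enumerated when there are at most `max_exhaustive` of them (e.g.
#' C(9,3) = 84 for the 3-vs-6 design, making the result seed-independent);
#' otherwise `n_perm` relabelings are sampled under `seed`.
#'
#' @inheritParams welch_test
#' @param n_perm Number of sampled relabelings when enumeration is infeasible.
#' @param seed RNG seed for sampled relabelings (required in that regime).
#' @param max_exhaustive Enumeration threshold (default 5000 relabelings).
#' @return Data.frame `site_id`, `p`, `q` over tested sites.
#' @export
permutation_q <- function(qm, contrast, n_perm = 1000, seed = NULL,
                          max_exhaustive = 5000, min_per_group = 2) {
  stopifnot(inherits(qm, "quant_matrix"), n_perm >= 1)
  samples <- c(contrast$resistant_samples, contrast$sensitive_samples)
  cols <- match(samples, colnames(qm$values))
  if (anyNA(cols)) stop_fmt("contrast sample(s) not in matrix")
  k <- length(contrast$resistant_samples)
  n <- length(samples)

  obs <- welch_stats(qm$values, cols[seq_len(k)], cols[-seq_len(k)], min_per_group)
  tested <- which(obs$tested)
  if (length(tested) == 0)
    return(data.frame(site_id = character(), p = numeric(), q = numeric()))
  p_obs <- obs$p[tested]
  X <- qm$values[tested, , drop = FALSE]

  if (choose(n, k) <= max_exhaustive) {
    relabelings <- utils::combn(n, k)
  } else {
    if (is.null(seed))
      stop_fmt("permutation_q: a seed is required when sampling relabelings")
    relabelings <- with_seed(seed, replicate(n_perm, sort(sample.int(n, k))))
  }
  B <- ncol(relabelings)
  pool <- vector("list", B)
  for (b in seq_len(B)) {
    i1 <- cols[relabelings[, b]]
    i2 <- cols[setdiff(seq_len(n), relabelings[, b])]
    pb <- welch_stats(X, i1, i2, min_per_group)
    pool[[b]] <- pb$p[pb$tested]
  }
  pool <- sort(unlist(pool, use.names = FALSE))

  # mean permutation count at or below each observed p, over observed count
  null_count <- findInterval(p_obs, pool)
  obs_count <- rank(p_obs, ties.method = "max")
  q_raw <- pmin(pmax((null_count / B) / obs_count, 0), 1)

  # monotonize: non-decreasing in p (step-up from the largest p)
  ord <- order(p_obs)
  q <- numeric(length(p_obs))
  q[ord] <- rev(cummin(rev(q_raw[ord])))

  data.frame(site_id = rownames(qm$values)[tested], p = p_obs, q = q,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential-site table for a contrast
#'
#' Runs [welch_test()] and [permutation_q()] and merges the results into a
#' single per-site table (untested sites keep `NA` p and q).
#'
#' @inheritParams permutation_q
#' @return Data.frame with the [welch_test()] columns plus `q`.
#' @export
diff_test <- function(qm, contrast, n_perm = 1000, seed = NULL,
                      max_exhaustive = 5000, min_per_group = 2) {
  w <- welch_test(qm, contrast, min_per_group)
  pq <- permutation_q(qm, contrast, n_perm = n_perm, seed = seed,
                      max_exhaustive = max_exhaustive,
                      min_per_group = min_per_group)
  w$q <- pq$q[match(w$site_id, pq$site_id)]
  w
}

#' Classify sites against the calibrated cutoffs
#'
#' Applies the volcano decision rule: a site is `increased` when
#' q < `alpha` and its log2 fold change is at least log2 of the calibrated
#' linear cutoff, `decreased` symmetrically, otherwise `ns`
#' (non-significant). Untested sites are labelled `untested`.
#'
#' @param diff Data.frame from [diff_test()] (columns `log2fc`, `q`,
#'   `tested`).
#' @param calibration A `cutoff_calibration` from [fold_change_cutoff()].
#' @param alpha q-value significance level (default 0.05).
#' @return `diff` with a `status` column added.
#' @export
classify_sites <- function(diff, calibration, alpha = 0.05) {
  stopifnot(inherits(calibration, "cutoff_calibration"), alpha > 0, alpha < 1)
  lc <- log2(calibration$linear_cutoff)
  status <- rep("ns", nrow(diff))
  sig <- !is.na(diff$q) & diff$q < alpha
  status[sig & diff$log2fc >= lc] <- "increased"
  status[sig & diff$log2fc <= -lc] <- "decreased"
  status[!diff$tested] <- "untested"
  diff$status <- status
  diff
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over `stats::p.adjust(p, "BH")`, the step-up false
#' discovery rate control used for the KSEA kinase scores and the
#' viability-screen tests.
#'
#' @param p Numeric vector of p-values.
#' @return Vector of BH-adjusted q-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Paired-t statistics for a viability screen
#'
#' For each perturbation (siRNA or compound), tests its replicate viability
#' values against matched control wells with a paired two-tailed Student's
#' t-test, then adjusts across perturbations with Benjamini-Hochberg. When
#' the paired differences are constant, p is 1 for zero difference and 0
#' otherwise (degenerate, flagged).
#'
#' @param viability Data.frame with columns `sirna`, `viability`, `control`
#'   (one row per matched replicate pair).
#' @return Data.frame `sirna`, `n_pairs`, `mean_diff`, `p`, `q`,
#'   `degenerate`.
#' @export
sirna_screen_test <- function(viability) {
  need <- c("sirna", "viability", "control")
  miss <- setdiff(need, names(viability))
  if (length(miss) > 0)
    stop_fmt("viability table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyNA(viability$viability) || anyNA(viability$control))
    stop_fmt("unmatched pairing: missing viability or control value")
  ids <- unique(viability$sirna)
  res <- lapply(ids, function(id) {
    d <- viability$viability[viability$sirna == id] -
      viability$control[viability$sirna == id]
    if (length(d) < 2)
      stop_fmt("siRNA '%s' has fewer than 2 replicate pairs", id)
    if (stats::sd(d) == 0) {
      p <- if (mean(d) == 0) 1 else 0
      degen <- mean(d) != 0
    } else {
      p <- stats::t.test(d)$p.value
      degen <- FALSE
    }
    data.frame(sirna = id, n_pairs = length(d), mean_diff = mean(d),
               p = p, degenerate = degen, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out[, c("sirna", "n_pairs", "mean_diff", "p", "q", "degenerate")]
}
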