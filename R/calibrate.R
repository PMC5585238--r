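# Technical-error calibration: the SD of the fold change between duplicate
# reference channels defines the fold-change significance cutoff (2 SD).

#' Per-set SD of the reference-channel fold change
#'
#' For each TMT set, computes the sample SD (n-1 denominator) over sites of
#' the log2 fold change between the set's two reference channels, using
#' only sites where both references are present. This estimates the
#' technical replication error of the experiment.
#'
#' @param qm A [quant_matrix()] (any normalization stage after log2; the
#'   reference difference is invariant to centering and bridging).
#' @param ref_channels Optional character pair selecting which two reference
#'   channels to compare; defaults to the first two reference channels of
#'   each set in design order (conventionally 126 and 127N).
#' @return Named numeric vector, one SD per TMT set.
#' @export
reference_fold_sd <- function(qm, ref_channels = NULL) {
  stopifnot(inherits(qm, "quant_matrix"))
  design <- qm$design
  sds <- c()
  for (s in unique(design$set_id)) {
    refs <- design[design$set_id == s & design$is_reference, , drop = FALSE]
    if (!is.null(ref_channels)) {
      refs <- refs[match(ref_channels, refs$channel), , drop = FALSE]
      if (any(is.na(refs$sample_id)))
        stop_fmt("set %s lacks reference channel(s) %s", s,
                 paste(ref_channels, collapse = ", "))
    }
    if (nrow(refs) < 2)
      stop_fmt("set %s has fewer than 2 reference channels", s)
    a <- qm$values[, refs$sample_id[1]]
    b <- qm$values[, refs$sample_id[2]]
    d <- (a - b)[!is.na(a) & !is.na(b)]
    if (length(d) < 3)
      stop_fmt("set %s has fewer than 3 complete reference pairs", s)
    sds[s] <- stats::sd(d)
  }
  sds
}

#' Derive the linear fold-change cutoff from reference SDs
#'
#' Averages the per-replicate reference-fold SDs, doubles the mean (the
#' 2-SD rule), and exponentiates to the linear fold-change scale. Full
#' precision is carried internally; rounding happens only at report time.
#'
#' @param per_replicate_sd Numeric vector of non-negative log2-scale SDs.
#' @return A `cutoff_calibration` list: `per_replicate_sd`, `mean_sd`,
#'   `two_sd`, `linear_cutoff` (= 2^two_sd).
#' @export
fold_change_cutoff <- function(per_replicate_sd) {
  if (length(per_replicate_sd) == 0)
    stop_fmt("fold_change_cutoff: empty SD list")
  if (any(!is.finite(per_replicate_sd)) || any(per_replicate_sd < 0))
    stop_fmt("fold_change_cutoff: SDs must be finite and non-negative")
  mean_sd <- mean(per_replicate_sd)
  two_sd <- 2 * mean_sd
  structure(list(per_replicate_sd = per_replicate_sd,
                 mean_sd = mean_sd,
                 two_sd = two_sd,
                 linear_cutoff = 2^two_sd),
            class = "cutoff_calibration")
}

#' @export
print.cutoff_calibration <- function(x, ...) {
  cat(sprintf(
    "fold-change calibration: mean reference SD %.4f, 2SD %.4f, linear cutoff %.3f\n",
    x$mean_sd, x$two_sd, x$linear_cutoff))
  invisible(x)
}

#' Calibrate the fold-change cutoff from a quant matrix
#'
#' Convenience wrapper: [reference_fold_sd()] then [fold_change_cutoff()].
#'
#' @inheritParams reference_fold_sd
#' @return A `cutoff_calibration`.
#' @export
calibrate_cutoff <- function(qm, ref_channels = NULL) {
  fold_change_cutoff(reference_fold_sd(qm, ref_channels))
}
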