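# Reporter intensities -> analysis-ready log2 matrix: missing handling,
# per-sample median centering, reference-channel bridging across TMT sets.

#' Construct a quant_matrix
#'
#' A `quant_matrix` holds the log2 site-by-sample matrix (NA = missing), the
#' attached sample design, and provenance flags recording which
#' normalization stages have been applied. The enforced stage order is
#' [to_log2_with_missing()] then [median_center()] then [reference_bridge()].
#'
#' @param values Numeric matrix, rows = site ids, cols = sample ids.
#' @param design Design data.frame (see [read_design_table()]).
#' @param centered,bridged Provenance flags.
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, design, centered = FALSE, bridged = FALSE) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  validate_design(design)
  structure(list(values = values, design = design,
                 centered = centered, bridged = bridged),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d sites x %d samples (%d TMT sets)\n",
              nrow(x$values), ncol(x$values), length(unique(x$design$set_id))))
  cat(sprintf("  missing: %.1f%%  centered: %s  bridged: %s\n",
              100 * mean(is.na(x$values)), x$centered, x$bridged))
  invisible(x)
}

#' Log2-transform reporter intensities, zeros becoming missing
#'
#' Converts a site table's reporter intensities into a log2 `quant_matrix`.
#' Intensities of 0 are treated as missing values and excluded from all
#' downstream analysis; negative intensities are rejected.
#'
#' @param sites Site-table data.frame with `I.<set>.<channel>` columns.
#' @param design Design data.frame covering every intensity column.
#' @return An uncentered, unbridged [quant_matrix()].
#' @export
to_log2_with_missing <- function(sites, design) {
  validate_design(design)
  cmap <- attr(sites, "channel_map")
  if (is.null(cmap)) stop_fmt("site table lacks its channel_map attribute")
  dcol <- paste0("I.", design$set_id, ".", design$channel)
  miss <- setdiff(dcol, cmap$col)
  if (length(miss) > 0)
    stop_fmt("design names channels absent from the site table: %s",
             paste(miss, collapse = ", "))
  vals <- as.matrix(sites[, dcol, drop = FALSE])
  if (any(vals < 0, na.rm = TRUE)) stop_fmt("negative reporter intensity")
  out <- matrix(NA_real_, nrow(vals), ncol(vals),
                dimnames = list(sites$site_id, design$sample_id))
  pos <- !is.na(vals) & vals > 0
  out[pos] <- log2(vals[pos])
  quant_matrix(out, design)
}

#' Median-center each sample column
#'
#' Shifts every sample column so that its median over non-missing values is
#' zero, the per-sample normalization applied before cross-set bridging.
#' Idempotent in effect; the provenance flag forbids accidental re-centering.
#'
#' @param qm An uncentered [quant_matrix()].
#' @return The centered `quant_matrix`.
#' @export
median_center <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (qm$centered) stop_fmt("matrix is already median-centered")
  meds <- apply(qm$values, 2, stats::median, na.rm = TRUE)
  empty <- names(meds)[is.na(meds)]
  if (length(empty) > 0)
    stop_fmt("sample(s) with no non-missing values: %s",
             paste(empty, collapse = ", "))
  qm$values <- sweep(qm$values, 2, meds, "-")
  qm$centered <- TRUE
  qm
}

#' Bridge TMT sets through their reference channels
#'
#' For each site and TMT set, subtracts the mean of that set's
#' reference-channel values from all of the set's samples, turning values
#' into log2 ratios to the common reference and removing any set-level
#' additive offset exactly. If only one of the reference channels is present
#' for a site in a set, the available one is used; if all are missing, every
#' value of that site in that set becomes missing.
#'
#' @param qm A centered [quant_matrix()].
#' @return The bridged `quant_matrix`.
#' @export
reference_bridge <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (!qm$centered) stop_fmt("median_center() must be applied before bridging")
  if (qm$bridged) stop_fmt("matrix is already reference-bridged")
  design <- qm$design
  if (!any(design$is_reference)) stop_fmt("design has no reference channels")
  for (s in unique(design$set_id)) {
    set_samples <- design$sample_id[design$set_id == s]
    ref_samples <- design$sample_id[design$set_id == s & design$is_reference]
    ref_mean <- rowMeans(qm$values[, ref_samples, drop = FALSE], na.rm = TRUE)
    ref_mean[is.nan(ref_mean)] <- NA_real_
    qm$values[, set_samples] <- qm$values[, set_samples, drop = FALSE] - ref_mean
  }
  qm$bridged <- TRUE
  qm
}

#' Full normalization: log2, median centering, reference bridging
#'
#' @inheritParams to_log2_with_missing
#' @return A centered, bridged [quant_matrix()].
#' @export
normalize_sites <- function(sites, design) {
  reference_bridge(median_center(to_log2_with_missing(sites, design)))
}
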