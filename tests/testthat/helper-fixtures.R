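# Fixture builders shared across the suite. Everything is generated in
# code; nothing is read from static data files.

# a minimal two-set design: 2 reference + 2 sample channels per set
tiny_design <- function(n_sets = 1) {
  rows <- list()
  for (s in seq_len(n_sets)) {
    set_id <- paste0("set", s)
    rows[[length(rows) + 1]] <- data.frame(
      set_id = set_id, channel = c("126", "127N", "128C", "129C"),
      sample_id = c(paste0(set_id, ".ref.126"), paste0(set_id, ".ref.127N"),
                    paste0("A_R", s), paste0("B_R", s)),
      cell_line = c("pooled_reference", "pooled_reference", "A", "B"),
      group = c("reference", "reference", "resistant", "sensitive"),
      treatment = "none", replicate = s,
      is_reference = c(TRUE, TRUE, FALSE, FALSE),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# quant_matrix straight from a values matrix and a design
qm_from_values <- function(values, design, centered = TRUE, bridged = TRUE) {
  quant_matrix(values, design, centered = centered, bridged = bridged)
}

# a quant_matrix for a 3-vs-6 contrast with arbitrary values; extra null
# columns provide the reference channels required by the design invariant
contrast_qm <- function(values_res, values_sen, extra_null_rows = 0) {
  stopifnot(ncol(values_res) == 3, ncol(values_sen) == 6,
            nrow(values_res) == nrow(values_sen))
  n <- nrow(values_res)
  design <- data.frame(
    set_id = "set1",
    channel = as.character(seq_len(11)),
    sample_id = c("ref1", paste0("res", 1:3), paste0("sen", 1:6), "ref2"),
    cell_line = "x", group = "x", treatment = "none", replicate = 1,
    is_reference = c(TRUE, rep(FALSE, 9), TRUE),
    stringsAsFactors = FALSE)
  vals <- cbind(ref1 = rep(0, n), values_res, values_sen, ref2 = rep(0, n))
  colnames(vals) <- design$sample_id
  rownames(vals) <- paste0("P", seq_len(n), "_S10_M1")
  quant_matrix(vals, design, centered = TRUE, bridged = TRUE)
}

std_contrast <- function() {
  make_contrast("test", paste0("res", 1:3), paste0("sen", 1:6))
}

# write a MaxQuant-like site table TSV from row specs
write_mq_fixture <- function(path, rows, channels = c("126", "127N", "128C"),
                             set_id = "set1", mults = 1) {
  cols <- c("Proteins", "Leading proteins", "Gene names", "Position",
            "Amino acid", "Localization prob", "Score", "Delta score",
            "Reverse", "Potential contaminant")
  rep_cols <- unlist(lapply(mults, function(m)
    sprintf("Reporter intensity %s %s___%d", channels, set_id, m)))
  header <- c(cols, rep_cols)
  lines <- vapply(rows, function(r) paste(r, collapse = "\t"), "")
  writeLines(c(paste(header, collapse = "\t"), lines), path)
  path
}

# default program design used by recovery tests: one strong planted kinase
program_design <- function(seed, effect = 3, n_sites = 800, n_substrates = 12) {
  sim_design(
    n_sites = n_sites,
    kinase_programs = list(
      kinase_program("KIN1", seq_len(n_substrates), effect = effect,
                     target_line = "HCT116", reg_position = 419)),
    seed = seed)
}

# run one arm of the pipeline for a single contrast on a simulation
run_contrast <- function(sim, contrast_name = "HCT116_none") {
  qm <- normalize_sites(filter_class1(sim$sites), sim$design_table)
  ct <- contrasts_from_design(sim$design_table)[[contrast_name]]
  qc <- replicate_complete_filter(qm, c(ct$resistant_samples,
                                        ct$sensitive_samples))
  cal <- calibrate_cutoff(qm)
  diff <- classify_sites(diff_test(qc, ct), cal)
  list(diff = diff, calibration = cal, contrast = ct, qm = qm)
}
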