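# Synthetic-data generator: determinism, noise calibration, ground truth.

test_that("identical designs give identical simulated output (bytes included)", {
  d <- sim_design(n_sites = 120, n_planted_diff = 5, seed = 33)
  s1 <- simulate_experiment(d)
  s2 <- simulate_experiment(d)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$truth, s2$truth)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_experiment(s1, dir1); write_experiment(s2, dir2)
  expect_identical(readBin(file.path(dir1, "site_table.tsv"), "raw", 1e7),
                   readBin(file.path(dir2, "site_table.tsv"), "raw", 1e7))
})

test_that("zero-noise, zero-effect design yields exactly zero fold changes", {
  d <- sim_design(n_sites = 80, sigma_meas = 0, sigma_ref = 0,
                  frac_missing = 0, frac_fail_class1 = 0,
                  frac_contaminant = 0, seed = 2)
  sim <- simulate_experiment(d)
  qm <- normalize_sites(sim$sites, sim$design_table)
  for (ct in contrasts_from_design(sim$design_table)) {
    w <- welch_test(qm, ct)
    expect_lt(max(abs(w$log2fc)), 1e-9)
  }
})

test_that("reference-channel difference SD matches sigma_ref * sqrt(2)", {
  sim <- simulate_experiment(sim_design(n_sites = 5000, sigma_ref = 0.35,
                                        frac_missing = 0, seed = 12))
  qm <- to_log2_with_missing(sim$sites, sim$design_table)
  sds <- reference_fold_sd(qm)
  expect_true(all(abs(sds / (0.35 * sqrt(2)) - 1) < 0.05))
})

test_that("the default layout reproduces the triplicate 3-vs-6 group sizes", {
  sim <- simulate_experiment(sim_design(n_sites = 10, seed = 1))
  d <- sim$design_table
  expect_equal(sum(d$is_reference), 6)        # 2 references x 3 sets
  expect_equal(sum(!d$is_reference), 24)      # 8 samples x 3 sets
  cts <- contrasts_from_design(d)
  expect_setequal(names(cts), c("HCT116_drug", "HCT116_none",
                                "HT29_drug", "HT29_none"))
  for (ct in cts) {
    expect_equal(length(ct$resistant_samples), 3)
    expect_equal(length(ct$sensitive_samples), 6)
  }
})

test_that("programs plant their substrates and ground truth records them", {
  d <- program_design(seed = 3, n_sites = 200)
  sim <- simulate_experiment(d)
  truth <- sim$truth
  expect_equal(truth$active_kinases$kinase_id, "KIN1")
  expect_equal(truth$active_kinases$reg_site, "Y419")
  # 12 substrates + the activation-loop site itself
  prog <- truth$diff_sites[truth$diff_sites$source == "program:KIN1", ]
  expect_equal(nrow(prog), 13)
  expect_true("KIN1" %in% prog$protein_id)
  expect_true(all(prog$target_line == "HCT116"))
  # the planted shift is present in the raw values
  qm <- normalize_sites(sim$sites, sim$design_table)
  ct <- contrasts_from_design(sim$design_table)$HCT116_none
  w <- welch_test(qm, ct)
  planted <- paste0(prog$protein_id, "_", prog$residue, prog$position, "_M1")
  fc <- w$log2fc[w$site_id %in% planted]
  expect_gt(mean(fc, na.rm = TRUE), 2)
})

test_that("invalid designs are rejected with informative messages", {
  expect_error(sim_design(sigma_meas = -1), "non-negative")
  expect_error(sim_design(reference_channels = c("126", "999")), "subset")
  expect_error(sim_design(kinase_programs = list(
    kinase_program("K1", 5:15, 1, "HCT116")), n_sites = 10), "K1")
  expect_error(sim_design(kinase_programs = list(
    kinase_program("K1", 1:3, 1, "NOSUCHLINE")), n_sites = 10), "NOSUCHLINE")
})

test_that("annotation fixtures contain every program's substrate pairs", {
  d <- sim_design(n_sites = 100, kinase_programs = list(
    kinase_program("K1", 1:4, 1, "HCT116", reg_position = 400),
    kinase_program("K2", 11:16, 1, "HT29", reg_position = 410)), seed = 6)
  sim <- simulate_experiment(d)
  tabs <- annotation_tables(sim)
  expect_gte(length(setdiff(unique(tabs$predicted$kinase_id), "")), 2)
  # all four (K1, sN) pairs present, enumerated against the assignment
  sa <- sim$site_assignment[1:4, ]
  k1 <- tabs$predicted[tabs$predicted$kinase_id == "K1", ]
  expect_equal(nrow(k1), 4)
  expect_setequal(paste(k1$substrate_protein_id, k1$substrate_position),
                  paste(sa$protein_id, sa$position))
  # one activation-loop activity_up site per program kinase
  up <- tabs$regulatory[tabs$regulatory$function_class == "activity_up", ]
  expect_setequal(up$kinase_id, c("K1", "K2"))
  expect_equal(up$position[up$kinase_id == "K2"], 410L)
})

test_that("multiplicity fraction produces second-multiplicity features", {
  sim <- simulate_experiment(sim_design(n_sites = 400, frac_multi = 0.25,
                                        seed = 14))
  tab <- table(sim$sites$multiplicity)
  expect_gt(tab["2"] / tab["1"], 0.15)
  expect_lt(tab["2"] / tab["1"], 0.40)
  # multiplicity features share the site coordinates
  m2 <- sim$sites[sim$sites$multiplicity == 2, ]
  key <- paste(m2$protein_id, m2$position, m2$residue)
  all_key <- paste(sim$sites$protein_id, sim$sites$position,
                   sim$sites$residue)[sim$sites$multiplicity == 1]
  expect_true(all(key %in% all_key))
})
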