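# Kinase-activity inference: regulatory-site evidence, KSEA, merging.

# brute-force KSEA recomputation with explicit loops (independent oracle)
ksea_brute <- function(fc_by_site, ksr_pairs, min_substrates = 3) {
  all_fc <- unname(unlist(fc_by_site))
  mean_all <- sum(all_fc) / length(all_fc)
  sd_all <- sqrt(sum((all_fc - mean_all)^2) / (length(all_fc) - 1))
  out <- list()
  for (k in sort(unique(ksr_pairs$kinase))) {
    subs <- ksr_pairs$site[ksr_pairs$kinase == k]
    subs <- subs[subs %in% names(fc_by_site)]
    m <- length(subs)
    if (m < min_substrates) next
    ms <- 0
    for (s in subs) ms <- ms + fc_by_site[[s]]
    ms <- ms / m
    z <- (ms - mean_all) * sqrt(m) / sd_all
    out[[k]] <- c(z = z, p = 2 * pnorm(-abs(z)))
  }
  out
}

# build a diff table + predicted KSR from named fold changes
diff_from_fc <- function(fc) {
  data.frame(site_id = paste0(names(fc), "_M1"),
             log2fc = unname(fc), tested = TRUE,
             stringsAsFactors = FALSE)
}

ksr_from_pairs <- function(pairs) {
  parts <- regmatches(pairs$site, regexec("^(.*)_([STY])([0-9]+)$", pairs$site))
  data.frame(kinase_id = pairs$kinase,
             substrate_protein_id = vapply(parts, `[`, "", 2),
             substrate_position = as.integer(vapply(parts, `[`, "", 4)),
             substrate_residue = vapply(parts, `[`, "", 3),
             source = "predicted", score = 2, stringsAsFactors = FALSE)
}

test_that("KSEA z and p match brute-force recomputation on random fixtures", {
  withr::local_seed(42)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    fc <- rnorm(n)
    names(fc) <- paste0("P", seq_len(n), "_Y", seq_len(n) * 3)
    n_k <- sample(2:5, 1)
    pairs <- do.call(rbind, lapply(seq_len(n_k), function(k) {
      data.frame(kinase = paste0("K", k),
                 site = sample(names(fc), sample(3:8, 1)),
                 stringsAsFactors = FALSE)
    }))
    res <- ksea_scores(diff_from_fc(fc), ksr_from_pairs(pairs))
    oracle <- ksea_brute(as.list(fc), pairs)
    expect_setequal(res$kinase_id, names(oracle))
    for (k in res$kinase_id) {
      expect_equal(res$z[res$kinase_id == k], unname(oracle[[k]]["z"]),
                   tolerance = 1e-12)
      expect_equal(res$p[res$kinase_id == k], unname(oracle[[k]]["p"]),
                   tolerance = 1e-12)
    }
  }
})

test_that("the m = 4, unit-shift, unit-SD case gives z = 2, p = 0.0455", {
  # exact construction: 4 substrates at +1, 10 background sites summing to
  # -4 with squares summing to 9, so the overall mean is 0 and the overall
  # sample SD is exactly 1; z = (1 - 0) * sqrt(4) / 1 = 2
  vals <- c(rep(1, 4),
            -0.4 + sqrt(3.7), -0.4 - sqrt(3.7), rep(-0.4, 8))
  stopifnot(abs(mean(vals)) < 1e-12, abs(sd(vals) - 1) < 1e-12)
  names(vals) <- paste0("P", seq_along(vals), "_Y10")
  pairs <- data.frame(kinase = "K1", site = names(vals)[1:4])
  res <- ksea_scores(diff_from_fc(vals), ksr_from_pairs(pairs))
  expect_equal(res$m, 4L)
  expect_equal(res$z, 2.0, tolerance = 1e-12)
  expect_equal(res$p, 0.04550026, tolerance = 1e-7)
})

test_that("substrates at the background mean give z = 0, p = 1", {
  fc <- c(a = 1, b = -1, c = 0.5, d = -0.5, e = 2, f = -2)
  names(fc) <- paste0("P", 1:6, "_S10")
  pairs <- data.frame(kinase = "K1", site = names(fc)[1:4])
  fc[1:4] <- c(0.3, -0.3, 0.15, -0.15)  # substrate mean = overall mean = 0
  res <- ksea_scores(diff_from_fc(fc), ksr_from_pairs(pairs))
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
})

test_that("KSEA rejects a degenerate zero-variance background", {
  fc <- rep(1, 5)
  names(fc) <- paste0("P", 1:5, "_S10")
  pairs <- data.frame(kinase = "K1", site = names(fc)[1:3])
  expect_error(ksea_scores(diff_from_fc(fc), ksr_from_pairs(pairs)),
               "degenerate")
})

test_that("regulatory evidence calls kinases with increased activity_up sites", {
  diff <- data.frame(
    site_id = c("SRC_Y419_M1", "LYN_Y397_M1", "ABL1_Y393_M1",
                "SRC_Y530_M1", "LCK_Y505_M1"),
    log2fc = c(2, 2, 0.1, 2, 2), tested = TRUE,
    status = c("increased", "increased", "ns", "increased", "increased"),
    stringsAsFactors = FALSE)
  reg <- data.frame(
    kinase_id = c("SRC", "LYN", "ABL1", "SRC", "LCK"),
    position = c(419L, 397L, 393L, 530L, 505L),
    residue = "Y",
    function_class = c("activity_up", "activity_up", "activity_up",
                       "other", "activity_down"),
    stringsAsFactors = FALSE)
  calls <- regulatory_evidence(diff, reg, "HCT116_none")
  # hand evaluation: SRC (Y419 up+increased), LYN (Y397 up+increased);
  # ABL1 up site not increased; SRC Y530 is class other; LCK down-class
  expect_equal(calls$kinase_id, c("LYN", "SRC"))
  expect_equal(calls$sites[calls$kinase_id == "SRC"], "Y419")
  down <- attr(calls, "down_sites")
  expect_equal(down$kinase_id, "LCK")
})

test_that("regulatory evidence is invariant to input row order", {
  withr::local_seed(9)
  diff <- data.frame(
    site_id = paste0("K", 1:6, "_Y", 100 + 1:6, "_M1"),
    log2fc = 2, tested = TRUE,
    status = rep(c("increased", "ns"), 3), stringsAsFactors = FALSE)
  reg <- data.frame(kinase_id = paste0("K", 1:6), position = 100L + 1:6,
                    residue = "Y", function_class = "activity_up",
                    stringsAsFactors = FALSE)
  a <- regulatory_evidence(diff, reg, "c")
  b <- regulatory_evidence(diff[sample(6), ], reg[sample(6), ], "c")
  expect_equal(a$kinase_id, b$kinase_id)
  expect_equal(a$sites, b$sites)
})

test_that("evidence merging labels kinases by their supporting routes", {
  reg_calls <- data.frame(kinase_id = c("LYN", "SRC"),
                          evidence = "regulatory_site",
                          sites = c("Y397", "Y419"), contrast = "c1",
                          stringsAsFactors = FALSE)
  ksea <- data.frame(kinase_id = c("LYN", "JAK2", "MAPK1"),
                     z = c(3, 2.5, -2.5), q = c(0.01, 0.02, 0.02),
                     activated = c(TRUE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  out <- merge_activity(reg_calls, ksea, "c1")
  expect_equal(out$kinase_id, c("JAK2", "LYN", "SRC"))
  expect_equal(out$evidence, c("ksea", "both", "regulatory_site"))
  expect_equal(out$sites[out$kinase_id == "LYN"], "Y397")
  # empty KSEA list: all calls stay regulatory
  out2 <- merge_activity(reg_calls, ksea[0, ], "c1")
  expect_equal(unique(out2$evidence), "regulatory_site")
  expect_error(merge_activity(reg_calls, ksea, "other_contrast"), "mismatch")
})

test_that("simulated program kinase is recovered by KSEA at q < 0.05", {
  sim <- simulate_experiment(program_design(seed = 17, effect = 1.0,
                                            n_sites = 600, n_substrates = 10))
  out <- run_contrast(sim)
  ann <- annotation_tables(sim)
  ksea <- ksea_scores(out$diff, ann$predicted)
  expect_true("KIN1" %in% ksea$kinase_id)
  expect_lt(ksea$q[ksea$kinase_id == "KIN1"], 0.05)
  expect_gt(ksea$z[ksea$kinase_id == "KIN1"], 0)
})
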