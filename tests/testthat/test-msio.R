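# Readers, writers and identification-quality filters.

test_that("site table reading expands multiplicities and flags contaminants", {
  path <- withr::local_tempfile(fileext = ".tsv")
  # row 2 is a contaminant; row 3 carries two populated multiplicities
  write_mq_fixture(path, mults = 1:2, rows = list(
    c("P1", "P1", "G1", "10", "S", "0.9", "80", "20", "", "",
      "100", "200", "300", "0", "0", "0"),
    c("P2", "P2", "G2", "20", "Y", "0.95", "90", "25", "", "+",
      "50", "60", "70", "0", "0", "0"),
    c("P3;P4", "P3;P4", "G3", "30", "T", "0.8", "70", "15", "", "",
      "10", "20", "30", "40", "50", "60")))
  sites <- read_site_table(path)
  expect_equal(nrow(sites), 4)  # 3 rows, one expanded into 2 multiplicities
  expect_equal(sum(sites$contaminant), 1)
  expect_equal(sites$protein_id[sites$gene_symbol == "G3"], c("P3", "P3"))
  m3 <- sites[sites$protein_id == "P3", ]
  expect_setequal(m3$multiplicity, c(1L, 2L))
  expect_equal(m3$position, c(30L, 30L))
  expect_equal(m3[["I.set1.126"]], c(10, 40))
})

test_that("a header-only site table yields an empty collection", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mq_fixture(path, rows = list())
  sites <- read_site_table(path)
  expect_equal(nrow(sites), 0)
})

test_that("schema and parse errors name the offending column/row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Proteins\tPosition", path)
  expect_error(read_site_table(path), "Leading proteins")
  write_mq_fixture(path, rows = list(
    c("P1", "P1", "G1", "10", "S", "0.9", "80", "20", "", "",
      "abc", "200", "300")))
  expect_error(read_site_table(path), "row 1")
})

test_that("site table write/read round-trips", {
  sim <- simulate_experiment(sim_design(n_sites = 60, seed = 42))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(sim$sites, path)
  back <- read_site_table(path)
  back <- back[order(back$site_id), ]
  orig <- sim$sites[order(sim$sites$site_id), ]
  expect_equal(back$site_id, orig$site_id)
  expect_equal(back$localization_prob, orig$localization_prob, tolerance = 1e-9)
  icol <- attr(orig, "channel_map")$col
  expect_equal(as.matrix(back[, icol]), as.matrix(orig[, icol]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("class-1 filter applies inclusive thresholds and drops flagged rows", {
  mk <- function(pos, score, delta, locprob, contaminant = FALSE,
                 reverse = FALSE) {
    data.frame(protein_id = "P1", proteins = "P1", gene_symbol = "G",
               position = pos, residue = "S", multiplicity = 1L,
               localization_prob = locprob, score = score,
               delta_score = delta, contaminant = contaminant,
               reverse = reverse, I.set1.126 = 100,
               stringsAsFactors = FALSE)
  }
  # enumerated pass pattern: rows 1-3 boundary/above, 4-7 each fail one
  # criterion, 8 contaminant, 9 reverse, 10 passes
  rows <- rbind(mk(1, 40, 8, 0.75), mk(2, 100, 20, 0.9), mk(3, 41, 8.1, 0.76),
                mk(4, 39.9, 8, 0.9), mk(5, 40, 7.9, 0.9), mk(6, 40, 8, 0.749),
                mk(7, 10, 2, 0.1), mk(8, 50, 10, 0.9, contaminant = TRUE),
                mk(9, 50, 10, 0.9, reverse = TRUE), mk(10, 60, 30, 0.8))
  cmap <- data.frame(set_id = "set1", channel = "126", col = "I.set1.126")
  sites <- validate_site_table(rows, cmap)
  kept <- filter_class1(sites)
  expect_equal(kept$position, c(1L, 2L, 3L, 10L))
  # idempotent
  expect_equal(filter_class1(kept), kept)
})

test_that("class-1 filter commutes with the completeness filter", {
  sim <- simulate_experiment(sim_design(n_sites = 150, seed = 5))
  scope <- sim$design_table$sample_id[!sim$design_table$is_reference][1:6]
  a <- replicate_complete_filter(
    normalize_sites(filter_class1(sim$sites), sim$design_table), scope)
  qm_all <- normalize_sites(sim$sites, sim$design_table)
  b <- replicate_complete_filter(qm_all, scope)
  keep <- intersect(rownames(b$values), filter_class1(sim$sites)$site_id)
  expect_setequal(rownames(a$values), keep)
})

test_that("completeness filter keeps exactly the fully observed sites", {
  design <- tiny_design(1)
  vals <- matrix(1, 5, 4, dimnames = list(paste0("P", 1:5, "_S10_M1"),
                                          design$sample_id))
  vals[1, "A_R1"] <- NA   # missing in 1 of the scoped samples -> dropped
  vals[2, "set1.ref.126"] <- NA  # missing outside scope -> kept
  qm <- qm_from_values(vals, design)
  out <- replicate_complete_filter(qm, c("A_R1", "B_R1"))
  expect_setequal(rownames(out$values),
                  paste0("P", c(2, 3, 4, 5), "_S10_M1"))
  # no missing values: identity
  qm2 <- qm_from_values(matrix(1, 3, 4, dimnames = list(
    paste0("Q", 1:3, "_S10_M1"), design$sample_id)), design)
  expect_equal(replicate_complete_filter(qm2, design$sample_id)$values,
               qm2$values)
  expect_error(replicate_complete_filter(qm, character()), "empty")
})

test_that("curated KSR reader parses the PhosphositePlus-like dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GENE\tKINASE\tSUB_ACC_ID\tSUB_GENE\tSUB_MOD_RSD",
               "SRC\tSRC\tPRKCD\tPRKCD\tY313",
               "SRC\tSRC\tPRKCD\tPRKCD\tY313"), path)
  expect_warning(ksr <- read_ksr_table(path, "curated"), "duplicate")
  expect_equal(nrow(ksr), 1)
  expect_equal(ksr$kinase_id, "SRC")
  expect_equal(ksr$substrate_protein_id, "PRKCD")
  expect_equal(ksr$substrate_position, 313L)
  expect_equal(ksr$substrate_residue, "Y")
})

test_that("predicted KSR reader validates scores and residues", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("kinase\tsubstrate\tposition\tresidue\tscore",
               "K1\tP1\t10\tY\t"), path)
  expect_error(read_ksr_table(path, "predicted"), "score")
  writeLines(c("kinase\tsubstrate\tposition\tresidue\tscore",
               "K1\tP1\t10\tX\t2.0"), path)
  expect_error(read_ksr_table(path, "predicted"), "row 1")
})

test_that("regulatory-site reader validates classes and deduplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("kinase\tposition\tresidue\tfunction_class",
               "SRC\t419\tY\tactivity_up",
               "SRC\t419\tY\tactivity_up",
               "SRC\t530\tY\tactivity_down"), path)
  expect_warning(reg <- read_regulatory_sites(path), "duplicate")
  expect_equal(nrow(reg), 2)
  writeLines(c("kinase\tposition\tresidue\tfunction_class",
               "SRC\t419\tY\tbogus"), path)
  expect_error(read_regulatory_sites(path), "function_class")
})

test_that("KSR and regulatory tables round-trip through their writers", {
  sim <- simulate_experiment(program_design(seed = 8, n_sites = 100))
  tabs <- annotation_tables(sim)
  dir <- withr::local_tempdir()
  paths <- write_annotation_fixtures(sim, dir)
  pred <- read_ksr_table(paths$predicted_ksr, "predicted")
  cur <- read_ksr_table(paths$curated_ksr, "curated")
  reg <- read_regulatory_sites(paths$regulatory_sites)
  expect_equal(pred, tabs$predicted, ignore_attr = TRUE)
  expect_equal(cur[, names(cur) != "score"],
               tabs$curated[, names(tabs$curated) != "score"],
               ignore_attr = TRUE)
  expect_equal(reg, tabs$regulatory, ignore_attr = TRUE)
})
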