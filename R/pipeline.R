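# End-to-end orchestration: quality filtering, normalization, calibration,
# differential statistics, kinase-activity inference and network export for
# one or two proteomic arms (global pSTY and phosphotyrosine pY), each arm
# calibrated separately, with their classified sites pooled for the
# kinase-activity stage.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

load_or <- function(x, loader) if (is.character(x)) loader(x) else x

#' Build a pipeline configuration
#'
#' @param site_tables Named list of site tables, one per proteomic arm
#'   (e.g. `pSTY`, `pY`); each entry a TSV path or an in-memory site table.
#' @param design Design table (path or data.frame).
#' @param predicted_ksr,curated_ksr,regulatory_sites Annotation tables
#'   (paths or data.frames).
#' @param out_dir Output directory; `NULL` keeps results in memory only.
#' @param min_score,min_delta,min_locprob Class-1 identification thresholds.
#' @param alpha q-value significance level.
#' @param min_substrates Minimum KSEA substrate count.
#' @param ksr_min_score Optional predicted-KSR score cutoff.
#' @param n_perm Sampled permutation count (exhaustive enumeration is used
#'   automatically when feasible).
#' @param min_per_group Minimum non-missing values per contrast side.
#' @param seed Integer seed for any sampled permutations.
#' @param contrasts Optional list of [make_contrast()] objects; defaults to
#'   [contrasts_from_design()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(site_tables, design, predicted_ksr, curated_ksr,
                            regulatory_sites, out_dir = NULL,
                            min_score = 40, min_delta = 8, min_locprob = 0.75,
                            alpha = 0.05, min_substrates = 3,
                            ksr_min_score = NULL, n_perm = 1000,
                            min_per_group = 2, seed = 1L, contrasts = NULL) {
  stopifnot(alpha > 0, alpha < 1, length(site_tables) >= 1,
            !is.null(names(site_tables)))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] arguments, with table arguments
#' given as file paths.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

#' Run the full pipeline
#'
#' For each arm: read the site table, apply the class-1 filter, normalize
#' (log2, median centering, reference bridging), and calibrate the
#' fold-change cutoff from the duplicate reference channels. For each
#' contrast and arm: keep sites complete across the contrast's samples,
#' compute Welch statistics and permutation q-values, and classify against
#' the arm's calibrated cutoff. The arms' classified sites are then pooled
#' per contrast for regulatory-site and KSEA kinase-activity calls, and the
#' called kinases are wired into the curated-KSR network. Identical
#' configuration and inputs give identical outputs.
#'
#' @param config A `pipeline_config` (or path to its YAML).
#' @return Invisibly, a result bundle: `calibrations` (per arm), `diff`
#'   (per contrast, per arm), `activity` and `networks` (per contrast),
#'   plus the contrasts and config used. Written to `out_dir` when set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config

  design <- stage("design", {
    d <- load_or(cfg$design, read_design_table); validate_design(d); d
  })
  predicted <- stage("annotations",
                     load_or(cfg$predicted_ksr,
                             function(p) read_ksr_table(p, "predicted")))
  curated <- stage("annotations",
                   load_or(cfg$curated_ksr,
                           function(p) read_ksr_table(p, "curated")))
  reg <- stage("annotations", load_or(cfg$regulatory_sites, read_regulatory_sites))
  contrasts <- if (is.null(cfg$contrasts))
    stage("contrasts", contrasts_from_design(design)) else cfg$contrasts

  arms <- names(cfg$site_tables)
  norm <- list(); calibrations <- list()
  for (arm in arms) {
    sites <- stage(paste0("msio:", arm),
                   load_or(cfg$site_tables[[arm]], read_site_table))
    sites <- stage(paste0("filter:", arm),
                   filter_class1(sites, cfg$min_score, cfg$min_delta,
                                 cfg$min_locprob))
    norm[[arm]] <- stage(paste0("normalize:", arm),
                         normalize_sites(sites, design))
    calibrations[[arm]] <- stage(paste0("calibrate:", arm),
                                 calibrate_cutoff(norm[[arm]]))
  }

  diff_out <- list(); activity <- list(); networks <- list()
  for (cn in names(contrasts)) {
    ct <- contrasts[[cn]]
    per_arm <- list()
    for (arm in arms) {
      per_arm[[arm]] <- stage(paste0("diffstats:", arm, ":", cn), {
        qc <- replicate_complete_filter(
          norm[[arm]], c(ct$resistant_samples, ct$sensitive_samples))
        diff <- diff_test(qc, ct, n_perm = cfg$n_perm, seed = cfg$seed,
                          min_per_group = cfg$min_per_group)
        classify_sites(diff, calibrations[[arm]], cfg$alpha)
      })
      per_arm[[arm]]$arm <- arm
    }
    diff_out[[cn]] <- per_arm
    pooled <- do.call(rbind, per_arm)
    activity[[cn]] <- stage(paste0("kinact:", cn), {
      reg_calls <- regulatory_evidence(pooled, reg, cn)
      ksea <- ksea_scores(pooled, predicted, cfg$min_substrates,
                          cfg$ksr_min_score, cfg$alpha)
      list(calls = merge_activity(reg_calls, ksea, cn), ksea = ksea,
           regulatory = reg_calls)
    })
    networks[[cn]] <- stage(paste0("network:", cn),
                            build_network(activity[[cn]]$calls, curated))
  }

  bundle <- list(calibrations = calibrations, diff = diff_out,
                 activity = activity, networks = networks,
                 contrasts = contrasts, config = cfg)
  if (!is.null(cfg$out_dir)) stage("write", write_bundle(bundle, cfg$out_dir))
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (arm in names(bundle$calibrations)) {
    cal <- bundle$calibrations[[arm]]
    jsonlite::write_json(
      list(per_replicate_sd = as.list(cal$per_replicate_sd),
           mean_sd = cal$mean_sd, two_sd = cal$two_sd,
           linear_cutoff = cal$linear_cutoff),
      file.path(out_dir, sprintf("calibration_%s.json", arm)),
      auto_unbox = TRUE, digits = NA)
  }
  for (cn in names(bundle$diff)) {
    for (arm in names(bundle$diff[[cn]])) {
      utils::write.table(
        bundle$diff[[cn]][[arm]],
        file.path(out_dir, sprintf("diff_%s_%s.tsv", arm, cn)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(
      bundle$activity[[cn]]$calls,
      file.path(out_dir, sprintf("activity_%s.tsv", cn)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    net <- bundle$networks[[cn]]
    export_network(net, file.path(out_dir, sprintf("network_%s.sif", cn)), "sif")
    export_network(net, file.path(out_dir, sprintf("network_%s.graphml", cn)),
                   "graphml")
    export_network(net, file.path(out_dir, sprintf("network_%s.tsv", cn)), "tsv")
  }
  log <- list(
    package_version = as.character(utils::packageVersion("phosphokin")),
    seed = bundle$config$seed, alpha = bundle$config$alpha,
    arms = names(bundle$calibrations),
    contrasts = names(bundle$contrasts),
    n_called = vapply(bundle$activity, function(a) nrow(a$calls), 0L))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
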