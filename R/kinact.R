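# Kinase-activity inference from classified sites: (a) kinase-regulatory
# phosphosite evidence, (b) KSEA over predicted kinase-substrate relations,
# and the merge of both evidence streams.

# Annotation joins ignore multiplicity: collapse classified site features to
# unique (protein, position, residue), averaging log2fc over multiplicities.
# A collapsed site counts as increased/decreased if any of its multiplicity
# features was.
collapse_multiplicity <- function(diff) {
  tested <- diff[diff$tested, , drop = FALSE]
  if (nrow(tested) == 0) return(tested)
  m <- regmatches(tested$site_id,
                  regexec("^(.*)_([STY])([0-9]+)_M[0-9]+$", tested$site_id))
  tested$protein_id <- vapply(m, `[`, "", 2)
  tested$residue <- vapply(m, `[`, "", 3)
  tested$position <- as.integer(vapply(m, `[`, "", 4))
  key <- paste(tested$protein_id, tested$position, tested$residue, sep = "\r")
  agg <- tested[!duplicated(key), c("protein_id", "position", "residue")]
  agg$log2fc <- as.numeric(tapply(tested$log2fc, key, mean)[unique(key)])
  if ("status" %in% names(tested)) {
    pick <- function(st) if ("increased" %in% st) "increased" else
      if ("decreased" %in% st) "decreased" else "ns"
    agg$status <- as.character(tapply(tested$status, key, pick)[unique(key)])
  }
  rownames(agg) <- NULL
  agg
}

#' Kinase activity calls from regulatory phosphosites
#'
#' A kinase is called active when at least one of its annotated
#' activity-increasing (`activity_up`) regulatory phosphosites is classified
#' `increased` in the contrast. Sites join on (kinase protein, position,
#' residue); multiplicity is ignored. Increases on `activity_down` sites are
#' reported in the `down_sites` attribute but never produce a call.
#'
#' @param diff Classified differential table from [classify_sites()].
#' @param reg Regulatory-site table from [read_regulatory_sites()].
#' @param contrast_name Label stored with the calls.
#' @return Data.frame `kinase_id`, `evidence` (`"regulatory_site"`),
#'   `sites` (supporting site labels, ";"-separated), `contrast`.
#' @export
regulatory_evidence <- function(diff, reg, contrast_name = "") {
  if (!"status" %in% names(diff))
    stop_fmt("diff table has no status column; run classify_sites() first")
  cs <- collapse_multiplicity(diff)
  inc <- cs[cs$status == "increased", , drop = FALSE]
  up <- reg[reg$function_class == "activity_up", , drop = FALSE]
  hit <- merge(up, inc,
               by.x = c("kinase_id", "position", "residue"),
               by.y = c("protein_id", "position", "residue"))
  down <- merge(reg[reg$function_class == "activity_down", , drop = FALSE], inc,
                by.x = c("kinase_id", "position", "residue"),
                by.y = c("protein_id", "position", "residue"))
  if (nrow(hit) == 0) {
    out <- data.frame(kinase_id = character(), evidence = character(),
                      sites = character(), contrast = character(),
                      stringsAsFactors = FALSE)
  } else {
    hit <- hit[order(hit$kinase_id, hit$position), , drop = FALSE]
    labs <- tapply(site_label(hit$residue, hit$position), hit$kinase_id,
                   paste, collapse = ";")
    out <- data.frame(kinase_id = sort(unique(hit$kinase_id)),
                      evidence = "regulatory_site",
                      sites = as.character(labs[sort(unique(hit$kinase_id))]),
                      contrast = contrast_name, stringsAsFactors = FALSE)
  }
  attr(out, "down_sites") <- down
  out
}

#' Kinase-substrate enrichment analysis (KSEA)
#'
#' For each kinase with at least `min_substrates` quantified substrate
#' sites among the predicted kinase-substrate relations, computes the
#' enrichment z-score
#' \deqn{z = (\bar m_S - \bar m_P)\,\sqrt{m}\,/\,\delta}
#' where \eqn{\bar m_S} is the mean log2 fold change of the kinase's
#' substrates, \eqn{\bar m_P} and \eqn{\delta} the mean and SD of all
#' tested sites' log2 fold changes, and \eqn{m} the substrate count; p is
#' the two-tailed normal tail probability and q the Benjamini-Hochberg
#' adjustment across scored kinases. A kinase is designated activated when
#' z > 0 and q < `alpha`.
#'
#' @param diff Differential table from [diff_test()] (classification not
#'   required).
#' @param ksr Predicted KSR table from [read_ksr_table()].
#' @param min_substrates Minimum quantified substrates to score a kinase
#'   (default 3).
#' @param min_score Optional lower bound on the prediction score.
#' @param alpha Significance level for the `activated` flag (default 0.05).
#' @return Data.frame `kinase_id`, `m`, `mean_sub`, `mean_all`, `sd_all`,
#'   `z`, `p`, `q`, `activated`.
#' @export
ksea_scores <- function(diff, ksr, min_substrates = 3, min_score = NULL,
                        alpha = 0.05) {
  cs <- collapse_multiplicity(diff)
  if (nrow(cs) < 2) stop_fmt("KSEA needs at least 2 tested sites")
  if (!is.null(min_score))
    ksr <- ksr[!is.na(ksr$score) & ksr$score >= min_score, , drop = FALSE]
  mean_all <- mean(cs$log2fc)
  sd_all <- stats::sd(cs$log2fc)
  if (sd_all == 0)
    stop_fmt("degenerate background: all tested sites have identical log2fc")
  hit <- merge(ksr, cs,
               by.x = c("substrate_protein_id", "substrate_position",
                        "substrate_residue"),
               by.y = c("protein_id", "position", "residue"))
  empty <- data.frame(kinase_id = character(), m = integer(),
                      mean_sub = numeric(), mean_all = numeric(),
                      sd_all = numeric(), z = numeric(), p = numeric(),
                      q = numeric(), activated = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(hit) == 0) return(empty)
  kin <- sort(unique(hit$kinase_id))
  m <- as.integer(table(hit$kinase_id)[kin])
  mean_sub <- as.numeric(tapply(hit$log2fc, hit$kinase_id, mean)[kin])
  keep <- m >= min_substrates
  if (!any(keep)) return(empty)
  kin <- kin[keep]; m <- m[keep]; mean_sub <- mean_sub[keep]
  z <- (mean_sub - mean_all) * sqrt(m) / sd_all
  p <- 2 * stats::pnorm(-abs(z))
  q <- bh_adjust(p)
  data.frame(kinase_id = kin, m = m, mean_sub = mean_sub,
             mean_all = mean_all, sd_all = sd_all, z = z, p = p, q = q,
             activated = z > 0 & q < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Merge regulatory-site and KSEA evidence
#'
#' Union of the kinases called by either route; a kinase carried by both is
#' labelled `both`. Output is ordered by kinase id.
#'
#' @param reg_calls Output of [regulatory_evidence()].
#' @param ksea Output of [ksea_scores()] (only `activated` rows are used).
#' @param contrast_name Label checked against `reg_calls` and stored in the
#'   output.
#' @return Data.frame `kinase_id`, `evidence`
#'   (`regulatory_site`/`ksea`/`both`), `sites`, `ksea_z`, `ksea_q`,
#'   `contrast`.
#' @export
merge_activity <- function(reg_calls, ksea, contrast_name = NULL) {
  if (is.null(contrast_name)) {
    contrast_name <- if (nrow(reg_calls) > 0) reg_calls$contrast[1] else ""
  } else if (nrow(reg_calls) > 0 &&
             any(reg_calls$contrast != contrast_name)) {
    stop_fmt("contrast mismatch: calls are for '%s', expected '%s'",
             reg_calls$contrast[1], contrast_name)
  }
  ksea_act <- ksea[ksea$activated, , drop = FALSE]
  ids <- sort(union(reg_calls$kinase_id, ksea_act$kinase_id))
  if (length(ids) == 0)
    return(data.frame(kinase_id = character(), evidence = character(),
                      sites = character(), ksea_z = numeric(),
                      ksea_q = numeric(), contrast = character(),
                      stringsAsFactors = FALSE))
  in_reg <- ids %in% reg_calls$kinase_id
  in_ksea <- ids %in% ksea_act$kinase_id
  data.frame(
    kinase_id = ids,
    evidence = ifelse(in_reg & in_ksea, "both",
                      ifelse(in_reg, "regulatory_site", "ksea")),
    sites = reg_calls$sites[match(ids, reg_calls$kinase_id)],
    ksea_z = ksea_act$z[match(ids, ksea_act$kinase_id)],
    ksea_q = ksea_act$q[match(ids, ksea_act$kinase_id)],
    contrast = contrast_name,
    stringsAsFactors = FALSE, row.names = NULL)
}
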