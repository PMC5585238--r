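# Readers/writers for the tabular dialects the pipeline touches, plus the
# identification-quality (class 1) filters.
#
# The site-table dialect is MaxQuant Phospho(STY)Sites-like: one row per
# phosphosite, reporter-ion intensity columns named
# "Reporter intensity <channel> <set>___<multiplicity>", and the usual
# identification metadata columns. Internally a site table is a data.frame
# with one row per site x multiplicity and intensity columns "I.<set>.<channel>",
# carrying a "channel_map" attribute.

REQUIRED_SITE_COLUMNS <- c(
  "Proteins", "Leading proteins", "Gene names", "Position", "Amino acid",
  "Localization prob", "Score", "Delta score"
)

#' Read a MaxQuant-style phosphosite table
#'
#' Parses a tab-separated phosphosite quantification table in the
#' Phospho(STY)Sites dialect: identification metadata plus reporter-ion
#' intensity columns `Reporter intensity <channel> <set>___<multiplicity>`.
#' Each file row is expanded into one record per populated multiplicity
#' (a multiplicity counts as populated when at least one of its reporter
#' intensities is positive). The first accession of "Leading proteins" is
#' taken as the protein id; the full list is kept in the `proteins` column.
#' Rows flagged "Potential contaminant" or "Reverse" are retained but
#' flagged; they are dropped later by [filter_class1()].
#'
#' @param path Path to the TSV file.
#' @return A site-table data.frame: columns `site_id`, `protein_id`,
#'   `proteins`, `gene_symbol`, `position`, `residue`, `multiplicity`,
#'   `localization_prob`, `score`, `delta_score`, `contaminant`, `reverse`,
#'   and one `I.<set>.<channel>` intensity column per TMT channel, with a
#'   `channel_map` attribute mapping those columns to (set, channel).
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop_fmt("site table not found: %s", path)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(REQUIRED_SITE_COLUMNS, names(raw))
  if (length(missing_cols) > 0)
    stop_fmt("site table is missing required column(s): %s",
             paste(missing_cols, collapse = ", "))

  rep_rx <- "^Reporter intensity (\\S+) (\\S+)___([0-9]+)$"
  rep_cols <- grep(rep_rx, names(raw), value = TRUE)
  if (length(rep_cols) == 0)
    stop_fmt("site table has no 'Reporter intensity <channel> <set>___<m>' columns")
  parts <- regmatches(rep_cols, regexec(rep_rx, rep_cols))
  rep_info <- data.frame(
    col = rep_cols,
    channel = vapply(parts, `[`, "", 2),
    set_id = vapply(parts, `[`, "", 3),
    mult = as.integer(vapply(parts, `[`, "", 4)),
    stringsAsFactors = FALSE
  )

  num <- function(col) {
    x <- raw[[col]]
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x) & nzchar(trimws(x)))
    if (length(bad) > 0)
      stop_fmt("non-numeric value in column '%s' at data row %d: '%s'",
               col, bad[1], x[bad[1]])
    v
  }

  position <- num("Position")
  locprob <- num("Localization prob")
  score <- num("Score")
  delta <- num("Delta score")
  intens <- vapply(rep_info$col, num, numeric(nrow(raw)))
  if (nrow(raw) == 1) intens <- matrix(intens, nrow = 1,
                                       dimnames = list(NULL, rep_info$col))
  intens[is.na(intens)] <- 0

  flag_col <- function(nm) {
    if (nm %in% names(raw)) trimws(raw[[nm]]) == "+" else rep(FALSE, nrow(raw))
  }
  contaminant <- flag_col("Potential contaminant")
  reverse <- flag_col("Reverse")
  protein_id <- vapply(strsplit(raw[["Leading proteins"]], ";"),
                       function(x) trimws(x[1]), "")

  channel_map <- unique(rep_info[, c("set_id", "channel")])
  channel_map$col <- paste0("I.", channel_map$set_id, ".", channel_map$channel)
  rownames(channel_map) <- NULL

  # expand each file row into one record per populated multiplicity
  records <- list()
  for (m in sort(unique(rep_info$mult))) {
    cols_m <- rep_info[rep_info$mult == m, , drop = FALSE]
    sub <- intens[, cols_m$col, drop = FALSE]
    keep <- rowSums(sub > 0) > 0
    if (!any(keep)) next
    rec <- data.frame(
      protein_id = protein_id[keep],
      proteins = raw[["Proteins"]][keep],
      gene_symbol = raw[["Gene names"]][keep],
      position = as.integer(position[keep]),
      residue = raw[["Amino acid"]][keep],
      multiplicity = m,
      localization_prob = locprob[keep],
      score = score[keep],
      delta_score = delta[keep],
      contaminant = contaminant[keep],
      reverse = reverse[keep],
      stringsAsFactors = FALSE
    )
    ints <- as.data.frame(sub[keep, , drop = FALSE])
    names(ints) <- paste0("I.", cols_m$set_id, ".", cols_m$channel)
    records[[length(records) + 1]] <- cbind(rec, ints[, channel_map$col, drop = FALSE])
  }
  out <- if (length(records) == 0) {
    empty_site_table(channel_map)
  } else {
    do.call(rbind, records)
  }
  validate_site_table(out, channel_map)
}

empty_site_table <- function(channel_map) {
  out <- data.frame(
    protein_id = character(), proteins = character(), gene_symbol = character(),
    position = integer(), residue = character(), multiplicity = integer(),
    localization_prob = numeric(), score = numeric(), delta_score = numeric(),
    contaminant = logical(), reverse = logical(), stringsAsFactors = FALSE
  )
  for (cl in channel_map$col) out[[cl]] <- numeric()
  out
}

validate_site_table <- function(sites, channel_map) {
  bad_res <- setdiff(unique(sites$residue), c("S", "T", "Y"))
  if (length(bad_res) > 0)
    stop_fmt("invalid residue(s) in site table: %s", paste(bad_res, collapse = ", "))
  if (nrow(sites) > 0 && any(sites$position < 1))
    stop_fmt("site positions must be >= 1")
  if (nrow(sites) > 0 &&
      any(sites$localization_prob < 0 | sites$localization_prob > 1, na.rm = TRUE))
    stop_fmt("localization probabilities must lie in [0, 1]")
  sites$site_id <- if (nrow(sites) == 0) character() else
    paste0(sites$protein_id, "_", sites$residue, sites$position,
           "_M", sites$multiplicity)
  if (anyDuplicated(sites$site_id))
    stop_fmt("duplicate site key(s): %s",
             paste(unique(sites$site_id[duplicated(sites$site_id)])[1:1], collapse = ", "))
  rownames(sites) <- NULL
  first <- c("site_id", setdiff(names(sites), "site_id"))
  sites <- sites[, first]
  attr(sites, "channel_map") <- channel_map
  sites
}

intensity_cols <- function(sites) attr(sites, "channel_map")$col

#' Write a site table in the MaxQuant-like dialect
#'
#' Inverse of [read_site_table()]: records sharing (protein, position,
#' residue) are collapsed back into one file row with `___<multiplicity>`
#' reporter columns; absent multiplicities are written as 0.
#'
#' @param sites A site-table data.frame as returned by [read_site_table()]
#'   or [simulate_experiment()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  cmap <- attr(sites, "channel_map")
  key <- paste(sites$protein_id, sites$position, sites$residue, sep = "\r")
  mults <- sort(unique(sites$multiplicity))
  rows <- !duplicated(key)
  base <- sites[rows, c("proteins", "protein_id", "gene_symbol", "position",
                        "residue", "localization_prob", "score", "delta_score",
                        "contaminant", "reverse")]
  out <- data.frame(
    "Proteins" = base$proteins,
    "Leading proteins" = base$protein_id,
    "Gene names" = base$gene_symbol,
    "Position" = base$position,
    "Amino acid" = base$residue,
    "Localization prob" = base$localization_prob,
    "Score" = base$score,
    "Delta score" = base$delta_score,
    "Reverse" = ifelse(base$reverse, "+", ""),
    "Potential contaminant" = ifelse(base$contaminant, "+", ""),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  ukey <- key[rows]
  for (m in mults) {
    sub <- sites[sites$multiplicity == m, , drop = FALSE]
    idx <- match(ukey, paste(sub$protein_id, sub$position, sub$residue, sep = "\r"))
    for (i in seq_len(nrow(cmap))) {
      colname <- sprintf("Reporter intensity %s %s___%d",
                         cmap$channel[i], cmap$set_id[i], m)
      v <- sub[[cmap$col[i]]][idx]
      v[is.na(v)] <- 0
      out[[colname]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply the class-1 identification filter
#'
#' Keeps confidently identified and localized phosphosites: Andromeda score,
#' delta score and localization probability at or above their thresholds
#' (inclusive boundaries), excluding contaminant and reverse hits. Defaults
#' are the conventional class-1 criteria (score 40, delta score 8,
#' localization probability 0.75). Row order is preserved and the filter is
#' idempotent.
#'
#' @param sites A site-table data.frame.
#' @param min_score,min_delta,min_locprob Inclusive lower bounds.
#' @return The filtered site table.
#' @export
filter_class1 <- function(sites, min_score = 40, min_delta = 8,
                          min_locprob = 0.75) {
  stopifnot(min_score >= 0, min_delta >= 0, min_locprob >= 0)
  keep <- sites$score >= min_score &
    sites$delta_score >= min_delta &
    sites$localization_prob >= min_locprob &
    !sites$contaminant & !sites$reverse
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "channel_map") <- attr(sites, "channel_map")
  out
}

#' Keep sites quantified in every sample of a scope
#'
#' Retains only sites with a non-missing value in each of the given samples,
#' the completeness requirement applied to replicate experiments before
#' group statistics.
#'
#' @param qm A [quant_matrix()].
#' @param scope Character vector of sample ids (subset of the matrix columns).
#' @return A `quant_matrix` restricted to complete sites.
#' @export
replicate_complete_filter <- function(qm, scope) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (length(scope) == 0) stop_fmt("replicate_complete_filter: empty sample scope")
  missing_samples <- setdiff(scope, colnames(qm$values))
  if (length(missing_samples) > 0)
    stop_fmt("scope sample(s) not in matrix: %s",
             paste(missing_samples, collapse = ", "))
  keep <- rowSums(is.na(qm$values[, scope, drop = FALSE])) == 0
  qm$values <- qm$values[keep, , drop = FALSE]
  qm
}

# ---- kinase-substrate and regulatory-site annotation tables -----------------

#' Read a kinase-substrate relationship table
#'
#' Two dialects are supported. `source = "curated"` reads a
#' PhosphositePlus Kinase_Substrate_Dataset-like TSV with columns
#' `GENE` (kinase gene), `SUB_ACC_ID`, `SUB_GENE` and `SUB_MOD_RSD`
#' (e.g. "Y419"). `source = "predicted"` reads a NetworKIN-like TSV with
#' columns `kinase`, `substrate`, `position`, `residue`, `score`; every
#' predicted row must carry a numeric score. Duplicate
#' (kinase, substrate, site) rows are collapsed with a warning.
#'
#' @param path TSV path.
#' @param source `"curated"` or `"predicted"`.
#' @return A KSR data.frame: `kinase_id`, `substrate_protein_id`,
#'   `substrate_position`, `substrate_residue`, `source`, `score`.
#' @export
read_ksr_table <- function(path, source = c("curated", "predicted")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop_fmt("KSR table not found: %s", path)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (source == "curated") {
    need <- c("GENE", "SUB_ACC_ID", "SUB_GENE", "SUB_MOD_RSD")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0)
      stop_fmt("curated KSR table missing column(s): %s", paste(miss, collapse = ", "))
    rsd <- trimws(raw$SUB_MOD_RSD)
    residue <- substr(rsd, 1, 1)
    position <- suppressWarnings(as.integer(substring(rsd, 2)))
    out <- data.frame(
      kinase_id = trimws(raw$GENE),
      substrate_protein_id = trimws(raw$SUB_ACC_ID),
      substrate_position = position,
      substrate_residue = residue,
      source = "curated",
      score = NA_real_,
      stringsAsFactors = FALSE
    )
  } else {
    need <- c("kinase", "substrate", "position", "residue", "score")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0)
      stop_fmt("predicted KSR table missing column(s): %s", paste(miss, collapse = ", "))
    score <- suppressWarnings(as.numeric(raw$score))
    if (any(is.na(score)))
      stop_fmt("predicted KSR row %d has a missing/non-numeric score",
               which(is.na(score))[1])
    out <- data.frame(
      kinase_id = trimws(raw$kinase),
      substrate_protein_id = trimws(raw$substrate),
      substrate_position = as.integer(raw$position),
      substrate_residue = trimws(raw$residue),
      source = "predicted",
      score = score,
      stringsAsFactors = FALSE
    )
  }
  bad <- which(!out$substrate_residue %in% c("S", "T", "Y"))
  if (length(bad) > 0)
    stop_fmt("KSR row %d has residue '%s' outside S/T/Y",
             bad[1], out$substrate_residue[bad[1]])
  if (any(is.na(out$substrate_position)))
    stop_fmt("KSR row %d has an unparseable site position",
             which(is.na(out$substrate_position))[1])
  key <- paste(out$kinase_id, out$substrate_protein_id,
               out$substrate_position, out$substrate_residue)
  if (anyDuplicated(key)) {
    warning(sprintf("collapsed %d duplicate KSR row(s)", sum(duplicated(key))),
            call. = FALSE)
    out <- out[!duplicated(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write a KSR table in its source dialect
#' @param ksr A KSR data.frame (single `source`).
#' @param path Output TSV path.
#' @param source Dialect to write when `ksr` has no rows (otherwise taken
#'   from the table itself).
#' @return `path`, invisibly.
#' @export
write_ksr_table <- function(ksr, path, source = c("curated", "predicted")) {
  src <- unique(ksr$source)
  if (length(src) == 0) src <- match.arg(source)
  stopifnot(length(src) == 1)
  if (src == "curated") {
    out <- data.frame(
      GENE = ksr$kinase_id,
      KINASE = ksr$kinase_id,
      SUB_ACC_ID = ksr$substrate_protein_id,
      SUB_GENE = ksr$substrate_protein_id,
      SUB_MOD_RSD = paste0(ksr$substrate_residue, ksr$substrate_position),
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(
      kinase = ksr$kinase_id,
      substrate = ksr$substrate_protein_id,
      position = ksr$substrate_position,
      residue = ksr$substrate_residue,
      score = ksr$score,
      stringsAsFactors = FALSE
    )
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kinase-regulatory phosphosite annotation table
#'
#' TSV with columns `kinase`, `position`, `residue`, `function_class`; the
#' function class says whether phosphorylation of the site increases
#' (`activity_up`), decreases (`activity_down`) or does not clearly affect
#' (`other`) the kinase's enzymatic activity. Duplicates are collapsed with
#' a warning.
#'
#' @param path TSV path.
#' @return Data.frame `kinase_id`, `position`, `residue`, `function_class`.
#' @export
read_regulatory_sites <- function(path) {
  if (!file.exists(path)) stop_fmt("regulatory-site table not found: %s", path)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("kinase", "position", "residue", "function_class")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop_fmt("regulatory-site table missing column(s): %s",
             paste(miss, collapse = ", "))
  out <- data.frame(
    kinase_id = trimws(raw$kinase),
    position = as.integer(raw$position),
    residue = trimws(raw$residue),
    function_class = trimws(raw$function_class),
    stringsAsFactors = FALSE
  )
  bad <- which(!out$residue %in% c("S", "T", "Y"))
  if (length(bad) > 0)
    stop_fmt("regulatory-site row %d has residue '%s' outside S/T/Y",
             bad[1], out$residue[bad[1]])
  bad_cls <- setdiff(unique(out$function_class),
                     c("activity_up", "activity_down", "other"))
  if (length(bad_cls) > 0)
    stop_fmt("unknown function_class: %s", paste(bad_cls, collapse = ", "))
  key <- paste(out$kinase_id, out$position, out$residue)
  if (anyDuplicated(key)) {
    warning(sprintf("collapsed %d duplicate regulatory-site row(s)",
                    sum(duplicated(key))), call. = FALSE)
    out <- out[!duplicated(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write a regulatory-site annotation table
#' @param reg Data.frame as from [read_regulatory_sites()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_regulatory_sites <- function(reg, path) {
  out <- data.frame(kinase = reg$kinase_id, position = reg$position,
                    residue = reg$residue, function_class = reg$function_class,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample-design table
#'
#' The design table maps each (TMT set, channel) to a sample: columns
#' `set_id`, `channel`, `sample_id`, `cell_line`, `group`
#' (`sensitive`/`resistant`/`reference`), `treatment`, `replicate`,
#' `is_reference`.
#'
#' @param path TSV path.
#' @return The design data.frame.
#' @export
read_design_table <- function(path) {
  if (!file.exists(path)) stop_fmt("design table not found: %s", path)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  d$is_reference <- as.logical(d$is_reference)
  validate_design(d)
  d
}

#' @rdname read_design_table
#' @param design Design data.frame.
#' @export
write_design_table <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_design <- function(design) {
  need <- c("set_id", "channel", "sample_id", "cell_line", "group",
            "treatment", "replicate", "is_reference")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0)
    stop_fmt("design table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(paste(design$set_id, design$channel)))
    stop_fmt("design table has duplicate (set, channel) rows")
  refs_per_set <- tapply(design$is_reference, design$set_id, sum)
  if (any(refs_per_set < 1))
    stop_fmt("every TMT set needs at least one reference channel; set(s) without: %s",
             paste(names(refs_per_set)[refs_per_set < 1], collapse = ", "))
  nonref <- design$sample_id[!design$is_reference]
  if (anyDuplicated(nonref))
    stop_fmt("duplicate non-reference sample_id(s): %s",
             paste(unique(nonref[duplicated(nonref)]), collapse = ", "))
  invisible(design)
}
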