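#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a locally-seeded RNG, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Format a count as a percentage of a total
#'
#' Small reporting helper used in summary tables: the percentage of `n` out
#' of `total`, rounded to `digits` decimal places.
#'
#' @param n Numerator count.
#' @param total Denominator count (> 0).
#' @param digits Decimal places to round to (default 1).
#' @return Numeric percentage, e.g. `fraction_pct(699, 13411)` is `5.2`.
#' @export
fraction_pct <- function(n, total, digits = 1) {
  stopifnot(is.numeric(n), is.numeric(total), total > 0)
  round(100 * n / total, digits)
}

# site label in the field's convention, e.g. "Y419"
site_label <- function(residue, position) paste0(residue, position)

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
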