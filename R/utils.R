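# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# period label -> closed year window (EU wild-bird ban splits the study window)
period_window <- function(period, periods = NULL) {
  periods <- periods %||% list(preban = c(1995L, 2005L), postban = c(2006L, 2017L))
  if (!period %in% names(periods)) {
    stop("unknown period label: '", period, "' (expected one of ",
         paste(names(periods), collapse = ", "), ")", call. = FALSE)
  }
  as.integer(periods[[period]])
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == round(x) && x >= 0

#' Min-max normalize columns to the unit interval
#'
#' Rescales each column of a numeric matrix (or data frame) linearly so that
#' its minimum maps to 0 and its maximum to 1. Used before fuzzy clustering so
#' Euclidean distance weights the rule-of-law and trade-barrier axes equally.
#'
#' @param x numeric matrix or data frame with at least two distinct values per
#'   column.
#' @return a matrix of the same dimension with all values in \[0, 1\].
#' @export
normalize_unit <- function(x) {
  x <- as.matrix(x)
  apply(x, 2L, function(col) {
    r <- range(col)
    if (diff(r) <= 0) stop("cannot normalize a constant axis", call. = FALSE)
    (col - r[1]) / diff(r)
  })
}
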