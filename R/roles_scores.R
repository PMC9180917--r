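#' Classify countries as suppliers or demanders
#'
#' A country is a supplier when it exported more live wild birds than it
#' imported over the period, and a demander when it imported more than it
#' exported. Countries with exactly equal totals carry no directional signal
#' and are marked `"excluded-tie"`; their count is reported via a message and
#' an attribute.
#'
#' @param totals data frame from [aggregate_totals()], with columns `country`,
#'   `total_exported`, `total_imported`.
#' @return the input with an added `role` column
#'   (`"supplier"`/`"demander"`/`"excluded-tie"`), attribute `n_ties`.
#' @export
assign_roles <- function(totals) {
  stopifnot(is.data.frame(totals),
            all(c("country", "total_exported", "total_imported") %in% names(totals)))
  role <- ifelse(totals$total_exported > totals$total_imported, "supplier",
                 ifelse(totals$total_imported > totals$total_exported, "demander",
                        "excluded-tie"))
  n_ties <- sum(role == "excluded-tie")
  if (n_ties > 0L) {
    message(n_ties, " countr", if (n_ties == 1L) "y" else "ies",
            " with exactly balanced trade excluded as ties")
  }
  out <- totals
  out$role <- role
  attr(out, "n_ties") <- n_ties
  out
}

#' Quintile "weakness" bins for a governance axis
#'
#' Bins one covariate axis (rule of law, or a trade-barrier proxy) into five
#' quintile groups within a role group. Bin 0 is the strongest fifth and bin 4
#' the weakest fifth, so the bin measures governance *weakness* regardless of
#' the covariate's native orientation.
#'
#' @param values numeric covariate values for one role group (one per country).
#' @param higher_is_stronger logical; `TRUE` when a larger covariate value
#'   means stronger governance (e.g. a rule-of-law index), `FALSE` when larger
#'   means weaker.
#' @return integer vector of bins in 0--4, same length as `values`.
#' @details Quintiles are rank based (`ceiling(5 * rank / n) - 1`) with ties
#'   broken by average rank; 25 evenly spaced values therefore land exactly 5
#'   per bin. Groups with fewer than 5 countries, or fewer than 5 distinct
#'   values, cannot be split into quintiles and raise a degenerate-binning
#'   error.
#' @export
bin_axis_weakness <- function(values, higher_is_stronger = TRUE) {
  stopifnot(is.numeric(values), length(higher_is_stronger) == 1L)
  if (anyNA(values)) stop("values contain NA", call. = FALSE)
  n <- length(values)
  if (n < 5L || length(unique(values)) < 5L) {
    stop("degenerate binning: need at least 5 countries with 5 distinct values ",
         "per role group to form quintiles; use coarser bins or pool groups",
         call. = FALSE)
  }
  weakness <- if (higher_is_stronger) -values else values
  r <- rank(weakness, ties.method = "average")
  bins <- as.integer(ceiling(5 * r / n)) - 1L
  pmin(pmax(bins, 0L), 4L)
}

#' Expected geopolitical score (0--8)
#'
#' Sum of the rule-of-law weakness bin and the trade-barrier weakness bin.
#' 0 means both axes are in the strongest fifth (strong rule of law and strong
#' trade barriers); 8 means both are in the weakest fifth.
#'
#' @param law_weakness_bin,barrier_weakness_bin integer bins in 0--4, as
#'   produced by [bin_axis_weakness()]. Vectorized.
#' @return integer score(s) in 0--8.
#' @export
expected_score <- function(law_weakness_bin, barrier_weakness_bin) {
  for (b in list(law_weakness_bin, barrier_weakness_bin)) {
    if (!is.numeric(b) || anyNA(b) || any(b != round(b)) || any(b < 0 | b > 4)) {
      stop("weakness bins must be integers in 0-4", call. = FALSE)
    }
  }
  as.integer(law_weakness_bin) + as.integer(barrier_weakness_bin)
}

#' Calibrate equal-interval log10 volume bins
#'
#' Fits the five equal-width bins, in log10 space, that convert a traded
#' volume into the 1--5 real trade score. By default the bins span the range
#' of the reference volumes; an explicit `log_range` may be supplied instead
#' (e.g. the known range of a synthetic world, so scores round-trip exactly).
#'
#' @param volumes positive reference volumes (birds).
#' @param log_range optional numeric length-2, log10 bounds for the bins.
#' @param role,period optional labels stored with the calibration.
#' @return an object of class `volume_bins` with element `edges`, the 6
#'   strictly increasing log10 bin edges.
#' @export
fit_volume_bins <- function(volumes, log_range = NULL, role = NULL, period = NULL) {
  stopifnot(is.numeric(volumes), length(volumes) >= 1L)
  if (anyNA(volumes) || any(volumes <= 0)) {
    stop("volumes must be positive to be log-binned", call. = FALSE)
  }
  if (is.null(log_range)) {
    if (length(unique(volumes)) < 2L) {
      stop("need at least 2 distinct volumes to span a bin range", call. = FALSE)
    }
    log_range <- range(log10(volumes))
  }
  stopifnot(length(log_range) == 2L, is.finite(log_range))
  if (diff(log_range) <= 0) stop("zero-width log range", call. = FALSE)
  structure(
    list(edges = seq(log_range[1], log_range[2], length.out = 6L),
         role = role, period = period),
    class = "volume_bins")
}

#' Real trade score (1--5) of a traded volume
#'
#' Bin index of `log10(volume)` under an equal-interval calibration:
#' 1 = countries of low importance in the bird trade, 5 = the heaviest
#' traders. The top bin is right-closed so the maximum reference volume maps
#' to 5; volumes outside the calibrated range are clamped to 1 or 5.
#'
#' @param volume positive volume(s) in birds.
#' @param calibration a `volume_bins` object from [fit_volume_bins()].
#' @return integer score(s) in 1--5.
#' @export
real_trade_score <- function(volume, calibration) {
  stopifnot(inherits(calibration, "volume_bins"))
  if (anyNA(volume) || any(volume <= 0)) {
    stop("volume must be positive", call. = FALSE)
  }
  idx <- findInterval(log10(volume), calibration$edges, rightmost.closed = TRUE)
  as.integer(pmin(pmax(idx, 1L), 5L))
}

#' Build the per-country score table for one period
#'
#' Joins role assignments with governance covariates and computes, within each
#' role group, the two quintile weakness bins, the expected score (0--8), the
#' role-relevant traded volume (exports for suppliers, imports for demanders)
#' and the real trade score (1--5). The trade-barrier proxy is role dependent:
#' cost of exportation for suppliers, import tariffs for demanders.
#'
#' Countries lacking covariates, and tie-excluded countries, are dropped with
#' counts recorded in the `excluded` attribute (nothing is dropped silently).
#'
#' @param roles output of [assign_roles()] for one period.
#' @param covariates a covariate table ([read_covariates()] or
#'   [emit_covariates()]) containing the same period.
#' @param period period label used to select covariate rows.
#' @param log_range optional log10 range forwarded to [fit_volume_bins()],
#'   fitted per role group on the observed volumes when `NULL`.
#' @return a `score_table` data frame (country, period, role, bins, expected
#'   score `E`, volume, trade score `T`) with attributes `calibrations` (per
#'   role) and `excluded` (named counts).
#' @export
build_score_table <- function(roles, covariates, period, log_range = NULL) {
  stopifnot(is.data.frame(roles), is.data.frame(covariates))
  cov <- covariates[covariates$period == period, , drop = FALSE]
  keep <- roles$role %in% c("supplier", "demander")
  n_ties <- sum(!keep)
  active <- roles[keep, , drop = FALSE]
  m <- match(active$country, cov$country)
  n_nocov <- sum(is.na(m))
  if (n_nocov > 0L) {
    message(n_nocov, " countr", if (n_nocov == 1L) "y" else "ies",
            " without covariates dropped from the ", period, " score table")
  }
  active <- active[!is.na(m), , drop = FALSE]
  cov <- cov[m[!is.na(m)], , drop = FALSE]

  pieces <- lapply(c("supplier", "demander"), function(r) {
    sel <- active$role == r
    if (!any(sel)) return(NULL)
    a <- active[sel, , drop = FALSE]
    cv <- cov[sel, , drop = FALSE]
    barrier <- if (r == "supplier") cv$export_cost else cv$import_tariff
    law_bin <- bin_axis_weakness(cv$rule_of_law, higher_is_stronger = TRUE)
    barrier_bin <- bin_axis_weakness(barrier, higher_is_stronger = TRUE)
    volume <- if (r == "supplier") a$total_exported else a$total_imported
    calib <- fit_volume_bins(volume, log_range = log_range, role = r, period = period)
    data.frame(
      country = a$country, period = period, role = r,
      rule_of_law = cv$rule_of_law, barrier = barrier,
      law_weakness_bin = law_bin, barrier_weakness_bin = barrier_bin,
      expected_score = expected_score(law_bin, barrier_bin),
      volume = volume,
      trade_score = real_trade_score(volume, calib),
      stringsAsFactors = FALSE)
  })
  names(pieces) <- c("supplier", "demander")
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  calibs <- lapply(c(supplier = "supplier", demander = "demander"), function(r) {
    sub <- out[out$role == r, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    fit_volume_bins(sub$volume, log_range = log_range, role = r, period = period)
  })
  structure(out,
            calibrations = calibs,
            excluded = c(ties = n_ties, missing_covariates = n_nocov),
            class = c("score_table", "data.frame"))
}
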