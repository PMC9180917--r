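# Monte Carlo projection of trade volumes under the four stylised
# geopolitical futures. Each scenario pins suppliers and demanders to a band
# of the 0-8 expected-score grid; scores are drawn uniformly over the band's
# integers, pushed through the calibrated ordinal models, and categories are
# back-transformed to bird volumes at their log-bin midpoints.

.scenario_table <- list(
  A = list(supplier = c(0L, 2L), demander = c(0L, 2L)),
  B = list(supplier = c(0L, 2L), demander = c(6L, 8L)),
  C = list(supplier = c(6L, 8L), demander = c(0L, 2L)),
  D = list(supplier = c(6L, 8L), demander = c(6L, 8L)))

#' Scenario definition
#'
#' Returns the expected-score bands of one of the four stylised geopolitical
#' futures: A (strong trade barriers and rule of law everywhere: both roles
#' score 0--2), B (strong suppliers 0--2, weak demanders 6--8), C (weak
#' suppliers 6--8, strong demanders 0--2), D (weak everywhere: both 6--8).
#'
#' @param name one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return a `scenario_spec` list with `name`, `supplier_range`,
#'   `demander_range` (inclusive integer bounds).
#' @export
scenario_spec <- function(name = c("A", "B", "C", "D")) {
  name <- match.arg(name)
  sp <- .scenario_table[[name]]
  structure(list(name = name, supplier_range = sp$supplier,
                 demander_range = sp$demander),
            class = "scenario_spec")
}

#' Volume at a trade-score category's bin midpoint
#'
#' Back-transforms a 1--5 real trade score to birds: `10 ^ midpoint` of the
#' category's log10 bin under the given calibration.
#'
#' @param T integer trade score(s) in 1--5.
#' @param calibration a `volume_bins` calibration.
#' @return positive volume(s) in birds.
#' @export
score_to_volume <- function(T, calibration) {
  stopifnot(inherits(calibration, "volume_bins"))
  if (anyNA(T) || any(T != round(T)) || any(T < 1L | T > 5L)) {
    stop("trade score must be an integer in 1-5", call. = FALSE)
  }
  T <- as.integer(T)
  e <- calibration$edges
  10^((e[T] + e[T + 1L]) / 2)
}

.project_role <- function(fit, countries, rng, calibration, n_reps, draw) {
  nc <- length(countries)
  scores <- rng[1]:rng[2]
  Em <- matrix(sample(scores, nc * n_reps, replace = TRUE), nc, n_reps)
  cum <- vapply(0:8, function(e) stats::plogis(fit$thresholds - fit$beta * e),
                numeric(4))  # 4 x 9 cumulative probabilities
  if (draw == "modal") {
    probs <- rbind(cum, 1) - rbind(0, cum)
    modal <- apply(probs, 2L, which.max)
    Tm <- matrix(modal[Em + 1L], nc, n_reps)
  } else {
    U <- matrix(stats::runif(nc * n_reps), nc, n_reps)
    Tm <- matrix(1L, nc, n_reps)
    for (k in 1:4) {
      Tm <- Tm + (U > matrix(cum[k, Em + 1L], nc, n_reps))
    }
  }
  mid <- score_to_volume(1:5, calibration)
  Vm <- matrix(mid[Tm], nc, n_reps)
  counts <- t(apply(Tm, 1L, tabulate, nbins = 5L))
  qs <- t(apply(Vm, 1L, stats::quantile, probs = c(0.025, 0.975), names = FALSE))
  summary <- data.frame(
    country = countries,
    mean_volume = rowMeans(Vm),
    volume_lo = qs[, 1], volume_hi = qs[, 2],
    modal_category = apply(counts, 1L, which.max),
    stringsAsFactors = FALSE)
  list(summary = summary, category_counts = counts, rep_totals = colSums(Vm))
}

#' Project trade volumes under a geopolitical scenario
#'
#' For each Monte Carlo replicate and country, draws an expected score
#' uniformly over the integers of the role's scenario band, samples a trade
#' score category from the role's calibrated cumulative-link model, and
#' converts the category to a bird volume at its log-bin midpoint. (With
#' `draw = "modal"` the most probable category is taken instead of
#' sampling.)
#'
#' @param fit_supplier,fit_demander `clm_fit` objects for the two roles
#'   (typically postban calibrations, the basis the published projections
#'   use). A fit may be `NULL` only if the corresponding role is absent from
#'   `roles`.
#' @param roles data frame with columns `country` and `role` (e.g. a score
#'   table or [assign_roles()] output); tie-excluded countries are skipped.
#' @param spec a [scenario_spec()].
#' @param calib_supplier,calib_demander `volume_bins` calibrations per role.
#' @param n_reps Monte Carlo replicates (default 1000).
#' @param seed integer seed.
#' @param draw `"sample"` (default; propagates model uncertainty) or
#'   `"modal"`.
#' @return a `scenario_projection`: per-country summaries (`countries`),
#'   per-country category counts over replicates (`category_counts`, rows sum
#'   to `n_reps`), per-replicate global totals per role (`rep_totals`), and
#'   the scenario/seed metadata.
#' @export
project_scenario <- function(fit_supplier, fit_demander, roles, spec,
                             calib_supplier, calib_demander,
                             n_reps = 1000L, seed = 1L,
                             draw = c("sample", "modal")) {
  draw <- match.arg(draw)
  stopifnot(inherits(spec, "scenario_spec"), is.data.frame(roles),
            all(c("country", "role") %in% names(roles)))
  if (!is_count(n_reps) || n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  set.seed(seed)
  fits <- list(supplier = fit_supplier, demander = fit_demander)
  calibs <- list(supplier = calib_supplier, demander = calib_demander)
  rngs <- list(supplier = spec$supplier_range, demander = spec$demander_range)
  out <- list()
  for (r in c("supplier", "demander")) {
    countries <- roles$country[roles$role == r]
    if (length(countries) == 0L) next
    if (is.null(fits[[r]])) {
      stop("no fitted model supplied for role present in data: ", r, call. = FALSE)
    }
    stopifnot(inherits(fits[[r]], "clm_fit"))
    pr <- .project_role(fits[[r]], countries, rngs[[r]], calibs[[r]], n_reps, draw)
    pr$summary$role <- r
    pr$summary$scenario <- spec$name
    out[[r]] <- pr
  }
  countries <- do.call(rbind, lapply(out, `[[`, "summary"))
  rownames(countries) <- NULL
  rep_totals <- do.call(cbind, lapply(out, `[[`, "rep_totals"))
  structure(list(scenario = spec$name, spec = spec,
                 countries = countries,
                 category_counts = lapply(out, `[[`, "category_counts"),
                 rep_totals = rep_totals,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 draw = draw),
            class = "scenario_projection")
}

#' @export
print.scenario_projection <- function(x, ...) {
  cat("Scenario", x$scenario, "projection:", nrow(x$countries), "countries,",
      x$n_reps, "replicates\n")
  print(global_totals(x))
  invisible(x)
}

#' Global projected totals per market role
#'
#' Sums projected country volumes within each replicate, then summarizes
#' across replicates (mean and central 95% interval).
#'
#' @param projection a `scenario_projection`.
#' @return data frame with columns `scenario`, `role`, `mean_total`,
#'   `total_lo`, `total_hi` (birds).
#' @export
global_totals <- function(projection) {
  stopifnot(inherits(projection, "scenario_projection"))
  roles <- colnames(projection$rep_totals)
  do.call(rbind, lapply(roles, function(r) {
    tot <- projection$rep_totals[, r]
    data.frame(scenario = projection$scenario, role = r,
               mean_total = mean(tot),
               total_lo = stats::quantile(tot, 0.025, names = FALSE),
               total_hi = stats::quantile(tot, 0.975, names = FALSE),
               stringsAsFactors = FALSE)
  }))
}
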