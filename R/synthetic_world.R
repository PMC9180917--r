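#' Configuration of a synthetic trade world
#'
#' Defines the ground truth of a simulated population of bird-trading
#' countries: how many suppliers and demanders exist, the true
#' cumulative-link parameters tying a country's geopolitical expected score
#' (0--8) to its real trade score category (1--5), and the log10 volume scale
#' used to back-fill bird volumes from categories.
#'
#' @param n_suppliers,n_demanders number of countries per market role
#'   (at least 2; quintile scoring additionally needs at least 5 per role).
#' @param beta_supplier,beta_demander true cumulative-link slopes; positive
#'   for suppliers (weak governance exports more) and negative for demanders
#'   (strong-governance, wealthy countries import more). Defaults mirror
#'   estimates of the published case study (+0.500, -0.578).
#' @param thresholds four strictly increasing true cutpoints of the latent
#'   ordinal model.
#' @param center_score score at which the latent linear predictor
#'   `beta * (E - center_score)` is zero; the default 4 (the mid score)
#'   keeps category frequencies balanced for both slope signs. Set 0 for the
#'   textbook parameterization `logit P(T <= k) = theta_k - beta * E`.
#' @param volume_log_mean,volume_log_sd centre and spread (log10 birds) of
#'   the volume scale; category bins are 5 equal log10 intervals over
#'   `volume_log_mean +/- 2 * volume_log_sd`.
#' @param covariate_noise_sd standard deviation of the Gaussian observation
#'   noise added to the latent governance positions when emitting covariates.
#' @param ban_shift additive strengthening of demander import tariffs in the
#'   postban period (the EU ban raised demand-side barriers).
#' @param seed integer seed; every downstream emission derives its stream
#'   from it.
#' @return a `synthetic_world_config` list.
#' @export
synthetic_world_config <- function(n_suppliers = 60L, n_demanders = 80L,
                                   beta_supplier = 0.5, beta_demander = -0.578,
                                   thresholds = c(-1.5, -0.5, 0.5, 1.5),
                                   center_score = 4,
                                   volume_log_mean = 3, volume_log_sd = 1,
                                   covariate_noise_sd = 0.05,
                                   ban_shift = 0.15, seed = 1L) {
  cfg <- list(n_suppliers = as.integer(n_suppliers),
              n_demanders = as.integer(n_demanders),
              beta_supplier = beta_supplier, beta_demander = beta_demander,
              thresholds = as.numeric(thresholds), center_score = center_score,
              volume_log_mean = volume_log_mean, volume_log_sd = volume_log_sd,
              covariate_noise_sd = covariate_noise_sd,
              ban_shift = ban_shift, seed = as.integer(seed))
  if (!is_count(cfg$n_suppliers) || !is_count(cfg$n_demanders) ||
      cfg$n_suppliers < 2L || cfg$n_demanders < 2L) {
    stop("need at least 2 countries per role", call. = FALSE)
  }
  if (length(cfg$thresholds) != 4L || any(diff(cfg$thresholds) <= 0)) {
    stop("thresholds must be 4 strictly increasing values", call. = FALSE)
  }
  for (f in c("beta_supplier", "beta_demander", "center_score",
              "volume_log_mean", "volume_log_sd", "covariate_noise_sd",
              "ban_shift")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !is.finite(cfg[[f]])) {
      stop("config field ", f, " must be a finite number", call. = FALSE)
    }
  }
  if (cfg$volume_log_sd <= 0) stop("volume_log_sd must be > 0", call. = FALSE)
  if (cfg$covariate_noise_sd < 0) stop("covariate_noise_sd must be >= 0", call. = FALSE)
  structure(cfg, class = "synthetic_world_config")
}

.country_codes <- function(prefix, n) {
  i <- seq_len(n) - 1L
  paste0(prefix, LETTERS[i %/% 26L + 1L], LETTERS[i %% 26L + 1L])
}

.volume_log_range <- function(config) {
  config$volume_log_mean + c(-2, 2) * config$volume_log_sd
}

#' Generate a synthetic world of bird-trading countries
#'
#' Draws latent rule-of-law and trade-barrier positions uniformly on \[0, 1\]
#' (1 = strongest governance) for each country, derives the true quintile
#' weakness bins and expected score E within each role group, samples the
#' true trade-score category from the cumulative-link model
#' `logit P(T <= k) = theta_k - beta_role * (E - center_score)`, and
#' back-fills a bird volume by drawing uniformly inside the category's
#' equal-width log10 bin (a hair away from the edges, so record-level
#' round-trips can never flip a bin).
#'
#' @param config a [synthetic_world_config()].
#' @return a `synthetic_world` with elements `countries` (one row per
#'   country: code, role, latent positions, true bins, true `expected_score`,
#'   true `trade_category`, true `volume`), `log_edges` (the 6 log10 bin
#'   edges) and the `config`. Deterministic given the config seed.
#' @export
generate_world <- function(config) {
  if (!inherits(config, "synthetic_world_config")) {
    config <- do.call(synthetic_world_config, as.list(config))
  }
  set.seed(config$seed)
  ns <- config$n_suppliers; nd <- config$n_demanders
  n <- ns + nd
  role <- rep(c("supplier", "demander"), c(ns, nd))
  country <- c(.country_codes("S", ns), .country_codes("D", nd))
  law <- stats::runif(n)
  barrier <- stats::runif(n)

  law_bin <- integer(n); barrier_bin <- integer(n)
  for (r in c("supplier", "demander")) {
    sel <- role == r
    law_bin[sel] <- bin_axis_weakness(law[sel], higher_is_stronger = TRUE)
    barrier_bin[sel] <- bin_axis_weakness(barrier[sel], higher_is_stronger = TRUE)
  }
  E <- expected_score(law_bin, barrier_bin)

  beta <- ifelse(role == "supplier", config$beta_supplier, config$beta_demander)
  eta <- beta * (E - config$center_score)
  cum <- vapply(config$thresholds, function(th) stats::plogis(th - eta), numeric(n))
  u <- stats::runif(n)
  categ <- 1L + rowSums(u > cum)

  edges <- seq(.volume_log_range(config)[1], .volume_log_range(config)[2],
               length.out = 6L)
  lo <- edges[categ]; hi <- edges[categ + 1L]
  w <- hi - lo
  logv <- stats::runif(n, lo + 1e-3 * w, hi - 1e-3 * w)

  countries <- data.frame(
    country = country, role = role,
    law_latent = law, barrier_latent = barrier,
    law_weakness_bin = law_bin, barrier_weakness_bin = barrier_bin,
    expected_score = E, trade_category = as.integer(categ),
    volume = 10^logv, stringsAsFactors = FALSE)
  structure(list(countries = countries, log_edges = edges, config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic bird-trade world:",
      sum(x$countries$role == "supplier"), "suppliers,",
      sum(x$countries$role == "demander"), "demanders\n")
  cat("  true slopes: supplier", x$config$beta_supplier,
      "| demander", x$config$beta_demander, "\n")
  cat("  volume range: 10^[", paste(round(range(x$log_edges), 2), collapse = ", "),
      "] birds\n", sep = "")
  invisible(x)
}

#' Emit CITES-style trade records for one period
#'
#' Produces bilateral wild-sourced live-bird records (Term "live", Source
#' "W", Class "Aves", blank Unit) whose reconciled aggregation recovers every
#' country's true volume exactly: suppliers on the exporter side, demanders
#' on the importer side. Bilateral flows follow a deterministic transport
#' plan `F_ij = S_i * D_j / max(sum S, sum D)` (supplier i to demander j),
#' which respects both margins; the imbalance between total supply and total
#' demand is routed through rest-of-world partner codes (`XW*`), countries
#' outside the study population. Record years are drawn uniformly from the
#' period window under a seed derived from the world seed.
#'
#' @param world a `synthetic_world`.
#' @param period `"preban"` (1995--2005) or `"postban"` (2006--2017).
#' @return a `trade_records` data frame (see [read_trade_csv()]) with
#'   provenance `"synthetic"`.
#' @export
emit_trade_records <- function(world, period = c("preban", "postban")) {
  stopifnot(inherits(world, "synthetic_world"))
  period <- match.arg(period)
  window <- period_window(period)
  set.seed(world$config$seed + if (period == "preban") 101L else 202L)

  cs <- world$countries
  sup <- cs[cs$role == "supplier", ]
  dem <- cs[cs$role == "demander", ]
  S <- sup$volume; D <- dem$volume
  total <- max(sum(S), sum(D))
  flow <- outer(S, D) / total

  rec <- data.frame(
    exporter = rep(sup$country, times = nrow(dem)),
    importer = rep(dem$country, each = nrow(sup)),
    qty = as.vector(flow), origin = "", stringsAsFactors = FALSE)
  rec$importer_qty <- rec$qty
  rec$exporter_qty <- rec$qty

  # residual flows through rest-of-world partners
  res_s <- S - rowSums(flow)
  res_d <- D - colSums(flow)
  keep_s <- res_s > 1e-9 * S
  keep_d <- res_d > 1e-9 * D
  if (any(keep_s)) {
    rec <- rbind(rec, data.frame(
      exporter = sup$country[keep_s], importer = "XWA",
      qty = res_s[keep_s], origin = "",
      importer_qty = NA_real_, exporter_qty = res_s[keep_s],
      stringsAsFactors = FALSE))
  }
  if (any(keep_d)) {
    rec <- rbind(rec, data.frame(
      exporter = "XWB", importer = dem$country[keep_d],
      qty = res_d[keep_d], origin = "",
      importer_qty = res_d[keep_d], exporter_qty = NA_real_,
      stringsAsFactors = FALSE))
  }
  rec <- rec[rec$qty > 0, , drop = FALSE]

  out <- data.frame(
    year = sample(window[1]:window[2], nrow(rec), replace = TRUE),
    taxon = "Psittacus erithacus", taxon_class = "Aves",
    importer = rec$importer, exporter = rec$exporter, origin = rec$origin,
    importer_qty = rec$importer_qty, exporter_qty = rec$exporter_qty,
    term = "live", unit = "", purpose = "T", source = "W",
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, provenance = "synthetic", period = window,
            class = c("trade_records", "data.frame"))
}

#' Emit noisy governance covariates for one period
#'
#' Observes each country's latent rule-of-law and trade-barrier positions
#' through additive Gaussian noise (sd `covariate_noise_sd`), truncated to
#' \[0, 1\]. The two barrier proxies (cost of exportation, import tariffs)
#' are independent noisy readings of the same latent barrier position. In the
#' postban period, demanders' import tariffs are additionally shifted up by
#' `ban_shift` (applied after truncation, so the shift is exactly uniform
#' within the group and rank-preserving).
#'
#' @param world a `synthetic_world`.
#' @param period `"preban"` or `"postban"`.
#' @return covariate data frame (`country`, `period`, `rule_of_law`,
#'   `import_tariff`, `export_cost`).
#' @export
emit_covariates <- function(world, period = c("preban", "postban")) {
  stopifnot(inherits(world, "synthetic_world"))
  period <- match.arg(period)
  set.seed(world$config$seed + if (period == "preban") 303L else 404L)
  cs <- world$countries
  n <- nrow(cs)
  sd <- world$config$covariate_noise_sd
  noise <- function() if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)
  rule_of_law <- clamp01(cs$law_latent + noise())
  export_cost <- clamp01(cs$barrier_latent + noise())
  import_tariff <- clamp01(cs$barrier_latent + noise())
  if (period == "postban") {
    shift <- world$config$ban_shift * (cs$role == "demander")
    import_tariff <- import_tariff + shift
  }
  data.frame(country = cs$country, period = period,
             rule_of_law = rule_of_law, import_tariff = import_tariff,
             export_cost = export_cost, stringsAsFactors = FALSE)
}
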