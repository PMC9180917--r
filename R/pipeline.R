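#' Assemble and validate a pipeline configuration
#'
#' Exactly one input source must be given: either `synthetic` (arguments for
#' [synthetic_world_config()], possibly an empty list for defaults) or the
#' pair `trade_csv` + `covariates_csv`. Periods must not overlap.
#'
#' @param synthetic `NULL`, or a (possibly empty) list of
#'   [synthetic_world_config()] arguments.
#' @param trade_csv,covariates_csv paths to real input files (`NULL` when
#'   simulating).
#' @param periods named list of closed year windows; defaults to the EU-ban
#'   split `preban = c(1995, 2005)`, `postban = c(2006, 2017)`.
#' @param volume_log_range optional log10 range for the trade-score bins
#'   (defaults to the synthetic world's configured range, or the observed
#'   range on real data).
#' @param cluster list of clustering options: `candidates`, `m`, `nstart`.
#' @param scenarios scenario names to project (default all of A--D).
#' @param n_reps Monte Carlo replicates per scenario.
#' @param seed master seed for clustering and projection stages.
#' @param output_dir directory for the run artifacts.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL, trade_csv = NULL,
                            covariates_csv = NULL,
                            periods = list(preban = c(1995, 2005),
                                           postban = c(2006, 2017)),
                            volume_log_range = NULL,
                            cluster = list(candidates = 2:5, m = 2, nstart = 5),
                            scenarios = c("A", "B", "C", "D"),
                            n_reps = 1000L, seed = 1L,
                            output_dir = NULL) {
  has_synth <- !is.null(synthetic)
  has_real <- !is.null(trade_csv) || !is.null(covariates_csv)
  if (has_synth == has_real) {
    stop("configure exactly one input source: synthetic, or trade_csv + covariates_csv",
         call. = FALSE)
  }
  if (has_real && (is.null(trade_csv) || is.null(covariates_csv))) {
    stop("real input needs both trade_csv and covariates_csv", call. = FALSE)
  }
  if (length(periods) < 1L || is.null(names(periods)) || any(names(periods) == "")) {
    stop("periods must be a named list of year windows", call. = FALSE)
  }
  for (p in periods) {
    if (length(p) != 2L || !is.numeric(p) || p[1] > p[2]) {
      stop("each period must be c(year_lo, year_hi) with lo <= hi", call. = FALSE)
    }
  }
  if (length(periods) > 1L) {
    win <- lapply(periods, function(p) p[1]:p[2])
    for (i in seq_along(win)) for (j in seq_len(i - 1L)) {
      if (length(intersect(win[[i]], win[[j]])) > 0L) {
        stop("periods '", names(periods)[j], "' and '", names(periods)[i],
             "' overlap", call. = FALSE)
      }
    }
  }
  scenarios <- match.arg(scenarios, c("A", "B", "C", "D"), several.ok = TRUE)
  structure(list(synthetic = synthetic, trade_csv = trade_csv,
                 covariates_csv = covariates_csv, periods = periods,
                 volume_log_range = volume_log_range,
                 cluster = utils::modifyList(list(candidates = 2:5, m = 2, nstart = 5),
                                             as.list(cluster)),
                 scenarios = scenarios, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; the `synthetic` block
#' mirrors [synthetic_world_config()] field names.
#'
#' @param path path to a YAML config file.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage: simulate (or ingest) trade records and
#' covariates, filter wild-sourced live birds per period, aggregate
#' reconciled country totals, assign market roles, build score tables, fit
#' the per-role cumulative-link models, cluster countries in the normalized
#' governance plane, and project scenario volumes from the last period's
#' fits. When `output_dir` is set, all tabular artifacts are written as CSV
#' together with a JSON run manifest (config echo, seeds, row counts,
#' exclusions, warnings); identical configs produce byte-identical outputs.
#'
#' @param config a `pipeline_config` (or a YAML path, read via
#'   [read_pipeline_config()]).
#' @return (invisibly) a list with `score_tables`, `fits`, `fit_summary`,
#'   `clusters`, `projections`, `global_totals`, `manifest`, and on synthetic
#'   runs the generated `world`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  warnings_seen <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  config_echo <- unclass(config)
  config_echo$output_dir <- NULL  # keep artifacts independent of where they land
  manifest <- list(config = config_echo, counts = list(), exclusions = list())
  periods <- config$periods

  # --- input stage ----------------------------------------------------------
  world <- NULL
  if (!is.null(config$synthetic)) {
    world <- .stage("simulate", {
      generate_world(do.call(synthetic_world_config, as.list(config$synthetic)))
    })
    records <- lapply(names(periods), function(p) emit_trade_records(world, p))
    names(records) <- names(periods)
    covariates <- do.call(rbind, lapply(names(periods),
                                        function(p) emit_covariates(world, p)))
    if (is.null(config$volume_log_range)) {
      config$volume_log_range <- range(world$log_edges)
    }
  } else {
    all_records <- .stage("ingest", read_trade_csv(config$trade_csv))
    manifest$counts$rows_read <- nrow(all_records) + attr(all_records, "dropped_rows")
    manifest$counts$rows_dropped <- attr(all_records, "dropped_rows")
    records <- lapply(periods, function(p) all_records)
    covariates <- .stage("ingest", read_covariates(config$covariates_csv))
  }

  # --- per-period scoring ---------------------------------------------------
  score_tables <- list(); fits <- list(); clusters <- list()
  fit_rows <- list()
  for (p in names(periods)) {
    filtered <- .stage("filter", filter_wild_live_birds(records[[p]], periods[[p]]))
    manifest$counts[[paste0("records_", p)]] <- nrow(filtered)
    totals <- .stage("aggregate", aggregate_totals(filtered))
    roles <- .stage("roles", collect(suppressMessages(assign_roles(totals))))
    st <- .stage("score", collect(suppressMessages(
      build_score_table(roles, covariates, p,
                        log_range = config$volume_log_range))))
    score_tables[[p]] <- st
    manifest$exclusions[[p]] <- as.list(attr(st, "excluded"))
    for (r in c("supplier", "demander")) {
      sub <- st[st$role == r, , drop = FALSE]
      if (nrow(sub) == 0L) next
      fit <- .stage("fit", collect(fit_clm(sub)))
      fits[[paste(r, p, sep = "_")]] <- fit
      fit_rows[[paste(r, p, sep = "_")]] <- data.frame(
        role = r, period = p, n = fit$n, beta = fit$beta, se = fit$se_beta,
        z = fit$z, p_value = fit$p_value,
        theta1 = fit$thresholds[1], theta2 = fit$thresholds[2],
        theta3 = fit$thresholds[3], theta4 = fit$thresholds[4],
        null_loglik = fit$null_loglik, loglik = fit$loglik,
        nagelkerke_R2 = fit$nagelkerke_R2, mcfadden_R2 = fit$mcfadden_R2,
        converged = fit$converged, stringsAsFactors = FALSE)

      pts <- normalize_unit(sub[, c("rule_of_law", "barrier")])
      cand <- config$cluster$candidates
      cand <- cand[cand <= nrow(sub) - 1L]
      cl <- .stage("cluster", {
        cc <- select_cluster_count(pts, cand, m = config$cluster$m,
                                   seed = config$seed,
                                   nstart = config$cluster$nstart)
        fit_c <- fcm(pts, as.integer(cc), m = config$cluster$m,
                     seed = config$seed + as.integer(cc),
                     nstart = config$cluster$nstart)
        list(n_clusters = as.integer(cc),
             partition_coefficients = attr(cc, "partition_coefficients"),
             fit = fit_c,
             quadrant = scenario_quadrant_labels(fit_c$centers),
             countries = sub$country)
      })
      clusters[[paste(r, p, sep = "_")]] <- cl
    }
  }
  fit_summary <- do.call(rbind, fit_rows)
  rownames(fit_summary) <- NULL

  # --- scenario projection (from the last period's calibration) -------------
  last <- names(periods)[length(periods)]
  calibs <- attr(score_tables[[last]], "calibrations")
  projections <- list()
  for (sc in config$scenarios) {
    projections[[sc]] <- .stage("project", project_scenario(
      fits[[paste0("supplier_", last)]], fits[[paste0("demander_", last)]],
      score_tables[[last]], scenario_spec(sc),
      calibs$supplier, calibs$demander,
      n_reps = config$n_reps, seed = config$seed + match(sc, LETTERS)))
  }
  totals <- do.call(rbind, lapply(projections, global_totals))
  rownames(totals) <- NULL

  manifest$seed <- config$seed
  manifest$projection_basis <- last
  manifest$warnings <- warnings_seen
  manifest$n_warnings <- length(warnings_seen)

  result <- list(world = world, score_tables = score_tables, fits = fits,
                 fit_summary = fit_summary, clusters = clusters,
                 projections = projections, global_totals = totals,
                 manifest = manifest)

  if (!is.null(config$output_dir)) {
    .stage("write", .write_artifacts(result, config))
  }
  invisible(result)
}

.write_artifacts <- function(result, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  for (p in names(result$score_tables)) {
    utils::write.csv(as.data.frame(result$score_tables[[p]]),
                     out(paste0("score_table_", p, ".csv")), row.names = FALSE)
  }
  utils::write.csv(result$fit_summary, out("clm_fits.csv"), row.names = FALSE)
  for (key in names(result$clusters)) {
    cl <- result$clusters[[key]]
    mem <- as.data.frame(cl$fit$memberships)
    names(mem) <- paste0("cluster_", seq_len(ncol(mem)), "_", cl$quadrant)
    mem <- cbind(country = cl$countries,
                 cluster = apply(cl$fit$memberships, 1L, which.max), mem)
    utils::write.csv(mem, out(paste0("memberships_", key, ".csv")),
                     row.names = FALSE)
  }
  for (sc in names(result$projections)) {
    utils::write.csv(result$projections[[sc]]$countries,
                     out(paste0("projection_", sc, ".csv")), row.names = FALSE)
  }
  utils::write.csv(result$global_totals, out("global_totals.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(config$output_dir)
}
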