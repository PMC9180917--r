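# shared fixtures and independent oracles

sample_skewness <- function(x) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

# small deterministic world used across tests
tiny_config <- function(...) {
  synthetic_world_config(n_suppliers = 12L, n_demanders = 12L,
                         covariate_noise_sd = 0, seed = 42L, ...)
}

# write a CITES-dialect CSV from a header + row strings
write_cites_fixture <- function(rows) {
  path <- tempfile(fileext = ".csv")
  hdr <- paste("Year,App.,Taxon,Class,Order,Family,Genus,Importer,Exporter,",
               "Origin,Importer reported quantity,Exporter reported quantity,",
               "Term,Unit,Purpose,Source", sep = "")
  writeLines(c(hdr, rows), path)
  path
}

# a CITES row with defaults matching the study filter
cites_row <- function(year = 2000, importer = "DE", exporter = "AR",
                      origin = "", iq = "", eq = "10", term = "live",
                      unit = "", source = "W", class = "Aves") {
  paste(year, "II", "Psittacus erithacus", class, "Psittaciformes",
        "Psittacidae", "Psittacus", importer, exporter, origin, iq, eq,
        term, unit, "T", source, sep = ",")
}

# exhaustive cyclic coordinate search of the CLM log-likelihood on a 0.01
# lattice; independent of the package optimizer (uses only clm_loglik)
grid_clm_mle <- function(data, step = 0.01, span = 0.8, max_sweeps = 100L) {
  counts <- tabulate(data$trade_score, 5L)
  cum <- pmin(pmax(cumsum(counts)[1:4] / nrow(data), 0.02), 0.98)
  par <- round(c(0, qlogis(cum)) / step) * step
  par[2:5] <- cummax(par[2:5] + c(0, 0.01, 0.02, 0.03))
  eval_ll <- function(p) {
    if (any(diff(p[2:5]) <= 0)) return(-Inf)
    clm_loglik(p[1], p[2:5], data)
  }
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    # single-coordinate exhaustive scans
    for (j in 1:5) {
      cand <- par[j] + seq(-span, span, by = step)
      lls <- vapply(cand, function(v) { p <- par; p[j] <- v; eval_ll(p) },
                    numeric(1))
      best <- cand[which.max(lls)]
      if (abs(best - par[j]) > 1e-12) { par[j] <- best; moved <- TRUE }
    }
    # paired scans escape lattice stalls along correlated ridges
    deltas <- seq(-5 * step, 5 * step, by = step)
    for (i in 1:4) for (j in (i + 1):5) {
      grid <- expand.grid(di = deltas, dj = deltas)
      lls <- vapply(seq_len(nrow(grid)), function(g) {
        p <- par
        p[i] <- p[i] + grid$di[g]; p[j] <- p[j] + grid$dj[g]
        eval_ll(p)
      }, numeric(1))
      g <- which.max(lls)
      if (abs(grid$di[g]) > 1e-12 || abs(grid$dj[g]) > 1e-12) {
        par[i] <- par[i] + grid$di[g]; par[j] <- par[j] + grid$dj[g]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  # full 5-D local polish: exhaustive +/-2-step lattice neighbourhoods until
  # the point is a joint lattice optimum, not merely a coordinate-wise one
  d2 <- seq(-2 * step, 2 * step, by = step)
  hood <- as.matrix(expand.grid(d2, d2, d2, d2, d2))
  repeat {
    lls <- vapply(seq_len(nrow(hood)), function(g) eval_ll(par + hood[g, ]),
                  numeric(1))
    g <- which.max(lls)
    if (all(abs(hood[g, ]) < 1e-12)) break
    par <- par + hood[g, ]
  }
  list(beta = par[1], theta = par[2:5], loglik = eval_ll(par))
}

# simulate (E, T) pairs straight from the cumulative-link model
simulate_clm <- function(n, beta, theta, scores = 0:8) {
  E <- sample(scores, n, replace = TRUE)
  cum <- vapply(theta, function(th) plogis(th - beta * E), numeric(n))
  Tc <- 1L + rowSums(runif(n) > cum)
  data.frame(expected_score = E, trade_score = Tc)
}

# seeded Gaussian blobs in the unit plane
make_blobs <- function(centers, n_per = 30L, sd = 0.04) {
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
  }))
}
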