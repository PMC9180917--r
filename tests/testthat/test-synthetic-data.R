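test_that("generation is deterministic and validates its configuration", {
  w1 <- generate_world(tiny_config())
  w2 <- generate_world(tiny_config())
  expect_identical(w1, w2)
  expect_identical(emit_trade_records(w1, "preban"), emit_trade_records(w2, "preban"))
  expect_identical(emit_covariates(w1, "postban"), emit_covariates(w2, "postban"))

  expect_error(synthetic_world_config(n_suppliers = 1), "at least 2")
  expect_error(synthetic_world_config(thresholds = c(1, 0, 2, 3)), "increasing")
  expect_error(synthetic_world_config(volume_log_sd = 0), "volume_log_sd")
  expect_error(emit_trade_records(generate_world(tiny_config()), "midban"))
})

test_that("a zero slope decouples trade categories from the expected score", {
  cfg <- synthetic_world_config(n_suppliers = 5000L, n_demanders = 5L,
                                beta_supplier = 0, seed = 11L)
  w <- generate_world(cfg)
  sup <- w$countries[w$countries$role == "supplier", ]
  p <- suppressWarnings(
    chisq.test(table(sup$expected_score, sup$trade_category)))$p.value
  expect_gt(p, 0.01)
})

test_that("empirical cumulative category frequencies match the closed-form model", {
  # textbook parameterization logit P(T<=k) = theta_k - beta*E (center 0)
  cfg <- synthetic_world_config(n_suppliers = 100000L, n_demanders = 5L,
                                beta_supplier = 0.5, center_score = 0,
                                seed = 5L)
  w <- generate_world(cfg)
  sup <- w$countries[w$countries$role == "supplier", ]
  for (e in sort(unique(sup$expected_score))) {
    cats <- sup$trade_category[sup$expected_score == e]
    emp <- cumsum(tabulate(cats, 5L))[1:4] / length(cats)
    theo <- plogis(cfg$thresholds - 0.5 * e)
    expect_true(all(abs(emp - theo) <= 0.02),
                label = paste("cumulative frequencies at E =", e))
  }
})

test_that("emitted records conserve every country's true volume on its own side", {
  w <- generate_world(tiny_config())
  rec <- emit_trade_records(w, "preban")
  expect_true(all(rec$year >= 1995 & rec$year <= 2005))
  expect_true(all(rec$source == "W" & rec$term == "live" & rec$taxon_class == "Aves"))

  sup <- w$countries[w$countries$role == "supplier", ]
  exp_sums <- tapply(rec$exporter_qty, rec$exporter, sum, na.rm = TRUE)
  expect_equal(as.numeric(exp_sums[sup$country]), sup$volume, tolerance = 1e-12)
  dem <- w$countries[w$countries$role == "demander", ]
  imp_sums <- tapply(rec$importer_qty, rec$importer, sum, na.rm = TRUE)
  expect_equal(as.numeric(imp_sums[dem$country]), dem$volume, tolerance = 1e-12)

  post <- emit_trade_records(w, "postban")
  expect_true(all(post$year >= 2006 & post$year <= 2017))
})

test_that("volumes are right-skewed raw and near-symmetric on the log scale", {
  w <- generate_world(synthetic_world_config(n_suppliers = 500L,
                                             n_demanders = 500L, seed = 3L))
  v <- w$countries$volume
  expect_gt(sample_skewness(v), 0)
  expect_lt(abs(sample_skewness(log10(v))), 0.3)
  # every volume lies inside its category's log bin
  lv <- log10(v)
  k <- w$countries$trade_category
  expect_true(all(lv > w$log_edges[k] & lv < w$log_edges[k + 1L]))
})

test_that("noiseless covariates identify every true weakness bin", {
  w <- generate_world(tiny_config())
  cov <- emit_covariates(w, "preban")
  for (r in c("supplier", "demander")) {
    sel <- w$countries$role == r
    expect_identical(bin_axis_weakness(cov$rule_of_law[sel], TRUE),
                     w$countries$law_weakness_bin[sel])
    barrier <- if (r == "supplier") cov$export_cost else cov$import_tariff
    expect_identical(bin_axis_weakness(barrier[sel], TRUE),
                     w$countries$barrier_weakness_bin[sel])
  }
})

test_that("the postban ban shift moves demander tariffs uniformly", {
  w <- generate_world(tiny_config(ban_shift = 0.2))
  pre <- emit_covariates(w, "preban")
  post <- emit_covariates(w, "postban")
  dem <- w$countries$role == "demander"
  expect_equal(post$import_tariff[dem] - pre$import_tariff[dem],
               rep(0.2, sum(dem)))
  expect_equal(post$import_tariff[!dem], pre$import_tariff[!dem])
})

test_that("moderate covariate noise still recovers most expected scores", {
  cfg <- synthetic_world_config(n_suppliers = 100L, n_demanders = 100L,
                                covariate_noise_sd = 0.05, seed = 9L)
  w <- generate_world(cfg)
  cov <- emit_covariates(w, "preban")
  hits <- 0L
  for (r in c("supplier", "demander")) {
    sel <- w$countries$role == r
    barrier <- if (r == "supplier") cov$export_cost else cov$import_tariff
    E_hat <- expected_score(bin_axis_weakness(cov$rule_of_law[sel], TRUE),
                            bin_axis_weakness(barrier[sel], TRUE))
    hits <- hits + sum(abs(E_hat - w$countries$expected_score[sel]) <= 1L)
  }
  expect_gte(hits / nrow(w$countries), 0.90)
})
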