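# a hand-built fit whose predicted distribution is degenerate at category 3
degenerate_fit <- function() {
  structure(list(beta = 0, thresholds = c(-40, -30, 30, 40), converged = TRUE),
            class = "clm_fit")
}

unit_calib <- function() fit_volume_bins(c(10, 1e5))  # log10 edges 1..5

test_that("scenario bands cross the strong/weak corners of the score grid", {
  expect_equal(scenario_spec("A")[c("supplier_range", "demander_range")],
               list(supplier_range = c(0L, 2L), demander_range = c(0L, 2L)))
  expect_equal(scenario_spec("B")$demander_range, c(6L, 8L))
  expect_equal(scenario_spec("C")$supplier_range, c(6L, 8L))
  expect_equal(scenario_spec("D")[c("supplier_range", "demander_range")],
               list(supplier_range = c(6L, 8L), demander_range = c(6L, 8L)))
  expect_error(scenario_spec("E"))
})

test_that("categories back-transform to log-bin midpoints", {
  calib <- unit_calib()
  expect_equal(score_to_volume(1L, calib), 10^1.4)
  expect_equal(score_to_volume(5L, calib), 10^4.6)
  # any volume maps to its own bin's midpoint, and midpoints are fixed points
  v <- 10^runif(50, 1, 5)
  mids <- score_to_volume(real_trade_score(v, calib), calib)
  expect_identical(real_trade_score(mids, calib), real_trade_score(v, calib))
  expect_error(score_to_volume(0L, calib), "1-5")
  expect_error(score_to_volume(6L, calib), "1-5")
})

test_that("a degenerate channel projects deterministically and additively", {
  roles1 <- data.frame(country = "SAA", role = "supplier")
  pr1 <- project_scenario(degenerate_fit(), NULL, roles1, scenario_spec("A"),
                          unit_calib(), NULL, n_reps = 20, seed = 5)
  mid3 <- score_to_volume(3L, unit_calib())
  expect_true(all(pr1$countries$mean_volume == mid3))
  expect_equal(pr1$countries$modal_category, 3)
  expect_equal(global_totals(pr1)$mean_total, mid3)
  expect_equal(unname(rowSums(pr1$category_counts$supplier)), 20)

  roles2 <- data.frame(country = c("SAA", "SAB"), role = "supplier")
  pr2 <- project_scenario(degenerate_fit(), NULL, roles2, scenario_spec("A"),
                          unit_calib(), NULL, n_reps = 20, seed = 5)
  expect_equal(global_totals(pr2)$mean_total, 2 * mid3)
})

test_that("projections are reproducible and demand both role fits", {
  set.seed(41)
  fit <- fit_clm(simulate_clm(300, 0.5, c(-1.5, -0.5, 0.5, 1.5)))
  roles <- data.frame(country = c("SAA", "SAB", "DAA"),
                      role = c("supplier", "supplier", "demander"))
  run <- function() project_scenario(fit, fit, roles, scenario_spec("D"),
                                     unit_calib(), unit_calib(),
                                     n_reps = 50, seed = 99)
  expect_identical(run(), run())
  expect_error(project_scenario(fit, NULL, roles, scenario_spec("D"),
                                unit_calib(), NULL, seed = 1),
               "demander")
})

test_that("a positive supplier slope orders scenario volumes by score band", {
  set.seed(43)
  fit <- fit_clm(simulate_clm(500, 0.5, c(0.5, 1.5, 2.5, 3.5)))
  roles <- data.frame(country = paste0("S", 1:10), role = "supplier")
  lo <- project_scenario(fit, NULL, roles, scenario_spec("A"), unit_calib(),
                         NULL, n_reps = 2000, seed = 7)
  hi <- project_scenario(fit, NULL, roles, scenario_spec("D"), unit_calib(),
                         NULL, n_reps = 2000, seed = 7)
  expect_gt(global_totals(hi)$mean_total, global_totals(lo)$mean_total)
})

test_that("Monte Carlo means stay inside their theoretical error bands", {
  fit <- structure(list(beta = 0.5, thresholds = c(0.5, 1.5, 2.5, 3.5),
                        converged = TRUE), class = "clm_fit")
  calib <- unit_calib()
  roles <- data.frame(country = "SAA", role = "supplier")
  # exact per-draw expectation: score uniform on 6..8, then the CLM channel
  mids <- score_to_volume(1:5, calib)
  exact <- mean(vapply(6:8, function(e) {
    sum(predict_category_probs(fit, e) * mids)
  }, numeric(1)))
  per_draw_var <- mean(vapply(6:8, function(e) {
    sum(predict_category_probs(fit, e) * mids^2)
  }, numeric(1))) - exact^2
  for (reps in c(200L, 5000L)) {
    pr <- project_scenario(fit, NULL, roles, scenario_spec("D"), calib, NULL,
                           n_reps = reps, seed = 13)
    tol <- 4 * sqrt(per_draw_var / reps)
    expect_lt(abs(global_totals(pr)$mean_total - exact), tol)
  }
})

test_that("modal draws remove sampling noise from the channel", {
  fit <- structure(list(beta = 2, thresholds = c(2, 5, 9, 13),
                        converged = TRUE), class = "clm_fit")
  roles <- data.frame(country = "DAA", role = "demander")
  pr <- project_scenario(NULL, fit, roles, scenario_spec("A"), NULL,
                         unit_calib(), n_reps = 100, seed = 3, draw = "modal")
  modal <- vapply(0:2, function(e) which.max(predict_category_probs(fit, e)),
                  integer(1))
  expect_true(all(pr$countries$volume_lo >= score_to_volume(min(modal), unit_calib())))
  expect_true(all(pr$countries$volume_hi <= score_to_volume(max(modal), unit_calib())))
})
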