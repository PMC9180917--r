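test_that("the log-likelihood matches closed forms and a naive product oracle", {
  # logistic(0) = 0.5 for a single observation at the first threshold
  d1 <- data.frame(expected_score = 0L, trade_score = 1L)
  expect_equal(clm_loglik(0, c(0, 1, 2, 3), d1), log(0.5))

  # beta = 0 with thresholds at the marginal cumulative logits gives the
  # saturated multinomial log-likelihood
  set.seed(14)
  d <- simulate_clm(120, 0.4, c(-1.5, -0.5, 0.5, 1.5))
  counts <- tabulate(d$trade_score, 5L)
  theta_hat <- qlogis(cumsum(counts)[1:4] / nrow(d))
  expect_equal(clm_loglik(0, theta_hat, d),
               sum(counts[counts > 0] * log(counts[counts > 0] / nrow(d))))

  # naive per-observation probability product
  beta <- 0.37; theta <- c(-1, -0.2, 0.6, 1.9)
  ll <- 0
  for (i in seq_len(nrow(d))) {
    cum <- c(0, plogis(theta - beta * d$expected_score[i]), 1)
    ll <- ll + log(cum[d$trade_score[i] + 1L] - cum[d$trade_score[i]])
  }
  expect_equal(clm_loglik(beta, theta, d), ll, tolerance = 1e-12)

  expect_error(clm_loglik(0, c(1, 0.5, 2, 3), d), "increasing")
})

test_that("the ML fit matches an independent proportional-odds implementation", {
  skip_if_not_installed("MASS")
  set.seed(25)
  d <- simulate_clm(400, 0.5, c(-1.5, -0.5, 0.5, 1.5), scores = 0:8)
  fit <- fit_clm(d)
  ref <- MASS::polr(factor(trade_score, levels = 1:5) ~ expected_score,
                    data = d, Hess = TRUE)
  expect_true(fit$converged)
  expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$thresholds, unname(ref$zeta), tolerance = 1e-4)
  expect_equal(fit$se_beta,
               sqrt(diag(vcov(ref)))[["expected_score"]], tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("a negative-slope fit recovers demander-like truth", {
  set.seed(26)
  d <- simulate_clm(600, -0.578, c(-3.8, -2.8, -1.8, -0.8), scores = 0:8)
  fit <- fit_clm(d)
  expect_lt(fit$beta, 0)
  expect_lt(abs(fit$beta + 0.578), 3 * fit$se_beta)
  expect_gte(fit$loglik, fit$null_loglik)
  expect_true(all(diff(fit$thresholds) > 0))
})

test_that("pseudo-R2 formulas evaluate exactly and guard their domain", {
  r <- pseudo_r2(-100, -80, 100)
  expect_equal(r$cox_snell, 1 - exp(-0.4))
  expect_equal(r$nagelkerke, (1 - exp(-0.4)) / (1 - exp(-2)))
  expect_equal(r$mcfadden, 0.2)

  same <- pseudo_r2(-50, -50, 80)
  expect_equal(same$nagelkerke, 0)
  expect_equal(same$mcfadden, 0)

  perfect <- pseudo_r2(-100, -1e-9, 100)
  expect_equal(perfect$nagelkerke, 1, tolerance = 1e-6)

  expect_error(pseudo_r2(0, 0, 10), "undefined")
  expect_error(pseudo_r2(-10, -20, 10), "below null")
})

test_that("predicted category probabilities are coherent and ordered", {
  set.seed(30)
  d <- simulate_clm(300, 0.5, c(-1.5, -0.5, 0.5, 1.5))
  fit <- fit_clm(d)
  p <- predict_category_probs(fit, 0:8)
  expect_equal(rowSums(p), rep(1, 9), tolerance = 1e-12)
  # stochastic ordering: P(T >= k | E) non-decreasing in E for every k
  for (k in 1:5) {
    upper <- rowSums(p[, k:5, drop = FALSE])
    expect_true(all(diff(upper) >= -1e-12))
  }
  expect_error(predict_category_probs(fit, 9), "0-8")

  flat <- structure(list(beta = 0, thresholds = fit$thresholds,
                         converged = TRUE), class = "clm_fit")
  p0 <- predict_category_probs(flat, c(0L, 8L))
  expect_identical(p0[1, ], p0[2, ])  # zero slope: same distribution at any E
})

test_that("shifting every expected score leaves the slope invariant", {
  set.seed(33)
  d <- simulate_clm(300, 0.5, c(-1.5, -0.5, 0.5, 1.5), scores = 0:6)
  f1 <- fit_clm(d)
  d2 <- d; d2$expected_score <- d2$expected_score + 2L
  f2 <- fit_clm(d2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
  expect_equal(f2$thresholds - f1$thresholds, rep(2 * f1$beta, 4),
               tolerance = 1e-4)
})

test_that("complete separation is flagged and stabilised, not returned raw", {
  d <- data.frame(expected_score = rep(c(0L, 4L, 8L), each = 10L),
                  trade_score = rep(c(1L, 3L, 5L), each = 10L))
  expect_warning(fit <- fit_clm(d), "separation")
  expect_true(is.finite(fit$beta))
})

test_that("a null slope is not spuriously detected", {
  set.seed(37)
  inside <- vapply(1:200, function(i) {
    d <- simulate_clm(500, 0, c(-1.5, -0.5, 0.5, 1.5))
    fit <- fit_clm(d)
    abs(fit$beta) < 3 * fit$se_beta
  }, logical(1))
  expect_gte(mean(inside), 0.99)
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(fit_clm(data.frame(expected_score = rep(1L, 20),
                                  trade_score = rep(1:5, 4))), "does not vary")
  expect_error(fit_clm(data.frame(expected_score = 1:20,
                                  trade_score = rep(2L, 20))), "does not vary")
  expect_error(fit_clm(data.frame(expected_score = 1:8,
                                  trade_score = c(1:5, 6L, 1L, 2L))), "1-5")
})
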