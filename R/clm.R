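# Proportional-odds cumulative-link (logit) regression of the real trade
# score T (1..5) on the expected geopolitical score E (0..8):
#   logit P(T <= k | E) = theta_k - beta * E,   k = 1..4
# One shared slope across thresholds (proportional odds); ML fit by
# quasi-Newton on an unconstrained reparameterization of the thresholds.

.check_thresholds <- function(theta) {
  if (length(theta) != 4L || anyNA(theta) || any(diff(theta) <= 0)) {
    stop("thresholds must be 4 strictly increasing values", call. = FALSE)
  }
}

.clm_cell_loglik <- function(beta, theta, E, Tc, w = rep(1, length(E))) {
  th <- c(-Inf, theta, Inf)
  eta <- beta * E
  p <- stats::plogis(th[Tc + 1L] - eta) - stats::plogis(th[Tc] - eta)
  sum(w * log(pmax(p, 1e-300)))
}

#' Cumulative-link model log-likelihood
#'
#' Evaluates `sum_i log[ F(theta_{T_i} - beta * E_i) - F(theta_{T_i - 1} -
#' beta * E_i) ]` with logistic F, `theta_0 = -Inf`, `theta_5 = +Inf`.
#'
#' @param beta slope on the expected score.
#' @param theta 4 strictly increasing thresholds.
#' @param data data frame with integer columns `expected_score` and
#'   `trade_score` (categories 1--5).
#' @return the log-likelihood (scalar).
#' @export
clm_loglik <- function(beta, theta, data) {
  .check_thresholds(theta)
  stopifnot(is.numeric(beta), length(beta) == 1L)
  E <- data$expected_score; Tc <- as.integer(data$trade_score)
  if (any(Tc < 1L | Tc > 5L)) stop("trade_score categories must lie in 1-5", call. = FALSE)
  .clm_cell_loglik(beta, theta, E, Tc)
}

#' Fit the proportional-odds model of trade score on expected score
#'
#' Maximum-likelihood fit of `logit P(T <= k) = theta_k - beta * E` with the
#' thresholds parameterized as (theta_1, log-increments) so ordering is
#' enforced, optimized by BFGS from a deterministic start (beta = 0, theta at
#' the marginal cumulative logits). Standard errors come from the inverse
#' observed information at the optimum; the null (thresholds-only) model has
#' the closed-form multinomial likelihood and feeds the Nagelkerke and
#' McFadden pseudo-R2.
#'
#' Data with (near) complete separation are refit with a tiny ridge penalty
#' (1e-6 * beta^2) and flagged with a warning rather than returned with a
#' diverging slope.
#'
#' @param data data frame with columns `expected_score` (0--8) and
#'   `trade_score` (1--5); both must vary.
#' @return an object of class `clm_fit`: `beta`, `thresholds`, `se_beta`,
#'   `z`, `p_value`, `loglik`, `null_loglik`, `nagelkerke_R2`,
#'   `mcfadden_R2`, `cox_snell_R2`, `n`, `converged`, plus the threshold
#'   standard errors `se_thresholds`.
#' @seealso [predict_category_probs()], [pseudo_r2()]
#' @export
fit_clm <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("expected_score", "trade_score") %in% names(data)))
  E <- as.numeric(data$expected_score)
  Tc <- as.integer(data$trade_score)
  n <- length(E)
  if (any(Tc < 1L | Tc > 5L)) stop("trade_score categories must lie in 1-5", call. = FALSE)
  if (length(unique(E)) < 2L) stop("expected score does not vary", call. = FALSE)
  if (length(unique(Tc)) < 2L) stop("trade score does not vary", call. = FALSE)
  if (n < 7L) stop("need more observations than free parameters", call. = FALSE)

  # collapse to cell counts: likelihood cost is O(#distinct cells), not O(n)
  cells <- stats::aggregate(list(w = rep(1L, n)),
                            by = list(E = E, Tc = Tc), FUN = sum)

  counts <- tabulate(Tc, nbins = 5L)
  cum <- cumsum(counts)[1:4] / n
  cum <- pmin(pmax(cum, 0.5 / n), 1 - 0.5 / n)
  q0 <- stats::qlogis(cum)
  q0 <- cummax(q0 + seq(0, 3e-3, length.out = 4L))  # enforce strict increase
  par0 <- c(0, q0[1], log(pmax(diff(q0), 1e-3)))

  unpack <- function(p) list(beta = p[1], theta = p[2] + cumsum(c(0, exp(p[3:5]))))
  make_nll <- function(ridge = 0) {
    function(p) {
      u <- unpack(p)
      -.clm_cell_loglik(u$beta, u$theta, cells$E, cells$Tc, cells$w) +
        ridge * u$beta^2
    }
  }
  make_grad <- function(ridge = 0) {
    function(p) {
      u <- unpack(p)
      th <- c(-Inf, u$theta, Inf)
      hi <- th[cells$Tc + 1L] - u$beta * cells$E
      lo <- th[cells$Tc] - u$beta * cells$E
      prob <- pmax(stats::plogis(hi) - stats::plogis(lo), 1e-300)
      dhi <- stats::dlogis(hi); dhi[!is.finite(hi)] <- 0
      dlo <- stats::dlogis(lo); dlo[!is.finite(lo)] <- 0
      g_beta <- sum(cells$w * (-cells$E) * (dhi - dlo) / prob)
      g_theta <- numeric(4L)
      for (k in 1:4) {
        g_theta[k] <- sum(cells$w * (dhi * (cells$Tc == k) -
                                       dlo * (cells$Tc == k + 1L)) / prob)
      }
      # chain rule into (theta1, log-increment) coordinates; negate for the
      # negative log-likelihood and add the ridge term on beta
      c(-g_beta + 2 * ridge * u$beta,
        -sum(g_theta),
        -exp(p[3]) * sum(g_theta[2:4]),
        -exp(p[4]) * sum(g_theta[3:4]),
        -exp(p[5]) * g_theta[4])
    }
  }
  run_fit <- function(ridge) {
    opt <- stats::optim(par0, make_nll(ridge), make_grad(ridge),
                        method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    # polish: restart from the solution to tighten convergence
    stats::optim(opt$par, make_nll(ridge), make_grad(ridge), method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
  }
  # observed information in the natural (beta, theta) parameterization
  nll_nat <- function(p) -.clm_cell_loglik(p[1], p[2:5], cells$E, cells$Tc, cells$w)
  info_se <- function(u) {
    vc <- tryCatch({
      H <- stats::optimHess(c(u$beta, u$theta), nll_nat)
      solve(H)
    }, error = function(e) matrix(NA_real_, 5L, 5L))
    sqrt(pmax(diag(vc), 0))
  }

  opt <- run_fit(0)
  u <- unpack(opt$par)
  se <- info_se(u)
  separated <- !all(is.finite(opt$par)) || abs(u$beta) > 15 ||
    !is.finite(se[1]) || se[1] <= 1e-8 || se[1] > 100 * max(1, abs(u$beta))
  if (separated) {
    warning("possible complete separation; slope stabilised with a 1e-6 ridge",
            call. = FALSE)
    opt <- run_fit(1e-6)
    u <- unpack(opt$par)
    se <- info_se(u)
  }
  loglik <- .clm_cell_loglik(u$beta, u$theta, cells$E, cells$Tc, cells$w)

  null_loglik <- sum(counts[counts > 0] * log(counts[counts > 0] / n))
  r2 <- pseudo_r2(null_loglik, loglik, n)

  z <- u$beta / se[1]
  structure(list(
    beta = u$beta, thresholds = u$theta,
    se_beta = se[1], se_thresholds = se[2:5],
    z = z, p_value = 2 * stats::pnorm(-abs(z)),
    loglik = loglik, null_loglik = null_loglik,
    nagelkerke_R2 = r2$nagelkerke, mcfadden_R2 = r2$mcfadden,
    cox_snell_R2 = r2$cox_snell,
    n = n, converged = opt$convergence == 0 && all(is.finite(se)) && se[1] > 0,
    separation = separated),
    class = "clm_fit")
}

#' @export
print.clm_fit <- function(x, ...) {
  cat("Cumulative-link (proportional odds) fit, n =", x$n, "\n")
  cat(sprintf("  beta = %.3f (SE %.3f), z = %.2f, p = %.3g\n",
              x$beta, x$se_beta, x$z, x$p_value))
  cat("  thresholds:", paste(sprintf("%.3f", x$thresholds), collapse = " "), "\n")
  cat(sprintf("  logLik %.3f (null %.3f) | Nagelkerke R2 = %.3f, McFadden R2 = %.3f\n",
              x$loglik, x$null_loglik, x$nagelkerke_R2, x$mcfadden_R2))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' Pseudo-R2 measures for a fitted ordinal model
#'
#' Cox-Snell `1 - exp(2 * (l0 - l1) / n)`, its Nagelkerke rescaling to a
#' \[0, 1\] maximum, and McFadden `1 - l1 / l0`. Values of 0.2--0.4 are
#' conventionally read as an excellent fit for McFadden-type measures.
#'
#' @param null_loglik,loglik log-likelihoods of the thresholds-only null
#'   model and the fitted model (`loglik >= null_loglik`).
#' @param n number of observations.
#' @return list with `cox_snell`, `nagelkerke`, `mcfadden`.
#' @export
pseudo_r2 <- function(null_loglik, loglik, n) {
  stopifnot(is.numeric(null_loglik), is.numeric(loglik), n > 0)
  if (loglik < null_loglik - 1e-8) {
    stop("model log-likelihood below null log-likelihood", call. = FALSE)
  }
  if (null_loglik == 0) {
    stop("McFadden R2 undefined: null log-likelihood is zero", call. = FALSE)
  }
  cox <- 1 - exp(2 * (null_loglik - loglik) / n)
  list(cox_snell = cox,
       nagelkerke = cox / (1 - exp(2 * null_loglik / n)),
       mcfadden = 1 - loglik / null_loglik)
}

#' Predicted category probabilities at an expected score
#'
#' Consecutive differences of the fitted cumulative probabilities
#' `P(T <= k | E) = logistic(theta_k - beta * E)`; each row sums to 1.
#'
#' @param fit a `clm_fit`.
#' @param E integer expected score(s) in 0--8.
#' @return a numeric matrix (length(E) x 5) of probabilities over the trade
#'   score categories; a plain vector when `E` is scalar.
#' @export
predict_category_probs <- function(fit, E) {
  stopifnot(inherits(fit, "clm_fit"))
  if (anyNA(E) || any(E != round(E)) || any(E < 0 | E > 8)) {
    stop("expected score must be an integer in 0-8", call. = FALSE)
  }
  cum <- vapply(fit$thresholds, function(th) stats::plogis(th - fit$beta * E),
                numeric(length(E)))
  cum <- matrix(cum, nrow = length(E))
  probs <- cbind(cum, 1) - cbind(0, cum)
  colnames(probs) <- paste0("T", 1:5)
  if (length(E) == 1L) probs[1L, ] else probs
}
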