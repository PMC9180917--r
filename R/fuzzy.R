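# Fuzzy c-means (Bezdek) on the two-axis governance plane, used to see how
# countries group relative to the four stylised scenarios.

.fcm_dist2 <- function(x, centers) {
  # squared Euclidean distances, n x c
  n <- nrow(x); cc <- nrow(centers)
  d2 <- matrix(0, n, cc)
  for (j in seq_len(cc)) {
    d2[, j] <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
  }
  d2
}

.fcm_memberships <- function(d2, m) {
  n <- nrow(d2)
  u <- matrix(0, n, ncol(d2))
  zero <- d2 < 1e-12
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    # point coincides with >= 1 center: crisp membership split over those
    u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  if (any(!hit)) {
    inv <- d2[!hit, , drop = FALSE]^(-1 / (m - 1))
    u[!hit, ] <- inv / rowSums(inv)
  }
  u
}

.fcm_once <- function(x, c, m, tol, max_iter) {
  n <- nrow(x)
  u <- matrix(stats::rgamma(n * c, shape = 1), n, c)
  u <- u / rowSums(u)
  trace <- numeric(0)
  centers <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    um <- u^m
    centers <- crossprod(um, x) / colSums(um)
    d2 <- .fcm_dist2(x, centers)
    u_new <- .fcm_memberships(d2, m)
    trace[iter] <- sum(u_new^m * d2)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) { converged <- TRUE; break }
  }
  J <- sum(u^m * .fcm_dist2(x, centers))
  list(centers = centers, u = u, J = J, trace = trace,
       iterations = iter, converged = converged)
}

#' Fuzzy c-means clustering
#'
#' Bezdek's alternating optimization of `J = sum_ij u_ij^m ||x_i - c_j||^2`:
#' memberships `u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1))`, centers as the
#' u^m-weighted means, iterated until the largest membership change drops
#' below `tol`. A point coinciding with a center receives crisp membership
#' there. Initialization is seeded random memberships; with `nstart > 1` the
#' restart with the lowest objective is returned.
#'
#' @param points numeric matrix (n x d), typically the min-max normalized
#'   (rule of law, trade barrier) coordinates from [normalize_unit()].
#' @param c number of clusters, `2 <= c <= n`.
#' @param m fuzzifier, > 1 (conventional default 2).
#' @param tol convergence tolerance on memberships.
#' @param max_iter iteration cap per restart.
#' @param seed integer seed (NULL leaves the RNG state alone).
#' @param nstart number of seeded random restarts.
#' @return an `fcm_fit`: `points`, `centers`, `memberships` (rows sum to 1),
#'   `m`, `J`, `trace` (objective per iteration), `iterations`, `converged`.
#' @export
fcm <- function(points, c, m = 2, tol = 1e-6, max_iter = 300L, seed = NULL,
                nstart = 1L) {
  x <- as.matrix(points)
  storage.mode(x) <- "double"
  if (!is_count(c) || c < 2L) stop("need at least 2 clusters", call. = FALSE)
  if (nrow(x) < c) stop("fewer points than clusters", call. = FALSE)
  if (m <= 1) stop("fuzzifier m must exceed 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (s in seq_len(nstart)) {
    run <- .fcm_once(x, c, m, tol, max_iter)
    if (is.null(best) || run$J < best$J) best <- run
  }
  structure(list(points = x, centers = best$centers,
                 memberships = best$u, m = m, J = best$J,
                 trace = best$trace, iterations = best$iterations,
                 converged = best$converged),
            class = "fcm_fit")
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat("Fuzzy c-means fit:", nrow(x$points), "points,", nrow(x$centers),
      "clusters, m =", x$m, "\n")
  cat(sprintf("  objective J = %.6g after %d iteration(s)%s\n", x$J,
              x$iterations, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Choose the number of clusters by the fuzzy partition coefficient
#'
#' Runs [fcm()] for each candidate count and returns the one maximizing the
#' partition coefficient `(1/n) sum_ij u_ij^2` (1 = crisp partition, 1/c =
#' fully fuzzy); ties go to the smaller count. This is a quantitative
#' stand-in for judging "well-defined" clusters by eye.
#'
#' @param points as in [fcm()].
#' @param candidates integer candidate cluster counts, all within
#'   `[2, n - 1]`.
#' @param m fuzzifier.
#' @param seed integer seed.
#' @param nstart restarts per candidate.
#' @return the selected count (integer), with the per-candidate coefficients
#'   in attribute `partition_coefficients`.
#' @export
select_cluster_count <- function(points, candidates = 2:5, m = 2, seed = 1L,
                                 nstart = 5L) {
  if (length(candidates) == 0L) stop("no candidate cluster counts", call. = FALSE)
  n <- nrow(as.matrix(points))
  if (any(candidates < 2L | candidates > n - 1L)) {
    stop("candidates must lie in [2, n - 1]", call. = FALSE)
  }
  candidates <- sort(unique(as.integer(candidates)))
  fpc <- vapply(candidates, function(cc) {
    fit <- fcm(points, cc, m = m, seed = seed + cc, nstart = nstart)
    mean(rowSums(fit$memberships^2))
  }, numeric(1))
  names(fpc) <- candidates
  structure(candidates[which.max(fpc)], partition_coefficients = fpc)
}

#' Label cluster centers by scenario quadrant
#'
#' Maps each center of the unit-square governance plane (column 1 = rule of
#' law, column 2 = trade barriers; 1 = strongest) to the stylised scenario
#' whose corner it occupies, splitting each axis at 0.5: both strong = A,
#' strong barriers / weak law = B, weak barriers / strong law = C, both weak
#' = D. Boundary values (exactly 0.5) count as strong, so the center of the
#' square labels A.
#'
#' @param centers numeric matrix (c x 2) of normalized centers.
#' @return character vector of labels, one per center.
#' @export
scenario_quadrant_labels <- function(centers) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2L)
  law_strong <- centers[, 1] >= 0.5
  barrier_strong <- centers[, 2] >= 0.5
  ifelse(barrier_strong & law_strong, "A",
         ifelse(barrier_strong & !law_strong, "B",
                ifelse(law_strong, "C", "D")))
}
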