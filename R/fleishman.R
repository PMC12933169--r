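#' Fleishman power-method coefficients for target skewness and kurtosis
#'
#' Solves for the cubic-polynomial coefficients of the Fleishman power
#' method: if \eqn{X} is standard normal, then
#' \eqn{Y = a + bX + cX^2 + dX^3} has zero mean, unit variance, and the
#' requested third and fourth standardized moments. The zero-mean
#' constraint forces \eqn{a = -c}; the remaining three coefficients are
#' found by damped Newton iteration on the classical moment equations,
#' restarted from several initial points.
#'
#' Kurtosis uses the Pearson (non-excess) convention, so a normal
#' distribution has kurtosis 3 and the identity transform is returned for
#' `(skewness, kurtosis) = (0, 3)`. Not every moment pair is reachable by
#' a cubic transform of a normal variate: the feasible region requires
#' kurtosis above roughly 1.85 at zero skewness and rises with
#' skewness^2; an infeasible pair raises an error naming the pair (see
#' [fleishman_feasible()]).
#'
#' @param skewness Target third standardized moment.
#' @param kurtosis Target fourth standardized moment (Pearson; normal = 3).
#' @param tol Convergence tolerance on the moment residuals.
#' @param max_iter Maximum Newton iterations per start.
#' @return A named numeric vector `c(a, b, c, d)` whose analytic moments
#'   match the targets to within `tol`.
#' @seealso [fleishman_moments()] for the analytic inverse direction.
#' @examples
#' fleishman_coefficients(0, 3)      # identity: c(0, 1, 0, 0)
#' fleishman_coefficients(1.28, 5.34)
#' @export
fleishman_coefficients <- function(skewness, kurtosis, tol = 1e-10,
                                   max_iter = 200L) {
  stopifnot(is.numeric(skewness), length(skewness) == 1L, is.finite(skewness),
            is.numeric(kurtosis), length(kurtosis) == 1L, is.finite(kurtosis))
  if (kurtosis <= skewness^2 + 1) {
    stop(sprintf(paste("no distribution has skewness %.4g with kurtosis %.4g:",
                       "kurtosis must exceed skewness^2 + 1"),
                 skewness, kurtosis), call. = FALSE)
  }
  g1 <- skewness
  g2 <- kurtosis - 3  # excess kurtosis, as in the original moment equations

  if (abs(g1) < 1e-14 && abs(g2) < 1e-14) {
    return(c(a = 0, b = 1, c = 0, d = 0))
  }

  sgn <- if (g1 >= 0) 1 else -1
  starts <- list(c(1, g1 / 6, g2 / 48),
                 c(1.2, g1 / 6, -0.12),
                 c(0.9, sgn * 0.15, 0.05),
                 c(1.35, g1 / 5, -0.16),
                 c(0.8, sgn * 0.3, 0.1))
  best <- NULL
  for (s in starts) {
    r <- .fleishman_newton(s, g1, g2, tol, max_iter)
    if (is.null(best) || r$res < best$res) best <- r
    if (best$res < tol) break
  }
  if (best$res >= 1e-8) {
    stop(sprintf(paste("Fleishman solver did not converge for skewness %.4g,",
                       "kurtosis %.4g (max residual %.3g): the moment pair is",
                       "outside the feasible region of the cubic transform"),
                 skewness, kurtosis, best$res), call. = FALSE)
  }
  p <- best$p
  c(a = -p[2], b = p[1], c = p[2], d = p[3])
}

.fleishman_resid <- function(p, g1, g2) {
  b <- p[1]; cc <- p[2]; d <- p[3]
  c(b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2 - 1,
    2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2) - g1,
    24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
            d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2)) - g2)
}

# damped Newton with numerical Jacobian and halving line search
.fleishman_newton <- function(p, g1, g2, tol, max_iter) {
  for (it in seq_len(max_iter)) {
    r <- .fleishman_resid(p, g1, g2)
    if (!all(is.finite(r))) break
    if (max(abs(r)) < tol) break
    J <- matrix(0, 3, 3)
    h <- pmax(abs(p), 1) * 1e-7
    for (j in 1:3) {
      pp <- p; pm <- p
      pp[j] <- pp[j] + h[j]; pm[j] <- pm[j] - h[j]
      J[, j] <- (.fleishman_resid(pp, g1, g2) -
                   .fleishman_resid(pm, g1, g2)) / (2 * h[j])
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    lam <- 1
    while (lam > 1e-10 &&
           sum(.fleishman_resid(p - lam * step, g1, g2)^2) >= sum(r^2)) {
      lam <- lam / 2
    }
    if (lam <= 1e-10) break
    p <- p - lam * step
  }
  list(p = p, res = max(abs(.fleishman_resid(p, g1, g2))))
}

#' Is a (skewness, kurtosis) pair reachable by the cubic transform?
#'
#' @param skewness,kurtosis Target standardized moments (Pearson
#'   kurtosis).
#' @return `TRUE` if [fleishman_coefficients()] can solve the pair.
#' @export
fleishman_feasible <- function(skewness, kurtosis) {
  !inherits(tryCatch(fleishman_coefficients(skewness, kurtosis),
                     error = function(e) e), "error")
}

#' Smallest kurtosis the cubic transform can reach at a given skewness
#'
#' Located by bisection on solver feasibility; useful for clamping
#' slightly infeasible empirical targets (light-tailed distributions sit
#' below the cubic transform's reach).
#'
#' @param skewness Target skewness.
#' @param precision Bisection precision on the kurtosis axis.
#' @return Minimal feasible Pearson kurtosis (slightly conservative:
#'   guaranteed feasible).
#' @export
fleishman_min_kurtosis <- function(skewness, precision = 1e-3) {
  lo <- skewness^2 + 1 + 1e-6
  hi <- skewness^2 + 4
  stopifnot(fleishman_feasible(skewness, hi))
  while (hi - lo > precision) {
    mid <- (lo + hi) / 2
    if (fleishman_feasible(skewness, mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Analytic moments of a Fleishman cubic transform
#'
#' Given coefficients `(a, b, c, d)` applied to a standard normal variate,
#' returns the analytic mean, variance, skewness and (Pearson) kurtosis of
#' the transformed variate. Used to verify solved coefficients without
#' Monte-Carlo error.
#'
#' @param coef Named or positional numeric vector `(a, b, c, d)`.
#' @return Named numeric vector `c(mean, variance, skewness, kurtosis)`.
#' @export
fleishman_moments <- function(coef) {
  stopifnot(is.numeric(coef), length(coef) == 4L)
  coef <- unname(coef)
  a <- coef[1]; b <- coef[2]; cc <- coef[3]; d <- coef[4]
  m <- a + cc
  v <- b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2
  g1 <- 2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2) / v^1.5
  g2 <- 24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
                d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2)) / v^2
  c(mean = m, variance = v, skewness = g1, kurtosis = g2 + 3)
}
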