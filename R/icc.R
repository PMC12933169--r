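#' One-way random-effects intraclass correlation for paired measurements
#'
#' The one-way random-effects ANOVA estimator for k = 2 measurements per
#' subject: with between- and within-subject mean squares
#' \deqn{MSB = 2 \sum_i (\bar y_i - \bar y)^2 / (m - 1), \quad
#'       MSW = \sum_i (y_{i1} - \bar y_i)^2 + (y_{i2} - \bar y_i)^2) / m,}
#' the ICC is \eqn{(MSB - MSW) / (MSB + MSW)}. It can be negative when
#' within-pair disagreement exceeds between-subject spread, and never
#' exceeds 1.
#'
#' @param a,b Numeric vectors: the two measurements per subject (here, a
#'   subsample mean and the full-period mean).
#' @return The ICC, a single number in (-1, 1].
#' @export
icc_oneway <- function(a, b) {
  stopifnot(length(a) == length(b), all(is.finite(a)), all(is.finite(b)))
  m <- length(a)
  if (m < 3L) stop("at least 3 subjects are required", call. = FALSE)
  pair_mean <- (a + b) / 2
  msb <- 2 * sum((pair_mean - mean(pair_mean))^2) / (m - 1)
  msw <- sum((a - b)^2) / (2 * m)
  if (msb + msw == 0)
    stop("zero total variance: ICC undefined", call. = FALSE)
  (msb - msw) / (msb + msw)
}

#' Per-subject means of random day subsets
#'
#' For each subject independently, draws `n` distinct days uniformly
#' without replacement from that subject's full period and averages them;
#' repeated for `n_combos` independent combinations. Distinct combinations
#' are not deduplicated (for `n` near 1 or N-1 fewer than `n_combos`
#' distinct subsets exist, so repeats are expected).
#'
#' @param day_matrix Numeric matrix, subjects x days (N columns).
#' @param n Subset size, `1 <= n <= N`.
#' @param n_combos Number of random combinations (columns of the result).
#' @return `m x n_combos` matrix of subsample means.
#' @export
subsample_means <- function(day_matrix, n, n_combos = 1L) {
  day_matrix <- as.matrix(day_matrix)
  N <- ncol(day_matrix)
  if (n < 1 || n > N) stop("subset size n must be in 1..N", call. = FALSE)
  .subsample_means_cpp(day_matrix, as.integer(n), as.integer(n_combos))
}

#' Distribution of ICCs over random day combinations
#'
#' For one subset size `n`, draws `n_combos` random day combinations (per
#' subject, without replacement), and for each combination computes the
#' one-way ICC between the per-subject subsample means and the per-subject
#' full-period means. Combinations with zero total variance yield an
#' undefined ICC; these are returned as `NA` and counted in the
#' `n_undefined` attribute rather than silently dropped.
#'
#' @param day_matrix Subjects x days matrix of step counts (full period).
#' @param n Subset size, `1 <= n <= N - 1`.
#' @param n_combos Number of random combinations.
#' @return Numeric vector of `n_combos` ICC values (possibly `NA`), with
#'   attribute `n_undefined`.
#' @export
icc_distribution <- function(day_matrix, n, n_combos = 500L) {
  day_matrix <- as.matrix(day_matrix)
  m <- nrow(day_matrix); N <- ncol(day_matrix)
  if (m < 3L) stop("at least 3 subjects are required", call. = FALSE)
  if (n < 1 || n > N - 1)
    stop("subset size n must be in 1..N-1", call. = FALSE)
  full <- rowMeans(day_matrix)
  S <- subsample_means(day_matrix, n, n_combos)
  # vectorized one-way ANOVA across combinations (k = 2 per subject)
  pm <- (S + full) / 2
  msb <- 2 * colSums((pm - matrix(colMeans(pm), m, n_combos,
                                  byrow = TRUE))^2) / (m - 1)
  msw <- colSums((S - full)^2) / (2 * m)
  tot <- msb + msw
  icc <- ifelse(tot == 0, NA_real_, (msb - msw) / tot)
  n_undef <- sum(tot == 0)
  if (n_undef > 0)
    message(n_undef, " of ", n_combos,
            " combinations had zero total variance (ICC undefined)")
  attr(icc, "n_undefined") <- n_undef
  icc
}

#' Reliability curve over all subset sizes
#'
#' Runs [icc_distribution()] for every subset size `n = 1..N-1` and
#' summarizes each distribution by its mean, SD and minimum. A
#' deterministic child seed is derived from `seed` for each subset size,
#' so any single row is reproducible in isolation.
#'
#' @param day_matrix Subjects x days matrix for one cluster.
#' @param n_combos Combinations per subset size.
#' @param seed Optional master seed for this curve.
#' @param keep_distributions Keep the full ICC vectors (in attribute
#'   `"distributions"`)?
#' @return Object of class `icc_curve`: data frame `n, mean_icc, sd_icc,
#'   min_icc, n_undefined` with attributes `N` (full period length) and
#'   `m` (subjects).
#' @export
icc_curve <- function(day_matrix, n_combos = 500L, seed = NULL,
                      keep_distributions = FALSE) {
  day_matrix <- as.matrix(day_matrix)
  N <- ncol(day_matrix)
  dists <- vector("list", N - 1L)
  rows <- vector("list", N - 1L)
  for (n in seq_len(N - 1L)) {
    if (!is.null(seed)) set.seed(derive_seed(seed, n))
    icc <- icc_distribution(day_matrix, n, n_combos)
    ok <- icc[!is.na(icc)]
    rows[[n]] <- data.frame(n = n, mean_icc = mean(ok),
                            sd_icc = stats::sd(ok), min_icc = min(ok),
                            n_undefined = attr(icc, "n_undefined"))
    if (keep_distributions) dists[[n]] <- icc
  }
  out <- do.call(rbind, rows)
  class(out) <- c("icc_curve", "data.frame")
  attr(out, "N") <- N
  attr(out, "m") <- nrow(day_matrix)
  if (keep_distributions) attr(out, "distributions") <- dists
  out
}

#' Minimum number of monitoring days for acceptable reliability
#'
#' First subset size at which the curve reaches the reliability
#' threshold: under rule `"mean"` the mean of the combination ICCs must
#' reach it, under rule `"all"` every combination (the distribution
#' minimum) must. First-crossing semantics: the curve is scanned from
#' n = 1 upward and monotonicity is not assumed (a non-monotone curve
#' triggers a message).
#'
#' @param curve An [icc_curve()].
#' @param rule `"mean"` or `"all"`.
#' @param threshold Reliability threshold (default 0.80; reaching it
#'   exactly qualifies).
#' @return Smallest qualifying `n`, or `NA_integer_` when no subset size
#'   up to N-1 qualifies.
#' @export
min_days <- function(curve, rule = c("mean", "all"), threshold = 0.80) {
  rule <- match.arg(rule)
  v <- if (rule == "mean") curve$mean_icc else curve$min_icc
  if (is.unsorted(v))
    message("ICC curve is not monotone in n; using first crossing")
  hit <- which(v >= threshold)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(curve$n[hit[1L]])
}

#' Expected subsample-vs-full-period ICC under the two-component model
#'
#' Large-sample expectation of the one-way ICC between the n-day subsample
#' mean A and the N-day full-period mean B of the same subject, under the
#' exchangeable two-component model with day-to-day variance
#' \eqn{\sigma_w^2}. Because the subsample's n days are a subset of the N,
#' the within-pair variance is
#' \eqn{E[(A - B)^2]/2 = \sigma_w^2 (1/n - 1/N)/2}, while the shared
#' component of the pair is the subject's full-period mean itself, whose
#' between-subject variance is \eqn{\sigma_b^2}. Hence
#' \deqn{ICC(n) = \frac{\sigma_b^2}
#'   {\sigma_b^2 + \sigma_w^2\,(1/n - 1/N)/2}.}
#' At `n = N` the subsample is the full period and the ICC is exactly 1.
#'
#' `sigma_b2` is the between-subject variance of *observed* full-period
#' mean step counts — the quantity a cluster-profile table reports as the
#' SD of subjects' mean steps, and equal to `Cov(A, B)`. For a
#' hierarchical generator with latent true means of variance
#' \eqn{\tau^2} and independent days, the observed full-period means have
#' variance \eqn{\tau^2 + \sigma_w^2 / N}, which is the value to pass
#' here.
#'
#' @param n Subset size, `1 <= n <= N`.
#' @param N Full period length.
#' @param sigma_b2 Between-subject variance of subjects' full-period mean
#'   step counts, (steps/day)^2.
#' @param sigma_w2 Within-subject day-to-day variance, (steps/day)^2.
#' @return Expected ICC.
#' @export
expected_icc <- function(n, N, sigma_b2, sigma_w2) {
  stopifnot(all(n >= 1), all(n <= N), sigma_b2 >= 0, sigma_w2 >= 0,
            sigma_b2 + sigma_w2 > 0)
  sigma_b2 / (sigma_b2 + sigma_w2 * (1 / n - 1 / N) / 2)
}
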