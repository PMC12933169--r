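test_that("one-way ICC matches hand-computed ANOVA cases", {
  # perfect agreement: MSW = 0
  expect_equal(icc_oneway(c(1, 2, 3), c(1, 2, 3)), 1)
  # worked example: pair means (1.5, 3.5, 5.5) -> MSB = 8, MSW = 0.5
  expect_equal(icc_oneway(c(1, 3, 5), c(2, 4, 6)), 7.5 / 8.5)
  # no between-subject spread, positive within-pair spread: negative ICC
  expect_lt(icc_oneway(c(1, 2, 1), c(2, 1, 2)), 0)

  expect_error(icc_oneway(c(1, 2), c(1, 2)), "3 subjects")
  expect_error(icc_oneway(rep(2, 5), rep(2, 5)), "zero total variance")
})

test_that("subsampled day sets contain n distinct days, uniformly", {
  # dyadic day values: a subsample mean times n is a sum of distinct
  # powers of two iff the drawn indices are distinct
  N <- 9; n <- 4
  y <- matrix(2^(0:(N - 1)), nrow = 5, ncol = N, byrow = TRUE)
  set.seed(12)
  S <- subsample_means(y, n, n_combos = 400)
  sums <- round(S * n)
  expect_true(all(vapply(as.vector(sums), function(s) {
    bits <- which(intToBits(s) == 1)
    length(bits) == n
  }, logical(1))))

  # leave-one-out case: every mean equals one of the N hand-computed
  # leave-one-out means, and all N appear
  days <- c(2, 4, 6, 8, 10, 12, 14)
  loo <- (sum(days) - days) / 6
  set.seed(4)
  S <- subsample_means(matrix(days, 1), 6, n_combos = 300)
  expect_true(all(S %in% loo))
  expect_setequal(round(as.vector(S), 10), round(loo, 10))
  # n = N recovers the full mean exactly
  expect_equal(as.vector(subsample_means(matrix(days, 1), 7, 5)),
               rep(mean(days), 5))

  expect_error(subsample_means(matrix(days, 1), 8), "1..N")
})

test_that("subsample means follow the uniform-subset distribution", {
  # against the plain-R oracle: same marginal mean/SD of subsample means
  set.seed(9)
  y <- matrix(rnorm(30 * 8, 5000, 1500), 30, 8)
  S <- subsample_means(y, 3, n_combos = 4000)
  O <- replicate(4000, oracle_subsample_means(y, 3))
  expect_equal(rowMeans(S), rowMeans(O), tolerance = 0.01)
  expect_equal(apply(S, 1, sd), apply(O, 1, sd), tolerance = 0.1)
})

test_that("ICC distributions are reproducible and flag undefined cases", {
  set.seed(101)
  y <- matrix(rnorm(50 * 7, 6000, 2000), 50, 7) + rnorm(50, 0, 1200)
  set.seed(55); v1 <- icc_distribution(y, 3, 200)
  set.seed(55); v2 <- icc_distribution(y, 3, 200)
  expect_identical(v1, v2)
  expect_length(v1, 200)
  expect_true(all(v1 <= 1))

  flat <- matrix(5000, 10, 7)
  expect_message(vf <- icc_distribution(flat, 2, 50), "zero total variance")
  expect_equal(attr(vf, "n_undefined"), 50)
  expect_true(all(is.na(vf)))
})

test_that("Monte-Carlo mean ICC agrees with the closed form across a grid", {
  # m = 500 subjects, 2000 combos; agreement within 3 Monte-Carlo SEs
  set.seed(404)
  grid <- expand.grid(sb = c(1000, 1540), sw = c(1620, 3070),
                      n = c(1, 2, 5), N = 7)
  grid <- rbind(grid, data.frame(sb = 950, sw = 2270, n = c(4, 9, 20),
                                 N = 28))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    m <- 500
    mu <- rnorm(m, 0, g$sb)
    e <- matrix(rnorm(m * g$N, 0, g$sw), m, g$N)
    y <- mu + (e - rowMeans(e))          # observed-mean anchoring
    icc <- icc_distribution(y, g$n, 2000)
    # closed form at the realized components: var of full-period means and
    # mean per-subject day variance; residual noise is then combo-sampling
    # only, plus an O(1/m) estimator bias allowance
    want <- expected_icc(g$n, g$N, var(rowMeans(y)), mean(apply(y, 1, var)))
    se <- sd(icc) / sqrt(2000)
    expect_equal(mean(icc), want,
                 tolerance = (3 * se + 2 / m) / abs(want))
  }
})

test_that("expected ICC is monotone, bounded and matches hand evaluations", {
  expect_equal(expected_icc(7, 7, 1538^2, 1619^2), 1)
  expect_equal(expected_icc(3, 28, 1000^2, 0), 1)
  expect_equal(expected_icc(2, 7, 1538^2, 1619^2), 0.8348, tolerance = 1e-4)
  expect_equal(expected_icc(1, 7, 1538^2, 1619^2), 0.6780, tolerance = 1e-4)
  curve <- expected_icc(1:28, 28, 950^2, 2270^2)
  expect_false(is.unsorted(curve))
  expect_true(all(curve > 0 & curve <= 1))
})

test_that("reliability curves tighten and improve as n grows", {
  sp <- cluster_spec("t", 5980, 1538, 1619, 685, n_subjects = 1)
  set.seed(66)
  y <- simulate_cluster_days(sp, 500, 7)
  cur <- icc_curve(y, n_combos = 500, seed = 13)
  expect_equal(nrow(cur), 6)
  expect_gt(cur$mean_icc[6], cur$mean_icc[1] + 3 *
              (cur$sd_icc[6] + cur$sd_icc[1]) / sqrt(500))
  expect_lt(cur$sd_icc[6], cur$sd_icc[1])
  # child-seed design: the same master seed reproduces the whole curve
  cur2 <- icc_curve(y, n_combos = 500, seed = 13)
  expect_identical(cur, cur2)
})

test_that("minimum-days rules use first-crossing semantics with a sentinel", {
  fake <- structure(
    data.frame(n = 1:6,
               mean_icc = c(0.7, 0.82, 0.81, 0.9, 0.95, 0.97),
               sd_icc = 0.02,
               min_icc = c(0.5, 0.6, 0.7, 0.75, 0.85, 0.9),
               n_undefined = 0L),
    class = c("icc_curve", "data.frame"))
  expect_message(expect_equal(min_days(fake, "mean"), 2), "not monotone")
  expect_equal(min_days(fake, "all"), 5)
  expect_equal(min_days(fake, "mean", threshold = 0.99), NA_integer_)

  always <- fake; always$mean_icc <- seq(0.85, 0.99, length.out = 6)
  expect_equal(min_days(always, "mean"), 1)
})
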