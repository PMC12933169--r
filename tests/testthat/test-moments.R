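test_that("subject moments follow the population-moment conventions", {
  m <- subject_moments(c(1, 2, 3, 4, 5))
  expect_equal(unname(m["mean"]), 3)
  expect_equal(unname(m["sd"]), sd(1:5))          # n-1 denominator
  expect_equal(unname(m["skewness"]), 0)          # symmetric series
  expect_equal(unname(m["kurtosis"]), 1.7)        # m4/m2^2 = 6.8/4

  expect_error(subject_moments(rep(7, 10)), "degenerate")
  expect_error(subject_moments(c(1, 2, 3)), "at least 4")
})

test_that("moment estimators are unbiased enough at scale", {
  set.seed(19)
  z <- rnorm(1e6)
  m <- subject_moments(z)
  expect_equal(unname(m["skewness"]), 0, tolerance = 0.01)
  expect_equal(unname(m["kurtosis"]), 3, tolerance = 0.03 / 3)
})

test_that("standardization centres and scales each moment feature", {
  # closed form for two subjects: each column becomes +-1/sqrt(2)*sqrt(2)
  two <- data.frame(subject_id = c("a", "b"), mean = c(1, 3),
                    sd = c(2, 6), skewness = c(0, 1), kurtosis = c(2, 4))
  z <- standardize_moments(two)
  expect_equal(unname(z[, "mean"]), c(-1, 1) / sqrt(2))
  expect_equal(unname(z[, "sd"]), c(-1, 1) / sqrt(2))

  set.seed(3)
  many <- data.frame(subject_id = paste0("s", 1:40),
                     mean = rnorm(40, 5000, 1000), sd = rnorm(40, 2000, 300),
                     skewness = rnorm(40), kurtosis = rnorm(40, 3, 0.5))
  z <- standardize_moments(many)
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4), tolerance = 1e-12)
  # idempotence: standardizing standardized input changes nothing
  zz <- standardize_moments(data.frame(subject_id = many$subject_id, z))
  expect_equal(unname(zz), unname(z), tolerance = 1e-12)

  const <- many; const$kurtosis <- 3
  expect_error(standardize_moments(const), "kurtosis")
})

test_that("complete linkage separates well-separated clouds and matches a brute-force oracle", {
  set.seed(21)
  x <- rbind(matrix(rnorm(40, 0, 0.3), ncol = 2),
             matrix(rnorm(40, 8, 0.3), ncol = 2))
  rownames(x) <- paste0("s", 1:40)
  truth <- rep(1:2, each = 20)
  asg <- cluster_complete_linkage(x, 2)
  expect_equal(ari(asg$cluster, truth), 1)
  # label-permutation invariance of the recovery metric
  expect_equal(ari(3 - asg$cluster, truth), 1)

  # every subject its own cluster at the full cut
  singl <- cluster_complete_linkage(x, 40)
  expect_equal(sort(unique(singl$cluster)), 1:40)
  expect_error(cluster_complete_linkage(x, 41), "more clusters")

  # six hand-placed points: agreement with first-principles agglomeration
  pts <- matrix(c(0, 0, 0.9, 0.12, 2.3, 0.1, 5, 5, 5.7, 5.2, 9, 1.4),
                ncol = 2, byrow = TRUE)
  rownames(pts) <- letters[1:6]
  for (k in c(2, 3)) {
    got <- cluster_complete_linkage(pts, k)
    want <- oracle_complete_linkage(pts, k)
    expect_equal(ari(got$cluster, want$labels), 1)
  }
  # complete linkage is monotone, so merge heights arrive sorted
  hc <- attr(cluster_complete_linkage(pts, 2), "hclust")
  expect_equal(hc$height, oracle_complete_linkage(pts, 1)$heights)
})

test_that("small clusters are pruned and survivors relabelled by size", {
  asg <- data.frame(
    subject_id = paste0("s", 1:135),
    cluster = rep(c(1, 2, 3, 4, 5), times = c(36, 22, 42, 30, 5)))
  pr <- prune_clusters(asg, 12)
  expect_equal(sum(!pr$retained), 5)
  expect_true(all(is.na(pr$cluster[!pr$retained])))
  sizes <- table(pr$cluster)
  expect_equal(unname(as.integer(sizes)), c(42, 36, 30, 22))  # size order
  expect_equal(length(sizes), 4)

  ok <- data.frame(subject_id = paste0("s", 1:30),
                   cluster = rep(1:2, each = 15))
  expect_true(all(prune_clusters(ok)$retained))
  both_small <- data.frame(subject_id = paste0("s", 1:22),
                           cluster = rep(1:2, each = 11))
  expect_error(prune_clusters(both_small), "minimum size")
})

test_that("cluster moment summaries recover the generating profiles", {
  # group generated subjects by their true labels: the per-cluster mean of
  # each moment feature must sit near the generating profile (the clusters
  # themselves overlap, so label recovery is not assessed here)
  set.seed(77)
  specs <- short_term_profiles()
  days <- lapply(specs, function(s) {
    suppressWarnings(simulate_cluster_days(s, 200, 28, anchor = "latent"))
  })
  mom <- do.call(rbind, lapply(days, function(d) {
    t(apply(d, 1, subject_moments))
  }))
  df <- data.frame(subject_id = paste0("s", seq_len(nrow(mom))), mom)
  asg <- data.frame(subject_id = df$subject_id,
                    cluster = rep(1:4, each = 200), retained = TRUE)
  summ <- cluster_summary(df, asg)
  for (i in 1:4) {
    expect_equal(summ$mean_mean[i], specs[[i]]$mean_of_means,
                 tolerance = 0.05)
    expect_equal(summ$sd_mean[i], specs[[i]]$mean_within_sd,
                 tolerance = 0.08)
  }
  # day-level skewness transfers in rank (28-day moment estimates are
  # attenuated toward zero, so absolute recovery is not expected)
  expect_gt(summ$skewness_mean[1], summ$skewness_mean[3])
  expect_gt(summ$skewness_mean[1], 0.7)
})
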