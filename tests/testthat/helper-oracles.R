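# Independent brute-force oracles used to cross-check the implementation.

# Adjusted Rand index from the contingency table.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# Pairwise-gap scan over sorted activity timestamps.
oracle_nonwear <- function(stream, gap_threshold = 60) {
  ts <- sort(stream$timestamp[stream$record_type == "activity"])
  out <- list()
  for (i in seq_len(length(ts) - 1)) {
    gap <- as.numeric(ts[i + 1] - ts[i], units = "mins")
    if (gap > gap_threshold)
      out[[length(out) + 1]] <- c(start = as.numeric(ts[i]),
                                  end = as.numeric(ts[i + 1]))
  }
  do.call(rbind, out)
}

# Exhaustive search over every subset of valid days: smallest number of
# skipped (invalid) calendar days straddled by any period_length-subset
# whose span fits the window; NA when none exists.
oracle_min_skip <- function(dates, valid, period_length, window_length) {
  vd <- sort(dates[valid])
  if (length(vd) < period_length) return(NA_integer_)
  best <- NA_integer_
  sets <- utils::combn(seq_along(vd), period_length)
  for (j in seq_len(ncol(sets))) {
    days <- vd[sets[, j]]
    span <- as.integer(max(days) - min(days)) + 1L
    if (span <= window_length) {
      skip <- span - period_length
      if (is.na(best) || skip < best) best <- skip
    }
  }
  best
}

# Greedy complete-linkage agglomeration from first principles: merge the
# pair of groups with the smallest maximum inter-point distance.
oracle_complete_linkage <- function(x, k) {
  groups <- as.list(seq_len(nrow(x)))
  D <- as.matrix(dist(x))
  heights <- numeric(0)
  while (length(groups) > k) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(groups)) {
      for (j in seq_len(i - 1)) {
        d <- max(D[groups[[i]], groups[[j]]])
        if (d < bestd) { bestd <- d; best <- c(j, i) }
      }
    }
    heights <- c(heights, bestd)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  lab <- integer(nrow(x))
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  list(labels = lab, heights = heights)
}

# Plain-R subset-mean resampling (single combination per call).
oracle_subsample_means <- function(day_matrix, n) {
  apply(day_matrix, 1, function(r) mean(sample(r, n)))
}

# Build a hand-specified single-subject stream: activity records at the
# given times (character "HH:MM" on the given dates) plus sleep
# annotations.
make_stream <- function(subject_id, activity, sleep_offset, sleep_onset) {
  ts <- function(x) as.POSIXct(x, tz = "UTC")
  rbind(
    data.frame(subject_id = subject_id, timestamp = ts(activity),
               record_type = "activity", value = 1),
    data.frame(subject_id = subject_id, timestamp = ts(sleep_offset),
               record_type = "sleep_offset", value = NA_real_),
    data.frame(subject_id = subject_id, timestamp = ts(sleep_onset),
               record_type = "sleep_onset", value = NA_real_)
  )
}
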