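test_that("nonwear detection uses a strict 60-minute threshold", {
  # records every 30 min: never nonwear
  s <- make_stream("a", sprintf("2024-01-01 %02d:%02d:00",
                                rep(8:19, each = 2), c(0, 30)),
                   "2024-01-01 07:30:00", "2024-01-01 22:00:00")
  expect_equal(nrow(detect_nonwear(s)), 0)

  # a gap of exactly 60 minutes is still wear
  s60 <- make_stream("a", c("2024-01-01 09:00:00", "2024-01-01 10:00:00"),
                     "2024-01-01 07:00:00", "2024-01-01 22:00:00")
  expect_equal(nrow(detect_nonwear(s60)), 0)

  # 150-minute gap: one interval with the right endpoints
  s150 <- make_stream("a", c("2024-01-01 09:00:00", "2024-01-01 11:30:00"),
                      "2024-01-01 07:00:00", "2024-01-01 22:00:00")
  nw <- detect_nonwear(s150)
  expect_equal(nrow(nw), 1)
  expect_equal(nw$minutes, 150)
  expect_equal(format(nw$start, "%H:%M", tz = "UTC"), "09:00")
  expect_equal(format(nw$end, "%H:%M", tz = "UTC"), "11:30")
})

test_that("nonwear detection matches a brute-force pairwise scan", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:20, 1)
    times <- as.POSIXct("2024-01-01 06:00:00", tz = "UTC") +
      sort(sample(0:(18 * 60), n)) * 60
    s <- data.frame(subject_id = "a", timestamp = times,
                    record_type = "activity", value = 1)
    got <- detect_nonwear(s)
    want <- oracle_nonwear(s)
    expect_equal(nrow(got), NROW(want))
    if (NROW(want) > 0) {
      expect_equal(as.numeric(got$start), unname(want[, "start"]))
      expect_equal(as.numeric(got$end), unname(want[, "end"]))
    }
  }
})

test_that("waking wear time subtracts nonwear overlap and assigns dates", {
  # 16-hour wake span, no nonwear: 16 h of wear, valid
  act <- sprintf("2024-01-01 %02d:00:00", 6:22)
  s <- make_stream("a", act, "2024-01-01 06:00:00", "2024-01-01 22:00:00")
  w <- flag_valid_days(wake_wear_time(s, detect_nonwear(s)))
  expect_equal(nrow(w), 1)
  expect_equal(w$date, as.Date("2024-01-01"))
  expect_equal(w$wear_hours, 16)
  expect_true(w$is_valid)

  # same span with a 7-hour interior gap: 9 h of wear, below the 10-h rule
  act7 <- c("2024-01-01 06:00:00", sprintf("2024-01-01 %02d:00:00", 7:9),
            sprintf("2024-01-01 %02d:00:00", 16:22))
  s7 <- make_stream("a", act7, "2024-01-01 06:00:00", "2024-01-01 22:00:00")
  w7 <- flag_valid_days(wake_wear_time(s7, detect_nonwear(s7)))
  expect_equal(w7$wear_hours, 9)
  expect_false(w7$is_valid)

  # wear of exactly 10.0 h is valid (the rule excludes "less than 10")
  w10 <- data.frame(subject_id = "a", date = as.Date("2024-01-01"),
                    wake_hours = 16, nonwear_hours = 6, wear_hours = 10)
  expect_true(flag_valid_days(w10)$is_valid)
  expect_identical(flag_valid_days(flag_valid_days(w10)),
                   flag_valid_days(w10))
})

test_that("a nonwear interval straddling sleep onset counts only before it", {
  # activity stops at 20:00; sleep begins 22:00; next morning record 07:30.
  # detected gap 20:00 -> 07:30 overlaps the wake span only until 22:00.
  act <- c(sprintf("2024-01-01 %02d:00:00", 7:20),
           sprintf("2024-01-02 %02d:30:00", 7:21))
  s <- make_stream("a", act,
                   c("2024-01-01 07:00:00", "2024-01-02 07:30:00"),
                   c("2024-01-01 22:00:00", "2024-01-02 21:30:00"))
  nw <- detect_nonwear(s)
  w <- wake_wear_time(s, nw)
  # day 1: wake 07:00-22:00 = 15 h; in-span nonwear 20:00-22:00 = 2 h
  d1 <- w[w$date == as.Date("2024-01-01"), ]
  expect_equal(d1$wake_hours, 15)
  expect_equal(d1$nonwear_hours, 2)
  expect_equal(d1$wear_hours, 13)
  # conservation on every assessable day, to within one second
  expect_true(all(abs(w$wake_hours - w$nonwear_hours - w$wear_hours)
                  < 1 / 3600))
})

test_that("validation recovers the stream generator's ground truth", {
  set.seed(17)
  gs <- generate_wear_stream("s1", n_days = 20,
                             wear_spec(record_interval = 15,
                                       nonwear_gap_rate = 1.2,
                                       gap_mean_min = 150, gap_sd_min = 60))
  v <- validate_wear(gs$stream)
  m <- merge(v, gs$truth, by = c("subject_id", "date"))
  expect_equal(nrow(m), 20)
  expect_equal(m$wear_hours.x, m$wear_hours.y, tolerance = 1e-8)
  expect_equal(m$wake_hours.x, m$wake_hours.y, tolerance = 1e-8)
  expect_identical(m$is_valid, m$wear_hours.y >= 10)
})

test_that("zero injected gaps yield wear equal to the full wake span", {
  set.seed(2)
  gs <- generate_wear_stream("s1", n_days = 5,
                             wear_spec(nonwear_gap_rate = 0))
  v <- validate_wear(gs$stream)
  expect_equal(v$wear_hours, v$wake_hours)
  expect_equal(v$wear_hours, gs$truth$wear_hours, tolerance = 1e-8)
})
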