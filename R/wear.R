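#' Specify the simulated wear behaviour of a device stream
#'
#' Controls the synthetic timestamped stream: activity records are emitted
#' on a regular grid during waking hours, sleep onset/offset annotations
#' bracket each night, and nonwear episodes are injected as runs of missing
#' records. Gap durations are snapped to the record grid so the
#' generator's ground truth is exact.
#'
#' @param record_interval Minutes between consecutive activity records;
#'   must be below 60 so worn periods are distinguishable from the
#'   60-minute nonwear threshold.
#' @param nonwear_gap_rate Expected number of injected nonwear gaps per day
#'   (Poisson).
#' @param gap_mean_min,gap_sd_min Mean and SD of the gamma-distributed gap
#'   duration, in minutes.
#' @param wake_time,sleep_time Mean clock hour of sleep offset (waking) and
#'   sleep onset.
#' @param clock_sd_hours SD of both clock times, in hours.
#' @return An object of class `wear_spec`.
#' @export
wear_spec <- function(record_interval = 30, nonwear_gap_rate = 0.5,
                      gap_mean_min = 120, gap_sd_min = 60,
                      wake_time = 7, sleep_time = 23, clock_sd_hours = 0.5) {
  stopifnot(record_interval > 0, record_interval < 60,
            nonwear_gap_rate >= 0, gap_mean_min > 0, gap_sd_min > 0,
            wake_time < sleep_time)
  structure(list(record_interval = record_interval,
                 nonwear_gap_rate = nonwear_gap_rate,
                 gap_mean_min = gap_mean_min, gap_sd_min = gap_sd_min,
                 wake_time = wake_time, sleep_time = sleep_time,
                 clock_sd_hours = clock_sd_hours),
            class = "wear_spec")
}

#' Generate a synthetic timestamped device stream
#'
#' Emulates the timestamped activity stream of a wrist device for one
#' subject over `n_days`: activity records every `record_interval` minutes
#' between sleep offset and sleep onset, sleep annotations for each night,
#' and injected nonwear gaps (runs of deleted records). The returned
#' ground truth records, per day, the wake span and the wear time that an
#' exact nonwear detector (gap threshold 60 minutes) should recover.
#'
#' @param subject_id Subject identifier.
#' @param n_days Number of calendar days.
#' @param wear A [wear_spec()].
#' @param start_date First calendar date.
#' @return List with `stream` (data frame `subject_id, timestamp,
#'   record_type, value`) and `truth` (data frame `subject_id, date,
#'   wake_hours, wear_hours`).
#' @export
generate_wear_stream <- function(subject_id, n_days, wear = wear_spec(),
                                 start_date = as.Date("2024-01-01")) {
  stopifnot(inherits(wear, "wear_spec"), n_days >= 1)
  start_date <- as.Date(start_date)
  ivl <- wear$record_interval
  rec_list <- list()
  truth <- data.frame(subject_id = character(), date = as.Date(character()),
                      wake_hours = numeric(), wear_hours = numeric())
  for (d in seq_len(n_days)) {
    day0 <- as.POSIXct(paste(start_date + d - 1L, "00:00:00"), tz = "UTC")
    off <- day0 + 3600 * stats::rnorm(1, wear$wake_time, wear$clock_sd_hours)
    on  <- day0 + 3600 * stats::rnorm(1, wear$sleep_time, wear$clock_sd_hours)
    # snap wake span to the record grid
    grid <- seq(from = off, to = on, by = ivl * 60)
    on <- grid[length(grid)]
    keep <- rep(TRUE, length(grid))
    n_gaps <- stats::rpois(1, wear$nonwear_gap_rate)
    gap_min <- 0
    if (n_gaps > 0 && length(grid) > 4) {
      for (g in seq_len(n_gaps)) {
        dur <- stats::rgamma(1, shape = (wear$gap_mean_min / wear$gap_sd_min)^2,
                             scale = wear$gap_sd_min^2 / wear$gap_mean_min)
        k <- max(1L, round(dur / ivl) - 1L)       # records to delete
        k <- min(k, length(grid) - 4L)
        s <- sample(2:(length(grid) - k), 1L)     # keep both endpoints worn
        keep[s:(s + k - 1L)] <- FALSE
      }
      # realized maximal gaps between surviving records
      surv <- grid[keep]
      gaps <- as.numeric(diff(surv), units = "mins")
      gap_min <- sum(gaps[gaps > 60])
    }
    wake_h <- as.numeric(on - off, units = "hours")
    rec_list[[length(rec_list) + 1L]] <- data.frame(
      subject_id = subject_id,
      timestamp = c(off, grid[keep], on),
      record_type = c("sleep_offset", rep("activity", sum(keep)),
                      "sleep_onset"),
      value = c(NA_real_, round(stats::runif(sum(keep), 0, 50)), NA_real_),
      stringsAsFactors = FALSE)
    truth <- rbind(truth, data.frame(
      subject_id = subject_id, date = start_date + d - 1L,
      wake_hours = wake_h, wear_hours = wake_h - gap_min / 60))
  }
  stream <- do.call(rbind, rec_list)
  stream <- stream[order(stream$timestamp), ]
  rownames(stream) <- NULL
  list(stream = stream, truth = truth)
}

#' Detect nonwear intervals in a timestamped stream
#'
#' A nonwear interval is a maximal gap between consecutive activity
#' records whose duration strictly exceeds `gap_threshold` minutes; a gap
#' of exactly the threshold is still wear. Sleep annotations are ignored
#' here — intersection with waking hours happens in [wake_wear_time()].
#'
#' @param stream Data frame `subject_id, timestamp, record_type, value`
#'   for a single subject.
#' @param gap_threshold Minutes; gaps strictly longer are nonwear.
#' @return Data frame `start, end, minutes`, disjoint and ordered; zero
#'   rows if none.
#' @export
detect_nonwear <- function(stream, gap_threshold = 60) {
  act <- stream[stream$record_type == "activity", , drop = FALSE]
  if (nrow(act) == 0L) {
    warning("stream contains no activity records; no nonwear detectable")
    return(data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      minutes = numeric()))
  }
  ts <- sort(act$timestamp)
  gaps <- as.numeric(diff(ts), units = "mins")
  hit <- which(gaps > gap_threshold)
  data.frame(start = ts[hit], end = ts[hit + 1L], minutes = gaps[hit])
}

#' Wear time during waking hours
#'
#' Pairs each sleep offset with the next sleep onset to form wake spans,
#' subtracts the overlap of detected nonwear intervals from each span, and
#' assigns each span to the calendar date of its sleep offset. Partial
#' spans before the first sleep offset or after the last sleep onset are
#' discarded; a wake span whose bracketing annotations are missing is
#' dropped with a message rather than passed through as valid.
#'
#' @param stream Single-subject stream as in [detect_nonwear()].
#' @param nonwear Output of [detect_nonwear()] for the same stream.
#' @return Data frame `subject_id, date, wake_hours, nonwear_hours,
#'   wear_hours`, one row per assessable wake span.
#' @export
wake_wear_time <- function(stream, nonwear) {
  sl <- stream[stream$record_type %in% c("sleep_offset", "sleep_onset"), ,
               drop = FALSE]
  sl <- sl[order(sl$timestamp), ]
  offs <- sl$timestamp[sl$record_type == "sleep_offset"]
  ons  <- sl$timestamp[sl$record_type == "sleep_onset"]
  out <- list()
  for (i in seq_along(offs)) {
    nxt <- ons[ons > offs[i]]
    if (length(nxt) == 0L) next                       # trailing partial span
    end <- nxt[1L]
    if (i < length(offs) && offs[i + 1L] < end) {
      message("unpaired sleep annotations near ",
              format(offs[i]), "; day skipped")
      next
    }
    span_h <- as.numeric(end - offs[i], units = "hours")
    ov <- 0
    if (nrow(nonwear) > 0L) {
      s <- pmax(as.numeric(nonwear$start), as.numeric(offs[i]))
      e <- pmin(as.numeric(nonwear$end), as.numeric(end))
      ov <- sum(pmax(0, e - s)) / 3600
    }
    out[[length(out) + 1L]] <- data.frame(
      subject_id = stream$subject_id[1L],
      date = as.Date(format(offs[i], "%Y-%m-%d", tz = "UTC")),
      wake_hours = span_h, nonwear_hours = ov, wear_hours = span_h - ov,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(subject_id = character(), date = as.Date(character()),
                      wake_hours = numeric(), nonwear_hours = numeric(),
                      wear_hours = numeric()))
  do.call(rbind, out)
}

#' Flag valid monitoring days
#'
#' A day is valid when wear time during waking hours is at least
#' `min_wear_hours` (days with less wear are excluded; exactly the
#' threshold is valid).
#'
#' @param summaries Output of [wake_wear_time()], possibly row-bound over
#'   subjects.
#' @param min_wear_hours Minimum waking wear time, hours.
#' @return `summaries` with an `is_valid` logical column appended.
#' @export
flag_valid_days <- function(summaries, min_wear_hours = 10) {
  summaries$is_valid <- summaries$wear_hours >= min_wear_hours
  summaries
}

#' Validate wear for a multi-subject stream table
#'
#' Convenience wrapper: splits a stream table by subject, runs nonwear
#' detection, waking wear-time computation and valid-day flagging, and
#' row-binds the results.
#'
#' @param streams Stream table for any number of subjects.
#' @param gap_threshold Minutes; see [detect_nonwear()].
#' @param min_wear_hours Hours; see [flag_valid_days()].
#' @return Valid-day table `subject_id, date, wake_hours, nonwear_hours,
#'   wear_hours, is_valid`.
#' @export
validate_wear <- function(streams, gap_threshold = 60, min_wear_hours = 10) {
  parts <- split(streams, streams$subject_id)
  res <- lapply(parts, function(s) {
    flag_valid_days(wake_wear_time(s, detect_nonwear(s, gap_threshold)),
                    min_wear_hours)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
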