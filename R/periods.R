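#' Enumerate candidate analysis periods for one subject
#'
#' A candidate is a set of exactly `period_length` valid days whose
#' calendar span (first to last day inclusive) does not exceed
#' `window_length`. Candidates are generated as span-minimal sets: for
#' each valid day taken as the start, the next `period_length - 1` valid
#' days are appended; any selection rule that prefers fewest skipped days
#' only ever needs these. `n_skipped` is the calendar span minus
#' `period_length` (the number of invalid days straddled).
#'
#' @param dates Vector of calendar `Date`s.
#' @param valid Logical vector parallel to `dates`.
#' @param period_length Required number of valid days (7 or 28).
#' @param window_length Maximum calendar span (10 or 40).
#' @return List of candidates, each a list with `days` (sorted `Date`
#'   vector), `span` and `n_skipped`; empty list if the subject is
#'   ineligible.
#' @export
enumerate_candidates <- function(dates, valid, period_length,
                                 window_length) {
  stopifnot(length(dates) == length(valid),
            period_length >= 1, period_length <= window_length)
  period_length <- as.integer(period_length)
  ord <- order(dates)
  vd <- sort(dates[ord][valid[ord]])
  out <- list()
  if (length(vd) < period_length) return(out)
  for (i in seq_len(length(vd) - period_length + 1L)) {
    days <- vd[i:(i + period_length - 1L)]
    span <- as.integer(days[period_length] - days[1L]) + 1L
    if (span <= window_length) {
      out[[length(out) + 1L]] <- list(days = days, span = span,
                                      n_skipped = span - period_length)
    }
  }
  out
}

#' Select one analysis period from candidates
#'
#' Chooses a candidate with the fewest skipped days (a fully consecutive
#' run has zero); when several candidates tie on that minimum, one of them
#' is chosen uniformly at random. An empty candidate list yields an
#' ineligible choice rather than an error.
#'
#' @param candidates Output of [enumerate_candidates()].
#' @return List with `eligible`, and if eligible `days`, `span`,
#'   `n_skipped`.
#' @export
select_period <- function(candidates) {
  if (length(candidates) == 0L) return(list(eligible = FALSE))
  skips <- vapply(candidates, `[[`, integer(1), "n_skipped")
  best <- which(skips == min(skips))
  pick <- if (length(best) == 1L) best else
    best[sample.int(length(best), 1L)]
  c(list(eligible = TRUE), candidates[[pick]])
}

#' Select analysis periods for a whole cohort
#'
#' Applies [enumerate_candidates()] and [select_period()] per subject to a
#' valid-day table.
#'
#' @param valid_days Data frame with columns `subject_id`, `date` and a
#'   logical validity column (`is_valid` or `valid`).
#' @param period_length,window_length See [enumerate_candidates()].
#' @param seed Optional integer seed for the randomized tie-breaks.
#' @return List with `summary` (data frame `subject_id, eligible,
#'   start_date, end_date, n_skipped`) and `chosen_days` (long data frame
#'   `subject_id, date` of the selected days of eligible subjects).
#' @export
select_periods <- function(valid_days, period_length, window_length,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vcol <- if ("is_valid" %in% names(valid_days)) "is_valid" else "valid"
  stopifnot(vcol %in% names(valid_days))
  parts <- split(valid_days, valid_days$subject_id)
  summ <- list(); chosen <- list()
  for (sid in names(parts)) {
    p <- parts[[sid]]
    ch <- select_period(enumerate_candidates(as.Date(p$date), p[[vcol]],
                                             period_length, window_length))
    if (ch$eligible) {
      summ[[sid]] <- data.frame(subject_id = sid, eligible = TRUE,
                                start_date = min(ch$days),
                                end_date = max(ch$days),
                                n_skipped = ch$n_skipped)
      chosen[[sid]] <- data.frame(subject_id = sid, date = ch$days)
    } else {
      summ[[sid]] <- data.frame(subject_id = sid, eligible = FALSE,
                                start_date = as.Date(NA),
                                end_date = as.Date(NA),
                                n_skipped = NA_integer_)
    }
  }
  out_s <- do.call(rbind, summ); rownames(out_s) <- NULL
  out_c <- if (length(chosen)) do.call(rbind, chosen) else
    data.frame(subject_id = character(), date = as.Date(character()))
  rownames(out_c) <- NULL
  list(summary = out_s, chosen_days = out_c)
}
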