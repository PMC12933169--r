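#!/usr/bin/env Rscript
# Stage 3: valid-period selection.
#
# For each subject, chooses 7 valid days within a 10-day window (short
# term) or 28 within 40 (medium term), preferring consecutive runs and
# randomizing only across ties; writes eligibility summaries and the
# chosen-day tables.

suppressMessages(library(stepdays))

for (arm in c("short", "medium")) {
  daily <- read.csv(sprintf("results/%s_daily.csv", arm))
  daily$date <- as.Date(daily$date)
  P <- if (arm == "short") 7 else 28
  W <- if (arm == "short") 10 else 40
  sel <- select_periods(daily, P, W, seed = 20240104)
  write.csv(sel$summary, sprintf("results/%s_periods.csv", arm),
            row.names = FALSE)
  chosen <- merge(sel$chosen_days, daily[, c("subject_id", "date", "steps")],
                  by = c("subject_id", "date"))
  write.csv(chosen, sprintf("results/%s_chosen_days.csv", arm),
            row.names = FALSE)
  cat(sprintf("%s term: %d of %d subjects eligible; mean days skipped %.2f\n",
              arm, sum(sel$summary$eligible), nrow(sel$summary),
              mean(sel$summary$n_skipped[sel$summary$eligible])))
}
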