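#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohorts.
#
# Builds one short-term (7-in-10) and one medium-term (28-in-40) cohort
# from the published cluster moment profiles, including invalid days (so
# the period rules have work to do) and timestamped wear streams for a
# subset of subjects (so wear validation can be demonstrated end to end).
# Writes the daily tables, profiles and streams under results/.

suppressMessages(library(stepdays))
dir.create("results", showWarnings = FALSE)

short_spec <- cohort_spec(short_term_profiles(), period_length = 7,
                          window_length = 10, missing_day_rate = 0.12,
                          seed = 20240101)
medium_spec <- cohort_spec(medium_term_profiles(), period_length = 28,
                           window_length = 40, missing_day_rate = 0.12,
                           seed = 20240102)

short <- suppressWarnings(generate_cohort(short_spec, extra_days = 4))
medium <- suppressWarnings(generate_cohort(medium_spec, extra_days = 8))

write.csv(short$daily, "results/short_daily.csv", row.names = FALSE)
write.csv(short$profiles, "results/short_profiles.csv", row.names = FALSE)
write.csv(medium$daily, "results/medium_daily.csv", row.names = FALSE)
write.csv(medium$profiles, "results/medium_profiles.csv", row.names = FALSE)

# timestamped streams for ten subjects of the short cohort
set.seed(20240103)
streams <- lapply(unique(short$daily$subject_id)[1:10], function(sid) {
  generate_wear_stream(sid, n_days = 14,
                       wear_spec(record_interval = 15,
                                 nonwear_gap_rate = 0.8,
                                 gap_mean_min = 150, gap_sd_min = 70))
})
stream_tab <- do.call(rbind, lapply(streams, `[[`, "stream"))
truth_tab <- do.call(rbind, lapply(streams, `[[`, "truth"))
write.csv(stream_tab, "results/wear_streams.csv", row.names = FALSE)
write.csv(truth_tab, "results/wear_truth.csv", row.names = FALSE)

cat(sprintf("short cohort: %d subjects x %d days (%d invalid days)\n",
            nrow(short$profiles), length(unique(short$daily$date)),
            sum(!short$daily$valid)))
cat(sprintf("medium cohort: %d subjects x %d days (%d invalid days)\n",
            nrow(medium$profiles), length(unique(medium$daily$date)),
            sum(!medium$daily$valid)))
cat(sprintf("wear streams: %d records for %d subjects\n",
            nrow(stream_tab), length(streams)))
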