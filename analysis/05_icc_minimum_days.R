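#!/usr/bin/env Rscript
# Stage 5: ICC resampling and minimum monitoring days.
#
# Within each retained cluster (and the unclustered baseline), compares
# n-day subsample means to the full-period mean over 500 random day
# combinations per subset size, summarizes the ICC distributions, and
# derives the minimum days under both rules (mean ICC >= 0.80; all 500
# combinations >= 0.80).

suppressMessages(library(stepdays))

all_md <- list()
for (arm in c("short", "medium")) {
  chosen <- read.csv(sprintf("results/%s_chosen_days.csv", arm))
  asg <- read.csv(sprintf("results/%s_moments_clusters.csv", arm))
  N <- if (arm == "short") 7 else 28

  day_mat <- function(sids) {
    t(vapply(sids, function(s) {
      d <- chosen[chosen$subject_id == s, ]
      d$steps[order(d$date)]
    }, numeric(N)))
  }
  groups <- split(asg$subject_id[asg$retained], asg$cluster[asg$retained])
  groups$baseline <- asg$subject_id

  curves <- list()
  for (g in names(groups)) {
    cur <- icc_curve(day_mat(groups[[g]]), n_combos = 500,
                     seed = derive_seed(20240105, match(g, names(groups))))
    curves[[g]] <- data.frame(analysis = arm, cluster = g,
                              as.data.frame(cur))
    for (rule in c("mean", "all")) {
      all_md[[paste(arm, g, rule)]] <- data.frame(
        analysis = arm, cluster = g, rule = rule,
        n_subjects = length(groups[[g]]),
        min_days = min_days(cur, rule, 0.80))
    }
  }
  write.csv(do.call(rbind, curves),
            sprintf("results/%s_icc_curves.csv", arm), row.names = FALSE)
}
md <- do.call(rbind, all_md); rownames(md) <- NULL
write.csv(md, "results/min_days_cohort.csv", row.names = FALSE)
cat("minimum days on the synthetic cohorts (cluster sizes as published):\n")
print(md, row.names = FALSE)
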