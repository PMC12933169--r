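#' Configuration for a full reliability analysis
#'
#' Bundles the study constants of one analysis arm: the short-term arm
#' uses 7 valid days within a 10-day window, the medium-term arm 28
#' within 40.
#'
#' @param analysis `"short"` or `"medium"`.
#' @param n_clusters Dendrogram cut (default 4 for short, 3 for medium).
#' @param min_cluster_size Smallest cluster retained.
#' @param n_combos Random day combinations per subset size.
#' @param threshold Reliability threshold.
#' @param gap_threshold Nonwear gap threshold, minutes.
#' @param min_wear_hours Minimum waking wear time, hours.
#' @param seed Master seed.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(analysis = c("short", "medium"),
                            n_clusters = NULL, min_cluster_size = 12L,
                            n_combos = 500L, threshold = 0.80,
                            gap_threshold = 60, min_wear_hours = 10,
                            seed = 1L) {
  analysis <- match.arg(analysis)
  dims <- if (analysis == "short") c(N = 7L, window = 10L) else
    c(N = 28L, window = 40L)
  if (is.null(n_clusters))
    n_clusters <- if (analysis == "short") 4L else 3L
  stopifnot(n_clusters >= 1, min_cluster_size >= 1, n_combos >= 1,
            threshold > 0, threshold <= 1, gap_threshold > 0,
            min_wear_hours > 0)
  structure(list(analysis = analysis, period_length = dims[["N"]],
                 window_length = dims[["window"]],
                 n_clusters = as.integer(n_clusters),
                 min_cluster_size = as.integer(min_cluster_size),
                 n_combos = as.integer(n_combos), threshold = threshold,
                 gap_threshold = gap_threshold,
                 min_wear_hours = min_wear_hours, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full reliability pipeline on a daily step table
#'
#' Executes the linear pipeline on already-validated daily data: period
#' selection, per-subject moments, standardization, complete-linkage
#' clustering, small-cluster pruning, per-cluster ICC resampling and the
#' minimum-days summary, plus the unclustered baseline. Filter accounting
#' (subjects in = eligible + excluded) is asserted at every stage.
#'
#' @param daily Data frame `subject_id, date, steps` plus a logical
#'   validity column (`valid` or `is_valid`).
#' @param config An [analysis_config()].
#' @return List with `periods`, `moments`, `assignment`,
#'   `cluster_profile`, `curves` (per retained cluster plus `"baseline"`),
#'   `min_days` (data frame `cluster, rule, min_days`), and `counts`.
#' @export
run_pipeline <- function(daily, config) {
  stopifnot(inherits(config, "analysis_config"))
  n_subj <- length(unique(daily$subject_id))

  periods <- select_periods(daily, config$period_length,
                            config$window_length,
                            seed = derive_seed(config$seed, 1L))
  elig <- periods$summary$eligible
  stopifnot(sum(elig) + sum(!elig) == n_subj)

  chosen <- merge(periods$chosen_days, daily[, c("subject_id", "date",
                                                 "steps")],
                  by = c("subject_id", "date"))
  moments <- cohort_moments(chosen)
  feats <- standardize_moments(moments)
  assignment <- prune_clusters(cluster_complete_linkage(feats,
                                                        config$n_clusters),
                               config$min_cluster_size)
  stopifnot(sum(assignment$retained) + sum(!assignment$retained) ==
              nrow(moments))
  profile <- cluster_summary(moments, assignment)

  # subjects x days matrix per retained cluster, days in calendar order
  day_mat <- function(sids) {
    t(vapply(sids, function(s) {
      chosen$steps[chosen$subject_id == s][
        order(chosen$date[chosen$subject_id == s])]
    }, numeric(config$period_length)))
  }
  groups <- split(assignment$subject_id[assignment$retained],
                  assignment$cluster[assignment$retained])
  groups$baseline <- assignment$subject_id  # unclustered comparison
  curves <- list(); md <- list()
  for (g in names(groups)) {
    cur <- icc_curve(day_mat(groups[[g]]), n_combos = config$n_combos,
                     seed = derive_seed(config$seed, 2L, match(g, names(groups))))
    curves[[g]] <- cur
    for (rule in c("mean", "all")) {
      md[[paste(g, rule)]] <- data.frame(
        cluster = g, rule = rule,
        min_days = min_days(cur, rule, config$threshold))
    }
  }
  min_days_tab <- do.call(rbind, md); rownames(min_days_tab) <- NULL

  list(periods = periods$summary, moments = moments,
       assignment = assignment, cluster_profile = profile,
       curves = curves, min_days = min_days_tab,
       counts = c(subjects = n_subj, eligible = sum(elig),
                  retained = sum(assignment$retained)))
}

#' Plot reliability curves
#'
#' One panel per cluster: mean ICC against subset size with a mean +/- SD
#' envelope and a horizontal reference line at the configured threshold.
#'
#' @param curves Named list of [icc_curve()] objects (as in
#'   [run_pipeline()] output).
#' @param threshold Reference line position.
#' @return A ggplot object, or `NULL` (with a warning) for an empty list.
#' @export
plot_icc_curves <- function(curves, threshold = 0.80) {
  if (length(curves) == 0L) {
    warning("no curves to plot")
    return(invisible(NULL))
  }
  df <- do.call(rbind, lapply(names(curves), function(g) {
    data.frame(cluster = g, as.data.frame(curves[[g]]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$mean_icc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_icc - .data$sd_icc,
                                      ymax = pmin(1, .data$mean_icc +
                                                    .data$sd_icc)),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "days in subsample (n)",
                  y = "intraclass correlation, mean ± SD") +
    ggplot2::theme_minimal()
}
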