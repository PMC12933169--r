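#' Specify one cluster of a synthetic cohort
#'
#' A cluster is described by the between-subject distribution of the four
#' moments of daily step count: subjects' true means are
#' Normal(`mean_of_means`, `sd_of_means`^2), their day-to-day SDs are
#' Normal(`mean_within_sd`, `sd_within_sd`^2) truncated below at a positive
#' floor, and all subjects in the cluster share the target day-level
#' `skewness` and `kurtosis` (Pearson convention, normal = 3).
#'
#' @param label Cluster label (character).
#' @param mean_of_means,sd_of_means Between-subject mean and SD of the
#'   subjects' true daily-step means (steps/day).
#' @param mean_within_sd,sd_within_sd Between-subject mean and SD of the
#'   subjects' within-subject day-to-day SD (steps/day).
#' @param skewness,kurtosis Target day-level standardized moments.
#' @param n_subjects Number of subjects to generate for this cluster.
#' @return An object of class `cluster_spec`.
#' @export
cluster_spec <- function(label, mean_of_means, sd_of_means,
                         mean_within_sd, sd_within_sd,
                         skewness = 0, kurtosis = 3, n_subjects = 1L) {
  stopifnot(sd_of_means >= 0, mean_within_sd > 0, sd_within_sd >= 0,
            n_subjects >= 1)
  if (kurtosis <= skewness^2 + 1)
    stop("kurtosis must exceed skewness^2 + 1", call. = FALSE)
  structure(list(label = as.character(label),
                 mean_of_means = mean_of_means, sd_of_means = sd_of_means,
                 mean_within_sd = mean_within_sd, sd_within_sd = sd_within_sd,
                 skewness = skewness, kurtosis = kurtosis,
                 n_subjects = as.integer(n_subjects)),
            class = "cluster_spec")
}

#' Specify a synthetic cohort
#'
#' @param clusters List of [cluster_spec()] objects.
#' @param period_length Analysis period length in valid days (7 or 28).
#' @param window_length Calendar window the valid days must fall in (10 or 40).
#' @param missing_day_rate Probability that any calendar day is invalid
#'   (insufficient wear).
#' @param seed Integer seed driving all cohort randomness.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(clusters, period_length = 7L, window_length = 10L,
                        missing_day_rate = 0.1, seed = 1L) {
  stopifnot(length(clusters) >= 1,
            all(vapply(clusters, inherits, logical(1), "cluster_spec")),
            period_length <= window_length,
            missing_day_rate >= 0, missing_day_rate < 1)
  structure(list(clusters = clusters,
                 period_length = as.integer(period_length),
                 window_length = as.integer(window_length),
                 missing_day_rate = missing_day_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Reference cluster profiles for the short-term (7-day) analysis
#'
#' Moment profiles — mean (SD) of subjects' daily-step mean, SD, skewness
#' and kurtosis — for the four activity clusters observed in a smartwatch
#' cohort of community-dwelling adults, used as the default calibration of
#' the synthetic generator. Cluster sizes are the observed ones
#' (n = 36, 22, 42, 30).
#'
#' @return List of four [cluster_spec()] objects.
#' @export
short_term_profiles <- function() {
  list(
    cluster_spec("1", 5883, 1298, 2192,  727, 1.28, 5.34, 36L),
    cluster_spec("2", 5980, 1538, 1619,  685, 0.82, 3.67, 22L),
    cluster_spec("3", 4391, 1058, 1467,  586, 0.50, 2.20, 42L),
    cluster_spec("4", 7179, 1028, 3068, 1132, 0.55, 1.96, 30L)
  )
}

#' Reference cluster profiles for the medium-term (28-day) analysis
#'
#' As [short_term_profiles()], for the three clusters observed in the
#' 28-day analysis (n = 23, 14, 16).
#'
#' @return List of three [cluster_spec()] objects.
#' @export
medium_term_profiles <- function() {
  list(
    cluster_spec("1", 7671, 1052, 2955, 655, 0.66, 3.65, 23L),
    cluster_spec("2", 4746,  947, 2265, 381, 0.87, 3.31, 14L),
    cluster_spec("3", 5775,  988, 1764, 398, 0.31, 2.87, 16L)
  )
}

#' Draw subject-level moment profiles from a cluster specification
#'
#' Realizes the between-subject heterogeneity of a cluster: each subject
#' gets a true mean and a true within-subject SD drawn from the cluster's
#' normal between-subject distributions; the within-subject SD is redrawn
#' until it exceeds `sd_floor` (truncated normal), which keeps every
#' subject's standardized day-level moments well defined.
#'
#' @param spec A [cluster_spec()].
#' @param sd_floor Lower truncation bound for the within-subject SD
#'   (steps/day).
#' @return Data frame with one row per subject: `subject_id`, `true_mean`,
#'   `true_within_sd`, `skewness`, `kurtosis`, `cluster_label`.
#' @export
sample_subject_profiles <- function(spec, sd_floor = 50) {
  stopifnot(inherits(spec, "cluster_spec"), sd_floor > 0)
  n <- spec$n_subjects
  true_mean <- stats::rnorm(n, spec$mean_of_means, spec$sd_of_means)
  true_sd <- stats::rnorm(n, spec$mean_within_sd, spec$sd_within_sd)
  # rejection sampling for the truncation: redraw rather than clamp, so no
  # probability mass piles up at the floor
  while (any(bad <- true_sd <= sd_floor)) {
    true_sd[bad] <- stats::rnorm(sum(bad), spec$mean_within_sd,
                                 spec$sd_within_sd)
  }
  data.frame(subject_id = paste0("c", spec$label, "_s", seq_len(n)),
             true_mean = true_mean, true_within_sd = true_sd,
             skewness = spec$skewness, kurtosis = spec$kurtosis,
             cluster_label = spec$label, stringsAsFactors = FALSE)
}

.transform_cache <- new.env(parent = emptyenv())

#' Moment transform for day-count generation, with feasibility clamp
#'
#' Returns the Fleishman coefficients for the target day-level moments.
#' Empirical cluster profiles can sit slightly below the cubic
#' transform's kurtosis floor (light-tailed daily patterns); such targets
#' are clamped to the smallest feasible kurtosis at that skewness, with a
#' one-time warning. Solutions are cached per moment pair.
#'
#' @param skewness,kurtosis Target day-level standardized moments.
#' @return Fleishman coefficient vector `c(a, b, c, d)`.
#' @export
day_transform <- function(skewness, kurtosis) {
  key <- paste(skewness, kurtosis)
  if (!is.null(.transform_cache[[key]])) return(.transform_cache[[key]])
  coef <- tryCatch(fleishman_coefficients(skewness, kurtosis),
                   error = function(e) NULL)
  if (is.null(coef)) {
    clamped <- fleishman_min_kurtosis(skewness) + 0.01
    if (clamped >= kurtosis) {
      warning(sprintf(paste("kurtosis %.3g at skewness %.3g is below the",
                            "cubic transform's reach; generating days with",
                            "kurtosis %.3g instead"),
                      kurtosis, skewness, clamped), call. = FALSE)
      coef <- fleishman_coefficients(skewness, clamped)
    } else {
      stop(sprintf("infeasible day-level moment pair (%.4g, %.4g)",
                   skewness, kurtosis), call. = FALSE)
    }
  }
  .transform_cache[[key]] <- coef
  coef
}

#' Generate one subject's daily step counts
#'
#' Day counts are `round(true_mean + true_within_sd * T(Z))` with `Z`
#' standard normal and `T` the Fleishman cubic transform matching the
#' profile's target skewness and kurtosis, truncated below at zero. Days
#' are exchangeable: independent and identically distributed, with no
#' day-of-week or autocorrelation structure.
#'
#' @param profile One row of [sample_subject_profiles()] output (or any
#'   list with `true_mean`, `true_within_sd`, `skewness`, `kurtosis`).
#' @param n_days Number of days to generate.
#' @return Integer-valued numeric vector of length `n_days`, all `>= 0`.
#' @export
generate_day_counts <- function(profile, n_days) {
  stopifnot(n_days >= 1)
  coef <- day_transform(profile$skewness, profile$kurtosis)
  z <- stats::rnorm(n_days)
  y <- coef[1] + coef[2] * z + coef[3] * z^2 + coef[4] * z^3
  pmax(0, round(profile$true_mean + profile$true_within_sd * y))
}

#' Generate a synthetic cohort's daily step-count table
#'
#' Generates, for every subject of every cluster in the spec, one step
#' count per calendar day of the window (plus `extra_days`), marks days
#' invalid with probability `missing_day_rate`, and returns the long daily
#' table the downstream validation and selection stages consume.
#'
#' @param spec A [cohort_spec()].
#' @param start_date First calendar date (`Date` or ISO-8601 string).
#' @param extra_days Additional calendar days beyond `window_length`, so
#'   period selection has room to slide.
#' @return List with `daily` (data frame `subject_id, date, steps,
#'   wear_hours, valid`) and `profiles` (the realized subject profiles).
#'   On invalid days `wear_hours` is drawn below the 10-hour validity
#'   minimum, on valid days above it.
#' @export
generate_cohort <- function(spec, start_date = as.Date("2024-01-01"),
                            extra_days = 0L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  start_date <- as.Date(start_date)
  n_days <- spec$window_length + as.integer(extra_days)
  dates <- start_date + seq_len(n_days) - 1L

  profiles <- do.call(rbind, lapply(spec$clusters, sample_subject_profiles))
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    steps <- generate_day_counts(p, n_days)
    valid <- stats::runif(n_days) >= spec$missing_day_rate
    wear <- ifelse(valid, stats::runif(n_days, 12, 16),
                   stats::runif(n_days, 2, 9.5))
    data.frame(subject_id = p$subject_id, date = dates,
               steps = as.integer(steps),
               wear_hours = round(wear, 2), valid = valid,
               stringsAsFactors = FALSE)
  })
  list(daily = do.call(rbind, rows), profiles = profiles)
}

#' Simulate a cluster's complete day matrix
#'
#' Draws `m` subject profiles from `spec` (overriding its `n_subjects`)
#' and generates exactly `n_days` step counts per subject.
#'
#' Two calibration modes control what the cluster's `mean_of_means` /
#' `sd_of_means` describe:
#' \describe{
#'   \item{`"observed"`}{(default) the subject-level draw is the subject's
#'     *observed* full-period mean: day residuals are centred within each
#'     subject, so the generated subjects' period means have between-subject
#'     SD equal to `sd_of_means`. This matches how cluster-profile tables
#'     are computed from data (the SD of subjects' observed mean steps) and
#'     is the mode the reliability calibration uses.}
#'   \item{`"latent"`}{the draw is a latent true mean and days are fully
#'     independent; observed period means then have variance
#'     `sd_of_means^2 + E[within_sd^2]/n_days`.}
#' }
#'
#' @param spec A [cluster_spec()].
#' @param m Number of subjects.
#' @param n_days Days per subject (the full period length N).
#' @param sd_floor Truncation floor for the within-subject SD.
#' @param anchor `"observed"` or `"latent"`; see Details.
#' @return Numeric matrix `m x n_days`, rows = subjects.
#' @export
simulate_cluster_days <- function(spec, m, n_days, sd_floor = 50,
                                  anchor = c("observed", "latent")) {
  anchor <- match.arg(anchor)
  spec$n_subjects <- as.integer(m)
  prof <- sample_subject_profiles(spec, sd_floor = sd_floor)
  coef <- day_transform(spec$skewness, spec$kurtosis)
  z <- matrix(stats::rnorm(m * n_days), m, n_days)
  y <- coef[1] + coef[2] * z + coef[3] * z^2 + coef[4] * z^3
  if (anchor == "observed") y <- y - rowMeans(y)
  pmax(round(prof$true_mean + prof$true_within_sd * y), 0)
}
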