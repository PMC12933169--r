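#' Four distributional moments of one subject's daily steps
#'
#' Computes the clustering feature vector: arithmetic mean, sample SD
#' (n - 1 denominator), and the population-moment skewness
#' \eqn{g_1 = m_3 / m_2^{3/2}} and Pearson kurtosis \eqn{m_4 / m_2^2}
#' (normal = 3), where \eqn{m_k} are central moments with denominator n.
#'
#' @param series Numeric vector of daily step counts, length at least 4
#'   (the fourth moment needs four points).
#' @return Named numeric vector `c(mean, sd, skewness, kurtosis)`.
#' @export
subject_moments <- function(series) {
  stopifnot(is.numeric(series), all(is.finite(series)))
  n <- length(series)
  if (n < 4L) stop("need at least 4 days to estimate four moments",
                   call. = FALSE)
  mu <- mean(series)
  d <- series - mu
  m2 <- mean(d^2)
  if (m2 == 0) stop("degenerate series: all days identical, ",
                    "skewness and kurtosis undefined", call. = FALSE)
  c(mean = mu, sd = stats::sd(series),
    skewness = mean(d^3) / m2^1.5, kurtosis = mean(d^4) / m2^2)
}

#' Moment table for a cohort of subjects
#'
#' @param chosen_days Long data frame `subject_id, steps` (one row per
#'   selected day), e.g. the chosen-day table joined to daily steps.
#' @return Data frame `subject_id, mean, sd, skewness, kurtosis`.
#' @export
cohort_moments <- function(chosen_days) {
  parts <- split(chosen_days$steps, chosen_days$subject_id)
  mom <- t(vapply(parts, subject_moments, numeric(4)))
  data.frame(subject_id = names(parts), mom, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Centre and scale the moment features
#'
#' Each of the four columns is centred to mean 0 and scaled to sample SD 1.
#'
#' @param moments Data frame from [cohort_moments()] (or any data frame
#'   with columns `mean, sd, skewness, kurtosis`).
#' @return Numeric matrix with rownames = subject ids.
#' @export
standardize_moments <- function(moments) {
  feats <- c("mean", "sd", "skewness", "kurtosis")
  stopifnot(all(feats %in% names(moments)), nrow(moments) >= 2)
  x <- as.matrix(moments[, feats])
  spread <- apply(x, 2, stats::sd)
  if (any(spread == 0))
    stop("feature(s) with zero spread cannot be standardized: ",
         paste(feats[spread == 0], collapse = ", "), call. = FALSE)
  z <- scale(x)
  attr(z, "scaled:center") <- NULL; attr(z, "scaled:scale") <- NULL
  rownames(z) <- moments$subject_id
  z
}

#' Complete-linkage agglomerative clustering of subjects
#'
#' Euclidean distances on the standardized moment features; agglomerative
#' hierarchy with complete linkage (merge cost = maximum pairwise
#' distance); the tree is cut into `n_clusters` flat clusters.
#'
#' @param features Standardized feature matrix from
#'   [standardize_moments()].
#' @param n_clusters Number of flat clusters to cut.
#' @return Data frame `subject_id, cluster` with the dendrogram stored in
#'   attribute `"hclust"`.
#' @export
cluster_complete_linkage <- function(features, n_clusters) {
  stopifnot(n_clusters >= 1)
  if (n_clusters > nrow(features))
    stop("more clusters requested than subjects", call. = FALSE)
  hc <- stats::hclust(stats::dist(features, method = "euclidean"),
                      method = "complete")
  cl <- stats::cutree(hc, k = n_clusters)
  out <- data.frame(subject_id = rownames(features), cluster = unname(cl),
                    stringsAsFactors = FALSE)
  attr(out, "hclust") <- hc
  out
}

#' Remove clusters below the minimum size
#'
#' Clusters with fewer than `min_cluster_size` subjects are excluded
#' (their subjects are dropped from the reliability analysis); retained
#' clusters are relabelled 1..K in descending size order, ties broken by
#' original label.
#'
#' @param assignment Data frame `subject_id, cluster`.
#' @param min_cluster_size Minimum number of subjects a cluster must have
#'   to be retained.
#' @return Data frame `subject_id, cluster, retained`; excluded subjects
#'   have `cluster = NA` and `retained = FALSE`.
#' @export
prune_clusters <- function(assignment, min_cluster_size = 12L) {
  sizes <- table(assignment$cluster)
  keep <- names(sizes)[sizes >= min_cluster_size]
  if (length(keep) == 0L)
    stop("every cluster is below the minimum size (", min_cluster_size,
         "); consider a different dendrogram cut", call. = FALSE)
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  relabel <- stats::setNames(seq_along(keep), keep)
  old <- as.character(assignment$cluster)
  retained <- old %in% keep
  data.frame(subject_id = assignment$subject_id,
             cluster = ifelse(retained, relabel[old], NA_integer_),
             retained = retained, stringsAsFactors = FALSE)
}

#' Per-cluster moment summary
#'
#' The mean (SD) of each of the four moment features per retained
#' cluster — the cluster-profile layout used to parameterize the synthetic
#' generator.
#'
#' @param moments Data frame from [cohort_moments()].
#' @param assignment Pruned assignment from [prune_clusters()].
#' @return Data frame, one row per retained cluster.
#' @export
cluster_summary <- function(moments, assignment) {
  m <- merge(moments, assignment[assignment$retained, ], by = "subject_id")
  agg <- function(f) {
    do.call(rbind, lapply(split(m[[f]], m$cluster), function(v)
      c(mean(v), stats::sd(v))))
  }
  cl <- sort(unique(m$cluster))
  out <- data.frame(cluster = cl, n = as.integer(table(m$cluster)[as.character(cl)]))
  for (f in c("mean", "sd", "skewness", "kurtosis")) {
    a <- agg(f)
    out[[paste0(f, "_mean")]] <- a[, 1]
    out[[paste0(f, "_sd")]] <- a[, 2]
  }
  out
}

#' Average silhouette width across dendrogram cuts
#'
#' Reports the mean silhouette width for cuts into 2..`max_k` clusters, an
#' objective stand-in for visually inspecting the dendrogram when choosing
#' the number of clusters.
#'
#' @param features Standardized feature matrix.
#' @param max_k Largest cut to evaluate.
#' @return Data frame `k, mean_silhouette`.
#' @export
silhouette_profile <- function(features, max_k = 8L) {
  d <- stats::dist(features)
  hc <- stats::hclust(d, method = "complete")
  ks <- 2:min(max_k, nrow(features) - 1L)
  width <- vapply(ks, function(k) {
    mean(cluster::silhouette(stats::cutree(hc, k), d)[, "sil_width"])
  }, numeric(1))
  data.frame(k = ks, mean_silhouette = width)
}
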