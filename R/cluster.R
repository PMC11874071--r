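#' Euclidean distances between differential complexity curves
#'
#' Rows (regions) with any missing window value are excluded with a warning
#' and listed in the `excluded` attribute, rather than imputed.
#'
#' @param curves A [differential_curves()] tibble or a numeric region-by-
#'   window matrix.
#' @return A `dist` object over the retained rows.
#' @export
curve_distances <- function(curves) {
  m <- if (is.matrix(curves)) curves else curves_matrix(curves)
  keep <- apply(m, 1L, function(r) all(is.finite(r)))
  if (!all(keep)) {
    warn(sprintf("%d curve(s) with missing values excluded from clustering: %s",
                 sum(!keep), paste(head(rownames(m)[!keep], 10L), collapse = ", ")))
  }
  d <- dist(m[keep, , drop = FALSE], method = "euclidean")
  attr(d, "excluded") <- rownames(m)[!keep]
  d
}

#' Complete-linkage agglomerative clustering
#'
#' Inter-cluster distance is the maximum pairwise member distance; merge
#' heights are therefore monotone non-decreasing.
#'
#' @param d A `dist` object or symmetric distance matrix with zero diagonal.
#' @return An `hclust` tree.
#' @export
complete_linkage <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d)) || any(diag(d) != 0)) {
      abort("Distance matrix must be symmetric with a zero diagonal.",
            class = "entrajectory_parameter_error")
    }
    d <- as.dist(d)
  }
  if (attr(d, "Size") < 2L) {
    abort("Clustering needs at least 2 items.", class = "entrajectory_parameter_error")
  }
  hclust(d, method = "complete")
}

#' Cut a linkage tree into k clusters
#'
#' @param linkage An `hclust` tree.
#' @param k Number of clusters, between 1 and the number of items.
#' @return Named integer vector of cluster labels.
#' @export
cut_tree <- function(linkage, k) {
  n <- if (is.null(linkage$labels)) nrow(linkage$merge) + 1L
       else length(linkage$labels)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n || k != round(k)) {
    abort(sprintf("`k` must be an integer in [1, %d].", n),
          class = "entrajectory_parameter_error")
  }
  cutree(linkage, k = k)
}

#' Calinski-Harabasz index of a clustering
#'
#' The ratio of between-cluster to within-cluster dispersion, normalized by
#' degrees of freedom: `[B/(k-1)] / [W/(n-k)]`, with B and W centroid sums
#' of squares. A clustering with zero within-cluster dispersion (all
#' singletons or exact duplicates) is reported as `Inf`.
#'
#' @param x Numeric matrix, one row per item.
#' @param labels Cluster assignment of each row (at least 2 nonempty
#'   clusters).
#' @return A single number (possibly `Inf`).
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  n <- nrow(x)
  if (k < 2L || k >= n + 1L) {
    abort("Need at least 2 nonempty clusters and k <= n.",
          class = "entrajectory_parameter_error")
  }
  grand <- colMeans(x)
  w <- 0; b <- 0
  for (g in unique(labels)) {
    rows <- x[labels == g, , drop = FALSE]
    cen <- colMeans(rows)
    w <- w + sum(sweep(rows, 2L, cen)^2)
    b <- b + nrow(rows) * sum((cen - grand)^2)
  }
  if (w == 0) {
    warn("Zero within-cluster dispersion; Calinski-Harabasz index is infinite.")
    return(Inf)
  }
  (b / (k - 1)) / (w / (n - k))
}

#' Dendrogram leaf order
#'
#' The deterministic left-to-right order in which items appear at the
#' bottom of the dendrogram, used to order heatmap rows for display.
#'
#' @param linkage An `hclust` tree.
#' @return Integer permutation of the items.
#' @export
leaf_ordering <- function(linkage) {
  linkage$order
}

#' Pearson correlations of mean entropy profiles between age windows
#'
#' @param mean_entropy_by_window Numeric window-by-region matrix (at least
#'   3 regions). Zero-variance rows yield missing correlations with a
#'   warning.
#' @return Symmetric window-by-window correlation matrix with unit diagonal.
#' @export
age_group_correlations <- function(mean_entropy_by_window) {
  m <- as.matrix(mean_entropy_by_window)
  if (ncol(m) < 3L) {
    abort("Need at least 3 regions to correlate window profiles.",
          class = "entrajectory_parameter_error")
  }
  v <- apply(m, 1L, sd)
  if (any(v == 0, na.rm = TRUE)) {
    warn("Zero-variance window profile(s); their correlations are missing.")
  }
  suppressWarnings(cor(t(m), use = "pairwise.complete.obs"))
}

#' Per-cluster mean differential trajectories and their extremes
#'
#' @param curves Region-by-window matrix (or [differential_curves()]).
#' @param labels Cluster labels, one per retained region row.
#' @return A list with `means` (tibble: cluster, window_index, mean_diff)
#'   and `extremes` (tibble: cluster, peak/trough values and window
#'   indices; extremes are not flagged for an all-zero curve).
#' @export
cluster_mean_curves <- function(curves, labels) {
  m <- if (is.matrix(curves)) curves else curves_matrix(curves)
  if (length(labels) != nrow(m)) {
    abort("One label per curve row is required.", class = "entrajectory_parameter_error")
  }
  if (any(table(labels) == 0)) abort("Empty cluster.", class = "entrajectory_parameter_error")
  win <- as.integer(sub("^window_", "", colnames(m)))
  means <- purrr::map_dfr(sort(unique(labels)), function(g) {
    mu <- colMeans(m[labels == g, , drop = FALSE])
    tibble::tibble(cluster = g, window_index = win, mean_diff = unname(mu))
  })
  extremes <- means |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      peak = max(.data$mean_diff),
      peak_window = .data$window_index[which.max(.data$mean_diff)],
      trough = min(.data$mean_diff),
      trough_window = .data$window_index[which.min(.data$mean_diff)],
      flat = all(.data$mean_diff == 0),
      .groups = "drop"
    )
  list(means = means, extremes = extremes)
}

#' Cluster differential curves with Calinski-Harabasz model selection
#'
#' Computes Euclidean distances between regional differential curves,
#' builds the complete-linkage tree, scans the Calinski-Harabasz index over
#' `k_range`, and cuts at the best k (defaulting to 2 when the scan is flat
#' or degenerate).
#'
#' @param curves A [differential_curves()] tibble or region-by-window
#'   matrix.
#' @param k_range Candidate cluster counts.
#' @param k Fixed cluster count overriding the scan (optional).
#' @return A list of class `cluster_result`: `dist`, `linkage`, `labels`,
#'   `k`, `ch_scores` (tibble k, ch), `leaf_order`, `excluded`.
#' @export
cluster_curves <- function(curves, k_range = 2:6, k = NULL) {
  m <- if (is.matrix(curves)) curves else curves_matrix(curves)
  d <- curve_distances(m)
  keep <- setdiff(rownames(m), attr(d, "excluded"))
  m <- m[keep, , drop = FALSE]
  hc <- complete_linkage(d)
  k_range <- k_range[k_range >= 2 & k_range < nrow(m)]
  ch <- purrr::map_dfr(k_range, function(kk) {
    tibble::tibble(k = kk, ch = calinski_harabasz(m, cut_tree(hc, kk)))
  })
  if (is.null(k)) {
    k <- if (nrow(ch) == 0L || all(!is.finite(ch$ch)) ||
             diff(range(ch$ch[is.finite(ch$ch)])) == 0) 2L else ch$k[which.max(ch$ch)]
  }
  labels <- cut_tree(hc, k)
  structure(
    list(dist = d, linkage = hc, labels = labels, k = as.integer(k),
         ch_scores = ch, leaf_order = leaf_ordering(hc),
         excluded = attr(d, "excluded")),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d curves, k = %d (sizes: %s)\n",
              length(x$labels), x$k,
              paste(table(x$labels), collapse = ", ")))
  if (nrow(x$ch_scores) > 0L) {
    cat("Calinski-Harabasz scan:\n")
    print(x$ch_scores, n = nrow(x$ch_scores))
  }
  invisible(x)
}

#' Compare the two clusters' mean trendlines
#'
#' A paired (by window, the default) or unpaired two-sided t test between
#' the per-window mean differential values of two clusters.
#'
#' @param mean_curves The `means` tibble from [cluster_mean_curves()].
#' @param clusters Which two cluster ids to compare.
#' @param paired Pair values by window (default) or treat windows as
#'   independent samples.
#' @return A tibble with `t`, `df`, `p_value`, `method`.
#' @export
compare_cluster_trendlines <- function(mean_curves, clusters = NULL, paired = TRUE) {
  ids <- sort(unique(mean_curves$cluster))
  if (is.null(clusters)) clusters <- ids[1:2]
  a <- mean_curves |> dplyr::filter(.data$cluster == clusters[1]) |>
    dplyr::arrange(.data$window_index)
  b <- mean_curves |> dplyr::filter(.data$cluster == clusters[2]) |>
    dplyr::arrange(.data$window_index)
  tt <- t.test(a$mean_diff, b$mean_diff, paired = paired, var.equal = !paired)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 method = if (paired) "paired-by-window" else "unpaired")
}
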