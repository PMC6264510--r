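#' Agglomerative clustering of a dissimilarity matrix
#'
#' Hierarchical clustering (stats::hclust) cut at `C` clusters.
#'
#' @param diss n x n dissimilarity matrix.
#' @param C number of clusters, 1..n.
#' @param linkage one of "average", "complete", "single", "ward"
#'   (ward.D2 on dissimilarities).
#' @return integer cluster labels named by individual id.
#' @export
agglomerative_cluster <- function(diss, C, linkage = "average") {
  n <- nrow(diss)
  if (C < 1 || C > n) stop("C must be between 1 and n = ", n)
  method <- switch(linkage, average = "average", complete = "complete",
                   single = "single", ward = "ward.D2",
                   stop("unknown linkage: ", linkage))
  hc <- stats::hclust(stats::as.dist(diss), method = method)
  stats::cutree(hc, k = C)
}

#' Silhouette scores for a clustering on a dissimilarity matrix
#'
#' For point i with intra-cluster mean distance `a_i` and nearest
#' other-cluster mean distance `b_i`, the silhouette is
#' `s_i = (b_i - a_i) / max(a_i, b_i)`; points in singleton clusters score
#' 0 by convention. The average over points measures how dense and well
#' separated the clustering is.
#'
#' @param labels integer cluster labels (at least 2 non-empty clusters).
#' @param diss n x n dissimilarity matrix.
#' @return list with `scores` (per point) and `average`.
#' @export
silhouette_scores <- function(labels, diss) {
  labels <- as.integer(factor(labels))
  n <- length(labels)
  stopifnot(nrow(diss) == n)
  ncl <- max(labels)
  if (ncl < 2) stop("silhouette undefined for a single cluster")
  sizes <- tabulate(labels, ncl)
  # mean distance from each point to each cluster (self excluded for own)
  member <- outer(labels, seq_len(ncl), "==") * 1
  sums <- diss %*% member                     # n x ncl total distances
  meand <- sweep(sums, 2, sizes, "/")
  own <- cbind(seq_len(n), labels)
  a <- ifelse(sizes[labels] > 1,
              sums[own] / (sizes[labels] - 1), 0)
  tmp <- meand
  tmp[own] <- Inf
  b <- apply(tmp, 1, min)
  s <- ifelse(sizes[labels] == 1, 0, (b - a) / pmax(a, b))
  s[!is.finite(s)] <- 0                        # a = b = 0 ties
  list(scores = as.vector(s), average = mean(s))
}

#' Average-silhouette selection of the number of genetic clusters
#'
#' Cuts the agglomerative dendrogram at every `C` in 2..C_max and scores
#' each partition by its average silhouette; `C = 1` is assigned score 0
#' by convention, so it can only win if every multi-cluster partition has
#' a negative average (reported with a warning). Ties break toward the
#' smaller `C`. In the field design, `C_max` is the number of host webs
#' sampled.
#'
#' @param diss n x n dissimilarity matrix.
#' @param C_max largest number of clusters scanned (>= 2).
#' @param linkage linkage method, see [agglomerative_cluster()].
#' @return list of class `"silhouette_profile"`: data.frame `profile`
#'   (C, average_silhouette), `optimal_C`, and `labels` at the optimum.
#' @export
optimal_clusters <- function(diss, C_max, linkage = "average") {
  if (C_max < 2) stop("C_max must be >= 2")
  C_max <- min(C_max, nrow(diss) - 1)
  avg <- numeric(C_max)
  avg[1] <- 0
  lab_list <- vector("list", C_max)
  for (C in 2:C_max) {
    lab <- agglomerative_cluster(diss, C, linkage)
    lab_list[[C]] <- lab
    avg[C] <- silhouette_scores(lab, diss)$average
  }
  best <- which.max(avg)   # ties -> smallest C
  if (best == 1) warning("all average silhouettes negative; optimal C = 1")
  structure(list(profile = data.frame(C = seq_len(C_max),
                                      average_silhouette = avg),
                 optimal_C = best,
                 labels = if (best > 1) lab_list[[best]] else
                   stats::setNames(rep(1L, nrow(diss)), rownames(diss)),
                 linkage = linkage),
            class = "silhouette_profile")
}

#' @export
print.silhouette_profile <- function(x, ...) {
  cat("Average-silhouette profile (linkage:", x$linkage, ")\n")
  cat("Optimal number of clusters:", x$optimal_C, "\n")
  best <- x$profile$average_silhouette[x$optimal_C]
  cat("Average silhouette at optimum:", format(best, digits = 3), "\n")
  invisible(x)
}

#' Plot the average-silhouette profile
#'
#' @param x a `"silhouette_profile"`.
#' @return a ggplot object with a dashed line at the optimum.
#' @export
plot_silhouette_profile <- function(x) {
  ggplot2::ggplot(x$profile,
                  ggplot2::aes(x = .data$C, y = .data$average_silhouette)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = x$optimal_C, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters C",
                  y = "average silhouette score") +
    ggplot2::theme_minimal()
}
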