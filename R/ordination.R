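#' Pairwise Jaccard dissimilarity of band profiles
#'
#' For two binary band profiles, let `B` be the binary Bray-Curtis
#' quotient, `sum |x - y| / sum (x + y)`. The dissimilarity used here is
#' `D = 2B / (1 + B)`, which is algebraically the classical Jaccard
#' distance: the number of mismatched bands divided by the size of the
#' band union. `D = 0` for identical profiles and `D = 1` for profiles
#' sharing no bands.
#'
#' @param m a filtered [marker_matrix()] (no all-zero rows).
#' @return symmetric n x n dissimilarity matrix with individual ids as
#'   dimnames.
#' @export
jaccard_dissimilarity <- function(m) {
  if (any(rowSums(m) == 0)) {
    stop("all-zero band profiles present: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "),
         " (run filter_loci first)")
  }
  x <- unclass(m)
  storage.mode(x) <- "double"
  shared <- tcrossprod(x)                       # a: bands present in both
  totals <- rowSums(x)
  un <- outer(totals, totals, "+") - shared      # a + b + c
  d <- (un - shared) / un                        # (b + c) / (a + b + c)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Kruskal stress-1 of a configuration against a dissimilarity matrix
#'
#' `stress = sqrt( sum (d - dhat)^2 / sum d^2 )` over unordered pairs,
#' where `d` are the configuration's Euclidean distances and `dhat` is the
#' monotone (isotonic, pool-adjacent-violators) regression of `d` onto the
#' rank order of the dissimilarities. Ties in the dissimilarities are
#' treated by the primary approach: tied pairs are pre-sorted by `d`, so
#' their fitted values are free to differ.
#'
#' A configuration with all points coincident has no distance scale; by
#' convention its stress is 1 (with a warning).
#'
#' @param config n x k coordinate matrix.
#' @param diss n x n dissimilarity matrix.
#' @return stress-1 in \[0, 1\].
#' @export
kruskal_stress <- function(config, diss) {
  config <- as.matrix(config)
  n <- nrow(config)
  stopifnot(nrow(diss) == n, ncol(diss) == n)
  d <- as.vector(stats::dist(config))
  if (all(d == 0)) {
    warning("degenerate configuration (all points coincident); stress = 1")
    return(1)
  }
  dd <- diss[lower.tri(diss)]
  ord <- order(dd, d)               # primary tie treatment
  fit <- stats::isoreg(d[ord])$yf   # PAVA on d in dissimilarity order
  sqrt(sum((d[ord] - fit)^2) / sum(d^2))
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Rank-based ordination minimizing Kruskal stress-1, run through
#' vegan's global NMDS engine with multiple random starts (the first
#' start from classical metric scaling, the rest random). A start
#' terminates when the stress ratio between iterations exceeds
#' `conv_ratio` or stress drops below 1e-4; the lowest-stress
#' configuration across starts is returned, centered.
#'
#' @param diss n x n dissimilarity matrix.
#' @param k number of dimensions (default 3).
#' @param max_starts maximum number of random starts.
#' @param conv_ratio within-start stress-ratio stopping criterion.
#' @param seed RNG seed for the random starts.
#' @param maxit iteration cap per start.
#' @return list of class `"nmds_result"`: `config` (n x k, centered, with
#'   individual ids), `stress` (stress-1 in \[0, 1\]), `n_starts_used`,
#'   `converged`.
#' @export
nmds <- function(diss, k = 3, max_starts = 100, conv_ratio = 0.999999,
                 seed = 1L, maxit = 500) {
  n <- nrow(diss)
  if (n < k + 1) {
    stop("need at least k + 1 = ", k + 1, " individuals for a ", k,
         "-dimensional ordination (got ", n, ")")
  }
  if (conv_ratio <= 0 || conv_ratio >= 1) stop("conv_ratio must be in (0, 1)")
  set.seed(seed)
  fit <- suppressMessages(
    vegan::metaMDS(stats::as.dist(diss), k = k, try = min(20, max_starts),
                   trymax = max_starts, maxit = maxit,
                   sratmax = conv_ratio, trace = 0, plot = FALSE,
                   autotransform = FALSE, wascores = FALSE)
  )
  config <- scale(fit$points, center = TRUE, scale = FALSE)
  attr(config, "scaled:center") <- NULL
  rownames(config) <- rownames(diss)
  colnames(config) <- paste0("dim", seq_len(k))
  structure(list(config = config, stress = fit$stress,
                 n_starts_used = fit$tries, converged = fit$converged > 0),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat("NMDS ordination:", nrow(x$config), "points in", ncol(x$config),
      "dimensions\n")
  cat("Kruskal stress-1:", format(x$stress, digits = 4),
      if (x$converged) "(converged)" else "(no convergent solution found)",
      "\n")
  invisible(x)
}

#' Scatter plot of an NMDS configuration with web-mates linked
#'
#' @param res an `"nmds_result"`.
#' @param meta metadata data.frame (for web membership).
#' @param dims the two dimensions to draw.
#' @return a ggplot object.
#' @export
plot_nmds <- function(res, meta, dims = c(1, 2)) {
  cfg <- as.data.frame(res$config[, dims, drop = FALSE])
  names(cfg) <- c("x", "y")
  cfg$individual_id <- rownames(res$config)
  cfg$web_id <- meta$web_id[match(cfg$individual_id, meta$individual_id)]
  ggplot2::ggplot(cfg, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$web_id)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$web_id), alpha = 0.4) +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste0("NMDS", dims[1]), y = paste0("NMDS", dims[2]),
                  colour = "host web",
                  subtitle = sprintf("stress = %.3f", res$stress)) +
    ggplot2::theme_minimal()
}
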