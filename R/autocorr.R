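#' Squared genetic distance between band profiles
#'
#' For binary band data the squared Euclidean genetic distance between two
#' individuals is simply the number of mismatching loci,
#' `d2_xy = sum_l (x_l - y_l)^2`.
#'
#' @param m a [marker_matrix()].
#' @return symmetric n x n integer matrix of mismatch counts.
#' @export
binary_squared_distance <- function(m) {
  x <- unclass(m)
  storage.mode(x) <- "double"
  shared <- tcrossprod(x)
  tot <- rowSums(x)
  d2 <- outer(tot, tot, "+") - 2 * shared     # b + c
  diag(d2) <- 0
  dimnames(d2) <- list(rownames(m), rownames(m))
  d2
}

#' Gower double-centering of a squared-distance matrix
#'
#' `c_xy = -1/2 (d2_xy - rowmean_x - rowmean_y + grandmean)`. The result
#' is a centered covariance-like matrix: symmetric, rows summing to zero,
#' diagonal terms playing the role of per-individual variances.
#'
#' @param d2 symmetric squared-distance matrix.
#' @return centered matrix of the same dimension.
#' @export
double_center <- function(d2) {
  rm <- rowMeans(d2)
  gm <- mean(d2)
  cmat <- -0.5 * (d2 - outer(rm, rep(1, ncol(d2))) -
                  outer(rep(1, nrow(d2)), rm) + gm)
  dimnames(cmat) <- dimnames(d2)
  cmat
}

#' Bin pairwise geographic distances into distance classes
#'
#' Each unordered pair is assigned to the first class whose upper bound is
#' at least the pair's distance. The first bound should be >= 1 m so that
#' same-web pairs (distance exactly 0) always form the first class. In
#' strict mode an empty class is an error; otherwise empty classes are
#' merged into the next class until none is empty, and a final bound below
#' the maximum distance is auto-extended.
#'
#' @param geo n x n planar distance matrix, meters.
#' @param bounds strictly increasing class upper bounds, meters.
#' @param strict error on empty classes instead of merging?
#' @return list of class `"distance_classes"`: `bounds`, `class_of` (n x n
#'   integer matrix, 0 on the diagonal), `n_pairs` per class.
#' @export
make_distance_classes <- function(geo, bounds, strict = FALSE) {
  if (is.unsorted(bounds, strictly = TRUE)) {
    stop("bounds must be strictly increasing")
  }
  mx <- max(geo)
  if (bounds[length(bounds)] < mx) {
    bounds <- c(bounds, mx)
  }
  repeat {
    # class h covers (bounds[h-1], bounds[h]]; class 1 covers [0, bounds[1]]
    cls <- matrix(findInterval(geo, bounds[-length(bounds)],
                               left.open = TRUE) + 1L, nrow(geo))
    diag(cls) <- 0L
    counts <- tabulate(cls[lower.tri(cls)], length(bounds))
    if (all(counts > 0)) break
    empty <- which(counts == 0)
    if (strict) {
      stop("empty distance class with upper bound ", bounds[empty[1]], " m")
    }
    bounds <- bounds[-empty[1]]   # merge empty class into the next one
    if (length(bounds) == 0) stop("no non-empty distance classes")
  }
  dimnames(cls) <- dimnames(geo)
  structure(list(bounds = bounds, class_of = cls, n_pairs = counts),
            class = "distance_classes")
}

# per-class index helpers: ordered pair indices and per-individual pair
# weights w_x(h) (number of partners of x in class h)
.class_pairs <- function(classes) {
  nb <- length(classes$bounds)
  cls <- classes$class_of
  n <- nrow(cls)
  lapply(seq_len(nb), function(h) {
    idx <- which(cls == h & row(cls) != col(cls), arr.ind = TRUE) # ordered
    w <- tabulate(idx[, 1], n)
    list(i = idx[, 1], j = idx[, 2], w = w)
  })
}

#' Spatial autocorrelation coefficient r per distance class
#'
#' From the double-centered genetic matrix `c`, the multivariate
#' autocorrelation coefficient of distance class h is
#' `r_h = sum over ordered pairs (x, y) in h of c_xy  /
#'        sum_x w_x(h) c_xx`,
#' where `w_x(h)` counts the partners of x in class h. Positive `r` means
#' individuals at that spatial scale are genetically more similar than the
#' population average.
#'
#' @param cmat double-centered matrix from [double_center()].
#' @param classes a `"distance_classes"` object.
#' @return data.frame with `class`, `upper_bound_m`, `n_pairs`, `r`.
#' @export
autocorr_r <- function(cmat, classes) {
  diagc <- diag(cmat)
  pairs <- .class_pairs(classes)
  r <- vapply(pairs, function(p) {
    num <- sum(cmat[cbind(p$i, p$j)])
    den <- sum(p$w * diagc)
    if (abs(den) < 1e-300) stop("autocorrelation undefined: zero variance ",
                                "(all genotypes identical?)")
    num / den
  }, numeric(1))
  data.frame(class = seq_along(r),
             upper_bound_m = classes$bounds,
             n_pairs = classes$n_pairs,
             r = r)
}

#' Bootstrap confidence intervals for r
#'
#' Within each distance class, pairs are resampled with replacement
#' `n_boot` times; each unordered pair (x, y) contributes `2 c_xy` to the
#' numerator and `c_xx + c_yy` to the denominator of the recomputed r.
#' The CI is the 2.5/97.5 percentile band. A class with a single pair has
#' a degenerate CI (flagged by equal bounds).
#'
#' @param cmat double-centered matrix.
#' @param classes a `"distance_classes"`.
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed.
#' @return data.frame with `class`, `boot_lo`, `boot_hi`.
#' @export
bootstrap_ci <- function(cmat, classes, n_boot = 1000, seed = 1L) {
  stopifnot(n_boot >= 1)
  set.seed(seed)
  diagc <- diag(cmat)
  cls <- classes$class_of
  nb <- length(classes$bounds)
  lo <- hi <- numeric(nb)
  for (h in seq_len(nb)) {
    sel <- which(cls == h & lower.tri(cls), arr.ind = TRUE)  # unordered
    num_c <- 2 * cmat[sel]
    den_c <- diagc[sel[, 1]] + diagc[sel[, 2]]
    np <- nrow(sel)
    rs <- vapply(seq_len(n_boot), function(b) {
      take <- sample.int(np, np, replace = TRUE)
      sum(num_c[take]) / sum(den_c[take])
    }, numeric(1))
    qs <- stats::quantile(rs, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
    lo[h] <- qs[1]; hi[h] <- qs[2]
  }
  data.frame(class = seq_len(nb), boot_lo = lo, boot_hi = hi)
}

#' Permutation null distribution of r
#'
#' Each permutation shuffles whole genotypes across geographic positions
#' (equivalently, relabels the rows/columns of the centered matrix while
#' the distance classes stay put) and recomputes r per class, giving the
#' distribution of r under no spatial structure. Returns the 2.5/97.5
#' percentile null band per class.
#'
#' @param cmat double-centered matrix.
#' @param classes a `"distance_classes"`.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param keep_null if `TRUE`, attach the full null matrix
#'   (n_perm x classes) as attribute `"null_r"`.
#' @return data.frame with `class`, `null_lo`, `null_hi`.
#' @export
permutation_null <- function(cmat, classes, n_perm = 999, seed = 1L,
                             keep_null = FALSE) {
  stopifnot(n_perm >= 1)
  set.seed(seed)
  n <- nrow(cmat)
  diagc <- diag(cmat)
  pairs <- .class_pairs(classes)
  nb <- length(pairs)
  null_r <- matrix(NA_real_, n_perm, nb)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    dp <- diagc[p]
    for (h in seq_len(nb)) {
      num <- sum(cmat[cbind(p[pairs[[h]]$i], p[pairs[[h]]$j])])
      den <- sum(pairs[[h]]$w * dp)
      null_r[b, h] <- num / den
    }
  }
  out <- data.frame(class = seq_len(nb),
                    null_lo = apply(null_r, 2, stats::quantile, 0.025,
                                    names = FALSE),
                    null_hi = apply(null_r, 2, stats::quantile, 0.975,
                                    names = FALSE))
  if (keep_null) attr(out, "null_r") <- null_r
  out
}

#' Genetic spatial autocorrelation correlogram
#'
#' Full correlogram for a marker matrix and web metadata: per distance
#' class, the autocorrelation coefficient r, its bootstrap 95% CI, the
#' permutation 95% null band around r = 0, the permutation significance
#' flag (`signif_perm`: r outside the null band), and the conservative
#' joint flag (`significant`: both r and its whole bootstrap CI outside
#' the null band).
#'
#' @param m a filtered [marker_matrix()].
#' @param meta metadata data.frame.
#' @param bounds distance-class upper bounds in meters (first >= 1 so the
#'   same-web class is class 1).
#' @param n_boot bootstrap resamples (default 1000).
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @param stratum optional selector passed to [stratify()].
#' @param strict error on empty distance classes instead of merging.
#' @return data.frame of class `"correlogram"`.
#' @export
correlogram <- function(m, meta, bounds, n_boot = 1000, n_perm = 999,
                        seed = 1L, stratum = NULL, strict = FALSE) {
  meta <- meta[match(rownames(m), meta$individual_id), , drop = FALSE]
  if (!is.null(stratum)) {
    ids <- stratify(meta, stratum)
    if (!length(ids)) stop("empty stratum")
    m <- m[rownames(m) %in% ids, , drop = FALSE]
    meta <- meta[meta$individual_id %in% ids, , drop = FALSE]
  }
  if (nrow(m) < 4) stop("stratum too small for autocorrelation (n = ",
                        nrow(m), " < 4)")
  geo <- geo_distance_matrix(meta)
  classes <- make_distance_classes(geo, bounds, strict = strict)
  cmat <- double_center(binary_squared_distance(m))

  # global identity: class numerators sum to -trace(c) (zero row sums)
  pairs <- .class_pairs(classes)
  tot_num <- sum(vapply(pairs, function(p) sum(cmat[cbind(p$i, p$j)]),
                        numeric(1)))
  if (abs(tot_num + sum(diag(cmat))) >
      1e-8 * max(1, sum(abs(diag(cmat))))) {
    warning("centering identity violated; numerical trouble in input")
  }

  est <- autocorr_r(cmat, classes)
  bt <- bootstrap_ci(cmat, classes, n_boot = n_boot, seed = seed + 1L)
  nl <- permutation_null(cmat, classes, n_perm = n_perm, seed = seed + 2L)
  out <- cbind(est, bt[, c("boot_lo", "boot_hi")],
               nl[, c("null_lo", "null_hi")])
  out$signif_perm <- out$r > out$null_hi | out$r < out$null_lo
  out$significant <- (out$r > out$null_hi & out$boot_lo > out$null_hi) |
                     (out$r < out$null_lo & out$boot_hi < out$null_lo)
  class(out) <- c("correlogram", class(out))
  attr(out, "n") <- nrow(m)
  out
}

#' Plot a correlogram
#'
#' Blue line: r per distance class with bootstrap error bars; red dashed
#' lines: the permutation null band around r = 0.
#'
#' @param x a `"correlogram"`.
#' @return a ggplot object.
#' @export
plot_correlogram <- function(x) {
  df <- as.data.frame(x)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$upper_bound_m))) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_lo, group = 1),
                       colour = "red", linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_hi, group = 1),
                       colour = "red", linetype = "dashed") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$boot_lo,
                                        ymax = .data$boot_hi), width = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$r, group = 1),
                       colour = "blue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$r), colour = "blue") +
    ggplot2::labs(x = "distance class upper bound (m)",
                  y = "autocorrelation r") +
    ggplot2::theme_minimal()
}
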