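#' Population band frequencies
#'
#' @param m a [marker_matrix()].
#' @return per-locus band presence frequency `p_l = count / n`.
#' @export
band_frequencies <- function(m) {
  colMeans(unclass(m))
}

#' Frequency-corrected pairwise relatedness for dominant markers
#'
#' The centered band-sharing correlation:
#' `r_xy = sum_l (x_l - p_l)(y_l - p_l) / sum_l p_l (1 - p_l)`,
#' with `p_l` the sample band frequencies. Sharing a rare band counts for
#' more than sharing a common one; the estimator is zero-centered by
#' construction, so a random pair has expected relatedness ~ 0 and the
#' population-wide mean over ordered pairs is exactly
#' `-(sum of diagonal self-terms) / (n (n - 1))`.
#'
#' The estimator is a band-phenotype statistic, not a pedigree coefficient:
#' it ranks full sibs above half sibs above unrelated pairs but its scale
#' depends on the dominant-band frequency spectrum.
#'
#' @param m a filtered [marker_matrix()] with at least 3 individuals.
#' @param p optional reference band frequencies (defaults to the sample's).
#' @return symmetric n x n relatedness matrix.
#' @export
pairwise_relatedness <- function(m, p = band_frequencies(m)) {
  if (nrow(m) < 3) stop("need at least 3 individuals")
  denom <- sum(p * (1 - p))
  if (denom <= 0) stop("all loci fixed; relatedness undefined")
  x <- sweep(unclass(m), 2, p)
  r <- tcrossprod(x) / denom
  dimnames(r) <- list(rownames(m), rownames(m))
  r
}

# mean pairwise relatedness among a set of row indices
.group_mean_r <- function(r, idx) {
  sub <- r[idx, idx]
  sum(sub[lower.tri(sub)]) / (length(idx) * (length(idx) - 1) / 2)
}

#' Per-web relatedness permutation test
#'
#' For each web with at least 3 members, compares the mean pairwise
#' relatedness of web-mates against the null distribution of means from
#' random groups of the same size drawn (without replacement) from the
#' whole sample. Reports the permutation 95% null band, the one-sided
#' p-value `p_ge = P(mean_random >= mean_observed)` with the +1
#' correction, and a bootstrap 95% CI from resampling within-web pairs
#' with replacement. Flags: `higher` / `lower` when the observed mean
#' falls above / below the null band, else `ns`.
#'
#' @param m a filtered [marker_matrix()].
#' @param meta metadata data.frame.
#' @param n_perm random groups drawn for the null (default 999).
#' @param n_boot pair resamples for the CI (default 1000).
#' @param seed RNG seed.
#' @param stratum optional selector passed to [stratify()] before
#'   anything is computed.
#' @param min_web_size smallest web analysed (default 3; the permutation
#'   and bootstrap bands coincide below that).
#' @return data.frame of class `"relatedness_report"`: one row per web
#'   with `web_id`, `n`, `mean_r`, `boot_lo`, `boot_hi`, `null_lo`,
#'   `null_hi`, `p_ge`, `flag`. Webs excluded by size are listed in
#'   attribute `"excluded_webs"`.
#' @export
group_relatedness_test <- function(m, meta, n_perm = 999, n_boot = 1000,
                                   seed = 1L, stratum = NULL,
                                   min_web_size = 3L) {
  meta <- meta[match(rownames(m), meta$individual_id), , drop = FALSE]
  if (!is.null(stratum)) {
    ids <- stratify(meta, stratum)
    if (!length(ids)) stop("empty stratum")
    m <- m[rownames(m) %in% ids, , drop = FALSE]
    meta <- meta[meta$individual_id %in% ids, , drop = FALSE]
  }
  n <- nrow(m)
  if (n < min_web_size + 1) stop("too few individuals after stratification")
  set.seed(seed)
  r <- pairwise_relatedness(m)
  sz <- table(meta$web_id)
  webs <- names(sz)[sz >= min_web_size]
  excluded <- names(sz)[sz < min_web_size]

  rows <- lapply(webs, function(w) {
    idx <- which(meta$web_id == w)
    k <- length(idx)
    obs <- .group_mean_r(r, idx)
    null_means <- vapply(seq_len(n_perm), function(b) {
      .group_mean_r(r, sample.int(n, k))
    }, numeric(1))
    qs <- stats::quantile(null_means, c(0.025, 0.975), names = FALSE)
    p_ge <- (1 + sum(null_means >= obs)) / (n_perm + 1)
    # bootstrap over within-web pairs
    pr <- r[idx, idx][lower.tri(diag(k))]
    boot_means <- vapply(seq_len(n_boot), function(b) {
      mean(pr[sample.int(length(pr), length(pr), replace = TRUE)])
    }, numeric(1))
    bq <- stats::quantile(boot_means, c(0.025, 0.975), names = FALSE)
    flag <- if (obs > qs[2]) "higher" else if (obs < qs[1]) "lower" else "ns"
    data.frame(web_id = w, n = k, mean_r = obs,
               boot_lo = bq[1], boot_hi = bq[2],
               null_lo = qs[1], null_hi = qs[2],
               p_ge = p_ge, flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("relatedness_report", class(out))
  attr(out, "excluded_webs") <- excluded
  out
}

#' Plot per-web relatedness against the permutation null band
#'
#' @param x a `"relatedness_report"`.
#' @return a ggplot object; asterisk marks webs significantly above the
#'   null band, hash marks webs below it.
#' @export
plot_relatedness <- function(x) {
  df <- as.data.frame(x)
  df$mark <- ifelse(df$flag == "higher", "*",
                    ifelse(df$flag == "lower", "#", ""))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$web_id)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_lo, group = 1),
                       colour = "red", linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_hi, group = 1),
                       colour = "red", linetype = "dashed") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$boot_lo,
                                        ymax = .data$boot_hi), width = 0.2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_r), colour = "blue",
                        shape = 95, size = 6) +
    ggplot2::geom_text(ggplot2::aes(y = .data$boot_hi, label = .data$mark),
                       vjust = -0.5) +
    ggplot2::labs(x = "host web", y = "mean within-web relatedness") +
    ggplot2::theme_minimal()
}
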