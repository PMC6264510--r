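#' Haploid admixture clustering of band profiles
#'
#' Bayesian admixture model for dominant band data treated as haploid:
#' each individual's profile is a mixture over K latent clusters with
#' ancestry proportions `q_x ~ Dirichlet(alpha)`, each locus draws its
#' origin from `q_x`, and cluster k shows the band at locus l with
#' frequency `p_kl` (Beta(1,1) prior). Loci are assumed independent
#' (linkage equilibrium), appropriate for anonymous AFLP fragments. A
#' single alpha is shared across clusters and sampled by random-walk
#' Metropolis on log(alpha) with a uniform prior on (0, `alpha_max`].
#'
#' The data log-likelihood is recorded every `thin` post-burn-in
#' iterations; `ln P(X|K)` is estimated as `mean(lnL) - var(lnL)/2`.
#'
#' @param m a filtered [marker_matrix()].
#' @param K number of clusters (1 <= K <= n).
#' @param burn_in burn-in iterations.
#' @param n_iter recorded iterations after burn-in.
#' @param seed RNG seed.
#' @param alpha initial ancestry concentration.
#' @param alpha_max upper bound of the uniform alpha prior.
#' @param alpha_step Metropolis step on log(alpha).
#' @param thin record the log-likelihood every `thin` iterations.
#' @return list of class `"admixture_run"`: `Q` (n x K posterior-mean
#'   ancestry, rows sum to 1), `P` (K x L posterior-mean band
#'   frequencies), `lnL_trace`, `lnPK`, `K`, `alpha`, `seed`, `burn_in`,
#'   `n_iter`.
#' @export
gibbs_admixture <- function(m, K, burn_in = 2000, n_iter = 4000, seed = 1L,
                            alpha = 1, alpha_max = 10, alpha_step = 0.05,
                            thin = 10) {
  stopifnot(K >= 1, burn_in >= 1, n_iter >= 1)
  if (K > nrow(m)) stop("K = ", K, " exceeds number of individuals")
  x <- unclass(m)
  storage.mode(x) <- "integer"
  if (length(unique(as.vector(x))) == 1) {
    warning("all band calls identical; posterior is prior-driven")
  }
  set.seed(seed)
  res <- gibbs_admixture_cpp(x, K, as.integer(burn_in), as.integer(n_iter),
                             alpha, K > 1, alpha_step, alpha_max,
                             as.integer(thin))
  rownames(res$Q) <- rownames(m)
  colnames(res$Q) <- paste0("cluster", seq_len(K))
  structure(list(Q = res$Q, P = res$P, lnL_trace = res$lnL_trace,
                 lnPK = estimate_lnPK_trace(res$lnL_trace),
                 K = K, alpha = res$alpha, seed = seed,
                 burn_in = burn_in, n_iter = n_iter),
            class = "admixture_run")
}

#' @export
print.admixture_run <- function(x, ...) {
  cat("Haploid admixture run: K =", x$K, "(", nrow(x$Q), "individuals,",
      ncol(x$P), "loci )\n")
  cat("ln P(X|K) estimate:", format(x$lnPK, digits = 6),
      " mean ancestry alpha:", format(x$alpha, digits = 3), "\n")
  invisible(x)
}

estimate_lnPK_trace <- function(trace) {
  if (length(trace) < 10) stop("log-likelihood trace too short (need >= 10)")
  mean(trace) - stats::var(trace) / 2
}

#' Estimate ln P(X|K) from a run's likelihood trace
#'
#' The usual harmonic-style adjustment: `mean(lnL) - var(lnL) / 2` over
#' the post-burn-in trace (sample variance).
#'
#' @param run an `"admixture_run"`.
#' @return a single number.
#' @export
estimate_lnPK <- function(run) {
  estimate_lnPK_trace(run$lnL_trace)
}

#' Replicate admixture runs across a K range
#'
#' @param m a filtered [marker_matrix()].
#' @param K_range contiguous K values (delta-K needs length >= 3).
#' @param n_reps replicate chains per K (>= 2 for delta-K).
#' @param seed base seed; chain seeds are derived per (K, replicate).
#' @param ... passed to [gibbs_admixture()].
#' @return list of class `"admixture_scan"`: `runs` (list of lists by K),
#'   `lnPK` matrix (K x replicate), `delta_k` table.
#' @export
admixture_scan <- function(m, K_range, n_reps = 5, seed = 1L, ...) {
  runs <- lapply(K_range, function(K) {
    lapply(seq_len(n_reps), function(rep) {
      gibbs_admixture(m, K, seed = derive_seed(seed, sprintf("K%d_r%d", K, rep)),
                      ...)
    })
  })
  names(runs) <- paste0("K", K_range)
  lnPK <- t(vapply(runs, function(rr) vapply(rr, `[[`, numeric(1), "lnPK"),
                   numeric(n_reps)))
  rownames(lnPK) <- K_range
  dk <- delta_k(lnPK, K_range)
  structure(list(runs = runs, lnPK = lnPK, delta_k = dk, K_range = K_range),
            class = "admixture_scan")
}

#' Evanno delta-K from replicate ln P(X|K) values
#'
#' `delta_K = |L(K+1) - 2 L(K) + L(K-1)| / sd(K)` with `L(K)` the mean and
#' `sd(K)` the standard deviation of ln P(X|K) over replicate runs at K;
#' defined only for interior K of a contiguous scan. K values whose
#' replicate sd is zero are flagged and excluded from the argmax.
#'
#' @param lnPK matrix of ln P(X|K), rows = K values, columns = replicates.
#' @param K_range the K value of each row (contiguous, length >= 3).
#' @return list of class `"delta_k_table"`: data.frame `table` (K,
#'   mean_lnPK, sd_lnPK, delta_k) and `optimal_K`.
#' @export
delta_k <- function(lnPK, K_range = as.integer(rownames(lnPK))) {
  lnPK <- as.matrix(lnPK)
  if (ncol(lnPK) < 2) stop("need >= 2 replicate runs per K")
  if (length(K_range) < 3) stop("need a contiguous K range of length >= 3")
  if (any(diff(K_range) != 1)) stop("K range must be contiguous")
  mn <- rowMeans(lnPK)
  sdv <- apply(lnPK, 1, stats::sd)
  nK <- length(K_range)
  dk <- rep(NA_real_, nK)
  for (i in 2:(nK - 1)) {
    if (sdv[i] == 0) next   # flagged: delta undefined
    dk[i] <- abs(mn[i + 1] - 2 * mn[i] + mn[i - 1]) / sdv[i]
  }
  if (all(is.na(dk))) {
    warning("delta-K undefined at every interior K (zero replicate sd)")
    opt <- NA_integer_
  } else {
    opt <- K_range[which.max(dk)]
  }
  structure(list(table = data.frame(K = K_range, mean_lnPK = mn,
                                    sd_lnPK = sdv, delta_k = dk),
                 optimal_K = opt),
            class = "delta_k_table")
}

#' @export
print.delta_k_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("Optimal K (argmax delta-K):", x$optimal_K, "\n")
  invisible(x)
}

#' Align cluster labels across replicate runs
#'
#' Label switching makes cluster indices arbitrary across chains; this
#' greedily matches each run's Q columns to the first run's by maximal
#' column correlation, for averaged ancestry displays.
#'
#' @param runs list of `"admixture_run"` objects at the same K.
#' @return list of Q matrices with columns permuted to match the first
#'   run; attribute `"permutations"` records the column orders used.
#' @export
align_labels <- function(runs) {
  if (length(runs) < 1) stop("no runs")
  K <- runs[[1]]$K
  if (any(vapply(runs, `[[`, numeric(1), "K") != K)) {
    stop("runs differ in K")
  }
  ref <- runs[[1]]$Q
  perms <- vector("list", length(runs))
  out <- vector("list", length(runs))
  for (r in seq_along(runs)) {
    Q <- runs[[r]]$Q
    if (K == 1) {
      perms[[r]] <- 1L
      out[[r]] <- Q
      next
    }
    cors <- suppressWarnings(stats::cor(ref, Q))
    cors[!is.finite(cors)] <- 0
    perm <- integer(K)
    used <- rep(FALSE, K)
    for (k in seq_len(K)) {          # greedy best match per reference col
      cand <- order(cors[k, ], decreasing = TRUE)
      perm[k] <- cand[!used[cand]][1]
      used[perm[k]] <- TRUE
    }
    perms[[r]] <- perm
    out[[r]] <- Q[, perm, drop = FALSE]
    colnames(out[[r]]) <- colnames(ref)
  }
  attr(out, "permutations") <- perms
  out
}

#' Stacked-bar ancestry plot ordered by web
#'
#' @param run an `"admixture_run"`.
#' @param meta metadata data.frame.
#' @return a ggplot object.
#' @export
plot_ancestry <- function(run, meta) {
  Q <- run$Q
  ord <- order(meta$web_id[match(rownames(Q), meta$individual_id)])
  df <- data.frame(individual_id = factor(rownames(Q)[ord],
                                          levels = rownames(Q)[ord]),
                   Q[ord, , drop = FALSE], check.names = FALSE)
  long <- stats::reshape(df, direction = "long",
                         varying = colnames(Q), v.names = "q",
                         timevar = "cluster", times = colnames(Q),
                         idvar = "individual_id")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$individual_id, y = .data$q,
                                     fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "ancestry proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
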