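# Independent brute-force oracles: explicit double loops, no matrix
# algebra, kept deliberately separate from the package implementations.

bf_jaccard <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- sum(x[i, ] == 1 & x[j, ] == 1)
      b <- sum(x[i, ] == 1 & x[j, ] == 0)
      cc <- sum(x[i, ] == 0 & x[j, ] == 1)
      d[i, j] <- if (a + b + cc == 0) 0 else (b + cc) / (a + b + cc)
    }
  }
  d
}

bf_silhouette <- function(labels, diss) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(diss[i, setdiff(own, i)])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(diss[i, labels == cl]))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(scores = s, average = mean(s))
}

bf_double_center <- function(d2) {
  n <- nrow(d2)
  cm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      cm[i, j] <- -0.5 * (d2[i, j] - mean(d2[i, ]) - mean(d2[j, ]) +
                          mean(d2))
    }
  }
  cm
}

bf_autocorr_r <- function(cmat, class_of, h) {
  n <- nrow(cmat)
  num <- 0; den <- 0
  for (x in seq_len(n)) {
    for (y in seq_len(n)) {
      if (x != y && class_of[x, y] == h) {
        num <- num + cmat[x, y]
        den <- den + cmat[x, x]
      }
    }
  }
  num / den
}

bf_relatedness <- function(x) {
  n <- nrow(x); L <- ncol(x)
  p <- numeric(L)
  for (l in seq_len(L)) p[l] <- sum(x[, l]) / n
  den <- 0
  for (l in seq_len(L)) den <- den + p[l] * (1 - p[l])
  r <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- 0
      for (l in seq_len(L)) {
        num <- num + (x[i, l] - p[l]) * (x[j, l] - p[l])
      }
      r[i, j] <- num / den
    }
  }
  r
}

# PAVA by hand for the stress oracle: repeatedly merge adjacent violators
bf_pava <- function(y) {
  blocks <- lapply(seq_along(y), function(i) list(sum = y[i], n = 1))
  i <- 1
  while (i < length(blocks)) {
    m1 <- blocks[[i]]$sum / blocks[[i]]$n
    m2 <- blocks[[i + 1]]$sum / blocks[[i + 1]]$n
    if (m1 > m2) {
      blocks[[i]] <- list(sum = blocks[[i]]$sum + blocks[[i + 1]]$sum,
                          n = blocks[[i]]$n + blocks[[i + 1]]$n)
      blocks[[i + 1]] <- NULL
      if (i > 1) i <- i - 1
    } else i <- i + 1
  }
  unlist(lapply(blocks, function(b) rep(b$sum / b$n, b$n)))
}

# random binary matrix with no all-zero rows and no invariant columns
random_marker_matrix <- function(n, L, p = 0.4) {
  repeat {
    x <- matrix(rbinom(n * L, 1, p), n, L)
    if (all(rowSums(x) > 0) && all(colSums(x) > 0) &&
        all(colSums(x) < n)) break
  }
  marker_matrix(x)
}

# minimal metadata for a matrix: webs of given sizes along a line
toy_meta <- function(ids, web_sizes, spacing = 100) {
  web <- rep(seq_along(web_sizes), web_sizes)
  data.frame(individual_id = ids, web_id = paste0("w", web),
             age_class = "adult",
             sex = rep_len(c("male", "female"), length(ids)),
             easting = 500000 + (web - 1) * spacing,
             northing = 0, stringsAsFactors = FALSE)
}
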