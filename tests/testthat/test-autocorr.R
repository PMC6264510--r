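test_that("squared genetic distance counts mismatching loci", {
  m <- marker_matrix(rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0),
                           c = c(1, 0, 1, 0)))
  d2 <- binary_squared_distance(m)
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 2)
  # equals the Jaccard union arithmetic b + c on random data
  for (s in 1:10) {
    set.seed(s)
    mm <- random_marker_matrix(sample(5:20, 1), sample(10:30, 1))
    x <- unclass(mm)
    d2r <- binary_squared_distance(mm)
    n <- nrow(x)
    for (i in 1:n) for (j in 1:n) {
      b <- sum(x[i, ] == 1 & x[j, ] == 0)
      cc <- sum(x[i, ] == 0 & x[j, ] == 1)
      expect_identical(unname(d2r[i, j]), as.numeric(b + cc))
    }
  }
})

test_that("double-centering matches the formula and zeroes row sums", {
  d2 <- rbind(c(0, 4), c(4, 0))
  expect_equal(unname(double_center(d2)), rbind(c(1, -1), c(-1, 1)))
  expect_equal(double_center(matrix(0, 3, 3)), matrix(0, 3, 3))
  for (s in 1:10) {
    set.seed(s)
    mm <- random_marker_matrix(sample(5:25, 1), 20)
    cm <- double_center(binary_squared_distance(mm))
    expect_equal(unname(cm), bf_double_center(binary_squared_distance(mm)),
                 tolerance = 1e-12)
    expect_lt(max(abs(rowSums(cm))), 1e-9 * max(1, max(abs(cm))))
    expect_gte(sum(diag(cm)), 0)
  }
})

test_that("distance classes partition pairs; empty classes merge or error", {
  meta <- toy_meta(paste0("i", 1:6), c(3, 3), spacing = 30)
  geo <- geo_distance_matrix(meta)
  cl <- make_distance_classes(geo, bounds = c(1, 50))
  expect_equal(cl$n_pairs, c(6L, 9L))        # same-web vs cross-web pairs
  expect_true(all(cl$class_of[1:3, 1:3][lower.tri(diag(3))] == 1))
  expect_true(all(cl$class_of[1:3, 4:6] == 2))

  # no pairs in (1, 5]: strict errors, lenient merges
  expect_error(make_distance_classes(geo, c(1, 5, 50), strict = TRUE),
               "empty distance class")
  cl2 <- make_distance_classes(geo, c(1, 5, 50))
  expect_equal(cl2$bounds, c(1, 50))

  # single class containing everything is legal
  cl3 <- make_distance_classes(geo, 1000)
  expect_equal(cl3$n_pairs, 15L)
  # last bound below max distance is auto-extended, empty middle merged
  cl4 <- make_distance_classes(geo, c(1, 10))
  expect_equal(cl4$bounds, c(1, 30))
  expect_equal(sum(cl4$n_pairs), 15L)
  expect_error(make_distance_classes(geo, c(5, 5)), "strictly increasing")
})

test_that("autocorrelation r hits its closed forms", {
  # two webs of identical clones, all loci differing between webs
  x <- rbind(a = rep(c(1, 0), each = 4), b = rep(c(1, 0), each = 4),
             c = rep(c(0, 1), each = 4), d = rep(c(0, 1), each = 4))
  m <- marker_matrix(x)
  meta <- toy_meta(rownames(m), c(2, 2), spacing = 100)
  geo <- geo_distance_matrix(meta)
  cm <- double_center(binary_squared_distance(m))
  cl <- make_distance_classes(geo, c(1, 200))
  r <- autocorr_r(cm, cl)
  expect_equal(r$r[1], 1)                       # clone-mates: r = +1

  # n = 2, single pair: r = -1
  m2 <- marker_matrix(rbind(a = c(1, 0, 1), b = c(0, 1, 1)))
  meta2 <- toy_meta(c("a", "b"), c(1, 1), spacing = 10)
  cm2 <- double_center(binary_squared_distance(m2))
  cl2 <- make_distance_classes(geo_distance_matrix(meta2), 100)
  expect_equal(autocorr_r(cm2, cl2)$r, -1)

  # single class holding all pairs: r = -1/(n-1) exactly
  for (s in 1:5) {
    set.seed(s)
    n <- sample(4:20, 1)
    mm <- random_marker_matrix(n, 25)
    metaa <- toy_meta(rownames(mm), rep(1, n), spacing = 7)
    cma <- double_center(binary_squared_distance(mm))
    cla <- make_distance_classes(geo_distance_matrix(metaa), 1e6)
    expect_equal(autocorr_r(cma, cla)$r, -1 / (n - 1), tolerance = 1e-10)
  }

  # identical genotypes: zero variance is an error
  mclone <- marker_matrix(matrix(rep(c(1, 0), 4), 4, 2, byrow = TRUE))
  cl0 <- make_distance_classes(
    geo_distance_matrix(toy_meta(rownames(mclone), c(2, 2))), c(1, 200))
  expect_error(autocorr_r(double_center(binary_squared_distance(mclone)),
                          cl0), "zero variance")
})

test_that("autocorrelation r equals the explicit double-loop oracle", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(6:30, 1)
    sizes <- rep(3, n %/% 3)
    if (sum(sizes) < n) sizes <- c(sizes, n - sum(sizes))
    mm <- random_marker_matrix(n, 30)
    meta <- toy_meta(rownames(mm), sizes, spacing = 40)
    geo <- geo_distance_matrix(meta)
    cm <- double_center(binary_squared_distance(mm))
    cl <- make_distance_classes(geo, c(1, 80, 1e5))
    r <- autocorr_r(cm, cl)
    for (h in seq_along(cl$bounds)) {
      expect_equal(r$r[h], bf_autocorr_r(cm, cl$class_of, h),
                   tolerance = 1e-12)
    }
    # global identity: sum of class numerators = -trace(c)
    nums <- vapply(seq_along(cl$bounds), function(h) {
      idx <- which(cl$class_of == h & row(cl$class_of) != col(cl$class_of))
      sum(cm[idx])
    }, numeric(1))
    expect_equal(sum(nums), -sum(diag(cm)), tolerance = 1e-8)
  }
})

test_that("bootstrap CIs are seeded, degenerate on clones, cover the point", {
  x <- rbind(a = rep(c(1, 0), each = 4), b = rep(c(1, 0), each = 4),
             c = rep(c(0, 1), each = 4), d = rep(c(0, 1), each = 4))
  m <- marker_matrix(x)
  meta <- toy_meta(rownames(m), c(2, 2), spacing = 100)
  cm <- double_center(binary_squared_distance(m))
  cl <- make_distance_classes(geo_distance_matrix(meta), c(1, 200))
  ci <- bootstrap_ci(cm, cl, n_boot = 200, seed = 1)
  expect_equal(ci$boot_lo[1], 1)               # clones: no variance
  expect_equal(ci$boot_hi[1], 1)
  expect_identical(ci, bootstrap_ci(cm, cl, n_boot = 200, seed = 1))

  hits <- 0
  for (s in 1:20) {
    set.seed(s + 100)
    mm <- random_marker_matrix(12, 40)
    meta2 <- toy_meta(rownames(mm), rep(3, 4), spacing = 50)
    cm2 <- double_center(binary_squared_distance(mm))
    cl2 <- make_distance_classes(geo_distance_matrix(meta2), c(1, 1e4))
    r2 <- autocorr_r(cm2, cl2)
    ci2 <- bootstrap_ci(cm2, cl2, n_boot = 300, seed = s)
    hits <- hits + all(ci2$boot_lo <= r2$r & r2$r <= ci2$boot_hi)
  }
  expect_gte(hits, 19)
})

test_that("permutation null is seeded and degenerate without geography", {
  set.seed(42)
  mm <- random_marker_matrix(10, 30)
  meta <- toy_meta(rownames(mm), 10)      # everyone on one web
  cm <- double_center(binary_squared_distance(mm))
  cl <- make_distance_classes(geo_distance_matrix(meta), 10)
  nl <- permutation_null(cm, cl, n_perm = 50, seed = 1, keep_null = TRUE)
  null_r <- attr(nl, "null_r")
  # permuting labels within a single location changes nothing
  expect_equal(max(null_r) - min(null_r), 0, tolerance = 1e-12)
  expect_equal(null_r[1], -1 / 9, tolerance = 1e-10)
  expect_identical(permutation_null(cm, cl, n_perm = 50, seed = 1),
                   permutation_null(cm, cl, n_perm = 50, seed = 1))
})

test_that("correlogram flags limited dispersal but not panmixia", {
  cfg <- colony_config(n_webs = 10, group_sizes = rep(6, 10), n_loci = 100,
                       sib_fraction = 1, migrant_rate = 0, seed = 314)
  sim <- simulate_population(cfg)
  m <- filter_loci(sim$matrix)
  meta <- sim$meta[sim$meta$individual_id %in% rownames(m), ]
  cg <- correlogram(m, meta, bounds = c(1, 250, 500, 1000),
                    n_boot = 300, n_perm = 199, seed = 9)
  expect_true(cg$significant[1])
  expect_gt(cg$r[1], 0)
  expect_true(all(cg$r[1] > cg$r[-1]))

  cfg0 <- colony_config(n_webs = 10, group_sizes = rep(6, 10), n_loci = 100,
                        sib_fraction = 0, seed = 315)
  sim0 <- simulate_population(cfg0)
  m0 <- filter_loci(sim0$matrix)
  meta0 <- sim0$meta[sim0$meta$individual_id %in% rownames(m0), ]
  cg0 <- correlogram(m0, meta0, bounds = c(1, 250, 500, 1000),
                     n_boot = 300, n_perm = 199, seed = 10)
  expect_false(any(cg0$significant))

  suppressWarnings(
    expect_error(correlogram(m, meta, bounds = c(1, 1000),
                             stratum = function(x) rep(FALSE, nrow(x))),
                 "empty stratum|no individuals"))
  expect_error(correlogram(m[1:3, ], meta[1:3, ], bounds = c(1, 1000)),
               "too small")
})
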