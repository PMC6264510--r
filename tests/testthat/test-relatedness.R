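test_that("band frequencies are column means", {
  m <- random_marker_matrix(10, 15)
  p <- band_frequencies(m)
  expect_equal(unname(p["locus3"] * 0 + sum(m[, 3]) / 10), unname(p[3]))
  expect_equal(unname(p), unname(colMeans(unclass(m))))
  set.seed(1)
  perm <- sample(10)
  expect_equal(band_frequencies(m[perm, ]), p)
})

test_that("relatedness hits hand values at p = 1/2", {
  # two identical profiles among fillers keeping every p_l at 0.5
  x <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0),
             c = c(0, 0, 1, 1), d = c(0, 0, 1, 1))
  m <- marker_matrix(x)
  r <- pairwise_relatedness(m)          # all p_l = 0.5
  expect_equal(r["a", "b"], 1)          # identical profiles
  expect_equal(r["a", "c"], -1)         # complementary profiles
})

test_that("relatedness matches the per-locus loop oracle and its identity", {
  for (s in 1:20) {
    set.seed(s)
    mm <- random_marker_matrix(sample(5:25, 1), sample(10:40, 1))
    r <- pairwise_relatedness(mm)
    expect_equal(unname(r), bf_relatedness(unclass(mm)), tolerance = 1e-12)
    # sample-centered: off-diagonal sum = -diagonal sum, exactly
    expect_equal(sum(r) - sum(diag(r)), -sum(diag(r)), tolerance = 1e-9)
  }
  expect_error(pairwise_relatedness(random_marker_matrix(2, 5)), "at least 3")
})

test_that("unrelated pairs average ~0; sibs rank full > half > unrelated", {
  cfg <- colony_config(n_webs = 1, group_sizes = 60, n_loci = 1000,
                       sib_fraction = 0, seed = 17)
  sim <- simulate_population(cfg)
  r <- pairwise_relatedness(filter_loci(sim$matrix))
  off <- r[lower.tri(r)]
  expect_lt(abs(mean(off)), 0.02)

  mean_sib_r <- function(sib_type, seed) {
    cfg <- colony_config(n_webs = 8, group_sizes = rep(5, 8), n_loci = 2000,
                         sib_fraction = 1, sib_type = sib_type,
                         migrant_rate = 0, seed = seed)
    sim <- simulate_population(cfg)
    m <- filter_loci(sim$matrix)
    meta <- sim$meta[sim$meta$individual_id %in% rownames(m), ]
    r <- pairwise_relatedness(m)
    same <- outer(meta$web_id, meta$web_id, "==") & lower.tri(r)
    c(within = mean(r[same]), between = mean(r[!same & lower.tri(r)]))
  }
  wins_full <- wins_half <- 0
  for (s in 1:10) {
    full <- mean_sib_r("full", 800 + s)
    half <- mean_sib_r("half", 900 + s)
    wins_full <- wins_full + unname(full["within"] > half["within"])
    wins_half <- wins_half + unname(half["within"] > half["between"])
  }
  expect_gte(wins_full, 9)
  expect_equal(wins_half, 10)
})

test_that("per-web permutation test flags sib webs and not random ones", {
  # one full-sib web planted in an unrelated population
  cfg <- colony_config(n_webs = 10, group_sizes = rep(10, 10), n_loci = 300,
                       sib_fraction = 0, seed = 55)
  sim <- simulate_population(cfg)
  m <- sim$matrix
  # overwrite web01 with a sib family drawn from the same locus frequencies
  sib <- simulate_population(colony_config(n_webs = 1, group_sizes = 10,
                                           n_loci = 300, sib_fraction = 1,
                                           migrant_rate = 0, seed = 56))
  x <- unclass(m)
  x[1:10, ] <- unclass(sib$matrix)
  m <- marker_matrix(x)
  m <- filter_loci(m)
  meta <- sim$meta[sim$meta$individual_id %in% rownames(m), ]
  rep_ <- group_relatedness_test(m, meta, n_perm = 499, n_boot = 200,
                                 seed = 57)
  expect_lt(rep_$p_ge[rep_$web_id == "web01"], 0.05)
  expect_equal(rep_$flag[rep_$web_id == "web01"], "higher")
  # unrelated webs mostly unflagged
  others <- rep_[rep_$web_id != "web01", ]
  expect_lte(sum(others$flag == "higher"), 2)

  # degenerate: the "web" is the entire population, so every null draw
  # ties the observed mean exactly and nothing can be flagged
  meta_all <- meta; meta_all$web_id <- "w"
  rep_all <- group_relatedness_test(m, meta_all, n_perm = 199, n_boot = 50,
                                    seed = 58)
  expect_equal(rep_all$p_ge, 1)
  expect_equal(rep_all$flag, "ns")

  # webs below the size floor are excluded with a record
  meta_small <- meta
  meta_small$web_id[meta_small$web_id == "web02"][1:8] <- "web11"
  rep_s <- group_relatedness_test(m, meta_small, n_perm = 99, n_boot = 50,
                                  seed = 59)
  expect_true("web02" %in% attr(rep_s, "excluded_webs"))
})

test_that("relatedness test is reproducible under a fixed seed", {
  cfg <- colony_config(n_webs = 5, group_sizes = rep(5, 5), n_loci = 100,
                       seed = 60)
  sim <- simulate_population(cfg)
  m <- filter_loci(sim$matrix)
  meta <- sim$meta[sim$meta$individual_id %in% rownames(m), ]
  a <- group_relatedness_test(m, meta, n_perm = 99, n_boot = 50, seed = 3)
  b <- group_relatedness_test(m, meta, n_perm = 99, n_boot = 50, seed = 3)
  expect_identical(a, b)
})
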