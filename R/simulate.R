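#' Configuration for the synthetic colony simulator
#'
#' The simulator emulates the field design: kleptoparasite groups ("webs")
#' positioned along a transect, each a mixture of one sib family and
#' unrelated settlers, genotyped at dominant biallelic loci. The latent
#' model is diploid: each individual carries two alleles per locus and
#' shows a band iff at least one copy is the dominant (band-producing)
#' allele, so that true kinship is known while the observed data have the
#' usual dominant-marker information loss.
#'
#' @param n_webs number of host webs.
#' @param transect_length transect length in meters; webs are evenly
#'   spaced along it (plus optional jitter).
#' @param web_jitter if `TRUE`, adds Uniform(0, spacing/2) positional noise.
#' @param mean_group_size expected members per web (Poisson, truncated to
#'   at least 2).
#' @param group_sizes optional explicit vector of web sizes, overriding
#'   `mean_group_size`.
#' @param n_loci number of dominant loci.
#' @param allele_freq_range range of the Uniform law for the per-locus
#'   dominant-allele frequency q_l; the default (0.1, 0.9) avoids
#'   quasi-invariant loci that the polymorphism filter would discard.
#' @param sib_fraction proportion of each web drawn from one sib family.
#' @param sib_type `"full"` (shared parents, pedigree relatedness 0.5) or
#'   `"half"` (shared mother only, 0.25).
#' @param migrant_rate probability that a sib-slot member is replaced by an
#'   unrelated draw from the global pool.
#' @param n_sources 1 or 2 latent source populations.
#' @param source_divergence for `n_sources = 2`, the allele-frequency
#'   offset between sources (0.9 gives near-fixed differences,
#'   0.05 vs 0.95).
#' @param admix_fraction for `n_sources = 2`, proportion of individuals
#'   with mixed (0.5, 0.5) ancestry rather than pure ancestry.
#' @param seed RNG seed; the same config and seed give an identical
#'   dataset.
#' @return a list of class `"colony_config"`.
#' @export
colony_config <- function(n_webs = 13, transect_length = 1000,
                          web_jitter = FALSE, mean_group_size = 11,
                          group_sizes = NULL, n_loci = 200,
                          allele_freq_range = c(0.1, 0.9),
                          sib_fraction = 0.5, sib_type = c("full", "half"),
                          migrant_rate = 0.1, n_sources = 1,
                          source_divergence = 0, admix_fraction = 0,
                          seed = 1L) {
  sib_type <- match.arg(sib_type)
  stopifnot(n_webs >= 1, n_loci >= 1, transect_length > 0,
            sib_fraction >= 0, sib_fraction <= 1,
            migrant_rate >= 0, migrant_rate <= 1,
            admix_fraction >= 0, admix_fraction <= 1,
            n_sources %in% c(1, 2))
  if (!is.null(group_sizes) && length(group_sizes) != n_webs) {
    stop("group_sizes must have length n_webs")
  }
  if (!is.null(group_sizes) && sib_fraction > 0 && any(group_sizes < 2)) {
    stop("sib_fraction > 0 needs group sizes of at least 2")
  }
  if (n_sources == 2 && source_divergence <= 0.01) {
    warning("source_divergence <= 0.01: sources effectively coincide")
  }
  structure(list(n_webs = n_webs, transect_length = transect_length,
                 web_jitter = web_jitter, mean_group_size = mean_group_size,
                 group_sizes = group_sizes, n_loci = n_loci,
                 allele_freq_range = allele_freq_range,
                 sib_fraction = sib_fraction, sib_type = sib_type,
                 migrant_rate = migrant_rate, n_sources = n_sources,
                 source_divergence = source_divergence,
                 admix_fraction = admix_fraction, seed = as.integer(seed)),
            class = "colony_config")
}

# draw one diploid individual: two allele vectors, Bernoulli(q) each
.draw_unrelated <- function(q) {
  cbind(stats::rbinom(length(q), 1, q), stats::rbinom(length(q), 1, q))
}

# Mendelian offspring of two diploid parents: one random allele from each
.draw_offspring <- function(p1, p2) {
  L <- nrow(p1)
  cbind(p1[cbind(seq_len(L), sample(1:2, L, replace = TRUE))],
        p2[cbind(seq_len(L), sample(1:2, L, replace = TRUE))])
}

#' Simulate a kleptoparasite population with known ground truth
#'
#' Per-locus dominant-allele frequencies are drawn from the configured
#' Uniform law (per source, offset by `source_divergence` when two sources
#' are simulated). Each web receives `round(sib_fraction * size)` members
#' bred from two random parents by Mendelian segregation (a sib family);
#' the remainder, plus any sib slot hit by `migrant_rate`, are unrelated
#' draws from the global pool. The observed band phenotype is the OR of
#' the two latent alleles.
#'
#' @param cfg a [colony_config()].
#' @return list of class `"colony_sim"` with elements `matrix`
#'   (a [marker_matrix()]), `meta` (metadata data.frame), and `truth`
#'   (per-individual `family_id`, `source_id`, ancestry and a pairwise
#'   pedigree relatedness matrix in \{0, 0.25, 0.5\}).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "colony_config"))
  set.seed(cfg$seed)
  L <- cfg$n_loci

  # per-source dominant-allele frequencies
  base <- stats::runif(L, cfg$allele_freq_range[1], cfg$allele_freq_range[2])
  if (cfg$n_sources == 2) {
    q_src <- list(pmin(pmax(base - cfg$source_divergence / 2, 0.02), 0.98),
                  pmin(pmax(base + cfg$source_divergence / 2, 0.02), 0.98))
  } else {
    q_src <- list(base)
  }

  sizes <- if (!is.null(cfg$group_sizes)) cfg$group_sizes else {
    s <- stats::rpois(cfg$n_webs, cfg$mean_group_size)
    pmax(s, 2L)
  }
  n <- sum(sizes)

  spacing <- if (cfg$n_webs > 1) cfg$transect_length / (cfg$n_webs - 1) else 0
  pos <- (seq_len(cfg$n_webs) - 1) * spacing
  if (cfg$web_jitter && cfg$n_webs > 1) {
    pos <- pos + stats::runif(cfg$n_webs, 0, spacing / 2)
  }

  geno <- matrix(0L, n, L)
  family <- integer(n)
  source_id <- integer(n)
  ancestry <- numeric(n)        # weight on source 1
  web <- character(n)
  east <- numeric(n)
  relat <- matrix(0, n, n)

  draw_for <- function(anc) {
    # anc = weight on source 1; each allele copy picks its source
    if (cfg$n_sources == 1) return(.draw_unrelated(q_src[[1]]))
    s1 <- stats::rbinom(L, 1, anc)
    s2 <- stats::rbinom(L, 1, anc)
    q1 <- ifelse(s1 == 1, q_src[[1]], q_src[[2]])
    q2 <- ifelse(s2 == 1, q_src[[1]], q_src[[2]])
    cbind(stats::rbinom(L, 1, q1), stats::rbinom(L, 1, q2))
  }
  pick_ancestry <- function() {
    if (cfg$n_sources == 1) return(1)
    if (stats::runif(1) < cfg$admix_fraction) return(0.5)
    if (stats::runif(1) < 0.5) 1 else 0
  }

  idx <- 0L
  fam_counter <- 0L
  for (w in seq_len(cfg$n_webs)) {
    s <- sizes[w]
    n_sib <- round(cfg$sib_fraction * s)
    if (n_sib == 1) n_sib <- 0L   # a "family" of one is just a settler
    members <- idx + seq_len(s)
    web[members] <- sprintf("web%02d", w)
    east[members] <- pos[w]

    sib_members <- integer(0)
    if (n_sib >= 2) {
      fam_counter <- fam_counter + 1L
      anc <- pick_ancestry()
      mother <- draw_for(anc)
      father <- if (cfg$sib_type == "full") draw_for(anc) else NULL
      for (k in seq_len(n_sib)) {
        idx <- idx + 1L
        if (stats::runif(1) < cfg$migrant_rate) {
          a <- pick_ancestry()
          g <- draw_for(a)
          geno[idx, ] <- as.integer(g[, 1] | g[, 2])
          family[idx] <- 0L
          ancestry[idx] <- a
        } else {
          pat <- if (cfg$sib_type == "full") father else draw_for(anc)
          g <- .draw_offspring(mother, pat)
          geno[idx, ] <- as.integer(g[, 1] | g[, 2])
          family[idx] <- fam_counter
          ancestry[idx] <- anc
          sib_members <- c(sib_members, idx)
        }
      }
    }
    while (idx < members[s]) {
      idx <- idx + 1L
      a <- pick_ancestry()
      g <- draw_for(a)
      geno[idx, ] <- as.integer(g[, 1] | g[, 2])
      family[idx] <- 0L
      ancestry[idx] <- a
    }
    if (length(sib_members) >= 2) {
      rr <- if (cfg$sib_type == "full") 0.5 else 0.25
      relat[sib_members, sib_members] <- rr
    }
  }
  diag(relat) <- 1
  source_id <- if (cfg$n_sources == 1) rep(1L, n) else
    ifelse(ancestry == 0.5, 0L, ifelse(ancestry == 1, 1L, 2L))

  ids <- sprintf("ind%03d", seq_len(n))
  m <- marker_matrix(geno, individual_ids = ids)
  ages <- c("instar1", "instar2", "instar3", "instar4", "adult")
  age <- sample(ages, n, replace = TRUE)
  sex <- ifelse(age %in% c("instar1", "instar2"), "unknown",
                sample(c("male", "female"), n, replace = TRUE))
  meta <- data.frame(individual_id = ids, web_id = web, age_class = age,
                     sex = sex, easting = 500000 + east, northing = 2695000,
                     stringsAsFactors = FALSE)
  dimnames(relat) <- list(ids, ids)
  truth <- list(individuals = data.frame(individual_id = ids,
                                         family_id = family,
                                         source_id = source_id,
                                         ancestry_source1 = ancestry,
                                         stringsAsFactors = FALSE),
                pedigree_relatedness = relat,
                allele_freqs = q_src)
  structure(list(matrix = m, meta = meta, truth = truth, config = cfg),
            class = "colony_sim")
}

#' Simulate a two-source admixed population
#'
#' Convenience wrapper for [simulate_population()] with `n_sources = 2`:
#' two latent pools with diverged allele-frequency spectra, each
#' individual carrying a true ancestry vector (pure or 50/50 mixed).
#' Ground truth for cluster-number recovery by the admixture module.
#'
#' @param cfg a [colony_config()] with `n_sources = 2` and
#'   `source_divergence > 0`.
#' @return a `"colony_sim"`, as [simulate_population()].
#' @export
simulate_two_source_admixture <- function(cfg) {
  if (cfg$n_sources != 2) stop("cfg$n_sources must be 2")
  if (cfg$source_divergence <= 0) stop("cfg$source_divergence must be > 0")
  simulate_population(cfg)
}

#' Write a simulated dataset as CSV fixtures
#'
#' Writes `<stem>_matrix.csv` in the [read_binary_matrix()] dialect,
#' `<stem>_meta.csv`, and `<stem>_truth.csv` (one row per individual).
#'
#' @param sim a `"colony_sim"` from [simulate_population()].
#' @param stem output path stem.
#' @return invisibly, the three file paths.
#' @export
write_fixture <- function(sim, stem) {
  stopifnot(inherits(sim, "colony_sim"))
  paths <- paste0(stem, c("_matrix.csv", "_meta.csv", "_truth.csv"))
  write_marker_matrix(sim$matrix, paths[1])
  utils::write.csv(sim$meta, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$truth$individuals, paths[3], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
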