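# kleptopop

Population-genetic structure analysis for binary dominant-marker (AFLP)
data from kleptoparasitic spiders — or any organism sampled in groups
("webs") along a transect. The package asks the question behind
group-living: are the individuals that share a host web close kin, or
just co-settlers at a rich resource?

AFLP fingerprints are *dominant*: a band is scored present/absent, and a
presence homozygote cannot be told from a heterozygote. All methods here
work directly on the binary band phenotypes:

- **Filtering** — keep loci whose presence count `c` satisfies
  `2 ≤ c ≤ n − 2` (invariant and singleton loci are uninformative or
  artefactual), drop bandless individuals and under-sampled webs.
- **Ordination** — pairwise Jaccard dissimilarity
  `D = 2B/(1+B)` (with `B = Σ|x_ij − x_ik| / Σ(x_ij + x_ik)`, the binary
  Bray–Curtis quotient; algebraically `D` = mismatched bands / band
  union), embedded by 3-D nonmetric multidimensional scaling minimizing
  Kruskal stress-1.
- **Cluster number** — hierarchical clustering scanned over `C` with the
  average silhouette `s_i = (b_i − a_i) / max(a_i, b_i)`.
- **Admixture** — a haploid admixture Gibbs sampler (ancestry `Q`,
  cluster band frequencies `P`, shared Dirichlet concentration `α`), with
  `ln P(X|K) ≈ mean(lnL) − var(lnL)/2` and Evanno's
  `ΔK = |L(K+1) − 2L(K) + L(K−1)| / sd(K)` for choosing `K`.
- **Relatedness** — the frequency-corrected band-sharing correlation
  `r_xy = Σ_l (x_l − p_l)(y_l − p_l) / Σ_l p_l(1 − p_l)`, with per-web
  permutation tests against random groups of the same size.
- **Spatial autocorrelation** — the multivariate (Smouse–Peakall style)
  coefficient `r` per geographic distance class from the double-centered
  squared genetic distance matrix, with 1000-bootstrap CIs and a
  permutation null; the 0–1 m class is exactly the same-web pairs.
- **Synthetic colonies** — a simulator with latent diploid biallelic loci
  expressed dominantly, webs on a transect, controllable sib-family
  structure, migration, and two-source admixture, so every stage has
  ground truth.

## Worked example

Simulate colonies of pure full-sib groups with no migration — the
strongest possible within-web kinship — and ask whether the analyses see
it:

```r
library(kleptopop)

cfg <- colony_config(n_webs = 8, mean_group_size = 6, n_loci = 120,
                     sib_fraction = 1, migrant_rate = 0, seed = 42)
sim <- simulate_population(cfg)
m    <- filter_loci(sim$matrix)
meta <- sim$meta[sim$meta$individual_id %in% rownames(m), ]

nmds(jaccard_dissimilarity(m), k = 3, max_starts = 20, seed = 1)
#> NMDS ordination: 55 points in 3 dimensions
#> Kruskal stress-1: 0.1684 (converged)

cg <- correlogram(m, meta, bounds = c(1, 150, 300, 600, 1000),
                  n_boot = 200, n_perm = 199, seed = 3)
cg[1, c("upper_bound_m", "n_pairs", "r", "boot_lo", "boot_hi",
        "null_lo", "null_hi", "significant")]
#>   upper_bound_m n_pairs         r   boot_lo   boot_hi     null_lo
#> 1             1     181 0.3980153 0.3817039 0.4130090 -0.03975211
#>       null_hi significant
#> 1 0.007238546        TRUE

head(group_relatedness_test(m, meta, n_perm = 199, n_boot = 200, seed = 4), 3)
#>   web_id n    mean_r   boot_lo   boot_hi    null_lo   null_hi  p_ge   flag
#> 1  web01 5 0.4819961 0.4394185 0.5249752 -0.1082322 0.1196666 0.005 higher
#> 2  web02 5 0.4901427 0.4030341 0.5708401 -0.1044686 0.1126846 0.005 higher
#> 3  web03 6 0.3386462 0.2882500 0.3872410 -0.0805413 0.1398764 0.005 higher
```

Same-web pairs autocorrelate strongly (`r = 0.398`, point estimate and
bootstrap CI both outside the permutation null band — the joint
significance rule), and every web's mean relatedness (≈ 0.5, the
full-sib expectation for this estimator at these band frequencies) is
far above the random-group null. Rerun with `sib_fraction = 0` and both
signals disappear.

The `analysis/` directory holds the full narrative workflow as numbered
scripts: `01_simulate.R` (the three study designs), `02_ordination_clustering.R`,
`03_admixture.R`, `04_relatedness_autocorr.R`, and `05_field_reproduction.R`;
each writes its tables under `results/`.

## Vignette

`vignettes/kleptopop-methods.Rmd` documents the models and estimators,
the simulator's assumptions, numerical choices, calibration evidence,
and known limitations.
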