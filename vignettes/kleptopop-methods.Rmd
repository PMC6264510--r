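---
title: "Models and methods for dominant-marker colony structure analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for dominant-marker colony structure analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

kleptopop analyses binary dominant-marker (AFLP-style) band profiles of
individuals sampled in groups that share a host web, positioned along a
field transect. This vignette is the package's own account of what each
stage computes, which choices were open, and what the synthetic tests do
and do not establish.

## The data and their information limit

A band profile is a vector of 0/1 calls per locus. Dominance means a
present band hides allele dosage: genotype (1,1) and (1,0) both print a
band. Consequently no estimator here can use heterozygosity; everything
is built on band presence frequencies. Loci are anonymous restriction
fragments scattered across the genome, so linkage equilibrium is a
reasonable working assumption and every analysis treats loci as
independent.

### Filtering

A locus with presence count below 2, or above `n - 2`, is either
uninformative (invariant) or indistinguishable from a scoring artefact
(a singleton band, or a single missing band). `filter_loci()` keeps
exactly the loci with `2 <= c <= n - 2`. An individual whose retained
profile is all zeros has no usable fingerprint — every dissimilarity
below would be undefined on it — so it is dropped by default
(`drop_empty_individuals = FALSE` turns this off); dropping individuals
can re-expose singleton loci, so the filter iterates to a fixed point,
which also makes it idempotent. Webs with fewer than two members carry
no within-group information and are removed before group analyses;
relatedness testing needs at least three members per web, since with one
or two the permutation and bootstrap bands coincide.

### Coordinates

Web GPS fixes are projected to UTM (WGS84, 6-degree zones, scale 0.9996)
with the standard transverse-Mercator series, accurate to well under a
meter within a zone — negligible against hand-held GPS error. Transects
spanning a zone boundary are rejected with advice to use a local planar
projection. All members of a web share one position, so same-web pairs
are at geographic distance exactly 0.

## Ordination

The dissimilarity is Jaccard's: `D = 2B/(1 + B)` where `B` is the binary
Bray–Curtis quotient `sum|x - y| / sum(x + y)`; algebraically `D` is the
number of mismatched bands over the size of the band union, which the
test suite asserts. `D` is 0 only for identical profiles and 1 for
band-disjoint ones.

NMDS is run through vegan's global engine (`metaMDS`/`monoMDS`) in three
dimensions: rank-based monotone regression, steepest-descent stress
minimization, many random starts with the first start from classical
metric scaling, a start stopping when the between-iteration stress ratio
exceeds 0.999999 (or stress falls below 1e-4), and the lowest-stress
configuration returned. The package's own `kruskal_stress()` —
pool-adjacent-violators regression of configuration distances onto the
dissimilarity rank order, primary tie treatment (tied dissimilarities
pre-sorted by fitted distance) — is an independent implementation used to
cross-check the optimizer's reported stress. Stress depends on the
dissimilarities only through their ranks; that invariance is exact for
`kruskal_stress()` and is tested as such. The optimizer itself is
stochastic, so two runs from different seeds may land in different local
minima; only the returned best-of-starts stress is meaningful, and a
degenerate all-coincident configuration is assigned stress 1 with a
warning.

## How many genetic clusters?

Hierarchical clustering of the Jaccard matrix is cut at every `C` from 2
to the number of webs sampled, and each partition is scored by the
average silhouette `s_i = (b_i - a_i)/max(a_i, b_i)` (`a` mean
within-cluster, `b` mean nearest-other-cluster dissimilarity; singleton
clusters score 0). The denominator is Rousseeuw's `max(a, b)`: the
alternative reading `|a - b|` would force every score to ±1 and carry no
information. `C = 1` has no silhouette and is assigned 0 by convention,
so it is reported (with a warning) only when every multi-cluster
partition scores negative; ties break toward smaller `C`.

Linkage is a genuinely open choice on distance-only input. The default
is average linkage (UPGMA), the conventional choice for ecological
dissimilarities; `optimal_clusters()` accepts average, complete, single
and Ward-type linkage, and the field-reproduction harness runs all four
and reports which reproduces a published optimum. Merge ties are
resolved by `hclust`'s deterministic convention, so results are
reproducible for a fixed input order.

## Haploid admixture model

Each individual `x` has ancestry proportions `q_x ~ Dirichlet(alpha)`
over `K` clusters; each locus independently draws an origin cluster from
`q_x` and then a band from that cluster's frequency `p_kl ~ Beta(1,1)`.
Treating the dominant band itself as the (haploid) allele is the same
modelling compromise the original field analysis made: it discards
dosage information the data never had. The Gibbs sampler (in C++ for
speed) alternates the conjugate updates of origins, `P`, and `Q`, and
updates the single shared `alpha` by random-walk Metropolis on
`log(alpha)` (step 0.05, uniform prior on (0, 10]). The data
log-likelihood is recorded every 10 post-burn-in iterations;
`ln P(X|K)` is estimated as `mean(lnL) - var(lnL)/2`, and Evanno's
`delta-K = |L(K+1) - 2L(K) + L(K-1)| / sd(K)` over replicate chains
picks `K`. `delta-K` is undefined at the ends of the scan and wherever
the replicate sd is zero (flagged, excluded from the argmax); its
magnitude depends on replicate noise, so only the argmax is treated as a
result. Label switching across chains is handled by greedy
column-correlation matching, used only for averaged displays.

Binary-locus mixtures mix quickly, so the package defaults to
2,000 + 4,000 iterations with 3–10 replicate chains; the reference-scale
setting (10^6 + 10^6) is supported but unnecessary for the problem sizes
here — posterior ancestry on strongly diverged two-source simulations is
already >0.95 confident at the short setting, and the scan recovers
K = 2 in ≥90% of replicates (tested).

## Relatedness on dominant bands

Codominant relatedness estimators (Queller–Goodnight and kin) need
allele dosage, which dominant bands hide. The package uses the centered
band-sharing correlation
`r_xy = sum_l (x_l - p_l)(y_l - p_l) / sum_l p_l(1 - p_l)`
with `p_l` the sample band frequencies. Its virtues: defined on
phenotypes, zero-centered for random pairs (matching a null of
"relatedness 0"), exactly anti-symmetric in the sample (the off-diagonal
sum equals minus the diagonal sum — an identity the tests assert), and
monotone in true kinship (full sibs > half sibs > unrelated, verified on
pedigree simulations). Its *scale* is not a pedigree coefficient: the
within-web means it produces are comparable across webs of one dataset,
not across datasets. The estimator sits behind a single function so a
Lynch–Milligan-style dominant estimator could be swapped in.

The per-web test draws `n_perm` random groups of the web's size from the
whole sample (without replacement within a draw — a random group of real
spiders), forming the null band of group means; `p_ge` is the one-sided
`P(mean_random >= mean_observed)` with the +1 correction so p is never
zero. A web comprising the entire sample makes every draw tie the
observed mean — `p_ge` is then 1 by construction and nothing is flagged.
Bootstrap CIs come from resampling within-web pairs with replacement.

## Spatial autocorrelation

The squared genetic distance between two binary profiles is their
mismatch count. Gower double-centering turns the squared-distance matrix
into a centered covariance-like matrix `c` (rows sum to zero — asserted
at 1e-9 relative tolerance on every run). For distance class `h`,

`r_h = sum_{(x,y) in h} c_xy / sum_x w_x(h) c_xx`

over ordered pairs, `w_x(h)` counting x's partners in the class. Useful
exact consequences, all tested: a lone pair gives `r = -1`; a single
class holding all pairs gives `r = -1/(n-1)`; clone-webs that share no
bands across webs give same-web `r = +1`; and the class numerators sum
to `-trace(c)`.

Distance classes are right-closed bins of the pairwise geographic
distances; the first bound must be at least 1 m so class 1 is exactly
the same-web pairs (the host web is about a meter across). Empty classes
are merged into their right neighbour (or rejected in strict mode), and
a final bound short of the maximum distance is extended.

Two uncertainty measures per class: a bootstrap CI (pairs resampled with
replacement within the class, each unordered pair contributing `2c_xy`
to the numerator and `c_xx + c_yy` to the denominator) and a permutation
null band (whole genotypes shuffled across positions — the individual,
not the web, is the permutation unit, matching a null of no spatial
structure at the individual level; a web-level mode would be a
sensitivity analysis). Defaults: 1000 bootstraps, 999 permutations.

Two flags are reported. `signif_perm` — the point estimate falls outside
the 95% permutation band — is the permutation test proper and holds its
nominal 5% level (calibrated at 5% ± 2% on 200 panmictic simulations in
the test suite, alongside uniformity of the permutation p-values).
`significant` — the point estimate *and* its whole bootstrap CI outside
the null band — is the deliberately conservative joint rule used for
biological claims; it trades type-I error well below nominal for fewer
false discoveries, which is why calibration is stated for the
permutation component and power for the joint rule.

## The synthetic colony simulator

`simulate_population()` emulates the field design: webs evenly spaced
(optionally jittered) along a 1 km transect, group sizes Poisson with
mean 11 (truncated at 2), 200 loci by default. The latent model is
diploid and biallelic with per-locus dominant-allele frequency drawn
Uniform(0.1, 0.9) — chosen so the band frequency `1 - (1-q)^2` stays
clear of the filter's singleton zone; the tested dominance law is
exactly that closed form. Each web receives a fraction of one sib family
(two shared parents for full sibs, a shared mother for half sibs,
Mendelian segregation) and unrelated settlers; `migrant_rate` replaces
sib slots with global draws. Two-source mode offsets the allele
frequency spectra by `source_divergence` (0.9 gives near-fixed
differences, 0.05 vs 0.95) and assigns pure or 50/50-mixed ancestry per
individual. Everything — family ids, source ids, pairwise pedigree
relatedness in {0, 0.25, 0.5} — is returned as ground truth, and the
same config and seed reproduce a dataset bit for bit.

What the simulator does *not* emulate: scoring error and band
homoplasy (co-migrating non-homologous fragments), linkage, null-allele
frequency drift between webs, isolation-by-distance within the settler
pool, and overlapping generations. Passing tests therefore show the
estimators are correct and calibrated under a clean dominant-marker
model, not that field data are free of those artefacts — on real AFLPs
the published mismatch rates (1.5–7.6%) add noise that attenuates all
signals.

## Problem sizes and numerical choices

The test suite and acceptance script use scaled designs chosen to make
Monte-Carlo bands tight while keeping a full run on one CPU in minutes:
calibration uses 200 panmictic replicates of 20 webs × 5 spiders × 300
loci with 199 permutations; power uses 50 replicates of 10 full-sib webs
× 6 with 100 loci (joint-rule significance ≥90%); admixture recovery
uses 20 replicates of 8 webs × 5 at 60 loci, K scanned 1–4 with 3 chains
of 500 + 1500 iterations; pedigree monotonicity uses 2000 loci where the
contrast is the point. Stage seeds derive from one global seed by an
integer hash (`derive_seed`), so any stage can be rerun alone and whole
reports are byte-stable under a fixed seed.

Degenerate inputs are handled explicitly: all-identical genotypes make
the autocorrelation denominator zero (an error naming the cause), a
coincident NMDS configuration scores stress 1 with a warning, silhouette
needs two clusters, delta-K needs interior K and nonzero replicate sd,
and the log-likelihood trace must hold at least 10 records.

## Known limitations

- The relatedness estimator's scale depends on the band-frequency
  spectrum; compare webs within a dataset only.
- Only the argmax of delta-K is interpretable; with truly panmictic data
  delta-K still names *some* K, so it should be read together with the
  silhouette profile and the correlogram.
- The NMDS stress surface has local minima; published stress values are
  reproducible only as best-of-many-starts at matching start counts.
- The joint significance rule is conservative by design; absence of a
  joint flag is not evidence of absence of structure at nominal 5%.
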