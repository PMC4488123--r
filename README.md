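# epifpca

Functional principal component analysis of genomic coverage profiles, and a
two-coefficient scheme for correlating pairs of epigenomic datasets.

## The problem

Pairwise comparison of ChIP-seq tracks is usually done by correlating read
enrichment directly: bin the coverage of two histone marks over a set of
windows (say ±5 kb around transcription start sites) and compute one Pearson
coefficient. By construction this can only detect signals that rise and fall
*in the same bases*. Two marks that are co-regulated but deposited in
different sub-intervals of the window — one at the promoter, one over the
gene body — correlate near zero and the association is invisible.

`epifpca` treats each region's coverage profile as a function
x<sub>i</sub>(t) on the window \[a, b\] and decomposes the collection of
profiles with a finite Karhunen–Loève transform (functional PCA):

x<sub>i</sub>(t) = μ(t) + Σ<sub>k</sub> η<sub>ik</sub> ξ<sub>k</sub>(t)

where the ξ<sub>k</sub> are orthonormal eigenfunctions of the covariance
function v(s, t) = Σ<sub>k</sub> λ<sub>k</sub> ξ<sub>k</sub>(s)
ξ<sub>k</sub>(t), the scores η<sub>ik</sub> = ∫(x<sub>i</sub> − μ)
ξ<sub>k</sub> are uncorrelated across components, and
λ<sub>k</sub> = var(η<sub>k</sub>). Numerically, profiles are expanded in a
B-spline basis φ<sub>1..K</sub> (coefficients by ordinary least squares,
x<sub>i</sub> ≈ Σ c<sub>ik</sub> φ<sub>k</sub>) and the eigenproblem is
solved in basis coordinates through the Cholesky factor of the Gram matrix
W = ∫φφᵀ.

For two datasets A and B, each component pair (j, k) then yields **two**
coefficients:

* **eigenfunction correlation** r<sub>ξ</sub> — Pearson correlation of
  ξ<sup>A</sup><sub>j</sub> and ξ<sup>B</sup><sub>k</sub> on a common grid:
  do the regions of variability co-localize?
* **score correlation** r<sub>η</sub> — Pearson correlation of the two
  score vectors over shared regions: do the signals co-vary, wherever each
  mark's variability happens to sit?

A mark pair with r<sub>η</sub> ≫ 0 but r<sub>ξ</sub> ≤ 0 is *correlated but
not co-localized* — exactly the situation the ordinary coverage correlation
cannot see. Score correlations are tested with two-sided t-tests and
Bonferroni correction over all component pairs.

The package is aimed at computational epigenomics work: inputs are bedGraph
coverage tracks (wigsum-normalized to 10⁸ total signal), BED6 anchor
regions (TSS convention, strand-aware, profiles transcription-oriented),
BED3 blacklists, and RPKM expression tables for score–expression
association. A synthetic-data generator with planted eigenfunctions, score
variances and cross-mark score correlations makes every pipeline stage
testable without external data.

## Worked example

Simulate the "correlated but not co-localized" scenario: 2000 regions, one
planted component with λ = 9, mark B's eigenfunction circularly shifted by
half the window, and a planted cross-mark score correlation of 0.8.

```r
library(epifpca)

spec <- simulation_spec(L = 2000, n_components = 1, lambdas = 9,
                        cross_rho = 0.8, eigen_family = "bumps",
                        eigen_shift_B = 5000, seed = 7)
sim  <- simulate_mark_pair(spec)

basis <- make_basis(-5000, 5000, K = 50)
fitA  <- fpca(fit_coefficients(sim$profiles_A, basis), J = 5)
fitB  <- fpca(fit_coefficients(sim$profiles_B, basis), J = 5)
fitA
#> Functional PCA: 2000 regions, K = 50 basis functions, J = 5 components
#>   lambda[1:5]: 9.092, 0.1338, 0.1302, 0.1287, 0.1266
#>   cumulative variance explained (J = 5): 68.7%

lay <- make_fixture_regions(spec$L, spec$flank)
cc <- cross_correlate(fitA, fitB, names_AB = c("markA", "markB"),
  trackA  = profiles_to_track(sim$profiles_A, lay$regions, lay$chrom_sizes),
  trackB  = profiles_to_track(sim$profiles_B, lay$regions, lay$chrom_sizes),
  regions = lay$regions)
cc
#> Cross-dataset FPCA comparison: markA vs markB (2000 shared regions)
#>   Ordinary coverage correlation:       0.000
#>   Max correlation of xi  (first 5):    0.577 (2,2), r_eta there  0.008
#>   Max correlation of eta (first 5):    0.787 (1,1), r_xi there -0.434
#>   Significant pairwise correlations: 1 of 25 (Bonferroni, alpha = 1e-06)
```

Reading the output: the fitted first component carries λ̂₁ ≈ 9.09 of
variance (the planted 9 plus the noise floor). The ordinary coverage
correlation is 0.000 — the two marks share no genomic sub-interval of
variability, and indeed the first components' eigenfunction correlation is
negative (−0.434). Yet their scores correlate at 0.787, recovering the
planted co-regulation of 0.8 (slightly attenuated by noise in the score
estimates), and that pair is the single Bonferroni-significant one among
the 25 tested.

Scores also carry the expression signal the generator plants through mark
A's first component:

```r
round(head(score_expression_correlation(fitA, sim$expression), 3), 3)
#>   component      r     p significant
#> 1         1  0.881 0.000           1
#> 2         2 -0.003 0.891           0
#> 3         3  0.007 0.765           0
```

For file-based workflows the same steps are available from the shell via
the installed script (subcommands `simulate`, `fit`, `correlate`,
`expression`, `coverage-corr`):

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "epifpca.R", package = "epifpca"))') \
    simulate --out bundle --L 200 --seed 1
```

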