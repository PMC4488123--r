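---
title: "Methods: functional PCA of coverage profiles and cross-dataset correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional PCA of coverage profiles and cross-dataset correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epifpca)
```

## Model

Each genomic region $i$ contributes a coverage profile $x_i(t)$ on a common
window $[a, b]$ around its anchor (for TSS analyses, $[-5000, 5000]$ bp in
transcription orientation). The collection of profiles is modelled by the
finite Karhunen--Loève expansion

$$x_i(t) = \mu(t) + \sum_{k=1}^{J} \eta_{ik}\, \xi_k(t) + \varepsilon_i(t),$$

with orthonormal eigenfunctions $\xi_k$ of the covariance function
$v(s,t) = \sum_k \lambda_k \xi_k(s)\xi_k(t)$, uncorrelated scores
$\eta_{ik} = \int (x_i - \mu)\,\xi_k$, and eigenvalues
$\lambda_k = \operatorname{var}(\eta_k)$, $\lambda_1 \ge \lambda_2 \ge
\dots$ The first eigenfunction is the dominant mode of variation *between
regions*; large $|\xi_k(t)|$ marks positions of high between-region
variability, not of high mean signal.

The assumptions are those of classical FPCA: profiles are square-integrable
realisations of a common random function, smooth enough to be represented
in a moderate spline basis, observed on a common equidistant grid, and
exchangeable across regions (no spatial dependence *between* windows is
modelled). Centering is across regions only: the mean function $\mu$ is
removed, but no per-region vertical shift is taken out, so a region with
uniformly elevated coverage legitimately loads on any component with a
non-zero mean-like shape.

## Numerical realisation

**Basis expansion.** Profiles are expanded in $K$ B-spline basis functions
of order 4 (cubic) with equidistant interior knots, boundary knots repeated
to full multiplicity. Coefficients are estimated by unpenalized ordinary
least squares on the profile grid, one shared normal-equations Cholesky
factorisation for all regions. Least squares (rather than a roughness
penalty) is appropriate here because smoothing is already implied by the
ratio of grid points to basis functions (1000 bins vs 50 functions at the
defaults); penalized variants are intentionally out of scope.

**Gram matrix.** All function-space geometry runs through the Gram matrix
$W_{jk} = \int \phi_j \phi_k$. $W$ is computed by per-knot-span
Gauss--Legendre quadrature with `order` nodes per span, which is exact for
the piecewise-polynomial integrand (degree $2(\mathrm{order}-1)$), so no
quadrature tolerance enters the decomposition itself.

**Eigenproblem.** With centered coefficient rows $C$ (an $L \times K$
matrix), coefficient covariance $\Sigma_c = C^\top C/(L-1)$ and Cholesky
factor $W = R^\top R$, the generalized eigenproblem is solved in the
symmetrized form $R\,\Sigma_c\,R^\top = U \Lambda U^\top$ with
$B = R^{-1} U$, giving $B^\top W B = I$ (orthonormal eigenfunctions in the
$L^2$ inner product, not merely in coefficient space). Scores are computed
exactly in basis algebra, $\eta = C W B$, which makes the score covariance
equal $\Lambda$ to machine precision: sample score variances equal the
eigenvalues and score columns are uncorrelated by construction, properties
the test suite asserts rather than assumes. Eigenvalues in
$(-10^{-10}, 0)$ are clipped to zero; the covariance divisor is $L - 1$
throughout.

**Sign convention.** Eigenfunction signs are mathematically arbitrary. For
reproducibility across linear-algebra backends each $\xi_k$ is evaluated on
2001 equidistant points and flipped, together with its score column, so
that the point of maximum $|\xi_k|$ is positive. Exactly degenerate spectra
keep the symmetric solver's output order; ties in the maximum location
resolve to the first grid point. One caveat documented here deliberately:
for shapes with two extremes of equal magnitude and opposite sign (a pure
sine, for instance) the convention is decided by noise, and a fitted pair
of datasets can come out with jointly flipped $(\xi_1, \eta_1)$. The two
cross-dataset coefficients then flip together, so their product and all
significance statements are invariant; only the individual signs are not
identified. Shapes with a unique dominant extreme are stable.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `flank` | 5000 | bp | TSS-centred ±5 kb window; covers promoter and first gene-body nucleosomes |
| `bin_size` / `grid_bin` | 10 | bp | per-base sampling is redundant once a smooth basis is fitted; 1000 bins per window |
| `K` | 50 | functions | enough local support to follow nucleosome-scale features over 10 kb; `K - 4` equidistant interior knots |
| `order` | 4 | — | cubic splines, the standard functional-data default |
| `J` | `min(K, L-1)` | components | the full spectrum; analyses typically inspect the first 5 |
| `target_wigsum` | 1e8 | signal·bp | library-size normalization of the genome-wide total signal |
| `alpha` | 1e-6 | — | family-wise level for Bonferroni over all `J_A x J_B` score-correlation tests |
| `J_report` | 5 | components | the maximum-correlation summary searches leading components only, where variance concentrates |

The Bonferroni family is the set of component pairs tested for *one*
dataset pair ($50 \times 50 = 2500$ tests at the defaults); no additional
correction is applied across dataset pairs, which is the user's
responsibility when screening many mark combinations.

## Input conventions and degenerate cases

Coordinates are 0-based half-open throughout (BED convention); the anchor
of a `+` feature is its `start`, of a `-` feature its `end - 1`. Profiles
of `-` strand regions are reversed so the functional coordinate is
transcription-oriented — chromatin signal around TSSs is asymmetric, and
mixing orientations would blur exactly the structure the decomposition is
meant to find. The ordinary coverage-correlation baseline deliberately does
*not* reverse (genome orientation), mirroring the behaviour of the
standard genome-browser correlation utilities it emulates; the asymmetry
between the two code paths is intended.

Uncovered bases are signal 0, not missing data (bedGraph omits zero runs by
convention). Tracks with zero total signal cannot be normalized (error).
Regions whose window leaves the chromosome are dropped with a reported
count; duplicate `(chrom, anchor, strand)` entries keep the first.
Blacklist filtering removes a region on any overlap of one base or more.
Zero-variance score columns in a correlation yield $r = 0$, $p = 1$ and a
warning rather than `NA`s. Quantile binning is by equal counts with stable
ties (input order) and remainders assigned to the lowest bins; bins with
fewer than two members are an error.

For the Q1-vs-Q10 expression contrast, two statistics are reported: a Welch
two-sample t-test (the primary one, making no pairing assumption) and a
rank-paired variant that pairs order statistics after truncation to equal
length. The pairing design behind published quantile contrasts of this
kind is ambiguous, so both are exposed and labelled; neither is claimed to
be canonical.

## The synthetic generator

`simulation_spec()` / `simulate_mark_pair()` generate paired datasets with
*planted* Karhunen--Loève structure: orthonormal eigenfunctions (Fourier,
shifted-Legendre, or compactly supported cosine bumps, orthonormalized
under trapezoid quadrature on the working grid), scores drawn per component
from a bivariate normal with variances $\lambda_k$ and cross-mark
correlation $\rho_k$, i.i.d. white noise per bin, and a positive baseline.
The defaults — $L = 1000$ regions, three components with
$\lambda = (9, 4, 1)$, $\rho = (0.8, 0.4, 0.2)$, noise sd 0.1 per 10 bp
bin, baseline 1 — are the canonical simulated study used throughout the
tests; the bump family with a half-window circular shift of mark B creates
the correlated-but-not-co-localized scenario. Expression is generated as
$\mathrm{softplus}(\sum_k w_k \eta^A_{ik} + \text{noise})$, which keeps
RPKM non-negative while preserving monotone dependence on the scores.
`write_fixture_bundle()` lays the profiles onto a toy two-chromosome genome
with non-overlapping, strand-alternating windows and emits
bedGraph/BED/TSV/JSON files that round-trip bit-exactly through the
package's readers.

What the generator does **not** emulate: read-level sampling noise
(counts, duplicates, mappability, GC bias), peak-shaped mean structure
correlated with the eigenfunctions, overlapping or nested windows, and
heavy-tailed region-to-region baseline variation. Passing tests therefore
demonstrate correctness of the decomposition and of the correlation
machinery under the stated model, not robustness to every artefact of real
ChIP-seq data.

A quantitative point worth knowing when interpreting recovered
correlations: estimated scores carry measurement noise of variance roughly
$\sigma^2 \Delta$ ($\sigma$ = noise sd per bin, $\Delta$ = bin width),
which attenuates a planted score correlation $\rho$ toward
$\rho\,\lambda/(\lambda + \sigma^2\Delta)$ and inflates $\hat\lambda_k$ by
about the same noise floor. At the default noise (0.1 per 10 bp bin,
floor 0.1) the attenuation of $\rho = 0.8$ with $\lambda = 9$ is about 1%,
well inside sampling error at $L = 2000$; at noise sd $0.3$ the expected
recovery is $\approx 0.73$ and no estimator of this type would return the
planted value. Recovery claims in the tests are made at the default noise
for this reason.

## Problem sizes and test design

The suite exercises the full pipeline at the sizes the analyses are
designed for while staying desk-sized: oracle comparisons run five
$L = 50$, $K = 10$ instances against a dense-grid (2001-point) weighted-PCA
computed by SVD, independent of the basis algebra; parameter recovery uses
$L = 1000$ with $K = 50$; the correlated-not-co-localized scenario
$L = 2000$; the null calibration 20 replicates of $L = 500$ with the full
$50 \times 50$ component-pair family. Quadrature-based checks compare the
exact per-span Gauss--Legendre Gram matrix against dense trapezoid
quadrature; agreement there is limited by the $O(h^2)$ error of the
*oracle* (about $10^{-7}$ at $10^4$ points), not of the implementation,
and tolerances are set accordingly.

## Known limitations

* No penalized/smoothed FPCA and no irregular-sampling designs; profiles
  must live on one common equidistant grid per analysis.
* No functional regression or canonical correlation; the comparison scheme
  is pairwise correlation of components.
* Individual eigenfunction signs are unidentified for symmetric two-lobed
  shapes (see the sign-convention caveat above).
* BigWig input is expected to be converted to bedGraph upstream; the core
  consumes text formats only, which keeps every interface testable.
* The ordinary-correlation baseline and the FPCA path intentionally differ
  in strand handling; comparing their numbers assumes that difference is
  understood.
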