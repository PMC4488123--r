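#' Specification of a synthetic paired-mark simulation
#'
#' Defines the planted Karhunen-Loeve structure for a pair of coverage
#' datasets ("mark A" and "mark B"): orthonormal eigenfunctions, score
#' variances `lambda_k`, planted cross-mark score correlations, white noise
#' and an expression model driven by mark A's scores. Mark B's
#' eigenfunctions can be circularly shifted relative to mark A's, which
#' creates the "correlated but not co-localized" scenario: the two marks'
#' scores co-vary while their regions of variability do not overlap.
#'
#' Default values describe the canonical simulated study: 1000 regions with
#' a +/- 5 kb window binned at 10 bp, three planted components with score
#' variances 9, 4, 1 and cross-mark score correlations 0.8, 0.4, 0.2,
#' white noise of sd 0.1 per grid point, and a positive baseline.
#'
#' @param L number of regions (>= 10).
#' @param flank window half-width in bp.
#' @param grid_bin bin width in bp.
#' @param n_components number of planted components `J_true`.
#' @param eigen_family `"fourier"`, `"legendre"` or `"bumps"`.
#' @param eigen_shift_B circular shift (bp) applied to mark B's
#'   eigenfunctions.
#' @param lambdas planted score variances, positive non-increasing.
#' @param cross_rho planted score correlations between marks, in `[-1, 1]`.
#' @param noise_sd white-noise sd added per grid point.
#' @param baseline constant added to keep signal mostly positive.
#' @param expression_weights weights of mark A's score columns in the
#'   expression model `rpkm = softplus(sum_k w_k eta_ik + noise)`.
#' @param expression_noise_sd expression noise sd.
#' @param seed integer RNG seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(L = 1000, flank = 5000, grid_bin = 10,
                            n_components = 3,
                            eigen_family = c("fourier", "legendre", "bumps"),
                            eigen_shift_B = 0,
                            lambdas = c(9, 4, 1)[seq_len(n_components)],
                            cross_rho = c(0.8, 0.4, 0.2)[seq_len(n_components)],
                            noise_sd = 0.1, baseline = 1,
                            expression_weights = rep(1, n_components),
                            expression_noise_sd = 0.5,
                            seed = 1L) {
  eigen_family <- match.arg(eigen_family)
  if (L < 10) stop("L must be >= 10")
  if (length(lambdas) != n_components || any(!is.finite(lambdas)) ||
      any(lambdas <= 0) ||
      is.unsorted(rev(lambdas)))
    stop("lambdas must be positive and non-increasing, length n_components")
  if (length(cross_rho) != n_components || any(!is.finite(cross_rho)) ||
      any(cross_rho < -1 | cross_rho > 1))
    stop("cross_rho entries must be in [-1, 1], length n_components")
  if ((2 * flank) %% grid_bin != 0)
    stop("2 * flank must be divisible by grid_bin")
  structure(list(L = L, flank = flank, grid_bin = grid_bin,
                 n_components = n_components, eigen_family = eigen_family,
                 eigen_shift_B = eigen_shift_B, lambdas = lambdas,
                 cross_rho = cross_rho, noise_sd = noise_sd,
                 baseline = baseline,
                 expression_weights = expression_weights,
                 expression_noise_sd = expression_noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate an orthonormal function set on a grid
#'
#' Builds `J` smooth functions of the requested family on the grid,
#' optionally applies a circular (wrap-around) translation, then
#' orthonormalizes them by Gram-Schmidt under the trapezoid-quadrature
#' inner product so the set is orthonormal on the grid to machine
#' precision. Families: `fourier` (sine/cosine pairs, no constant),
#' `legendre` (shifted Legendre polynomials of degree >= 1), `bumps`
#' (Gaussian bumps at distinct centres).
#'
#' @param family `"fourier"`, `"legendre"` or `"bumps"`.
#' @param J number of functions (>= 1).
#' @param interval numeric length-2 interval `[a, b]`.
#' @param shift circular translation in the grid's units (e.g. bp).
#' @param grid evaluation grid (equidistant); default 1001 points over the
#'   interval.
#' @return A `length(grid) x J` matrix with attribute `grid`.
#' @export
make_orthonormal_set <- function(family, J, interval, shift = 0,
                                 grid = NULL) {
  if (J < 1) stop("J must be >= 1")
  a <- interval[1]; b <- interval[2]
  if (is.null(grid)) grid <- seq(a, b, length.out = 1001)
  u <- (grid - a) / (b - a)
  G <- length(grid)
  raw <- switch(
    family,
    fourier = {
      sapply(seq_len(J), function(k) {
        h <- ceiling(k / 2)
        if (k %% 2 == 1) sin(2 * pi * h * u) else cos(2 * pi * h * u)
      })
    },
    legendre = {
      # shifted Legendre P_k(2u - 1), degree k = 1..J, by recurrence
      x <- 2 * u - 1
      P <- matrix(0, G, J + 1)
      P[, 1] <- 1
      if (J >= 1) P[, 2] <- x
      if (J >= 2) for (k in 2:J)
        P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
      P[, -1, drop = FALSE]
    },
    bumps = {
      # compactly supported cosine bumps packed into the left half of the
      # interval, so a half-interval circular shift gives exactly zero
      # overlap; supports are mutually disjoint (orthogonal by design)
      centers <- a + (b - a) * (2 * seq_len(J) - 1) / (4 * J)
      half <- 0.45 * (b - a) / (2 * J)
      sapply(seq_len(J), function(k) {
        d <- abs(grid - centers[k])
        ifelse(d < half, cos(pi * d / (2 * half))^2, 0)
      })
    },
    stop("unsupported eigenfunction family: ", family)
  )
  raw <- matrix(raw, nrow = G)
  if (shift != 0) {
    step <- grid[2] - grid[1]
    k <- round(shift / step) %% G
    if (k != 0) raw <- raw[c((G - k + 1):G, seq_len(G - k)), , drop = FALSE]
  }
  # trapezoid weights on the grid
  w <- rep(grid[2] - grid[1], G)
  w[c(1, G)] <- w[c(1, G)] / 2
  # Gram-Schmidt under the quadrature inner product
  for (j in seq_len(J)) {
    v <- raw[, j]
    if (j > 1) {
      proj <- crossprod(raw[, seq_len(j - 1), drop = FALSE], w * v)
      v <- v - raw[, seq_len(j - 1), drop = FALSE] %*% proj
    }
    nrm <- sqrt(sum(w * v^2))
    if (nrm < 1e-12) stop("degenerate function set (family ", family, ")")
    raw[, j] <- v / nrm
  }
  attr(raw, "grid") <- grid
  raw
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Simulate a pair of coverage-profile datasets with planted KL structure
#'
#' Draws, for each component `k`, region scores from a bivariate normal
#' with variances `lambda_k` for both marks and correlation
#' `cross_rho[k]`, independent across components and regions; builds
#' profiles `x_i(t) = baseline + sum_k eta_ik xi_k(t) + noise` for each
#' mark, with mark B using the circularly shifted eigenfunction set.
#' Expression values driven by mark A's scores are generated as
#' `softplus(sum_k w_k eta_ik + noise)`. Fully deterministic given
#' `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @return A list with `profiles_A`, `profiles_B` (both
#'   [profile_matrix()]), `expression` (named vector) and `truth` (list
#'   holding the planted scores, eigenfunction matrices, grid and the
#'   spec).
#' @export
simulate_mark_pair <- function(spec) {
  set.seed(spec$seed)
  G <- as.integer(2 * spec$flank / spec$grid_bin)
  grid <- -spec$flank + (seq_len(G) - 1) * spec$grid_bin
  interval <- c(-spec$flank, spec$flank)
  xi_A <- make_orthonormal_set(spec$eigen_family, spec$n_components,
                               interval, shift = 0, grid = grid)
  xi_B <- make_orthonormal_set(spec$eigen_family, spec$n_components,
                               interval, shift = spec$eigen_shift_B,
                               grid = grid)
  L <- spec$L
  J <- spec$n_components
  scores_A <- matrix(0, L, J)
  scores_B <- matrix(0, L, J)
  for (k in seq_len(J)) {
    z1 <- stats::rnorm(L)
    z2 <- stats::rnorm(L)
    rho <- spec$cross_rho[k]
    sdk <- sqrt(spec$lambdas[k])
    scores_A[, k] <- sdk * z1
    scores_B[, k] <- sdk * (rho * z1 + sqrt(1 - rho^2) * z2)
  }
  region_ids <- sprintf("region_%05d", seq_len(L))
  XA <- spec$baseline + tcrossprod(scores_A, xi_A) +
    matrix(stats::rnorm(L * G, sd = spec$noise_sd), L, G)
  XB <- spec$baseline + tcrossprod(scores_B, xi_B) +
    matrix(stats::rnorm(L * G, sd = spec$noise_sd), L, G)
  expr <- softplus(drop(scores_A %*% spec$expression_weights) +
                     stats::rnorm(L, sd = spec$expression_noise_sd))
  names(expr) <- region_ids
  list(profiles_A = profile_matrix(XA, region_ids, grid),
       profiles_B = profile_matrix(XB, region_ids, grid),
       expression = expr,
       truth = list(scores_A = scores_A, scores_B = scores_B,
                    xi_A = xi_A, xi_B = xi_B, grid = grid, spec = spec))
}

#' Lay out non-overlapping fixture regions on a toy two-chromosome genome
#'
#' Regions alternate between two chromosomes and between strands; windows
#' are separated by a gap so they never overlap (wigsum arithmetic over the
#' windows is then exact).
#'
#' @param L number of regions.
#' @param flank window half-width in bp.
#' @param gap gap between consecutive windows in bp.
#' @return A list with `regions` (a [region_set()]) and `chrom_sizes`.
#' @export
make_fixture_regions <- function(L, flank, gap = 1000) {
  chrom <- rep(c("chrS1", "chrS2"), length.out = L)
  idx_on_chrom <- stats::ave(seq_len(L), chrom, FUN = seq_along)
  anchor <- gap + flank + (idx_on_chrom - 1) * (2 * flank + gap)
  strand <- rep(c("+", "-"), length.out = L)
  chrom_sizes <- sapply(c("chrS1", "chrS2"), function(ch) {
    n <- sum(chrom == ch)
    gap + n * (2 * flank + gap)
  })
  regions <- region_set(
    data.frame(region_id = sprintf("region_%05d", seq_len(L)),
               chrom = chrom, anchor = anchor, strand = strand,
               class_label = "pc"),
    flank)
  list(regions = regions, chrom_sizes = chrom_sizes)
}

#' Build a coverage track carrying given per-region profiles
#'
#' Inverse of [extract_profiles()]: writes each region's binned profile
#' onto the genome as constant-value intervals of one bin each, reversing
#' `-` strand profiles back to genome orientation. Region windows must not
#' overlap. Re-extracting profiles from the returned track with the same
#' bin size reproduces the input values exactly.
#'
#' @param profiles a [profile_matrix()] whose rows match `regions`.
#' @param regions a [region_set()] with non-overlapping windows.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @return A [coverage_track()].
#' @export
profiles_to_track <- function(profiles, regions, chrom_sizes) {
  e <- regions$entries
  stopifnot(identical(profiles$region_ids, e$region_id))
  G <- ncol(profiles$values)
  bin <- (2 * regions$flank) / G
  vals <- profiles$values
  neg <- which(e$strand == "-")
  if (length(neg) > 0)
    vals[neg, ] <- vals[neg, G:1, drop = FALSE]
  win_start <- e$anchor - regions$flank
  starts <- rep(win_start, each = G) +
    rep(seq_len(G) - 1, times = nrow(e)) * bin
  iv <- data.frame(chrom = rep(e$chrom, each = G),
                   start = starts, end = starts + bin,
                   value = as.vector(t(vals)))
  iv <- iv[iv$value != 0, , drop = FALSE]
  coverage_track(iv, chrom_sizes)
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits, for a simulated mark pair on the toy two-chromosome genome:
#' `markA.bedgraph` and `markB.bedgraph`, `regions.bed` (BED6),
#' `chrom.sizes`, `blacklist.bed` (two intervals overlapping the first
#' region window of each chromosome), `expression.tsv` and `truth.json`
#' (planted parameters, eigenfunctions and scores). Re-reading the bundle
#' through the bedGraph/BED readers reproduces the simulated profile
#' matrices exactly (bin-for-bin).
#'
#' @param spec a [simulation_spec()].
#' @param outdir output directory (created if missing).
#' @return A named list of written file paths, plus
#'   `blacklisted_region_ids`, invisibly.
#' @export
write_fixture_bundle <- function(spec, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_mark_pair(spec)
  lay <- make_fixture_regions(spec$L, spec$flank)
  trackA <- profiles_to_track(sim$profiles_A, lay$regions, lay$chrom_sizes)
  trackB <- profiles_to_track(sim$profiles_B, lay$regions, lay$chrom_sizes)
  e <- lay$regions$entries
  # blacklist the first region window on each chromosome
  designated <- c(which(e$chrom == "chrS1")[1], which(e$chrom == "chrS2")[1])
  bl <- data.frame(chrom = e$chrom[designated],
                   start = e$anchor[designated],
                   end = e$anchor[designated] + 100)
  paths <- list(
    markA = file.path(outdir, "markA.bedgraph"),
    markB = file.path(outdir, "markB.bedgraph"),
    regions = file.path(outdir, "regions.bed"),
    chrom_sizes = file.path(outdir, "chrom.sizes"),
    blacklist = file.path(outdir, "blacklist.bed"),
    expression = file.path(outdir, "expression.tsv"),
    truth = file.path(outdir, "truth.json"))
  write_bedgraph(trackA, paths$markA)
  write_bedgraph(trackB, paths$markB)
  write_regions_bed(lay$regions, paths$regions)
  write_chrom_sizes(lay$chrom_sizes, paths$chrom_sizes)
  writeLines(sprintf("%s\t%s\t%s", bl$chrom,
                     format(bl$start, scientific = FALSE, trim = TRUE),
                     format(bl$end, scientific = FALSE, trim = TRUE)),
             paths$blacklist)
  write_expression(sim$expression, paths$expression)
  jsonlite::write_json(
    list(spec = unclass(sim$truth$spec),
         grid = sim$truth$grid,
         xi_A = sim$truth$xi_A, xi_B = sim$truth$xi_B,
         scores_A = sim$truth$scores_A, scores_B = sim$truth$scores_B,
         blacklisted_region_ids = e$region_id[designated]),
    paths$truth, auto_unbox = TRUE, digits = NA, matrix = "columnmajor")
  out <- paths
  out$blacklisted_region_ids <- e$region_id[designated]
  invisible(out)
}
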