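#' Pearson correlation between eigenfunctions of two fits
#'
#' Evaluates both sets of eigenfunctions on a common equidistant grid over
#' the shared interval and returns the matrix of pairwise Pearson
#' correlations. Large `|r|` means the two components place their
#' variability in the same genomic sub-intervals (co-localization);
#' near-zero or negative values mean the regions of variability do not
#' overlap.
#'
#' @param resA,resB fitted [fpca()] objects on the same interval.
#' @param grid_points number of grid points; default 1000.
#' @return A `J_A x J_B` correlation matrix.
#' @export
eigenfunction_correlation <- function(resA, resB, grid_points = 1000) {
  if (!isTRUE(all.equal(resA$basis$interval, resB$basis$interval)))
    stop("mismatched basis intervals")
  g <- seq(resA$basis$interval[1], resA$basis$interval[2],
           length.out = grid_points)
  stats::cor(evaluate_eigenfunctions(resA, g),
             evaluate_eigenfunctions(resB, g))
}

#' Pearson correlation between FPC scores of two fits
#'
#' Matches regions of the two fits by id (inner join, in the order of
#' `resA`), then correlates every score column of A with every score column
#' of B. Two-sided p-values use the t-distribution with `n_shared - 2`
#' degrees of freedom. A zero-variance score column yields `r = 0`,
#' `p = 1` and a warning.
#'
#' @param resA,resB fitted [fpca()] objects with at least 3 shared region
#'   ids.
#' @return A list with `r_eta` (J_A x J_B), `p_eta` (matching p-values) and
#'   `n_shared`.
#' @export
score_correlation <- function(resA, resB) {
  shared <- intersect(resA$region_ids, resB$region_ids)
  n <- length(shared)
  if (n < 3) stop("need at least 3 shared region ids")
  SA <- resA$scores[match(shared, resA$region_ids), , drop = FALSE]
  SB <- resB$scores[match(shared, resB$region_ids), , drop = FALSE]
  sdA <- apply(SA, 2, stats::sd)
  sdB <- apply(SB, 2, stats::sd)
  if (any(sdA == 0) || any(sdB == 0))
    warning("zero-variance score column; r recorded as 0 with p = 1")
  r <- matrix(0, ncol(SA), ncol(SB))
  ok_a <- sdA > 0
  ok_b <- sdB > 0
  if (any(ok_a) && any(ok_b))
    r[ok_a, ok_b] <- stats::cor(SA[, ok_a, drop = FALSE],
                                SB[, ok_b, drop = FALSE])
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!ok_a, ] <- 1
  p[, !ok_b] <- 1
  list(r_eta = r, p_eta = p, n_shared = n)
}

#' Bonferroni-corrected significance mask over a p-value matrix
#'
#' The family is the full set of `J_A x J_B` component pairs tested for one
#' dataset pair, so the corrected threshold is `alpha / (J_A * J_B)`.
#'
#' @param p_eta matrix of two-sided p-values.
#' @param alpha family-wise significance level, default `1e-6`.
#' @return A list with `mask` (logical matrix `p <= alpha_corrected`),
#'   `count` and `alpha_corrected`.
#' @export
bonferroni_significant <- function(p_eta, alpha = 1e-6) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha_corrected <- alpha / length(p_eta)
  mask <- p_eta <= alpha_corrected
  list(mask = mask, count = sum(mask), alpha_corrected = alpha_corrected)
}

#' Maximum-correlation summary over leading components
#'
#' Restricted to the first `J_report` components on each side, finds the
#' entry of maximum `|r_xi|` (reporting its signed value, its 1-based
#' component indices and the `r_eta` at the same indices) and symmetrically
#' the maximum `|r_eta|` with the corresponding `r_xi`. Ties are broken by
#' row-major order.
#'
#' @param r_xi,r_eta correlation matrices from
#'   [eigenfunction_correlation()] and [score_correlation()].
#' @param J_report number of leading components searched; default 5.
#' @return A list with `max_xi` and `max_eta`, each a list
#'   `(value, indices, other)` where `other` is the companion coefficient
#'   at the same indices.
#' @export
max_summary <- function(r_xi, r_eta, J_report = 5) {
  jr <- min(J_report, nrow(r_xi), nrow(r_eta))
  jc <- min(J_report, ncol(r_xi), ncol(r_eta))
  A <- r_xi[seq_len(jr), seq_len(jc), drop = FALSE]
  B <- r_eta[seq_len(jr), seq_len(jc), drop = FALSE]
  argmax_rowmajor <- function(m) {
    key <- abs(m)
    best <- which(key == max(key))
    # row-major tie-break: smallest (row - 1) * ncol + col
    rows <- (best - 1) %% nrow(m) + 1
    cols <- (best - 1) %/% nrow(m) + 1
    ord <- order((rows - 1) * ncol(m) + cols)
    c(rows[ord[1]], cols[ord[1]])
  }
  ia <- argmax_rowmajor(A)
  ib <- argmax_rowmajor(B)
  list(max_xi = list(value = A[ia[1], ia[2]], indices = ia,
                     other = B[ia[1], ia[2]]),
       max_eta = list(value = B[ib[1], ib[2]], indices = ib,
                      other = A[ib[1], ib[2]]))
}

#' Ordinary coverage correlation over region windows
#'
#' The conventional baseline: Pearson correlation between the two tracks'
#' binned coverage concatenated over all region windows, in genome
#' orientation (no strand reversal), emulating restricted genome-wide
#' coverage correlation utilities.
#'
#' @param trackA,trackB [coverage_track()] objects (normally already
#'   wigsum-normalized).
#' @param regions a non-empty [region_set()].
#' @param bin_size bin width in bp.
#' @return Pearson correlation coefficient (scalar).
#' @export
ordinary_coverage_correlation <- function(trackA, trackB, regions,
                                          bin_size = 10) {
  if (nrow(regions$entries) == 0) stop("empty region set")
  a <- as.vector(extract_profiles(trackA, regions, bin_size,
                                  oriented = FALSE)$values)
  b <- as.vector(extract_profiles(trackB, regions, bin_size,
                                  oriented = FALSE)$values)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in flattened coverage vector")
  stats::cor(a, b)
}

#' Two-sample Kolmogorov-Smirnov comparison of correlation collections
#'
#' Compares two collections of correlation coefficients (e.g. the
#' component-pair correlations obtained for protein-coding vs non-coding
#' regions) with a two-sample KS test (asymptotic two-sided p-value).
#'
#' @param r_list_1,r_list_2 numeric vectors, each of length >= 2.
#' @return A list with `D` (KS statistic) and `p`.
#' @export
compare_correlation_distributions <- function(r_list_1, r_list_2) {
  stopifnot(length(r_list_1) >= 2, length(r_list_2) >= 2)
  kt <- suppressWarnings(stats::ks.test(r_list_1, r_list_2,
                                        exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Full cross-dataset comparison of two FPCA fits
#'
#' Computes the two coefficients of the comparison scheme for every
#' component pair -- eigenfunction correlation (co-localization of
#' variability) and score correlation (co-variation of signal) -- together
#' with Bonferroni-corrected significance over all component pairs,
#' Table-style maximum summaries over the first `J_report` components, and
#' optionally the ordinary coverage-correlation baseline.
#'
#' @param resA,resB fitted [fpca()] objects.
#' @param names_AB character vector of length 2 naming the two datasets.
#' @param alpha family-wise significance level for the Bonferroni test.
#' @param J_report components searched by the maximum summary.
#' @param grid_points grid size for eigenfunction correlation.
#' @param trackA,trackB,regions,bin_size optional inputs for the ordinary
#'   coverage-correlation baseline; all of `trackA`, `trackB`, `regions`
#'   must be given for it to be computed.
#' @return An object of class `crosscorr_summary` with fields `marks`,
#'   `J_pair`, `r_xi`, `r_eta`, `p_eta`, `n_shared`, `alpha`,
#'   `alpha_corrected`, `n_significant`, `significant_mask`, `max_xi`,
#'   `max_eta`, `J_report` and `ordinary_r` (`NA` when not computed).
#' @export
cross_correlate <- function(resA, resB, names_AB = c("A", "B"),
                            alpha = 1e-6, J_report = 5, grid_points = 1000,
                            trackA = NULL, trackB = NULL, regions = NULL,
                            bin_size = 10) {
  r_xi <- eigenfunction_correlation(resA, resB, grid_points)
  sc <- score_correlation(resA, resB)
  bf <- bonferroni_significant(sc$p_eta, alpha)
  mx <- max_summary(r_xi, sc$r_eta, J_report)
  ordinary_r <- NA_real_
  if (!is.null(trackA) && !is.null(trackB) && !is.null(regions))
    ordinary_r <- ordinary_coverage_correlation(trackA, trackB, regions,
                                                bin_size)
  structure(list(marks = names_AB,
                 J_pair = c(resA$J, resB$J),
                 r_xi = r_xi, r_eta = sc$r_eta, p_eta = sc$p_eta,
                 n_shared = sc$n_shared,
                 alpha = alpha,
                 alpha_corrected = bf$alpha_corrected,
                 n_significant = bf$count,
                 significant_mask = bf$mask,
                 max_xi = mx$max_xi, max_eta = mx$max_eta,
                 J_report = J_report,
                 ordinary_r = ordinary_r),
            class = "crosscorr_summary")
}

#' @export
print.crosscorr_summary <- function(x, ...) {
  cat(sprintf("Cross-dataset FPCA comparison: %s vs %s (%d shared regions)\n",
              x$marks[1], x$marks[2], x$n_shared))
  if (!is.na(x$ordinary_r))
    cat(sprintf("  Ordinary coverage correlation:      % .3f\n",
                x$ordinary_r))
  cat(sprintf("  Max correlation of xi  (first %d):   % .3f (%d,%d), r_eta there % .3f\n",
              x$J_report, x$max_xi$value, x$max_xi$indices[1],
              x$max_xi$indices[2], x$max_xi$other))
  cat(sprintf("  Max correlation of eta (first %d):   % .3f (%d,%d), r_xi there % .3f\n",
              x$J_report, x$max_eta$value, x$max_eta$indices[1],
              x$max_eta$indices[2], x$max_eta$other))
  cat(sprintf("  Significant pairwise correlations: %d of %d (Bonferroni, alpha = %g)\n",
              x$n_significant, length(x$p_eta), x$alpha))
  invisible(x)
}

#' Serialize a cross-correlation summary (matrices TSV + summary JSON)
#'
#' Writes `<prefix>_r_xi.tsv`, `<prefix>_r_eta.tsv`, `<prefix>_p_eta.tsv`,
#' a long-format `<prefix>_pairs.tsv` (component_j, component_k, r_xi,
#' r_eta, p, significant) and `<prefix>_summary.json`.
#'
#' @param summary a [cross_correlate()] result.
#' @param prefix output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_crosscorr <- function(summary, prefix) {
  write_mat <- function(m, path) {
    df <- as.data.frame(format(m, digits = 17, trim = TRUE))
    names(df) <- paste0("B", seq_len(ncol(m)))
    utils::write.table(cbind(A = paste0("A", seq_len(nrow(m))), df), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths <- paste0(prefix, c("_r_xi.tsv", "_r_eta.tsv", "_p_eta.tsv",
                            "_pairs.tsv", "_summary.json"))
  write_mat(summary$r_xi, paths[1])
  write_mat(summary$r_eta, paths[2])
  write_mat(summary$p_eta, paths[3])
  long <- data.frame(
    component_j = rep(seq_len(nrow(summary$r_xi)), ncol(summary$r_xi)),
    component_k = rep(seq_len(ncol(summary$r_xi)),
                      each = nrow(summary$r_xi)),
    r_xi = format(as.vector(summary$r_xi), digits = 17, trim = TRUE),
    r_eta = format(as.vector(summary$r_eta), digits = 17, trim = TRUE),
    p = format(as.vector(summary$p_eta), digits = 17, trim = TRUE),
    significant = as.vector(summary$significant_mask))
  utils::write.table(long, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(marks = summary$marks, J_pair = summary$J_pair,
         n_shared = summary$n_shared, alpha = summary$alpha,
         alpha_corrected = summary$alpha_corrected,
         n_significant = summary$n_significant,
         J_report = summary$J_report,
         max_xi = summary$max_xi, max_eta = summary$max_eta,
         ordinary_r = summary$ordinary_r),
    paths[5], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
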