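#' Construct a B-spline basis with equidistant interior knots
#'
#' Builds `K` B-spline basis functions of the given order (order 4 = cubic)
#' on `[a, b]`, with `K - order` equidistant interior knots and boundary
#' knots repeated `order` times. The Gram matrix
#' `W[j, k] = integral of phi_j(t) * phi_k(t) dt` is computed exactly by
#' per-span Gauss-Legendre quadrature with `order` nodes per knot span,
#' which is degree-exact for the piecewise-polynomial product (degree
#' `2 * (order - 1)`).
#'
#' @param a,b interval endpoints, `b > a`.
#' @param K number of basis functions, `K >= order`.
#' @param order spline order (degree + 1); default 4 (cubic).
#' @return An object of class `bspline_basis` with elements `interval`,
#'   `order`, `K`, `knots` (full knot vector) and `gram` (K x K matrix).
#' @export
make_basis <- function(a, b, K, order = 4) {
  if (!(b > a)) stop("require b > a")
  if (K < order) stop("require K >= order")
  n_interior <- K - order
  breaks <- seq(a, b, length.out = n_interior + 2)
  knots <- c(rep(a, order), breaks[-c(1, length(breaks))], rep(b, order))
  basis <- structure(list(interval = c(a, b), order = order, K = K,
                          knots = knots, gram = NULL),
                     class = "bspline_basis")
  gl <- pracma::gaussLegendre(order, -1, 1)
  W <- matrix(0, K, K)
  for (i in seq_len(length(breaks) - 1)) {
    lo <- breaks[i]; hi <- breaks[i + 1]
    x <- (hi - lo) / 2 * gl$x + (hi + lo) / 2
    w <- (hi - lo) / 2 * gl$w
    Phi <- evaluate_basis(basis, x)
    W <- W + crossprod(Phi, Phi * w)
  }
  basis$gram <- (W + t(W)) / 2
  basis
}

#' @export
print.bspline_basis <- function(x, ...) {
  cat(sprintf("bspline_basis: K = %d, order = %d on [%g, %g]\n",
              x$K, x$order, x$interval[1], x$interval[2]))
  invisible(x)
}

#' Evaluate B-spline basis functions on a grid
#'
#' Cox-de Boor evaluation (via [splines::splineDesign()]) of all `K` basis
#' functions at the supplied points. Rows sum to 1 (partition of unity).
#'
#' @param basis a [make_basis()] object.
#' @param grid numeric vector of evaluation points, all within the basis
#'   interval.
#' @return A `length(grid) x K` matrix.
#' @export
evaluate_basis <- function(basis, grid) {
  a <- basis$interval[1]; b <- basis$interval[2]
  if (any(grid < a) || any(grid > b))
    stop("evaluation point outside basis interval [", a, ", ", b, "]")
  splines::splineDesign(basis$knots, grid, ord = basis$order)
}

#' Least-squares B-spline expansion of coverage profiles
#'
#' Approximates each profile row by a linear combination of the basis
#' functions, with coefficients estimated by ordinary least squares on the
#' profile grid. One normal-equations Cholesky factorisation is shared
#' across all rows. The per-region root-mean-square fit residual is
#' recorded.
#'
#' @param profiles a [profile_matrix()] whose grid lies inside the basis
#'   interval and has at least `K` points.
#' @param basis a [make_basis()] object.
#' @return An object of class `functional_dataset` with elements `basis`,
#'   `coeffs` (L x K), `region_ids` and `residual_rms` (length L).
#' @export
fit_coefficients <- function(profiles, basis) {
  grid <- profiles$grid
  if (length(grid) < basis$K)
    stop("need at least K grid points for least squares (G >= K)")
  Phi <- evaluate_basis(basis, grid)
  A <- crossprod(Phi)
  R <- tryCatch(chol(A), error = function(e)
    stop("rank-deficient design: degenerate grid for this basis"))
  Y <- profiles$values
  # coeffs = Y Phi A^{-1}; one shared Cholesky factor for all rows
  B <- crossprod(Phi, t(Y))
  Ct <- backsolve(R, forwardsolve(t(R), B))
  coeffs <- t(Ct)
  fitted <- tcrossprod(coeffs, Phi)
  residual_rms <- sqrt(rowMeans((Y - fitted)^2))
  structure(list(basis = basis, coeffs = coeffs,
                 region_ids = profiles$region_ids,
                 residual_rms = residual_rms),
            class = "functional_dataset")
}

#' @export
print.functional_dataset <- function(x, ...) {
  cat(sprintf(
    "functional_dataset: %d regions x %d basis coefficients, median RMS residual %.4g\n",
    nrow(x$coeffs), ncol(x$coeffs), stats::median(x$residual_rms)))
  invisible(x)
}

#' Serialize a functional dataset (coefficients TSV + basis JSON sidecar)
#'
#' @param data a [fit_coefficients()] result.
#' @param prefix output path prefix; writes `<prefix>_coeffs.tsv` and
#'   `<prefix>_basis.json`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_functional_dataset <- function(data, prefix) {
  coeff_path <- paste0(prefix, "_coeffs.tsv")
  basis_path <- paste0(prefix, "_basis.json")
  df <- data.frame(region_id = data$region_ids,
                   residual_rms = data$residual_rms,
                   data$coeffs, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("c", seq_len(ncol(data$coeffs)))
  utils::write.table(df, coeff_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(interval = data$basis$interval,
                            order = data$basis$order, K = data$basis$K),
                       basis_path, auto_unbox = TRUE, digits = NA)
  invisible(c(coeff_path, basis_path))
}

#' Read a functional dataset written by [write_functional_dataset()]
#' @param prefix path prefix used at write time.
#' @return A `functional_dataset`.
#' @export
read_functional_dataset <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_basis.json"),
                              simplifyVector = TRUE)
  basis <- make_basis(meta$interval[1], meta$interval[2], meta$K, meta$order)
  df <- utils::read.table(paste0(prefix, "_coeffs.tsv"), sep = "\t",
                          header = TRUE, check.names = FALSE,
                          colClasses = "character")
  coeffs <- matrix(as.numeric(as.matrix(df[, -(1:2), drop = FALSE])),
                   nrow = nrow(df))
  structure(list(basis = basis, coeffs = coeffs,
                 region_ids = df[[1]],
                 residual_rms = as.numeric(df[[2]])),
            class = "functional_dataset")
}
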