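# Shared oracles and fixture builders. Oracles are deliberately independent
# of the implementation paths they check (dense-grid linear algebra, direct
# recursions, brute-force scans).

# trapezoid quadrature weights on an equidistant grid
trapz_weights <- function(grid) {
  w <- rep(grid[2] - grid[1], length(grid))
  w[c(1, length(grid))] <- w[1] / 2
  w
}

# dense-grid weighted multivariate PCA: the FPCA oracle. Operates on raw
# profile samples with trapezoid quadrature weights, no basis involved.
dense_pca_oracle <- function(X, grid) {
  w <- trapz_weights(grid)
  Xc <- sweep(X, 2, colMeans(X))
  Y <- Xc * rep(sqrt(w), each = nrow(X))
  sv <- svd(Y)
  list(values = sv$d^2 / (nrow(X) - 1),
       funcs = sweep(sv$v, 1, sqrt(w), "/"),
       scores = Y %*% sv$v)
}

# Cox-de Boor recursion written directly from the definition
cox_de_boor <- function(knots, order, k, t) {
  if (order == 1)
    return(as.numeric(knots[k] <= t & t < knots[k + 1]))
  d1 <- knots[k + order - 1] - knots[k]
  d2 <- knots[k + order] - knots[k + 1]
  a <- if (d1 > 0) (t - knots[k]) / d1 * cox_de_boor(knots, order - 1, k, t) else 0
  b <- if (d2 > 0) (knots[k + order] - t) / d2 *
    cox_de_boor(knots, order - 1, k + 1, t) else 0
  a + b
}

# textbook Pearson r and two-sided t-test p-value
hand_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), df = n - 2))
}

# brute-force two-sample KS statistic by ECDF sweep over all data points
ks_D_bruteforce <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
}

# small in-span functional dataset: random coefficients, profiles evaluated
# on a dense grid so basis fitting is exact
random_smooth_profiles <- function(L, basis, grid, coef_decay = TRUE) {
  K <- basis$K
  C <- matrix(rnorm(L * K), L, K)
  if (coef_decay) C <- C * rep(1 / seq_len(K), each = L)
  Phi <- evaluate_basis(basis, grid)
  list(coeffs = C,
       profiles = profile_matrix(tcrossprod(C, Phi),
                                 sprintf("r%04d", seq_len(L)), grid))
}

# minimal stand-in fpca object with prescribed scores, for operations that
# only consume scores and region ids
fake_fit <- function(scores, region_ids = sprintf("g%04d", seq_len(nrow(scores)))) {
  structure(list(scores = scores, region_ids = region_ids,
                 J = ncol(scores), L = nrow(scores)),
            class = "fpca")
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}
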