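#' Functional principal component analysis of coverage profiles
#'
#' Estimates the finite Karhunen-Loeve decomposition of a set of profiles
#' represented in a B-spline basis: the mean function, orthonormal
#' eigenfunctions `xi_k(t)`, eigenvalues `lambda_k = var(eta_k)` and
#' per-region scores `eta_ik = integral of (x_i - mu) * xi_k`.
#'
#' Writing the centred basis coefficients as rows of `C` (L x K), their
#' covariance `Sigma_c = C'C / (L - 1)` and the basis Gram matrix
#' `W = R'R` (Cholesky), the eigenfunctions solve the generalized problem
#' `W Sigma_c W b = lambda W b`. It is solved in symmetrized form: the
#' symmetric matrix `R Sigma_c R'` is eigendecomposed as `U Lambda U'` and
#' the eigenfunction coefficients are `B = R^{-1} U`, which satisfies
#' `B' W B = I` (orthonormal eigenfunctions). Scores are computed exactly in
#' basis algebra as `eta = C W B`, so the sample variance of score column
#' `k` equals `lambda_k` and score columns are uncorrelated.
#'
#' Eigenfunction signs are fixed by a reproducible convention: each
#' `xi_k` is evaluated on 2001 equidistant points and flipped if needed so
#' that the point of maximum `|xi_k|` has a positive value.
#'
#' @param data a `functional_dataset` from [fit_coefficients()], or a
#'   [profile_matrix()] (in which case a basis is built with `K` and `order`
#'   on the grid's span extended to `interval` if given).
#' @param J number of components to retain; at most `min(K, L - 1)`.
#'   Defaults to `min(K, L - 1)`.
#' @param K,order,interval basis parameters, used only when `data` is a
#'   profile matrix; `K` defaults to 50, `order` to 4 and `interval` to the
#'   profile grid span extended by one bin.
#' @return An object of class `fpca` with elements `basis`, `mean_coeffs`,
#'   `eig_coeffs` (K x J matrix `B`), `eigenvalues`, `scores` (L x J),
#'   `region_ids`, `var_explained`, `cum_var_explained`, `total_variance`
#'   (trace of `W Sigma_c`), `L` and `J`.
#' @examples
#' b <- make_basis(0, 1, 8)
#' g <- seq(0, 1, length.out = 101)
#' x <- outer(rnorm(40), sin(2 * pi * g)) + 1
#' fit <- fpca(fit_coefficients(profile_matrix(x, paste0("r", 1:40), g), b),
#'             J = 3)
#' fit$eigenvalues
#' @export
fpca <- function(data, J = NULL, K = 50, order = 4, interval = NULL) {
  if (inherits(data, "profile_matrix")) {
    if (is.null(interval)) {
      step <- if (length(data$grid) > 1) data$grid[2] - data$grid[1] else 1
      interval <- c(data$grid[1], data$grid[length(data$grid)] + step)
    }
    basis <- make_basis(interval[1], interval[2], K, order)
    data <- fit_coefficients(data, basis)
  }
  if (!inherits(data, "functional_dataset"))
    stop("data must be a functional_dataset or profile_matrix")
  basis <- data$basis
  Kb <- basis$K
  L <- nrow(data$coeffs)
  if (L < 2) stop("need at least 2 regions (L >= 2)")
  J_max <- min(Kb, L - 1)
  if (is.null(J)) J <- J_max
  if (J > J_max) stop("J must be <= min(K, L - 1) = ", J_max)
  W <- basis$gram
  mean_coeffs <- colMeans(data$coeffs)
  Cc <- sweep(data$coeffs, 2, mean_coeffs)
  Sigma_c <- crossprod(Cc) / (L - 1)
  R <- chol(W) # W = R'R; W is SPD for a valid basis
  M <- R %*% Sigma_c %*% t(R)
  ee <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- ee$values
  lam[lam < 0 & lam > -1e-10] <- 0
  total_variance <- sum(lam)
  B_full <- backsolve(R, ee$vectors)
  B <- B_full[, seq_len(J), drop = FALSE]
  # sign convention: positive value at the grid point of max |xi_k|
  sgrid <- seq(basis$interval[1], basis$interval[2], length.out = 2001)
  Xi <- evaluate_basis(basis, sgrid) %*% B
  flip <- vapply(seq_len(J), function(k) {
    v <- Xi[which.max(abs(Xi[, k])), k]
    if (v < 0) -1 else 1
  }, numeric(1))
  B <- B * rep(flip, each = Kb)
  scores <- Cc %*% (W %*% B)
  lamJ <- lam[seq_len(J)]
  structure(list(basis = basis,
                 mean_coeffs = mean_coeffs,
                 eig_coeffs = B,
                 eigenvalues = lamJ,
                 scores = scores,
                 region_ids = data$region_ids,
                 var_explained = lamJ / total_variance,
                 cum_var_explained = cumsum(lamJ) / total_variance,
                 total_variance = total_variance,
                 L = L, J = J),
            class = "fpca")
}

#' @export
print.fpca <- function(x, ...) {
  cat(sprintf("Functional PCA: %d regions, K = %d basis functions, J = %d components\n",
              x$L, x$basis$K, x$J))
  jshow <- min(x$J, 5)
  cat(sprintf("  lambda[1:%d]: %s\n", jshow,
              paste(signif(x$eigenvalues[1:jshow], 4), collapse = ", ")))
  cat(sprintf("  cumulative variance explained (J = %d): %.1f%%\n",
              x$J, 100 * x$cum_var_explained[x$J]))
  invisible(x)
}

#' @export
summary.fpca <- function(object, ...) {
  tab <- data.frame(component = seq_len(object$J),
                    eigenvalue = object$eigenvalues,
                    prop_var = object$var_explained,
                    cum_prop_var = object$cum_var_explained)
  structure(list(table = tab, L = object$L, K = object$basis$K,
                 J = object$J, total_variance = object$total_variance),
            class = "summary.fpca")
}

#' @export
print.summary.fpca <- function(x, ...) {
  cat(sprintf("Functional PCA of %d profiles (K = %d, J = %d)\n",
              x$L, x$K, x$J))
  cat(sprintf("Total functional variance: %.6g\n", x$total_variance))
  print(format(utils::head(x$table, 10), digits = 4), row.names = FALSE)
  if (x$J > 10) cat("  ...", x$J - 10, "more components\n")
  invisible(x)
}

#' @describeIn fpca eigenfunction coefficients in the basis (`K x J`).
#' @param object,... method arguments.
#' @export
coef.fpca <- function(object, ...) object$eig_coeffs

#' Project profiles onto fitted eigenfunctions (FPC scores)
#'
#' Computes scores `eta_ik = (c_i - mean_coeffs)' W B[, k]` for a (possibly
#' new) functional dataset expanded in the same basis. On the training data
#' this reproduces `object$scores` exactly.
#'
#' @param object a fitted [fpca()] object.
#' @param newdata a `functional_dataset` on the identical basis; `NULL`
#'   returns the training scores.
#' @param ... unused.
#' @return An L x J score matrix.
#' @export
predict.fpca <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  project_scores(object, newdata)
}

#' @rdname predict.fpca
#' @param result a fitted [fpca()] object.
#' @param data a `functional_dataset` on the identical basis.
#' @export
project_scores <- function(result, data) {
  b1 <- result$basis; b2 <- data$basis
  if (!isTRUE(all.equal(b1$interval, b2$interval)) ||
      b1$order != b2$order || b1$K != b2$K)
    stop("basis mismatch between fpca fit and data")
  Cc <- sweep(data$coeffs, 2, result$mean_coeffs)
  Cc %*% (b1$gram %*% result$eig_coeffs)
}

#' Evaluate fitted eigenfunctions on a grid
#'
#' @param result a fitted [fpca()] object.
#' @param grid numeric vector within the basis interval.
#' @return A `length(grid) x J` matrix of `xi_k(t)` values.
#' @export
evaluate_eigenfunctions <- function(result, grid) {
  evaluate_basis(result$basis, grid) %*% result$eig_coeffs
}

#' Evaluate the fitted mean function on a grid
#' @inheritParams evaluate_eigenfunctions
#' @return Numeric vector of `mu(t)` values.
#' @export
evaluate_mean <- function(result, grid) {
  drop(evaluate_basis(result$basis, grid) %*% result$mean_coeffs)
}

#' Fitted covariance function on a grid
#'
#' Evaluates `v(s, t) = sum_k lambda_k xi_k(s) xi_k(t)` over the retained
#' components.
#'
#' @param result a fitted [fpca()] object.
#' @param s_grid,t_grid evaluation grids within the basis interval.
#' @return A `length(s_grid) x length(t_grid)` matrix.
#' @export
covariance_function <- function(result, s_grid, t_grid = s_grid) {
  Xs <- evaluate_eigenfunctions(result, s_grid)
  Xt <- evaluate_eigenfunctions(result, t_grid)
  Xs %*% (t(Xt) * result$eigenvalues)
}

#' Reconstruct profiles from leading components
#'
#' Evaluates the truncated Karhunen-Loeve expansion
#' `xhat_i(t) = mu(t) + sum_{k <= J_use} eta_ik xi_k(t)` on a grid.
#'
#' @param result a fitted [fpca()] object.
#' @param J_use number of components to use (`0 <= J_use <= J`); `J_use = 0`
#'   returns the mean function in every row.
#' @param grid evaluation grid within the basis interval.
#' @return A [profile_matrix()] of reconstructed profiles.
#' @export
reconstruct <- function(result, J_use, grid) {
  if (J_use > result$J) stop("J_use must be <= J")
  mu <- evaluate_mean(result, grid)
  vals <- matrix(mu, nrow = result$L, ncol = length(grid), byrow = TRUE)
  if (J_use > 0) {
    Xi <- evaluate_eigenfunctions(result, grid)[, seq_len(J_use),
                                                drop = FALSE]
    vals <- vals + result$scores[, seq_len(J_use), drop = FALSE] %*% t(Xi)
  }
  profile_matrix(vals, result$region_ids, grid)
}

#' @describeIn fpca draw new profiles from the fitted Karhunen-Loeve model
#'   (scores sampled from `N(0, lambda_k)`, no residual noise). Returns a
#'   list of [profile_matrix()] objects of length `nsim`.
#' @param nsim number of simulated datasets.
#' @param seed optional integer seed.
#' @param n_regions rows per simulated dataset; defaults to the fitted `L`.
#' @param grid evaluation grid for simulated profiles (default 401 points).
#' @export
simulate.fpca <- function(object, nsim = 1, seed = NULL,
                          n_regions = object$L, grid = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid))
    grid <- seq(object$basis$interval[1], object$basis$interval[2],
                length.out = 401)
  mu <- evaluate_mean(object, grid)
  Xi <- evaluate_eigenfunctions(object, grid)
  lapply(seq_len(nsim), function(i) {
    eta <- matrix(stats::rnorm(n_regions * object$J), n_regions, object$J)
    eta <- eta * rep(sqrt(object$eigenvalues), each = n_regions)
    vals <- matrix(mu, n_regions, length(grid), byrow = TRUE) +
      eta %*% t(Xi)
    profile_matrix(vals, sprintf("sim_%d_%d", i, seq_len(n_regions)), grid)
  })
}

#' @describeIn fpca plot the leading eigenfunctions and the scree of
#'   variance explained.
#' @param x a fitted `fpca` object.
#' @param n_plot number of eigenfunctions to draw.
#' @export
plot.fpca <- function(x, n_plot = min(3, x$J), ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  grid <- seq(x$basis$interval[1], x$basis$interval[2], length.out = 401)
  Xi <- evaluate_eigenfunctions(x, grid)[, seq_len(n_plot), drop = FALSE]
  graphics::matplot(grid, Xi, type = "l", lty = 1,
                    xlab = "position (bp relative to anchor)",
                    ylab = expression(xi[k](t)),
                    main = "Eigenfunctions")
  graphics::legend("topright", legend = paste0("FPC", seq_len(n_plot)),
                   col = seq_len(n_plot), lty = 1, bty = "n")
  graphics::plot(seq_len(x$J), x$cum_var_explained, type = "b",
                 xlab = "component", ylab = "cumulative proportion of variance",
                 ylim = c(0, 1), main = "Variance explained", log = "x")
  invisible(x)
}

#' Serialize an fpca fit (scores/eigenfunctions/eigenvalues TSV + JSON)
#'
#' Writes `<prefix>_scores.tsv` (region_id x J), `<prefix>_eigenfunctions.tsv`
#' (grid x J evaluated values), `<prefix>_eigenvalues.tsv` (eigenvalue,
#' proportion and cumulative proportion of variance) and `<prefix>_fpca.json`
#' (basis description, mean and eigenfunction coefficients, enough to
#' reload the fit exactly).
#'
#' @param result a fitted [fpca()] object.
#' @param prefix output path prefix.
#' @param grid_points number of grid points for the evaluated-eigenfunction
#'   table.
#' @return Character vector of written paths, invisibly.
#' @export
write_fpca <- function(result, prefix, grid_points = 1000) {
  paths <- paste0(prefix, c("_scores.tsv", "_eigenfunctions.tsv",
                            "_eigenvalues.tsv", "_fpca.json"))
  sc <- data.frame(region_id = result$region_ids,
                   format(result$scores, digits = 17, trim = TRUE),
                   check.names = FALSE)
  names(sc)[-1] <- paste0("FPC", seq_len(result$J))
  utils::write.table(sc, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- seq(result$basis$interval[1], result$basis$interval[2],
           length.out = grid_points)
  ef <- data.frame(position = g,
                   format(evaluate_eigenfunctions(result, g), digits = 17,
                          trim = TRUE), check.names = FALSE)
  names(ef)[-1] <- paste0("xi", seq_len(result$J))
  utils::write.table(ef, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ev <- data.frame(component = seq_len(result$J),
                   eigenvalue = format(result$eigenvalues, digits = 17,
                                       trim = TRUE),
                   prop_var = format(result$var_explained, digits = 17,
                                     trim = TRUE),
                   cum_prop_var = format(result$cum_var_explained,
                                         digits = 17, trim = TRUE))
  utils::write.table(ev, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(basis = list(interval = result$basis$interval,
                      order = result$basis$order, K = result$basis$K),
         L = result$L, J = result$J,
         total_variance = result$total_variance,
         sign_convention = "max-abs-positive/2001-grid/v1",
         mean_coeffs = result$mean_coeffs,
         eig_coeffs = result$eig_coeffs,
         eigenvalues = result$eigenvalues),
    paths[4], auto_unbox = TRUE, digits = NA, matrix = "columnmajor")
  invisible(paths)
}

#' Reload an fpca fit written by [write_fpca()]
#' @param prefix path prefix used at write time.
#' @return An object of class `fpca`.
#' @export
read_fpca <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_fpca.json"),
                              simplifyVector = TRUE)
  basis <- make_basis(meta$basis$interval[1], meta$basis$interval[2],
                      meta$basis$K, meta$basis$order)
  sc <- utils::read.table(paste0(prefix, "_scores.tsv"), sep = "\t",
                          header = TRUE, check.names = FALSE,
                          colClasses = "character")
  scores <- matrix(as.numeric(as.matrix(sc[, -1, drop = FALSE])),
                   nrow = nrow(sc))
  # written column-major: rows of the parsed matrix are the columns of B
  B <- t(matrix(unlist(meta$eig_coeffs), ncol = meta$basis$K, byrow = !is.matrix(meta$eig_coeffs)))
  lam <- as.numeric(meta$eigenvalues)
  structure(list(basis = basis,
                 mean_coeffs = as.numeric(meta$mean_coeffs),
                 eig_coeffs = B,
                 eigenvalues = lam,
                 scores = scores,
                 region_ids = sc[[1]],
                 var_explained = lam / meta$total_variance,
                 cum_var_explained = cumsum(lam) / meta$total_variance,
                 total_variance = meta$total_variance,
                 L = meta$L, J = meta$J),
            class = "fpca")
}
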