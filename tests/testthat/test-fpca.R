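make_inspan <- function(L, basis, grid, seed) {
  set.seed(seed)
  random_smooth_profiles(L, basis, grid)
}

test_that("rank-1 data yields lambda_1 = var(a) * ||f||^2 and xi_1 = f/||f||", {
  set.seed(31)
  b <- make_basis(0, 1, 8, 4)
  g <- seq(0, 1, length.out = 201)
  cf <- rnorm(8)
  f <- drop(evaluate_basis(b, g) %*% cf)
  a <- rnorm(30, sd = 2)
  pm <- profile_matrix(outer(a, f), sprintf("r%02d", 1:30), g)
  fit <- fpca(fit_coefficients(pm, b), J = 4)
  f_norm2 <- drop(crossprod(cf, b$gram %*% cf))
  expect_equal(fit$eigenvalues[1], var(a) * f_norm2, tolerance = 1e-8)
  expect_lt(max(fit$eigenvalues[-1]), 1e-8 * fit$eigenvalues[1])
  xi1 <- drop(evaluate_eigenfunctions(fit, g)[, 1])
  target <- f / sqrt(f_norm2)
  s <- sign(sum(xi1 * target))
  expect_lt(max(abs(xi1 - s * target)), 1e-6)
  # covariance function of the rank-1 fit is sigma^2 f(s) f(t)
  v <- covariance_function(fit, g[c(1, 51, 101)], g[c(26, 151)])
  expect_equal(v, var(a) * outer(f[c(1, 51, 101)], f[c(26, 151)]),
               tolerance = 1e-6)
})

test_that("two orthogonal planted signals give exact eigenvalue ratio", {
  set.seed(32)
  b <- make_basis(-1, 1, 10, 4)
  g <- seq(-1, 1, length.out = 301)
  # two W-orthonormal coefficient vectors
  R <- chol(b$gram)
  q <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
  V <- backsolve(R, q) # V' W V = I
  # score vectors with exact sample variances 4 and 1, exactly uncorrelated
  z1 <- rnorm(40); z1 <- z1 - mean(z1)
  z2 <- rnorm(40); z2 <- z2 - mean(z2)
  z2 <- z2 - z1 * sum(z1 * z2) / sum(z1^2)
  s1 <- 2 * z1 / sd(z1)
  s2 <- z2 / sd(z2)
  C <- cbind(s1, s2) %*% t(V)
  pm <- profile_matrix(tcrossprod(C, evaluate_basis(b, g)),
                       sprintf("r%02d", 1:40), g)
  fit <- fpca(fit_coefficients(pm, b), J = 2)
  expect_equal(fit$eigenvalues[1] / fit$eigenvalues[2], 4,
               tolerance = 1e-6)
})

test_that("fpca matches the dense-grid weighted-PCA oracle", {
  b <- make_basis(-1, 1, 10, 4)
  g <- seq(-1, 1, length.out = 2001)
  for (seed in 1:5) {
    d <- make_inspan(50, b, g, seed)
    fit <- fpca(fit_coefficients(d$profiles, b), J = 5)
    or <- dense_pca_oracle(d$profiles$values, g)
    expect_equal(fit$eigenvalues, or$values[1:5], tolerance = 1e-3)
    Xi <- evaluate_eigenfunctions(fit, g)
    for (k in 1:5) {
      s <- sign(sum(Xi[, k] * or$funcs[, k]))
      expect_lt(max(abs(Xi[, k] - s * or$funcs[, k])) /
                  max(abs(or$funcs[, k])), 1e-3)
      expect_lt(max(abs(fit$scores[, k] - s * or$scores[, k])) /
                  max(abs(or$scores[, k])), 1e-3)
    }
  }
})

test_that("fitted decomposition satisfies the KL invariants", {
  b <- make_basis(-1, 1, 12, 4)
  g <- seq(-1, 1, length.out = 401)
  d <- make_inspan(60, b, g, 77)
  fit <- fpca(fit_coefficients(d$profiles, b), J = 8)
  W <- b$gram
  B <- fit$eig_coeffs
  # orthonormal eigenfunctions: B' W B = I
  expect_lt(max(abs(crossprod(B, W %*% B) - diag(8))), 1e-8)
  # eigenvalues non-increasing, non-negative
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_true(all(fit$eigenvalues >= 0))
  # score variances equal eigenvalues; score columns uncorrelated
  expect_equal(apply(fit$scores, 2, var), fit$eigenvalues,
               tolerance = 1e-6)
  cc <- cor(fit$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)
  # conservation: sum of all eigenvalues = trace(W Sigma_c)
  Cc <- sweep(fit_coefficients(d$profiles, b)$coeffs, 2, fit$mean_coeffs)
  total <- sum(diag(W %*% (crossprod(Cc) / 59)))
  expect_equal(fit$total_variance, total, tolerance = 1e-8)
  # sign convention: max |xi_k| point is positive
  sg <- seq(-1, 1, length.out = 2001)
  Xi <- evaluate_eigenfunctions(fit, sg)
  for (k in 1:8)
    expect_gt(Xi[which.max(abs(Xi[, k])), k], 0)
  # quadrature orthonormality of evaluated eigenfunctions
  G2 <- crossprod(Xi, Xi * trapz_weights(sg))
  expect_lt(max(abs(G2 - diag(8))), 1e-4)
})

test_that("trace of the fitted covariance equals the retained eigenvalue sum", {
  b <- make_basis(-1, 1, 10, 4)
  g <- seq(-1, 1, length.out = 2001)
  d <- make_inspan(50, b, g, 5)
  fit <- fpca(fit_coefficients(d$profiles, b), J = 5)
  gq <- seq(-1, 1, length.out = 20001)
  v_diag <- rowSums(evaluate_eigenfunctions(fit, gq)^2 *
                      rep(fit$eigenvalues, each = length(gq)))
  expect_equal(sum(v_diag * trapz_weights(gq)), sum(fit$eigenvalues),
               tolerance = 1e-6)
  # symmetry on a common grid
  v <- covariance_function(fit, g[1:50])
  expect_equal(v, t(v), tolerance = 1e-12)
})

test_that("project_scores reproduces training scores and planted profiles", {
  b <- make_basis(-1, 1, 10, 4)
  g <- seq(-1, 1, length.out = 401)
  d <- make_inspan(40, b, g, 9)
  fd <- fit_coefficients(d$profiles, b)
  fit <- fpca(fd, J = 4)
  expect_identical(project_scores(fit, fd), fit$scores) # bit-for-bit
  expect_identical(predict(fit), fit$scores)

  # the mean profile projects to zero scores
  mean_prof <- profile_matrix(matrix(colMeans(d$profiles$values), 1),
                              "mean", g)
  s0 <- project_scores(fit, fit_coefficients(mean_prof, b))
  expect_lt(max(abs(s0)), 1e-8)

  # mu + 2 * xi_1 projects to (2, 0, 0, 0)
  mu <- evaluate_mean(fit, g)
  xi1 <- evaluate_eigenfunctions(fit, g)[, 1]
  planted <- profile_matrix(matrix(mu + 2 * xi1, 1), "p", g)
  sp <- project_scores(fit, fit_coefficients(planted, b))
  expect_equal(drop(sp), c(2, 0, 0, 0), tolerance = 1e-8)

  b_other <- make_basis(-1, 1, 12, 4)
  expect_error(project_scores(fit, fit_coefficients(d$profiles, b_other)),
               "basis mismatch")
})

test_that("reconstruction is exact at full rank and improves with J_use", {
  b <- make_basis(0, 1, 8, 4)
  g <- seq(0, 1, length.out = 161)
  set.seed(41)
  # noiseless rank-2 data
  R <- chol(b$gram)
  V <- backsolve(R, qr.Q(qr(matrix(rnorm(16), 8, 2))))
  S <- cbind(rnorm(25, sd = 3), rnorm(25))
  C <- S %*% t(V) + rep(rnorm(8), each = 25) * 0 + 1
  pm <- profile_matrix(tcrossprod(C, evaluate_basis(b, g)),
                       sprintf("r%02d", 1:25), g)
  fit <- fpca(fit_coefficients(pm, b), J = 3)
  rec <- reconstruct(fit, 3, g)
  expect_equal(rec$values, pm$values, tolerance = 1e-8)
  rec0 <- reconstruct(fit, 0, g)
  expect_equal(rec0$values,
               matrix(evaluate_mean(fit, g), 25, 161, byrow = TRUE),
               tolerance = 1e-12)

  # monotone reconstruction error on random data
  d <- make_inspan(30, b, g, 55)
  fit <- fpca(fit_coefficients(d$profiles, b), J = 5)
  errs <- sapply(1:5, function(ju)
    mean((reconstruct(fit, ju, g)$values - d$profiles$values)^2))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("adding a constant function shifts the mean only", {
  b <- make_basis(-1, 1, 10, 4)
  g <- seq(-1, 1, length.out = 301)
  d <- make_inspan(40, b, g, 13)
  fit1 <- fpca(fit_coefficients(d$profiles, b), J = 4)
  pm2 <- profile_matrix(d$profiles$values + 7, d$profiles$region_ids, g)
  fit2 <- fpca(fit_coefficients(pm2, b), J = 4)
  expect_equal(fit2$eigenvalues, fit1$eigenvalues, tolerance = 1e-8)
  expect_equal(fit2$eig_coeffs, fit1$eig_coeffs, tolerance = 1e-8)
  expect_equal(evaluate_mean(fit2, g), evaluate_mean(fit1, g) + 7,
               tolerance = 1e-8)
})

test_that("fpca recovers planted eigenfunctions and variances under noise", {
  spec <- simulation_spec(L = 1000, n_components = 3, lambdas = c(9, 4, 1),
                          cross_rho = c(0, 0, 0), noise_sd = 0.1, seed = 5)
  sim <- simulate_mark_pair(spec)
  b <- make_basis(-5000, 5000, 50)
  fit <- fpca(fit_coefficients(sim$profiles_A, b), J = 3)
  Xi <- evaluate_eigenfunctions(fit, sim$truth$grid)
  # white noise of sd sigma per bin of width delta adds ~ sigma^2 * delta
  # to each score variance (the noise floor)
  floor <- spec$noise_sd^2 * spec$grid_bin
  for (k in 1:3) {
    expect_gte(abs(cor(Xi[, k], sim$truth$xi_A[, k])), 0.99)
    expect_lt(abs(fit$eigenvalues[k] - spec$lambdas[k] - floor),
              0.1 * spec$lambdas[k])
  }
})

test_that("fpca input validation and method surface", {
  b <- make_basis(0, 1, 6, 4)
  g <- seq(0, 1, length.out = 51)
  d <- make_inspan(10, b, g, 2)
  fd <- fit_coefficients(d$profiles, b)
  expect_error(fpca(fd, J = 10), "min\\(K, L - 1\\)")
  fit <- fpca(fd, J = 3)
  expect_s3_class(fit, "fpca")
  expect_output(print(fit), "Functional PCA")
  expect_output(print(summary(fit)), "variance")
  expect_equal(dim(coef(fit)), c(6, 3))
  sims <- simulate(fit, nsim = 2, seed = 1, n_regions = 5)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]$values), c(5, 401))
  # fpca directly from a profile matrix
  fit2 <- fpca(d$profiles, J = 3, K = 6, interval = c(0, 1))
  expect_equal(fit2$eigenvalues, fit$eigenvalues, tolerance = 1e-10)
})

test_that("fpca fits serialize and reload exactly", {
  b <- make_basis(-1, 1, 8, 4)
  g <- seq(-1, 1, length.out = 201)
  d <- make_inspan(20, b, g, 3)
  fit <- fpca(fit_coefficients(d$profiles, b), J = 4)
  prefix <- tempfile()
  write_fpca(fit, prefix, grid_points = 101)
  fit2 <- read_fpca(prefix)
  expect_equal(fit2$eigenvalues, fit$eigenvalues, tolerance = 1e-12)
  expect_equal(fit2$eig_coeffs, fit$eig_coeffs, tolerance = 1e-12)
  expect_equal(fit2$scores, fit$scores, tolerance = 1e-12)
  expect_equal(fit2$region_ids, fit$region_ids)
})
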