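test_that("B-spline basis rows form a partition of unity and match the de Boor oracle", {
  basis <- build_basis(1:9, n_basis = 6, degree = 3)
  expect_equal(dim(basis$design), c(9, 6))
  expect_equal(rowSums(basis$design), rep(1, 9), tolerance = 1e-10)
  oracle <- bspline_design_oracle(basis$knots, 3, 1:9)
  expect_equal(basis$design, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # off-grid points too
  xs <- seq(1.3, 8.7, by = 0.9)
  expect_equal(basis_matrix(basis, xs), bspline_design_oracle(basis$knots, 3, xs),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("second-order difference penalty annihilates constant and linear coefficients", {
  basis <- build_basis(1:9, n_basis = 6, degree = 3, penalty_order = 2)
  expect_equal(drop(basis$penalty %*% rep(1, 6)), rep(0, 6), tolerance = 1e-12)
  expect_equal(drop(basis$penalty %*% (1:6)), rep(0, 6), tolerance = 1e-12)
  expect_true(isSymmetric(basis$penalty))
  expect_true(all(eigen(basis$penalty, only.values = TRUE)$values > -1e-10))
})

test_that("basis construction rejects unidentifiable or degenerate requests", {
  expect_error(build_basis(1:3, n_basis = 8, degree = 3), "unidentifiable")
  expect_error(build_basis(5, n_basis = 6), "at least 2 distinct")
  expect_error(build_basis(1:9, n_basis = 3, degree = 3), "degree")
})

test_that("penalized fit matches a brute-force linear solve and nests least squares", {
  basis <- build_basis(1:9, n_basis = 6)
  set.seed(101)
  y <- rnorm(9, 70, 3)
  fit <- fit_pspline(1:9, y, basis, lambda = 10)
  oracle <- pspline_solve_oracle(basis$design, basis$penalty, y, 10)
  expect_equal(fit$coefficients, drop(oracle), tolerance = 1e-10)
  # lambda = 0 reduces to unpenalized least squares on the basis
  fit0 <- fit_pspline(1:9, y, basis, lambda = 0)
  ls <- qr.coef(qr(basis$design), y)
  expect_equal(fit0$coefficients, unname(ls), tolerance = 1e-8)
})

test_that("linear trends pass through the second-order penalty unshrunk", {
  basis <- build_basis(1:9, n_basis = 6, penalty_order = 2)
  y <- 60 + 1.5 * (1:9)
  for (lam in c(0, 1, 1e4)) {
    fit <- fit_pspline(1:9, y, basis, lam)
    expect_equal(drop(basis$design %*% fit$coefficients), y, tolerance = 1e-8)
  }
})

test_that("edf decreases monotonically in lambda and reaches the straight-line limit", {
  basis <- build_basis(1:9, n_basis = 6)
  set.seed(7)
  y <- rnorm(9, 70, 2)
  lambdas <- 10^seq(-4, 8, length.out = 25)
  edfs <- vapply(lambdas, function(l) fit_pspline(1:9, y, basis, l)$edf, numeric(1))
  expect_true(all(diff(edfs) <= 1e-8))
  expect_equal(edfs[length(edfs)], 2, tolerance = 0.01)
  expect_true(all(edfs <= basis$n_basis + 1e-8 & edfs >= 1))
  # RSS at lambda = 0 is never beaten by a penalized fit
  rss0 <- fit_pspline(1:9, y, basis, 0)$rss
  expect_true(all(vapply(lambdas, function(l) fit_pspline(1:9, y, basis, l)$rss,
                         numeric(1)) >= rss0 - 1e-10))
})

test_that("GCV selection agrees with a direct recomputation and honors the tie rule", {
  basis <- build_basis(1:9, n_basis = 6)
  set.seed(11)
  grid <- 10^seq(-3, 3, length.out = 13)
  for (rep in 1:5) {
    y <- rnorm(9, 70, 2)
    chosen <- select_lambda(1:9, y, basis, grid)
    gcv <- vapply(grid, function(l) {
      f <- fit_pspline(1:9, y, basis, l)
      length(y) * f$rss / (length(y) - f$edf)^2
    }, numeric(1))
    expect_equal(chosen, grid[which.min(gcv)])
  }
  expect_equal(select_lambda(1:9, rnorm(9, 70, 2), basis, grid = 3.5), 3.5)
  # exact GCV ties (perfect linear fit at every lambda) resolve to the smallest
  expect_equal(select_lambda(1:9, 60 + 2 * (1:9), basis, grid), min(grid))
  expect_error(select_lambda(1:9, rnorm(9), basis, grid = numeric(0)), "non-empty")
})

test_that("random small instances reproduce the ridge-type closed form", {
  set.seed(202)
  for (rep in 1:25) {
    months <- sort(sample(1:12, sample(5:10, 1)))
    nb <- sample(4:min(6, length(months) + 3), 1)
    basis <- build_basis(months, n_basis = nb, degree = 3,
                         penalty_order = sample(1:2, 1))
    x <- sample(months, 30, replace = TRUE)
    y <- rnorm(30, 65 + 0.5 * x, 2)
    lam <- runif(1, 0, 50)
    fit <- fit_pspline(x, y, basis, lam)
    B <- basis_matrix(basis, x)
    expect_equal(fit$coefficients,
                 drop(pspline_solve_oracle(B, basis$penalty, y, lam)),
                 tolerance = 1e-8)
  }
})

test_that("subject log-likelihood has the Gaussian closed form", {
  basis <- build_basis(1:9, n_basis = 6)
  y <- 60 + 1.5 * (1:9)
  model <- fit_pspline(1:9, y, basis, 1)
  model$sigma2 <- 1 / (2 * pi)
  model$sigma2_b <- 0
  # zero residuals with sigma^2 = 1/(2*pi): the log term vanishes exactly
  expect_equal(subject_loglik(1:9, y, model), 0, tolerance = 1e-10)
  # a uniform shift d costs 9 d^2 / (2 sigma^2)
  d <- 0.7
  expect_equal(subject_loglik(1:9, y + d, model),
               -9 * d^2 / (2 * model$sigma2), tolerance = 1e-8)
  expect_error(subject_loglik(c(5, 10), c(70, 71), model), "extrapolation")
})

test_that("compound-symmetry likelihood matches a direct multivariate normal oracle", {
  basis <- build_basis(1:9, n_basis = 6)
  set.seed(13)
  model <- fit_pspline(1:9, rnorm(9, 70, 2), basis, 5)
  model$sigma2_b <- 4
  model$sigma2_w <- 1.5
  months <- c(2, 5, 7)
  w <- c(68, 71, 73.5)
  r <- w - predict(model, months)
  Sigma <- 4 + diag(1.5, 3)
  expect_equal(subject_loglik(months, w, model, random_intercept = TRUE),
               as.numeric(mvn_loglik_oracle(r, Sigma)), tolerance = 1e-10)
  # unbalanced subject (single observation) degenerates to a univariate normal
  r1 <- 69 - predict(model, 3)
  expect_equal(subject_loglik(3, 69, model, random_intercept = TRUE),
               dnorm(r1, 0, sqrt(5.5), log = TRUE), tolerance = 1e-10)
})

test_that("variance components recover a known random-intercept structure", {
  set.seed(21)
  n_subj <- 400
  b <- rnorm(n_subj, 0, 2)
  subject <- rep(seq_len(n_subj), each = 9)
  resid <- b[subject] + rnorm(n_subj * 9, 0, 1)
  vc <- trajsmm:::estimate_variance_components(resid, subject)
  expect_equal(vc$sigma2_b, 4, tolerance = 0.5)
  expect_equal(vc$sigma2_w, 1, tolerance = 0.1)
})
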