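# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: the B-spline oracle is a direct Cox-de Boor
# recursion, the penalized fit oracle a plain linear solve, and the Gaussian
# density oracles direct matrix evaluations.

# Cox-de Boor recursion for a single B-spline basis function B_{i,p} on knot
# vector t; the domain's right endpoint is treated as inside the last span.
cox_deboor <- function(x, i, p, t) {
  if (p == 0) {
    tmax <- max(t)
    inside <- (x >= t[i] && x < t[i + 1]) || (x == tmax && t[i] < t[i + 1] && t[i + 1] == tmax)
    return(as.numeric(inside))
  }
  a <- 0
  if (t[i + p] > t[i]) a <- (x - t[i]) / (t[i + p] - t[i]) * cox_deboor(x, i, p - 1, t)
  b <- 0
  if (t[i + p + 1] > t[i + 1]) b <- (t[i + p + 1] - x) / (t[i + p + 1] - t[i + 1]) * cox_deboor(x, i + 1, p - 1, t)
  a + b
}

bspline_design_oracle <- function(knots, degree, x) {
  n_basis <- length(knots) - degree - 1
  vapply(seq_len(n_basis), function(i)
    vapply(x, cox_deboor, numeric(1), i = i, p = degree, t = knots),
    numeric(length(x)))
}

# brute-force penalized least squares: solve (B'B + lambda P) beta = B'y
pspline_solve_oracle <- function(B, P, y, lambda) {
  solve(crossprod(B) + lambda * P, crossprod(B, y))
}

# multivariate normal log-density with mean 0, generic covariance
mvn_loglik_oracle <- function(r, Sigma) {
  -0.5 * (length(r) * log(2 * pi) + determinant(Sigma, logarithm = TRUE)$modulus +
            drop(crossprod(r, solve(Sigma, r))))
}

# Bernoulli log-likelihood maximized numerically, as an IRLS-free oracle
logistic_mle_oracle <- function(X, y) {
  negll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  optim(rep(0, ncol(X)), negll, method = "BFGS",
        control = list(maxit = 500, reltol = 1e-14))$par
}

# small noise-free K-class cohort with unequal proportions so that the
# rank-split initialization does not coincide with the truth
noise_free_cfg <- function(K, n, seed = 1) {
  props <- switch(as.character(K),
                  "2" = c(0.55, 0.45),
                  "3" = c(0.38, 0.36, 0.26),
                  "4" = c(0.30, 0.28, 0.24, 0.18))
  cohort_config(n_subjects = n, class_proportions = props,
                class_baselines = seq(58, by = 8.5, length.out = K),
                random_intercept_sd = 0, residual_sd = 0, seed = seed)
}

# contingency-table cohort: a of exposed with event, b exposed without,
# c unexposed with event, d unexposed without
table_2x2_data <- function(a, b, c, d) {
  data.frame(x = rep(c(1, 1, 0, 0), c(a, b, c, d)),
             y = rep(c(1, 0, 1, 0), c(a, b, c, d)))
}
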