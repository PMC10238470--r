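#' Build a penalized B-spline basis
#'
#' Cubic (by default) B-spline design on equally spaced knots spanning the
#' observed month range, with a difference penalty on adjacent coefficients —
#' the standard P-spline construction. The second-order penalty's null space
#' contains constant and linear functions, so linear gain trends are never
#' penalized.
#'
#' @param months sorted evaluation points (at least 2 distinct values).
#' @param n_basis number of basis functions; must satisfy
#'   `degree + 1 <= n_basis <= n_distinct_months + degree`.
#' @param degree spline degree (3 = cubic).
#' @param penalty_order order of the difference penalty.
#' @return an object of class `spline_basis` with elements `months`, `knots`
#'   (full knot vector), `degree`, `design` (length(months) x n_basis) and
#'   `penalty` (n_basis x n_basis, symmetric PSD).
#' @export
build_basis <- function(months, n_basis = 6L, degree = 3L, penalty_order = 2L) {
  months <- sort(unique(as.numeric(months)))
  if (length(months) < 2) stop("need at least 2 distinct months")
  if (n_basis < degree + 1) stop("n_basis must be at least degree + 1")
  if (n_basis > length(months) + degree)
    stop("n_basis exceeds number of distinct months + degree: basis unidentifiable")
  if (penalty_order < 1 || penalty_order >= n_basis) stop("invalid penalty_order")
  lo <- min(months); hi <- max(months)
  # equally spaced knots extended beyond the boundaries (Eilers-Marx
  # convention): keeps the Greville sites equidistant, so the difference
  # penalty's null space really contains constant and linear trends
  h <- (hi - lo) / (n_basis - degree)
  knots <- seq(lo - degree * h, hi + degree * h, by = h)
  design <- splines::splineDesign(knots, months, ord = degree + 1L)
  D <- diff(diag(n_basis), differences = penalty_order)
  structure(list(
    months = months,
    knots = knots,
    degree = as.integer(degree),
    n_basis = as.integer(n_basis),
    penalty_order = as.integer(penalty_order),
    design = design,
    penalty = crossprod(D)
  ), class = "spline_basis")
}

#' Evaluate the basis design matrix at arbitrary points
#'
#' @param basis a [build_basis()] object.
#' @param x evaluation points; must lie inside the fitted month range
#'   (no extrapolation).
#' @return matrix `length(x) x n_basis`.
#' @export
basis_matrix <- function(basis, x) {
  stopifnot(inherits(basis, "spline_basis"))
  rng <- range(basis$months)
  if (any(x < rng[1] | x > rng[2]))
    stop("evaluation point outside the fitted month range [", rng[1], ", ", rng[2],
         "]: extrapolation is not supported")
  splines::splineDesign(basis$knots, x, ord = basis$degree + 1L)
}

#' Fit a penalized-spline smoother
#'
#' Solves the penalized least-squares problem
#' `min ||y - B beta||^2 + lambda * beta' P beta` via the normal equations
#' `(B'B + lambda P) beta = B'y`. The effective degrees of freedom are the
#' trace of the hat matrix; the residual variance is `RSS / (n - edf)`,
#' floored at `variance_floor` to keep downstream likelihoods finite.
#'
#' @param x months of the observations (aligned with `y`).
#' @param y observed responses (kg).
#' @param basis a [build_basis()] object.
#' @param lambda smoothing parameter, finite and >= 0.
#' @param variance_floor lower bound for the residual variance (kg^2).
#' @return an object of class `class_model`: `coefficients`, `lambda`, `edf`,
#'   `sigma2`, `fitted_curve` (at `basis$months`), `n_obs`, `basis`, and
#'   compound-symmetry components `sigma2_b` (0 unless set later) / `sigma2_w`.
#' @export
fit_pspline <- function(x, y, basis, lambda, variance_floor = 1e-6) {
  stopifnot(inherits(basis, "spline_basis"), length(x) == length(y))
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be finite and >= 0")
  B <- basis_matrix(basis, x)
  BtB <- crossprod(B)
  if (lambda == 0 && qr(B)$rank < basis$n_basis)
    stop("design is rank deficient at lambda = 0: fewer distinct months than basis functions")
  A <- BtB + lambda * basis$penalty
  Ainv_BtB <- solve(A, BtB)
  beta <- drop(solve(A, crossprod(B, y)))
  edf <- sum(diag(Ainv_BtB))
  fitted <- drop(B %*% beta)
  rss <- sum((y - fitted)^2)
  n <- length(y)
  sigma2 <- max(rss / max(n - edf, 1), variance_floor)
  structure(list(
    coefficients = beta,
    lambda = lambda,
    edf = edf,
    sigma2 = sigma2,
    sigma2_b = 0,
    sigma2_w = sigma2,
    rss = rss,
    fitted_curve = drop(basis$design %*% beta),
    n_obs = n,
    basis = basis
  ), class = "class_model")
}

#' Predict the fitted class curve at given months
#'
#' @param object a `class_model`.
#' @param months months inside the fitted range.
#' @param ... unused.
#' @return fitted mean weights (kg).
#' @export
predict.class_model <- function(object, months = object$basis$months, ...) {
  drop(basis_matrix(object$basis, months) %*% object$coefficients)
}

#' Select the smoothing parameter by generalized cross-validation
#'
#' Minimizes `GCV(lambda) = n RSS(lambda) / (n - tr H(lambda))^2` over a grid;
#' ties go to the smaller lambda.
#'
#' @param x,y observations as in [fit_pspline()].
#' @param basis a [build_basis()] object.
#' @param grid positive candidate lambdas (default log-spaced 1e-4..1e4,
#'   41 points).
#' @return the selected lambda (a single number).
#' @export
select_lambda <- function(x, y, basis, grid = 10^seq(-4, 4, length.out = 41)) {
  if (length(grid) == 0 || any(grid <= 0)) stop("grid must be non-empty and positive")
  grid <- sort(grid)
  B <- basis_matrix(basis, x)
  BtB <- crossprod(B)
  Bty <- crossprod(B, y)
  yty <- sum(y^2)
  n <- length(y)
  gcv <- vapply(grid, function(lam) {
    A <- BtB + lam * basis$penalty
    beta <- solve(A, Bty)
    edf <- sum(diag(solve(A, BtB)))
    rss <- yty - 2 * sum(beta * Bty) + drop(crossprod(beta, BtB %*% beta))
    n * max(rss, 0) / (n - edf)^2
  }, numeric(1))
  if (all(!is.finite(gcv))) stop("GCV is non-finite over the whole grid")
  # ties (to numerical precision) resolve to the smallest lambda
  best <- min(gcv, na.rm = TRUE)
  grid[which(gcv <= best + 1e-10 * (1 + abs(best)))[1]]
}

#' Per-subject Gaussian log-likelihood under a class model
#'
#' Under the default independent-residual model the log-likelihood is the sum
#' of univariate normal log-densities of the residuals with variance
#' `sigma2`. When the model carries a positive random-intercept variance
#' `sigma2_b`, the multivariate normal log-density under the
#' compound-symmetry covariance `sigma2_b * J + sigma2_w * I` is used
#' (evaluated in closed form via the Sherman–Morrison identity, so unbalanced
#' subjects are handled directly).
#'
#' @param months,weights the subject's observations; months must lie inside
#'   the model's fitted range.
#' @param model a `class_model`.
#' @param random_intercept use the compound-symmetry likelihood.
#' @return the log-likelihood (a single number).
#' @export
subject_loglik <- function(months, weights, model, random_intercept = model$sigma2_b > 0) {
  r <- weights - predict(model, months)
  m <- length(r)
  if (random_intercept && model$sigma2_b > 0) {
    s2 <- model$sigma2_w
    sb2 <- model$sigma2_b
    denom <- s2 + m * sb2
    quad <- (sum(r^2) - sb2 * sum(r)^2 / denom) / s2
    logdet <- (m - 1) * log(s2) + log(denom)
    -0.5 * (m * log(2 * pi) + logdet + quad)
  } else {
    sum(dnorm(r, 0, sqrt(model$sigma2), log = TRUE))
  }
}

# Method-of-moments variance components from within-class residuals
# (one-way random-intercept ANOVA estimators on possibly unbalanced data).
# residuals: numeric vector; subject: factor/vector aligned with residuals.
estimate_variance_components <- function(residuals, subject, variance_floor = 1e-6) {
  subject <- factor(subject)
  m_i <- as.vector(table(subject))
  n <- length(residuals)
  g <- length(m_i)
  means <- tapply(residuals, subject, mean)
  ssw <- sum((residuals - means[subject])^2)
  grand <- mean(residuals)
  ssb <- sum(m_i * (means - grand)^2)
  if (g <= 1 || n <= g) {
    return(list(sigma2_w = max(stats::var(residuals), variance_floor), sigma2_b = 0))
  }
  msw <- ssw / (n - g)
  msb <- ssb / (g - 1)
  m0 <- (n - sum(m_i^2) / n) / (g - 1)
  sigma2_b <- max((msb - msw) / m0, 0)
  list(sigma2_w = max(msw, variance_floor), sigma2_b = sigma2_b)
}
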