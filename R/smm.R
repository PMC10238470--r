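#' Control parameters for the smoothing mixture model
#'
#' @param n_basis,degree,penalty_order P-spline basis settings passed to
#'   [build_basis()].
#' @param lambda_grid candidate smoothing parameters for per-class GCV
#'   selection at every M step.
#' @param random_intercept if `TRUE`, each class model carries a
#'   compound-symmetry (random-intercept) covariance whose variance
#'   components are estimated by method of moments at every M step, and the
#'   E step classifies with the corresponding multivariate-normal marginal
#'   likelihood. If `FALSE`, residuals are treated as independent.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum number of EM iterations.
#' @param variance_floor lower bound for residual variances (kg^2); protects
#'   the E step from degenerate zero-variance classes.
#' @param reseed_empty if `TRUE`, an empty class is reseeded with the single
#'   worst-fitting subject instead of aborting the fit.
#' @param bic_n whether the BIC sample size is the total number of weight
#'   observations (default) or the number of subjects.
#' @return a list of class `smm_control`.
#' @export
smm_control <- function(n_basis = 6L, degree = 3L, penalty_order = 2L,
                        lambda_grid = 10^seq(-4, 4, length.out = 41),
                        random_intercept = TRUE,
                        tol = 1e-6, max_iter = 100L,
                        variance_floor = 1e-6,
                        reseed_empty = FALSE,
                        bic_n = c("observations", "subjects")) {
  structure(list(
    n_basis = as.integer(n_basis), degree = as.integer(degree),
    penalty_order = as.integer(penalty_order),
    lambda_grid = lambda_grid,
    random_intercept = isTRUE(random_intercept),
    tol = tol, max_iter = as.integer(max_iter),
    variance_floor = variance_floor,
    reseed_empty = isTRUE(reseed_empty),
    bic_n = match.arg(bic_n)
  ), class = "smm_control")
}

validate_long <- function(data) {
  need <- c("subject_id", "month", "weight_kg")
  if (!all(need %in% names(data)))
    stop("longitudinal data must have columns ", paste(need, collapse = ", "))
  if (nrow(data) == 0) stop("longitudinal data is empty")
  invisible(data)
}

canonical_ids <- function(data) sort(unique(as.character(data$subject_id)))

subject_mean_weights <- function(data, ids = canonical_ids(data)) {
  means <- tapply(data$weight_kg, factor(as.character(data$subject_id), levels = ids), mean)
  as.vector(means)
}

#' Initial class assignment by mean trajectory level
#'
#' Ranks subjects by their mean observed weight and splits the ranking into K
#' contiguous groups of near-equal size (larger groups first); ties in mean
#' weight are broken by subject-id order. Class 1 holds the lowest-weight
#' subjects.
#'
#' @param data long-format data.frame (`subject_id`, `month`, `weight_kg`).
#' @param K number of classes.
#' @return integer class per subject, named by subject id (sorted order).
#' @export
initialize_classes <- function(data, K) {
  validate_long(data)
  ids <- canonical_ids(data)
  if (K < 1) stop("K must be at least 1")
  if (K > length(ids)) stop("K exceeds the number of subjects")
  means <- subject_mean_weights(data, ids)
  rank_order <- order(means, ids, method = "radix")
  assignment <- integer(length(ids))
  assignment[rank_order] <- rep.int(seq_len(K), split_sizes(length(ids), K))
  names(assignment) <- ids
  assignment
}

degenerate_class_error <- function(k, iteration = NA_integer_) {
  structure(
    list(message = sprintf("class %d has no members%s", k,
                           if (is.na(iteration)) "" else sprintf(" at iteration %d", iteration)),
         call = NULL, class_index = k, iteration = iteration),
    class = c("trajsmm_degenerate_class", "error", "condition")
  )
}

#' M step: fit one penalized-spline smoother per class
#'
#' Pools the (month, weight) observations of every subject currently assigned
#' to each class and fits an independent P-spline, reselecting the smoothing
#' parameter by GCV each time. With `control$random_intercept`, within-class
#' variance components are estimated from the class residuals by method of
#' moments and attached to the model.
#'
#' @param data long-format data.frame.
#' @param assignment named integer class per subject.
#' @param control an [smm_control()].
#' @param K number of classes (defaults to the largest index in
#'   `assignment`).
#' @param basis optional shared [build_basis()]; built from the data's months
#'   when omitted.
#' @return list of `class_model`, length K.
#' @export
m_step <- function(data, assignment, control = smm_control(), K = max(assignment),
                   basis = NULL) {
  validate_long(data)
  if (is.null(basis))
    basis <- build_basis(sort(unique(data$month)), control$n_basis,
                         control$degree, control$penalty_order)
  cls <- assignment[as.character(data$subject_id)]
  lapply(seq_len(K), function(k) {
    rows <- which(cls == k)
    if (length(rows) == 0) stop(degenerate_class_error(k))
    x <- data$month[rows]; y <- data$weight_kg[rows]
    lambda <- select_lambda(x, y, basis, control$lambda_grid)
    model <- fit_pspline(x, y, basis, lambda, control$variance_floor)
    if (control$random_intercept) {
      resid <- y - predict(model, x)
      vc <- estimate_variance_components(resid, data$subject_id[rows], control$variance_floor)
      model$sigma2_w <- vc$sigma2_w
      model$sigma2_b <- vc$sigma2_b
      model$sigma2 <- vc$sigma2_w + vc$sigma2_b
    }
    model
  })
}

# per-subject log-likelihood matrix (n_subjects x K), vectorized over subjects
loglik_matrix <- function(data, models, ids = canonical_ids(data)) {
  fs <- factor(as.character(data$subject_id), levels = ids)
  um <- sort(unique(data$month))
  midx <- match(data$month, um)
  m_i <- as.vector(table(fs))
  ll <- matrix(NA_real_, length(ids), length(models))
  for (k in seq_along(models)) {
    model <- models[[k]]
    curve <- predict(model, um)
    r <- data$weight_kg - curve[midx]
    if (model$sigma2_b > 0) {
      s2 <- model$sigma2_w; sb2 <- model$sigma2_b
      sse <- as.vector(rowsum(r^2, fs))
      s <- as.vector(rowsum(r, fs))
      denom <- s2 + m_i * sb2
      quad <- (sse - sb2 * s^2 / denom) / s2
      logdet <- (m_i - 1) * log(s2) + log(denom)
      ll[, k] <- -0.5 * (m_i * log(2 * pi) + logdet + quad)
    } else {
      obs_ll <- dnorm(r, 0, sqrt(model$sigma2), log = TRUE)
      ll[, k] <- as.vector(rowsum(obs_ll, fs))
    }
  }
  rownames(ll) <- ids
  ll
}

#' E step: reassign every subject to its best-likelihood class
#'
#' Each subject goes to the class whose estimated trajectory gives it the
#' largest log-likelihood (for equal class variances this is the class with
#' the smallest sum of squared deviations, i.e. "most similar" trajectory).
#' Exact ties go to the lowest class index.
#'
#' @param data long-format data.frame.
#' @param models list of `class_model` from [m_step()].
#' @return list with `assignment` (named integer vector), `per_subject_ll`
#'   (achieved maxima) and `ll_matrix` (n_subjects x K).
#' @export
e_step <- function(data, models) {
  validate_long(data)
  if (length(models) == 0) stop("need at least one class model")
  ll <- loglik_matrix(data, models)
  assignment <- max.col(ll, ties.method = "first")
  names(assignment) <- rownames(ll)
  per_subject_ll <- ll[cbind(seq_len(nrow(ll)), assignment)]
  names(per_subject_ll) <- rownames(ll)
  list(assignment = assignment, per_subject_ll = per_subject_ll, ll_matrix = ll)
}

#' Bayesian information criterion
#'
#' `BIC = -2 * total_ll + p * log(n_obs)`; smaller is better.
#'
#' @param total_ll total log-likelihood.
#' @param p effective number of parameters.
#' @param n_obs sample size entering the penalty (must be positive).
#' @return a single number.
#' @export
compute_bic <- function(total_ll, p, n_obs) {
  if (n_obs <= 0) stop("n_obs must be positive")
  -2 * total_ll + p * log(n_obs)
}

#' Fit a K-class smoothing mixture model by hard-assignment EM
#'
#' Starts from the mean-trajectory rank split of [initialize_classes()] and
#' alternates [m_step()] and [e_step()] until class memberships stop changing
#' and the total best-class log-likelihood is stable (both conditions
#' required), or `max_iter` is reached. The whole fit is deterministic: no
#' randomness enters the algorithm.
#'
#' Each iteration embeds an exactness check: for fixed class models,
#' reassigning subjects to their argmax class can never decrease the total
#' log-likelihood; a violation aborts with an internal error.
#'
#' @param data long-format data.frame (`subject_id`, `month`, `weight_kg`).
#' @param K number of latent classes (>= 1).
#' @param control an [smm_control()].
#' @return an object of class `smm_fit`: `K`, `models`, `assignment`,
#'   `class_labels`, `per_subject_ll`, `total_ll`, `bic`, `p_effective`,
#'   `n_obs`, `n_iterations`, `converged`, `trace` (per-iteration total_ll
#'   and number of reassignments), `initial_assignment`, `control`.
#' @export
fit_smm <- function(data, K, control = smm_control()) {
  validate_long(data)
  ids <- canonical_ids(data)
  basis <- build_basis(sort(unique(data$month)), control$n_basis,
                       control$degree, control$penalty_order)
  assignment <- initialize_classes(data, K)
  initial_assignment <- assignment
  prev_ll <- -Inf
  per_subject_ll <- NULL
  models <- NULL
  trace <- data.frame(iteration = integer(), total_ll = numeric(), n_changed = integer())
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    models <- tryCatch(
      m_step(data, assignment, control, K = K, basis = basis),
      trajsmm_degenerate_class = function(cond) {
        if (!control$reseed_empty || is.null(per_subject_ll)) {
          cond$iteration <- iter
          cond$message <- sprintf("class %d has no members at iteration %d",
                                  cond$class_index, iter)
          stop(cond)
        }
        # reseed: move the single worst-fitting subject into the empty class
        worst <- names(which.min(per_subject_ll))
        assignment[worst] <<- cond$class_index
        m_step(data, assignment, control, K = K, basis = basis)
      }
    )
    es <- e_step(data, models)
    ll_old_assignment <- sum(es$ll_matrix[cbind(seq_along(ids), assignment[ids])])
    total_ll <- sum(es$per_subject_ll)
    if (total_ll < ll_old_assignment - 1e-8 * (1 + abs(ll_old_assignment)))
      stop("internal error: E-step reassignment decreased the total log-likelihood")
    n_changed <- sum(es$assignment[ids] != assignment[ids])
    trace <- rbind(trace, data.frame(iteration = iter, total_ll = total_ll,
                                     n_changed = n_changed))
    ll_stable <- is.finite(prev_ll) &&
      abs(total_ll - prev_ll) <= control$tol * (1 + abs(prev_ll))
    assignment <- es$assignment
    per_subject_ll <- es$per_subject_ll
    prev_ll <- total_ll
    if (n_changed == 0 && ll_stable) {
      converged <- TRUE
      break
    }
  }
  n_var_params <- if (control$random_intercept) 2L else 1L
  p <- sum(vapply(models, `[[`, numeric(1), "edf")) + n_var_params * K
  n_bic <- if (control$bic_n == "observations") nrow(data) else length(ids)
  structure(list(
    K = as.integer(K),
    models = models,
    assignment = assignment,
    class_labels = NULL,
    per_subject_ll = per_subject_ll,
    total_ll = prev_ll,
    bic = compute_bic(prev_ll, p, n_bic),
    p_effective = p,
    n_obs = nrow(data),
    n_subjects = length(ids),
    n_iterations = iter,
    converged = converged,
    trace = trace,
    initial_assignment = initial_assignment,
    control = control
  ), class = "smm_fit")
}

#' @export
print.smm_fit <- function(x, ...) {
  cat(sprintf("Smoothing mixture model: K = %d, %d subjects, %d observations\n",
              x$K, x$n_subjects, x$n_obs))
  cat(sprintf("  total log-likelihood %.2f, BIC %.2f (p = %.1f)\n",
              x$total_ll, x$bic, x$p_effective))
  cat(sprintf("  %d iteration(s), converged: %s\n", x$n_iterations, x$converged))
  sizes <- table(factor(x$assignment, levels = seq_len(x$K)))
  lbl <- x$class_labels %||% as.character(seq_len(x$K))
  cat("  class sizes:", paste(sprintf("%s=%d", lbl, sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Reorder classes by trajectory level
#'
#' Reindexes classes in ascending order of their fitted-curve mean, so class
#' 1 is always the lowest trajectory. Log-likelihoods, BIC and within-class
#' memberships are untouched. For K = 3 the labels "low", "medium", "high"
#' are attached.
#'
#' @param fit an `smm_fit`.
#' @return the relabeled `smm_fit`.
#' @export
relabel <- function(fit) {
  stopifnot(inherits(fit, "smm_fit"))
  level <- vapply(fit$models, function(m) mean(m$fitted_curve), numeric(1))
  ord <- order(level)            # ord[j] = old index of new class j
  perm <- integer(fit$K)
  perm[ord] <- seq_len(fit$K)    # perm[old] = new index
  fit$models <- fit$models[ord]
  fit$assignment[] <- perm[fit$assignment]
  if (fit$K == 3) fit$class_labels <- c("low", "medium", "high")
  fit
}

#' Cross-tabulate two class assignments
#'
#' Contingency table of an initial versus a final grouping over the same
#' subjects, with the concordance percentage (share of subjects on the
#' diagonal).
#'
#' @param initial,final named integer class vectors over identical subject
#'   sets, with classes in 1..K.
#' @param K number of classes (defaults to the largest index seen).
#' @return list of class `smm_crosstab` with `table` (K x K) and
#'   `concordance` (percent).
#' @export
crosstab <- function(initial, final, K = max(c(initial, final))) {
  if (!setequal(names(initial), names(final)))
    stop("initial and final assignments cover different subjects")
  final <- final[names(initial)]
  tab <- table(factor(initial, levels = seq_len(K)),
               factor(final, levels = seq_len(K)),
               dnn = c("initial", "final"))
  structure(list(table = tab,
                 concordance = 100 * sum(diag(tab)) / length(initial)),
            class = "smm_crosstab")
}

#' @export
print.smm_crosstab <- function(x, ...) {
  print(x$table)
  cat(sprintf("concordance: %.1f%%\n", x$concordance))
  invisible(x)
}

#' Fit candidate class counts and select one by BIC with a parsimony margin
#'
#' Fits the model for every K in `k_range` and tabulates BIC, total
#' log-likelihood and the per-class medians (IQR) of subjects' mean observed
#' weights. The selected K is the smallest whose BIC lies within
#' `parsimony_margin * |min BIC|` of the minimum: with flexible smoothers BIC
#' often keeps creeping down as classes are added, so a small relative margin
#' favors the parsimonious description; a note records when the margin
#' overrode the strict BIC minimum. A K whose fit aborts with an empty class
#' is recorded as failed, not fatal.
#'
#' @param data long-format data.frame.
#' @param k_range candidate class counts.
#' @param control an [smm_control()].
#' @param parsimony_margin relative BIC margin (default 0.035).
#' @return object of class `smm_selection`: `table` (one row per K),
#'   `fits` (list), `selected_k`, `bic_optimal_k`, `best_fit` (relabeled fit
#'   for `selected_k`), `parsimony_note`.
#' @export
select_k <- function(data, k_range, control = smm_control(), parsimony_margin = 0.035) {
  if (length(k_range) == 0) stop("k_range must be non-empty")
  k_range <- sort(unique(as.integer(k_range)))
  ids <- canonical_ids(data)
  means <- subject_mean_weights(data, ids)
  fits <- list()
  rows <- lapply(k_range, function(K) {
    fit <- tryCatch(fit_smm(data, K, control), trajsmm_degenerate_class = function(e) e)
    if (inherits(fit, "error")) {
      return(data.frame(K = K, failed = TRUE, converged = NA, bic = NA_real_,
                        total_ll = NA_real_, n_iterations = NA_integer_,
                        class_medians = conditionMessage(fit),
                        stringsAsFactors = FALSE))
    }
    fit <- relabel(fit)
    fits[[as.character(K)]] <<- fit
    med <- vapply(seq_len(K), function(k) {
      w <- means[fit$assignment[ids] == k]
      sprintf("%.1f (%.1f)", median(w), IQR(w))
    }, character(1))
    data.frame(K = K, failed = FALSE, converged = fit$converged, bic = fit$bic,
               total_ll = fit$total_ll, n_iterations = fit$n_iterations,
               class_medians = paste(med, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- which(!tab$failed)
  if (length(ok) == 0) stop("every candidate K failed")
  min_bic <- min(tab$bic[ok])
  bic_optimal_k <- tab$K[ok][which.min(tab$bic[ok])]
  within <- ok[tab$bic[ok] <= min_bic + parsimony_margin * abs(min_bic)]
  selected_k <- min(tab$K[within])
  note <- if (selected_k != bic_optimal_k) {
    sprintf("K = %d selected on parsimony: BIC within %.1f%% of the minimum at K = %d",
            selected_k, 100 * parsimony_margin, bic_optimal_k)
  } else NULL
  structure(list(table = tab, fits = fits,
                 selected_k = selected_k, bic_optimal_k = bic_optimal_k,
                 best_fit = fits[[as.character(selected_k)]],
                 parsimony_margin = parsimony_margin,
                 parsimony_note = note),
            class = "smm_selection")
}

#' @export
print.smm_selection <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("selected K = %d (BIC optimum at K = %d)\n", x$selected_k, x$bic_optimal_k))
  if (!is.null(x$parsimony_note)) cat(x$parsimony_note, "\n")
  invisible(x)
}
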