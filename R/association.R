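#' Fit a logistic regression on a design matrix
#'
#' Maximum-likelihood fit by iteratively reweighted least squares (via
#' `stats::glm.fit` with a binomial family), returning the coefficient vector
#' and the inverse-information covariance. Complete separation is detected
#' (diverging coefficients / degenerate fitted probabilities) and raised as an
#' error naming the offending predictor rather than returning a silently
#' unstable fit.
#'
#' @param design numeric matrix including an intercept column; column names
#'   are used as coefficient names.
#' @param y 0/1 outcome vector, not constant.
#' @return object of class `logistic_fit`: `coefficients`, `vcov`,
#'   `converged`, `n`, `deviance`.
#' @export
fit_logistic <- function(design, y) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- c("(Intercept)", paste0("x", seq_len(ncol(design) - 1)))
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  if (length(unique(y)) < 2) stop("y is constant: the model is not estimable")
  if (nrow(design) <= ncol(design)) stop("need more observations than predictors")
  fit <- suppressWarnings(stats::glm.fit(design, y, family = stats::binomial()))
  beta <- fit$coefficients
  if (anyNA(beta)) stop("design is rank deficient: ",
                        paste(names(beta)[is.na(beta)], collapse = ", "))
  mu <- fit$fitted.values
  degenerate <- mu < 1e-8 | mu > 1 - 1e-8
  if (max(abs(beta[-1]), 0) > 15 || (!fit$converged && any(degenerate))) {
    worst <- names(beta)[which.max(abs(beta))]
    stop("complete or quasi-complete separation detected on predictor '", worst, "'")
  }
  # qr of glm.fit is of sqrt(W) X at convergence, so R'R = X'WX
  R <- qr.R(fit$qr)
  vcov <- chol2inv(R)
  # undo any pivoting
  piv <- fit$qr$pivot
  vcov[piv, piv] <- vcov
  dimnames(vcov) <- list(names(beta), names(beta))
  structure(list(coefficients = beta, vcov = vcov, converged = fit$converged,
                 n = length(y), deviance = fit$deviance),
            class = "logistic_fit")
}

#' Wald odds ratios from a fitted logistic model
#'
#' `OR = exp(beta)`, 95% CI `exp(beta +/- 1.96 SE)`, two-sided Wald p-value
#' `2 * pnorm(-|beta| / SE)`.
#'
#' @param fit a `logistic_fit`.
#' @param terms coefficient names to report (default: all but the intercept).
#' @param outcome outcome name recorded in the result.
#' @param adjusted logical flag recorded in the result.
#' @param covariates covariate names recorded in the result.
#' @return data.frame of class `or_result`: one row per term with `estimate`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @export
odds_ratios <- function(fit, terms = NULL, outcome = NA_character_,
                        adjusted = FALSE, covariates = character(0)) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (is.null(terms)) terms <- setdiff(names(fit$coefficients), "(Intercept)")
  missing <- setdiff(terms, names(fit$coefficients))
  if (length(missing)) stop("contrast not in the fit: ", paste(missing, collapse = ", "))
  beta <- fit$coefficients[terms]
  se <- sqrt(diag(fit$vcov)[terms])
  res <- data.frame(
    outcome = outcome,
    contrast = terms,
    estimate = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    adjusted = adjusted,
    covariates = paste(covariates, collapse = "+"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(res) <- c("or_result", "data.frame")
  res
}

#' Univariate confounder screen at p < 0.2
#'
#' For each outcome, each candidate covariate is fitted alone (with an
#' intercept) in a univariate logistic model and retained when its Wald
#' p-value is strictly below the threshold. A candidate whose univariate fit
#' fails (e.g. separation) is recorded as not retained rather than aborting
#' the screen.
#'
#' @param outcomes data.frame holding the outcome and covariate columns.
#' @param outcome_names outcome columns to screen for.
#' @param candidates candidate covariate columns.
#' @param threshold strict retention threshold on the p-value (default 0.2).
#' @return named list: for each outcome, the character vector of retained
#'   covariates.
#' @export
screen_confounders <- function(outcomes, outcome_names, candidates,
                               threshold = 0.2) {
  missing <- setdiff(c(outcome_names, candidates), names(outcomes))
  if (length(missing)) stop("columns absent from the outcome table: ",
                            paste(missing, collapse = ", "))
  res <- lapply(outcome_names, function(oc) {
    keep <- vapply(candidates, function(v) {
      p <- tryCatch({
        X <- cbind(1, outcomes[[v]])
        colnames(X) <- c("(Intercept)", v)
        fit <- fit_logistic(X, outcomes[[oc]])
        odds_ratios(fit, v)$p_value
      }, error = function(e) NA_real_)
      isTRUE(p < threshold)
    }, logical(1))
    candidates[keep]
  })
  names(res) <- outcome_names
  res
}

# design matrix of class dummies (reference omitted) + optional covariates
class_design <- function(class_f, covariate_data = NULL) {
  X <- stats::model.matrix(~class_f)
  colnames(X) <- sub("^class_f", "class_", colnames(X))
  if (!is.null(covariate_data) && ncol(covariate_data) > 0)
    X <- cbind(X, as.matrix(covariate_data))
  X
}

#' Crude and adjusted odds ratios of outcomes across trajectory classes
#'
#' For every outcome, fits a crude logistic model (class dummies only, with
#' the medium trajectory as reference) and an adjusted model additionally
#' containing the covariates retained by the univariate p < 0.2 screen for
#' that outcome (or all candidates when `force_adjust = TRUE`). Emits one
#' crude and one adjusted odds-ratio row per non-reference class.
#'
#' @param assignment named integer class vector (from a relabeled
#'   [fit_smm()]), or a data.frame with `subject_id` and `class` columns.
#' @param outcomes data.frame with `subject_id`, 0/1 outcome columns and
#'   covariate columns.
#' @param outcome_names outcome columns to analyse (default: every 0/1 column
#'   that is not a covariate).
#' @param candidates covariate columns eligible for adjustment.
#' @param reference reference class index; defaults to the class of median
#'   rank (the middle trajectory).
#' @param class_labels optional labels (e.g. low/medium/high) used in the
#'   contrast names.
#' @param force_adjust always adjust for all candidates, bypassing the
#'   screen.
#' @param min_events outcomes with fewer events than this are flagged
#'   `low_information` (still fitted).
#' @return data.frame: one row per (outcome, contrast, crude/adjusted) with
#'   OR, 95% CI, p-value, covariates used, event count and flags.
#' @export
run_association <- function(assignment, outcomes,
                            outcome_names = NULL,
                            candidates = c("age", "gestational_age", "gravidity"),
                            reference = NULL,
                            class_labels = NULL,
                            force_adjust = FALSE,
                            min_events = 5L) {
  if (is.data.frame(assignment)) {
    a <- assignment$class
    names(a) <- assignment$subject_id
    assignment <- a
  }
  idx <- match(names(assignment), outcomes$subject_id)
  if (anyNA(idx)) stop("outcome table is missing subjects: ",
                       paste(utils::head(names(assignment)[is.na(idx)], 5), collapse = ", "))
  outcomes <- outcomes[idx, , drop = FALSE]
  K <- max(assignment)
  if (is.null(reference)) reference <- as.integer(ceiling(K / 2))
  if (is.null(class_labels)) {
    class_labels <- if (K == 3) c("low", "medium", "high") else paste0("class", seq_len(K))
  }
  if (is.null(outcome_names)) {
    is_binary <- vapply(outcomes, function(x) is.numeric(x) && all(x %in% c(0, 1)),
                        logical(1))
    outcome_names <- setdiff(names(outcomes)[is_binary], c("subject_id", candidates))
  }
  candidates <- intersect(candidates, names(outcomes))
  class_f <- stats::relevel(factor(assignment, levels = seq_len(K), labels = class_labels),
                            ref = class_labels[reference])
  screened <- if (force_adjust) {
    stats::setNames(rep(list(candidates), length(outcome_names)), outcome_names)
  } else {
    screen_confounders(outcomes, outcome_names, candidates)
  }
  rows <- lapply(outcome_names, function(oc) {
    y <- outcomes[[oc]]
    n_events <- sum(y)
    low_info <- n_events < min_events
    crude_fit <- fit_logistic(class_design(class_f), y)
    terms <- paste0("class_", setdiff(class_labels, class_labels[reference]))
    crude <- odds_ratios(crude_fit, terms, outcome = oc, adjusted = FALSE)
    covs <- screened[[oc]]
    adj <- if (length(covs) > 0) {
      adj_fit <- fit_logistic(class_design(class_f, outcomes[covs]), y)
      odds_ratios(adj_fit, terms, outcome = oc, adjusted = TRUE, covariates = covs)
    } else {
      # nothing passed the screen: the adjusted model is the crude model
      transform(crude, adjusted = TRUE)
    }
    out <- rbind(crude, adj)
    out$n_events <- n_events
    out$low_information <- low_info
    out
  })
  res <- do.call(rbind, rows)
  res$contrast <- paste0(sub("^class_", "", res$contrast), " vs ", class_labels[reference])
  rownames(res) <- NULL
  res
}
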