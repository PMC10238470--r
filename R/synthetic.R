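#' Configuration of a synthetic longitudinal weight cohort
#'
#' Describes the generative model the classification method assumes: `K`
#' latent weight classes whose mean curves are a class baseline plus a shared
#' monotone gain curve, subject-level Gaussian random intercepts, and
#' independent Gaussian measurement noise at each monthly visit.
#'
#' The defaults emulate a pregnancy cohort of 877 women weighed once a month
#' for nine months: three latent classes with proportions 38/36/26%, a gain
#' curve rising from 0 to 8.9 kg and plateauing after month 7, and baselines
#' placed so that the classes' mean observed weights center near 63, 71.5 and
#' 79.5 kg. The within-class dispersion defaults (random intercept SD 2 kg,
#' residual SD 1 kg) are plausible values for serial adult weight
#' measurements, not cohort-reported quantities.
#'
#' @param n_subjects number of subjects.
#' @param class_proportions simplex weights, one per class; must sum to 1.
#' @param class_baselines strictly increasing baseline weights (kg), one per
#'   class.
#' @param gain_curve kg gained relative to the first month, one value per
#'   month (first entry 0).
#' @param random_intercept_sd SD (kg) of the subject-level intercept.
#' @param residual_sd SD (kg) of the visit-level measurement noise.
#' @param months ordered integer measurement occasions.
#' @param monotone require the gain curve to be non-decreasing.
#' @param class_counts optional explicit integer class sizes overriding the
#'   deterministic largest-remainder allocation.
#' @param multinomial draw class memberships multinomially instead of with
#'   exact deterministic counts.
#' @param dropout_rate MCAR probability of dropping any single visit
#'   (default 0 = balanced panel); every subject retains at least one visit.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return an object of class `cohort_config`.
#' @seealso [generate_cohort()], [class_mean_curve()]
#' @export
cohort_config <- function(n_subjects = 877,
                          class_proportions = c(0.38, 0.36, 0.26),
                          class_baselines = NULL,
                          gain_curve = c(0, 1.6, 3.1, 4.7, 6.3, 7.9, 8.7, 8.8, 8.9),
                          random_intercept_sd = 2,
                          residual_sd = 1,
                          months = 1:9,
                          monotone = TRUE,
                          class_counts = NULL,
                          multinomial = FALSE,
                          dropout_rate = 0,
                          seed = NULL) {
  k <- length(class_proportions)
  if (abs(sum(class_proportions) - 1) > 1e-9) stop("class_proportions must sum to 1")
  if (is.null(class_baselines)) {
    if (k != 3) stop("class_baselines must be given explicitly when n_classes != 3")
    # anchor the three classes' mean observed weights at 63 / 71.5 / 79.5 kg
    class_baselines <- c(63, 71.5, 79.5) - mean(gain_curve)
  }
  if (length(class_baselines) != k) stop("class_baselines and class_proportions disagree on the number of classes")
  if (any(class_proportions < 0)) stop("class_proportions must be non-negative")
  if (k > 1 && any(diff(class_baselines) <= 0)) stop("class_baselines must be strictly increasing")
  if (length(gain_curve) != length(months)) stop("gain_curve must have one entry per month")
  if (monotone && any(diff(gain_curve) < 0)) stop("gain_curve must be non-decreasing")
  if (random_intercept_sd < 0 || residual_sd < 0) stop("standard deviations must be >= 0")
  if (is.unsorted(months, strictly = TRUE)) stop("months must be strictly increasing")
  if (n_subjects < k) stop("n_subjects must be at least the number of classes")
  if (!is.null(class_counts)) {
    class_counts <- as.integer(class_counts)
    if (length(class_counts) != k || sum(class_counts) != n_subjects)
      stop("class_counts must have one entry per class and sum to n_subjects")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_classes = as.integer(k),
    class_proportions = class_proportions,
    class_baselines = class_baselines,
    gain_curve = gain_curve,
    random_intercept_sd = random_intercept_sd,
    residual_sd = residual_sd,
    months = as.integer(months),
    monotone = monotone,
    class_counts = class_counts,
    multinomial = multinomial,
    dropout_rate = dropout_rate,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "cohort_config")
}

#' Noise-free mean weight of a latent class at a given month
#'
#' @param cfg a [cohort_config()].
#' @param k class index (1-based).
#' @param month a month present in `cfg$months`.
#' @return mean weight in kg: `class_baselines[k] + gain_curve[month]`.
#' @export
class_mean_curve <- function(cfg, k, month) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (any(k < 1L) || any(k > cfg$n_classes)) stop("unknown class index")
  idx <- match(month, cfg$months)
  if (anyNA(idx)) stop("month not in the configured measurement grid")
  cfg$class_baselines[k] + cfg$gain_curve[idx]
}

#' Generate a synthetic longitudinal cohort with known class labels
#'
#' Draws `y_it = mu_k(t) + b_i + e_it` with `b_i ~ N(0, random_intercept_sd^2)`
#' and `e_it ~ N(0, residual_sd^2)`. By default class sizes are allocated
#' deterministically by the largest-remainder rule, so ground-truth counts are
#' exact and recovery tests have no allocation noise.
#'
#' @param cfg a [cohort_config()].
#' @return a list with `data` (data.frame: `subject_id`, `month`, `weight_kg`)
#'   and `labels` (integer class per subject, named by subject id).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_subjects
  ids <- sprintf("S%05d", seq_len(n))
  if (cfg$multinomial) {
    labels <- sample.int(cfg$n_classes, n, replace = TRUE, prob = cfg$class_proportions)
  } else {
    counts <- cfg$class_counts %||% largest_remainder(n, cfg$class_proportions)
    labels <- rep.int(seq_len(cfg$n_classes), counts)
  }
  names(labels) <- ids
  b <- rnorm(n, 0, cfg$random_intercept_sd)
  m <- length(cfg$months)
  mu <- outer(cfg$class_baselines[labels] + b, cfg$gain_curve, "+") # n x m
  eps <- matrix(rnorm(n * m, 0, cfg$residual_sd), n, m)
  data <- data.frame(
    subject_id = rep(ids, each = m),
    month = rep(cfg$months, times = n),
    weight_kg = as.vector(t(mu + eps)),
    stringsAsFactors = FALSE
  )
  if (cfg$dropout_rate > 0) {
    keep <- runif(nrow(data)) >= cfg$dropout_rate
    # never lose a subject entirely: retain its first visit if all were dropped
    lost <- !(ids %in% unique(data$subject_id[keep]))
    if (any(lost)) keep[match(ids[lost], data$subject_id)] <- TRUE
    data <- data[keep, , drop = FALSE]
    rownames(data) <- NULL
  }
  list(data = data, labels = labels)
}

#' Simulate subject-level covariates
#'
#' Maternal age ~ Normal(29, 5) truncated to 18–40 years, gestational age at
#' delivery ~ Normal(38, 1) weeks, gravidity ~ 1 + Poisson(1).
#'
#' @param subject_ids character vector of subject ids.
#' @param seed optional integer seed.
#' @return data.frame with `subject_id`, `age`, `gestational_age`, `gravidity`.
#' @export
generate_covariates <- function(subject_ids, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(subject_ids)
  age <- rnorm(n, 29, 5)
  bad <- age < 18 | age > 40
  while (any(bad)) {
    age[bad] <- rnorm(sum(bad), 29, 5)
    bad <- age < 18 | age > 40
  }
  data.frame(
    subject_id = subject_ids,
    age = age,
    gestational_age = rnorm(n, 38, 1),
    gravidity = 1 + rpois(n, 1),
    stringsAsFactors = FALSE
  )
}

#' Configuration of outcome generation
#'
#' Each elementary binary outcome is drawn per subject as
#' `Bernoulli(plogis(qlogis(prevalence) + class_log_odds[class] + covariate
#' terms))`, where the reference class (log-odds 0) is the middle-weight
#' class. Composite outcomes are the logical OR of their components. Default
#' prevalences and class effects reflect a cohort in which the low-weight
#' trajectory carries moderately elevated neonatal risk (e.g. odds ratio 1.85
#' for composite-neonatal-event components versus the medium class is
#' attained approximately through its components).
#'
#' @param outcome_names elementary outcome names.
#' @param baseline_prevalence named prevalences (reference-class scale), one
#'   per outcome, each strictly inside (0, 1).
#' @param class_log_odds matrix `n_classes x n_outcomes` of additive log-odds
#'   versus the reference class; the reference row must be 0.
#' @param reference_class class index whose log-odds are all zero.
#' @param covariate_effects named log-odds per unit of `age`,
#'   `gestational_age`, `gravidity` (applied to covariates centered at
#'   29 / 38 / 2).
#' @param composites named list mapping composite outcome names to component
#'   outcome names.
#' @param seed optional integer seed used by [generate_outcomes()].
#' @return an object of class `outcome_config`.
#' @export
outcome_config <- function(outcome_names = c("icterus", "abnormality", "nicu_admission",
                                             "preterm_delivery", "preeclampsia", "gdm"),
                           baseline_prevalence = c(icterus = 0.288, abnormality = 0.033,
                                                   nicu_admission = 0.169,
                                                   preterm_delivery = 0.137,
                                                   preeclampsia = 0.157, gdm = 0.061),
                           class_log_odds = NULL,
                           reference_class = 2L,
                           covariate_effects = c(age = 0, gestational_age = 0, gravidity = 0),
                           composites = list(
                             composite_maternal = c("preterm_delivery", "preeclampsia", "gdm"),
                             composite_neonatal = c("icterus", "abnormality", "nicu_admission")
                           ),
                           seed = NULL) {
  if (is.null(class_log_odds)) {
    # low and high class effects vs the medium reference, per outcome
    class_log_odds <- rbind(
      log(c(icterus = 1.69, abnormality = 1.50, nicu_admission = 1.77,
            preterm_delivery = 1.82, preeclampsia = 0.93, gdm = 0.96)),
      0,
      log(c(icterus = 1.44, abnormality = 2.56, nicu_admission = 1.09,
            preterm_delivery = 1.11, preeclampsia = 1.19, gdm = 1.21))
    )
    colnames(class_log_odds) <- outcome_names
  }
  baseline_prevalence <- baseline_prevalence[outcome_names]
  if (anyNA(baseline_prevalence)) stop("baseline_prevalence must name every outcome")
  if (any(baseline_prevalence <= 0) || any(baseline_prevalence >= 1))
    stop("baseline_prevalence must lie strictly inside (0, 1)")
  if (ncol(class_log_odds) != length(outcome_names))
    stop("class_log_odds needs one column per outcome")
  if (reference_class < 1 || reference_class > nrow(class_log_odds))
    stop("reference_class out of range")
  if (any(class_log_odds[reference_class, ] != 0))
    stop("the reference class must have log-odds 0 for every outcome")
  for (comp in composites) {
    if (!all(comp %in% outcome_names)) stop("composite components must be elementary outcomes")
  }
  structure(list(
    outcome_names = outcome_names,
    baseline_prevalence = baseline_prevalence,
    class_log_odds = class_log_odds,
    reference_class = as.integer(reference_class),
    covariate_effects = covariate_effects,
    composites = composites,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "outcome_config")
}

# covariate centering used when covariate_effects are non-zero, so that
# baseline_prevalence keeps its reference-class interpretation
.covariate_centers <- c(age = 29, gestational_age = 38, gravidity = 2)

#' Generate binary outcomes linked to latent class membership
#'
#' @param labels integer class per subject, named by subject id.
#' @param covariates data.frame from [generate_covariates()] (or equivalent)
#'   covering every labelled subject.
#' @param ocfg an [outcome_config()].
#' @return data.frame with `subject_id`, one 0/1 column per elementary and
#'   composite outcome, and the covariate columns.
#' @export
generate_outcomes <- function(labels, covariates, ocfg = outcome_config()) {
  stopifnot(inherits(ocfg, "outcome_config"))
  ids <- names(labels)
  row <- match(ids, covariates$subject_id)
  if (anyNA(row)) stop("missing covariates for subjects: ",
                       paste(utils::head(ids[is.na(row)], 5), collapse = ", "))
  covariates <- covariates[row, , drop = FALSE]
  if (max(labels) > nrow(ocfg$class_log_odds)) stop("labels reference a class absent from class_log_odds")
  if (!is.null(ocfg$seed)) set.seed(ocfg$seed)
  cov_term <- rep(0, length(ids))
  for (v in names(ocfg$covariate_effects)) {
    if (ocfg$covariate_effects[[v]] != 0) {
      cov_term <- cov_term + ocfg$covariate_effects[[v]] * (covariates[[v]] - .covariate_centers[[v]])
    }
  }
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (j in ocfg$outcome_names) {
    eta <- qlogis(ocfg$baseline_prevalence[[j]]) + ocfg$class_log_odds[labels, j] + cov_term
    out[[j]] <- rbinom(length(ids), 1, plogis(eta))
  }
  for (comp in names(ocfg$composites)) {
    out[[comp]] <- as.integer(rowSums(out[ocfg$composites[[comp]]]) > 0)
  }
  cbind(out, covariates[setdiff(names(covariates), "subject_id")])
}
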