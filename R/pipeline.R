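#' Read and validate a long-format weight table
#'
#' Expects columns `subject_id`, `month`, `weight_kg`. Months must be
#' integers; duplicate (subject, month) pairs and non-positive or implausible
#' (>= 250 kg) weights are rejected with the offending row numbers.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_long_csv <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "month", "weight_kg")
  if (!all(need %in% names(data)))
    stop("long CSV must have columns ", paste(need, collapse = ", "),
         "; found: ", paste(names(data), collapse = ", "))
  data$subject_id <- as.character(data$subject_id)
  if (!is.numeric(data$month) || any(data$month != round(data$month)))
    stop("month must be integer-valued")
  data$month <- as.integer(data$month)
  if (!is.numeric(data$weight_kg)) stop("weight_kg must be numeric")
  dup <- duplicated(data[c("subject_id", "month")])
  if (any(dup))
    stop("duplicate (subject, month) observations at rows: ",
         paste(utils::head(which(dup), 10), collapse = ", "))
  bad <- which(!is.finite(data$weight_kg) | data$weight_kg <= 0 | data$weight_kg >= 250)
  if (length(bad))
    stop("weights must be positive and below 250 kg; offending rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  data
}

#' Write a long-format weight table as CSV
#'
#' @param data data.frame with `subject_id`, `month`, `weight_kg`.
#' @param path output path.
#' @export
write_long_csv <- function(data, path) {
  validate_long(data)
  utils::write.csv(data[c("subject_id", "month", "weight_kg")], path, row.names = FALSE)
  invisible(path)
}

#' Read a per-subject outcome/covariate table
#'
#' @param path CSV with `subject_id`, 0/1 outcome columns and numeric
#'   covariates.
#' @return validated data.frame.
#' @export
read_outcomes_csv <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(data)) stop("outcomes CSV must have a subject_id column")
  data$subject_id <- as.character(data$subject_id)
  if (anyDuplicated(data$subject_id)) stop("duplicate subject_id in outcomes CSV")
  data
}

#' Table-style descriptive statistics with normality checks
#'
#' Continuous variables (each monthly weight, plus any covariates present in
#' the outcome table) are summarized as mean, SD, median and quartiles
#' (linear-interpolation quantiles); binary variables as count and percent.
#' Each monthly weight additionally gets Shapiro–Wilk and Lilliefors
#' (Kolmogorov–Smirnov) normality statistics.
#'
#' @param data long-format weight data.
#' @param outcomes optional outcome/covariate table.
#' @return list of class `descriptive_table` with data.frames `continuous`,
#'   `binary`, `normality`.
#' @export
summarize_cohort <- function(data, outcomes = NULL) {
  validate_long(data)
  cont_var <- function(name, x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(variable = name, n = length(x), mean = mean(x), sd = stats::sd(x),
               q1 = q[1], median = q[2], q3 = q[3], stringsAsFactors = FALSE)
  }
  months <- sort(unique(data$month))
  cont <- lapply(months, function(m)
    cont_var(sprintf("weight_month_%d", m), data$weight_kg[data$month == m]))
  norm <- lapply(months, function(m) {
    x <- data$weight_kg[data$month == m]
    sw <- if (length(x) >= 3 && length(x) <= 5000) stats::shapiro.test(x) else NULL
    ks <- if (length(x) >= 5) nortest::lillie.test(x) else NULL
    data.frame(variable = sprintf("weight_month_%d", m),
               shapiro_W = if (is.null(sw)) NA_real_ else unname(sw$statistic),
               shapiro_p = if (is.null(sw)) NA_real_ else sw$p.value,
               ks_D = if (is.null(ks)) NA_real_ else unname(ks$statistic),
               ks_p = if (is.null(ks)) NA_real_ else ks$p.value,
               stringsAsFactors = FALSE)
  })
  bin <- list()
  if (!is.null(outcomes)) {
    for (v in setdiff(names(outcomes), "subject_id")) {
      x <- outcomes[[v]]
      if (is.numeric(x) && all(x %in% c(0, 1))) {
        bin[[v]] <- data.frame(variable = v, count = sum(x),
                               percent = 100 * mean(x), stringsAsFactors = FALSE)
      } else if (is.numeric(x)) {
        cont[[length(cont) + 1]] <- cont_var(v, x)
      }
    }
  }
  structure(list(
    continuous = do.call(rbind, cont),
    binary = if (length(bin)) do.call(rbind, bin) else
      data.frame(variable = character(), count = integer(), percent = numeric()),
    normality = do.call(rbind, norm)
  ), class = "descriptive_table")
}

#' Quantile grouping on baseline weight
#'
#' Splits subjects into K near-equal groups ranked by their earliest observed
#' weight (group 1 = lightest). This is the "initial grouping" used for the
#' concordance cross-tabulation against the model-based classes; it differs
#' from the EM initialization, which ranks by the mean over all months.
#'
#' @param data long-format weight data.
#' @param K number of groups.
#' @return named integer group per subject.
#' @export
baseline_grouping <- function(data, K) {
  validate_long(data)
  ids <- canonical_ids(data)
  first_month <- tapply(data$month, factor(as.character(data$subject_id), levels = ids), min)
  key <- paste(as.character(data$subject_id), data$month)
  baseline <- data$weight_kg[match(paste(ids, first_month), key)]
  rank_order <- order(baseline, ids, method = "radix")
  grouping <- integer(length(ids))
  grouping[rank_order] <- rep.int(seq_len(K), split_sizes(length(ids), K))
  names(grouping) <- ids
  grouping
}

#' Pipeline run configuration
#'
#' @param long_csv,outcomes_csv input paths; both `NULL` means a synthetic
#'   cohort is simulated from `cohort`, `outcome`.
#' @param out_dir output directory (created if needed).
#' @param k_range candidate class counts.
#' @param control an [smm_control()].
#' @param parsimony_margin relative BIC margin for [select_k()].
#' @param cohort a [cohort_config()] for the simulation path.
#' @param outcome an [outcome_config()] for the simulation path.
#' @param force_adjust always adjust for all screened covariate candidates.
#' @param seed run seed (simulation and figure subsampling).
#' @param figures attempt figure generation (requires ggplot2).
#' @return list of class `run_config`.
#' @export
run_config <- function(long_csv = NULL, outcomes_csv = NULL, out_dir = "trajsmm_out",
                       k_range = 2:5, control = smm_control(),
                       parsimony_margin = 0.035,
                       cohort = cohort_config(), outcome = outcome_config(),
                       force_adjust = FALSE, seed = 1L, figures = TRUE) {
  if (any(k_range < 1) || any(k_range > 10)) stop("k_range must lie in 1..10")
  structure(list(long_csv = long_csv, outcomes_csv = outcomes_csv, out_dir = out_dir,
                 k_range = k_range, control = control,
                 parsimony_margin = parsimony_margin,
                 cohort = cohort, outcome = outcome,
                 force_adjust = force_adjust, seed = as.integer(seed),
                 figures = isTRUE(figures)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the arguments of [run_config()]; the
#' `control`, `cohort` and `outcome` keys take the corresponding constructor
#' arguments as nested mappings.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("long_csv", "outcomes_csv", "out_dir", "k_range",
                                  "parsimony_margin", "force_adjust", "seed", "figures"))]
  if (!is.null(y$k_range) && is.character(y$k_range)) {
    parts <- as.integer(strsplit(y$k_range, ":")[[1]])
    args$k_range <- seq(parts[1], parts[2])
  }
  if (!is.null(y$control)) args$control <- do.call(smm_control, y$control)
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_config, y$cohort)
  if (!is.null(y$outcome)) args$outcome <- do.call(outcome_config, y$outcome)
  do.call(run_config, args)
}

write_fit_json <- function(fit, path) {
  summary <- list(
    K = fit$K,
    total_ll = fit$total_ll,
    bic = fit$bic,
    p_effective = fit$p_effective,
    n_subjects = fit$n_subjects,
    n_obs = fit$n_obs,
    n_iterations = fit$n_iterations,
    converged = fit$converged,
    class_labels = fit$class_labels,
    class_sizes = as.integer(table(factor(fit$assignment, levels = seq_len(fit$K)))),
    models = lapply(fit$models, function(m)
      list(coefficients = m$coefficients, lambda = m$lambda, edf = m$edf,
           sigma2 = m$sigma2, sigma2_b = m$sigma2_b, sigma2_w = m$sigma2_w,
           knots = m$basis$knots, fitted_curve = m$fitted_curve))
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full trajectory-classification pipeline
#'
#' Simulates or reads the cohort, computes descriptives, selects the class
#' count by BIC with parsimony, relabels the chosen fit by trajectory level,
#' cross-tabulates a baseline-weight grouping against the model classes,
#' estimates crude and adjusted odds ratios per outcome, and writes every
#' table as CSV plus a JSON manifest, a markdown report and (best-effort)
#' spaghetti / predicted-trajectory figures into `out_dir`.
#'
#' @param config a [run_config()] or path to a YAML file.
#' @return invisibly, a list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    message("[trajsmm] stage: ", name)
    st <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    res
  }

  labels <- NULL
  if (is.null(config$long_csv)) {
    sim <- stage("simulate", {
      cohort_cfg <- config$cohort
      cohort_cfg$seed <- cohort_cfg$seed %||% config$seed
      gen <- generate_cohort(cohort_cfg)
      cov <- generate_covariates(names(gen$labels))
      ocfg <- config$outcome
      out <- generate_outcomes(gen$labels, cov, ocfg)
      list(data = gen$data, labels = gen$labels, outcomes = out)
    })
    data <- sim$data
    outcomes <- sim$outcomes
    labels <- sim$labels
    write_long_csv(data, file.path(config$out_dir, "long.csv"))
    utils::write.csv(outcomes, file.path(config$out_dir, "outcomes.csv"), row.names = FALSE)
    utils::write.csv(data.frame(subject_id = names(labels), class = as.integer(labels)),
                     file.path(config$out_dir, "true_labels.csv"), row.names = FALSE)
  } else {
    data <- stage("read", read_long_csv(config$long_csv))
    outcomes <- if (!is.null(config$outcomes_csv)) read_outcomes_csv(config$outcomes_csv) else NULL
  }

  desc <- stage("summarize", summarize_cohort(data, outcomes))
  utils::write.csv(desc$continuous, file.path(config$out_dir, "descriptives_continuous.csv"),
                   row.names = FALSE)
  utils::write.csv(desc$binary, file.path(config$out_dir, "descriptives_binary.csv"),
                   row.names = FALSE)
  utils::write.csv(desc$normality, file.path(config$out_dir, "normality.csv"),
                   row.names = FALSE)

  selection <- stage("select_k",
                     select_k(data, config$k_range, config$control, config$parsimony_margin))
  utils::write.csv(selection$table, file.path(config$out_dir, "selection.csv"),
                   row.names = FALSE)
  fit <- selection$best_fit
  lbl <- fit$class_labels %||% as.character(seq_len(fit$K))
  assignments <- data.frame(subject_id = names(fit$assignment),
                            class_index = as.integer(fit$assignment),
                            class_label = lbl[fit$assignment],
                            per_subject_ll = unname(fit$per_subject_ll),
                            stringsAsFactors = FALSE)
  utils::write.csv(assignments, file.path(config$out_dir, "assignments.csv"), row.names = FALSE)
  curves <- data.frame(month = fit$models[[1]]$basis$months)
  for (k in seq_len(fit$K)) curves[[paste0("fitted_", lbl[k])]] <- fit$models[[k]]$fitted_curve
  utils::write.csv(curves, file.path(config$out_dir, "curves.csv"), row.names = FALSE)
  write_fit_json(fit, file.path(config$out_dir, "fit.json"))

  xt <- stage("crosstab", {
    initial <- baseline_grouping(data, fit$K)
    crosstab(initial, fit$assignment, K = fit$K)
  })
  xt_df <- as.data.frame.matrix(xt$table)
  xt_df <- cbind(initial_group = rownames(xt_df), xt_df)
  utils::write.csv(xt_df, file.path(config$out_dir, "crosstab.csv"), row.names = FALSE)

  or_table <- NULL
  if (!is.null(outcomes)) {
    or_table <- stage("association",
                      run_association(fit$assignment, outcomes,
                                      force_adjust = config$force_adjust))
    utils::write.csv(or_table, file.path(config$out_dir, "odds_ratios.csv"), row.names = FALSE)
  }

  figures <- character(0)
  if (config$figures) {
    figures <- tryCatch(stage("figures", plot_pipeline_figures(data, fit, config)),
                        error = function(e) {
                          message("[trajsmm] figure generation skipped: ", conditionMessage(e))
                          character(0)
                        })
  }

  manifest <- list(
    created = format(t0, "%Y-%m-%d %H:%M:%S"),
    package_version = as.character(utils::packageVersion("trajsmm")),
    seed = config$seed,
    k_range = config$k_range,
    selected_k = selection$selected_k,
    bic_optimal_k = selection$bic_optimal_k,
    parsimony_margin = config$parsimony_margin,
    concordance = xt$concordance,
    timings_sec = timings,
    artifacts = c("descriptives_continuous.csv", "descriptives_binary.csv",
                  "normality.csv", "selection.csv", "assignments.csv", "curves.csv",
                  "fit.json", "crosstab.csv",
                  if (!is.null(or_table)) "odds_ratios.csv",
                  if (is.null(config$long_csv)) c("long.csv", "outcomes.csv", "true_labels.csv"),
                  basename(figures), "report.md", "manifest.json")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_report(file.path(config$out_dir, "report.md"), desc, selection, xt, or_table)
  message(sprintf("[trajsmm] done in %.1f s; outputs in %s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")), config$out_dir))
  invisible(list(data = data, outcomes = outcomes, labels = labels,
                 descriptives = desc, selection = selection, fit = fit,
                 crosstab = xt, or_table = or_table, manifest = manifest))
}

md_table <- function(df, digits = 2) {
  fmt <- function(x) if (is.numeric(x)) formatC(x, digits = digits, format = "f") else as.character(x)
  body <- as.data.frame(lapply(df, fmt), stringsAsFactors = FALSE, check.names = FALSE)
  lines <- c(paste0("| ", paste(names(df), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
             apply(body, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
  lines
}

write_report <- function(path, desc, selection, xt, or_table) {
  lines <- c(
    "# Trajectory classification report", "",
    "## Descriptive statistics (continuous)", "", md_table(desc$continuous), "",
    "## Descriptive statistics (binary)", "", md_table(desc$binary), "",
    "## Normality of monthly weights", "", md_table(desc$normality, digits = 4), "",
    "## Class-count selection", "", md_table(selection$table), "",
    sprintf("Selected K = %d (BIC optimum at K = %d).",
            selection$selected_k, selection$bic_optimal_k),
    if (!is.null(selection$parsimony_note)) selection$parsimony_note, "",
    "## Baseline grouping vs model classes", "",
    md_table(cbind(initial_group = rownames(as.data.frame.matrix(xt$table)),
                   as.data.frame.matrix(xt$table)), digits = 0), "",
    sprintf("Concordance: %.1f%%.", xt$concordance), ""
  )
  if (!is.null(or_table)) {
    lines <- c(lines, "## Odds ratios by trajectory class", "", md_table(or_table, digits = 3), "")
  }
  writeLines(unlist(lines), path)
  invisible(path)
}

# Spaghetti plot of a 50% subsample and the fitted class curves (best-effort;
# requires ggplot2).
plot_pipeline_figures <- function(data, fit, config) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is not installed")
  set.seed(config$seed)
  ids <- canonical_ids(data)
  half <- sample(ids, ceiling(length(ids) / 2))
  sub <- data[data$subject_id %in% half, ]
  p1 <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$month, y = .data$weight_kg,
                                          group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.2) +
    ggplot2::labs(x = "Month", y = "Weight (kg)",
                  title = "Observed trajectories (50% subsample)") +
    ggplot2::theme_minimal()
  lbl <- fit$class_labels %||% as.character(seq_len(fit$K))
  curve_df <- do.call(rbind, lapply(seq_len(fit$K), function(k)
    data.frame(month = fit$models[[k]]$basis$months,
               weight_kg = fit$models[[k]]$fitted_curve,
               class = lbl[k])))
  p2 <- ggplot2::ggplot(curve_df, ggplot2::aes(x = .data$month, y = .data$weight_kg,
                                               colour = .data$class)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "Month", y = "Weight (kg)",
                  title = "Predicted class trajectories") +
    ggplot2::theme_minimal()
  f1 <- file.path(config$out_dir, "spaghetti.png")
  f2 <- file.path(config$out_dir, "predicted_trajectories.png")
  ggplot2::ggsave(f1, p1, width = 7, height = 5, dpi = 150)
  ggplot2::ggsave(f2, p2, width = 7, height = 5, dpi = 150)
  c(f1, f2)
}
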