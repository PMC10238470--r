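make_long <- function(weights_by_subject, months = 1:9) {
  do.call(rbind, lapply(names(weights_by_subject), function(id)
    data.frame(subject_id = id, month = months,
               weight_kg = weights_by_subject[[id]], stringsAsFactors = FALSE)))
}

test_that("initialization splits the mean-weight ranking into contiguous groups", {
  w <- stats::setNames(lapply(c(61, 62, 63, 71, 72, 73), function(m) rep(m, 9)),
                       sprintf("A%d", 1:6))
  data <- make_long(w)
  a <- initialize_classes(data, 2)
  expect_identical(unname(a[sprintf("A%d", 1:6)]), c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_identical(unique(unname(initialize_classes(data, 1))), 1L)
  w7 <- stats::setNames(lapply(seq(60, 72, by = 2), function(m) rep(m, 9)),
                        sprintf("B%d", 1:7))
  a7 <- initialize_classes(make_long(w7), 3)
  expect_identical(as.integer(table(a7)), c(3L, 2L, 2L))
  expect_error(initialize_classes(data, 10), "exceeds")
})

test_that("the M step refits each class exactly as a standalone P-spline", {
  g <- generate_cohort(cohort_config(n_subjects = 60, seed = 8))
  ctrl <- smm_control(random_intercept = FALSE)
  a <- initialize_classes(g$data, 3)
  models <- m_step(g$data, a, ctrl)
  expect_length(models, 3)
  basis <- build_basis(1:9, ctrl$n_basis, ctrl$degree, ctrl$penalty_order)
  for (k in 1:3) {
    rows <- g$data[a[g$data$subject_id] == k, ]
    lam <- select_lambda(rows$month, rows$weight_kg, basis, ctrl$lambda_grid)
    standalone <- fit_pspline(rows$month, rows$weight_kg, basis, lam)
    expect_equal(models[[k]]$coefficients, standalone$coefficients, tolerance = 1e-10)
    expect_equal(models[[k]]$lambda, standalone$lambda)
  }
})

test_that("a class of identical linear trajectories is fitted exactly with floored variance", {
  w <- stats::setNames(rep(list(60 + 1.2 * (1:9)), 5), sprintf("C%d", 1:5))
  data <- make_long(w)
  a <- stats::setNames(rep(1L, 5), names(w))
  model <- m_step(data, a, smm_control(), K = 1)[[1]]
  expect_equal(model$fitted_curve, 60 + 1.2 * (1:9), tolerance = 1e-6)
  expect_equal(model$sigma2, smm_control()$variance_floor)
})

test_that("the M step raises a degenerate-class condition for empty classes", {
  g <- generate_cohort(cohort_config(n_subjects = 30, seed = 9))
  a <- initialize_classes(g$data, 2)
  err <- tryCatch(m_step(g$data, a, smm_control(), K = 3),
                  trajsmm_degenerate_class = function(e) e)
  expect_s3_class(err, "trajsmm_degenerate_class")
  expect_equal(err$class_index, 3L)
})

test_that("the E step agrees with an exhaustive per-subject likelihood loop", {
  g <- generate_cohort(cohort_config(n_subjects = 40, seed = 10))
  for (ri in c(TRUE, FALSE)) {
    ctrl <- smm_control(random_intercept = ri)
    models <- m_step(g$data, initialize_classes(g$data, 3), ctrl)
    es <- e_step(g$data, models)
    ids <- sort(unique(g$data$subject_id))
    for (id in ids) {
      rows <- g$data[g$data$subject_id == id, ]
      lls <- vapply(models, function(m)
        subject_loglik(rows$month, rows$weight_kg, m), numeric(1))
      expect_equal(unname(es$assignment[id]), which.max(lls))
      expect_equal(unname(es$per_subject_ll[id]), max(lls), tolerance = 1e-10)
    }
  }
})

test_that("exact likelihood ties are broken toward the lowest class index", {
  w <- stats::setNames(rep(list(rep(70, 9)), 4), sprintf("D%d", 1:4))
  data <- make_long(w)
  basis <- build_basis(1:9, 6)
  m <- fit_pspline(rep(1:9, 4), data$weight_kg, basis, 1)
  es <- e_step(data, list(m, m))
  expect_true(all(es$assignment == 1L))
})

test_that("hard EM recovers noise-free classes exactly and deterministically", {
  g <- generate_cohort(noise_free_cfg(3, 90))
  f1 <- fit_smm(g$data, 3)
  f2 <- fit_smm(g$data, 3)
  expect_equal(adjusted_rand_index(f1$assignment[names(g$labels)], g$labels), 1)
  expect_identical(f1$assignment, f2$assignment)  # fully deterministic
  expect_identical(f1$total_ll, f2$total_ll)
  expect_true(f1$converged)
  # K = 1 degenerates to a single smoother over everyone
  f_one <- fit_smm(g$data, 1)
  es <- e_step(g$data, f_one$models)
  expect_equal(f_one$total_ll, sum(es$per_subject_ll), tolerance = 1e-10)
})

test_that("total log-likelihood equals the sum of per-subject maxima", {
  g <- generate_cohort(cohort_config(n_subjects = 120, seed = 14))
  f <- fit_smm(g$data, 3)
  expect_equal(f$total_ll, sum(f$per_subject_ll), tolerance = 1e-10)
  ll <- trajsmm:::loglik_matrix(g$data, f$models)
  expect_equal(unname(f$per_subject_ll), unname(apply(ll, 1, max)), tolerance = 1e-10)
  # every subject assigned to exactly one class, all classes in 1..K
  expect_true(all(f$assignment %in% 1:3))
  expect_length(f$assignment, 120)
})

test_that("reassignment under fixed models never lowers the classification objective", {
  g <- generate_cohort(cohort_config(n_subjects = 100, seed = 15))
  models <- m_step(g$data, initialize_classes(g$data, 3), smm_control())
  es <- e_step(g$data, models)
  n <- nrow(es$ll_matrix)
  best <- sum(es$per_subject_ll)
  set.seed(16)
  for (rep in 1:20) {
    arbitrary <- sample.int(3, n, replace = TRUE)
    expect_lte(sum(es$ll_matrix[cbind(seq_len(n), arbitrary)]), best + 1e-10)
  }
})

test_that("BIC follows its closed form and grows with model size", {
  expect_equal(compute_bic(-100, 5, 100), 200 + 5 * log(100), tolerance = 1e-12)
  expect_equal(compute_bic(-100, 5, 100), 223.0259, tolerance = 1e-4)
  expect_gt(compute_bic(-100, 8, 100), compute_bic(-100, 5, 100))
  expect_error(compute_bic(-100, 5, 0), "positive")
  g <- generate_cohort(cohort_config(n_subjects = 80, seed = 17))
  f <- fit_smm(g$data, 2)
  p <- sum(vapply(f$models, `[[`, numeric(1), "edf")) + 2 * 2  # edf + 2 variances/class
  expect_equal(f$bic, compute_bic(f$total_ll, p, nrow(g$data)), tolerance = 1e-10)
})

test_that("relabeling orders classes by trajectory level without touching the fit", {
  g <- generate_cohort(cohort_config(n_subjects = 90, seed = 18))
  f <- fit_smm(g$data, 3)
  # scramble the class order, then relabel back
  perm <- c(2L, 3L, 1L)
  scrambled <- f
  scrambled$models <- f$models[perm]
  inv <- order(perm)
  scrambled$assignment[] <- inv[f$assignment]
  r <- relabel(scrambled)
  means <- vapply(r$models, function(m) mean(m$fitted_curve), numeric(1))
  expect_true(all(diff(means) > 0))
  expect_identical(r$assignment, f$assignment)
  expect_identical(r$class_labels, c("low", "medium", "high"))
  expect_identical(r$bic, f$bic)
  expect_identical(r$total_ll, f$total_ll)
  # idempotence
  expect_identical(relabel(r)$assignment, r$assignment)
})

test_that("cross-tabulation conserves subjects and measures concordance", {
  a <- stats::setNames(rep(1:3, each = 10), sprintf("S%02d", 1:30))
  xt <- crosstab(a, a)
  expect_equal(xt$concordance, 100)
  expect_equal(sum(xt$table), 30)
  expect_true(all(xt$table[upper.tri(xt$table) | lower.tri(xt$table)] == 0))
  shifted <- stats::setNames((a %% 3) + 1L, names(a))
  expect_equal(crosstab(a, shifted)$concordance, 0)
  expect_equal(sum(crosstab(a, shifted)$table), 30)
  b <- a
  names(b)[1] <- "X99"
  expect_error(crosstab(a, b), "different subjects")
})

test_that("class-count selection tabulates every K and applies the parsimony margin", {
  g <- generate_cohort(noise_free_cfg(3, 90, seed = 31))
  sel <- select_k(g$data, 2:4)
  expect_equal(nrow(sel$table), 3)
  expect_equal(sel$selected_k, 3)
  sel2 <- select_k(g$data, 2)
  expect_equal(sel2$selected_k, 2)
  expect_equal(sel2$best_fit$K, 2L)
})

test_that("the adjusted Rand index agrees with an established implementation", {
  set.seed(27)
  for (rep in 1:10) {
    a <- sample.int(4, 60, replace = TRUE)
    b <- sample.int(3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(rep(1:3, 10), rep(1:3, 10)), 1)
})

test_that("unbalanced panels degrade recovery only mildly", {
  full <- generate_cohort(cohort_config(n_subjects = 400, seed = 23))
  thin <- generate_cohort(cohort_config(n_subjects = 400, dropout_rate = 0.3, seed = 23))
  ari_full <- adjusted_rand_index(fit_smm(full$data, 3)$assignment[names(full$labels)],
                                  full$labels)
  ari_thin <- adjusted_rand_index(fit_smm(thin$data, 3)$assignment[names(thin$labels)],
                                  thin$labels)
  expect_gte(ari_thin, ari_full - 0.08)
  expect_gte(ari_thin, 0.75)
})
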