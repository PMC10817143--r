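test_that("missing-first-trimester detection uses the inclusive 5-13 window", {
  v <- data.frame(subject_id = c("a", "a", "b", "c"),
                  ga_weeks = c(5L, 20L, 14L, 13L))
  expect_setequal(find_missing_first_trimester(v), "b")
  expect_length(find_missing_first_trimester(v[0L, ]), 0L)
})

test_that("random week assignment is uniform, reproducible and degenerate-safe", {
  expect_true(all(assign_random_week(letters, window = 7L, seed = 1) == 7L))
  a <- assign_random_week(letters, seed = 42)
  b <- assign_random_week(letters, seed = 42)
  expect_identical(a, b)
  wk <- assign_random_week(sprintf("s%d", 1:10000), seed = 3)
  expect_true(all(wk %in% 5:13))
  freq <- as.numeric(table(factor(wk, levels = 5:13))) / 10000
  half <- stats::qnorm(0.995) * sqrt((1 / 9) * (8 / 9) / 10000)
  expect_true(all(abs(freq - 1 / 9) < half))
})

test_that("norm.boot reproduces a noiseless line exactly and is seed-stable", {
  x <- 1:30
  y <- 2 + 3 * x
  imp <- norm_boot_impute(cbind(x = x), y, cbind(x = c(5.5, 10.5)), m = 4, seed = 1)
  expect_equal(imp, matrix(rep(2 + 3 * c(5.5, 10.5), 4), 2, 4), tolerance = 1e-8)
  set.seed(4); yy <- y + rnorm(30)
  expect_identical(norm_boot_impute(cbind(x = x), yy, cbind(x = 5), m = 3, seed = 9),
                   norm_boot_impute(cbind(x = x), yy, cbind(x = 5), m = 3, seed = 9))
  expect_error(norm_boot_impute(cbind(x = 1:3), 1:3, cbind(x = 2), m = 2), "few")
})

test_that("norm.boot imputations are unbiased for a known linear truth", {
  set.seed(55)
  bias <- replicate(50, {
    ga <- sample(5:13, 2000, replace = TRUE)
    y <- 45 + 0.3 * ga + rnorm(2000)
    ga_mis <- sample(5:13, 200, replace = TRUE)
    imp <- norm_boot_impute(cbind(ga = ga), y, cbind(ga = ga_mis), m = 1)
    mean(imp[, 1] - (45 + 0.3 * ga_mis))
  })
  expect_lt(abs(mean(bias)), 0.15)
})

test_that("Rubin pooling matches the closed form", {
  p <- rubin_pool(c(10, 10, 10), c(4, 4, 4))
  expect_equal(p$Qbar, 10); expect_equal(p$B, 0); expect_equal(p$T, 4)
  expect_equal(p$df, Inf)
  p2 <- rubin_pool(c(1, 2, 3), c(1, 1, 1))
  expect_equal(p2$Qbar, 2); expect_equal(p2$Ubar, 1); expect_equal(p2$B, 1)
  expect_equal(p2$T, 1 + (4 / 3) * 1, tolerance = 1e-12)
  expect_equal(p2$df, 2 * (1 + 1 / (4 / 3))^2)
  expect_equal(rubin_pool(c(0, 0), c(0, 0))$T, 0)
  expect_error(rubin_pool(1, 1), "m >= 2")
})

test_that("the imputation pipeline alters only missing-window subjects", {
  coh <- generate_cohort(small_cohort_config(seed = 13L))
  res <- apply_eligibility(coh$subjects, coh$visits)
  s <- derive_bmi_category(res$subjects)
  spec <- imputation_spec(categories = c("normal", "overweight"), seed = 2L)
  out <- impute_pipeline(s, res$visits, spec)
  expect_length(out$completed, 5L)
  obs_cols <- setdiff(names(out$completed[[1]]), "imputation")
  for (k in 2:5)
    expect_identical(out$completed[[k]][!out$completed[[k]]$imputed, obs_cols],
                     out$completed[[1]][!out$completed[[1]]$imputed, obs_cols])
  imp1 <- out$completed[[1]][out$completed[[1]]$imputed, ]
  miss <- find_missing_first_trimester(res$visits, spec$window)
  cat_of <- s$bmi_category[match(imp1$subject_id, s$subject_id)]
  expect_true(all(as.character(cat_of) %in% c("normal", "overweight")))
  expect_true(all(imp1$subject_id %in% miss))
  expect_true(all(imp1$ga_weeks %in% 5:13))
  # assigned week is identical across the m copies
  for (k in 2:5) {
    impk <- out$completed[[k]][out$completed[[k]]$imputed, ]
    expect_identical(impk$ga_weeks[order(impk$subject_id)],
                     imp1$ga_weeks[order(imp1$subject_id)])
  }
  # no-op when every category is toggled off
  none <- impute_pipeline(s, res$visits, imputation_spec(categories = character(0)))
  expect_identical(none$completed[[1]][obs_cols], none$completed[[3]][obs_cols])
  expect_equal(sum(none$completed[[1]]$imputed), 0L)
})

test_that("missing-fraction diagnostics match the generator's MNAR rate", {
  cfg <- cohort_config(n_sites = 2, subjects_per_site = 500,
                       outlier_rate = 0, seed = 23L)
  coh <- generate_cohort(cfg)
  res <- apply_eligibility(coh$subjects, coh$visits)
  s <- derive_bmi_category(res$subjects)
  out <- impute_pipeline(s, res$visits, imputation_spec(categories = "normal"))
  d <- out$diagnostics
  overall <- sum(d$n_missing_first_trimester) / sum(d$n_subjects)
  p <- first_trimester_missing_prob(cfg)
  half <- stats::qnorm(0.995) * sqrt(p * (1 - p) / sum(d$n_subjects))
  expect_lt(abs(overall - p), half)
})

test_that("imputed first-trimester GWG stays inside the observed envelope", {
  coh <- generate_cohort(cohort_config(n_sites = 3, subjects_per_site = 300,
                                       seed = 29L))
  res <- apply_eligibility(coh$subjects, coh$visits)
  s <- derive_bmi_category(res$subjects)
  out <- impute_pipeline(s, res$visits,
                         imputation_spec(categories = c("normal", "overweight")))
  obs <- res$visits$gwg_kg[res$visits$ga_weeks >= 5 & res$visits$ga_weeks <= 13]
  env <- c(min(obs) - 2 * sd(obs), max(obs) + 2 * sd(obs))
  for (k in 1:5) {
    v <- out$completed[[k]]
    imp <- v$gwg_kg[v$imputed]
    expect_true(all(imp > env[1] & imp < env[2]))
  }
})

test_that("Rubin intervals for mean GWG at week 9 reach nominal-ish coverage", {
  set.seed(71)
  true_val <- gwg_mean_curve(9, default_trajectory_params()$normal)
  hits <- replicate(100, {
    cfg <- cohort_config(n_sites = 2, subjects_per_site = 500,
                         site_gwg_shift_sd = 0, outlier_rate = 0,
                         first_visit_week_distribution =
                           default_first_visit_distribution(p_late = 0.10),
                         seed = sample.int(1e6, 1))
    coh <- generate_cohort(cfg)
    s <- coh$subjects
    s$bmi_category <- coh$truth$subject_effects$bmi_category
    v <- coh$visits
    v$gwg_kg <- v$weight_kg - s$prepreg_weight_kg[match(v$subject_id, s$subject_id)]
    out <- impute_pipeline(s, v, imputation_spec(categories = "normal",
                                                 seed = sample.int(1e6, 1)))
    QU <- vapply(out$completed, function(d) {
      d$bmi_category <- s$bmi_category[match(d$subject_id, s$subject_id)]
      w <- d[d$bmi_category == "normal" & d$ga_weeks >= 5 & d$ga_weeks <= 13, ]
      fit <- lm(gwg_kg ~ ga_weeks, data = w)
      pr <- predict(fit, newdata = data.frame(ga_weeks = 9), se.fit = TRUE)
      c(pr$fit, pr$se.fit^2)
    }, numeric(2))
    p <- rubin_pool(QU[1, ], QU[2, ])
    hw <- stats::qt(0.975, min(p$df, 1e6)) * sqrt(p$T)
    abs(p$Qbar - true_val) < hw
  })
  expect_gte(mean(hits), 0.90)
})
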