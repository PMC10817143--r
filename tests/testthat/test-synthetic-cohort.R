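test_that("the same config and seed give byte-identical tables", {
  cfg <- small_cohort_config(seed = 77L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$visits, b$visits)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(small_cohort_config(seed = 78L))
  expect_false(identical(a$visits, c$visits))
})

test_that("nothing is injected when outliers and missingness are off", {
  cfg <- small_cohort_config(outlier_rate = 0,
                             first_visit_week_distribution =
                               default_first_visit_distribution(p_late = 0),
                             seed = 1L)
  coh <- generate_cohort(cfg)
  expect_length(coh$truth$outlier_rows, 0L)
  expect_equal(nrow(coh$truth$mnar_deleted), 0L)
  miss <- find_missing_first_trimester(coh$visits)
  expect_length(miss, 0L)
})

test_that("every subject has second- and third-trimester coverage", {
  coh <- generate_cohort(small_cohort_config(seed = 3L))
  v <- coh$visits
  has2 <- tapply(v$ga_weeks, v$subject_id, function(w) any(w >= 14 & w <= 27))
  has3 <- tapply(v$ga_weeks, v$subject_id, function(w) any(w >= 28 & w <= 42))
  expect_true(all(has2) && all(has3))
  expect_true(all(v$ga_weeks >= 2 & v$ga_weeks <= 42))
  expect_true(all(v$weight_kg > 0))
})

test_that("MNAR deletion hits the configured fraction and only weeks 5-13", {
  cfg <- small_cohort_config(
    first_visit_week_distribution = default_first_visit_distribution(p_late = 0.10),
    seed = 11L)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$truth$mnar_deleted$ga_weeks >= 5 &
                    coh$truth$mnar_deleted$ga_weeks <= 13))
  frac <- length(find_missing_first_trimester(coh$visits)) / nrow(coh$subjects)
  n <- nrow(coh$subjects)
  half <- stats::qnorm(0.995) * sqrt(0.1 * 0.9 / n)   # binomial 99% interval
  expect_gt(frac, 0.10 - half)
  expect_lt(frac, 0.10 + half)
  # the deletion is driven by the latent entry week (the MNAR mechanism)
  late <- coh$truth$subject_effects$first_care_week > 13
  expect_setequal(find_missing_first_trimester(coh$visits),
                  coh$truth$subject_effects$subject_id[late])
})

test_that("outlier truth indices refer to existing interior visits", {
  coh <- generate_cohort(small_cohort_config(outlier_rate = 0.05, seed = 5L))
  rows <- coh$truth$outlier_rows
  expect_gt(length(rows), 0L)
  expect_true(all(rows >= 1 & rows <= nrow(coh$visits)))
  first <- !duplicated(coh$visits$subject_id)
  last <- !duplicated(coh$visits$subject_id, fromLast = TRUE)
  expect_false(any(first[rows] | last[rows]))
})

test_that("BMI-category frequencies match the configured mix (chi-square GOF)", {
  coh <- generate_cohort(cohort_config(n_sites = 9, subjects_per_site = 600,
                                       seed = 21L))
  probs <- coh$config$bmi_category_probs
  counts <- table(factor(coh$truth$subject_effects$bmi_category,
                         levels = names(probs)))
  gof <- suppressWarnings(stats::chisq.test(counts, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("invalid configs are rejected", {
  expect_error(cohort_config(bmi_category_probs = c(0.5, 0.5, 0.1, 0.1)), "sum to 1")
  expect_error(cohort_config(bmi_category_probs = c(-0.1, 0.9, 0.1, 0.1)))
  expect_error(cohort_config(n_sites = 0))
  bad <- default_trajectory_params()
  bad$normal <- c(flat_rate = -5, ramp_rate = -2, ramp_accel = 0)
  expect_error(cohort_config(trajectory_params = bad), "negative weights")
})

test_that("cohort and config survive a text round trip", {
  cfg <- small_cohort_config(seed = 9L)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$subjects, coh$subjects)
  expect_equal(back$visits, coh$visits)
  expect_equal(back$truth$outlier_rows, coh$truth$outlier_rows)
  cfg_path <- file.path(dir, "config.yaml")
  write_cohort_config(cfg, cfg_path)
  cfg2 <- read_cohort_config(cfg_path)
  expect_identical(generate_cohort(cfg2)$visits, coh$visits)
})
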