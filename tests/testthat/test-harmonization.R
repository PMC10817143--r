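test_that("conception dating follows the obstetric-wheel rules", {
  expect_equal(conception_date(lmp = as.Date("2020-01-01")), as.Date("2020-01-15"))
  # EDD rule checked against an explicit calendar count of 266 days
  edd <- as.Date("2020-10-07")
  oracle <- seq(edd, by = "-1 day", length.out = 267)[267]
  expect_equal(conception_date(edd = edd), oracle)
  expect_equal(conception_date(edd = edd), as.Date("2020-01-15"))
  expect_equal(conception_date(ga_weeks = 2, at_date = as.Date("2020-01-15")),
               as.Date("2020-01-15"))
  expect_error(conception_date(), "exactly one")
  expect_error(conception_date(lmp = as.Date("2020-01-01"), edd = edd), "exactly one")
})

test_that("maternal age is completed years at conception (birthday rule)", {
  expect_equal(maternal_age(as.Date("2000-01-01"), as.Date("2015-01-01")), 15L)
  expect_equal(maternal_age(as.Date("2000-01-02"), as.Date("2020-01-01")), 19L)
  expect_equal(maternal_age(as.Date("2000-01-01"), as.Date("2020-01-01")), 20L)
  # leap-year day arithmetic stays on the calendar, not day/365 counts
  expect_equal(maternal_age(as.Date("2004-02-29"), as.Date("2020-02-28")), 15L)
  expect_equal(maternal_age(as.Date("2004-02-29"), as.Date("2020-03-01")), 16L)
  expect_error(maternal_age(as.Date("2010-01-01"), as.Date("2009-01-01")))
})

test_that("cumulative GWG is the visit minus pre-pregnancy weight", {
  expect_equal(cumulative_gwg(60, 55), 5)
  expect_equal(cumulative_gwg(53, 55), -2)   # negative GWG is legal
  expect_equal(cumulative_gwg(55, 55), 0)
  expect_error(cumulative_gwg(60, NA), "missing")
})

test_that("trajectory flagging finds the shifted visit and nothing else", {
  wk <- c(8, 14, 20, 26, 32, 38)
  clean <- 55 + 0.4 * (wk - 8)
  expect_true(all(flag_implausible_trajectory(wk, clean) == "ok"))
  for (j in 2:5) {
    w <- clean; w[j] <- w[j] + 10
    fl <- flag_implausible_trajectory(wk, w)
    expect_equal(which(fl == "implausible"), j)
  }
  # two visits: below the minimum, untouched
  expect_true(all(flag_implausible_trajectory(c(10, 20), c(55, 58)) == "ok"))
  # duplicate GA with discordant weights: both flagged and reported
  fl <- flag_implausible_trajectory(c(10, 10, 20, 30), c(55, 60, 58, 61))
  expect_equal(which(fl == "implausible"), c(1L, 2L))
  expect_equal(attr(fl, "duplicates"), c(1L, 2L))
  # concordant duplicates are fine
  fl2 <- flag_implausible_trajectory(c(10, 10, 20, 30), c(55, 55, 58, 61))
  expect_true(all(fl2 == "ok"))
})

test_that("flagging recovers injected outliers with few false alarms", {
  cfg <- cohort_config(n_sites = 2, subjects_per_site = 500,
                       outlier_rate = 0.04, outlier_magnitude = 10,
                       residual_sd = 0.6, seed = 31L)
  coh <- generate_cohort(cfg)
  flags <- gwgchart:::qc_flag_visits(coh$visits)
  truth <- coh$truth$outlier_rows
  sens <- mean(flags[truth] == "implausible")
  false_rate <- mean(flags[-truth] == "implausible")
  expect_gte(sens, 0.95)
  expect_lte(false_rate, 0.02)
})

test_that("eligibility keeps/excludes on each rule and conserves counts", {
  fx <- make_eligibility_fixture()
  res <- apply_eligibility(fx$subjects, fx$visits)
  led <- res$ledger
  expect_equal(led$subjects_removed, fx$expected$subjects_removed)
  expect_equal(led$visits_removed, fx$expected$visits_removed)
  expect_equal(nrow(res$subjects), fx$n_kept_subjects)
  expect_equal(nrow(res$visits), fx$n_kept_visits)
  # conservation: in = out + removed
  expect_equal(attr(led, "initial_subjects"),
               nrow(res$subjects) + sum(led$subjects_removed))
  expect_equal(attr(led, "initial_visits"),
               nrow(res$visits) + sum(led$visits_removed))
  # the trajectory-outlier subject is kept, its bad visit is not
  expect_true("traj_outlier" %in% res$subjects$subject_id)
  expect_equal(sum(res$visits$subject_id == "traj_outlier"), 4L)
  expect_false("gwg_cap" %in% res$subjects$subject_id)  # 30.0 kg: inclusive cap
})

test_that("refiltering is a no-op and row order does not matter", {
  fx <- make_eligibility_fixture()
  res <- apply_eligibility(fx$subjects, fx$visits)
  again <- apply_eligibility(res$subjects, res$visits)
  expect_equal(again$subjects, res$subjects)
  expect_equal(again$visits[names(res$visits)], res$visits)
  expect_true(all(again$ledger$subjects_removed == 0L))
  expect_true(all(again$ledger$visits_removed == 0L))
  set.seed(8)
  shuf <- apply_eligibility(fx$subjects[sample(nrow(fx$subjects)), ],
                            fx$visits[sample(nrow(fx$visits)), ])
  expect_setequal(shuf$subjects$subject_id, res$subjects$subject_id)
  expect_equal(nrow(shuf$visits), nrow(res$visits))
})

test_that("empty input yields an empty output and an all-zero ledger", {
  fx <- make_eligibility_fixture()
  res <- apply_eligibility(fx$subjects[0L, ], fx$visits[0L, ])
  expect_equal(nrow(res$subjects), 0L)
  expect_equal(nrow(res$visits), 0L)
  expect_true(all(res$ledger$subjects_removed == 0L))
})
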