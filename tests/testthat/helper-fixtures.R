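# Fixtures are built in code; nothing is read from disk except the bundled
# synthetic reference tables under inst/extdata.

# A subject row satisfying every eligibility criterion, with overrides.
base_subject <- function(id, ...) {
  s <- data.frame(subject_id = id, site = "siteA", maternal_age_years = 16L,
                  prepreg_weight_kg = 55, prepreg_weight_source = "measured",
                  height_cm = 158, prepreg_bmi = round(55 / 1.58^2, 2),
                  bmi_zscore = 0.1, haz = 0,
                  hypertension = FALSE, preeclampsia = FALSE, diabetes = FALSE,
                  tuberculosis = FALSE, cardiovascular = FALSE,
                  ga_at_birth_weeks = 39L, birth_weight_g = 3200,
                  birth_length_cm = 49, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) s[[nm]] <- over[[nm]]
  s
}

# Linear, plausible 5-visit trajectory (0.3 kg/week from week 8).
base_visits <- function(id, weeks = c(8L, 16L, 24L, 32L, 38L),
                        weights = 55 + 0.3 * (c(8, 16, 24, 32, 38) - 8)) {
  data.frame(subject_id = id, site = "siteA", ga_weeks = weeks,
             weight_kg = weights, stringsAsFactors = FALSE)
}

# 60-subject fixture exercising each exclusion rule once. Expected counts
# are frozen alongside: 47 plain eligible subjects, 13 special cases, of
# which the trajectory-outlier subject is *kept* (only its visit is removed).
make_eligibility_fixture <- function() {
  subj <- list(); vis <- list()
  add <- function(s, v) { subj[[length(subj) + 1L]] <<- s; vis[[length(vis) + 1L]] <<- v }

  for (i in 1:47) add(base_subject(sprintf("ok%02d", i)), base_visits(sprintf("ok%02d", i)))
  add(base_subject("age_young", maternal_age_years = 9L), base_visits("age_young"))
  add(base_subject("age_old", maternal_age_years = 20L), base_visits("age_old"))
  add(base_subject("cov_no2nd"),
      base_visits("cov_no2nd", weeks = c(8L, 30L, 38L), weights = c(55, 61, 64)))
  add(base_subject("cov_no3rd"),
      base_visits("cov_no3rd", weeks = c(8L, 16L, 24L), weights = c(55, 57.4, 59.8)))
  add(base_subject("preterm", ga_at_birth_weeks = 36L), base_visits("preterm"))
  add(base_subject("postterm", ga_at_birth_weeks = 43L), base_visits("postterm"))
  add(base_subject("bw_low", birth_weight_g = 2450), base_visits("bw_low"))
  add(base_subject("bw_high", birth_weight_g = 4100), base_visits("bw_high"))
  add(base_subject("disease", hypertension = TRUE), base_visits("disease"))
  add(base_subject("stunted", haz = -2.01), base_visits("stunted"))
  # exactly 30.0 kg maximal cumulative GWG: 1 kg/week, inclusive cap
  add(base_subject("gwg_cap"),
      base_visits("gwg_cap", weights = 55 + c(0, 8, 16, 24, 30)))
  # +10 kg error at week 24: the visit is flagged, the subject kept
  add(base_subject("traj_outlier"),
      base_visits("traj_outlier", weights = c(55, 57.4, 69.8, 62.2, 64)))
  add(base_subject("incomplete", birth_length_cm = NA_real_), base_visits("incomplete"))

  expected <- data.frame(
    criterion = c("age", "visit_coverage", "term_birth", "birth_weight",
                  "diseases", "stunting", "gwg_cap", "implausible_visits",
                  "completeness"),
    subjects_removed = c(2L, 2L, 2L, 2L, 1L, 1L, 1L, 0L, 1L),
    visits_removed = c(10L, 6L, 10L, 10L, 5L, 5L, 5L, 1L, 5L))
  # 58 subjects x 5 visits + 2 x 3 visits = 296 in; 57 removed -> 239 kept
  list(subjects = do.call(rbind, subj), visits = do.call(rbind, vis),
       expected = expected, n_kept_subjects = 48L, n_kept_visits = 239L)
}

# Small LMS table with non-trivial curves, for interpolation tests.
make_lms_fixture <- function() {
  lms_table(age = c(10, 12, 14, 16, 18),
            L = c(1.0, 0.8, 0.5, 0.2, -0.2),
            M = c(140, 148, 155, 159, 161),
            S = c(0.040, 0.042, 0.045, 0.047, 0.048),
            indicator = "height_for_age")
}

# small cohort config used across tests (kept light for runtime)
small_cohort_config <- function(...) {
  cohort_config(n_sites = 2L, subjects_per_site = 100L, ...)
}
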