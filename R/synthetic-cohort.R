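#' Configuration for the synthetic multi-site pregnancy cohort
#'
#' Defines the statistical structure of a simulated pooled dataset of pregnant
#' adolescents: a number of sites (countries) with site-level shifts in height
#' and in gestational weight gain (GWG), a four-category pre-pregnancy
#' BMI mix dominated by normal weight, monotone individual GWG trajectories
#' that rise mainly in the third trimester, missing-not-at-random (MNAR)
#' first-trimester records driven by a latent late entry into prenatal care,
#' and occasional implausible weight records injected for the QC stage to
#' find.
#'
#' The defaults emulate a pooled nine-country adolescent cohort: nine sites of
#' 750 subjects, BMI-category probabilities 1.5/71.8/21.4/5.3%, roughly 11%
#' of subjects entering prenatal care after week 13 (hence lacking any
#' first-trimester weight), visits every ~6 weeks, and ~5.5 weight records
#' per subject.
#'
#' @param n_sites number of sites (countries), >= 1.
#' @param subjects_per_site subjects generated per site, >= 1.
#' @param site_height_shift_sd SD (cm) of the site-level height shift.
#' @param site_gwg_shift_sd SD (kg at term) of the site-level GWG shift; the
#'   shift is applied proportionally to gestational age so GWG is 0 at
#'   conception.
#' @param bmi_category_probs probabilities of the four pre-pregnancy BMI
#'   categories (underweight, normal, overweight, obesity); must sum to 1.
#' @param trajectory_params per-category mean-GWG curve coefficients; see
#'   [default_trajectory_params()].
#' @param residual_sd visit-level measurement noise SD (kg).
#' @param first_visit_week_distribution data.frame with columns `week`
#'   (integer gestational weeks, within 2-20) and `prob` (summing to 1):
#'   distribution of the latent week of entry into prenatal care. Mass at
#'   weeks > 13 is the MNAR first-trimester missingness rate.
#' @param visit_spacing_weeks mean gap between consecutive visits (weeks).
#' @param outlier_rate probability that an interior visit weight is replaced
#'   by an implausible value.
#' @param outlier_magnitude absolute size (kg) of the injected shift.
#' @param disease_rate probability a subject carries one (randomly chosen)
#'   exclusion-relevant disease flag.
#' @param seed integer seed; the same config and seed give byte-identical
#'   output.
#' @return a list of class `"cohort_config"`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_sites = 9L,
                          subjects_per_site = 750L,
                          site_height_shift_sd = 1.5,
                          site_gwg_shift_sd = 0.4,
                          bmi_category_probs = c(underweight = 0.015,
                                                 normal = 0.718,
                                                 overweight = 0.214,
                                                 obesity = 0.053),
                          trajectory_params = default_trajectory_params(),
                          residual_sd = 0.6,
                          first_visit_week_distribution = default_first_visit_distribution(),
                          visit_spacing_weeks = 7,
                          outlier_rate = 0.01,
                          outlier_magnitude = 10,
                          disease_rate = 0.02,
                          seed = 20240126L) {
  cfg <- list(n_sites = as.integer(n_sites),
              subjects_per_site = as.integer(subjects_per_site),
              site_height_shift_sd = site_height_shift_sd,
              site_gwg_shift_sd = site_gwg_shift_sd,
              bmi_category_probs = bmi_category_probs,
              trajectory_params = trajectory_params,
              residual_sd = residual_sd,
              first_visit_week_distribution = first_visit_week_distribution,
              visit_spacing_weeks = visit_spacing_weeks,
              outlier_rate = outlier_rate,
              outlier_magnitude = outlier_magnitude,
              disease_rate = disease_rate,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_sites >= 1L, cfg$subjects_per_site >= 1L,
            cfg$site_height_shift_sd >= 0, cfg$site_gwg_shift_sd >= 0,
            cfg$residual_sd >= 0, cfg$visit_spacing_weeks >= 1,
            cfg$outlier_rate >= 0, cfg$outlier_rate <= 1,
            cfg$outlier_magnitude >= 0,
            cfg$disease_rate >= 0, cfg$disease_rate <= 1)
  p <- cfg$bmi_category_probs
  if (length(p) != 4L || any(p < 0) || any(p > 1))
    stop("bmi_category_probs must be 4 probabilities in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9) stop("bmi_category_probs must sum to 1")
  d <- cfg$first_visit_week_distribution
  if (!is.data.frame(d) || !all(c("week", "prob") %in% names(d)))
    stop("first_visit_week_distribution must be a data.frame(week, prob)")
  if (any(d$week < 2) || any(d$week > 20))
    stop("first-visit weeks must lie in [2, 20]")
  if (abs(sum(d$prob) - 1) > 1e-9) stop("first-visit probabilities must sum to 1")
  tp <- cfg$trajectory_params
  if (!is.list(tp) || !all(bmi_category_levels() %in% names(tp)))
    stop("trajectory_params must be a named list with one entry per BMI category")
  # a mean curve driving typical weights negative at any week is a config error
  for (cat in bmi_category_levels()) {
    curve <- gwg_mean_curve(0:42, tp[[cat]])
    if (any(35 + curve <= 0))
      stop(sprintf("trajectory curve for '%s' produces negative weights", cat))
  }
  invisible(cfg)
}

#' Default mean-GWG curve coefficients per BMI category
#'
#' Each curve is a monotone piecewise quadratic in gestational week `t`:
#' a near-flat first trimester `flat_rate * min(t, 13)` followed by
#' `ramp_rate * (t - 13) + ramp_accel * (t - 13)^2` beyond week 13, so that
#' most gain accrues in the third trimester (the pattern seen in adolescent
#' cohorts, unlike the second-trimester-dominated adult pattern). Total gain
#' at week 40 under the defaults: ~13.1 kg (underweight), ~11.4 (normal),
#' ~9.4 (overweight), ~7.4 (obesity).
#'
#' @return named list of coefficient vectors
#'   `c(flat_rate, ramp_rate, ramp_accel)` in kg/week (and kg/week^2).
#' @export
default_trajectory_params <- function() {
  list(underweight = c(flat_rate = 0.06, ramp_rate = 0.28, ramp_accel = 0.0065),
       normal      = c(flat_rate = 0.05, ramp_rate = 0.25, ramp_accel = 0.0055),
       overweight  = c(flat_rate = 0.04, ramp_rate = 0.22, ramp_accel = 0.0040),
       obesity     = c(flat_rate = 0.03, ramp_rate = 0.18, ramp_accel = 0.0030))
}

#' Mean GWG (kg) at gestational week(s) `t` for one coefficient vector
#' @param t gestational weeks.
#' @param params coefficient vector `c(flat_rate, ramp_rate, ramp_accel)`.
#' @return numeric vector of mean cumulative GWG values.
#' @export
gwg_mean_curve <- function(t, params) {
  p <- unname(params)
  late <- pmax(t - 13, 0)
  p[1L] * pmin(t, 13) + p[2L] * late + p[3L] * late^2
}

#' Default distribution of the latent first prenatal-care week
#'
#' Mass over integer weeks 2-20; the mass beyond week 13 (`p_late`, default
#' 0.11) is the fraction of subjects with no first-trimester weight record —
#' the MNAR mechanism mimicking late entry into prenatal care.
#'
#' @param p_late probability that care starts after week 13.
#' @return data.frame with columns `week`, `prob`.
#' @export
default_first_visit_distribution <- function(p_late = 0.11) {
  stopifnot(p_late >= 0, p_late < 1)
  early_w <- c(1, 2, 3, 5, 7, 8, 8, 7, 6, 5, 4, 3)    # weeks 2..13
  late_w <- c(6, 5, 4, 3, 2, 1.5, 1)                  # weeks 14..20
  data.frame(week = 2:20,
             prob = c(early_w / sum(early_w) * (1 - p_late),
                      late_w / sum(late_w) * p_late))
}

#' MNAR first-trimester missingness probability implied by a config
#' @param config a [cohort_config()].
#' @return probability that a generated subject has no visit in weeks 5-13.
#' @export
first_trimester_missing_prob <- function(config) {
  d <- config$first_visit_week_distribution
  sum(d$prob[d$week > 13])
}

#' Generate a synthetic multi-site pregnancy cohort
#'
#' Simulates subject-level records (identifiers, dates, pre-pregnancy
#' anthropometry, disease flags, birth outcomes) and longitudinal visit-level
#' weight records, together with the ground truth needed for
#' parameter-recovery tests. Visit weights are pre-pregnancy weight plus the
#' category-specific mean GWG curve scaled by a subject-level random effect,
#' plus a site-level GWG shift growing linearly with gestational age, plus
#' Gaussian measurement noise. Every subject has at least one visit in weeks
#' 14-27 and one in weeks 28-42. Subjects whose latent first prenatal-care
#' week falls after week 13 lose all their week-5-13 visits (MNAR: the
#' deletion depends only on the latent entry week). Implausible records are
#' injected as additive shifts of `+/- outlier_magnitude` at random interior
#' visits.
#'
#' @param config a [cohort_config()].
#' @return list of class `"synthetic_cohort"` with elements `subjects`,
#'   `visits` (data.frames) and `truth` (list of class `"cohort_truth"`:
#'   `subject_effects`, `site_effects`, `outlier_rows` — row indices into
#'   `visits` — and `mnar_deleted`).
#' @examples
#' coh <- generate_cohort(cohort_config(n_sites = 2, subjects_per_site = 20))
#' nrow(coh$subjects); nrow(coh$visits)
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  K <- config$n_sites
  nps <- config$subjects_per_site
  N <- K * nps
  site_lab <- sprintf("site%02d", seq_len(K))
  site_effects <- data.frame(site = site_lab,
                             height_shift_cm = stats::rnorm(K, 0, config$site_height_shift_sd),
                             gwg_shift_kg = stats::rnorm(K, 0, config$site_gwg_shift_sd))
  site_idx <- rep(seq_len(K), each = nps)

  subject_id <- sprintf("s%05d", seq_len(N))
  age_years <- sample(13:19, N, replace = TRUE,
                      prob = c(0.06, 0.12, 0.13, 0.13, 0.13, 0.21, 0.22))
  conception <- as.Date("2003-01-01") + sample.int(6574L, N, replace = TRUE) - 1L
  dob <- conception - round(age_years * 365.2425 + stats::runif(N, 10, 360))
  lmp <- conception - 14L

  cat_idx <- sample.int(4L, N, replace = TRUE, prob = config$bmi_category_probs)
  zlo <- c(-2.8, -1.9, 1.05, 2.05)[cat_idx]
  zhi <- c(-2.05, 0.95, 1.95, 3.2)[cat_idx]
  bmi_z <- stats::runif(N, zlo, zhi)
  # synthetic BMI-for-age reference: L = 0, M = 21 kg/m^2, S = 0.11
  bmi <- 21 * exp(0.11 * bmi_z)
  haz <- stats::rnorm(N, -0.3, 0.9)
  height <- round(158 + 5.5 * haz + site_effects$height_shift_cm[site_idx] +
                    stats::rnorm(N, 0, 1), 1)
  prepreg_weight <- round(bmi * (height / 100)^2, 1)
  prepreg_bmi <- round(prepreg_weight / (height / 100)^2, 2)

  disease <- matrix(FALSE, N, 5L,
                    dimnames = list(NULL, c("hypertension", "preeclampsia",
                                            "diabetes", "tuberculosis",
                                            "cardiovascular")))
  has_dis <- stats::runif(N) < config$disease_rate
  if (any(has_dis))
    disease[cbind(which(has_dis), sample.int(5L, sum(has_dis), replace = TRUE))] <- TRUE

  subjects <- data.frame(
    subject_id = subject_id,
    site = site_lab[site_idx],
    date_of_birth = dob,
    lmp_date = lmp,
    prepreg_weight_kg = prepreg_weight,
    prepreg_weight_source = sample(c("measured", "medical-record", "self-reported"),
                                   N, replace = TRUE, prob = c(0.3, 0.5, 0.2)),
    height_cm = height,
    prepreg_bmi = prepreg_bmi,
    bmi_zscore = bmi_z,
    haz = haz,
    disease,
    ga_at_birth_weeks = sample(37:42, N, replace = TRUE,
                               prob = c(0.08, 0.20, 0.34, 0.24, 0.10, 0.04)),
    birth_weight_g = round(stats::rnorm(N, 3200, 280)),
    birth_length_cm = round(stats::rnorm(N, 49.5, 2), 1),
    stringsAsFactors = FALSE
  )

  # visits start at the latent week of entry into prenatal care and recur
  # every ~ visit_spacing_weeks until week 40; entry after week 13 therefore
  # leaves no first-trimester record (MNAR: driven only by the latent week)
  fdist <- config$first_visit_week_distribution
  w0 <- sample(fdist$week, N, replace = TRUE, prob = fdist$prob)
  max_vis <- ceiling((40 - 2) / max(config$visit_spacing_weeks - 1, 1)) + 1L
  gaps <- matrix(config$visit_spacing_weeks +
                   sample(-1:1, N * (max_vis - 1L), replace = TRUE),
                 N, max_vis - 1L)
  cumgaps <- if (ncol(gaps) == 1L) gaps else t(apply(gaps, 1L, cumsum))
  weeks <- w0 + cbind(0L, cumgaps)
  observed <- weeks <= 40
  # counterfactual early-entry schedule: the first-trimester visits a late
  # entrant would have had, recorded as the MNAR-deleted ground truth
  cf_weeks <- sample(5:9, N, replace = TRUE) + cbind(0L, cumgaps)
  deleted <- (w0 > 13) & cf_weeks <= 13

  u_mult <- pmax(0.4, stats::rnorm(N, 1, 0.12))
  curve <- matrix(0, N, ncol(weeks))
  for (k in 1:4) {
    rows <- which(cat_idx == k)
    if (length(rows))
      curve[rows, ] <- gwg_mean_curve(weeks[rows, , drop = FALSE],
                                      config$trajectory_params[[bmi_category_levels()[k]]])
  }
  wt <- prepreg_weight + u_mult * curve +
    site_effects$gwg_shift_kg[site_idx] * weeks / 40 +
    stats::rnorm(length(weeks), 0, config$residual_sd)
  wt <- round(wt, 1)
  if (any(wt[observed] <= 0)) stop("generated non-positive visit weight; check trajectory_params")

  ord <- which(t(observed))  # row-major: groups visits by subject, weeks ascending
  subj_of <- rep(seq_len(N), times = rowSums(observed))
  visits <- data.frame(subject_id = subject_id[subj_of],
                       site = site_lab[site_idx[subj_of]],
                       ga_weeks = as.integer(t(weeks))[ord],
                       weight_kg = t(wt)[ord],
                       stringsAsFactors = FALSE)

  del_ord <- which(t(deleted))
  mnar_deleted <- data.frame(
    subject_id = subject_id[rep(seq_len(N), times = rowSums(deleted))],
    ga_weeks = as.integer(t(cf_weeks))[del_ord])

  # outliers only at interior visits, so QC rate bounds see a jump on both sides
  first <- !duplicated(visits$subject_id)
  last <- !duplicated(visits$subject_id, fromLast = TRUE)
  hit <- which(stats::runif(nrow(visits)) < config$outlier_rate & !first & !last)
  if (length(hit)) {
    sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
    visits$weight_kg[hit] <- visits$weight_kg[hit] + sgn * config$outlier_magnitude
  }

  truth <- structure(list(
    subject_effects = data.frame(subject_id = subject_id,
                                 bmi_category = bmi_category_levels()[cat_idx],
                                 gwg_multiplier = u_mult,
                                 first_care_week = w0),
    site_effects = site_effects,
    outlier_rows = hit,
    mnar_deleted = mnar_deleted), class = "cohort_truth")

  structure(list(subjects = subjects, visits = visits, truth = truth,
                 config = config), class = "synthetic_cohort")
}

#' Write / read a synthetic cohort as delimited text
#'
#' Tables go to `subjects.csv` and `visits.csv` (comma-separated, header row,
#' UTF-8, '.' decimal separator); the ground truth goes to sidecar
#' `truth_*.csv` files.
#'
#' @param cohort a `"synthetic_cohort"` from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written ([write_cohort()]) or the cohort list
#'   ([read_cohort()]; `truth` is `NULL` if no sidecars are present).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(subjects = file.path(dir, "subjects.csv"),
             visits = file.path(dir, "visits.csv"),
             subject_effects = file.path(dir, "truth_subject_effects.csv"),
             site_effects = file.path(dir, "truth_site_effects.csv"),
             outlier_rows = file.path(dir, "truth_outlier_rows.csv"),
             mnar_deleted = file.path(dir, "truth_mnar_deleted.csv"))
  utils::write.csv(cohort$subjects, paths["subjects"], row.names = FALSE)
  utils::write.csv(cohort$visits, paths["visits"], row.names = FALSE)
  tr <- cohort$truth
  if (!is.null(tr)) {
    utils::write.csv(tr$subject_effects, paths["subject_effects"], row.names = FALSE)
    utils::write.csv(tr$site_effects, paths["site_effects"], row.names = FALSE)
    utils::write.csv(data.frame(row = tr$outlier_rows), paths["outlier_rows"],
                     row.names = FALSE)
    utils::write.csv(tr$mnar_deleted, paths["mnar_deleted"], row.names = FALSE)
  }
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  for (col in c("date_of_birth", "lmp_date"))
    if (col %in% names(subjects)) subjects[[col]] <- as.Date(subjects[[col]])
  visits <- utils::read.csv(file.path(dir, "visits.csv"), stringsAsFactors = FALSE)
  truth <- NULL
  tse <- file.path(dir, "truth_subject_effects.csv")
  if (file.exists(tse)) {
    truth <- structure(list(
      subject_effects = utils::read.csv(tse, stringsAsFactors = FALSE),
      site_effects = utils::read.csv(file.path(dir, "truth_site_effects.csv"),
                                     stringsAsFactors = FALSE),
      outlier_rows = utils::read.csv(file.path(dir, "truth_outlier_rows.csv"))$row,
      mnar_deleted = utils::read.csv(file.path(dir, "truth_mnar_deleted.csv"),
                                     stringsAsFactors = FALSE)),
      class = "cohort_truth")
  }
  structure(list(subjects = subjects, visits = visits, truth = truth),
            class = "synthetic_cohort")
}

#' Write / read a cohort configuration as structured text (YAML)
#' @param config a [cohort_config()].
#' @param path file path.
#' @return [read_cohort_config()] returns a validated [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  x <- unclass(config)
  x$bmi_category_probs <- as.list(config$bmi_category_probs)
  x$trajectory_params <- lapply(config$trajectory_params, as.list)
  x$first_visit_week_distribution <-
    list(week = config$first_visit_week_distribution$week,
         prob = config$first_visit_week_distribution$prob)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  renorm <- function(p) {   # undo sub-1e-6 float drift from text serialization
    if (abs(sum(p) - 1) < 1e-6) p / sum(p) else p
  }
  x$bmi_category_probs <- renorm(unlist(x$bmi_category_probs))
  x$trajectory_params <- lapply(x$trajectory_params, unlist)
  x$first_visit_week_distribution <-
    data.frame(week = unlist(x$first_visit_week_distribution$week),
               prob = renorm(unlist(x$first_visit_week_distribution$prob)))
  do.call(cohort_config, x)
}
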