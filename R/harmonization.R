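#' Date of conception from a single dating anchor
#'
#' Conception is dated from exactly one of three anchors, following the usual
#' obstetric-wheel conventions: last menstrual period (conception = LMP + 14
#' days), estimated due date (conception = EDD - 266 days), or a known
#' gestational age on a known date (conception = date - (GA_weeks * 7 - 14)
#' days; gestational age is counted from the LMP).
#'
#' @param lmp last-menstrual-period date (`Date`).
#' @param edd estimated-due-date (`Date`).
#' @param ga_weeks gestational age in completed weeks at `at_date`.
#' @param at_date the date at which `ga_weeks` applies (`Date`).
#' @return conception date (`Date`).
#' @examples
#' conception_date(lmp = as.Date("2020-01-01"))
#' @export
conception_date <- function(lmp = NULL, edd = NULL, ga_weeks = NULL, at_date = NULL) {
  anchors <- c(lmp = !is.null(lmp), edd = !is.null(edd),
               ga = !is.null(ga_weeks) || !is.null(at_date))
  if (sum(anchors) != 1L)
    stop("supply exactly one anchor: lmp, edd, or ga_weeks + at_date")
  if (anchors["lmp"]) return(as.Date(lmp) + 14L)
  if (anchors["edd"]) return(as.Date(edd) - 266L)
  if (is.null(ga_weeks) || is.null(at_date))
    stop("the gestational-age anchor needs both ga_weeks and at_date")
  as.Date(at_date) - (as.integer(ga_weeks) * 7L - 14L)
}

#' Maternal age in completed years at conception
#'
#' The difference between the date of birth and the date of conception,
#' floored to completed calendar years (the birthday rule: the year count
#' increases only once the anniversary of the birth date is reached).
#'
#' @param dob date of birth (`Date`), vectorized.
#' @param conception conception date (`Date`), vectorized.
#' @return integer completed years.
#' @export
maternal_age <- function(dob, conception) {
  dob <- as.Date(dob); conception <- as.Date(conception)
  if (any(conception <= dob)) stop("conception must be after date of birth")
  d <- as.POSIXlt(dob); cc <- as.POSIXlt(conception)
  yrs <- cc$year - d$year
  before_bday <- cc$mon < d$mon | (cc$mon == d$mon & cc$mday < d$mday)
  as.integer(yrs - before_bday)
}

#' Cumulative gestational weight gain at a visit
#'
#' The difference between the weight measured at the visit and the
#' pre-pregnancy weight; negative values are legitimate (weight loss in
#' early pregnancy).
#'
#' @param visit_weight visit weight (kg), positive.
#' @param prepregnancy_weight pre-pregnancy weight (kg), positive.
#' @return GWG in kg.
#' @export
cumulative_gwg <- function(visit_weight, prepregnancy_weight) {
  if (any(is.na(prepregnancy_weight))) stop("missing pre-pregnancy weight")
  if (any(visit_weight <= 0, na.rm = TRUE) || any(prepregnancy_weight <= 0))
    stop("weights must be positive")
  visit_weight - prepregnancy_weight
}

#' Options controlling eligibility filtering and trajectory QC
#'
#' @param age_range completed years at conception, inclusive.
#' @param term_range gestational age at birth (weeks), inclusive.
#' @param birth_weight_range grams, inclusive.
#' @param trimester2,trimester3 inclusive week windows used for the
#'   visit-coverage criterion (at least one weight in each).
#' @param gwg_cap_kg subjects whose maximal cumulative GWG reaches this value
#'   are excluded (inclusive at the cap).
#' @param qc_threshold_kg residual threshold of the implausible-trajectory
#'   rule; 4 kg by default (well beyond measurement error at any visit).
#' @param qc_rate_bounds plausible inter-visit weight-change rates, kg/week;
#'   sustained gain above 3 kg/week or loss beyond 1 kg/week is not
#'   biologically plausible.
#' @return list of class `"harmonization_options"`.
#' @export
harmonization_options <- function(age_range = c(10L, 19L),
                                  term_range = c(37L, 42L),
                                  birth_weight_range = c(2500, 4000),
                                  trimester2 = c(14L, 27L),
                                  trimester3 = c(28L, 42L),
                                  gwg_cap_kg = 30,
                                  qc_threshold_kg = 4,
                                  qc_rate_bounds = c(-1, 3)) {
  structure(list(age_range = age_range, term_range = term_range,
                 birth_weight_range = birth_weight_range,
                 trimester2 = trimester2, trimester3 = trimester3,
                 gwg_cap_kg = gwg_cap_kg, qc_threshold_kg = qc_threshold_kg,
                 qc_rate_bounds = qc_rate_bounds),
            class = "harmonization_options")
}

# Siegel repeated-median line: robust to nearly half the points being wild.
repeated_median_line <- function(x, y) {
  n <- length(x)
  slopes <- numeric(n)
  for (i in seq_len(n)) {
    dx <- x[-i] - x[i]
    dy <- y[-i] - y[i]
    ok <- dx != 0   # tied ages carry no slope information
    slopes[i] <- if (any(ok)) stats::median(dy[ok] / dx[ok]) else NA_real_
  }
  b <- stats::median(slopes, na.rm = TRUE)
  a <- stats::median(y - b * x)
  c(intercept = a, slope = b)
}

#' Flag biologically implausible weight measurements in one trajectory
#'
#' Automates the manual plausibility review of longitudinal pregnancy weights:
#' a robust straight line (repeated-median slope and intercept) is fitted to
#' weight versus gestational age; the visit with the largest absolute residual
#' is flagged when that residual exceeds `threshold_kg` or when either of its
#' adjacent inter-visit weight-change rates falls outside `rate_bounds`
#' (kg/week); the line is refitted on the remaining visits and the rule is
#' repeated until nothing is flagged or only two visits remain. Duplicated
#' gestational ages with discordant weights are all flagged up front. Fewer
#' than three visits with distinct gestational ages are left untouched.
#' Flags mark measurements, never subjects.
#'
#' @param ga_weeks gestational ages (completed weeks) of one subject's visits.
#' @param weight_kg corresponding weights (kg).
#' @param threshold_kg residual threshold (kg).
#' @param rate_bounds length-2 plausible rate interval (kg/week).
#' @return character vector (`"ok"`/`"implausible"`) aligned with the input;
#'   attribute `"duplicates"` carries indices flagged by the duplicate rule.
#' @export
flag_implausible_trajectory <- function(ga_weeks, weight_kg, threshold_kg = 4,
                                        rate_bounds = c(-1, 3)) {
  n <- length(ga_weeks)
  stopifnot(length(weight_kg) == n)
  flags <- rep("ok", n)
  dup_idx <- integer(0)
  for (g in unique(ga_weeks[duplicated(ga_weeks)])) {
    idx <- which(ga_weeks == g)
    if (length(unique(weight_kg[idx])) > 1L) dup_idx <- c(dup_idx, idx)
  }
  flags[dup_idx] <- "implausible"
  active <- which(flags == "ok")
  repeat {
    if (length(unique(ga_weeks[active])) < 3L) break
    ord <- active[order(ga_weeks[active])]
    x <- ga_weeks[ord]; y <- weight_kg[ord]
    fit <- repeated_median_line(x, y)
    res <- y - (fit["intercept"] + fit["slope"] * x)
    j <- which.max(abs(res))
    rates <- diff(y) / diff(x)
    adj <- c(if (j > 1L) rates[j - 1L], if (j < length(x)) rates[j])
    adj <- adj[is.finite(adj)]   # tied-age pairs carry no rate information
    bad_rate <- length(adj) > 0L &&
      any(adj < rate_bounds[1L] | adj > rate_bounds[2L])
    if (abs(res[j]) > threshold_kg || bad_rate) {
      flags[ord[j]] <- "implausible"
      active <- which(flags == "ok")
    } else break
  }
  attr(flags, "duplicates") <- dup_idx
  flags
}

# QC flags for a whole visit table, subject by subject.
qc_flag_visits <- function(visits, opts = harmonization_options()) {
  flags <- rep("ok", nrow(visits))
  for (idx in split(seq_len(nrow(visits)), visits$subject_id)) {
    flags[idx] <- as.character(flag_implausible_trajectory(
      visits$ga_weeks[idx], visits$weight_kg[idx],
      threshold_kg = opts$qc_threshold_kg, rate_bounds = opts$qc_rate_bounds))
  }
  flags
}

#' Apply the eligibility criteria and emit a flowchart-style exclusion ledger
#'
#' Retains exactly the subjects satisfying all of: completed age 10-19 at
#' conception; at least one plausible weight in the second (weeks 14-27) and
#' one in the third (weeks 28-42) trimester; birth at term (37-42 weeks);
#' birth weight 2,500-4,000 g; none of the five disease flags (hypertension,
#' preeclampsia, diabetes/gestational diabetes, tuberculosis, cardiovascular);
#' not stunted (height-for-age z >= -2); maximal cumulative GWG below 30 kg
#' (inclusive cap); and no missing value among the variables of interest.
#' Implausible measurements found by [flag_implausible_trajectory()] are
#' removed as visits (never as subjects) and all visit-dependent criteria are
#' evaluated on the plausible visits, which makes the filter idempotent.
#'
#' Ledger rows appear in a fixed documented order: age, visit coverage, term
#' birth, birth weight, diseases, stunting, GWG cap, implausible-visit
#' removal, completeness.
#'
#' @param subjects subject table; must carry `subject_id`,
#'   `prepreg_weight_kg`, `height_cm`, `prepreg_bmi`, the five disease flag
#'   columns, `haz`, `ga_at_birth_weeks`, `birth_weight_g`, `birth_length_cm`,
#'   and either `maternal_age_years` or (`date_of_birth` + `lmp_date`).
#' @param visits visit table with `subject_id`, `ga_weeks`, `weight_kg`.
#' @param opts a [harmonization_options()].
#' @return list with `subjects`, `visits` (kept rows; visits gain `gwg_kg`
#'   and `qc_flag` columns) and `ledger` (class `"exclusion_ledger"`).
#' @export
apply_eligibility <- function(subjects, visits, opts = harmonization_options()) {
  if (!all(visits$subject_id %in% subjects$subject_id))
    stop("visits reference subject ids absent from the subject table")
  if (nrow(subjects) == 0L) {
    led <- empty_ledger(0L, 0L)
    out_v <- visits[0L, , drop = FALSE]
    out_v$gwg_kg <- numeric(0); out_v$qc_flag <- character(0)
    return(list(subjects = subjects, visits = out_v, ledger = led))
  }
  if (!"maternal_age_years" %in% names(subjects)) {
    conc <- conception_date(lmp = subjects$lmp_date)
    subjects$maternal_age_years <- maternal_age(subjects$date_of_birth, conc)
  }
  visits <- visits[order(match(visits$subject_id, subjects$subject_id),
                         visits$ga_weeks), , drop = FALSE]
  rownames(visits) <- NULL
  pw <- subjects$prepreg_weight_kg[match(visits$subject_id, subjects$subject_id)]
  visits$gwg_kg <- visits$weight_kg - pw
  visits$qc_flag <- qc_flag_visits(visits, opts)

  ok_vis <- visits$qc_flag == "ok"
  sid <- subjects$subject_id
  vis_sid <- visits$subject_id

  in2 <- ok_vis & visits$ga_weeks >= opts$trimester2[1L] & visits$ga_weeks <= opts$trimester2[2L]
  in3 <- ok_vis & visits$ga_weeks >= opts$trimester3[1L] & visits$ga_weeks <= opts$trimester3[2L]
  max_gwg <- tapply_default(visits$gwg_kg[ok_vis], vis_sid[ok_vis], max, sid, -Inf)

  disease_cols <- c("hypertension", "preeclampsia", "diabetes",
                    "tuberculosis", "cardiovascular")
  any_disease <- rowSums(as.matrix(subjects[disease_cols])) > 0
  required <- c("maternal_age_years", "prepreg_weight_kg", "height_cm",
                "prepreg_bmi", "haz", "birth_weight_g", "birth_length_cm",
                "ga_at_birth_weeks")
  complete_subj <- stats::complete.cases(subjects[required])
  vis_complete <- !(is.na(visits$ga_weeks) | is.na(visits$gwg_kg))
  complete_vis <- tapply_default(vis_complete[ok_vis], vis_sid[ok_vis], all, sid, TRUE)

  crit <- list(
    age = subjects$maternal_age_years >= opts$age_range[1L] &
      subjects$maternal_age_years <= opts$age_range[2L],
    visit_coverage = sid %in% vis_sid[in2] & sid %in% vis_sid[in3],
    term_birth = subjects$ga_at_birth_weeks >= opts$term_range[1L] &
      subjects$ga_at_birth_weeks <= opts$term_range[2L],
    birth_weight = subjects$birth_weight_g >= opts$birth_weight_range[1L] &
      subjects$birth_weight_g <= opts$birth_weight_range[2L],
    diseases = !any_disease,
    stunting = !is_stunted(subjects$haz),
    gwg_cap = max_gwg < opts$gwg_cap_kg,
    implausible_visits = TRUE,   # removes visits, not subjects
    completeness = complete_subj & complete_vis
  )
  crit <- lapply(crit, function(x) { x[is.na(x)] <- FALSE; x })

  keep <- rep(TRUE, nrow(subjects))
  vis_alive <- rep(TRUE, nrow(visits))
  rows <- vector("list", length(crit))
  for (i in seq_along(crit)) {
    nm <- names(crit)[i]
    if (nm == "implausible_visits") {
      # flagged measurements are removed as visits, never as subjects
      out_v <- vis_alive & !ok_vis
      vis_alive <- vis_alive & !out_v
      rows[[i]] <- data.frame(criterion = nm, subjects_removed = 0L,
                              visits_removed = sum(out_v))
      next
    }
    newly_out <- keep & !crit[[i]]
    keep <- keep & crit[[i]]
    out_v <- vis_alive & vis_sid %in% sid[newly_out]
    vis_alive <- vis_alive & !out_v
    rows[[i]] <- data.frame(criterion = nm, subjects_removed = sum(newly_out),
                            visits_removed = sum(out_v))
  }
  ledger <- finalize_ledger(do.call(rbind, rows), nrow(subjects), nrow(visits))

  kept_subjects <- subjects[keep, , drop = FALSE]
  kept_visits <- visits[vis_alive, , drop = FALSE]
  rownames(kept_subjects) <- NULL; rownames(kept_visits) <- NULL
  list(subjects = kept_subjects, visits = kept_visits, ledger = ledger)
}

tapply_default <- function(x, by, fn, levels, default) {
  out <- rep(default, length(levels))
  if (length(x)) {
    agg <- tapply(x, by, fn)
    m <- match(names(agg), levels)
    out[m[!is.na(m)]] <- unlist(agg)[!is.na(m)]
  }
  out
}

empty_ledger <- function(n_subj, n_vis) {
  finalize_ledger(data.frame(
    criterion = c("age", "visit_coverage", "term_birth", "birth_weight",
                  "diseases", "stunting", "gwg_cap", "implausible_visits",
                  "completeness"),
    subjects_removed = 0L, visits_removed = 0L), n_subj, n_vis)
}

finalize_ledger <- function(ledger, n_subj, n_vis) {
  ledger$subjects_remaining <- n_subj - cumsum(ledger$subjects_removed)
  ledger$visits_remaining <- n_vis - cumsum(ledger$visits_removed)
  structure(ledger, initial_subjects = n_subj, initial_visits = n_vis,
            class = c("exclusion_ledger", "data.frame"))
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat(sprintf("Exclusion ledger: %d subjects, %d visits at entry\n",
              attr(x, "initial_subjects"), attr(x, "initial_visits")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-20s -%5d subjects  -%5d visits   (%d / %d remain)\n",
                x$criterion[i], x$subjects_removed[i], x$visits_removed[i],
                x$subjects_remaining[i], x$visits_remaining[i]))
  invisible(x)
}

#' Write an exclusion ledger as delimited text
#' @param ledger an `"exclusion_ledger"`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_ledger <- function(ledger, path) {
  df <- as.data.frame(ledger)
  df <- cbind(df, initial_subjects = attr(ledger, "initial_subjects"),
              initial_visits = attr(ledger, "initial_visits"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
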