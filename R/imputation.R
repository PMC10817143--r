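#' Specification of the first-trimester imputation procedure
#'
#' Subjects with no weight record in the first-trimester window (weeks 5-13,
#' inclusive) receive one randomly assigned week in that window and `m`
#' imputed weights at that week, drawn under the normal linear model with
#' bootstrap ([norm_boot_impute()]). The week is drawn once per subject and
#' shared by all `m` imputations.
#'
#' @param window inclusive integer weeks of the imputation window.
#' @param m number of imputations (>= 2).
#' @param iterations iteration count kept for API fidelity with
#'   chained-equations software; for this single-block univariate imputation
#'   it is a no-op and is recorded, not looped over.
#' @param predictors covariates of the normal linear model, drawn from
#'   `"week"` (gestational age of the assigned or observed first-trimester
#'   visit), `"n_visits"` (the subject's number of antenatal visits),
#'   `"prepreg_weight"` and `"height"`. The default includes pre-pregnancy
#'   weight: the response is the weight at the assigned week, and without a
#'   subject-level weight covariate the imputed weights scatter with the
#'   between-subject SD (~8 kg), putting the derived GWG far outside the
#'   observed first-trimester envelope.
#' @param categories BMI categories whose subjects are imputed (default:
#'   underweight and overweight, the categories whose sparse first trimester
#'   needs completion).
#' @param method `"norm_boot"` or the predictive-mean-matching comparator
#'   `"pmm"`.
#' @param pmm_k donor pool size for `"pmm"`.
#' @param seed integer seed for the assignment and the imputation draws.
#' @return list of class `"imputation_spec"`.
#' @export
imputation_spec <- function(window = 5:13, m = 5L, iterations = 50L,
                            predictors = c("week", "n_visits", "prepreg_weight"),
                            categories = c("underweight", "overweight"),
                            method = c("norm_boot", "pmm"), pmm_k = 5L,
                            seed = 1L) {
  method <- match.arg(method)
  stopifnot(m >= 2L, length(window) >= 1L, all(window >= 0L & window <= 13L),
            length(predictors) >= 1L)
  structure(list(window = as.integer(window), m = as.integer(m),
                 iterations = as.integer(iterations), predictors = predictors,
                 categories = categories, method = method,
                 pmm_k = as.integer(pmm_k), seed = as.integer(seed)),
            class = "imputation_spec")
}

#' Subjects lacking any first-trimester weight record
#' @param visits visit table with `subject_id`, `ga_weeks`.
#' @param window inclusive integer weeks (default 5-13).
#' @return character vector of subject ids with zero visits in the window.
#' @export
find_missing_first_trimester <- function(visits, window = 5:13) {
  ids <- unique(visits$subject_id)
  has <- unique(visits$subject_id[visits$ga_weeks %in% window])
  setdiff(ids, has)
}

#' Assign a random first-trimester week per subject
#' @param subject_ids subjects to assign.
#' @param window inclusive integer weeks to draw from, uniformly.
#' @param seed optional integer seed.
#' @return named integer vector, one week per subject.
#' @export
assign_random_week <- function(subject_ids, window = 5:13, seed = NULL) {
  stopifnot(length(window) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  wk <- window[sample.int(length(window), length(subject_ids), replace = TRUE)]
  stats::setNames(as.integer(wk), subject_ids)
}

#' Univariate imputation under the normal linear model with bootstrap
#'
#' For each of the `m` imputations: draw a bootstrap sample of the complete
#' cases, take the least-squares coefficients and residual SD from the
#' refitted linear model (this propagates sampling variability into the
#' parameters), and impute `X_mis %*% beta* + Normal(0, sigma*^2)` noise.
#' When the bootstrap design matrix is rank deficient the sample is redrawn
#' (up to `max_redraws` times).
#'
#' @param X_obs numeric matrix/data.frame of complete-case predictors
#'   (no intercept column; one is added).
#' @param y_obs observed responses.
#' @param X_mis predictors of the cases to impute.
#' @param m number of imputations.
#' @param seed optional integer seed.
#' @param max_redraws redraw limit on rank deficiency.
#' @return numeric matrix, `nrow(X_mis)` rows by `m` columns.
#' @export
norm_boot_impute <- function(X_obs, y_obs, X_mis, m = 5L, seed = NULL,
                             max_redraws = 100L) {
  X_obs <- cbind(1, as.matrix(X_obs)); X_mis <- cbind(1, as.matrix(X_mis))
  y_obs <- as.numeric(y_obs)   # force before touching the RNG state
  n <- nrow(X_obs); p <- ncol(X_obs)
  if (n <= p + 1L) stop("too few complete cases for the normal linear model")
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_real_, nrow(X_mis), m)
  for (k in seq_len(m)) {
    fit <- NULL
    for (try in seq_len(max_redraws)) {
      idx <- sample.int(n, n, replace = TRUE)
      f <- stats::lm.fit(X_obs[idx, , drop = FALSE], y_obs[idx])
      if (f$rank == p) { fit <- f; break }
    }
    if (is.null(fit)) stop("persistent rank deficiency in bootstrap samples")
    sigma <- sqrt(sum(fit$residuals^2) / (n - p))
    out[, k] <- drop(X_mis %*% fit$coefficients) +
      stats::rnorm(nrow(X_mis), 0, sigma)
  }
  out
}

#' Predictive-mean-matching comparator imputation
#'
#' Fits least squares on the complete cases, finds for each target the `k`
#' complete cases with the closest predicted means, and imputes the observed
#' response of a donor drawn uniformly among them. Provided as the optional
#' comparator in the imputation-method comparison workflow.
#'
#' @inheritParams norm_boot_impute
#' @param k donor pool size.
#' @return numeric matrix, `nrow(X_mis)` rows by `m` columns.
#' @export
pmm_impute <- function(X_obs, y_obs, X_mis, m = 5L, k = 5L, seed = NULL) {
  X_obs <- cbind(1, as.matrix(X_obs)); X_mis <- cbind(1, as.matrix(X_mis))
  if (!is.null(seed)) set.seed(seed)
  f <- stats::lm.fit(X_obs, y_obs)
  if (f$rank < ncol(X_obs)) stop("rank-deficient design")
  mu_obs <- drop(X_obs %*% f$coefficients)
  mu_mis <- drop(X_mis %*% f$coefficients)
  out <- matrix(NA_real_, nrow(X_mis), m)
  for (j in seq_len(nrow(X_mis))) {
    pool <- order(abs(mu_obs - mu_mis[j]))[seq_len(min(k, length(mu_obs)))]
    out[j, ] <- y_obs[pool[sample.int(length(pool), m, replace = TRUE)]]
  }
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' `Qbar = mean(Q)`; within-imputation variance `Ubar = mean(U)`;
#' between-imputation variance `B = var(Q)` (sample variance); total
#' `T = Ubar + (1 + 1/m) B`; degrees of freedom
#' `df = (m - 1) (1 + Ubar / ((1 + 1/m) B))^2`, infinite when `B = 0`.
#'
#' @param Q point estimates from the `m` completed datasets.
#' @param U their within-imputation variances (>= 0).
#' @return list of class `"pooled_estimate"`: `Qbar`, `Ubar`, `B`, `T`,
#'   `df`, `m`.
#' @examples
#' rubin_pool(c(1, 2, 3), c(1, 1, 1))
#' @export
rubin_pool <- function(Q, U) {
  m <- length(Q)
  if (m < 2L) stop("Rubin pooling needs m >= 2")
  stopifnot(length(U) == m, all(U >= 0))
  Qbar <- mean(Q); Ubar <- mean(U); B <- stats::var(Q)
  Tv <- Ubar + (1 + 1 / m) * B
  df <- if (B == 0) Inf else (m - 1) * (1 + Ubar / ((1 + 1 / m) * B))^2
  structure(list(Qbar = Qbar, Ubar = Ubar, B = B, T = Tv, df = df, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Rubin-pooled estimate (m = %d): Qbar = %.4g, Ubar = %.4g, B = %.4g, T = %.4g, df = %.3g\n",
              x$m, x$Qbar, x$Ubar, x$B, x$T, x$df))
  invisible(x)
}

#' First-trimester imputation pipeline
#'
#' Applies, per toggled BMI category, the random-week assignment and the
#' chosen univariate imputer to every subject with no observed weight in the
#' window, producing `m` completed visit tables. The response modelled is
#' the weight (kg) at the first-trimester visit; the complete cases are the
#' subjects of the same category that do have a window visit (their earliest
#' one). Cumulative GWG for imputed rows is derived from the imputed weight,
#' never imputed directly. Observed rows are identical across the `m`
#' completed datasets.
#'
#' @param subjects cleaned subject table with a `bmi_category` column
#'   (see [derive_bmi_category()]).
#' @param visits cleaned visit table (`subject_id`, `ga_weeks`, `weight_kg`,
#'   `gwg_kg`).
#' @param spec an [imputation_spec()].
#' @return list of class `"imputation_result"`: `completed` (list of `m`
#'   visit tables with `imputed` and `imputation` columns), `assigned_weeks`,
#'   and `diagnostics` (per-category subjects, missing count and fraction).
#' @export
impute_pipeline <- function(subjects, visits, spec = imputation_spec()) {
  stopifnot(inherits(spec, "imputation_spec"))
  if (!"bmi_category" %in% names(subjects))
    stop("subjects need a bmi_category column; see derive_bmi_category()")
  if (!"gwg_kg" %in% names(visits)) {
    pw <- subjects$prepreg_weight_kg[match(visits$subject_id, subjects$subject_id)]
    visits$gwg_kg <- visits$weight_kg - pw
  }
  set.seed(spec$seed)
  n_visits <- table(visits$subject_id)

  diag_rows <- list(); assigned_all <- integer(0)
  imp_rows <- vector("list", length(spec$categories))
  names(imp_rows) <- spec$categories

  for (cat in levels(factor(subjects$bmi_category))) {
    ids <- subjects$subject_id[subjects$bmi_category == cat]
    vis_c <- visits[visits$subject_id %in% ids, , drop = FALSE]
    missing_ids <- find_missing_first_trimester(vis_c, spec$window)
    diag_rows[[cat]] <- data.frame(
      bmi_category = cat, n_subjects = length(ids),
      n_missing_first_trimester = length(missing_ids),
      missing_fraction = if (length(ids)) length(missing_ids) / length(ids) else NA_real_,
      imputed = cat %in% spec$categories)
    if (!(cat %in% spec$categories)) next

    win <- vis_c[vis_c$ga_weeks %in% spec$window, , drop = FALSE]
    win <- win[order(win$subject_id, win$ga_weeks), , drop = FALSE]
    first_win <- win[!duplicated(win$subject_id), , drop = FALSE]
    if (nrow(first_win) == 0L)
      stop(sprintf("category '%s' is toggled on but has no complete cases", cat))
    if (length(missing_ids) == 0L) next

    assigned <- assign_random_week(missing_ids, spec$window)
    assigned_all <- c(assigned_all, assigned)
    X_obs <- build_predictors(spec$predictors, first_win$subject_id,
                              first_win$ga_weeks, n_visits, subjects)
    X_mis <- build_predictors(spec$predictors, missing_ids,
                              as.integer(assigned), n_visits, subjects)
    y_obs <- first_win$weight_kg
    imp <- switch(spec$method,
                  norm_boot = norm_boot_impute(X_obs, y_obs, X_mis, m = spec$m),
                  pmm = pmm_impute(X_obs, y_obs, X_mis, m = spec$m, k = spec$pmm_k))
    pw <- subjects$prepreg_weight_kg[match(missing_ids, subjects$subject_id)]
    site <- if ("site" %in% names(visits))
      visits$site[match(missing_ids, visits$subject_id)] else NA_character_
    imp_rows[[cat]] <- lapply(seq_len(spec$m), function(k) {
      df <- data.frame(subject_id = missing_ids, site = site,
                       ga_weeks = as.integer(assigned),
                       weight_kg = imp[, k], gwg_kg = imp[, k] - pw,
                       stringsAsFactors = FALSE)
      df
    })
  }

  visits$imputed <- FALSE
  completed <- lapply(seq_len(spec$m), function(k) {
    add <- do.call(rbind, lapply(imp_rows[!vapply(imp_rows, is.null, TRUE)],
                                 function(l) l[[k]]))
    if (is.null(add) || nrow(add) == 0L) {
      out <- visits
    } else {
      add$imputed <- TRUE
      for (col in setdiff(names(visits), names(add)))
        add[[col]] <- if (col == "qc_flag") "ok" else NA
      out <- rbind(visits, add[names(visits)])
    }
    out$imputation <- k
    rownames(out) <- NULL
    out
  })

  structure(list(completed = completed,
                 assigned_weeks = assigned_all,
                 diagnostics = do.call(rbind, c(diag_rows, list(make.row.names = FALSE))),
                 spec = spec),
            class = "imputation_result")
}

build_predictors <- function(predictors, ids, week, n_visits, subjects) {
  sm <- match(ids, subjects$subject_id)
  cols <- lapply(predictors, function(p) switch(
    p,
    week = as.numeric(week),
    n_visits = as.numeric(n_visits[ids]),
    prepreg_weight = subjects$prepreg_weight_kg[sm],
    height = subjects$height_cm[sm],
    stop(sprintf("unknown imputation predictor '%s'", p))))
  X <- do.call(cbind, cols)
  colnames(X) <- predictors
  X
}

#' Derive the BMI-for-age category column for a subject table
#'
#' Uses an existing `bmi_zscore` column if present; otherwise computes the
#' BMI-for-age z-score from `prepreg_bmi`, `maternal_age_years` and a
#' user-supplied LMS reference table.
#'
#' @param subjects subject table.
#' @param bmi_reference optional [lms_table()] for BMI-for-age.
#' @return `subjects` with a `bmi_category` factor column.
#' @export
derive_bmi_category <- function(subjects, bmi_reference = NULL) {
  if (!"bmi_zscore" %in% names(subjects)) {
    if (is.null(bmi_reference))
      stop("no bmi_zscore column: supply a BMI-for-age LMS reference table")
    subjects$bmi_zscore <- lms_zscore(subjects$prepreg_bmi,
                                      subjects$maternal_age_years, bmi_reference)
  }
  subjects$bmi_category <- classify_bmi_category(subjects$bmi_zscore)
  subjects
}
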