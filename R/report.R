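#' Descriptive median/IQR tables
#'
#' Medians and interquartile ranges (25th-75th percentiles, linear
#' interpolation convention, `stats::quantile` type 7) of the subject-level
#' variables of interest, by arbitrary grouping keys (site, BMI category,
#' ...). "Third-trimester weight" is the last observed weight in weeks 28-42
#' (switchable to the maximum).
#'
#' @param subjects cleaned subject table.
#' @param visits cleaned visit table.
#' @param by character vector of grouping columns of `subjects`
#'   (may be empty for an overall table).
#' @param variables subject-level variables to summarize; defaults to
#'   maternal age, pre-pregnancy BMI, height, pre-pregnancy weight,
#'   third-trimester weight, birth weight and gestational age at birth.
#' @param third_trimester `"last"` or `"max"` weight in weeks 28-42.
#' @return data.frame with one row per group and variable: grouping keys,
#'   `variable`, `n`, `median`, `q25`, `q75`.
#' @export
describe_cohort <- function(subjects, visits, by = "site",
                            variables = c("maternal_age_years", "prepreg_bmi",
                                          "height_cm", "prepreg_weight_kg",
                                          "third_trimester_weight_kg",
                                          "birth_weight_g", "ga_at_birth_weeks"),
                            third_trimester = c("last", "max")) {
  third_trimester <- match.arg(third_trimester)
  if ("third_trimester_weight_kg" %in% variables &&
      !"third_trimester_weight_kg" %in% names(subjects)) {
    v3 <- visits[visits$ga_weeks >= 28 & visits$ga_weeks <= 42, , drop = FALSE]
    v3 <- v3[order(v3$subject_id, v3$ga_weeks), , drop = FALSE]
    w3 <- if (third_trimester == "last")
      tapply(v3$weight_kg, v3$subject_id, function(x) x[length(x)])
    else tapply(v3$weight_kg, v3$subject_id, max)
    subjects$third_trimester_weight_kg <-
      as.numeric(w3[subjects$subject_id])
  }
  groups <- if (length(by)) split(subjects, subjects[by], drop = FALSE)
  else list(overall = subjects)
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    per_var <- lapply(variables, function(v) {
      x <- d[[v]]
      x <- x[!is.na(x)]
      if (length(x) == 0L)
        return(data.frame(variable = v, n = 0L, median = NA_real_,
                          q25 = NA_real_, q75 = NA_real_))
      qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(variable = v, n = length(x), median = qs[2L],
                 q25 = qs[1L], q75 = qs[3L])
    })
    out <- do.call(rbind, per_var)
    if (length(by)) {
      keys <- if (nrow(d)) d[1L, by, drop = FALSE]
      else stats::setNames(as.data.frame(as.list(strsplit(g, "\\.")[[1L]])), by)
      rownames(keys) <- NULL
      out <- cbind(keys[rep(1L, nrow(out)), , drop = FALSE], out)
    } else out <- cbind(group = g, out)
    rownames(out) <- NULL
    out
  })
  do.call(rbind, rows)
}

#' Configuration for the end-to-end pipeline
#'
#' @param cohort a [cohort_config()] for the synthetic generator, or `NULL`
#'   when reading input files.
#' @param input_dir directory with `subjects.csv` / `visits.csv` when
#'   `cohort` is `NULL`.
#' @param harmonization a [harmonization_options()].
#' @param ssd_min_n site-size threshold of the SSD sensitivity analysis.
#' @param imputation an [imputation_spec()], or `NULL` to skip imputation.
#' @param centile_shift positive-support shift (kg) for centile fitting.
#' @param centile_df degrees of freedom of the centile fit.
#' @param centile_grid gestational-age grid of the emitted curve tables.
#' @param centiles centile probabilities of the emitted curve tables.
#' @param fit_centiles logical; fit centile curves per BMI category.
#' @param min_fit_n minimum visits for a category to be fitted.
#' @param seed master seed for the run.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort = cohort_config(), input_dir = NULL,
                            harmonization = harmonization_options(),
                            ssd_min_n = 10L,
                            imputation = imputation_spec(),
                            centile_shift = 10,
                            centile_df = c(mu = 3, sigma = 2, nu = 1),
                            centile_grid = 5:42,
                            centiles = c(0.03, 0.10, 0.25, 0.50, 0.75, 0.90, 0.97),
                            fit_centiles = TRUE, min_fit_n = 200L,
                            seed = 1L) {
  structure(list(cohort = cohort, input_dir = input_dir,
                 harmonization = harmonization, ssd_min_n = ssd_min_n,
                 imputation = imputation, centile_shift = centile_shift,
                 centile_df = centile_df, centile_grid = centile_grid,
                 centiles = centiles, fit_centiles = fit_centiles,
                 min_fit_n = min_fit_n, seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full chart-construction pipeline
#'
#' Executes simulate/load -> clean -> describe -> SSD (+ sensitivity) ->
#' impute -> fit-centiles, writing every artifact as delimited text into
#' `out_dir` and finishing with a manifest (file name, MD5 hash). Identical
#' config and seed give byte-identical artifacts and manifest. Each stage
#' logs a one-line summary to `stderr`; any stage failure aborts with the
#' stage name.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest data.frame.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }

  data <- pipeline_stage("simulate", {
    if (!is.null(config$cohort)) {
      cfg <- config$cohort
      cfg$seed <- as.integer((as.numeric(config$seed) * 1000003 + cfg$seed) %% 2147483647)
      coh <- generate_cohort(cfg)
      say("simulate: %d subjects, %d visits", nrow(coh$subjects), nrow(coh$visits))
      coh
    } else {
      coh <- read_cohort(config$input_dir)
      say("load: %d subjects, %d visits", nrow(coh$subjects), nrow(coh$visits))
      coh
    }
  })
  emit(data$subjects, "subjects_raw.csv")
  emit(data$visits, "visits_raw.csv")

  clean <- pipeline_stage("clean", {
    res <- apply_eligibility(data$subjects, data$visits, config$harmonization)
    say("clean: %d subjects, %d visits kept", nrow(res$subjects), nrow(res$visits))
    res
  })
  write_ledger(clean$ledger, file.path(out_dir, "exclusion_ledger.csv"))
  written <- c(written, file.path(out_dir, "exclusion_ledger.csv"))
  subjects <- pipeline_stage("clean", derive_bmi_category(clean$subjects))
  visits <- clean$visits
  visits$bmi_category <- as.character(
    subjects$bmi_category[match(visits$subject_id, subjects$subject_id)])
  emit(subjects, "subjects_clean.csv")
  emit(visits, "visits_clean.csv")

  desc <- pipeline_stage("describe", {
    if (!"maternal_age_years" %in% names(subjects))
      stop("maternal_age_years missing after cleaning")
    describe_cohort(subjects, visits, by = "site")
  })
  emit(desc, "descriptives_by_site.csv")
  emit(describe_cohort(subjects, visits, by = "bmi_category"),
       "descriptives_by_bmi_category.csv")

  ssd <- pipeline_stage("ssd", {
    vis <- visits
    vis$ga_bin <- as.character(assign_ga_bin(vis$ga_weeks))
    gwg_cells <- ssd_by_cell(vis, "gwg_kg", by = c("bmi_category", "ga_bin"))
    subj <- subjects
    subj$age_years <- subjects$maternal_age_years
    haz_cells <- ssd_by_cell(subj, "haz", by = c("bmi_category", "age_years"))
    sens <- sensitivity_filter(vis, "gwg_kg", by = c("bmi_category", "ga_bin"),
                               min_n = config$ssd_min_n)
    say("ssd: %d GWG cells, %.1f%% homogeneous", nrow(gwg_cells),
        100 * mean(gwg_cells$verdict == "homogeneous"))
    list(gwg = gwg_cells, haz = haz_cells, sens = sens)
  })
  emit(ssd$gwg, "ssd_gwg.csv")
  emit(ssd$haz, "ssd_haz.csv")
  emit(ssd$sens, "ssd_gwg_sensitivity.csv")

  completed <- list(visits)
  if (!is.null(config$imputation)) {
    impres <- pipeline_stage("impute", {
      spec <- config$imputation
      spec$seed <- as.integer((as.numeric(config$seed) * 7919 + spec$seed) %% 2147483647)
      r <- impute_pipeline(subjects, visits, spec)
      r$completed <- lapply(r$completed, function(v) {
        v$bmi_category <- as.character(
          subjects$bmi_category[match(v$subject_id, subjects$subject_id)])
        v
      })
      say("impute: %s", paste(sprintf("%s %.1f%%", r$diagnostics$bmi_category,
                                      100 * r$diagnostics$missing_fraction),
                              collapse = ", "))
      r
    })
    emit(impres$diagnostics, "imputation_diagnostics.csv")
    for (k in seq_along(impres$completed))
      emit(impres$completed[[k]], sprintf("visits_imp%d.csv", k))
    completed <- impres$completed
    pooled <- pipeline_stage("impute", {
      win <- config$imputation$window
      per_cat <- lapply(split_first_trimester_means(completed, win), function(qu)
        rubin_pool(qu$Q, qu$U))
      df <- do.call(rbind, lapply(names(per_cat), function(cat) {
        p <- per_cat[[cat]]
        data.frame(bmi_category = cat, Qbar = p$Qbar, Ubar = p$Ubar,
                   B = p$B, T = p$T, df = p$df)
      }))
      df
    })
    emit(pooled, "pooled_first_trimester_gwg.csv")
  }

  if (config$fit_centiles) {
    cent <- pipeline_stage("fit-centiles", {
      out <- list()
      for (cat in bmi_category_levels()) {
        tabs <- lapply(completed, function(v) {
          d <- v[v$bmi_category == cat & !is.na(v$gwg_kg), , drop = FALSE]
          d <- d[d$gwg_kg + config$centile_shift > 0, , drop = FALSE]
          if (nrow(d) < config$min_fit_n) return(NULL)
          fit <- fit_gwg_centiles(d$ga_weeks, d$gwg_kg,
                                  shift = config$centile_shift,
                                  df = config$centile_df)
          evaluate_centiles(fit, config$centile_grid, config$centiles)
        })
        tabs <- tabs[!vapply(tabs, is.null, TRUE)]
        if (length(tabs)) out[[cat]] <- pool_centile_curves(tabs)
      }
      say("fit-centiles: %s", paste(names(out), collapse = ", "))
      out
    })
    for (cat in names(cent))
      emit(cent[[cat]], sprintf("centiles_%s.csv", cat))
  }

  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  say("done: %d artifacts in %s", nrow(manifest), out_dir)
  invisible(manifest)
}

# Q/U of mean first-trimester GWG per completed dataset, split by category
split_first_trimester_means <- function(completed, window) {
  cats <- sort(unique(unlist(lapply(completed, function(v)
    unique(v$bmi_category[v$ga_weeks %in% window])))))
  out <- list()
  for (cat in cats) {
    Q <- U <- numeric(length(completed))
    ok <- TRUE
    for (k in seq_along(completed)) {
      v <- completed[[k]]
      x <- v$gwg_kg[v$bmi_category == cat & v$ga_weeks %in% window & !is.na(v$gwg_kg)]
      if (length(x) < 2L) { ok <- FALSE; break }
      Q[k] <- mean(x); U[k] <- stats::var(x) / length(x)
    }
    if (ok) out[[cat]] <- list(Q = Q, U = U)
  }
  out
}
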