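#' Gestational-age bin scheme for the heterogeneity assessment
#'
#' Default bins: 0-7, 8-14, 15-21, 22-28, 29-35, 36-42 completed weeks
#' (inclusive, disjoint, exhaustive over 0-42).
#'
#' @param lower,upper integer vectors of inclusive bin edges.
#' @return list of class `"ga_bin_scheme"` with `lower`, `upper`, `labels`.
#' @export
ga_bin_scheme <- function(lower = c(0L, 8L, 15L, 22L, 29L, 36L),
                          upper = c(7L, 14L, 21L, 28L, 35L, 42L)) {
  stopifnot(length(lower) == length(upper), all(lower <= upper))
  if (any(lower[-1L] != utils::head(upper, -1L) + 1L))
    stop("bins must be disjoint and exhaustive")
  structure(list(lower = as.integer(lower), upper = as.integer(upper),
                 labels = sprintf("%d-%d", lower, upper)),
            class = "ga_bin_scheme")
}

#' Assign gestational ages to bins
#' @param ga_weeks completed gestational weeks, within `[min(lower), max(upper)]`.
#' @param scheme a [ga_bin_scheme()].
#' @return factor of bin labels.
#' @export
assign_ga_bin <- function(ga_weeks, scheme = ga_bin_scheme()) {
  if (any(ga_weeks < scheme$lower[1L] | ga_weeks > scheme$upper[length(scheme$upper)]))
    stop("gestational age outside the bin scheme range")
  idx <- findInterval(ga_weeks, scheme$lower)
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Standardized Site Differences within one cell
#'
#' For one stratum (e.g. a BMI-category by gestational-age-bin cell), each
#' site's mean is standardized against the pooled mean and pooled sample SD
#' of all individual observations in the cell:
#' `ssd = (site_mean - pooled_mean) / pooled_sd`. Sites with `|ssd| <= 0.5`
#' are judged homogeneous (combinable into a single dataset).
#'
#' @param values numeric observations in the cell.
#' @param sites site label per observation.
#' @return data.frame with one row per site: `site`, `n_site`, `site_mean`,
#'   `pooled_mean`, `pooled_sd`, `ssd`, `verdict`, `included_in_sensitivity`.
#' @examples
#' compute_ssd(c(1, 2, 3, 3, 4, 5), rep(c("A", "B"), each = 3))
#' @export
compute_ssd <- function(values, sites) {
  stopifnot(length(values) == length(sites), length(values) >= 2L)
  if (any(!is.finite(values))) stop("non-finite values")
  pooled_mean <- mean(values)
  pooled_sd <- stats::sd(values)          # sample SD, n - 1 denominator
  site_mean <- tapply(values, sites, mean)
  n_site <- tapply(values, sites, length)
  if (pooled_sd == 0) {
    if (length(unique(site_mean)) > 1L)
      stop("pooled SD is zero while site means differ")
    ssd <- rep(0, length(site_mean))
  } else {
    ssd <- (site_mean - pooled_mean) / pooled_sd
  }
  data.frame(site = names(site_mean), n_site = as.integer(n_site),
             site_mean = as.numeric(site_mean), pooled_mean = pooled_mean,
             pooled_sd = pooled_sd, ssd = as.numeric(ssd),
             verdict = ifelse(abs(ssd) <= 0.5, "homogeneous", "heterogeneous"),
             included_in_sensitivity = TRUE, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' SSD table over strata
#'
#' Runs [compute_ssd()] within every combination of the grouping columns
#' (e.g. BMI category by gestational-age bin) and stacks the per-site rows.
#'
#' @param data data.frame holding the observations.
#' @param value_col column with the measurement (e.g. `gwg_kg` or `haz`).
#' @param site_col column with the site label.
#' @param by character vector of stratifying columns (may be empty).
#' @return data.frame of SSD cells with the `by` columns prepended.
#' @export
ssd_by_cell <- function(data, value_col, site_col = "site", by = character(0)) {
  groups <- if (length(by)) split(data, data[by], drop = TRUE) else list(all = data)
  out <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    d <- d[is.finite(d[[value_col]]), , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    cells <- compute_ssd(d[[value_col]], d[[site_col]])
    if (length(by)) {
      keys <- d[1L, by, drop = FALSE]
      rownames(keys) <- NULL
      cells <- cbind(keys[rep(1L, nrow(cells)), , drop = FALSE], cells)
      rownames(cells) <- NULL
    }
    cells
  })
  do.call(rbind, out)
}

#' Small-cell sensitivity analysis
#'
#' Drops sites contributing fewer than `min_n` observations to a cell and
#' recomputes the pooled statistics and SSDs from the remaining observations;
#' dropped sites are kept in the output with `included_in_sensitivity =
#' FALSE` and `ssd = NA`. A cell whose sites are all dropped is returned
#' empty (no retained rows), not as an error.
#'
#' @inheritParams ssd_by_cell
#' @param min_n minimum site size retained in a cell (default 10; a site is
#'   dropped when `n_site < min_n`).
#' @return data.frame in the layout of [ssd_by_cell()].
#' @export
sensitivity_filter <- function(data, value_col, site_col = "site",
                               by = character(0), min_n = 10L) {
  stopifnot(min_n >= 1L)
  groups <- if (length(by)) split(data, data[by], drop = TRUE) else list(all = data)
  out <- lapply(groups, function(d) {
    d <- d[is.finite(d[[value_col]]), , drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    n_site <- table(d[[site_col]])
    small <- names(n_site)[n_site < min_n]
    kept <- d[!(d[[site_col]] %in% small), , drop = FALSE]
    cells <- if (nrow(kept) >= 2L) compute_ssd(kept[[value_col]], kept[[site_col]]) else NULL
    if (length(small)) {
      dropped <- data.frame(site = small,
                            n_site = as.integer(n_site[small]),
                            site_mean = as.numeric(tapply(d[[value_col]], d[[site_col]], mean)[small]),
                            pooled_mean = NA_real_, pooled_sd = NA_real_,
                            ssd = NA_real_, verdict = NA_character_,
                            included_in_sensitivity = FALSE,
                            stringsAsFactors = FALSE)
      cells <- rbind(cells, dropped)
    }
    if (is.null(cells)) return(NULL)
    if (length(by)) {
      keys <- d[1L, by, drop = FALSE]
      rownames(keys) <- NULL
      cells <- cbind(keys[rep(1L, nrow(cells)), , drop = FALSE], cells)
    }
    rownames(cells) <- NULL
    cells
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cohen-style magnitude label for a standardized difference
#'
#' `|ssd| < 0.2` is small, `0.2 <= |ssd| < 0.8` acceptable, `|ssd| >= 0.8`
#' large (half-open bands; the boundary conventions are a package choice).
#'
#' @param ssd finite standardized site difference(s).
#' @return factor with levels small, acceptable, large.
#' @export
cohen_magnitude <- function(ssd) {
  if (any(!is.finite(ssd))) stop("non-finite ssd")
  a <- abs(ssd)
  factor(ifelse(a < 0.2, "small", ifelse(a < 0.8, "acceptable", "large")),
         levels = c("small", "acceptable", "large"))
}

#' Dot plot of SSD values by site (one panel row per stratum)
#'
#' Minimal base-graphics analogue of the usual SSD dot plots, with reference
#' lines at +/-0.5.
#'
#' @param cells output of [ssd_by_cell()].
#' @param main plot title.
#' @return invisibly, `cells`.
#' @export
plot_ssd <- function(cells, main = "Standardized site differences") {
  ok <- is.finite(cells$ssd)
  y <- seq_len(sum(ok))
  graphics::plot(cells$ssd[ok], y, xlim = range(c(-1, 1, cells$ssd[ok])),
                 pch = 19, xlab = "SSD (SD units)", ylab = "", yaxt = "n",
                 main = main)
  graphics::abline(v = c(-0.5, 0.5), lty = 2)
  graphics::axis(2, at = y, labels = cells$site[ok], las = 1, cex.axis = 0.6)
  invisible(cells)
}
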