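#' LMS growth-reference tables
#'
#' An LMS reference table stores, for a grid of ages, the three parameters of
#' the LMS method: the Box-Cox power `L`, the median `M` (in measurement
#' units) and the coefficient of variation `S`. Together they define the
#' age-conditional distribution of a measurement, and hence z-scores such as
#' height-for-age or BMI-for-age.
#'
#' @param age numeric vector of ages, strictly increasing.
#' @param L,M,S numeric vectors of LMS parameters, recycled to `length(age)`.
#'   `M` and `S` must be strictly positive.
#' @param indicator label for the measurement the table refers to
#'   (e.g. `"height_for_age"`).
#' @param sex optional sex label; the pipeline concerns pregnant adolescents,
#'   so `"female"` is the default.
#' @param age_unit `"years"` or `"months"`.
#' @return A `data.frame` with columns `age`, `L`, `M`, `S` and class
#'   `"lms_table"`; `indicator`, `sex` and `age_unit` are kept as attributes.
#' @examples
#' tab <- lms_table(10:19, L = 1, M = 160, S = 0.05)
#' lms_zscore(168, 12, tab)
#' @export
lms_table <- function(age, L, M, S, indicator = "measurement",
                      sex = "female", age_unit = c("years", "months")) {
  age_unit <- match.arg(age_unit)
  n <- length(age)
  if (n < 1L) stop("`age` must have at least one row")
  if (is.unsorted(age, strictly = TRUE)) stop("`age` must be strictly increasing")
  tab <- data.frame(age = as.numeric(age), L = rep_len(as.numeric(L), n),
                    M = rep_len(as.numeric(M), n), S = rep_len(as.numeric(S), n))
  if (any(!is.finite(tab$L))) stop("non-finite L")
  if (any(!is.finite(tab$M)) || any(tab$M <= 0)) stop("M must be positive")
  if (any(!is.finite(tab$S)) || any(tab$S <= 0)) stop("S must be positive")
  structure(tab, indicator = indicator, sex = sex, age_unit = age_unit,
            class = c("lms_table", "data.frame"))
}

#' Build an LMS reference table from parameter curves
#'
#' Convenience constructor used mainly by the synthetic-data machinery: the
#' L, M and S curves may be given either as numeric vectors on `age_grid` or
#' as functions of age.
#'
#' @param age_grid numeric grid of ages, strictly increasing.
#' @param L_curve,M_curve,S_curve numeric vectors (recycled) or functions of
#'   age returning the respective parameter.
#' @inheritParams lms_table
#' @return An [lms_table()].
#' @export
generate_reference_table <- function(age_grid, L_curve, M_curve, S_curve,
                                     indicator = "measurement", sex = "female",
                                     age_unit = c("years", "months")) {
  ev <- function(curve) if (is.function(curve)) curve(age_grid) else curve
  lms_table(age_grid, ev(L_curve), ev(M_curve), ev(S_curve),
            indicator = indicator, sex = sex, age_unit = match.arg(age_unit))
}

# Linear interpolation of L, M, S at `age`; error outside the table range.
lms_interpolate <- function(table, age) {
  stopifnot(inherits(table, "lms_table"))
  if (any(!is.finite(age))) stop("non-finite age")
  rng <- range(table$age)
  if (any(age < rng[1] | age > rng[2]))
    stop(sprintf("age outside reference table range [%g, %g]", rng[1], rng[2]))
  list(L = stats::approx(table$age, table$L, xout = age)$y,
       M = stats::approx(table$age, table$M, xout = age)$y,
       S = stats::approx(table$age, table$S, xout = age)$y)
}

#' LMS z-score of a measurement
#'
#' Computes `z = ((value/M)^L - 1) / (L * S)`, with the continuous limit
#' `z = log(value/M) / S` as `L -> 0`. L, M and S are linearly interpolated
#' between adjacent table rows; ages outside the table range are an error,
#' never an extrapolation.
#'
#' @param value positive measurement, in the units of the table's `M`.
#' @param age age in the table's `age_unit`.
#' @param table an [lms_table()].
#' @return z-score(s) in SD units. Vectorized over `value` and `age`.
#' @export
lms_zscore <- function(value, age, table) {
  if (any(!is.finite(value)) || any(value <= 0)) stop("`value` must be positive and finite")
  n <- max(length(value), length(age))
  value <- rep_len(value, n); age <- rep_len(age, n)
  p <- lms_interpolate(table, age)
  ifelse(abs(p$L) < 1e-7,
         log(value / p$M) / p$S,
         ((value / p$M)^p$L - 1) / (p$L * p$S))
}

#' Measurement value at a given z-score (inverse of [lms_zscore()])
#'
#' @param z z-score in SD units.
#' @inheritParams lms_zscore
#' @return measurement value(s).
#' @export
lms_value <- function(z, age, table) {
  if (any(!is.finite(z))) stop("non-finite z")
  n <- max(length(z), length(age))
  z <- rep_len(z, n); age <- rep_len(age, n)
  p <- lms_interpolate(table, age)
  ifelse(abs(p$L) < 1e-7,
         p$M * exp(p$S * z),
         p$M * (1 + p$L * p$S * z)^(1 / p$L))
}

#' WHO BMI-for-age category of an adolescent
#'
#' Applies the WHO BMI-for-age z-score bands: underweight below -2 SD, normal
#' weight from -2 SD to +1 SD (both boundaries inclusive), overweight above
#' +1 SD up to and including +2 SD, obesity above +2 SD.
#'
#' @param z finite BMI-for-age z-score(s).
#' @return factor with levels `underweight`, `normal`, `overweight`, `obesity`.
#' @export
classify_bmi_category <- function(z) {
  if (any(!is.finite(z))) stop("non-finite z")
  lv <- bmi_category_levels()
  out <- ifelse(z < -2, lv[1L], ifelse(z <= 1, lv[2L], ifelse(z <= 2, lv[3L], lv[4L])))
  factor(out, levels = lv)
}

bmi_category_levels <- function() c("underweight", "normal", "overweight", "obesity")

#' Stunting flag from a height-for-age z-score
#'
#' Stunting is defined as height-for-age strictly below -2 z of the growth
#' reference; exactly -2 is not stunted.
#'
#' @param haz finite height-for-age z-score(s).
#' @return logical vector.
#' @export
is_stunted <- function(haz) {
  if (any(!is.finite(haz))) stop("non-finite height-for-age z-score")
  haz < -2
}

#' Read / write an LMS reference table
#'
#' Tables are stored as comma-separated text with a header row
#' (`age,L,M,S`), in the layout of the WHO 2007 references. Metadata
#' (age unit, indicator, sex) travels in `#`-prefixed comment lines of the
#' form `# key: value`.
#'
#' @param path file path.
#' @return [read_lms_table()] returns an [lms_table()].
#' @export
read_lms_table <- function(path) {
  hdr <- readLines(path, n = 20L)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- list(indicator = "measurement", sex = "female", age_unit = "years")
  for (ln in hdr) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("age", "L", "M", "S")
  if (!all(need %in% names(df))) stop("reference table must have columns age, L, M, S")
  lms_table(df$age, df$L, df$M, df$S, indicator = meta$indicator,
            sex = meta$sex, age_unit = meta$age_unit)
}

#' @param table an [lms_table()] to write.
#' @rdname read_lms_table
#' @export
write_lms_table <- function(table, path) {
  stopifnot(inherits(table, "lms_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# indicator: %s", attr(table, "indicator")), con)
  writeLines(sprintf("# sex: %s", attr(table, "sex")), con)
  writeLines(sprintf("# age_unit: %s", attr(table, "age_unit")), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
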