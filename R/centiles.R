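#' The Box-Cox Cole-Green (BCCG/LMS) distribution
#'
#' The three-parameter distribution underlying the LMS method of growth-chart
#' construction: a measurement `y > 0` has `z = ((y/mu)^nu - 1)/(nu sigma)`
#' (log form for `nu = 0`) standard normal, truncated so that `y` stays
#' positive. `mu > 0` is the median, `sigma > 0` approximately the
#' coefficient of variation, and `nu` the Box-Cox skewness power. The usual
#' truncation convention is used: densities are normalized by
#' `pnorm(1/(sigma |nu|))`.
#'
#' @param x,q positive quantiles.
#' @param p probabilities in (0, 1).
#' @param n number of draws.
#' @param mu,sigma,nu distribution parameters (recycled).
#' @param log return the log density.
#' @return density, probability, quantile or random vectors.
#' @name bccg
NULL

bccg_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, n)
}

bccg_z <- function(x, mu, sigma, nu) {
  r <- bccg_recycle(x, mu, sigma, nu)
  with(stats::setNames(r, c("x", "mu", "sigma", "nu")),
       ifelse(abs(nu) < 1e-12, log(x / mu) / sigma,
              (exp(nu * log(x / mu)) - 1) / (nu * sigma)))
}

# log of the truncation normalizer Phi(1/(sigma|nu|)); 0 when nu == 0
bccg_lognorm <- function(sigma, nu) {
  cc <- 1 / (sigma * abs(nu))
  ifelse(is.finite(cc), stats::pnorm(cc, log.p = TRUE), 0)
}

#' @rdname bccg
#' @export
dbccg <- function(x, mu = 1, sigma = 0.1, nu = 1, log = FALSE) {
  stopifnot(all(mu > 0), all(sigma > 0))
  r <- bccg_recycle(x, mu, sigma, nu)
  x <- r[[1L]]; mu <- r[[2L]]; sigma <- r[[3L]]; nu <- r[[4L]]
  z <- bccg_z(x, mu, sigma, nu)
  ll <- (nu - 1) * base::log(x) - nu * base::log(mu) - base::log(sigma) -
    0.5 * z^2 - 0.5 * base::log(2 * pi) - bccg_lognorm(sigma, nu)
  ll[x <= 0] <- -Inf
  if (log) ll else exp(ll)
}

#' @rdname bccg
#' @export
pbccg <- function(q, mu = 1, sigma = 0.1, nu = 1) {
  stopifnot(all(mu > 0), all(sigma > 0))
  r <- bccg_recycle(q, mu, sigma, nu)
  q <- r[[1L]]; mu <- r[[2L]]; sigma <- r[[3L]]; nu <- r[[4L]]
  z <- bccg_z(q, mu, sigma, nu)
  lo <- ifelse(nu > 0, stats::pnorm(-1 / (sigma * abs(nu))), 0)
  p <- (stats::pnorm(z) - lo) / exp(bccg_lognorm(sigma, nu))
  pmin(pmax(p, 0), 1)
}

#' @rdname bccg
#' @export
qbccg <- function(p, mu = 1, sigma = 0.1, nu = 1) {
  stopifnot(all(p > 0), all(p < 1), all(mu > 0), all(sigma > 0))
  r <- bccg_recycle(p, mu, sigma, nu)
  p <- r[[1L]]; mu <- r[[2L]]; sigma <- r[[3L]]; nu <- r[[4L]]
  lo <- ifelse(nu > 0, stats::pnorm(-1 / (sigma * abs(nu))), 0)
  z <- stats::qnorm(p * exp(bccg_lognorm(sigma, nu)) + lo)
  ifelse(abs(nu) < 1e-12, mu * exp(sigma * z),
         mu * exp(log1p(pmax(nu * sigma * z, -1 + 1e-15)) / nu))
}

#' @rdname bccg
#' @export
rbccg <- function(n, mu = 1, sigma = 0.1, nu = 1) {
  qbccg(stats::runif(n), mu, sigma, nu)
}

# --- regression bases -------------------------------------------------------

# df = 1 -> intercept only; df > 1 -> intercept + B-spline with df - 1 terms
make_basis_spec <- function(t, df, degree = 3L) {
  df <- as.integer(df)
  stopifnot(df >= 1L)
  if (df == 1L) return(list(df = 1L))
  deg <- min(degree, df - 1L)
  B <- splines::bs(t, df = df - 1L, degree = deg)
  list(df = df, degree = deg, knots = attr(B, "knots"),
       boundary = attr(B, "Boundary.knots"))
}

eval_basis <- function(spec, t) {
  if (spec$df == 1L) return(matrix(1, length(t), 1L))
  t <- pmin(pmax(t, spec$boundary[1L]), spec$boundary[2L])
  cbind(1, splines::bs(t, knots = spec$knots, degree = spec$degree,
                       Boundary.knots = spec$boundary))
}

# --- likelihood and analytic gradient --------------------------------------

bccg_negll_parts <- function(par, blocks, B, logy, nu_fixed) {
  b <- relist_blocks(par, blocks)
  eta_mu <- drop(B$mu %*% b$mu)
  eta_sg <- pmin(pmax(drop(B$sigma %*% b$sigma), -15), 15)
  nu <- if (is.null(nu_fixed)) drop(B$nu %*% b$nu) else rep(nu_fixed, length(logy))
  sigma <- exp(eta_sg)
  s <- logy - eta_mu
  nus <- pmin(pmax(nu * s, -250), 250)
  w <- exp(nus)
  z <- ifelse(abs(nu) < 1e-8, s / sigma, (w - 1) / (nu * sigma))
  cc <- 1 / (sigma * abs(nu))
  lognorm <- ifelse(abs(nu) < 1e-12 | cc > 37, 0, stats::pnorm(cc, log.p = TRUE))
  ll <- (nu - 1) * logy - nu * eta_mu - eta_sg - 0.5 * z^2 -
    0.5 * log(2 * pi) - lognorm
  list(ll = ll, eta_mu = eta_mu, sigma = sigma, nu = nu, s = s, w = w, z = z,
       cc = cc)
}

relist_blocks <- function(par, blocks) {
  out <- list(); i <- 0L
  for (nm in names(blocks)) {
    out[[nm]] <- par[i + seq_len(blocks[[nm]])]
    i <- i + blocks[[nm]]
  }
  out
}

bccg_negll <- function(par, blocks, B, logy, nu_fixed) {
  p <- bccg_negll_parts(par, blocks, B, logy, nu_fixed)
  v <- -sum(p$ll)
  if (!is.finite(v)) 1e10 else v
}

bccg_negll_grad <- function(par, blocks, B, logy, nu_fixed) {
  p <- bccg_negll_parts(par, blocks, B, logy, nu_fixed)
  mills <- ifelse(p$cc > 37 | !is.finite(p$cc), 0,
                  exp(stats::dnorm(p$cc, log = TRUE) - stats::pnorm(p$cc, log.p = TRUE)))
  d_mu <- -p$nu + p$z * p$w / p$sigma
  d_sg <- -1 + p$z^2 + p$cc * mills
  d_sg[!is.finite(p$cc)] <- (-1 + p$z^2)[!is.finite(p$cc)]
  g <- c(-drop(crossprod(B$mu, d_mu)), -drop(crossprod(B$sigma, d_sg)))
  if (is.null(nu_fixed)) {
    small <- abs(p$nu) < 1e-5
    dz_dnu <- ifelse(small, p$s^2 / (2 * p$sigma),
                     (p$s * p$w) / (p$nu * p$sigma) - p$z / p$nu)
    phi_term <- ifelse(small | p$cc > 37, 0,
                       mills * sign(p$nu) / (p$sigma * p$nu^2))
    d_nu <- p$s - p$z * dz_dnu + phi_term
    g <- c(g, -drop(crossprod(B$nu, d_nu)))
  }
  ifelse(is.finite(g), g, 0)
}

# --- fitting ----------------------------------------------------------------

#' Fit a BCCG centile model over gestational age
#'
#' Maximum-likelihood fit of the BCCG (LMS) distribution with smooth
#' parameter curves: `log mu(t)` and `log sigma(t)` are linear in B-spline
#' bases of the stated degrees of freedom, `nu(t)` is constant or linear
#' (identity scale) or may be fixed. Estimation cycles backfitting-style
#' through the three coefficient blocks, each updated by BFGS with analytic
#' gradients; a block update is only accepted if it does not increase the
#' deviance, so the deviance trace is non-increasing. Cycling stops when the
#' relative deviance change falls below `tol` or after `max_cycles` cycles
#' (the convergence flag records which).
#'
#' Initialization: `nu = 1`, `mu` from a least-squares fit of `log y` on the
#' `mu` basis (a smoothed running mean), `sigma` constant at the sample
#' coefficient of variation.
#'
#' @param t gestational ages (weeks), within `[0, 42]`.
#' @param y positive responses (GWG already shifted to positive support; see
#'   [fit_gwg_centiles()]).
#' @param df named vector/list with elements `mu`, `sigma`, `nu`: degrees of
#'   freedom (coefficient counts; 1 = constant) of each parameter curve.
#' @param nu_fixed if non-`NULL`, `nu` is held at this value and not
#'   estimated.
#' @param shift positive support shift (kg) recorded in the model and undone
#'   by [evaluate_centiles()].
#' @param tol relative deviance tolerance between cycles.
#' @param max_cycles cycle cap.
#' @param min_obs minimum number of observations.
#' @return object of class `"bccg_model"`: coefficient blocks, basis
#'   specifications, `deviance` (-2 log-likelihood), `aic`, `edf`,
#'   `deviance_trace`, `converged`, and the data signature used by
#'   [compare_models()].
#' @export
fit_bccg <- function(t, y, df = c(mu = 3, sigma = 2, nu = 1), nu_fixed = NULL,
                     shift = 0, tol = 1e-6, max_cycles = 200L, min_obs = 50L) {
  stopifnot(length(t) == length(y))
  if (length(y) < min_obs) stop(sprintf("need at least %d observations", min_obs))
  if (any(y <= 0)) stop("responses must be positive (apply a support shift)")
  if (any(t < 0 | t > 42)) stop("gestational ages must lie in [0, 42]")
  df <- as.list(df)
  basis <- list(mu = make_basis_spec(t, df$mu), sigma = make_basis_spec(t, df$sigma))
  B <- list(mu = eval_basis(basis$mu, t), sigma = eval_basis(basis$sigma, t))
  if (is.null(nu_fixed)) {
    basis$nu <- make_basis_spec(t, df$nu)
    B$nu <- eval_basis(basis$nu, t)
  }
  logy <- log(y)

  b_mu <- stats::lm.fit(B$mu, logy)$coefficients
  b_mu[is.na(b_mu)] <- 0
  cv <- stats::sd(y) / mean(y)
  b_sigma <- c(log(max(cv, 1e-3)), rep(0, ncol(B$sigma) - 1L))
  blocks <- list(mu = ncol(B$mu), sigma = ncol(B$sigma))
  par <- c(b_mu, b_sigma)
  if (is.null(nu_fixed)) {
    blocks$nu <- ncol(B$nu)
    par <- c(par, c(1, rep(0, ncol(B$nu) - 1L)))
  }

  block_idx <- relist_blocks(seq_along(par), blocks)
  negll <- bccg_negll(par, blocks, B, logy, nu_fixed)
  trace <- 2 * negll
  converged <- FALSE
  cycles <- 0L
  for (cycle in seq_len(max_cycles)) {
    cycles <- cycle
    for (nm in names(blocks)) {
      idx <- block_idx[[nm]]
      fn <- function(pb) { pp <- par; pp[idx] <- pb
        bccg_negll(pp, blocks, B, logy, nu_fixed) }
      gr <- function(pb) { pp <- par; pp[idx] <- pb
        bccg_negll_grad(pp, blocks, B, logy, nu_fixed)[idx] }
      res <- try(stats::optim(par[idx], fn, gr, method = "BFGS",
                              control = list(maxit = 60)), silent = TRUE)
      if (!inherits(res, "try-error") && is.finite(res$value) &&
          res$value <= negll) {
        par[idx] <- res$par
        negll <- res$value
      }
    }
    dev <- 2 * negll
    trace <- c(trace, dev)
    prev <- trace[length(trace) - 1L]
    if (abs(prev - dev) < tol * (abs(dev) + 0.1)) { converged <- TRUE; break }
  }

  coefs <- relist_blocks(par, blocks)
  edf <- sum(unlist(blocks))
  dev <- 2 * negll
  structure(list(coef = coefs, basis = basis, nu_fixed = nu_fixed,
                 shift = shift, deviance = dev, aic = dev + 2 * edf,
                 edf = edf, deviance_trace = trace, converged = converged,
                 cycles = cycles, n = length(y), t_range = range(t),
                 data_sig = c(length(y), sum(t), sum(y))),
            class = "bccg_model")
}

#' Generalized Akaike information criterion of a fitted model
#' @param model a `"bccg_model"`.
#' @param k penalty per effective degree of freedom (`k = 2` gives the AIC).
#' @return numeric GAIC value.
#' @export
gaic <- function(model, k = 2) model$deviance + k * model$edf

#' Parameter curves of a fitted BCCG model at new gestational ages
#' @param model a `"bccg_model"`.
#' @param t gestational ages.
#' @return data.frame with columns `t`, `mu`, `sigma`, `nu` (shifted scale).
#' @export
predict_bccg <- function(model, t) {
  mu <- exp(drop(eval_basis(model$basis$mu, t) %*% model$coef$mu))
  sigma <- exp(pmin(pmax(drop(eval_basis(model$basis$sigma, t) %*% model$coef$sigma), -15), 15))
  nu <- if (is.null(model$nu_fixed))
    drop(eval_basis(model$basis$nu, t) %*% model$coef$nu)
  else rep(model$nu_fixed, length(t))
  data.frame(t = t, mu = mu, sigma = sigma, nu = nu)
}

#' @export
print.bccg_model <- function(x, ...) {
  cat(sprintf("BCCG centile model: n = %d, edf = %d, deviance = %.2f, AIC = %.2f (%s, %d cycles)\n",
              x$n, x$edf, x$deviance, x$aic,
              if (x$converged) "converged" else "NOT converged", x$cycles))
  invisible(x)
}

#' Evaluate centile curves of a fitted model
#'
#' `y_p(t) = mu(t) (1 + nu(t) sigma(t) z_p)^{1/nu(t)}` (log form as
#' `nu -> 0`), with `z_p` the standard-normal quantile adjusted for the
#' positive-support truncation; the support shift recorded in the model is
#' undone, so values are on the original GWG scale.
#'
#' @param model a `"bccg_model"`.
#' @param t gestational-age grid.
#' @param centiles probabilities in (0, 1).
#' @return data.frame with columns `ga_weeks`, `p`, `value`.
#' @export
evaluate_centiles <- function(model, t, centiles = c(0.03, 0.10, 0.25, 0.50,
                                                     0.75, 0.90, 0.97)) {
  if (any(centiles <= 0 | centiles >= 1)) stop("centiles must lie in (0, 1)")
  par <- predict_bccg(model, t)
  out <- lapply(centiles, function(p)
    data.frame(ga_weeks = t, p = p,
               value = qbccg(p, par$mu, par$sigma, par$nu) - model$shift))
  do.call(rbind, out)
}

#' Quantile-residual diagnostics of a fitted centile model
#'
#' Normalized quantile residuals `r_i = qnorm(F_BCCG(y_i))` should be
#' standard normal under a correct model; the function reports them together
#' with per-centile empirical coverage (the fraction of observations below
#' each fitted centile curve), a Shapiro-Wilk normality statistic on the
#' residuals (on an evenly spaced subsample of at most 5,000 when larger)
#' and a homoscedasticity check (Pearson correlation of `|r|` with `t`).
#'
#' @param model a `"bccg_model"`.
#' @param t,y the training data on the original (unshifted) response scale.
#' @param centiles coverage probabilities to check.
#' @return list of class `"bccg_diagnostics"`: `residuals`, `coverage`
#'   (data.frame `p`, `empirical`), `shapiro_W`, `shapiro_p`,
#'   `homoscedasticity_cor`, `homoscedasticity_p`.
#' @export
quantile_diagnostics <- function(model, t, y,
                                 centiles = c(0.03, 0.10, 0.50, 0.90, 0.97)) {
  ys <- y + model$shift
  if (any(ys <= 0)) stop("data below the model support shift")
  par <- predict_bccg(model, t)
  u <- pbccg(ys, par$mu, par$sigma, par$nu)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  r <- stats::qnorm(u)
  cov <- vapply(centiles, function(p)
    mean(y < qbccg(p, par$mu, par$sigma, par$nu) - model$shift), numeric(1))
  rs <- if (length(r) > 5000L) r[round(seq(1L, length(r), length.out = 5000L))] else r
  sw <- stats::shapiro.test(rs)
  ct <- stats::cor.test(abs(r), t)
  structure(list(residuals = r,
                 coverage = data.frame(p = centiles, empirical = cov),
                 shapiro_W = unname(sw$statistic), shapiro_p = sw$p.value,
                 homoscedasticity_cor = unname(ct$estimate),
                 homoscedasticity_p = ct$p.value),
            class = "bccg_diagnostics")
}

#' Rank fitted centile models by GAIC
#'
#' Models must be fitted on identical data (checked through the stored data
#' signature). Ties in GAIC are broken in favour of fewer effective degrees
#' of freedom.
#'
#' @param models list of `"bccg_model"` objects.
#' @param k GAIC penalty (`k = 2` reproduces the AIC ranking).
#' @return data.frame ranked best-first: `model`, `edf`, `deviance`, `aic`,
#'   `gaic`.
#' @export
compare_models <- function(models, k = 2) {
  stopifnot(length(models) >= 2L)
  sigs <- vapply(models, function(m) paste(signif(m$data_sig, 12), collapse = "|"), "")
  if (length(unique(sigs)) > 1L) stop("models were fitted on different data")
  nm <- names(models)
  if (is.null(nm)) nm <- sprintf("model%d", seq_along(models))
  tab <- data.frame(model = nm,
                    edf = vapply(models, function(m) m$edf, numeric(1)),
                    deviance = vapply(models, function(m) m$deviance, numeric(1)),
                    aic = vapply(models, function(m) m$aic, numeric(1)),
                    gaic = vapply(models, gaic, numeric(1), k = k))
  tab <- tab[order(tab$gaic, tab$edf), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Fit GWG centile curves, handling the positive-support shift
#'
#' GWG can legitimately be negative in early pregnancy, while the BCCG
#' distribution needs positive support; a fixed documented shift (default
#' +10 kg) is added before fitting and removed when centiles are evaluated.
#' Optionally selects the degrees of freedom by GAIC over a small grid.
#'
#' @param ga_weeks,gwg_kg visit-level gestational ages and cumulative GWG.
#' @param shift support shift in kg; all `gwg_kg + shift` must be positive.
#' @param df degrees of freedom used when `df_grid` is `NULL`.
#' @param df_grid optional list of `df` vectors to compare by GAIC.
#' @param k GAIC penalty used for the grid selection.
#' @param ... passed to [fit_bccg()].
#' @return a `"bccg_model"`; when a grid was searched, the selection table is
#'   attached as attribute `"selection"`.
#' @export
fit_gwg_centiles <- function(ga_weeks, gwg_kg, shift = 10,
                             df = c(mu = 3, sigma = 2, nu = 1),
                             df_grid = NULL, k = 3, ...) {
  y <- gwg_kg + shift
  if (any(y <= 0))
    stop("gwg_kg + shift must be positive; increase `shift`")
  if (is.null(df_grid))
    return(fit_bccg(ga_weeks, y, df = df, shift = shift, ...))
  fits <- lapply(df_grid, function(d) fit_bccg(ga_weeks, y, df = d, shift = shift, ...))
  names(fits) <- vapply(df_grid, function(d)
    sprintf("mu%d_sigma%d_nu%d", d[["mu"]], d[["sigma"]], d[["nu"]]), "")
  sel <- compare_models(fits, k = k)
  best <- fits[[sel$model[1L]]]
  attr(best, "selection") <- sel
  best
}

#' Pointwise pooling of centile curves across imputed datasets
#'
#' Fits produced on each of the `m` completed datasets are combined by
#' averaging the centile values pointwise over the gestational-age grid
#' (Rubin-style pooling of the curves).
#'
#' @param curve_tables list of [evaluate_centiles()] outputs on a common
#'   grid and centile set.
#' @return data.frame in the same layout with pooled `value`s.
#' @export
pool_centile_curves <- function(curve_tables) {
  stopifnot(length(curve_tables) >= 1L)
  ref <- curve_tables[[1L]][c("ga_weeks", "p")]
  vals <- vapply(curve_tables, function(d) {
    stopifnot(identical(d$ga_weeks, curve_tables[[1L]]$ga_weeks),
              identical(d$p, curve_tables[[1L]]$p))
    d$value
  }, numeric(nrow(ref)))
  cbind(ref, value = rowMeans(as.matrix(vals)))
}
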