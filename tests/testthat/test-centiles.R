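test_that("BCCG distribution functions are mutually consistent", {
  mu <- 12; sigma <- 0.15; nu <- 0.5
  p <- c(0.03, 0.1, 0.5, 0.9, 0.97)
  q <- qbccg(p, mu, sigma, nu)
  expect_equal(pbccg(q, mu, sigma, nu), p, tolerance = 1e-9)
  expect_equal(qbccg(0.5, mu, sigma, nu), mu, tolerance = 1e-9)
  # nu = 0 log-normal branch
  q0 <- qbccg(p, mu, sigma, 0)
  expect_equal(q0, mu * exp(sigma * qnorm(p)), tolerance = 1e-12)
  expect_equal(pbccg(q0, mu, sigma, 0), p, tolerance = 1e-9)
  # density integrates to ~1
  ig <- integrate(function(x) dbccg(x, mu, sigma, nu), 0, Inf)
  expect_equal(ig$value, 1, tolerance = 1e-6)
  # nu continuity near 0
  expect_lt(max(abs(dbccg(q, mu, sigma, 1e-9) - dbccg(q, mu, sigma, 0))), 1e-6)
})

test_that("with nu fixed at 1 the fit equals a direct two-parameter ML oracle", {
  set.seed(2)
  y <- rnorm(600, 10, 2)
  tt <- runif(600, 5, 40)
  fit <- fit_bccg(tt, y, df = c(mu = 1, sigma = 1, nu = 1), nu_fixed = 1)
  par <- predict_bccg(fit, 20)
  oracle <- optim(c(log(10), log(0.2)), function(p)
    -sum(dbccg(y, exp(p[1]), exp(p[2]), 1, log = TRUE)), method = "BFGS",
    control = list(reltol = 1e-14))
  expect_equal(par$mu, exp(oracle$par[1]), tolerance = 1e-4)
  expect_equal(par$sigma, exp(oracle$par[2]), tolerance = 1e-4)
  # mu recovered within 3 SE of truth; sigma ~ cv = 0.2
  se_mu <- 2 / sqrt(600)
  expect_lt(abs(par$mu - 10), 3 * se_mu)
  expect_lt(abs(par$sigma - 0.2), 3 * 0.2 / sqrt(2 * 600) * 3)
})

test_that("the deviance trace never increases and refits are deterministic", {
  set.seed(3)
  tt <- runif(800, 5, 42)
  y <- rbccg(800, exp(2 + 0.02 * tt), 0.13, 0.5)
  f1 <- fit_bccg(tt, y, df = c(mu = 3, sigma = 2, nu = 1))
  expect_true(all(diff(f1$deviance_trace) <= 1e-8))
  f2 <- fit_bccg(tt, y, df = c(mu = 3, sigma = 2, nu = 1))
  expect_equal(f1$deviance, f2$deviance, tolerance = 1e-8)
  expect_true(f1$converged)
  expect_error(fit_bccg(tt[1:10], y[1:10]), "at least")
  expect_error(fit_bccg(tt, y - 100), "positive")
})

test_that("centile evaluation matches closed forms and never crosses", {
  set.seed(4)
  tt <- runif(600, 5, 42)
  y <- rbccg(600, 10, 0.2, 1)
  fit <- fit_bccg(tt, y, df = c(mu = 1, sigma = 1, nu = 1), nu_fixed = 1)
  par <- predict_bccg(fit, 20)
  ec <- evaluate_centiles(fit, 20, c(0.1, 0.5, 0.9))
  # nu = 1: y_p = mu (1 + sigma z_p), with negligible truncation at sigma = 0.2
  zp <- qnorm(c(0.1, 0.5, 0.9))
  expect_equal(ec$value, par$mu * (1 + par$sigma * zp), tolerance = 1e-6)
  # median is mu up to the (tiny) positive-support truncation at sigma = 0.2
  expect_equal(ec$value[2], par$mu, tolerance = 1e-6)
  grid_fit <- fit_bccg(tt, y, df = c(mu = 3, sigma = 2, nu = 1))
  ec2 <- evaluate_centiles(grid_fit, 5:42, c(0.03, 0.1, 0.5, 0.9, 0.97))
  wide <- matrix(ec2$value, nrow = length(5:42))
  expect_true(all(apply(wide, 1, function(r) all(diff(r) > 0))))
  expect_error(evaluate_centiles(fit, 20, 1.2), "\\(0, 1\\)")
})

test_that("model comparison ranks by GAIC with edf tie-breaks; GAIC(2) is AIC", {
  set.seed(5)
  tt <- runif(2000, 5, 42)
  y <- rbccg(2000, exp(2 + 0.02 * tt), 0.13, 0.5)
  lean <- fit_bccg(tt, y, df = c(mu = 2, sigma = 1, nu = 1))
  rich <- fit_bccg(tt, y, df = c(mu = 8, sigma = 4, nu = 2))
  expect_equal(gaic(lean, 2), lean$aic)
  expect_equal(gaic(rich, 2), rich$aic)
  rank3 <- compare_models(list(lean = lean, rich = rich), k = 3)
  expect_equal(rank3$model[1], "lean")  # parsimonious truth wins at k = 3
  tie <- compare_models(list(a = lean, b = lean), k = 2)
  expect_equal(tie$model, c("a", "b"))
  other <- fit_bccg(tt[1:1000], y[1:1000], df = c(mu = 2, sigma = 1, nu = 1))
  expect_error(compare_models(list(lean, other)), "different data")
})

test_that("quantile residuals are standard normal under the true model", {
  set.seed(6)
  n <- 4000
  tt <- runif(n, 5, 42)
  y <- rbccg(n, exp(2 + 0.02 * tt), 0.13, 0.5)
  fit <- fit_bccg(tt, y, df = c(mu = 2, sigma = 1, nu = 1))
  d <- quantile_diagnostics(fit, tt, y)
  expect_lt(abs(mean(d$residuals)), 3 / sqrt(n))
  expect_lt(abs(sd(d$residuals) - 1), 0.05)
  expect_gt(d$shapiro_p, 0.001)
  expect_lt(abs(d$homoscedasticity_cor), 0.05)
  expect_true(all(diff(d$coverage$empirical) > 0))  # monotone across centiles
})

test_that("the GWG wrapper handles the support shift and df selection", {
  set.seed(9)
  tt <- runif(1500, 5, 42)
  gwg <- rbccg(1500, exp(2.3 + 0.015 * tt), 0.12, 0.8) - 10   # negative GWG legal
  expect_lt(min(gwg), 0)
  fit <- fit_gwg_centiles(tt, gwg, shift = 10)
  expect_equal(fit$shift, 10)
  med <- evaluate_centiles(fit, 30, 0.5)$value
  expect_equal(med, exp(2.3 + 0.015 * 30) - 10, tolerance = 0.05)
  expect_error(fit_gwg_centiles(tt, gwg, shift = 1), "positive")
  sel <- fit_gwg_centiles(tt, gwg, shift = 10,
                          df_grid = list(c(mu = 2, sigma = 1, nu = 1),
                                         c(mu = 3, sigma = 2, nu = 1)))
  expect_s3_class(attr(sel, "selection"), "data.frame")
  pooled <- pool_centile_curves(list(evaluate_centiles(fit, 5:42),
                                     evaluate_centiles(sel, 5:42)))
  expect_equal(nrow(pooled), length(5:42) * 7)
})
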