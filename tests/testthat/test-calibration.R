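test_that("standard curve recovers a proportional relationship exactly", {
  conc <- 10^seq(-2, 2, length.out = 6)
  sc <- fit_standard_curve(conc, 107.31 * conc)
  expect_equal(sc$slope, 107.31, tolerance = 1e-7)
  sc2 <- fit_standard_curve(c(1, 10, 100), 3.7 * c(1, 10, 100))
  expect_equal(sc2$slope, 3.7, tolerance = 1e-10)
  expect_error(fit_standard_curve(c(1, 10), c(1, 10)), "at least 3")
  expect_error(fit_standard_curve(c(0, 1, 10), c(1, 2, 3)), "positive")
  expect_error(fit_standard_curve(c(1, 2, 3), c(-1, 2, 3)), "positive")
})

test_that("standard-curve slope is unbiased under multiplicative noise", {
  # per-replicate log-slope error should behave like N(0, sigma/sqrt(n))
  sigma <- 0.2; n <- 8
  log_err <- vapply(1:500, function(s) {
    d <- gen_standard_curve_data(107.31, c(1e-2, 1e2), n = n,
      noise = noise_model("multiplicative_lognormal", sigma, seed = s))
    log(fit_standard_curve(d)$slope / 107.31)
  }, numeric(1))
  band <- 2 * sigma / sqrt(n)
  expect_gt(mean(abs(log_err) <= band), 0.9)   # ~95% nominal
  expect_lt(abs(mean(log_err)), 3 * sigma / sqrt(n) / sqrt(500) + sigma^2)
})

test_that("fluorescence converts to concentration through the curve", {
  sc <- fit_standard_curve(c(1, 10, 100), 50 * c(1, 10, 100))
  expect_equal(rfu_to_concentration(0, sc), 0)
  expect_equal(rfu_to_concentration(sc$slope, sc), 1)
  expect_equal(rfu_to_concentration(sc$slope * c(0.5, 7), sc), c(0.5, 7))
  ts <- riboswitch_timeseries(c(0, 600), c(100, 200), unit = "RFU",
                              c_tot = 4.4, label = "well A1")
  conv <- rfu_to_concentration(ts, sc)
  expect_identical(attr(conv, "unit"), "uM")
  expect_equal(conv$value, c(100, 200) / sc$slope)
  expect_identical(attr(conv, "c_tot"), 4.4)
  expect_error(rfu_to_concentration(conv, sc), "already in uM")
  expect_error(rfu_to_concentration(1, -3), "positive")
})

test_that("basal kinetics are recovered exactly from noiseless control data", {
  p <- math_params(p0 = 20)
  tt <- seq(0, 86400, 600)
  ctrl <- riboswitch_timeseries(tt, basal_curve(tt, p$k4, p$k5, 20),
                                unit = "uM", c_tot = 0)
  fit <- fit_basal(ctrl)
  expect_lt(abs(coef(fit)[["k4"]] - p$k4) / p$k4, 1e-3)
  expect_lt(abs(coef(fit)[["k5"]] - p$k5) / p$k5, 1e-3)
  expect_lt(abs(coef(fit)[["p0"]] - 20) / 20, 1e-3)
  expect_false(fit$degenerate)
  expect_equal(predict(fit, tt), ctrl$value, tolerance = 1e-6)
})

test_that("a flat control leaves the decay rate unidentifiable and is flagged", {
  tt <- seq(0, 86400, 3600)
  ctrl <- riboswitch_timeseries(tt, rep(176.9, length(tt)), unit = "uM",
                                c_tot = 0)
  fit <- fit_basal(ctrl)
  expect_true(fit$degenerate)
  ci <- confint(fit)
  expect_true(any(!is.finite(ci[, "upper"]) | ci[, "upper"] == Inf))
})

test_that("basal fit quality on realistically noisy controls is high", {
  p <- math_params(p0 = 20)
  ctrl <- rfu_to_concentration(
    gen_timeseries(p, 0, curve = 107.31,
                   noise = noise_model("multiplicative_lognormal", 0.02,
                                       seed = 421)),
    107.31)
  fit <- fit_basal(ctrl)
  expect_gt(fit$r_squared, 0.99)
})

test_that("fitters refuse raw fluorescence input and mismatched exposures", {
  tt <- seq(0, 86400, 600)
  rfu <- riboswitch_timeseries(tt, rep(100, length(tt)), unit = "RFU",
                               c_tot = 0)
  expect_error(fit_basal(rfu), "rfu_to_concentration")
  exposed <- riboswitch_timeseries(tt, rep(100, length(tt)), unit = "uM",
                                   c_tot = 44)
  expect_error(fit_basal(exposed), "c_tot = 0")
  ctrl <- riboswitch_timeseries(tt, rep(100, length(tt)), unit = "uM")
  expect_error(fit_exposure(ctrl, fixed = list()), "c_tot > 0")
})

test_that("dissociation constant is recovered from a clean isotherm", {
  d <- gen_binding_assay(K_D = 0.3216, r0 = 1, noise = noise_model("none"))
  fit <- suppressWarnings(fit_kd(d))
  expect_lt(abs(coef(fit)[["K_D"]] - 0.3216) / 0.3216, 1e-4)
  expect_lt(abs(coef(fit)[["r0"]] - 1), 1e-4)

  # half-max anchor: (K_D, r0/2) plus near-endpoints
  conc <- c(0.001, 0.32, 320, 3200)
  sig <- binding_isotherm(conc, 0.32, 2)
  fit2 <- suppressWarnings(fit_kd(conc, sig))
  expect_lt(abs(coef(fit2)[["K_D"]] - 0.32) / 0.32, 1e-4)

  expect_error(fit_kd(c(1, 2, 3), c(1, 2, 3)), "at least 4")
  expect_error(fit_kd(c(1, 2, 3, 4), c(1, 2, 3, 4)), "two decades")
})

test_that("K_D estimation is accurate in log space under assay noise", {
  log_err <- vapply(1:500, function(s) {
    d <- gen_binding_assay(K_D = 0.3216, r0 = 1,
      conc_grid = 0.3216 * 10^seq(-2, 2, length.out = 10),
      noise = noise_model("multiplicative_lognormal", 0.1, seed = s))
    abs(log10(suppressWarnings(fit_kd(d))$estimates[["K_D"]] / 0.3216))
  }, numeric(1))
  expect_lt(median(log_err), 0.2)
})

test_that("one-sided assay data triggers a wide-interval warning, not failure", {
  # all points far below K_D: signal is linear, so K_D and r0 trade off
  # along a ridge that measurement noise makes visible
  conc <- 10^seq(-4, -1.5, length.out = 8)
  sig <- riboswitchr:::with_seed(12,
    riboswitchr:::apply_noise(binding_isotherm(conc, 100, 1),
                              noise_model("multiplicative_lognormal",
                                          0.05)))
  expect_warning(fit <- fit_kd(conc, sig), "weakly constrained")
  expect_s3_class(fit, "rsw_fit")
})

test_that("transport and abundance are recovered exactly from a clean exposure series", {
  p <- math_params()
  tt <- seq(0, 86400, 600)
  exposed <- riboswitch_timeseries(tt, p_approx(tt, p, 45), unit = "uM",
                                   c_tot = 45)
  fixed <- list(k3 = p$k3, k4 = p$k4, k5 = p$k5, p0 = p$p0,
                P = p$P, K_D = p$K_D)
  fit <- fit_exposure(exposed, fixed = fixed)
  expect_lt(abs(coef(fit)[["k1_minus"]] - 8.059e-8) / 8.059e-8, 1e-3)
  expect_lt(abs(coef(fit)[["r_tot"]] - 3.512) / 3.512, 1e-3)
  # freeing k3 keeps the predicted trajectory exact even if constants trade off
  fit2 <- fit_exposure(exposed, fixed = fixed[names(fixed) != "k3"])
  expect_true("k3" %in% names(coef(fit2)))
  expect_lt(max(abs(predict(fit2, tt) - exposed$value) /
                  exposed$value), 1e-3)
  expect_error(fit_exposure(exposed, fixed = list(k4 = 1)), "missing")
})

test_that("exposure fit quality at realistic noise matches the assay scale", {
  p <- math_params(p0 = 20)
  exposed <- rfu_to_concentration(
    gen_timeseries(p, 45, curve = 107.31,
                   noise = noise_model("multiplicative_lognormal", 0.02,
                                       seed = 77)),
    107.31)
  fit <- fit_exposure(exposed,
                      fixed = list(k3 = p$k3, k4 = p$k4, k5 = p$k5,
                                   p0 = 20, P = p$P, K_D = p$K_D))
  expect_gt(fit$r_squared, 0.98)
})

test_that("joint ODE fit reproduces the generating trajectories", {
  p <- comp_params(p0 = 20)
  tt <- seq(0, 86400, 1800)
  ctrl <- riboswitch_timeseries(tt, dsred_response(p, 0, tt, "ode"),
                                unit = "uM", c_tot = 0)
  exposed <- riboswitch_timeseries(tt, dsred_response(p, 44, tt, "ode"),
                                   unit = "uM", c_tot = 44)
  start <- p
  for (nm in c("k1_plus", "k1_minus", "k2_plus", "k2_minus", "k3", "k4",
               "k5", "r_tot"))
    start[[nm]] <- p[[nm]] * 1.3
  fit <- fit_ode(list(ctrl, exposed), start = start)
  # identifiability is degenerate in the raw constants; the trajectory is
  # the validated object
  expect_lt(max(abs(fit$fitted - fit$observed) /
                  pmax(fit$observed, 1e-9)), 1e-3)
  expect_true(all(fit$per_series_r2 > 0.999))
})

test_that("control-only ODE fits flag the unidentifiable constants", {
  p <- comp_params(p0 = 20)
  tt <- seq(0, 86400, 3600)
  ctrl <- riboswitch_timeseries(tt, dsred_response(p, 0, tt, "ode"),
                                unit = "uM", c_tot = 0)
  fit <- fit_ode(list(ctrl), start = p)
  expect_true(any(grepl("unidentifiable", fit$flags)))
  expect_setequal(names(coef(fit)), c("k4", "k5", "p0"))
  expect_error(fit_ode(list()), "length")
  exposed <- riboswitch_timeseries(tt, rep(1, length(tt)), unit = "uM",
                                   c_tot = 44)
  expect_error(fit_ode(list(exposed)), "control")
})

test_that("coefficient of determination follows its definition", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(4, 7, 2, 9)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 2)), 0.5)
  expect_error(r_squared(c(1, 1), c(1, 2)), "zero variance")
  expect_error(r_squared(1, c(1, 2)), "equal length")
})

test_that("fit objects expose the standard modelling interface", {
  p <- math_params(p0 = 20)
  tt <- seq(0, 86400, 1200)
  ctrl <- riboswitch_timeseries(tt, basal_curve(tt, p$k4, p$k5, 20) *
                                  exp(rnorm(length(tt), 0, 0.01)),
                                unit = "uM", c_tot = 0)
  fit <- fit_basal(ctrl)
  expect_s3_class(fit, "rsw_fit")
  expect_named(coef(fit), c("k4", "k5", "p0"))
  expect_equal(dim(confint(fit)), c(3L, 2L))
  expect_equal(fitted(fit) + residuals(fit), ctrl$value)
  expect_output(print(fit), "R\\^2")
  expect_output(print(summary(fit)), "residual SD")
  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_length(sims, 3)
  sims2 <- simulate(fit, nsim = 3, seed = 5)
  expect_identical(sims[[1]]$value, sims2[[1]]$value)
  f <- tempfile(); grDevices::pdf(f)
  expect_silent(plot(fit))
  grDevices::dev.off(); unlink(f)
})
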