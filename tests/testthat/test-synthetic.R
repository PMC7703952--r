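test_that("a 24 h assay sampled every 10 minutes yields 145 points", {
  p <- math_params()
  ts <- gen_timeseries(p, 44, curve = 107.31, noise = noise_model("none"))
  expect_equal(nrow(ts), 145)
  expect_equal(ts$time_s[2] - ts$time_s[1], 600)
  expect_identical(attr(ts, "unit"), "RFU")
})

test_that("clean generated fluorescence is exactly slope times the predictor", {
  p <- math_params(p0 = 20)
  for (pred in c("approx", "integral")) {
    ts <- gen_timeseries(p, 4.4, curve = 107.31,
                         noise = noise_model("none"), predictor = pred,
                         duration = 7200, interval = 600)
    expect_equal(ts$value / 107.31,
                 dsred_response(p, 4.4, ts$time_s, pred),
                 tolerance = 1e-12)
  }
  expect_error(gen_timeseries(p, 4.4, curve = 107.31,
                              predictor = "bogus"))
  expect_error(gen_timeseries(p, 4.4, curve = 107.31, interval = 0),
               "interval")
})

test_that("generation is reproducible under a fixed seed and varies across seeds", {
  p <- math_params()
  mk <- function(s) gen_timeseries(p, 44, curve = 107.31,
    noise = noise_model("multiplicative_lognormal", 0.02, seed = s),
    duration = 7200, interval = 600)
  expect_identical(mk(42)$value, mk(42)$value)
  expect_false(identical(mk(42)$value, mk(43)$value))
  # seeded generation leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(mk(42)); after <- runif(1)
  expect_identical(before, after)
})

test_that("written synthetic CSVs are byte-identical across runs", {
  p <- math_params()
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_timeseries_csv(gen_timeseries(p, 44, 107.31,
    noise = noise_model("multiplicative_lognormal", 0.02, seed = 7),
    duration = 7200, interval = 600), f1)
  write_timeseries_csv(gen_timeseries(p, 44, 107.31,
    noise = noise_model("multiplicative_lognormal", 0.02, seed = 7),
    duration = 7200, interval = 600), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("standard-curve data are log-spaced and positivity-preserving", {
  d <- gen_standard_curve_data(107.31, c(1e-2, 1e2), n = 8,
                               noise = noise_model("none"))
  expect_equal(d$rfu / d$dsred_uM, rep(107.31, 8))
  expect_equal(diff(log10(d$dsred_uM)),
               rep(diff(log10(d$dsred_uM))[1], 7), tolerance = 1e-12)
  d3 <- gen_standard_curve_data(50, c(1, 10), n = 3,
                                noise = noise_model("none"))
  expect_equal(d3$dsred_uM, c(1, sqrt(10), 10), tolerance = 1e-12)
  dn <- gen_standard_curve_data(107.31, c(1e-2, 1e2), n = 50,
    noise = noise_model("multiplicative_lognormal", 1, seed = 3))
  expect_true(all(dn$rfu > 0))
})

test_that("binding-assay data span the isotherm and close the loop with the fitter", {
  d <- gen_binding_assay(K_D = 0.3216, r0 = 2,
                         conc_grid = 0.3216 * 10^(-2:2),
                         noise = noise_model("none"))
  expect_equal(d$bound_signal[d$ligand_uM == 0.3216], 1, tolerance = 1e-12)
  wide <- gen_binding_assay(K_D = 1, r0 = 1,
                            conc_grid = 10^seq(-2, 2, length.out = 9),
                            noise = noise_model("none"))
  expect_lt(min(wide$bound_signal), 0.01)
  expect_gt(max(wide$bound_signal), 0.99)
  fit <- suppressWarnings(fit_kd(d))
  expect_equal(coef(fit)[["K_D"]], 0.3216, tolerance = 1e-5)
})

test_that("poisson-like noise has variance equal to the mean in count units", {
  nm <- noise_model("poisson_like", sigma = 1, seed = 8)
  mu <- 400
  draws <- riboswitchr:::with_seed(8, riboswitchr:::apply_noise(
    rep(mu, 1000), noise_model("poisson_like", sigma = 1)))
  expect_lt(abs(sd(draws) / sqrt(mu) - 1), 0.05)
  expect_error(noise_model("poisson_like", sigma = -1), "non-negative")
  expect_error(noise_model("white"))
})

test_that("end-to-end closure: staged calibration reconstructs the generating trajectory", {
  p <- math_params(p0 = 20)
  tt <- seq(0, 86400, 600)
  truth <- p_approx(tt, p, 44)
  errs <- vapply(1:20, function(s) {
    ctrl <- rfu_to_concentration(gen_timeseries(p, 0, 107.31,
      noise = noise_model("multiplicative_lognormal", 0.02,
                          seed = 1000 + s)), 107.31)
    exposed <- rfu_to_concentration(gen_timeseries(p, 44, 107.31,
      noise = noise_model("multiplicative_lognormal", 0.02,
                          seed = 2000 + s)), 107.31)
    fb <- fit_basal(ctrl)
    fe <- fit_exposure(exposed,
                       fixed = list(k4 = coef(fb)[["k4"]],
                                    k5 = coef(fb)[["k5"]],
                                    p0 = coef(fb)[["p0"]],
                                    P = p$P, K_D = p$K_D))
    mean(abs(predict(fe, tt) - truth) / truth)
  }, numeric(1))
  expect_lt(max(errs), 0.02)
})
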