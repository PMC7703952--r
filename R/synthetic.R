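#' Measurement-noise models for synthetic data
#'
#' Describes how noise is applied to a clean signal by the synthetic-data
#' generators:
#' * `"none"` — the clean signal.
#' * `"additive_gaussian"` — `x + N(0, sigma)`, `sigma` in signal units.
#' * `"multiplicative_lognormal"` — `x * exp(N(-sigma^2/2, sigma))`
#'   (mean-unbiased; `sigma` is the log-scale SD, so roughly the relative
#'   noise level).
#' * `"poisson_like"` — variance proportional to the mean, as for
#'   molecule-counting statistics: `sigma * Poisson(x / sigma)`, with
#'   `sigma` the signal units per effective count (variance = mean in
#'   count units).
#'
#' @param kind Noise kind, one of the four above.
#' @param sigma Non-negative scale (meaning depends on `kind`).
#' @param seed Optional integer; when set, generators using this model
#'   are bit-reproducible and the caller's RNG state is untouched.
#' @return An object of class `rsw_noise`.
#' @export
noise_model <- function(kind = c("none", "additive_gaussian",
                                 "multiplicative_lognormal",
                                 "poisson_like"),
                        sigma = 0.02, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("'sigma' must be a single non-negative number", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(kind = kind, sigma = sigma, seed = seed),
            class = "rsw_noise")
}

# apply a noise model to a clean signal (uses the current RNG stream;
# seeding is the generator's job so one seed covers the whole dataset)
apply_noise <- function(x, noise) {
  stopifnot(inherits(noise, "rsw_noise"))
  n <- length(x)
  switch(noise$kind,
    none = x,
    additive_gaussian = x + stats::rnorm(n, 0, noise$sigma),
    multiplicative_lognormal =
      x * exp(stats::rnorm(n, -noise$sigma^2 / 2, noise$sigma)),
    poisson_like = {
      if (noise$sigma == 0) x
      else noise$sigma * stats::rpois(n, x / noise$sigma)
    })
}

#' Generate a synthetic plate-reader fluorescence time series
#'
#' Emulates the expression assay behind the model: a culture is exposed
#' to the chemical at `t = 0` and fluorescence is read at fixed intervals
#' (by default every 10 minutes for 24 hours). The clean signal is
#' `slope * p(t)` with `p(t)` from the chosen predictor, and noise is
#' applied per the [noise_model()].
#'
#' @param params An [rsw_params][riboswitch_params] object (ground truth).
#' @param c_tot Exposure concentration, uM.
#' @param curve An [rsw_standard_curve][fit_standard_curve] or a slope in
#'   RFU/uM.
#' @param duration Assay duration, seconds.
#' @param interval Sampling interval, seconds.
#' @param noise A [noise_model()].
#' @param predictor `"ode"`, `"integral"` or `"approx"` (see
#'   [dsred_response()]).
#' @return An [rsw_timeseries][riboswitch_timeseries] in RFU, with the
#'   clean reporter curve attached as attribute `"truth_p_uM"`.
#' @examples
#' pars <- riboswitch_defaults("mathematical")
#' ts <- gen_timeseries(pars, c_tot = 44, curve = 107.31,
#'                      noise = noise_model("none"))
#' nrow(ts)  # 145 points: every 10 min over 24 h
#' @export
gen_timeseries <- function(params, c_tot, curve,
                           duration = 24 * 3600, interval = 600,
                           noise = noise_model("multiplicative_lognormal",
                                               sigma = 0.02),
                           predictor = c("approx", "integral", "ode")) {
  predictor <- match.arg(predictor)
  if (interval <= 0 || duration < interval)
    stop("'interval' must be positive and no larger than 'duration'",
         call. = FALSE)
  slope <- if (inherits(curve, "rsw_standard_curve")) curve$slope
           else as.numeric(curve)
  stopifnot(is.finite(slope), slope > 0)
  times <- seq(0, duration, by = interval)
  p <- dsred_response(params, c_tot, times, predictor = predictor)
  rfu <- with_seed(noise$seed, apply_noise(slope * p, noise))
  out <- riboswitch_timeseries(times, rfu, unit = "RFU", c_tot = c_tot,
                               label = sprintf("synthetic %g uM exposure",
                                               c_tot))
  attr(out, "truth_p_uM") <- p
  attr(out, "slope") <- slope
  out
}

#' Generate synthetic standard-curve data
#'
#' Log-spaced reporter concentrations across the requested decades with
#' `RFU = slope * conc` plus noise — the multi-decade proportional
#' calibration dataset the standard-curve fitter expects.
#'
#' @param slope True slope, RFU/uM.
#' @param conc_range `(low, high)` concentration span, uM, both positive.
#' @param n Number of points (>= 3).
#' @param noise A [noise_model()].
#' @return Data frame with columns `dsred_uM` and `rfu`.
#' @export
gen_standard_curve_data <- function(slope = 107.31,
                                    conc_range = c(1e-2, 1e2), n = 8,
                                    noise = noise_model(
                                      "multiplicative_lognormal",
                                      sigma = 0.2)) {
  stopifnot(n >= 3, conc_range[1] > 0, conc_range[2] > conc_range[1],
            slope > 0)
  conc <- 10^seq(log10(conc_range[1]), log10(conc_range[2]),
                 length.out = n)
  rfu <- with_seed(noise$seed, apply_noise(slope * conc, noise))
  data.frame(dsred_uM = conc, rfu = rfu)
}

#' Generate synthetic cell-free binding-assay data
#'
#' Saturable binding isotherm `signal = r0 * c / (K_D + c)` over a
#' concentration grid, plus noise.
#'
#' @param K_D True dissociation constant, uM.
#' @param r0 Total aptamer (signal amplitude), uM.
#' @param conc_grid Ligand concentrations, uM, positive; default spans
#'   `K_D/100` to `100 K_D`.
#' @param noise A [noise_model()].
#' @return Data frame with columns `ligand_uM` and `bound_signal`.
#' @export
gen_binding_assay <- function(K_D = 0.3216, r0 = 1,
                              conc_grid = K_D * 10^seq(-2, 2,
                                                       length.out = 10),
                              noise = noise_model(
                                "multiplicative_lognormal", sigma = 0.1)) {
  stopifnot(all(conc_grid > 0))
  clean <- binding_isotherm(conc_grid, K_D, r0)
  data.frame(ligand_uM = conc_grid,
             bound_signal = with_seed(noise$seed,
                                      apply_noise(clean, noise)))
}
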