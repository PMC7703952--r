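#' Exposure-response curve at a fixed exposure time
#'
#' Evaluates the closed-form reporter response over a grid of total
#' chemical concentrations at one elapsed exposure time.
#'
#' @param params An [rsw_params][riboswitch_params] object.
#' @param t Exposure time, seconds (single non-negative value).
#' @param c_grid Positive, sorted concentrations, uM.
#' @return Data frame with columns `c_tot_uM` and `p_uM`.
#' @export
exposure_response <- function(params, t, c_grid) {
  stop_if_analytic_incomplete(params)
  check_time(t)
  if (any(c_grid <= 0) || any(diff(c_grid) < 0))
    stop("'c_grid' must be positive and sorted", call. = FALSE)
  data.frame(c_tot_uM = c_grid,
             p_uM = vapply(c_grid, function(cc) p_approx(t, params, cc),
                           numeric(1)))
}

# dose-dependent part of p_approx, i.e. (p(t;c) - p(t;0)) * k4/(k3 r_tot);
# p0 cancels here, which is what makes c50 independent of it
dose_bracket <- function(t, params, c_tot) {
  k <- qss_const(params, c_tot)
  k4 <- params$k4
  Ekt <- exp(-k4 * t)
  Ebt <- exp(-k$b * t)
  f <- -expm1(-k$b * t)
  den <- k$a + f
  (-expm1(-k4 * t)) * f / den -
    (params$k1_minus / k4) * k$a * (1 + params$P) *
    (1 - (1 + k4 * t) * Ekt) * Ebt / den^2
}

#' Half-maximal exposure concentration at a given exposure time
#'
#' The sensor's sensitivity metric: the total chemical concentration
#' `c50` whose reporter response at exposure time `t` lies halfway
#' between the unexposed response and the saturating-dose limit,
#' \deqn{p(t; c_{50}) = \tfrac12\bigl(p(t; 0) +
#'       \lim_{c \to \infty} p(t; c)\bigr).}
#' The saturating limit is evaluated analytically (it is finite and
#' closed-form), and the equation is solved by bracketed root-finding on
#' `log10(c_tot)`. The initial reporter level `p0` cancels from both
#' sides, so `c50` is independent of it.
#'
#' @param params An [rsw_params][riboswitch_params] object.
#' @param t Exposure time(s), seconds, positive (vectorised).
#' @param bracket Search range for `c50`, uM; widen it if the response is
#'   flat over the default span.
#' @param tol Relative tolerance of the root on the `log10` scale.
#' @return `c50` in uM, one value per time.
#' @examples
#' pars <- riboswitch_defaults("mathematical")
#' c50(pars, 219 * 3600)   # about 1 uM at 219 h
#' @export
c50 <- function(params, t, bracket = c(1e-6, 1e3), tol = 1e-6) {
  stop_if_analytic_incomplete(params)
  if (any(!is.finite(t)) || any(t <= 0))
    stop("'t' must be positive and finite", call. = FALSE)
  vapply(t, function(ti) {
    # half of the saturating-dose bracket: a -> 0 collapses the dose term
    # to (1 - e^{-k4 t}), the c -> Inf limit
    target <- 0.5 * (-expm1(-params$k4 * ti))
    h <- function(lc) dose_bracket(ti, params, 10^lc) - target
    lo <- log10(bracket[1]); hi <- log10(bracket[2])
    if (h(lo) * h(hi) > 0)
      stop("response is flat in c_tot over [", bracket[1], ", ",
           bracket[2], "] uM; no half-maximal crossing", call. = FALSE)
    10^stats::uniroot(h, c(lo, hi), tol = tol)$root
  }, numeric(1))
}

#' Detection-sensitivity curve over exposure times
#'
#' Computes `c50` over a grid of exposure times, the input to the
#' power-law fit of [power_law_fit()]. The default grid is 24 log-spaced
#' times between 1 and 168 hours (one week).
#'
#' @param params An [rsw_params][riboswitch_params] object.
#' @param t_hours Exposure times, hours, positive.
#' @param ... Passed to [c50()].
#' @return An `rsw_sensitivity`: data frame with `t_hours` and `c50_uM`.
#' @export
sensitivity_curve <- function(params,
                              t_hours = 10^seq(0, log10(168),
                                               length.out = 24),
                              ...) {
  if (any(t_hours <= 0)) stop("'t_hours' must be positive", call. = FALSE)
  structure(data.frame(t_hours = t_hours,
                       c50_uM = c50(params, t_hours * 3600, ...)),
            class = c("rsw_sensitivity", "data.frame"), params = params)
}

#' @export
plot.rsw_sensitivity <- function(x, ...) {
  graphics::plot(x$t_hours, x$c50_uM, log = "xy",
                 xlab = "exposure time (h)", ylab = "c50 (uM)", ...)
  invisible(x)
}

#' Fit the power law linking sensitivity to exposure time
#'
#' Fits `c50 = (tau / t)^gamma` to a detection-sensitivity curve by
#' ordinary least squares in log-log space:
#' `log(c50) = gamma*log(tau) - gamma*log(t)`, so the regression slope is
#' `-gamma` and the intercept `gamma*log(tau)`. The 95% interval for
#' `gamma` comes from the regression slope; `tau`'s is propagated from
#' the coefficient covariance by the delta method on `log(tau)`.
#'
#' A `gamma` near 1 means sensitivity and exposure time are inversely
#' proportional: every 10-fold gain in detectable concentration costs
#' about a 10-fold longer exposure, until the system approaches steady
#' state (time scale `max(1/k1_minus, 1/k4)`) and `c50` plateaus at
#' `K_D (1+P)/P`.
#'
#' @param curve An [rsw_sensitivity][sensitivity_curve] or data frame
#'   with positive `t_hours` and `c50_uM` (>= 5 points).
#' @return An `rsw_powerlaw` with `tau` (hours), `gamma`
#'   (dimensionless), `ci95` (2 x 2 matrix), `fit` (the underlying
#'   [lm][stats::lm]) and the input curve.
#' @export
power_law_fit <- function(curve) {
  stopifnot(all(c("t_hours", "c50_uM") %in% names(curve)))
  t <- curve$t_hours; c50v <- curve$c50_uM
  if (length(t) < 5) stop("need at least 5 points", call. = FALSE)
  if (any(t <= 0) || any(c50v <= 0))
    stop("times and c50 values must be positive", call. = FALSE)
  fit <- stats::lm(log(c50v) ~ log(t))
  b <- stats::coef(fit)
  # covariance assembled by hand: summary.lm() warns on exact fits
  rss <- sum(fit$residuals^2)
  s2 <- rss / fit$df.residual
  V <- s2 * chol2inv(qr.R(fit$qr))
  dimnames(V) <- list(names(b), names(b))
  gamma <- -b[[2]]
  log_tau <- -b[[1]] / b[[2]]
  tau <- exp(log_tau)
  dfres <- fit$df.residual
  tq <- stats::qt(0.975, dfres)
  ci_gamma <- gamma + c(-1, 1) * tq * sqrt(V[2, 2])
  grad <- c(-1 / b[[2]], b[[1]] / b[[2]]^2)       # d log_tau / d (b0, b1)
  se_log_tau <- sqrt(drop(t(grad) %*% V %*% grad))
  ci_tau <- exp(log_tau + c(-1, 1) * tq * se_log_tau)
  ci <- rbind(tau = ci_tau, gamma = ci_gamma)
  colnames(ci) <- c("lower", "upper")
  tss <- sum((log(c50v) - mean(log(c50v)))^2)
  structure(list(tau = tau, gamma = gamma, ci95 = ci, fit = fit,
                 curve = curve,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_),
            class = "rsw_powerlaw")
}

#' @export
print.rsw_powerlaw <- function(x, ...) {
  cat(sprintf(
    "Power law c50 = (tau/t)^gamma:\n  tau   = %.4g h [%.4g, %.4g]\n  gamma = %.5g  [%.5g, %.5g]\n",
    x$tau, x$ci95["tau", 1], x$ci95["tau", 2],
    x$gamma, x$ci95["gamma", 1], x$ci95["gamma", 2]))
  invisible(x)
}

#' @export
coef.rsw_powerlaw <- function(object, ...)
  c(tau = object$tau, gamma = object$gamma)

#' @export
confint.rsw_powerlaw <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95)
    stop("only 95% intervals are stored", call. = FALSE)
  ci <- object$ci95
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Minimum agreement between the closed form and the ODE model
#'
#' Quantifies how faithfully the quasi-steady-state closed form tracks
#' the exact numerical solution at one dose: on a log-spaced time grid,
#' `agreement(t) = 100 * (1 - |p_approx(t) - p_ode(t)| / p_ode(t))`
#' (relative deviation against the ODE solution, the more exact model),
#' and the minimum over the grid is reported. Agreement improves with
#' dose: the quasi-steady-state argument is best when binding is
#' saturated.
#'
#' @param params An ODE-capable [rsw_params][riboswitch_params] object.
#' @param c_tot Total chemical concentration, uM, positive.
#' @param t_window Time window `(lo, hi)` in seconds.
#' @param points_per_decade Grid density (>= 50 recommended).
#' @return Minimum agreement in percent; the full per-time curve is
#'   attached as attribute `"curve"`.
#' @examples
#' \donttest{
#' pars <- riboswitch_defaults("computational")
#' model_agreement(pars, c_tot = 1000)  # > 96 at mM dose
#' }
#' @export
model_agreement <- function(params, c_tot, t_window = c(1e2, 1e7),
                            points_per_decade = 50) {
  stopifnot(inherits(params, "rsw_params"))
  if (!is_ode_capable(params))
    stop("model_agreement() needs an ODE-capable parameter set",
         call. = FALSE)
  check_ctot(c_tot)
  stopifnot(length(t_window) == 2, t_window[1] > 0,
            t_window[2] > t_window[1])
  decades <- log10(t_window[2] / t_window[1])
  n <- max(2L, ceiling(points_per_decade * decades) + 1L)
  grid <- 10^seq(log10(t_window[1]), log10(t_window[2]), length.out = n)
  p_ode <- dsred_response(params, c_tot, grid, predictor = "ode")
  if (any(p_ode <= 0))
    stop("ODE reporter concentration is not positive on the grid; ",
         "cannot normalise agreement", call. = FALSE)
  p_app <- p_approx(grid, params, c_tot)
  agree <- 100 * (1 - abs(p_app - p_ode) / p_ode)
  structure(min(agree),
            curve = data.frame(time_s = grid, agreement_pct = agree))
}

#' Minimum exposure time to reach a detection threshold
#'
#' Smallest exposure time at which the dose-induced reporter increment
#' `p(t; c_tot) - p(t; 0)` reaches a detector's optical threshold, found
#' by bracketed root search. If the threshold exceeds the steady-state
#' increment achievable at this dose the search fails explicitly,
#' reporting the achievable maximum.
#'
#' @param params An [rsw_params][riboswitch_params] object.
#' @param threshold Detection threshold as reporter concentration above
#'   basal, uM (non-negative).
#' @param c_tot Exposure concentration, uM, positive.
#' @return Required exposure time in hours.
#' @export
min_exposure_time <- function(params, threshold, c_tot) {
  stop_if_analytic_incomplete(params)
  check_ctot(c_tot)
  if (c_tot == 0) stop("'c_tot' must be positive", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("'threshold' must be a single non-negative concentration",
         call. = FALSE)
  if (threshold == 0) return(0)
  amp <- params$k3 * params$r_tot / params$k4
  half <- params$K_D * (1 + params$P) / params$P
  max_incr <- amp * c_tot / (half + c_tot)     # steady-state increment
  if (threshold >= max_incr)
    stop("threshold ", threshold, " uM is below steady-state capability: ",
         "the maximum achievable increment at ", c_tot, " uM is ",
         signif(max_incr, 6), " uM", call. = FALSE)
  incr <- function(t) amp * dose_bracket(t, params, c_tot)
  hi <- 3600
  while (incr(hi) < threshold && hi < 1e15) hi <- hi * 4
  stats::uniroot(function(t) incr(t) - threshold, c(1e-6, hi),
                 tol = 1e-6 * hi)$root / 3600
}
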