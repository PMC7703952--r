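#' Quasi-steady-state closed forms for the riboswitch reporter
#'
#' Under time-scale separation — membrane transport and aptamer binding
#' equilibrate fast relative to reporter turnover (a Briggs-Haldane style
#' quasi-steady-state argument) — the reporter concentration admits the
#' integral solution
#' \deqn{p(t) = \frac{k_5}{k_4} + \left(p_0 - \frac{k_5}{k_4}\right)
#'   e^{-k_4 t} + \int_0^t G(s)\, e^{-k_4 (t-s)}\, ds,}
#' with production kernel
#' \deqn{G(s) = \frac{k_3\, r_{tot}}
#'   {1 + \frac{K_D}{c_{tot}} \frac{1+P}{P}
#'    \left(1 - e^{-(1+P) k_1^- s}\right)^{-1}}.}
#' `p_integral()` evaluates this by adaptive quadrature; `p_approx()`
#' evaluates the first-order Taylor expansion of the kernel about
#' `s = t` (where the integrand peaks), which is closed-form; and
#' `p_steady()` the `t -> Inf` limit
#' \deqn{p_\infty = \frac{k_5}{k_4} +
#'   \frac{c_{tot}}{K_D \frac{1+P}{P} + c_{tot}} \frac{k_3}{k_4} r_{tot}.}
#' `cin_fast()` is the fast-transport intracellular concentration and
#' `g_kernel()` the kernel itself.
#'
#' At `c_tot = 0` every dose-dependent term is defined by its continuous
#' limit, 0, leaving the basal mono-exponential
#' `k5/k4 + (p0 - k5/k4) exp(-k4 t)`.
#'
#' @param t,s Time(s) since exposure, seconds (vectorised, non-negative).
#' @param params An [rsw_params][riboswitch_params] object (analytic
#'   fields required; the full rate set is not needed).
#' @param c_tot Total chemical concentration, uM (non-negative scalar).
#' @return Reporter concentration in uM (`p_*`), intracellular chemical in
#'   uM (`cin_fast`), or production rate in uM/s (`g_kernel`), one value
#'   per input time.
#' @name analytic
#' @seealso [simulate_riboswitch()] for the exact numerical solution,
#'   [dsred_response()] for a predictor-agnostic front end.
NULL

# internal: common pieces; a = (K_D/c_tot)(1+P)/P, b = (1+P) k1_minus
qss_const <- function(params, c_tot) {
  list(a = if (c_tot > 0) (params$K_D / c_tot) * (1 + params$P) / params$P
           else Inf,
       b = (1 + params$P) * params$k1_minus)
}

check_time <- function(t, what = "t") {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("'", what, "' must be non-negative", call. = FALSE)
  invisible(t)
}
check_ctot <- function(c_tot) {
  if (!is.numeric(c_tot) || length(c_tot) != 1L || is.na(c_tot) || c_tot < 0)
    stop("'c_tot' must be a single non-negative concentration (uM)",
         call. = FALSE)
  invisible(c_tot)
}

#' @rdname analytic
#' @export
cin_fast <- function(t, params, c_tot) {
  stop_if_analytic_incomplete(params)
  check_time(t); check_ctot(c_tot)
  b <- (1 + params$P) * params$k1_minus
  c_tot * params$P / (1 + params$P) * (-expm1(-b * t))
}

#' @rdname analytic
#' @export
g_kernel <- function(s, params, c_tot) {
  stop_if_analytic_incomplete(params)
  check_time(s, "s"); check_ctot(c_tot)
  if (c_tot == 0) return(rep(0, length(s)))
  k <- qss_const(params, c_tot)
  f <- -expm1(-k$b * s)                    # in [0, 1)
  params$k3 * params$r_tot * f / (f + k$a)
}

#' @rdname analytic
#' @export
p_integral <- function(t, params, c_tot) {
  stop_if_analytic_incomplete(params)
  check_time(t); check_ctot(c_tot)
  k4 <- params$k4
  basal <- params$k5 / k4 + (params$p0 - params$k5 / k4) * exp(-k4 * t)
  if (c_tot == 0) return(basal)
  k <- qss_const(params, c_tot)
  kmax <- params$k3 * params$r_tot
  # substitute u = t - s: integrand kmax f(t-u)/(f+a) e^{-k4 u} decays on
  # the 1/k4 scale; truncating at 40/k4 discards < e^-40 of the mass
  conv <- vapply(t, function(ti) {
    if (ti == 0) return(0)
    integrand <- function(u) {
      f <- -expm1(-k$b * (ti - u))
      kmax * f / (f + k$a) * exp(-k4 * u)
    }
    upper <- min(ti, 40 / k4)
    val <- try(stats::integrate(integrand, 0, upper, rel.tol = 1e-8,
                                abs.tol = 0, subdivisions = 400L),
               silent = TRUE)
    if (inherits(val, "try-error") || val$message != "OK")
      stop("quadrature failed at t = ", ti, " s", call. = FALSE)
    val$value
  }, numeric(1))
  basal + conv
}

#' @rdname analytic
#' @export
p_approx <- function(t, params, c_tot) {
  stop_if_analytic_incomplete(params)
  check_time(t); check_ctot(c_tot)
  k4 <- params$k4
  Ekt <- exp(-k4 * t)
  basal <- params$k5 / k4 + (params$p0 - params$k5 / k4) * Ekt
  if (c_tot == 0) return(basal)
  k <- qss_const(params, c_tot)
  Ebt <- exp(-k$b * t)
  f <- -expm1(-k$b * t)
  den <- k$a + f
  term1 <- (-expm1(-k4 * t)) * f / den
  term2 <- (params$k1_minus / k4) * k$a * (1 + params$P) *
    (1 - (1 + k4 * t) * Ekt) * Ebt / den^2
  basal + params$k3 * params$r_tot / k4 * (term1 - term2)
}

#' @rdname analytic
#' @export
p_steady <- function(params, c_tot) {
  stop_if_analytic_incomplete(params)
  check_ctot(c_tot)
  half <- params$K_D * (1 + params$P) / params$P
  dose <- if (c_tot == 0) 0 else c_tot / (half + c_tot)
  params$k5 / params$k4 + params$k3 * params$r_tot / params$k4 * dose
}

#' Equilibrium ligand-binding isotherm
#'
#' Bound-complex concentration of the reversible reaction
#' `c + r <-> r*` at binding equilibrium with conserved total aptamer:
#' \deqn{[r^*] = \frac{[c]}{K_D + [c]}\, [r]_0.}
#'
#' @param c Free ligand concentration(s), uM (non-negative).
#' @param K_D Dissociation constant, uM (positive).
#' @param r0 Total aptamer concentration, uM (positive).
#' @return Bound complex, uM, in `[0, r0)`.
#' @examples
#' binding_isotherm(0.3216, K_D = 0.3216, r0 = 2)  # half-saturation
#' @export
binding_isotherm <- function(c, K_D, r0) {
  if (any(c < 0)) stop("'c' must be non-negative", call. = FALSE)
  if (K_D <= 0) stop("'K_D' must be positive", call. = FALSE)
  if (r0 <= 0) stop("'r0' must be positive", call. = FALSE)
  c / (K_D + c) * r0
}

#' Predict the reporter time course by any of the three model routes
#'
#' A single front end over the exact numerical solution (`"ode"`), the
#' quasi-steady-state integral solution (`"integral"`) and its closed-form
#' Taylor approximation (`"approx"`), so downstream calibration and
#' sensitivity code can swap predictors by name.
#'
#' @param params An [rsw_params][riboswitch_params] object (`"ode"` needs
#'   the full rate set).
#' @param c_tot Total chemical concentration, uM.
#' @param times Time grid, seconds; must start at 0 and increase for the
#'   ODE route.
#' @param predictor One of `"ode"`, `"integral"`, `"approx"`.
#' @return Numeric vector of reporter concentrations, uM, one per time.
#' @export
dsred_response <- function(params, c_tot, times,
                           predictor = c("approx", "integral", "ode")) {
  predictor <- match.arg(predictor)
  switch(predictor,
    approx = p_approx(times, params, c_tot),
    integral = p_integral(times, params, c_tot),
    ode = {
      tms <- times
      prepend <- tms[1] > 0
      if (prepend) tms <- c(0, tms)
      traj <- simulate_riboswitch(params, c_tot, tms)
      if (prepend) traj$p_uM[-1] else traj$p_uM
    })
}
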