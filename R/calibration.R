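#' Fit the fluorescence standard curve
#'
#' Calibrates the proportional relationship `RFU = slope * [DsRed]`
#' between purified reporter concentration and plate-reader fluorescence.
#' Because both variables span several decades, the fit is performed on
#' log-scaled data — `log(RFU) = log(slope) + log(conc)` — by unweighted
#' least squares, which keeps low-concentration points from being washed
#' out by the high end. In log space the slope is an intercept-only
#' regression of `log(RFU) - log(conc)`, so the 95% confidence interval is
#' the usual t-interval, exponentiated (multiplicative about the
#' estimate).
#'
#' @param conc Reporter concentrations, uM, all positive (or a two-column
#'   data frame `dsred_uM`, `rfu`, with `rfu` omitted).
#' @param rfu Fluorescence readings, all positive.
#' @return An object of class `rsw_standard_curve` with elements `slope`
#'   (RFU/uM), `ci95`, `n`, `log_residual_sd`.
#' @examples
#' sc <- fit_standard_curve(c(0.1, 1, 10), 107.31 * c(0.1, 1, 10))
#' sc$slope
#' @export
fit_standard_curve <- function(conc, rfu) {
  if (is.data.frame(conc)) {
    stopifnot(all(c("dsred_uM", "rfu") %in% names(conc)))
    rfu <- conc$rfu; conc <- conc$dsred_uM
  }
  if (length(conc) != length(rfu))
    stop("'conc' and 'rfu' must have equal length", call. = FALSE)
  if (length(conc) < 3)
    stop("need at least 3 calibration points", call. = FALSE)
  if (any(conc <= 0) || any(rfu <= 0))
    stop("all concentrations and RFU values must be positive ",
         "(log scaling is undefined otherwise)", call. = FALSE)
  z <- log(rfu) - log(conc)
  n <- length(z)
  m <- mean(z)
  s <- stats::sd(z)
  half <- stats::qt(0.975, n - 1) * s / sqrt(n)
  structure(list(slope = exp(m),
                 ci95 = exp(m + c(-half, half)),
                 n = n,
                 log_residual_sd = s),
            class = "rsw_standard_curve")
}

#' @export
print.rsw_standard_curve <- function(x, ...) {
  cat(sprintf(
    "Fluorescence standard curve: slope = %.6g RFU/uM [%.4g, %.4g] (n = %d)\n",
    x$slope, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Convert fluorescence readings to reporter concentration
#'
#' Inverts the proportional standard curve: `conc = RFU / slope`.
#'
#' @param rfu Fluorescence readings (vector) or an
#'   [rsw_timeseries][riboswitch_timeseries] tagged `"RFU"`.
#' @param curve An [rsw_standard_curve][fit_standard_curve], or a single
#'   positive slope in RFU/uM.
#' @return Concentrations in uM; for a time-series input, a new
#'   `rsw_timeseries` tagged `"uM"`.
#' @export
rfu_to_concentration <- function(rfu, curve) {
  slope <- if (inherits(curve, "rsw_standard_curve")) curve$slope
           else as.numeric(curve)
  if (!is.finite(slope) || slope <= 0)
    stop("standard-curve slope must be positive", call. = FALSE)
  if (inherits(rfu, "rsw_timeseries")) {
    if (attr(rfu, "unit") != "RFU")
      stop("time series is already in uM", call. = FALSE)
    return(riboswitch_timeseries(rfu$time_s, rfu$value / slope, unit = "uM",
                                 c_tot = attr(rfu, "c_tot"),
                                 label = attr(rfu, "label")))
  }
  rfu / slope
}

#' Fit basal reporter kinetics from an unexposed control
#'
#' With no chemical present the closed-form solution collapses to the
#' mono-exponential `p(t) = k5/k4 + (p0 - k5/k4) exp(-k4 t)`, from which
#' the reporter destruction rate `k4`, basal synthesis `k5` and initial
#' level `p0` are identified by unweighted least squares. This is the
#' first stage of the calibration protocol; its estimates are then held
#' fixed by [fit_exposure()].
#'
#' A flat series leaves `k4` unidentifiable (the model is constant for
#' any `k4` once `p0 = k5/k4`); such fits are flagged `degenerate` with
#' `(0, Inf)` intervals on the flat directions rather than failing.
#'
#' @param control An [rsw_timeseries][riboswitch_timeseries] in uM with
#'   `c_tot = 0` and at least 5 points.
#' @param n_starts,seed Multi-start settings for the bounded
#'   Levenberg-Marquardt optimiser (guards against local minima).
#' @return An [rsw_fit] for `k4`, `k5`, `p0`.
#' @seealso [fit_exposure()], [fit_ode()], [predict.rsw_fit()]
#' @export
fit_basal <- function(control, n_starts = 5L, seed = 20201130L) {
  require_uM(control, "fit_basal")
  if (attr(control, "c_tot") != 0)
    stop("fit_basal() needs an unexposed control (c_tot = 0)", call. = FALSE)
  if (nrow(control) < 5)
    stop("need at least 5 time points", call. = FALSE)
  tt <- control$time_s; y <- control$value

  model <- function(est, t) {
    pinf <- est[["k5"]] / est[["k4"]]
    pinf + (est[["p0"]] - pinf) * exp(-est[["k4"]] * t)
  }
  # heuristic start: plateau from the series tail, decay over the span
  pinf0 <- max(mean(y[seq(max(1, length(y) - 4), length(y))]), 1e-8)
  k40 <- 1 / max(tt[length(tt)] / 3, 1e-6)
  start <- c(k4 = k40, k5 = k40 * pinf0, p0 = max(y[1], 1e-8))
  lmfit <- ls_minimize(function(est) model(est, tt) - y, start,
                       n_starts = n_starts, seed = seed)
  fit <- make_rsw_fit(lmfit, names(start), y,
                      function(est) model(est, tt),
                      model = "basal reporter kinetics", data = control)
  fit$predict_times <- tt
  fit$time_model <- model
  fit
}

#' Fit the aptamer-ligand dissociation constant from a binding assay
#'
#' Fits the equilibrium isotherm `signal = r0 * c / (K_D + c)` to
#' cell-free binding-assay data by unweighted least squares. Because assay
#' concentrations span decades, `K_D` is optimised on the log scale (the
#' confidence interval is therefore multiplicative — binding-affinity CIs
#' routinely span decades and this keeps them positive).
#'
#' @param conc Ligand concentrations, uM, non-negative, spanning at least
#'   two decades over the positive entries (or a data frame
#'   `ligand_uM`, `bound_signal`).
#' @param signal Bound-complex signal, same length.
#' @param n_starts,seed Multi-start settings.
#' @return An [rsw_fit] for `K_D` (uM) and the amplitude `r0`. Data that
#'   never leave the linear or the saturated regime produce a wide-CI
#'   warning, not a failure.
#' @export
fit_kd <- function(conc, signal, n_starts = 5L, seed = 20201130L) {
  if (is.data.frame(conc)) {
    stopifnot(all(c("ligand_uM", "bound_signal") %in% names(conc)))
    signal <- conc$bound_signal; conc <- conc$ligand_uM
  }
  if (length(conc) != length(signal))
    stop("'conc' and 'signal' must have equal length", call. = FALSE)
  pos <- conc[conc > 0]
  if (length(conc) < 4)
    stop("need at least 4 assay points", call. = FALSE)
  if (length(pos) < 2 || log10(max(pos) / min(pos)) < 2)
    stop("assay concentrations must span at least two decades",
         call. = FALSE)
  model <- function(est) binding_isotherm(conc, est[["K_D"]], est[["r0"]])
  start <- c(K_D = exp(mean(log(pos))), r0 = max(signal) * 1.05)
  lmfit <- ls_minimize(function(est) model(est) - signal, start,
                       n_starts = n_starts, seed = seed)
  fit <- make_rsw_fit(lmfit, names(start), signal, function(est) model(est),
                      model = "equilibrium binding isotherm",
                      data = data.frame(ligand_uM = conc,
                                        bound_signal = signal))
  ciK <- fit$ci95["K_D", ]
  kd_hat <- fit$estimates[["K_D"]]
  if (any(!is.finite(ciK)) ||
      ciK[2] / max(ciK[1], .Machine$double.xmin) > 1e3)
    warning("K_D is weakly constrained by these data (95% CI spans > 3 ",
            "decades)", call. = FALSE)
  else if (kd_hat > max(pos) || kd_hat < min(pos))
    warning("K_D is weakly constrained by these data (estimate lies ",
            "outside the assayed concentration range, so the isotherm's ",
            "bend was never observed)", call. = FALSE)
  fit
}

#' Fit transport and riboswitch abundance from an exposure time course
#'
#' Second calibration stage: with the basal parameters (`k4`, `k5`, `p0`)
#' and the equilibrium constants (`P`, `K_D`) fixed, the efflux rate
#' `k1_minus` and total riboswitch concentration `r_tot` — and, unless
#' supplied in `fixed`, the production rate `k3` — are identified by
#' unweighted least squares of the closed-form approximation [p_approx()]
#' against an exposed time course.
#'
#' @param exposed An [rsw_timeseries][riboswitch_timeseries] in uM with
#'   `c_tot > 0`.
#' @param fixed Named list (or [rsw_params][riboswitch_params]) supplying
#'   `k4`, `k5`, `p0`, `P`, `K_D`, and optionally `k3`. When `k3` is
#'   present it is held fixed; when absent it is fitted jointly.
#' @param n_starts,seed Multi-start settings.
#' @return An [rsw_fit] for `k1_minus`, `r_tot` (and `k3` if freed),
#'   flagged when an estimate runs into the search bounds.
#' @export
fit_exposure <- function(exposed, fixed, n_starts = 5L, seed = 20201130L) {
  require_uM(exposed, "fit_exposure")
  c_tot <- attr(exposed, "c_tot")
  if (c_tot <= 0)
    stop("fit_exposure() needs an exposed series (c_tot > 0)", call. = FALSE)
  fixed <- as.list(fixed)
  need <- c("k4", "k5", "p0", "P", "K_D")
  miss <- setdiff(need, names(fixed)[!vapply(fixed, function(v)
    is.null(v) || is.na(v), logical(1))])
  if (length(miss))
    stop("'fixed' must supply ", paste(need, collapse = ", "),
         " (missing: ", paste(miss, collapse = ", "), ")", call. = FALSE)
  free_k3 <- !("k3" %in% names(fixed)) || is.na(fixed$k3)
  tt <- exposed$time_s; y <- exposed$value

  mk_params <- function(est) {
    riboswitch_params(k1_minus = est[["k1_minus"]],
                      k3 = if (free_k3) est[["k3"]] else fixed$k3,
                      k4 = fixed$k4, k5 = fixed$k5, p0 = fixed$p0,
                      P = fixed$P, K_D = fixed$K_D, r_tot = est[["r_tot"]])
  }
  model <- function(est, t) p_approx(t, mk_params(est), c_tot)

  # amplitude-based start for r_tot; the efflux time scale is only weakly
  # constrained a priori, so seed starts across several decades of k1_minus
  amp <- max(max(y) - min(y), max(y) - fixed$k5 / fixed$k4, 1e-3)
  k3_start <- if (free_k3) fixed$k4 * 10 else fixed$k3
  k1m0 <- 1 / ((1 + fixed$P) * max(tt))
  start <- c(k1_minus = k1m0, r_tot = amp * fixed$k4 / k3_start)
  if (free_k3) start <- c(start, k3 = k3_start)
  extra <- lapply(10^c(-2, -1, 1, 2), function(f) {
    s <- start; s[["k1_minus"]] <- k1m0 * f; s
  })
  # box bounds keep the k3 * r_tot amplitude ridge (when k3 is freed, those
  # two enter the model only through their product) from running away
  lower <- c(k1_minus = 1e-12, r_tot = 1e-4, k3 = 1e-9)
  upper <- c(k1_minus = 1e-2, r_tot = 1e4, k3 = 1)
  lmfit <- ls_minimize(function(est) model(est, tt) - y, start,
                       n_starts = n_starts, seed = seed,
                       extra_starts = extra,
                       lower = lower[names(start)],
                       upper = upper[names(start)])
  flags <- character()
  if (length(lmfit$at_bound))
    flags <- c(flags, paste0("estimate pinned at a search bound: ",
                             paste(lmfit$at_bound, collapse = ", "),
                             "; the data do not constrain it"))
  fit <- make_rsw_fit(lmfit, names(start), y,
                      function(est) model(est, tt),
                      model = sprintf("exposure kinetics (c_tot = %g uM)",
                                      c_tot),
                      data = exposed, flags = flags)
  fit$predict_times <- tt
  fit$time_model <- model
  fit$c_tot <- c_tot
  fit$fixed <- fixed
  fit$params <- mk_params(fit$estimates)
  fit
}

#' Fit the full kinetic model to control and exposure series jointly
#'
#' Simultaneous unweighted least-squares fit of the numerically integrated
#' five-species model to one or more time courses (at least one control
#' and, for identifiability of the transport/binding constants, at least
#' one exposed series). All eight rate constants plus `r_tot` and `p0`
#' are free.
#'
#' The joint problem is multi-parameter degenerate — many rate-constant
#' combinations produce indistinguishable reporter trajectories — so the
#' fit is validated on predicted trajectories, not on raw constants, and
#' individual estimates should be read with their (often enormous)
#' intervals in mind.
#'
#' @param datasets List of [rsw_timeseries][riboswitch_timeseries] in uM.
#' @param start Optional starting [rsw_params][riboswitch_params] or named
#'   vector; defaults to the shipped `"computational"` set with `p0` from
#'   the first control observation.
#' @param n_starts,seed,maxiter Optimiser settings (multi-start is off by
#'   default here; each objective evaluation integrates the ODE system
#'   once per dataset).
#' @return An [rsw_fit] whose `estimates` hold
#'   `k1_plus, k1_minus, k2_plus, k2_minus, k3, k4, k5, r_tot, p0`.
#'   Without an exposed series the transport/binding constants and
#'   `r_tot` are held at their starting values and flagged unidentifiable.
#' @export
fit_ode <- function(datasets, start = NULL, n_starts = 1L,
                    seed = 20201130L, maxiter = 100L) {
  if (inherits(datasets, "rsw_timeseries")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1)
  for (d in datasets) require_uM(d, "fit_ode")
  ctots <- vapply(datasets, function(d) attr(d, "c_tot"), numeric(1))
  if (!any(ctots == 0))
    stop("fit_ode() needs at least one control (c_tot = 0) series",
         call. = FALSE)
  has_exposure <- any(ctots > 0)

  if (is.null(start)) {
    start <- riboswitch_defaults("computational")
    start$p0 <- max(datasets[[which(ctots == 0)[1]]]$value[1], 1e-6)
  }
  start <- as.list(start)
  parnames_all <- c("k1_plus", "k1_minus", "k2_plus", "k2_minus",
                    "k3", "k4", "k5", "r_tot", "p0")
  sv <- unlist(start[parnames_all])
  if (length(sv) != 9 || any(!is.finite(sv)) || any(sv <= 0))
    stop("'start' must supply positive values for all of ",
         paste(parnames_all, collapse = ", "), call. = FALSE)

  flags <- character()
  free <- parnames_all
  if (!has_exposure) {
    free <- c("k4", "k5", "p0")
    flags <- c(flags, paste("k1_plus, k1_minus, k2_plus, k2_minus and",
                            "r_tot are unidentifiable without an exposed",
                            "series; held at starting values"))
  }
  fixed_vals <- sv[setdiff(parnames_all, free)]

  mk_params <- function(est) {
    v <- c(est, fixed_vals)[parnames_all]
    do.call(riboswitch_params, as.list(v))
  }
  model <- function(est) {
    prm <- mk_params(est)
    unlist(lapply(datasets, function(d) {
      tms <- d$time_s
      prepend <- tms[1] > 0
      if (prepend) tms <- c(0, tms)
      p <- simulate_riboswitch(prm, attr(d, "c_tot"), tms)$p_uM
      if (prepend) p[-1] else p
    }))
  }
  observed <- unlist(lapply(datasets, function(d) d$value))
  lmfit <- ls_minimize(function(est) model(est) - observed, sv[free],
                       n_starts = n_starts, start_sd = 0.3, seed = seed,
                       maxiter = maxiter)
  fit <- make_rsw_fit(lmfit, free, observed, function(est) model(est),
                      model = "full kinetic model (joint ODE fit)",
                      data = datasets, flags = flags)
  full <- c(fit$estimates, fixed_vals)[parnames_all]
  fit$estimates_full <- full
  fit$params <- mk_params(fit$estimates)
  fit$per_series_r2 <- {
    pred <- fit$fitted
    idx <- cumsum(vapply(datasets, nrow, integer(1)))
    lo <- c(1, utils::head(idx, -1) + 1)
    mapply(function(a, b, d) r_squared(d$value, pred[a:b]),
           lo, idx, datasets)
  }
  fit
}
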