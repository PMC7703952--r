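#' Fitted calibration-stage object
#'
#' All stage fitters ([fit_basal()], [fit_kd()], [fit_exposure()],
#' [fit_ode()]) return an object of class `rsw_fit` holding the parameter
#' estimates on their natural (positive) scale, asymptotic 95% confidence
#' intervals (computed on the log scale, hence multiplicative), the
#' residual sum of squares and coefficient of determination, fitted
#' values and residuals, and a predictor closure. The usual accessors
#' apply: [coef()], [confint()], [fitted()], [residuals()], [predict()],
#' [summary()], [plot()].
#'
#' @name rsw_fit
#' @aliases rsw_fit-class
NULL

#' @export
print.rsw_fit <- function(x, ...) {
  cat("Riboswitch model fit:", x$model, "\n")
  cat(sprintf("  n = %d, RSS = %.6g, R^2 = %s\n", x$n_obs, x$rss,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared)))
  est <- cbind(estimate = x$estimates, x$ci95)
  print(signif(est, 5))
  for (f in x$flags) cat("  NOTE:", f, "\n")
  invisible(x)
}

#' @export
summary.rsw_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.rsw_fit")
}

#' @export
print.summary.rsw_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  residual SD = %.6g on %d degrees of freedom\n",
              sqrt(f$rss / f$df_residual), f$df_residual))
  if (!is.null(f$per_series_r2)) {
    cat("  per-series R^2:", paste(sprintf("%.4f", f$per_series_r2),
                                   collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.rsw_fit <- function(object, ...) object$estimates

#' @export
confint.rsw_fit <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95)
    stop("only 95% intervals are stored for rsw_fit objects", call. = FALSE)
  ci <- object$ci95
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.rsw_fit <- function(object, ...) object$fitted

#' @export
residuals.rsw_fit <- function(object, ...) object$residuals

#' Predict from a fitted calibration stage
#'
#' For time-course fits ([fit_basal()], [fit_exposure()]) `newdata` is a
#' vector of times in seconds; for [fit_kd()] a vector of ligand
#' concentrations in uM. Omitting `newdata` returns the fitted values.
#'
#' @param object An [rsw_fit].
#' @param newdata Times (s) or concentrations (uM), depending on the
#'   stage.
#' @param ... Unused.
#' @return Predicted reporter concentration (uM) or bound signal.
#' @export
predict.rsw_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (!is.null(object$time_model))
    return(object$time_model(object$estimates, newdata))
  if (identical(object$model, "equilibrium binding isotherm"))
    return(binding_isotherm(newdata, object$estimates[["K_D"]],
                            object$estimates[["r0"]]))
  stop("prediction at new inputs is not available for this fit type; ",
       "use the returned $params with a predictor function", call. = FALSE)
}

#' @export
plot.rsw_fit <- function(x, ...) {
  d <- x$data
  if (inherits(d, "rsw_timeseries")) {
    graphics::plot(d$time_s / 3600, d$value, xlab = "time (h)",
                   ylab = "DsRed (uM)", main = x$model, ...)
    graphics::lines(d$time_s / 3600, x$fitted, col = 2, lwd = 2)
  } else if (is.data.frame(d) && "ligand_uM" %in% names(d)) {
    graphics::plot(d$ligand_uM, d$bound_signal, log = "x",
                   xlab = "ligand (uM)", ylab = "bound signal",
                   main = x$model, ...)
    ord <- order(d$ligand_uM)
    graphics::lines(d$ligand_uM[ord], x$fitted[ord], col = 2, lwd = 2)
  } else {
    graphics::plot(x$observed, x$fitted, xlab = "observed",
                   ylab = "fitted", main = x$model, ...)
    graphics::abline(0, 1, col = 2)
  }
  invisible(x)
}

#' Simulate new datasets from a fitted time-course model
#'
#' Draws replicate noisy series from the fitted mean curve, mirroring the
#' synthetic-data generator's noise models — useful for parametric
#' bootstrap or design exploration.
#'
#' @param object An [rsw_fit] from [fit_basal()] or [fit_exposure()].
#' @param nsim Number of replicate series.
#' @param seed RNG seed (restores the caller's RNG state afterwards).
#' @param noise A [noise_model()]; default multiplicative lognormal with
#'   2% scale.
#' @param ... Unused.
#' @return A list of `nsim` [rsw_timeseries][riboswitch_timeseries]
#'   objects in uM.
#' @export
simulate.rsw_fit <- function(object, nsim = 1, seed = NULL,
                             noise = noise_model("multiplicative_lognormal",
                                                 sigma = 0.02), ...) {
  if (is.null(object$time_model) || is.null(object$predict_times))
    stop("simulate() is available for time-course fits only", call. = FALSE)
  tt <- object$predict_times
  mean_curve <- object$time_model(object$estimates, tt)
  c_tot <- if (!is.null(object$c_tot)) object$c_tot else 0
  with_seed(seed, lapply(seq_len(nsim), function(i)
    riboswitch_timeseries(tt, apply_noise(mean_curve, noise), unit = "uM",
                          c_tot = c_tot,
                          label = sprintf("simulated replicate %d", i))))
}
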