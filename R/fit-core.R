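# Shared nonlinear least-squares machinery for the calibration stages.
#
# All stage fitters minimise an unweighted residual sum of squares with a
# bounded Levenberg-Marquardt step (minpack.lm). Positivity of kinetic
# parameters is enforced by optimising log-parameters; confidence
# intervals are asymptotic (local curvature of the objective at the
# optimum), computed on the log scale and exponentiated, so they are
# multiplicative about the estimate.

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  eval.parent(substitute(expr))
}

# resid_fun(par_natural) -> residual vector; start: named positive vector.
# Multi-start LM on log(par): the given start plus (n_starts - 1) seeded
# log-normal perturbations, keeping the lowest-RSS solution.
ls_minimize <- function(resid_fun, start, n_starts = 5L, start_sd = 0.7,
                        seed = 20201130L, maxiter = 200L,
                        extra_starts = list(), lower = NULL, upper = NULL) {
  stopifnot(all(start > 0), !is.null(names(start)))
  npar <- length(start)
  lo <- if (is.null(lower)) rep(-Inf, npar) else log(lower[names(start)])
  hi <- if (is.null(upper)) rep(Inf, npar) else log(upper[names(start)])
  n_resid <- length(resid_fun(start))
  fn <- function(theta) {
    r <- tryCatch(resid_fun(stats::setNames(exp(theta), names(start))),
                  error = function(e) rep(1e12, n_resid))
    r[!is.finite(r)] <- 1e12
    r
  }
  starts <- with_seed(seed, {
    s <- matrix(rep(log(start), n_starts), nrow = n_starts, byrow = TRUE)
    if (n_starts > 1L)
      s[-1, ] <- s[-1, ] + matrix(stats::rnorm((n_starts - 1L) * npar,
                                               sd = start_sd),
                                  nrow = n_starts - 1L)
    for (es in extra_starts)
      s <- rbind(s, log(es[names(start)]))
    s
  })
  n_starts <- nrow(starts)
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- try(minpack.lm::nls.lm(par = pmin(pmax(starts[i, ], lo), hi),
                                  fn = fn, lower = lo, upper = hi,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = maxiter, ftol = 1e-12,
                                    ptol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("least-squares optimisation failed to converge from any start",
         call. = FALSE)
  best$par <- stats::setNames(best$par, names(start))
  best$at_bound <- names(start)[best$par <= lo + 1e-3 |
                                  best$par >= hi - 1e-3]
  best
}

# Assemble an rsw_fit object from an nls.lm solution in log-parameter
# space. `predict_fun(estimates)` must return fitted values aligned with
# `observed`.
make_rsw_fit <- function(lmfit, start_names, observed, predict_fun,
                         model, data = NULL, flags = character()) {
  theta <- lmfit$par
  est <- stats::setNames(exp(theta), start_names)
  fitted <- predict_fun(est)
  resid <- observed - fitted
  rss <- sum(resid^2)
  n <- length(observed)
  p <- length(est)
  dfres <- max(n - p, 1L)
  tss <- sum((observed - mean(observed))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_

  jtj <- as.matrix(lmfit$hessian)      # J'J in log-parameter space
  degenerate <- FALSE
  vcov_log <- matrix(NA_real_, p, p, dimnames = list(start_names, start_names))
  se_log <- rep(NA_real_, p)
  kap <- tryCatch(kappa(jtj, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kap) || kap > 1e10) {
    degenerate <- TRUE
    flags <- c(flags, "degenerate: objective is locally flat in at least one parameter direction")
  }
  inv <- tryCatch(solve(jtj), error = function(e) NULL)
  if (!is.null(inv)) {
    sigma2 <- rss / dfres
    vcov_log <- sigma2 * inv
    se_log <- sqrt(pmax(diag(vcov_log), 0))
  } else degenerate <- TRUE
  tq <- stats::qt(0.975, dfres)
  ci <- cbind(lower = est * exp(-tq * se_log),
              upper = est * exp(tq * se_log))
  wide <- !is.finite(se_log) | se_log > 20   # unidentifiable direction
  ci[wide, 1] <- 0; ci[wide, 2] <- Inf
  rownames(ci) <- start_names

  structure(list(estimates = est, ci95 = ci, se_log = se_log,
                 vcov_log = vcov_log, rss = rss, r_squared = r2,
                 n_obs = n, df_residual = dfres, fitted = fitted,
                 residuals = resid, observed = observed, data = data,
                 model = model, predict_fun = predict_fun,
                 degenerate = degenerate, flags = flags,
                 convergence = lmfit$info, message = lmfit$message),
            class = "rsw_fit")
}

#' Coefficient of determination of a model fit
#'
#' `1 - RSS/TSS` with the total sum of squares taken about the observed
#' mean.
#'
#' @param observed,predicted Equal-length numeric vectors (>= 2 points).
#' @return A single number, at most 1.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 2))  # 0.5
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop("'observed' and 'predicted' must have equal length >= 2",
         call. = FALSE)
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0)
    stop("observed series has zero variance; R^2 undefined", call. = FALSE)
  1 - sum((observed - predicted)^2) / tss
}
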