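#' Instantaneous rates of the five-species riboswitch model
#'
#' Evaluates the mass-action right-hand side of the kinetic model:
#' reversible chemical transport across the cell membrane
#' (`k1_plus`/`k1_minus`), reversible binding of intracellular chemical to
#' the free riboswitch (`k2_plus`/`k2_minus`), and reporter turnover
#' (basal synthesis `k5`, complex-driven production `k3`, destruction
#' `k4`):
#'
#' \deqn{d[c_{out}]/dt = k_1^- [c_{in}] - k_1^+ [c_{out}]}
#' \deqn{d[c_{in}]/dt  = k_1^+ [c_{out}] - k_1^- [c_{in}]
#'                       - k_2^+ [c_{in}][r] + k_2^- [r^*]}
#' \deqn{d[r^*]/dt     = k_2^+ [c_{in}][r] - k_2^- [r^*]}
#' \deqn{d[r]/dt       = k_2^- [r^*] - k_2^+ [c_{in}][r]}
#' \deqn{d[p]/dt       = k_5 + k_3 [r^*] - k_4 [p]}
#'
#' The binding flux appears in the intracellular-chemical equation so that
#' both conservation laws hold by construction:
#' `r + r_star` and `c_out + c_in + r_star` have zero net rate.
#'
#' @param state Named numeric vector with components `c_out`, `c_in`,
#'   `r_star`, `r`, `p` (all uM).
#' @param params An ODE-capable [rsw_params][riboswitch_params] object.
#' @return Named numeric vector of time derivatives, uM/s, in the same
#'   order as `state`.
#' @export
riboswitch_rates <- function(state, params) {
  stopifnot(inherits(params, "rsw_params"))
  if (!is_ode_capable(params))
    stop("incomplete parameters: the rate equations need k1_plus, k1_minus, ",
         "k2_plus and k2_minus (analytic-only set supplied)", call. = FALSE)
  nm <- c("c_out", "c_in", "r_star", "r", "p")
  if (!all(nm %in% names(state)))
    stop("state must be named with ", paste(nm, collapse = ", "),
         call. = FALSE)
  s <- state[nm]
  if (!all(is.finite(s))) stop("state fields must be finite", call. = FALSE)
  bind <- params$k2_plus * s[["c_in"]] * s[["r"]] -
    params$k2_minus * s[["r_star"]]
  c(c_out  = params$k1_minus * s[["c_in"]] - params$k1_plus * s[["c_out"]],
    c_in   = params$k1_plus * s[["c_out"]] - params$k1_minus * s[["c_in"]] - bind,
    r_star = bind,
    r      = -bind,
    p      = params$k5 + params$k3 * s[["r_star"]] - params$k4 * s[["p"]])
}

#' Simulate the riboswitch reporter kinetics
#'
#' Integrates the five-species model from the moment a chemical aliquot is
#' added to the culture: initial state
#' `(c_out, c_in, r_star, r, p) = (c_tot, 0, 0, r_tot, p0)`.
#' Integration uses a stiff-capable variable-step solver
#' ([deSolve::lsoda]) — the rate constants span roughly five orders of
#' magnitude, so stiffness is assumed — at relative tolerance `1e-8` and
#' absolute tolerance `1e-10` uM.
#'
#' @param params An ODE-capable [rsw_params][riboswitch_params] object.
#' @param c_tot Total chemical concentration added at `t = 0`, uM
#'   (non-negative).
#' @param times Strictly increasing time grid in seconds starting at 0.
#' @return An `rsw_trajectory`: a data frame with columns `time_s`,
#'   `c_out_uM`, `c_in_uM`, `r_star_uM`, `r_uM`, `p_uM`, carrying the
#'   parameter set and `c_tot` as attributes.
#' @examples
#' pars <- riboswitch_defaults("computational")
#' traj <- simulate_riboswitch(pars, c_tot = 44, times = seq(0, 86400, 600))
#' max(abs(traj$r_uM + traj$r_star_uM - pars$r_tot))  # conservation
#' @export
simulate_riboswitch <- function(params, c_tot, times) {
  stopifnot(inherits(params, "rsw_params"))
  if (!is.numeric(c_tot) || length(c_tot) != 1L || is.na(c_tot) || c_tot < 0)
    stop("'c_tot' must be a single non-negative concentration (uM)",
         call. = FALSE)
  if (length(times) < 2L || times[1] != 0 || any(diff(times) <= 0))
    stop("'times' must be strictly increasing and start at 0", call. = FALSE)
  if (!is_ode_capable(params))
    stop("incomplete parameters: simulation needs the full rate-constant set",
         call. = FALSE)

  y0 <- c(c_out = c_tot, c_in = 0, r_star = 0, r = params$r_tot,
          p = params$p0)
  deriv <- function(t, y, p) list(unname(riboswitch_rates_fast(y, p)))
  out <- try(deSolve::lsoda(y0, times, deriv, params,
                            rtol = 1e-8, atol = 1e-10), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times)) {
    reached <- if (inherits(out, "try-error")) times[1] else out[nrow(out), 1]
    stop("ODE solver failed to converge over [", reached, ", ",
         times[length(times)], "] s", call. = FALSE)
  }
  traj <- data.frame(time_s = out[, "time"],
                     c_out_uM = out[, "c_out"], c_in_uM = out[, "c_in"],
                     r_star_uM = out[, "r_star"], r_uM = out[, "r"],
                     p_uM = out[, "p"])
  structure(traj, class = c("rsw_trajectory", "data.frame"),
            params = params, c_tot = c_tot)
}

# internal: unchecked rhs for the solver inner loop
riboswitch_rates_fast <- function(s, p) {
  bind <- p$k2_plus * s[["c_in"]] * s[["r"]] - p$k2_minus * s[["r_star"]]
  c(p$k1_minus * s[["c_in"]] - p$k1_plus * s[["c_out"]],
    p$k1_plus * s[["c_out"]] - p$k1_minus * s[["c_in"]] - bind,
    bind,
    -bind,
    p$k5 + p$k3 * s[["r_star"]] - p$k4 * s[["p"]])
}

#' @export
print.rsw_trajectory <- function(x, ...) {
  cat("Riboswitch trajectory: ", nrow(x), " time points over [0, ",
      format(x$time_s[nrow(x)]), "] s, c_tot = ",
      format(attr(x, "c_tot")), " uM\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more rows\n")
  invisible(x)
}

#' @export
plot.rsw_trajectory <- function(x, species = "p_uM", xlab = "time (h)",
                                ylab = "concentration (uM)", type = "l",
                                ...) {
  graphics::plot(x$time_s / 3600, x[[species]], type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Write / read a simulated trajectory as CSV
#'
#' Plain comma-separated text with the header
#' `time_s,c_out_uM,c_in_uM,r_star_uM,r_uM,p_uM`.
#'
#' @param traj An `rsw_trajectory` (any data frame with those columns).
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a data frame.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("time_s", "c_out_uM", "c_in_uM", "r_star_uM", "r_uM", "p_uM")
  stopifnot(all(cols %in% names(traj)))
  utils::write.csv(as.data.frame(traj)[cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  cols <- c("time_s", "c_out_uM", "c_in_uM", "r_star_uM", "r_uM", "p_uM")
  if (!all(cols %in% names(df)))
    stop("not a trajectory CSV (expected header ",
         paste(cols, collapse = ","), ")", call. = FALSE)
  df
}
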