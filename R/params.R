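#' Kinetic parameter set for the riboswitch biosensor model
#'
#' Bundles the rate constants and derived equilibrium constants of the
#' five-species riboswitch reporter model. Two flavours are supported:
#' a *full* (ODE-capable) set carrying all four transport/binding rate
#' constants, and an *analytic-only* set carrying just the quantities the
#' closed-form solutions need (`k1_minus`, `k3`, `k4`, `k5`, `P`, `K_D`,
#' `r_tot`, `p0`).
#'
#' Derived constants are filled in automatically: the partition ratio
#' `P = k1_plus / k1_minus` (equilibrium ratio of intracellular to
#' extracellular chemical) and the dissociation constant
#' `K_D = k2_minus / k2_plus` (ligand concentration at which half the
#' aptamer is bound). If a derived constant is supplied *and* both rates it
#' derives from are present, the two must agree to within `1e-6` relative.
#'
#' @param k1_plus Influx rate of chemical into cells, 1/s.
#' @param k1_minus Efflux rate of chemical from cells, 1/s.
#' @param k2_plus Association rate of the chemical-riboswitch complex,
#'   1/(uM s).
#' @param k2_minus Dissociation rate of the complex, 1/s.
#' @param k3 Reporter (DsRed) production rate per unit complex, 1/s.
#' @param k4 Reporter destruction rate, 1/s.
#' @param k5 Basal reporter synthesis in absence of complex, uM/s.
#' @param r_tot Total riboswitch concentration, uM.
#' @param p0 Initial reporter concentration, uM. Defaults to the basal
#'   steady state `k5 / k4` (an unexposed culture equilibrated before the
#'   chemical aliquot is added).
#' @param P Partition ratio (dimensionless); derived from `k1_plus/k1_minus`
#'   when omitted.
#' @param K_D Dissociation constant, uM; derived from `k2_minus/k2_plus`
#'   when omitted.
#' @return An object of class `rsw_params`: a named list of the eleven
#'   quantities above (absent rate constants stored as `NA`).
#' @seealso [riboswitch_defaults()] for the two shipped reference parameter
#'   sets, [simulate_riboswitch()] and [p_approx()] for what consumes them.
#' @examples
#' pars <- riboswitch_params(k1_minus = 8.059e-8, k3 = 1.244e-4,
#'                           k4 = 7.342e-6, k5 = 1.299e-3,
#'                           P = 7.413, K_D = 0.3216, r_tot = 3.512)
#' pars$p0  # defaults to k5/k4
#' @export
riboswitch_params <- function(k1_plus = NULL, k1_minus = NULL,
                              k2_plus = NULL, k2_minus = NULL,
                              k3 = NULL, k4 = NULL, k5 = NULL,
                              r_tot = NULL, p0 = NULL,
                              P = NULL, K_D = NULL) {
  num1 <- function(x, nm) {
    if (is.null(x) || (length(x) == 1L && is.na(x))) return(NA_real_)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  p <- list(
    k1_plus = num1(k1_plus, "k1_plus"), k1_minus = num1(k1_minus, "k1_minus"),
    k2_plus = num1(k2_plus, "k2_plus"), k2_minus = num1(k2_minus, "k2_minus"),
    k3 = num1(k3, "k3"), k4 = num1(k4, "k4"), k5 = num1(k5, "k5"),
    r_tot = num1(r_tot, "r_tot"), p0 = num1(p0, "p0"),
    P = num1(P, "P"), K_D = num1(K_D, "K_D"))

  # derive or cross-check the equilibrium constants
  if (!is.na(p$k1_plus) && !is.na(p$k1_minus)) {
    ratio <- p$k1_plus / p$k1_minus
    if (is.na(p$P)) p$P <- ratio
    else if (abs(p$P - ratio) > 1e-6 * abs(ratio))
      stop("inconsistent parameters: P = ", p$P, " but k1_plus/k1_minus = ",
           signif(ratio, 8), call. = FALSE)
  }
  if (!is.na(p$k2_plus) && !is.na(p$k2_minus)) {
    ratio <- p$k2_minus / p$k2_plus
    if (is.na(p$K_D)) p$K_D <- ratio
    else if (abs(p$K_D - ratio) > 1e-6 * abs(ratio))
      stop("inconsistent parameters: K_D = ", p$K_D,
           " but k2_minus/k2_plus = ", signif(ratio, 8), call. = FALSE)
  }

  needed <- c("k1_minus", "k3", "k4", "k5", "r_tot", "P", "K_D")
  miss <- needed[vapply(p[needed], is.na, logical(1))]
  if (length(miss))
    stop("incomplete parameters: missing ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.na(p$p0)) p$p0 <- p$k5 / p$k4

  pos <- setdiff(names(p), "p0")
  for (nm in pos)
    if (!is.na(p[[nm]]) && p[[nm]] <= 0)
      stop("'", nm, "' must be strictly positive", call. = FALSE)
  if (p$p0 < 0) stop("'p0' must be non-negative", call. = FALSE)

  structure(p, class = "rsw_params")
}

#' Reference parameter sets for the RDX-sensing riboswitch
#'
#' Two calibrated parameter sets for the DsRed riboswitch reporter
#' responding to hexahydro-1,3,5-trinitro-1,3,5-triazine (RDX) in
#' *E. coli*. `"computational"` carries the full set of rate constants
#' identified by fitting the ODE system to plate-reader time series;
#' `"mathematical"` is the analytic-only set identified by fitting the
#' quasi-steady-state closed form, with `P` taken from the octanol-water
#' partition ratio of RDX and `K_D` from a cell-free binding assay.
#'
#' The sets are shipped as plain-text config files under
#' `system.file("extdata", package = "riboswitchr")` and can be edited or
#' replaced via [read_params_config()].
#'
#' @param set Which parameter set, `"computational"` or `"mathematical"`.
#' @return An [rsw_params][riboswitch_params] object.
#' @export
riboswitch_defaults <- function(set = c("computational", "mathematical")) {
  set <- match.arg(set)
  path <- system.file("extdata", paste0("params_", set, ".yaml"),
                      package = "riboswitchr", mustWork = TRUE)
  read_params_config(path)
}

#' Load a kinetic parameter set from a YAML config file
#'
#' The file holds top-level keys named after the model symbols:
#' `k1_plus`, `k1_minus`, `k2_plus`, `k2_minus`, `k3`, `k4`, `k5`,
#' `r_tot`, `p0`, `P`, `K_D`. Any key may be omitted subject to the
#' completeness rules of [riboswitch_params()]; unknown keys are an error.
#'
#' @param path Path to the YAML file.
#' @return An [rsw_params][riboswitch_params] object.
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- c("k1_plus", "k1_minus", "k2_plus", "k2_minus",
             "k3", "k4", "k5", "r_tot", "p0", "P", "K_D")
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop("unknown parameter keys in ", path, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  do.call(riboswitch_params, vals)
}

#' Is a parameter set ODE-capable?
#'
#' The numerical model needs all four transport/binding rate constants;
#' an analytic-only set (only `P` and `K_D` known) supports the
#' closed-form solutions but not [simulate_riboswitch()].
#'
#' @param params An [rsw_params][riboswitch_params] object.
#' @return `TRUE` if all of `k1_plus`, `k1_minus`, `k2_plus`, `k2_minus`,
#'   `k3`, `k4`, `k5`, `r_tot` are present.
#' @export
is_ode_capable <- function(params) {
  stopifnot(inherits(params, "rsw_params"))
  need <- c("k1_plus", "k1_minus", "k2_plus", "k2_minus",
            "k3", "k4", "k5", "r_tot")
  !any(vapply(params[need], is.na, logical(1)))
}

#' @export
print.rsw_params <- function(x, ...) {
  cat("Riboswitch kinetic parameters",
      if (is_ode_capable(x)) "(ODE-capable)" else "(analytic-only)", "\n")
  units <- c(k1_plus = "1/s", k1_minus = "1/s", k2_plus = "1/(uM s)",
             k2_minus = "1/s", k3 = "1/s", k4 = "1/s", k5 = "uM/s",
             r_tot = "uM", p0 = "uM", P = "", K_D = "uM")
  for (nm in names(units)) {
    v <- x[[nm]]
    cat(sprintf("  %-9s %s %s\n", nm,
                if (is.na(v)) "-" else format(signif(v, 6)), units[[nm]]))
  }
  invisible(x)
}

# internal: insist that the analytic quantities are present
stop_if_analytic_incomplete <- function(params) {
  stopifnot(inherits(params, "rsw_params"))
  need <- c("k1_minus", "k3", "k4", "k5", "r_tot", "P", "K_D", "p0")
  miss <- need[vapply(params[need], is.na, logical(1))]
  if (length(miss))
    stop("incomplete parameters: missing ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(params)
}
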