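#' Model parameters for the knotweed--psyllid system
#'
#' Constructs and validates the full parameter set of the stage-structured
#' delay model: maturation and stem life-span delays, larval/adult/stem/
#' rhizome loss rates, the Ricker (Nicholson-blowflies) egg-laying function
#' per stem, and the Holling type II sap-consumption response of the larvae.
#'
#' Two named presets ship with the package. `"eq52"` is the simulation set
#' used throughout the numerical work (P = 16.9867); `"table1"` is identical
#' except for the larger tabulated maximal egg-laying rate P = 23.9798. Both
#' presets use the calibration k_l = 1 - m, so that larval mortality at zero
#' stem biomass is exactly 1 per day. The two P values are deliberately kept
#' as distinct presets and are not reconciled.
#'
#' The per-stem birth rate `b_p` and the stem-dependent larval mortality
#' `mu_l` are pluggable: the Ricker form `b_p(x) = P x exp(-q x)` and the
#' exponentially decreasing mortality `mu_l(S) = k_l exp(-S) + m` are the
#' defaults, but arbitrary closures (with their derivatives) may be supplied
#' so that the threshold-level analysis, which only assumes qualitative
#' properties of these functions, can be exercised with other forms. The
#' compiled fast integrator path requires the default forms; custom closures
#' fall back to the pure-R stepper.
#'
#' @param preset `"eq52"` (default) or `"table1"`.
#' @param h handling (digestion) time, days per unit stem biomass per larva.
#'   The model's key bifurcation parameter. `NA` is allowed for the analytic
#'   operations that do not involve `h` (e.g. `alpha_ratio()`,
#'   `critical_handling_time()`); simulation and equilibrium computation
#'   require a finite value.
#' @param ... named overrides of individual fields (see Details).
#' @param birth_fn,birth_deriv optional custom per-stem birth closure
#'   `b_p(x)` and its derivative; both or neither must be given.
#' @param mortality_fn,mortality_deriv optional custom larval mortality
#'   closure `mu_l(S)` and its derivative; both or neither must be given.
#'
#' @details Fields (all rates per day, delays in days, biomass in abstract
#' units):
#' \describe{
#'   \item{tau_p}{egg-to-adult maturation delay of the psyllid (32.2 d).}
#'   \item{tau_s}{life-span of a stem (150 d).}
#'   \item{k_l}{excess larval mortality scale when sap is short (1 - m).}
#'   \item{m}{asymptotic larval mortality when sap is plentiful (0.0205).}
#'   \item{P}{maximal per-adult egg-laying rate.}
#'   \item{q}{crowdedness constant of the Ricker birth function.}
#'   \item{mu_a}{adult per-capita mortality (0.0806).}
#'   \item{mu_s}{natural per-capita loss of stem biomass (0.01).}
#'   \item{e}{sap encounter rate (1).}
#'   \item{sigma}{ingested fraction of encountered biomass (1).}
#'   \item{h}{handling time (see above).}
#'   \item{k_s}{stem production coefficient, `b_s(R) = k_s R` (0.1).}
#'   \item{k_r}{rhizome production coefficient, `b_r(S) = k_r S` (0.1).}
#'   \item{mu_r}{rhizome per-capita loss (0.01).}
#' }
#'
#' @return An object of class `"kw_params"`: a named list of the fields
#'   above plus the closures `b_p`, `b_p_deriv`, `mu_l`, `mu_l_deriv` and a
#'   logical `custom_forms`.
#' @examples
#' p <- kw_params(h = 1)
#' p$mu_l(0)          # = k_l + m = 1
#' p$b_p(1 / p$q)     # maximum of the Ricker birth function
#' @export
kw_params <- function(preset = c("eq52", "table1"), h = NA_real_, ...,
                      birth_fn = NULL, birth_deriv = NULL,
                      mortality_fn = NULL, mortality_deriv = NULL) {
  preset <- match.arg(preset)
  m <- 0.0205
  base <- list(
    tau_p = 32.2, tau_s = 150,
    k_l = 1 - m, m = m,
    P = if (preset == "eq52") 16.9867 else 23.9798,
    q = 1, mu_a = 0.0806, mu_s = 0.01,
    e = 1, sigma = 1, h = as.numeric(h),
    k_s = 0.1, k_r = 0.1, mu_r = 0.01
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(base))
    if (length(bad)) {
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
    }
    base[names(overrides)] <- lapply(overrides, as.numeric)
  }
  build_kw_params(base, birth_fn, birth_deriv, mortality_fn, mortality_deriv)
}

# Assemble + validate a kw_params object from a flat named list of fields.
build_kw_params <- function(fields, birth_fn = NULL, birth_deriv = NULL,
                            mortality_fn = NULL, mortality_deriv = NULL) {
  p <- fields[kw_param_names()]
  names(p) <- kw_param_names()
  p <- lapply(p, as.numeric)

  if (xor(is.null(birth_fn), is.null(birth_deriv))) {
    stop("custom birth_fn requires birth_deriv (and vice versa)")
  }
  if (xor(is.null(mortality_fn), is.null(mortality_deriv))) {
    stop("custom mortality_fn requires mortality_deriv (and vice versa)")
  }
  custom <- !is.null(birth_fn) || !is.null(mortality_fn)

  if (is.null(birth_fn)) {
    P <- p$P; q <- p$q
    birth_fn <- function(x) P * x * exp(-q * x)
    birth_deriv <- function(x) P * exp(-q * x) * (1 - q * x)
  }
  if (is.null(mortality_fn)) {
    k_l <- p$k_l; m <- p$m
    mortality_fn <- function(S) k_l * exp(-S) + m
    mortality_deriv <- function(S) -k_l * exp(-S)
  }
  p$b_p <- birth_fn
  p$b_p_deriv <- birth_deriv
  p$mu_l <- mortality_fn
  p$mu_l_deriv <- mortality_deriv
  p$custom_forms <- custom
  class(p) <- "kw_params"
  validate_kw_params(p)
  p
}

kw_param_names <- function() {
  c("tau_p", "tau_s", "k_l", "m", "P", "q", "mu_a", "mu_s",
    "e", "sigma", "h", "k_s", "k_r", "mu_r")
}

#' Validate a parameter set
#'
#' Checks positivity of every rate and delay, `h >= 0` (NA permitted until a
#' simulation or equilibrium computation needs it), `sigma <= 1`, and that
#' the derived mortality at zero biomass `mu_l(0) = k_l + m` genuinely
#' exceeds the asymptotic mortality `m`.
#'
#' @param p a `kw_params` object.
#' @return `p`, invisibly; errors name every offending field.
#' @export
validate_kw_params <- function(p) {
  stopifnot(inherits(p, "kw_params"))
  vals <- unlist(p[kw_param_names()])
  bad <- character(0)
  must_pos <- setdiff(kw_param_names(), "h")
  for (nm in must_pos) {
    v <- p[[nm]]
    if (!is.finite(v) || v <= 0) bad <- c(bad, sprintf("%s must be > 0 (got %s)", nm, format(v)))
  }
  if (!is.na(p$h) && (!is.finite(p$h) || p$h < 0)) {
    bad <- c(bad, sprintf("h must be >= 0 (got %s)", format(p$h)))
  }
  if (is.finite(p$sigma) && p$sigma > 1) {
    bad <- c(bad, sprintf("sigma must be <= 1 (got %s)", format(p$sigma)))
  }
  if (is.finite(p$k_l) && p$k_l <= 0) {
    bad <- c(bad, "k_l must be > 0 so that mu_l is genuinely decreasing")
  }
  if (length(bad)) stop("invalid parameters:\n  ", paste(bad, collapse = "\n  "))
  invisible(p)
}

#' Replace the handling time in a parameter set
#'
#' Convenience for sweeps in `h`: returns a copy of `p` with `h` replaced
#' and (if the default forms are in use) closures untouched, since none of
#' them involve `h`.
#'
#' @param p a `kw_params` object.
#' @param h new handling time, days per unit biomass per larva.
#' @return a `kw_params` object.
#' @export
set_handling_time <- function(p, h) {
  stopifnot(inherits(p, "kw_params"))
  p$h <- as.numeric(h)
  validate_kw_params(p)
  p
}

#' @export
print.kw_params <- function(x, ...) {
  cat("Knotweed biocontrol model parameters\n")
  flds <- unlist(x[kw_param_names()])
  cat(paste0("  ", format(names(flds), width = 6), " = ", format(flds)), sep = "\n")
  if (x$custom_forms) cat("  (custom birth/mortality closures supplied)\n")
  invisible(x)
}

# h must be finite for the requested operation
require_h <- function(p, what) {
  if (is.na(p$h)) stop("parameter h is NA but ", what, " requires a handling time")
  invisible(p)
}
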