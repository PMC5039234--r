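#' Stem-dependent larval mortality
#'
#' Per-capita mortality of psyllid larvae as a function of available stem
#' biomass. The default form `mu_l(S) = k_l exp(-S) + m` decreases from
#' `k_l + m` at `S = 0` (sap shortage) to the natural rate `m` as biomass
#' becomes plentiful.
#'
#' @param S stem biomass (units), `>= 0`; vectorised.
#' @param params a [kw_params()] object.
#' @return per-day mortality rate(s), in `(m, k_l + m]` for the default form.
#' @examples
#' p <- kw_params()
#' larval_mortality(0, p)   # k_l + m = 1
#' larval_mortality(1e6, p) # ~ m
#' @export
larval_mortality <- function(S, params) {
  if (any(S < 0)) stop("S must be >= 0")
  params$mu_l(S)
}

#' Per-stem egg-laying rate
#'
#' The Ricker (Nicholson-blowflies) birth function `b_p(x) = P x exp(-q x)`
#' of the number of adults per stem `x`. It rises almost linearly (slope `P`
#' at the origin), peaks at `x = 1/q`, and falls off for crowded stems where
#' oviposition sites run out.
#'
#' @param x adults per stem, `>= 0`; vectorised.
#' @param params a [kw_params()] object.
#' @return eggs per stem per day.
#' @export
birth_per_stem <- function(x, params) {
  if (any(x < 0)) stop("x must be >= 0")
  params$b_p(x)
}

#' Total egg-laying rate of the stand
#'
#' `S * b_p(A/S)`, the whole-stand oviposition rate. At `S = 0` there are no
#' leaves and hence no oviposition sites, so the continuous extension 0 is
#' used (for the Ricker default the rate is `P A exp(-q A/S)`, which indeed
#' vanishes as `S -> 0+` for `A > 0`).
#'
#' @param A number of adult psyllids, `>= 0`.
#' @param S stem biomass (units), `>= 0`.
#' @param params a [kw_params()] object.
#' @return eggs per day. Vectorised over `A` and `S`.
#' @export
egg_laying_total <- function(A, S, params) {
  if (any(A < 0) || any(S < 0)) stop("A and S must be >= 0")
  n <- max(length(A), length(S))
  A <- rep_len(A, n); S <- rep_len(S, n)
  out <- numeric(n)
  pos <- S > 0 & A > 0
  out[pos] <- S[pos] * params$b_p(A[pos] / S[pos])
  out
}

#' Holling type II per-unit-biomass predation rate
#'
#' `e sigma L / (1 + h e sigma S)`: the per-day, per-unit-stem-biomass rate
#' at which larvae remove sap. Saturates in `S` through the handling time
#' `h`; with `h = 0` it reduces to the linear response `e sigma L`.
#'
#' @param L number of larvae, `>= 0`.
#' @param S stem biomass (units), `>= 0`.
#' @param params a [kw_params()] object (finite `h` required).
#' @return per-day rate. Vectorised over `L` and `S`.
#' @export
functional_response <- function(L, S, params) {
  require_h(params, "functional_response()")
  params$e * params$sigma * L / (1 + params$h * params$e * params$sigma * S)
}

#' Mean survival kernel g(x) = (1 - exp(-x)) / x
#'
#' The positive, strictly decreasing, convex function that arises whenever a
#' constant per-capita loss rate is averaged over a finite stage duration;
#' it appears throughout the characteristic-equation analysis. The removable
#' singularity at `x = 0` is filled with the limit value 1 (a fourth-order
#' Taylor series is used for `|x| < 1e-4` to avoid cancellation).
#'
#' @param x real; vectorised.
#' @return g(x), positive for all real x.
#' @export
g_decay <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  xs <- x[small]
  out[small] <- 1 - xs / 2 + xs^2 / 6 - xs^3 / 24
  out[!small] <- (1 - exp(-x[!small])) / x[!small]
  out
}

# derivative of g, with series for small x (needed at the lambda = 0
# removable singularities of the linearisation functions)
g_decay_deriv <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  xs <- x[small]
  out[small] <- -1 / 2 + xs / 3 - xs^2 / 8 + xs^3 / 30
  xl <- x[!small]
  out[!small] <- (exp(-xl) * (1 + xl) - 1) / xl^2
  out
}

#' Stem and rhizome production rates
#'
#' The linear production laws `b_s(R) = k_s R` (new shoots from rhizome) and
#' `b_r(S) = k_r S` (carbohydrate return from stems to rhizome). Linearity is
#' deliberate: an invasive stand has no intrinsic carrying capacity over the
#' time scale of interest, and unbounded growth is a real model outcome.
#'
#' @param R rhizome biomass (units), `>= 0`.
#' @param S stem biomass (units), `>= 0`.
#' @param params a [kw_params()] object.
#' @return biomass units per day.
#' @export
stem_production <- function(R, params) {
  if (any(R < 0)) stop("R must be >= 0")
  params$k_s * R
}

#' @rdname stem_production
#' @export
rhizome_production <- function(S, params) {
  if (any(S < 0)) stop("S must be >= 0")
  params$k_r * S
}
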