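#' Equilibrium predation pressure c*
#'
#' At any coexistence equilibrium the per-unit-biomass predation pressure
#' `c = e sigma L* / (1 + h e sigma S*)` must satisfy
#' `mu_s + c = (k_r k_s / mu_r) (1 - exp(-(mu_s + c) tau_s))`,
#' which has a unique positive root `c*` precisely when the knotweed grows
#' in the absence of the insect (`mu_r mu_s < k_r k_s (1 - exp(-mu_s
#' tau_s))`). Note that `c*` does not involve `h`.
#'
#' @param params a [kw_params()] object.
#' @return the root `c*`, per day (bisection to 1e-12 relative).
#' @examples
#' solve_cstar(kw_params())  # 0.99 for the simulation parameter set
#' @export
solve_cstar <- function(params) {
  p <- params
  if (!classify_insect_free(p) == "grows") {
    stop("no positive c* exists: the insect-free growth condition ",
         "mu_r mu_s < k_r k_s (1 - exp(-mu_s tau_s)) fails")
  }
  f <- function(cc) {
    (p$mu_s + cc) - (p$k_r * p$k_s / p$mu_r) *
      (1 - exp(-(p$mu_s + cc) * p$tau_s))
  }
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(1e-15, upper), tol = 1e-14)$root
}

#' Equilibrium adults-per-stem ratio phi(S)
#'
#' The positive root of `b_p(phi) exp(-tau_p mu_l(S)) = mu_a phi`: the
#' adults-per-stem ratio at which per-stem recruitment of new adults
#' balances per-stem adult mortality, given stem biomass `S`. For the
#' Ricker default this has the closed form
#' `phi(S) = (1/q) log(P exp(-tau_p mu_l(S)) / mu_a)`,
#' defined if and only if the log argument exceeds 1; `phi` is increasing
#' in `S` and tends to `alpha(0)` as `S -> Inf`. Where no positive root
#' exists (larval mortality too high at small `S`), `NA` is returned.
#'
#' @param S stem biomass, `> 0`; vectorised.
#' @param params a [kw_params()] object.
#' @return adults per stem, or `NA` where undefined.
#' @export
phi_adults_per_stem <- function(S, params) {
  if (any(S <= 0)) stop("S must be > 0")
  vapply(S, function(s) phi_scalar(s, params), numeric(1))
}

phi_scalar <- function(S, params) {
  surv <- exp(-params$tau_p * params$mu_l(S))
  if (!params$custom_forms) {
    arg <- params$P * surv / params$mu_a
    if (arg <= 1) return(NA_real_)
    return(log(arg) / params$q)
  }
  # general closure: positive root of b_p(x) surv - mu_a x
  f <- function(x) params$b_p(x) * surv - params$mu_a * x
  eps <- 1e-10
  if (f(eps) <= 0) return(NA_real_)
  upper <- 1
  it <- 0
  while (f(upper) > 0 && it < 200) { upper <- upper * 2; it <- it + 1 }
  if (f(upper) > 0) return(NA_real_)
  stats::uniroot(f, c(eps, upper), tol = 1e-14)$root
}

# smallest S for which phi is defined (default forms: closed form)
phi_domain_lower <- function(params) {
  if (!params$custom_forms) {
    target <- log(params$P / params$mu_a) / params$tau_p  # mu_l at boundary
    if (target >= params$k_l + params$m) return(0)
    if (target <= params$m) return(Inf)
    return(-log((target - params$m) / params$k_l))
  }
  if (!is.na(phi_scalar(1e-12, params))) return(0)
  lo <- 1e-12; hi <- 1
  it <- 0
  while (is.na(phi_scalar(hi, params)) && it < 100) { hi <- hi * 2; it <- it + 1 }
  if (is.na(phi_scalar(hi, params))) return(Inf)
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (is.na(phi_scalar(mid, params))) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-12) break
  }
  hi
}

#' Coexistence equilibrium of the full model
#'
#' Computes the positive equilibrium `(L*, A*, S*, R*)` for the current
#' handling time `h`. With `c*` from [solve_cstar()] and `phi` from
#' [phi_adults_per_stem()], the stem component `S*` must satisfy the scalar
#' equation
#' `mu_l(S) (1 + h e sigma S) c* / (e sigma) =
#'  S b_p(phi(S)) (1 - exp(-tau_p mu_l(S)))`,
#' whose left side is the larval loss needed to hold predation pressure at
#' `c*` and whose right side is larval recruitment. The equation is scanned
#' for sign changes on a 2000-point logarithmic grid over the domain where
#' `phi` is defined (capped at `S = 1e8`, beyond which both sides are
#' affine and no further roots arise), and each bracket is refined by
#' bisection to 1e-12 relative. The remaining components follow from
#' `A* = S* phi(S*)`, `L* = (1 + h e sigma S*) c* / (e sigma)`,
#' `R* = k_r S* / mu_r`. For large `h` the left side outgrows the right
#' everywhere and no equilibrium exists (`exists = FALSE`).
#'
#' Where several roots are bracketed, all are reported and the smallest is
#' the primary. The restriction of the scan to the `phi`-defined domain is
#' deliberate: stem biomasses at which no positive adults-per-stem balance
#' exists cannot support a positive-insect equilibrium.
#'
#' @param params a [kw_params()] object with finite `h`.
#' @param S_max upper scan cap, biomass units (default 1e8).
#' @param n_grid scan grid size (default 2000).
#' @return An object of class `"kw_equilibrium"`: `exists`, components
#'   `L_star`, `A_star`, `S_star`, `R_star`, the scalars `c_star` and
#'   `phi_star`, relative `residuals` of the four equilibrium balance
#'   equations, and `all_S_roots`.
#' @export
solve_equilibrium <- function(params, S_max = 1e8, n_grid = 2000) {
  require_h(params, "solve_equilibrium()")
  p <- params
  cs <- solve_cstar(p)
  esig <- p$e * p$sigma

  lhs <- function(S) p$mu_l(S) * (1 + p$h * esig * S) * cs / esig
  rhs <- function(S) {
    ph <- vapply(S, function(s) phi_scalar(s, p), numeric(1))
    out <- numeric(length(S))
    ok <- !is.na(ph)
    out[!ok] <- NA_real_
    out[ok] <- S[ok] * p$b_p(ph[ok]) * (1 - exp(-p$tau_p * p$mu_l(S[ok])))
    out
  }

  S_lo <- phi_domain_lower(p)
  if (!is.finite(S_lo)) {
    return(kw_equilibrium_absent(cs, p))
  }
  S_lo <- max(S_lo * (1 + 1e-9), 1e-12)
  grid <- exp(seq(log(S_lo), log(S_max), length.out = n_grid))
  fval <- lhs(grid) - rhs(grid)
  ok <- which(!is.na(fval))
  roots <- numeric(0)
  if (length(ok) >= 2) {
    g <- grid[ok]; fv <- fval[ok]
    flips <- which(fv[-1] * fv[-length(fv)] <= 0 & fv[-1] != fv[-length(fv)])
    for (i in flips) {
      r <- stats::uniroot(function(S) lhs(S) - rhs(S), c(g[i], g[i + 1]),
                          tol = 1e-12 * max(1, g[i]))$root
      roots <- c(roots, r)
    }
    exact <- g[fv == 0]
    roots <- sort(unique(c(roots, exact)))
  }
  if (!length(roots)) {
    return(kw_equilibrium_absent(cs, p))
  }

  S_star <- roots[1]
  phi_star <- phi_scalar(S_star, p)
  A_star <- S_star * phi_star
  L_star <- (1 + p$h * esig * S_star) * cs / esig
  R_star <- p$k_r * S_star / p$mu_r
  res <- equilibrium_residuals(L_star, A_star, S_star, R_star, p)

  structure(list(
    exists = TRUE, L_star = L_star, A_star = A_star, S_star = S_star,
    R_star = R_star, c_star = cs, phi_star = phi_star,
    residuals = res, all_S_roots = roots, h = p$h
  ), class = "kw_equilibrium")
}

kw_equilibrium_absent <- function(cs, p) {
  structure(list(
    exists = FALSE, L_star = NA_real_, A_star = NA_real_,
    S_star = NA_real_, R_star = NA_real_, c_star = cs,
    phi_star = NA_real_, residuals = rep(NA_real_, 4),
    all_S_roots = numeric(0), h = p$h
  ), class = "kw_equilibrium")
}

# relative residuals of the four equilibrium balance equations
equilibrium_residuals <- function(L, A, S, R, p) {
  esig <- p$e * p$sigma
  cc <- esig * L / (1 + p$h * esig * S)
  ml <- p$mu_l(S)
  bp <- p$b_p(A / S)
  rel <- function(a, b) abs(a - b) / max(abs(a), abs(b), 1e-300)
  c(
    stems   = rel((p$mu_s + cc) * S,
                  p$k_s * R * (1 - exp(-p$mu_s * p$tau_s) * exp(-p$tau_s * cc))),
    rhizome = rel(p$k_r * S, p$mu_r * R),
    larvae  = rel(ml * L, S * bp * (1 - exp(-p$tau_p * ml))),
    adults  = rel(S * bp * exp(-p$tau_p * ml), p$mu_a * A)
  )
}

#' @export
print.kw_equilibrium <- function(x, ...) {
  if (!x$exists) {
    cat(sprintf(
      "No coexistence equilibrium at h = %.6g (c* = %.6g)\n", x$h, x$c_star))
    return(invisible(x))
  }
  cat(sprintf("Coexistence equilibrium at h = %.6g\n", x$h))
  cat(sprintf("  L* = %.6g  A* = %.6g  S* = %.6g  R* = %.6g\n",
              x$L_star, x$A_star, x$S_star, x$R_star))
  cat(sprintf("  c* = %.6g per day, phi(S*) = %.6g adults/stem\n",
              x$c_star, x$phi_star))
  cat(sprintf("  max residual = %.3g\n", max(x$residuals)))
  if (length(x$all_S_roots) > 1) {
    cat("  additional S roots:",
        paste(format(x$all_S_roots[-1]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sweep equilibrium existence over handling times
#'
#' @param params a [kw_params()] object (its `h` is ignored).
#' @param h_grid numeric vector of handling times.
#' @return data.frame with columns `h`, `exists`, `S_star`, `L_star`,
#'   `A_star`, `R_star`.
#' @export
equilibrium_sweep <- function(params, h_grid) {
  rows <- lapply(h_grid, function(h) {
    eq <- solve_equilibrium(set_handling_time(params, h))
    data.frame(h = h, exists = eq$exists, S_star = eq$S_star,
               L_star = eq$L_star, A_star = eq$A_star, R_star = eq$R_star)
  })
  do.call(rbind, rows)
}
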