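#' Insect-free growth/decay classification
#'
#' With no psyllids, the rhizome obeys a linear distributed-delay equation
#' whose dominant eigenvalue is real: the stand grows exponentially when
#' `mu_r mu_s < k_r k_s (1 - exp(-mu_s tau_s))` and decays when the
#' inequality is reversed.
#'
#' @param params a [kw_params()] object.
#' @return `"grows"`, `"decays"`, or `"boundary"` at exact equality.
#' @export
classify_insect_free <- function(params) {
  p <- params
  lhs <- p$mu_r * p$mu_s
  rhs <- p$k_r * p$k_s * (1 - exp(-p$mu_s * p$tau_s))
  if (lhs < rhs) "grows" else if (lhs > rhs) "decays" else "boundary"
}

#' Dominant real root of the insect-free characteristic equation
#'
#' Solves `lambda + mu_r = k_r k_s (1 - exp(-(lambda + mu_s) tau_s)) /
#' (lambda + mu_s)` for its unique real root. The left side is increasing
#' and the right side decreasing in `lambda`, so the root is found by
#' bracket expansion and bisection; its sign reproduces the insect-free
#' growth/decay classification.
#'
#' @param params a [kw_params()] object.
#' @return per-day exponential rate (positive in the growth regime).
#' @examples
#' insect_free_growth_rate(kw_params())  # ~ 0.0900 per day
#' @export
insect_free_growth_rate <- function(params) {
  p <- params
  f <- function(lam) {
    x <- lam + p$mu_s
    (lam + p$mu_r) - p$k_r * p$k_s * p$tau_s * g_decay(x * p$tau_s)
  }
  lo <- -min(p$mu_r, p$mu_s) + 1e-12
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  while (f(lo) > 0) lo <- lo - (hi - lo)
  stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
}

#' Psyllid low-density growth condition
#'
#' Checks `b_p'(0) exp(-m tau_p) > mu_a`: with unlimited stems and few
#' adults, the insect population grows only if per-adult recruitment
#' (discounted by larval survival at plentiful sap) exceeds adult
#' mortality. Strict inequality is required.
#'
#' @param params a [kw_params()] object.
#' @return logical.
#' @export
psyllid_growth_condition <- function(params) {
  params$b_p_deriv(0) * exp(-params$m * params$tau_p) > params$mu_a
}

#' Adults-per-stem amplitude ratio alpha(lambda)
#'
#' In a solution where all four variables grow like `exp(lambda t)`, the
#' adults-per-stem ratio approaches the positive solution `alpha(lambda)`
#' of `(lambda + mu_a) alpha = exp(-(lambda + m) tau_p) b_p(alpha)`. For
#' the Ricker default this has the closed form
#' `alpha(lambda) = (1/q) log(P exp(-(lambda + m) tau_p) / (lambda + mu_a))`,
#' defined while the log argument exceeds 1; `alpha(0)` does not involve
#' `h` and `alpha` decreases in `lambda` near 0. Where no positive solution
#' exists, `NA` is returned.
#'
#' @param lambda exponential rate, per day, `>= 0`; vectorised.
#' @param params a [kw_params()] object.
#' @param method `"closed_form"` (Ricker default only) or `"bisection"`
#'   (any birth closure); `"auto"` picks the closed form when available.
#' @return adults per stem, or `NA` where undefined.
#' @examples
#' alpha_ratio(0, kw_params())  # 4.6906 adults per stem
#' @export
alpha_ratio <- function(lambda, params,
                        method = c("auto", "closed_form", "bisection")) {
  method <- match.arg(method)
  if (any(lambda < 0)) stop("lambda must be >= 0")
  if (method == "auto") {
    method <- if (params$custom_forms) "bisection" else "closed_form"
  }
  if (method == "closed_form" && params$custom_forms) {
    stop("closed form requires the default Ricker birth function")
  }
  vapply(lambda, function(l) alpha_scalar(l, params, method), numeric(1))
}

alpha_scalar <- function(lambda, p, method) {
  surv <- exp(-(lambda + p$m) * p$tau_p)
  if (method == "closed_form") {
    arg <- p$P * surv / (lambda + p$mu_a)
    if (arg <= 1) return(NA_real_)
    return(log(arg) / p$q)
  }
  f <- function(x) surv * p$b_p(x) - (lambda + p$mu_a) * x
  eps <- 1e-12
  if (f(eps) <= 0) return(NA_real_)
  upper <- 1
  it <- 0
  while (f(upper) > 0 && it < 200) { upper <- upper * 2; it <- it + 1 }
  if (f(upper) > 0) return(NA_real_)
  stats::uniroot(f, c(eps, upper), tol = 1e-14)$root
}

# right-hand side of the growth characteristic equation at rate lambda
growth_char_rhs <- function(lambda, p) {
  a <- alpha_ratio(lambda, p)
  if (is.na(a)) return(NA_real_)
  mp <- lambda + p$m
  # per-unit-biomass predation pressure of the exponential ansatz, c1/(c3 h)
  press <- p$b_p(a) * (1 - exp(-mp * p$tau_p)) / (p$h * mp)
  x <- lambda + p$mu_s + press
  p$k_r * p$k_s * p$tau_s * g_decay(x * p$tau_s)
}

#' Joint growth rate of knotweed and psyllid
#'
#' Smallest positive real root of the characteristic equation for the
#' regime in which all four variables grow exponentially together: the
#' insect-free equation with the per-unit-biomass predation pressure
#' `b_p(alpha(lambda)) (1 - exp(-(lambda + m) tau_p)) / (h (lambda + m))`
#' added to the stem loss rate. The window `(0, lambda_max]` (default
#' `lambda_max` = insect-free rate) is scanned densely for sign changes and
#' each bracket refined by bisection. Any root is strictly below the
#' insect-free rate: predation can slow the growth but, in this regime, not
#' stop it. As `h -> Inf` the equation collapses to the insect-free one.
#'
#' @param params a [kw_params()] object with finite `h > 0`.
#' @param lambda_max upper end of the scan window (default: insect-free
#'   dominant root).
#' @param n_grid scan grid size (default 2000).
#' @return An object of class `"kw_spectral_scan"` with fields `equation =
#'   "growth"`, `roots`, `dominant_root` (`NA` if none), and at the
#'   smallest root the amplitude ratios `alpha` (= adults per stem, c2/c3)
#'   and `c1_over_c3` (larvae per unit stem biomass).
#' @export
coupled_growth_rate <- function(params, lambda_max = NULL, n_grid = 2000) {
  require_h(params, "coupled_growth_rate()")
  if (params$h <= 0) stop("coupled growth requires h > 0")
  p <- params
  if (is.null(lambda_max)) lambda_max <- insect_free_growth_rate(p)
  if (lambda_max <= 0) stop("lambda_max must be > 0")
  f <- function(lam) lam + p$mu_r - growth_char_rhs(lam, p)
  grid <- seq(lambda_max * 1e-6, lambda_max, length.out = n_grid)
  fv <- vapply(grid, f, numeric(1))
  ok <- which(!is.na(fv))
  if (length(ok) < 2) {
    return(new_spectral_scan("growth", c(0, lambda_max), n_grid,
                             numeric(0), note = "alpha(lambda) nonexistent on the window"))
  }
  g <- grid[ok]; fvo <- fv[ok]
  flips <- which(fvo[-1] * fvo[-length(fvo)] < 0)
  roots <- vapply(flips, function(i) {
    stats::uniroot(f, c(g[i], g[i + 1]), tol = 1e-14)$root
  }, numeric(1))
  roots <- sort(roots)
  scan <- new_spectral_scan("growth", c(0, lambda_max), n_grid, roots)
  if (length(roots)) {
    lam <- roots[1]
    a <- alpha_ratio(lam, p)
    scan$alpha <- a
    scan$c1_over_c3 <- p$b_p(a) * (1 - exp(-(lam + p$m) * p$tau_p)) /
      (lam + p$m)
  }
  scan
}

#' Critical handling time h_crit
#'
#' The threshold handling time below which bounded, controlled dynamics are
#' conjectured: the value of `h` at which the growth characteristic
#' equation loses its small positive root, i.e. the unique root of
#' `mu_r = k_r k_s (1 - exp(-X tau_s)) / X` with
#' `X = mu_s + b_p(alpha(0)) (1 - exp(-m tau_p)) / (m h)`.
#' The right-hand side increases with `h` (and `alpha(0)` does not involve
#' `h`), so the root is unique; it is found by bisection on
#' `[1e-6, 1e4]`.
#'
#' @param params a [kw_params()] object (`h` ignored).
#' @param interval bracketing interval for the bisection.
#' @return days per unit biomass per larva.
#' @examples
#' critical_handling_time(kw_params())  # ~ 17.4172
#' @export
critical_handling_time <- function(params, interval = c(1e-6, 1e4)) {
  p <- params
  if (classify_insect_free(p) != "grows") {
    stop("h_crit requires the insect-free growth condition to hold")
  }
  a0 <- alpha_ratio(0, p)
  if (is.na(a0)) stop("alpha(0) does not exist for these parameters")
  f <- function(h) {
    x <- p$mu_s + p$b_p(a0) * (1 - exp(-p$m * p$tau_p)) / (p$m * h)
    p$mu_r - p$k_r * p$k_s * p$tau_s * g_decay(x * p$tau_s)
  }
  flo <- f(interval[1]); fhi <- f(interval[2])
  if (flo * fhi > 0) {
    stop(sprintf(
      "bisection bracket failure: f(%g) = %g, f(%g) = %g",
      interval[1], flo, interval[2], fhi))
  }
  stats::uniroot(f, interval, tol = 1e-12)$root
}

#' Linearisation functions F1--F6 about the coexistence equilibrium
#'
#' Evaluates the six real functions whose combination
#' `F3 = -F1 F4 F5 / (F2 F5 + F6)` is the characteristic equation of the
#' linearisation about the coexistence equilibrium, with all amplitude
#' components eliminated. They are built from the mean survival kernel
#' `g(x) = (1 - exp(-x))/x`, the local slopes `b_p'(phi(S*))` and
#' `mu_l'(S*)`, and the equilibrium pressure `c*`. The removable
#' singularities at `lambda = 0` (difference quotients of `g` in `lambda`)
#' are evaluated by the analytic limit `-tau g'(x)`.
#'
#' Violations of the stability hypotheses (`b_p'(phi(S*)) <= 0`, concavity
#' reserve `b_p(phi*) - phi* b_p'(phi*) <= 0`, or
#' `mu_a <= b_p'(phi*) exp(-tau_p mu_l(S*))`) are attached as a
#' `"hypothesis_warnings"` attribute rather than raising errors.
#'
#' @param lambda real rate(s), per day; vectorised.
#' @param equilibrium a [solve_equilibrium()] result with `exists = TRUE`.
#' @param params the generating [kw_params()] object.
#' @return matrix with one row per `lambda` and columns `F1`..`F6`.
#' @export
linearisation_F <- function(lambda, equilibrium, params) {
  stopifnot(inherits(equilibrium, "kw_equilibrium"))
  if (!equilibrium$exists) stop("equilibrium does not exist")
  p <- params
  eq <- equilibrium
  S <- eq$S_star
  phi <- eq$phi_star
  cs <- eq$c_star
  esig <- p$e * p$sigma
  mlS <- p$mu_l(S)
  mlpS <- p$mu_l_deriv(S)
  bp <- p$b_p(phi)
  bpd <- p$b_p_deriv(phi)
  conc <- bp - phi * bpd

  warns <- character(0)
  if (bpd <= 0) warns <- c(warns, "b_p'(phi(S*)) <= 0")
  if (conc <= 0) warns <- c(warns, "b_p(phi*) - phi* b_p'(phi*) <= 0")
  if (p$mu_a <= bpd * exp(-p$tau_p * mlS)) {
    warns <- c(warns, "mu_a <= b_p'(phi*) exp(-tau_p mu_l(S*))")
  }

  # difference quotient (g(x0) - g(x0 + tau*lambda)) / lambda with analytic
  # lambda -> 0 limit -tau g'(x0)
  quot <- function(lambda, tau, x0) {
    ifelse(abs(lambda) < 1e-8,
           -tau * g_decay_deriv(x0),
           (g_decay(x0) - g_decay(x0 + tau * lambda)) / lambda)
  }

  xp <- p$tau_p * (lambda + mlS)
  Qp <- quot(lambda, p$tau_p, p$tau_p * mlS)
  xs0 <- p$tau_s * (p$mu_s + cs)
  Qs <- quot(lambda, p$tau_s, xs0)
  sat <- 1 + p$h * esig * S

  F1 <- bpd * p$tau_p * g_decay(xp)
  F2 <- conc * p$tau_p * g_decay(xp) - mlpS * S * bp * p$tau_p * Qp
  F3 <- lambda + p$mu_a - bpd * exp(-xp)
  F4 <- exp(-xp) * conc -
    mlpS * S * bp * p$tau_p * exp(-p$tau_p * mlS) * g_decay(p$tau_p * lambda)
  F5 <- (p$k_r * p$k_s * S * esig * p$tau_s / (p$mu_r * sat)) * Qs
  F6 <- 1 - (p$k_r * p$k_s * p$tau_s / (lambda + p$mu_r)) *
    g_decay(p$tau_s * (lambda + p$mu_s + cs)) -
    (p$k_r * p$k_s * S * p$h * esig * cs * p$tau_s / (p$mu_r * sat)) * Qs

  out <- cbind(F1 = F1, F2 = F2, F3 = F3, F4 = F4, F5 = F5, F6 = F6)
  if (length(warns)) attr(out, "hypothesis_warnings") <- warns
  out
}

#' Real-root scan of the linearised characteristic equation
#'
#' Scans `G(lambda) = F3 (F2 F5 + F6) + F1 F4 F5` for sign changes on a
#' real window and refines each bracket by bisection. Roots of the
#' characteristic equation are `G = 0` with non-vanishing denominator
#' `F2 F5 + F6`; denominator zeros are excluded and reported separately, as
#' is the pole of `F6` at `lambda = -mu_r`. Only real roots are sought;
#' negativity of all real roots is necessary but not sufficient for local
#' stability (the dominant root need not be real).
#'
#' @param params a [kw_params()] object with finite `h`.
#' @param equilibrium optional precomputed [solve_equilibrium()] result.
#' @param window real scan window (default `c(-0.5, 1)`).
#' @param n_grid scan grid size (default 2000).
#' @return An object of class `"kw_spectral_scan"` with `equation =
#'   "linearised"`, sorted `roots`, `dominant_root` (largest real root or
#'   `NA`), `denominator_zeros`, and per-root residuals of `G`.
#' @export
linearised_real_roots <- function(params, equilibrium = NULL,
                                  window = c(-0.5, 1), n_grid = 2000) {
  require_h(params, "linearised_real_roots()")
  if (is.null(equilibrium)) equilibrium <- solve_equilibrium(params)
  if (!equilibrium$exists) stop("no coexistence equilibrium at this h")

  Gfun <- function(lam) {
    F <- linearisation_F(lam, equilibrium, params)
    F[, "F3"] * (F[, "F2"] * F[, "F5"] + F[, "F6"]) +
      F[, "F1"] * F[, "F4"] * F[, "F5"]
  }
  Dfun <- function(lam) {
    F <- linearisation_F(lam, equilibrium, params)
    F[, "F2"] * F[, "F5"] + F[, "F6"]
  }

  pole <- -params$mu_r
  grid <- seq(window[1], window[2], length.out = n_grid)
  # keep clear of the F6 pole at lambda = -mu_r
  grid <- grid[abs(grid - pole) > 1e-6]
  gv <- Gfun(grid)
  dv <- Dfun(grid)

  find_roots <- function(vals, fn) {
    flips <- which(vals[-1] * vals[-length(vals)] < 0)
    # a sign flip across the pole is not a zero
    flips <- flips[!(grid[flips] < pole & grid[flips + 1] > pole)]
    vapply(flips, function(i) {
      stats::uniroot(fn, c(grid[i], grid[i + 1]), tol = 1e-14)$root
    }, numeric(1))
  }
  droots <- sort(find_roots(dv, Dfun))
  groots <- sort(find_roots(gv, Gfun))
  if (length(droots) && length(groots)) {
    near_pole <- vapply(groots, function(r) any(abs(r - droots) < 1e-8),
                        logical(1))
    groots <- groots[!near_pole]
  }
  scale <- max(abs(gv), 1)
  scan <- new_spectral_scan("linearised", window, n_grid, groots)
  scan$residuals <- if (length(groots)) abs(Gfun(groots)) / scale else numeric(0)
  scan$denominator_zeros <- droots
  scan
}

new_spectral_scan <- function(equation, window, n_grid, roots, note = NULL) {
  structure(list(
    equation = equation, window = window, n_grid = n_grid,
    roots = sort(roots),
    dominant_root = if (length(roots)) max(roots) else NA_real_,
    note = note
  ), class = "kw_spectral_scan")
}

#' @export
print.kw_spectral_scan <- function(x, ...) {
  cat(sprintf("Real-root scan of the %s characteristic equation\n",
              x$equation))
  cat(sprintf("  window [%g, %g], %d grid points\n",
              x$window[1], x$window[2], x$n_grid))
  if (length(x$roots)) {
    cat("  roots:", paste(format(x$roots, digits = 8), collapse = ", "), "\n")
    cat(sprintf("  dominant real root: %.8g\n", x$dominant_root))
  } else {
    cat("  no real roots found\n")
  }
  if (!is.null(x$denominator_zeros) && length(x$denominator_zeros)) {
    cat("  denominator zeros:",
        paste(format(x$denominator_zeros, digits = 8), collapse = ", "), "\n")
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
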