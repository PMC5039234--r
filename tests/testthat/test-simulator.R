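# build a bare trajectory object around analytic series, for testing the
# trajectory statistics without running the solver
fake_traj <- function(times, S, L = S, status = "ok") {
  structure(list(times = times, L = L, A = L, S = S, R = S,
                 Ml = cumsum(c(0, diff(times))), Mf = times * 0,
                 step = diff(times)[1], status = status),
            class = "kw_trajectory")
}

test_that("zero insect history stays at zero and leaves the plant insect-free", {
  p <- set_handling_time(sim_params, 1)
  tr <- simulate_stand(p, make_history(p, A0 = 0, R0 = 500), t_end = 400)
  expect_true(all(tr$L == 0))
  expect_true(all(tr$A == 0))
  expect_true(all(tr$Mf == 0))
  expect_true(all(tr$S > 0) && all(tr$R > 0))
})

test_that("insect-free rhizome growth matches an independent DDE solution and the characteristic rate", {
  p <- set_handling_time(sim_params, 1)
  h0 <- make_history(p, A0 = 0, R0 = 500)
  tr <- simulate_stand(p, h0, t_end = 400)

  # oracle: deSolve::dede on the reduced linear (S, R) system with one
  # discrete lag (adaptive multistep -- an independent integration route)
  library(deSolve)
  derivs <- function(t, y, parms) {
    Rlag <- if (t < p$tau_s) h0$R0 else deSolve::lagvalue(t - p$tau_s, 2)
    list(c(-p$mu_s * y[1] + p$k_s * y[2] -
             exp(-p$mu_s * p$tau_s) * p$k_s * Rlag,
           p$k_r * y[1] - p$mu_r * y[2]))
  }
  out <- deSolve::dede(y = c(h0$S0, h0$R0), times = seq(0, 400, 0.5),
                       func = derivs, parms = NULL,
                       atol = 1e-12, rtol = 1e-12)
  iR <- stats::approx(out[, 1], out[, 3], xout = tr$times)$y
  expect_lt(max(abs(iR - tr$R) / abs(iR)), 1e-6)

  # asymptotic rate equals the dominant root of the characteristic equation
  lam <- insect_free_growth_rate(p)
  tr2 <- simulate_stand(p, h0, t_end = 900)
  expect_equal(growth_rate_estimate(tr2, "R", c(600, 900)), lam,
               tolerance = 1e-3)
})

test_that("full model agrees with an independent adaptive DDE solution", {
  p <- set_handling_time(sim_params, hc_ref - 1)
  hs <- make_history(p)
  tr <- simulate_stand(p, hs, t_end = 150)
  mul0 <- p$mu_l(hs$S0)
  fr0 <- functional_response(hs$L0, hs$S0, p)
  derivs <- function(t, y, parms) {
    tp <- t - p$tau_p; ts <- t - p$tau_s
    if (tp < 0) {
      Ap <- hs$A0; Sp <- hs$S0; Mlp <- tp * mul0
    } else {
      Ap <- deSolve::lagvalue(tp, 2); Sp <- deSolve::lagvalue(tp, 3)
      Mlp <- deSolve::lagvalue(tp, 5)
    }
    if (ts < 0) {
      Rs <- hs$R0; Mfs <- ts * fr0
    } else {
      Rs <- deSolve::lagvalue(ts, 4); Mfs <- deSolve::lagvalue(ts, 6)
    }
    ml <- p$mu_l(y[3])
    f <- functional_response(y[1], max(y[3], 0), p)
    mat <- egg_laying_total(max(Ap, 0), max(Sp, 0), p) * exp(-(y[5] - Mlp))
    list(c(-ml * y[1] + egg_laying_total(y[2], max(y[3], 0), p) - mat,
           mat - p$mu_a * y[2],
           -(p$mu_s + f) * y[3] + p$k_s * y[4] -
             exp(-p$mu_s * p$tau_s) * exp(-(y[6] - Mfs)) * p$k_s * Rs,
           p$k_r * y[3] - p$mu_r * y[4], ml, f))
  }
  out <- deSolve::dede(y = c(hs$L0, hs$A0, hs$S0, hs$R0, 0, 0),
                       times = seq(0, 150, 0.5), func = derivs,
                       parms = NULL, atol = 1e-10, rtol = 1e-10,
                       maxsteps = 100000)
  for (j in 1:4) {
    v <- c("L", "A", "S", "R")[j]
    iv <- stats::approx(out[, 1], out[, 1 + j], xout = tr$times)$y
    # the transient has near-singular stem collapses; agreement of two very
    # different integration routes to a few percent pins down the dynamics
    expect_lt(max(abs(iv - tr[[v]]) / pmax(abs(iv), 1e-6)), 0.05)
  }
})

test_that("states stay non-negative and cumulants non-decreasing along trajectories", {
  for (h in c(hc_ref - 1, hc_ref + 15)) {
    tr <- suppressWarnings(run_short(h = h, t_end = 600))
    for (v in c("L", "A", "S", "R")) expect_true(all(tr[[v]] >= 0))
    expect_true(all(diff(tr$Ml) >= 0))
    expect_true(all(diff(tr$Mf) >= 0))
  }
})

test_that("halving the step barely changes the solution in the convergent regime", {
  a <- utils::tail(as.data.frame(run_short(t_end = 1000, step = 0.05)), 1)
  b <- utils::tail(as.data.frame(run_short(t_end = 1000, step = 0.025)), 1)
  expect_lt(max(abs(a[2:5] - b[2:5]) / abs(b[2:5])), 1e-4)
})

test_that("the pure-R engine reproduces the compiled engine", {
  p <- set_handling_time(sim_params, hc_ref - 1)
  hs <- make_history(p)
  a <- as.data.frame(simulate_stand(p, hs, t_end = 60, engine = "cpp"))
  b <- as.data.frame(simulate_stand(p, hs, t_end = 60, engine = "r"))
  expect_equal(b, a, tolerance = 1e-10)
})

test_that("custom closures run through the R engine and change the dynamics", {
  bp <- function(x) 16.9867 * x / (1 + x)^2   # Beverton-Holt-like crowding
  bpd <- function(x) 16.9867 * (1 - x) / (1 + x)^3
  p <- kw_params(h = 1, birth_fn = bp, birth_deriv = bpd)
  hs <- make_history(p, A0 = 5, R0 = 50)
  tr <- simulate_stand(p, hs, t_end = 30, step = 0.1)
  expect_identical(tr$status, "ok")
  expect_error(simulate_stand(p, hs, t_end = 10, engine = "cpp"),
               "custom birth/mortality")
})

test_that("predation can only slow the stand down, never speed it up", {
  # horizon kept short of the point where the explicit stepper's cost
  # explodes: with h this large the larval load grows ~e^{0.09 t} and the
  # stem troughs become ever stiffer
  p <- set_handling_time(sim_params, 10 * hc_ref)
  with_insects <- simulate_stand(p, make_history(p), t_end = 300)
  no_insects <- simulate_stand(p, make_history(p, A0 = 0), t_end = 300)
  expect_true(all(with_insects$S <= no_insects$S * (1 + 1e-8)))
})

test_that("integral forms of L and S are reproduced along trajectories", {
  # insect-free: stem integral is exact up to solver error
  p0 <- set_handling_time(sim_params, 1)
  tr0 <- simulate_stand(p0, make_history(p0, A0 = 0), t_end = 900)
  chk0 <- integral_consistency_check(tr0, c(300, 600, 900))
  expect_lt(chk0$max_residual, 1e-4)
  expect_true(all(tr0$L == 0))
  # full model, sampled densely enough to resolve the collapse fronts
  tr <- run_short(t_end = 600, out_dt = 0.05)
  chk <- integral_consistency_check(tr, seq(160, 590, length.out = 10))
  expect_lt(chk$max_residual, 1e-3)
  expect_error(integral_consistency_check(tr, 10), "must lie in")
})

test_that("growth-rate estimator recovers exact rates", {
  tt <- seq(0, 100, 0.5)
  tr <- fake_traj(tt, S = exp(0.05 * tt))
  expect_equal(growth_rate_estimate(tr, "S", c(0, 100)), 0.05)
  trc <- fake_traj(tt, S = rep(2, length(tt)))
  expect_equal(growth_rate_estimate(trc, "S", c(0, 100)), 0)
  trn <- fake_traj(tt, S = sin(tt))
  expect_error(growth_rate_estimate(trn, "S", c(0, 100)),
               "strictly positive")
})

test_that("oscillation period recovers a known 12-day cycle and rejects flat series", {
  tt <- seq(0, 400, 0.1)
  tr <- fake_traj(tt, S = 2 + sin(2 * pi * tt / 12))
  expect_equal(oscillation_period(tr, "S", c(0, 400)), 12, tolerance = 0.05)
  trc <- fake_traj(tt, S = rep(1, length(tt)))
  expect_error(oscillation_period(trc, "S", c(0, 400)), "fewer than 3 peaks")
})

test_that("regime classifier separates decay, stationary cycles, and growth", {
  tt <- seq(0, 2000, 0.5)
  dec <- fake_traj(tt, S = 5 + exp(-tt / 200) * sin(2 * pi * tt / 12))
  expect_identical(classify_regime_numeric(dec), "converged")
  sus <- fake_traj(tt, S = 5 + 2 * sin(2 * pi * tt / 12))
  expect_identical(classify_regime_numeric(sus), "sustained_oscillation")
  unb <- fake_traj(tt, S = exp(0.01 * tt) * (2 + sin(tt)))
  expect_identical(classify_regime_numeric(unb), "unbounded")
  tru <- fake_traj(tt, S = 5 + 0 * tt, status = "overflow")
  expect_identical(classify_regime_numeric(tru), "unbounded")
})

test_that("the overflow guard truncates runaway growth with a warning", {
  p <- set_handling_time(sim_params, 1)
  h0 <- make_history(p, A0 = 0, R0 = 500)
  expect_warning(
    tr <- simulate_stand(p, h0, t_end = 4000, guard = 1e30),
    "overflow guard")
  expect_identical(tr$status, "overflow")
  expect_lt(max(tr$times), 4000)
  expect_identical(classify_regime_numeric(tr), "unbounded")
})
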