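test_that("insect-free classification matches the threshold inequality and the root sign", {
  expect_identical(classify_insect_free(sim_params), "grows")
  expect_identical(classify_insect_free(kw_params(mu_r = 1)), "decays")
  expect_equal(insect_free_growth_rate(sim_params), 0.0900, tolerance = 1e-3)
  # the root solves the characteristic balance
  p <- sim_params
  lam <- insect_free_growth_rate(p)
  expect_equal((lam + p$mu_r) * (lam + p$mu_s),
               p$k_r * p$k_s * (1 - exp(-(lam + p$mu_s) * p$tau_s)),
               tolerance = 1e-12)
  # vanishing production: root tends to -mu_r
  pv <- kw_params(k_r = 1e-12)
  expect_equal(insect_free_growth_rate(pv), -pv$mu_r, tolerance = 1e-6)
})

test_that("classification sign equals root sign across random parameter draws", {
  set.seed(42)
  for (p in random_params(100)) {
    cls <- classify_insect_free(p)
    lam <- insect_free_growth_rate(p)
    expect_identical(cls, if (lam > 0) "grows" else "decays")
  }
})

test_that("the psyllid low-density growth condition is a strict threshold", {
  expect_true(psyllid_growth_condition(sim_params))
  expect_false(psyllid_growth_condition(kw_params(P = 0.1)))
  # exactly at threshold: strict inequality fails
  p <- sim_params
  P_star <- p$mu_a / exp(-p$m * p$tau_p)
  expect_false(psyllid_growth_condition(kw_params(P = P_star)))
})

test_that("alpha(lambda): closed form, bisection, monotonicity, h-independence", {
  p <- sim_params
  expect_equal(alpha_ratio(0, p), 4.6906, tolerance = 1e-4)
  lam <- seq(0, 0.05, length.out = 21)
  cf <- alpha_ratio(lam, p, method = "closed_form")
  bi <- alpha_ratio(lam, p, method = "bisection")
  expect_lt(max(abs(cf - bi)), 1e-10)
  expect_true(all(diff(cf) < 0))  # decreasing near 0
  # h never enters
  expect_identical(alpha_ratio(0.01, set_handling_time(p, 1)),
                   alpha_ratio(0.01, set_handling_time(p, 1e3)))
  expect_error(alpha_ratio(-0.1, p), "lambda must be")
})

test_that("h_crit reproduces its defining fixed point and monotone bracketing", {
  p <- sim_params
  hc <- critical_handling_time(p)
  expect_equal(hc, 17.4172, tolerance = 1e-4)
  a0 <- alpha_ratio(0, p)
  rhs28 <- function(h) {
    x <- p$mu_s + p$b_p(a0) * (1 - exp(-p$m * p$tau_p)) / (p$m * h)
    p$k_r * p$k_s * (1 - exp(-x * p$tau_s)) / x
  }
  expect_equal(rhs28(hc), p$mu_r, tolerance = 1e-10)
  expect_gt(rhs28(2 * hc), p$mu_r)   # right side increases with h
  expect_lt(rhs28(hc / 2), p$mu_r)
  expect_error(critical_handling_time(kw_params(mu_r = 1)),
               "growth condition")
})

test_that("joint growth rate exists above threshold, sits below the insect-free rate, and collapses to it as h grows", {
  p <- sim_params
  lam_if <- insect_free_growth_rate(p)
  for (h in c(2 * hc_ref, 10 * hc_ref)) {
    sc <- coupled_growth_rate(set_handling_time(p, h))
    expect_gt(length(sc$roots), 0)
    expect_gt(sc$roots[1], 0)
    expect_lt(sc$roots[1], lam_if)
    expect_true(is.finite(sc$alpha) && sc$alpha > 0)
    expect_true(is.finite(sc$c1_over_c3) && sc$c1_over_c3 > 0)
  }
  sc_inf <- coupled_growth_rate(set_handling_time(p, 1e6))
  expect_lt(abs(sc_inf$roots[1] - lam_if), 1e-4)
})

test_that("linearisation functions have the proved sign and limit structure at small h", {
  p <- set_handling_time(sim_params, 1)
  eq <- solve_equilibrium(p)
  lam <- seq(0, 5, length.out = 101)
  F <- linearisation_F(lam, eq, p)
  expect_null(attr(F, "hypothesis_warnings"))
  for (nm in c("F1", "F2", "F4", "F5")) {
    expect_true(all(F[, nm] > 0))
    expect_true(all(diff(F[, nm]) < 0))
  }
  expect_true(all(diff(F[, "F3"]) > 0))  # increasing
  expect_gt(F[1, "F3"], 0)               # F3(0) > 0 under the hypotheses
  D <- F[, "F2"] * F[, "F5"] + F[, "F6"]
  expect_true(all(D > 0))
  # large-lambda limits of F6 and the denominator (decay is O(1/lambda))
  for (lambig in c(1e3, 1e6)) {
    Fb <- linearisation_F(lambig, eq, p)
    tol <- if (lambig >= 1e6) 1e-6 else 1e-3
    expect_lt(abs(Fb[, "F6"] - 1), tol)
    expect_lt(abs(Fb[, "F2"] * Fb[, "F5"] + Fb[, "F6"] - 1), tol)
  }
  # lambda = 0 difference-quotient limit agrees with a small-lambda evaluation
  F0 <- linearisation_F(0, eq, p)
  Fe <- linearisation_F(1e-7, eq, p)
  expect_equal(as.numeric(F0), as.numeric(Fe), tolerance = 1e-5)
})

test_that("all real roots of the linearised characteristic equation are negative at small h", {
  p <- set_handling_time(sim_params, 1)
  sc <- linearised_real_roots(p)
  expect_true(length(sc$roots) > 0)
  expect_true(all(sc$roots < 0))
  expect_true(all(sc$residuals < 1e-10))
  # the pole of the rhizome factor is never reported as a zero
  expect_false(any(abs(sc$denominator_zeros + p$mu_r) < 1e-8))
})
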