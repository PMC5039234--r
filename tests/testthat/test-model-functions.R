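test_that("larval mortality has the exponential-decay form and bounds", {
  p <- sim_params
  expect_equal(larval_mortality(0, p), 1)            # k_l + m with k_l = 1 - m
  expect_equal(larval_mortality(1, p), 0.38084, tolerance = 1e-4)
  expect_equal(larval_mortality(1e9, p), p$m)
  # strictly decreasing with range (m, k_l + m] on a grid (the excess term
  # falls below double resolution of m beyond S ~ 40)
  S <- seq(0, 20, length.out = 400)
  v <- larval_mortality(S, p)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > p$m & v <= p$k_l + p$m))
  expect_error(larval_mortality(-1, p), "S must be")
})

test_that("per-stem birth rate is Ricker-shaped: slope P at 0, peak at 1/q", {
  p <- sim_params
  expect_equal(birth_per_stem(0, p), 0)
  expect_equal(birth_per_stem(1, p), 6.2491, tolerance = 1e-4)  # P/e
  eps <- 1e-8
  expect_equal(birth_per_stem(eps, p) / eps, p$P, tolerance = 1e-6)
  x <- seq(0, 10, length.out = 2001)
  v <- birth_per_stem(x, p)
  expect_equal(x[which.max(v)], 1 / p$q, tolerance = 1e-2)
  # unimodal: increasing then decreasing
  d <- diff(v)
  expect_true(all(d[x[-1] < 1 / p$q] > 0))
  expect_true(all(d[x[-length(x)] > 1 / p$q] < 0))
  expect_error(birth_per_stem(-0.1, p), "x must be")
})

test_that("stand-level egg laying vanishes without stems or adults and is continuous at S = 0", {
  p <- sim_params
  expect_identical(egg_laying_total(50, 0, p), 0)
  expect_identical(egg_laying_total(0, 1000, p), 0)
  expect_equal(egg_laying_total(10, 1000, p), 168.18, tolerance = 1e-4)
  # continuous extension: values -> 0 as S -> 0+ for fixed A (the rate
  # underflows to exactly 0 once the crowding exponent is extreme)
  S <- 10^seq(-1, -12, by = -1)
  v <- egg_laying_total(5, S, p)
  expect_true(all(diff(v) <= 0))
  expect_lt(v[1], 1e-15)
  expect_identical(v[length(v)], 0)
})

test_that("Holling type II response saturates in S and is linear when h = 0", {
  p <- set_handling_time(sim_params, 17)
  expect_identical(functional_response(0, 100, p), 0)
  expect_equal(functional_response(10, 100, p), 10 / 1701)
  p0 <- set_handling_time(sim_params, 0)
  L <- c(1, 5, 20); S <- c(0, 3, 500)
  expect_equal(functional_response(L, S, p0), p0$e * p0$sigma * L)
  # bounded by the linear response, equality iff h*S = 0
  grid <- expand.grid(L = c(1, 10), S = c(0, 0.5, 50))
  v <- functional_response(grid$L, grid$S, p)
  lin <- p$e * p$sigma * grid$L
  expect_true(all(v <= lin + 1e-12))
  expect_equal(v[grid$S == 0], lin[grid$S == 0])
  expect_true(all(v[grid$S > 0] < lin[grid$S > 0]))
})

test_that("the mean survival kernel g is 1 at 0, positive, decreasing, convex", {
  expect_equal(g_decay(0), 1)
  expect_equal(g_decay(1), 1 - exp(-1))
  expect_lt(g_decay(2), g_decay(1))
  x <- seq(-3, 30, length.out = 500)
  v <- g_decay(x)
  expect_true(all(v > 0))
  expect_true(all(diff(v) < 0))
  expect_true(all(diff(v, differences = 2) > 0))  # convex
  # series branch matches the direct formula at the crossover
  xx <- c(-2e-4, -5e-5, 5e-5, 2e-4)
  expect_equal(g_decay(xx), (1 - exp(-xx)) / xx, tolerance = 1e-12)
  # the direct derivative formula cancels catastrophically near 0, so only
  # ~8 digits of the reference value are meaningful there
  expect_equal(g_decay_deriv(xx),
               (exp(-xx) * (1 + xx) - 1) / xx^2, tolerance = 1e-6)
  expect_equal(g_decay_deriv(c(0.5, 2, 10)),
               (exp(-c(0.5, 2, 10)) * (1 + c(0.5, 2, 10)) - 1) /
                 c(0.5, 2, 10)^2, tolerance = 1e-12)
})

test_that("stem and rhizome production are the linear laws", {
  p <- sim_params
  expect_identical(stem_production(0, p), 0)
  expect_equal(stem_production(500, p), 50)
  expect_equal(rhizome_production(100, p), 10)
})

test_that("parameter validation names offending fields and enforces bounds", {
  expect_error(kw_params(sigma = 1.5), "sigma")
  expect_error(kw_params(mu_a = -1), "mu_a")
  expect_error(kw_params(zeta = 1), "unknown parameter")
  p <- kw_params(h = 2)
  expect_equal(set_handling_time(p, 5)$h, 5)
  expect_error(knotweedbc:::require_h(kw_params(), "x"), "requires a handling time")
})

test_that("custom birth/mortality closures are accepted and used", {
  bp <- function(x) 3 * x / (1 + x^2)       # alternative unimodal form
  bpd <- function(x) 3 * (1 - x^2) / (1 + x^2)^2
  p <- kw_params(h = 1, birth_fn = bp, birth_deriv = bpd)
  expect_true(p$custom_forms)
  expect_equal(birth_per_stem(2, p), 1.2)
  expect_error(kw_params(birth_fn = bp), "birth_deriv")
})
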