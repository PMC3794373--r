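test_that("mean degree solves the edge balance relation", {
  expect_equal(mean_degree(params_growth()), 10)
  expect_equal(mean_degree(params_deletion()), 8)
  expect_equal(mean_degree(params_pure_pa(4)), 8)  # 2c without internal edges
  # generic: <k>(1-r) = 2(c + m - r<k> - qm) holds for random parameter sets
  set.seed(7)
  for (i in 1:20) {
    p <- evo_params(c = sample(1:6, 1), m = sample(0:5, 1),
                    r = runif(1, 0, 0.95), q = runif(1), a = 1, b = 1,
                    s = 1, t = 1)
    kb <- mean_degree(p)
    expect_equal(kb * (1 - p$r), 2 * (p$c + p$m - p$r * kb - p$q * p$m),
                 tolerance = 1e-12)
  }
})

test_that("aggregate rates assemble the rate-equation coefficients", {
  ar <- aggregate_rates(params_growth())
  expect_equal(ar$phi, 7 / 10.5, tolerance = 1e-12)
  expect_equal(ar$psi, 3.5 / 10.5, tolerance = 1e-12)
  expect_equal(ar$dee, 0)
  ar2 <- aggregate_rates(params_deletion())
  expect_equal(ar2$phi, 7 / 8.5, tolerance = 1e-12)
  expect_equal(ar2$dee, 0.25, tolerance = 1e-12)
  expect_equal(aggregate_rates(params_pure_pa())$phi, 0.5)
  expect_equal(aggregate_rates(params_pure_pa())$psi, 0)
})

test_that("degree exponent limits match the known special cases", {
  # pure external preferential attachment: gamma = 3 for any c
  for (c in 1:5) expect_equal(predict_exponent(params_pure_pa(c)), 3)
  # edge deletion with q -> 1 restores the pure-PA exponent
  gq <- function(q) predict_exponent(
    evo_params(c = 3, m = 2, q = q, a = 0, b = 1, s = 0, t = 1))
  expect_equal(gq(1), 3, tolerance = 1e-12)
  # node deletion only: gamma = 1 + 2/(1-r), diverging as r -> 1
  for (r in c(0.1, 0.5, 0.9)) {
    g <- predict_exponent(evo_params(c = 3, r = r, a = 0, b = 1))
    expect_equal(g, 1 + 2 / (1 - r), tolerance = 1e-12)
  }
  expect_gt(predict_exponent(evo_params(c = 3, r = 0.999, a = 0, b = 1)), 1000)
  # double preferential attachment: 2 < gamma < 3
  for (c in 1:5) for (m in c(1, 5, 50)) {
    g <- predict_exponent(evo_params(c = c, m = m, a = 0, b = 1, s = 0, t = 1))
    expect_gt(g, 2); expect_lt(g, 3)
  }
  # random external attachment pushes gamma above 3
  for (a in c(0.1, 1, 10)) for (c in c(1, 3)) {
    g <- predict_exponent(evo_params(c = c, a = a, b = 1))
    expect_gt(g, 3)
    expect_equal(g, 3 + a / c, tolerance = 1e-12)  # known closed form
  }
  # benchmark parameter sets
  expect_equal(predict_exponent(params_growth()), 2.5, tolerance = 1e-12)
  expect_equal(predict_exponent(params_deletion()), 1 + 1 / (7 / 8.5 - 0.25),
               tolerance = 1e-12)
  # exponential phase has no exponent
  expect_error(predict_exponent(
    evo_params(c = 3, m = 2, r = 0.2, q = 0.1, a = 25, b = 1, s = 25, t = 1)),
    "exponential phase")
})

test_that("gamma is monotone in the homogenizing and heterogenizing directions", {
  gam <- function(...) predict_exponent(evo_params(...))
  # nondecreasing in a and in s
  ga <- vapply(seq(0, 5, 0.5), function(a)
    gam(c = 3, m = 2, a = a, b = 1, s = 0.5, t = 1), numeric(1))
  expect_true(all(diff(ga) >= 0))
  gs <- vapply(seq(0, 5, 0.5), function(s)
    gam(c = 3, m = 2, a = 0.5, b = 1, s = s, t = 1), numeric(1))
  expect_true(all(diff(gs) >= 0))
  # nonincreasing in m under double preferential attachment
  gm <- vapply(1:20, function(m)
    gam(c = 3, m = m, a = 0, b = 1, s = 0, t = 1), numeric(1))
  expect_true(all(diff(gm) <= 0))
})

test_that("small-degree shift is Psi/Phi under pure growth, zero without randomness", {
  expect_equal(predict_shift(params_pure_pa()), 0)
  expect_equal(predict_shift(params_growth()), 0.5, tolerance = 1e-12)
  expect_equal(predict_shift(evo_params(c = 3, a = 2, b = 1)), 2)  # a/b
  # continuity: shift -> 0 as a -> 0
  sh <- vapply(c(1, 0.1, 0.01, 1e-4), function(a)
    predict_shift(evo_params(c = 3, a = a, b = 1)), numeric(1))
  expect_true(all(diff(sh) < 0) && sh[4] < 1e-3)
  expect_error(predict_shift(params_deletion()), "pure growth")
})

test_that("exact pure-growth recurrence reproduces the known distribution", {
  d <- exact_pure_growth_pk(params_pure_pa(), k_max = 5000, normalize = FALSE)
  expect_equal(d$prob[d$k == 3], 0.4, tolerance = 1e-9)
  expect_equal(d$prob[d$k == 4], 0.2, tolerance = 1e-9)
  expect_equal(d$prob[d$k == 5], 24 / 210, tolerance = 1e-9)
  expect_true(all(d$prob[d$k < 3] == 0))  # no process reduces degree
  # mass converges to 1
  expect_equal(attr(d, "raw_mass"), 1, tolerance = 1e-5)
  dg <- exact_pure_growth_pk(params_growth(), k_max = 10000, normalize = FALSE)
  expect_equal(attr(dg, "raw_mass"), 1, tolerance = 1e-3)
  # pure-PA tail ratio consistent with gamma = 3: p_k/p_{k-1} = 1 - 3/k + O(1/k^2)
  r1000 <- d$prob[d$k == 1000] / d$prob[d$k == 999]
  expect_equal(r1000, 1 - 3 / 1000, tolerance = 1e-5)
  expect_error(exact_pure_growth_pk(params_deletion()), "pure growth")
})

test_that("omega is Phi/D clipped at one, with the raw ratio reported", {
  om <- omega_factor(params_growth())
  expect_equal(as.numeric(om), 1)
  expect_equal(attr(om, "raw_ratio"), Inf)
  om2 <- omega_factor(params_deletion())
  expect_equal(as.numeric(om2), 1)
  expect_equal(attr(om2, "raw_ratio"), (7 / 8.5) / 0.25, tolerance = 1e-12)
  om3 <- omega_factor(evo_params(c = 3, m = 2, r = 0.2, q = 0.1,
                                 a = 25, b = 1, s = 25, t = 1))
  expect_equal(attr(om3, "raw_ratio"), 7 / (33 * 0.25), tolerance = 1e-12)
  expect_lt(as.numeric(om3), 1)
})

test_that("phase boundaries satisfy their defining conditions", {
  bd <- phase_boundaries(params_deletion())
  expect_equal(bd$a_c, 20, tolerance = 1e-12)
  expect_equal(bd$a_tilde_c, 4 / 3, tolerance = 1e-12)
  # q = 0: r_c = m/c
  bd0 <- phase_boundaries(evo_params(c = 3, m = 2, r = 0.1, a = 0, b = 1,
                                     s = 0, t = 1))
  expect_equal(bd0$r_c, 2 / 3, tolerance = 1e-12)
  # defining equations, checked on random deletion geometries:
  set.seed(11)
  for (i in 1:10) {
    c <- sample(1:5, 1); m <- sample(1:4, 1)
    r <- runif(1, 0.05, 0.6); q <- runif(1, 0, 1)
    base <- evo_params(c = c, m = m, r = r, q = q, a = 0, b = 1, s = 0, t = 1)
    bd <- phase_boundaries(base)
    at <- function(a) evo_params(c = c, m = m, r = r, q = q, a = a, b = 1,
                                 s = a, t = 1)
    # gamma(a_tilde_c) = 3 and raw omega(a_c) = 1
    if (bd$a_tilde_c > 0)
      expect_equal(predict_exponent(at(bd$a_tilde_c)), 3, tolerance = 1e-9)
    expect_equal(attr(omega_factor(at(bd$a_c)), "raw_ratio"), 1,
                 tolerance = 1e-9)
    # r_c recast: deleted links match added internal links at r = r_c
    # (only meaningful when r_c is an admissible growing-network rate)
    if (bd$r_c < 1) {
      pc <- evo_params(c = c, m = m, r = bd$r_c, q = q, a = 0, b = 1,
                      s = 0, t = 1)
      expect_equal(bd$r_c * mean_degree(pc) + 2 * m * q, 2 * m,
                   tolerance = 1e-12)
      # and a_tilde_c vanishes exactly there
      expect_equal(phase_boundaries(pc)$a_tilde_c, 0, tolerance = 1e-9)
    }
  }
  # no exponential phase without deletion
  expect_equal(phase_boundaries(params_growth())$a_c, Inf)
})

test_that("phase classification follows the boundary ordering", {
  expect_equal(classify_phase(params_deletion()), "powerlaw_infinite_variance")
  at <- function(a) evo_params(c = 3, m = 2, r = 0.2, q = 0.1, a = a, b = 1,
                               s = a, t = 1)
  expect_equal(classify_phase(at(10)), "powerlaw_finite_variance")
  expect_equal(predict_exponent(at(10)), 8.2, tolerance = 1e-9)
  expect_equal(classify_phase(at(25)), "exponential")
  expect_equal(classify_phase(at(20)), "critical_stretched")
})

test_that("phase grid reproduces the green-phase extents", {
  # node-deletion axis at q = 0: infinite-variance phase ends at r = m/c
  pg <- phase_grid(c = 3, m = 2, axis = "r", fixed_other = 0,
                   a_values = c(0.01), axis_values = seq(0.05, 0.95, 0.05))
  green <- pg$grid$phase == "powerlaw_infinite_variance"
  expect_true(all(pg$grid$axis_value[green] < 2 / 3 + 1e-9))
  expect_true(all(pg$grid$axis_value[!green] > 2 / 3 - 1e-9))
  expect_true(all(pg$boundaries$a_tilde_c[pg$boundaries$axis_value < 2 / 3] > 0))
  # edge-deletion axis at r = 0: infinite-variance phase present at every q
  # (a_tilde_c > 0 strictly below q = 1; it closes to 0 exactly at q = 1)
  pq <- phase_grid(c = 3, m = 2, axis = "q", fixed_other = 0,
                   a_values = c(0.01), axis_values = seq(0, 1, 0.1))
  expect_true(all(pq$boundaries$a_tilde_c >= 0))
  expect_true(all(pq$boundaries$a_tilde_c[pq$boundaries$axis_value < 1] > 0))
  expect_true(all(pq$grid$phase[pq$grid$axis_value < 1]
                  == "powerlaw_infinite_variance"))
  # no deletion anywhere: every point is a power law
  p0 <- phase_grid(c = 3, m = 2, axis = "r", fixed_other = 0,
                   a_values = c(0.5, 5, 50), axis_values = 0)
  expect_true(all(grepl("powerlaw", p0$grid$phase)))
  expect_equal(p0$boundaries$a_c, Inf)
})
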