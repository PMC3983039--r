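test_that("memory-model continuous exposure declines in two phases", {
  tr <- continuous_exposure(mem_ref(), t_end = 1e5)
  expect_equal(attr(tr, "final_z"), 100, tolerance = 1e-4)
  prof <- log_slope_profile(tr)
  # early decline is much faster than the long-term decline
  early <- min(prof$slope[prof$t_mid > 1 & prof$t_mid < 20])
  late <- attr(tr, "late_rate")
  expect_lt(early, 5 * late)   # both negative: early is > 5x faster
  expect_equal(-late, decline_rate(mem_ref()), tolerance = 0.01)
})

test_that("unirradiated populations neither decline nor accumulate damage", {
  tr <- continuous_exposure(memory_model(alpha = 0, p = 0.05, eta = 0.01),
                            t_end = 1e3)
  expect_equal(attr(tr, "final_z"), 0, tolerance = 1e-8)
  expect_equal(tr$x, rep(100, nrow(tr)), tolerance = 1e-8)
})

test_that("priming arms share every schedule entry except the priming alpha", {
  sch_p <- radcell:::priming_schedule(0.1, 100, 0.05, 0.5, c(0, 10), c(20, 25))
  sch_u <- radcell:::priming_schedule(0, 100, 0.05, 0.5, c(0, 10), c(20, 25))
  expect_identical(sch_p[-1, ], sch_u[-1, ])
  expect_identical(sch_p$p, sch_u$p)
  expect_identical(sch_p$alpha[-1], sch_u$alpha[-1])
  expect_identical(sch_u$alpha[1], 0)
})

test_that("priming raising only the hit rate cannot reduce altered cells", {
  pr <- priming_challenge(mem_ref(), alpha_low = 0.1, alpha_high = 100,
                          p_low = 0.05, p_high = 0.05)
  expect_gte(pr$z_primed, pr$z_unprimed)
  # and the same ordering holds across other memory-model parameter sets
  for (eta in c(0.005, 0.05)) {
    pars <- memory_model(alpha = 0.1, p = 0.05, eta = eta)
    pri <- priming_challenge(pars, alpha_low = 0.1, alpha_high = 50,
                             p_low = 0.05, p_high = 0.05, n = 2L)
    expect_gte(pri$z_primed, pri$z_unprimed)
  }
})

test_that("priming protects when dose raises the failure probability tenfold", {
  pr <- priming_challenge(mem_ref(), alpha_low = 0.1, alpha_high = 100,
                          p_low = 0.05, p_high = 0.5)
  expect_lt(pr$z_primed, pr$z_unprimed)
})

test_that("communication-mediated priming protects without dose-dependent p", {
  pr <- priming_challenge(comm_ref(beta0 = 10), alpha_low = 0.1,
                          alpha_high = 100, p_low = 0.05, p_high = 0.05)
  expect_lt(pr$z_primed, pr$z_unprimed)
})

test_that("the priming ratio declines with the fold change and crosses one", {
  base <- memory_model(alpha = 0, p = 0.05, eta = 0.01)
  rc <- suppressWarnings(
    priming_ratio_curve(base, alpha_low = 0.1, alpha_high = 100,
                        p_low = 0.05, n_values = 1:20))
  expect_gt(rc$ratio[rc$n == 1], 1)
  expect_true(all(diff(rc$ratio) <= 1e-9))
  n_star <- attr(rc, "n_star")
  expect_true(is.finite(n_star))
  expect_gt(n_star, 1); expect_lt(n_star, 2)
})

test_that("grid interpolation and bisection locate the same threshold", {
  base <- memory_model(alpha = 0, p = 0.05, eta = 0.01)
  n_bis <- threshold_fold_change(base, 0.1, 100, 0.05, tol = 1e-3)
  # a fine grid around the crossing interpolates to the bisection root
  rc <- priming_ratio_curve(base, 0.1, 100, 0.05,
                            n_values = seq(1, 1.5, by = 0.05))
  expect_equal(attr(rc, "n_star"), n_bis, tolerance = 1e-2)
  # and the coarse integer grid brackets it
  expect_gt(n_bis, 1); expect_lt(n_bis, 2)
})

test_that("no priming dose means identical arms and a flat ratio", {
  base <- memory_model(alpha = 0, p = 0.05, eta = 0.01)
  rc <- priming_ratio_curve(base, alpha_low = 0, alpha_high = 100,
                            p_low = 0.05, n_values = c(1, 3, 5))
  expect_equal(rc$ratio, rep(1, 3), tolerance = 1e-10)
})

test_that("adapted-cell communication sustains protection at x = eta/beta1", {
  pars <- communication_model(alpha = 0, p = 0.05, eta = 0.01,
                              beta0 = 10, beta1 = 1)
  sch <- radiation_schedule(c(0, 20), c(10, 25), alpha = c(0.1, 100), p = 0.05)
  tr <- simulate_cells(sch, times = seq(0, 30, length.out = 31),
                       base_params = pars)
  st <- cell_state(x = tail(tr$x, 1), y = tail(tr$y, 1),
                   w = tail(tr$w, 1), z = tail(tr$z, 1))
  pp <- persistent_protection(pars, st)
  expect_identical(pp$status, "equilibrium")
  expect_equal(pp$x_inf, pars$eta / pars$beta1, tolerance = 0.05)
  expect_gt(pp$w_inf, 1)
})

test_that("without adapted-cell communication protection wanes exponentially", {
  pars <- communication_model(alpha = 0, p = 0.05, eta = 0.01,
                              beta0 = 10, beta1 = 0)
  st <- cell_state(x = 50, y = 0, w = 45, z = 5)
  pp <- persistent_protection(pars, st, t_end = 2000)
  expect_identical(pp$status, "extinction")
  # closed form: w(t) = w0 exp(-eta t) while x only grows
  tr <- pp$trajectory
  expect_equal(tr$w, 45 * exp(-0.01 * tr$t), tolerance = 1e-6)
})

test_that("protection is permanent when eta = 0 and beta1 > 0", {
  pars <- communication_model(alpha = 0, p = 0.05, eta = 0, beta1 = 1)
  pp <- persistent_protection(pars, cell_state(x = 50, y = 0, w = 45, z = 5),
                              t_end = 2000)
  expect_identical(pp$status, "equilibrium")
  expect_equal(pp$x_inf, 0, tolerance = 1e-6)
  expect_equal(pp$w_inf, 95, tolerance = 1e-6)
})
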