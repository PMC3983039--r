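test_that("dose-survival CSV round-trips and validates", {
  ds <- simulate_dose_survival(recovery_truth(), recovery_mapping(),
                               recovery_doses(), noise_sigma = 0.05, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dose_survival(ds, path)
  back <- read_dose_survival(path)
  expect_equal(as.data.frame(back), as.data.frame(ds), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(nrow(read_dose_survival(path)), 12)
})

test_that("malformed dose-survival files raise format errors naming the row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dose,surviving_fraction", "0.1,0.9", "0.5,1.2", "1,0.5"), path)
  expect_error(read_dose_survival(path), "row 2",
               class = "radcell_format_error")
  writeLines(c("dose,surviving_fraction", "0.1,0.9", "0.5,abc"), path)
  expect_error(read_dose_survival(path), class = "radcell_format_error")
  writeLines(c("dose,fraction", "0.1,0.9"), path)
  expect_error(read_dose_survival(path), "surviving_fraction",
               class = "radcell_format_error")
})

test_that("the objective vanishes at the generating parameters", {
  th <- recovery_truth()
  ds <- simulate_dose_survival(th, recovery_mapping(), recovery_doses(),
                               noise_sigma = 0, seed = 1)
  expect_lt(survival_objective(th, ds, recovery_mapping()), 1e-10)
})

test_that("perturbing any parameter away from the truth raises the objective", {
  th <- recovery_truth()
  ds <- simulate_dose_survival(th, recovery_mapping(), recovery_doses(),
                               noise_sigma = 0, seed = 1)
  for (i in seq_along(th)) {
    up <- th; up[i] <- up[i] * 1.1
    expect_gt(survival_objective(up, ds, recovery_mapping()), 1e-6)
  }
})

test_that("doubling all standard errors divides the objective by four", {
  th <- recovery_truth()
  ds <- simulate_dose_survival(th, recovery_mapping(), recovery_doses(),
                               noise_sigma = 0.05, seed = 2)
  ds1 <- dplyr::mutate(ds, se = 0.02 * surviving_fraction)
  ds2 <- dplyr::mutate(ds, se = 0.04 * surviving_fraction)
  off <- recovery_truth() * c(1.2, 1, 1, 1)
  expect_equal(survival_objective(off, ds1, recovery_mapping()) / 4,
               survival_objective(off, ds2, recovery_mapping()),
               tolerance = 1e-10)
})

test_that("the fast linear propagator agrees with the stiff integrator", {
  for (th in list(c(0.5, 0.1, 0.3), c(2, 0.01, 0.9), c(0.05, 1, 0.5))) {
    pars <- memory_model(alpha = th[1], p = th[3], eta = th[2])
    tr <- simulate_cells(pars, initial = cell_state(x = 1), times = c(0, 7),
                         rtol = 1e-10, atol = 1e-12)
    expect_equal(radcell:::memory_survival(th[1], th[2], th[3], 7),
                 sum(tr[nrow(tr), c("x", "y", "w")]), tolerance = 1e-8)
  }
})

test_that("noiseless synthetic data is recovered to within one percent", {
  th <- recovery_truth()
  ds <- simulate_dose_survival(th, recovery_mapping(), recovery_doses(),
                               noise_sigma = 0, seed = 1)
  fit <- fit_memory_model(ds, recovery_mapping(), n_starts = 6, seed = 1)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$estimates - th) / th), 0.01)
  expect_lt(fit$objective, 1e-10)
})

test_that("fitting fewer than five records is a precondition error", {
  ds <- tibble::tibble(dose = c(0.1, 1), surviving_fraction = c(0.9, 0.5))
  expect_error(fit_memory_model(ds, recovery_mapping()),
               class = "radcell_config_error")
})

test_that("fits are deterministic given dataset, seed and bounds", {
  ds <- simulate_dose_survival(recovery_truth(), recovery_mapping(),
                               recovery_doses(), noise_sigma = 0.05, seed = 5)
  f1 <- fit_memory_model(ds, recovery_mapping(), n_starts = 4, seed = 9)
  f2 <- fit_memory_model(ds, recovery_mapping(), n_starts = 4, seed = 9)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$objective, f2$objective)
})

test_that("tidy and glance expose estimates and fit diagnostics", {
  ds <- simulate_dose_survival(recovery_truth(), recovery_mapping(),
                               recovery_doses(), noise_sigma = 0, seed = 1)
  fit <- fit_memory_model(ds, recovery_mapping(), n_starts = 2, seed = 1)
  td <- tidy(fit)
  expect_identical(td$term, c("alpha", "eta", "p0", "p1"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(fit)
  expect_identical(names(gl),
                   c("objective", "converged", "n_obs", "n_starts",
                     "best_start"))
})

test_that("identical datasets produce zero spread across fits", {
  ds <- simulate_dose_survival(recovery_truth(), recovery_mapping(),
                               recovery_doses(), noise_sigma = 0, seed = 1)
  fit <- fit_memory_model(ds, recovery_mapping(), n_starts = 2, seed = 1)
  sm <- summarize_estimates(list(fit, fit, fit))
  expect_equal(sm$max - sm$min, rep(0, 4))
  expect_equal(sm$cv, rep(0, 4))
  expect_error(summarize_estimates(list(fit)), class = "radcell_config_error")
})
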