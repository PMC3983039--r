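#' Continuous-exposure experiment
#'
#' Irradiates a homogeneous population at constant dose rate and summarises
#' the outcome: the final altered count and the late-phase decline rate of
#' the unaltered pool `u = x + y + w`. Under the memory mechanism `u` falls
#' in two phases (a fast transient, then a slow decline set by the protected
#' pool); with effective communication a third, quasi-stationary phase
#' appears between them.
#'
#' @param params A [model_params()] object with `alpha > 0`.
#' @param k Initial (healthy) population size.
#' @param t_end Simulation horizon in time units.
#' @param n Number of output samples (log-spaced).
#' @return A `radcell_trajectory` tibble with attributes `final_z` and
#'   `late_rate` (measured log-slope over the last decade of decline, `NA`
#'   if the decline has not progressed far enough).
#' @examples
#' tr <- continuous_exposure(memory_model(alpha = 0.1, p = 0.05, eta = 0.01),
#'                           t_end = 1e4)
#' attr(tr, "final_z")
#' @export
continuous_exposure <- function(params, k = 100, t_end = 1e5, n = 400) {
  traj <- simulate_cells(params, initial = cell_state(x = k),
                         times = time_grid(t_end, n = n))
  u <- traj$x + traj$y + traj$w
  rate <- tryCatch(measure_late_rate(traj$t, u), error = function(e) NA_real_)
  structure(traj, final_z = traj$z[[nrow(traj)]], late_rate = rate)
}

# Final-phase log-slope of u. Only the numerically trustworthy part of the
# decline is used: below ~1e-6 of the initial population the integrator's
# absolute tolerance dominates and log-slopes are meaningless. The rate is
# the mean of the last few sliding-window slopes inside that region.
measure_late_rate <- function(t, u, window = 5, n_windows = 3, floor = 1e-6) {
  valid <- u >= floor * max(u)
  t <- t[valid]; u <- u[valid]
  if (length(u) < window + n_windows - 1) {
    abort("Too few trustworthy points for a final-phase rate.",
          class = "radcell_horizon_error")
  }
  u_last <- u[[length(u)]]
  if (max(u) < 10 * u_last && u_last < 0.99 * max(u)) {
    abort("Final phase not reached (less than one decade of decline); extend the horizon.",
          class = "radcell_horizon_error")
  }
  prof <- window_slopes(t, log(u), window = window)
  mean(tail(prof$slope, n_windows))
}

#' Priming/challenge radioadaptation protocol
#'
#' Runs the canonical two-arm in-silico experiment: a low-dose priming window
#' followed by a high-dose challenge window, against a control arm whose
#' schedule is identical except that the priming segment's `alpha` is zero.
#' A radioadaptive response corresponds to fewer permanently altered cells in
#' the primed arm.
#'
#' @param params A [model_params()] object supplying `c`, `eta`, `beta0`,
#'   `beta1` and the memory switch (its `alpha`/`p` are ignored).
#' @param alpha_low,alpha_high Hit rates during priming and challenge.
#' @param p_low,p_high Failure probabilities during priming and challenge.
#' @param prime_window,challenge_window Length-2 numeric `(start, end)` in
#'   time units; must be ordered and non-overlapping.
#' @param k Initial population size.
#' @param t_end Readout time (after the challenge window; `z` has plateaued
#'   once repairing cells drain).
#' @param n Output samples per arm.
#' @return An object of class `radcell_priming`: a list with `trajectories`
#'   (tibble with an `arm` column), `z_primed`, `z_unprimed` and their ratio.
#'   [tidy()] returns the per-arm summary.
#' @examples
#' pr <- priming_challenge(memory_model(alpha = 0.1, p = 0.05, eta = 0.01),
#'                         alpha_low = 0.1, alpha_high = 100,
#'                         p_low = 0.05, p_high = 0.5)
#' tidy(pr)
#' @export
priming_challenge <- function(params, alpha_low, alpha_high,
                              p_low, p_high = p_low,
                              prime_window = c(0, 10),
                              challenge_window = c(20, 25),
                              k = 100, t_end = 200, n = 200) {
  if (length(prime_window) != 2L || length(challenge_window) != 2L ||
      prime_window[[2]] > challenge_window[[1]]) {
    abort("Windows must be ordered and non-overlapping.",
          class = "radcell_config_error")
  }
  arms <- list(
    primed   = priming_schedule(alpha_low, alpha_high, p_low, p_high,
                                prime_window, challenge_window),
    unprimed = priming_schedule(0, alpha_high, p_low, p_high,
                                prime_window, challenge_window)
  )
  times <- seq(0, t_end, length.out = n)
  trajs <- imap(arms, function(sch, nm) {
    tr <- simulate_cells(sch, initial = cell_state(x = k), times = times,
                         base_params = params)
    mutate(as_tibble(tr), arm = nm)
  })
  traj <- list_rbind(trajs)
  zf <- map_dbl(trajs, ~ .x$z[[nrow(.x)]])
  structure(
    list(trajectories = traj,
         z_primed = zf[["primed"]], z_unprimed = zf[["unprimed"]],
         ratio = zf[["primed"]] / zf[["unprimed"]]),
    class = "radcell_priming"
  )
}

priming_schedule <- function(alpha_low, alpha_high, p_low, p_high,
                             prime_window, challenge_window) {
  radiation_schedule(
    t_start = c(prime_window[[1]], challenge_window[[1]]),
    t_end   = c(prime_window[[2]], challenge_window[[2]]),
    alpha   = c(alpha_low, alpha_high),
    p       = c(p_low, p_high),
    default_p = p_low
  )
}

#' @export
print.radcell_priming <- function(x, ...) {
  cat("<radcell_priming>\n")
  cat(sprintf("  z_primed = %.4g, z_unprimed = %.4g, ratio = %.4g\n",
              x$z_primed, x$z_unprimed, x$ratio))
  cat(if (x$ratio < 1) "  radioadaptive response (priming protects)\n"
      else "  no radioadaptive response\n")
  invisible(x)
}

#' @method tidy radcell_priming
#' @export
tidy.radcell_priming <- function(x, ...) {
  tibble(arm = c("primed", "unprimed"),
         z_final = c(x$z_primed, x$z_unprimed))
}

#' Priming-ratio curve over fold increases in p
#'
#' Scans how the benefit of priming depends on how strongly the failure
#' probability rises with dose: the challenge-phase `p` is set to `n * p_low`
#' (capped at 1, with a warning) and the ratio of altered cells
#' primed/unprimed is recorded for each fold change `n`. A ratio below 1
#' means priming protects; the threshold fold change `n*` where the curve
#' crosses 1 is located by linear interpolation between grid points (a grid
#' point landing exactly on 1 reports that `n`).
#'
#' @inheritParams priming_challenge
#' @param n_values Fold increases to scan (>= 1).
#' @return A tibble of class `radcell_ratio_curve` with columns `n`, `ratio`
#'   and attribute `n_star` (NA when the curve never crosses 1).
#' @examples
#' \donttest{
#' rc <- priming_ratio_curve(memory_model(alpha = 0.1, p = 0.05, eta = 0.01),
#'                           alpha_low = 0.1, alpha_high = 100, p_low = 0.05,
#'                           n_values = c(1, 2, 4, 8))
#' attr(rc, "n_star")
#' }
#' @export
priming_ratio_curve <- function(params, alpha_low, alpha_high, p_low,
                                n_values = 1:20,
                                prime_window = c(0, 10),
                                challenge_window = c(20, 25),
                                k = 100, t_end = 200) {
  if (any(n_values < 1)) {
    abort("`n_values` must be >= 1.", class = "radcell_config_error")
  }
  if (any(n_values * p_low > 1)) {
    warn("Some n * p_low exceed 1; p is capped at 1 for those entries.")
  }
  ratio <- map_dbl(n_values, function(n) {
    pr <- priming_challenge(params, alpha_low, alpha_high,
                            p_low = p_low, p_high = min(n * p_low, 1),
                            prime_window = prime_window,
                            challenge_window = challenge_window,
                            k = k, t_end = t_end, n = 2L)
    if (pr$z_unprimed <= 0) {
      abort("Unprimed arm produced no altered cells; ratio undefined.",
            class = "radcell_numerical_error")
    }
    pr$ratio
  })
  curve <- tibble(n = as.numeric(n_values), ratio = ratio)
  structure(curve, class = c("radcell_ratio_curve", class(curve)),
            n_star = interp_crossing(curve$n, curve$ratio))
}

interp_crossing <- function(n, ratio, level = 1) {
  on_grid <- which(ratio == level)
  if (length(on_grid) > 0) return(n[[on_grid[[1]]]])
  s <- sign(ratio - level)
  flip <- which(diff(s) != 0)
  if (length(flip) == 0) return(NA_real_)
  i <- flip[[1]]
  approx(ratio[c(i, i + 1)], n[c(i, i + 1)], xout = level)$y
}

#' Threshold fold change by bisection
#'
#' Locates the fold change `n*` at which the priming ratio equals 1 by
#' bisection on `ratio(n) - 1`, independent of any precomputed grid. Used to
#' cross-check the interpolated threshold from [priming_ratio_curve()].
#'
#' @inheritParams priming_ratio_curve
#' @param interval Search interval for `n`.
#' @param tol Bisection tolerance on `n`.
#' @return The threshold fold change.
#' @export
threshold_fold_change <- function(params, alpha_low, alpha_high, p_low,
                                  interval = c(1, 20), tol = 1e-3,
                                  prime_window = c(0, 10),
                                  challenge_window = c(20, 25),
                                  k = 100, t_end = 200) {
  f <- function(n) {
    priming_challenge(params, alpha_low, alpha_high,
                      p_low = p_low, p_high = min(n * p_low, 1),
                      prime_window = prime_window,
                      challenge_window = challenge_window,
                      k = k, t_end = t_end, n = 2L)$ratio - 1
  }
  uniroot(f, interval = interval, tol = tol)$root
}

#' Persistent protection after radiation stops
#'
#' With communication between adapted and healthy cells (`beta1 > 0`) the
#' protected pool can sustain itself after irradiation ends, like an
#' endemic infection: generation `beta1 * x * w` balances loss `eta * w`,
#' which pins the healthy pool at `x = eta / beta1` whenever an interior
#' equilibrium exists. Without that route (`beta1 = 0`) protection wanes
#' exponentially at rate `eta`.
#'
#' @param params A [model_params()] object (post-radiation constants; its
#'   `alpha` is ignored and set to 0).
#' @param initial State at the moment radiation stops (`w > 0`).
#' @param t_end Relaxation horizon.
#' @return A list with `x_inf`, `w_inf`, `status` (`"equilibrium"` or
#'   `"extinction"`) and the relaxation `trajectory`.
#' @examples
#' st <- cell_state(x = 50, y = 0, w = 45, z = 5)
#' pp <- persistent_protection(
#'   communication_model(alpha = 0, p = 0.05, eta = 0.01, beta1 = 1),
#'   initial = st)
#' pp$x_inf
#' @export
persistent_protection <- function(params, initial, t_end = 5000) {
  if (initial[["w"]] <= 0) {
    abort("Requires a protected pool (w > 0) at the start.",
          class = "radcell_config_error")
  }
  off <- model_params(alpha = 0, p = params$p, c = params$c, eta = params$eta,
                      beta0 = params$beta0, beta1 = params$beta1,
                      memory = params$memory)
  traj <- simulate_cells(off, initial = initial, times = time_grid(t_end))
  nlast <- nrow(traj)
  w_inf <- traj$w[[nlast]]
  x_inf <- traj$x[[nlast]]
  k <- attr(traj, "k")
  status <- if (w_inf > 1e-6 * k) "equilibrium" else "extinction"
  list(x_inf = x_inf, w_inf = w_inf, status = status, trajectory = traj)
}
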