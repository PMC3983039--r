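#' Synthetic dose-survival dataset with known ground truth
#'
#' Generates a clonogenic dataset from the memory model: the noiseless
#' prediction at each dose is multiplied by lognormal noise
#' `exp(e), e ~ N(0, noise_sigma^2)` -- the standard error structure for
#' clonogenic assays and the counterpart of fitting in `ln S` space -- and
#' clipped to `(0, 1]`. With `noise_sigma = 0` the dataset reproduces the
#' model exactly. Fully reproducible from the seed.
#'
#' @param theta_true `(alpha, eta, p0, p1)` generating parameters.
#' @param mapping A [dose_mapping()].
#' @param doses Dose grid (non-empty).
#' @param noise_sigma Standard deviation of the log-scale noise (>= 0).
#' @param seed Integer seed.
#' @return A `radcell_dose_survival` tibble; attributes `theta_true` and
#'   `n_clipped` (observations clipped at 1).
#' @examples
#' mp <- dose_mapping("saturating", p0 = 0.3, p1 = 0.95,
#'                    mode = "fixed_rate", alpha = 0.5)
#' simulate_dose_survival(c(0.5, 0.02, 0.3, 0.95), mp,
#'                        doses = c(0.1, 1, 10), noise_sigma = 0.05, seed = 1)
#' @export
simulate_dose_survival <- function(theta_true, mapping, doses,
                                   noise_sigma = 0.05, seed = 1) {
  if (length(doses) == 0) {
    abort("Empty dose grid.", class = "radcell_config_error")
  }
  if (noise_sigma < 0) {
    abort("`noise_sigma` must be >= 0.", class = "radcell_config_error")
  }
  doses <- sort(doses)
  pred <- exp(predict_ln_survival(theta_true, doses, mapping))
  set.seed(seed)
  eps <- if (noise_sigma > 0) rnorm(length(doses), 0, noise_sigma) else
    rep(0, length(doses))
  sf <- pred * exp(eps)
  n_clipped <- sum(sf > 1)
  sf <- pmin(pmax(sf, .Machine$double.xmin), 1)
  out <- as_dose_survival(tibble(dose = doses, surviving_fraction = sf))
  attr(out, "theta_true") <- theta_true
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Noisy cell-count time series under a radiation schedule
#'
#' Integrates the model under an arbitrary schedule and samples the
#' trajectory at the requested times, either exactly (`counting = "none"`)
#' or with multinomial counting noise emulating the scoring of `n_sampled`
#' cells (`counting = "binomial"`: each compartment's count is drawn from
#' the true fractions at that time and rescaled to the population size).
#'
#' @param params Base [model_params()] (constants other than `alpha`/`p`).
#' @param schedule A [radiation_schedule()].
#' @param sample_times Times at which to record (within the horizon).
#' @param counting `"none"` for exact states or `"binomial"` for sampled
#'   counts.
#' @param n_sampled Cells scored per time point (`counting = "binomial"`).
#' @param initial Initial state.
#' @param seed Integer seed.
#' @return A tibble `t, x, y, w, z`; for binomial counting the rows are
#'   noisy but still sum to the population total.
#' @export
simulate_counts <- function(params, schedule, sample_times,
                            counting = c("none", "binomial"),
                            n_sampled = 1e4, initial = cell_state(100),
                            seed = 1) {
  counting <- match.arg(counting)
  if (counting == "binomial" && n_sampled <= 0) {
    abort("`n_sampled` must be positive.", class = "radcell_config_error")
  }
  times <- sort(unique(c(0, sample_times)))
  traj <- simulate_cells(schedule, initial = initial, times = times,
                         base_params = params)
  traj <- filter(as_tibble(traj), .data$t %in% sample_times)
  if (counting == "none") return(traj)
  k <- sum(initial)
  set.seed(seed)
  noisy <- pmap(traj, function(t, x, y, w, z) {
    fr <- c(x, y, w, z) / k
    counts <- as.numeric(stats::rmultinom(1, size = n_sampled, prob = fr))
    tibble(t = t, x = counts[1] / n_sampled * k, y = counts[2] / n_sampled * k,
           w = counts[3] / n_sampled * k, z = counts[4] / n_sampled * k)
  })
  list_rbind(noisy)
}

#' Fixture panel of dose-survival datasets
#'
#' Eight synthetic datasets emulating a panel of independent clonogenic
#' experiments on different cell lines: all share the same hit rate and
#' protection-loss rate (`alpha = 0.2`, `eta = 0.05`), while the
#' dose-sensitivity coefficients differ per dataset (`p0` log-uniform on
#' `[0.02, 2]`, `p1` uniform on `[0.1, 0.95]`), reflecting the view that
#' how dose translates into lethal damage is the cell-type-specific part.
#' Each dataset carries 5% multiplicative noise on 12 doses log-spaced over
#' `[0.05, 10]` Gy-equivalents.
#'
#' @param seed Integer seed; the panel is byte-identical for equal seeds.
#' @param n_datasets Number of datasets.
#' @param alpha,eta Shared generating values.
#' @param p0_range,p1_range Per-dataset draw ranges (`p0` log-uniform,
#'   `p1` uniform).
#' @param noise_sigma Log-scale noise sd.
#' @param doses Dose grid shared by all datasets.
#' @return A named list of `radcell_dose_survival` tibbles; attribute
#'   `truth` holds the per-dataset generating parameters.
#' @export
survival_panel <- function(seed = 1, n_datasets = 8, alpha = 0.2, eta = 0.05,
                           p0_range = c(0.02, 2), p1_range = c(0.1, 0.95),
                           noise_sigma = 0.05,
                           doses = 10^seq(log10(0.05), log10(10),
                                          length.out = 12)) {
  set.seed(seed)
  truth <- tibble(
    dataset = paste0("set", seq_len(n_datasets)),
    alpha = alpha, eta = eta,
    p0 = exp(runif(n_datasets, log(p0_range[[1]]), log(p0_range[[2]]))),
    p1 = runif(n_datasets, p1_range[[1]], p1_range[[2]])
  )
  sub_seeds <- sample.int(2^30, n_datasets)
  mapping <- dose_mapping("saturating", p0 = 1, p1 = 0.9,
                          mode = "fixed_rate", alpha = alpha)
  panel <- map(seq_len(n_datasets), function(i) {
    simulate_dose_survival(
      c(truth$alpha[[i]], truth$eta[[i]], truth$p0[[i]], truth$p1[[i]]),
      mapping, doses, noise_sigma = noise_sigma, seed = sub_seeds[[i]])
  })
  names(panel) <- truth$dataset
  attr(panel, "truth") <- truth
  panel
}
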