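#' Read and write dose-survival datasets
#'
#' A dose-survival dataset is a tibble with columns `dose` (>= 0, strictly
#' increasing after sorting), `surviving_fraction` (in `(0, 1]`) and an
#' optional `se` (standard error of the surviving fraction). Reading
#' validates every row and names the offending row on failure; writing then
#' reading a dataset returns it unchanged.
#'
#' @param path File path of a CSV with a header row.
#' @return A validated tibble of class `radcell_dose_survival`.
#' @export
read_dose_survival <- function(path) {
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("Cannot read CSV: ", conditionMessage(e)),
                              class = "radcell_format_error")
  )
  as_dose_survival(df)
}

#' @rdname read_dose_survival
#' @param data A data frame with the columns above.
#' @export
as_dose_survival <- function(data) {
  need <- c("dose", "surviving_fraction")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "radcell_format_error")
  }
  for (col in intersect(c(need, "se"), names(data))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(data[[col]]))))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric `%s` at row %d.", col, bad[[1]]),
            class = "radcell_format_error")
    }
  }
  bad <- which(data$dose < 0)
  if (length(bad) > 0) {
    abort(sprintf("Negative dose at row %d.", bad[[1]]),
          class = "radcell_format_error")
  }
  bad <- which(data$surviving_fraction <= 0 | data$surviving_fraction > 1)
  if (length(bad) > 0) {
    abort(sprintf("surviving_fraction outside (0, 1] at row %d.", bad[[1]]),
          class = "radcell_format_error")
  }
  out <- arrange(as_tibble(data), .data$dose)
  if (any(duplicated(out$dose))) {
    abort("Doses must be distinct.", class = "radcell_format_error")
  }
  class(out) <- c("radcell_dose_survival", class(as_tibble(out)))
  out
}

#' @rdname read_dose_survival
#' @param dataset A dose-survival tibble.
#' @export
write_dose_survival <- function(dataset, path) {
  readr::write_csv(as_tibble(dataset), path)
  invisible(path)
}

# ---- fast memory-model survival -------------------------------------------
# For constant (alpha, p) the unaltered compartments obey a linear ODE
#   d(x,y,w)/dt = A (x,y,w),  A = [[-a,0,e],[a,-c,0],[0,(1-p)c,-e]]
# solved exactly by eigendecomposition; falls back to the stiff integrator
# when the eigenbasis is ill-conditioned. Returns S/k = (x+y+w)/k at time t.
memory_survival <- function(alpha, eta, p, t, c = 1) {
  A <- matrix(c(-alpha, 0, eta,
                alpha, -c, 0,
                0, (1 - p) * c, -eta), 3, 3, byrow = TRUE)
  dec <- tryCatch({
    e <- eigen(A)
    co <- solve(e$vectors, c(1, 0, 0))
    rc <- rcond(abs(e$vectors))
    if (!is.finite(rc) || rc < 1e-10) NULL else list(e = e, co = co)
  }, error = function(err) NULL)
  if (is.null(dec)) {
    pars <- memory_model(alpha = alpha, p = p, c = c, eta = eta)
    return(map_dbl(t, function(tt) {
      tr <- simulate_cells(pars, initial = cell_state(x = 1),
                           times = c(0, tt))
      max(sum(tr[nrow(tr), c("x", "y", "w")]), .Machine$double.xmin)
    }))
  }
  map_dbl(t, function(tt) {
    s <- Re(sum(dec$e$vectors %*% (dec$co * exp(dec$e$values * tt))))
    min(max(s, .Machine$double.xmin), 1)
  })
}

#' Predicted log surviving fraction over a dose grid
#'
#' Model prediction used by the fitting objective: for each dose the
#' exposure `(alpha, t)` is realized through the mapping, the failure
#' probability is `p_of_dose(dose)`, and survival is the unaltered fraction
#' at the end of the exposure (computed with the exact linear-system
#' propagator of the memory model).
#'
#' @param theta Named or positional numeric `(alpha, eta, p0, p1)`.
#' @param doses Dose grid (> 0).
#' @param mapping A [dose_mapping()]; its `p0`/`p1`/`alpha` entries are
#'   overridden by `theta`.
#' @param c Repair-resolution rate, fixed (not estimated) to anchor the
#'   time scale.
#' @return Numeric vector of `ln S` values.
#' @export
predict_ln_survival <- function(theta, doses, mapping, c = 1) {
  alpha <- theta[[1]]; eta <- theta[[2]]; p0 <- theta[[3]]; p1 <- theta[[4]]
  m <- mapping
  m$p0 <- p0; m$p1 <- p1
  if (m$mode == "fixed_rate") m$alpha <- alpha
  map_dbl(doses, function(d) {
    ex <- dose_to_exposure(d, m)
    a <- if (m$mode == "fixed_duration") ex$alpha else alpha
    log(memory_survival(a, eta, p_of_dose(d, m), ex$time, c = c))
  })
}

#' Weighted least-squares objective in log-survival space
#'
#' Sum of squared residuals between observed and predicted `ln S`, weighted
#' by `1 / se_ln^2` when standard errors are present (`se` on the surviving
#' fraction is propagated to the log scale as `se / surviving_fraction`).
#' Doses at which the predicted survival underflows contribute a large
#' penalty rather than an error.
#'
#' @param theta `(alpha, eta, p0, p1)`.
#' @param dataset A dose-survival dataset ([as_dose_survival()]).
#' @param mapping A [dose_mapping()] with `mode = "fixed_rate"` for
#'   conventional clonogenic protocols.
#' @return Scalar objective value (>= 0).
#' @export
survival_objective <- function(theta, dataset, mapping) {
  pred <- predict_ln_survival(theta, dataset$dose, mapping)
  obs <- log(dataset$surviving_fraction)
  r <- obs - pred
  r[!is.finite(r)] <- 1e6
  w <- objective_weights(dataset)
  sum(w * r^2)
}

objective_weights <- function(dataset) {
  if ("se" %in% names(dataset) && all(is.finite(dataset$se)) &&
      all(dataset$se > 0)) {
    se_ln <- dataset$se / dataset$surviving_fraction
    1 / se_ln^2
  } else {
    rep(1, nrow(dataset))
  }
}

#' Fit the memory model to dose-survival data
#'
#' Multi-start bounded Levenberg-Marquardt estimation of
#' `(alpha, eta, p0, p1)` in log10-parameter space, minimizing the weighted
#' sum of squared `ln S` residuals. Starts are drawn log-uniformly within
#' the bounds from the given seed (plus one central start), making the fit
#' deterministic given `(dataset, seed, bounds)`. The repair-resolution rate
#' `c` is fixed at 1 so that `alpha` carries the time scale.
#'
#' @param dataset A dose-survival dataset with at least 5 records.
#' @param mapping A [dose_mapping()] (typically saturating, fixed_rate).
#' @param bounds Named list of `c(lower, upper)` for `alpha`, `eta`, `p0`,
#'   `p1`.
#' @param n_starts Number of random multi-starts.
#' @param seed Integer seed for the start draws.
#' @return An object of class `radcell_fit`: estimates, objective value,
#'   residuals, convergence flag, index of the winning start and per-start
#'   diagnostics. Use [tidy()] for the estimates and [glance()] for the fit
#'   summary.
#' @examples
#' \donttest{
#' mp <- dose_mapping("saturating", p0 = 0.3, p1 = 0.95, mode = "fixed_rate",
#'                    alpha = 1)
#' ds <- simulate_dose_survival(c(0.5, 0.02, 0.3, 0.95), mp,
#'                              doses = 10^seq(log10(0.05), log10(50), length.out = 12),
#'                              noise_sigma = 0, seed = 1)
#' fit <- fit_memory_model(ds, mp, n_starts = 4, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_memory_model <- function(dataset, mapping, bounds = default_bounds(),
                             n_starts = 10, seed = 1) {
  dataset <- as_dose_survival(dataset)
  if (nrow(dataset) < 5) {
    abort("Need at least 5 dose-survival records to fit 4 parameters.",
          class = "radcell_config_error")
  }
  par_names <- c("alpha", "eta", "p0", "p1")
  lb <- log10(map_dbl(bounds, 1)[par_names])
  ub <- log10(map_dbl(bounds, 2)[par_names])
  obs <- log(dataset$surviving_fraction)
  sw <- sqrt(objective_weights(dataset))
  resid_fn <- function(lth) {
    r <- sw * (obs - predict_ln_survival(10^lth, dataset$dose, mapping))
    r[!is.finite(r)] <- 1e3
    r
  }
  set.seed(seed)
  starts <- matrix(runif(4L * n_starts, rep(lb, each = n_starts),
                         rep(ub, each = n_starts)), ncol = 4L)
  starts[1L, ] <- pmin(pmax(log10(c(1, 0.05, 1, 0.8)), lb), ub)
  runs <- map(seq_len(n_starts), function(i) {
    tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lb, upper = ub,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-8, ptol = 1e-8)),
      error = function(e) NULL)
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) {
    abort("All optimizer starts failed.", class = "radcell_numerical_error")
  }
  dev <- map_dbl(runs, ~ if (is.null(.x)) Inf else .x$deviance)
  best_i <- which.min(dev)
  best <- runs[[best_i]]
  est <- setNames(10^best$par, par_names)
  structure(
    list(estimates = est, fixed = c(c = 1), objective = best$deviance,
         residuals = resid_fn(best$par),
         converged = best$info %in% 1:4,
         best_start = best_i, seed = seed, n_starts = n_starts,
         start_objectives = dev, bounds = bounds, mapping = mapping,
         n_obs = nrow(dataset)),
    class = "radcell_fit"
  )
}

#' @rdname fit_memory_model
#' @export
default_bounds <- function() {
  list(alpha = c(1e-3, 1e3), eta = c(1e-4, 10),
       p0 = c(1e-3, 1e2), p1 = c(1e-3, 1))
}

#' @export
print.radcell_fit <- function(x, ...) {
  cat("<radcell_fit> memory model, ln-survival least squares\n")
  est <- x$estimates
  cat(sprintf("  alpha = %.4g, eta = %.4g, p0 = %.4g, p1 = %.4g (c fixed at %g)\n",
              est[["alpha"]], est[["eta"]], est[["p0"]], est[["p1"]],
              x$fixed[["c"]]))
  cat(sprintf("  objective = %.4g over %d records; converged: %s (start %d of %d)\n",
              x$objective, x$n_obs, x$converged, x$best_start, x$n_starts))
  invisible(x)
}

#' @method tidy radcell_fit
#' @export
tidy.radcell_fit <- function(x, ...) {
  tibble(term = names(x$estimates), estimate = unname(x$estimates))
}

#' @method glance radcell_fit
#' @export
glance.radcell_fit <- function(x, ...) {
  tibble(objective = x$objective, converged = x$converged,
         n_obs = x$n_obs, n_starts = x$n_starts, best_start = x$best_start)
}

#' Summarise parameter estimates across fits
#'
#' Per-parameter spread statistics over a collection of fits, mirroring the
#' box-and-whisker comparison of estimate variability across datasets:
#' median, quartiles, range and coefficient of variation.
#'
#' @param fits A list of two or more `radcell_fit` objects.
#' @return A tibble with one row per parameter.
#' @export
summarize_estimates <- function(fits) {
  if (!is.list(fits) || length(fits) < 2 ||
      !all(vapply(fits, inherits, logical(1), "radcell_fit"))) {
    abort("Need a list of >= 2 radcell_fit objects.",
          class = "radcell_config_error")
  }
  est <- map(fits, "estimates")
  params <- names(est[[1]])
  rows <- map(params, function(pn) {
    v <- map_dbl(est, pn)
    tibble(parameter = pn, median = median(v),
           q1 = unname(quantile(v, 0.25)), q3 = unname(quantile(v, 0.75)),
           min = min(v), max = max(v), cv = sd(v) / mean(v))
  })
  list_rbind(rows)
}
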