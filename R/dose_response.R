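#' Dose-to-parameter mapping for survival curves
#'
#' Connects the reported dose axis to the model constants. Cumulative dose is
#' proportional to `alpha * t`; an experiment either fixes the exposure
#' duration and varies the dose rate (`mode = "fixed_duration"`, so
#' `alpha = dose / (T * dose_scale)`) or fixes the dose rate and varies the
#' duration (`mode = "fixed_rate"`, so `t = dose / (alpha * dose_scale)`).
#' The failure probability rises with dose through either a linear form
#' `min(p0 + p1 * d, 1)` or a saturating form `p1 * d / (d + p0)` with
#' plateau `p1 <= 1`.
#'
#' @param form `"linear"` or `"saturating"`.
#' @param p0,p1 Non-negative dimensionless coefficients (`p1 <= 1` for the
#'   saturating form).
#' @param mode `"fixed_duration"` or `"fixed_rate"`.
#' @param duration Exposure duration in time units (fixed_duration mode).
#' @param alpha Dose rate (fixed_rate mode).
#' @param dose_scale Proportionality constant linking the model dose
#'   `alpha * t` to reported dose units (default 1: doses are in the model's
#'   own units).
#' @return An object of class `radcell_mapping`.
#' @examples
#' # duration fixed at 150 time units, dose axis equal to the dose rate
#' dose_mapping("linear", p0 = 0.4, p1 = 0.55, mode = "fixed_duration",
#'              duration = 150, dose_scale = 1 / 150)
#' @export
dose_mapping <- function(form = c("linear", "saturating"), p0, p1,
                         mode = c("fixed_duration", "fixed_rate"),
                         duration = NULL, alpha = NULL, dose_scale = 1) {
  form <- match.arg(form)
  mode <- match.arg(mode)
  if (p0 < 0 || p1 < 0) {
    abort("`p0` and `p1` must be non-negative.", class = "radcell_config_error")
  }
  if (form == "saturating" && p1 > 1) {
    abort("Saturating form requires p1 <= 1 (it is the plateau of p).",
          class = "radcell_config_error")
  }
  if (mode == "fixed_duration" && (is.null(duration) || duration <= 0)) {
    abort("fixed_duration mode needs a positive `duration`.",
          class = "radcell_config_error")
  }
  if (mode == "fixed_rate" && (is.null(alpha) || alpha <= 0)) {
    abort("fixed_rate mode needs a positive `alpha`.",
          class = "radcell_config_error")
  }
  structure(list(form = form, p0 = p0, p1 = p1, mode = mode,
                 duration = duration, alpha = alpha,
                 dose_scale = dose_scale),
            class = "radcell_mapping")
}

#' Failure probability as a function of dose
#'
#' @param dose Non-negative dose(s) in reported units.
#' @param mapping A [dose_mapping()].
#' @return `p(dose)`, clipped to `[0, 1]`, non-decreasing in dose.
#' @examples
#' m <- dose_mapping("linear", 0.4, 0.55, "fixed_duration", duration = 150,
#'                   dose_scale = 1 / 150)
#' p_of_dose(1, m)  # 0.95
#' @export
p_of_dose <- function(dose, mapping) {
  if (any(dose < 0)) abort("`dose` must be >= 0.", class = "radcell_config_error")
  switch(mapping$form,
    linear = pmin(mapping$p0 + mapping$p1 * dose, 1),
    saturating = mapping$p1 * dose / (dose + mapping$p0)
  )
}

# (alpha, exposure time) pair realizing a reported dose under a mapping
dose_to_exposure <- function(dose, mapping) {
  if (mapping$mode == "fixed_duration") {
    list(alpha = dose / (mapping$duration * mapping$dose_scale),
         time = mapping$duration)
  } else {
    list(alpha = mapping$alpha,
         time = dose / (mapping$alpha * mapping$dose_scale))
  }
}

#' Clonogenic surviving fraction after a radiation exposure
#'
#' Integrates the model through an exposure realizing each dose (with
#' `p = p_of_dose(dose)` held constant for its duration) and reads the
#' surviving fraction `S/k = (x + y + w)/k` at the end of the exposure, with
#' no post-exposure rest. Vectorized over `dose`.
#'
#' @param params A [model_params()] object; its `alpha` and `p` are replaced
#'   per dose according to the mapping.
#' @param mapping A [dose_mapping()].
#' @param dose Doses in reported units (>= 0).
#' @param k Initial population size.
#' @return A tibble with columns `dose`, `surviving_fraction`, `ln_sf`.
#' @export
survival_fraction <- function(params, mapping, dose, k = 100) {
  rows <- map(dose, function(d) {
    if (d == 0) return(tibble(dose = 0, surviving_fraction = 1, ln_sf = 0))
    ex <- dose_to_exposure(d, mapping)
    pd <- model_params(alpha = ex$alpha, p = p_of_dose(d, mapping),
                       c = params$c, eta = params$eta,
                       beta0 = params$beta0, beta1 = params$beta1,
                       memory = params$memory)
    tr <- simulate_cells(pd, initial = cell_state(x = k),
                         times = c(0, ex$time))
    s <- (tr$x + tr$y + tr$w)[[nrow(tr)]] / k
    s <- min(max(s, .Machine$double.xmin), 1)
    tibble(dose = d, surviving_fraction = s, ln_sf = log(s))
  })
  list_rbind(rows)
}

#' Dose-response curve
#'
#' Computes `ln S` over a dose grid. A dense (>= 50 point) log-spaced grid is
#' recommended so that [classify_phases()] can estimate slopes reliably.
#'
#' @inheritParams survival_fraction
#' @param doses Dose grid.
#' @return A tibble of class `radcell_drc` (columns `dose`,
#'   `surviving_fraction`, `ln_sf`).
#' @examples
#' \donttest{
#' mp <- dose_mapping("linear", 0.4, 0.55, "fixed_duration", duration = 150,
#'                    dose_scale = 1 / 150)
#' drc <- dose_response_curve(memory_model(alpha = 1, p = 0.5, eta = 0.01),
#'                            mp, doses = 10^seq(-3, 0, length.out = 60))
#' }
#' @export
dose_response_curve <- function(params, mapping, doses, k = 100) {
  curve <- survival_fraction(params, mapping, doses, k = k)
  structure(curve, class = c("radcell_drc", class(curve)),
            mapping = mapping, params = params)
}

#' Classify HRS/IRR/high-dose phases of a survival curve
#'
#' Estimates windowed least-squares slopes of `ln S` against dose and
#' summarises the curve by three characteristic slopes: `s_hrs`, the
#' steepest slope in the lowest-dose decile; `s_irr`, the shallowest slope
#' between the HRS region and the final decile; and `s_high`, the steepest
#' slope in the final decile. The hyper-radiosensitivity / induced
#' radioresistance signature requires
#' `|s_hrs| > |s_high| > |s_irr|` together with a material re-steepening
#' after the plateau, `|s_high| >= rebound * |s_irr|`; without the rebound
#' requirement, monotonically flattening curves with slight endpoint
#' curvature would be labelled as showing the signature.
#'
#' @param curve A `radcell_drc` from [dose_response_curve()] (dense grid).
#' @param window Points per sliding slope window.
#' @param rebound Minimum ratio `|s_high| / |s_irr|` for a genuine
#'   IRR-to-high-dose re-steepening.
#' @return An object of class `radcell_phases`: list with `signature`
#'   (logical), `slopes` (named: `s_hrs`, `s_irr`, `s_high`), `profile`
#'   (tibble of windowed slopes) and per-dose `labels`.
#' @export
classify_phases <- function(curve, window = 5, rebound = 1.5) {
  if (nrow(curve) < 2 * window) {
    abort("Curve too sparse for phase classification.",
          class = "radcell_config_error")
  }
  prof <- window_slopes(curve$dose, curve$ln_sf, window = window)
  lo <- quantile(curve$dose, 0.1)
  hi <- quantile(curve$dose, 0.9)
  low_band  <- prof$slope[prof$mid <= lo]
  mid_band  <- prof$slope[prof$mid > lo & prof$mid < hi]
  high_band <- prof$slope[prof$mid >= hi]
  if (length(low_band) == 0 || length(mid_band) == 0 || length(high_band) == 0) {
    return(no_signature(prof, curve))
  }
  s_hrs  <- low_band[which.max(abs(low_band))]
  s_irr  <- mid_band[which.min(abs(mid_band))]
  s_high <- high_band[which.max(abs(high_band))]
  signature <- isTRUE(abs(s_hrs) > abs(s_high) &&
                      abs(s_high) > abs(s_irr) &&
                      abs(s_high) >= rebound * abs(s_irr))
  labels <- mutate(
    as_tibble(curve),
    phase = dplyr::case_when(
      dose <= lo ~ "HRS",
      dose >= hi ~ "high-dose",
      TRUE ~ "IRR"
    )
  )
  structure(list(signature = signature,
                 slopes = c(s_hrs = s_hrs, s_irr = s_irr, s_high = s_high),
                 profile = prof, labels = labels),
            class = "radcell_phases")
}

no_signature <- function(prof, curve) {
  structure(list(signature = FALSE,
                 slopes = c(s_hrs = NA_real_, s_irr = NA_real_,
                            s_high = NA_real_),
                 profile = prof, labels = as_tibble(curve)),
            class = "radcell_phases")
}

#' @export
print.radcell_phases <- function(x, ...) {
  cat("<radcell_phases>\n")
  cat(sprintf("  s_hrs = %.4g, s_irr = %.4g, s_high = %.4g\n",
              x$slopes[["s_hrs"]], x$slopes[["s_irr"]], x$slopes[["s_high"]]))
  cat("  HRS/IRR signature:", x$signature, "\n")
  invisible(x)
}

# sliding least-squares slopes of y against x over `window`-point windows
window_slopes <- function(x, y, window = 5) {
  n <- length(x)
  idx <- seq_len(n - window + 1L)
  mid <- map_dbl(idx, ~ mean(x[.x:(.x + window - 1L)]))
  slope <- map_dbl(idx, function(i) {
    j <- i:(i + window - 1L)
    xs <- x[j] - mean(x[j])
    sum(xs * (y[j] - mean(y[j]))) / sum(xs^2)
  })
  tibble(mid = mid, slope = slope)
}
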