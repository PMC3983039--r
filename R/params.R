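#' Rate constants for the radiation-response models
#'
#' Bundles the kinetic constants shared by the three model variants: cells are
#' hit at rate `alpha`, resolve repair at rate `c`, fail repair (and become
#' permanently altered) with probability `p`, lose acquired protection at rate
#' `eta`, and -- when communication is active -- induce protection in healthy
#' cells by mass action at rates `beta0` (repairing cells) and `beta1`
#' (adapted cells). The `memory` switch selects what happens on successful
#' repair: `1` sends the cell to the adapted pool (intracellular memory),
#' `0` returns it to the susceptible pool (no memory).
#'
#' @param alpha Radiation hit rate per cell per time unit (>= 0).
#' @param p Probability that repair fails and the alteration becomes
#'   permanent; dimensionless, in `[0, 1]`.
#' @param c Repair-resolution rate of hit cells per time unit (> 0).
#' @param eta Rate of loss of protection per time unit (>= 0); `1/eta` is the
#'   mean duration of the protected state.
#' @param beta0 Mass-action rate at which repairing cells induce adaptation in
#'   healthy cells (>= 0).
#' @param beta1 Mass-action rate at which adapted cells induce adaptation in
#'   healthy cells (>= 0).
#' @param memory Binary switch: `1` for the memory mechanism (successful
#'   repair confers protection), `0` for none (successful repair restores
#'   susceptibility).
#'
#' @return An object of class `radcell_params`: a named list of validated
#'   numeric constants.
#'
#' @details `memory_model()`, `communication_model()` and `full_model()` are
#'   thin wrappers selecting the conventional variants: memory only
#'   (`memory = 1`, `beta0 = beta1 = 0`), communication only (`memory = 0`),
#'   and both mechanisms together.
#'
#' @examples
#' memory_model(alpha = 0.1, p = 0.05, eta = 0.01)
#' communication_model(alpha = 0.1, p = 0.05, eta = 0.01, beta0 = 10)
#' @export
model_params <- function(alpha, p, c = 1, eta = 0, beta0 = 0, beta1 = 0,
                         memory = 1) {
  vals <- list(alpha = alpha, p = p, c = c, eta = eta,
               beta0 = beta0, beta1 = beta1, memory = memory)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm),
            class = "radcell_config_error")
    }
  }
  if (alpha < 0) abort("`alpha` must be >= 0.", class = "radcell_config_error")
  if (p < 0 || p > 1) abort("`p` must lie in [0, 1].", class = "radcell_config_error")
  if (c <= 0) abort("`c` must be > 0.", class = "radcell_config_error")
  if (eta < 0) abort("`eta` must be >= 0.", class = "radcell_config_error")
  if (beta0 < 0 || beta1 < 0) {
    abort("`beta0` and `beta1` must be >= 0.", class = "radcell_config_error")
  }
  if (!memory %in% c(0, 1)) {
    abort("`memory` must be 0 or 1.", class = "radcell_config_error")
  }
  structure(vals, class = "radcell_params")
}

#' @rdname model_params
#' @export
memory_model <- function(alpha, p, c = 1, eta = 0) {
  model_params(alpha = alpha, p = p, c = c, eta = eta,
               beta0 = 0, beta1 = 0, memory = 1)
}

#' @rdname model_params
#' @export
communication_model <- function(alpha, p, c = 1, eta = 0, beta0 = 0,
                                beta1 = 0) {
  model_params(alpha = alpha, p = p, c = c, eta = eta,
               beta0 = beta0, beta1 = beta1, memory = 0)
}

#' @rdname model_params
#' @export
full_model <- function(alpha, p, c = 1, eta = 0, beta0 = 0, beta1 = 0) {
  model_params(alpha = alpha, p = p, c = c, eta = eta,
               beta0 = beta0, beta1 = beta1, memory = 1)
}

#' @export
print.radcell_params <- function(x, ...) {
  variant <- if (x$memory == 1 && x$beta0 == 0 && x$beta1 == 0) {
    "memory"
  } else if (x$memory == 0) {
    "communication"
  } else {
    "full (memory + communication)"
  }
  cat("<radcell_params> ", variant, " model\n", sep = "")
  cat(sprintf("  alpha = %g, p = %g, c = %g, eta = %g, beta0 = %g, beta1 = %g\n",
              x$alpha, x$p, x$c, x$eta, x$beta0, x$beta1))
  invisible(x)
}

#' Initial cell-population state
#'
#' A population state is a named numeric vector with components `x` (healthy
#' susceptible), `y` (hit, repairing), `w` (adapted/protected) and `z`
#' (permanently altered). The total `x + y + w + z` is conserved by the
#' dynamics because cells do not divide.
#'
#' @param x,y,w,z Non-negative cell counts (continuous).
#' @return A named numeric vector of length 4.
#' @examples
#' cell_state(100)
#' @export
cell_state <- function(x = 100, y = 0, w = 0, z = 0) {
  s <- c(x = x, y = y, w = w, z = z)
  validate_state(s)
  s
}

validate_state <- function(state, tol = 0) {
  if (!is.numeric(state) || length(state) != 4L) {
    abort("A cell state must be a numeric vector (x, y, w, z).",
          class = "radcell_state_error")
  }
  if (is.null(names(state)) || !identical(names(state), c("x", "y", "w", "z"))) {
    names(state) <- c("x", "y", "w", "z")
  }
  k <- sum(state)
  if (any(state < -tol * max(k, 1))) {
    abort("Cell state has a negative component beyond tolerance.",
          class = "radcell_state_error")
  }
  state
}

#' Piecewise-constant radiation schedule
#'
#' Describes an exposure protocol as ordered, non-overlapping segments, each
#' carrying its own hit rate `alpha` and failure probability `p`. Outside all
#' segments the population is unirradiated (`alpha = 0`) and hit cells that
#' are still repairing resolve with the `p` of the most recent segment
#' (damage severity is set at hit time); before any segment has started,
#' `default_p` applies.
#'
#' @param t_start,t_end Numeric vectors of segment boundaries
#'   (`t_start < t_end`, segments must not overlap).
#' @param alpha Hit rate during each segment (>= 0); recycled if length 1.
#' @param p Failure probability during each segment (in `[0, 1]`); recycled
#'   if length 1.
#' @param default_p `p` in force before the first segment begins.
#' @return A tibble of class `radcell_schedule` with columns `t_start`,
#'   `t_end`, `alpha`, `p` and attribute `default_p`.
#' @examples
#' # low-dose priming then a high-dose challenge
#' radiation_schedule(t_start = c(0, 20), t_end = c(10, 25),
#'                    alpha = c(0.1, 100), p = 0.05)
#' @export
radiation_schedule <- function(t_start, t_end, alpha, p, default_p = p[[1]]) {
  n <- max(length(t_start), length(t_end), length(alpha), length(p))
  seg <- tibble(
    t_start = rep_len(as.numeric(t_start), n),
    t_end   = rep_len(as.numeric(t_end), n),
    alpha   = rep_len(as.numeric(alpha), n),
    p       = rep_len(as.numeric(p), n)
  )
  seg <- arrange(seg, .data$t_start)
  if (any(seg$t_start >= seg$t_end)) {
    abort("Each schedule segment needs t_start < t_end.",
          class = "radcell_config_error")
  }
  if (n > 1 && any(seg$t_start[-1] < seg$t_end[-n] - 1e-12)) {
    abort("Schedule segments must not overlap.", class = "radcell_config_error")
  }
  if (any(seg$alpha < 0)) {
    abort("Schedule `alpha` values must be >= 0.", class = "radcell_config_error")
  }
  if (any(seg$p < 0 | seg$p > 1)) {
    abort("Schedule `p` values must lie in [0, 1].", class = "radcell_config_error")
  }
  structure(seg, class = c("radcell_schedule", class(seg)),
            default_p = as.numeric(default_p))
}

is_schedule <- function(x) inherits(x, "radcell_schedule")

#' Flatten a schedule over an integration horizon
#'
#' Internal: returns consecutive (t0, t1, alpha, p) pieces covering
#' `[0, t_end]` with radiation-free gaps filled in (`alpha = 0`, `p` carried
#' over from the most recent segment).
#' @noRd
schedule_pieces <- function(schedule, t_end) {
  default_p <- attr(schedule, "default_p") %||% schedule$p[[1]]
  pieces <- list()
  t_cur <- 0
  p_cur <- default_p
  for (i in seq_len(nrow(schedule))) {
    s <- schedule[i, ]
    if (s$t_start >= t_end) break
    if (s$t_start > t_cur) {
      pieces[[length(pieces) + 1L]] <-
        list(t0 = t_cur, t1 = s$t_start, alpha = 0, p = p_cur)
    }
    seg_end <- min(s$t_end, t_end)
    pieces[[length(pieces) + 1L]] <-
      list(t0 = max(s$t_start, t_cur), t1 = seg_end, alpha = s$alpha, p = s$p)
    t_cur <- seg_end
    p_cur <- s$p
  }
  if (t_cur < t_end) {
    pieces[[length(pieces) + 1L]] <-
      list(t0 = t_cur, t1 = t_end, alpha = 0, p = p_cur)
  }
  pieces
}
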