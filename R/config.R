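#' Load a run configuration
#'
#' Reads a structured YAML config describing a model variant, its
#' parameters, an optional radiation schedule, the initial state and the
#' output grid. Unknown keys raise a config error listing them; this keeps
#' silently ignored typos out of simulation runs. Packaged example configs
#' live under `system.file("configs", package = "radcell")`.
#'
#' @param path Path to a YAML file.
#' @return A list of class `radcell_config` with elements `params`
#'   ([model_params()]), `schedule` ([radiation_schedule()] or `NULL`),
#'   `initial` ([cell_state()]), `t_end`, `n_out`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Reading configs requires the yaml package.",
          class = "radcell_config_error")
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    abort(paste0("Cannot parse config: ", conditionMessage(e)),
          class = "radcell_config_error"))
  known_top <- c("model", "params", "schedule", "initial", "output")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "radcell_config_error")
  }
  pk <- raw$params %||% list()
  known_par <- c("alpha", "p", "c", "eta", "beta0", "beta1")
  unknown <- setdiff(names(pk), known_par)
  if (length(unknown) > 0) {
    abort(paste0("Unknown params key(s): ", paste(unknown, collapse = ", ")),
          class = "radcell_config_error")
  }
  for (nm in names(pk)) {
    if (!is.numeric(pk[[nm]])) {
      abort(sprintf("Config parameter `%s` must be numeric, got \"%s\".",
                    nm, pk[[nm]]), class = "radcell_config_error")
    }
  }
  variant <- raw$model %||% "memory"
  builder <- switch(variant,
    memory = function(a) memory_model(alpha = a$alpha %||% 0, p = a$p %||% 0,
                                      c = a$c %||% 1, eta = a$eta %||% 0),
    communication = function(a) communication_model(
      alpha = a$alpha %||% 0, p = a$p %||% 0, c = a$c %||% 1,
      eta = a$eta %||% 0, beta0 = a$beta0 %||% 0, beta1 = a$beta1 %||% 0),
    full = function(a) full_model(
      alpha = a$alpha %||% 0, p = a$p %||% 0, c = a$c %||% 1,
      eta = a$eta %||% 0, beta0 = a$beta0 %||% 0, beta1 = a$beta1 %||% 0),
    abort(sprintf("Unknown model variant \"%s\".", variant),
          class = "radcell_config_error")
  )
  params <- builder(pk)
  schedule <- NULL
  if (!is.null(raw$schedule)) {
    seg <- raw$schedule
    schedule <- radiation_schedule(
      t_start = map_dbl(seg, ~ .x$t_start),
      t_end = map_dbl(seg, ~ .x$t_end),
      alpha = map_dbl(seg, ~ .x$alpha),
      p = map_dbl(seg, ~ .x$p %||% params$p)
    )
  }
  ini <- raw$initial %||% list()
  initial <- cell_state(x = ini$x %||% 100, y = ini$y %||% 0,
                        w = ini$w %||% 0, z = ini$z %||% 0)
  out <- raw$output %||% list()
  structure(list(params = params, schedule = schedule, initial = initial,
                 t_end = out$t_end %||% 100, n_out = out$n %||% 400),
            class = "radcell_config")
}

#' Run a simulation described by a config
#'
#' @param config A `radcell_config` from [read_config()] or a path to one.
#' @return A `radcell_trajectory` tibble.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  times <- time_grid(config$t_end, n = config$n_out)
  if (is.null(config$schedule)) {
    simulate_cells(config$params, initial = config$initial, times = times)
  } else {
    simulate_cells(config$schedule, initial = config$initial, times = times,
                   base_params = config$params)
  }
}

#' Write a trajectory to CSV
#'
#' Standard trajectory interchange format: header `t,x,y,w,z`, floating
#' point values.
#'
#' @param trajectory A `radcell_trajectory` (or any tibble with those
#'   columns).
#' @param path Output file.
#' @export
write_trajectory <- function(trajectory, path) {
  readr::write_csv(as_tibble(trajectory)[, c("t", "x", "y", "w", "z")], path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("t", "x", "y", "w", "z")
  if (!all(need %in% names(df))) {
    abort("Trajectory CSV needs columns t, x, y, w, z.",
          class = "radcell_format_error")
  }
  tr <- as_tibble(df)[, need]
  structure(tr, class = c("radcell_trajectory", class(tr)),
            k = sum(tr[1, c("x", "y", "w", "z")]))
}
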