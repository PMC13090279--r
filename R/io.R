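config_schema <- function() {
  list(
    parameters = c(names(default_parameter_values())),
    initial_condition = c("x0", "levels", "breaks"),
    solver = c("h", "T_max", "blowup_threshold", "record_every"),
    experiment = c("n", "seed", "model", "tau_values", "g_values")
  )
}

#' Load a run configuration
#'
#' Reads a YAML configuration with sections `parameters`,
#' `initial_condition`, `solver`, `experiment` (all optional); unknown
#' sections or keys are rejected by name, and missing values are filled
#' with the model's selected parameter values and the standard solver
#' settings (`h = 0.005`, `T_max = 500`, `blowup_threshold = 1000`).
#'
#' @param path YAML file path.
#' @return An `agepp_config`: list with built `params`
#'   (`agepp_parameters`), `ic` (`agepp_initial_condition`), `solver`, and
#'   `experiment` lists, plus the raw values.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  schema <- config_schema()
  bad <- setdiff(names(raw), names(schema))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in names(raw)) {
    unknown <- setdiff(names(raw[[sec]]), schema[[sec]])
    if (length(unknown))
      stop("unknown key(s) in section '", sec, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  pl <- raw$parameters
  variant <- pl$variant %||% "baseline"
  pl$variant <- NULL
  params <- tryCatch(
    do.call(model_parameters, c(pl, list(variant = variant))),
    error = function(e) stop("invalid parameters: ", conditionMessage(e),
                             call. = FALSE))
  icr <- raw$initial_condition
  ic <- if (is.null(icr)) default_initial_condition(params)
  else if (!is.null(icr$levels))
    initial_condition(icr$x0 %||% 0.5,
                      list(levels = icr$levels, breaks = icr$breaks))
  else {
    def <- default_initial_condition(params)
    initial_condition(icr$x0 %||% 0.5, def$u0)
  }
  solver <- modifyList(list(h = 0.005, T_max = 500,
                            blowup_threshold = 1000, record_every = 0.25),
                       raw$solver %||% list())
  structure(list(params = params, ic = ic, solver = solver,
                 experiment = raw$experiment %||% list(), raw = raw),
            class = "agepp_config")
}

#' Save a run configuration
#'
#' Writes the configuration back to YAML; [load_config()] of the result
#' reproduces the same parameters, initial condition and solver settings.
#'
#' @param config `agepp_config`.
#' @param path output file.
#' @export
save_config <- function(config, path) {
  p <- config$params
  raw <- list(
    parameters = p[names(default_parameter_values())],
    solver = config$solver
  )
  if (!is.null(config$raw$initial_condition))
    raw$initial_condition <- config$raw$initial_condition
  if (length(config$experiment)) raw$experiment <- config$experiment
  yaml::write_yaml(raw, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

result_header <- function(params, extra = list()) {
  vals <- c(params[setdiff(names(params), "variant")],
            list(variant = params$variant), extra)
  paste0("# ", names(vals), ": ",
         vapply(vals, function(v) paste(format(v), collapse = " "),
                character(1)))
}

#' Write a result object to columnar text
#'
#' Trajectories become `(time, x, y1, y2)` tables; phase diagrams long
#' `(tau_star, g, label, ...)` tables; equilibria `(age, density)` tables
#' with the summary in the header.  Every file starts with `#`-prefixed
#' header lines carrying the full parameter set so a run is reproducible
#' from its output alone.
#'
#' @param x an `agepp_trajectory`, `agepp_phase_diagram`, or
#'   `agepp_equilibrium`.
#' @param path output file.
#' @param ... unused.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

#' @export
write_results.agepp_trajectory <- function(x, path, ...) {
  hdr <- result_header(x$params, list(status = x$status, t_end = x$t_end))
  writeLines(hdr, path)
  suppressWarnings(
    write.table(x$series, path, append = TRUE, sep = "\t",
                row.names = FALSE, quote = FALSE))
  if (!is.null(x$snapshots)) {
    long <- data.frame(
      time = rep(x$snapshot_times, each = nrow(x$snapshots)),
      age = rep(x$grid$ages, times = length(x$snapshot_times)),
      density = as.vector(x$snapshots))
    spath <- paste0(path, ".density")
    writeLines(hdr, spath)
    suppressWarnings(
      write.table(long, spath, append = TRUE, sep = "\t",
                  row.names = FALSE, quote = FALSE))
  }
  invisible(path)
}

#' @export
write_results.agepp_phase_diagram <- function(x, path, ...) {
  writeLines("# phase diagram (long format)", path)
  suppressWarnings(
    write.table(as.data.frame(x), path, append = TRUE, sep = "\t",
                row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' @export
write_results.agepp_equilibrium <- function(x, path, ...) {
  hdr <- c(result_header(x$params,
                         list(X_star = x$X_star,
                              residual_norm = x$residual_norm,
                              converged = x$converged)),
           paste0("# h: ", x$grid$h))
  writeLines(hdr, path)
  suppressWarnings(
    write.table(data.frame(age = x$grid$ages, density = x$U_star),
                path, append = TRUE, sep = "\t",
                row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' Read back a columnar result file
#'
#' @param path file written by [write_results()].
#' @return data frame with attribute `header` (the `#` lines).
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  attr(df, "header") <- hdr
  df
}
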