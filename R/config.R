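## Shared plumbing: YAML run configuration and a lightweight timestamped
## logger. Every randomized stage logs its seed so runs can be replayed.

.nl_env <- new.env(parent = emptyenv())
.nl_env$level <- "info"

LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the logging threshold
#' @param level One of "debug", "info", "warn", "error".
#' @export
nl_log_level <- function(level = c("info", "debug", "warn", "error")) {
  .nl_env$level <- match.arg(level)
  invisible(.nl_env$level)
}

#' Timestamped log message
#' @param level Message level.
#' @param ... Message parts, pasted.
#' @export
nl_log <- function(level = "info", ...) {
  if (LOG_LEVELS[[level]] < LOG_LEVELS[[.nl_env$level]]) return(invisible(NULL))
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                  toupper(level), paste0(..., collapse = "")))
  invisible(NULL)
}

#' Log the RNG seed a stage is about to use
#' @param stage Stage name.
#' @param seed Integer seed.
#' @export
nl_log_seed <- function(stage, seed) {
  nl_log("info", stage, ": seed = ", seed)
  invisible(seed)
}

#' Read a run configuration file
#'
#' YAML with sections `geometry`, `forcefield`, `protocol`, `analysis`;
#' missing sections fall back to package defaults. Returns materialized
#' parameter objects alongside the raw list.
#'
#' @param path YAML file path.
#' @return List: `geometry` ([nanostar_geometry()]), `forcefield`
#'   ([force_field()]), `params` ([langevin_params()]), `protocol`
#'   ([simulation_protocol()]), `analysis` (raw list), `raw`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  take <- function(section, builder) {
    args <- raw[[section]]
    if (is.null(args)) builder() else do.call(builder, args)
  }
  list(geometry = take("geometry", nanostar_geometry),
       forcefield = take("forcefield", force_field),
       params = take("langevin", langevin_params),
       protocol = take("protocol", simulation_protocol),
       analysis = raw$analysis %||% list(),
       raw = raw)
}
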