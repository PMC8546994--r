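# Configuration: one nested list covering every tunable, loadable from JSON.
# Unknown keys are rejected so typos fail loudly; the effective configuration
# is echoed to a log file by the pipeline driver.

#' Default pipeline configuration
#'
#' @return nested list of all tunables with their defaults: normalization
#'   (mode, ALR reference), filters (metabolite mean / zero-variance, minimum
#'   time points per subject), top-variance selection, spline smoothing,
#'   resampling rate/origin (days), alignment layer and search grid, DBN
#'   constraints, maximum parents, bootstrap repetitions, validation
#'   thresholds and random-network count, and the master seed.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out = "modbn_out",
    log_level = "info",
    normalization = list(mode = "relative", reference_feature = NULL),
    filters = list(metabolite_min_mean = 0.001, min_timepoints = 5L),
    selection = list(top_k_per_layer = NULL),
    spline = list(smoothing = "gcv"),
    resample = list(rate_days = 14, origin = NULL),
    alignment = list(enabled = TRUE, layer = "genes", n_features = 10,
                     a_min = 0.5, a_max = 2, a_step = 0.05,
                     b_min = -30, b_max = 30, b_step = 1,
                     min_overlap = 0.5, error_grid_days = 1),
    dbn = list(constraints = "skeleton", max_parents = 3L,
               augmented_intra = TRUE, augmented_inter = TRUE,
               bootstrap = 100L),
    evaluate = list(target_layer = "taxa", cv_bootstrap = FALSE,
                    thresholds = seq(0, 0.9, by = 0.1), n_random = 1000L,
                    use_intersection = FALSE),
    simulate = NULL,
    input = NULL
  )
}

merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    key <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base)) stop("unknown config key: ", key)
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], override[[k]], key)
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a configuration file
#'
#' Reads a JSON file of overrides and merges it onto [default_config()];
#' unknown keys are rejected.
#'
#' @param path JSON file, or `NULL` for pure defaults.
#' @param overrides optional list of further overrides applied last.
#' @return the effective configuration list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- merge_config(cfg, user)
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

LOG_LEVELS <- c(debug = 1, info = 2, warn = 3, error = 4)

modbn_log <- function(level, ..., cfg_level = getOption("modbn.log_level", "info"),
                      file = getOption("modbn.log_file", NULL)) {
  if (LOG_LEVELS[[level]] < LOG_LEVELS[[cfg_level]]) return(invisible())
  msg <- sprintf("[%s] %s %s", toupper(level),
                 format(Sys.time(), "%H:%M:%S"), paste0(..., collapse = ""))
  message(msg)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE)
}

#' Write the effective configuration to a log file
#' @param config configuration list.
#' @param path output file (JSON).
#' @return invisibly, `path`.
#' @export
log_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
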