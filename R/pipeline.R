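# End-to-end pipeline driver and a small subcommand CLI
# (simulate | preprocess | align | learn | predict | validate | constraints).

preprocess_dataset <- function(dataset, cfg) {
  mode <- cfg$normalization$mode
  if (mode %in% c("relative", "alr")) dataset <- normalize_relative(dataset)
  has_met <- any(vapply(dataset$layers, function(l) l$kind == "metabolite",
                        TRUE))
  if (has_met) {
    dataset <- filter_metabolites(dataset,
                                  min_mean = cfg$filters$metabolite_min_mean)
  }
  dataset <- filter_subjects(dataset,
                             min_timepoints = cfg$filters$min_timepoints)
  k <- cfg$selection$top_k_per_layer
  if (!is.null(k)) {
    for (nm in names(dynamic_layers(dataset, OMIC_KINDS))) {
      if (k <= length(dataset$layers[[nm]]$features)) {
        dataset <- select_top_variance(dataset, nm, k)
      }
    }
  }
  if (mode == "alr") {
    dataset <- normalize_alr(dataset, cfg$normalization$reference_feature)
  }
  dataset
}

#' Run the full pipeline
#'
#' preprocess -> spline fit -> temporal alignment -> uniform resampling ->
#' structure learning (+ bootstrap) -> leave-one-out prediction ->
#' edge validation (when a database is configured), writing the network
#' (TSV + GraphML), warps TSV, prediction report and validation report into
#' the output directory. Any stage failure aborts with a stage-labelled
#' error.
#'
#' @param config configuration list (see [default_config()]); `config$input`
#'   names the layer/metadata TSVs, or `config$simulate` holds a
#'   [simulation_config()]-shaped list to generate inputs.
#' @param stop_after optional stage name (`"preprocess"`, `"align"`,
#'   `"learn"`, `"predict"`, `"validate"`) to stop at.
#' @return (invisibly) list of artifacts produced so far.
#' @export
run_pipeline <- function(config, stop_after = NULL) {
  cfg <- merge_config(default_config(), config)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  options(modbn.log_level = cfg$log_level,
          modbn.log_file = file.path(cfg$out, "pipeline.log"))
  on.exit(options(modbn.log_file = NULL))
  log_config(cfg[setdiff(names(cfg), "simulate")],
             file.path(cfg$out, "effective_config.json"))
  stage <- function(name, expr) {
    modbn_log("info", "stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  art <- list()
  done <- function(name) !is.null(stop_after) && identical(stop_after, name)

  dataset <- stage("input", {
    if (!is.null(cfg$simulate)) {
      sim_cfg <- do.call(simulation_config, cfg$simulate)
      generate(sim_cfg)$dataset
    } else if (!is.null(cfg$input)) {
      read_dataset(unlist(cfg$input$layers), cfg$input$metadata,
                   layer_kinds = unlist(cfg$input$layer_kinds))
    } else stop("config needs either 'input' or 'simulate'")
  })
  dataset <- stage("preprocess", preprocess_dataset(dataset, cfg))
  if (done("preprocess")) return(invisible(art))

  relative <- cfg$normalization$mode == "relative"
  if (isTRUE(cfg$alignment$enabled) && length(dataset$subjects) >= 2) {
    al <- stage("align", {
      acfg <- cfg$alignment
      layer <- if (acfg$layer %in% names(dataset$layers)) acfg$layer else NULL
      align_dataset(dataset, layer = layer, n_features = acfg$n_features,
                    smoothing = cfg$spline$smoothing,
                    a_grid = seq(acfg$a_min, acfg$a_max, by = acfg$a_step),
                    b_grid = seq(acfg$b_min, acfg$b_max, by = acfg$b_step),
                    min_overlap = acfg$min_overlap,
                    grid_step = acfg$error_grid_days)
    })
    dataset <- al$dataset
    art$warps <- file.path(cfg$out, "warps.tsv")
    write_warps(al$alignment, art$warps)
    if (done("align")) return(invisible(art))
  }

  resampled <- stage("resample", {
    origin <- cfg$resample$origin
    if (is.null(origin)) origin <- 0
    resample_dataset(dataset, rate_days = cfg$resample$rate_days,
                     origin = origin, smoothing = cfg$spline$smoothing,
                     clip_negative = relative)
  })
  network <- stage("learn", {
    bootstrap_network(resampled, cfg$dbn$constraints,
                      n_reps = cfg$dbn$bootstrap, seed = cfg$seed,
                      max_parents = cfg$dbn$max_parents)
  })
  art$network_tsv <- file.path(cfg$out, "network.tsv")
  export_network(network, art$network_tsv, "tsv")
  art$network_graphml <- file.path(cfg$out, "network.graphml")
  export_network(network, art$network_graphml, "graphml")
  if (done("learn")) return(invisible(art))

  report <- stage("predict", {
    target <- if (identical(cfg$evaluate$target_layer, "metabolites"))
      "metabolite" else "taxon"
    loocv_mae(resampled, cfg$dbn$constraints, target_kind = target,
              max_parents = cfg$dbn$max_parents, renormalize = relative,
              cv_bootstrap = if (isTRUE(cfg$evaluate$cv_bootstrap))
                cfg$dbn$bootstrap else 0,
              seed = cfg$seed)
  })
  art$prediction <- file.path(cfg$out, "prediction_report.tsv")
  write_prediction_report(report, art$prediction)
  modbn_log("info", sprintf("LOOCV MAE: %.4g", report$mae_overall))
  if (done("predict")) return(invisible(art))

  if (!is.null(cfg$input$validation_db)) {
    val <- stage("validate", {
      db <- read_validation_db(cfg$input$validation_db$path,
                               kind = cfg$input$validation_db$kind)
      rep <- validate_edges(network, db,
                            thresholds = cfg$evaluate$thresholds)
      base <- random_network_null(network, cfg$dbn$constraints, db,
                                  n_random = cfg$evaluate$n_random,
                                  seed = cfg$seed)
      list(report = rep, baseline = base)
    })
    art$validation <- file.path(cfg$out, "validation_report.tsv")
    write_validation_report(val$report, art$validation, val$baseline)
  }
  invisible(art)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run`, `preprocess`, `align`, `learn`,
#' `predict`, `validate`, `constraints`. Shared flags: `--config`, `--seed`,
#' `--out`, `--log-level`. `constraints` takes `--preset skeleton|augmented`
#' and writes the matrix as JSON.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name), e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly (0 on success).
#' @export
main_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    message("usage: modbn <simulate|run|preprocess|align|learn|predict|",
            "validate|constraints> [--config F] [--seed N] [--out DIR]")
    return(invisible(1L))
  }
  cmd <- argv[1]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--seed", type = "integer", default = NULL),
      optparse::make_option("--out", type = "character", default = NULL),
      optparse::make_option("--log-level", type = "character", default = NULL,
                            dest = "log_level"),
      optparse::make_option("--preset", type = "character",
                            default = "skeleton"))),
    args = argv[-1])
  ov <- list()
  for (k in c("seed", "out", "log_level")) {
    if (!is.null(opts[[k]])) ov[[k]] <- opts[[k]]
  }
  cfg <- load_config(opts$config, ov)

  status <- tryCatch({
    if (cmd == "constraints") {
      dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(cfg$out, paste0("constraints_", opts$preset, ".json"))
      write_constraints(get_constraints(opts$preset, cfg$dbn), path)
      message("wrote ", path)
    } else if (cmd == "simulate") {
      sim_cfg <- do.call(simulation_config,
                         c(cfg$simulate, list(seed = cfg$seed)))
      out <- generate(sim_cfg)
      dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
      write_dataset(out$dataset, cfg$out)
      export_network(out$truth$model, file.path(cfg$out, "truth_network.tsv"),
                     "tsv")
      jsonlite::write_json(
        lapply(out$truth$warps, function(w) w[c("subject", "a", "b")]),
        file.path(cfg$out, "truth_warps.json"), auto_unbox = TRUE, digits = NA)
      message("wrote dataset + truth to ", cfg$out)
    } else if (cmd == "run") {
      run_pipeline(cfg)
    } else if (cmd %in% c("preprocess", "align", "learn", "predict",
                          "validate")) {
      run_pipeline(cfg, stop_after = if (cmd == "validate") NULL else cmd)
    } else {
      stop("unknown subcommand '", cmd, "'")
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
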