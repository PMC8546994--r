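# Two-slice observation tables. Each aligned subject is resampled on a
# common uniform grid; one table row per consecutive grid pair (t_i, t_{i+1})
# per subject, with every node's value at slice t and slice t+1 (static
# host-gene and env values copied into both slices).

#' Resample every dynamic layer of a dataset onto a uniform grid
#'
#' Fits a spline per subject/feature and evaluates it on the grid
#' `{origin, origin + rate, ...}` intersected with the subject's observed
#' domain (intersection over dynamic omic layers). Environmental variables
#' are linearly interpolated, except a variable named `week`, which is set to
#' the aligned grid time in weeks (grid time / 7).
#'
#' @param dataset aligned [omics_dataset()].
#' @param rate_days grid spacing (days); default 14.
#' @param origin grid origin; default 0.
#' @param smoothing spline smoothing mode (`"gcv"` or `"none"`).
#' @param clip_negative clip negative spline excursions to zero (relative
#'   abundance mode).
#' @return a `ResampledDataset`: list with `grids` (per subject time vector),
#'   `values` (per subject node x grid matrix over dynamic nodes),
#'   `static` (per subject named vector over static nodes), `nodes`
#'   (data frame id/kind/feature/dynamic), `rate_days`.
#' @export
resample_dataset <- function(dataset, rate_days = 14, origin = 0,
                             smoothing = "gcv", clip_negative = FALSE) {
  dyn <- dynamic_layers(dataset, OMIC_KINDS)
  env <- dataset$layers[["env"]]
  nodes <- do.call(rbind, c(
    lapply(dyn, function(l) {
      data.frame(id = node_id(l$kind, l$features), kind = l$kind,
                 feature = l$features, dynamic = TRUE, stringsAsFactors = FALSE)
    }),
    if (!is.null(env)) list(data.frame(
      id = node_id("env", env$features), kind = "env", feature = env$features,
      dynamic = TRUE, stringsAsFactors = FALSE)),
    lapply(static_layers(dataset), function(l) {
      data.frame(id = node_id(l$kind, l$features), kind = l$kind,
                 feature = l$features, dynamic = FALSE, stringsAsFactors = FALSE)
    })))
  rownames(nodes) <- NULL

  grids <- list(); values <- list(); statics <- list()
  for (s in dataset$subjects) {
    doms <- lapply(dyn, function(l) {
      d <- l$data[[s]]
      if (is.null(d)) NULL else range(d$times)
    })
    doms <- Filter(Negate(is.null), doms)
    if (!length(doms)) next
    lo <- max(vapply(doms, `[`, 0, 1)); hi <- min(vapply(doms, `[`, 0, 2))
    grid <- grid_times(c(lo, hi), rate_days, origin)
    if (length(grid) < 2) {
      modbn_log("warn", "subject ", s, " has < 2 grid points; skipped")
      next
    }
    dyn_nodes <- nodes$id[nodes$dynamic]
    m <- matrix(NA_real_, nrow = length(dyn_nodes), ncol = length(grid),
                dimnames = list(dyn_nodes, NULL))
    for (l in dyn) {
      d <- l$data[[s]]
      for (f in l$features) {
        cv <- fit_bspline(d$times, d$values[f, ], smoothing = smoothing,
                          subject = s, layer = l$name, feature = f)
        v <- eval_curve(cv, grid)
        if (clip_negative) v <- pmax(v, 0)
        m[node_id(l$kind, f), ] <- v
      }
    }
    if (!is.null(env)) {
      d <- env$data[[s]]
      for (f in env$features) {
        m[node_id("env", f), ] <- if (identical(f, "week")) grid / 7 else
          stats::approx(d$times, d$values[f, ], grid, rule = 2)$y
      }
    }
    sv <- numeric(0)
    for (l in static_layers(dataset)) {
      d <- l$data[[s]]
      if (is.null(d)) d <- stats::setNames(rep(0, length(l$features)), l$features)
      v <- d[l$features]
      names(v) <- node_id(l$kind, l$features)
      sv <- c(sv, v)
    }
    grids[[s]] <- grid; values[[s]] <- m; statics[[s]] <- sv
  }
  structure(list(grids = grids, values = values, static = statics,
                 nodes = nodes, rate_days = rate_days),
            class = "ResampledDataset")
}

#' Build the two-slice observation table
#'
#' @param resampled a `ResampledDataset` (see [resample_dataset()]), or an
#'   [omics_dataset()] (then resampled first with `rate_days`).
#' @param rate_days grid spacing if a raw dataset is given.
#' @param subjects subject multiset to include (with repetition, for
#'   bootstrap); default all resampled subjects once.
#' @param ... passed to [resample_dataset()] when a raw dataset is given.
#' @return an `ObservationTable`: list with `X` (rows = transitions, columns
#'   = every node at slice t and t1), `cols` (data frame id/kind/feature/
#'   slice), `subject` (per row), `n`.
#' @export
build_observations <- function(resampled, rate_days = 14, subjects = NULL, ...) {
  if (inherits(resampled, "OmicsDataset")) {
    resampled <- resample_dataset(resampled, rate_days = rate_days, ...)
  }
  if (is.null(subjects)) subjects <- names(resampled$grids)
  nodes <- resampled$nodes
  dyn_ids <- nodes$id[nodes$dynamic]
  stat_ids <- nodes$id[!nodes$dynamic]
  all_ids <- c(dyn_ids, stat_ids)
  cols <- rbind(
    data.frame(id = paste0(all_ids, "@t"),
               node = all_ids,
               kind = nodes$kind[match(all_ids, nodes$id)],
               feature = nodes$feature[match(all_ids, nodes$id)],
               slice = "t", stringsAsFactors = FALSE),
    data.frame(id = paste0(all_ids, "@t1"),
               node = all_ids,
               kind = nodes$kind[match(all_ids, nodes$id)],
               feature = nodes$feature[match(all_ids, nodes$id)],
               slice = "t1", stringsAsFactors = FALSE))
  rows <- list(); subj <- character(0)
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    m <- resampled$values[[s]]
    if (is.null(m) || ncol(m) < 2) next
    sv <- resampled$static[[s]]
    nT <- ncol(m)
    for (j in seq_len(nT - 1)) {
      row <- c(m[dyn_ids, j], sv[stat_ids], m[dyn_ids, j + 1], sv[stat_ids])
      rows[[length(rows) + 1]] <- row
      subj <- c(subj, s)
    }
  }
  if (!length(rows)) stop("build_observations: no usable transitions")
  X <- do.call(rbind, rows)
  colnames(X) <- cols$id
  structure(list(X = X, cols = cols, subject = subj, n = nrow(X),
                 nodes = nodes),
            class = "ObservationTable")
}
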