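# Linear temporal alignment: warp tau(t) = a*t + b maps a subject's sample
# time to reference time. The error functional is the mean squared difference
# between reference and warped sample curves, integrated by the trapezoid
# rule on a fixed grid over the overlapping interval, divided by overlap
# length and summed over alignment features. Candidates are searched on a
# grid (a in [0.5, 2] step 0.05, b in [-30, 30] step 1) then refined by
# Nelder-Mead.

# Precompute a fine evaluation table for a set of curves (one per feature).
curve_table <- function(curves, step = 0.5) {
  dom <- range(unlist(lapply(curves, `[[`, "domain")))
  tt <- seq(dom[1], dom[2], by = step)
  if (tt[length(tt)] < dom[2]) tt <- c(tt, dom[2])
  vals <- vapply(curves, function(cv) {
    out <- rep(NA_real_, length(tt))
    inside <- tt >= cv$domain[1] - 1e-9 & tt <= cv$domain[2] + 1e-9
    out[inside] <- eval_curve(cv, tt[inside])
    out
  }, numeric(length(tt)))
  list(t = tt, v = as.matrix(vals), domain = dom)
}

trapz_mean <- function(x, y) {
  # integral of y dt / (range of x), trapezoid rule
  n <- length(x)
  if (n < 2) return(mean(y))
  sum(diff(x) * (y[-1] + y[-n]) / 2) / (x[n] - x[1])
}

warp_error <- function(a, b, ref_tab, smp_tab, min_overlap, grid_step) {
  if (a <= 0) return(Inf)
  lo <- max(ref_tab$domain[1], a * smp_tab$domain[1] + b)
  hi <- min(ref_tab$domain[2], a * smp_tab$domain[2] + b)
  ref_len <- diff(ref_tab$domain)
  if (hi - lo < min_overlap * ref_len) return(Inf)
  tau <- seq(lo, hi, by = grid_step)
  if (tau[length(tau)] < hi) tau <- c(tau, hi)
  if (length(tau) < 2) return(Inf)
  err <- 0
  for (j in seq_len(ncol(ref_tab$v))) {
    rv <- stats::approx(ref_tab$t, ref_tab$v[, j], tau, rule = 2)$y
    sv <- stats::approx(smp_tab$t, smp_tab$v[, j], (tau - b) / a, rule = 2)$y
    err <- err + trapz_mean(tau, (rv - sv)^2)
  }
  err
}

#' Align one subject's curves to a reference subject
#'
#' Finds the linear warp `tau(t) = a*t + b` minimizing the mean squared
#' curve difference over the overlapping interval (see the methods vignette
#' for the exact functional), by grid search plus local refinement.
#'
#' @param sample_curves named list of `Curve`s for the subject (one per
#'   alignment feature).
#' @param reference_curves matching named list of `Curve`s for the reference.
#' @param a_grid,b_grid candidate slopes and offsets.
#' @param min_overlap minimum warped-domain overlap, as a fraction of the
#'   reference domain (default 0.5).
#' @param grid_step integration step for the error functional, days.
#' @param refine run Nelder-Mead refinement from the best grid point?
#' @return a `TimeWarp`: list with `subject`, `a`, `b`, `error`,
#'   `reference_subject`.
#' @export
align_pair <- function(sample_curves, reference_curves,
                       a_grid = seq(0.5, 2, by = 0.05),
                       b_grid = seq(-30, 30, by = 1),
                       min_overlap = 0.5, grid_step = 1, refine = TRUE) {
  feats <- names(reference_curves)
  if (!all(feats %in% names(sample_curves))) {
    stop("align_pair: sample lacks curves for some alignment features")
  }
  smp_tab <- curve_table(sample_curves[feats])
  ref_tab <- curve_table(reference_curves)
  best <- c(NA, NA); best_err <- Inf
  for (a in a_grid) {
    for (b in b_grid) {
      e <- warp_error(a, b, ref_tab, smp_tab, min_overlap, grid_step)
      if (e < best_err) { best_err <- e; best <- c(a, b) }
    }
  }
  if (!is.finite(best_err)) {
    stop("align_pair: no candidate warp yields >= ", min_overlap * 100,
         "% overlap with the reference domain")
  }
  if (refine) {
    opt <- stats::optim(best, function(p) {
      e <- warp_error(p[1], p[2], ref_tab, smp_tab, min_overlap, grid_step)
      if (is.finite(e)) e else 1e12
    }, method = "Nelder-Mead",
    control = list(reltol = 1e-10, maxit = 400))
    if (opt$value <= best_err) { best <- opt$par; best_err <- opt$value }
  }
  structure(list(subject = sample_curves[[1]]$subject, a = best[1],
                 b = best[2], error = best_err,
                 reference_subject = reference_curves[[1]]$subject),
            class = "TimeWarp")
}

identity_warp <- function(subject) {
  structure(list(subject = subject, a = 1, b = 0, error = 0,
                 reference_subject = subject), class = "TimeWarp")
}

#' Select the optimal reference subject
#'
#' Evaluates every subject as a candidate reference, aligning all other
#' subjects against it, and picks the one minimizing the total alignment
#' error; ties break by subject id order. A candidate is disqualified if any
#' pairwise alignment fails.
#'
#' @param curve_sets named list (by subject) of named lists of `Curve`s over
#'   a common feature subset.
#' @param ... passed to [align_pair()].
#' @return an `AlignmentResult`: list with `reference`, `warps` (one per
#'   subject, reference's own warp is the identity), `mu`, `delta`,
#'   `dropped` (empty until [filter_aligned()]).
#' @export
select_reference <- function(curve_sets, ...) {
  subjects <- sort(names(curve_sets))
  if (length(subjects) < 2) stop("select_reference needs >= 2 subjects")
  best_ref <- NULL; best_total <- Inf; best_warps <- NULL
  for (r in subjects) {
    warps <- list(); total <- 0; ok <- TRUE
    for (s in subjects) {
      if (s == r) { warps[[s]] <- identity_warp(r); next }
      w <- tryCatch(align_pair(curve_sets[[s]], curve_sets[[r]], ...),
                    error = function(e) NULL)
      if (is.null(w)) { ok <- FALSE; break }
      w$subject <- s
      warps[[s]] <- w
      total <- total + w$error
    }
    if (ok && total < best_total) {
      best_total <- total; best_ref <- r; best_warps <- warps
    }
  }
  if (is.null(best_ref)) stop("select_reference: every candidate reference failed")
  errs <- vapply(best_warps[setdiff(subjects, best_ref)], `[[`, 0, "error")
  structure(list(reference = best_ref, warps = best_warps,
                 total_error = best_total,
                 mu = mean(errs), delta = stats::sd(errs),
                 dropped = character(0)),
            class = "AlignmentResult")
}

#' Drop subjects with abnormal alignment error
#'
#' Computes the mean (mu) and standard deviation (delta) of the alignment
#' error over non-reference subjects and drops those exceeding
#' `mu + 2 * delta`. May legitimately drop nobody.
#'
#' @param result an `AlignmentResult` from [select_reference()].
#' @return the result with `dropped` filled in.
#' @export
filter_aligned <- function(result) {
  others <- setdiff(names(result$warps), result$reference)
  if (length(others) < 1) return(result)
  errs <- vapply(result$warps[others], `[[`, 0, "error")
  mu <- mean(errs)
  delta <- if (length(errs) > 1) stats::sd(errs) else 0
  result$mu <- mu; result$delta <- delta
  result$dropped <- others[errs > mu + 2 * delta]
  result
}

#' Apply a subject's time warp to all its dynamic layers
#'
#' Replaces every dynamic-layer observation time for the subject by
#' `tau(t) = a*t + b`; values and static layers are untouched.
#'
#' @param warp a `TimeWarp`.
#' @param dataset an [omics_dataset()].
#' @return the warped dataset.
#' @export
propagate_warp <- function(warp, dataset) {
  s <- warp$subject
  for (nm in names(dataset$layers)) {
    l <- dataset$layers[[nm]]
    if (!l$dynamic || is.null(l$data[[s]])) next
    dataset$layers[[nm]]$data[[s]]$times <- warp$a * l$data[[s]]$times + warp$b
  }
  dataset
}

#' Fit alignment curves and align a whole dataset
#'
#' Convenience wrapper: fits spline curves for the `n_features`
#' highest-mean-abundance features of the alignment layer, selects the
#' optimal reference, filters subjects by alignment error, and propagates
#' each surviving subject's warp to all dynamic layers.
#'
#' @param dataset an [omics_dataset()] (preprocessed).
#' @param layer alignment layer name (default the gene layer, which the
#'   method favours for alignment).
#' @param n_features number of top-mean features used for alignment.
#' @param smoothing spline smoothing mode.
#' @param ... passed to [align_pair()] via [select_reference()].
#' @return list with `dataset` (warped, dropped subjects removed) and
#'   `alignment` (the `AlignmentResult`).
#' @export
align_dataset <- function(dataset, layer = NULL, n_features = 10,
                          smoothing = "gcv", ...) {
  if (is.null(layer)) layer <- layer_by_kind(dataset, "gene")
  l <- dataset$layers[[layer]]
  if (is.null(l)) stop("align_dataset: no layer '", layer, "'")
  means <- pooled_stats(l)$mean
  feats <- l$features[order(-means, l$features)][seq_len(min(n_features,
                                                             length(l$features)))]
  curve_sets <- lapply(dataset$subjects, function(s) {
    d <- l$data[[s]]
    if (is.null(d)) return(NULL)
    cs <- lapply(feats, function(f) {
      fit_bspline(d$times, d$values[f, ], smoothing = smoothing,
                  subject = s, layer = layer, feature = f)
    })
    names(cs) <- feats
    cs
  })
  names(curve_sets) <- dataset$subjects
  curve_sets <- Filter(Negate(is.null), curve_sets)
  res <- filter_aligned(select_reference(curve_sets, ...))
  keep <- setdiff(names(res$warps), res$dropped)
  dataset$subjects <- intersect(dataset$subjects, keep)
  for (nm in names(dataset$layers)) {
    dataset$layers[[nm]]$data <-
      dataset$layers[[nm]]$data[intersect(names(dataset$layers[[nm]]$data),
                                          dataset$subjects)]
  }
  for (s in dataset$subjects) dataset <- propagate_warp(res$warps[[s]], dataset)
  list(dataset = dataset, alignment = res)
}

#' Write alignment warps as TSV
#' @param result an `AlignmentResult`.
#' @param path output TSV (subject, a, b, error, dropped flag).
#' @return invisibly, `path`.
#' @export
write_warps <- function(result, path) {
  df <- do.call(rbind, lapply(result$warps, function(w) {
    data.frame(subject = w$subject, a = w$a, b = w$b, error = w$error,
               dropped = w$subject %in% result$dropped,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$subject), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
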