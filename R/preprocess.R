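# Normalization and filtering. Pipeline order (fixed): relative
# normalization -> metabolite filter -> subject filter -> top-variance
# selection -> optional ALR on the taxon layer.

layer_by_kind <- function(ds, kind) {
  hits <- names(ds$layers)[vapply(ds$layers, function(l) l$kind == kind, TRUE)]
  if (!length(hits)) stop("dataset has no layer of kind '", kind, "'")
  hits[1]
}

map_layer_values <- function(ds, layer, f) {
  l <- ds$layers[[layer]]
  for (s in names(l$data)) {
    l$data[[s]]$values <- f(l$data[[s]]$values, s)
  }
  ds$layers[[layer]] <- l
  ds
}

#' Relative (total-sum) normalization
#'
#' Within each sample of each dynamic omic layer, values are divided by their
#' sum so that each omic type sums to 1. Zeros are preserved; an all-zero
#' sample is an error.
#'
#' @param dataset an [omics_dataset()].
#' @param layers layer names to normalize; default all dynamic taxon / gene /
#'   metabolite layers.
#' @return the normalized dataset.
#' @export
normalize_relative <- function(dataset, layers = NULL) {
  if (is.null(layers)) layers <- names(dynamic_layers(dataset, OMIC_KINDS))
  for (nm in layers) {
    dataset <- map_layer_values(dataset, nm, function(v, s) {
      cs <- colSums(v, na.rm = TRUE)
      if (any(cs <= 0)) {
        t0 <- dataset$layers[[nm]]$data[[s]]$times[which(cs <= 0)[1]]
        stop("all-zero sample in layer '", nm, "': subject ", s,
             ", time ", t0)
      }
      sweep(v, 2, cs, "/")
    })
  }
  dataset
}

#' Additive log-ratio (ALR) transform of the taxon layer
#'
#' Each taxon value becomes `log(x / x_ref)` within its sample, with a fixed
#' reference feature (e.g. a ubiquitous species); the reference's transformed
#' trajectory is identically zero. Zero abundances are replaced by half the
#' smallest nonzero value of the layer before the log, keeping values finite.
#'
#' @param dataset an [omics_dataset()].
#' @param reference_feature taxon used as the log-ratio denominator.
#' @param layer taxon layer name; default the layer of kind `"taxon"`.
#' @return the transformed dataset (values unbounded in sign).
#' @export
normalize_alr <- function(dataset, reference_feature, layer = NULL) {
  if (is.null(layer)) layer <- layer_by_kind(dataset, "taxon")
  l <- dataset$layers[[layer]]
  if (!reference_feature %in% l$features) {
    stop("reference feature '", reference_feature, "' absent from layer '",
         layer, "'")
  }
  pool <- unlist(lapply(l$data, function(d) d$values))
  nz <- pool[is.finite(pool) & pool > 0]
  pc <- if (length(nz)) min(nz) / 2 else 1e-12
  map_layer_values(dataset, layer, function(v, s) {
    v[v == 0] <- pc
    sweep(log(v), 2, log(v[reference_feature, ]), "-")
  })
}

pooled_stats <- function(layer) {
  vals <- do.call(cbind, lapply(layer$data, function(d) d$values))
  list(mean = rowMeans(vals, na.rm = TRUE),
       var = apply(vals, 1, stats::var, na.rm = TRUE))
}

drop_features <- function(ds, layer, drop) {
  l <- ds$layers[[layer]]
  keep <- setdiff(l$features, drop)
  l$features <- keep
  for (s in names(l$data)) {
    l$data[[s]]$values <- l$data[[s]]$values[keep, , drop = FALSE]
  }
  ds$layers[[layer]] <- l
  ds
}

#' Filter low-intensity and constant metabolites
#'
#' Removes metabolites whose mean relative intensity over all original
#' samples (pooled across subjects) is below `min_mean`, or whose pooled
#' variance is zero.
#'
#' @param dataset a dataset with a relative-normalized metabolite layer.
#' @param min_mean mean-intensity threshold on the sum-to-1 scale
#'   (default 0.001, i.e. 0.1%).
#' @param layer metabolite layer name; default the layer of kind
#'   `"metabolite"`.
#' @return the filtered dataset (a warning is issued if nothing survives).
#' @export
filter_metabolites <- function(dataset, min_mean = 0.001, layer = NULL) {
  if (is.null(layer)) layer <- layer_by_kind(dataset, "metabolite")
  st <- pooled_stats(dataset$layers[[layer]])
  drop <- dataset$layers[[layer]]$features[st$mean < min_mean | st$var == 0]
  for (f in drop) modbn_log("debug", "filter_metabolites: removing ", f)
  if (length(drop) == length(st$mean)) {
    warning("filter_metabolites removed every metabolite")
  }
  drop_features(dataset, layer, drop)
}

#' Remove subjects with too few measured time points
#'
#' A subject is retained only if it has at least `min_timepoints` measured
#' time points in *every* dynamic omic layer.
#'
#' @param dataset an [omics_dataset()].
#' @param min_timepoints minimum per-layer count (default 5).
#' @return the filtered dataset; error if no subject remains.
#' @export
filter_subjects <- function(dataset, min_timepoints = 5) {
  lay <- dynamic_layers(dataset, OMIC_KINDS)
  ok <- vapply(dataset$subjects, function(s) {
    all(vapply(lay, function(l) {
      d <- l$data[[s]]
      !is.null(d) && length(d$times) >= min_timepoints
    }, TRUE))
  }, TRUE)
  dropped <- dataset$subjects[!ok]
  for (s in dropped) modbn_log("debug", "filter_subjects: removing ", s)
  if (!any(ok)) stop("filter_subjects: no subject has >= ", min_timepoints,
                     " time points in every layer")
  dataset$subjects <- dataset$subjects[ok]
  for (nm in names(dataset$layers)) {
    dataset$layers[[nm]]$data <-
      dataset$layers[[nm]]$data[intersect(names(dataset$layers[[nm]]$data),
                                          dataset$subjects)]
  }
  dataset
}

#' Keep the top-variance features of a layer
#'
#' Variance is computed on the (normalized) values pooled over all subjects'
#' original samples; ties are broken lexicographically by feature name for
#' reproducibility.
#'
#' @param dataset an [omics_dataset()].
#' @param layer layer name.
#' @param k number of features to keep.
#' @return the reduced dataset.
#' @export
select_top_variance <- function(dataset, layer, k = 20) {
  l <- dataset$layers[[layer]]
  if (is.null(l)) stop("no layer named '", layer, "'")
  if (k > length(l$features)) {
    stop("select_top_variance: k = ", k, " exceeds ", length(l$features),
         " features")
  }
  v <- if (l$dynamic) pooled_stats(l)$var else {
    vals <- do.call(cbind, l$data)
    apply(vals, 1, stats::var, na.rm = TRUE)
  }
  ord <- order(-v, l$features)
  keep <- l$features[ord][seq_len(k)]
  drop_features(dataset, layer, setdiff(l$features, keep))
}
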