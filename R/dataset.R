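#' @keywords internal
"_PACKAGE"

# Node kinds recognised throughout the package. host_gene and env nodes are
# exogenous: they may parent other nodes but never receive edges.
OMIC_KINDS <- c("taxon", "gene", "metabolite")
ALL_KINDS <- c(OMIC_KINDS, "host_gene", "env")

node_id <- function(kind, feature) paste(kind, feature, sep = ":")

#' Construct a layer of an omics dataset
#'
#' A layer is one omic measurement type: a dynamic layer holds, for each
#' subject, a time vector and a features-by-times value matrix; a static layer
#' holds one value per feature per subject (e.g. baseline host expression).
#'
#' @param name layer name (unique within a dataset).
#' @param kind one of `"taxon"`, `"gene"`, `"metabolite"`, `"host_gene"`,
#'   `"env"`.
#' @param dynamic logical; does the layer vary over time?
#' @param features character vector of feature names (unique).
#' @param data named list keyed by subject. Dynamic: each element is
#'   `list(times = <numeric>, values = <features x times matrix>)` with times
#'   strictly increasing. Static: each element is a named numeric vector over
#'   `features`.
#' @return an `omics_layer` list.
#' @export
omics_layer <- function(name, kind, dynamic, features, data) {
  kind <- match.arg(kind, ALL_KINDS)
  if (anyDuplicated(features)) {
    stop("duplicate feature names in layer '", name, "'")
  }
  structure(list(name = name, kind = kind, dynamic = isTRUE(dynamic),
                 features = as.character(features), data = data),
            class = "omics_layer")
}

#' Construct a multi-omics longitudinal dataset
#'
#' The central container: per-subject longitudinal matrices for each dynamic
#' layer plus optional static layers, with time measured in days.
#'
#' @param layers named list of [omics_layer()] objects.
#' @param subjects character vector of subject ids; defaults to the union of
#'   subjects seen in the layers.
#' @param validate check invariants (finite values, sorted times)?
#' @return an `OmicsDataset`.
#' @export
omics_dataset <- function(layers, subjects = NULL, validate = TRUE) {
  names(layers) <- vapply(layers, `[[`, "", "name")
  if (is.null(subjects)) {
    subjects <- sort(unique(unlist(lapply(layers, function(l) names(l$data)))))
  }
  ds <- structure(list(subjects = as.character(subjects), layers = layers,
                       time_unit = "days"),
                  class = "OmicsDataset")
  if (validate) validate_dataset(ds)
  ds
}

#' @export
print.OmicsDataset <- function(x, ...) {
  cat("OmicsDataset:", length(x$subjects), "subjects,",
      length(x$layers), "layers\n")
  for (l in x$layers) {
    cat(sprintf("  %-12s kind=%-10s %s  %d features\n", l$name, l$kind,
                if (l$dynamic) "dynamic" else "static ", length(l$features)))
  }
  invisible(x)
}

validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "OmicsDataset"))
  for (l in ds$layers) {
    for (s in names(l$data)) {
      if (!s %in% ds$subjects) stop("layer '", l$name, "' has unknown subject ", s)
      d <- l$data[[s]]
      if (l$dynamic) {
        if (length(d$times) != ncol(d$values)) {
          stop("layer '", l$name, "' subject ", s, ": times/values mismatch")
        }
        if (is.unsorted(d$times, strictly = TRUE)) {
          stop("layer '", l$name, "' subject ", s,
               ": times must be strictly increasing")
        }
        if (any(is.nan(d$values)) || any(is.infinite(d$values))) {
          stop("layer '", l$name, "' subject ", s, ": non-finite values")
        }
      } else {
        if (any(!is.finite(d))) {
          stop("layer '", l$name, "' subject ", s, ": non-finite values")
        }
      }
    }
  }
  invisible(ds)
}

dynamic_layers <- function(ds, kinds = NULL) {
  keep <- vapply(ds$layers, function(l) {
    l$dynamic && (is.null(kinds) || l$kind %in% kinds)
  }, TRUE)
  ds$layers[keep]
}

static_layers <- function(ds) {
  ds$layers[!vapply(ds$layers, `[[`, TRUE, "dynamic")]
}

guess_kind <- function(layer_name) {
  n <- tolower(layer_name)
  if (grepl("tax", n)) return("taxon")
  if (grepl("host", n)) return("host_gene")
  if (grepl("metab", n)) return("metabolite")
  if (grepl("gene|expr|transcript", n)) return("gene")
  if (grepl("env|meta", n)) return("env")
  stop("cannot guess node kind for layer '", layer_name,
       "'; pass layer_kinds explicitly")
}

read_tsv_table <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE,
                         na.strings = "")
  if (ncol(x) < 2) stop("table '", path, "' needs a feature column plus data")
  x
}

#' Read a multi-omics dataset from TSV tables
#'
#' Layer tables are features-by-samples TSVs (first column the feature id);
#' the metadata table maps each sample id to a subject and a time. Static
#' layers (e.g. host genes measured once) are features-by-subjects.
#'
#' @param layer_paths named character vector, layer name -> TSV path.
#' @param metadata_path TSV with columns `sample_id`, `subject_id` and `time`
#'   (days) or `week` (converted as week x 7); any further numeric columns
#'   become environmental variables.
#' @param layer_kinds optional named character vector overriding the node kind
#'   guessed from each layer name.
#' @param static_layers character vector of layer names to treat as static
#'   per-subject tables; defaults to layers of kind `host_gene`.
#' @return an [omics_dataset()].
#' @export
read_dataset <- function(layer_paths, metadata_path, layer_kinds = NULL,
                         static_layers = NULL) {
  meta <- read_tsv_table(metadata_path)
  need <- c("sample_id", "subject_id")
  if (!all(need %in% names(meta))) {
    stop("metadata '", metadata_path, "' is missing column(s): ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  }
  if (!"time" %in% names(meta)) {
    if ("week" %in% names(meta)) {
      meta$time <- as.numeric(meta$week) * 7
    } else {
      stop("metadata '", metadata_path, "' needs a 'time' or 'week' column")
    }
  }
  meta$time <- as.numeric(meta$time)
  meta$sample_id <- as.character(meta$sample_id)
  meta$subject_id <- as.character(meta$subject_id)
  if (anyDuplicated(meta$sample_id)) {
    stop("metadata '", metadata_path, "' has duplicate sample ids")
  }
  env_cols <- setdiff(names(meta), c("sample_id", "subject_id", "time"))
  env_cols <- env_cols[vapply(meta[env_cols], is.numeric, TRUE)]

  kinds <- vapply(names(layer_paths), function(nm) {
    if (!is.null(layer_kinds) && nm %in% names(layer_kinds)) layer_kinds[[nm]]
    else guess_kind(nm)
  }, "")
  if (is.null(static_layers)) static_layers <- names(layer_paths)[kinds == "host_gene"]

  layers <- list()
  for (nm in names(layer_paths)) {
    path <- layer_paths[[nm]]
    tab <- read_tsv_table(path)
    features <- as.character(tab[[1]])
    if (anyDuplicated(features)) stop("duplicate features in '", path, "'")
    vals <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- features
    if (nm %in% static_layers) {
      data <- lapply(colnames(vals), function(s) {
        v <- vals[, s]
        names(v) <- features
        v
      })
      names(data) <- colnames(vals)
      layers[[nm]] <- omics_layer(nm, kinds[[nm]], FALSE, features, data)
      next
    }
    samples <- colnames(vals)
    missing <- setdiff(samples, meta$sample_id)
    if (length(missing)) {
      stop("layer '", path, "': sample(s) absent from metadata: ",
           paste(missing, collapse = ", "))
    }
    neg <- which(vals < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      stop("layer '", path, "': negative abundance for feature '",
           features[neg[1, 1]], "', sample '", samples[neg[1, 2]], "'")
    }
    mrows <- meta[match(samples, meta$sample_id), ]
    key <- paste(mrows$subject_id, mrows$time)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1]
      stop("layer '", path, "': duplicate (subject, time) sample: ", dup)
    }
    data <- list()
    for (s in unique(mrows$subject_id)) {
      sel <- which(mrows$subject_id == s)
      ord <- sel[order(mrows$time[sel])]
      data[[s]] <- list(times = mrows$time[ord],
                        values = vals[, ord, drop = FALSE])
    }
    layers[[nm]] <- omics_layer(nm, kinds[[nm]], TRUE, features, data)
  }

  if (length(env_cols)) {
    data <- list()
    for (s in unique(meta$subject_id)) {
      sel <- meta$subject_id == s
      ord <- order(meta$time[sel])
      v <- t(as.matrix(meta[sel, env_cols, drop = FALSE][ord, , drop = FALSE]))
      dimnames(v) <- list(env_cols, NULL)
      data[[s]] <- list(times = meta$time[sel][ord], values = v)
    }
    layers[["env"]] <- omics_layer("env", "env", TRUE, env_cols, data)
  }
  omics_dataset(layers)
}

fmt_num <- function(x, digits = 12) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else formatC(v, digits = digits, format = "g")
  }, "")
  out
}

fmt_time <- function(t) formatC(t, digits = 12, format = "g")

#' Write a dataset as canonical TSV tables
#'
#' Subjects and times are sorted so that identical datasets serialize to
#' byte-identical files; values are written at 12 significant digits and empty
#' cells encode missing values (zeros are data). Sample ids are synthesised as
#' `<subject>.<time>`.
#'
#' @param dataset an [omics_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- sort(dataset$subjects)
  files <- c()
  # metadata rows: union of (subject, time) over dynamic layers
  st <- unique(do.call(rbind, lapply(dynamic_layers(dataset), function(l) {
    do.call(rbind, lapply(names(l$data), function(s) {
      data.frame(subject_id = s, time = l$data[[s]]$times,
                 stringsAsFactors = FALSE)
    }))
  })))
  st <- st[order(st$subject_id, st$time), ]
  st$sample_id <- paste(st$subject_id, fmt_time(st$time), sep = ".")
  env <- dataset$layers[["env"]]
  meta <- data.frame(sample_id = st$sample_id, subject_id = st$subject_id,
                     time = fmt_time(st$time), stringsAsFactors = FALSE)
  if (!is.null(env)) {
    for (f in env$features) {
      v <- rep(NA_real_, nrow(st))
      for (i in seq_len(nrow(st))) {
        d <- env$data[[st$subject_id[i]]]
        j <- match(TRUE, abs(d$times - st$time[i]) < 1e-9)
        if (!is.na(j)) v[i] <- d$values[f, j]
      }
      meta[[f]] <- fmt_num(v)
    }
  }
  mp <- file.path(dir, "metadata.tsv")
  utils::write.table(meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  files["metadata"] <- mp

  for (l in dataset$layers) {
    if (l$name == "env") next
    fp <- file.path(dir, paste0(l$name, ".tsv"))
    if (l$dynamic) {
      sel <- st[st$subject_id %in% names(l$data), ]
      cols <- character(0); mat <- NULL
      for (i in seq_len(nrow(sel))) {
        d <- l$data[[sel$subject_id[i]]]
        j <- match(TRUE, abs(d$times - sel$time[i]) < 1e-9)
        if (is.na(j)) next
        cols <- c(cols, sel$sample_id[i])
        mat <- cbind(mat, d$values[, j])
      }
      out <- data.frame(feature_id = l$features, stringsAsFactors = FALSE)
      for (k in seq_along(cols)) out[[cols[k]]] <- fmt_num(mat[, k])
    } else {
      out <- data.frame(feature_id = l$features, stringsAsFactors = FALSE)
      for (s in intersect(subjects, names(l$data))) {
        out[[s]] <- fmt_num(l$data[[s]][l$features])
      }
    }
    utils::write.table(out, fp, sep = "\t", quote = FALSE, row.names = FALSE)
    files[l$name] <- fp
  }
  invisible(files)
}
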