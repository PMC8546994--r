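# In-silico edge validation. A predicted edge of the database's kind is
# "evaluable" if both endpoints are in the database universes; it is
# "validated" if the (parent, child) pair is listed. Precision is
# validated / evaluable. Significance comes from an exact Poisson-binomial
# tail over per-edge chance probabilities (child's validated in-degree
# fraction), compared against a random-network baseline.

#' Construct a validation database
#'
#' @param pairs data frame with columns `parent_feature`, `child_feature`.
#' @param kind `"T_G"` (taxon -> gene) or `"T_M"` (taxon -> metabolite).
#' @param parent_universe,child_universe feature sets covered by the
#'   database; inferred from `pairs` when omitted.
#' @return a `ValidationDB`.
#' @export
validation_db <- function(pairs, kind = c("T_G", "T_M"),
                          parent_universe = NULL, child_universe = NULL) {
  kind <- match.arg(kind)
  pairs <- unique(pairs[, c("parent_feature", "child_feature")])
  if (is.null(parent_universe)) parent_universe <- unique(pairs$parent_feature)
  if (is.null(child_universe)) child_universe <- unique(pairs$child_feature)
  bad <- !(pairs$parent_feature %in% parent_universe &
             pairs$child_feature %in% child_universe)
  if (any(bad)) stop("validation_db: pairs outside the declared universes")
  structure(list(kind = kind, pairs = pairs,
                 parent_universe = unique(parent_universe),
                 child_universe = unique(child_universe)),
            class = "ValidationDB")
}

#' Read a validation database TSV (one parent/child pair per row)
#' @param path TSV with columns `parent_feature`, `child_feature`.
#' @param kind database kind (`"T_G"` or `"T_M"`).
#' @param parent_universe,child_universe optional explicit universe files
#'   (one feature per line) or character vectors.
#' @return a `ValidationDB`.
#' @export
read_validation_db <- function(path, kind = c("T_G", "T_M"),
                               parent_universe = NULL, child_universe = NULL) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_universe <- function(u) {
    if (is.character(u) && length(u) == 1 && file.exists(u)) readLines(u) else u
  }
  validation_db(x, match.arg(kind), as_universe(parent_universe),
                as_universe(child_universe))
}

db_kinds <- function(kind) {
  switch(kind, T_G = c("taxon", "gene"), T_M = c("taxon", "metabolite"))
}

#' Exact Poisson-binomial upper tail
#'
#' `P(X >= k)` for `X` the number of successes among independent Bernoulli
#' trials with heterogeneous probabilities, computed by the exact O(n^2)
#' convolution recursion (no normal approximation).
#'
#' @param probabilities vector of per-trial success probabilities in [0, 1].
#' @param k threshold count, `0 <= k <= n`.
#' @return `P(X >= k)`.
#' @export
poisson_binomial_tail <- function(probabilities, k) {
  p <- probabilities
  n <- length(p)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  if (k == 0) return(1)
  pmf <- c(1, rep(0, n))  # pmf of successes over trials processed so far
  for (i in seq_len(n)) {
    pmf <- c(pmf[1] * (1 - p[i]),
             pmf[2:(n + 1)] * (1 - p[i]) + pmf[1:n] * p[i])
  }
  min(1, max(0, sum(pmf[(k + 1):(n + 1)])))
}

#' Chance probability of one edge being validated
#'
#' The child's validated in-degree fraction: the number of database parents
#' listed for this child, divided by the size of the parent universe. Hub
#' children (essential genes/metabolites) thus get high chance probabilities,
#' which is what motivates the Poisson-binomial rather than binomial null.
#'
#' @param child_feature child feature name (must be in the child universe).
#' @param db a `ValidationDB`.
#' @return probability in [0, 1].
#' @export
edge_chance_probability <- function(child_feature, db) {
  if (!child_feature %in% db$child_universe) {
    stop("edge_chance_probability: child '", child_feature,
         "' not in database universe")
  }
  sum(db$pairs$child_feature == child_feature) / length(db$parent_universe)
}

evaluable_edges <- function(edges, db) {
  kk <- db_kinds(db$kind)
  e <- edges[edges$parent_layer == kk[1] & edges$child_layer == kk[2], ,
             drop = FALSE]
  e[e$parent_feature %in% db$parent_universe &
      e$child_feature %in% db$child_universe, , drop = FALSE]
}

score_edges <- function(e, db) {
  if (!nrow(e)) {
    return(list(n_evaluable = 0, n_validated = 0, precision = NA_real_,
                pb_tail = NA_real_))
  }
  key <- paste(e$parent_feature, e$child_feature)
  dbkey <- paste(db$pairs$parent_feature, db$pairs$child_feature)
  nv <- sum(key %in% dbkey)
  probs <- vapply(e$child_feature, edge_chance_probability, 0, db = db)
  list(n_evaluable = nrow(e), n_validated = nv, precision = nv / nrow(e),
       pb_tail = poisson_binomial_tail(probs, nv))
}

#' Validate predicted edges against a database over a support-threshold sweep
#'
#' For each bootstrap-support threshold, restricts the network to edges of
#' the database's kind with support strictly above the threshold and both
#' endpoints in the database universes, then reports precision and the exact
#' Poisson-binomial tail probability of validating at least that many edges
#' by chance.
#'
#' @param network a `BootstrapNetwork`, `DBNModel`, or edge data frame.
#' @param db a `ValidationDB`.
#' @param thresholds support thresholds (default 0, 0.1, ..., 0.9).
#' @return a `ValidationReport` data frame: threshold, n_evaluable,
#'   n_validated, precision (NA when nothing is evaluable), pb_tail.
#' @export
validate_edges <- function(network, db, thresholds = seq(0, 0.9, by = 0.1)) {
  edges <- model_edges(network)
  ev0 <- evaluable_edges(edges, db)
  out <- do.call(rbind, lapply(thresholds, function(th) {
    sup <- ev0$bootstrap_support
    sup[is.na(sup)] <- 1  # single-run models: every edge fully supported
    sc <- score_edges(ev0[sup > th, , drop = FALSE], db)
    data.frame(threshold = th, n_evaluable = sc$n_evaluable,
               n_validated = sc$n_validated, precision = sc$precision,
               pb_tail = sc$pb_tail)
  }))
  class(out) <- c("ValidationReport", class(out))
  out
}

#' Random-network validation baseline
#'
#' Draws `n_random` networks with the same nodes and the same number of
#' edges of the database's kind as the learned network, selecting
#' (parent, child) pairs uniformly without within-run duplicates from the
#' constraint-allowed list, and averages precision and the Poisson-binomial
#' tail over runs.
#'
#' @param network learned network (edge source for the count and node set).
#' @param constraints a `ConstraintMatrix` or preset name.
#' @param db a `ValidationDB`.
#' @param n_random number of random networks (default 1000).
#' @param seed RNG seed.
#' @return list with `precision_mean`, `pb_tail_mean`, `n_edges`,
#'   `n_allowed`, `n_random`.
#' @export
random_network_null <- function(network, constraints, db, n_random = 1000,
                                seed = 1) {
  constraints <- get_constraints(constraints)
  kk <- db_kinds(db$kind)
  edges <- model_edges(network)
  nodes <- model_nodes(network)
  parents <- sub("^[^:]+:", "", nodes[startsWith(nodes, paste0(kk[1], ":"))])
  children <- sub("^[^:]+:", "", nodes[startsWith(nodes, paste0(kk[2], ":"))])
  lags <- unique(constraints$allowed$lag[
    constraints$allowed$parent_kind == kk[1] &
      constraints$allowed$child_kind == kk[2] &
      !constraints$allowed$self_only])
  if (!length(lags)) stop("random_network_null: constraints allow no ",
                          kk[1], " -> ", kk[2], " edges")
  allowed <- expand.grid(parent_feature = parents, child_feature = children,
                         stringsAsFactors = FALSE)
  k <- sum(edges$parent_layer == kk[1] & edges$child_layer == kk[2])
  if (k > nrow(allowed)) {
    stop("random_network_null: learned edge count exceeds allowed pairs")
  }
  if (k == 0) stop("random_network_null: network has no ", kk[1], " -> ",
                   kk[2], " edges")
  set.seed(as.integer(seed))
  prec <- pb <- rep(NA_real_, n_random)
  for (r in seq_len(n_random)) {
    idx <- sample.int(nrow(allowed), k)
    e <- data.frame(parent_layer = kk[1],
                    parent_feature = allowed$parent_feature[idx],
                    child_layer = kk[2],
                    child_feature = allowed$child_feature[idx],
                    lag = sample(lags, k, replace = TRUE),
                    stringsAsFactors = FALSE)
    sc <- score_edges(evaluable_edges(e, db), db)
    prec[r] <- sc$precision; pb[r] <- sc$pb_tail
  }
  n_ok <- sum(!is.na(prec))
  list(precision_mean = mean(prec, na.rm = TRUE),
       precision_se = stats::sd(prec, na.rm = TRUE) / sqrt(max(n_ok, 1)),
       pb_tail_mean = mean(pb, na.rm = TRUE),
       n_edges = k, n_allowed = nrow(allowed), n_random = n_random)
}

#' Rank metabolite -> taxon edges by confidence
#'
#' Confidence is `|normalized_weight| * bootstrap_support`, the criterion
#' used to shortlist interactions for experimental validation. Descending
#' order; ties break by edge identity.
#'
#' @param network a `BootstrapNetwork`, `DBNModel`, or edge data frame.
#' @return the M -> T edges with a `confidence` column, ordered.
#' @export
rank_mt_edges <- function(network) {
  e <- model_edges(network)
  e <- e[e$parent_layer == "metabolite" & e$child_layer == "taxon", ,
         drop = FALSE]
  sup <- e$bootstrap_support
  sup[is.na(sup)] <- 1
  e$confidence <- abs(e$normalized_weight) * sup
  e[order(-e$confidence, e$parent_feature, e$child_feature, e$lag), ,
    drop = FALSE]
}

#' Write a validation report (with optional random baseline) as TSV
#' @param report a `ValidationReport`.
#' @param path output file.
#' @param baseline optional result of [random_network_null()].
#' @return invisibly, `path`.
#' @export
write_validation_report <- function(report, path, baseline = NULL) {
  out <- as.data.frame(report)
  if (!is.null(baseline)) {
    out$random_precision_mean <- baseline$precision_mean
    out$random_pb_mean <- baseline$pb_tail_mean
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
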