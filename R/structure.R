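# Greedy hill-climbing structure search scored by BIC. The search starts
# from a network with a self-loop inter-edge for every dynamic node, then
# repeatedly adds the single constraint-valid edge with the largest positive
# BIC gain (the score decomposes per child, so a gain is L1 - L0 - log(n)/2)
# until no positive gain remains or every child is at max_parents. Additions
# only; ties break lexicographically by (child, parent, lag).

child_col <- function(node) paste0(node, "@t1")
parent_col <- function(node, lag) {
  paste0(node, ifelse(lag == "inter", "@t", "@t1"))
}

candidate_parents <- function(child_node, child_kind, nodes, constraints) {
  a <- constraints$allowed[constraints$allowed$child_kind == child_kind, ,
                           drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(a))) {
    pk <- a$parent_kind[i]; lag <- a$lag[i]
    pn <- nodes$id[nodes$kind == pk]
    if (a$self_only[i]) pn <- intersect(pn, child_node)
    if (lag == "intra") pn <- setdiff(pn, child_node)
    if (!length(pn)) next
    out <- rbind(out, data.frame(parent = pn, lag = lag,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out)) out <- data.frame(parent = character(0), lag = character(0),
                                      stringsAsFactors = FALSE)
  unique(out)
}

child_loglik <- function(y, X, n) {
  fit <- ols_fit(y, X)
  if (is.null(fit)) return(NULL)
  list(loglik = gauss_loglik(n, fit$sigma2), fit = fit)
}

#' Learn a two-slice DBN structure by greedy BIC hill-climbing
#'
#' @param table an `ObservationTable` from [build_observations()].
#' @param constraints a `ConstraintMatrix` or preset name.
#' @param max_parents maximum parents per child; the initializing self-loop
#'   counts toward the cap (default 3).
#' @param init_self_loops start from the self-loop network (default TRUE)?
#' @return a `DBNModel`: list with `nodes`, `edges` (the standard edge data
#'   frame), `cpds` (per child `GaussianCPD`), `constraints_id`, `bic`,
#'   `bic_trace` (monotone non-decreasing along the greedy path).
#' @export
learn_structure <- function(table, constraints, max_parents = 3,
                            init_self_loops = TRUE) {
  constraints <- get_constraints(constraints)
  if (!table$n) stop("learn_structure: empty observation table")
  nodes <- table$nodes
  children <- nodes$id[nodes$dynamic & nodes$kind %in% OMIC_KINDS]
  n <- table$n
  penalty <- log(n) / 2

  state <- list()
  for (ch in children) {
    y <- table$X[, child_col(ch)]
    parents <- data.frame(parent = character(0), lag = character(0),
                          stringsAsFactors = FALSE)
    if (init_self_loops &&
        edge_allowed(constraints, nodes$kind[nodes$id == ch],
                     nodes$kind[nodes$id == ch], "inter", is_self = TRUE)) {
      parents <- data.frame(parent = ch, lag = "inter",
                            stringsAsFactors = FALSE)
    }
    repeat {
      cols <- parent_col(parents$parent, parents$lag)
      res <- child_loglik(y, table$X[, cols, drop = FALSE], n)
      if (!is.null(res)) break
      if (!nrow(parents)) stop("learn_structure: degenerate child ", ch)
      parents <- parents[0, , drop = FALSE]  # constant self-loop: drop it
    }
    state[[ch]] <- list(parents = parents, loglik = res$loglik,
                        fit = res$fit, y = y,
                        kind = nodes$kind[nodes$id == ch])
  }

  bic_of_state <- function() {
    sum(vapply(state, `[[`, 0, "loglik")) -
      penalty * sum(vapply(state, function(s) nrow(s$parents) + 2, 0)) * 1
  }
  trace <- bic_of_state()

  gains_for <- function(ch) {
    st <- state[[ch]]
    if (nrow(st$parents) >= max_parents) return(NULL)
    cand <- candidate_parents(ch, st$kind, nodes, constraints)
    have <- paste(st$parents$parent, st$parents$lag)
    cand <- cand[!paste(cand$parent, cand$lag) %in% have, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    base_cols <- parent_col(st$parents$parent, st$parents$lag)
    g <- vapply(seq_len(nrow(cand)), function(i) {
      cols <- c(base_cols, parent_col(cand$parent[i], cand$lag[i]))
      res <- child_loglik(st$y, table$X[, cols, drop = FALSE], n)
      if (is.null(res)) -Inf else res$loglik - st$loglik - penalty
    }, 0)
    cbind(cand, data.frame(child = ch, gain = g, stringsAsFactors = FALSE))
  }

  gains <- lapply(children, gains_for)
  names(gains) <- children

  repeat {
    all_g <- do.call(rbind, gains)
    if (is.null(all_g) || !nrow(all_g)) break
    gmax <- max(all_g$gain)
    if (!is.finite(gmax) || gmax <= 0) break
    sel <- all_g[all_g$gain >= gmax - 1e-12, , drop = FALSE]
    sel <- sel[order(sel$child, sel$parent, sel$lag), , drop = FALSE][1, ]
    ch <- sel$child
    st <- state[[ch]]
    st$parents <- rbind(st$parents,
                        data.frame(parent = sel$parent, lag = sel$lag,
                                   stringsAsFactors = FALSE))
    cols <- parent_col(st$parents$parent, st$parents$lag)
    res <- child_loglik(st$y, table$X[, cols, drop = FALSE], n)
    st$loglik <- res$loglik; st$fit <- res$fit
    state[[ch]] <- st
    trace <- c(trace, bic_of_state())
    gains[[ch]] <- gains_for(ch)
  }

  edges <- empty_edges(); cpds <- list()
  for (ch in children) {
    st <- state[[ch]]
    ck <- st$kind; cf <- sub("^[^:]+:", "", ch)
    if (nrow(st$parents)) {
      pk <- nodes$kind[match(st$parents$parent, nodes$id)]
      pf <- sub("^[^:]+:", "", st$parents$parent)
      edges <- rbind(edges, data.frame(
        parent_layer = pk, parent_feature = pf, child_layer = ck,
        child_feature = cf, lag = st$parents$lag,
        coefficient = st$fit$betas, normalized_weight = NA_real_,
        bootstrap_support = NA_real_, stringsAsFactors = FALSE))
    }
    cpds[[child_col(ch)]] <- structure(
      list(child = child_col(ch),
           parents = parent_col(st$parents$parent, st$parents$lag),
           parent_meta = st$parents, beta0 = st$fit$beta0,
           betas = st$fit$betas, sigma2 = st$fit$sigma2),
      class = "GaussianCPD")
  }
  model <- structure(list(nodes = nodes$id, node_meta = nodes,
                          edges = canonical_edge_order(edges), cpds = cpds,
                          constraints_id = constraints$name,
                          max_parents = max_parents,
                          bic = trace[length(trace)], bic_trace = trace),
                     class = "DBNModel")
  annotate_normalized_weights(model, table)
}

#' @export
print.DBNModel <- function(x, ...) {
  cat("DBNModel:", length(x$cpds), "children,", nrow(x$edges), "edges",
      sprintf("(constraints: %s, BIC: %.3f)\n", x$constraints_id, x$bic))
  invisible(x)
}

#' Standardized edge weight
#'
#' The statistical influence of an edge after normalizing for parent scale:
#' `beta * sd(parent) / sd(child)`, computed on the observation table. The
#' sign of the coefficient is preserved; a zero-variance child is an error.
#'
#' @param beta edge coefficient.
#' @param parent_values,child_values observation-table columns for parent
#'   (at its slice) and child (slice t+1).
#' @return the normalized weight.
#' @export
normalized_weight <- function(beta, parent_values, child_values) {
  sdc <- stats::sd(child_values)
  if (sdc == 0) stop("normalized_weight: zero child variance")
  beta * stats::sd(parent_values) / sdc
}

annotate_normalized_weights <- function(model, table) {
  e <- model$edges
  if (!nrow(e)) return(model)
  for (i in seq_len(nrow(e))) {
    pcol <- parent_col(node_id(e$parent_layer[i], e$parent_feature[i]), e$lag[i])
    ccol <- child_col(node_id(e$child_layer[i], e$child_feature[i]))
    sdc <- stats::sd(table$X[, ccol])
    e$normalized_weight[i] <- if (sdc == 0) NA_real_ else
      normalized_weight(e$coefficient[i], table$X[, pcol], table$X[, ccol])
  }
  model$edges <- e
  model
}

edge_key <- function(e) {
  paste(e$parent_layer, e$parent_feature, e$child_layer, e$child_feature,
        e$lag, sep = "\r")
}

#' Bootstrap the network over subjects
#'
#' Each repetition resamples subjects with replacement (duplicated subjects
#' contribute duplicated transition rows), rebuilds the observation table and
#' learns a model. The output is the union of edges over repetitions, each
#' with its bootstrap support (occurrence fraction) and averaged coefficient
#' and normalized weight. Per-repetition seeds derive from the master seed,
#' so the result is reproducible and independent of execution order.
#'
#' @param resampled a `ResampledDataset` (see [resample_dataset()]).
#' @param constraints a `ConstraintMatrix` or preset name.
#' @param n_reps bootstrap repetitions (default 100).
#' @param seed master seed.
#' @param max_parents maximum parents per child.
#' @param identity_resample if TRUE, every repetition uses the original
#'   subject list (no resampling); useful for testing.
#' @return a `BootstrapNetwork`: list with `edges` (union edge data frame
#'   with `bootstrap_support` in (0, 1]), `n_reps`, `seed`,
#'   `constraints_id`.
#' @export
bootstrap_network <- function(resampled, constraints, n_reps = 100, seed = 1,
                              max_parents = 3, identity_resample = FALSE) {
  constraints <- get_constraints(constraints)
  subjects <- names(resampled$grids)
  if (length(subjects) < 2 && !identity_resample) {
    stop("bootstrap_network needs >= 2 subjects")
  }
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2147483646L, n_reps)
  acc <- new.env(parent = emptyenv())
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    draw <- if (identity_resample) subjects else
      sort(sample(subjects, length(subjects), replace = TRUE))
    tab <- build_observations(resampled, subjects = draw)
    m <- learn_structure(tab, constraints, max_parents = max_parents)
    e <- m$edges
    if (!nrow(e)) next
    keys <- edge_key(e)
    for (i in seq_len(nrow(e))) {
      k <- keys[i]
      prev <- if (exists(k, envir = acc)) get(k, envir = acc) else
        list(row = e[i, ], count = 0, coef = 0, nw = 0)
      prev$count <- prev$count + 1
      prev$coef <- prev$coef + e$coefficient[i]
      prev$nw <- prev$nw + ifelse(is.na(e$normalized_weight[i]), 0,
                                  e$normalized_weight[i])
      assign(k, prev, envir = acc)
    }
  }
  keys <- sort(ls(acc))
  edges <- empty_edges()
  for (k in keys) {
    v <- get(k, envir = acc)
    row <- v$row
    row$coefficient <- v$coef / v$count
    row$normalized_weight <- v$nw / v$count
    row$bootstrap_support <- v$count / n_reps
    edges <- rbind(edges, row)
  }
  structure(list(edges = canonical_edge_order(edges), n_reps = n_reps,
                 seed = seed, constraints_id = constraints$name,
                 nodes = unique(c(
                   node_id(resampled$nodes$kind, resampled$nodes$feature)))),
            class = "BootstrapNetwork")
}

#' @export
print.BootstrapNetwork <- function(x, ...) {
  cat("BootstrapNetwork:", nrow(x$edges), "union edges over", x$n_reps,
      "repetitions (constraints:", x$constraints_id, ")\n")
  invisible(x)
}
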