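# Seeded generator of multi-omics longitudinal datasets with a known
# ground-truth DBN, subject time warps, and matching validation databases.
# Latent dynamics are simulated in unconstrained space exactly in the
# conditional linear-Gaussian family the learner assumes; emission either
# passes the latent values through ("raw") or maps each omic layer to the
# simplex via softmax ("relative").

#' Synthetic-data configuration
#'
#' Defaults emulate a year-long cohort profiled roughly every two weeks:
#' 50 subjects on a 25-point, 14-day grid, coefficient magnitudes in
#' [0.5, 1], process noise sd 0.1. Warps, sampling jitter, missingness and
#' softmax emission are off by default so that the generating process is
#' exactly the learner's model family (recovery failures then indicate
#' bugs); each knob can be turned on to emulate messier real data.
#'
#' @param n_subjects,n_taxa,n_genes,n_metabolites,n_host_genes entity counts.
#' @param t0,rate_days,n_points the reference sampling grid.
#' @param warp_a,warp_b ranges (length-2) of subject warp slopes/offsets;
#'   degenerate ranges give identity warps.
#' @param noise_sd process (CPD residual) noise sd.
#' @param obs_noise_sd additional observation noise sd.
#' @param edge_density probability of each allowed cross-edge pair.
#' @param env_edge_density probability of env -> taxon edges (default 0: a
#'   linear-in-week parent is non-stationary; see the methods vignette).
#' @param coef_range magnitude range of cross-edge coefficients.
#' @param self_coef_range range of (positive) self-loop coefficients.
#' @param neg_fraction probability a cross edge is negative.
#' @param missingness fraction of observations dropped at random.
#' @param jitter_days uniform jitter applied to observation times.
#' @param emission `"raw"` or `"relative"` (per-layer softmax).
#' @param constraints constraint preset or matrix the truth must respect.
#' @param max_parents parent cap the truth must respect.
#' @param seed RNG seed.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_subjects = 50, n_taxa = 8, n_genes = 6,
                              n_metabolites = 6, n_host_genes = 3,
                              t0 = 0, rate_days = 14, n_points = 25,
                              warp_a = c(1, 1), warp_b = c(0, 0),
                              noise_sd = 0.1, obs_noise_sd = 0,
                              edge_density = 0.15, env_edge_density = 0,
                              coef_range = c(0.5, 1),
                              self_coef_range = c(0.4, 0.8),
                              neg_fraction = 0.33,
                              missingness = 0, jitter_days = 0,
                              emission = c("raw", "relative"),
                              constraints = "augmented", max_parents = 3,
                              seed = 1) {
  emission <- match.arg(emission)
  stopifnot(n_subjects >= 1, n_taxa >= 1, n_genes >= 1, n_metabolites >= 1,
            noise_sd >= 0, obs_noise_sd >= 0, all(warp_a > 0),
            n_points >= 2)
  structure(as.list(environment()), class = "SimulationConfig")
}

draw_truth_edges <- function(cfg, nodes, constraints) {
  a <- constraints$allowed
  edges <- empty_edges()
  add <- function(pk, pf, ck, cf, lag, coef) {
    rbind(edges, data.frame(parent_layer = pk, parent_feature = pf,
                            child_layer = ck, child_feature = cf, lag = lag,
                            coefficient = coef, normalized_weight = NA_real_,
                            bootstrap_support = NA_real_,
                            stringsAsFactors = FALSE))
  }
  # self-loops always present
  for (k in OMIC_KINDS) {
    for (f in nodes$feature[nodes$kind == k]) {
      edges <- add(k, f, k, f, "inter",
                   stats::runif(1, cfg$self_coef_range[1],
                                cfg$self_coef_range[2]))
    }
  }
  for (i in seq_len(nrow(a))) {
    if (a$self_only[i]) next
    pk <- a$parent_kind[i]; ck <- a$child_kind[i]; lag <- a$lag[i]
    dens <- if (pk == "env") cfg$env_edge_density else cfg$edge_density
    if (dens <= 0) next
    for (pf in nodes$feature[nodes$kind == pk]) {
      for (cf in nodes$feature[nodes$kind == ck]) {
        if (pk == ck && pf == cf) next
        if (stats::runif(1) < dens) {
          mag <- stats::runif(1, cfg$coef_range[1], cfg$coef_range[2])
          sgn <- if (stats::runif(1) < cfg$neg_fraction) -1 else 1
          edges <- add(pk, pf, ck, cf, lag, sgn * mag)
        }
      }
    }
  }
  # enforce the parent cap per child: keep the self-loop plus a random
  # subset of cross parents
  keep <- rep(TRUE, nrow(edges))
  ckey <- node_id(edges$child_layer, edges$child_feature)
  for (ch in unique(ckey)) {
    idx <- which(ckey == ch)
    if (length(idx) <= cfg$max_parents) next
    is_self <- edges$parent_layer[idx] == edges$child_layer[idx] &
      edges$parent_feature[idx] == edges$child_feature[idx]
    cross <- idx[!is_self]
    n_keep <- cfg$max_parents - sum(is_self)
    drop <- sample(cross, length(cross) - n_keep)
    keep[drop] <- FALSE
  }
  edges[keep, , drop = FALSE]
}

lag_matrix <- function(edges, dyn_ids, lag) {
  A <- matrix(0, length(dyn_ids), length(dyn_ids),
              dimnames = list(dyn_ids, dyn_ids))
  e <- edges[edges$lag == lag, , drop = FALSE]
  for (i in seq_len(nrow(e))) {
    pid <- node_id(e$parent_layer[i], e$parent_feature[i])
    cid <- node_id(e$child_layer[i], e$child_feature[i])
    if (pid %in% dyn_ids && cid %in% dyn_ids) A[cid, pid] <- e$coefficient[i]
  }
  A
}

# Effective slice-to-slice transition: x_{t+1} = B x_{t+1} + A x_t + ...
# solves to (I - B)^{-1} A. Checking the inter matrix A alone is not enough:
# intra chains (B) can amplify an otherwise stable A into divergence.
effective_transition <- function(edges, dyn_ids) {
  A <- lag_matrix(edges, dyn_ids, "inter")
  B <- lag_matrix(edges, dyn_ids, "intra")
  solve(diag(length(dyn_ids)) - B, A)
}

#' Generate a synthetic multi-omics dataset with known ground truth
#'
#' Draws a constraint-respecting random DBN (self-loops always present;
#' stability enforced by spectral radius < 1 of the inter-slice coefficient
#' matrix, with up to 100 redraws), simulates each subject forward through
#' the Gaussian CPDs on the reference grid, maps observation times through
#' the inverse of each subject's warp (plus optional jitter/missingness),
#' and emits values raw or on the simplex.
#'
#' @param config a [simulation_config()].
#' @return list with `dataset` (an [omics_dataset()]), `truth` (list:
#'   `model` (a `DBNModel` with the true coefficients), `warps`,
#'   `intercepts`, `config`).
#' @export
generate <- function(config) {
  cfg <- config
  set.seed(as.integer(cfg$seed))
  constraints <- get_constraints(cfg$constraints)
  nodes <- rbind(
    data.frame(kind = "taxon", feature = sprintf("T%02d", seq_len(cfg$n_taxa)),
               stringsAsFactors = FALSE),
    data.frame(kind = "gene", feature = sprintf("G%02d", seq_len(cfg$n_genes)),
               stringsAsFactors = FALSE),
    data.frame(kind = "metabolite",
               feature = sprintf("M%02d", seq_len(cfg$n_metabolites)),
               stringsAsFactors = FALSE),
    if (cfg$n_host_genes > 0)
      data.frame(kind = "host_gene",
                 feature = sprintf("H%02d", seq_len(cfg$n_host_genes)),
                 stringsAsFactors = FALSE))
  nodes$id <- node_id(nodes$kind, nodes$feature)
  dyn <- nodes[nodes$kind %in% OMIC_KINDS, ]

  edges <- NULL
  for (try in seq_len(100)) {
    cand <- draw_truth_edges(cfg, nodes, constraints)
    M <- effective_transition(cand, dyn$id)
    if (max(abs(eigen(M, only.values = TRUE)$values)) < 1) {
      edges <- cand; break
    }
  }
  if (is.null(edges)) stop("generate: no stable coefficient draw in 100 tries")
  intercepts <- stats::setNames(stats::runif(nrow(dyn), -0.3, 0.3), dyn$id)

  # per-child parent lists in within-slice topological order
  kind_order <- c(taxon = 1, gene = 2, metabolite = 3)
  dyn <- dyn[order(kind_order[dyn$kind]), ]
  parents_of <- lapply(dyn$id, function(ch) {
    sel <- edges[node_id(edges$child_layer, edges$child_feature) == ch, ,
                 drop = FALSE]
    sel
  })
  names(parents_of) <- dyn$id

  grid <- cfg$t0 + (seq_len(cfg$n_points) - 1) * cfg$rate_days
  warps <- list()
  taxa_ids <- dyn$id[dyn$kind == "taxon"]
  gene_ids <- dyn$id[dyn$kind == "gene"]
  met_ids <- dyn$id[dyn$kind == "metabolite"]

  layer_data <- list(taxa = list(), genes = list(), metabolites = list())
  host_data <- list()
  latent <- list()
  subjects <- sprintf("S%03d", seq_len(cfg$n_subjects))
  burn <- 50  # long enough that sigma = 0 fixed points are reached
  for (s in subjects) {
    host <- stats::setNames(stats::rnorm(cfg$n_host_genes),
                            nodes$id[nodes$kind == "host_gene"])
    X <- matrix(0, nrow(dyn), cfg$n_points + burn,
                dimnames = list(dyn$id, NULL))
    X[, 1] <- stats::rnorm(nrow(dyn), 0, 1)
    for (j in 2:(cfg$n_points + burn)) {
      for (ch in dyn$id) {  # dyn is in within-slice topological order
        pe <- parents_of[[ch]]
        mu <- intercepts[[ch]]
        if (nrow(pe)) {
          for (i in seq_len(nrow(pe))) {
            pid <- node_id(pe$parent_layer[i], pe$parent_feature[i])
            val <- if (pe$parent_layer[i] == "host_gene") host[[pid]]
            else if (pe$parent_layer[i] == "env") grid[max(j - burn, 1)] / 7
            else if (pe$lag[i] == "inter") X[pid, j - 1]
            else X[pid, j]
            mu <- mu + pe$coefficient[i] * val
          }
        }
        X[ch, j] <- mu + stats::rnorm(1, 0, cfg$noise_sd)
      }
    }
    X <- X[, (burn + 1):(cfg$n_points + burn), drop = FALSE]
    latent[[s]] <- X

    a <- stats::runif(1, cfg$warp_a[1], cfg$warp_a[2])
    b <- stats::runif(1, cfg$warp_b[1], cfg$warp_b[2])
    warps[[s]] <- structure(list(subject = s, a = a, b = b, error = NA_real_,
                                 reference_subject = NA_character_),
                            class = "TimeWarp")
    times <- (grid - b) / a
    if (cfg$jitter_days > 0) {
      times <- times + stats::runif(length(times), -cfg$jitter_days,
                                    cfg$jitter_days)
      ord <- order(times)
      times <- times[ord]; X <- X[, ord, drop = FALSE]
    }
    keep <- rep(TRUE, length(times))
    if (cfg$missingness > 0 && length(times) > 2) {
      drop <- stats::runif(length(times)) < cfg$missingness
      drop[c(1, length(times))] <- FALSE  # keep the domain ends
      keep <- !drop
    }
    times <- times[keep]; X <- X[, keep, drop = FALSE]
    if (cfg$obs_noise_sd > 0) {
      X <- X + matrix(stats::rnorm(length(X), 0, cfg$obs_noise_sd), nrow(X))
    }
    emit <- function(ids) {
      v <- X[ids, , drop = FALSE]
      if (cfg$emission == "relative") {
        ev <- exp(v)
        v <- sweep(ev, 2, colSums(ev), "/")
      }
      rownames(v) <- sub("^[^:]+:", "", ids)
      v
    }
    layer_data$taxa[[s]] <- list(times = times, values = emit(taxa_ids))
    layer_data$genes[[s]] <- list(times = times, values = emit(gene_ids))
    layer_data$metabolites[[s]] <- list(times = times, values = emit(met_ids))
    hostv <- host
    names(hostv) <- sub("^[^:]+:", "", names(host))
    host_data[[s]] <- hostv
  }

  feat <- function(k) nodes$feature[nodes$kind == k]
  layers <- list(
    omics_layer("taxa", "taxon", TRUE, feat("taxon"), layer_data$taxa),
    omics_layer("genes", "gene", TRUE, feat("gene"), layer_data$genes),
    omics_layer("metabolites", "metabolite", TRUE, feat("metabolite"),
                layer_data$metabolites))
  if (cfg$n_host_genes > 0) {
    layers <- c(layers, list(omics_layer("host_genes", "host_gene", FALSE,
                                         feat("host_gene"), host_data)))
  }
  env_data <- lapply(layer_data$taxa, function(d) {
    list(times = d$times, values = matrix(d$times / 7, 1,
                                          dimnames = list("week", NULL)))
  })
  layers <- c(layers, list(omics_layer("env", "env", TRUE, "week", env_data)))
  dataset <- omics_dataset(layers, subjects)

  truth_model <- structure(
    list(nodes = nodes$id, node_meta = nodes,
         edges = canonical_edge_order(edges), cpds = NULL,
         constraints_id = constraints$name, max_parents = cfg$max_parents,
         bic = NA_real_, bic_trace = numeric(0)),
    class = "DBNModel")
  list(dataset = dataset,
       truth = list(model = truth_model, warps = warps,
                    intercepts = intercepts, latent = latent,
                    grid = grid, config = cfg))
}

#' Build a validation database from simulation ground truth
#'
#' Pairs are the planted taxon -> gene (kind `"T_G"`) or taxon -> metabolite
#' (`"T_M"`) relations; universes cover all generated features of the two
#' kinds. `extra_negative_fraction` appends that fraction (of the true pair
#' count) of random non-planted decoy pairs.
#'
#' @param truth the `truth` component returned by [generate()].
#' @param kind `"T_G"` or `"T_M"`.
#' @param extra_negative_fraction decoy pairs to add, as a fraction of the
#'   planted pair count.
#' @param seed RNG seed for decoy sampling.
#' @return a `ValidationDB`.
#' @export
make_validation_db <- function(truth, kind = c("T_G", "T_M"),
                               extra_negative_fraction = 0, seed = 1) {
  kind <- match.arg(kind)
  kk <- db_kinds(kind)
  nodes <- truth$model$node_meta
  e <- truth$model$edges
  pairs <- unique(e[e$parent_layer == kk[1] & e$child_layer == kk[2],
                    c("parent_feature", "child_feature"), drop = FALSE])
  pu <- nodes$feature[nodes$kind == kk[1]]
  cu <- nodes$feature[nodes$kind == kk[2]]
  if (extra_negative_fraction > 0 && nrow(pairs)) {
    set.seed(as.integer(seed))
    all_pairs <- expand.grid(parent_feature = pu, child_feature = cu,
                             stringsAsFactors = FALSE)
    key <- paste(all_pairs$parent_feature, all_pairs$child_feature)
    neg <- all_pairs[!key %in% paste(pairs$parent_feature,
                                     pairs$child_feature), , drop = FALSE]
    n_extra <- min(nrow(neg), round(extra_negative_fraction * nrow(pairs)))
    if (n_extra > 0) {
      pairs <- rbind(pairs, neg[sample.int(nrow(neg), n_extra), ])
    }
  }
  validation_db(pairs, kind, parent_universe = pu, child_universe = cu)
}
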