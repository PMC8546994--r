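# Forward prediction, LOOCV MAE, and the in-silico validation statistics.

make_self_loop_model <- function(rs, beta = 1, beta0 = 0) {
  nodes <- rs$nodes
  children <- nodes$id[nodes$dynamic & nodes$kind %in%
                         c("taxon", "gene", "metabolite")]
  cpds <- lapply(children, function(ch) {
    structure(list(child = paste0(ch, "@t1"), parents = paste0(ch, "@t"),
                   parent_meta = data.frame(parent = ch, lag = "inter",
                                            stringsAsFactors = FALSE),
                   beta0 = beta0, betas = beta, sigma2 = 1e-9),
              class = "GaussianCPD")
  })
  names(cpds) <- paste0(children, "@t1")
  structure(list(nodes = nodes$id, node_meta = nodes, edges = NULL,
                 cpds = cpds, constraints_id = "custom", max_parents = 3,
                 bic = NA_real_, bic_trace = numeric(0)),
            class = "DBNModel")
}

test_that("identity dynamics predict the previous observation", {
  sim <- small_sim(seed = 17, n_subjects = 4, n_points = 8,
                   emission = "relative")
  rs <- resample_dataset(sim$dataset, 14, 0, smoothing = "none",
                         clip_negative = TRUE)
  model <- make_self_loop_model(rs)
  s <- names(rs$grids)[1]
  p <- predict_subject(model, rs, s, "taxon", renormalize = TRUE)
  m <- rs$values[[s]]
  taxa <- grep("^taxon:", rownames(m), value = TRUE)
  prev <- m[taxa, -ncol(m), drop = FALSE]
  prev <- sweep(pmax(prev, 0), 2, colSums(pmax(prev, 0)), "/")
  expect_equal(unname(p$predicted), unname(prev), tolerance = 1e-9)
})

test_that("a single-taxon layer predicts 1.0 after renormalization", {
  sim <- generate(simulation_config(n_subjects = 3, n_taxa = 1, n_genes = 2,
                                    n_metabolites = 2, n_host_genes = 0,
                                    n_points = 8, seed = 2))
  rs <- resample_dataset(sim$dataset, 14, 0, smoothing = "none")
  model <- make_self_loop_model(rs)
  p <- predict_subject(model, rs, names(rs$grids)[1], "taxon")
  expect_true(all(p$predicted == 1))
})

test_that("predictions from the true model match the generator", {
  # sigma -> 0: the subject's values follow the CPD means exactly, so the
  # true-coefficient model must reproduce them before renormalization
  sim <- generate(simulation_config(n_subjects = 3, n_taxa = 3, n_genes = 2,
                                    n_metabolites = 2, n_host_genes = 0,
                                    n_points = 10, seed = 9, noise_sd = 0))
  rs <- resample_dataset(sim$dataset, 14, 0, smoothing = "none")
  # assemble the truth CPDs
  truth <- sim$truth
  nodes <- rs$nodes
  children <- nodes$id[nodes$dynamic & nodes$kind %in%
                         c("taxon", "gene", "metabolite")]
  cpds <- lapply(children, function(ch) {
    e <- truth$model$edges
    sel <- e[paste(e$child_layer, e$child_feature) ==
               paste(nodes$kind[nodes$id == ch],
                     nodes$feature[nodes$id == ch]), , drop = FALSE]
    pm <- data.frame(parent = paste(sel$parent_layer, sel$parent_feature,
                                    sep = ":"),
                     lag = sel$lag, stringsAsFactors = FALSE)
    structure(list(child = paste0(ch, "@t1"),
                   parents = paste0(pm$parent,
                                    ifelse(pm$lag == "inter", "@t", "@t1")),
                   parent_meta = pm, beta0 = truth$intercepts[[ch]],
                   betas = sel$coefficient, sigma2 = 1e-9),
              class = "GaussianCPD")
  })
  names(cpds) <- paste0(children, "@t1")
  model <- structure(list(nodes = nodes$id, node_meta = nodes, edges = NULL,
                          cpds = cpds, constraints_id = "augmented",
                          max_parents = 3, bic = NA_real_,
                          bic_trace = numeric(0)), class = "DBNModel")
  s <- names(rs$grids)[1]
  p <- predict_subject(model, rs, s, "taxon", renormalize = FALSE)
  obs <- rs$values[[s]][grep("^taxon:", rownames(rs$values[[s]])), -1,
                        drop = FALSE]
  expect_equal(unname(p$raw), unname(obs), tolerance = 1e-6)
})

test_that("loocv_mae: true-model family beats intercept-only dynamics", {
  sim <- generate(simulation_config(n_subjects = 10, n_taxa = 3, n_genes = 2,
                                    n_metabolites = 2, n_host_genes = 0,
                                    n_points = 12, seed = 14,
                                    noise_sd = 0.05))
  rs <- resample_dataset(sim$dataset, 14, 0, smoothing = "none")
  rep_full <- loocv_mae(rs, "augmented", renormalize = FALSE)
  expect_gte(rep_full$mae_overall, 0)
  # intercept-only baseline: predict the training mean everywhere
  taxa <- grep("^taxon:", rownames(rs$values[[1]]), value = TRUE)
  base_mae <- mean(vapply(names(rs$grids), function(s) {
    train <- setdiff(names(rs$grids), s)
    mu <- rowMeans(do.call(cbind, lapply(train, function(u)
      rs$values[[u]][taxa, , drop = FALSE])))
    obs <- rs$values[[s]][taxa, -1, drop = FALSE]
    mean(abs(obs - mu))
  }, 0))
  expect_lt(rep_full$mae_overall, base_mae)
  # MAE is invariant to subject order
  rs_rev <- rs
  ord <- rev(names(rs$grids))
  rs_rev$grids <- rs_rev$grids[ord]; rs_rev$values <- rs_rev$values[ord]
  rs_rev$static <- rs_rev$static[ord]
  rep_rev <- loocv_mae(rs_rev, "augmented", renormalize = FALSE)
  expect_equal(rep_rev$mae_overall, rep_full$mae_overall, tolerance = 1e-12)
})

test_that("poisson_binomial_tail is exact", {
  expect_equal(poisson_binomial_tail(c(0.5, 0.5), 2), 0.25)
  expect_equal(poisson_binomial_tail(stats::runif(7), 0), 1)
  expect_error(poisson_binomial_tail(c(0.5), 2), "k must")
  expect_error(poisson_binomial_tail(c(1.2), 1), "probabilities")
  # n = 12: matches full 2^12 enumeration for every k
  set.seed(6)
  p <- stats::runif(12)
  outcomes <- expand.grid(rep(list(0:1), 12))
  probs <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
  ks <- rowSums(outcomes)
  for (k in 0:12) {
    expect_lt(abs(poisson_binomial_tail(p, k) - sum(probs[ks >= k])), 1e-12)
  }
  # equal p: collapses to the binomial tail
  for (k in 0:9) {
    expect_equal(poisson_binomial_tail(rep(0.3, 9), k),
                 stats::pbinom(k - 1, 9, 0.3, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # monotone non-increasing in k
  tails <- vapply(0:12, function(k) poisson_binomial_tail(p, k), 0)
  expect_true(all(diff(tails) <= 1e-15))
})

test_that("edge_chance_probability is the child's in-degree fraction", {
  db <- validation_db(data.frame(parent_feature = c("T1", "T2", "T3", "T1"),
                                 child_feature = c("G1", "G1", "G1", "G2")),
                      "T_G",
                      parent_universe = c("T1", "T2", "T3", "T4"),
                      child_universe = c("G1", "G2", "G3"))
  expect_equal(edge_chance_probability("G1", db), 3 / 4)
  expect_equal(edge_chance_probability("G2", db), 1 / 4)
  expect_equal(edge_chance_probability("G3", db), 0)
  expect_error(edge_chance_probability("G9", db), "not in database")
})

test_that("validate_edges computes precision over evaluable edges", {
  db <- validation_db(data.frame(parent_feature = "A", child_feature = "B"),
                      "T_G", parent_universe = c("A", "Z"),
                      child_universe = c("B", "C"))
  e <- data.frame(parent_layer = "taxon", parent_feature = c("A", "A", "A"),
                  child_layer = "gene", child_feature = c("B", "C", "OUT"),
                  lag = "intra", coefficient = 1, normalized_weight = 1,
                  bootstrap_support = c(0.9, 0.6, 0.95),
                  stringsAsFactors = FALSE)
  r <- validate_edges(e, db, thresholds = c(0, 0.8, 0.99))
  # OUT's child is outside the universe -> excluded from evaluable
  expect_equal(r$n_evaluable, c(2, 1, 0))
  expect_equal(r$precision, c(0.5, 1, NA))
  expect_true(is.na(r$pb_tail[3]))
  # n_evaluable is non-increasing in the threshold
  expect_true(all(diff(r$n_evaluable) <= 0))
})

test_that("random_network_null matches its analytic extremes and mean", {
  nodes <- c(paste0("taxon:T", 1:4), paste0("gene:G", 1:5))
  e <- data.frame(parent_layer = "taxon", parent_feature = c("T1", "T2"),
                  child_layer = "gene", child_feature = c("G1", "G2"),
                  lag = "intra", coefficient = 1, normalized_weight = 1,
                  bootstrap_support = 1, stringsAsFactors = FALSE)
  net <- structure(list(edges = e, nodes = nodes), class = "DBNModel")
  all_pairs <- expand.grid(parent_feature = paste0("T", 1:4),
                           child_feature = paste0("G", 1:5),
                           stringsAsFactors = FALSE)
  db_all <- validation_db(all_pairs, "T_G")
  r <- random_network_null(net, "skeleton", db_all, n_random = 50, seed = 1)
  expect_equal(r$precision_mean, 1)
  db_none <- validation_db(all_pairs[0, ], "T_G",
                           parent_universe = paste0("T", 1:4),
                           child_universe = paste0("G", 1:5))
  r0 <- random_network_null(net, "skeleton", db_none, n_random = 50, seed = 1)
  expect_equal(r0$precision_mean, 0)
  # law of large numbers: mean precision ~= validated density of allowed pairs
  some <- all_pairs[1:7, ]
  db_some <- validation_db(some, "T_G", parent_universe = paste0("T", 1:4),
                           child_universe = paste0("G", 1:5))
  r1 <- random_network_null(net, "skeleton", db_some, n_random = 1000,
                            seed = 2)
  density <- 7 / 20
  expect_lt(abs(r1$precision_mean - density), 3 * r1$precision_se)
})

test_that("rank_mt_edges sorts by |normalized weight| x support", {
  set.seed(12)
  n <- 20
  e <- data.frame(parent_layer = "metabolite",
                  parent_feature = sprintf("M%02d", 1:n),
                  child_layer = "taxon", child_feature = sprintf("T%02d", 1:n),
                  lag = "inter", coefficient = stats::rnorm(n),
                  normalized_weight = stats::rnorm(n),
                  bootstrap_support = stats::runif(n),
                  stringsAsFactors = FALSE)
  # a couple of edges of other kinds must be ignored
  other <- e[1:2, ]; other$parent_layer <- "taxon"; other$child_layer <- "gene"
  r <- rank_mt_edges(rbind(e, other))
  expect_equal(nrow(r), n)
  oracle <- order(-abs(e$normalized_weight) * e$bootstrap_support)
  expect_equal(r$parent_feature, e$parent_feature[oracle])
  # support dominates when |weights| tie; zero weight ranks last
  e2 <- e[1:2, ]
  e2$normalized_weight <- c(0.5, -0.5)
  e2$bootstrap_support <- c(0.5, 1)
  expect_equal(rank_mt_edges(e2)$parent_feature[1], e2$parent_feature[2])
  e3 <- rbind(e, transform(e[1, ], parent_feature = "MZZ",
                           normalized_weight = 0))
  r3 <- rank_mt_edges(e3)
  expect_equal(r3$parent_feature[nrow(r3)], "MZZ")
})
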