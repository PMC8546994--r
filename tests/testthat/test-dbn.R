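# Observation tables, CPD fitting, BIC, constraints and greedy search.

obs_from_sim <- function(sim, ...) {
  rs <- resample_dataset(sim$dataset, rate_days = 14, origin = 0,
                         smoothing = "none", ...)
  list(rs = rs, tab = build_observations(rs))
}

test_that("constraint presets encode the allowed interaction flow", {
  sk <- skeleton_constraints()
  expect_false(edge_allowed(sk, "gene", "taxon", "intra"))   # disallowed
  expect_true(edge_allowed(sk, "metabolite", "taxon", "inter"))
  expect_true(edge_allowed(sk, "env", "taxon", "intra"))
  expect_true(edge_allowed(sk, "host_gene", "taxon", "intra"))
  expect_true(edge_allowed(sk, "taxon", "gene", "intra"))
  expect_true(edge_allowed(sk, "gene", "metabolite", "intra"))
  # self-loops for dynamic nodes only; env gets no incoming edges at all
  expect_true(edge_allowed(sk, "taxon", "taxon", "inter", is_self = TRUE))
  expect_false(edge_allowed(sk, "taxon", "taxon", "inter", is_self = FALSE))
  expect_false(edge_allowed(sk, "env", "env", "inter", is_self = TRUE))
  # augmented = skeleton + direct taxon -> metabolite
  au <- augmented_constraints()
  expect_true(edge_allowed(au, "taxon", "metabolite", "intra"))
  expect_true(edge_allowed(au, "taxon", "metabolite", "inter"))
  expect_false(edge_allowed(sk, "taxon", "metabolite", "intra"))
  sk_cells <- do.call(paste, skeleton_constraints()$allowed)
  au_cells <- do.call(paste, au$allowed)
  expect_true(all(sk_cells %in% au_cells))  # skeleton subset of augmented
  # constraint JSON round-trips
  p <- tempfile(fileext = ".json")
  write_constraints(au, p)
  back <- read_constraints(p)
  expect_identical(back$allowed, au$allowed)
  expect_error(get_constraints("bogus"), "unknown constraint preset")
})

test_that("build_observations emits one row per consecutive grid pair", {
  sim <- small_sim(seed = 5, n_subjects = 3, n_points = 5)
  o <- obs_from_sim(sim)
  expect_equal(o$tab$n, 3 * (5 - 1))
  # row values equal the sampled series at the two grid times
  s <- names(o$rs$grids)[1]
  m <- o$rs$values[[s]]
  i <- which(o$tab$subject == s)[2]
  expect_equal(unname(o$tab$X[i, "taxon:T01@t"]), unname(m["taxon:T01", 2]))
  expect_equal(unname(o$tab$X[i, "taxon:T01@t1"]), unname(m["taxon:T01", 3]))
  # static host genes are copied into both slices
  expect_equal(unname(o$tab$X[i, "host_gene:H01@t"]),
               unname(o$tab$X[i, "host_gene:H01@t1"]))
  expect_equal(unname(o$tab$X[i, "host_gene:H01@t"]),
               unname(o$rs$static[[s]][["host_gene:H01"]]))
  expect_false(anyNA(o$tab$X))
})

test_that("fit_cpd is the closed-form Gaussian MLE", {
  sim <- small_sim(seed = 6, n_subjects = 6, n_points = 10)
  tab <- obs_from_sim(sim)$tab
  # self-loop on its own noiseless copy: identity regression, floored sigma2
  tab2 <- tab
  tab2$X[, "taxon:T01@t1"] <- tab2$X[, "taxon:T01@t"]
  cpd <- fit_cpd("taxon:T01@t1", "taxon:T01@t", tab2)
  expect_equal(cpd$beta0, 0, tolerance = 1e-9)
  expect_equal(cpd$betas, 1, tolerance = 1e-9)
  expect_equal(cpd$sigma2, 1e-9)  # the floor
  # zero-parent fit: sample mean and population (MLE) variance
  cpd0 <- fit_cpd("gene:G01@t1", character(0), tab)
  y <- tab$X[, "gene:G01@t1"]
  expect_equal(cpd0$beta0, mean(y))
  expect_equal(cpd0$sigma2, mean((y - mean(y))^2))
  # 3-parent fit matches the normal-equations oracle to 1e-8
  pars <- c("metabolite:M01@t", "taxon:T02@t", "gene:G02@t1")
  cpd3 <- fit_cpd("taxon:T02@t1", pars, tab)
  X <- cbind(1, tab$X[, pars])
  beta <- solve(t(X) %*% X, t(X) %*% tab$X[, "taxon:T02@t1"])
  expect_equal(c(cpd3$beta0, cpd3$betas), c(beta), tolerance = 1e-8)
  r <- tab$X[, "taxon:T02@t1"] - X %*% beta
  expect_equal(cpd3$sigma2, mean(r^2), tolerance = 1e-10)
  # degenerate designs error
  tab3 <- tab
  tab3$X[, "taxon:T03@t"] <- tab3$X[, "taxon:T02@t"]
  expect_error(fit_cpd("taxon:T02@t1", c("taxon:T02@t", "taxon:T03@t"), tab3),
               "rank-deficient")
})

test_that("bic_score equals a hand-computed density sum minus penalty", {
  sim <- small_sim(seed = 8, n_subjects = 5, n_points = 8)
  tab <- obs_from_sim(sim)$tab
  cpds <- list(fit_cpd("taxon:T01@t1", "taxon:T01@t", tab),
               fit_cpd("gene:G01@t1", c("taxon:T01@t1", "gene:G01@t"), tab),
               fit_cpd("metabolite:M01@t1", character(0), tab))
  # brute-force oracle: per-row Gaussian log densities
  ll <- 0
  for (cpd in cpds) {
    mu <- cpd$beta0
    if (length(cpd$betas)) {
      mu <- mu + as.vector(tab$X[, cpd$parents, drop = FALSE] %*% cpd$betas)
    }
    ll <- ll + sum(stats::dnorm(tab$X[, cpd$child], mu, sqrt(cpd$sigma2),
                                log = TRUE))
  }
  n_par <- sum(vapply(cpds, function(c) length(c$betas) + 2, 0))
  expect_equal(bic_score(cpds, tab), ll - n_par / 2 * log(tab$n),
               tolerance = 1e-8)
  # adding a true-zero parent costs about half a log|D| (penalty arithmetic)
  set.seed(1)
  n <- 500
  fake <- list(X = cbind(`a@t` = stats::rnorm(n), `b@t` = stats::rnorm(n),
                         `y@t1` = stats::rnorm(n)),
               n = n)
  c1 <- fit_cpd("y@t1", "a@t", fake)
  c2 <- fit_cpd("y@t1", c("a@t", "b@t"), fake)
  dbic <- bic_score(list(c2), fake) - bic_score(list(c1), fake)
  expect_lt(abs(dbic + log(n) / 2), 0.5 * log(n) / 2)
})

test_that("greedy search never beats exhaustive enumeration and is monotone", {
  # 4 dynamic nodes, max_parents = 2: per-child exhaustive parent subsets
  sim <- generate(simulation_config(n_subjects = 10, n_taxa = 2, n_genes = 1,
                                    n_metabolites = 1, n_host_genes = 0,
                                    n_points = 10, seed = 3,
                                    constraints = "augmented"))
  o <- obs_from_sim(sim)
  m <- learn_structure(o$tab, "augmented", max_parents = 2)
  expect_true(all(diff(m$bic_trace) > 0))
  # exhaustive oracle: the BIC decomposes per child
  cons <- augmented_constraints()
  nodes <- o$tab$nodes
  children <- nodes$id[nodes$dynamic & nodes$kind %in%
                         c("taxon", "gene", "metabolite")]
  best_total <- 0
  for (ch in children) {
    kind <- nodes$kind[nodes$id == ch]
    cand <- list()
    for (p in nodes$id[nodes$dynamic]) {
      pk <- nodes$kind[nodes$id == p]
      if (edge_allowed(cons, pk, kind, "inter", is_self = p == ch)) {
        cand[[length(cand) + 1]] <- c(p, "inter")
      }
      if (p != ch && edge_allowed(cons, pk, kind, "intra")) {
        cand[[length(cand) + 1]] <- c(p, "intra")
      }
    }
    best <- -Inf
    for (k in 0:2) {
      combos <- utils::combn(length(cand), k, simplify = FALSE)
      for (cb in combos) {
        cols <- vapply(cand[cb], function(pc) {
          paste0(pc[1], if (pc[2] == "inter") "@t" else "@t1")
        }, "")
        cpd <- tryCatch(fit_cpd(paste0(ch, "@t1"), cols, o$tab),
                        error = function(e) NULL)
        if (is.null(cpd)) next
        sc <- bic_score(list(cpd), o$tab)
        if (sc > best) best <- sc
      }
    }
    best_total <- best_total + best
  }
  expect_lte(m$bic, best_total + 1e-9)
})

test_that("learner adds no cross edges to independent noise", {
  # all nodes independent, |D| = 25 x 20 = 500: only the self-loop
  # initialization should survive; cross additions are BIC false positives
  fp <- 0; n_children <- 0
  for (seed in 1:20) {
    sim <- generate(simulation_config(
      n_subjects = 25, n_taxa = 2, n_genes = 2, n_metabolites = 2,
      n_host_genes = 0, n_points = 21, seed = 100 + seed,
      edge_density = 0, self_coef_range = c(0, 0), noise_sd = 1,
      constraints = "skeleton"))
    o <- obs_from_sim(sim)
    m <- learn_structure(o$tab, "skeleton")
    self <- m$edges$parent_layer == m$edges$child_layer &
      m$edges$parent_feature == m$edges$child_feature
    fp <- fp + sum(!self)
    n_children <- n_children + 6
  }
  expect_lte(fp / n_children, 0.05)
})

test_that("planted strong edges are recovered with correct signs", {
  sim <- generate(simulation_config(n_subjects = 25, n_taxa = 3, n_genes = 2,
                                    n_metabolites = 3, n_host_genes = 0,
                                    n_points = 12, seed = 23,
                                    coef_range = c(0.6, 0.9),
                                    noise_sd = 0.1))
  o <- obs_from_sim(sim)
  m <- learn_structure(o$tab, "augmented")
  truth <- sim$truth$model$edges
  planted_mt <- truth[truth$parent_layer == "metabolite" &
                        truth$child_layer == "taxon", , drop = FALSE]
  expect_gt(nrow(planted_mt), 0)  # seed chosen so the draw plants M->T edges
  found <- edge_keys(m$edges)
  expect_true(all(edge_keys(planted_mt) %in% found))
  # recovered edges agree in sign with the planted coefficients
  shared <- merge(m$edges, truth,
                  by = c("parent_layer", "parent_feature", "child_layer",
                         "child_feature", "lag"))
  shared <- shared[!(shared$parent_feature == shared$child_feature &
                       shared$parent_layer == shared$child_layer), ]
  expect_gte(mean(sign(shared$coefficient.x) == sign(shared$coefficient.y)),
             0.95)
})

test_that("every learned edge satisfies the constraint matrix", {
  for (seed in c(2, 31)) {
    for (cons in list(skeleton_constraints(), augmented_constraints())) {
      sim <- small_sim(seed = seed, n_subjects = 8, n_points = 8)
      o <- obs_from_sim(sim)
      m <- learn_structure(o$tab, cons)
      e <- m$edges
      for (i in seq_len(nrow(e))) {
        is_self <- e$parent_layer[i] == e$child_layer[i] &
          e$parent_feature[i] == e$child_feature[i]
        expect_true(edge_allowed(cons, e$parent_layer[i], e$child_layer[i],
                                 e$lag[i], is_self))
      }
      # parent cap: self-loop counts toward max_parents
      cnt <- table(paste(e$child_layer, e$child_feature))
      expect_true(all(cnt <= 3))
    }
  }
})

test_that("normalized_weight is the standardized coefficient", {
  set.seed(10)
  p <- stats::rnorm(200, 0, 2); ch <- stats::rnorm(200, 0, 0.5)
  beta <- 0.4
  nw <- normalized_weight(beta, p, ch)
  expect_equal(nw, beta * stats::sd(p) / stats::sd(ch))
  # standardized columns: weight equals beta
  expect_equal(normalized_weight(beta, scale(p)[, 1], scale(ch)[, 1]), beta)
  # scaling the parent by 10 shrinks beta x10 but leaves the weight fixed
  expect_equal(normalized_weight(beta / 10, p * 10, ch), nw)
  expect_error(normalized_weight(1, p, rep(1, 200)), "zero child variance")
})

test_that("bootstrap_network supports, union and determinism", {
  sim <- small_sim(seed = 13, n_subjects = 6, n_points = 8)
  rs <- resample_dataset(sim$dataset, 14, 0, smoothing = "none")
  # identity resample, one rep: equals a single structure learn, support 1
  bn1 <- bootstrap_network(rs, "augmented", n_reps = 1, seed = 4,
                           identity_resample = TRUE)
  single <- learn_structure(build_observations(rs), "augmented")
  expect_setequal(edge_keys(bn1$edges), edge_keys(single$edges))
  expect_true(all(bn1$edges$bootstrap_support == 1))
  # union semantics: adding repetitions can only grow the edge set
  bn <- bootstrap_network(rs, "augmented", n_reps = 6, seed = 4)
  expect_gte(nrow(bn$edges), length(unique(edge_keys(bn1$edges))) -
               sum(!edge_keys(bn1$edges) %in% edge_keys(bn$edges)))
  expect_gt(nrow(bn$edges), 0)
  expect_true(all(bn$edges$bootstrap_support > 0 &
                    bn$edges$bootstrap_support <= 1))
  # same seed -> identical result
  bn2 <- bootstrap_network(rs, "augmented", n_reps = 6, seed = 4)
  expect_identical(bn$edges, bn2$edges)
  bn3 <- bootstrap_network(rs, "augmented", n_reps = 6, seed = 5)
  expect_false(identical(bn$edges$bootstrap_support,
                         bn3$edges$bootstrap_support) &&
                 identical(edge_keys(bn$edges), edge_keys(bn3$edges)))
})
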