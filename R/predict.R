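# Forward prediction and leave-one-subject-out evaluation. Starting from the
# second grid point, each target node at t_{i+1} is predicted from observed
# values (inter-parents at t_i, intra-parents at t_{i+1}); predicted taxa are
# renormalized to the simplex in relative mode. Observed values, never
# previous predictions, feed each step.

#' Predict a held-out subject's trajectories under a learned model
#'
#' @param model a `DBNModel` trained without this subject.
#' @param resampled a `ResampledDataset` containing the subject.
#' @param subject subject id.
#' @param target_kind node kind to predict (`"taxon"` or `"metabolite"`).
#' @param renormalize renormalize target predictions to sum to 1 per time
#'   point (relative mode); negative predictions are clipped to 0 first.
#' @return list with `times` (grid times predicted, from the second point),
#'   `predicted` and `observed` (feature x time matrices), `raw` (before
#'   renormalization).
#' @export
predict_subject <- function(model, resampled, subject,
                            target_kind = "taxon", renormalize = TRUE) {
  m <- resampled$values[[subject]]
  if (is.null(m)) stop("predict_subject: unknown subject ", subject)
  sv <- resampled$static[[subject]]
  nodes <- resampled$nodes
  targets <- nodes$id[nodes$dynamic & nodes$kind == target_kind]
  cpd_children <- names(model$cpds)
  need <- child_col(targets)
  if (!all(need %in% cpd_children)) {
    stop("predict_subject: model lacks CPDs for some target nodes")
  }
  lookup <- function(node, idx) {
    if (node %in% rownames(m)) m[node, idx] else {
      if (!node %in% names(sv)) stop("predict_subject: subject missing node ",
                                     node)
      sv[[node]]
    }
  }
  nT <- ncol(m)
  pred <- matrix(NA_real_, length(targets), nT - 1,
                 dimnames = list(targets, NULL))
  for (i in seq_len(nT - 1)) {
    for (tg in targets) {
      cpd <- model$cpds[[child_col(tg)]]
      v <- cpd$beta0
      if (length(cpd$betas)) {
        pm <- cpd$parent_meta
        for (j in seq_len(nrow(pm))) {
          idx <- if (pm$lag[j] == "inter") i else i + 1
          v <- v + cpd$betas[j] * lookup(pm$parent[j], idx)
        }
      }
      pred[tg, i] <- v
    }
  }
  raw <- pred
  if (renormalize) {
    pred <- pmax(pred, 0)
    cs <- colSums(pred)
    pred <- sweep(pred, 2, ifelse(cs > 0, cs, 1), "/")
    pred[, cs == 0] <- 1 / nrow(pred)
  }
  obs <- m[targets, -1, drop = FALSE]
  if (renormalize) {
    obs <- pmax(obs, 0)
    ocs <- colSums(obs)
    obs <- sweep(obs, 2, ifelse(ocs > 0, ocs, 1), "/")
  }
  list(times = resampled$grids[[subject]][-1], predicted = pred,
       observed = obs, raw = raw)
}

#' Leave-one-subject-out forward-prediction MAE
#'
#' For each subject: train a model on all other subjects (a single structure
#' learn per fold by default; bootstrap folds via `cv_bootstrap`), predict
#' the held-out subject's target trajectories, and compute the per-feature
#' mean absolute error over predicted time points. The overall MAE averages
#' over features, then subjects.
#'
#' @param resampled a `ResampledDataset`.
#' @param constraints a `ConstraintMatrix` or preset name.
#' @param target_kind `"taxon"` or `"metabolite"`.
#' @param max_parents maximum parents per child.
#' @param renormalize relative-mode renormalization of predictions.
#' @param cv_bootstrap if > 0, use a bootstrap of this many repetitions per
#'   fold and predict with support-weighted averaged coefficients (off by
#'   default for tractability).
#' @param seed seed for any fold randomness.
#' @return a `PredictionReport`: list with `mae_overall`,
#'   `mae_per_subject`, `mae_per_feature` (subject x feature matrix),
#'   `predictions` (per subject), `target_kind`.
#' @export
loocv_mae <- function(resampled, constraints, target_kind = "taxon",
                      max_parents = 3, renormalize = TRUE, cv_bootstrap = 0,
                      seed = 1) {
  subjects <- names(resampled$grids)
  if (length(subjects) < 3) stop("loocv_mae needs >= 3 subjects")
  constraints <- get_constraints(constraints)
  per_feature <- NULL; preds <- list()
  for (s in subjects) {
    train <- setdiff(subjects, s)
    tab <- build_observations(resampled, subjects = train)
    model <- if (cv_bootstrap > 0) {
      sub <- resampled
      sub$grids <- sub$grids[train]; sub$values <- sub$values[train]
      sub$static <- sub$static[train]
      bn <- bootstrap_network(sub, constraints, n_reps = cv_bootstrap,
                              seed = seed, max_parents = max_parents)
      bootstrap_to_model(bn, tab)
    } else {
      learn_structure(tab, constraints, max_parents = max_parents)
    }
    p <- predict_subject(model, resampled, s, target_kind = target_kind,
                         renormalize = renormalize)
    preds[[s]] <- p
    mae <- rowMeans(abs(p$predicted - p$observed))
    per_feature <- rbind(per_feature, mae)
  }
  rownames(per_feature) <- subjects
  mae_subj <- rowMeans(per_feature)
  structure(list(mae_overall = mean(mae_subj),
                 mae_per_subject = mae_subj,
                 mae_per_feature = per_feature,
                 predictions = preds, target_kind = target_kind),
            class = "PredictionReport")
}

# Collapse a bootstrap union network into a predictive model by refitting
# CPDs on the full table with each child's highest-support parents (capped).
bootstrap_to_model <- function(bn, table, max_parents = 3,
                               min_support = 0.5) {
  nodes <- table$nodes
  children <- nodes$id[nodes$dynamic & nodes$kind %in% OMIC_KINDS]
  cpds <- list()
  e <- bn$edges
  for (ch in children) {
    ck <- nodes$kind[nodes$id == ch]; cf <- sub("^[^:]+:", "", ch)
    sel <- e[e$child_layer == ck & e$child_feature == cf &
               e$bootstrap_support >= min_support, , drop = FALSE]
    sel <- sel[order(-sel$bootstrap_support, sel$parent_layer,
                     sel$parent_feature), , drop = FALSE]
    if (nrow(sel) > max_parents) sel <- sel[seq_len(max_parents), ]
    pm <- data.frame(parent = node_id(sel$parent_layer, sel$parent_feature),
                     lag = sel$lag, stringsAsFactors = FALSE)
    cols <- parent_col(pm$parent, pm$lag)
    fit <- ols_fit(table$X[, child_col(ch)],
                   table$X[, cols, drop = FALSE])
    if (is.null(fit)) {
      pm <- pm[0, , drop = FALSE]
      fit <- ols_fit(table$X[, child_col(ch)],
                     table$X[, character(0), drop = FALSE])
    }
    cpds[[child_col(ch)]] <- structure(
      list(child = child_col(ch), parents = parent_col(pm$parent, pm$lag),
           parent_meta = pm, beta0 = fit$beta0, betas = fit$betas,
           sigma2 = fit$sigma2), class = "GaussianCPD")
  }
  structure(list(nodes = nodes$id, node_meta = nodes, edges = bn$edges,
                 cpds = cpds, constraints_id = bn$constraints_id,
                 max_parents = max_parents, bic = NA_real_,
                 bic_trace = numeric(0)),
            class = "DBNModel")
}

#' Write a prediction report as TSV
#' @param report a `PredictionReport`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_prediction_report <- function(report, path) {
  df <- data.frame(subject = rownames(report$mae_per_feature),
                   mae = report$mae_per_subject, stringsAsFactors = FALSE)
  df <- rbind(df, data.frame(subject = "OVERALL", mae = report$mae_overall))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
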