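# Conditional linear-Gaussian CPDs: the child given its parents is
# N(beta0 + sum_i beta_i u_i, sigma2). Parameters are the Gaussian MLE:
# ordinary least squares for the betas, mean squared residual for sigma2
# (floored at 1e-9 so the log-likelihood stays finite on noiseless fits).

SIGMA2_FLOOR <- 1e-9

ols_fit <- function(y, X) {
  # X without intercept column; returns NULL on rank deficiency
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xi, y)
  if (fit$rank < ncol(Xi) || anyNA(fit$coefficients)) return(NULL)
  rss <- sum(fit$residuals^2)
  list(beta0 = unname(fit$coefficients[1]),
       betas = unname(fit$coefficients[-1]),
       sigma2 = max(rss / length(y), SIGMA2_FLOOR))
}

gauss_loglik <- function(n, sigma2) {
  # log-likelihood at the MLE: -n/2 * (log(2 pi sigma2) + 1)
  -n / 2 * (log(2 * pi * sigma2) + 1)
}

#' Fit one conditional linear-Gaussian CPD
#'
#' @param child column id of the child (slice t+1) in the observation table.
#' @param parents character vector of parent column ids (possibly empty).
#' @param table an `ObservationTable` from [build_observations()].
#' @return a `GaussianCPD`: list with `child`, `parents`, `beta0`, `betas`,
#'   `sigma2`.
#' @export
fit_cpd <- function(child, parents, table) {
  y <- table$X[, child]
  k <- length(parents)
  if (table$n <= k + 1) stop("fit_cpd: |D| must exceed the parameter count")
  X <- table$X[, parents, drop = FALSE]
  fit <- ols_fit(y, X)
  if (is.null(fit)) {
    stop("fit_cpd: rank-deficient design for child ", child)
  }
  structure(list(child = child, parents = parents, beta0 = fit$beta0,
                 betas = fit$betas, sigma2 = fit$sigma2),
            class = "GaussianCPD")
}

cpd_loglik <- function(cpd, table) gauss_loglik(table$n, cpd$sigma2)

#' BIC score of a fitted model
#'
#' `BIC(G, D) = log P(D | Theta, G) - |Theta|/2 * log |D|`, where the
#' log-likelihood sums per-child Gaussian log-densities at the MLE and
#' `|Theta|` counts beta0, beta1..betak and sigma2 for every child
#' (k + 2 per child).
#'
#' @param cpds list of `GaussianCPD`s (one per child), e.g. `model$cpds`.
#' @param table the `ObservationTable` the CPDs were fitted on.
#' @return the BIC score (higher is better).
#' @export
bic_score <- function(cpds, table) {
  if (inherits(cpds, "DBNModel")) cpds <- cpds$cpds
  ll <- sum(vapply(cpds, cpd_loglik, 0, table = table))
  n_par <- sum(vapply(cpds, function(c) length(c$betas) + 2, 0))
  ll - n_par / 2 * log(table$n)
}
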