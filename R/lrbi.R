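# The LRBI estimator: per-gene Bayesian linear regression under a
# Normal-Gamma conjugate prior, sampled with an iterative Gibbs-style scheme.
#
# For gene i with response y (length N) and design D (m x N; the other
# genes' expression rows plus the gene's own eQTL genotype row), the model is
#
#   y_k = theta' d_k + e_k,   e_k ~ N(0, 1/tau)
#   theta | tau ~ N(mu0, (tau Lambda0)^{-1}),   tau ~ Gamma(alpha0, beta0)
#
# Conjugacy gives closed-form posterior parameters (mu_n, Lambda_n, alpha_n,
# beta_n). With those fixed, draws of tau would be independent of the
# coefficient draws, so the plain two-step sampler never propagates
# coefficient information into the precision. The sampler therefore
# recomputes the Gamma rate at every iteration from the CURRENT coefficient
# draw theta_t:
#
#   beta_n(theta_t) = beta0 + 1/2 ||y - theta_t' D||^2
#                          + 1/2 (theta_t - mu0)' Lambda0 (theta_t - mu0)
#
# together with the matching full-conditional Gamma shape
# alpha0 + (N + m)/2 (the coefficient prior scales with tau, so its m
# dimensions enter the conditional of tau). This tau/theta pair is exactly
# the Gibbs sampler of the Normal-Gamma posterior: theta | tau, y is
# N(mu_n, (tau Lambda_n)^{-1}) and tau | theta, y is Gamma as above, so the
# chain is stable and its stationary coefficient mean is mu_n. (Using the
# marginal shape alpha0 + N/2 with the conditional rate makes tau
# overdispersed and the chain can diverge when N is small relative to m.)
# The point estimate is the average of the second half of the retained
# draws (first-half burn-in), and the chain stops when the running
# second-half mean moves less than epsilon (squared Euclidean distance)
# between successive checkpoints.

#' Normal-Gamma prior for one row regression
#'
#' @param mu0 Prior mean vector for the m regression coefficients.
#' @param Lambda0 m x m symmetric positive-definite prior precision-scale
#'   matrix; the identity (default) is used throughout the package.
#' @param alpha0,beta0 Gamma shape and rate for the noise precision
#'   (both > 0; weakly informative defaults 1, 1).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mu0, Lambda0 = diag(length(mu0)),
                       alpha0 = 1, beta0 = 1) {
  mu0 <- as.numeric(mu0)
  Lambda0 <- as.matrix(Lambda0)
  m <- length(mu0)
  if (!all(is.finite(mu0))) stop("mu0 must be finite")
  if (!all(dim(Lambda0) == c(m, m))) stop("Lambda0 must be ", m, " x ", m)
  if (!isSymmetric(Lambda0, tol = 1e-10)) stop("Lambda0 must be symmetric")
  ev <- tryCatch(min(eigen(Lambda0, symmetric = TRUE, only.values = TRUE)$values),
                 error = function(e) -Inf)
  if (ev <= 0) stop("Lambda0 must be positive definite (min eigenvalue ", ev, ")")
  if (alpha0 <= 0 || beta0 <= 0) stop("alpha0 and beta0 must be > 0")
  structure(list(mu0 = mu0, Lambda0 = Lambda0,
                 alpha0 = alpha0, beta0 = beta0),
            class = "prior_spec")
}

#' Default per-gene prior builder
#'
#' Returns a function mapping a [build_row_regression()] object to its prior:
#' `mu0` is one-hot with the 1 at the last coefficient position — the gene's
#' own eQTL effect `F[i,i]` — and 0 everywhere else. Regulatory networks are
#' sparse, so a zero prior mean on every `B[i,j]` is the natural choice,
#' while the cis-eQTL is expected to perturb its gene with effect near 1.
#' `Lambda0` is the identity and `alpha0 = beta0 = 1`.
#'
#' @param alpha0,beta0 Gamma hyperparameters passed to every row prior.
#' @return A function `row_regression -> prior_spec`.
#' @export
default_prior_builder <- function(alpha0 = 1, beta0 = 1) {
  function(row) {
    stopifnot(inherits(row, "row_regression"))
    m <- length(row$coef_labels)
    mu0 <- c(rep(0, m - 1), 1)
    prior_spec(mu0, diag(m), alpha0 = alpha0, beta0 = beta0)
  }
}

#' LRBI sampler configuration
#'
#' @param epsilon Convergence tolerance: the chain stops once the squared
#'   Euclidean distance between the running second-half means at two
#'   successive checkpoints falls below `epsilon`. Smaller values give more
#'   accurate estimates at the cost of more iterations.
#' @param min_iters,max_iters Iteration bounds (defaults 200 and 5000).
#' @param check_every Iterations between convergence checkpoints (default 50).
#' @param threshold Edge-decision cutoff: a directed edge is declared present
#'   when `|B_hat[i, j]| >= threshold` (ties count as edges). Default 0.05.
#' @param seed Root seed; each gene's sampler runs on its own derived
#'   sub-stream, so results do not depend on row execution order.
#' @param standardize If `TRUE`, expression rows are centered and scaled to
#'   unit variance before inference. Default `FALSE`.
#' @return An object of class `lrbi_config`.
#' @export
lrbi_config <- function(epsilon = 1e-6, min_iters = 200, max_iters = 5000,
                        check_every = 50, threshold = 0.05, seed = 1L,
                        standardize = FALSE) {
  stopifnot(epsilon > 0, min_iters >= 1, check_every >= 1, threshold >= 0)
  if (min_iters >= max_iters) stop("min_iters must be < max_iters")
  structure(list(epsilon = epsilon, min_iters = as.integer(min_iters),
                 max_iters = as.integer(max_iters),
                 check_every = as.integer(check_every),
                 threshold = threshold, seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "lrbi_config")
}

#' Closed-form conjugate posterior for one row regression
#'
#' Computes the Normal-Gamma posterior parameters of the linear model
#' `response = coef' design + noise`:
#' `Lambda_n = Lambda0 + D D'`,
#' `mu_n = Lambda_n^{-1} (Lambda0 mu0 + D y)`,
#' `alpha_n = alpha0 + N/2`,
#' `beta_n = beta0 + (y'y + mu0' Lambda0 mu0 - mu_n' Lambda_n mu_n) / 2`.
#'
#' @param row A [build_row_regression()] object.
#' @param prior A [prior_spec()].
#' @return A list with elements `mu_n`, `Lambda_n`, `alpha_n`, `beta_n`.
#' @export
conjugate_posterior <- function(row, prior) {
  stopifnot(inherits(row, "row_regression"), inherits(prior, "prior_spec"))
  D <- row$design
  y <- row$response
  if (length(y) < 1) stop("row regression has no observations")
  Lambda_n <- prior$Lambda0 + tcrossprod(D)
  Lambda_n <- (Lambda_n + t(Lambda_n)) / 2
  chol_n <- tryCatch(chol(Lambda_n), error = function(e) {
    stop("posterior precision Lambda_n is not positive definite ",
         "(condition number ", format(kappa(Lambda_n)), "): ",
         conditionMessage(e))
  })
  mu_n <- drop(chol2inv(chol_n) %*% (prior$Lambda0 %*% prior$mu0 + D %*% y))
  alpha_n <- prior$alpha0 + length(y) / 2
  beta_n <- prior$beta0 + 0.5 * (sum(y^2) +
    drop(crossprod(prior$mu0, prior$Lambda0 %*% prior$mu0)) -
    drop(crossprod(mu_n, Lambda_n %*% mu_n)))
  list(mu_n = mu_n, Lambda_n = Lambda_n, alpha_n = alpha_n, beta_n = beta_n,
       chol_Lambda_n = chol_n)
}

# One tau/coefficient draw of the modified sampler. `pre` carries the
# precomputed posterior pieces; `coef` is the current coefficient draw.
lrbi_draw <- function(pre, coef) {
  resid <- pre$y - drop(coef %*% pre$D)
  dev <- coef - pre$mu0
  beta_t <- pre$beta0 +
    0.5 * sum(resid^2) +
    0.5 * drop(crossprod(dev, pre$Lambda0 %*% dev))
  tau <- stats::rgamma(1, shape = pre$alpha_gibbs, rate = beta_t)
  coef_new <- pre$mu_n + backsolve(pre$chol_Lambda_n, stats::rnorm(pre$m)) / sqrt(tau)
  list(tau = tau, coef = coef_new, beta_n = beta_t)
}

precompute_row <- function(row, prior) {
  post <- conjugate_posterior(row, prior)
  list(D = row$design, y = row$response, m = length(prior$mu0),
       mu0 = prior$mu0, Lambda0 = prior$Lambda0, beta0 = prior$beta0,
       mu_n = post$mu_n, Lambda_n = post$Lambda_n,
       alpha_n = post$alpha_n, beta_n0 = post$beta_n,
       alpha_gibbs = prior$alpha0 + (length(row$response) + length(prior$mu0)) / 2,
       chol_Lambda_n = post$chol_Lambda_n)
}

#' Initialize the sampler state for one row regression
#'
#' @param row A [build_row_regression()] object.
#' @param prior A [prior_spec()].
#' @return An object of class `posterior_state` holding the fixed posterior
#'   parameters, the current draws (`coef_sample` starts at `mu0`,
#'   `tau_sample` at the posterior mean `alpha_n / beta_n`), the draw history
#'   and the iteration counter.
#' @export
init_posterior_state <- function(row, prior) {
  pre <- precompute_row(row, prior)
  structure(list(mu_n = pre$mu_n, Lambda_n = pre$Lambda_n,
                 alpha_n = pre$alpha_n, beta_n = pre$beta_n0,
                 tau_sample = pre$alpha_n / pre$beta_n0,
                 coef_sample = prior$mu0,
                 sample_history = matrix(numeric(0), nrow = 0, ncol = pre$m),
                 iteration = 0L,
                 pre = pre),
            class = "posterior_state")
}

#' One iteration of the modified Gibbs sampler
#'
#' Draws the noise precision `tau` from its full conditional
#' `Gamma(alpha0 + (N + m)/2, beta_n(coef))`, where the rate is recomputed
#' from the current coefficient draw (residual sum of squares plus prior
#' quadratic form), then draws the coefficients from
#' `Normal(mu_n, (tau Lambda_n)^{-1})`. Appends the new coefficient draw to
#' the history and increments the iteration counter.
#'
#' @param state A [init_posterior_state()] object.
#' @param row,prior The row regression and prior the state was built from
#'   (kept in the signature for clarity; the state caches what it needs).
#' @return The updated `posterior_state`.
#' @export
gibbs_step <- function(state, row = NULL, prior = NULL) {
  stopifnot(inherits(state, "posterior_state"))
  draw <- lrbi_draw(state$pre, state$coef_sample)
  if (!all(is.finite(draw$coef)) || !is.finite(draw$tau)) {
    stop("non-finite sampler draw at iteration ", state$iteration + 1L)
  }
  state$tau_sample <- draw$tau
  state$coef_sample <- draw$coef
  state$beta_n <- draw$beta_n
  state$sample_history <- rbind(state$sample_history, draw$coef)
  state$iteration <- state$iteration + 1L
  state
}

#' Infer one gene's coefficients by iterative sampling
#'
#' Runs the modified Gibbs sampler until convergence or `max_iters`.
#' Convergence is declared when the running mean of the second half of all
#' draws so far moves by less than `epsilon` (squared Euclidean distance)
#' between two successive checkpoints; checkpoints occur every `check_every`
#' iterations starting at `min_iters`. The returned estimate is the average
#' of the second half of the retained draws — the first half is treated as
#' burn-in, during which the coefficient trajectory is still far from its
#' steady state.
#'
#' @param row A [build_row_regression()] object.
#' @param prior A [prior_spec()].
#' @param config An [lrbi_config()].
#' @return A list: `estimate` (length-m coefficient vector named by
#'   `row$coef_labels`), `iterations`, `converged`, `mu_n` (closed-form
#'   posterior mean, as a diagnostic), `n_averaged` (draws in the second-half
#'   average).
#' @export
infer_row <- function(row, prior, config) {
  stopifnot(inherits(row, "row_regression"), inherits(prior, "prior_spec"),
            inherits(config, "lrbi_config"))
  pre <- precompute_row(row, prior)
  m <- pre$m
  history <- matrix(NA_real_, nrow = config$max_iters, ncol = m)
  coef <- prior$mu0
  prev_est <- NULL
  converged <- FALSE
  t_used <- config$max_iters
  for (t in seq_len(config$max_iters)) {
    draw <- lrbi_draw(pre, coef)
    if (!all(is.finite(draw$coef)) || !is.finite(draw$tau)) {
      stop("non-finite sampler draw at iteration ", t,
           " for gene ", row$gene_index)
    }
    coef <- draw$coef
    history[t, ] <- coef
    if (t >= config$min_iters && (t - config$min_iters) %% config$check_every == 0) {
      est <- colMeans(history[(t %/% 2 + 1):t, , drop = FALSE])
      if (!is.null(prev_est) && sum((est - prev_est)^2) < config$epsilon) {
        converged <- TRUE
        t_used <- t
        break
      }
      prev_est <- est
    }
  }
  second_half <- (t_used %/% 2 + 1):t_used
  estimate <- colMeans(history[second_half, , drop = FALSE])
  names(estimate) <- row$coef_labels
  list(estimate = estimate, iterations = t_used, converged = converged,
       mu_n = pre$mu_n, n_averaged = length(second_half))
}

#' Infer a full regulatory network with LRBI
#'
#' For each gene `i`: builds the row regression, the row prior (one-hot
#' `mu0`, identity `Lambda0` by default), runs the iterative sampler on its
#' own seed sub-stream, and scatters the estimate into row `i` of `B_hat`
#' and into `F_hat[i]`. Entries with `|B_hat[i, j]| < threshold` are then
#' dropped to form the edge set (ties, `|B_hat| == threshold`, count as
#' edges). The full pre-threshold `B_hat` is retained for numerical-error
#' analysis.
#'
#' @param dataset A [grn_dataset()] (m >= 2).
#' @param config An [lrbi_config()].
#' @param prior_builder A function `row_regression -> prior_spec`; defaults
#'   to [default_prior_builder()].
#' @return An object of class `lrbi_result`: `B_hat` (m x m, zero diagonal,
#'   pre-threshold), `F_hat` (length m), `edges` (data frame with columns
#'   `target`, `regulator`, `weight`, `sign`), `threshold`, `per_gene_iters`,
#'   `converged`, `gene_ids`.
#' @examples
#' sim <- simulate_grn(sim_config(m = 5, n_samples = 40, ne = 2, seed = 11))
#' fit <- infer_network(sim$dataset, lrbi_config(seed = 11))
#' fit$edges
#' @export
infer_network <- function(dataset, config = lrbi_config(),
                          prior_builder = default_prior_builder()) {
  stopifnot(inherits(dataset, "grn_dataset"), inherits(config, "lrbi_config"))
  m <- dataset$m
  if (m < 2) stop("need at least 2 genes (m = ", m, ")")
  if (config$standardize) {
    Y <- t(scale(t(dataset$Y)))
    dataset <- grn_dataset(Y, dataset$X, dataset$gene_ids,
                           genotype_codes = dataset$genotype_codes)
  }
  B_hat <- matrix(0, m, m, dimnames = list(dataset$gene_ids, dataset$gene_ids))
  F_hat <- stats::setNames(numeric(m), dataset$gene_ids)
  iters <- integer(m)
  conv <- logical(m)
  for (i in seq_len(m)) {
    row <- build_row_regression(dataset, i)
    prior <- prior_builder(row)
    fit <- tryCatch(
      withr::with_seed(derive_seed(config$seed, 1000L + i),
                       infer_row(row, prior, config)),
      error = function(e) {
        stop("inference failed for gene ", dataset$gene_ids[i], ": ",
             conditionMessage(e))
      })
    B_hat[i, row$regulators] <- fit$estimate[seq_len(m - 1)]
    F_hat[i] <- fit$estimate[m]
    iters[i] <- fit$iterations
    conv[i] <- fit$converged
  }
  res <- structure(list(B_hat = B_hat, F_hat = F_hat,
                        threshold = config$threshold,
                        edges = NULL,
                        per_gene_iters = iters, converged = conv,
                        gene_ids = dataset$gene_ids),
                   class = "lrbi_result")
  res$edges <- edge_table(B_hat, config$threshold, dataset$gene_ids)
  res
}

edge_table <- function(B_hat, threshold, gene_ids) {
  keep <- which(abs(B_hat) >= threshold & row(B_hat) != col(B_hat),
                arr.ind = TRUE)
  w <- B_hat[keep]
  data.frame(target = gene_ids[keep[, 1]],
             regulator = gene_ids[keep[, 2]],
             target_index = as.integer(keep[, 1]),
             regulator_index = as.integer(keep[, 2]),
             weight = w,
             sign = ifelse(w >= 0, "+", "-"),
             stringsAsFactors = FALSE)[order(keep[, 1], keep[, 2]), ]
}

#' Re-threshold an inference result
#'
#' Recomputes the edge set of an existing [infer_network()] result at a new
#' decision cutoff without re-running the sampler. Edge sets are nested:
#' a larger threshold always yields a subset of the edges.
#'
#' @param result An `lrbi_result`.
#' @param threshold New cutoff on `|B_hat[i, j]|`.
#' @return The result with `threshold` and `edges` replaced.
#' @export
apply_threshold <- function(result, threshold) {
  stopifnot(inherits(result, "lrbi_result"), threshold >= 0)
  result$threshold <- threshold
  result$edges <- edge_table(result$B_hat, threshold, result$gene_ids)
  result
}

#' @export
print.lrbi_result <- function(x, ...) {
  cat("<lrbi_result> ", length(x$gene_ids), " genes, ",
      nrow(x$edges), " edges at |B| >= ", x$threshold,
      "; ", sum(x$converged), "/", length(x$converged),
      " rows converged (median ", stats::median(x$per_gene_iters),
      " iterations)\n", sep = "")
  invisible(x)
}
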