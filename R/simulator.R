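# Random-network and dataset simulator. Emulates the standard benchmark for
# SEM-based network inference from eQTL perturbations: directed acyclic or
# cyclic networks with an average of Ne out-edges per gene, edge weights of
# magnitude Uniform(weight_low, weight_high) with random sign, F = identity
# (each marker perturbs its own gene with unit effect), biallelic genotype
# codes {0,1,2} drawn with probabilities (0.25, 0.5, 0.25) as in an F2
# cross, and i.i.d. Gaussian expression noise.

#' Simulation configuration
#'
#' @param m Gene count.
#' @param n_samples Number of individuals N.
#' @param ne Average number of edges per gene (0 < `ne` <= m - 1); each
#'   admissible directed pair carries an edge independently with probability
#'   `ne / (m - 1)`.
#' @param cyclic If `FALSE` (default) a random topological order is drawn and
#'   only order-respecting edges are admissible (directed acyclic network);
#'   if `TRUE` every ordered pair is admissible and networks are resampled
#'   until `(I - B)` is well conditioned.
#' @param sigma2 Expression noise variance (default 0.01).
#' @param weight_low,weight_high Magnitude bounds of nonzero regulatory
#'   effects; weights are `sign * Uniform(weight_low, weight_high)` with the
#'   sign +/- equiprobable. Defaults 0.5 and 1.0.
#' @param genotype_probs Probabilities of the three genotype codes; default
#'   `c(0.25, 0.5, 0.25)`.
#' @param genotype_codes The code set itself; default `c(0, 1, 2)`.
#' @param edge_rate_basis `"per_pair"` (default): every admissible ordered
#'   pair has edge probability `ne / (m - 1)`, so an acyclic network has
#'   about `m * ne / 2` edges in total. `"total"`: the probability is scaled
#'   so the expected total is `m * ne` regardless of topology.
#' @param seed Root integer seed; sub-seeds for the network, the genotypes
#'   and the noise are derived deterministically from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(m, n_samples, ne = 3, cyclic = FALSE, sigma2 = 0.01,
                       weight_low = 0.5, weight_high = 1.0,
                       genotype_probs = c(0.25, 0.5, 0.25),
                       genotype_codes = c(0, 1, 2),
                       edge_rate_basis = c("per_pair", "total"),
                       seed = 1L) {
  edge_rate_basis <- match.arg(edge_rate_basis)
  stopifnot(m >= 2, n_samples >= 1, sigma2 > 0,
            length(genotype_probs) == length(genotype_codes))
  if (ne <= 0 || ne > m - 1) stop("ne must satisfy 0 < ne <= m - 1")
  if (!(weight_low > 0 && weight_low < weight_high)) {
    stop("need 0 < weight_low < weight_high")
  }
  if (abs(sum(genotype_probs) - 1) > 1e-8) stop("genotype_probs must sum to 1")
  structure(list(m = as.integer(m), n_samples = as.integer(n_samples),
                 ne = ne, cyclic = isTRUE(cyclic), sigma2 = sigma2,
                 weight_low = weight_low, weight_high = weight_high,
                 genotype_probs = genotype_probs,
                 genotype_codes = genotype_codes,
                 edge_rate_basis = edge_rate_basis,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Edge probability per admissible ordered pair under the configured basis.
edge_prob <- function(config, n_admissible) {
  p <- switch(config$edge_rate_basis,
    per_pair = config$ne / (config$m - 1),
    total    = config$m * config$ne / n_admissible)
  min(p, 1)
}

#' Sample a random network model
#'
#' Draws a directed network with, on average, `ne` edges per gene. In acyclic
#' mode a random topological order is drawn first and only order-respecting
#' ordered pairs (regulator earlier than target) are admissible, so `B` is
#' strictly triangular after permutation by that order. In cyclic mode all
#' ordered pairs are admissible and the draw is rejected (up to 100 times)
#' while `(I - B)` has condition number >= 1e8, which guarantees the SEM has
#' a stable algebraic solution. `F` is the identity.
#'
#' @param config A [sim_config()].
#' @return A [grn_model()]; in acyclic mode the drawn topological order is
#'   attached as attribute `"topo_order"`.
#' @export
sample_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$m
  withr::with_seed(derive_seed(config$seed, 1), {
    for (attempt in seq_len(100)) {
      B <- matrix(0, m, m)
      if (config$cyclic) {
        admissible <- which(row(B) != col(B))
        topo <- NULL
      } else {
        topo <- sample.int(m) # topo[k] = gene in position k
        pos <- order(topo)    # pos[g]  = position of gene g
        # regulator j must precede target i in the topological order
        admissible <- which(pos[col(B)] < pos[row(B)])
      }
      p <- edge_prob(config, length(admissible))
      on_edges <- admissible[stats::runif(length(admissible)) < p]
      if (length(on_edges) > 0) {
        mag <- stats::runif(length(on_edges), config$weight_low, config$weight_high)
        sgn <- sample(c(-1, 1), length(on_edges), replace = TRUE)
        B[on_edges] <- sgn * mag
      }
      if (!config$cyclic || kappa(diag(m) - B, exact = FALSE) < 1e8) {
        model <- grn_model(B, diag(m))
        attr(model, "topo_order") <- topo
        return(model)
      }
    }
    stop("could not sample a stable cyclic network in 100 attempts ",
         "(ne = ", config$ne, ", m = ", m, ")")
  })
}

#' Sample a genotype matrix
#'
#' Draws an m x N matrix of i.i.d. genotype codes with the configured
#' probabilities (default codes 0/1/2 with probabilities 0.25/0.5/0.25,
#' matching the genotype frequencies of an F2 intercross).
#'
#' @param config A [sim_config()].
#' @return An m x N integer-valued matrix.
#' @export
sample_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, 2), {
    matrix(sample(config$genotype_codes, config$m * config$n_samples,
                  replace = TRUE, prob = config$genotype_probs),
           nrow = config$m, ncol = config$n_samples)
  })
}

#' Simulate a network and a matching dataset
#'
#' Composes [sample_network()], [sample_genotypes()] and
#' [generate_expression()] with independent sub-seeds derived from
#' `config$seed`, so the ground truth and the data are jointly reproducible.
#'
#' @param config A [sim_config()].
#' @return A list with elements `model` (the generating [grn_model()]) and
#'   `dataset` (the simulated [grn_dataset()]).
#' @export
simulate_grn <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  model <- sample_network(config)
  X <- sample_genotypes(config)
  dataset <- generate_expression(model, X, noise_spec(config$sigma2),
                                 seed = derive_seed(config$seed, 3),
                                 genotype_codes = config$genotype_codes)
  list(model = model, dataset = dataset)
}
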