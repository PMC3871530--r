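# Independent oracles and small fixture builders shared across tests.

# Ordinary least squares on one row regression: coefficients of
# response ~ t(design) without intercept, by QR. Independent of the
# package's Bayesian machinery.
ols_row <- function(row) {
  qr.coef(qr(t(row$design)), row$response)
}

# Noise-free dataset generated directly from the SEM solve, bypassing
# generate_expression: Y = (I - B)^{-1} F X exactly.
noise_free_dataset <- function(model, X) {
  Y <- solve(diag(model$m) - model$B, model$F %*% X)
  grn_dataset(Y, X)
}

# Wrap a coefficient matrix as a minimal inference result so evaluation
# functions can be exercised without running the sampler.
fake_result <- function(B_hat, threshold, gene_ids = paste0("g", seq_len(nrow(B_hat)))) {
  diag(B_hat) <- 0
  dimnames(B_hat) <- list(gene_ids, gene_ids)
  res <- structure(list(B_hat = B_hat, F_hat = rep(1, nrow(B_hat)),
                        threshold = 0, edges = NULL,
                        per_gene_iters = integer(nrow(B_hat)),
                        converged = logical(nrow(B_hat)),
                        gene_ids = gene_ids),
                   class = "lrbi_result")
  apply_threshold(res, threshold)
}

# Brute-force PD/FDR by explicit enumeration over all ordered gene pairs.
brute_pd_fdr <- function(B_true, B_hat, threshold) {
  m <- nrow(B_true)
  nt <- nf <- nb <- nbp <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    true_edge <- B_true[i, j] != 0
    inf_edge <- abs(B_hat[i, j]) >= threshold
    nb <- nb + true_edge
    nbp <- nbp + inf_edge
    nt <- nt + (true_edge && inf_edge)
    nf <- nf + (!true_edge && inf_edge)
  }
  list(pd = if (nb == 0) NA_real_ else nt / nb,
       fdr = if (nbp == 0) 0 else nf / nbp)
}

# Small genotype matrix with fixed seed.
toy_genotypes <- function(m, N, seed = 99) {
  withr::with_seed(seed, matrix(sample(0:2, m * N, replace = TRUE,
                                       prob = c(0.25, 0.5, 0.25)), m, N))
}
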