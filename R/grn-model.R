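# Core domain types for the linear structural equation model (SEM)
#
#   Y = B Y + F X + E
#
# Y (m x N): expression of m genes over N individuals; B (m x m): directed
# regulatory effects, B[i, j] = effect of gene j on gene i, zero diagonal;
# X (m x N): genotype codes of each gene's cis-eQTL; F (m x m diagonal):
# eQTL effect sizes; E: i.i.d. Gaussian noise. Because every unknown sits
# in one row of [B F], the system decomposes into m independent linear
# regressions, one per gene.

#' Construct a gene regulatory network model
#'
#' Bundles the directed regulatory-effect matrix `B` and the diagonal
#' eQTL-effect matrix `F` of a linear SEM for gene expression. The
#' convention throughout the package is `B[i, j]` = effect of gene `j`
#' (regulator) on gene `i` (target), so row `i` collects everything that
#' regulates gene `i`.
#'
#' @param B m x m numeric matrix of regulatory effects; the diagonal must be
#'   exactly zero (no self-loops).
#' @param F m x m diagonal numeric matrix of eQTL effects (defaults to the
#'   identity, i.e. each marker perturbs its gene with unit effect).
#' @return An object of class `grn_model` with elements `B`, `F`, `m`.
#' @examples
#' B <- matrix(0, 3, 3); B[1, 2] <- 0.8
#' grn_model(B)
#' @export
grn_model <- function(B, F = diag(nrow(B))) {
  B <- as.matrix(B)
  F <- as.matrix(F)
  if (nrow(B) != ncol(B)) stop("B must be square, got ", nrow(B), " x ", ncol(B))
  m <- nrow(B)
  if (!all(dim(F) == c(m, m))) stop("F must be ", m, " x ", m)
  if (any(diag(B) != 0)) {
    stop("B has nonzero diagonal entries (self-loops) at gene(s): ",
         paste(which(diag(B) != 0), collapse = ", "))
  }
  offdiag <- F
  diag(offdiag) <- 0
  if (any(offdiag != 0)) stop("F must be diagonal (one cis-eQTL per gene)")
  structure(list(B = B, F = F, m = m), class = "grn_model")
}

#' @export
print.grn_model <- function(x, ...) {
  cat("<grn_model> ", x$m, " genes, ",
      sum(x$B != 0), " directed edges, ",
      "F diagonal range [", format(min(diag(x$F))), ", ",
      format(max(diag(x$F))), "]\n", sep = "")
  invisible(x)
}

#' Number of directed edges in a network model
#'
#' Counts the nonzero off-diagonal entries of `B`.
#' @param model A [grn_model()].
#' @return Integer edge count.
#' @export
n_edges <- function(model) {
  stopifnot(inherits(model, "grn_model"))
  sum(model$B != 0)
}

#' Construct an expression + genotype dataset
#'
#' Pairs an expression matrix `Y` with a genotype matrix `X` of identical
#' shape, where row `i` of `X` is the genotype of gene `i`'s pre-determined
#' cis-eQTL and column `k` of both matrices refers to the same individual.
#'
#' @param Y m x N numeric expression matrix (genes in rows).
#' @param X m x N genotype matrix; entries must belong to `genotype_codes`.
#' @param gene_ids Character vector of m gene identifiers shared by the rows
#'   of `Y` and `X`; defaults to `g1 ... gm`.
#' @param genotype_codes Admissible genotype codes; default `c(0, 1, 2)`
#'   (standard F2-cross coding). Use `c(1, 2, 3)` for 1-based coding.
#' @return An object of class `grn_dataset` with elements `Y`, `X`, `m`, `N`,
#'   `gene_ids`.
#' @export
grn_dataset <- function(Y, X, gene_ids = NULL,
                        genotype_codes = c(0, 1, 2)) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (!all(dim(Y) == dim(X))) {
    stop("Y and X must have identical shape; got ",
         paste(dim(Y), collapse = "x"), " vs ", paste(dim(X), collapse = "x"))
  }
  if (!is.numeric(Y) || anyNA(Y)) stop("Y must be numeric with no missing values")
  if (!all(X %in% genotype_codes)) {
    bad <- setdiff(unique(as.vector(X)), genotype_codes)
    stop("X contains codes outside {", paste(genotype_codes, collapse = ","),
         "}: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  m <- nrow(Y)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(m))
  if (length(gene_ids) != m) stop("gene_ids must have length ", m)
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  rownames(Y) <- rownames(X) <- gene_ids
  structure(list(Y = Y, X = X, m = m, N = ncol(Y), gene_ids = gene_ids,
                 genotype_codes = genotype_codes),
            class = "grn_dataset")
}

#' @export
print.grn_dataset <- function(x, ...) {
  cat("<grn_dataset> ", x$m, " genes x ", x$N, " samples\n", sep = "")
  invisible(x)
}

#' Noise specification for the SEM
#'
#' @param sigma2 Noise variance of the i.i.d. Gaussian measurement noise
#'   (strictly positive).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma2) {
  if (!is.numeric(sigma2) || length(sigma2) != 1 || sigma2 <= 0) {
    stop("sigma2 must be a single value > 0")
  }
  structure(list(sigma2 = sigma2), class = "noise_spec")
}

#' Decompose the SEM into one gene's linear regression
#'
#' Row `i` of the SEM reads `y_i = sum_{j != i} B[i,j] y_j + F[i,i] x_i + e_i`,
#' so gene `i`'s unknowns are estimable by regressing its expression on the
#' other genes' expression plus its own eQTL genotype. The design stacks the
#' other genes' expression rows in ascending gene index (skipping `i`) and the
#' genotype row of gene `i` last, giving exactly `m` regressors.
#'
#' @param dataset A [grn_dataset()].
#' @param gene_index Target gene, 1-based, in `1..m`.
#' @return An object of class `row_regression` with elements `gene_index`,
#'   `response` (length-N vector), `design` (m x N matrix, regressors in
#'   rows), and `coef_labels` (length-m character vector mapping coefficient
#'   positions to `B[i,j]` entries and, last, `F[i,i]`).
#' @examples
#' ds <- grn_dataset(Y = rbind(c(1, 2), c(3, 4)),
#'                   X = rbind(c(0, 1), c(2, 0)))
#' rr <- build_row_regression(ds, 1)
#' rr$coef_labels  # "B[1,2]" "F[1,1]"
#' @export
build_row_regression <- function(dataset, gene_index) {
  stopifnot(inherits(dataset, "grn_dataset"))
  m <- dataset$m
  if (m < 2) stop("need at least 2 genes to form a regression (m = ", m, ")")
  if (length(gene_index) != 1 || gene_index < 1 || gene_index > m ||
      gene_index != as.integer(gene_index)) {
    stop("gene_index ", gene_index, " out of range 1..", m)
  }
  i <- as.integer(gene_index)
  others <- setdiff(seq_len(m), i)
  design <- rbind(dataset$Y[others, , drop = FALSE],
                  dataset$X[i, , drop = FALSE])
  labels <- c(sprintf("B[%d,%d]", i, others), sprintf("F[%d,%d]", i, i))
  rownames(design) <- labels
  structure(list(gene_index = i,
                 response = as.numeric(dataset$Y[i, ]),
                 design = design,
                 coef_labels = labels,
                 regulators = others),
            class = "row_regression")
}

#' Generate expression data from a network model
#'
#' Solves the SEM forward: draws `E` with i.i.d. Normal(0, sigma2) entries and
#' computes `Y = (I - B)^{-1} (F X + E)`, the unique solution of
#' `Y = B Y + F X + E`. Cyclic networks are handled algebraically through the
#' same solve, provided `(I - B)` is well-conditioned.
#'
#' @param model A [grn_model()].
#' @param X m x N genotype matrix.
#' @param noise A [noise_spec()].
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @param genotype_codes Passed through to [grn_dataset()].
#' @return A [grn_dataset()]; the realized noise matrix is attached as
#'   attribute `"E"` so that the SEM identity can be verified exactly.
#' @export
generate_expression <- function(model, X, noise, seed,
                                genotype_codes = c(0, 1, 2)) {
  stopifnot(inherits(model, "grn_model"), inherits(noise, "noise_spec"))
  X <- as.matrix(X)
  if (nrow(X) != model$m) stop("X must have ", model$m, " rows")
  ImB <- diag(model$m) - model$B
  if (kappa(ImB, exact = FALSE) > 1e8) {
    stop("unstable network: (I - B) condition number exceeds 1e8")
  }
  E <- withr::with_seed(seed, {
    matrix(stats::rnorm(model$m * ncol(X), mean = 0, sd = sqrt(noise$sigma2)),
           nrow = model$m)
  })
  Y <- solve(ImB, model$F %*% X + E)
  ds <- grn_dataset(Y, X, genotype_codes = genotype_codes)
  attr(ds, "E") <- E
  ds
}
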