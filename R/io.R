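# Tab-separated interchange formats. Matrices are written genes-in-rows with
# a header of sample ids and a first column of gene/marker ids; full float
# precision (%.17g) so write -> read round-trips are lossless.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a numeric matrix as tab-separated text
#'
#' @param mat Numeric matrix; row names (gene/marker ids) and column names
#'   (sample ids) are written, defaulting to `g<i>` / `s<k>` when absent.
#' @param path Output file.
#' @param id_col Name of the first (id) column in the header.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "id") {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  lines <- c(paste(c(id_col, colnames(mat)), collapse = "\t"),
             vapply(seq_len(nrow(mat)), function(i) {
               paste(c(rownames(mat)[i], fmt_num(mat[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a tab-separated numeric matrix
#'
#' Expects a header row of sample ids and a first column of gene/marker ids.
#'
#' @param path Input file.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(path, ": expected an id column plus data columns")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop(path, ": duplicate row id '", ids[anyDuplicated(ids)], "'")
  }
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    if (anyNA(v) && !anyNA(body[[j]])) {
      bad <- which(is.na(v))[1]
      stop(path, ": non-numeric cell at row '", ids[bad], "', column '",
           colnames(body)[j], "'")
    }
    body[[j]] <- v
  }
  mat <- as.matrix(body)
  rownames(mat) <- ids
  mat
}

#' Read paired expression and genotype matrices into a dataset
#'
#' Sample columns are aligned by the intersection of the two headers, kept in
#' expression-file order; gene/marker rows are aligned by id. Every
#' expression gene must have a marker row of the same id.
#'
#' @param expr_path Expression matrix file (genes in rows).
#' @param geno_path Genotype matrix file (markers in rows, ids matching the
#'   expression genes).
#' @param genotype_codes Admissible genotype codes (default `c(0, 1, 2)`).
#' @return A [grn_dataset()].
#' @export
read_dataset <- function(expr_path, geno_path, genotype_codes = c(0, 1, 2)) {
  Y <- read_matrix_tsv(expr_path)
  X <- read_matrix_tsv(geno_path)
  samples <- intersect(colnames(Y), colnames(X))
  if (length(samples) == 0) {
    stop("no shared sample ids between ", expr_path, " and ", geno_path)
  }
  missing <- setdiff(rownames(Y), rownames(X))
  if (length(missing) > 0) {
    stop("genotype file ", geno_path, " is missing marker row(s) for gene(s): ",
         paste(missing, collapse = ", "))
  }
  grn_dataset(Y[, samples, drop = FALSE],
              X[rownames(Y), samples, drop = FALSE],
              gene_ids = rownames(Y),
              genotype_codes = genotype_codes)
}

#' Write a dataset's expression and genotype matrices
#'
#' @param dataset A [grn_dataset()].
#' @param expr_path,geno_path Output files.
#' @export
write_dataset <- function(dataset, expr_path, geno_path) {
  stopifnot(inherits(dataset, "grn_dataset"))
  write_matrix_tsv(dataset$Y, expr_path, id_col = "gene")
  write_matrix_tsv(dataset$X, geno_path, id_col = "marker")
  invisible(c(expr_path, geno_path))
}

#' Write an inferred network to files
#'
#' Writes up to three files under a common prefix: `<prefix>_Bhat.tsv`, the
#' full pre-threshold coefficient matrix; `<prefix>_edges.tsv`, the
#' thresholded edge list (`regulator_id`, `target_id`, `weight`, `sign`);
#' and `<prefix>.sif`, a `regulator <sign> target` file for network viewers.
#'
#' @param result An [infer_network()] result.
#' @param prefix Output path prefix.
#' @param formats Any of `"matrix"`, `"edges"`, `"sif"`.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(result, prefix,
                          formats = c("matrix", "edges", "sif")) {
  stopifnot(inherits(result, "lrbi_result"))
  formats <- match.arg(formats, several.ok = TRUE)
  paths <- character(0)
  if ("matrix" %in% formats) {
    p <- paste0(prefix, "_Bhat.tsv")
    write_matrix_tsv(result$B_hat, p, id_col = "gene")
    paths <- c(paths, p)
  }
  if ("edges" %in% formats) {
    p <- paste0(prefix, "_edges.tsv")
    e <- result$edges
    lines <- c("regulator_id\ttarget_id\tweight\tsign",
               if (nrow(e) > 0) {
                 paste(e$regulator, e$target, fmt_num(e$weight), e$sign,
                       sep = "\t")
               })
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  if ("sif" %in% formats) {
    p <- paste0(prefix, ".sif")
    e <- result$edges
    writeLines(if (nrow(e) > 0) paste(e$regulator, e$sign, e$target) else character(0), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a thresholded edge list
#'
#' @param path An edge-list file as written by [write_network()].
#' @return Data frame with columns `regulator_id`, `target_id`, `weight`,
#'   `sign`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("regulator_id", "target_id", "weight", "sign")
  if (!all(need %in% colnames(df))) {
    stop(path, ": expected columns ", paste(need, collapse = ", "))
  }
  if (any(df$regulator_id == df$target_id)) {
    stop(path, ": self-loop edge(s) present")
  }
  df
}
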