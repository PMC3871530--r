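# Benchmark metrics for network recovery. With NB true edges, NB' inferred
# edges, Nt edges in both and Nf inferred-but-not-true edges (so
# NB' = Nt + Nf):
#   power of detection  PD  = Nt / NB
#   false discovery rate FDR = Nf / NB'
# Edge membership is decided on directed (target, regulator) positions only;
# sign and magnitude do not enter PD/FDR. The inference numerical error
# INEr(i, j) = |B[i, j] - B_hat[i, j]| is evaluated at every true-edge
# position using the pre-threshold estimate.

#' Compare an inferred network against the generating truth
#'
#' @param true_model The generating [grn_model()].
#' @param result An [infer_network()] result (same gene count).
#' @return An object of class `eval_result`: edge counts (`n_true_edges`,
#'   `n_inferred_edges`, `n_true_pos`, `n_false`), `pd`, `fdr`, `iners`
#'   (data frame `target`, `regulator`, `b_true`, `b_hat`, `iner` over true
#'   edges), and `sign_agreement` (fraction of true positives whose estimated
#'   sign matches the truth; reported separately, PD/FDR ignore sign).
#'   `pd` is `NA` when the truth has no edges; `fdr` is 0 when nothing was
#'   inferred (no discoveries, no false discoveries).
#' @examples
#' B <- matrix(0, 3, 3); B[1, 2] <- 0.9
#' truth <- grn_model(B)
#' sim <- simulate_grn(sim_config(m = 3, n_samples = 50, ne = 1, seed = 5))
#' fit <- infer_network(sim$dataset, lrbi_config(seed = 5))
#' compute_metrics(sim$model, fit)
#' @export
compute_metrics <- function(true_model, result) {
  stopifnot(inherits(true_model, "grn_model"), inherits(result, "lrbi_result"))
  m <- true_model$m
  if (m != nrow(result$B_hat)) {
    stop("gene counts differ: truth ", m, ", result ", nrow(result$B_hat))
  }
  true_set <- which(true_model$B != 0 & row(true_model$B) != col(true_model$B))
  inf_set <- (result$edges$regulator_index - 1L) * m + result$edges$target_index
  n_true <- length(true_set)
  n_inf <- length(inf_set)
  n_tp <- length(intersect(inf_set, true_set))
  n_false <- n_inf - n_tp
  idx <- arrayInd(true_set, c(m, m))
  iners <- data.frame(target = idx[, 1], regulator = idx[, 2],
                      b_true = true_model$B[true_set],
                      b_hat = result$B_hat[true_set],
                      iner = abs(true_model$B[true_set] - result$B_hat[true_set]))
  tp_set <- intersect(inf_set, true_set)
  sign_agree <- if (length(tp_set) == 0) NA_real_ else {
    mean(sign(true_model$B[tp_set]) == sign(result$B_hat[tp_set]))
  }
  structure(list(n_true_edges = n_true, n_inferred_edges = n_inf,
                 n_true_pos = n_tp, n_false = n_false,
                 pd = if (n_true == 0) NA_real_ else n_tp / n_true,
                 fdr = if (n_inf == 0) 0 else n_false / n_inf,
                 iners = iners, sign_agreement = sign_agree),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result> PD = ", format(x$pd, digits = 4),
      ", FDR = ", format(x$fdr, digits = 4),
      " (", x$n_true_pos, "/", x$n_true_edges, " true edges recovered, ",
      x$n_false, " false)\n", sep = "")
  invisible(x)
}

#' Summarize inference numerical errors
#'
#' @param true_model The generating [grn_model()].
#' @param result An [infer_network()] result.
#' @param top Number of largest-magnitude true edges to list (default 12).
#' @return A list: `median`, `mean`, `max` INEr over true-edge positions, and
#'   `table`, the per-edge listing (target, regulator, true and inferred
#'   coefficients, INEr) for the `top` largest `|B|`. Empty when the truth
#'   has no edges.
#' @export
summarize_iner <- function(true_model, result, top = 12) {
  ev <- compute_metrics(true_model, result)
  if (nrow(ev$iners) == 0) {
    return(list(median = NA_real_, mean = NA_real_, max = NA_real_,
                table = ev$iners))
  }
  ord <- order(-abs(ev$iners$b_true))
  list(median = stats::median(ev$iners$iner),
       mean = mean(ev$iners$iner),
       max = max(ev$iners$iner),
       table = utils::head(ev$iners[ord, ], top))
}

#' Define a simulation experiment grid
#'
#' @param base_config A [sim_config()] template; its `n_samples`, `sigma2`
#'   and `seed` are overridden cell by cell.
#' @param n_samples Vector of sample sizes to sweep.
#' @param thresholds Vector of edge-decision cutoffs; each replicate is
#'   inferred once and re-thresholded, so edge sets across thresholds are
#'   nested by construction.
#' @param sigma2 Vector of noise variances.
#' @param replicates Independent simulated networks per cell (default 20).
#' @param lrbi Sampler settings, an [lrbi_config()]; its `threshold` and
#'   `seed` are overridden per cell.
#' @param seed Root seed for the whole experiment.
#' @return An object of class `experiment_grid`.
#' @export
experiment_grid <- function(base_config, n_samples = c(10, 20, 50, 100, 200),
                            thresholds = 0.05, sigma2 = 0.01,
                            replicates = 20, lrbi = lrbi_config(),
                            seed = 1L) {
  stopifnot(inherits(base_config, "sim_config"),
            length(n_samples) > 0, length(thresholds) > 0,
            length(sigma2) > 0, replicates >= 1)
  structure(list(base_config = base_config, n_samples = n_samples,
                 thresholds = thresholds, sigma2 = sigma2,
                 replicates = as.integer(replicates), lrbi = lrbi,
                 seed = as.integer(seed)),
            class = "experiment_grid")
}

#' Run a simulation experiment
#'
#' For every (n_samples, sigma2) cell and replicate: simulate a network and
#' dataset, run [infer_network()], and score PD/FDR against the truth at each
#' requested threshold (re-thresholding the same inference). Returns per-cell
#' means and standard errors. Replicate failures are recorded and skipped so
#' a single unstable draw does not abort a sweep.
#'
#' @param grid An [experiment_grid()].
#' @param verbose Print a progress line per cell.
#' @return A data frame with one row per (n_samples, threshold, sigma2):
#'   `mean_pd`, `se_pd`, `mean_fdr`, `se_fdr`, `mean_iner_median`,
#'   `replicates`. Failed replicates, if any, are attached as attribute
#'   `"failures"`.
#' @export
run_experiment <- function(grid, verbose = FALSE) {
  stopifnot(inherits(grid, "experiment_grid"))
  cells <- expand.grid(n_samples = grid$n_samples, sigma2 = grid$sigma2,
                       KEEP.OUT.ATTRS = FALSE)
  out <- list()
  failures <- list()
  for (ci in seq_len(nrow(cells))) {
    N <- cells$n_samples[ci]
    s2 <- cells$sigma2[ci]
    pd <- matrix(NA_real_, grid$replicates, length(grid$thresholds))
    fdr <- matrix(NA_real_, grid$replicates, length(grid$thresholds))
    med_iner <- rep(NA_real_, grid$replicates)
    for (r in seq_len(grid$replicates)) {
      rep_seed <- derive_seed(grid$seed, ci * 10000L + r)
      res <- tryCatch({
        cfg <- grid$base_config
        cfg$n_samples <- as.integer(N)
        cfg$sigma2 <- s2
        cfg$seed <- rep_seed
        sim <- simulate_grn(cfg)
        lcfg <- grid$lrbi
        lcfg$seed <- rep_seed
        fit <- infer_network(sim$dataset, lcfg)
        for (k in seq_along(grid$thresholds)) {
          ev <- compute_metrics(sim$model, apply_threshold(fit, grid$thresholds[k]))
          pd[r, k] <- ev$pd
          fdr[r, k] <- ev$fdr
        }
        med_iner[r] <- stats::median(compute_metrics(sim$model, fit)$iners$iner)
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res)) {
        failures[[length(failures) + 1]] <-
          data.frame(n_samples = N, sigma2 = s2, replicate = r, error = res)
      }
    }
    for (k in seq_along(grid$thresholds)) {
      ok <- !is.na(pd[, k])
      n_ok <- sum(ok)
      se <- function(v) if (sum(!is.na(v)) > 1) {
        stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
      } else NA_real_
      out[[length(out) + 1]] <- data.frame(
        n_samples = N, threshold = grid$thresholds[k], sigma2 = s2,
        mean_pd = mean(pd[ok, k]), se_pd = se(pd[ok, k]),
        mean_fdr = mean(fdr[ok, k]), se_fdr = se(fdr[ok, k]),
        mean_iner_median = mean(med_iner, na.rm = TRUE),
        replicates = n_ok)
    }
    if (verbose) {
      message("cell N=", N, " sigma2=", s2, " done (",
              ci, "/", nrow(cells), ")")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (length(failures) > 0) attr(res, "failures") <- do.call(rbind, failures)
  res
}

#' Plot PD and FDR against sample size
#'
#' Draws the PD-vs-N and FDR-vs-N curves of a [run_experiment()] table, one
#' line per (threshold, sigma2) combination, with +/- 1 standard-error bars.
#' Requires ggplot2.
#'
#' @param results A [run_experiment()] data frame.
#' @return A ggplot object.
#' @export
plot_experiment <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_experiment requires the ggplot2 package")
  }
  long <- rbind(
    data.frame(results[c("n_samples", "threshold", "sigma2")],
               metric = "PD", value = results$mean_pd, se = results$se_pd),
    data.frame(results[c("n_samples", "threshold", "sigma2")],
               metric = "FDR", value = results$mean_fdr, se = results$se_fdr))
  long$group <- interaction(long$threshold, long$sigma2, drop = TRUE)
  long$ymin <- long$value - long$se
  long$ymax <- long$value + long$se
  ggplot2::ggplot(long, ggplot2::aes(x = n_samples, y = value,
                                     colour = group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = ymin, ymax = ymax),
                           width = 0.02, na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "samples (N)", y = NULL,
                  colour = "threshold.sigma2") +
    ggplot2::theme_minimal()
}
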