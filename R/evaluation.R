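# Metrics and model-comparison machinery: balanced accuracy, ROC curves
# averaged across reseeded runs on a common FPR grid, paired t-tests, and the
# latent-space export for visualization.

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity; insensitive to the severe class
#' imbalance typical of survival subgroups.
#'
#' @param y True 0/1 labels (both classes must be present).
#' @param y_hat Predicted 0/1 classes.
#' @return Value in `[0, 1]`.
#' @export
balanced_accuracy <- function(y, y_hat) {
  assert_binary(y, "y"); assert_binary(y_hat, "y_hat")
  if (length(unique(y)) < 2L) {
    stopf("balanced accuracy is undefined when `y` contains a single class")
  }
  sens <- sum(y == 1 & y_hat == 1) / sum(y == 1)
  spec <- sum(y == 0 & y_hat == 0) / sum(y == 0)
  (sens + spec) / 2
}

#' ROC curve points
#'
#' Threshold sweep over the unique scores (predict positive when
#' `score >= threshold`), yielding the staircase vertices from (0, 0) to
#' (1, 1). Tied scores collapse into a single (diagonal) threshold step.
#'
#' @param y True 0/1 labels (both classes present).
#' @param scores Numeric scores, higher = more positive.
#' @return Data frame with columns `fpr`, `tpr`, monotone non-decreasing in
#'   both coordinates.
#' @export
roc_points <- function(y, scores) {
  assert_binary(y, "y")
  if (length(unique(y)) < 2L) stopf("ROC undefined for single-class `y`")
  if (length(y) != length(scores)) stopf("`y` and `scores` lengths differ")
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys == 1); fp <- cumsum(ys == 0)
  last <- which(!duplicated(ss, fromLast = TRUE))  # last index of each threshold
  data.frame(fpr = c(0, fp[last] / n_neg), tpr = c(0, tp[last] / n_pos))
}

# Evaluate a run's ROC staircase at grid points: the step function taking, at
# grid value g, the highest TPR among vertices with fpr <= g.
roc_on_grid <- function(pts, grid) {
  o <- order(pts$fpr, pts$tpr)
  f <- pts$fpr[o]; t_ <- cummax(pts$tpr[o])
  t_[findInterval(grid, f)]
}

#' ROC curve and AUC averaged across runs
#'
#' Per run, the TPR is interpolated onto a common FPR grid on `[0, 1]`; the
#' interpolated TPRs are averaged pointwise, and the AUC is the trapezoidal
#' area under the mean curve. With a single run this agrees with the
#' pairwise-concordance (Mann-Whitney) AUC up to the grid resolution.
#'
#' @param runs List of runs, each a list (or two-element list) with elements
#'   `y` (0/1 labels) and `scores`.
#' @param grid_size Number of FPR grid points (default 101).
#' @return List with `curve` (data frame `fpr`, `tpr` of the mean curve) and
#'   `auc`.
#' @export
averaged_roc_auc <- function(runs, grid_size = 101L) {
  if (length(runs) < 1L) stopf("need at least one run")
  grid <- seq(0, 1, length.out = grid_size)
  tprs <- vapply(runs, function(r) {
    roc_on_grid(roc_points(r$y, r$scores), grid)
  }, numeric(grid_size))
  mean_tpr <- rowMeans(matrix(tprs, nrow = grid_size))
  auc <- sum(diff(grid) * (utils::head(mean_tpr, -1L) + utils::tail(mean_tpr, -1L)) / 2)
  list(curve = data.frame(fpr = grid, tpr = mean_tpr), auc = auc)
}

#' Compare two models' per-run accuracies with a t-test
#'
#' Paired two-sided by default (the runs share their splits); set
#' `paired = FALSE` for a Welch test. Zero variance in the differences is
#' flagged degenerate, with `p = 1` when the means agree and `p = 0`
#' otherwise.
#'
#' @param acc_a,acc_b Per-run metric vectors (equal length when paired).
#' @param paired Paired test (default `TRUE`).
#' @return List with `statistic`, `p_value`, `mean_diff`, `degenerate`.
#' @export
compare_models <- function(acc_a, acc_b, paired = TRUE) {
  if (paired && length(acc_a) != length(acc_b)) {
    stopf("paired comparison requires equal lengths")
  }
  if (length(acc_a) < 2L || length(acc_b) < 2L) stopf("need at least two runs")
  if (paired) {
    d <- acc_a - acc_b
    if (stats::sd(d) == 0) {
      return(list(statistic = NA_real_,
                  p_value = if (mean(d) == 0) 1 else 0,
                  mean_diff = mean(d), degenerate = TRUE))
    }
    tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  } else {
    if (stats::sd(acc_a) == 0 && stats::sd(acc_b) == 0) {
      return(list(statistic = NA_real_,
                  p_value = if (mean(acc_a) == mean(acc_b)) 1 else 0,
                  mean_diff = mean(acc_a) - mean(acc_b), degenerate = TRUE))
    }
    tt <- stats::t.test(acc_a, acc_b, paired = FALSE)
  }
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = mean(acc_a) - mean(acc_b), degenerate = FALSE)
}

#' Export fused latents with a 2-D embedding
#'
#' Runs the model in evaluation mode and returns one row per sample: the fused
#' latent vector, the class label, and 2-D embedding coordinates for
#' visualization. The embedding is a principal-component projection of the
#' latent space (deterministic up to a fixed sign convention; the `seed`
#' argument is accepted for interface stability and any future stochastic
#' embedding). Diagnostic output only — no quantitative claims should rest
#' on the 2-D coordinates.
#'
#' @param model A trained `fusion_model`.
#' @param dataset A [multiomics()] dataset with the modalities the variant
#'   reads.
#' @param seed Seed (unused by the PCA embedding; kept for reproducibility of
#'   the interface).
#' @return Data frame: `sample_id`, `label`, latent columns `z1..zH`,
#'   embedding columns `dim1`, `dim2`.
#' @export
export_latents <- function(model, dataset, seed = 1L) {
  pred <- stats::predict(model, dataset)
  Z <- pred$latent
  k <- min(2L, ncol(Z), nrow(Z) - 1L)
  pc <- stats::prcomp(Z, center = TRUE, scale. = FALSE, rank. = k)
  emb <- pc$x
  # fix the sign so the embedding is reproducible across platforms
  for (j in seq_len(ncol(emb))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) emb[, j] <- -emb[, j]
  }
  if (ncol(emb) < 2L) emb <- cbind(emb, 0)
  out <- data.frame(sample_id = dataset$sample_ids,
                    label = if (!is.null(dataset$labels)) dataset$labels else NA_integer_)
  colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  cbind(out, Z, data.frame(dim1 = emb[, 1L], dim2 = emb[, 2L]))
}
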