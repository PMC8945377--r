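# The repeated missing-modality experiment: reseeded stratified holdouts,
# per-variant training on the reference portion and evaluation on the target
# portion, with the unshared modality withheld from the conditions that must
# not see it.

VARIANTS <- c("CFA", "IFA", "CFA-2M", "SMA-m1", "SMA-m2", "SMA-m3")

# Which modalities a condition is allowed to read at inference time. CFA and
# SMA-m2 are ground-truth conditions: they read the modality that would be
# missing in practice, which a fully controlled simulation still has.
variant_test_inputs <- function(variant, all_mods, missing) {
  switch(variant,
         "CFA" = all_mods,
         "IFA" = setdiff(all_mods, missing),
         "CFA-2M" = setdiff(all_mods, missing),
         paste0("m", sub("SMA-m", "", variant)))
}

build_variant <- function(variant, dims, spec, seed, missing) {
  available <- setdiff(names(dims), missing)
  switch(variant,
         "CFA" = build_cfa(dims, spec, seed),
         "IFA" = build_ifa(dims[available], d2 = dims[[missing]], spec, seed,
                           missing_name = missing),
         "CFA-2M" = build_cfa(dims[available], spec, seed),
         {
           nm <- sub("SMA-", "", variant)
           build_sma(dims[[nm]], spec, seed, name = nm)
         })
}

#' Run the missing-modality benchmark experiment
#'
#' For each of `n_runs` runs r: split the dataset into reference/target with
#' seed `base_seed + r` (stratified 36% holdout by default), z-score
#' normalize with reference statistics, train every requested variant on the
#' reference portion, and evaluate on the target portion. Conditions that
#' model a missing modality (IFA, CFA-2M, SMA on a present modality) never
#' receive the withheld matrix at inference: it is removed from their view of
#' the target data. CFA and SMA on the withheld modality are ground-truth
#' conditions, possible only because the study is fully controlled.
#'
#' Repeated reseeded holdouts (Monte-Carlo cross-validation) are the default
#' protocol; `scheme = "kfold"` uses classical disjoint folds instead, with
#' `n_runs` folds.
#'
#' @param dataset A labeled [multiomics()] with all modalities present.
#' @param variants Subset of `c("CFA", "IFA", "CFA-2M", "SMA-m1", "SMA-m2",
#'   "SMA-m3")`.
#' @param n_runs Number of reseeded runs (default 5).
#' @param test_fraction Holdout fraction (default 0.36).
#' @param missing Name of the modality withheld from the target source
#'   (default `"m2"`).
#' @param base_seed Base seed; run r uses `base_seed + r`.
#' @param config A [train_config()].
#' @param spec An [encoder_spec()].
#' @param scheme `"mccv"` (default) or `"kfold"`.
#' @param normalization `"train"` (statistics from the reference portion only;
#'   default) or `"global"` (statistics from all samples before splitting).
#' @return An `evaluation_report`: `per_run_metrics` (data frame run, variant,
#'   balanced_accuracy, auc), `averaged_roc` (per-variant mean ROC curve and
#'   AUC), `comparisons` (pairwise paired t-tests), and `scores` (per-run
#'   labels and scores, for reuse).
#' @export
run_experiment <- function(dataset,
                           variants = VARIANTS,
                           n_runs = 5L, test_fraction = 0.36,
                           missing = "m2", base_seed = 0L,
                           config = train_config(), spec = encoder_spec(),
                           scheme = c("mccv", "kfold"),
                           normalization = c("train", "global")) {
  scheme <- match.arg(scheme)
  normalization <- match.arg(normalization)
  variants <- match.arg(variants, VARIANTS, several.ok = TRUE)
  if (is.null(dataset$labels)) stopf("dataset must be labeled")
  if (length(unique(dataset$labels)) < 2L) stopf("need both classes present")
  dims <- vapply(dataset$modalities, ncol, integer(1L))
  folds <- NULL
  if (scheme == "kfold") {
    folds <- with_seed(base_seed, {
      y <- dataset$labels
      idx <- unlist(lapply(split(seq_along(y), y), sample), use.names = FALSE)
      split(idx, rep_len(seq_len(n_runs), length(idx)))
    })
  }
  rows <- list(); scores <- list()
  for (r in seq_len(n_runs)) {
    seed_r <- base_seed + r
    if (scheme == "mccv") {
      sp <- make_missing_modality_split(dataset, test_fraction,
                                        missing_in_test = character(0L),
                                        seed = seed_r)
    } else {
      test_idx <- sort(folds[[r]])
      sp <- list(reference = subset_samples(dataset, setdiff(seq_len(n_samples(dataset)), test_idx)),
                 target = subset_samples(dataset, test_idx))
    }
    if (normalization == "train") {
      ref <- zscore_normalize(sp$reference)
      tgt <- apply_normalization(sp$target, attr(ref, "norm_stats"))
    } else {
      norm_all <- zscore_normalize(dataset)
      ref <- subset_samples(norm_all, sp$plan$train_indices %||% setdiff(seq_len(n_samples(dataset)), sort(folds[[r]])))
      tgt <- subset_samples(norm_all, sp$plan$test_indices %||% sort(folds[[r]]))
    }
    y_test <- tgt$labels
    if (length(unique(y_test)) < 2L) {
      stopf("run %d produced a single-class test set; enable stratification", r)
    }
    for (v in variants) {
      model <- build_variant(v, dims, spec, seed_r, missing)
      cfg <- config; cfg$seed <- seed_r
      fit <- train_fusion(model, ref, cfg)
      allowed <- variant_test_inputs(v, names(dims), missing)
      view <- tgt
      view$modalities <- view$modalities[intersect(names(view$modalities), allowed)]
      pred <- stats::predict(fit$model, view)
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, variant = v,
        balanced_accuracy = balanced_accuracy(y_test, pred$class),
        auc = averaged_roc_auc(list(list(y = y_test, scores = pred$prob)))$auc)
      scores[[v]] <- c(scores[[v]], list(list(y = y_test, scores = pred$prob)))
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  avg_roc <- lapply(scores, averaged_roc_auc)
  comparisons <- NULL
  if (length(variants) >= 2L) {
    pairs <- utils::combn(variants, 2L)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      cm <- compare_models(metrics$balanced_accuracy[metrics$variant == a],
                           metrics$balanced_accuracy[metrics$variant == b])
      data.frame(variant_a = a, variant_b = b, statistic = cm$statistic,
                 p_value = cm$p_value, mean_diff = cm$mean_diff,
                 degenerate = cm$degenerate)
    }))
  }
  structure(list(per_run_metrics = metrics, averaged_roc = avg_roc,
                 comparisons = comparisons, scores = scores,
                 missing = missing, scheme = scheme),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d runs (%s), modality '%s' withheld\n",
              max(x$per_run_metrics$run), x$scheme, x$missing))
  agg <- stats::aggregate(cbind(balanced_accuracy, auc) ~ variant,
                          data = x$per_run_metrics, FUN = mean)
  agg$mean_roc_auc <- vapply(agg$variant, function(v) x$averaged_roc[[v]]$auc,
                             numeric(1L))
  print(agg, row.names = FALSE, digits = 3L)
  invisible(x)
}

#' Summarize an evaluation report
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return Data frame of per-variant mean balanced accuracy, mean per-run AUC
#'   and averaged-curve AUC.
#' @export
summary.evaluation_report <- function(object, ...) {
  agg <- stats::aggregate(cbind(balanced_accuracy, auc) ~ variant,
                          data = object$per_run_metrics, FUN = mean)
  agg$mean_roc_auc <- vapply(agg$variant, function(v) object$averaged_roc[[v]]$auc,
                             numeric(1L))
  agg
}
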