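# Core containers: one omics modality and an aligned multi-modality dataset.

#' Construct a modality matrix
#'
#' A modality is one omics data type (gene expression, DNA methylation beta
#' values, miRNA expression, ...) measured on a common set of samples, stored
#' samples-in-rows with sample and feature identifiers as dimnames.
#'
#' @param name Modality label, e.g. `"m1"`.
#' @param values Numeric matrix, `n_samples x n_features`. Row names are sample
#'   identifiers, column names feature identifiers; both must be unique. All
#'   entries must be finite (missing values are rejected, not imputed: filling
#'   in absent measurements is the fusion model's job, not the container's).
#' @return An object of class `modality_matrix` (a numeric matrix with a
#'   `modality` attribute).
#' @examples
#' m <- modality_matrix("m1", matrix(rnorm(6), 3, 2,
#'   dimnames = list(c("s1", "s2", "s3"), c("g1", "g2"))))
#' dim(m)
#' @export
modality_matrix <- function(name, values) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stopf("modality `name` must be a non-empty string")
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("modality '%s': `values` must be a numeric matrix", name)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("modality '%s': `values` needs sample row names and feature column names",
          name)
  }
  if (anyDuplicated(rownames(values))) {
    stopf("modality '%s': duplicate sample identifiers: %s", name,
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stopf("modality '%s': duplicate feature identifiers", name)
  }
  bad <- which(!is.finite(values))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(values))
    stopf("modality '%s': non-finite value at sample '%s', feature '%s'",
          name, rownames(values)[i[1L]], colnames(values)[i[2L]])
  }
  structure(values, modality = name, class = c("modality_matrix", "matrix", "array"))
}

modality_name <- function(x) attr(x, "modality")

#' @export
print.modality_matrix <- function(x, ...) {
  cat(sprintf("<modality '%s'> %d samples x %d features\n",
              modality_name(x), nrow(x), ncol(x)))
  invisible(x)
}

#' Construct a multi-omics dataset
#'
#' Bundles aligned modality matrices with optional binary class labels and
#' survival information. All present modalities must share an identical sample
#' ordering. The presence mask records which of the possible modalities exist
#' in this source: a modality that is entirely absent (the "unshared" modality
#' of a target cohort) has `presence = FALSE` and no matrix.
#'
#' @param modalities Named list of [modality_matrix()] objects with identical
#'   row (sample) ordering.
#' @param labels Optional integer vector in `{0, 1}` (1 = positive class, e.g.
#'   short-term survivor), one per sample, named or in sample order.
#' @param survival Optional data frame with columns `sample_id`, `days`
#'   (non-negative), `event` (1 = death observed, 0 = censored).
#' @param presence Optional named logical covering every *possible* modality
#'   (including absent ones). Defaults to `TRUE` for each supplied modality.
#' @return An object of class `multiomics`.
#' @export
multiomics <- function(modalities, labels = NULL, survival = NULL,
                       presence = NULL) {
  if (!is.list(modalities) || length(modalities) == 0L) {
    stopf("`modalities` must be a non-empty list of modality matrices")
  }
  if (is.null(names(modalities)) || any(!nzchar(names(modalities)))) {
    names(modalities) <- vapply(modalities, modality_name, character(1L))
  }
  ids <- rownames(modalities[[1L]])
  for (m in modalities) {
    if (!inherits(m, "modality_matrix")) {
      stopf("all elements of `modalities` must be modality_matrix objects")
    }
    if (!identical(rownames(m), ids)) {
      stopf("modality '%s' has a different sample ordering; use align_samples()",
            modality_name(m))
    }
  }
  n <- length(ids)
  if (!is.null(labels)) {
    if (!is.null(names(labels))) labels <- labels[ids]
    if (length(labels) != n || anyNA(labels)) {
      stopf("`labels` must cover every sample exactly once")
    }
    assert_binary(labels, "labels")
    labels <- as.integer(labels)
    names(labels) <- ids
  }
  if (!is.null(survival)) {
    req <- c("sample_id", "days", "event")
    if (!is.data.frame(survival) || !all(req %in% names(survival))) {
      stopf("`survival` must be a data frame with columns sample_id, days, event")
    }
    survival <- survival[match(ids, survival$sample_id), req]
    if (anyNA(survival$sample_id)) stopf("`survival` missing some samples")
    if (any(survival$days < 0)) stopf("survival `days` must be non-negative")
    assert_binary(survival$event, "event")
    rownames(survival) <- NULL
  }
  if (is.null(presence)) {
    presence <- stats::setNames(rep(TRUE, length(modalities)), names(modalities))
  }
  if (is.null(names(presence)) || !all(names(modalities) %in% names(presence))) {
    stopf("`presence` must be a named logical covering every present modality")
  }
  structure(
    list(modalities = modalities, labels = labels, survival = survival,
         presence = presence, sample_ids = ids),
    class = "multiomics"
  )
}

#' @export
print.multiomics <- function(x, ...) {
  cat(sprintf("<multiomics> %d samples, %d/%d modalities present\n",
              length(x$sample_ids), length(x$modalities), length(x$presence)))
  for (nm in names(x$presence)) {
    if (isTRUE(x$presence[[nm]])) {
      cat(sprintf("  %s: %d features\n", nm, ncol(x$modalities[[nm]])))
    } else {
      cat(sprintf("  %s: absent in this source\n", nm))
    }
  }
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d positive / %d negative\n",
                sum(x$labels == 1L), sum(x$labels == 0L)))
  }
  invisible(x)
}

#' Number of samples in a multi-omics dataset
#' @param dataset A [multiomics()] object.
#' @return Integer sample count.
#' @export
n_samples <- function(dataset) length(dataset$sample_ids)

#' Restrict a multi-omics dataset to a subset of samples
#'
#' @param dataset A [multiomics()] object.
#' @param idx Integer indices or sample identifiers.
#' @return A [multiomics()] object containing the selected samples in the
#'   requested order.
#' @export
subset_samples <- function(dataset, idx) {
  if (is.character(idx)) idx <- match(idx, dataset$sample_ids)
  if (anyNA(idx) || any(idx < 1L) || any(idx > n_samples(dataset))) {
    stopf("`idx` out of range")
  }
  mods <- lapply(dataset$modalities, function(m) {
    modality_matrix(modality_name(m), m[idx, , drop = FALSE])
  })
  surv <- if (!is.null(dataset$survival)) dataset$survival[idx, , drop = FALSE]
  multiomics(mods, labels = dataset$labels[idx], survival = surv,
             presence = dataset$presence)
}

#' Align modalities on their common samples
#'
#' Restricts a collection of modality matrices (and optional label / survival
#' tables) to the intersection of their sample identifiers, in a canonical
#' (sorted) order so that the result does not depend on input ordering.
#' Dropped identifiers are reported via a message.
#'
#' @param modalities List of [modality_matrix()] objects.
#' @param labels Optional named vector or two-column data frame
#'   (`sample_id`, `class`) of binary labels.
#' @param survival Optional data frame (`sample_id`, `days`, `event`).
#' @param quiet Suppress the dropped-sample message.
#' @return A [multiomics()] dataset on the common samples.
#' @export
align_samples <- function(modalities, labels = NULL, survival = NULL,
                          quiet = FALSE) {
  if (length(modalities) < 1L) stopf("need at least one modality")
  if (any(vapply(modalities, nrow, integer(1L)) < 1L)) {
    stopf("every modality needs at least one sample")
  }
  id_sets <- lapply(modalities, rownames)
  common <- Reduce(intersect, id_sets)
  if (!is.null(labels) && is.data.frame(labels)) {
    lab <- stats::setNames(labels[[2L]], labels[[1L]])
    labels <- lab
  }
  if (!is.null(labels)) common <- intersect(common, names(labels))
  if (length(common) == 0L) {
    stopf("no samples shared by all inputs (empty intersection)")
  }
  common <- sort(common)
  dropped <- setdiff(unique(unlist(id_sets)), common)
  if (length(dropped) && !quiet) {
    message(sprintf("align_samples: dropped %d sample(s) not shared by all inputs",
                    length(dropped)))
  }
  mods <- lapply(modalities, function(m) {
    modality_matrix(modality_name(m), m[common, , drop = FALSE])
  })
  names(mods) <- vapply(mods, modality_name, character(1L))
  if (!is.null(survival)) survival <- survival[survival$sample_id %in% common, ]
  multiomics(mods, labels = if (!is.null(labels)) labels[common],
             survival = survival)
}

#' Z-score normalize every modality along its feature dimension
#'
#' Each feature (column) is centered and scaled using mean and population
#' standard deviation computed on the `stats_from` rows only; the remaining
#' rows are transformed with those same statistics. The default of computing
#' statistics on the training rows prevents information leaking from a test
#' set into the scaling; passing all rows reproduces a global normalization.
#' Features that are constant on `stats_from` are mapped to zero everywhere.
#'
#' @param dataset A [multiomics()] object.
#' @param stats_from Integer indices of the rows used to compute the per-feature
#'   statistics (default: all rows).
#' @return The dataset with normalized modalities; the fitted statistics are
#'   attached as the `"norm_stats"` attribute (a per-modality list with
#'   `center`, `scale`, `constant`).
#' @export
zscore_normalize <- function(dataset, stats_from = seq_len(n_samples(dataset))) {
  if (length(stats_from) == 0L) stopf("`stats_from` must be non-empty")
  if (any(stats_from < 1L) || any(stats_from > n_samples(dataset))) {
    stopf("`stats_from` indices out of range")
  }
  stats <- list()
  mods <- lapply(dataset$modalities, function(m) {
    sub <- m[stats_from, , drop = FALSE]
    mu <- colMeans(sub)
    # population (ddof = 0) standard deviation
    sd0 <- sqrt(colMeans(sweep(sub, 2L, mu)^2))
    const <- sd0 <= 0
    out <- sweep(unclass(m), 2L, mu)
    out <- sweep(out, 2L, ifelse(const, 1, sd0), "/")
    if (any(const)) out[, const] <- 0
    stats[[modality_name(m)]] <<- list(center = mu, scale = sd0, constant = const)
    modality_matrix(modality_name(m), out)
  })
  out <- multiomics(mods, labels = dataset$labels, survival = dataset$survival,
                    presence = dataset$presence)
  attr(out, "norm_stats") <- stats
  out
}

#' Apply previously fitted normalization statistics to a dataset
#'
#' Used at inference time: a target cohort is scaled with the reference
#' cohort's statistics (stored in a model checkpoint).
#'
#' @param dataset A [multiomics()] object.
#' @param stats The `"norm_stats"` attribute produced by [zscore_normalize()].
#' @return The normalized dataset.
#' @export
apply_normalization <- function(dataset, stats) {
  mods <- lapply(dataset$modalities, function(m) {
    s <- stats[[modality_name(m)]]
    if (is.null(s)) return(m)
    out <- sweep(unclass(m), 2L, s$center)
    out <- sweep(out, 2L, ifelse(s$constant, 1, s$scale), "/")
    if (any(s$constant)) out[, s$constant] <- 0
    modality_matrix(modality_name(m), out)
  })
  multiomics(mods, labels = dataset$labels, survival = dataset$survival,
             presence = dataset$presence)
}

#' Split into a reference source and a target source with a missing modality
#'
#' Emulates the partially coupled two-source setting: a fraction of samples is
#' held out as the target cohort and the listed modalities are removed from it
#' entirely (matrix dropped, presence mask set to `FALSE`). The reference
#' cohort keeps every modality. The holdout size is `floor(test_fraction * n)`
#' and, by default, the draw is stratified by class so that severely
#' imbalanced cohorts still yield both classes in the target set.
#'
#' @param dataset A labeled [multiomics()] object.
#' @param test_fraction Fraction of samples assigned to the target source,
#'   in (0, 1). Default 0.36.
#' @param missing_in_test Character vector of modality names removed from the
#'   target source.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param stratify Stratify the draw by class label (default `TRUE`).
#' @return A list with elements `reference` and `target` ([multiomics()]
#'   objects) and `plan` (train/test indices, fraction, missing set, seed).
#' @export
make_missing_modality_split <- function(dataset, test_fraction = 0.36,
                                        missing_in_test = "m2", seed = 1L,
                                        stratify = TRUE) {
  assert_scalar_number(test_fraction, "test_fraction", 0, 1, strict = TRUE)
  if (is.null(dataset$labels)) stopf("dataset must be labeled before splitting")
  missing_in_test <- as.character(missing_in_test)
  unknown <- setdiff(missing_in_test, names(dataset$modalities))
  if (length(unknown)) {
    stopf("modalities not in dataset: %s", paste(unknown, collapse = ", "))
  }
  n <- n_samples(dataset)
  n_test <- floor(test_fraction * n)
  if (n_test < 1L || n_test >= n) stopf("test fraction leaves an empty set")
  test_idx <- with_seed(seed, {
    if (stratify) {
      y <- dataset$labels
      classes <- sort(unique(y))
      # largest-remainder apportionment so per-class counts total n_test
      quota <- n_test * tabulate(match(y, classes)) / n
      base <- floor(quota)
      rem <- n_test - sum(base)
      if (rem > 0) {
        extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
      }
      unlist(lapply(seq_along(classes), function(k) {
        pool <- which(y == classes[k])
        sample(pool, min(base[k], length(pool)))
      }), use.names = FALSE)
    } else {
      sample(n, n_test)
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  reference <- subset_samples(dataset, train_idx)
  target <- subset_samples(dataset, test_idx)
  target$modalities[missing_in_test] <- NULL
  target$presence[missing_in_test] <- FALSE
  list(
    reference = reference,
    target = target,
    plan = list(train_indices = train_idx, test_indices = test_idx,
                test_fraction = test_fraction,
                missing_in_test = missing_in_test, seed = as.integer(seed),
                stratified = stratify)
  )
}
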