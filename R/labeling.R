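# Short-/long-term survivor labeling: a simplified consensus-clustering
# stand-in (multi-modality k-means agreement + hierarchical co-clustering),
# the survival-based manual-correction rule, and Kaplan-Meier / log-rank
# validation. Externally supplied labels remain the primary path; this module
# generates them when none exist.

#' Consensus clustering across modalities
#'
#' A deliberately simple stand-in for full perturbation clustering: for each
#' candidate k, every modality is partitioned with k-means (identically seeded
#' per modality, so identical modalities yield identical partitions); the k
#' maximizing the mean pairwise adjusted Rand agreement between modality
#' partitions is chosen; final labels come from average-linkage hierarchical
#' clustering of the co-clustering dissimilarity, cut at the chosen k. With a
#' single modality the agreement is computed between seeded k-means restarts
#' (a stability score) instead.
#'
#' @param dataset A [multiomics()] with at least one modality.
#' @param k_candidates Candidate cluster counts (default `2:5`).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param n_restarts Restarts used for the single-modality stability score.
#' @return List with `cluster` (per-sample integer labels in `1..k`),
#'   `k` (chosen number of clusters), and `agreement` (per-k mean pairwise
#'   adjusted Rand index).
#' @export
consensus_cluster <- function(dataset, k_candidates = 2:5, seed = 1L,
                              n_restarts = 5L) {
  n <- n_samples(dataset)
  if (n < max(k_candidates)) {
    stopf("need at least %d samples for k up to %d", max(k_candidates),
          max(k_candidates))
  }
  mods <- lapply(dataset$modalities, unclass)
  agreement <- stats::setNames(numeric(length(k_candidates)),
                               as.character(k_candidates))
  partitions <- list()
  for (ki in seq_along(k_candidates)) {
    k <- k_candidates[ki]
    parts <- if (length(mods) > 1L) {
      lapply(mods, function(m) {
        # same derived seed for every modality at this k, so identical data
        # give identical partitions
        with_seed(seed + k, stats::kmeans(m, centers = k, nstart = 10L)$cluster)
      })
    } else {
      lapply(seq_len(n_restarts), function(r) {
        with_seed(seed + k * 131L + r,
                  stats::kmeans(mods[[1L]], centers = k, nstart = 1L)$cluster)
      })
    }
    pairs <- utils::combn(length(parts), 2L)
    agreement[ki] <- mean(vapply(seq_len(ncol(pairs)), function(j) {
      mclust::adjustedRandIndex(parts[[pairs[1L, j]]], parts[[pairs[2L, j]]])
    }, numeric(1L)))
    partitions[[ki]] <- parts
  }
  best <- which.max(agreement)
  k <- k_candidates[best]
  # co-clustering frequency across modality partitions -> dissimilarity
  co <- matrix(0, n, n)
  for (p in partitions[[best]]) co <- co + outer(p, p, `==`)
  co <- co / length(partitions[[best]])
  hc <- stats::hclust(stats::as.dist(1 - co), method = "average")
  cl <- stats::cutree(hc, k = k)
  names(cl) <- dataset$sample_ids
  list(cluster = cl, k = k, agreement = agreement)
}

#' Correct cluster-derived survivor labels against observed survival
#'
#' Implements the manual-correction rule for outliers: a sample labeled
#' long-term that died (`event = 1`) before `t_short` days is flipped to
#' short-term; a sample labeled short-term that survived past `t_long` days
#' (dead or censored — either way it lived that long) is flipped to
#' long-term. Censored samples below `t_long` are never flipped to long-term:
#' censoring short of the threshold is insufficient evidence. The operation
#' is idempotent and every flip is logged.
#'
#' @param labels Integer 0/1 vector, 1 = short-term survivor, named by sample
#'   or in `survival` order.
#' @param survival Data frame `sample_id`, `days`, `event`.
#' @param t_short Days below which an observed death contradicts a long-term
#'   label (default 365).
#' @param t_long Days beyond which survival contradicts a short-term label
#'   (default 1095).
#' @return List with `labels` (corrected) and `changes` (data frame
#'   `sample_id`, `from`, `to`, `days`, `event`, `reason`).
#' @export
correct_labels_by_survival <- function(labels, survival, t_short = 365,
                                       t_long = 1095) {
  if (t_short >= t_long) stopf("`t_short` must be below `t_long`")
  assert_binary(labels, "labels")
  if (!is.null(names(labels))) {
    labels <- labels[survival$sample_id]
  } else if (length(labels) != nrow(survival)) {
    stopf("`labels` and `survival` lengths differ")
  }
  labels <- as.integer(labels)
  to_short <- labels == 0L & survival$event == 1 & survival$days < t_short
  to_long <- labels == 1L & survival$days > t_long
  changes <- rbind(
    if (any(to_short)) data.frame(
      sample_id = survival$sample_id[to_short], from = 0L, to = 1L,
      days = survival$days[to_short], event = survival$event[to_short],
      reason = sprintf("died before %g days while labeled long-term", t_short)),
    if (any(to_long)) data.frame(
      sample_id = survival$sample_id[to_long], from = 1L, to = 0L,
      days = survival$days[to_long], event = survival$event[to_long],
      reason = sprintf("survived past %g days while labeled short-term", t_long))
  )
  labels[to_short] <- 1L
  labels[to_long] <- 0L
  names(labels) <- survival$sample_id
  if (is.null(changes)) {
    changes <- data.frame(sample_id = character(0L), from = integer(0L),
                          to = integer(0L), days = numeric(0L),
                          event = numeric(0L), reason = character(0L))
  }
  list(labels = labels, changes = changes)
}

#' Kaplan-Meier curves and log-rank test for two survivor groups
#'
#' Product-limit estimate per group and the two-group log-rank test,
#' validating that a candidate labeling separates survival.
#'
#' @param labels 0/1 group labels (1 = short-term), named by sample or in
#'   `survival` order.
#' @param survival Data frame `sample_id`, `days`, `event`.
#' @return List with `km` (data frame `time`, `survival`, `group` of the
#'   stepwise estimates), `fit` (the `survfit` object), `statistic` (log-rank
#'   chi-square), `p_value`, and `cox` (hazard ratio of group 1 vs 0 from a
#'   univariate Cox model, `NA` if it fails to fit).
#' @export
km_logrank <- function(labels, survival) {
  assert_binary(labels, "labels")
  if (!is.null(names(labels))) labels <- labels[survival$sample_id]
  if (length(labels) != nrow(survival)) {
    stopf("`labels` and `survival` lengths differ")
  }
  group <- factor(labels, levels = c(0, 1), labels = c("long", "short"))
  if (any(table(group) == 0L)) stopf("both groups must be non-empty")
  df <- data.frame(days = survival$days, event = survival$event, group = group)
  if (any(tapply(df$event, df$group, sum) == 0)) {
    stopf("each group needs at least one observed event for the log-rank test")
  }
  fit <- survival::survfit(survival::Surv(days, event) ~ group, data = df)
  sdiff <- survival::survdiff(survival::Surv(days, event) ~ group, data = df)
  p <- stats::pchisq(sdiff$chisq, df = 1L, lower.tail = FALSE)
  km <- data.frame(
    time = fit$time, survival = fit$surv,
    group = rep(sub("group=", "", names(fit$strata)), fit$strata))
  hr <- tryCatch({
    cx <- survival::coxph(survival::Surv(days, event) ~ group, data = df)
    unname(exp(stats::coef(cx)))
  }, error = function(e) NA_real_, warning = function(w) NA_real_)
  list(km = km, fit = fit, statistic = unname(sdiff$chisq), p_value = p,
       cox = hr)
}

#' Generate survivor labels for a dataset
#'
#' Convenience pipeline: consensus clustering (restricted to two groups by
#' mapping the chosen clustering onto its two dominant branches when k > 2 is
#' selected), orientation of the clusters by median survival (the
#' shorter-lived cluster becomes the short-term group), then the
#' survival-based correction rule.
#'
#' @param dataset A [multiomics()] with a survival table attached.
#' @param k_candidates Candidate cluster counts (default `2:5`).
#' @param seed Integer seed.
#' @param t_short,t_long Correction thresholds in days (see
#'   [correct_labels_by_survival()]).
#' @return List with `labels`, `changes`, `k`, `validation` (the
#'   [km_logrank()] output on the corrected labels).
#' @export
generate_labels <- function(dataset, k_candidates = 2:5, seed = 1L,
                            t_short = 365, t_long = 1095) {
  if (is.null(dataset$survival)) stopf("dataset has no survival table")
  cc <- consensus_cluster(dataset, k_candidates, seed)
  cl <- cc$cluster
  if (cc$k > 2L) {
    # collapse to the two largest branches' sides via a 2-cut of the same tree
    big <- names(sort(table(cl), decreasing = TRUE))[1:2]
    cl <- ifelse(cl == big[1L], 1L, 2L)
  }
  med <- tapply(dataset$survival$days, cl[dataset$survival$sample_id], stats::median)
  short_cluster <- as.integer(names(med)[which.min(med)])
  labels <- stats::setNames(as.integer(cl == short_cluster), names(cl))
  corrected <- correct_labels_by_survival(labels, dataset$survival,
                                          t_short, t_long)
  validation <- km_logrank(corrected$labels, dataset$survival)
  list(labels = corrected$labels, changes = corrected$changes, k = cc$k,
       validation = validation)
}
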