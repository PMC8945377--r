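make_blob_dataset <- function(n_per = 20L, sep = 10, seed = 13L) {
  # two well-separated blobs visible in every modality
  set.seed(seed)
  n <- 2L * n_per
  ids <- sprintf("s%03d", seq_len(n))
  centers <- rep(c(0, sep), each = n_per)
  mods <- lapply(c(m1 = 5L, m2 = 8L, m3 = 3L), function(d) {
    matrix(rnorm(n * d, mean = centers), n, d,
           dimnames = list(ids, sprintf("f%d", seq_len(d))))
  })
  mods <- Map(modality_matrix, names(mods), mods)
  list(dataset = multiomics(mods), truth = rep(c(0L, 1L), each = n_per))
}

test_that("consensus clustering recovers well-separated blobs at k = 2", {
  blob <- make_blob_dataset()
  cc <- consensus_cluster(blob$dataset, k_candidates = 2:5, seed = 3)
  expect_identical(cc$k, 2L)
  expect_gt(mclust::adjustedRandIndex(cc$cluster, blob$truth), 0.95)
})

test_that("identical modalities agree perfectly at every k", {
  blob <- make_blob_dataset(n_per = 15L)
  m <- blob$dataset$modalities$m1
  ds <- multiomics(list(m1 = m, m2 = modality_matrix("m2", unclass(m)),
                        m3 = modality_matrix("m3", unclass(m))))
  cc <- consensus_cluster(ds, k_candidates = 2:4, seed = 3)
  expect_equal(unname(cc$agreement), rep(1, 3), tolerance = 1e-12)
})

test_that("consensus clustering is deterministic given the seed", {
  blob <- make_blob_dataset()
  a <- consensus_cluster(blob$dataset, seed = 11)
  b <- consensus_cluster(blob$dataset, seed = 11)
  expect_identical(a$cluster, b$cluster)
  expect_identical(a$k, b$k)
  expect_error(consensus_cluster(subset_samples(blob$dataset, 1:3),
                                 k_candidates = 2:5), "at least 5")
})

test_that("survival correction flips contradicted labels and is idempotent", {
  surv <- data.frame(sample_id = c("a", "b", "c", "d"),
                     days = c(203, 400, 1200, 100),
                     event = c(1, 1, 0, 0))
  # a: labeled long-term but died at day 203 -> flipped to short-term
  # b: short-term, died at 400 (between thresholds) -> kept
  # c: short-term but survived past 1095 (censored) -> flipped to long-term
  # d: long-term, censored at day 100 -> kept (insufficient evidence)
  labels <- c(a = 0L, b = 1L, c = 1L, d = 0L)
  res <- correct_labels_by_survival(labels, surv, t_short = 365, t_long = 1095)
  expect_identical(unname(res$labels), c(1L, 1L, 0L, 0L))
  expect_identical(sort(res$changes$sample_id), c("a", "c"))

  # idempotence
  res2 <- correct_labels_by_survival(res$labels, surv, 365, 1095)
  expect_identical(res2$labels, res$labels)
  expect_identical(nrow(res2$changes), 0L)

  # consistent labels: zero flips
  ok <- correct_labels_by_survival(c(a = 1L, b = 1L, c = 0L, d = 0L), surv)
  expect_identical(nrow(ok$changes), 0L)
  expect_error(correct_labels_by_survival(labels, surv, 1000, 500), "t_short")
})

test_that("log-rank separates groups and matches a hand computation", {
  # forced separation: all deaths in group 1 at day 100, group 0 at day 1000
  surv <- data.frame(sample_id = sprintf("s%d", 1:60),
                     days = rep(c(100, 1000), each = 30),
                     event = 1)
  labels <- rep(c(1L, 0L), each = 30)
  res <- km_logrank(labels, surv)
  expect_lt(res$p_value, 0.001)

  # textbook log-rank on a small fixture: O-E and V computed by hand
  surv2 <- data.frame(sample_id = sprintf("t%d", 1:6),
                      days = c(1, 2, 3, 4, 5, 6),
                      event = c(1, 1, 1, 1, 1, 1))
  g <- c(1L, 0L, 1L, 0L, 1L, 0L)
  hand_logrank <- function(days, event, group) {
    times <- sort(unique(days[event == 1]))
    O <- 0; E <- 0; V <- 0
    for (tt in times) {
      at_risk <- days >= tt
      n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
      d <- sum(days == tt & event == 1)
      d1 <- sum(days == tt & event == 1 & group == 1)
      O <- O + d1
      E <- E + d * n1 / n
      if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
  }
  res2 <- km_logrank(g, surv2)
  expect_equal(res2$statistic, hand_logrank(surv2$days, surv2$event, g),
               tolerance = 1e-8)

  # group-label swap leaves the statistic unchanged
  expect_equal(km_logrank(1L - g, surv2)$statistic, res2$statistic,
               tolerance = 1e-10)
})

test_that("KM curves are valid survival estimates", {
  set.seed(3)
  surv <- data.frame(sample_id = sprintf("s%d", 1:40),
                     days = c(rexp(20, 1 / 300), rexp(20, 1 / 1500)),
                     event = 1)
  labels <- rep(c(1L, 0L), each = 20)
  res <- km_logrank(labels, surv)
  for (grp in unique(res$km$group)) {
    s <- res$km$survival[res$km$group == grp]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(max(s), 1)
    # no censoring: the estimate reaches zero after the last event
    expect_equal(s[length(s)], 0)
  }
  # identical survival in both groups: statistic near zero
  surv_same <- data.frame(sample_id = sprintf("s%d", 1:40),
                          days = rep(c(100, 200, 300, 400), each = 10),
                          event = 1)
  # alternate groups within each death time: identical survival experience
  res_null <- km_logrank(rep(c(0L, 1L), 20), surv_same)
  expect_lt(res_null$statistic, 0.2)
  expect_gt(res_null$p_value, 0.5)
  expect_error(km_logrank(rep(1L, 40), surv), "non-empty")
})

test_that("label generation pipeline orients clusters by survival", {
  blob <- make_blob_dataset(n_per = 20L)
  # blob group 1 dies early, group 0 late
  set.seed(9)
  surv <- data.frame(sample_id = blob$dataset$sample_ids,
                     days = ifelse(blob$truth == 1, rexp(40, 1 / 200),
                                   rexp(40, 1 / 2000)),
                     event = 1)
  ds <- multiomics(blob$dataset$modalities, survival = surv)
  res <- generate_labels(ds, seed = 5)
  # short-term (1) should be the early-dying blob
  expect_gt(mean(res$labels[blob$truth == 1]), 0.8)
  expect_lt(mean(res$labels[blob$truth == 0]), 0.2)
  expect_lt(res$validation$p_value, 0.001)
})
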