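test_that("reconstruction loss follows the summed squared-error definition", {
  x <- list(matrix(c(1, 2), 1, 2))
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(x, list(matrix(0, 1, 2))), 5)  # 1^2 + 2^2
  # additivity over modalities
  expect_equal(reconstruction_loss(c(x, x), list(matrix(0, 1, 2),
                                                 matrix(0, 1, 2))), 10)
  # batch averaging: the same per-sample error over 4 samples is unchanged
  x4 <- list(matrix(rep(c(1, 2), each = 4), 4, 2))
  expect_equal(reconstruction_loss(x4, list(matrix(0, 4, 2))), 5)
  expect_equal(reconstruction_loss(x4, list(matrix(0, 4, 2)), reduce = "sum"), 20)
  expect_error(reconstruction_loss(x, list(matrix(0, 2, 2))), "shape")
})

test_that("cross entropy matches its closed form, symmetric and clamped", {
  expect_equal(classification_loss(1, 0.5), log(2), tolerance = 1e-9)
  expect_equal(classification_loss(0, 0.5), log(2), tolerance = 1e-9)
  expect_lt(classification_loss(1, 1 - 1e-9), 1e-6)
  # saturated wrong predictions are clamped to a finite loss
  expect_true(is.finite(classification_loss(1, 0)))
  expect_equal(classification_loss(1, 0), -log(1e-7))
  expect_equal(classification_loss(c(1, 0), c(0.8, 0.3)),
               mean(c(-log(0.8), -log(0.7))))
  # positive-class reweighting scales only the positive terms
  expect_equal(classification_loss(1, 0.5, pos_weight = 2), 2 * log(2))
  expect_equal(classification_loss(0, 0.5, pos_weight = 2), log(2))
})

test_that("training history satisfies the joint-loss identity at every epoch", {
  sim <- tiny_dataset()
  ds <- zscore_normalize(sim$dataset)
  cfg <- train_config(epochs = 8, alpha = 1.5, beta = 0.5)
  fit <- train_fusion(build_cfa(sapply(ds$modalities, ncol), tiny_spec()),
                      ds, cfg)
  expect_identical(nrow(fit$history), 8L)
  expect_equal(fit$history$l_joint,
               1.5 * fit$history$l_rec + 0.5 * fit$history$l_ce,
               tolerance = 1e-10)
  expect_true(all(fit$history$l_rec >= 0))
  expect_true(all(fit$history$l_ce >= 0))
})

test_that("training is deterministic given the seed", {
  sim <- tiny_dataset()
  ds <- zscore_normalize(sim$dataset)
  run <- function() {
    train_fusion(build_cfa(sapply(ds$modalities, ncol), tiny_spec(), seed = 5),
                 ds, train_config(epochs = 5, seed = 5))
  }
  a <- run(); b <- run()
  expect_equal(a$history$l_joint, b$history$l_joint, tolerance = 1e-6)
  expect_identical(a$model$clf$blocks[[1]]$W, b$model$clf$blocks[[1]]$W)

  # mini-batch shuffling is seeded too
  run_mb <- function() {
    train_fusion(build_cfa(sapply(ds$modalities, ncol), tiny_spec(), seed = 5),
                 ds, train_config(epochs = 5, seed = 5, batch_size = 16))
  }
  expect_equal(run_mb()$history$l_joint, run_mb()$history$l_joint)
})

test_that("loss weights gate the gradient flow to their heads", {
  sim <- tiny_dataset()
  ds <- zscore_normalize(sim$dataset)
  dims <- sapply(ds$modalities, ncol)

  # beta = 0: the classifier head receives no gradient and never moves
  m0 <- build_cfa(dims, tiny_spec(), seed = 2)
  fit <- train_fusion(m0, ds, train_config(epochs = 3, beta = 0))
  expect_identical(fit$model$clf$blocks[[1]]$W, m0$clf$blocks[[1]]$W)
  expect_identical(fit$model$clf$blocks[[1]]$b, m0$clf$blocks[[1]]$b)

  # alpha = 0: the decoders receive no gradient and never move
  m1 <- build_cfa(dims, tiny_spec(), seed = 2)
  fit1 <- train_fusion(m1, ds, train_config(epochs = 3, alpha = 0))
  for (nm in names(m1$threads)) {
    expect_identical(fit1$model$threads[[nm]]$dec$blocks[[1]]$W,
                     m1$threads[[nm]]$dec$blocks[[1]]$W)
  }
})

test_that("joint training reduces the loss on learnable data", {
  sim <- tiny_dataset(n = 80L)
  ds <- zscore_normalize(sim$dataset)
  fit <- train_fusion(build_cfa(sapply(ds$modalities, ncol), tiny_spec()),
                      ds, train_config(epochs = 30))
  expect_lt(fit$history$l_joint[30L], fit$history$l_joint[1L])
})

test_that("IFA training requires the unshared modality in the reference data", {
  sim <- tiny_dataset()
  ds <- zscore_normalize(sim$dataset)
  ds$modalities$m2 <- NULL
  ds$presence["m2"] <- FALSE
  ifa <- build_ifa(c(m1 = 12L, m3 = 6L), d2 = 18L, tiny_spec())
  expect_error(train_fusion(ifa, ds), "m2")
})

test_that("diverging training aborts naming the epoch", {
  sim <- tiny_dataset()
  ds <- zscore_normalize(sim$dataset)
  expect_error(
    train_fusion(build_cfa(sapply(ds$modalities, ncol), tiny_spec()),
                 ds, train_config(learning_rate = 1e154, epochs = 10)),
    "epoch \\d+")
})

test_that("the experiment driver returns one metric row per run and variant", {
  sim <- tiny_dataset(n = 50L)
  rep <- run_experiment(sim$dataset, variants = c("IFA", "CFA-2M"),
                        n_runs = 2, base_seed = 1,
                        config = train_config(epochs = 3),
                        spec = tiny_spec())
  expect_identical(nrow(rep$per_run_metrics), 4L)
  expect_setequal(unique(rep$per_run_metrics$variant), c("IFA", "CFA-2M"))
  expect_true(all(rep$per_run_metrics$balanced_accuracy >= 0 &
                  rep$per_run_metrics$balanced_accuracy <= 1))
  expect_identical(nrow(rep$comparisons), 1L)
  # same driver call reproduces identical metrics
  rep2 <- run_experiment(sim$dataset, variants = c("IFA", "CFA-2M"),
                         n_runs = 2, base_seed = 1,
                         config = train_config(epochs = 3),
                         spec = tiny_spec())
  expect_identical(rep$per_run_metrics, rep2$per_run_metrics)
})

test_that("the k-fold scheme partitions samples into disjoint folds", {
  sim <- tiny_dataset(n = 50L)
  rep <- run_experiment(sim$dataset, variants = "SMA-m3", n_runs = 5,
                        base_seed = 2, config = train_config(epochs = 2),
                        spec = tiny_spec(), scheme = "kfold")
  expect_identical(nrow(rep$per_run_metrics), 5L)
})
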