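test_that("modality loading round-trips shape, values and orientation", {
  ids <- c("s1", "s2", "s3"); feats <- c("g1", "g2")
  vals <- c(1.5, -2.25, 3.125, 0.5, 10, -0.001)
  path <- write_temp_modality(vals, ids, feats)
  m <- load_modality(path, name = "m1")
  expect_s3_class(m, "modality_matrix")
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(rownames(m), ids)
  expect_identical(colnames(m), feats)

  # write -> load identity on values
  expect_equal(unclass(m)[ids, feats],
               matrix(vals, 3, 2, dimnames = list(ids, feats)),
               tolerance = 1e-12)

  # a transposed file read samples_in_cols gives the identical matrix
  tpath <- tempfile(fileext = ".tsv")
  tm <- modality_matrix("m1", t(unclass(m)))
  write_modality(tm, tpath)
  m2 <- load_modality(tpath, name = "m1", orientation = "samples_in_cols")
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-12)
})

test_that("non-numeric cells and duplicate ids are rejected, never imputed", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tg1\tg2", "s1\t1.0\tNA", "s2\t2.0\t3.0"), path)
  expect_error(load_modality(path), "non-numeric.*s1.*g2")

  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tg1", "s1\t1", "s1\t2"), path2)
  expect_error(load_modality(path2), "duplicate")

  expect_error(
    modality_matrix("m1", matrix(c(1, NaN), 1, 2,
                                 dimnames = list("s1", c("a", "b")))),
    "non-finite")
})

test_that("align_samples intersects ids order-independently and reports drops", {
  mk <- function(ids, name) {
    modality_matrix(name, matrix(seq_along(ids), length(ids), 1,
                                 dimnames = list(ids, "f1")))
  }
  expect_message(
    ds <- align_samples(list(mk(c("a", "b", "c"), "m1"),
                             mk(c("b", "c", "d"), "m2"))),
    "dropped 2")
  expect_identical(ds$sample_ids, c("b", "c"))

  # same id -> value mapping presented in different row orders
  mk2 <- function(ids, name) {
    vals <- stats::setNames(c(a = 10, b = 20, c = 30)[ids], ids)
    modality_matrix(name, matrix(vals, length(ids), 1,
                                 dimnames = list(ids, "f1")))
  }
  ds1 <- align_samples(list(mk2(c("a", "b", "c"), "m1"),
                            mk2(c("c", "a", "b"), "m2")), quiet = TRUE)
  ds2 <- align_samples(list(mk2(c("c", "b", "a"), "m1"),
                            mk2(c("a", "b", "c"), "m2")), quiet = TRUE)
  expect_identical(ds1$sample_ids, ds2$sample_ids)
  expect_equal(unclass(ds1$modalities$m2), unclass(ds2$modalities$m2))

  expect_error(align_samples(list(mk(c("a", "b"), "m1"), mk(c("x", "y"), "m2"))),
               "empty intersection")
})

test_that("z-scoring centers and scales with population sd, zeroes constants", {
  ids <- c("s1", "s2", "s3")
  m <- modality_matrix("m1", matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
                                    dimnames = list(ids, c("f1", "f2"))))
  ds <- multiomics(list(m1 = m))
  nd <- zscore_normalize(ds)
  expect_equal(nd$modalities$m1[, "f1"],
               c(s1 = -1.2247449, s2 = 0, s3 = 1.2247449), tolerance = 1e-6)
  expect_equal(unname(nd$modalities$m1[, "f2"]), c(0, 0, 0))
})

test_that("train-only statistics leave a test row at the train mean at zero", {
  ids <- sprintf("s%d", 1:4)
  m <- modality_matrix("m1", matrix(c(1, 3, 10, 2), 4, 1,
                                    dimnames = list(ids, "f1")))
  ds <- multiomics(list(m1 = m))
  nd <- zscore_normalize(ds, stats_from = 1:2)  # train mean 2, sd 1
  expect_equal(unname(nd$modalities$m1["s4", "f1"]), 0)
  expect_equal(unname(nd$modalities$m1["s3", "f1"]), 8)
})

test_that("z-scoring is idempotent for a fixed stats_from", {
  sim <- tiny_dataset()
  for (stats_from in list(seq_len(60L), 1:40)) {
    once <- zscore_normalize(sim$dataset, stats_from)
    twice <- zscore_normalize(once, stats_from)
    for (nm in names(once$modalities)) {
      expect_equal(unclass(twice$modalities[[nm]]),
                   unclass(once$modalities[[nm]]), tolerance = 1e-10)
    }
  }
})

test_that("missing-modality split sizes follow the floor rule", {
  sim <- tiny_dataset(n = 100L)
  sp <- make_missing_modality_split(sim$dataset, 0.36, "m2", seed = 1)
  expect_identical(n_samples(sp$target), 36L)
  expect_identical(n_samples(sp$reference), 64L)
  expect_false(sp$target$presence[["m2"]])
  expect_null(sp$target$modalities$m2)
  expect_true(all(c("m1", "m2", "m3") %in% names(sp$reference$modalities)))

  sim273 <- tiny_dataset(n = 273L)
  sp273 <- make_missing_modality_split(sim273$dataset, 0.36, "m2", seed = 1)
  expect_identical(n_samples(sp273$target), 98L)  # floor(0.36 * 273)
})

test_that("splits are deterministic, partition the samples, and stratify", {
  sim <- tiny_dataset(n = 50L)
  a <- make_missing_modality_split(sim$dataset, seed = 7)
  b <- make_missing_modality_split(sim$dataset, seed = 7)
  expect_identical(a$plan$test_indices, b$plan$test_indices)

  for (seed in 1:1000) {
    sp <- make_missing_modality_split(sim$dataset, 0.36, "m2", seed = seed)
    idx <- sort(c(sp$plan$train_indices, sp$plan$test_indices))
    expect_identical(idx, 1:50)
    expect_length(intersect(sp$plan$train_indices, sp$plan$test_indices), 0L)
  }

  # severe imbalance: stratification keeps both classes in the target set
  cfg <- simulation_config(120L, c(m1 = 4L, m2 = 4L, m3 = 4L),
                           prevalence = 20 / 273, seed = 5)
  imb <- simulate_multiomics(cfg)$dataset
  for (seed in 1:20) {
    sp <- make_missing_modality_split(imb, 0.36, "m2", seed = seed)
    expect_gt(sum(sp$target$labels == 1L), 0L)
    expect_gt(sum(sp$target$labels == 0L), 0L)
  }
  expect_error(make_missing_modality_split(sim$dataset, 1.2, "m2", seed = 1),
               "test_fraction")
})
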