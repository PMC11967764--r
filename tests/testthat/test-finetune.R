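# scaffold splitting, metrics, supervised fine-tuning

test_that("scaffold split keeps scaffold groups intact", {
  co <- fixture_corpus()
  sp <- scaffold_split(co$molecules, seed = 3)
  n <- length(co$molecules)
  expect_identical(sort(unname(unlist(sp))), seq_len(n))
  keys <- vapply(co$molecules, function(m)
    molssl:::murcko_scaffold_key(m$graph), "")
  for (k in unique(keys)) {
    members <- which(keys == k)
    in_split <- c(any(members %in% sp$train), any(members %in% sp$valid),
                  any(members %in% sp$test))
    expect_identical(sum(in_split), 1L)
  }
  expect_identical(scaffold_split(co$molecules, seed = 3), sp)
})

test_that("ten singleton scaffolds split 8/1/1 under default fractions", {
  smiles <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCNCC1", "c1ccoc1",
              "C1CCOC1", "c1ccsc1", "C1CCOCC1", "c1cncnc1", "C1CCCC1")
  mols <- lapply(smiles, parse_smiles)
  sp <- scaffold_split(mols, c(0.8, 0.1, 0.1), seed = 1)
  expect_identical(lengths(sp)[c("train", "valid", "test")],
                   c(train = 8L, valid = 1L, test = 1L))
})

test_that("single-scaffold datasets degenerate with a warning", {
  mols <- lapply(c("c1ccccc1C", "c1ccccc1O", "c1ccccc1N"), parse_smiles)
  expect_warning(sp <- scaffold_split(mols), "empty subset")
  expect_identical(sp$train, 1:3)
})

test_that("AUROC matches pair enumeration and the reference implementation", {
  # printed 4-point example: 3 of 4 positive-negative pairs concordant
  expect_identical(
    compute_metrics(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8),
                    "classification")$auroc, 0.75)
  # perfect ranking
  expect_identical(
    compute_metrics(c(0, 1, 0, 1), c(0.1, 0.9, 0.2, 0.8),
                    "classification")$auroc, 1)
  # cross-check against an independent implementation on random data
  set.seed(31)
  y <- rbinom(200, 1, 0.4)
  s <- runif(200) + 0.3 * y
  ours <- compute_metrics(y, s, "classification")$auroc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("regression metrics follow their definitions", {
  y <- c(1.5, 2, 3.5, 7)
  m <- compute_metrics(y, y, "regression")
  expect_identical(m$rmse, 0)
  expect_identical(m$mae, 0)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$spearman_r, 1)
  p <- y + c(1, -1, 1, -1)
  m2 <- compute_metrics(y, p, "regression")
  expect_equal(m2$rmse, 1)
  expect_equal(m2$mae, 1)
  expect_error(compute_metrics(c(1, 1, 1), c(0.1, 0.2, 0.3),
                               "classification"), "single-class")
})

test_that("label permutation gives chance-level AUROC", {
  set.seed(55)
  y <- rbinom(1000, 1, 0.5)
  s <- runif(1000)   # scores independent of labels
  expect_gt(compute_metrics(y, s, "classification")$auroc, 0.4)
  expect_lt(compute_metrics(y, s, "classification")$auroc, 0.6)
})

test_that("property datasets validate splits and labels", {
  co <- fixture_two_family()
  y <- generate_labels(co, "aromatic_ring")
  sp <- random_split(co$molecules, seed = 2)
  ds <- property_dataset(co$molecules, y, splits = sp)
  expect_identical(ds$task_type, "classification")
  bad <- sp; bad$train <- bad$train[-1]
  expect_error(property_dataset(co$molecules, y, splits = bad), "partition")
  expect_error(property_dataset(co$molecules, y + 2, "classification",
                                splits = sp), "0/1")
})

test_that("fine-tuning learns a structure-determined rule", {
  co <- fixture_two_family()      # aromatic vs saturated family
  y <- generate_labels(co, "aromatic_ring")
  ds <- property_dataset(co$molecules, y,
                         splits = random_split(co$molecules, seed = 4))
  enc <- init_encoder(fixture_encoder_config(seed = 8))
  res <- finetune(enc, ds, finetune_config(epochs = 15, batch_size = 64,
                                           learning_rate = 3e-3, seed = 9))
  expect_gte(res$metrics$test$auroc, 0.85)
  # reported metrics exist per split and come from held-out data only
  expect_named(res$metrics, c("train", "valid", "test"))
  # predictions on new molecules are probabilities
  p <- predict(res, co$molecules[1:5])
  expect_true(all(p >= 0 & p <= 1))
})

test_that("degenerate labels are handled per task type", {
  co <- fixture_two_family()
  sp <- random_split(co$molecules, seed = 4)
  y1 <- rep(1, length(co$molecules))
  expect_error(
    finetune(init_encoder(fixture_encoder_config()),
             property_dataset(co$molecules, y1, "classification",
                              splits = sp)),
    "single-class")
  # constant regression target is fit nearly exactly (head-only training)
  yc <- structure(rep(2.5, length(co$molecules)), task_type = "regression")
  res <- finetune(init_encoder(fixture_encoder_config(seed = 1)),
                  property_dataset(co$molecules, yc, splits = sp),
                  finetune_config(epochs = 40, learning_rate = 2e-2,
                                  freeze_encoder = TRUE, seed = 2))
  expect_lt(res$metrics$test$rmse, 0.25)
})
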