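# two well-separated Gaussian clusters per class, padded to a fixed dimension
toy_features <- function(n_per, centers, dim = 12, sd = 0.2, seed = 1) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_along(centers), function(k)
      matrix(rnorm(n_per * dim, centers[[k]], sd), n_per, dim, byrow = TRUE)))
    list(X = X, y = rep(names(centers), each = n_per))
  })
}

test_that("training fits separable data and is deterministic", {
  d <- toy_features(10, list(rare = rep(0, 12), sparse = rep(1, 12)))
  m1 <- texture_train(d$X, d$y, train_config(nrounds = 40))
  expect_identical(unname(predict(m1, d$X)), d$y)       # 100% on separable data

  m2 <- texture_train(d$X, d$y, train_config(nrounds = 40))
  held <- matrix(rnorm(5 * 12, 0.5, 1), 5, 12)
  expect_identical(predict(m1, held, type = "margin"),
                   predict(m2, held, type = "margin"))

  expect_error(texture_train(d$X, rep("rare", 20)), "degenerate training")
  expect_error(predict(m1, matrix(0, 1, 7)), "dimension mismatch")
  expect_identical(length(predict(m1, rep(0, 12))), 1L)  # totality on zeros
})

test_that("probabilities are coherent and ties break by class order", {
  d <- toy_features(8, list(rare = rep(0, 12), sparse = rep(2, 12),
                            dense = rep(4, 12)))
  m <- texture_train(d$X, d$y, train_config(nrounds = 30))
  p <- predict(m, d$X, type = "prob")
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)))
  expect_identical(colnames(p), c("rare", "sparse", "dense"))
  # an all-equal margin row (no trees yet) resolves to the first class
  m0 <- m
  m0$trees <- list()
  expect_identical(predict(m0, d$X[1, , drop = FALSE]), "rare")
})

test_that("serialization round-trips bit-exactly", {
  d <- toy_features(10, list(rare = rep(0, 12), sparse = rep(1.5, 12)))
  m <- texture_train(d$X, d$y, train_config(nrounds = 30))
  f <- withr::local_tempfile(fileext = ".bin")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict(m, d$X, type = "margin"),
                   predict(m2, d$X, type = "margin"))
  expect_true(file.exists(paste0(f, ".json")))
})

test_that("leave-one-out on separable clusters gives the identity matrix", {
  d <- toy_features(3, list(rare = rep(0, 12), sparse = rep(3, 12),
                            dense = rep(6, 12)), sd = 0.1)
  cm <- loo_evaluate(d$X, d$y, train_config(nrounds = 25), mode = "loo")
  expect_identical(attr(cm, "protocol"), "leave-one-out")
  expect_equal(unname(diag(cm)), c(3, 3, 3))
  expect_equal(sum(cm), 9)
})

test_that("confusion rows conserve class supports under cross-validation", {
  d <- toy_features(8, list(rare = rep(0, 10), sparse = rep(1, 10),
                            dense = rep(2, 10)), dim = 10, sd = 0.6, seed = 3)
  cm <- loo_evaluate(d$X, d$y, train_config(nrounds = 25), mode = "kfold", k = 4)
  expect_identical(attr(cm, "protocol"), "4-fold")
  expect_equal(unname(rowSums(cm)), c(8, 8, 8))
  expect_equal(sum(cm), 24)
})

test_that("grouped evaluation leaves whole groups out and reports absent classes", {
  d <- toy_features(6, list(rare = rep(0, 8), sparse = rep(2, 8)), dim = 8)
  groups <- rep(1:3, times = 4)
  cm <- loo_evaluate(d$X, d$y, train_config(nrounds = 20), groups = groups)
  expect_identical(attr(cm, "protocol"), "leave-one-group-out")
  expect_equal(sum(cm), 12)

  # dense appears in exactly one group: its folds must be reported, not fatal
  y2 <- d$y; y2[groups == 2 & y2 == "sparse"] <- "dense"
  cm2 <- loo_evaluate(d$X, y2, train_config(nrounds = 20), groups = groups)
  expect_gt(length(attr(cm2, "missing_class_folds")), 0)
  expect_equal(sum(cm2), 12)
})

test_that("label permutation permutes the confusion matrix consistently", {
  d <- toy_features(6, list(rare = rep(0, 10), sparse = rep(1, 10),
                            dense = rep(2, 10)), dim = 10, sd = 0.7, seed = 5)
  cm <- loo_evaluate(d$X, d$y, train_config(nrounds = 25), mode = "kfold", k = 3)
  map <- c(rare = "dense", sparse = "rare", dense = "sparse")
  cm2 <- loo_evaluate(d$X, unname(map[d$y]), train_config(nrounds = 25),
                      mode = "kfold", k = 3,
                      class_levels = unname(map[colnames(cm)]))
  expect_equal(unclass(cm2), unclass(cm), ignore_attr = TRUE)
})

test_that("an imbalanced synthetic benchmark reaches high held-out accuracy", {
  counts <- c(rare = 40, sparse = 20, dense = 8)  # Table-1-like prevalences, scaled
  classes <- c(rep("absent", 20), rep("spotted", 20), rep("dotted", 10),
               rep("complex", 10), rep("marbled", 8))
  patches <- lapply(seq_along(classes), function(i)
    generate_patch(classes[i], 72, rng_seed = 500 + i))
  X <- feature_matrix(patches)
  y <- texture_group(classes)
  cm <- loo_evaluate(X, y, train_config(nrounds = 80), mode = "kfold", k = 5)
  expect_gte(overall_accuracy(cm), 0.9)
  expect_equal(unname(rowSums(cm)[names(counts)]), unname(counts))
})
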