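#' Training configuration for the texture classifier
#'
#' Gradient-boosted decision trees with a multi-class softmax objective.
#' Defaults: 200 rounds of depth-4 trees at learning rate 0.1, L2 leaf
#' penalty 1 -- conventional settings for a few hundred samples with ~200
#' features. Training is deterministic (no row/column subsampling), so
#' `rng_seed` only seeds fold assignment in cross-validation.
#'
#' @param nrounds boosting rounds.
#' @param eta learning rate.
#' @param max_depth maximum tree depth.
#' @param lambda L2 regularization on leaf weights.
#' @param gamma minimum split gain.
#' @param min_child_weight minimum hessian sum per child.
#' @param rng_seed integer seed.
#' @return a `train_config` list.
#' @export
train_config <- function(nrounds = 200, eta = 0.1, max_depth = 4, lambda = 1,
                         gamma = 0, min_child_weight = 1e-3, rng_seed = 0) {
  structure(list(nrounds = as.integer(nrounds), eta = eta,
                 max_depth = as.integer(max_depth), lambda = lambda,
                 gamma = gamma, min_child_weight = min_child_weight,
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Train the rare/sparse/dense texture classifier
#'
#' Fits a gradient-boosted tree ensemble (softmax objective) on seed feature
#' vectors. Class imbalance is not reweighted by default, mirroring the
#' behaviour expected on germplasm collections where the dense class is rare;
#' pass `weights` for the optional weighted variant.
#'
#' @param features numeric matrix, one 198-item descriptor per row (any fixed
#'   dimension is accepted; prediction then requires that same dimension).
#' @param labels character/factor vector aligned with `features`; at least
#'   two classes must be present.
#' @param config a [train_config()].
#' @param class_levels fixed class order (ties in prediction break toward the
#'   earlier class); defaults to [texture_levels()] when the labels fit it,
#'   otherwise to order of first appearance.
#' @param weights optional per-sample weights.
#' @return object of class `lentil_gbt`.
#' @export
texture_train <- function(features, labels, config = train_config(),
                          class_levels = NULL, weights = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  if (is.null(class_levels)) {
    class_levels <- if (all(labels %in% texture_levels()))
      intersect(texture_levels(), unique(labels)) else unique(labels)
  }
  stopifnot(all(labels %in% class_levels))
  if (length(unique(labels)) < 2)
    stop("degenerate training: a single class is present")
  if (!is.null(weights)) {
    # optional class weighting via deterministic oversampling
    reps <- pmax(1L, as.integer(round(weights / min(weights))))
    idx <- rep(seq_along(labels), reps)
    features <- features[idx, , drop = FALSE]
    labels <- labels[idx]
  }
  y <- match(labels, class_levels) - 1L
  trees <- gbt_train_cpp(features, y, length(class_levels), config$nrounds,
                         config$eta, config$max_depth, config$lambda,
                         config$gamma, config$min_child_weight)
  structure(list(trees = trees, class_levels = class_levels,
                 feature_dim = ncol(features), config = config,
                 fingerprint = paste(unlist(config), collapse = "|"),
                 rng_seed = config$rng_seed),
            class = "lentil_gbt")
}

#' @export
print.lentil_gbt <- function(x, ...) {
  cat(sprintf("gradient-boosted texture classifier: %d classes (%s), %d trees, %d features\n",
              length(x$class_levels), paste(x$class_levels, collapse = "/"),
              length(x$trees), x$feature_dim))
  invisible(x)
}

#' Predict texture classes
#'
#' @param object a `lentil_gbt` model.
#' @param newdata feature matrix or single feature vector of the training
#'   dimension (198 in the standard pipeline).
#' @param type `"class"` (default), `"prob"` or `"margin"`.
#' @param ... unused.
#' @return class labels, or an `n x K` matrix for `"prob"`/`"margin"`.
#' @export
predict.lentil_gbt <- function(object, newdata, type = c("class", "prob", "margin"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$feature_dim)
    stop("feature dimension mismatch: model expects ", object$feature_dim,
         ", got ", ncol(newdata))
  m <- gbt_margin_cpp(object$trees, newdata, length(object$class_levels))
  colnames(m) <- object$class_levels
  if (type == "margin") return(m)
  p <- exp(m - apply(m, 1, max))
  p <- p / rowSums(p)
  if (type == "prob") return(p)
  # arg-max; ties break toward the earlier class in the fixed order
  object$class_levels[max.col(m, ties.method = "first")]
}

#' @rdname predict.lentil_gbt
#' @param model a `lentil_gbt` model.
#' @param features feature matrix.
#' @export
texture_predict <- function(model, features) predict(model, features, type = "class")

#' Persist / restore a trained model
#'
#' The model is written to a single file (R serialization, bit-exact on
#' round trip) with a JSON metadata sidecar (`<path>.json`) describing class
#' order, feature dimension and training configuration.
#'
#' @param model a `lentil_gbt`.
#' @param path file path.
#' @return `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    list(class_levels = model$class_levels, feature_dim = model$feature_dim,
         n_trees = length(model$trees), config = unclass(model$config),
         fingerprint = model$fingerprint),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Cross-validated evaluation of the texture classifier
#'
#' `mode = "loo"` is the fidelity protocol: each sample is predicted by a
#' model trained on all others. `mode = "kfold"` is the fast fallback, and
#' `groups` gives the grouped variant (leave-one-group-out, e.g. one image
#' out) -- the chosen protocol is recorded in the result's `protocol`
#' attribute. A class absent from some training fold is reported in the
#' metadata, not fatal: that fold simply cannot predict it.
#'
#' @param features feature matrix.
#' @param labels aligned labels.
#' @param config a [train_config()]; `rng_seed` fixes the fold assignment.
#' @param mode `"kfold"` (default) or `"loo"`.
#' @param k folds for `"kfold"`.
#' @param groups optional grouping vector; overrides `mode`.
#' @param class_levels fixed class order.
#' @return a [confusion_matrix] of ground truth (rows) vs prediction
#'   (columns), with attributes `protocol` and `missing_class_folds`.
#' @export
loo_evaluate <- function(features, labels, config = train_config(),
                         mode = c("kfold", "loo"), k = 10, groups = NULL,
                         class_levels = NULL) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  labels <- as.character(labels)
  n <- length(labels)
  stopifnot(n >= 3, nrow(features) == n)
  if (is.null(class_levels)) {
    class_levels <- if (all(labels %in% texture_levels()))
      intersect(texture_levels(), unique(labels)) else unique(labels)
  }
  if (!is.null(groups)) {
    fold <- as.integer(factor(groups))
    protocol <- "leave-one-group-out"
  } else if (mode == "loo") {
    fold <- seq_len(n)
    protocol <- "leave-one-out"
  } else {
    k <- min(k, n)
    fold <- withr::with_seed(config$rng_seed, sample(rep(seq_len(k), length.out = n)))
    protocol <- sprintf("%d-fold", k)
  }
  pred <- character(n)
  missing_folds <- character(0)
  for (f in sort(unique(fold))) {
    test <- fold == f
    tr_lab <- labels[!test]
    present <- intersect(class_levels, unique(tr_lab))
    if (length(present) < length(class_levels))
      missing_folds <- c(missing_folds,
                         sprintf("fold %s lacks: %s", f,
                                 paste(setdiff(class_levels, present), collapse = ",")))
    model <- texture_train(features[!test, , drop = FALSE], tr_lab, config,
                           class_levels = present)
    pred[test] <- predict(model, features[test, , drop = FALSE])
  }
  cm <- confusion(labels, pred, class_levels)
  attr(cm, "protocol") <- protocol
  attr(cm, "missing_class_folds") <- missing_folds
  cm
}
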