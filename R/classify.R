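#' Congruence-invariant features of a shape
#'
#' Encodes a reconstructed shape in features that are identical for the
#' shape, any rigid transform of it, and its mirror image: the sorted
#' pairwise distances, their sum (perimeter for a triangle), and — for
#' triangles — the Heron area. For three points the sorted edge triple is a
#' complete congruence invariant; for four points the sorted distances are
#' a near-complete invariant (rare non-congruent configurations share them).
#' Absolute size is kept deliberately: it is informative for recognition.
#'
#' @param shape A [reconstructed_shape()] or coordinate matrix (nm).
#' @return Named numeric vector (`d1` <= `d2` <= ..., `perimeter`, and
#'   `area` when n = 3). A degenerate zero-size shape yields all zeros with
#'   attribute `degenerate = TRUE`.
#' @export
#' @examples
#' featurize(reconstruct_triangle(3, 4, 5))  # edges 3,4,5; area 6
featurize <- function(shape) {
  X <- if (inherits(shape, "reconstructed_shape")) shape$coords
       else as.matrix(shape)
  n <- nrow(X)
  d <- sort(as.numeric(stats::dist(X)))
  out <- stats::setNames(d, paste0("d", seq_along(d)))
  out <- c(out, perimeter = sum(d))
  if (n == 3L) {
    s <- sum(d) / 2
    area2 <- s * (s - d[1L]) * (s - d[2L]) * (s - d[3L])
    out <- c(out, area = sqrt(max(area2, 0)))
  }
  if (all(d < 1e-12)) {
    out[] <- 0
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Train a tree-ensemble classifier on invariant shape features
#'
#' Gradient-boosted shallow trees on [featurize()] features, with a
#' molecule-level train/held-out split (no molecule contributes to both
#' sides) and the confusion matrix evaluated only on held-out molecules.
#'
#' @param features Matrix or data frame, one row per molecule.
#' @param labels Class label per molecule (factor or character).
#' @param split_seed Integer seed for the molecule-level split.
#' @param train_fraction Fraction of molecules used for training.
#' @param nrounds,max_depth,eta Boosting parameters (shallow defaults).
#' @return Object of class `shape_classifier`: list with `model` (the
#'   xgboost booster), `classes`, `confusion` (row-normalized confusion
#'   matrix on held-out molecules), `accuracy` (overall held-out accuracy),
#'   `holdout_index`, `config`.
#' @export
train_classifier <- function(features, labels, split_seed = 1L,
                             train_fraction = 0.7, nrounds = 100L,
                             max_depth = 3L, eta = 0.3) {
  X <- as.matrix(features)
  y <- factor(labels)
  stopifnot(nrow(X) == length(y))
  classes <- levels(y)
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  counts <- table(y)
  if (any(counts < 2L)) {
    stop("every class needs at least 2 molecules; got ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  # stratified molecule-level split
  idx_test <- with_seed(split_seed, {
    unlist(lapply(classes, function(cl) {
      i <- which(y == cl)
      n_tr <- max(1L, round(train_fraction * length(i)))
      sample(i)[-seq_len(n_tr)]
    }))
  })
  idx_test <- sort(idx_test)
  idx_train <- setdiff(seq_len(nrow(X)), idx_test)
  ytr <- as.integer(y[idx_train]) - 1L
  dtrain <- xgboost::xgb.DMatrix(X[idx_train, , drop = FALSE], label = ytr)
  model <- with_seed(split_seed, {
    xgboost::xgb.train(params = list(objective = "multi:softprob",
                                     num_class = length(classes),
                                     max_depth = max_depth, eta = eta,
                                     nthread = 1L),
                       data = dtrain, nrounds = nrounds, verbose = 0)
  })
  pred_class <- classes[predict_class_index(model,
                                            X[idx_test, , drop = FALSE],
                                            length(classes))]
  truth <- y[idx_test]
  confusion <- confusion_matrix(truth, factor(pred_class, levels = classes))
  structure(list(model = model, classes = classes, confusion = confusion,
                 accuracy = mean(pred_class == as.character(truth)),
                 holdout_index = idx_test,
                 config = list(split_seed = split_seed,
                               train_fraction = train_fraction,
                               nrounds = nrounds, max_depth = max_depth,
                               eta = eta)),
            class = "shape_classifier")
}

#' Predict classes for new shapes
#'
#' @param object A `shape_classifier`.
#' @param features Feature matrix as used in [train_classifier()].
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.shape_classifier <- function(object, features, ...) {
  X <- as.matrix(features)
  idx <- predict_class_index(object$model, X, length(object$classes))
  factor(object$classes[idx], levels = object$classes)
}

# class index (1-based) from a softprob booster, robust to predict()
# returning either a matrix or a flat vector
predict_class_index <- function(model, X, n_class) {
  p <- stats::predict(model, xgboost::xgb.DMatrix(X))
  if (is.null(dim(p))) {
    p <- matrix(p, ncol = n_class, byrow = TRUE)
  }
  max.col(p, ties.method = "first")
}

#' Row-normalized confusion matrix
#'
#' Each row is a ground-truth class and gives the fraction of its molecules
#' ascribed to each predicted class; rows sum to 1 and the diagonal holds
#' the per-class accuracies.
#'
#' @param truth,predicted Factors with identical levels.
#' @return Square matrix of row fractions.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- factor(truth)
  predicted <- factor(predicted, levels = levels(truth))
  tab <- table(truth = truth, predicted = predicted)
  rs <- rowSums(tab)
  rs[rs == 0] <- 1
  sweep(unclass(tab), 1, rs, `/`)
}

#' @export
print.shape_classifier <- function(x, ...) {
  cat(sprintf("Shape classifier: %d classes, held-out accuracy %.3f\n",
              length(x$classes), x$accuracy))
  cat("Confusion matrix (rows = truth, row-normalized):\n")
  print(round(x$confusion, 3))
  invisible(x)
}
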