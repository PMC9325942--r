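#' Fit a random-forest classifier
#'
#' A compact CART random forest (Gini impurity, bootstrap resampling, `mtry`
#' features sampled at each split, leaf class proportions averaged across
#' trees). The environment this package targets ships no tree learner, so the
#' forest is implemented in C++ within the package.
#'
#' @param x numeric matrix or data frame of predictors (rows = samples).
#' @param y factor (or vector coercible to factor) of class labels.
#' @param ntree number of trees.
#' @param mtry number of candidate features per split (default
#'   `floor(sqrt(ncol(x)))`).
#' @param min_split minimum node size eligible for splitting.
#' @param max_depth maximum tree depth.
#' @param seed integer seed; the forest is fully deterministic given the seed.
#' @return an object of class `cog_rf`.
#' @examples
#' fit <- grow_forest(iris[, 1:4], iris$Species, ntree = 25, seed = 1)
#' head(predict(fit, iris[, 1:4]))
#' @export
grow_forest <- function(x, y, ntree = 100, mtry = NULL, min_split = 2,
                        max_depth = 30, seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.factor(y)
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  classes <- levels(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  if (mtry < 1 || mtry > ncol(x)) stop("mtry must be in [1, ncol(x)]")
  if (ntree < 1) stop("ntree must be >= 1")
  trees <- rf_fit_cpp(x, as.integer(y) - 1L, length(classes),
                      as.integer(ntree), as.integer(mtry),
                      as.integer(min_split), as.integer(max_depth),
                      as.double(seed))
  structure(
    list(trees = trees, classes = classes, features = colnames(x),
         ntree = ntree, mtry = mtry, seed = seed),
    class = "cog_rf")
}

#' Predict class probabilities from a `cog_rf` forest
#'
#' @param object a fitted `cog_rf`.
#' @param newdata matrix or data frame with the training columns.
#' @param type `"prob"` for the class-probability matrix, `"class"` for labels
#'   (argmax with ties broken by class order).
#' @param ... unused.
#' @return a numeric matrix (samples x classes) or a factor.
#' @export
predict.cog_rf <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (!is.null(object$features) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$features, drop = FALSE]
  p <- rf_predict_cpp(object$trees, newdata, length(object$classes))
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  factor(object$classes[max.col(p, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.cog_rf <- function(x, ...) {
  cat("Random forest:", x$ntree, "trees, mtry =", x$mtry,
      "| classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}
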