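#' Ensemble classifier configuration
#'
#' Settings for the class-balanced undersampling random-forest ensemble.
#' Defaults follow the reference protocol (`U = 100` undersampled retrainings
#' of `n_train = 500` samples per class, nested stratified 3-fold
#' hyperparameter search, leave-one-subject-out CV). `cv = "grouped-kfold"`
#' with small `U`/`n_train` is the desk-scale alternative: subjects (not rows)
#' are partitioned into `n_folds` folds so no subject leaks across folds.
#'
#' @param U number of undersampled retrainings per CV round.
#' @param n_train training samples drawn per class per retraining.
#' @param inner_k folds of the inner stratified CV for the grid search.
#' @param ntree_grid,mtry_grid hyperparameter candidates.
#' @param cv `"loso"` (leave one subject out) or `"grouped-kfold"`.
#' @param n_folds folds for `"grouped-kfold"`.
#' @param min_split,max_depth tree-growth controls passed to [grow_forest()].
#' @param keep_models retain the fitted forests (needed for explanation).
#' @param seed integer master seed.
#' @return an object of class `ensemble_config`.
#' @export
ensemble_config <- function(U = 100, n_train = 500, inner_k = 3,
                            ntree_grid = c(100, 300, 500),
                            mtry_grid = c(2, 3, 4),
                            cv = c("loso", "grouped-kfold"), n_folds = 5,
                            min_split = 2, max_depth = 30,
                            keep_models = TRUE, seed = 1) {
  cv <- match.arg(cv)
  stopifnot(U >= 1, n_train >= 1, inner_k >= 2, n_folds >= 2,
            length(ntree_grid) >= 1, length(mtry_grid) >= 1)
  structure(list(U = as.integer(U), n_train = as.integer(n_train),
                 inner_k = as.integer(inner_k),
                 ntree_grid = as.integer(ntree_grid),
                 mtry_grid = as.integer(mtry_grid), cv = cv,
                 n_folds = as.integer(n_folds),
                 min_split = as.integer(min_split),
                 max_depth = as.integer(max_depth),
                 keep_models = isTRUE(keep_models),
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Leave-one-subject-out folds
#'
#' Splits a cohort into one fold per subject; all visits of a subject are held
#' out together, so train and test never share a subject.
#'
#' @param cohort a cohort table.
#' @return list of folds, each `list(subjects, train, test)` with row indices.
#' @export
loso_split <- function(cohort) {
  subjects <- sort(unique(cohort$subject_id))
  if (length(subjects) < 2) stop("LOSO needs at least 2 distinct subjects")
  lapply(subjects, function(s) {
    test <- which(cohort$subject_id == s)
    list(subjects = s, train = setdiff(seq_len(nrow(cohort)), test), test = test)
  })
}

#' Grouped k-fold split by subject
#'
#' Subjects (all their visits together) are assigned to folds, stratified by
#' baseline diagnosis so every training pool keeps all three classes.
#'
#' @param cohort a cohort table.
#' @param n_folds number of folds.
#' @param seed fold-assignment seed.
#' @return list of folds as in [loso_split()].
#' @export
grouped_kfold <- function(cohort, n_folds = 5, seed = 1) {
  subjects <- sort(unique(cohort$subject_id))
  if (length(subjects) < n_folds) stop("fewer subjects than folds")
  set.seed(as.integer(seed))
  first <- cohort[!duplicated(cohort$subject_id), ]
  base_dx <- first$diagnosis[match(subjects, first$subject_id)]
  fold_of <- integer(length(subjects))
  for (cl in unique(base_dx)) {
    rows <- which(base_dx == cl)
    fold_of[rows] <- sample(rep_len(seq_len(n_folds), length(rows)))
  }
  lapply(seq_len(n_folds), function(f) {
    held <- subjects[fold_of == f]
    test <- which(cohort$subject_id %in% held)
    list(subjects = held, train = setdiff(seq_len(nrow(cohort)), test),
         test = test)
  })
}

#' Class-balanced undersampling of a training pool
#'
#' Draws exactly `n_per_class` rows per diagnostic class without replacement.
#'
#' @param train a cohort table (training pool).
#' @param n_per_class rows to draw per class.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return the balanced subset (rows in class order NC, MCI, AD).
#' @export
undersample_train <- function(train, n_per_class, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  picks <- lapply(DIAG_LEVELS, function(cl) {
    rows <- which(train$diagnosis == cl)
    if (length(rows) < n_per_class)
      stop("insufficient class size for ", cl, ": ", length(rows),
           " < ", n_per_class)
    sample(rows, n_per_class)
  })
  train[unlist(picks), , drop = FALSE]
}

# stratified fold ids (1..k) preserving class proportions
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    rows <- which(y == cl)
    fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  fold
}

#' Fit one forest with nested hyperparameter search
#'
#' Selects `(ntree, mtry)` from the config grid by stratified `inner_k`-fold
#' cross-validation maximizing mean multiclass accuracy, then refits on the
#' full balanced training set with the winning pair. Ties go to the earlier
#' grid point (smaller `ntree`, then smaller `mtry`).
#'
#' @param balanced a balanced training cohort table.
#' @param config an [ensemble_config()].
#' @return a `cog_rf` forest with attributes `ntree`/`mtry` selected.
#' @export
fit_one_model <- function(balanced, config) {
  X <- as.matrix(balanced[, cog_indexes(), drop = FALSE])
  y <- factor(balanced$diagnosis, levels = DIAG_LEVELS)
  grid <- expand.grid(mtry = config$mtry_grid, ntree = config$ntree_grid)
  grid <- grid[order(grid$ntree, grid$mtry), c("ntree", "mtry")]
  best <- grid[1, ]
  if (nrow(grid) > 1) {
    if (min(table(y)) < config$inner_k)
      stop("inner_k exceeds the smallest class count")
    fold <- stratified_folds(y, config$inner_k)
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(seq_len(config$inner_k), function(f) {
        tr <- fold != f
        fit <- grow_forest(X[tr, , drop = FALSE], y[tr],
                           ntree = grid$ntree[g], mtry = grid$mtry[g],
                           min_split = config$min_split,
                           max_depth = config$max_depth,
                           seed = sample.int(.Machine$integer.max, 1))
        mean(predict(fit, X[!tr, , drop = FALSE], type = "class") == y[!tr])
      }, numeric(1)))
    }, numeric(1))
    best <- grid[which.max(acc), ]
  }
  grow_forest(X, y, ntree = best$ntree, mtry = best$mtry,
              min_split = config$min_split, max_depth = config$max_depth,
              seed = sample.int(.Machine$integer.max, 1))
}

#' Final label from averaged class probabilities
#'
#' Argmax over the averaged probability triple; ties broken by the fixed class
#' order NC < MCI < AD.
#'
#' @param probs numeric vector (or matrix with columns) named NC, MCI, AD.
#' @param tol tolerance on the unit-sum check.
#' @return character label(s).
#' @export
aggregate_label <- function(probs, tol = 1e-6) {
  p <- if (is.matrix(probs)) probs else matrix(probs, 1,
         dimnames = list(NULL, names(probs)))
  p <- p[, DIAG_LEVELS, drop = FALSE]
  if (any(abs(rowSums(p) - 1) > tol)) stop("probabilities must sum to 1")
  DIAG_LEVELS[max.col(p, ties.method = "first")]
}

#' Classify a cohort with the undersampling ensemble
#'
#' The fitting function of the package's classification stage. For each CV
#' round (LOSO or grouped k-fold) the training pool is undersampled `U` times
#' to `n_train` rows per class; each balanced draw is fitted with the nested
#' grid search of [fit_one_model()]; the held-out visits receive `U`
#' probability triples that are averaged into the final probability and label.
#'
#' @param cohort a cohort table (see [generate_cohort()] / [read_cohort()]).
#' @param config an [ensemble_config()].
#' @return an object of class `cog_ensemble` with elements `predictions`
#'   (subject_id, visit_index, true, p_NC, p_MCI, p_AD, final, category),
#'   `metrics`, `auroc`, `confusion`, `folds`, and (if `keep_models`) the
#'   per-fold forests and balanced training pools.
#' @export
classify_cohort <- function(cohort, config = ensemble_config()) {
  stopifnot(is.data.frame(cohort))
  folds <- if (config$cv == "loso") loso_split(cohort)
           else grouped_kfold(cohort, config$n_folds, seed = config$seed)
  set.seed(config$seed)
  X_all <- as.matrix(cohort[, cog_indexes(), drop = FALSE])
  probs <- matrix(NA_real_, nrow(cohort), 3,
                  dimnames = list(NULL, DIAG_LEVELS))
  models <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    train <- cohort[fold$train, , drop = FALSE]
    acc <- matrix(0, length(fold$test), 3)
    fits <- vector("list", config$U)
    for (u in seq_len(config$U)) {
      balanced <- undersample_train(train, config$n_train)
      fit <- fit_one_model(balanced, config)
      acc <- acc + predict(fit, X_all[fold$test, , drop = FALSE])
      fits[[u]] <- fit
    }
    probs[fold$test, ] <- acc / config$U
    if (config$keep_models) models[[f]] <- fits
  }
  final <- aggregate_label(probs)
  predictions <- data.frame(
    subject_id = cohort$subject_id, visit_index = cohort$visit_index,
    true = cohort$diagnosis, p_NC = probs[, "NC"], p_MCI = probs[, "MCI"],
    p_AD = probs[, "AD"], final = final,
    category = assign_category(cohort$diagnosis, final),
    stringsAsFactors = FALSE)
  structure(list(predictions = predictions,
                 metrics = compute_metrics(predictions),
                 auroc = ovr_auroc(predictions),
                 confusion = confusion_matrix(predictions),
                 folds = folds, models = if (config$keep_models) models,
                 config = config, cohort = cohort),
            class = "cog_ensemble")
}

#' Predict from a fitted ensemble
#'
#' Averages class probabilities over every retained forest (all folds, all
#' undersampling repeats).
#'
#' @param object a `cog_ensemble` fitted with `keep_models = TRUE`.
#' @param newdata data frame/matrix containing the ten index columns.
#' @param type `"prob"` or `"class"`.
#' @param ... unused.
#' @export
predict.cog_ensemble <- function(object, newdata,
                                 type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.null(object$models)) stop("models were not retained; refit with keep_models = TRUE")
  X <- as.matrix(as.data.frame(newdata)[, cog_indexes(), drop = FALSE])
  fits <- unlist(object$models, recursive = FALSE)
  p <- Reduce(`+`, lapply(fits, predict, newdata = X)) / length(fits)
  if (type == "prob") return(p)
  factor(aggregate_label(p), levels = DIAG_LEVELS)
}

#' @export
print.cog_ensemble <- function(x, ...) {
  cfg <- x$config
  cat("Undersampling random-forest ensemble (", cfg$cv, " CV)\n", sep = "")
  cat("  U =", cfg$U, "| n_train/class =", cfg$n_train,
      "| folds =", length(x$folds), "\n")
  cat("  samples:", nrow(x$predictions), "| OVR AUROC:",
      paste(sprintf("%s %.3f", names(x$auroc), x$auroc), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cog_ensemble <- function(object, ...) {
  cat("Confusion matrix (true x predicted):\n")
  print(object$confusion)
  cat("\nPer-class one-vs-rest metrics:\n")
  print(object$metrics, row.names = FALSE, digits = 4)
  cat("\nOne-vs-rest AUROC:\n")
  print(round(object$auroc, 4))
  invisible(object)
}

#' Confusion matrix of an ensemble's final labels
#'
#' @param records prediction records with `true` and `final` columns.
#' @return a 3x3 table, rows = true, columns = predicted.
#' @export
confusion_matrix <- function(records) {
  table(true = factor(records$true, DIAG_LEVELS),
        predicted = factor(records$final, DIAG_LEVELS))
}

#' One-vs-rest classification metrics
#'
#' Per class j, with one-vs-rest counts TP, FP, TN, FN: accuracy
#' (TP+TN)/(TP+FP+TN+FN), sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' precision TP/(TP+FP); plus a macro (unweighted mean) "Global" row.
#' A published variant prints specificity with the accuracy formula
#' (evidently a typo, since it reports distinct accuracy and specificity
#' values); `spec_as_printed = TRUE` reproduces that formula.
#' Undefined ratios (zero denominator) are reported as `NA`, never 0.
#'
#' @param records prediction records with `true` and `final` columns.
#' @param spec_as_printed use the accuracy formula for specificity.
#' @return data.frame with rows NC, MCI, AD, Global and columns class,
#'   accuracy, sensitivity, specificity, precision.
#' @export
compute_metrics <- function(records, spec_as_printed = FALSE) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  rows <- lapply(DIAG_LEVELS, function(cl) {
    tp <- sum(records$true == cl & records$final == cl)
    fp <- sum(records$true != cl & records$final == cl)
    fn <- sum(records$true == cl & records$final != cl)
    tn <- sum(records$true != cl & records$final != cl)
    data.frame(class = cl,
               accuracy = ratio(tp + tn, tp + fp + tn + fn),
               sensitivity = ratio(tp, tp + fn),
               specificity = if (spec_as_printed)
                 ratio(tp + tn, tp + fp + tn + fn) else ratio(tn, tn + fp),
               precision = ratio(tp, tp + fp))
  })
  out <- do.call(rbind, rows)
  macro <- data.frame(class = "Global", t(colMeans(out[, -1])))
  rbind(out, macro)
}

# rank-based (Mann-Whitney) AUROC with midrank tie handling
auroc_score <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both positives and negatives")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest AUROC per class
#'
#' AUROC of the averaged probability of class j against the indicator
#' `true == j` (the normalized Mann-Whitney U statistic), plus the unweighted
#' macro average.
#'
#' @param records prediction records with `true`, `p_NC`, `p_MCI`, `p_AD`.
#' @return named numeric vector `c(NC, MCI, AD, macro)`.
#' @export
ovr_auroc <- function(records) {
  per <- vapply(DIAG_LEVELS, function(cl)
    auroc_score(records[[paste0("p_", cl)]], records$true == cl), numeric(1))
  c(per, macro = mean(per))
}

#' Predict one subject's visits under leave-one-subject-out
#'
#' Runs a single LOSO round for `subject_id`: all other subjects form the
#' training pool, which is undersampled and refitted `U` times; each of the
#' subject's visits receives `U` probability triples that are averaged.
#'
#' @param cohort a cohort table.
#' @param subject_id the held-out subject.
#' @param config an [ensemble_config()].
#' @param keep_stack retain the U x 3 probability stack per visit.
#' @return prediction records for the subject's visits; if `keep_stack`, a
#'   `prob_stack` attribute holds one U x 3 matrix per visit.
#' @export
predict_subject <- function(cohort, subject_id, config = ensemble_config(),
                            keep_stack = FALSE) {
  test <- which(cohort$subject_id == subject_id)
  if (length(test) == 0) stop("unknown subject: ", subject_id)
  train <- cohort[-test, , drop = FALSE]
  X_test <- as.matrix(cohort[test, cog_indexes(), drop = FALSE])
  set.seed(config$seed)
  stack <- array(NA_real_, c(config$U, length(test), 3))
  for (u in seq_len(config$U)) {
    fit <- fit_one_model(undersample_train(train, config$n_train), config)
    stack[u, , ] <- predict(fit, X_test)
  }
  probs <- apply(stack, c(2, 3), mean)
  colnames(probs) <- DIAG_LEVELS
  rec <- data.frame(
    subject_id = cohort$subject_id[test], visit_index = cohort$visit_index[test],
    true = cohort$diagnosis[test], p_NC = probs[, "NC"], p_MCI = probs[, "MCI"],
    p_AD = probs[, "AD"], final = aggregate_label(probs),
    stringsAsFactors = FALSE)
  if (keep_stack)
    attr(rec, "prob_stack") <- lapply(seq_along(test), function(i) {
      m <- stack[, i, , drop = FALSE]; dim(m) <- c(config$U, 3)
      colnames(m) <- DIAG_LEVELS; m
    })
  rec
}
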