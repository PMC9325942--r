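#' Value function for Shapley attribution
#'
#' Wraps a model and a background set into the coalition value function
#' v(F) = E_b[ f(x on F, b elsewhere) ]: features outside the coalition F are
#' marginalized interventionally over the background rows.
#'
#' @param model either a `cog_rf` forest (then `class` selects the probability
#'   column that is explained) or a function mapping a numeric matrix of rows
#'   to a numeric score per row.
#' @param background numeric matrix/data frame of reference rows (non-empty),
#'   same columns as the explained vectors.
#' @param class class label whose probability is explained (for `cog_rf`).
#' @return an object of class `value_function`.
#' @export
value_function <- function(model, background, class = NULL) {
  background <- as.matrix(background)
  storage.mode(background) <- "double"
  if (nrow(background) == 0) stop("background must be non-empty")
  scorer <- if (is.function(model)) {
    model
  } else if (inherits(model, "cog_rf")) {
    if (is.null(class) || !class %in% model$classes)
      stop("class not in model outputs: ", class)
    function(X) predict(model, X)[, class]
  } else stop("model must be a function or a cog_rf")
  structure(list(scorer = scorer, background = background, class = class),
            class = "value_function")
}

#' Coalition value
#'
#' Mean model score over the background rows of the hybrid vectors that take
#' `x` on the coalition `F` and the background values elsewhere.
#'
#' @param vf a [value_function()].
#' @param x numeric feature vector (length S).
#' @param F integer coalition, subset of `1:S` (may be empty).
#' @return scalar value v(F).
#' @export
coalition_value <- function(vf, x, F = integer(0)) {
  S <- length(x)
  if (length(F) && (any(F < 1) || any(F > S))) stop("F must be a subset of 1:S")
  hybrid <- vf$background
  if (length(F)) hybrid[, F] <- matrix(x[F], nrow(hybrid), length(F), byrow = TRUE)
  mean(vf$scorer(hybrid))
}

# hybrid rows for all 2^S coalitions in mask order
# (mask m's bit j-1 = feature j fixed to x)
coalition_design <- function(background, x) {
  S <- length(x)
  B <- nrow(background)
  masks <- 0:(2L^S - 1L)
  big <- background[rep(seq_len(B), length(masks)), , drop = FALSE]
  for (j in seq_len(S)) {
    on <- which(bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0L)
    if (length(on))
      big[rep((on - 1L) * B, each = B) + seq_len(B), j] <- x[j]
  }
  big
}

# values of all 2^S coalitions in mask order
all_coalition_values <- function(vf, x, design = NULL) {
  B <- nrow(vf$background)
  scores <- vf$scorer(design %||% coalition_design(vf$background, x))
  colMeans(matrix(scores, nrow = B))
}

new_shap_vector <- function(phi, baseline, prediction, class = NULL) {
  structure(list(phi = phi, baseline = baseline, prediction = prediction,
                 class = class),
            class = "shap_vector")
}

#' @export
print.shap_vector <- function(x, ...) {
  cat("Shapley attribution (baseline", round(x$baseline, 4),
      "-> prediction", round(x$prediction, 4), ")\n")
  print(round(x$phi, 4))
  invisible(x)
}

#' Exact Shapley values by full coalition enumeration
#'
#' For each feature j, sums |F|! (S-|F|-1)! / S! * (v(F u j) - v(F)) over all
#' coalitions F not containing j, from one pass over all 2^S coalition values.
#' Feasible for the S = 10 cognitive indexes (1024 coalitions).
#'
#' @param vf a [value_function()].
#' @param x numeric feature vector to explain.
#' @param enumeration_cap refuse enumeration above this many features
#'   (use [monte_carlo_shapley()] instead).
#' @return a `shap_vector`: per-feature attributions `phi`, `baseline`
#'   (value of the empty coalition) and `prediction` (full coalition); local
#'   accuracy `baseline + sum(phi) == prediction` holds to machine precision.
#' @export
exact_shapley <- function(vf, x, enumeration_cap = 15) {
  x <- as.numeric_named(x, vf)
  S <- length(x)
  if (S > enumeration_cap)
    stop("S = ", S, " exceeds the enumeration cap; use monte_carlo_shapley()")
  exact_shapley_from_values(all_coalition_values(vf, x), x, vf$class)
}

exact_shapley_from_values <- function(v, x, class = NULL) {
  S <- length(x)
  masks <- 0:(2L^S - 1L)
  pc <- integer(length(masks))
  for (j in seq_len(S))
    pc <- pc + (bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0L)
  w <- exp(lfactorial(0:(S - 1)) + lfactorial(S - (0:(S - 1)) - 1) - lfactorial(S))
  phi <- vapply(seq_len(S), function(j) {
    bit <- bitwShiftL(1L, j - 1L)
    noj <- masks[bitwAnd(masks, bit) == 0L]
    sum(w[pc[noj + 1L] + 1L] * (v[noj + bit + 1L] - v[noj + 1L]))
  }, numeric(1))
  names(phi) <- names(x)
  new_shap_vector(phi, baseline = v[1L], prediction = v[length(v)],
                  class = class)
}

as.numeric_named <- function(x, vf) {
  x <- unlist(x)
  if (is.null(names(x)) && !is.null(colnames(vf$background)))
    names(x) <- colnames(vf$background)
  x
}

#' Monte Carlo Shapley values
#'
#' Averages the marginal contribution of each feature over `n_permutations`
#' random feature orderings (an unbiased estimator of the exact value), then
#' redistributes the residual efficiency gap equally across features so that
#' local accuracy holds exactly.
#'
#' @param vf a [value_function()].
#' @param x numeric feature vector to explain.
#' @param n_permutations number of sampled orderings (>= 1).
#' @param seed integer seed.
#' @return a `shap_vector` (see [exact_shapley()]).
#' @export
monte_carlo_shapley <- function(vf, x, n_permutations = 1000, seed = 1) {
  x <- as.numeric_named(x, vf)
  S <- length(x)
  stopifnot(n_permutations >= 1)
  set.seed(as.integer(seed))
  B <- nrow(vf$background)
  baseline <- coalition_value(vf, x, integer(0))
  prediction <- coalition_value(vf, x, seq_len(S))
  phi <- numeric(S)
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(S)
    # hybrid rows for the S-1 proper prefixes of the ordering
    if (S > 1) {
      big <- vf$background[rep(seq_len(B), S - 1L), , drop = FALSE]
      for (k in seq_len(S - 1L)) {
        rows <- (k - 1L) * B + seq_len(B)
        big[rows, ord[seq_len(k)]] <-
          matrix(x[ord[seq_len(k)]], B, k, byrow = TRUE)
      }
      vk <- c(baseline, colMeans(matrix(vf$scorer(big), nrow = B)), prediction)
    } else {
      vk <- c(baseline, prediction)
    }
    phi[ord] <- phi[ord] + diff(vk)
  }
  phi <- phi / n_permutations
  phi <- phi + (prediction - baseline - sum(phi)) / S  # efficiency correction
  names(phi) <- names(x)
  new_shap_vector(phi, baseline, prediction, class = vf$class)
}

#' Ensemble-averaged Shapley attribution
#'
#' Explains one sample with each of the `U` ensemble members and averages the
#' attribution vectors arithmetically; baseline and explained prediction are
#' averaged identically, so local accuracy is preserved by linearity.
#'
#' @param x numeric feature vector to explain.
#' @param models list of fitted `cog_rf` forests.
#' @param class class label whose probability is explained.
#' @param background background rows for the value function.
#' @param method `"exact"` or `"montecarlo"`.
#' @param n_permutations,seed Monte Carlo settings.
#' @return a `shap_vector`.
#' @export
ensemble_shap <- function(x, models, class, background,
                          method = c("exact", "montecarlo"),
                          n_permutations = 1000, seed = 1) {
  method <- match.arg(method)
  stopifnot(length(models) >= 1)
  vfs <- lapply(models, value_function, background = background, class = class)
  x <- as.numeric_named(x, vfs[[1]])
  if (method == "exact") {
    # the coalition design depends only on (x, background): build it once
    # and score it with each of the U models
    design <- coalition_design(vfs[[1]]$background, x)
    svs <- lapply(vfs, function(vf)
      exact_shapley_from_values(all_coalition_values(vf, x, design), x, class))
  } else {
    svs <- lapply(vfs, monte_carlo_shapley, x = x,
                  n_permutations = n_permutations, seed = seed)
  }
  new_shap_vector(
    phi = Reduce(`+`, lapply(svs, `[[`, "phi")) / length(svs),
    baseline = mean(vapply(svs, `[[`, numeric(1), "baseline")),
    prediction = mean(vapply(svs, `[[`, numeric(1), "prediction")),
    class = class)
}

#' Explain every prediction of a fitted ensemble
#'
#' Computes one Shapley attribution vector per subject-visit: each sample is
#' explained by the `U` forests of its own CV round (so explanation, like
#' prediction, is out-of-fold) against a class-balanced background drawn from
#' that round's training pool, and the `U` vectors are averaged.
#'
#' @param fit a `cog_ensemble` from [classify_cohort()] with retained models.
#' @param target `"predicted"` (explain the probability of the sample's final
#'   ensemble label, the default) or one of `"NC"`, `"MCI"`, `"AD"`.
#' @param method `"exact"` or `"montecarlo"`.
#' @param background_size maximum background rows (balanced across classes).
#' @param n_permutations Monte Carlo orderings (if `method = "montecarlo"`).
#' @param seed integer seed for background draws (and MC orderings).
#' @param rows optional row indices of `fit$cohort` to explain (default all).
#' @return a `shap_matrix` data frame: `subject_id`, `visit_index`, one
#'   attribution column per index, `baseline`, `prediction`, `target_class`.
#' @export
explain_cohort <- function(fit, target = "predicted",
                           method = c("exact", "montecarlo"),
                           background_size = 100, n_permutations = 1000,
                           seed = 1, rows = NULL) {
  method <- match.arg(method)
  if (is.null(fit$models)) stop("refit with keep_models = TRUE to explain")
  if (!target %in% c("predicted", DIAG_LEVELS)) stop("unknown target: ", target)
  cohort <- fit$cohort
  if (is.null(rows)) rows <- seq_len(nrow(cohort))
  set.seed(as.integer(seed))
  idx <- cog_indexes()
  X <- as.matrix(cohort[, idx, drop = FALSE])
  out <- vector("list", length(rows))
  for (f in seq_along(fit$folds)) {
    fold <- fit$folds[[f]]
    take <- intersect(fold$test, rows)
    if (!length(take)) next
    pool <- cohort[fold$train, , drop = FALSE]
    n_bg <- max(1L, background_size %/% 3L)
    n_bg <- min(n_bg, min(table(factor(pool$diagnosis, DIAG_LEVELS))))
    bg <- as.matrix(undersample_train(pool, n_bg)[, idx, drop = FALSE])
    for (i in take) {
      cl <- if (target == "predicted") fit$predictions$final[i] else target
      sv <- ensemble_shap(X[i, ], fit$models[[f]], cl, bg, method = method,
                          n_permutations = n_permutations, seed = seed)
      out[[match(i, rows)]] <- data.frame(
        subject_id = cohort$subject_id[i], visit_index = cohort$visit_index[i],
        as.data.frame(as.list(sv$phi)), baseline = sv$baseline,
        prediction = sv$prediction, target_class = cl,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("shap_matrix", "data.frame")
  res
}

#' Local-accuracy gap of an attribution vector
#'
#' @param sv a `shap_vector`.
#' @return `prediction - baseline - sum(phi)` (0 up to numerical error).
#' @export
shap_gap <- function(sv) sv$prediction - sv$baseline - sum(sv$phi)
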