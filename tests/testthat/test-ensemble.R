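test_that("LOSO folds partition the cohort by subject", {
  co <- generate_cohort(list(
    trajectory_spec("NC", n_subjects = 1, n_visits = 2),
    trajectory_spec("MCI", n_subjects = 1, n_visits = 3),
    trajectory_spec("AD", n_subjects = 1, n_visits = 1)), seed = 1)
  folds <- loso_split(co)
  expect_length(folds, 3)
  expect_setequal(vapply(folds, function(f) length(f$test), 1L), c(2, 3, 1))
  all_test <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(all_test, seq_len(nrow(co)))      # union = table
  expect_false(anyDuplicated(all_test) > 0)         # no duplicates
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_false(any(co$subject_id[f$train] %in% co$subject_id[f$test]))
  }
  # fold content is order-independent
  shuf <- co[rev(seq_len(nrow(co))), ]
  folds2 <- loso_split(shuf)
  key <- function(fs, d) sort(vapply(fs, function(f)
    paste(sort(unique(d$subject_id[f$test])), collapse = ","), ""))
  expect_identical(key(folds, co), key(folds2, shuf))
  expect_error(loso_split(co[co$subject_id == co$subject_id[1], ]), "2 distinct")
})

test_that("grouped k-fold never leaks a subject across folds", {
  co <- tiny_cohort(n = 10, n_visits = 2)
  folds <- grouped_kfold(co, n_folds = 4, seed = 3)
  for (f in folds)
    expect_length(intersect(unique(co$subject_id[f$train]),
                            unique(co$subject_id[f$test])), 0)
  expect_setequal(unlist(lapply(folds, `[[`, "test")), seq_len(nrow(co)))
})

test_that("undersampling balances classes and errors on short pools", {
  co <- tiny_cohort(n = 20)
  bal <- undersample_train(co, 12, seed = 5)
  expect_equal(unname(table(bal$diagnosis)[c("NC", "MCI", "AD")]),
               rep(12L, 3), ignore_attr = TRUE)
  expect_false(anyDuplicated(rownames(bal)) > 0)   # without replacement
  expect_identical(undersample_train(co, 12, seed = 5),
                   undersample_train(co, 12, seed = 5))
  expect_error(undersample_train(co, 25), "insufficient class size for NC")
})

test_that("the forest separates blob data and is seed-deterministic", {
  set.seed(2)
  X <- matrix(rnorm(240 * 3), 240)
  y <- factor(rep(c("NC", "MCI", "AD"), each = 80), c("NC", "MCI", "AD"))
  X[y == "MCI", 1] <- X[y == "MCI", 1] + 8
  X[y == "AD", 2] <- X[y == "AD", 2] + 8
  fit <- grow_forest(X, y, ntree = 50, seed = 4)
  expect_gt(mean(predict(fit, X, type = "class") == y), 0.99)
  p <- predict(fit, X)
  expect_equal(rowSums(p), rep(1, nrow(X)), tolerance = 1e-12)
  expect_identical(p, predict(grow_forest(X, y, ntree = 50, seed = 4), X))
})

test_that("nested grid search selects a grid point and is deterministic", {
  co <- tiny_cohort(n = 15)
  cfg1 <- fast_config(ntree_grid = 40, mtry_grid = 2)
  bal <- undersample_train(co, 10, seed = 1)
  m <- fit_one_model(bal, cfg1)
  expect_s3_class(m, "cog_rf")
  expect_equal(m$ntree, 40)  # single grid point: selected without search
  expect_equal(m$mtry, 2)

  # separable toy data: some grid point reaches inner accuracy 1
  set.seed(9)
  toy <- data.frame(matrix(rnorm(90 * 10), 90))
  names(toy) <- cog_indexes()
  toy$diagnosis <- rep(c("NC", "MCI", "AD"), each = 30)
  toy$ADAS11 <- c(rep(0, 30), rep(10, 30), rep(20, 30)) + rnorm(90, 0, 0.01)
  cfg2 <- fast_config(ntree_grid = c(20, 40), mtry_grid = c(2, 10))
  set.seed(1); m1 <- fit_one_model(toy, cfg2)
  set.seed(1); m2 <- fit_one_model(toy, cfg2)
  expect_equal(c(m1$ntree, m1$mtry), c(m2$ntree, m2$mtry))
  expect_gt(mean(predict(m1, toy[, cog_indexes()], type = "class") ==
                   toy$diagnosis), 0.99)
})

test_that("final labels are the argmax with the declared NC < MCI < AD tie-break", {
  expect_equal(aggregate_label(c(NC = 0.2, MCI = 0.3, AD = 0.5)), "AD")
  expect_equal(aggregate_label(c(NC = 1, MCI = 1, AD = 1) / 3), "NC")
  expect_equal(aggregate_label(c(NC = 0.5, MCI = 0.5, AD = 0)), "NC")
  expect_equal(aggregate_label(c(AD = 0.5, NC = 0.1, MCI = 0.4)), "AD")
  expect_error(aggregate_label(c(NC = 0.9, MCI = 0.3, AD = 0.5)), "sum to 1")
})

test_that("U-averaged probabilities behave like means", {
  # U = 2 stacks averaging
  stack <- rbind(c(0.6, 0.3, 0.1), c(0.4, 0.5, 0.1))
  avg <- colMeans(stack)
  names(avg) <- c("NC", "MCI", "AD")
  expect_equal(unname(avg), c(0.5, 0.4, 0.1))
  expect_equal(aggregate_label(avg), "NC")

  co <- tiny_cohort(n = 8, n_visits = 2)
  rec <- predict_subject(co, co$subject_id[1],
                         fast_config(U = 2, n_train = 8), keep_stack = TRUE)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$p_NC + rec$p_MCI + rec$p_AD, rep(1, 2), tolerance = 1e-9)
  st <- attr(rec, "prob_stack")[[1]]
  expect_equal(dim(st), c(2, 3))
  expect_equal(unname(colMeans(st)),
               unname(unlist(rec[1, c("p_NC", "p_MCI", "p_AD")])),
               tolerance = 1e-12)
  # U = 1: average equals the single model's triple (sums to 1 exactly)
  rec1 <- predict_subject(co, co$subject_id[1], fast_config(U = 1, n_train = 8))
  expect_equal(rec1$p_NC + rec1$p_MCI + rec1$p_AD, rep(1, 2), tolerance = 1e-12)
})

test_that("classification metrics match hand-computed confusion counts", {
  # perfect predictions
  rec <- data.frame(true = c("NC", "MCI", "AD"), final = c("NC", "MCI", "AD"))
  m <- compute_metrics(rec)
  expect_true(all(m[m$class != "Global", -1] == 1))

  # TP=50 FN=10 FP=5 TN=100 for class NC (one-vs-rest oracle arithmetic)
  rec2 <- data.frame(
    true = c(rep("NC", 60), rep("MCI", 105)),
    final = c(rep("NC", 50), rep("MCI", 10), rep("NC", 5), rep("MCI", 100)))
  m2 <- compute_metrics(rec2)
  nc <- m2[m2$class == "NC", ]
  expect_equal(nc$sensitivity, 50 / 60, tolerance = 1e-12)   # 0.8333
  expect_equal(nc$specificity, 100 / 105, tolerance = 1e-12) # 0.9524
  expect_equal(nc$precision, 50 / 55, tolerance = 1e-12)     # 0.9091
  expect_equal(nc$accuracy, 150 / 165, tolerance = 1e-12)    # 0.9091
  # printed-formula variant: specificity collapses onto accuracy
  m2p <- compute_metrics(rec2, spec_as_printed = TRUE)
  expect_equal(m2p$specificity, m2p$accuracy)

  # all predictions one class: that class SENS = 1, others 0; and the
  # absent-prediction classes have undefined (NA) precision, never 0
  rec3 <- data.frame(true = rep(c("NC", "MCI", "AD"), 5), final = "NC")
  m3 <- compute_metrics(rec3)
  expect_equal(m3$sensitivity[m3$class == "NC"], 1)
  expect_equal(m3$sensitivity[m3$class %in% c("MCI", "AD")], c(0, 0))
  expect_true(all(is.na(m3$precision[m3$class %in% c("MCI", "AD")])))
})

test_that("rank-based AUROC agrees with the brute-force pair count", {
  # boundary cases: perfect ranking -> 1, anti-ranking -> 0
  pos <- rep(c(TRUE, FALSE), each = 5)
  expect_equal(cogshap:::auroc_score(c(6:10, 1:5) / 10, pos), 1)
  expect_equal(cogshap:::auroc_score(c(1:5, 6:10) / 10, pos), 0)
  rec <- data.frame(true = rep(c("NC", "MCI"), each = 5),
                    p_NC = c(6:10, 1:5) / 10, p_MCI = 0, p_AD = 0)
  expect_error(ovr_auroc(rec), "positives and negatives") # no AD rows

  set.seed(31)
  for (r in 1:5) {
    n <- 40
    scores <- sample(seq(0, 1, length.out = 15), n, replace = TRUE) # with ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_equal(cogshap:::auroc_score(scores, pos), brute_auroc(scores, pos),
                 tolerance = 1e-12)
  }
  # label-independent scores at n = 10000 sit near 0.5
  set.seed(32)
  s <- runif(10000); pos <- runif(10000) < 0.5
  expect_lt(abs(cogshap:::auroc_score(s, pos) - 0.5), 0.02)
})

test_that("ensemble classification is deterministic and order-invariant in U", {
  co <- tiny_cohort(n = 9)
  cfg <- fast_config(U = 3, n_train = 6)
  fit1 <- classify_cohort(co, cfg)
  fit2 <- classify_cohort(co, cfg)
  expect_equal(fit1$predictions, fit2$predictions)
  expect_true(all(abs(rowSums(as.matrix(
    fit1$predictions[, c("p_NC", "p_MCI", "p_AD")])) - 1) < 1e-9))
  expect_s3_class(fit1, "cog_ensemble")
  expect_output(print(fit1), "AUROC")
})
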