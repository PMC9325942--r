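test_that("coalition values marginalize absent features over the background", {
  set.seed(21)
  w <- c(0.4, -0.3, 0.2, 0.1)
  bg <- matrix(rnorm(32), 8, 4)
  vf <- value_function(linear_scorer(w, scale = 4), bg)
  x <- c(1, 2, -1, 0.5)
  # full coalition: scorer(x) exactly
  expect_equal(coalition_value(vf, x, 1:4),
               0.5 + sum(w * x) / 4, tolerance = 1e-12)
  # empty coalition: mean scorer over background
  expect_equal(coalition_value(vf, x, integer(0)),
               mean(0.5 + bg %*% w / 4), tolerance = 1e-12)
  # partial coalition: closed form with background means
  mu <- colMeans(bg)
  F <- c(1, 3)
  expect_equal(coalition_value(vf, x, F),
               0.5 + (sum(w[F] * x[F]) + sum(w[-F] * mu[-F])) / 4,
               tolerance = 1e-12)
  expect_error(value_function(linear_scorer(w), bg[0, , drop = FALSE]),
               "non-empty")
})

test_that("exact Shapley equals the brute-force all-orderings average", {
  set.seed(22)
  # nonlinear scorer so the oracle is not trivially linear
  scorer <- function(X) {
    X <- as.matrix(X)
    as.numeric(stats::plogis(0.8 * X[, 1] - 0.5 * X[, 2] * X[, 3] +
                               0.3 * X[, 4]^2 - 0.4 * X[, 5]))
  }
  bg <- matrix(rnorm(30), 6, 5)
  vf <- value_function(scorer, bg)
  for (r in 1:3) {
    x <- rnorm(5)
    sv <- exact_shapley(vf, x)
    expect_lt(max(abs(sv$phi - brute_shapley(vf, x))), 1e-10)
    expect_lt(abs(shap_gap(sv)), 1e-9)  # local accuracy
  }
})

test_that("exact Shapley reproduces the linear closed form w_j (x_j - mu_j)", {
  set.seed(23)
  w <- rnorm(6)
  bg <- matrix(rnorm(60), 10, 6)
  vf <- value_function(linear_scorer(w, scale = 10), bg)
  x <- rnorm(6)
  sv <- exact_shapley(vf, x)
  expect_equal(unname(sv$phi), (w / 10) * (x - colMeans(bg)), tolerance = 1e-10)
})

test_that("single-feature and symmetry axioms hold under enumeration", {
  bg <- matrix(rnorm(5), 5, 1)
  vf1 <- value_function(function(X) as.numeric(stats::plogis(X[, 1])), bg)
  sv1 <- exact_shapley(vf1, 0.7)
  expect_equal(unname(sv1$phi), sv1$prediction - sv1$baseline, tolerance = 1e-12)

  # exchangeable features with identical values get equal attributions
  bg2 <- matrix(rep(rnorm(6), 2), 6, 2)
  vfs <- value_function(function(X) as.numeric(0.3 + 0.2 * (X[, 1] + X[, 2])),
                        bg2)
  svs <- exact_shapley(vfs, c(1.3, 1.3))
  expect_equal(svs$phi[[1]], svs$phi[[2]], tolerance = 1e-12)

  # dummy feature: ignored by the scorer -> attribution 0
  bg3 <- matrix(rnorm(12), 6, 2)
  vfd <- value_function(function(X) as.numeric(stats::plogis(X[, 1])), bg3)
  svd <- exact_shapley(vfd, c(0.4, 2))
  expect_equal(unname(svd$phi[2]), 0, tolerance = 1e-12)
})

test_that("Monte Carlo Shapley converges to exact and honors determinism", {
  set.seed(24)
  scorer <- function(X) {
    X <- as.matrix(X)
    as.numeric(stats::plogis(X[, 1] - 0.7 * X[, 2] + 0.5 * X[, 3] * X[, 4]))
  }
  bg <- matrix(rnorm(40), 10, 4)
  vf <- value_function(scorer, bg)
  x <- c(0.8, -0.5, 1.2, 0.3)
  ex <- exact_shapley(vf, x)
  mc <- monte_carlo_shapley(vf, x, n_permutations = 5000, seed = 3)
  rng <- diff(range(ex$phi))
  expect_lt(max(abs(mc$phi - ex$phi)), 0.05 * rng)
  expect_lt(abs(shap_gap(mc)), 1e-12)  # efficiency enforced exactly
  mc2 <- monte_carlo_shapley(vf, x, n_permutations = 5000, seed = 3)
  expect_identical(mc$phi, mc2$phi)
  expect_error(exact_shapley(vf, x, enumeration_cap = 3), "monte_carlo")
})

test_that("ensemble averaging preserves local accuracy by linearity", {
  co <- tiny_cohort(n = 10)
  bal <- undersample_train(co, 8, seed = 2)
  X <- as.matrix(bal[, cog_indexes()])
  y <- bal$diagnosis
  models <- lapply(1:3, function(s) grow_forest(X, y, ntree = 15, seed = s))
  bg <- X[seq(1, 24, by = 2), ]
  x <- as.numeric(co[1, cog_indexes()])
  names(x) <- cog_indexes()
  sv <- ensemble_shap(x, models, class = "NC", background = bg)
  expect_lt(abs(shap_gap(sv)), 1e-9)
  per <- lapply(models, function(m)
    exact_shapley(value_function(m, bg, "NC"), x))
  expect_equal(sv$phi, Reduce(`+`, lapply(per, `[[`, "phi")) / 3,
               tolerance = 1e-12)
  # U identical models = single-model vector
  sv1 <- ensemble_shap(x, models[c(1, 1)], "NC", bg)
  expect_equal(sv1$phi, per[[1]]$phi, tolerance = 1e-12)
})

test_that("explain_cohort yields out-of-fold, locally accurate attributions", {
  co <- tiny_cohort(n = 9)
  fit <- classify_cohort(co, fast_config(U = 2, n_train = 6, ntree_grid = 20))
  shap <- explain_cohort(fit, background_size = 12, seed = 5,
                         rows = c(1:4, 11:12))
  expect_equal(nrow(shap), 6)
  gap <- shap$prediction - shap$baseline - rowSums(shap[, cog_indexes()])
  expect_lt(max(abs(gap)), 1e-9)
  expect_true(all(shap$target_class %in% c("NC", "MCI", "AD")))
  # explained class defaults to the ensemble's final label
  m <- match(paste(shap$subject_id, shap$visit_index),
             paste(fit$predictions$subject_id, fit$predictions$visit_index))
  expect_equal(shap$target_class, fit$predictions$final[m])
})
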