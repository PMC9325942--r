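# Shared fixtures and independent oracles.

# small single-visit cohort, n subjects per class
tiny_cohort <- function(n = 25, n_visits = 1, seed = 11) {
  specs <- lapply(c("NC", "MCI", "AD"), function(cl)
    trajectory_spec(cl, n_subjects = n, n_visits = n_visits))
  generate_cohort(specs, seed = seed)
}

fast_config <- function(...) {
  args <- utils::modifyList(
    list(U = 2, n_train = 15, cv = "grouped-kfold", n_folds = 3,
         ntree_grid = 30, mtry_grid = 3, seed = 7),
    list(...))
  do.call(ensemble_config, args)
}

# --- independent Shapley oracle: average marginal contribution over ALL
# orderings, evaluated with direct coalition values (no shared code path
# with exact_shapley's weighted-subset formula).
perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  out
}

brute_shapley <- function(vf, x) {
  S <- length(x)
  phi <- numeric(S)
  all_ords <- perms_of(seq_len(S))
  for (ord in all_ords) {
    for (k in seq_len(S)) {
      before <- if (k > 1) ord[seq_len(k - 1)] else integer(0)
      phi[ord[k]] <- phi[ord[k]] +
        coalition_value(vf, x, c(before, ord[k])) -
        coalition_value(vf, x, before)
    }
  }
  phi / length(all_ords)
}

# --- brute-force AUROC: all positive/negative pairs, ties count 1/2
brute_auroc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# --- exhaustive k = 2 medoid search: best medoid pair by total distance
brute_two_medoids <- function(D) {
  n <- nrow(D)
  best <- NULL; best_cost <- Inf
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    cost <- sum(pmin(D[, a], D[, b]))
    if (cost < best_cost) { best_cost <- cost; best <- c(a, b) }
  }
  assign <- ifelse(D[, best[1]] <= D[, best[2]], 1L, 2L)
  list(medoids = best, assignment = assign, cost = best_cost)
}

# linear probability scorer in [0,1] for Shapley tests
linear_scorer <- function(w, b = 0.5, scale = 1) {
  force(w); force(b); force(scale)
  function(X) as.numeric(b + (as.matrix(X) %*% w) / scale)
}

# planted two-cluster Euclidean distance matrix (separation in SD units)
planted_blobs <- function(n = 50, sep = 10, d = 2, seed = 1) {
  set.seed(seed)
  half <- n %/% 2
  X <- rbind(matrix(rnorm(half * d), half),
             matrix(rnorm((n - half) * d, mean = sep), n - half))
  list(D = as.matrix(dist(X)), truth = rep(1:2, c(half, n - half)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal shap_matrix-shaped frame from an attribution matrix
fake_shap <- function(M, ids = NULL, visits = 0L) {
  d <- as.data.frame(M)
  names(d) <- cog_indexes()
  cbind(data.frame(subject_id = ids %||% sprintf("S%03d", seq_len(nrow(M))),
                   visit_index = visits), d,
        baseline = 0.3, prediction = 0.3 + rowSums(M), target_class = "NC")
}
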