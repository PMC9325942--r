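#' k-medoids (PAM) partition of a distance matrix
#'
#' Partitioning around medoids (BUILD + SWAP, via `cluster::pam`) on a square
#' symmetric distance matrix. PAM is deterministic; the `seed` argument is
#' accepted for interface symmetry with the stochastic stages. The trivial
#' `k = n` partition (every point its own medoid, cost 0) is handled directly.
#'
#' @param D square symmetric nonnegative distance matrix with zero diagonal.
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed unused (PAM has no randomness); kept for a uniform interface.
#' @return list with `medoids` (indices), `assignment` (cluster id per member)
#'   and `cost` (total distance to assigned medoids).
#' @export
pam_kmedoids <- function(D, k, seed = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (ncol(D) != n || !isTRUE(all.equal(D, t(D))))
    stop("D must be a square symmetric matrix")
  if (any(D < 0) || any(abs(diag(D)) > 1e-12))
    stop("D must be nonnegative with zero diagonal")
  if (k < 1 || k > n) stop("k must be in [1, n]")
  if (k == n)
    return(list(medoids = seq_len(n), assignment = seq_len(n), cost = 0))
  fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
  medoids <- as.integer(fit$id.med)
  assignment <- as.integer(fit$clustering)
  cost <- sum(D[cbind(seq_len(n), medoids[assignment])])
  list(medoids = medoids, assignment = assignment, cost = cost)
}

#' Jaccard similarity of two sets
#'
#' `|A intersect B| / |A union B|`; two empty sets are identical (1).
#'
#' @param a,b vectors treated as sets.
#' @return scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Bootstrap clusterwise stability of k-medoid partitions
#'
#' For each candidate k: partition the full data with PAM; then, for each of
#' `B` bootstrap resamples (members drawn with replacement), re-cluster the
#' resample (duplicates and all), classify every original member to its
#' nearest bootstrap medoid, and record, for every original cluster, the
#' maximum Jaccard overlap with any bootstrap cluster (full member sets,
#' the reference convention for bootstrap cluster stability; clustering the
#' multiset keeps the bootstrap perturbation honest, where deduplicating
#' would collapse it to a mild subsample). A cluster's stability is
#' its mean Jaccard across bootstraps; a partition qualifies as stable when
#' its least stable cluster still reaches `stable_threshold`. Among the
#' qualifying k >= 2, the selected k is the one with the highest minimum
#' per-cluster stability (ties: higher mean stability, then smaller k); if no
#' k >= 2 qualifies, k = 1 is returned (a single cluster is trivially
#' stable). Selecting by stability rather than by the count of stable
#' clusters avoids over-partitioning: on strongly separated data, halves of a
#' true cluster can individually clear the threshold, but they are always
#' less stable than the intact cluster.
#'
#' @param D square symmetric distance matrix.
#' @param k_range candidate cluster counts (default 1:20, truncated to n-1).
#' @param B bootstrap resamples per k.
#' @param seed integer seed.
#' @param stable_threshold mean-Jaccard threshold defining a stable cluster.
#' @return object of class `stability_result`: `best_k`, `assignment`,
#'   `medoids`, `stability` (per-cluster mean Jaccard at `best_k`),
#'   `by_k` (data.frame k, n_stable, min_stability, mean_stability), `B`,
#'   `k_range`.
#' @export
clusterwise_stability <- function(D, k_range = 1:20, B = 100, seed = 1,
                                  stable_threshold = 0.75) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(B >= 1)
  k_range <- sort(unique(k_range[k_range >= 1 & k_range <= max(1, n - 1)]))
  if (length(k_range) == 0) stop("k_range empty after truncation to [1, n-1]")
  set.seed(as.integer(seed))
  per_k <- list()
  for (k in k_range) {
    full <- pam_kmedoids(D, k)
    orig <- split(seq_len(n), full$assignment)
    jac <- matrix(NA_real_, B, k)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) <= k) next  # degenerate draw, skip
      sub <- pam_kmedoids(D[idx, idx, drop = FALSE], k)
      bmed <- idx[sub$medoids]
      assign_b <- max.col(-D[, bmed, drop = FALSE], ties.method = "first")
      boot_clusters <- split(seq_len(n), assign_b)
      for (ci in seq_len(k))
        jac[b, ci] <- max(vapply(boot_clusters, jaccard, numeric(1),
                                 a = orig[[ci]]))
    }
    stab <- colMeans(jac, na.rm = TRUE)
    per_k[[as.character(k)]] <- list(k = k, fit = full, stability = stab)
  }
  by_k <- do.call(rbind, lapply(per_k, function(e) data.frame(
    k = e$k, n_stable = sum(e$stability >= stable_threshold),
    min_stability = min(e$stability), mean_stability = mean(e$stability))))
  rownames(by_k) <- NULL
  cand <- by_k[by_k$k >= 2 & by_k$min_stability >= stable_threshold, ]
  best_k <- if (nrow(cand) == 0) 1L else {
    ord <- order(-cand$min_stability, -cand$mean_stability, cand$k)
    cand$k[ord[1]]
  }
  best <- per_k[[as.character(best_k)]]
  if (is.null(best)) {  # k = 1 fallback outside the scanned range
    fit1 <- pam_kmedoids(D, 1)
    best <- list(k = 1L, fit = fit1, stability = 1)
  }
  structure(list(best_k = best$k, assignment = best$fit$assignment,
                 medoids = best$fit$medoids, stability = best$stability,
                 by_k = by_k, B = B, k_range = k_range,
                 stable_threshold = stable_threshold),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Clusterwise stability (B =", x$B, "bootstraps, k in",
      paste(range(x$k_range), collapse = ".."), ")\n")
  cat("  selected k =", x$best_k, "| per-cluster mean Jaccard:",
      paste(sprintf("%.3f", x$stability), collapse = ", "), "\n")
  invisible(x)
}

#' Per-feature characterization of clusters
#'
#' Compares the original feature distributions between the clusters of a
#' partition: two clusters use Student's two-sample t-test per feature, more
#' than two use one-way ANOVA (or Kruskal-Wallis when
#' `parametric = FALSE`). Per-feature cluster means and SDs are reported.
#' Singleton clusters are dropped with a warning.
#'
#' @param assignment integer cluster id per row of `features`.
#' @param features data frame / matrix of the original feature values.
#' @param parametric use t-test/ANOVA (`TRUE`) or Kruskal-Wallis (`FALSE`).
#' @return data.frame with one row per feature: `feature`,
#'   `mean_k` / `sd_k` per cluster, `statistic`, `p_value`, `test`.
#' @export
cluster_feature_tests <- function(assignment, features, parametric = TRUE) {
  features <- as.data.frame(features)
  stopifnot(length(assignment) == nrow(features))
  sizes <- table(assignment)
  keep_cl <- names(sizes)[sizes >= 2]
  if (length(keep_cl) < length(sizes))
    warning("singleton cluster(s) skipped in feature tests")
  if (length(keep_cl) < 2) stop("need >= 2 clusters with >= 2 members")
  keep <- assignment %in% as.integer(keep_cl)
  g <- factor(assignment[keep])
  rows <- lapply(names(features), function(fn) {
    v <- features[[fn]][keep]
    ms <- tapply(v, g, mean); ss <- tapply(v, g, sd)
    desc <- stats::setNames(
      as.list(c(ms, ss)),
      c(paste0("mean_", levels(g)), paste0("sd_", levels(g))))
    if (var(v) == 0) {
      stat <- 0; p <- 1
      test <- "degenerate"
    } else if (!parametric) {
      kw <- kruskal.test(v, g); stat <- unname(kw$statistic); p <- kw$p.value
      test <- "kruskal-wallis"
    } else if (nlevels(g) == 2) {
      tt <- t.test(v ~ g, var.equal = TRUE)
      stat <- unname(tt$statistic); p <- tt$p.value
      test <- "t-test"
    } else {
      tab <- summary(aov(v ~ g))[[1]]
      stat <- tab$`F value`[1]; p <- tab$`Pr(>F)`[1]
      test <- "anova"
    }
    cbind(data.frame(feature = fn), as.data.frame(desc),
          data.frame(statistic = stat, p_value = p, test = test))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
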