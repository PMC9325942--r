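#' True x predicted classification category
#'
#' Maps each sample's (true, final) label pair to one of the seven analysis
#' categories NC-NC, NC-MCI, MCI-NC, MCI-MCI, MCI-AD, AD-MCI, AD-AD. The two
#' extreme cross pairs NC-AD and AD-NC are mapped to `"EXCLUDED"` (too few
#' members to analyze).
#'
#' @param true,final vectors of labels in NC/MCI/AD.
#' @return character vector of category labels.
#' @examples
#' assign_category("NC", "NC")   # "NC-NC"
#' assign_category("MCI", "AD")  # "MCI-AD"
#' assign_category("NC", "AD")   # "EXCLUDED"
#' @export
assign_category <- function(true, final) {
  if (!all(true %in% DIAG_LEVELS) || !all(final %in% DIAG_LEVELS))
    stop("unknown label")
  cat <- paste(true, final, sep = "-")
  cat[cat %in% c("NC-AD", "AD-NC")] <- "EXCLUDED"
  cat
}

#' Category labels in canonical order
#' @return the seven analysis categories.
#' @export
category_levels <- function() {
  c("NC-NC", "NC-MCI", "MCI-NC", "MCI-MCI", "MCI-AD", "AD-MCI", "AD-AD")
}

#' Cosine distance between attribution vectors
#'
#' `1 - u.v / (|u| |v|)`, in `[0, 2]`. A zero-norm vector has no direction;
#' by convention its distance to anything is 1 (orthogonality), with a warning.
#'
#' @param u,v numeric vectors of equal length.
#' @return scalar distance.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("zero-norm vector: cosine distance set to 1 by convention")
    return(1)
  }
  1 - sum(u * v) / (nu * nv)
}

# condensed pairwise cosine distances of matrix rows, pair order
# (1,2),(1,3),...,(2,3),... over the supplied row order
pairwise_cosine <- function(M) {
  norms <- sqrt(rowSums(M^2))
  zero <- norms == 0
  if (any(zero)) {
    warning("zero-norm vector: cosine distance set to 1 by convention")
    norms[zero] <- 1
  }
  Mn <- M / norms
  cosmat <- tcrossprod(Mn)
  if (any(zero)) {
    cosmat[zero, ] <- 0; cosmat[, zero] <- 0
  }
  d <- 1 - cosmat[lower.tri(cosmat)]
  # lower.tri runs column-wise: (2,1),(3,1),...; relabel to row-major pairs
  pairs <- which(lower.tri(cosmat), arr.ind = TRUE)
  ord <- order(pairs[, 2], pairs[, 1])
  list(d = pmin(pmax(d[ord], 0), 2),
       i = pairs[ord, 2], j = pairs[ord, 1])
}

#' Within-category similarity network
#'
#' All pairwise cosine distances between the attribution vectors of one
#' category's members, in stable row-major order over sorted sample ids.
#'
#' @param shap a `shap_matrix` (or data frame) restricted to one category,
#'   with `subject_id`/`visit_index` columns and the ten index attribution
#'   columns.
#' @param category label attached to the network.
#' @return an object of class `similarity_network`: `category`, `members`
#'   (sample ids), `distances` (length n(n-1)/2), and the pair index columns.
#' @export
build_network <- function(shap, category = "") {
  ids <- paste(shap$subject_id, shap$visit_index, sep = ":")
  ord <- order(ids)
  shap <- shap[ord, , drop = FALSE]
  ids <- ids[ord]
  if (length(ids) < 2) {
    return(structure(list(category = category, members = ids,
                          distances = numeric(0), pair_i = integer(0),
                          pair_j = integer(0), empty = TRUE),
                     class = "similarity_network"))
  }
  M <- as.matrix(shap[, cog_indexes(), drop = FALSE])
  pc <- pairwise_cosine(M)
  structure(list(category = category, members = ids, distances = pc$d,
                 pair_i = pc$i, pair_j = pc$j, empty = FALSE),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat("Similarity network [", x$category, "]: ", length(x$members),
      " members, ", length(x$distances), " pairwise cosine distances",
      if (length(x$distances)) sprintf(" (mean %.3f)", mean(x$distances)),
      "\n", sep = "")
  invisible(x)
}

#' Compare distance distributions across categories
#'
#' One-way ANOVA (or Kruskal-Wallis) across named groups of distances, with
#' pairwise post-hoc comparisons: Tukey HSD on the ANOVA fit (default) or
#' pairwise Welch t-tests with Holm correction. Groups whose values are all
#' identical across the board return p = 1 by convention.
#'
#' @param groups named list of numeric vectors (each length >= 2).
#' @param parametric ANOVA + Tukey if `TRUE`, Kruskal-Wallis otherwise.
#' @param posthoc `"tukey"` or `"welch-holm"`.
#' @return list with `statistic`, `p_value`, `method`, and `posthoc`
#'   (symmetric matrix of adjusted pairwise p-values).
#' @export
compare_distributions <- function(groups, parametric = TRUE,
                                  posthoc = c("tukey", "welch-holm")) {
  posthoc <- match.arg(posthoc)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs >= 2 values")
  x <- unlist(groups, use.names = FALSE)
  # internal hyphen-free level codes: group names like "NC-MCI" would break
  # the parsing of TukeyHSD contrast labels
  codes <- paste0("g", seq_along(groups))
  g <- factor(rep(codes, vapply(groups, length, 1L)), levels = codes)
  k <- length(groups)
  pmat <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  diag(pmat) <- 1
  if (var(x) == 0) {
    pmat[] <- 1
    return(list(statistic = 0, p_value = 1, method = "degenerate",
                posthoc = pmat))
  }
  if (parametric) {
    fit <- aov(x ~ g)
    tab <- summary(fit)[[1]]
    statistic <- tab$`F value`[1]
    p_value <- tab$`Pr(>F)`[1]
    method <- "one-way ANOVA"
    if (posthoc == "tukey") {
      tk <- TukeyHSD(fit)$g
      for (r in rownames(tk)) {
        ab <- match(strsplit(r, "-", fixed = TRUE)[[1]], codes)
        pmat[ab[1], ab[2]] <- pmat[ab[2], ab[1]] <- tk[r, "p adj"]
      }
    }
  } else {
    kw <- kruskal.test(x, g)
    statistic <- unname(kw$statistic)
    p_value <- kw$p.value
    method <- "Kruskal-Wallis"
    posthoc <- "welch-holm"
  }
  if (posthoc == "welch-holm") {
    raw <- c()
    pairs <- utils::combn(names(groups), 2)
    for (q in seq_len(ncol(pairs))) {
      a <- groups[[pairs[1, q]]]; b <- groups[[pairs[2, q]]]
      raw[q] <- if (var(c(a, b)) == 0) 1 else t.test(a, b)$p.value
    }
    adj <- stats::p.adjust(raw, "holm")
    for (q in seq_len(ncol(pairs)))
      pmat[pairs[1, q], pairs[2, q]] <- pmat[pairs[2, q], pairs[1, q]] <- adj[q]
  }
  list(statistic = statistic, p_value = p_value, method = method,
       posthoc = pmat)
}

#' Per-index attribution importance within a category
#'
#' Signed mean and mean absolute attribution per index, ranked by mean |SHAP|.
#'
#' @param shap a `shap_matrix` restricted to one category (>= 1 row).
#' @return data.frame `index`, `mean_shap`, `mean_abs_shap`, `rank` (1 = most
#'   important by mean absolute attribution).
#' @export
variable_importance <- function(shap) {
  if (nrow(shap) == 0) stop("empty category")
  M <- as.matrix(shap[, cog_indexes(), drop = FALSE])
  out <- data.frame(index = cog_indexes(),
                    mean_shap = colMeans(M),
                    mean_abs_shap = colMeans(abs(M)))
  out$rank <- rank(-out$mean_abs_shap, ties.method = "first")
  rownames(out) <- NULL
  out
}

#' Cross-sectional (non-retrospective) analysis of attribution vectors
#'
#' Splits explained samples into the seven true x predicted categories, builds
#' a within-category cosine-distance similarity network for each, compares the
#' distance distributions across categories (ANOVA + post-hoc), and summarizes
#' per-category variable importance. Optionally runs the bootstrap k-medoid
#' stability analysis ([clusterwise_stability()]) per category network.
#'
#' @param shap a `shap_matrix` from [explain_cohort()].
#' @param predictions prediction records with `true` and `final` (aligned by
#'   subject_id/visit_index).
#' @param min_members networks smaller than this are skipped in comparisons.
#' @param stability run the cluster-stability stage per category.
#' @param k_range,B stability settings (see [clusterwise_stability()]).
#' @param seed seed for the stability bootstrap.
#' @param posthoc post-hoc procedure, see [compare_distributions()].
#' @return list of class `cross_sectional_analysis`: `networks`, `anova`
#'   (omnibus + post-hoc on distances), `importance` (per category),
#'   `stability` (per category, if requested), `categories` (per-sample
#'   labels).
#' @export
cross_sectional_analysis <- function(shap, predictions, min_members = 3,
                                     stability = FALSE, k_range = 1:20,
                                     B = 100, seed = 1,
                                     posthoc = c("tukey", "welch-holm")) {
  key <- function(d) paste(d$subject_id, d$visit_index, sep = ":")
  m <- match(key(shap), key(predictions))
  if (anyNA(m)) stop("shap matrix and predictions do not align")
  category <- assign_category(predictions$true[m], predictions$final[m])
  networks <- list()
  for (cl in category_levels()) {
    rows <- which(category == cl)
    if (length(rows) >= 2)
      networks[[cl]] <- build_network(shap[rows, , drop = FALSE], cl)
  }
  dist_groups <- lapply(networks, `[[`, "distances")
  dist_groups <- dist_groups[vapply(dist_groups, length, 1L) >= min_members]
  anova_res <- if (length(dist_groups) >= 2)
    compare_distributions(dist_groups, posthoc = match.arg(posthoc))
  importance <- lapply(networks, function(nw) {
    rows <- which(category == nw$category)
    variable_importance(shap[rows, , drop = FALSE])
  })
  stab <- NULL
  if (stability) {
    stab <- lapply(networks, function(nw) {
      n <- length(nw$members)
      if (n < 4) return(NULL)
      D <- matrix(0, n, n)
      D[cbind(nw$pair_i, nw$pair_j)] <- nw$distances
      D <- D + t(D)
      clusterwise_stability(D, k_range = k_range[k_range <= n - 1],
                            B = B, seed = seed)
    })
  }
  structure(list(networks = networks, anova = anova_res,
                 importance = importance, stability = stab,
                 categories = category),
            class = "cross_sectional_analysis")
}
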