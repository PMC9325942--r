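#' Select subjects for retrospective analysis
#'
#' Keeps subjects with at least `min_visits` visits and returns their first
#' and last visit (chronological order by `visit_index`).
#'
#' @param cohort a cohort table.
#' @param min_visits minimum visit count (default 3).
#' @return data.frame `subject_id`, `first_visit`, `last_visit`, `n_visits`,
#'   `first_diagnosis`, `last_diagnosis`.
#' @export
select_longitudinal <- function(cohort, min_visits = 3) {
  sp <- split(seq_len(nrow(cohort)), cohort$subject_id)
  rows <- lapply(sp, function(ix) {
    ix <- ix[order(cohort$visit_index[ix])]
    if (length(ix) < min_visits) return(NULL)
    data.frame(subject_id = cohort$subject_id[ix[1]],
               first_visit = cohort$visit_index[ix[1]],
               last_visit = cohort$visit_index[ix[length(ix)]],
               n_visits = length(ix),
               first_diagnosis = cohort$diagnosis[ix[1]],
               last_diagnosis = cohort$diagnosis[ix[length(ix)]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (is.null(out))
    out <- data.frame(subject_id = character(0), first_visit = integer(0),
                      last_visit = integer(0), n_visits = integer(0),
                      first_diagnosis = character(0),
                      last_diagnosis = character(0))
  out
}

#' Trajectory class from first/last diagnosis
#'
#' The six analysis classes: stable NC/MCI/AD and the three progressions
#' (NC conv MCI, NC conv AD, MCI conv AD). Diagnostic reversions (e.g.
#' AD -> MCI) are labelled `"OTHER"` and excluded from group comparisons.
#'
#' @param first,last diagnosis labels at first and last visit.
#' @return character vector of trajectory classes.
#' @examples
#' assign_trajectory("NC", "NC")   # "stable NC"
#' assign_trajectory("MCI", "AD")  # "MCI conv AD"
#' assign_trajectory("AD", "MCI")  # "OTHER"
#' @export
assign_trajectory <- function(first, last) {
  if (!all(first %in% DIAG_LEVELS) || !all(last %in% DIAG_LEVELS))
    stop("unknown label")
  out <- ifelse(first == last, paste("stable", first),
                paste(first, "conv", last))
  reverted <- match(last, DIAG_LEVELS) < match(first, DIAG_LEVELS)
  out[reverted] <- "OTHER"
  out
}

#' Trajectory class labels in canonical order
#' @return the six trajectory classes.
#' @export
trajectory_levels <- function() {
  c("stable NC", "stable MCI", "stable AD",
    "NC conv MCI", "NC conv AD", "MCI conv AD")
}

#' Build per-subject trajectory records
#'
#' Joins the first- and last-visit attribution vectors of each retrospective
#' subject, assigns the trajectory class, and computes the first-vs-last
#' cosine distance of the attribution vectors. Demographic covariates (age,
#' sex, education at first visit) are carried along for the ANCOVA.
#'
#' @param shap a `shap_matrix` covering at least the first and last visits.
#' @param cohort the cohort table the attributions refer to.
#' @param min_visits minimum visit count (default 3).
#' @return data.frame of class `trajectory_table`: `subject_id`, `trajectory`,
#'   `distance`, covariates, plus `first_<index>` / `last_<index>` attribution
#'   columns.
#' @export
trajectory_records <- function(shap, cohort, min_visits = 3) {
  sel <- select_longitudinal(cohort, min_visits)
  idx <- cog_indexes()
  key <- function(s, v) paste(s, v, sep = ":")
  skey <- key(shap$subject_id, shap$visit_index)
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    kf <- match(key(sel$subject_id[i], sel$first_visit[i]), skey)
    kl <- match(key(sel$subject_id[i], sel$last_visit[i]), skey)
    if (is.na(kf) || is.na(kl)) return(NULL)
    u <- as.numeric(shap[kf, idx]); v <- as.numeric(shap[kl, idx])
    crow <- cohort[cohort$subject_id == sel$subject_id[i] &
                     cohort$visit_index == sel$first_visit[i], ][1, ]
    fv <- stats::setNames(as.list(u), paste0("first_", idx))
    lv <- stats::setNames(as.list(v), paste0("last_", idx))
    cbind(data.frame(subject_id = sel$subject_id[i],
                     trajectory = assign_trajectory(sel$first_diagnosis[i],
                                                    sel$last_diagnosis[i]),
                     distance = cosine_distance(u, v),
                     AGE = crow$AGE, SEX = crow$SEX,
                     EDUCATION = crow$EDUCATION, stringsAsFactors = FALSE),
          as.data.frame(fv), as.data.frame(lv))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trajectory_table", "data.frame")
  out
}

#' First-vs-last attribution distance of one record
#'
#' @param record one row of a `trajectory_table`.
#' @return cosine distance between the first- and last-visit vectors.
#' @export
longitudinal_distance <- function(record) {
  idx <- cog_indexes()
  cosine_distance(as.numeric(record[paste0("first_", idx)]),
                  as.numeric(record[paste0("last_", idx)]))
}

#' ANCOVA of longitudinal distances across trajectory classes
#'
#' Linear model `distance ~ trajectory + AGE + SEX + EDUCATION`; the class
#' effect is the F-test of the trajectory factor adjusted for the covariates.
#' Post-hoc: Tukey-style studentized-range comparisons of the
#' covariate-adjusted class means (`ptukey` with the residual df).
#'
#' @param records a `trajectory_table` (OTHER rows are dropped).
#' @param min_per_class classes with fewer subjects are dropped.
#' @return list `f_statistic`, `p_value`, `posthoc` (adjusted p matrix),
#'   `adjusted_means`, `model` (the `lm` fit), `n_per_class`.
#' @export
ancova_compare <- function(records, min_per_class = 3) {
  d <- records[records$trajectory != "OTHER", , drop = FALSE]
  keep <- names(which(table(d$trajectory) >= min_per_class))
  d <- d[d$trajectory %in% keep, , drop = FALSE]
  if (length(unique(d$trajectory)) < 2)
    stop("need >= 2 trajectory classes with >= ", min_per_class, " subjects")
  d$trajectory <- factor(d$trajectory,
                         levels = intersect(trajectory_levels(), keep))
  d$SEX <- factor(d$SEX)
  covars <- c("AGE", "EDUCATION", if (nlevels(d$SEX) > 1) "SEX")
  form <- stats::reformulate(c("trajectory", covars), response = "distance")
  fit <- lm(form, data = d)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient ANCOVA design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  reduced <- lm(stats::reformulate(covars, response = "distance"), data = d)
  cmp <- anova(reduced, fit)
  f_stat <- cmp$F[2]; p_val <- cmp$`Pr(>F)`[2]
  # covariate-adjusted class means: predictions at covariate means
  lv <- levels(d$trajectory)
  newd <- d[rep(1, length(lv)), , drop = FALSE]
  newd$trajectory <- factor(lv, levels = lv)
  newd$AGE <- mean(d$AGE); newd$EDUCATION <- mean(d$EDUCATION)
  if ("SEX" %in% covars) newd$SEX <- factor(levels(d$SEX)[1], levels(d$SEX))
  Xn <- model.matrix(stats::delete.response(stats::terms(fit)), newd)
  adj <- drop(Xn %*% coef(fit))
  names(adj) <- lv
  V <- Xn %*% vcov(fit) %*% t(Xn)
  k <- length(lv)
  pmat <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  diag(pmat) <- 1
  dfres <- fit$df.residual
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    se <- sqrt(V[a, a] + V[b, b] - 2 * V[a, b])
    q <- abs(adj[a] - adj[b]) / (se / sqrt(2))
    pmat[a, b] <- pmat[b, a] <- ptukey(q, k, dfres, lower.tail = FALSE)
  }
  list(f_statistic = f_stat, p_value = p_val, posthoc = pmat,
       adjusted_means = adj, model = fit,
       n_per_class = table(d$trajectory))
}

perm_result <- function(observed, null_stats, alternative, seed) {
  r <- switch(alternative,
              greater = sum(null_stats >= observed),
              less = sum(null_stats <= observed))
  structure(list(observed = observed, null = null_stats,
                 p_value = (r + 1) / (length(null_stats) + 1),
                 B_perm = length(null_stats), alternative = alternative,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test: observed =", signif(x$observed, 5),
      "| p =", signif(x$p_value, 4),
      sprintf("(%s, B = %d)\n", x$alternative, x$B_perm))
  invisible(x)
}

#' Class-level permutation test of above-chance longitudinal change
#'
#' Observed statistic: mean within-subject cosine distance between first- and
#' last-visit attribution vectors in one trajectory class. Null: last-visit
#' vectors are randomly re-paired across subjects of the class (breaking the
#' longitudinal coupling while keeping both marginals), `B_perm` times. The
#' one-sided p-value `(r + 1) / (B_perm + 1)` with `r = #(null >= observed)`
#' (direction `"greater"`, configurable) asks whether within-subject change
#' reaches beyond what unrelated first/last pairings produce. Note that
#' within-subject first/last swaps would leave the symmetric cosine distance
#' unchanged, hence the cross-subject re-pairing null.
#'
#' @param records `trajectory_table` rows of one class (>= `min_subjects`).
#' @param B_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param alternative `"greater"` (observed larger than null) or `"less"`.
#' @param min_subjects minimum class size.
#' @return a `permutation_result`.
#' @export
class_distance_permutation <- function(records, B_perm = 1000, seed = 1,
                                       alternative = c("greater", "less"),
                                       min_subjects = 5) {
  alternative <- match.arg(alternative)
  n <- nrow(records)
  if (n < min_subjects) stop("class too small: ", n, " subjects")
  idx <- cog_indexes()
  Fm <- as.matrix(records[, paste0("first_", idx), drop = FALSE])
  Lm <- as.matrix(records[, paste0("last_", idx), drop = FALSE])
  pair_mean <- function(perm) {
    mean(vapply(seq_len(n),
                function(i) cosine_distance(Fm[i, ], Lm[perm[i], ]),
                numeric(1)))
  }
  observed <- pair_mean(seq_len(n))
  set.seed(as.integer(seed))
  null_stats <- vapply(seq_len(B_perm),
                       function(b) pair_mean(sample.int(n)), numeric(1))
  perm_result(observed, null_stats, alternative, seed)
}

#' Per-index sign-flip permutation test of longitudinal attribution change
#'
#' Observed statistic: |mean over subjects of (last - first) attribution of
#' index `j`|. Null: each subject's first/last assignment is independently
#' swapped (a sign flip of its difference), which is exact when the
#' difference distribution is symmetric around 0 under no change.
#'
#' @param records `trajectory_table` rows of one class.
#' @param index index name (one of [cog_indexes()]) or its position.
#' @param B_perm number of sign-flip draws (default 1000).
#' @param seed integer seed.
#' @param min_subjects minimum class size.
#' @return a `permutation_result` (two-sided via the absolute statistic).
#' @export
per_index_change_test <- function(records, index, B_perm = 1000, seed = 1,
                                  min_subjects = 5) {
  n <- nrow(records)
  if (n < min_subjects) stop("class too small: ", n, " subjects")
  if (is.numeric(index)) index <- cog_indexes()[index]
  diffs <- records[[paste0("last_", index)]] - records[[paste0("first_", index)]]
  observed <- abs(mean(diffs))
  set.seed(as.integer(seed))
  null_stats <- vapply(seq_len(B_perm), function(b) {
    abs(mean(diffs * (1 - 2 * rbinom(n, 1, 0.5))))
  }, numeric(1))
  perm_result(observed, null_stats, "greater", seed)
}

#' Retrospective (longitudinal) analysis
#'
#' Builds trajectory records, runs the ANCOVA across trajectory classes, the
#' class-level re-pairing permutation test, and the per-index sign-flip test
#' for every class with enough subjects; also tabulates per-class mean first
#' and last attribution profiles (radar-plot data).
#'
#' @param shap a `shap_matrix` from [explain_cohort()].
#' @param cohort the cohort table.
#' @param min_visits minimum visits for inclusion (default 3).
#' @param B_perm permutations per test (default 1000).
#' @param seed integer seed.
#' @param min_subjects minimum class size for the permutation tests.
#' @return list of class `longitudinal_analysis`: `records`, `ancova`,
#'   `class_tests` (per class), `index_tests` (class x index p-value matrix),
#'   `radar` (per class/visit mean attribution profile).
#' @export
longitudinal_analysis <- function(shap, cohort, min_visits = 3, B_perm = 1000,
                                  seed = 1, min_subjects = 5) {
  records <- trajectory_records(shap, cohort, min_visits)
  classes <- intersect(trajectory_levels(), unique(records$trajectory))
  usable <- classes[vapply(classes, function(cl)
    sum(records$trajectory == cl) >= min_subjects, logical(1))]
  ancova <- tryCatch(ancova_compare(records), error = function(e) NULL)
  class_tests <- stats::setNames(lapply(seq_along(usable), function(i) {
    class_distance_permutation(records[records$trajectory == usable[i], ],
                               B_perm = B_perm, seed = seed + i)
  }), usable)
  idx <- cog_indexes()
  index_tests <- matrix(NA_real_, length(usable), length(idx),
                        dimnames = list(usable, idx))
  for (i in seq_along(usable)) {
    rc <- records[records$trajectory == usable[i], ]
    for (j in seq_along(idx))
      index_tests[i, j] <- per_index_change_test(
        rc, idx[j], B_perm = B_perm, seed = seed + 97 * i + j)$p_value
  }
  radar <- do.call(rbind, lapply(usable, function(cl) {
    rc <- records[records$trajectory == cl, ]
    data.frame(trajectory = cl, visit = c("first", "last"),
               rbind(colMeans(rc[, paste0("first_", idx), drop = FALSE]),
                     stats::setNames(colMeans(rc[, paste0("last_", idx),
                                                 drop = FALSE]),
                                     paste0("first_", idx))),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  if (!is.null(radar)) names(radar) <- c("trajectory", "visit", idx)
  structure(list(records = records, ancova = ancova,
                 class_tests = class_tests, index_tests = index_tests,
                 radar = radar),
            class = "longitudinal_analysis")
}
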