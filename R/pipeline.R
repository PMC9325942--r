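#' Validate a cohort table or CSV
#'
#' Enforces the cohort schema: required columns present, no missing values,
#' labels in NC/MCI/AD, unique (subject_id, visit_index) with visit indexes
#' contiguous from 0 per subject. Violations are reported with row numbers.
#'
#' @param x a data frame or path to a cohort CSV.
#' @return the validated table with class `cohort_table`.
#' @export
validate_cohort <- function(x) {
  if (is.character(x)) x <- read.csv(x, stringsAsFactors = FALSE)
  required <- c("subject_id", "visit_index", "diagnosis", cog_indexes(),
                "AGE", "SEX", "EDUCATION")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(x) == 0) stop("empty cohort table")
  bad <- which(!complete.cases(x[, required]))
  if (length(bad))
    stop("missing values in row(s): ",
         paste(head(bad, 10), collapse = ", "))
  bad <- which(!x$diagnosis %in% DIAG_LEVELS)
  if (length(bad))
    stop("unknown diagnosis label in row(s): ",
         paste(head(bad, 10), collapse = ", "), " (",
         paste(unique(x$diagnosis[bad]), collapse = ", "), ")")
  key <- paste(x$subject_id, x$visit_index)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, visit_index) in row(s): ",
         paste(head(which(duplicated(key)), 10), collapse = ", "))
  for (s in unique(x$subject_id)) {
    v <- sort(x$visit_index[x$subject_id == s])
    if (!identical(as.integer(v), seq_along(v) - 1L))
      stop("visit_index not contiguous from 0 for subject ", s)
  }
  class(x) <- c("cohort_table", "data.frame")
  x
}

#' Pipeline run configuration
#'
#' A single configuration object driving [run_full()]. Exactly one of `input`
#' (cohort CSV path) or `synthetic` (generator settings) must be given.
#' Settings may come from a YAML file via `load_run_config()`.
#'
#' @param input path to a cohort CSV, or `NULL`.
#' @param synthetic list with `specs` (list of [trajectory_spec()] argument
#'   lists: `from`, `to`, `n_subjects`, `n_visits`, `drift`) or `NULL`.
#' @param ensemble named list of [ensemble_config()] overrides.
#' @param explain named list: `method`, `background_size`, `target`,
#'   `n_permutations`.
#' @param analysis named list: `posthoc`, `B` (stability bootstraps),
#'   `B_perm`, `k_range` (max k), `stability` (logical), `min_visits`.
#' @param seed global seed; all stage seeds derive from it.
#' @param outdir output directory for [run_full()].
#' @param paper_scale restore the full-scale preset (U = 100, n_train = 500,
#'   LOSO) on top of the desk-scale defaults (U = 10, n_train = 100,
#'   grouped 5-fold).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input = NULL, synthetic = NULL, ensemble = list(),
                       explain = list(), analysis = list(), seed = 1,
                       outdir = tempfile("cogshap_run_"),
                       paper_scale = FALSE) {
  if (is.null(input) == is.null(synthetic))
    stop("exactly one of 'input' and 'synthetic' must be given")
  ens_defaults <- list(U = 10, n_train = 100, cv = "grouped-kfold",
                       n_folds = 5, inner_k = 3,
                       ntree_grid = c(100, 300, 500), mtry_grid = c(2, 3, 4))
  if (paper_scale)
    ens_defaults[c("U", "n_train", "cv")] <- list(100, 500, "loso")
  ens <- utils::modifyList(ens_defaults, ensemble)
  exp_defaults <- list(method = "exact", background_size = 100,
                       target = "predicted", n_permutations = 1000)
  ana_defaults <- list(posthoc = "tukey", B = 100, B_perm = 1000,
                       k_range = 20, stability = TRUE, min_visits = 3)
  structure(list(input = input, synthetic = synthetic, ensemble = ens,
                 explain = utils::modifyList(exp_defaults, explain),
                 analysis = utils::modifyList(ana_defaults, analysis),
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose top-level keys match [run_config()] arguments.
#' @param ... overrides applied after the file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  y <- utils::modifyList(y, list(...))
  do.call(run_config, y)
}

# deterministic stage seeds derived from the global seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483647
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
}

#' Run the full workflow
#'
#' Executes simulate (or load) -> classify -> explain -> cross-sectional
#' analysis -> longitudinal analysis, writes every stage output under
#' `config$outdir`, and returns (and writes) a run manifest with the config
#' echo, derived stage seeds, row counts and the declared output files.
#' Identical config and seed give identical outputs.
#'
#' @param config a [run_config()].
#' @param verbose log stage progress to stderr.
#' @return the manifest, invisibly; the analysis objects are attached as
#'   attributes `ensemble`, `shap`, `cross_sectional`, `longitudinal`.
#' @export
run_full <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[cogshap] ", ...)
  outfile <- function(name) file.path(config$outdir, name)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  say("stage: cohort")
  cohort <- stage("cohort", {
    if (!is.null(config$input)) validate_cohort(config$input)
    else {
      specs <- lapply(config$synthetic$specs, function(s)
        do.call(trajectory_spec, s))
      generate_cohort(specs, seed = stage_seed(config$seed, 1))
    }
  })
  write_cohort(cohort, outfile("cohort.csv"))
  files <- c(files, "cohort.csv")

  say("stage: classify")
  fit <- stage("classify", {
    cfg <- do.call(ensemble_config,
                   c(config$ensemble,
                     list(seed = stage_seed(config$seed, 2),
                          keep_models = TRUE)))
    classify_cohort(cohort, cfg)
  })
  write.csv(fit$predictions, outfile("predictions.csv"), row.names = FALSE)
  write.csv(fit$metrics, outfile("metrics.csv"), row.names = FALSE)
  write.csv(as.data.frame(fit$confusion), outfile("confusion.csv"),
            row.names = FALSE)
  write_json_report(list(auroc = as.list(fit$auroc)), outfile("metrics.json"))
  files <- c(files, "predictions.csv", "metrics.csv", "confusion.csv",
             "metrics.json")

  say("stage: explain")
  shap <- stage("explain", {
    explain_cohort(fit, target = config$explain$target,
                   method = config$explain$method,
                   background_size = config$explain$background_size,
                   n_permutations = config$explain$n_permutations,
                   seed = stage_seed(config$seed, 3))
  })
  write.csv(shap, outfile("shap_matrix.csv"), row.names = FALSE)
  files <- c(files, "shap_matrix.csv")

  say("stage: cross-sectional analysis")
  cs <- stage("analyze-cross", {
    cross_sectional_analysis(
      shap, fit$predictions, stability = isTRUE(config$analysis$stability),
      k_range = seq_len(config$analysis$k_range), B = config$analysis$B,
      seed = stage_seed(config$seed, 4), posthoc = config$analysis$posthoc)
  })
  dist_tab <- do.call(rbind, lapply(cs$networks, function(nw)
    if (!nw$empty) data.frame(category = nw$category,
                              sample_i = nw$members[nw$pair_i],
                              sample_j = nw$members[nw$pair_j],
                              distance = nw$distances)))
  if (!is.null(dist_tab))
    write.csv(dist_tab, outfile("category_distances.csv"), row.names = FALSE)
  imp_tab <- do.call(rbind, lapply(names(cs$importance), function(cl)
    cbind(category = cl, cs$importance[[cl]])))
  if (!is.null(imp_tab))
    write.csv(imp_tab, outfile("variable_importance.csv"), row.names = FALSE)
  if (!is.null(cs$anova))
    write_json_report(list(statistic = cs$anova$statistic,
                           p_value = cs$anova$p_value,
                           method = cs$anova$method,
                           posthoc = as.data.frame(cs$anova$posthoc)),
                      outfile("category_anova.json"))
  files <- c(files, "category_distances.csv", "variable_importance.csv",
             if (!is.null(cs$anova)) "category_anova.json")
  if (!is.null(cs$stability)) {
    stab_rep <- lapply(cs$stability, function(st) if (!is.null(st))
      list(best_k = st$best_k, stability = st$stability, B = st$B,
           by_k = st$by_k))
    write_json_report(stab_rep, outfile("stability.json"))
    files <- c(files, "stability.json")
    ftests <- do.call(rbind, lapply(names(cs$stability), function(cl) {
      st <- cs$stability[[cl]]
      if (is.null(st) || st$best_k < 2 || min(table(st$assignment)) < 2)
        return(NULL)
      nw <- cs$networks[[cl]]
      rows <- match(nw$members,
                    paste(cohort$subject_id, cohort$visit_index, sep = ":"))
      cbind(category = cl,
            cluster_feature_tests(st$assignment,
                                  cohort[rows, cog_indexes()]))
    }))
    if (!is.null(ftests)) {
      write.csv(ftests, outfile("cluster_feature_tests.csv"),
                row.names = FALSE)
      files <- c(files, "cluster_feature_tests.csv")
    }
  }

  say("stage: longitudinal analysis")
  lg <- stage("analyze-long", {
    longitudinal_analysis(shap, cohort,
                          min_visits = config$analysis$min_visits,
                          B_perm = config$analysis$B_perm,
                          seed = stage_seed(config$seed, 5))
  })
  write.csv(lg$records, outfile("trajectories.csv"), row.names = FALSE)
  files <- c(files, "trajectories.csv")
  if (!is.null(lg$ancova))
    write_json_report(list(f_statistic = lg$ancova$f_statistic,
                           p_value = lg$ancova$p_value,
                           adjusted_means = as.list(lg$ancova$adjusted_means),
                           posthoc = as.data.frame(lg$ancova$posthoc)),
                      outfile("longitudinal_ancova.json"))
  files <- c(files, if (!is.null(lg$ancova)) "longitudinal_ancova.json")
  if (nrow(lg$index_tests) > 0) {
    ptab <- data.frame(trajectory = rownames(lg$index_tests),
                       class_p = vapply(lg$class_tests, `[[`, numeric(1),
                                        "p_value"),
                       lg$index_tests, check.names = FALSE)
    write.csv(ptab, outfile("permutation_pvalues.csv"), row.names = FALSE)
    files <- c(files, "permutation_pvalues.csv")
  }
  if (!is.null(lg$radar)) {
    write.csv(lg$radar, outfile("radar_profiles.csv"), row.names = FALSE)
    files <- c(files, "radar_profiles.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cogshap")),
    seed = config$seed,
    stage_seeds = stats::setNames(as.list(stage_seed(config$seed, 1:5)),
                                  c("cohort", "classify", "explain",
                                    "analyze-cross", "analyze-long")),
    config = list(input = config$input, synthetic = config$synthetic,
                  ensemble = config$ensemble, explain = config$explain,
                  analysis = config$analysis),
    rows = list(cohort = nrow(cohort), predictions = nrow(fit$predictions),
                shap = nrow(shap), trajectories = nrow(lg$records)),
    outputs = files)
  write_json_report(manifest, outfile("manifest.json"))
  say("done: ", config$outdir)
  attr(manifest, "ensemble") <- fit
  attr(manifest, "shap") <- shap
  attr(manifest, "cross_sectional") <- cs
  attr(manifest, "longitudinal") <- lg
  invisible(manifest)
}
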