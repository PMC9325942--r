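#' Canonical cognitive index names
#'
#' The ten cognitive/clinical indexes used throughout the package, in the
#' fixed column order of the cohort CSV schema.
#'
#' @return character vector of length 10.
#' @export
cog_indexes <- function() {
  c("ADAS11", "ADAS13", "MMSE", "MOCA", "FAQ",
    "RAVLT_immediate", "RAVLT_learning", "RAVLT_percforgetting",
    "EcogPtTotal", "EcogSPTotal")
}

#' Valid instrument score ranges
#'
#' Instrument-defined score ranges used to clip synthetic Gaussian draws
#' (e.g. MMSE is a 0-30 screen; Everyday Cognition totals average items rated
#' 1-4). Published class standard deviations can otherwise generate
#' out-of-range values.
#'
#' @return named list of `c(lo, hi)` pairs, one per index.
#' @export
index_ranges <- function() {
  list(ADAS11 = c(0, 70), ADAS13 = c(0, 85), MMSE = c(0, 30),
       MOCA = c(0, 30), FAQ = c(0, 30), RAVLT_immediate = c(0, 75),
       RAVLT_learning = c(-15, 15), RAVLT_percforgetting = c(-100, 100),
       EcogPtTotal = c(1, 4), EcogSPTotal = c(1, 4))
}

#' Per-class generative parameters
#'
#' Container for the class-conditional Gaussian parameters of the ten indexes
#' plus demographics (age and education Gaussians, male proportion).
#'
#' @param label one of `"NC"`, `"MCI"`, `"AD"`.
#' @param means,sds named numeric vectors over [cog_indexes()]; all sds > 0.
#' @param age_mean,age_sd,edu_mean,edu_sd demographic Gaussian parameters.
#' @param male_prop proportion of male subjects in `[0, 1]`.
#' @return an object of class `class_params`.
#' @export
class_params <- function(label, means, sds, age_mean, age_sd,
                         edu_mean, edu_sd, male_prop) {
  idx <- cog_indexes()
  if (!label %in% DIAG_LEVELS)
    stop("unknown class label: ", label)
  means <- means[idx]; sds <- sds[idx]
  if (anyNA(means) || anyNA(sds))
    stop("means/sds must be named over the 10 canonical indexes")
  if (any(sds <= 0)) stop("all index sds must be positive")
  if (age_sd <= 0 || edu_sd <= 0) stop("demographic sds must be positive")
  if (male_prop < 0 || male_prop > 1) stop("male_prop must be in [0, 1]")
  structure(list(label = label, means = means, sds = sds,
                 age_mean = age_mean, age_sd = age_sd,
                 edu_mean = edu_mean, edu_sd = edu_sd,
                 male_prop = male_prop),
            class = "class_params")
}

#' Reference class parameters for the NC/MCI/AD cohort
#'
#' Published per-class means and standard deviations of the ten indexes and
#' demographics in a large longitudinal ageing cohort (normal controls, mild
#' cognitive impairment, Alzheimer's dementia). These are the generator's
#' defaults; male proportions come from the printed male/female counts
#' (NC 1082/2408, MCI 1691/2912, AD 577/965).
#'
#' @return named list of three [class_params()] objects (`NC`, `MCI`, `AD`).
#' @export
default_class_params <- function() {
  idx <- cog_indexes()
  m <- function(v) stats::setNames(v, idx)
  list(
    NC = class_params("NC",
      means = m(c(6.7, 10, 29, 25.9, 0.2, 46.5, 5.9, 34.2, 1.4, 1.2)),
      sds   = m(c(3.2, 4.7, 1.2, 2.5, 0.9, 10.8, 2.4, 29.7, 0.3, 0.2)),
      age_mean = 75.2, age_sd = 7.1, edu_mean = 16.6, edu_sd = 2.4,
      male_prop = 1082 / 2408),
    MCI = class_params("MCI",
      means = m(c(9.6, 15.1, 27.8, 23.5, 2.7, 36.6, 4.5, 56.7, 1.7, 1.7)),
      sds   = m(c(4.7, 7.1, 1.9, 3.2, 3.9, 11.2, 2.6, 47.2, 0.5, 0.6)),
      age_mean = 74.5, age_sd = 7.9, edu_mean = 16.1, edu_sd = 2.7,
      male_prop = 1691 / 2912),
    AD = class_params("AD",
      means = m(c(20.6, 30.9, 22.5, 17.3, 15.4, 22.5, 1.9, 90.2, 1.9, 2.9)),
      sds   = m(c(7.3, 9, 3.6, 4.7, 7.2, 7.9, 2.8, 25.6, 0.6, 0.6)),
      age_mean = 76.5, age_sd = 7.5, edu_mean = 15.9, edu_sd = 2.5,
      male_prop = 577 / 965))
}

#' Trajectory specification for synthetic subjects
#'
#' Describes one group of subjects sharing a diagnostic trajectory: stable
#' (`from == to`) or converter (`from != to`, progression only). Converters
#' carry the start label before the switch visit and the end label from it on;
#' with `drift = "linear"` the index means (and sds) additionally interpolate
#' linearly across visits, with `"step"` they jump at the switch visit.
#'
#' @param from,to diagnosis at first / last visit (`"NC"`, `"MCI"`, `"AD"`).
#' @param n_subjects number of subjects.
#' @param n_visits visits per subject (>= 1; >= 3 for retrospective use).
#' @param drift `"step"` or `"linear"` index-mean dynamics for converters.
#' @param switch_visit 0-based visit at which the label switches
#'   (default: midpoint, `floor(n_visits / 2)`).
#' @return an object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(from, to = from, n_subjects, n_visits = 1,
                            drift = c("step", "linear"), switch_visit = NULL) {
  drift <- match.arg(drift)
  if (!from %in% DIAG_LEVELS || !to %in% DIAG_LEVELS)
    stop("unknown class label: ", from, "/", to)
  if (match(to, DIAG_LEVELS) < match(from, DIAG_LEVELS))
    stop("trajectories never revert: 'to' must not precede 'from'")
  if (n_subjects < 1 || n_visits < 1) stop("n_subjects and n_visits must be >= 1")
  if (from != to && n_visits < 2) stop("a converter needs at least 2 visits")
  if (is.null(switch_visit)) switch_visit <- floor(n_visits / 2)
  if (from != to && (switch_visit < 1 || switch_visit > n_visits - 1))
    stop("switch_visit must lie in [1, n_visits - 1]")
  label <- if (from == to) paste("stable", from) else paste(from, "conv", to)
  structure(list(from = from, to = to, n_subjects = as.integer(n_subjects),
                 n_visits = as.integer(n_visits), drift = drift,
                 switch_visit = as.integer(switch_visit), label = label),
            class = "trajectory_spec")
}

#' Interpolate class index means along a trajectory
#'
#' @param start,end [class_params()] of the start and end class.
#' @param visit_fraction position along the trajectory in `[0, 1]`.
#' @param shape `"linear"` interpolation or `"step"` (start means below
#'   `switch_fraction`, end means at/after it).
#' @param switch_fraction switch point for the `"step"` shape.
#' @return named numeric vector of per-index means.
#' @examples
#' p <- default_class_params()
#' drift_means(p$NC, p$AD, 0.5)[["MMSE"]]  # (29 + 22.5) / 2
#' @export
drift_means <- function(start, end, visit_fraction,
                        shape = c("linear", "step"), switch_fraction = 0.5) {
  shape <- match.arg(shape)
  if (visit_fraction < 0 || visit_fraction > 1)
    stop("visit_fraction must be in [0, 1]")
  if (shape == "step")
    return(if (visit_fraction < switch_fraction) start$means else end$means)
  (1 - visit_fraction) * start$means + visit_fraction * end$means
}

# sds interpolated the same way as means (linear drift), so converter noise
# levels transition smoothly between the class regimes.
drift_sds <- function(start, end, visit_fraction, shape, switch_fraction = 0.5) {
  if (shape == "step")
    return(if (visit_fraction < switch_fraction) start$sds else end$sds)
  (1 - visit_fraction) * start$sds + visit_fraction * end$sds
}

clip_indexes <- function(x, ranges = index_ranges()) {
  for (nm in names(ranges))
    x[[nm]] <- pmin(pmax(x[[nm]], ranges[[nm]][1]), ranges[[nm]][2])
  x
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws subject-visit rows with class-conditional Gaussian index values
#' (independent across indexes by default, or coupled through a Gaussian
#' copula via `index_corr`), demographics per class, and stable/converter
#' diagnostic trajectories. Draws are clipped to the instrument ranges of
#' [index_ranges()].
#'
#' @param specs a [trajectory_spec()] or list of them.
#' @param params named list of [class_params()] covering NC, MCI and AD
#'   (default [default_class_params()]).
#' @param seed integer seed; identical seed and specs give identical tables.
#' @param index_corr optional 10x10 correlation matrix coupling the index
#'   draws (Gaussian copula on the marginal Gaussians).
#' @param visit_interval_years spacing between visits used to age subjects.
#' @param clip clip index draws to [index_ranges()] (default). Clipping
#'   censors the Gaussian marginals, so sample means of strongly clipped
#'   indexes (FAQ and Ecog near their floors, MMSE near its ceiling) sit
#'   slightly off the nominal class means; `clip = FALSE` gives the pure
#'   Gaussian sampler.
#' @return a `data.frame` (class `cohort_table`): `subject_id`, `visit_index`
#'   (0-based, contiguous), `diagnosis`, the ten indexes, `AGE`, `SEX`
#'   (`"M"`/`"F"`), `EDUCATION`, plus a `trajectory` attribute column.
#' @export
generate_cohort <- function(specs, params = default_class_params(), seed = 1,
                            index_corr = NULL, visit_interval_years = 0.5,
                            clip = TRUE) {
  if (inherits(specs, "trajectory_spec")) specs <- list(specs)
  if (length(specs) == 0) stop("empty spec list")
  if (!all(vapply(specs, inherits, TRUE, "trajectory_spec")))
    stop("specs must be trajectory_spec objects")
  if (!all(DIAG_LEVELS %in% names(params)))
    stop("params must cover NC, MCI and AD")
  idx <- cog_indexes()
  chol_R <- NULL
  if (!is.null(index_corr)) {
    index_corr <- as.matrix(index_corr)
    if (!isTRUE(all.equal(dim(index_corr), c(10L, 10L))) ||
        !isTRUE(all.equal(index_corr, t(index_corr))))
      stop("index_corr must be a symmetric 10x10 matrix")
    chol_R <- chol(index_corr)
  }
  set.seed(as.integer(seed))
  out <- list()
  sid <- 0L
  for (sp in specs) {
    start <- params[[sp$from]]; end <- params[[sp$to]]
    for (s in seq_len(sp$n_subjects)) {
      sid <- sid + 1L
      subject <- sprintf("S%05d", sid)
      sex <- if (stats::runif(1) < start$male_prop) "M" else "F"
      age0 <- min(max(rnorm(1, start$age_mean, start$age_sd), 55), 90)
      edu <- max(rnorm(1, start$edu_mean, start$edu_sd), 0)
      nv <- sp$n_visits
      z <- matrix(rnorm(nv * 10), nv, 10)
      if (!is.null(chol_R)) z <- z %*% chol_R
      colnames(z) <- idx
      rows <- vector("list", nv)
      for (v in seq_len(nv) - 1L) {
        frac <- if (nv == 1) 0 else v / (nv - 1)
        diag_v <- if (v < sp$switch_visit || sp$from == sp$to) sp$from else sp$to
        mu <- drift_means(start, end, frac, shape = sp$drift,
                          switch_fraction = sp$switch_visit / nv)
        sg <- drift_sds(start, end, frac, shape = sp$drift,
                        switch_fraction = sp$switch_visit / nv)
        vals <- as.list(mu + sg * z[v + 1L, ])
        if (clip) vals <- clip_indexes(vals)
        rows[[v + 1L]] <- data.frame(
          subject_id = subject, visit_index = v, diagnosis = diag_v,
          as.data.frame(vals), AGE = age0 + v * visit_interval_years,
          SEX = sex, EDUCATION = edu, trajectory = sp$label,
          stringsAsFactors = FALSE)
      }
      out[[length(out) + 1L]] <- do.call(rbind, rows)
    }
  }
  cohort <- do.call(rbind, out)
  rownames(cohort) <- NULL
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

#' Write / read a cohort CSV
#'
#' The CSV schema is `subject_id, visit_index, diagnosis, <10 indexes>, AGE,
#' SEX, EDUCATION` (the `trajectory` column, if present, is kept as a trailing
#' convenience column).
#'
#' @param cohort a cohort table.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   validated cohort table (see [validate_cohort()]).
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  validate_cohort(read.csv(path, stringsAsFactors = FALSE))
}
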