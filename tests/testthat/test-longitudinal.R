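# trajectory table built directly from attribution matrices
fake_records <- function(first, last, trajectory = "stable NC", seed = 61) {
  set.seed(seed)
  n <- nrow(first)
  idx <- cog_indexes()
  fv <- as.data.frame(first); names(fv) <- paste0("first_", idx)
  lv <- as.data.frame(last); names(lv) <- paste0("last_", idx)
  cbind(data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                   trajectory = trajectory,
                   distance = vapply(seq_len(n), function(i)
                     cosine_distance(as.numeric(first[i, ]),
                                     as.numeric(last[i, ])), numeric(1)),
                   AGE = rnorm(n, 75, 7), SEX = sample(c("M", "F"), n, TRUE),
                   EDUCATION = rnorm(n, 16, 2), stringsAsFactors = FALSE),
        fv, lv)
}

test_that("retrospective selection keeps subjects with >= 3 visits", {
  co <- generate_cohort(list(
    trajectory_spec("NC", n_subjects = 3, n_visits = 2),
    trajectory_spec("MCI", n_subjects = 2, n_visits = 3),
    trajectory_spec("MCI", "AD", n_subjects = 2, n_visits = 5)), seed = 60)
  sel <- select_longitudinal(co)
  expect_equal(nrow(sel), 4)              # 2-visit subjects excluded
  expect_true(all(sel$n_visits >= 3))
  expect_equal(sel$first_visit, rep(0L, 4))
  expect_equal(sort(unique(sel$last_visit)), c(2L, 4L))  # middle visits unused
  conv <- sel[sel$n_visits == 5, ]
  expect_equal(conv$first_diagnosis, rep("MCI", 2))
  expect_equal(conv$last_diagnosis, rep("AD", 2))
})

test_that("trajectory classes map as declared, reversions to OTHER", {
  expect_equal(assign_trajectory("NC", "NC"), "stable NC")
  expect_equal(assign_trajectory("MCI", "AD"), "MCI conv AD")
  expect_equal(assign_trajectory("NC", "AD"), "NC conv AD")
  expect_equal(assign_trajectory("AD", "MCI"), "OTHER")
  expect_equal(assign_trajectory("MCI", "NC"), "OTHER")
  expect_error(assign_trajectory("NC", "bad"), "unknown label")
})

test_that("longitudinal distance is the first-vs-last cosine distance", {
  M <- matrix(rnorm(20), 2, 10)
  rec <- fake_records(M, M)                      # identical -> 0
  expect_equal(rec$distance, c(0, 0), tolerance = 1e-12)
  expect_equal(longitudinal_distance(rec[1, ]), 0, tolerance = 1e-12)
  rec2 <- fake_records(M, -M)                    # antipodal -> 2
  expect_equal(rec2$distance, c(2, 2), tolerance = 1e-12)
  u <- c(1, 0, rep(0, 8)); v <- c(0, 1, rep(0, 8))
  rec3 <- fake_records(rbind(u, u), rbind(v, v)) # orthogonal -> 1
  expect_equal(rec3$distance, c(1, 1), tolerance = 1e-12)
})

test_that("ANCOVA detects class effects and matches plain ANOVA when covariates are inert", {
  set.seed(62)
  n <- 60
  M <- matrix(rnorm(2 * n * 10), 2 * n, 10)
  rec <- fake_records(M, M + rnorm(2 * n * 10, 0, 0.1),
                      trajectory = rep(c("stable NC", "MCI conv AD"), each = n))
  rec$distance <- rnorm(2 * n, 0.5, 0.1) +
    ifelse(rec$trajectory == "MCI conv AD", 0.2, 0)  # 2 SD shift
  res <- ancova_compare(rec)
  expect_lt(res$p_value, 1e-3)
  expect_lt(res$posthoc["stable NC", "MCI conv AD"], 0.01)
  # inert covariates: class p close to covariate-free ANOVA
  plain <- summary(aov(distance ~ trajectory, data = rec))[[1]]$`Pr(>F)`[1]
  expect_equal(log10(res$p_value), log10(plain), tolerance = 0.5)
  # adjusted means preserve the true ordering
  expect_gt(res$adjusted_means["MCI conv AD"], res$adjusted_means["stable NC"])
})

test_that("ANCOVA class test is calibrated under a pure covariate effect", {
  set.seed(63)
  pvals <- replicate(300, {
    n <- 30
    rec <- fake_records(matrix(rnorm(2 * n * 10), 2 * n, 10),
                        matrix(rnorm(2 * n * 10), 2 * n, 10),
                        trajectory = rep(c("stable NC", "stable MCI"), each = n),
                        seed = sample.int(1e6, 1))
    rec$distance <- 0.5 + 0.05 * (rec$AGE - 75) + rnorm(2 * n, 0, 0.1)
    ancova_compare(rec)$p_value
  })
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.02); expect_lt(rate, 0.08)
})

test_that("class-level permutation test honors its degenerate and floor cases", {
  set.seed(64)
  M <- matrix(rnorm(80), 8, 10)
  # last = first for every subject: observed 0, p = 1
  rec <- fake_records(M, M)
  res <- class_distance_permutation(rec, B_perm = 200, seed = 1)
  expect_equal(res$observed, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  # p floor = 1/(B+1)
  expect_gte(res$p_value, 1 / 201)
  res_b1000 <- class_distance_permutation(rec, B_perm = 1000, seed = 1)
  expect_gte(res_b1000$p_value, 1 / 1001)
  expect_error(class_distance_permutation(rec[1:3, ]), "too small")
})

test_that("permutation tests are calibrated under their nulls", {
  # class-level test: i.i.d. first/last vectors -> uniform p on its grid
  set.seed(65)
  p1 <- replicate(400, {
    rec <- fake_records(matrix(rnorm(100), 10, 10),
                        matrix(rnorm(100), 10, 10),
                        seed = sample.int(1e6, 1))
    class_distance_permutation(rec, B_perm = 99,
                               seed = sample.int(1e6, 1))$p_value
  })
  rate1 <- mean(p1 <= 0.05)
  expect_gt(rate1, 0.03); expect_lt(rate1, 0.07)
  expect_gt(mean(p1), 0.45); expect_lt(mean(p1), 0.55)

  # per-index sign-flip test under a symmetric-difference null
  set.seed(66)
  p2 <- replicate(500, {
    F1 <- matrix(rnorm(200), 20, 10)
    rec <- fake_records(F1, F1 + matrix(rnorm(200), 20, 10),
                        seed = sample.int(1e6, 1))
    per_index_change_test(rec, "MMSE", B_perm = 99,
                          seed = sample.int(1e6, 1))$p_value
  })
  rate2 <- mean(p2 <= 0.05)
  expect_gt(rate2, 0.03); expect_lt(rate2, 0.07)
})

test_that("per-index test finds consistent attribution drift", {
  set.seed(67)
  F1 <- matrix(rnorm(300), 30, 10)
  L1 <- F1
  L1[, 3] <- L1[, 3] + 3 * sd(F1[, 3])   # consistent +3 SD shift in MMSE
  rec <- fake_records(F1, L1)
  res <- per_index_change_test(rec, "MMSE", B_perm = 999, seed = 2)
  expect_lte(res$p_value, 0.001)
  # unchanged index: observed 0 -> p = 1
  L2 <- F1; rec2 <- fake_records(F1, L2)
  expect_equal(per_index_change_test(rec2, "ADAS11", B_perm = 99,
                                     seed = 3)$p_value, 1)
})

test_that("longitudinal analysis orders stable NC below converters on drifting data", {
  set.seed(68)
  n <- 15
  base <- matrix(rnorm(n * 10, 0, 0.2), n, 10)
  stable_first <- sweep(base, 2, c(rep(1, 5), rep(0, 5)), `+`)
  stable_last <- stable_first + matrix(rnorm(n * 10, 0, 0.1), n, 10)
  conv_first <- stable_first
  conv_last <- sweep(matrix(rnorm(n * 10, 0, 0.2), n, 10), 2,
                     c(rep(0, 5), rep(1, 5)), `+`)  # rotated direction
  rec <- rbind(fake_records(stable_first, stable_last, "stable NC"),
               fake_records(conv_first, conv_last, "NC conv AD", seed = 69))
  rec$subject_id <- sprintf("S%03d", seq_len(2 * n))
  m_stable <- mean(rec$distance[rec$trajectory == "stable NC"])
  m_conv <- mean(rec$distance[rec$trajectory == "NC conv AD"])
  expect_lt(m_stable, m_conv)
})
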