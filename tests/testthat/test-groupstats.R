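make_profiles <- function(per_subj_fun, depths = seq(0, 1, 0.25),
                          n_subj = 5, conditions = c("motion", "dynamic")) {
  do.call(rbind, lapply(seq_len(n_subj), function(s)
    do.call(rbind, lapply(conditions, function(cond)
      data.frame(subject = s, condition = cond, area = "V1",
                 depth = depths, psc = per_subj_fun(s, cond, depths))))))
}

test_that("condition contrasts difference per subject then average", {
  prof <- make_profiles(function(s, cond, d)
    ifelse(cond == "motion", 0.3 - d, -d) + 0.01 * s)
  ct <- condition_contrast(prof, "motion", "dynamic")
  expect_equal(ct$mean, rep(0.3, 5), tolerance = 1e-12)
  expect_equal(ct$sem, rep(0, 5), tolerance = 1e-12)
  # identical conditions: zero profile
  ct0 <- condition_contrast(prof, "motion", "motion")
  expect_true(all(ct0$mean == 0))
  # SEM equals sd / sqrt(n) by direct formula
  prof2 <- make_profiles(function(s, cond, d)
    (cond == "motion") * s * d)
  ct2 <- condition_contrast(prof2, "motion", "dynamic")
  expect_equal(ct2$sem, apply(ct2$per_subject, 1, sd) / sqrt(5))
  # unbalanced subjects error
  expect_error(condition_contrast(prof[prof$subject > 1 |
                                         prof$condition == "motion", ],
                                  "motion", "dynamic"), "every subject")
})

test_that("phantom truth contrast is recovered exactly without noise", {
  ph <- small_phantom()
  depths <- ph$depth_fractions
  inc_col <- which(ph$columns$ecc >= 1 & ph$columns$ecc <= 3)
  truth_diff <- ph$sustained[inc_col[1], , "motion"] -
    ph$sustained[inc_col[1], , "dynamic"]
  prof <- do.call(rbind, lapply(1:3, function(s)
    do.call(rbind, lapply(c("motion", "dynamic"), function(cond)
      data.frame(subject = s, condition = cond, area = "V1", depth = depths,
                 psc = ph$sustained[inc_col[1], , cond])))))
  ct <- condition_contrast(prof, "motion", "dynamic")
  expect_equal(ct$mean, truth_diff, tolerance = 1e-12)
  # the 0.3% increment peaks at the grid depth nearest 25%
  expect_lte(abs(ct$depth[which.max(ct$mean)] - 0.25), 0.05)
  expect_equal(max(ct$mean),
               0.3 * exp(-0.05^2 / (2 * 0.15^2)), tolerance = 1e-12)
})

test_that("onset detection finds programmed steps and nothing in null data", {
  set.seed(31)
  null_ts <- matrix(rnorm(12 * 8, 0, 1), 12, 8)
  expect_true(is.na(detect_response_onset(null_ts, alpha = 1e-4)$onset_index))
  zero_ts <- matrix(0, 6, 4)
  expect_warning(res <- detect_response_onset(zero_ts))
  expect_true(is.na(res$onset_index))
  # large step at volume 5 (10x the subject SD)
  step <- matrix(rnorm(15 * 8, 0, 0.1), 15, 8)
  step[5:15, ] <- step[5:15, ] + 1
  expect_equal(detect_response_onset(step)$onset_index, 5)
})

test_that("two ROIs with steps one volume apart yield onsets one apart", {
  set.seed(32)
  mk <- function(k, sign) {
    m <- matrix(rnorm(15 * 9, 0, 0.08), 15, 9)
    m[k:15, ] <- m[k:15, ] + sign * 1
    m
  }
  edge <- detect_response_onset(mk(4, +1))$onset_index
  centre <- detect_response_onset(mk(5, -1))$onset_index
  expect_equal(centre - edge, 1)
})

test_that("onset detection is monotone in alpha", {
  set.seed(33)
  m <- matrix(rnorm(20 * 7, 0, 0.3), 20, 7)
  # effect ramping up over time: stricter alpha detects it later
  for (k in 8:20) m[k, ] <- m[k, ] + 0.25 * (k - 7)
  o_small <- detect_response_onset(m, alpha = 0.005)$onset_index
  o_large <- detect_response_onset(m, alpha = 0.5)$onset_index
  expect_false(is.na(o_small) || is.na(o_large))
  expect_lte(o_large, o_small)
})

test_that("peak classification uses the upper-third rule and superficial
           tie-breaking", {
  d <- seq(0, 1, 0.25)
  p1 <- classify_peak(c(0, 1, 0.5, 0.2, 0), d)   # peak at 25% depth
  expect_equal(p1$peak_depth, 0.25)
  expect_true(p1$superficial)
  p2 <- classify_peak(c(0, 0.2, 1, 0.2, 0), d)   # peak at 50% depth
  expect_false(p2$superficial)
  p3 <- classify_peak(rev(sort(runif(5))), d)    # monotone toward pial
  expect_equal(p3$peak_depth, 0)
  expect_true(p3$superficial)
  tie <- classify_peak(c(1, 0.5, 1, 0.2, 1), d)
  expect_equal(tie$peak_depth, 0)
  flat <- classify_peak(rep(2, 5), d)
  expect_true(flat$degenerate)
  expect_equal(flat$peak_depth, 0)
})

test_that("superficial-ratio chi-squared matches hand-computed values", {
  # 2x2 table (7,1; 5,11)
  calls <- c(rep(TRUE, 7), rep(FALSE, 1), rep(TRUE, 5), rep(FALSE, 11))
  grp <- c(rep("V1", 8), rep("V23", 16))
  res <- superficial_ratio_chisq(calls, grp)
  O <- matrix(c(7, 5, 1, 11), 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$df, 1)
  # label swap invariance
  res2 <- superficial_ratio_chisq(calls,
                                  ifelse(grp == "V1", "V23", "V1"))
  expect_equal(res2$statistic, res$statistic)
  # identical proportions: statistic 0; 3 groups give df 2
  calls3 <- rep(c(TRUE, FALSE), 9)
  grp3 <- rep(c("V1", "V2", "V3"), each = 6)
  res3 <- superficial_ratio_chisq(calls3, grp3)
  expect_equal(res3$statistic, 0, tolerance = 1e-12)
  expect_equal(res3$df, 2)
  expect_error(superficial_ratio_chisq(rep(TRUE, 4), rep(c("a", "b"), 2)),
               "zero")
})

test_that("mixed-model LRT is non-negative, nested, and degenerate-safe", {
  d <- make_profile_table(1)
  r <- lme_interaction_lrt(d, drop_term = "condition:area")
  expect_gte(r$statistic, 0)
  expect_equal(r$df, 1)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  r2 <- lme_interaction_lrt(d, drop_term = "depth:area")
  expect_gte(r2$statistic, 0)
  # full model == null model
  r0 <- lme_interaction_lrt(d, drop_term = NULL)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$df, 0)
  expect_error(lme_interaction_lrt(d, drop_term = "banana"), "drop_term")
})

test_that("a strong programmed interaction is detected", {
  d <- make_profile_table(2, interaction = 5)
  r <- lme_interaction_lrt(d, drop_term = "condition:area")
  expect_lt(r$p_value, 0.001)
})
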