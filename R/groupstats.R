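#' Group-level condition contrast over depth
#'
#' Per-subject, per-depth difference in percent signal change between two
#' conditions, with the group mean and standard error across subjects.
#'
#' @param profiles data.frame with columns subject, condition, depth
#'   (fraction from pial), psc, and optionally area
#' @param cond_a,cond_b condition labels; the contrast is `cond_a - cond_b`
#' @return list: `depth` (fractions), `per_subject` (depths x subjects),
#'   `mean`, `sem`
#' @export
condition_contrast <- function(profiles, cond_a, cond_b) {
  pa <- profiles[profiles$condition == cond_a, ]
  pb <- profiles[profiles$condition == cond_b, ]
  subj <- sort(unique(profiles$subject))
  if (!setequal(unique(pa$subject), subj) ||
      !setequal(unique(pb$subject), subj))
    stop("both conditions must be present for every subject")
  depths <- sort(unique(profiles$depth))
  per_subj <- sapply(subj, function(s) {
    a <- pa[pa$subject == s, ]
    b <- pb[pb$subject == s, ]
    a <- a[order(a$depth), ]; b <- b[order(b$depth), ]
    if (!isTRUE(all.equal(a$depth, depths)) ||
        !isTRUE(all.equal(b$depth, depths)))
      stop("unbalanced depth grid for subject ", s)
    a$psc - b$psc
  })
  per_subj <- matrix(per_subj, nrow = length(depths))
  m <- rowMeans(per_subj)
  sem <- if (length(subj) > 1)
    apply(per_subj, 1, stats::sd) / sqrt(length(subj)) else
      rep(NA_real_, length(depths))
  list(depth = depths, per_subject = per_subj, mean = m, sem = sem,
       n_subjects = length(subj))
}

#' Detect the response onset in a group event-related time course
#'
#' Per time point, a two-sided one-sample t-test across subjects against
#' zero; the Bonferroni-adjusted threshold is `alpha / n_tests` with
#' `n_tests` the number of in-window time points. Returns the earliest
#' significant time point (sign-agnostic), or `NA` if none. Zero-variance
#' time points are skipped with a warning.
#'
#' @param group_ts matrix time points x subjects
#' @param alpha family-wise significance level (default 0.05)
#' @param n_tests Bonferroni family size (default: number of rows)
#' @return list: `onset_index` (row index or NA), `p_values`,
#'   `threshold`
#' @export
detect_response_onset <- function(group_ts, alpha = 0.05, n_tests = NULL) {
  Y <- as.matrix(group_ts)
  if (ncol(Y) < 2) stop("need at least 2 subjects")
  if (is.null(n_tests)) n_tests <- nrow(Y)
  thr <- alpha / n_tests
  p <- apply(Y, 1, function(v) {
    if (stats::sd(v) < 1e-14) return(NA_real_)
    stats::t.test(v, mu = 0)$p.value
  })
  if (anyNA(p))
    warning(sum(is.na(p)), " time point(s) with zero variance skipped")
  sig <- which(!is.na(p) & p < thr)
  list(onset_index = if (length(sig)) min(sig) else NA_integer_,
       p_values = p, threshold = thr)
}

#' Classify the peak depth of a contrast profile
#'
#' The peak is the global maximum of the depth profile; it is "superficial"
#' if it lies in the upper third of the grey matter, i.e. within 33.33%
#' cortical depth of the pial/CSF border. Ties are broken toward the more
#' superficial depth (and the call flagged degenerate if the whole profile is
#' constant).
#'
#' @param profile numeric vector of contrast values
#' @param depth depth fractions from the pial surface (same length)
#' @return a `peak_call` list: `peak_depth`, `peak_index`, `superficial`,
#'   `degenerate`
#' @export
classify_peak <- function(profile, depth) {
  stopifnot(length(profile) >= 1, length(profile) == length(depth))
  ord <- order(depth)
  profile <- profile[ord]; depth <- depth[ord]
  mx <- max(profile)
  cand <- which(profile >= mx - 0)           # exact ties
  idx <- cand[which.min(depth[cand])]        # most superficial wins
  structure(list(peak_depth = depth[idx], peak_index = idx,
                 superficial = depth[idx] <= 1 / 3,
                 degenerate = all(profile == profile[1])),
            class = "peak_call")
}

#' Chi-squared comparison of superficial-peak ratios between areas
#'
#' Pearson chi-squared test (no continuity correction) on the areas x
#' (superficial, not superficial) contingency table of per-subject peak
#' calls. Groups can be pooled beforehand (e.g. V1 vs V2+V3).
#'
#' @param superficial logical vector of peak calls
#' @param group factor/character of group (area) labels, same length
#' @return list: `statistic`, `df`, `p_value`, `table`
#' @export
superficial_ratio_chisq <- function(superficial, group) {
  stopifnot(length(superficial) == length(group))
  tab <- table(group, factor(superficial, levels = c(TRUE, FALSE)))
  if (nrow(tab) < 2) stop("need at least 2 groups")
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts == 0)) stop("expected cell count of zero")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, table = tab)
}

#' Likelihood-ratio test between nested depth-profile mixed models
#'
#' Fits linear mixed-effects models of percent signal change with fixed
#' factors ROI (area), stimulus condition and cortical depth, a random
#' depth slope per subject, and a continuous AR(1) correlation structure over
#' depth within subjects; both models by maximum likelihood, compared with a
#' likelihood-ratio test. The full model has all two-way interactions; the
#' null omits the term named in `drop_term` (e.g. `"condition:area"` to test
#' a differential effect of condition between areas, or `"depth:area"` for
#' differences in depth profiles between areas).
#'
#' @param profiles data.frame with columns subject, area, condition, depth
#'   (numeric fraction), psc
#' @param drop_term interaction dropped in the null model
#' @param random random-effects formula (default `~ depth | subject`)
#' @param correlation residual correlation structure (default
#'   `nlme::corCAR1(form = ~ depth | subject)`); `NULL` for independence
#' @return an `lrt_result` list: `statistic` (2 dLogLik), `df`, `p_value`,
#'   `full`, `null` (fitted models), `terms`
#' @export
lme_interaction_lrt <- function(profiles, drop_term = "condition:area",
                                random = ~ depth | subject,
                                correlation = "car1") {
  profiles$subject <- factor(profiles$subject)
  profiles$area <- factor(profiles$area)
  profiles$condition <- factor(profiles$condition)
  two_way <- c("condition:area", "depth:area", "condition:depth")
  if (!is.null(drop_term) && !drop_term %in% two_way)
    stop("drop_term must be NULL or one of: ",
         paste(two_way, collapse = ", "))
  full_rhs <- paste(c("area", "condition", "depth", two_way), collapse = " + ")
  null_rhs <- paste(c("area", "condition", "depth",
                      setdiff(two_way, drop_term)), collapse = " + ")
  # the CAR(1) index must be unique within its grouping, so the correlation
  # groups are the depth series within each subject x area x condition cell
  if (identical(correlation, "car1"))
    correlation <- nlme::corCAR1(form = ~ depth | subject / area / condition)
  # optim occasionally walks into a non-finite region on hard surfaces;
  # fall back to nlminb before giving up
  fit_one <- function(rhs) {
    form <- stats::as.formula(paste("psc ~", rhs))
    for (opt in c("optim", "nlminb")) {
      ctrl <- nlme::lmeControl(opt = opt, maxIter = 200, msMaxIter = 200,
                               returnObject = TRUE)
      fit <- tryCatch(
        suppressWarnings(
          nlme::lme(form, data = profiles, random = random,
                    correlation = correlation, method = "ML",
                    control = ctrl)),
        error = function(e) e)
      if (!inherits(fit, "error")) return(fit)
    }
    stop("mixed-model fit failed to converge for: psc ~ ", rhs,
         " (", conditionMessage(fit), ")")
  }
  full <- fit_one(full_rhs)
  null <- fit_one(null_rhs)
  ll_f <- as.numeric(stats::logLik(full))
  ll_n <- as.numeric(stats::logLik(null))
  df <- attr(stats::logLik(full), "df") - attr(stats::logLik(null), "df")
  if (df < 0) stop("models are not nested (full has fewer parameters)")
  stat <- max(0, 2 * (ll_f - ll_n))
  structure(list(statistic = stat, df = df,
                 p_value = if (df == 0) 1 else
                   stats::pchisq(stat, df, lower.tail = FALSE),
                 full = full, null = null,
                 terms = list(full = full_rhs, null = null_rhs,
                              dropped = if (is.null(drop_term)) "none" else
                                drop_term)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("likelihood ratio (df): %.2f (%d), p = %.4g  [dropped: %s]\n",
              x$statistic, x$df, x$p_value, x$terms$dropped))
  invisible(x)
}
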