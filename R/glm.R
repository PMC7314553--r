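#' Build the task design matrix
#'
#' Per condition, two predictors: a sustained regressor (boxcar over the
#' whole block, HRF-convolved) and a transient regressor (unit-area delta
#' functions at block onset and offset sharing one column, HRF-convolved).
#' Optional single nuisance column for fixation-target events. All task
#' regressors are peak-normalised to 1 before filtering, and the same
#' discrete-cosine high-pass filter (cutoff 35 s by default) that is applied
#' to the data is applied to the matrix.
#'
#' @param schedules a [make_run_schedule()] result or a named list of them,
#'   one per condition
#' @param targets optional [decorrelate_target_events()] result
#' @param hrf HRF kernel from [double_gamma_hrf()] (default canonical at the
#'   schedule TR)
#' @param hp_cutoff_s high-pass cutoff, s (default 35); `NA` disables
#' @return a `design_matrix` list: `X` (filtered regressors), `X_raw`
#'   (pre-filter), `tr`, `n_volumes`, `hp_cutoff_s`, `columns`
#' @export
build_design_matrix <- function(schedules, targets = NULL, hrf = NULL,
                                hp_cutoff_s = 35) {
  if (inherits(schedules, "run_schedule")) {
    nm <- unique(schedules$condition)
    schedules <- stats::setNames(list(schedules),
                                 if (length(nm) == 1) nm else "stimulus")
  }
  tr <- schedules[[1]]$tr
  n_vol <- schedules[[1]]$n_volumes
  for (s in schedules) {
    stopifnot(inherits(s, "run_schedule"), s$tr == tr, s$n_volumes == n_vol)
    if (length(s$onsets) > 1 &&
        any(diff(s$onsets) < s$durations[-length(s$durations)] - 1e-9))
      stop("overlapping blocks in schedule")
  }
  if (is.null(hrf)) hrf <- double_gamma_hrf(tr = tr)

  cols <- list()
  for (cond in names(schedules)) {
    s <- schedules[[cond]]
    if (length(s$onsets) == 0) next
    sus <- convolve_boxcar(s$onsets, s$durations, hrf, tr, n_vol)
    trn <- convolve_delta(c(s$onsets, s$onsets + s$durations), hrf, tr, n_vol)
    cols[[paste0(cond, "_sustained")]] <- sus / max(abs(sus))
    cols[[paste0(cond, "_transient")]] <- trn / max(abs(trn))
  }
  if (!is.null(targets) && length(targets$onsets)) {
    tg <- convolve_boxcar(targets$onsets,
                          rep(targets$duration_s, length(targets$onsets)),
                          hrf, tr, n_vol)
    cols[["target"]] <- tg / max(abs(tg))
  }
  X_raw <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), n_vol, 0)
  X <- if (is.na(hp_cutoff_s) || ncol(X_raw) == 0) X_raw else
    highpass_filter(X_raw, tr, hp_cutoff_s)
  structure(list(X = X, X_raw = X_raw, tr = tr, n_volumes = n_vol,
                 hp_cutoff_s = hp_cutoff_s, columns = colnames(X_raw)),
            class = "design_matrix")
}

#' Fit the GLM to one or many time courses
#'
#' Ordinary least squares after applying the design's high-pass filter to the
#' data (the matrix is already filtered). An intercept is implicit in the
#' filtering: both data and regressors are drift- and mean-projected.
#'
#' @param timecourse numeric vector, or matrix with time in rows and units in
#'   columns
#' @param design a [build_design_matrix()] result
#' @return a `glm_result` list: `betas` (columns x units), `residual_var`,
#'   `baseline` (unit means of the raw data), `design`
#' @export
fit_glm <- function(timecourse, design) {
  Y_raw <- if (is.null(dim(timecourse))) matrix(timecourse, ncol = 1) else
    timecourse
  stopifnot(nrow(Y_raw) == design$n_volumes)
  X <- design$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- design$columns[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("design matrix rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Y <- if (is.na(design$hp_cutoff_s)) Y_raw else
    highpass_filter(Y_raw, design$tr, design$hp_cutoff_s)
  betas <- qr.coef(qrX, Y)
  resid <- Y - X %*% betas
  df <- design$n_volumes - ncol(X) -
    (if (is.na(design$hp_cutoff_s)) 0 else
       ncol(dct_highpass_basis(design$n_volumes, design$tr,
                               design$hp_cutoff_s)))
  rownames(betas) <- design$columns
  structure(list(betas = betas,
                 residual_var = colSums(resid^2) / max(df, 1),
                 baseline = colMeans(Y_raw),
                 design = design),
            class = "glm_result")
}

#' Convert GLM betas to percent signal change
#'
#' PSC = 100 x beta / mean(raw signal over the initial pre-stimulus baseline
#' window). Because task regressors are peak-normalised, a beta equals the
#' peak response amplitude in raw signal units. Units with non-positive
#' baseline are flagged (PSC set to NA).
#'
#' @param fit a [fit_glm()] result
#' @param raw_timecourse the unfiltered data passed to [fit_glm()]
#' @param baseline_window_s length of the initial baseline window, s
#'   (default 20.8)
#' @return matrix of PSC values (design columns x units); attribute
#'   `baseline_mean` holds the per-unit baseline means
#' @export
to_percent_signal_change <- function(fit, raw_timecourse,
                                     baseline_window_s = 20.8) {
  Y <- if (is.null(dim(raw_timecourse))) matrix(raw_timecourse, ncol = 1) else
    raw_timecourse
  tr <- fit$design$tr
  n_base <- round(baseline_window_s / tr)
  stopifnot(n_base >= 1, n_base <= nrow(Y))
  base <- colMeans(Y[seq_len(n_base), , drop = FALSE])
  bad <- base <= 0
  psc <- 100 * sweep(fit$betas, 2, base, "/")
  psc[, bad] <- NA_real_
  attr(psc, "baseline_mean") <- base
  attr(psc, "flagged") <- which(bad)
  psc
}

#' Event-related average around block onsets
#'
#' Cuts a peri-onset window out of each block repetition, expresses each
#' segment as percent signal change relative to the pre-block baseline rule,
#' and averages over repetitions. With a matrix input (subjects in columns)
#' the per-subject averages are returned along with the group mean and SEM.
#'
#' @param timecourse vector or matrix (time x subjects) of raw signal
#' @param schedule a [make_run_schedule()] result
#' @param window_s window length after block onset, s
#' @param pre_s baseline window before onset, s (default 2 volumes)
#' @param baseline_rule "pre_block_mean" (default) or "none"
#' @return list: `time_s` (relative to onset), `mean`, `sem`,
#'   `per_subject` (matrix time x subjects), `n_reps`
#' @export
event_related_average <- function(timecourse, schedule, window_s = 16,
                                  pre_s = NULL, baseline_rule = "pre_block_mean") {
  Y <- if (is.null(dim(timecourse))) matrix(timecourse, ncol = 1) else
    timecourse
  tr <- schedule$tr
  if (is.null(pre_s)) pre_s <- 2 * tr
  n_pre <- round(pre_s / tr)
  n_win <- round(window_s / tr)
  onset_vol <- round(schedule$onsets / tr) + 1
  keep <- onset_vol - n_pre >= 1 & onset_vol + n_win - 1 <= nrow(Y)
  onset_vol <- onset_vol[keep]
  if (length(onset_vol) < 2) stop("need at least 2 block repetitions")

  per_subj <- sapply(seq_len(ncol(Y)), function(j) {
    segs <- sapply(onset_vol, function(v) {
      seg <- Y[(v - n_pre):(v + n_win - 1), j]
      if (baseline_rule == "pre_block_mean") {
        b <- mean(seg[seq_len(n_pre)])
        100 * (seg - b) / b
      } else seg
    })
    rowMeans(segs)
  })
  per_subj <- matrix(per_subj, nrow = n_pre + n_win)
  m <- rowMeans(per_subj)
  sem <- if (ncol(per_subj) > 1)
    apply(per_subj, 1, stats::sd) / sqrt(ncol(per_subj)) else
      rep(NA_real_, nrow(per_subj))
  list(time_s = (seq_len(n_pre + n_win) - n_pre - 1) * tr,
       mean = m, sem = sem, per_subject = per_subj,
       n_reps = length(onset_vol))
}
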