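#' Block-design run schedules
#'
#' A `run_schedule` holds the block structure of one functional run: condition
#' labels, onsets and durations (seconds, exact integer multiples of the TR),
#' the TR and the total volume count. Stimulus blocks alternate with rest
#' periods; the run opens with a fixed initial rest.
#'
#' @name run_schedule
NULL

# Snap a nominal duration (possibly printed rounded, e.g. 10.4 s for 5 TRs of
# 2.079 s) to an integer number of TRs; error if it is not within `tol` of one.
snap_to_tr <- function(dur_s, tr_s, tol = 0.06) {
  k <- round(dur_s / tr_s)
  if (any(abs(dur_s - k * tr_s) > tol))
    stop("duration(s) not an integer multiple of the TR: ",
         paste(dur_s[abs(dur_s - k * tr_s) > tol], collapse = ", "))
  k
}

#' Build a block-design run schedule
#'
#' `n_blocks` stimulus blocks of fixed duration alternate with rest periods of
#' variable duration. The run begins with a fixed initial rest and ends with
#' one of the variable rests, so there are `n_blocks + 1` rest periods in
#' total. Variable rest durations are counterbalanced: counts per duration are
#' as equal as possible, the remainder going to the middle duration(s), and
#' the order is shuffled deterministically by `seed`.
#'
#' All durations must be (within rounding of the printed value) integer
#' multiples of the TR; stored onsets/durations are exact TR multiples.
#'
#' @param n_blocks number of stimulus blocks (default 16)
#' @param block_dur_s stimulus block duration, s (default 10.4, i.e. 5 TRs)
#' @param rest_durations_s possible variable rest durations, s
#'   (default 18.7, 20.8, 22.9, i.e. 9/10/11 TRs)
#' @param initial_rest_s fixed initial rest, s (default 20.8)
#' @param tr_s repetition time, s (default 2.079)
#' @param condition condition label applied to all blocks
#' @param seed integer seed for the rest-order shuffle
#' @return a `run_schedule` list: `condition`, `onsets`, `durations` (s),
#'   `tr`, `n_volumes`, `initial_rest`, `rests` (durations, s),
#'   `total_s`
#' @export
make_run_schedule <- function(n_blocks = 16, block_dur_s = 10.4,
                              rest_durations_s = c(18.7, 20.8, 22.9),
                              initial_rest_s = 20.8, tr_s = 2.079,
                              condition = "stimulus", seed = 1) {
  stopifnot(n_blocks >= 0, tr_s > 0, length(rest_durations_s) >= 1)
  block_tr <- snap_to_tr(block_dur_s, tr_s)
  rest_tr <- snap_to_tr(rest_durations_s, tr_s)
  init_tr <- snap_to_tr(initial_rest_s, tr_s)

  if (n_blocks == 0) {
    sched <- list(condition = character(0), onsets = numeric(0),
                  durations = numeric(0), tr = tr_s, n_volumes = init_tr,
                  initial_rest = init_tr * tr_s, rests = numeric(0),
                  total_s = init_tr * tr_s)
    class(sched) <- "run_schedule"
    return(sched)
  }

  # counterbalance the n_blocks variable rests over the available durations;
  # remainder assigned starting from the middle duration
  n_dur <- length(rest_tr)
  base <- n_blocks %/% n_dur
  counts <- rep(base, n_dur)
  rem <- n_blocks - base * n_dur
  if (rem > 0) {
    mid_order <- order(abs(seq_len(n_dur) - (n_dur + 1) / 2))
    counts[mid_order[seq_len(rem)]] <- counts[mid_order[seq_len(rem)]] + 1
  }
  pool <- rep(rest_tr, counts)
  rests <- pool[sample_with_seed(length(pool), seed)]

  # segments: initial rest, then block/rest pairs; block onsets are the
  # cumulative TR counts of the preceding segments
  seg_tr <- c(init_tr, rbind(rep(block_tr, n_blocks), rests))
  starts <- cumsum(c(0, seg_tr[-length(seg_tr)]))
  block_idx <- seq(2, by = 2, length.out = n_blocks)
  onsets <- starts[block_idx] * tr_s
  n_vol <- sum(seg_tr)

  sched <- list(condition = rep(condition, n_blocks),
                onsets = onsets,
                durations = rep(block_tr * tr_s, n_blocks),
                tr = tr_s, n_volumes = n_vol,
                initial_rest = init_tr * tr_s,
                rests = rests * tr_s,
                total_s = n_vol * tr_s)
  class(sched) <- "run_schedule"
  sched
}

# deterministic permutation of seq_len(n) under a local RNG seed
sample_with_seed <- function(n, seed) {
  if (n <= 1) return(seq_len(n))
  rng <- local_rng(seed)
  on.exit(rng())
  sample.int(n)
}

# Save/restore .Random.seed around a locally seeded computation so package
# functions never disturb the caller's RNG stream.
local_rng <- function(seed) {
  if (is.null(seed)) stop("a seed is required for reproducibility")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.run_schedule <- function(x, ...) {
  cat(sprintf(
    "run_schedule: %d block(s), TR %.3f s, %d volumes, %.2f s total\n",
    length(x$onsets), x$tr, x$n_volumes, x$total_s))
  invisible(x)
}

#' Place fixation-target events decorrelated from the stimulus predictor
#'
#' Draws pseudo-random fixation-target onsets (mean inter-trial interval
#' `mean_iti_s`, uniform range +/- `iti_range_s`, none within the first or
#' last 15 s of the run) and accepts a draw only when the Pearson correlation
#' between the HRF-convolved stimulus predictor and the HRF-convolved target
#' predictor is below `r_max` in absolute value. Rejection sampling with a
#' hard iteration cap.
#'
#' @param schedule a [make_run_schedule()] result
#' @param hrf HRF kernel sampled at the TR (default [double_gamma_hrf()])
#' @param mean_iti_s mean inter-trial interval, s (default 30)
#' @param iti_range_s half-range of the uniform ITI jitter, s (default 10)
#' @param target_dur_s target event duration, s (default 0.8)
#' @param exclusion_s protected window at run start and end, s (default 15)
#' @param r_max acceptance threshold on |r| (default 0.001)
#' @param max_iter iteration cap (default 1e5)
#' @param seed integer seed
#' @return list `onsets` (s), `duration_s`, `achieved_r`, `n_iter`
#' @export
decorrelate_target_events <- function(schedule, hrf = NULL, mean_iti_s = 30,
                                      iti_range_s = 10, target_dur_s = 0.8,
                                      exclusion_s = 15, r_max = 0.001,
                                      max_iter = 1e5, seed = 1) {
  stopifnot(r_max > 0, inherits(schedule, "run_schedule"))
  if (is.null(hrf)) hrf <- double_gamma_hrf(tr = schedule$tr)
  total <- schedule$n_volumes * schedule$tr
  lo <- exclusion_s
  hi <- total - exclusion_s
  n_targets <- max(0L, floor((hi - lo) / mean_iti_s))
  if (n_targets == 0)
    return(list(onsets = numeric(0), duration_s = target_dur_s,
                achieved_r = 0, n_iter = 0L))

  stim_pred <- convolve_boxcar(schedule$onsets, schedule$durations,
                               hrf, schedule$tr, schedule$n_volumes)
  rng <- local_rng(seed)
  on.exit(rng())
  best_r <- Inf
  for (iter in seq_len(max_iter)) {
    itis <- runif(n_targets, mean_iti_s - iti_range_s, mean_iti_s + iti_range_s)
    onsets <- lo + cumsum(itis) - itis[1] * runif(1)
    onsets <- onsets[onsets >= lo & onsets + target_dur_s <= hi]
    if (length(onsets) == 0) next
    targ_pred <- convolve_boxcar(onsets, rep(target_dur_s, length(onsets)),
                                 hrf, schedule$tr, schedule$n_volumes)
    r <- suppressWarnings(cor(stim_pred, targ_pred))
    if (is.na(r)) r <- 0
    if (abs(r) < best_r) best_r <- abs(r)
    if (abs(r) < r_max)
      return(list(onsets = onsets, duration_s = target_dur_s,
                  achieved_r = r, n_iter = iter))
  }
  stop(sprintf(
    "no target design with |r| < %g found in %d iterations (best |r| = %g)",
    r_max, max_iter, best_r))
}

#' Write a schedule (plus optional target events) as a BIDS-style events table
#'
#' Tab-separated columns onset/duration/trial_type.
#' @param schedule a [make_run_schedule()] result
#' @param path output file path
#' @param targets optional [decorrelate_target_events()] result
#' @export
write_events_tsv <- function(schedule, path, targets = NULL) {
  ev <- data.frame(onset = schedule$onsets,
                   duration = schedule$durations,
                   trial_type = schedule$condition)
  if (!is.null(targets) && length(targets$onsets))
    ev <- rbind(ev, data.frame(onset = targets$onsets,
                               duration = targets$duration_s,
                               trial_type = "target"))
  ev <- ev[order(ev$onset), ]
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events table
#' @param path events TSV path
#' @return data.frame with onset/duration/trial_type
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
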