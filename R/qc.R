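#' Spatial-correlation quality gate for a run
#'
#' Pearson correlation of every volume against a reference volume (e.g. the
#' session-mean EPI image) over in-mask voxels; the run fails if the mean
#' correlation falls below the threshold (default 0.95).
#'
#' @param run_volumes matrix volumes x voxels (or 4D array, time last)
#' @param reference numeric vector (or array) of reference voxel values
#' @param threshold pass threshold on the mean correlation (default 0.95)
#' @param mask optional logical voxel mask
#' @return list: `pass`, `mean_r`, `per_volume_r`, `threshold`
#' @export
qc_spatial_correlation <- function(run_volumes, reference, threshold = 0.95,
                                   mask = NULL) {
  if (length(dim(run_volumes)) > 2) {
    d <- dim(run_volumes)
    run_volumes <- t(matrix(run_volumes, prod(d[-length(d)]), d[length(d)]))
  }
  ref <- as.vector(reference)
  stopifnot(ncol(run_volumes) == length(ref))
  if (is.null(mask)) mask <- rep(TRUE, length(ref))
  if (!any(mask)) stop("empty mask")
  r <- apply(run_volumes[, mask, drop = FALSE], 1, stats::cor, y = ref[mask])
  mean_r <- mean(r)
  list(pass = mean_r >= threshold, mean_r = mean_r, per_volume_r = r,
       threshold = threshold)
}

#' Behavioural hit-rate quality gate
#'
#' A target counts as hit if a response occurs within `window_s` after its
#' onset; each response credits at most one target (greedy earliest-first
#' matching). The run fails if the hit rate falls below the threshold
#' (default 0.70).
#'
#' @param target_onsets target onset times, s
#' @param response_times response (button-press) times, s, sorted
#' @param window_s response window after each target, s (default 2)
#' @param threshold pass threshold on the hit rate (default 0.70)
#' @return list: `pass` (NA with zero targets), `hit_rate`, `n_hits`,
#'   `n_targets`
#' @export
qc_hit_rate <- function(target_onsets, response_times, window_s = 2,
                        threshold = 0.70) {
  if (length(target_onsets) == 0)
    return(list(pass = NA, hit_rate = NA_real_, n_hits = 0L,
                n_targets = 0L))
  responses <- sort(response_times)
  used <- rep(FALSE, length(responses))
  hits <- 0L
  for (t in sort(target_onsets)) {
    ok <- which(!used & responses >= t & responses <= t + window_s)
    if (length(ok)) {
      used[ok[1]] <- TRUE
      hits <- hits + 1L
    }
  }
  rate <- hits / length(target_onsets)
  list(pass = rate >= threshold, hit_rate = rate, n_hits = hits,
       n_targets = length(target_onsets))
}
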