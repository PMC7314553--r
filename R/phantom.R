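#' Build a ground-truthed cortical phantom
#'
#' A lattice "flattened cortex": columns x depth levels, with a smooth
#' retinotopic map over visual areas V1/V2/V3 and known laminar response
#' amplitudes per condition and response component. The programmed response
#' pattern mirrors a textured-background surface experiment: columns whose
#' pRF falls on the stimulus interior (centre band, eccentricity 1-3 deg)
#' carry a negative sustained response; columns on the stimulus edge
#' (3.5-4 deg) carry a positive transient response; the motion-induction
#' condition additionally receives a small depth-localised sustained
#' increment (default +0.3% peaking at 25% cortical depth in V1).
#'
#' @param areas area labels (default V1, V2, V3)
#' @param n_ecc,n_angle columns per area laid out over an eccentricity x
#'   polar-angle grid
#' @param ecc_range eccentricity range of the map, deg
#' @param n_depths number of depth levels (default 11, i.e. 10 compartments)
#' @param conditions condition labels (default motion, static, dynamic)
#' @param sustained_amp sustained amplitude of centre columns, percent
#'   signal change (default -2.5, the negative interior response)
#' @param transient_amp transient amplitude of edge columns, percent (default
#'   1.5)
#' @param increment_amp peak of the motion-condition sustained increment,
#'   percent (default 0.3)
#' @param increment_depth depth fraction (from pial) of the increment peak
#'   (default 0.25)
#' @param increment_width Gaussian width of the increment over depth
#'   (default 0.15)
#' @param increment_area area receiving the increment (default "V1")
#' @param increment_condition condition receiving it (default "motion")
#' @param baseline mean-EPI baseline intensity (default 10000)
#' @param intensity_cv coefficient of variation of the static voxel-wise
#'   EPI intensity field (tissue contrast; default 0.1)
#' @param dim_every every k-th column is given sub-threshold EPI intensity
#'   (6500) to exercise the vein-exclusion rule; 0 disables (default 20)
#' @param seed seed for the static intensity field (default 42)
#' @param prf_sigma_slope pRF width model sigma = 0.2 + slope x eccentricity
#'   (default 0.1)
#' @return a `cortical_phantom` list; see Details
#' @details Fields: `columns` (data.frame: id, area, ecc, angle, x, y,
#'   sigma), `depth_fractions` (from pial, increasing), `conditions`,
#'   `sustained`, `transient` (arrays columns x depths x conditions, percent
#'   signal change), `epi` (columns x depths), `baseline`.
#' @export
build_phantom <- function(areas = c("V1", "V2", "V3"), n_ecc = 10,
                          n_angle = 6, ecc_range = c(0.6, 4.2),
                          n_depths = 11,
                          conditions = c("motion", "static", "dynamic"),
                          sustained_amp = -2.5, transient_amp = 1.5,
                          increment_amp = 0.3, increment_depth = 0.25,
                          increment_width = 0.15, increment_area = "V1",
                          increment_condition = "motion",
                          baseline = 10000, intensity_cv = 0.1,
                          dim_every = 20, prf_sigma_slope = 0.1,
                          seed = 42) {
  stopifnot(n_depths >= 2, n_ecc >= 1, n_angle >= 1)
  if (!increment_area %in% areas || !increment_condition %in% conditions)
    stop("increment area/condition not in the phantom spec")
  ecc <- seq(ecc_range[1], ecc_range[2], length.out = n_ecc)
  ang <- seq(-80, 80, length.out = n_angle)   # right hemifield map
  cols <- do.call(rbind, lapply(areas, function(a)
    data.frame(area = a,
               ecc = rep(ecc, each = n_angle),
               angle = rep(ang, times = n_ecc))))
  cols$x <- cols$ecc * cos(cols$angle * pi / 180)
  cols$y <- cols$ecc * sin(cols$angle * pi / 180)
  cols$sigma <- 0.2 + prf_sigma_slope * cols$ecc
  cols$id <- seq_len(nrow(cols))
  n_col <- nrow(cols)

  depth_fr <- seq(0, 1, length.out = n_depths)
  centre <- cols$ecc >= 1 & cols$ecc <= 3
  edge <- cols$ecc >= 3.5 & cols$ecc <= 4.0

  sus <- array(0, c(n_col, n_depths, length(conditions)),
               dimnames = list(NULL, NULL, conditions))
  trn <- array(0, c(n_col, n_depths, length(conditions)),
               dimnames = list(NULL, NULL, conditions))
  for (cond in conditions) {
    sus[centre, , cond] <- sustained_amp
    trn[edge, , cond] <- transient_amp
  }
  bump <- increment_amp *
    exp(-(depth_fr - increment_depth)^2 / (2 * increment_width^2))
  inc_cols <- centre & cols$area == increment_area
  sus[inc_cols, , increment_condition] <-
    sus[inc_cols, , increment_condition] +
    matrix(bump, sum(inc_cols), n_depths, byrow = TRUE)

  epi <- matrix(baseline, n_col, n_depths)
  # mild superficial intensity gradient, as in gradient-echo EPI
  epi <- epi * matrix(1 + 0.05 * (1 - depth_fr), n_col, n_depths,
                      byrow = TRUE)
  # static voxel-wise tissue contrast (receive-field and partial-volume
  # variation); drawn once, deterministically under `seed`
  if (intensity_cv > 0) {
    rng <- local_rng(seed)
    epi <- epi * pmax(0.5, 1 + intensity_cv *
                        matrix(stats::rnorm(n_col * n_depths), n_col))
    rng()
  }
  if (dim_every > 0) {
    dim_cols <- seq(dim_every, n_col, by = dim_every)
    epi[dim_cols, 1] <- 6500
  }

  structure(list(columns = cols, depth_fractions = depth_fr,
                 conditions = conditions, sustained = sus, transient = trn,
                 epi = epi, baseline = baseline,
                 increment = list(amp = increment_amp,
                                  depth = increment_depth,
                                  width = increment_width,
                                  area = increment_area,
                                  condition = increment_condition)),
            class = "cortical_phantom")
}

#' @export
print.cortical_phantom <- function(x, ...) {
  cat(sprintf(
    "cortical_phantom: %d columns (%s), %d depth levels, conditions: %s\n",
    nrow(x$columns), paste(unique(x$columns$area), collapse = "/"),
    length(x$depth_fractions), paste(x$conditions, collapse = ", ")))
  invisible(x)
}

#' Acquisition model for synthetic runs
#'
#' @param tr repetition time, s (default 2.079)
#' @param noise_sd white-noise SD, percent of baseline signal (default 0.5)
#' @param ar_coef lag-1 autocorrelation of the noise (default 0.3)
#' @param drift_amp amplitude of the slow cosine drift, percent (default 0.5)
#' @param subject_sd SD of the multiplicative per-subject response scaling
#'   (default 0.1)
#' @return an `acquisition_model` list
#' @export
acquisition_model <- function(tr = 2.079, noise_sd = 0.5, ar_coef = 0.3,
                              drift_amp = 0.5, subject_sd = 0.1) {
  stopifnot(tr > 0, noise_sd >= 0, abs(ar_coef) < 1, drift_amp >= 0,
            subject_sd >= 0)
  structure(list(tr = tr, noise_sd = noise_sd, ar_coef = ar_coef,
                 drift_amp = drift_amp, subject_sd = subject_sd),
            class = "acquisition_model")
}

#' Simulate one functional run from the phantom
#'
#' Per column and depth, the neural response is the sustained boxcar plus
#' onset/offset transients scaled by the phantom truth amplitudes; the
#' laminar amplitude vector is passed through the draining forward model,
#' the response is HRF-convolved (via the same regressor construction the
#' analysis GLM uses), and AR(1)-correlated Gaussian noise plus a slow cosine
#' drift are added on top of the mean-EPI baseline.
#'
#' @param phantom a [build_phantom()]
#' @param schedule a [make_run_schedule()] (its condition label selects the
#'   truth amplitudes)
#' @param leakage a [leakage_model()] with `n_depths` matching the phantom
#' @param acquisition an [acquisition_model()]
#' @param seed integer seed (mandatory: runs must be reproducible)
#' @param subject_scale multiplicative response scaling (default 1)
#' @return a `synthetic_run` list: `data` (volumes x voxels), `voxels`
#'   (data.frame voxel/column/depth_index/depth_fraction), `schedule`,
#'   `condition`, `truth` (observed laminar amplitudes after leakage),
#'   `seed`
#' @export
simulate_run <- function(phantom, schedule, leakage = NULL,
                         acquisition = acquisition_model(), seed,
                         subject_scale = 1) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducibility")
  cond <- unique(schedule$condition)
  if (length(cond) != 1 || !cond %in% phantom$conditions)
    stop("schedule condition must be exactly one phantom condition")
  n_depths <- length(phantom$depth_fractions)
  if (is.null(leakage)) leakage <- leakage_model(n_depths, lambda = 0)
  if (leakage$n_depths != n_depths)
    stop("leakage model depth count does not match phantom")
  stopifnot(abs(schedule$tr - acquisition$tr) < 1e-9)

  # laminar truth through the draining forward model (deep-first ordering)
  drain <- function(amp_cd) {   # columns x depths, pial-first
    t(forward_drain(flip_depth_convention(t(amp_cd)), leakage))[,
      rev(seq_len(n_depths)), drop = FALSE]
  }
  sus_obs <- drain(phantom$sustained[, , cond] * subject_scale)
  trn_obs <- drain(phantom$transient[, , cond] * subject_scale)

  design <- build_design_matrix(schedule, hp_cutoff_s = NA)
  x_sus <- design$X_raw[, paste0(cond, "_sustained")]
  x_trn <- design$X_raw[, paste0(cond, "_transient")]

  n_col <- nrow(phantom$columns)
  n_vol <- schedule$n_volumes
  vox <- data.frame(voxel = seq_len(n_col * n_depths),
                    column = rep(seq_len(n_col), times = n_depths),
                    depth_index = rep(seq_len(n_depths), each = n_col),
                    depth_fraction = rep(phantom$depth_fractions,
                                         each = n_col))
  B <- as.vector(phantom$epi)                       # per-voxel baseline
  amp_s <- as.vector(sus_obs); amp_t <- as.vector(trn_obs)

  rng <- local_rng(seed)
  on.exit(rng())
  tvol <- seq_len(n_vol)
  drift <- acquisition$drift_amp / 100 *
    cos(2 * pi * tvol / n_vol + stats::runif(1, 0, 2 * pi))
  n_vox <- length(B)
  eps <- matrix(stats::rnorm(n_vol * n_vox), n_vol, n_vox)
  if (acquisition$ar_coef != 0) {
    for (t in 2:n_vol)
      eps[t, ] <- acquisition$ar_coef * eps[t - 1, ] +
        sqrt(1 - acquisition$ar_coef^2) * eps[t, ]
  }
  noise <- acquisition$noise_sd / 100 * eps

  resp <- outer(x_sus, amp_s / 100) + outer(x_trn, amp_t / 100)
  data <- sweep(1 + resp + drift + noise, 2, B, "*")

  structure(list(data = data, voxels = vox, schedule = schedule,
                 condition = cond,
                 truth = list(sustained_observed = sus_obs,
                              transient_observed = trn_obs,
                              leakage = leakage$W,
                              subject_scale = subject_scale),
                 seed = seed),
            class = "synthetic_run")
}

#' Simulate a multi-subject dataset
#'
#' One run per condition per subject; per-subject multiplicative response
#' scaling drawn once per subject from N(1, subject_sd). Seeds are derived
#' deterministically from the master seed.
#'
#' @inheritParams simulate_run
#' @param n_subjects number of subjects
#' @param conditions conditions to simulate (default: all in the phantom)
#' @param schedule_seed seed offset for per-condition schedules
#' @return list of subjects, each a named list of `synthetic_run`s
#' @export
simulate_subjects <- function(phantom, n_subjects,
                              conditions = phantom$conditions,
                              leakage = NULL,
                              acquisition = acquisition_model(), seed,
                              schedule_seed = 100) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  rng <- local_rng(seed)
  scales <- 1 + acquisition$subject_sd * stats::rnorm(n_subjects)
  rng()
  scales <- pmax(scales, 0.2)
  lapply(seq_len(n_subjects), function(s) {
    runs <- lapply(seq_along(conditions), function(ci) {
      sched <- make_run_schedule(condition = conditions[ci],
                                 tr_s = acquisition$tr,
                                 seed = schedule_seed + ci)
      simulate_run(phantom, sched, leakage, acquisition,
                   seed = seed + s * 1000 + ci,
                   subject_scale = scales[s])
    })
    names(runs) <- conditions
    runs
  })
}

#' Simulate pRF-mapping time courses from true receptive fields
#'
#' Bar configurations are presented one TR each in a seeded random order with
#' a given number of repetitions, padded with initial and final rest volumes;
#' the noiseless response is the pRF-aperture overlap convolved with the HRF,
#' to which white noise is added at the requested SNR (ratio of response
#' amplitude SD to noise SD; `Inf` for noiseless).
#'
#' @param prf_truth data.frame with columns x0, y0, sigma
#' @param movie bar apertures from [render_bar_apertures()]
#' @param n_reps repetitions of each configuration (default 12)
#' @param pad_volumes rest volumes prepended and appended (default 8 each,
#'   explicit because the padding is a free design parameter)
#' @param tr repetition time, s
#' @param snr signal-to-noise ratio (default Inf)
#' @param seed integer seed
#' @return list: `data` (volumes x units), `volume_frames` (frame shown per
#'   volume, 0 = rest), `config_sequence`, `n_volumes`
#' @export
simulate_prf_run <- function(prf_truth, movie, n_reps = 12,
                             pad_volumes = c(8, 8), tr = 2.079, snr = Inf,
                             seed = 1) {
  n_cfg <- dim(movie$frames)[1]
  rng <- local_rng(seed)
  on.exit(rng())
  seq_cfg <- as.vector(replicate(n_reps, sample.int(n_cfg)))
  n_vol <- pad_volumes[1] + length(seq_cfg) + pad_volumes[2]
  volume_frames <- c(rep(0L, pad_volumes[1]), seq_cfg,
                     rep(0L, pad_volumes[2]))
  hrf <- double_gamma_hrf(tr = tr)

  # overlap of every unit with every configuration, then map to volumes
  d <- dim(movie$frames)
  flat <- matrix(movie$frames, d[1], d[2] * d[3])
  G <- sapply(seq_len(nrow(prf_truth)), function(k)
    as.vector(prf_field(prf_truth$x0[k], prf_truth$y0[k],
                        prf_truth$sigma[k], d[2], movie$deg_per_pixel)))
  ov_cfg <- flat %*% G                      # cfg x units
  neural <- matrix(0, n_vol, nrow(prf_truth))
  neural[volume_frames > 0, ] <- ov_cfg[seq_cfg, ]
  clean <- apply(neural, 2, convolve_neural, kernel = hrf)
  if (is.finite(snr)) {
    sig_sd <- apply(clean, 2, stats::sd)
    noise <- matrix(stats::rnorm(length(clean)), nrow(clean)) *
      matrix(sig_sd / snr, nrow(clean), ncol(clean), byrow = TRUE)
    clean <- clean + noise
  }
  list(data = clean, volume_frames = volume_frames,
       config_sequence = seq_cfg, n_volumes = n_vol)
}
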