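test_that("pRF predictions behave on degenerate apertures", {
  b <- render_bar_apertures(deg_per_pixel = 0.2)
  zero <- aperture_movie(array(0, c(3, 10, 10)), 0.2, 1)
  p <- prf_model(1, 0.5, 0.6)
  expect_true(all(prf_predicted_timecourse(p, zero, hrf = 1) == 0))
  # full-field aperture: neural overlap constant, proportional to the
  # Gaussian mass on the grid (identity kernel isolates the overlap)
  full <- aperture_movie(array(1, c(4, 20, 20)), 0.2, 1)
  ov <- prf_predicted_timecourse(p, full, hrf = 1)
  expect_equal(max(ov) - min(ov), 0, tolerance = 1e-12)
  g <- lamsurf:::prf_field(1, 0.5, 0.6, 20, 0.2)
  expect_equal(ov[1], sum(g))
  expect_error(prf_model(0, 0, -1), "sigma")
})

test_that("bar-sweep overlap peaks at the configuration covering the pRF", {
  b <- render_bar_apertures(deg_per_pixel = 0.1)
  p <- prf_model(x0 = 0, y0 = 2, sigma = 0.4)
  ov <- prf_predicted_timecourse(p, b, hrf = 1)   # one volume per config
  # brute-force oracle over all 32 configurations
  d <- dim(b$frames)
  g <- as.vector(lamsurf:::prf_field(0, 2, 0.4, d[2], 0.1))
  brute <- sapply(seq_len(d[1]), function(i)
    sum(as.vector(b$frames[i, , ]) * g))
  expect_equal(as.numeric(ov), brute, tolerance = 1e-12)
  best <- b$configs[which.max(ov), ]
  # the winning bar's band must cover the pRF centre (0, 2)
  th <- best$orientation_deg * pi / 180
  dist_to_band <- abs((-0 * sin(th) + 2 * cos(th)) - best$position_deg)
  expect_lte(dist_to_band, 1.25 / 2)
})

test_that("grid fitting recovers noiseless parameters exactly on-grid", {
  bars <- render_bar_apertures(deg_per_pixel = 0.1)
  truth <- data.frame(x0 = c(2, -1.5, 0), y0 = c(1, 0.5, -2),
                      sigma = c(0.8, 0.5, 0.5))
  run <- simulate_prf_run(truth, bars, snr = Inf, seed = 3)
  grid <- prf_grid_spec(x = seq(-3, 3, 0.5), y = seq(-3, 3, 0.5),
                        sigma = c(0.5, 0.8, 1.2))
  cand <- prf_candidate_predictions(grid, bars, run$volume_frames)
  fit <- fit_prf_grid(run$data, cand)
  expect_equal(fit$x0, truth$x0)
  expect_equal(fit$y0, truth$y0)
  expect_equal(fit$sigma, truth$sigma)
  expect_true(all(fit$r_squared > 0.999))
})

test_that("degenerate time courses are flagged, not fitted", {
  bars <- render_bar_apertures(deg_per_pixel = 0.2)
  grid <- prf_grid_spec(x = 0, y = 0, sigma = 1)
  cand <- prf_candidate_predictions(grid, bars)
  fit <- fit_prf_grid(rep(5, dim(bars$frames)[1]), cand)
  expect_true(is.na(fit$r_squared))
  expect_true(is.na(fit$x0))
})

test_that("R-squared is invariant under affine scaling of the time course", {
  bars <- render_bar_apertures(deg_per_pixel = 0.1)
  truth <- data.frame(x0 = 1, y0 = 1, sigma = 0.6)
  run <- simulate_prf_run(truth, bars, snr = 5, seed = 9)
  grid <- prf_grid_spec(x = seq(-2, 2, 0.5), y = seq(-2, 2, 0.5),
                        sigma = c(0.4, 0.6, 1))
  cand <- prf_candidate_predictions(grid, bars, run$volume_frames)
  f1 <- fit_prf_grid(run$data, cand)
  f2 <- fit_prf_grid(3.7 * run$data + 120, cand)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-10)
  expect_equal(f1$x0, f2$x0)
})

test_that("added noise never increases expected fit quality", {
  bars <- render_bar_apertures(deg_per_pixel = 0.1)
  truth <- data.frame(x0 = rep(1, 30), y0 = rep(-0.5, 30),
                      sigma = rep(0.6, 30))
  grid <- prf_grid_spec(x = seq(-2, 2, 0.5), y = seq(-2, 2, 0.5),
                        sigma = c(0.4, 0.6, 1))
  r2_at <- function(snr, seed) {
    run <- simulate_prf_run(truth, bars, snr = snr, seed = seed)
    cand <- prf_candidate_predictions(grid, bars, run$volume_frames)
    mean(fit_prf_grid(run$data, cand)$r_squared)
  }
  r2 <- sapply(c(20, 5, 1), r2_at, seed = 4)
  expect_true(all(diff(r2) < 0))
})

test_that("retinotopy maps follow the closed forms", {
  m <- data.frame(x0 = c(3, 0, -1, NA), y0 = c(4, 2, 0, NA))
  r <- derive_retinotopy(m)
  expect_equal(r$eccentricity_deg[1:3], c(5, 2, 1))
  expect_equal(r$polar_angle_deg[1:3], c(atan2(4, 3) * 180 / pi, 90, 180))
  expect_true(is.na(r$eccentricity_deg[4]))
  # batch equals element-wise recomputation
  set.seed(2)
  mb <- data.frame(x0 = rnorm(20), y0 = rnorm(20))
  rb <- derive_retinotopy(mb)
  for (i in seq_len(20)) {
    expect_equal(rb$eccentricity_deg[i], sqrt(mb$x0[i]^2 + mb$y0[i]^2))
    expect_equal(rb$polar_angle_deg[i],
                 atan2(mb$y0[i], mb$x0[i]) * 180 / pi)
  }
})
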