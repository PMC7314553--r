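test_that("double-gamma HRF has the canonical shape", {
  h <- double_gamma_hrf(tr = 2.079)
  expect_equal(max(h), 1)
  peak <- which.max(h)
  expect_true(all(h[peak:length(h)] <= h[peak]))
  expect_true(any(h < 0))                     # undershoot present
  expect_lt(which.max(h < 0 & seq_along(h) > peak), length(h))
  expect_error(double_gamma_hrf(peak_disp = 0), "dispersion")
})

test_that("TR-sampled kernel equals the dense kernel subsampled at the TR", {
  tr <- 2.079
  h_tr <- double_gamma_hrf(tr = tr)
  t_fine <- seq(0, 32, by = 0.001)          # grid containing every TR sample
  h_fine <- lamsurf:::hrf_shape(t_fine)
  h_fine <- h_fine / max(lamsurf:::hrf_shape(seq(0, 32, by = tr)))
  idx <- round(seq(0, 32, by = tr) / 0.001) + 1
  expect_equal(as.numeric(h_tr), h_fine[idx], tolerance = 1e-9)
})

test_that("high-pass filtering is an idempotent projection", {
  set.seed(1)
  x <- cumsum(rnorm(250)) + sin(seq_len(250) / 9)
  f1 <- highpass_filter(x, tr = 2.079, cutoff_s = 35)
  f2 <- highpass_filter(f1, tr = 2.079, cutoff_s = 35)
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_lt(abs(mean(f1)), 1e-12)
})

test_that("the full task design has the expected columns", {
  scheds <- lapply(c(motion = "motion", static = "static",
                     dynamic = "dynamic"), function(cond)
    make_run_schedule(condition = cond, seed = 3))
  te <- decorrelate_target_events(scheds[[1]], seed = 2)
  dm <- build_design_matrix(scheds, targets = te)
  expect_equal(ncol(dm$X), 7)   # 3 conditions x 2 components + 1 nuisance
  expect_true(all(abs(colMeans(dm$X)) < 1e-10))   # filtered columns
  empty <- build_design_matrix(make_run_schedule(n_blocks = 0))
  expect_equal(ncol(empty$X), 0)
})

test_that("sustained regressor integral matches the convolution identity", {
  # integral of boxcar * HRF over a long window = HRF integral x duration
  tr <- 2.079
  n_vol <- 120
  h <- double_gamma_hrf(tr = tr)
  pred <- lamsurf:::convolve_boxcar(20.79, 10.395, h, tr, n_vol)
  t_fine <- seq(0, 32, by = 0.001)
  hrf_int <- sum(lamsurf:::hrf_shape(t_fine)) * 0.001 /
    max(lamsurf:::hrf_shape(t_fine))
  expect_equal(sum(pred) * tr, hrf_int * 10.395, tolerance = 0.02)
})

test_that("GLM recovers known betas exactly without noise", {
  sched <- make_run_schedule(condition = "motion", seed = 4)
  dm <- build_design_matrix(sched)
  truth <- c(2.5, -1.2)
  y <- as.numeric(dm$X %*% truth)
  fit <- fit_glm(y, dm)
  expect_equal(as.numeric(fit$betas), truth, tolerance = 1e-10)
})

test_that("pure-noise data gives condition betas within 3 SE of zero", {
  sched <- make_run_schedule(condition = "motion", seed = 4)
  dm <- build_design_matrix(sched)
  set.seed(42)
  n_mc <- 200
  z <- replicate(n_mc, {
    fit <- fit_glm(rnorm(dm$n_volumes), dm)
    fit$betas[1, 1]
  })
  expect_lt(abs(mean(z)) / (sd(z) / sqrt(n_mc)), 3)
})

test_that("rank-deficient designs are rejected with the offending column", {
  sched <- make_run_schedule(condition = "motion", seed = 4)
  dm <- build_design_matrix(sched)
  dm$X <- cbind(dm$X, dm$X[, 1])
  dm$columns <- c(dm$columns, "dup")
  expect_error(fit_glm(rnorm(dm$n_volumes), dm), "collinear")
})

test_that("percent signal change follows its definition and gauge", {
  sched <- make_run_schedule(condition = "motion", seed = 4)
  dm <- build_design_matrix(sched)
  base <- 10000
  y <- base * (1 + 0.01 * dm$X_raw[, 1])   # 1% sustained response
  fit <- fit_glm(y, dm)
  psc <- to_percent_signal_change(fit, y)
  expect_equal(unname(psc["motion_sustained", 1]), 1.0, tolerance = 1e-6)
  expect_equal(unname(psc["motion_transient", 1]), 0.0, tolerance = 1e-6)
  # gauge: adding a constant c rescales PSC by baseline / (baseline + c)
  c0 <- 2500
  fit2 <- fit_glm(y + c0, dm)
  psc2 <- to_percent_signal_change(fit2, y + c0)
  expect_equal(unname(psc2["motion_sustained", 1]),
               unname(psc["motion_sustained", 1]) * base / (base + c0),
               tolerance = 1e-8)
  # zero beta maps to zero PSC; non-positive baseline flagged
  expect_equal(unname(to_percent_signal_change(fit, y)["motion_transient", 1]),
               0, tolerance = 1e-6)
  yneg <- y - 2 * base
  fit3 <- fit_glm(yneg, dm)
  expect_true(all(is.na(to_percent_signal_change(fit3, yneg))))
})

test_that("event-related averages recover constants and steps", {
  sched <- make_run_schedule(condition = "motion", seed = 4)
  flat <- event_related_average(rep(100, sched$n_volumes), sched,
                                window_s = 10)
  expect_true(all(abs(flat$mean) < 1e-12))
  # step response at each block onset
  y <- rep(1000, sched$n_volumes)
  on_vol <- round(sched$onsets / sched$tr) + 1
  for (v in on_vol) y[v:(v + 4)] <- 1010
  er <- event_related_average(y, sched, window_s = 10)
  post <- er$time_s >= 0 & er$time_s <= 8
  expect_equal(unname(er$mean[post]), rep(1, sum(post)), tolerance = 1e-6)
  expect_error(event_related_average(y, make_run_schedule(n_blocks = 0)),
               "repetitions")
})
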