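test_that("the phantom encodes the programmed response pattern", {
  ph <- build_phantom()
  centre_v1 <- ph$columns$area == "V1" & ph$columns$ecc >= 1 &
    ph$columns$ecc <= 3
  expect_true(all(ph$sustained[centre_v1, , "dynamic"] < 0))
  expect_true(all(ph$sustained[centre_v1, , "motion"] < 0))
  edge <- ph$columns$ecc >= 3.5 & ph$columns$ecc <= 4.0
  expect_true(all(ph$transient[edge, , "motion"] > 0))
  # condition increment peaks at the depth index nearest 25%
  diff_tab <- ph$sustained[, , "motion"] - ph$sustained[, , "dynamic"]
  col <- which(rowSums(abs(diff_tab)) > 0)[1]
  pk <- ph$depth_fractions[which.max(diff_tab[col, ])]
  expect_lte(abs(pk - 0.25), 0.05)
  # zero-amplitude spec gives an all-zero truth table
  z <- build_phantom(sustained_amp = 0, transient_amp = 0,
                     increment_amp = 0)
  expect_true(all(z$sustained == 0) && all(z$transient == 0))
  expect_error(build_phantom(increment_area = "V9"), "increment")
})

test_that("noiseless simulation with identity leakage round-trips through
           the GLM", {
  ph <- small_phantom()
  sch <- make_run_schedule(condition = "motion", seed = 2)
  run <- simulate_run(ph, sch, leakage = leakage_model(11, lambda = 0),
                      acquisition = noiseless_acq(), seed = 5)
  fit <- fit_glm(run$data, build_design_matrix(sch))
  psc <- to_percent_signal_change(fit, run$data)
  n_d <- length(ph$depth_fractions)
  sus <- matrix(psc["motion_sustained", ], nrow(ph$columns), n_d)
  trn <- matrix(psc["motion_transient", ], nrow(ph$columns), n_d)
  expect_equal(sus, ph$sustained[, , "motion"], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(trn, ph$transient[, , "motion"], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("with draining leakage the observed profile is W times truth", {
  ph <- small_phantom()
  sch <- make_run_schedule(condition = "motion", seed = 2)
  L <- leakage_model(11, lambda = 0.3)
  run <- simulate_run(ph, sch, leakage = L,
                      acquisition = noiseless_acq(), seed = 5)
  fit <- fit_glm(run$data, build_design_matrix(sch))
  psc <- to_percent_signal_change(fit, run$data)
  sus <- matrix(psc["motion_sustained", ], nrow(ph$columns), 11)
  for (col in c(1, 7, 15)) {
    local_deep_first <- rev(ph$sustained[col, , "motion"])
    expect_equal(rev(sus[col, ]),
                 as.numeric(L$W %*% local_deep_first), tolerance = 1e-8)
    # and deconvolution recovers the local truth
    expect_equal(rev(deconvolve_drain(rev(sus[col, ]), L)),
                 ph$sustained[col, , "motion"], tolerance = 1e-8)
  }
})

test_that("simulation is deterministic under the seed and requires one", {
  ph <- small_phantom()
  sch <- make_run_schedule(condition = "static", seed = 2)
  r1 <- simulate_run(ph, sch, seed = 9)
  r2 <- simulate_run(ph, sch, seed = 9)
  expect_identical(r1$data, r2$data)
  expect_error(simulate_run(ph, sch, seed = NULL), "seed")
})

test_that("group-mean depth profile lies within 3 SEM of the truth", {
  ph <- small_phantom()
  L <- leakage_model(11, lambda = 0)
  acq <- acquisition_model(noise_sd = 0.5, subject_sd = 0)
  subs <- simulate_subjects(ph, 10, conditions = "motion", leakage = L,
                            acquisition = acq, seed = 77)
  centre <- ph$columns$ecc >= 1 & ph$columns$ecc <= 3
  profs <- sapply(subs, function(s) {
    run <- s$motion
    fit <- fit_glm(run$data, build_design_matrix(run$schedule))
    psc <- to_percent_signal_change(fit, run$data)
    colMeans(matrix(psc["motion_sustained", ], nrow(ph$columns),
                    11)[centre, ])
  })
  m <- rowMeans(profs)
  sem <- apply(profs, 1, sd) / sqrt(10)
  truth <- colMeans(ph$sustained[centre, , "motion"])
  expect_true(all(abs(m - truth) <= 3 * sem + 1e-9))
})

test_that("datasets round-trip bit-exactly through disk", {
  ph <- small_phantom()
  sch <- make_run_schedule(condition = "motion", seed = 2)
  run <- simulate_run(ph, sch, seed = 13)
  dir <- tempfile("ds")
  write_dataset(run, dir)
  back <- read_dataset(dir, "motion")
  expect_equal(back$data, run$data, ignore_attr = TRUE)
  expect_equal(back$truth$sustained_observed,
               run$truth$sustained_observed, ignore_attr = TRUE)
  expect_equal(back$truth$leakage, run$truth$leakage, ignore_attr = TRUE)
  expect_equal(back$events$onset[back$events$trial_type == "motion"],
               sch$onsets)
  # manifest seed regenerates identical truth tables
  run2 <- simulate_run(ph, sch, seed = back$manifest$seed)
  expect_identical(run2$truth$sustained_observed,
                   run$truth$sustained_observed)
  expect_identical(run2$data, run$data)
  unlink(dir, recursive = TRUE)
})

test_that("acquisition model validates its parameters", {
  expect_error(acquisition_model(ar_coef = 1), "abs")
  expect_error(acquisition_model(noise_sd = -1), "noise_sd")
})
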