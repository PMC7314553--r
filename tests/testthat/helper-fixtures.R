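# Shared small fixtures, built in code at test time.

small_phantom <- function(...) {
  build_phantom(areas = "V1", n_ecc = 6, n_angle = 3, dim_every = 0, ...)
}

noiseless_acq <- function() {
  acquisition_model(noise_sd = 0, ar_coef = 0, drift_amp = 0,
                    subject_sd = 0)
}

# depth-profile table for the mixed-model tests: random subject intercepts
# and depth slopes, additive fixed effects, optional condition-by-area
# interaction of the given size (units of the residual SD)
make_profile_table <- function(seed, n_subj = 9, n_depth = 6,
                               areas = c("V1", "V2"),
                               conditions = c("a", "b"),
                               interaction = 0, resid_sd = 0.2) {
  set.seed(seed)
  d <- expand.grid(subject = seq_len(n_subj), area = areas,
                   condition = conditions,
                   depth = seq(0, 1, length.out = n_depth))
  icpt <- rnorm(n_subj, 0, 0.3)
  slope <- rnorm(n_subj, 0, 0.3)
  d$psc <- icpt[d$subject] + slope[d$subject] * d$depth +
    0.2 * (d$area == areas[2]) + 0.1 * (d$condition == conditions[2]) -
    0.3 * d$depth +
    interaction * resid_sd *
      (d$area == areas[2]) * (d$condition == conditions[2]) +
    rnorm(nrow(d), 0, resid_sd)
  d
}
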