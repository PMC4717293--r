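# Shared fixture builders. All fixtures are generated in code; sizes are kept
# small so the whole suite runs in minutes on one core.

ge_meta <- function() acquisition_meta(0.0055, 0.040, "gradient_echo")
se_meta <- function() acquisition_meta(0.030, 2.0, "spin_echo")
dsc_meta <- function(baseline_frames = 75)
  acquisition_meta(0.010, 0.4, "dynamic_epi", baseline_frames = baseline_frames)

# small phantom for unit tests (regions down to 8 voxels are accepted)
small_phantom <- function() make_phantom(c(16, 16, 4), min_voxels = 8)

default_truth_maps <- function(phantom = make_phantom())
  qvasc:::build_truth_maps(phantom, default_region_truth())

# short DSC series fixture: 120 frames, 20-frame (8 s) baseline
short_dsc <- function(phantom, truth, noise_sigma = 0, seed = 1,
                      aif = default_aif_params(t0 = 10)) {
  synth_dsc(phantom, truth, dsc_meta(baseline_frames = 20), n_frames = 120,
            noise_sigma = noise_sigma, seed = seed, aif_params = aif)
}

trapz <- function(y, dt) dt * (sum(y) - 0.5 * (y[1] + y[length(y)]))

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
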