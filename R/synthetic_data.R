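#' @rdname make_phantom
#' @export
REGION_NAMES <- c("olfactory_bulb", "cortex", "striatum", "hippocampus",
                  "thalamus", "cerebellum")

#' Evaluate a gamma-variate bolus curve
#'
#' \eqn{C(t) = A (t - t_0)^\alpha e^{-(t - t_0)/\beta}} for \eqn{t > t_0},
#' 0 otherwise. The standard first-pass bolus shape (recirculation excluded).
#'
#' @param t Time points (seconds).
#' @param A Amplitude (s^-1 * s^-alpha).
#' @param t0 Onset time (seconds).
#' @param alpha Shape parameter (> 0).
#' @param beta Scale parameter (seconds, > 0).
#' @return Curve values, same length as `t`.
#' @export
gamma_variate <- function(t, A, t0, alpha, beta) {
  dt <- t - t0
  out <- numeric(length(t))
  pos <- dt > 0
  out[pos] <- A * dt[pos]^alpha * exp(-dt[pos] / beta)
  out
}

#' Default arterial-input-function parameters
#'
#' A gamma-variate bolus arriving 3 s after the end of the 30 s baseline,
#' peaking at 60 s^-1 in the artery. The default width (full width at half
#' maximum about 3 s) follows from the injection protocol being emulated: a
#' pump infusion of roughly 80 ul at 2 ml/min takes about 2.5 s, plus modest
#' cardiopulmonary dispersion. The amplitude is derived from the requested
#' peak: the curve maximum sits at `t0 + alpha*beta` with value
#' `A (alpha beta)^alpha e^-alpha`.
#'
#' @param t0 Bolus arrival time in the artery (s).
#' @param alpha,beta Gamma-variate shape/scale.
#' @param peak Peak arterial concentration (Delta-R2*, s^-1).
#' @return A named list with elements `A`, `t0`, `alpha`, `beta`.
#' @export
default_aif_params <- function(t0 = 33, alpha = 2, beta = 1, peak = 60) {
  A <- peak / ((alpha * beta)^alpha * exp(-alpha))
  list(A = A, t0 = t0, alpha = alpha, beta = beta)
}

#' Default per-region ground-truth vascular parameters
#'
#' Region values for the six gray-matter ROIs. The relaxation shift index
#' baseline averages 0.63 s^(-1/3) across regions, the steady-state
#' Delta-R2* is 40 s^-1 (high-dose intravascular iron oxide), regional
#' relative CBF is ~0.15 s^-1 with a 1.8 s mean transit time, and
#' dR2 = q * dR2*^(2/3) by construction.
#'
#' @param parenchyma_q,parenchyma_cbf Values used for in-brain voxels outside
#'   any named ROI.
#' @return A list with named per-region vectors `q`, `dr2star`, `cbf`, `mtt`
#'   plus scalar `parenchyma` defaults.
#' @export
default_region_truth <- function(parenchyma_q = 0.63, parenchyma_cbf = 0.15) {
  q <- c(olfactory_bulb = 0.66, cortex = 0.64, striatum = 0.60,
         hippocampus = 0.62, thalamus = 0.61, cerebellum = 0.65)
  dr2star <- stats::setNames(rep(40, 6), REGION_NAMES)
  cbf <- c(olfactory_bulb = 0.16, cortex = 0.18, striatum = 0.14,
           hippocampus = 0.15, thalamus = 0.15, cerebellum = 0.17)
  mtt <- stats::setNames(rep(1.8, 6), REGION_NAMES)
  list(q = q, dr2star = dr2star, cbf = cbf, mtt = mtt,
       parenchyma = list(q = parenchyma_q, dr2star = 40,
                         cbf = parenchyma_cbf, mtt = 1.8))
}

#' Genotype effect tables
#'
#' Multiplicative factors applied to the transgenic group's per-region truth.
#' `"arcab_24mo"` encodes the 24-month arcAb-vs-littermate contrasts this
#' package is designed to recover: relaxation-shift-index reductions of
#' 11/15/26/20/0/19% (olfactory bulb, cortex, striatum, hippocampus,
#' thalamus, cerebellum), a 25% cortical increase in steady-state Delta-R2*
#' (i.e. rCBV(dR2*)), a 21% cortical increase in DSC blood volume and a 35%
#' cerebellar blood-flow reduction. Because microvessel density scales as the
#' cube of the shift index, the equivalent density-level factors (`n_density`)
#' are the cubes of the `q` factors; effects are configured on the parameter
#' whose recovered change is of interest. DSC volume/flow factors are applied
#' to both CBF and CBV (mean transit time preserved: a parallel change in
#' vessel density scales flow and volume together).
#'
#' `"null"` sets every factor to 1 (no genotype effect).
#'
#' @param name `"arcab_24mo"` or `"null"`.
#' @return A list of named per-region factor vectors `q`, `dr2star`, `cbf`,
#'   `cbv`, plus derived `n_density`.
#' @export
cohort_effects <- function(name = c("arcab_24mo", "null")) {
  name <- match.arg(name)
  ones <- stats::setNames(rep(1, 6), REGION_NAMES)
  eff <- list(q = ones, dr2star = ones, cbf = ones, cbv = ones)
  if (name == "arcab_24mo") {
    eff$q <- c(olfactory_bulb = 0.89, cortex = 0.85, striatum = 0.74,
               hippocampus = 0.80, thalamus = 1.00, cerebellum = 0.81)
    eff$dr2star[["cortex"]] <- 1.25
    eff$cbf[["cortex"]] <- 1.21        # flow follows volume, MTT preserved
    eff$cbv[["cortex"]] <- 1.21
    eff$cbf[["cerebellum"]] <- 0.65
    eff$cbv[["cerebellum"]] <- 0.65    # volume follows flow, MTT preserved
  }
  eff$n_density <- eff$q^3
  eff
}

#' Build a deterministic digital brain phantom
#'
#' Partitions a 3D grid into background, an in-brain parenchyma shell, six
#' rectangular gray-matter ROI bands and a small artery strip used for
#' arterial-input-function selection. ROIs are inset two voxels from the
#' brain edge so region statistics are not contaminated by the air/tissue
#' boundary. The construction is fully deterministic.
#'
#' @param shape Grid dimensions, length 3.
#' @param spacing_mm Voxel size in mm.
#' @param min_voxels Minimum voxels required per region (default 50).
#' @return A [region_set()] with labels 1..6 = regions (see `REGION_NAMES`),
#'   7 = artery, 0 = background/non-ROI; plus a logical `$brain` array
#'   marking the signal-bearing foreground.
#' @export
make_phantom <- function(shape = c(24, 24, 6), spacing_mm = c(0.2, 0.2, 0.8),
                         min_voxels = 50) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive integers")
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  bx <- 3:(nx - 2); by <- 3:(ny - 2)           # brain box, 2-voxel air margin
  rx <- 5:(nx - 4); ry <- 5:(ny - 4)           # ROI area, 2 voxels inside brain
  if (nx < 12 || ny < 16 || length(rx) < 1 || length(ry) < 6)
    stop("shape too small to host 6 regions plus an artery")
  labels <- array(0L, shape)
  brain <- array(FALSE, shape)
  brain[bx, by, ] <- TRUE
  # six contiguous y-bands over the ROI area
  band <- split(ry, cut(seq_along(ry), 6, labels = FALSE))
  for (b in seq_len(6)) labels[rx, band[[b]], ] <- b
  # artery: strip in the parenchyma shell between brain edge and ROI inset
  ay_len <- max(2L, ceiling(min_voxels / (2 * nz)))
  ay <- ry[seq_len(min(ay_len, length(ry)))]
  labels[3:4, ay, ] <- 7L
  counts <- table(factor(labels[labels > 0], levels = 1:7))
  if (any(counts < min_voxels))
    stop("shape too small: smallest region has ", min(counts),
         " voxels (need >= ", min_voxels, ")")
  rs <- region_set(labels, stats::setNames(1:7, c(REGION_NAMES, "artery")),
                   spacing_mm = spacing_mm)
  rs$brain <- brain
  rs
}

# Expand per-region parameter values into a voxel map on the phantom grid.
# `values` is a named vector over REGION_NAMES; parenchyma/artery defaults
# fill in-brain voxels without a gray-matter label.
region_map <- function(phantom, values, parenchyma, artery = parenchyma) {
  m <- array(0, dim(phantom$labels))
  m[phantom$brain] <- parenchyma
  for (r in REGION_NAMES) {
    lab <- phantom$names[[r]]
    m[phantom$labels == lab] <- values[[r]]
  }
  m[phantom$labels == phantom$names[["artery"]]] <- artery
  m
}

# Per-animal voxel truth maps from per-region parameters.
build_truth_maps <- function(phantom, params) {
  q <- region_map(phantom, params$q, params$parenchyma$q)
  dr2star <- region_map(phantom, params$dr2star, params$parenchyma$dr2star)
  cbf <- region_map(phantom, params$cbf, params$parenchyma$cbf, artery = 0)
  mtt <- region_map(phantom, params$mtt, params$parenchyma$mtt, artery = 0)
  list(q = q, dr2star = dr2star, dr2 = q * dr2star^(2 / 3),
       cbf = cbf, mtt = mtt, cbv = cbf * mtt)
}

# Nearest-neighbour block upsampling of a map by integer factor per axis.
upsample_map <- function(m, f) {
  f <- rep(as.integer(f), length.out = 3)
  d <- dim(m)
  m[rep(seq_len(d[1]), each = f[1]),
    rep(seq_len(d[2]), each = f[2]),
    rep(seq_len(d[3]), each = f[3]), drop = FALSE]
}

#' Simulate steady-state pre/post contrast volumes
#'
#' Forward model for the steady-state pathway: with an intravascular tracer
#' at steady concentration, the post-contrast signal is
#' `S_post = S_pre * exp(-TE * dR2)` (spin echo) and
#' `S*_post = S*_pre * exp(-TE * dR2*)` (gradient echo). The gradient-echo
#' pair is emitted on a grid `ge_upsample` times finer than the spin-echo
#' grid, as acquired in practice, to exercise grid resampling downstream.
#' Zero-mean Gaussian noise of s.d. `noise_sigma * baseline` is added to
#' every volume independently (high-SNR magnitude approximation; set
#' `rician = TRUE` for Rician magnitude noise).
#'
#' @param phantom A [make_phantom()] region set.
#' @param truth Voxel truth maps (`dr2`, `dr2star`) on the phantom grid, as
#'   built from [default_region_truth()]; see [make_cohort()].
#' @param meta_ge,meta_se [acquisition_meta()] for the two sequences.
#' @param noise_sigma Noise s.d. as a fraction of the baseline signal.
#' @param seed RNG seed, or `NULL` to use the current RNG stream.
#' @param ge_upsample Integer grid-refinement factor for the GE pair.
#' @param baseline Pre-contrast in-brain signal level (a.u.).
#' @param rician If `TRUE`, apply noise as Rician magnitude noise.
#' @return List of four [volume_image()]s: `ge_pre`, `ge_post`, `se_pre`,
#'   `se_post`.
#' @export
synth_steady_state <- function(phantom, truth, meta_ge, meta_se,
                               noise_sigma = 0.025, seed = NULL,
                               ge_upsample = 2, baseline = 1000,
                               rician = FALSE) {
  if (meta_ge$te_s <= 0 || meta_se$te_s <= 0) stop("echo times must be positive")
  if (!is.null(seed)) set.seed(seed)
  add_noise <- function(s) {
    if (noise_sigma == 0) return(s)
    if (rician) {
      sqrt((s + stats::rnorm(length(s), sd = noise_sigma * baseline))^2 +
             stats::rnorm(length(s), sd = noise_sigma * baseline)^2)
    } else s + stats::rnorm(length(s), sd = noise_sigma * baseline)
  }
  attenuate <- function(pre, dr2, te) {
    att <- exp(-te * dr2)
    if (any(att[pre > 0] < .Machine$double.eps)) {
      warning("TE * dR2 so large that the post-contrast signal underflows; flooring")
      att <- pmax(att, .Machine$double.eps)
    }
    pre * att
  }
  se_pre0 <- array(0, dim(phantom$labels)); se_pre0[phantom$brain] <- baseline
  se_post0 <- attenuate(se_pre0, truth$dr2, meta_se$te_s)
  ge_pre0 <- upsample_map(se_pre0, ge_upsample)
  ge_post0 <- attenuate(ge_pre0, upsample_map(truth$dr2star, ge_upsample),
                        meta_ge$te_s)
  sp <- phantom$spacing_mm
  list(
    ge_pre = volume_image(array(add_noise(ge_pre0), dim(ge_pre0)),
                          sp / ge_upsample, meta_ge),
    ge_post = volume_image(array(add_noise(ge_post0), dim(ge_post0)),
                           sp / ge_upsample, meta_ge),
    se_pre = volume_image(array(add_noise(se_pre0), dim(se_pre0)), sp, meta_se),
    se_post = volume_image(array(add_noise(se_post0), dim(se_post0)), sp, meta_se)
  )
}

#' Simulate a DSC bolus-passage series
#'
#' Indicator-dilution forward model: artery voxels carry the gamma-variate
#' arterial input C_a(t); tissue voxels carry
#' `C_t(t) = CBF * (C_a (*) R)(t)` with exponential residue
#' `R(t) = exp(-t / MTT)`, `MTT = CBV / CBF` (central volume theorem).
#' Concentration is encoded into signal as `S(t) = S0 exp(-TE * C(t))`
#' (proportionality constant k = 1) and Gaussian noise of s.d.
#' `noise_sigma * S0` is added to the signal.
#'
#' @param phantom A [make_phantom()] region set.
#' @param truth Voxel truth maps (`cbf`, `cbv`) on the phantom grid.
#' @param meta [acquisition_meta()] with `sequence = "dynamic_epi"`.
#' @param n_frames Number of frames (>= `baseline_frames + 30`).
#' @param noise_sigma Noise s.d. as a fraction of baseline signal.
#' @param seed RNG seed, or `NULL` to continue the current stream.
#' @param aif_params Gamma-variate AIF parameters ([default_aif_params()]).
#' @param baseline Pre-contrast in-brain signal level (a.u.).
#' @return A [dynamic_series()].
#' @export
synth_dsc <- function(phantom, truth, meta, n_frames = 300,
                      noise_sigma = 0.025, seed = NULL,
                      aif_params = default_aif_params(), baseline = 1000) {
  if (n_frames < meta$baseline_frames + 30)
    stop("n_frames must be >= baseline_frames + 30")
  bad <- truth$cbf == 0 & truth$cbv > 0
  if (any(bad)) stop("cbf_true = 0 with cbv_true > 0: mean transit time undefined")
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(n_frames) - 1) * meta$tr_s
  ca <- gamma_variate(t, aif_params$A, aif_params$t0, aif_params$alpha,
                      aif_params$beta)
  if (any(ca < 0)) stop("aif_params yield a negative curve")
  # one convolution per distinct MTT, scaled per voxel by CBF
  conc <- matrix(0, n_frames, length(phantom$labels))
  vox_mtt <- ifelse(truth$cbf > 0, truth$cbv / truth$cbf, 0)
  in_tissue <- phantom$brain & phantom$labels != phantom$names[["artery"]] &
    truth$cbf > 0
  for (m in unique(vox_mtt[in_tissue])) {
    shape <- convolve_residue(aif_params, m, meta$tr_s, n_frames)
    idx <- which(in_tissue & vox_mtt == m)
    conc[, idx] <- outer(shape, truth$cbf[idx])
  }
  conc[, which(phantom$labels == phantom$names[["artery"]])] <- ca
  s0 <- as.numeric(ifelse(phantom$brain, baseline, 0))
  sig <- matrix(rep(s0, each = n_frames), n_frames) * exp(-meta$te_s * conc)
  if (noise_sigma > 0)
    sig <- sig + stats::rnorm(length(sig), sd = noise_sigma * baseline)
  dynamic_series(array(t(sig), c(dim(phantom$labels), n_frames)), meta,
                 spacing_mm = phantom$spacing_mm)
}

# (C_a (*) R)(t) at the frame times, for a gamma-variate input and an
# exponential residue exp(-t/mtt). The MR signal samples a continuous
# process, so the convolution integral is evaluated by trapezoidal
# quadrature on a grid `substep` times finer than the frame spacing and
# then sampled at the frame times; a rectangle-rule sum on the frame grid
# itself would inflate the integral of the residue (and hence the apparent
# blood volume) by about dt/(2*MTT). mtt = 0 gives the zero-volume limit.
convolve_residue <- function(aif_params, mtt, dt, n_frames, substep = 10L) {
  if (mtt <= 0) return(numeric(n_frames))
  dtf <- dt / substep
  nf <- (n_frames - 1L) * substep + 1L
  tf <- (seq_len(nf) - 1) * dtf
  ca <- gamma_variate(tf, aif_params$A, aif_params$t0, aif_params$alpha,
                      aif_params$beta)
  r <- exp(-tf / mtt)
  full <- dtf * stats::convolve(ca, rev(r), type = "open")[seq_len(nf)]
  full <- full - 0.5 * dtf * (ca * r[1] + ca[1] * r)   # trapezoid endpoints
  # causal product of nonnegative curves: clear FFT round-off so pre-bolus
  # frames are exactly zero (and signals exactly at baseline)
  full[tf <= aif_params$t0 | full < 0] <- 0
  full[seq(1L, nf, by = substep)]
}

#' Specify a synthetic two-genotype cohort
#'
#' The default design mirrors a 24-month mouse imaging study: 14 control and
#' 8 transgenic animals, 5% lognormal per-animal biological scatter around
#' the group truth, measurement noise at SNR 40 (`noise_sigma = 0.025`), a
#' 300-frame DSC series at 0.4 s resolution with a 75-frame (30 s) baseline,
#' gradient-echo TE 5.5 ms, spin-echo TE 30 ms, DSC TE 10 ms.
#'
#' @param n_control,n_transgenic Group sizes (>= 2).
#' @param region_truth Per-region truth, see [default_region_truth()].
#' @param effect Genotype effect factors, see [cohort_effects()].
#' @param noise_sigma Measurement noise s.d. as fraction of baseline signal.
#' @param scatter_sd Lognormal s.d. of per-animal biological variability.
#' @param seed RNG seed (cohort is bit-reproducible given the spec).
#' @param shape Phantom grid dimensions.
#' @param ge_upsample GE grid-refinement factor.
#' @param n_frames DSC frame count.
#' @param baseline_frames Pre-bolus frames in the DSC series.
#' @param age_group Label attached to summaries ("24mo" or "13mo").
#' @param modalities Which modalities to synthesize per animal:
#'   `"steady_state"`, `"dsc"`, or both.
#' @param aif_params Arterial-input gamma-variate parameters
#'   ([default_aif_params()]).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_control = 14, n_transgenic = 8,
                        region_truth = default_region_truth(),
                        effect = cohort_effects("arcab_24mo"),
                        noise_sigma = 0.025, scatter_sd = 0.05, seed = 1,
                        shape = c(24, 24, 6), ge_upsample = 2,
                        n_frames = 300, baseline_frames = 75,
                        age_group = "24mo",
                        modalities = c("steady_state", "dsc"),
                        aif_params = default_aif_params()) {
  if (n_control < 2 || n_transgenic < 2) stop("group sizes must be >= 2")
  if (noise_sigma < 0 || scatter_sd < 0) stop("noise/scatter must be >= 0")
  stopifnot(all(unlist(region_truth[c("q", "dr2star", "cbf", "mtt")]) >= 0),
            all(unlist(effect[c("q", "dr2star", "cbf", "cbv")]) >= 0))
  modalities <- match.arg(modalities, several.ok = TRUE)
  structure(list(n_control = n_control, n_transgenic = n_transgenic,
                 region_truth = region_truth, effect = effect,
                 noise_sigma = noise_sigma, scatter_sd = scatter_sd,
                 seed = seed, shape = shape, ge_upsample = ge_upsample,
                 n_frames = n_frames, baseline_frames = baseline_frames,
                 age_group = age_group, modalities = modalities,
                 meta_ge = acquisition_meta(0.0055, 0.040, "gradient_echo"),
                 meta_se = acquisition_meta(0.030, 2.0, "spin_echo"),
                 meta_dsc = acquisition_meta(0.010, 0.4, "dynamic_epi",
                                             baseline_frames = baseline_frames),
                 aif_params = aif_params,
                 baseline_signal = 1000),
            class = "cohort_spec")
}

# Apply genotype effect factors to per-region truth; MTT follows cbv/cbf.
apply_effect <- function(params, effect) {
  params$q <- params$q * effect$q
  params$dr2star <- params$dr2star * effect$dr2star
  cbv <- params$cbf * params$mtt * effect$cbv
  params$cbf <- params$cbf * effect$cbf
  params$mtt <- ifelse(params$cbf > 0, cbv / params$cbf, 0)
  params
}

# Mean-preserving lognormal scatter: E[exp(N(mu, s^2))] = 1 when
# mu = -s^2/2.
lognormal_scatter <- function(n, sd) {
  if (sd == 0) rep(1, n) else stats::rlnorm(n, meanlog = -sd^2 / 2, sdlog = sd)
}

#' Generate a synthetic cohort
#'
#' Draws per-animal regional truth (group truth times mean-preserving
#' lognormal scatter, independently per region and parameter), then
#' synthesizes the requested modalities per animal. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `spec`, `phantom`, `phantom_ge` (labels upsampled to
#'   the GE grid), and `animals`: per animal `id`, `genotype`, regional
#'   `params`, voxel `truth` maps, `steady` volumes and/or `dsc` series.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  phantom <- make_phantom(spec$shape)
  phantom_ge <- upsample_map(phantom$labels, spec$ge_upsample)
  genotypes <- c(rep("control", spec$n_control),
                 rep("transgenic", spec$n_transgenic))
  animals <- vector("list", length(genotypes))
  for (i in seq_along(genotypes)) {
    params <- spec$region_truth
    if (genotypes[i] == "transgenic") params <- apply_effect(params, spec$effect)
    for (p in c("q", "dr2star", "cbf"))
      params[[p]] <- params[[p]] * lognormal_scatter(length(params[[p]]),
                                                     spec$scatter_sd)
    truth <- build_truth_maps(phantom, params)
    animal <- list(id = sprintf("%s_%02d", substr(genotypes[i], 1, 2), i),
                   genotype = genotypes[i], params = params, truth = truth)
    if ("steady_state" %in% spec$modalities)
      animal$steady <- synth_steady_state(
        phantom, truth, spec$meta_ge, spec$meta_se,
        noise_sigma = spec$noise_sigma, seed = NULL,
        ge_upsample = spec$ge_upsample, baseline = spec$baseline_signal)
    if ("dsc" %in% spec$modalities)
      animal$dsc <- synth_dsc(
        phantom, truth, spec$meta_dsc, n_frames = spec$n_frames,
        noise_sigma = spec$noise_sigma, seed = NULL,
        aif_params = spec$aif_params, baseline = spec$baseline_signal)
    animals[[i]] <- animal
  }
  list(spec = spec, phantom = phantom, phantom_ge = phantom_ge,
       animals = animals)
}
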