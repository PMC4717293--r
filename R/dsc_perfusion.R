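#' Convert a dynamic signal series to concentration-time curves
#'
#' `C(t) = -(k / TE) * ln(S(t) / S0)` voxelwise, with `S0` the mean over the
#' pre-bolus baseline frames. With an intravascular susceptibility tracer
#' the relaxation-rate change is proportional to tracer concentration; the
#' proportionality constant `k` is unknown and fixed at 1, so concentrations
#' are in s^-1 and all derived quantities are relative. Voxels whose
#' baseline mean is nonpositive are masked out (`NA` columns); nonpositive
#' samples inside valid voxels are clamped to machine epsilon and the voxel
#' is flagged.
#'
#' @param series A [dynamic_series()].
#' @param baseline_frames Number of pre-bolus frames (defaults to metadata).
#' @param te_s Echo time in seconds (defaults to metadata).
#' @param k Proportionality constant (default 1).
#' @return A `concentration_set`: list with `time_s`, `conc` (frames x
#'   voxels matrix), `dim` (spatial dims), `valid` (voxels with positive
#'   baseline), `flagged` (voxels with clamped samples), `s0`.
#' @export
signal_to_concentration <- function(series, baseline_frames = NULL,
                                    te_s = NULL, k = 1) {
  stopifnot(inherits(series, "dynamic_series"))
  baseline_frames <- baseline_frames %||% series$meta$baseline_frames
  te_s <- te_s %||% series$meta$te_s
  if (te_s <= 0) stop("te_s must be positive")
  d <- dim(series$values)
  n_t <- d[4]
  if (baseline_frames < 1 || baseline_frames >= n_t)
    stop("baseline_frames must lie inside the series")
  sig <- t(matrix(series$values, ncol = n_t))        # frames x voxels
  s0 <- colMeans(sig[seq_len(baseline_frames), , drop = FALSE])
  valid <- is.finite(s0) & s0 > 0
  flagged <- rep(FALSE, length(s0))
  conc <- matrix(NA_real_, n_t, length(s0))
  if (any(valid)) {
    sv <- sig[, valid, drop = FALSE]
    clamped <- sv <= 0
    if (any(clamped)) {
      sv[clamped] <- .Machine$double.eps
      flagged[valid] <- colSums(clamped) > 0
    }
    conc[, valid] <- -(k / te_s) * log(sweep(sv, 2, s0[valid], "/"))
  }
  structure(list(time_s = series$time_s, conc = conc, dim = d[1:3],
                 valid = valid, flagged = flagged, s0 = s0,
                 baseline_frames = as.integer(baseline_frames)),
            class = "concentration_set")
}

#' Single concentration-time curve
#'
#' @param time_s Frame times (s).
#' @param conc Concentration values (s^-1), same length.
#' @return A `concentration_curve`.
#' @export
concentration_curve <- function(time_s, conc) {
  if (length(time_s) != length(conc)) stop("time and concentration lengths differ")
  if (any(!is.finite(conc))) stop("concentration values must be finite")
  structure(list(time_s = time_s, conc = conc), class = "concentration_curve")
}

#' Brain mask from a dynamic series
#'
#' Voxels whose baseline mean signal exceeds `threshold` times the robust
#' (99th-percentile) maximum of the baseline means.
#'
#' @param series A [dynamic_series()].
#' @param threshold Fraction of the robust maximum (default 0.2).
#' @return Logical 3D array.
#' @export
make_brain_mask <- function(series, threshold = 0.2) {
  stopifnot(inherits(series, "dynamic_series"))
  n_b <- series$meta$baseline_frames
  d <- dim(series$values)
  sig <- matrix(series$values, ncol = d[4])
  bm <- rowMeans(sig[, seq_len(n_b), drop = FALSE])
  robust_max <- stats::quantile(bm, 0.99, names = FALSE)
  mask <- bm > threshold * robust_max & bm > 0
  if (!any(mask)) stop("brain mask is empty")
  array(mask, d[1:3])
}

#' Estimate bolus arrival time with a piecewise linear-quadratic model
#'
#' For each candidate breakpoint the curve up to the time-to-peak is fitted
#' by a straight line joined continuously to a quadratic at the breakpoint;
#' the bolus arrival time (BAT) is the breakpoint minimizing the total
#' residual sum of squares (ties broken toward the earliest frame).
#' Curves with no discernible bolus (maximum below the baseline mean plus
#' two baseline standard deviations) raise a no-bolus error.
#'
#' @param curve A [concentration_curve()] (or numeric vector of
#'   concentrations with `time_s` supplied via `time_s`).
#' @param baseline_frames Number of pre-bolus frames.
#' @param time_s Frame times if `curve` is a bare vector.
#' @return A `bolus_timing` list: `bat_s`, `ttp_s`, `fit_rss`.
#' @export
estimate_bolus_arrival <- function(curve, baseline_frames, time_s = NULL) {
  if (inherits(curve, "concentration_curve")) {
    time_s <- curve$time_s; y <- curve$conc
  } else y <- curve
  res <- bat_matrix(matrix(y, ncol = 1), time_s, baseline_frames)
  if (!res$ok[1]) stop("no bolus detected: curve maximum within baseline noise")
  structure(list(bat_s = res$bat_s[1], ttp_s = res$ttp_s[1],
                 fit_rss = res$rss[1]), class = "bolus_timing")
}

# Vectorized BAT/TTP over the columns of a frames x voxels matrix.
# Voxels are grouped by time-to-peak index so each (ttp, breakpoint) pair
# costs one least-squares solve for all voxels in the group.
bat_matrix <- function(conc, time_s, baseline_frames) {
  n_t <- nrow(conc); n_v <- ncol(conc)
  bl <- conc[seq_len(baseline_frames), , drop = FALSE]
  bl_mean <- colMeans(bl)
  bl_sd <- apply(bl, 2, stats::sd)
  peak_idx <- max.col(t(conc), ties.method = "first")
  peak_val <- conc[cbind(peak_idx, seq_len(n_v))]
  ok <- is.finite(peak_val) & peak_val > bl_mean + 2 * bl_sd & peak_idx >= 5
  bat_i <- rep(NA_integer_, n_v); rss <- rep(NA_real_, n_v)
  for (m in unique(peak_idx[ok])) {
    vox <- which(ok & peak_idx == m)
    y <- conc[seq_len(m), vox, drop = FALSE]
    t_fit <- time_s[seq_len(m)]
    best_rss <- rep(Inf, length(vox)); best_b <- rep(NA_integer_, length(vox))
    for (b in 3:(m - 1)) {
      dtb <- pmax(t_fit - t_fit[b], 0)
      X <- cbind(1, t_fit, dtb, dtb^2)
      fit <- stats::lm.fit(X, y)
      r <- colSums(as.matrix(fit$residuals)^2)
      better <- r < best_rss - 1e-12          # strict: ties keep earliest b
      best_rss[better] <- r[better]; best_b[better] <- b
    }
    bat_i[vox] <- best_b; rss[vox] <- best_rss
  }
  ok <- ok & !is.na(bat_i)
  list(ok = ok, bat_i = bat_i, ttp_i = peak_idx,
       bat_s = ifelse(ok, time_s[pmax(bat_i, 1)], NA_real_),
       ttp_s = ifelse(ok, time_s[peak_idx], NA_real_), rss = rss)
}

#' Fit a gamma-variate to the first-pass window of a concentration curve
#'
#' Least-squares fit of `C(t) = A (t - t0)^alpha exp(-(t - t0)/beta)` over
#' the window from bolus arrival to `bat + 2.5 * (ttp - bat)`, initialized
#' by log-linearization with `t0` at the bolus arrival time and refined by
#' bounded Levenberg-Marquardt.
#'
#' @param curve A [concentration_curve()].
#' @param timing A `bolus_timing` from [estimate_bolus_arrival()].
#' @param window_factor Width of the fit window in multiples of `ttp - bat`
#'   beyond the arrival time (default 2.5).
#' @param max_iter Maximum optimizer iterations.
#' @return A `gamma_fit`: `A`, `t0`, `alpha`, `beta`, `window`, `rss`,
#'   `converged`.
#' @export
fit_gamma_variate <- function(curve, timing, window_factor = 2.5,
                              max_iter = 50) {
  stopifnot(inherits(curve, "concentration_curve"))
  fit_gamma_window(curve$time_s, curve$conc, timing$bat_s, timing$ttp_s,
                   window_factor = window_factor, max_iter = max_iter)
}

fit_gamma_window <- function(time_s, y, bat_s, ttp_s, window_factor = 2.5,
                             max_iter = 50) {
  w_end <- bat_s + window_factor * (ttp_s - bat_s)
  in_win <- time_s >= bat_s & time_s <= w_end
  if (sum(in_win) < 5)
    stop("fit window holds ", sum(in_win), " frames; need >= 5")
  tw <- time_s[in_win]; yw <- y[in_win]
  dt <- time_s[2] - time_s[1]
  # log-linear initialization with t0 fixed at bat
  t0_init <- bat_s
  pos <- yw > 0 & tw > t0_init
  init <- c(logA = 0, t0 = t0_init, alpha = 2, beta = max((ttp_s - bat_s) / 2, dt))
  if (sum(pos) >= 3) {
    lx <- log(tw[pos] - t0_init)
    co <- tryCatch(stats::lm.fit(cbind(1, lx, tw[pos] - t0_init),
                                 log(yw[pos]))$coefficients,
                   error = function(e) NULL)
    if (!is.null(co) && all(is.finite(co)) && co[2] > 0 && co[3] < 0)
      init <- c(logA = unname(co[1]), t0 = t0_init, alpha = unname(co[2]),
                beta = unname(-1 / co[3]))
  }
  resid_fn <- function(p)
    yw - gamma_variate(tw, exp(p[1]), p[2], p[3], p[4])
  lower <- c(-30, bat_s - 2 * dt, 0.05, 0.05)
  upper <- c(30, ttp_s - dt, 12, 60)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = init, fn = resid_fn,
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = max_iter)),
    error = function(e) NULL)
  failed <- structure(list(A = NA_real_, t0 = NA_real_, alpha = NA_real_,
                           beta = NA_real_, window = c(bat_s, w_end),
                           rss = NA_real_, r2 = NA_real_, converged = FALSE,
                           credible = FALSE),
                      class = "gamma_fit")
  if (is.null(fit)) return(failed)
  p <- fit$par
  rss <- sum(fit$fvec^2)
  tss <- sum((yw - mean(yw))^2)
  # a fit with shape/scale pinned at the box bounds is a runaway, not a bolus
  at_bounds <- p[[3]] >= upper[3] - 1e-6 || p[[4]] >= upper[4] - 1e-6 ||
    p[[3]] <= lower[3] + 1e-6
  structure(list(A = exp(p[[1]]), t0 = p[[2]], alpha = p[[3]], beta = p[[4]],
                 window = c(bat_s, w_end), rss = rss,
                 r2 = if (tss > 0) 1 - rss / tss else NA_real_,
                 converged = fit$info %in% 1:4,
                 credible = fit$info %in% 1:4 && !at_bounds),
            class = "gamma_fit")
}

#' Closed-form area under a gamma-variate fit
#'
#' The integral of `A (t - t0)^alpha exp(-(t - t0)/beta)` over all t is
#' `A * beta^(alpha + 1) * Gamma(alpha + 1)`.
#'
#' @param fit A `gamma_fit`.
#' @return Area (s^-1 * s).
#' @export
gamma_area <- function(fit) {
  if (!isTRUE(fit$converged)) return(NA_real_)
  fit$A * fit$beta^(fit$alpha + 1) * gamma(fit$alpha + 1)
}

# Fitted-curve peak value and full width at half maximum.
gamma_peak <- function(fit)
  fit$A * (fit$alpha * fit$beta)^fit$alpha * exp(-fit$alpha)

gamma_fwhm <- function(fit) {
  xm <- fit$alpha * fit$beta          # peak location in t - t0
  f <- function(x) x^fit$alpha * exp(-x / fit$beta) -
    0.5 * xm^fit$alpha * exp(-xm / fit$beta)
  left <- tryCatch(stats::uniroot(f, c(xm * 1e-9, xm))$root,
                   error = function(e) NA_real_)
  right <- tryCatch(stats::uniroot(f, c(xm, xm + 50 * fit$beta))$root,
                    error = function(e) NA_real_)
  right - left
}

#' Select an arterial input function by an artery-likelihood search
#'
#' Scores every candidate voxel with a composite likelihood
#' `z(peak) + z(1/FWHM) + z(-BAT)` (z = standard score over candidates):
#' arterial voxels show the tallest, narrowest and earliest first-pass
#' curves. The top `m` voxels' measured curves are averaged and the average
#' refitted with a gamma-variate.
#'
#' @param concset A `concentration_set` from [signal_to_concentration()].
#' @param fits Per-voxel `gamma_fit` list (as from [fit_dsc_voxels()]).
#' @param timing Per-voxel timing from [bat_matrix] results (`fit_dsc_voxels`
#'   output carries it).
#' @param candidates Logical/integer voxel selector (e.g. brain mask, or an
#'   artery ROI restriction); defaults to all fitted voxels.
#' @param m Number of top-scoring voxels averaged (default 10).
#' @param min_r2 Sanity filter: minimum fraction of the windowed curve's
#'   variance the fit must explain (fits of pure noise score low).
#' @param min_fwhm_frames Sanity filter: minimum credible fitted width in
#'   frames; a first pass narrower than the sampling resolution is a noise
#'   artifact, not an artery.
#' @param peak_quantile Pre-filter: only candidates whose fitted peak
#'   reaches this quantile of the candidate peaks enter the ranking. An
#'   artery is by definition among the brightest first-pass curves; the
#'   pre-filter keeps the z-score composite from being dominated by the
#'   bulk-tissue tail.
#' @return An `arterial_input`: `curve`, `fit`, `timing`, `voxel_ids`,
#'   `likelihood` (scores of the selected voxels).
#' @export
select_aif <- function(concset, fits, timing, candidates = NULL, m = 10,
                       min_r2 = 0.5, min_fwhm_frames = 2,
                       peak_quantile = 0.75) {
  ok <- vapply(fits, function(f) isTRUE(f$credible), logical(1))
  area <- vapply(fits, function(f) if (isTRUE(f$credible)) gamma_area(f) else NA_real_,
                 numeric(1))
  peak <- vapply(fits, function(f) if (isTRUE(f$credible)) gamma_peak(f) else NA_real_,
                 numeric(1))
  r2 <- vapply(fits, function(f) if (isTRUE(f$credible)) f$r2 else NA_real_,
               numeric(1))
  cand <- ok & is.finite(area) & area > 0 & is.finite(peak) & peak > 0 &
    is.finite(r2) & r2 >= min_r2
  if (!is.null(candidates)) {
    sel <- rep(FALSE, length(fits))
    sel[candidates] <- TRUE
    cand <- cand & sel
  }
  dt <- concset$time_s[2] - concset$time_s[1]
  # likelihood features from the measured curves (lightly smoothed so a
  # single noise dip cannot fake a narrow half-max run), robust against the
  # runaway fitted widths a fitted-parameter metric rewards
  post <- seq(concset$baseline_frames + 1L, length(concset$time_s))
  box <- rep(1 / 5, 5)
  feats <- vapply(which(cand), function(i) {
    y <- stats::filter(concset$conc[post, i], box, sides = 2)
    y <- y[!is.na(y)]
    pk_i <- which.max(y)
    pk <- y[pk_i]
    above <- y >= pk / 2
    lo <- pk_i; while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- pk_i; while (hi < length(y) && above[hi + 1]) hi <- hi + 1
    c(pk, (hi - lo + 1) * dt)
  }, numeric(2))
  peak_meas <- fwhm_meas <- rep(NA_real_, length(fits))
  peak_meas[cand] <- feats[1, ]
  fwhm_meas[cand] <- feats[2, ]
  cand <- cand & is.finite(fwhm_meas) & fwhm_meas >= min_fwhm_frames * dt &
    is.finite(peak_meas) & peak_meas > 0
  if (any(cand))
    cand <- cand & peak_meas >= stats::quantile(peak_meas[cand], peak_quantile,
                                                names = FALSE, na.rm = TRUE) &
      peak_meas >= 0.5 * max(peak_meas[cand], na.rm = TRUE)
  idx <- which(cand)
  if (length(idx) == 0) stop("no AIF candidate passes the sanity filters")
  if (m > length(idx))
    stop("m = ", m, " exceeds the ", length(idx), " available candidates")
  bat <- timing$bat_s[idx]
  z <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else rep(0, length(x))
  score <- z(peak_meas[idx]) + z(1 / fwhm_meas[idx]) + z(-bat)
  top <- idx[order(score, decreasing = TRUE)[seq_len(m)]]
  mean_curve <- rowMeans(concset$conc[, top, drop = FALSE])
  tm <- estimate_bolus_arrival(concentration_curve(concset$time_s, mean_curve),
                               concset$baseline_frames)
  fit <- fit_gamma_variate(concentration_curve(concset$time_s, mean_curve), tm)
  structure(list(curve = concentration_curve(concset$time_s, mean_curve),
                 fit = fit, timing = tm, voxel_ids = top,
                 likelihood = score[match(top, idx)]),
            class = "arterial_input")
}

#' Relative cerebral blood volume from bolus integrals
#'
#' `rCBV = area(tissue gamma fit) / area(AIF gamma fit)`: the tissue
#' first-pass integral normalized by the arterial input integral.
#'
#' @param tissue_fits List of per-voxel `gamma_fit`s (or a single fit).
#' @param aif An `arterial_input`.
#' @return Numeric vector of rCBV values (NA where the fit failed).
#' @export
compute_rcbv_dsc <- function(tissue_fits, aif) {
  aif_area <- gamma_area(aif$fit)
  if (!is.finite(aif_area) || aif_area <= 0)
    stop("AIF area must be positive")
  if (inherits(tissue_fits, "gamma_fit")) tissue_fits <- list(tissue_fits)
  vapply(tissue_fits, function(f) {
    if (!isTRUE(f$credible %||% f$converged)) return(NA_real_)
    if (is.finite(f$r2 %||% NA_real_) && f$r2 < 0.2) return(NA_real_)
    gamma_area(f) / aif_area
  }, numeric(1))
}

#' Relative cerebral blood flow by truncated-SVD deconvolution
#'
#' Deconvolves tissue concentration curves with the arterial input:
#' `C_t = CBF * (C_a (*) R)` is discretized as a lower-triangular Toeplitz
#' system scaled by the frame spacing, inverted by singular value
#' decomposition with singular values below `r_trunc` times the largest set
#' to zero. rCBF is the maximum of the recovered scaled residue function,
#' floored at zero (negative residue samples are permitted internally).
#'
#' @param conc Frames x voxels concentration matrix (or a
#'   `concentration_set`, or a single `concentration_curve`).
#' @param aif An `arterial_input` (its gamma fit, evaluated on the time
#'   grid, forms the convolution matrix; set `use_fitted_aif = FALSE` to use
#'   the averaged measured curve instead).
#' @param r_trunc Truncation threshold as a fraction of the largest singular
#'   value (default 0.2).
#' @param time_s Time grid of `conc` when a bare matrix is given; must be
#'   identical to the AIF grid.
#' @param use_fitted_aif Use the fitted (noise-free) AIF curve.
#' @return List with `rcbf` (per voxel) and `residue` (frames x voxels).
#' @export
compute_rcbf <- function(conc, aif, r_trunc = 0.2, time_s = NULL,
                         use_fitted_aif = TRUE) {
  if (inherits(conc, "concentration_set")) {
    time_s <- conc$time_s; conc <- conc$conc
  } else if (inherits(conc, "concentration_curve")) {
    time_s <- conc$time_s; conc <- matrix(conc$conc, ncol = 1)
  }
  if (is.null(time_s)) stop("time_s required with a bare concentration matrix")
  if (length(time_s) != length(aif$curve$time_s) ||
      max(abs(time_s - aif$curve$time_s)) > 1e-9)
    stop("tissue and AIF time grids differ")
  ca <- if (use_fitted_aif && isTRUE(aif$fit$converged))
    gamma_variate(time_s, aif$fit$A, aif$fit$t0, aif$fit$alpha, aif$fit$beta)
  else aif$curve$conc
  dt <- time_s[2] - time_s[1]
  n <- length(time_s)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) A[j:n, j] <- ca[seq_len(n - j + 1)]
  A <- A * dt
  sv <- svd(A)
  keep <- sv$d >= r_trunc * max(sv$d)
  d_inv <- ifelse(keep, 1 / sv$d, 0)
  conc0 <- conc
  conc0[is.na(conc0)] <- 0
  residue <- sv$v %*% (d_inv * (t(sv$u) %*% conc0))
  rcbf <- pmax(apply(residue, 2, max), 0)
  rcbf[colSums(is.na(conc)) > 0] <- NA_real_
  list(rcbf = rcbf, residue = residue)
}

#' Fit bolus timing and gamma-variates for every voxel of a series
#'
#' Runs [bat_matrix] and per-voxel gamma-variate fits over the voxels of a
#' concentration set within a mask. Voxels without a detectable bolus or
#' with a non-converged fit are flagged and excluded from maps.
#'
#' @param concset A `concentration_set`.
#' @param mask Logical 3D array (e.g. from [make_brain_mask()]).
#' @param window_factor,max_iter Passed to the gamma-variate fitter.
#' @param presmooth_frames Width (frames) of a centered moving average
#'   applied to each voxel curve before timing estimation and fitting.
#'   Per-voxel area estimates from nonlinear fits of noisy curves carry a
#'   skewed, amplitude-dependent bias; mild temporal smoothing (default 3
#'   frames) suppresses it while preserving curve integrals. Set to 1 to
#'   disable.
#' @return List: `fits` (per-voxel list, NULL outside mask), `timing`
#'   (vectors from the breakpoint search), `mask`.
#' @export
fit_dsc_voxels <- function(concset, mask, window_factor = 2.5, max_iter = 50,
                           presmooth_frames = 3) {
  stopifnot(inherits(concset, "concentration_set"))
  vox <- which(as.logical(mask) & concset$valid)
  cmat <- concset$conc[, vox, drop = FALSE]
  if (presmooth_frames > 1) {
    sm <- stats::filter(cmat, rep(1 / presmooth_frames, presmooth_frames),
                        sides = 2)
    na_rows <- !stats::complete.cases(sm)
    sm[na_rows, ] <- cmat[na_rows, ]        # keep raw values at the edges
    cmat <- as.matrix(sm)
  }
  timing <- bat_matrix(cmat, concset$time_s, concset$baseline_frames)
  fits <- vector("list", length(concset$valid))
  for (j in seq_along(vox)) {
    if (!timing$ok[j]) next
    f <- tryCatch(
      fit_gamma_window(concset$time_s, cmat[, j],
                       timing$bat_s[j], timing$ttp_s[j],
                       window_factor = window_factor, max_iter = max_iter),
      error = function(e) NULL)
    fits[[vox[j]]] <- f
  }
  full <- list(ok = rep(FALSE, length(concset$valid)),
               bat_s = rep(NA_real_, length(concset$valid)),
               ttp_s = rep(NA_real_, length(concset$valid)))
  full$ok[vox] <- timing$ok
  full$bat_s[vox] <- timing$bat_s
  full$ttp_s[vox] <- timing$ttp_s
  list(fits = fits, timing = full, mask = mask)
}

#' Run the full DSC perfusion pathway on one series
#'
#' Concentration conversion, brain masking, voxelwise bolus timing and
#' gamma-variate fitting, arterial-input selection, rCBV(DSC) from the
#' integral ratio and rCBF from truncated-SVD deconvolution of the raw
#' concentration curves.
#'
#' @param series A [dynamic_series()].
#' @param r_trunc SVD truncation fraction (default 0.2).
#' @param aif_m Number of voxels averaged into the AIF (default 10).
#' @param aif_candidates Optional voxel selector restricting the AIF search
#'   (e.g. an artery label mask); default: whole brain mask.
#' @param mask_threshold Brain-mask threshold (see [make_brain_mask()]).
#' @param window_factor Gamma-fit window width factor.
#' @return A `perfusion_maps` list: `rcbv`, `rcbf`, `bat` (3D maps, NaN
#'   outside mask/failed voxels), `mask`, `aif`.
#' @export
process_dsc <- function(series, r_trunc = 0.2, aif_m = 10,
                        aif_candidates = NULL, mask_threshold = 0.2,
                        window_factor = 2.5) {
  concset <- signal_to_concentration(series)
  mask <- make_brain_mask(series, threshold = mask_threshold)
  vx <- fit_dsc_voxels(concset, mask, window_factor = window_factor)
  aif <- select_aif(concset, vx$fits, vx$timing,
                    candidates = aif_candidates, m = aif_m)
  d <- concset$dim
  rcbv <- array(NaN, d); rcbf <- array(NaN, d); bat <- array(NaN, d)
  fitted_vox <- which(!vapply(vx$fits, is.null, logical(1)))
  if (length(fitted_vox) > 0)
    rcbv[fitted_vox] <- pmax(
      compute_rcbv_dsc(vx$fits[fitted_vox], aif), 0)
  bolus_vox <- which(vx$timing$ok)
  bat[bolus_vox] <- vx$timing$bat_s[bolus_vox]
  dec <- compute_rcbf(concset$conc[, bolus_vox, drop = FALSE], aif,
                      r_trunc = r_trunc, time_s = concset$time_s)
  rcbf[bolus_vox] <- dec$rcbf
  structure(list(rcbv = rcbv, rcbf = rcbf, bat = bat, mask = mask, aif = aif),
            class = "perfusion_maps")
}
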