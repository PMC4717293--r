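#' Steady-state change in transverse relaxation rate (spin echo)
#'
#' `dR2 = (1/TE) * ln(S_pre / S_post)` voxelwise, from pre/post contrast
#' spin-echo volumes. Negative values (post signal above pre, i.e. noise)
#' are set to zero; voxels with nonpositive signal in either input are
#' masked to `NaN` and counted in a warning.
#'
#' @param pre,post [volume_image()]s (or bare 3D arrays) on the same grid.
#' @param te_s Echo time in seconds.
#' @return A 3D array (s^-1) with attribute `n_masked`.
#' @export
compute_delta_r2 <- function(pre, post, te_s) {
  delta_rate(pre, post, te_s)
}

#' Steady-state change in transverse relaxation rate (gradient echo)
#'
#' `dR2* = (1/TE) * ln(S*_pre / S*_post)`, the gradient-echo analogue of
#' [compute_delta_r2()]; with an intravascular tracer at steady state dR2*
#' is proportional to blood volume (all vessel calibres contribute).
#'
#' @inheritParams compute_delta_r2
#' @return A 3D array (s^-1) with attribute `n_masked`.
#' @export
compute_delta_r2star <- function(pre, post, te_s) {
  delta_rate(pre, post, te_s)
}

delta_rate <- function(pre, post, te_s) {
  a <- if (inherits(pre, "volume_image")) pre$values else pre
  b <- if (inherits(post, "volume_image")) post$values else post
  if (!identical(dim(a), dim(b))) stop("pre and post must share one grid")
  if (!is.numeric(te_s) || te_s <= 0) stop("te_s must be positive")
  ok <- is.finite(a) & is.finite(b) & a > 0 & b > 0
  out <- array(NaN, dim(a))
  out[ok] <- pmax(log(a[ok] / b[ok]) / te_s, 0)  # negatives clipped to 0
  n_masked <- sum(!ok)
  if (n_masked > 0)
    warning(n_masked, " voxel(s) with nonpositive signal masked to NaN")
  attr(out, "n_masked") <- n_masked
  out
}

#' Resample a volume onto the grid of another via cubic splines
#'
#' Separable natural cubic-spline interpolation along each axis, assuming
#' corner-aligned grids (voxel centre i at `(i - 0.5) * spacing`). Target
#' points outside the source extent become `NaN`. Constants and polynomials
#' up to degree 3 along an axis are reproduced exactly; a source already on
#' the target grid passes through unchanged.
#'
#' @param src [volume_image()] to resample.
#' @param target [volume_image()] defining the output grid.
#' @return A [volume_image()] on the target grid (target's spacing, source's
#'   metadata).
#' @export
resample_to_grid <- function(src, target) {
  stopifnot(inherits(src, "volume_image"), inherits(target, "volume_image"))
  vals <- src$values
  for (ax in 1:3) {
    n_src <- dim(vals)[ax]
    x_src <- axis_coords(n_src, src$spacing_mm[ax])
    x_tgt <- axis_coords(dim(target$values)[ax], target$spacing_mm[ax])
    if (min(x_tgt) > max(x_src) + src$spacing_mm[ax] ||
        max(x_tgt) < min(x_src) - src$spacing_mm[ax])
      stop("source and target extents are disjoint along axis ", ax)
    inside <- x_tgt >= min(x_src) & x_tgt <= max(x_src)
    vals <- interp_axis(vals, ax, x_src, x_tgt, inside)
  }
  volume_image(vals, target$spacing_mm, src$meta)
}

# Interpolate a 3D array along one axis; lines with any NA propagate NA at
# affected target points via spline on the finite subset where possible.
interp_axis <- function(vals, ax, x_src, x_tgt, inside) {
  perm <- c(ax, setdiff(1:3, ax))
  v <- aperm(vals, perm)
  d <- dim(v)
  m <- matrix(v, nrow = d[1])
  out <- matrix(NaN, nrow = length(x_tgt), ncol = ncol(m))
  if (length(x_src) == 1L) {
    out[inside, ] <- rep(m[1, ], each = sum(inside))
  } else {
    for (j in seq_len(ncol(m))) {
      y <- m[, j]
      if (anyNA(y)) {
        ok <- is.finite(y)
        if (sum(ok) < 2) next
        f <- stats::splinefun(x_src[ok], y[ok], method = "natural")
        keep <- inside & x_tgt >= min(x_src[ok]) & x_tgt <= max(x_src[ok])
        out[keep, j] <- f(x_tgt[keep])
      } else {
        f <- stats::splinefun(x_src, y, method = "natural")
        out[inside, j] <- f(x_tgt[inside])
      }
    }
  }
  v2 <- array(out, c(length(x_tgt), d[2], d[3]))
  aperm(v2, order(perm))
}

#' Relaxation shift index Q
#'
#' `Q = dR2 / (dR2*)^(2/3)`, voxelwise. Q is approximately independent of
#' tracer dose and blood volume and scales with microvessel density. Inputs
#' must already be clipped to nonnegative values ([compute_delta_r2()] does
#' this); voxels with `dR2* < eps` get Q = 0, and voxels that are `NaN` in
#' either input stay `NaN`.
#'
#' @param dr2,dr2star Nonnegative 3D arrays on one grid (s^-1).
#' @param eps Threshold below which dR2* is treated as zero (s^-1).
#' @return Q map (s^(-1/3)).
#' @export
compute_q <- function(dr2, dr2star, eps = 1e-6) {
  if (inherits(dr2, "volume_image")) dr2 <- dr2$values
  if (inherits(dr2star, "volume_image")) dr2star <- dr2star$values
  if (!identical(dim(dr2), dim(dr2star))) stop("maps must share one grid")
  if (any(dr2 < 0, na.rm = TRUE) || any(dr2star < 0, na.rm = TRUE))
    stop("inputs must be nonnegative: clip negative relaxation rates first")
  q <- array(NaN, dim(dr2))
  both <- is.finite(dr2) & is.finite(dr2star)
  zero <- both & dr2star < eps
  pos <- both & !zero
  q[pos] <- dr2[pos] / dr2star[pos]^(2 / 3)
  q[zero] <- 0
  q
}

#' Microvessel density estimate from Q
#'
#' `N = Q^3 * 329` in the source convention's printed unit (s/mm^2);
#' interpreting N as vessels per mm^2 of tissue cross-section is
#' conventional.
#'
#' @param q Q map (s^(-1/3)), nonnegative.
#' @return Density map.
#' @export
compute_vessel_density <- function(q) {
  if (inherits(q, "volume_image")) q <- q$values
  if (any(q < 0, na.rm = TRUE)) stop("q must be nonnegative")
  q^3 * 329
}

#' Steady-state relative blood volume from dR2*
#'
#' At steady tracer concentration the total intravascular tracer in a voxel
#' is proportional to its blood volume, so the clipped dR2* map itself is a
#' relative CBV estimate in arbitrary units. Kept as a separately named
#' output for reporting.
#'
#' @param dr2star Clipped dR2* map (s^-1).
#' @return The same values, as an rCBV(dR2*) map.
#' @export
compute_rcbv_ss <- function(dr2star) {
  if (inherits(dr2star, "volume_image")) dr2star <- dr2star$values
  dr2star
}

#' Run the full steady-state mapping pathway
#'
#' dR2 from the spin-echo pair, dR2* from the gradient-echo pair, cubic-
#' spline resampling of dR2* onto the spin-echo grid, then Q, microvessel
#' density and rCBV(dR2*).
#'
#' @param ge_pre,ge_post Gradient-echo pre/post [volume_image()]s.
#' @param se_pre,se_post Spin-echo pre/post [volume_image()]s.
#' @param te_ge_s,te_se_s Echo times (s); default to each volume's metadata.
#' @param eps Zero-threshold for dR2* in [compute_q()].
#' @return A list of maps on the spin-echo grid: `dr2`, `dr2star`, `q`,
#'   `n_density`, `rcbv_ss` (class `relaxation_maps`).
#' @export
process_qmap <- function(ge_pre, ge_post, se_pre, se_post,
                         te_ge_s = NULL, te_se_s = NULL, eps = 1e-6) {
  te_ge_s <- te_ge_s %||% ge_pre$meta$te_s
  te_se_s <- te_se_s %||% se_pre$meta$te_s
  dr2 <- compute_delta_r2(se_pre, se_post, te_se_s)
  dr2star_ge <- compute_delta_r2star(ge_pre, ge_post, te_ge_s)
  dr2star <- if (identical(dim(dr2star_ge), dim(dr2)) &&
                 isTRUE(all.equal(ge_pre$spacing_mm, se_pre$spacing_mm)))
    dr2star_ge
  else {
    res <- resample_to_grid(volume_image(dr2star_ge, ge_pre$spacing_mm),
                            volume_image(dr2, se_pre$spacing_mm))$values
    array(pmax(res, 0), dim(res))  # spline undershoot re-clipped
  }
  q <- compute_q(dr2, dr2star, eps = eps)
  structure(list(dr2 = dr2, dr2star = dr2star, q = q,
                 n_density = compute_vessel_density(pmax(q, 0)),
                 rcbv_ss = compute_rcbv_ss(dr2star),
                 spacing_mm = se_pre$spacing_mm),
            class = "relaxation_maps")
}
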