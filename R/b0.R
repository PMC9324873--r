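# Pose-dependent B0 model: the linear-coefficient (LC) frequency field, the
# echo-time phase operator, and the multi-pose fitting pipeline (phase
# difference -> unwrap -> voxelized least squares).

#' B0 field map
#'
#' Voxelwise frequency offset in Hz (head frame) with an optional validity
#' mask.
#' @param field real 3D array, Hz
#' @param mask logical array of valid voxels (default: all valid)
#' @export
field_map <- function(field, mask = NULL) {
  stopifnot(is.array(field), length(dim(field)) == 3L)
  if (is.null(mask)) mask <- array(TRUE, dim(field))
  stopifnot(identical(dim(mask), dim(field)))
  if (any(!is.finite(field[mask])))
    stop("field map must be finite inside its mask", call. = FALSE)
  structure(list(field = field, mask = mask), class = "field_map")
}

#' First-order pose-dependent frequency field
#'
#' The linear model `omega(r) = dpitch(r) * theta_pitch + droll(r) * theta_roll`
#' (Hz). There is no zeroth-order term: the pose-independent field is absorbed
#' into the complex image. Yaw and translations do not contribute.
#'
#' @param lc [lc_maps()]
#' @param theta_pitch,theta_roll rotation angles in degrees
#' @return a [field_map()]
#' @export
taylor_frequency_field <- function(lc, theta_pitch, theta_roll) {
  if (!is.finite(theta_pitch) || !is.finite(theta_roll))
    stop("angles must be finite", call. = FALSE)
  field_map(lc$dpitch * theta_pitch + lc$droll * theta_roll)
}

#' Echo-time phase factor of a B0 field
#'
#' `exp(-i 2 pi omega(r) TE)`: the phase a frequency offset `omega` accrues on
#' the transverse magnetization at echo time `TE`. Unit modulus at every voxel.
#'
#' @param field a [field_map()] or real 3D array (Hz)
#' @param TE echo time in seconds, > 0
#' @return complex 3D array
#' @export
phase_operator <- function(field, TE) {
  if (!is.numeric(TE) || length(TE) != 1L || !is.finite(TE) || TE <= 0)
    stop("TE must be a positive scalar (seconds)", call. = FALSE)
  f <- if (inherits(field, "field_map")) field$field else field
  exp(-2i * pi * f * TE)
}

#' Extract a B0 field map from two co-registered complex volumes
#'
#' Computes the unwrapped phase difference between `moved` and `ref` and
#' converts it to frequency. The sign is pinned to the package's phase
#' convention: if `moved = ref * exp(-i 2 pi omega TE)` (the echo-time phase of
#' [phase_operator()]), the extracted field is `+omega`.
#'
#' Zero-magnitude voxels inside the mask carry no phase and are flagged
#' invalid in the returned mask.
#'
#' @param ref,moved co-registered complex volumes ([mr_volume()] or arrays)
#' @param TE echo time in seconds
#' @param mask logical array; default keeps voxels whose reference magnitude
#'   exceeds 10% of its robust (99th percentile) maximum
#' @return a [field_map()] in Hz
#' @export
extract_field_map <- function(ref, moved, TE, mask = NULL) {
  r <- as_vol(ref)$data
  m <- as_vol(moved)$data
  if (!identical(dim(r), dim(m)))
    stop("reference and moved volumes must share a grid", call. = FALSE)
  if (!is.numeric(TE) || TE <= 0) stop("TE must be positive (seconds)", call. = FALSE)
  mag <- Mod(r)
  if (is.null(mask)) {
    mask <- mag > 0.1 * stats::quantile(mag, 0.99, names = FALSE)
  }
  stopifnot(identical(dim(mask), dim(r)))
  valid <- mask & (mag > 0) & (Mod(m) > 0)
  ph <- Arg(r * Conj(m))                       # = +2*pi*omega*TE under Eq-phase data
  phu <- unwrap_phase_3d(ph, mask = valid, quality = mag * Mod(m))
  w <- phu / (2 * pi * TE)
  w[!valid] <- 0
  field_map(w, valid)
}

#' Voxelized least-squares fit of LC maps from multi-pose field maps
#'
#' Ordinary least squares of the linear pose model per voxel, over a set of
#' field maps observed at known (pitch, roll) angles. Returns the fitted
#' [lc_maps()] with the per-voxel mean absolute residual over poses attached as
#' attribute `mae` and the fitted-voxel mask as attribute `mask`.
#'
#' @param fields list of [field_map()]s (or bare 3D arrays, Hz) on one grid
#' @param angles numeric matrix `n x 2` of (theta_pitch, theta_roll) in degrees
#' @param spacing voxel spacing recorded on the result
#' @return an [lc_maps()] object
#' @export
fit_lc_maps <- function(fields, angles, spacing = c(1, 1, 1)) {
  angles <- as.matrix(angles)
  if (length(fields) < 2L || nrow(angles) != length(fields) || ncol(angles) != 2L)
    stop("need >= 2 field maps and an n x 2 angle matrix", call. = FALSE)
  tp <- angles[, 1]; tr <- angles[, 2]
  spp <- sum(tp^2); spr <- sum(tp * tr); srr <- sum(tr^2)
  det <- spp * srr - spr^2
  if (det <= 1e-12 * max(spp * srr, 1e-300)) {
    dir <- if (spp <= 1e-12) "pitch"
           else if (srr <= 1e-12) "roll"
           else "pitch/roll (collinear angles)"
    stop(sprintf("singular angle design: no information in the %s direction", dir),
         call. = FALSE)
  }
  f1 <- fields[[1]]
  d <- dim(if (inherits(f1, "field_map")) f1$field else f1)
  bp <- array(0, d); br <- array(0, d)
  mask <- array(TRUE, d)
  for (n in seq_along(fields)) {
    fn <- fields[[n]]
    if (inherits(fn, "field_map")) { mask <- mask & fn$mask; fn <- fn$field }
    stopifnot(identical(dim(fn), d))
    bp <- bp + tp[n] * fn
    br <- br + tr[n] * fn
  }
  dpitch <- (srr * bp - spr * br) / det
  droll <- (spp * br - spr * bp) / det
  dpitch[!mask] <- 0
  droll[!mask] <- 0
  mae <- array(0, d)
  for (n in seq_along(fields)) {
    fn <- fields[[n]]
    if (inherits(fn, "field_map")) fn <- fn$field
    mae <- mae + abs(fn - tp[n] * dpitch - tr[n] * droll)
  }
  mae <- mae / length(fields)
  mae[!mask] <- NA_real_
  out <- lc_maps(dpitch, droll, spacing)
  attr(out, "mae") <- mae
  attr(out, "mask") <- mask
  out
}
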