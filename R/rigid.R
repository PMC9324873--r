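# Rigid motion operator T_z implemented with FFT phase ramps (translations)
# and a three-pass k-space shear decomposition per rotation.  Every pass
# multiplies by a unit-modulus phase in a mixed domain, so the composite
# operator is numerically unitary: its adjoint equals its inverse and is
# obtained by replaying the passes in reverse with negated parameters.
# Out-of-FOV content wraps cyclically (a property of the FFT shears); the
# synthetic phantoms keep a zero margin so tissue never reaches the boundary.

# One shear pass: resamples x(a - s*u_b) along axis `a`, with u_b the centered
# coordinate (mm) along axis `b` and `s` the dimensionless shear coefficient.
# The array is permuted to (a, b, c) order once so the (na x nb) phase matrix
# can be recycled along the spectator axis without materializing a 3D phase.
#' @keywords internal
shear_pass <- function(x, a, b, s, spacing) {
  if (s == 0) return(x)
  d <- dim(x)
  na <- d[a]; nb <- d[b]
  # per-line shift in voxels of axis a
  shift_vox <- s * centered_coord(nb) * spacing[b] / spacing[a]
  ph_ab <- exp(outer(freq_index(na), shift_vox,
                     function(k, dl) -2i * pi * k * dl / na))
  cax <- setdiff(1:3, c(a, b))
  perm <- c(a, b, cax)
  xp <- if (a == 1L && b == 2L) x else aperm(x, perm)
  dim(xp) <- c(na, nb * d[cax])
  xp <- mvfft(xp)
  xp <- xp * as.vector(ph_ab)            # recycles over the spectator axis
  xp <- mvfft(xp, inverse = TRUE) / na
  dim(xp) <- c(na, nb, d[cax])
  if (a == 1L && b == 2L) xp else aperm(xp, order(perm))
}

# Rotation by `ang_deg` (right-handed about the axis completing plane (a,b),
# +a rotating toward +b) as three shear passes about the volume center.
#' @keywords internal
rotate_pass <- function(x, a, b, ang_deg, spacing) {
  if (ang_deg == 0) return(x)
  phi <- ang_deg * pi / 180
  alpha <- -tan(phi / 2)
  beta <- sin(phi)
  x <- shear_pass(x, a, b, alpha, spacing)
  x <- shear_pass(x, b, a, beta, spacing)
  shear_pass(x, a, b, alpha, spacing)
}

# Cyclic subvoxel translation by t (mm) along all axes: one 3D FFT pair with
# a separable phase ramp applied axis by axis through recycling.
#' @keywords internal
translate_pass <- function(x, t_mm, spacing) {
  if (all(t_mm == 0)) return(x)
  d <- dim(x)
  X <- fft(x)
  for (ax in 1:3) {
    if (t_mm[ax] == 0) next
    n <- d[ax]
    ph1 <- exp(-2i * pi * freq_index(n) * (t_mm[ax] / spacing[ax]) / n)
    X <- X * rep(ph1, each = prod(d[seq_len(ax - 1L)]))   # recycles beyond ax
  }
  fft(X, inverse = TRUE) / prod(d)
}

#' Apply a rigid transform to a complex volume
#'
#' Resamples the volume under the 3D rigid transform parameterized by a
#' [motion_state()]: Euler rotations applied pitch (about LR), then roll
#' (about AP), then yaw (about FH), about the volume center
#' (voxel `floor(dim/2)+1`), followed by the translation. A point at head-frame
#' position `r` (mm, centered) moves to `R_yaw R_roll R_pitch r + t`.
#'
#' The implementation composes FFT phase ramps and three-pass k-space shears,
#' so the operator is unitary to floating point: `direction = "inverse"` is both
#' the exact inverse and the adjoint.
#'
#' @param vol an [mr_volume()] or a complex 3D array
#' @param z a [motion_state()] or numeric vector
#'   `(t_lr, t_ap, t_fh, r_pitch, r_roll, r_yaw)` in mm / degrees
#' @param direction `"forward"` applies the transform, `"inverse"` undoes it
#' @param spacing voxel spacing in mm when `vol` is a bare array
#' @return same type as `vol`
#' @examples
#' x <- array(0 + 0i, c(16, 16, 16)); x[9, 12, 9] <- 1
#' y <- rigid_transform(x, motion_state(r_yaw = 90))
#' which(abs(y) == max(abs(y)), arr.ind = TRUE)  # voxel rotated about center
#' @export
rigid_transform <- function(vol, z, direction = c("forward", "inverse"),
                            spacing = NULL) {
  direction <- match.arg(direction)
  z <- as.numeric(z)
  if (length(z) != 6L || any(!is.finite(z)))
    stop("motion state must be 6 finite numbers", call. = FALSE)
  v <- as_vol(vol, spacing)
  x <- v$data; sp <- v$spacing
  # rotation planes: pitch about LR = plane (AP, FH); roll about AP = (FH, LR);
  # yaw about FH = (LR, AP) -- right-handed, cyclic axis order
  if (direction == "forward") {
    x <- rotate_pass(x, 2L, 3L, z[4], sp)   # pitch
    x <- rotate_pass(x, 3L, 1L, z[5], sp)   # roll
    x <- rotate_pass(x, 1L, 2L, z[6], sp)   # yaw
    x <- translate_pass(x, z[1:3], sp)
  } else {
    x <- translate_pass(x, -z[1:3], sp)
    x <- rotate_pass(x, 1L, 2L, -z[6], sp)
    x <- rotate_pass(x, 3L, 1L, -z[5], sp)
    x <- rotate_pass(x, 2L, 3L, -z[4], sp)
  }
  if (inherits(vol, "mrvol")) mr_volume(x, v$spacing, vol$frame) else x
}

#' Rotation matrix of a motion state
#'
#' The 3x3 matrix `R = R_yaw R_roll R_pitch` mapping centered head-frame
#' coordinates (mm) under the same convention as [rigid_transform()].
#' @param z motion state (only the rotation entries are used)
#' @export
rotation_matrix <- function(z) {
  z <- as.numeric(z)
  ang <- z[4:6] * pi / 180
  cp <- cos(ang[1]); sp <- sin(ang[1])
  cr <- cos(ang[2]); sr <- sin(ang[2])
  cy <- cos(ang[3]); sy <- sin(ang[3])
  # pitch: +AP -> +FH ; roll: +FH -> +LR ; yaw: +LR -> +AP
  Rp <- matrix(c(1, 0, 0,  0, cp, sp,  0, -sp, cp), 3, 3)
  Rr <- matrix(c(cr, 0, -sr,  0, 1, 0,  sr, 0, cr), 3, 3)
  Ry <- matrix(c(cy, sy, 0,  -sy, cy, 0,  0, 0, 1), 3, 3)
  Ry %*% Rr %*% Rp
}

# ---- pose algebra ----------------------------------------------------------

#' Compose and invert rigid poses
#'
#' `compose_pose(za, zb)` returns the pose whose transform equals applying
#' `zb` first and `za` second (`T_za T_zb`); `invert_pose(z)` returns the pose
#' of the inverse transform. Euler angles follow the package's
#' pitch-roll-yaw convention.
#'
#' @param za,zb,z motion states (6-vectors: mm, degrees)
#' @return a [motion_state()]-style numeric vector
#' @export
compose_pose <- function(za, zb) {
  za <- as.numeric(za); zb <- as.numeric(zb)
  R <- rotation_matrix(za) %*% rotation_matrix(zb)
  t <- za[1:3] + as.vector(rotation_matrix(za) %*% zb[1:3])
  c(t, euler_from_matrix(R))
}

#' @rdname compose_pose
#' @export
invert_pose <- function(z) {
  z <- as.numeric(z)
  R <- t(rotation_matrix(z))
  c(as.vector(-R %*% z[1:3]), euler_from_matrix(R))
}

# Euler angles (pitch, roll, yaw in degrees) of a rotation matrix under the
# package's R = R_yaw R_roll R_pitch convention.
#' @keywords internal
euler_from_matrix <- function(R) {
  roll <- asin(pmin(1, pmax(-1, -R[3, 1])))
  pitch <- atan2(R[3, 2], R[3, 3])
  yaw <- atan2(R[2, 1], R[1, 1])
  c(pitch, roll, yaw) * 180 / pi
}
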