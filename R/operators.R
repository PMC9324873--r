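# The encoding chain  y_n = A_n F S T_zn P_thetan(d) x  and its adjoint.
#
# P applies the pose-dependent B0 phase in the head frame *before* the rigid
# transform (the phase moves with the head); T is the shear-FFT rigid
# transform; S multiplies by each coil sensitivity; F is the centered
# orthonormal 3D FFT; A_n samples full readout (kx) columns at the shot's
# (ky, kz) phase-encode points.
#
# The solvers evaluate the chain many times, so the shift bookkeeping of the
# centered FFT is precomputed once in an "encoding context": coils are stored
# pre-ifftshifted, and sampling happens directly on uncentered FFT output
# through index maps, which is algebraically identical to fftshifting the
# whole spectrum and then sampling.

#' Multi-coil k-space data container
#'
#' Per-shot, per-coil complex samples together with the segmentation and
#' acquisition metadata. Shot `n` holds a complex array
#' `c(nx, m_n, n_coils)` where `m_n` is the number of phase-encode points of
#' the shot (full readout implied, centered kx indexing).
#'
#' @param y list of per-shot complex arrays
#' @param seg the [generate_disorder()] segmentation the data were sampled with
#' @param TE echo time in seconds
#' @param shape full image grid shape
#' @param spacing voxel spacing in mm
#' @export
kspace_data <- function(y, seg, TE, shape, spacing = c(1, 1, 1)) {
  stopifnot(is.list(y), inherits(seg, "shot_seg"))
  if (length(y) != seg$n_shots)
    stop("shot count mismatch between data and segmentation", call. = FALSE)
  for (n in seq_along(y)) {
    dn <- dim(y[[n]])
    if (length(dn) != 3L || dn[1] != shape[1] || dn[2] != nrow(seg$shots[[n]]))
      stop(sprintf("shot %d: samples inconsistent with segmentation", n), call. = FALSE)
  }
  if (!is.numeric(TE) || TE <= 0) stop("TE must be positive (seconds)", call. = FALSE)
  structure(list(y = y, seg = seg, TE = TE, shape = as.integer(shape),
                 spacing = as.numeric(spacing)), class = "kspace")
}

#' @export
print.kspace <- function(x, ...) {
  nc <- dim(x$y[[1]])[3]
  cat(sprintf("<kspace> %d shots, %d coils, grid %s, TE %.1f ms\n",
              length(x$y), nc, paste(x$shape, collapse = " x "), x$TE * 1000))
  invisible(x)
}

# ---- encoding context ------------------------------------------------------

# Precomputes everything shot-independent: ifftshifted coils (forward),
# conjugate ifftshifted coils (adjoint), the centered->uncentered index maps
# for readout rows and phase-encode columns, and per-shot mask columns.
#' @keywords internal
encode_ctx <- function(S, seg, TE, spacing) {
  d <- dim(S$data)[1:3]
  nc <- dim(S$data)[4]
  sqV <- sqrt(prod(d))
  Ssh <- array(0i, c(d, nc))
  for (c in seq_len(nc)) {
    sc <- S$data[, , , c, drop = FALSE]
    dim(sc) <- d
    Ssh[, , , c] <- ifftshift3(sc)
  }
  f1 <- fftshift_index(d[1]); f2 <- fftshift_index(d[2]); f3 <- fftshift_index(d[3])
  # centered (ky,kz) -> flat column into the uncentered (ny*nz) spectrum
  cols <- lapply(seg$shots, function(mk) {
    if (nrow(mk) == 0L) integer(0) else (f3[mk[, 2]] - 1L) * d[2] + f2[mk[, 1]]
  })
  list(d = d, nc = nc, sqV = sqV, Ssh = Ssh, Scj = Conj(Ssh),
       rows = f1, cols = cols, seg = seg, TE = TE, spacing = spacing)
}

# Head-frame B0 phase factor for one shot (NULL lc -> NULL, meaning "skip").
#' @keywords internal
shot_phase <- function(lc, z, TE) {
  if (is.null(lc)) return(NULL)
  omega <- lc$dpitch * z[4] + lc$droll * z[5]   # Hz = Hz/deg * deg
  exp(-2i * pi * omega * TE)
}

# Forward chain for one shot: returns complex array (nx, m_n, n_coils) in
# centered indexing.
#' @keywords internal
shot_forward_n <- function(ctx, x, z, lc, n) {
  d <- ctx$d
  cols <- ctx$cols[[n]]
  m <- length(cols)
  if (m == 0L) return(array(0i, c(d[1], 0L, ctx$nc)))
  ph <- shot_phase(lc, z, ctx$TE)
  w <- if (is.null(ph)) x else x * ph
  if (any(z != 0)) w <- rigid_transform(w, z, "forward", spacing = ctx$spacing)
  wsh <- ifftshift3(w)
  yn <- array(0i, c(d[1], m, ctx$nc))
  for (c in seq_len(ctx$nc)) {
    sc <- ctx$Ssh[, , , c, drop = FALSE]
    dim(sc) <- d
    X <- fft(sc * wsh) / ctx$sqV
    dim(X) <- c(d[1], d[2] * d[3])
    yn[, , c] <- X[ctx$rows, cols]
  }
  yn
}

# Staged version of the per-shot forward chain.  Returns the sampled k-space
# together with the intermediate volumes after the phase, pitch, roll and yaw
# stages; shot_forward_stage() then re-evaluates the chain for a motion state
# that differs from the cached one in a single parameter, starting from the
# deepest still-valid stage.  Exact same arithmetic as shot_forward_n.
#' @keywords internal
shot_forward_cached <- function(ctx, x, z, lc, n) {
  d <- ctx$d
  ph <- shot_phase(lc, z, ctx$TE)
  u <- if (is.null(ph)) x else x * ph
  r1 <- rotate_pass(u, 2L, 3L, z[4], ctx$spacing)
  r2 <- rotate_pass(r1, 3L, 1L, z[5], ctx$spacing)
  r3 <- rotate_pass(r2, 1L, 2L, z[6], ctx$spacing)
  w <- translate_pass(r3, z[1:3], ctx$spacing)
  list(z = z, u = u, r1 = r1, r2 = r2, r3 = r3,
       y = sample_coils(ctx, w, n))
}

#' @keywords internal
sample_coils <- function(ctx, w, n) {
  d <- ctx$d
  cols <- ctx$cols[[n]]
  wsh <- ifftshift3(w)
  yn <- array(0i, c(d[1], length(cols), ctx$nc))
  for (c in seq_len(ctx$nc)) {
    sc <- ctx$Ssh[, , , c, drop = FALSE]
    dim(sc) <- d
    X <- fft(sc * wsh) / ctx$sqV
    dim(X) <- c(d[1], d[2] * d[3])
    yn[, , c] <- X[ctx$rows, cols]
  }
  yn
}

# Re-evaluate the cached chain with parameter j of the motion state replaced.
#' @keywords internal
shot_forward_stage <- function(ctx, cache, x, lc, n, j, value) {
  z <- cache$z
  z[j] <- value
  sp <- ctx$spacing
  if (j == 4L) {                      # pitch: phase (if any) and all rotations
    ph <- shot_phase(lc, z, ctx$TE)
    u <- if (is.null(ph)) x else x * ph
    r1 <- rotate_pass(u, 2L, 3L, z[4], sp)
    r2 <- rotate_pass(r1, 3L, 1L, z[5], sp)
    r3 <- rotate_pass(r2, 1L, 2L, z[6], sp)
  } else if (j == 5L) {               # roll: phase and the last two rotations
    ph <- shot_phase(lc, z, ctx$TE)
    u <- if (is.null(ph)) x else x * ph
    r1 <- if (is.null(ph)) cache$r1 else rotate_pass(u, 2L, 3L, z[4], sp)
    r2 <- rotate_pass(r1, 3L, 1L, z[5], sp)
    r3 <- rotate_pass(r2, 1L, 2L, z[6], sp)
  } else if (j == 6L) {               # yaw only
    r3 <- rotate_pass(cache$r2, 1L, 2L, z[6], sp)
  } else {                            # translations: last stage only
    r3 <- cache$r3
  }
  w <- translate_pass(r3, z[1:3], sp)
  sample_coils(ctx, w, n)
}

# Adjoint chain for one shot: embeds samples, inverse FFT, conjugate coils,
# inverse rigid transform, conjugate B0 phase.
#' @keywords internal
shot_adjoint_n <- function(ctx, yn, z, lc, n, apply_phase = TRUE) {
  d <- ctx$d
  cols <- ctx$cols[[n]]
  if (length(cols) == 0L) return(array(0i, d))
  gsh <- array(0i, d)
  for (c in seq_len(ctx$nc)) {
    X <- matrix(0i, d[1], d[2] * d[3])
    X[ctx$rows, cols] <- yn[, , c, drop = FALSE]
    dim(X) <- d
    sc <- ctx$Scj[, , , c, drop = FALSE]
    dim(sc) <- d
    gsh <- gsh + sc * (fft(X, inverse = TRUE) / ctx$sqV)
  }
  g <- fftshift3(gsh)
  if (any(z != 0)) g <- rigid_transform(g, z, "inverse", spacing = ctx$spacing)
  if (apply_phase) {
    ph <- shot_phase(lc, z, ctx$TE)
    if (!is.null(ph)) g <- g * Conj(ph)
  }
  g
}

# ---- public operators ------------------------------------------------------

#' Forward encoding model
#'
#' Applies, for each shot, the pose-dependent B0 phase (if LC maps are given),
#' the rigid transform of the shot's motion state, the coil sensitivities, the
#' centered orthonormal FFT, and the shot's sampling mask. With `lc = NULL`
#' (or all-zero maps) the chain reduces exactly to the motion-only
#' aligned-SENSE model; with identity motion, a single unit coil and a single
#' full shot it reduces to the discrete Fourier transform.
#'
#' @param x image: [mr_volume()] or complex 3D array
#' @param trace [motion_trace()] with one row per shot
#' @param lc [lc_maps()] or `NULL` for no B0 modelling
#' @param S [coil_maps()]
#' @param seg [generate_disorder()] segmentation
#' @param TE echo time, seconds
#' @param spacing voxel spacing in mm when `x` is a bare array
#' @return a [kspace_data()] object
#' @export
forward_model <- function(x, trace, lc, S, seg, TE, spacing = NULL) {
  v <- as_vol(x, spacing)
  d <- dim(v$data)
  if (!identical(dim(S$data)[1:3], d))
    stop("coil maps and image grids disagree", call. = FALSE)
  if (!is.null(lc) && !identical(dim(lc$dpitch), d))
    stop("LC maps and image grids disagree", call. = FALSE)
  if (nrow(trace) != seg$n_shots)
    stop("motion trace and segmentation disagree on shot count", call. = FALSE)
  ctx <- encode_ctx(S, seg, TE, v$spacing)
  y <- vector("list", seg$n_shots)
  for (n in seq_len(seg$n_shots))
    y[[n]] <- shot_forward_n(ctx, v$data, trace[n, ], lc, n)
  kspace_data(y, seg, TE, d, v$spacing)
}

#' Adjoint of the forward encoding model
#'
#' Conjugate-transpose chain: embed samples at their mask positions, inverse
#' FFT, multiply by conjugate sensitivities, sum over coils, inverse rigid
#' transform, conjugate B0 phase; accumulated over shots. Verified against
#' [forward_model()] by randomized dot-product tests.
#'
#' @param y a [kspace_data()] object
#' @inheritParams forward_model
#' @return complex 3D array (head frame)
#' @export
adjoint_model <- function(y, trace, lc, S, seg, TE) {
  if (length(y$y) != seg$n_shots || nrow(trace) != seg$n_shots)
    stop("shot count mismatch between data, trace and segmentation", call. = FALSE)
  ctx <- encode_ctx(S, seg, TE, y$spacing)
  acc <- array(0i, ctx$d)
  for (n in seq_len(seg$n_shots))
    acc <- acc + shot_adjoint_n(ctx, y$y[[n]], trace[n, ], lc, n)
  acc
}

# ---- k-space utilities -----------------------------------------------------

#' @keywords internal
kspace_dot <- function(a, b) {
  s <- 0i
  for (n in seq_along(a$y)) s <- s + sum(Conj(a$y[[n]]) * b$y[[n]])
  s
}

#' @keywords internal
kspace_norm2 <- function(a) {
  s <- 0
  for (n in seq_along(a$y)) s <- s + sum(Mod(a$y[[n]])^2)
  s
}

#' Merge the shots of a k-space object into a single shot
#'
#' Companion of [collapse_shots()] for the uncorrected (plain SENSE)
#' reconstruction: concatenates the per-shot samples in shot order.
#' @param y a [kspace_data()] object
#' @export
collapse_kspace <- function(y) {
  seg1 <- collapse_shots(y$seg)
  nc <- dim(y$y[[1]])[3]
  M <- nrow(seg1$shots[[1]])
  yy <- array(0i, c(y$shape[1], M, nc))
  at <- 0L
  for (n in seq_along(y$y)) {
    m <- dim(y$y[[n]])[2]
    if (m > 0L) yy[, at + seq_len(m), ] <- y$y[[n]]
    at <- at + m
  }
  kspace_data(list(yy), seg1, y$TE, y$shape, y$spacing)
}
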