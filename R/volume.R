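# Domain containers: complex image volumes, coil sensitivities, motion states,
# linear-coefficient (LC) maps.
#
# Axis convention (fixed package-wide): dimension 1 = left-right (LR, readout),
# dimension 2 = anterior-posterior (AP), dimension 3 = foot-head (FH).
# Rotations: pitch about the LR axis, roll about the AP axis, yaw about the FH
# axis, all in degrees; translations in mm along (LR, AP, FH).

#' Complex image volume
#'
#' A 3D complex-valued image on a voxel grid with physical spacing. This is the
#' container for the image to be reconstructed and for any scalar complex field
#' defined on the same grid.
#'
#' @param data 3D numeric or complex array
#' @param spacing voxel spacing in mm, length 3, all finite and positive
#' @param frame coordinate frame the volume lives in, `"head"` or `"scanner"`
#' @return an object of class `mrvol`
#' @export
mr_volume <- function(data, spacing = c(1, 1, 1), frame = c("head", "scanner")) {
  frame <- match.arg(frame)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  if (!is.complex(data)) {
    if (!is.numeric(data)) stop("`data` must be numeric or complex", call. = FALSE)
    storage.mode(data) <- "double"
    data <- data + 0i
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 finite positive numbers (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing, frame = frame), class = "mrvol")
}

#' @export
dim.mrvol <- function(x) dim(x$data)

#' @export
print.mrvol <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mrvol> %d x %d x %d complex volume, spacing %s mm, %s frame\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              x$frame))
  invisible(x)
}

#' @export
as.array.mrvol <- function(x, ...) x$data

# Accept either an mrvol or a bare 3D complex array; return list(data, spacing).
#' @keywords internal
as_vol <- function(x, spacing = NULL) {
  if (inherits(x, "mrvol")) return(list(data = x$data, spacing = x$spacing))
  if (is.array(x) && length(dim(x)) == 3L) {
    if (!is.complex(x)) x <- x + 0i
    return(list(data = x, spacing = if (is.null(spacing)) c(1, 1, 1) else spacing))
  }
  stop("expected an `mrvol` or a 3D array", call. = FALSE)
}

#' Coil sensitivity maps
#'
#' Smooth complex per-coil sensitivity volumes on the same grid as the image.
#'
#' @param data 4D complex array, `dim = c(nx, ny, nz, n_coils)`
#' @param spacing voxel spacing in mm
#' @return an object of class `coil_maps`
#' @export
coil_maps <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("coil maps must be a 4D array (x, y, z, coil)", call. = FALSE)
  if (dim(data)[4] < 1L) stop("need at least one coil", call. = FALSE)
  if (!is.complex(data)) data <- data + 0i
  structure(list(data = data, spacing = as.numeric(spacing)), class = "coil_maps")
}

#' @export
dim.coil_maps <- function(x) dim(x$data)

#' @export
print.coil_maps <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<coil_maps> %d coils on %d x %d x %d grid\n", d[4], d[1], d[2], d[3]))
  invisible(x)
}

#' Rigid motion state
#'
#' Six rigid parameters for one shot: translations (mm) along LR/AP/FH and
#' rotations (degrees) pitch (about LR), roll (about AP), yaw (about FH).
#'
#' @param t_lr,t_ap,t_fh translations in mm
#' @param r_pitch,r_roll,r_yaw rotations in degrees
#' @return named numeric vector of class `motion_state`
#' @export
motion_state <- function(t_lr = 0, t_ap = 0, t_fh = 0,
                         r_pitch = 0, r_roll = 0, r_yaw = 0) {
  z <- c(t_lr = t_lr, t_ap = t_ap, t_fh = t_fh,
         r_pitch = r_pitch, r_roll = r_roll, r_yaw = r_yaw)
  if (any(!is.finite(z))) stop("motion parameters must be finite", call. = FALSE)
  structure(z, class = "motion_state")
}

#' Motion trace
#'
#' Per-shot rigid motion states as an `n_shots x 6` matrix with columns
#' `t_lr, t_ap, t_fh, r_pitch, r_roll, r_yaw`.
#'
#' @param params numeric matrix `n_shots x 6` (or vector of length 6 for one shot)
#' @return matrix of class `motion_trace`
#' @export
motion_trace <- function(params) {
  if (is.null(dim(params))) params <- matrix(params, nrow = 1)
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("a motion trace has 6 columns", call. = FALSE)
  if (any(!is.finite(params))) stop("motion parameters must be finite", call. = FALSE)
  colnames(params) <- c("t_lr", "t_ap", "t_fh", "r_pitch", "r_roll", "r_yaw")
  structure(params, class = c("motion_trace", "matrix"))
}

#' Identity motion trace of a given length
#' @param n_shots number of shots
#' @export
identity_trace <- function(n_shots) motion_trace(matrix(0, n_shots, 6))

#' Linear-coefficient (LC) maps of the pose-dependent B0 model
#'
#' Two real volumes in Hz/degree, defined in the head frame: `dpitch` maps a
#' pitch rotation (about LR) to a voxelwise frequency offset, `droll` does the
#' same for roll (about AP). Yaw and translations do not enter the model.
#'
#' @param dpitch,droll real 3D arrays, Hz/degree
#' @param spacing voxel spacing in mm
#' @return an object of class `lc_maps`
#' @export
lc_maps <- function(dpitch, droll, spacing = c(1, 1, 1)) {
  if (!is.array(dpitch) || !is.array(droll) ||
      !identical(dim(dpitch), dim(droll)) || length(dim(dpitch)) != 3L)
    stop("LC maps must be two 3D arrays of identical shape", call. = FALSE)
  if (is.complex(dpitch) || is.complex(droll))
    stop("LC maps are real-valued (Hz/degree)", call. = FALSE)
  if (any(!is.finite(dpitch)) || any(!is.finite(droll)))
    stop("LC maps must be finite", call. = FALSE)
  structure(list(dpitch = dpitch, droll = droll, spacing = as.numeric(spacing)),
            class = "lc_maps")
}

#' All-zero LC maps on a given grid
#' @param shape grid shape, length 3
#' @param spacing voxel spacing in mm
#' @export
zero_lc_maps <- function(shape, spacing = c(1, 1, 1)) {
  z <- array(0, shape)
  lc_maps(z, z, spacing)
}

#' @export
print.lc_maps <- function(x, ...) {
  d <- dim(x$dpitch)
  cat(sprintf("<lc_maps> dpitch/droll on %d x %d x %d grid, range [%.2f, %.2f] Hz/deg\n",
              d[1], d[2], d[3], min(x$dpitch, x$droll), max(x$dpitch, x$droll)))
  invisible(x)
}
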