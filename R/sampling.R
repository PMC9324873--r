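# DISORDER shot segmentation of the Cartesian phase-encode plane.
#
# The (ky, kz) plane is restricted to an elliptical shutter and partitioned
# into temporally ordered shots.  The random-checkered variant tiles the plane
# into a checkerboard and deals the (shuffled) points of each tile round-robin
# across shots, so every shot is a spatially distributed, incoherent subset.

#' Elliptical shutter over the phase-encode plane
#'
#' Keeps the phase-encode points inside the inscribed ellipse of the
#' `ny x nz` plane: `(ky/(ny/2))^2 + (kz/(nz/2))^2 <= 1` in centered integer
#' coordinates (DC at `floor(n/2)+1`).
#'
#' @param ny,nz phase-encode grid size (>= 2)
#' @return integer matrix with columns `ky, kz` (1-based grid indices)
#' @export
elliptical_shutter <- function(ny, nz) {
  if (ny < 2 || nz < 2) stop("phase-encode grid must be at least 2 x 2", call. = FALSE)
  ky <- centered_coord(ny)
  kz <- centered_coord(nz)
  keep <- outer(ky / (ny / 2), kz / (nz / 2), function(a, b) a^2 + b^2) <= 1
  idx <- which(keep, arr.ind = TRUE)
  colnames(idx) <- c("ky", "kz")
  idx
}

#' DISORDER random-checkered shot segmentation
#'
#' Partitions the shuttered phase-encode plane into `n_shots` temporally
#' ordered shots. The plane is tiled into an `a x b` checkerboard with
#' `a*b ~ n_shots` (aspect matched to the plane); within each tile the points
#' are shuffled and dealt round-robin across shots with a running counter, so
#' shot sizes are balanced to +/-1 and each shot's points are spread over the
#' whole plane. Deterministic given `seed`.
#'
#' @param ny,nz phase-encode grid size
#' @param n_shots number of shots (1 <= n_shots <= number of shuttered points)
#' @param seed integer seed for the in-tile shuffles
#' @return an object of class `shot_seg`: list with `n_shots`, `ny`, `nz`,
#'   `seed`, and `shots`, a list of integer matrices (`ky`, `kz`) in temporal
#'   order (raster over tiles within each shot)
#' @export
generate_disorder <- function(ny, nz, n_shots, seed = 0L) {
  pts <- elliptical_shutter(ny, nz)
  np <- nrow(pts)
  if (n_shots < 1 || n_shots > np)
    stop(sprintf("n_shots must be in [1, %d] for a %d x %d shutter", np, ny, nz),
         call. = FALSE)
  if (n_shots == 1L) {
    return(structure(list(n_shots = 1L, ny = ny, nz = nz, seed = as.integer(seed),
                          shots = list(pts)), class = "shot_seg"))
  }
  # checkerboard tiling: a*b ~ n_shots, aspect ratio matching the plane
  a <- max(1L, round(sqrt(n_shots * ny / nz)))
  b <- max(1L, ceiling(n_shots / a))
  tile_y <- pmin(ceiling((pts[, 1] - 0.5) / (ny / a)), a)
  tile_z <- pmin(ceiling((pts[, 2] - 0.5) / (nz / b)), b)
  tile_id <- (tile_z - 1L) * a + tile_y
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed))
  ord <- integer(np)
  pos <- 0L
  for (t in sort(unique(tile_id))) {          # raster over tiles
    members <- which(tile_id == t)
    members <- members[sample.int(length(members))]
    ord[pos + seq_along(members)] <- members
    pos <- pos + length(members)
  }
  shot_of <- ((seq_len(np) - 1L) %% n_shots) + 1L   # round-robin dealing
  shots <- vector("list", n_shots)
  for (s in seq_len(n_shots)) {
    shots[[s]] <- pts[ord[shot_of == s], , drop = FALSE]
  }
  structure(list(n_shots = as.integer(n_shots), ny = ny, nz = nz,
                 seed = as.integer(seed), shots = shots), class = "shot_seg")
}

#' @export
print.shot_seg <- function(x, ...) {
  sz <- vapply(x$shots, nrow, 1L)
  cat(sprintf("<shot_seg> %d shots over %d x %d plane (%d points, sizes %d-%d)\n",
              x$n_shots, x$ny, x$nz, sum(sz), min(sz), max(sz)))
  invisible(x)
}

#' Merge all shots of a segmentation into a single shot
#'
#' Used by the uncorrected reconstruction, where all shots share the identity
#' motion state and the encoding collapses to plain SENSE.
#' @param seg a `shot_seg`
#' @export
collapse_shots <- function(seg) {
  structure(list(n_shots = 1L, ny = seg$ny, nz = seg$nz, seed = seg$seed,
                 shots = list(do.call(rbind, seg$shots))), class = "shot_seg")
}

#' Sequential (linear) segmentation of the shuttered plane
#'
#' Reference ordering used to audit the incoherence of the DISORDER pattern:
#' shuttered points in raster order cut into `n_shots` consecutive runs.
#' @param ny,nz phase-encode grid size
#' @param n_shots number of shots
#' @export
sequential_segmentation <- function(ny, nz, n_shots) {
  pts <- elliptical_shutter(ny, nz)
  np <- nrow(pts)
  shot_of <- ceiling(seq_len(np) / (np / n_shots))
  shots <- lapply(seq_len(n_shots), function(s) pts[shot_of == s, , drop = FALSE])
  structure(list(n_shots = as.integer(n_shots), ny = ny, nz = nz, seed = NA_integer_,
                 shots = shots), class = "shot_seg")
}
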