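# File formats: complex volumes and LC maps as NIfTI-1 (real/imaginary pairs
# along the 4th axis), k-space containers as serialized R lists, motion traces
# and cost histories as CSV, manifests as JSON.

#' Write a complex volume to NIfTI
#'
#' Complex data are stored as a 4D volume with the real and imaginary parts
#' stacked along the 4th axis (the package's documented dialect); purely real
#' volumes may be read back from plain 3D files. Voxel spacing is carried in
#' the NIfTI pixdim.
#'
#' @param vol an [mr_volume()] or complex/numeric 3D array
#' @param path output path (`.nii` or `.nii.gz`)
#' @param spacing spacing when `vol` is a bare array
#' @return `path`, invisibly
#' @export
write_volume <- function(vol, path, spacing = NULL) {
  v <- as_vol(vol, spacing)
  arr <- array(0, c(dim(v$data), 2L))
  arr[, , , 1] <- Re(v$data)
  arr[, , , 2] <- Im(v$data)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(v$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a complex volume from NIfTI
#'
#' Accepts the package's 4D real/imaginary dialect or a plain 3D (real)
#' volume. Anything else is a format error naming the offending axis.
#'
#' @param path NIfTI file
#' @param frame coordinate frame to record on the volume
#' @return an [mr_volume()]
#' @export
read_volume <- function(path, frame = "head") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 3L) {
    data <- arr + 0i
  } else if (length(d) == 4L && d[4] == 2L) {
    data <- arr[, , , 1] + 1i * arr[, , , 2]
  } else {
    stop(sprintf("expected a 3D volume or a 4D real/imaginary pair; got %d axes (4th axis length %s)",
                 length(d), if (length(d) >= 4) d[4] else "none"), call. = FALSE)
  }
  sp <- RNifti::pixdim(img)[seq_len(min(3L, length(d)))]
  mr_volume(data, spacing = sp, frame = frame)
}

#' Write / read LC maps as a 4D NIfTI (dpitch, droll)
#'
#' Units are Hz/degree; the two maps are stacked along the 4th axis.
#' @param lc an [lc_maps()] object
#' @param path NIfTI path
#' @export
write_lc_maps <- function(lc, path) {
  arr <- array(0, c(dim(lc$dpitch), 2L))
  arr[, , , 1] <- lc$dpitch
  arr[, , , 2] <- lc$droll
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(lc$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_lc_maps
#' @export
read_lc_maps <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L || dim(arr)[4] != 2L)
    stop("LC-map files carry exactly two volumes along the 4th axis", call. = FALSE)
  lc_maps(arr[, , , 1], arr[, , , 2], RNifti::pixdim(img)[1:3])
}

#' Serialize / load a k-space container
#'
#' The in-memory list layout (per-shot sample arrays, segmentation, TE, grid)
#' is written as an R serialization; a paired `.json` sidecar records the
#' metadata for inspection without loading the data.
#'
#' @param y a [kspace_data()] object
#' @param path output path (`.rds`)
#' @export
save_kspace <- function(y, path) {
  saveRDS(y, path)
  meta <- list(n_shots = length(y$y), n_coils = dim(y$y[[1]])[3],
               shape = y$shape, spacing = y$spacing, TE = y$TE,
               seed = y$seg$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_kspace
#' @export
load_kspace <- function(path) {
  y <- readRDS(path)
  if (!inherits(y, "kspace")) stop("not a k-space container", call. = FALSE)
  y
}

#' Write / read a motion trace as CSV (shot, 6 parameters)
#' @param trace a [motion_trace()]
#' @param path CSV path
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(shot = seq_len(nrow(trace)), unclass(trace)[, , drop = FALSE])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  motion_trace(as.matrix(df[, c("t_lr", "t_ap", "t_fh", "r_pitch", "r_roll", "r_yaw")]))
}

#' Build a manifest of a pipeline stage
#'
#' Snapshot of the configuration, seeds, output files and their MD5 checksums;
#' re-running a deterministic stage with the same manifest reproduces the same
#' checksums.
#'
#' @param config configuration list (stored as-is)
#' @param files character vector of produced files
#' @param stage stage name
#' @return list of class `b0moco_manifest`
#' @export
build_manifest <- function(config, files = character(0), stage = "run") {
  files <- files[file.exists(files)]
  structure(list(stage = stage,
                 package_version = as.character(utils::packageVersion("b0moco")),
                 config = config,
                 files = as.list(files),
                 checksums = as.list(unname(tools::md5sum(files))),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            class = "b0moco_manifest")
}

#' @rdname build_manifest
#' @param manifest a manifest
#' @param path JSON path
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
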