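# Image-quality metrics: SNR (mean-power-ratio formula), SSIM, histogram
# mutual information, artifact power.

#' Reconstruction SNR in dB
#'
#' `10*log10( mean(|x_gt|^2) / mean(|x - x_gt|^2) )` over the whole FOV or a
#' mask: the ratio of mean ground-truth signal power to mean error power.
#' An exact match is reported as `Inf` with attribute `exact = TRUE` rather
#' than an error.
#'
#' @param x reconstruction ([mr_volume()] or complex array)
#' @param x_gt ground-truth image on the same grid
#' @param mask optional logical array restricting the evaluation region
#' @return SNR in dB
#' @export
snr_db <- function(x, x_gt, mask = NULL) {
  a <- as_vol(x)$data
  b <- as_vol(x_gt)$data
  if (!identical(dim(a), dim(b))) stop("grids disagree", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  sig <- mean(Mod(b[mask])^2)
  err <- mean(Mod(a[mask] - b[mask])^2)
  if (err == 0) {
    out <- Inf
    attr(out, "exact") <- TRUE
    return(out)
  }
  10 * log10(sig / err)
}

#' Artifact power
#'
#' Mean squared error energy normalized by reference energy:
#' `mean(|x - x_ref|^2) / mean(|x_ref|^2)`.
#' @inheritParams snr_db
#' @param x_ref reference image
#' @export
artifact_power <- function(x, x_ref, mask = NULL) {
  a <- as_vol(x)$data
  b <- as_vol(x_ref)$data
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  mean(Mod(a[mask] - b[mask])^2) / mean(Mod(b[mask])^2)
}

# ---- SSIM ------------------------------------------------------------------

# Valid-region box sums along one axis (cumulative-sum trick).
#' @keywords internal
boxsum_axis <- function(x, w, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  dim(xp) <- c(dp[1], dp[2] * dp[3])
  cs <- apply(xp, 2, cumsum)
  out <- cs[w:dp[1], , drop = FALSE] -
    rbind(0, cs[seq_len(dp[1] - w), , drop = FALSE])
  dim(out) <- c(dp[1] - w + 1L, dp[2], dp[3])
  aperm(out, order(perm))
}

#' @keywords internal
boxmean3 <- function(x, w) {
  for (ax in 1:3) x <- boxsum_axis(x, w, ax)
  x / w^3
}

#' Structural similarity of two 3D magnitude images
#'
#' Standard windowed SSIM with a cubic uniform window (default 7 voxels) and
#' the usual regularizers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` where `L` is
#' the dynamic range of the reference magnitude. Computed on magnitudes; the
#' mean is taken over windows fully inside the volume.
#'
#' @inheritParams artifact_power
#' @param window cubic window width in voxels
#' @return mean SSIM in [-1, 1]
#' @export
ssim3d <- function(x, x_ref, window = 7L) {
  a <- Mod(as_vol(x)$data)
  b <- Mod(as_vol(x_ref)$data)
  if (!identical(dim(a), dim(b))) stop("grids disagree", call. = FALSE)
  if (any(dim(a) < window)) stop("volume smaller than the SSIM window", call. = FALSE)
  L <- diff(range(b))
  if (L == 0) L <- 1
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  mu_a <- boxmean3(a, window)
  mu_b <- boxmean3(b, window)
  va <- pmax(0, boxmean3(a^2, window) - mu_a^2)
  vb <- pmax(0, boxmean3(b^2, window) - mu_b^2)
  cab <- boxmean3(a * b, window) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Histogram mutual information of two magnitude images
#'
#' Joint histogram on a fixed `bins x bins` grid over each image's own
#' magnitude range; MI in nats. Constant images carry no information: the
#' result is 0 with attribute `constant = TRUE`.
#'
#' @inheritParams artifact_power
#' @param bins number of histogram bins per image (default 64)
#' @export
mutual_information <- function(x, x_ref, mask = NULL, bins = 64L) {
  a <- Mod(as_vol(x)$data)
  b <- Mod(as_vol(x_ref)$data)
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  a <- a[mask]; b <- b[mask]
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) {
    out <- 0
    attr(out, "constant") <- TRUE
    return(out)
  }
  ia <- pmin(bins, 1L + floor((a - ra[1]) / diff(ra) * bins))
  ib <- pmin(bins, 1L + floor((b - rb[1]) / diff(rb) * bins))
  joint <- tabulate((ib - 1L) * bins + ia, nbins = bins * bins) / length(a)
  dim(joint) <- c(bins, bins)
  pa <- rowSums(joint)
  pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
}

#' Full similarity report
#'
#' SNR and artifact power on the complex images, SSIM and mutual information
#' on the magnitudes, over the whole FOV or a mask.
#'
#' @inheritParams artifact_power
#' @param ssim_window SSIM window width
#' @param mi_bins mutual-information histogram bins
#' @return one-row data.frame: `snr_db`, `ssim`, `mutual_information`,
#'   `artifact_power`, `region`
#' @export
similarity_suite <- function(x, x_ref, mask = NULL, ssim_window = 7L,
                             mi_bins = 64L) {
  data.frame(snr_db = as.numeric(snr_db(x, x_ref, mask)),
             ssim = ssim3d(x, x_ref, ssim_window),
             mutual_information = as.numeric(mutual_information(x, x_ref, mask, mi_bins)),
             artifact_power = artifact_power(x, x_ref, mask),
             region = if (is.null(mask)) "whole_fov" else "mask")
}
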