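# Synthetic-data generator: brain-like complex phantom, smooth multi-coil
# sensitivities, ground-truth LC maps with localized features near
# air-tissue-like loci, an interleaved piecewise-constant motion trace with
# drift back toward neutral, and noisy multi-coil k-space synthesis with
# SNR-calibrated complex Gaussian noise.

# Run code under a given RNG seed, restoring the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv))
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Simulation design
#'
#' Bundles the study conditions of the synthetic experiments: grid, coil
#' count, shot segmentation, interleaved motion design (number of poses,
#' uniform translation/rotation ranges, drift), target noise level and echo
#' time. The defaults are the desk-scale simulation conditions: a 64 cubed
#' grid at 1.5 mm, 8 coils, 128 DISORDER shots shared by 13 poses drawn from
#' [-5, 5] mm and [-7.5, 7.5] degrees with a slow drift back toward neutral,
#' 30 dB target SNR and TE = 5 ms.
#'
#' @param shape grid shape (LR, AP, FH)
#' @param spacing_mm voxel spacing
#' @param n_coils number of receiver coils
#' @param n_shots number of DISORDER shots
#' @param n_poses number of distinct poses (contiguous shot blocks)
#' @param translation_range_mm half-range of uniform translations (symmetric)
#' @param rotation_range_deg half-range of uniform rotations (symmetric)
#' @param drift_fraction per-shot geometric decay of each pose toward neutral
#' @param target_snr_db target SNR of the motion-free uncorrected
#'   reconstruction; `Inf` for noise-free synthesis
#' @param TE echo time in seconds
#' @param first_pose_neutral keep the first pose block at zero (consistent
#'   with the reconstruction gauge that pins the first shot's motion)
#' @param seed master seed; all generator randomness derives from it
#' @return list of class `sim_spec`
#' @export
simulation_spec <- function(shape = c(64, 64, 64), spacing_mm = c(1.5, 1.5, 1.5),
                            n_coils = 8, n_shots = 128, n_poses = 13,
                            translation_range_mm = 5, rotation_range_deg = 7.5,
                            drift_fraction = 0.05, target_snr_db = 30,
                            TE = 0.005, first_pose_neutral = TRUE, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8),
            all(spacing_mm > 0), n_coils >= 1, n_shots >= 1,
            n_poses >= 1, n_poses <= n_shots,
            translation_range_mm >= 0, rotation_range_deg >= 0,
            drift_fraction >= 0, drift_fraction < 1,
            target_snr_db > 0, TE > 0)
  structure(list(shape = as.integer(shape), spacing_mm = as.numeric(spacing_mm),
                 n_coils = as.integer(n_coils), n_shots = as.integer(n_shots),
                 n_poses = as.integer(n_poses),
                 translation_range_mm = translation_range_mm,
                 rotation_range_deg = rotation_range_deg,
                 drift_fraction = drift_fraction,
                 target_snr_db = target_snr_db, TE = TE,
                 first_pose_neutral = isTRUE(first_pose_neutral),
                 seed = as.integer(seed)), class = "sim_spec")
}

# Shared geometry: fractional centered coordinates, head-ellipsoid radius
# field, and the support mask with its >= 8 voxel boundary margin.
#' @keywords internal
phantom_geometry <- function(spec) {
  d <- spec$shape
  # 8 voxels at the default 64-cube design, proportionally fewer on the small
  # grids used for unit tests and coarse levels
  margin <- min(8L, max(2L, round(min(d) / 8)))
  u <- lapply(1:3, function(ax) centered_coord(d[ax]) / (d[ax] / 2))
  rmax <- (d / 2 - margin) / (d / 2)            # largest radius honouring the margin
  rout <- rmax * c(1.00, 0.92, 0.96)            # outer head ellipsoid, per axis
  ux <- array(rep(u[[1]], times = d[2] * d[3]), d)
  uy <- array(rep(rep(u[[2]], each = d[1]), times = d[3]), d)
  uz <- array(rep(u[[3]], each = d[1] * d[2]), d)
  e <- (ux / rout[1])^2 + (uy / rout[2])^2 + (uz / rout[3])^2
  list(d = d, ux = ux, uy = uy, uz = uz, e = e, rout = rout,
       support = e <= 1)
}

#' Brain-like complex phantom
#'
#' Piecewise-smooth nested-ellipsoid magnitude (head, brain, ventricles, a few
#' seeded focal structures) with a smooth background phase; identically zero
#' within at least 8 voxels of every volume face so the cyclic wrap of the
#' shear-FFT transform never recirculates tissue.
#'
#' @param spec a [simulation_spec()]
#' @return an [mr_volume()] in the head frame
#' @export
make_phantom <- function(spec) {
  g <- phantom_geometry(spec)
  mag <- ifelse(g$e <= 1, 0.75, 0)              # scalp/skull shell
  # brain compartment, deliberately off-center and asymmetric front-back and
  # top-bottom the way a head is -- a near-symmetric phantom under-constrains
  # rotation estimation
  eb <- ((g$ux - 0.04) / (0.80 * g$rout[1]))^2 +
        ((g$uy + 0.07) / (0.76 * g$rout[2]))^2 +
        ((g$uz - 0.06) / (0.78 * g$rout[3]))^2
  brain <- eb <= 1
  modulation <- 1 + 0.12 * cos(6 * g$uy) * cos(4 * g$uz) +
    0.10 * sin(5 * g$ux + 1) * sin(3 * g$uz - 0.5) +
    0.08 * cos(4 * g$ux - 2 * g$uy + 1.3)
  mag[brain] <- modulation[brain]
  # cerebellum-like denser inferior-posterior compartment
  ec <- ((g$ux) / 0.28)^2 + ((g$uy + 0.45 * g$rout[2]) / 0.22)^2 +
        ((g$uz + 0.45 * g$rout[3]) / 0.20)^2
  mag[ec <= 1 & g$e <= 1] <- 1.15
  # frontal air-like cavity (sinus) just above the nasal region
  es <- ((g$ux) / 0.10)^2 + ((g$uy - 0.52 * g$rout[2]) / 0.09)^2 +
        ((g$uz + 0.38 * g$rout[3]) / 0.10)^2
  mag[es <= 1] <- 0.05
  for (s in c(-1, 1)) {                         # ventricles, unequal sizes
    ev <- ((g$ux - s * 0.12) / (0.10 + 0.02 * s))^2 + ((g$uy + 0.05) / 0.22)^2 +
      ((g$uz - 0.08) / 0.14)^2
    mag[ev <= 1] <- 0.25
  }
  lesions <- with_seed(spec$seed, {
    cbind(x = runif(5, -0.4, 0.4), y = runif(5, -0.4, 0.4),
          z = runif(5, -0.4, 0.4), r = runif(5, 0.05, 0.09),
          a = rep(c(1.35, 0.5), length.out = 5))
  })
  for (k in seq_len(nrow(lesions))) {
    el <- ((g$ux - lesions[k, 1]) / lesions[k, 4])^2 +
          ((g$uy - lesions[k, 2]) / lesions[k, 4])^2 +
          ((g$uz - lesions[k, 3]) / lesions[k, 4])^2
    mag[el <= 1 & brain] <- lesions[k, 5]
  }
  phase <- 0.6 * exp(-(g$ux^2 + g$uy^2 + g$uz^2) / 0.35) - 0.2 * g$uz
  x <- mag * exp(1i * phase)
  x[g$e > 1] <- 0
  # band-limit the phantom to the elliptical-shutter support: the ground
  # truth of the acquisition lives in the measured k-space, so an image with
  # corner-spectrum energy the sampling can never see would build a spurious
  # error floor into every reconstruction
  X <- cfft3(x)
  dim(X) <- c(g$d[1], g$d[2] * g$d[3])
  sh <- elliptical_shutter(g$d[2], g$d[3])
  keep <- logical(g$d[2] * g$d[3])
  keep[(sh[, 2] - 1L) * g$d[2] + sh[, 1]] <- TRUE
  X[, !keep] <- 0i
  dim(X) <- g$d
  x <- cifft3(X)
  # the projection rings faintly outside the head; keep the boundary margin
  # identically zero so cyclic transforms never recirculate signal
  margin <- min(8L, max(2L, round(min(g$d) / 8)))
  idx <- lapply(g$d, function(n) c(seq_len(margin), n - margin + seq_len(margin)))
  x[idx[[1]], , ] <- 0i
  x[, idx[[2]], ] <- 0i
  x[, , idx[[3]]] <- 0i
  mr_volume(x, spec$spacing_mm, frame = "head")
}

#' Smooth synthetic coil sensitivities
#'
#' Gaussian receive lobes centered on a ring around the head (alternating
#' above/below the axial midplane) with a gentle linear phase per coil. The
#' root-sum-of-squares magnitude is strictly positive over the phantom
#' support. `n_coils = 1` yields a uniform unit sensitivity.
#'
#' @param spec a [simulation_spec()]
#' @return a [coil_maps()] object
#' @export
make_coil_maps <- function(spec) {
  g <- phantom_geometry(spec)
  nc <- spec$n_coils
  if (nc == 1L)
    return(coil_maps(array(1 + 0i, c(g$d, 1L)), spec$spacing_mm))
  out <- array(0i, c(g$d, nc))
  zlev <- c(-0.45, 0, 0.45)
  for (c in seq_len(nc)) {
    a <- 2 * pi * (c - 1) / nc
    ctr <- c(1.15 * cos(a), 1.15 * sin(a), zlev[(c - 1) %% 3 + 1])
    r2 <- (g$ux - ctr[1])^2 + (g$uy - ctr[2])^2 + (g$uz - ctr[3])^2
    ph <- 0.4 * (ctr[1] * g$ux + ctr[2] * g$uy) + 2 * pi * (c - 1) / nc
    out[, , , c] <- exp(-r2 / (2 * 0.85^2)) * exp(1i * ph)
  }
  coil_maps(out, spec$spacing_mm)
}

#' Ground-truth LC maps
#'
#' Emulates the structure of in-vivo linear-coefficient maps: a smooth
#' antisymmetric base pattern (opposite signs on opposite sides of each
#' rotation axis: `dpitch` odd in the AP coordinate, `droll` odd in LR) plus
#' localized high-magnitude lobes near two air-tissue-like loci (a frontal
#' "sinus" locus and lateral "ear-canal" loci), clipped to [-10, 10]
#' Hz/degree and zero outside the phantom support. The lobe centers and
#' radius are attached as attribute `blobs` so local deviations from
#' antisymmetry can be excluded in audits.
#'
#' @param spec a [simulation_spec()]
#' @return an [lc_maps()] object
#' @export
make_gt_lcmaps <- function(spec) {
  g <- phantom_geometry(spec)
  taper <- pmin(1, pmax(0, (1 - g$e) / 0.3))
  dpitch <- -5.5 * (g$uy / g$rout[2]) * taper * (1 + 0.3 * (g$uz / g$rout[3]))
  droll <-  5.5 * (g$ux / g$rout[1]) * taper * (1 + 0.3 * (g$uz / g$rout[3]))
  sig <- 0.16
  blobs <- rbind(sinus = c(0, 0.55 * g$rout[2], -0.35 * g$rout[3]),
                 ear_l = c(-0.65 * g$rout[1], 0, -0.25 * g$rout[3]),
                 ear_r = c(0.65 * g$rout[1], 0, -0.25 * g$rout[3]))
  bump <- function(ctr) exp(-((g$ux - ctr[1])^2 + (g$uy - ctr[2])^2 +
                                (g$uz - ctr[3])^2) / (2 * sig^2))
  dpitch <- dpitch + 8 * bump(blobs["sinus", ]) -
    6 * (bump(blobs["ear_l", ]) + bump(blobs["ear_r", ]))
  droll <- droll + 7 * (bump(blobs["ear_r", ]) - bump(blobs["ear_l", ])) +
    4 * bump(blobs["sinus", ])
  dpitch <- pmin(pmax(dpitch, -10), 10) * taper
  droll <- pmin(pmax(droll, -10), 10) * taper
  dpitch[!g$support] <- 0
  droll[!g$support] <- 0
  out <- lc_maps(dpitch, droll, spec$spacing_mm)
  attr(out, "blobs") <- cbind(blobs, radius = 3 * sig)
  out
}

#' Interleaved motion trace with drift
#'
#' `n_poses` contiguous blocks of shots (sizes equal to within one shot). Each
#' block's base pose is drawn uniformly from the configured symmetric ranges;
#' within a block every parameter decays geometrically toward the neutral
#' position by `drift_fraction` per shot. With `first_pose_neutral` the first
#' block stays at zero, matching the reconstruction gauge.
#'
#' @param spec a [simulation_spec()]
#' @return a [motion_trace()] with attribute `pose_block` (block id per shot)
#' @export
make_motion_trace <- function(spec) {
  ns <- spec$n_shots; np <- spec$n_poses
  base_sz <- ns %/% np
  sizes <- rep(base_sz, np) + c(rep(1L, ns %% np), rep(0L, np - ns %% np))
  poses <- with_seed(spec$seed + 33L, {
    t(vapply(seq_len(np), function(p) {
      if (p == 1L && spec$first_pose_neutral) rep(0, 6)
      else c(runif(3, -spec$translation_range_mm, spec$translation_range_mm),
             runif(3, -spec$rotation_range_deg, spec$rotation_range_deg))
    }, numeric(6)))
  })
  params <- matrix(0, ns, 6)
  block <- integer(ns)
  at <- 0L
  for (p in seq_len(np)) {
    for (j in seq_len(sizes[p])) {
      params[at + j, ] <- poses[p, ] * (1 - spec$drift_fraction)^(j - 1)
      block[at + j] <- p
    }
    at <- at + sizes[p]
  }
  out <- motion_trace(params)
  attr(out, "pose_block") <- block
  out
}

# Unit-variance complex Gaussian k-space noise with the layout of `y`.
#' @keywords internal
kspace_noise <- function(y, seed) {
  with_seed(seed, {
    e <- y
    for (n in seq_along(e$y)) {
      ln <- length(e$y[[n]])
      e$y[[n]] <- array(complex(real = stats::rnorm(ln, 0, 1 / sqrt(2)),
                                imaginary = stats::rnorm(ln, 0, 1 / sqrt(2))),
                        dim(e$y[[n]]))
    }
    e
  })
}

#' Synthesize multi-coil k-space with SNR-calibrated noise
#'
#' Runs the forward model and adds i.i.d. complex Gaussian noise whose
#' variance is calibrated operationally so that an uncorrected reconstruction
#' of motion-free, B0-free data from the same phantom attains
#' `target_snr_db` (whole-FOV SNR against the ground-truth image):
#' the motion-free data are reconstructed once to measure the noise-free error
#' floor, the unit-variance noise realization that will be added is
#' reconstructed once to measure its image-domain power, and the noise
#' standard deviation is solved from the two. `target_snr_db = Inf` returns
#' the noise-free forward model bitwise.
#'
#' @inheritParams forward_model
#' @param target_snr_db target SNR in dB (`Inf`: no noise)
#' @param seed seed of the added noise realization
#' @param cg_iters CG iterations of the calibration reconstructions
#' @return a [kspace_data()] object; attributes `sigma` (per-sample complex
#'   noise SD) and `calibration` (error floor, noise gain, target) document
#'   the calibration
#' @export
synthesize_kspace <- function(x, trace, lc, S, seg, TE, target_snr_db = Inf,
                              seed = 1L, cg_iters = 15) {
  v <- as_vol(x)
  y <- forward_model(x, trace, lc, S, seg, TE)
  if (!is.finite(target_snr_db)) return(y)
  motion_free <- all(unclass(trace) == 0) && is.null(lc)
  y0 <- if (motion_free) y else
    forward_model(x, identity_trace(seg$n_shots), NULL, S, seg, TE)
  x0 <- reconstruct(y0, S, mode = "uncorrected",
                    cfg = recon_config(cg_iters = cg_iters))$image$data
  sig_pow <- mean(Mod(v$data)^2)
  err_floor <- mean(Mod(x0 - v$data)^2)
  err_target <- sig_pow / 10^(target_snr_db / 10)
  if (err_target <= err_floor)
    stop(sprintf(paste0("target SNR %.1f dB unreachable: the noise-free ",
                        "reconstruction error floor is %.1f dB"),
                 target_snr_db, 10 * log10(sig_pow / err_floor)), call. = FALSE)
  e <- kspace_noise(y, seed)
  # measure the image-domain response to this noise draw as a perturbation of
  # the reconstruction (not alone: the iterative solve filters a pure-noise
  # input differently than noise riding on signal)
  e_alone <- e
  e_alone$seg <- y0$seg
  g0 <- mean(Mod(reconstruct(e_alone, S, mode = "uncorrected",
                             cfg = recon_config(cg_iters = cg_iters))$image$data)^2)
  sigma1 <- sqrt((err_target - err_floor) / g0)
  yp <- y0
  for (n in seq_along(yp$y)) yp$y[[n]] <- yp$y[[n]] + sigma1 * e$y[[n]]
  xp <- reconstruct(yp, S, mode = "uncorrected",
                    cfg = recon_config(cg_iters = cg_iters))$image$data
  noise_gain <- mean(Mod(xp - x0)^2) / sigma1^2
  sigma <- sqrt((err_target - err_floor) / noise_gain)
  for (n in seq_along(y$y)) y$y[[n]] <- y$y[[n]] + sigma * e$y[[n]]
  attr(y, "sigma") <- sigma
  attr(y, "calibration") <- list(target_snr_db = target_snr_db,
                                 err_floor = err_floor,
                                 noise_gain = noise_gain,
                                 signal_power = sig_pow)
  y
}
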