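# Synthetic-data generator: phantom, coils, ground-truth LC maps, motion
# trace, SNR-calibrated k-space.

spec24 <- simulation_spec(shape = c(24, 24, 24), spacing_mm = c(4, 4, 4),
                          n_coils = 4, n_shots = 8, n_poses = 3,
                          target_snr_db = 30, seed = 5)

test_that("phantom generation is deterministic and honours the boundary margin", {
  a <- make_phantom(spec24)
  b <- make_phantom(spec24)
  expect_identical(a$data, b$data)
  expect_true(all(a$data[1:3, , ] == 0))     # 3-voxel margin at this grid size
  expect_true(all(a$data[, 1:3, ] == 0))
  expect_true(all(a$data[, , 22:24] == 0))
})

test_that("default phantom has a plausible support and a full 8-voxel margin", {
  spec <- simulation_spec()                      # default 64^3 design
  x <- make_phantom(spec)
  support <- mean(Mod(x$data) > 0.01 * max(Mod(x$data)))
  shutter_equiv <- support / (pi / 4)
  expect_gt(shutter_equiv, 0.2)
  expect_lt(shutter_equiv, 0.6)
  expect_true(all(x$data[c(1:8, 57:64), , ] == 0))
  expect_true(all(x$data[, c(1:8, 57:64), ] == 0))
  expect_true(all(x$data[, , c(1:8, 57:64)] == 0))
})

test_that("coil maps are smooth, unit for one coil, and jointly cover the head", {
  expect_equal(make_coil_maps(simulation_spec(shape = c(16, 16, 16), n_coils = 1))$data,
               array(1 + 0i, c(16, 16, 16, 1)))
  spec <- simulation_spec(shape = c(24, 24, 24), n_coils = 32, seed = 2)
  S <- make_coil_maps(spec)
  x <- make_phantom(spec)
  rss <- sqrt(apply(Mod(S$data)^2, 1:3, sum))
  expect_true(all(rss[Mod(x$data) > 0] > 0))
  # smoothness: largest voxel-to-voxel change small relative to the peak
  for (c in c(1, 17)) {
    sc <- S$data[, , , c]
    n <- dim(sc)
    step <- max(Mod(sc[-1, , ] - sc[-n[1], , ]),
                Mod(sc[, -1, ] - sc[, -n[2], ]),
                Mod(sc[, , -1] - sc[, , -n[3]]))
    expect_lt(step / max(Mod(sc)), 0.15)
  }
})

test_that("ground-truth LC maps are bounded, supported, and antisymmetric off-blob", {
  spec <- simulation_spec(shape = c(32, 32, 32), seed = 3)
  lc <- make_gt_lcmaps(spec)
  x <- make_phantom(spec)
  expect_lte(max(abs(lc$dpitch), abs(lc$droll)), 10)
  expect_true(all(lc$dpitch[Mod(x$data) == 0 & abs(lc$dpitch) > 0] == 0) ||
                all(abs(lc$dpitch[g <- Mod(x$data) == 0]) == 0))
  # mirror antisymmetry of dpitch in AP, away from the localized lobes
  d <- dim(lc$dpitch)
  ctr <- d %/% 2 + 1
  blobs <- attr(lc, "blobs")
  u <- lapply(1:3, function(ax) b0moco:::centered_coord(d[ax]) / (d[ax] / 2))
  near_blob <- array(FALSE, d)
  for (k in seq_len(nrow(blobs))) {
    r2 <- outer(outer((u[[1]] - blobs[k, 1])^2, (u[[2]] - blobs[k, 2])^2, "+"),
                (u[[3]] - blobs[k, 3])^2, "+")
    near_blob <- near_blob | (r2 < (2.2 * blobs[k, "radius"])^2)
    # include the AP mirror of each lobe
    r2m <- outer(outer((u[[1]] - blobs[k, 1])^2, (u[[2]] + blobs[k, 2])^2, "+"),
                 (u[[3]] - blobs[k, 3])^2, "+")
    near_blob <- near_blob | (r2m < (2.2 * blobs[k, "radius"])^2)
  }
  iy <- 2:d[2]
  miry <- 2 * ctr[2] - iy
  dp <- lc$dpitch
  asym <- abs(dp[, iy, ] + dp[, miry, ])
  ok <- !(near_blob[, iy, ] | near_blob[, miry, ])
  expect_lt(max(asym[ok]), 0.35 * max(abs(dp)))
})

test_that("motion traces respect ranges, block structure and drift", {
  spec <- simulation_spec(n_shots = 128, n_poses = 13, seed = 4)
  tr <- make_motion_trace(spec)
  expect_equal(nrow(tr), 128)
  expect_true(all(abs(unclass(tr)[, 1:3]) <= 5))
  expect_true(all(abs(unclass(tr)[, 4:6]) <= 7.5))
  blocks <- attr(tr, "pose_block")
  sizes <- table(blocks)
  expect_equal(length(sizes), 13L)
  expect_lte(diff(range(sizes)), 1)
  expect_true(all(unclass(tr)[blocks == 1, ] == 0))  # neutral start (gauge)
  # geometric drift toward neutral inside a block
  b2 <- which(blocks == 2)
  p <- unclass(tr)[b2, 4]
  expect_equal(p[-1] / p[-length(p)], rep(1 - spec$drift_fraction, length(p) - 1),
               tolerance = 1e-12)
  # drift_fraction = 0 gives a piecewise-constant trace
  spec0 <- simulation_spec(n_shots = 12, n_poses = 3, drift_fraction = 0, seed = 4)
  tr0 <- make_motion_trace(spec0)
  for (b in unique(attr(tr0, "pose_block"))) {
    rows <- unclass(tr0)[attr(tr0, "pose_block") == b, , drop = FALSE]
    expect_equal(max(apply(rows, 2, function(v) diff(range(v)))), 0)
  }
})

test_that("noise-free synthesis equals the forward model bitwise", {
  spec <- simulation_spec(shape = c(16, 16, 16), n_coils = 2, n_shots = 4,
                          n_poses = 2, target_snr_db = Inf, seed = 6,
                          spacing_mm = c(4, 4, 4))
  x <- make_phantom(spec)
  S <- make_coil_maps(spec)
  tr <- make_motion_trace(spec)
  seg <- generate_disorder(16, 16, 4, seed = 6)
  y1 <- synthesize_kspace(x, tr, NULL, S, seg, spec$TE, Inf, seed = 6)
  y2 <- forward_model(x, tr, NULL, S, seg, spec$TE)
  expect_identical(y1$y, y2$y)
})

test_that("the same seed reproduces the same noise realization", {
  spec <- spec24
  x <- make_phantom(spec)
  S <- make_coil_maps(spec)
  seg <- generate_disorder(24, 24, 8, seed = 5)
  tr <- identity_trace(8)
  y1 <- synthesize_kspace(x, tr, NULL, S, seg, spec$TE, 30, seed = 9)
  y2 <- synthesize_kspace(x, tr, NULL, S, seg, spec$TE, 30, seed = 9)
  expect_identical(y1$y, y2$y)
  y3 <- synthesize_kspace(x, tr, NULL, S, seg, spec$TE, 30, seed = 10)
  expect_false(identical(y1$y, y3$y))
})

test_that("SNR calibration is self-consistent across seeds", {
  spec <- simulation_spec(shape = c(24, 24, 24), spacing_mm = c(4, 4, 4),
                          n_coils = 4, n_shots = 8, n_poses = 3,
                          target_snr_db = 25, seed = 1)
  x <- make_phantom(spec)
  S <- make_coil_maps(spec)
  seg <- generate_disorder(24, 24, 8, seed = 1)
  tr <- identity_trace(8)
  for (sd in 1:5) {
    y <- synthesize_kspace(x, tr, NULL, S, seg, spec$TE, 25, seed = sd)
    rec <- reconstruct(y, S, mode = "uncorrected", cfg = recon_config(cg_iters = 15))
    expect_lt(abs(snr_db(rec$image, x) - 25), 0.5)
  }
})
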