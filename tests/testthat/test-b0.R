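# Pose-dependent B0 model: linear frequency field, echo-time phase operator,
# field-map extraction and the voxelized LC fit.

test_that("the frequency field is linear in the angles with no zeroth-order term", {
  d <- c(8, 8, 8)
  lc <- rand_lc(d, seed = 1)
  expect_equal(taylor_frequency_field(lc, 0, 0)$field, array(0, d))
  expect_equal(taylor_frequency_field(lc, 1, 0)$field, lc$dpitch)
  expect_equal(taylor_frequency_field(lc, 0, 1)$field, lc$droll)
  f1 <- taylor_frequency_field(lc, 2.5, -1)$field
  f2 <- taylor_frequency_field(lc, -1.5, 4)$field
  f12 <- taylor_frequency_field(lc, 1, 3)$field
  expect_equal(f1 + f2, f12, tolerance = 1e-12)
})

test_that("the echo-time phase factor has unit modulus and the documented sign", {
  d <- c(6, 6, 6)
  expect_equal(phase_operator(array(0, d), 0.005), array(1 + 0i, d))
  # 100 Hz at TE = 5 ms is half a cycle: phase -1
  f <- array(0, d); f[3, 3, 3] <- 100
  p <- phase_operator(f, 0.005)
  expect_equal(p[3, 3, 3], -1 + 0i, tolerance = 1e-12)
  set.seed(2)
  pr <- phase_operator(array(rnorm(prod(d), 0, 50), d), 0.005)
  expect_equal(Mod(pr), array(1, d), tolerance = 1e-12)
  expect_error(phase_operator(f, 0), "TE")
  expect_error(phase_operator(f, -1), "TE")
})

test_that("field extraction round-trips the phase operator with positive sign", {
  d <- c(12, 12, 12)
  set.seed(3)
  mag <- array(0, d)
  mag[3:10, 3:10, 3:10] <- 1 + runif(8^3)
  ref <- mag * exp(1i * 0.3)
  # uniform 40 Hz offset applied through the model's own phase term
  moved <- ref * phase_operator(array(40, d), 0.005)
  fm <- extract_field_map(ref, moved, 0.005)
  expect_equal(mean(fm$field[fm$mask]), 40, tolerance = 1e-6)
  expect_true(all(abs(fm$field[fm$mask] - 40) < 1e-6))
  # zero-difference case
  fm0 <- extract_field_map(ref, ref, 0.005)
  expect_equal(max(abs(fm0$field[fm0$mask])), 0, tolerance = 1e-12)
})

test_that("a phase ramp wrapping several times across the mask is recovered", {
  d <- c(24, 24, 8)
  u <- b0moco:::centered_coord(24)
  ramp_hz <- array(rep(12 * u, times = 24 * 8), d)        # +-138 Hz across LR
  mag <- array(0, d)
  mag[3:22, 3:22, 2:7] <- 1
  ctr <- exp(-(outer(u^2, u^2, "+")) / 200)               # quality peak at center
  mag <- mag * array(rep(ctr, 8), d) + 0
  ref <- mag + 0i
  moved <- ref * phase_operator(ramp_hz, 0.005)           # |phase| up to 4.3 rad
  fm <- extract_field_map(ref, moved, 0.005)
  expect_lt(max(abs(fm$field[fm$mask] - ramp_hz[fm$mask])), 1)
})

test_that("noise-free two-pose LC fit is exact and the design errors are named", {
  d <- c(8, 8, 8)
  lc <- rand_lc(d, seed = 4)
  fs <- list(taylor_frequency_field(lc, 1, 0), taylor_frequency_field(lc, 0, 1))
  fit <- fit_lc_maps(fs, rbind(c(1, 0), c(0, 1)))
  expect_equal(fit$dpitch, lc$dpitch, tolerance = 1e-12)
  expect_equal(fit$droll, lc$droll, tolerance = 1e-12)
  expect_equal(max(attr(fit, "mae"), na.rm = TRUE), 0, tolerance = 1e-12)
  expect_error(fit_lc_maps(fs, rbind(c(0, 0), c(0, 0))), "singular")
  expect_error(fit_lc_maps(fs, rbind(c(0, 1), c(0, 2))), "pitch")
  expect_error(fit_lc_maps(fs, rbind(c(1, 0), c(2, 0))), "roll")
  expect_error(fit_lc_maps(fs, rbind(c(1, 1), c(2, 2))), "collinear")
})

test_that("multi-pose noisy LC fit matches a per-voxel regression oracle", {
  d <- c(6, 6, 6)
  lc <- rand_lc(d, seed = 5, sd = 4)
  set.seed(6)
  angles <- cbind(runif(8, -10, 10), runif(8, -10, 10))
  fields <- lapply(seq_len(8), function(n) {
    taylor_frequency_field(lc, angles[n, 1], angles[n, 2])$field +
      array(rnorm(prod(d), 0, 1), d)
  })
  fit <- fit_lc_maps(fields, angles)
  # independent oracle: stats::lm voxel by voxel on a sample of voxels
  set.seed(7)
  vox <- sample(prod(d), 25)
  sigma2 <- solve(crossprod(angles))      # per-unit-noise parameter covariance
  for (v in vox) {
    yv <- vapply(fields, function(f) f[v], numeric(1))
    co <- coef(stats::lm(yv ~ 0 + angles))
    expect_equal(unname(co[1]), fit$dpitch[v], tolerance = 1e-8)
    expect_equal(unname(co[2]), fit$droll[v], tolerance = 1e-8)
    expect_lt(abs(fit$dpitch[v] - lc$dpitch[v]), 3 * sqrt(sigma2[1, 1]) + 1e-9)
    expect_lt(abs(fit$droll[v] - lc$droll[v]), 3 * sqrt(sigma2[2, 2]) + 1e-9)
  }
})

test_that("the fit is equivariant under pose permutation", {
  d <- c(6, 6, 6)
  lc <- rand_lc(d, seed = 8)
  set.seed(9)
  angles <- cbind(runif(5, -8, 8), runif(5, -8, 8))
  fields <- lapply(seq_len(5), function(n)
    taylor_frequency_field(lc, angles[n, 1], angles[n, 2])$field)
  perm <- c(3, 1, 5, 2, 4)
  f1 <- fit_lc_maps(fields, angles)
  f2 <- fit_lc_maps(fields[perm], angles[perm, ])
  expect_equal(f1$dpitch, f2$dpitch, tolerance = 1e-10)
  expect_equal(f1$droll, f2$droll, tolerance = 1e-10)
})

test_that("end-to-end: fields synthesized from poses round-trip through extraction and fit", {
  d <- c(16, 16, 16)
  spec <- simulation_spec(shape = d, n_coils = 1, n_shots = 4, n_poses = 2,
                          target_snr_db = Inf, seed = 10)
  ref <- make_phantom(spec)
  lcgt <- make_gt_lcmaps(spec)
  set.seed(11)
  angles <- cbind(runif(6, -10, 10), runif(6, -10, 10))
  fields <- lapply(seq_len(6), function(n) {
    om <- taylor_frequency_field(lcgt, angles[n, 1], angles[n, 2])
    moved <- ref$data * phase_operator(om, spec$TE)
    extract_field_map(ref, moved, spec$TE)
  })
  fit <- fit_lc_maps(fields, angles)
  m <- attr(fit, "mask")
  expect_gt(cor(fit$dpitch[m], lcgt$dpitch[m]), 0.99)
  expect_gt(cor(fit$droll[m], lcgt$droll[m]), 0.99)
})
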