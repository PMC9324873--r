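# Encoding-chain building blocks: rigid transform, FFT convention, forward
# model and its adjoint.

test_that("rigid transform is the identity for a zero motion state", {
  x <- rand_cvol(c(12, 12, 12))
  expect_identical(rigid_transform(x, motion_state()), x)
})

test_that("rigid transform is unitary and invertible over the motion range", {
  x <- rand_cvol(c(16, 16, 16), seed = 2)
  set.seed(4)
  for (k in 1:6) {
    z <- c(runif(3, -10, 10), runif(3, -15, 15))
    y <- rigid_transform(x, z)
    expect_lt(abs(sqrt(sum(Mod(y)^2) / sum(Mod(x)^2)) - 1), 1e-3)
    back <- rigid_transform(y, z, "inverse")
    expect_lt(relerr(back, x), 1e-6)
  }
})

test_that("rotations relocate a point mass as the rotation-matrix oracle predicts", {
  d <- c(16, 16, 16)
  ctr <- d %/% 2 + 1
  # independent coordinate oracle: 3x3 matrix built from first principles
  oracle <- function(p, ang_deg, axis) {
    t <- ang_deg * pi / 180
    R <- switch(axis,
      x = matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3),
      y = matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3),
      z = matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3))
    as.vector(R %*% p)
  }
  cases <- list(list(z = motion_state(r_yaw = 90), axis = "z", which = 6),
                list(z = motion_state(r_pitch = 90), axis = "x", which = 4),
                list(z = motion_state(r_roll = 90), axis = "y", which = 5))
  for (cs in cases) {
    p <- c(3, 1, -4)
    x <- array(0i, d)
    x[ctr[1] + p[1], ctr[2] + p[2], ctr[3] + p[3]] <- 1
    y <- rigid_transform(x, cs$z)
    peak <- which(Mod(y) == max(Mod(y)), arr.ind = TRUE)[1, ]
    expect_equal(unname(peak - ctr), round(oracle(p, 90, cs$axis)),
                 info = cs$axis)
  }
})

test_that("forward and inverse transforms compose to the identity", {
  x <- blocky_object()
  z <- c(1.3, -2.1, 0.4, 5, -3, 7)
  expect_lt(relerr(rigid_transform(rigid_transform(x, z), z, "inverse"), x), 1e-7)
})

test_that("centered orthonormal FFT satisfies Parseval exactly", {
  x <- rand_cvol(c(8, 10, 12), seed = 5)
  X <- b0moco:::cfft3(x)
  expect_equal(sum(Mod(X)^2), sum(Mod(x)^2), tolerance = 1e-12)
  expect_lt(relerr(b0moco:::cifft3(X), x), 1e-12)
})

test_that("forward model collapses to the Fourier transform in the trivial case", {
  d <- c(8, 8, 8)
  x <- rand_cvol(d, seed = 6)
  y <- forward_model(x, identity_trace(1), NULL, unit_coils(d), full_seg(8, 8), 0.005)
  X <- b0moco:::cfft3(x)
  dim(X) <- c(8, 64)
  expect_identical(y$y[[1]][, , 1], X)
})

test_that("all-zero LC maps reproduce the motion-only forward model bitwise", {
  d <- c(8, 8, 8)
  x <- rand_cvol(d, seed = 7)
  S <- rand_coils(d, 2, seed = 7)
  seg <- generate_disorder(8, 8, 4, seed = 1)
  set.seed(8)
  tr <- motion_trace(matrix(rnorm(24, 0, 3), 4, 6))
  y0 <- forward_model(x, tr, NULL, S, seg, 0.005)
  yz <- forward_model(x, tr, zero_lc_maps(d), S, seg, 0.005)
  expect_identical(y0$y, yz$y)
})

test_that("adjoint passes randomized dot-product tests with motion and LC maps", {
  d <- c(8, 8, 8)
  seg <- generate_disorder(8, 8, 4, seed = 2)
  S <- rand_coils(d, 2, seed = 9)
  lc <- rand_lc(d, seed = 9)
  for (k in 1:3) {
    set.seed(10 + k)
    tr <- motion_trace(matrix(rnorm(24, 0, 3), 4, 6))
    x <- rand_cvol(d, seed = 20 + k)
    Ex <- forward_model(x, tr, lc, S, seg, 0.005)
    yr <- Ex
    for (n in 1:4) yr$y[[n]] <- array(complex(real = rnorm(length(Ex$y[[n]])),
                                              imaginary = rnorm(length(Ex$y[[n]]))),
                                      dim(Ex$y[[n]]))
    Ehy <- adjoint_model(yr, tr, lc, S, seg, 0.005)
    gap <- Mod(b0moco:::kspace_dot(yr, Ex) - sum(Conj(Ehy) * x)) /
      sqrt(b0moco:::kspace_norm2(Ex) * sum(Mod(x)^2))
    expect_lt(gap, 1e-6)
  }
})

test_that("adjoint of zero k-space is the zero volume and full sampling inverts F", {
  d <- c(8, 8, 8)
  seg <- full_seg(8, 8)
  y <- forward_model(rand_cvol(d, seed = 30), identity_trace(1), NULL,
                     unit_coils(d), seg, 0.005)
  y0 <- y
  y0$y[[1]][] <- 0i
  expect_equal(adjoint_model(y0, identity_trace(1), NULL, unit_coils(d), seg, 0.005),
               array(0i, d))
  # unit coil + full sampling: E^H y = F^{-1} y
  back <- adjoint_model(y, identity_trace(1), NULL, unit_coils(d), seg, 0.005)
  Y <- y$y[[1]][, , 1]
  dim(Y) <- d
  expect_lt(relerr(back, b0moco:::cifft3(Y)), 1e-12)
})

test_that("mismatched grids and shot counts raise shape errors", {
  d <- c(8, 8, 8)
  x <- rand_cvol(d)
  S <- rand_coils(c(8, 8, 10), 2)
  expect_error(forward_model(x, identity_trace(1), NULL, S, full_seg(8, 8), 0.005),
               "grids disagree")
  expect_error(forward_model(x, identity_trace(2), NULL, rand_coils(d, 2),
                             full_seg(8, 8), 0.005), "shot count")
  expect_error(rigid_transform(x, c(1, NA, 0, 0, 0, 0)), "finite")
})

test_that("pose composition and inversion agree with the rotation matrices", {
  set.seed(31)
  for (k in 1:4) {
    za <- c(runif(3, -5, 5), runif(3, -10, 10))
    zb <- c(runif(3, -5, 5), runif(3, -10, 10))
    zc <- compose_pose(za, zb)
    expect_equal(rotation_matrix(zc), rotation_matrix(za) %*% rotation_matrix(zb),
                 tolerance = 1e-12)
    expect_equal(max(abs(compose_pose(za, invert_pose(za)))), 0, tolerance = 1e-12)
  }
})
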