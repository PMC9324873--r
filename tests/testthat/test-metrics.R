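# Image-quality metrics.

test_that("SNR matches its closed forms", {
  d <- c(12, 12, 12)
  gt <- rand_cvol(d, seed = 1)
  # error energy equal to signal energy -> 0 dB
  e <- rand_cvol(d, seed = 2)
  e <- e * sqrt(mean(Mod(gt)^2) / mean(Mod(e)^2))
  expect_equal(snr_db(gt + e, gt), 0, tolerance = 1e-10)
  # error power 1e-3 of signal power -> 30 dB
  e30 <- e * sqrt(1e-3)
  expect_equal(snr_db(gt + e30, gt), 30, tolerance = 1e-10)
  # exact match flagged as infinite, not an error
  s <- snr_db(gt, gt)
  expect_true(is.infinite(s) && isTRUE(attr(s, "exact")))
})

test_that("masked and whole-FOV SNR differ when error is concentrated outside the mask", {
  d <- c(12, 12, 12)
  gt <- rand_cvol(d, seed = 3)
  mask <- array(FALSE, d)
  mask[4:9, 4:9, 4:9] <- TRUE
  x <- gt
  x[!mask] <- x[!mask] + 0.5           # corrupt only outside the mask
  expect_gt(snr_db(x, gt, mask) - snr_db(x, gt), 20)
})

test_that("SNR decreases monotonically with added noise variance", {
  d <- c(12, 12, 12)
  gt <- rand_cvol(d, seed = 4)
  e <- rand_cvol(d, seed = 5)
  snrs <- vapply(c(0.01, 0.03, 0.1, 0.3, 1), function(s) snr_db(gt + s * e, gt),
                 numeric(1))
  expect_true(all(diff(snrs) < 0))
})

test_that("SSIM is 1 for identical images and collapses under voxel permutation", {
  spec <- simulation_spec(shape = c(24, 24, 24), spacing_mm = c(4, 4, 4),
                          n_coils = 1, seed = 6)
  x <- make_phantom(spec)$data
  expect_equal(ssim3d(x, x), 1, tolerance = 1e-12)
  set.seed(7)
  xp <- array(x[sample(length(x))], dim(x))     # identical marginal histogram
  expect_lt(ssim3d(xp, x), 0.2)
  # while mutual information also drops (sensitivity check on a different axis)
  expect_lt(mutual_information(xp, x), 0.5 * mutual_information(x, x))
})

test_that("artifact power is linear in error power and zero at equality", {
  d <- c(10, 10, 10)
  ref <- rand_cvol(d, seed = 8)
  e <- rand_cvol(d, seed = 9)
  expect_equal(artifact_power(ref, ref), 0)
  a1 <- artifact_power(ref + e, ref)
  a2 <- artifact_power(ref + sqrt(2) * e, ref)
  expect_equal(a2 / a1, 2, tolerance = 1e-10)
})

test_that("metrics are invariant to a global phase on both inputs", {
  spec <- simulation_spec(shape = c(16, 16, 16), n_coils = 1, seed = 10,
                          spacing_mm = c(4, 4, 4))
  gt <- make_phantom(spec)$data
  x <- gt + 0.05 * rand_cvol(dim(gt), seed = 11)
  ph <- exp(1i * 1.234)
  m1 <- similarity_suite(x, gt)
  m2 <- similarity_suite(x * ph, gt * ph)
  for (col in c("snr_db", "ssim", "mutual_information", "artifact_power"))
    expect_equal(m1[[col]], m2[[col]], tolerance = 1e-9, info = col)
})

test_that("constant images yield zero mutual information with a flag", {
  d <- c(8, 8, 8)
  cst <- array(1 + 0i, d)
  mi <- mutual_information(cst, rand_cvol(d, seed = 12))
  expect_equal(as.numeric(mi), 0)
  expect_true(isTRUE(attr(mi, "constant")))
})
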