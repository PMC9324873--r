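# Solver blocks: CG image update, Levenberg-Marquardt motion update,
# gradient-descent LC update, and reductions of the full driver.

dense_operator <- function(tr, lc, S, seg, TE, d) {
  V <- prod(d)
  nsamp <- sum(vapply(seg$shots, nrow, 1L)) * d[1] * dim(S$data)[4]
  E <- matrix(0i, nsamp, V)
  for (v in seq_len(V)) {
    e <- array(0i, d); e[v] <- 1
    E[, v] <- unlist(lapply(forward_model(e, tr, lc, S, seg, TE)$y, as.vector))
  }
  E
}

test_that("CG matches a densely assembled least-squares solution", {
  d <- c(8, 8, 1)
  seg <- split_seg(8, 1, 2)
  set.seed(7)
  S <- rand_coils(d, 2, seed = 7)
  lc <- rand_lc(d, seed = 7, sd = 5)
  tr <- motion_trace(rbind(rep(0, 6), c(1, -0.5, 0, 3, -2, 4)))
  xt <- rand_cvol(d, seed = 8)
  y <- forward_model(xt, tr, lc, S, seg, 0.005)
  E <- dense_operator(tr, lc, S, seg, 0.005, d)
  xd <- qr.solve(E, unlist(lapply(y$y, as.vector)))
  xc <- solve_image_cg(y, tr, lc, S, seg, 0.005, cg_iters = 300, cg_tol = 1e-13)
  expect_lt(relerr(as.vector(xc), xd), 1e-5)
})

test_that("trivial CG cases: identity encoding and zero data", {
  d <- c(8, 8, 8)
  x <- rand_cvol(d, seed = 9)
  seg <- full_seg(8, 8)
  y <- forward_model(x, identity_trace(1), NULL, unit_coils(d), seg, 0.005)
  xs <- solve_image_cg(y, identity_trace(1), NULL, unit_coils(d), seg, 0.005,
                       cg_iters = 2, cg_tol = 1e-10)
  expect_lt(relerr(xs, x), 1e-10)                 # E^H E = identity
  y0 <- y; y0$y[[1]][] <- 0i
  x0 <- solve_image_cg(y0, identity_trace(1), NULL, unit_coils(d), seg, 0.005)
  expect_equal(as.vector(x0), rep(0i, prod(d)))
})

test_that("CG residual norms are non-increasing", {
  d <- c(8, 8, 8)
  seg <- split_seg(8, 8, 3)
  S <- rand_coils(d, 2, seed = 10)
  set.seed(11)
  tr <- motion_trace(matrix(rnorm(18, 0, 2), 3, 6))
  y <- forward_model(rand_cvol(d, seed = 12), tr, NULL, S, seg, 0.005)
  xs <- solve_image_cg(y, tr, NULL, S, seg, 0.005, cg_iters = 25, cg_tol = 1e-14)
  res <- attr(xs, "residuals")
  expect_true(all(diff(res) <= 1e-12))
})

test_that("LM is stationary at the generating motion and recovers a pose from zero", {
  d <- c(16, 16, 16)
  x <- blocky_object(d)
  seg <- full_seg(16, 16)
  S <- unit_coils(d)
  zt <- c(1, -1, 0.5, 2, -1, 0.5)
  y <- forward_model(x, motion_trace(zt), NULL, S, seg, 0.005)
  cfg <- recon_config(lm_iters = 15, fix_first_shot = FALSE)
  # stationarity
  tr0 <- solve_motion_lm(y, x, motion_trace(zt), NULL, S, seg, 0.005, cfg)
  expect_lt(max(abs(unclass(tr0) - zt)), 1e-3)
  # noise-free registration from scratch
  tr1 <- solve_motion_lm(y, x, identity_trace(1), NULL, S, seg, 0.005, cfg)
  expect_lt(max(abs(unclass(tr1) - zt)), 0.1)
  # independent check: the recovered pose is a local minimum on a parameter grid
  cost_at <- function(z) {
    yt <- forward_model(x, motion_trace(z), NULL, S, seg, 0.005)
    sum(vapply(seq_along(yt$y),
               function(n) sum(Mod(yt$y[[n]] - y$y[[n]])^2), numeric(1)))
  }
  c0 <- cost_at(as.numeric(unclass(tr1)))
  for (j in 1:6) for (s in c(-0.1, 0.1)) {
    zp <- as.numeric(unclass(tr1)); zp[j] <- zp[j] + s
    expect_gt(cost_at(zp), c0)
  }
})

test_that("accepted LM steps never increase the per-shot cost", {
  d <- c(12, 12, 12)
  seg <- split_seg(12, 12, 4)
  S <- rand_coils(d, 2, seed = 13)
  x <- blocky_object(d)
  set.seed(14)
  tr_gt <- motion_trace(matrix(rnorm(24, 0, 2), 4, 6))
  y <- forward_model(x, tr_gt, NULL, S, seg, 0.005)
  cfg <- recon_config(lm_iters = 2, fix_first_shot = FALSE)
  tr <- identity_trace(4)
  ctx <- b0moco:::encode_ctx(S, seg, 0.005, c(1, 1, 1))
  prev <- vapply(1:4, function(n) sum(Mod(b0moco:::shot_forward_n(ctx, x, tr[n, ], NULL, n) -
                                            y$y[[n]])^2), numeric(1))
  for (it in 1:3) {
    tr <- solve_motion_lm(y, x, tr, NULL, S, seg, 0.005, cfg)
    cur <- attr(tr, "cost")
    expect_true(all(cur <= prev + 1e-9))
    prev <- cur
  }
})

test_that("the analytic LC gradient matches central finite differences", {
  d <- c(8, 8, 8)
  seg <- generate_disorder(8, 8, 4, seed = 1)
  S <- rand_coils(d, 2, seed = 15)
  set.seed(16)
  tr <- motion_trace(matrix(runif(24, -5, 5), 4, 6))
  xt <- rand_cvol(d, seed = 17)
  lc_gen <- rand_lc(d, seed = 18)
  y <- forward_model(xt, tr, lc_gen, S, seg, 0.005)
  lc0 <- rand_lc(d, seed = 19)
  ctx <- b0moco:::encode_ctx(S, seg, 0.005, c(1, 1, 1))
  g <- b0moco:::lc_gradient(ctx, y, xt, tr, lc0)
  eps <- 1e-4
  set.seed(20)
  for (v in sample(prod(d), 8)) {
    for (which in c("dpitch", "droll")) {
      lcp <- lc0; lcm <- lc0
      lcp[[which]][v] <- lcp[[which]][v] + eps
      lcm[[which]][v] <- lcm[[which]][v] - eps
      fd <- (b0moco:::lc_data_cost(ctx, y, xt, tr, lcp) -
               b0moco:::lc_data_cost(ctx, y, xt, tr, lcm)) / (2 * eps)
      an <- if (which == "dpitch") g$gp[v] else g$gr[v]
      expect_lt(abs(fd - an) / max(abs(fd), 1e-8), 1e-4)
    }
  }
})

test_that("LC descent is stationary at the truth and strictly decreases from zero", {
  d <- c(12, 12, 12)
  spec <- simulation_spec(shape = d, n_coils = 4, n_shots = 6, n_poses = 3,
                          target_snr_db = Inf, seed = 21, spacing_mm = c(3, 3, 3))
  x <- make_phantom(spec)
  S <- make_coil_maps(spec)
  lcgt <- make_gt_lcmaps(spec)
  tr <- make_motion_trace(spec)
  seg <- generate_disorder(12, 12, 6, seed = 21)
  y <- forward_model(x, tr, lcgt, S, seg, spec$TE)
  cfg <- recon_config(gd_iters = 1)
  # stationary point: starting at the generating maps barely moves
  at_gt <- solve_lc_gd(y, x$data, tr, lcgt, S, seg, spec$TE, cfg)
  expect_lt(max(abs(at_gt$dpitch - lcgt$dpitch), abs(at_gt$droll - lcgt$droll)), 0.05)
  # descent contract: one step from zero maps lowers the data cost
  ctx <- b0moco:::encode_ctx(S, seg, spec$TE, spec$spacing_mm)
  lc0 <- zero_lc_maps(d, spec$spacing_mm)
  c0 <- b0moco:::lc_data_cost(ctx, y, x$data, tr, lc0)
  lc1 <- solve_lc_gd(y, x$data, tr, lc0, S, seg, spec$TE, cfg)
  expect_lt(attr(lc1, "cost"), c0)
})

test_that("zero LC maps held fixed reproduce the motion-only solve bitwise", {
  d <- c(12, 12, 12)
  seg <- split_seg(12, 12, 3)
  S <- rand_coils(d, 2, seed = 22)
  set.seed(23)
  tr <- motion_trace(matrix(rnorm(18, 0, 2), 3, 6))
  y <- forward_model(blocky_object(d), tr, NULL, S, seg, 0.005)
  cfg <- recon_config(cg_iters = 8)
  a <- reconstruct(y, S, mode = "provided", cfg = cfg, trace_init = tr,
                   lc_init = NULL)
  b <- reconstruct(y, S, mode = "provided", cfg = cfg, trace_init = tr,
                   lc_init = zero_lc_maps(d))
  expect_identical(a$image$data, b$image$data)
})

test_that("reconstruction is deterministic", {
  d <- c(12, 12, 12)
  spec <- simulation_spec(shape = d, n_coils = 4, n_shots = 4, n_poses = 2,
                          target_snr_db = Inf, seed = 24, spacing_mm = c(3, 3, 3))
  x <- make_phantom(spec)
  S <- make_coil_maps(spec)
  seg <- generate_disorder(12, 12, 4, seed = 24)
  tr <- make_motion_trace(spec)
  y <- forward_model(x, tr, NULL, S, seg, spec$TE)
  cfg <- recon_config(levels = c(2, 1), outer_iters = c(3, 2))
  r1 <- reconstruct(y, S, mode = "moco", cfg = cfg)
  r2 <- reconstruct(y, S, mode = "moco", cfg = cfg)
  expect_identical(r1$image$data, r2$image$data)
  expect_identical(unclass(r1$trace), unclass(r2$trace))
})
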