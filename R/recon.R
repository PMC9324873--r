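# Joint alternating estimation of image, per-shot motion and LC maps:
#   image        -> conjugate gradient on the normal equations
#   motion z_n   -> per-shot Levenberg-Marquardt (6 rigid parameters)
#   LC maps d    -> gradient descent with a phase-wrapping stabilizer
# run over a two-level multiresolution schedule (k-space cropped between
# levels; motion copied, LC maps Fourier-interpolated).

#' Reconstruction configuration
#'
#' @param levels downsampling factor per resolution level, coarse to fine
#'   (default `c(2, 1)`: half resolution, then full)
#' @param outer_iters outer (alternation) iterations per level
#' @param cg_iters conjugate-gradient iterations for plain (non-alternating)
#'   image solves and the final polish
#' @param cg_iters_outer CG iterations per outer iteration (warm-started)
#' @param cg_tol relative residual tolerance for CG early exit
#' @param lm_iters Levenberg-Marquardt iterations per shot per outer iteration
#' @param lm_damping_init,lm_damping_up,lm_damping_down Marquardt damping:
#'   initial value, inflation on rejection, deflation on acceptance
#' @param lm_fd_step finite-difference step (degrees / mm) for the motion
#'   Jacobian
#' @param gd_iters gradient-descent steps on the LC maps per outer iteration
#' @param gd_step_init initial step length (`NULL`: scaled automatically from
#'   the first gradient)
#' @param gd_backtrack_factor,gd_max_backtracks backtracking line search
#' @param gd_step_max cap on the LC line-search step (`Inf`: uncapped); a
#'   finite cap keeps the LC maps from absorbing, in one outer iteration,
#'   phase structure that really belongs to still-unconverged motion
#' @param gd_delta_max largest change of any LC voxel per descent step, in
#'   Hz/degree (`Inf`: unbounded); bounds how fast the field model can move in
#'   physical units, so a descent direction computed against a still-wrong
#'   image cannot lock in a large wrong field in one jump
#' @param gd_lowpass_frac if finite, the LC gradient is low-pass filtered to
#'   this fraction of k-space at levels coarser than full resolution; the
#'   true coefficient maps are spatially smooth while motion-artifact
#'   residuals are not, so early iterations then move the maps only along
#'   their credible (smooth) component
#' @param lm_step_max trust region on the per-iteration motion update: a step
#'   whose rotation (degrees) or translation (mm) change exceeds this is
#'   scaled back onto the bound (`Inf`: unrestricted)
#' @param stabilizer_weight weight of the phase-wrapping stabilizer penalty
#' @param lm_phase_fixed evaluate the pose-dependent phase of each shot at its
#'   incoming pose during the motion update (the phase factor is lagged one
#'   outer iteration; the motion Jacobian is purely geometric)
#' @param gd_precondition use the diagonal curvature preconditioner for the
#'   LC gradient (plain gradient descent when `FALSE`)
#' @param lc_mask_frac LC updates are restricted to voxels whose current image
#'   magnitude exceeds this fraction of its robust (99th percentile) maximum
#'   (0 disables); where there is no signal the phase -- and hence the LC
#'   model -- is unobservable, and free voxels there only absorb artifacts
#' @param continuation initialize the motion+B0 solve by a continuation over
#'   pose magnitude at the coarsest level: the joint problem is solved on the
#'   mildest quasi-static segments first and stronger segments join one at a
#'   time, each registered with the field predicted by the current LC maps
#' @param lc_block_init after the warm-up, re-initialize the LC maps from
#'   low-pass field estimates of quasi-static shot segments (segment-wise CG
#'   reconstructions, unwrapped phase differences, voxelwise regression on
#'   the segment angles with an intercept) instead of descending from zero
#' @param b0_warmup outer iterations of the first (coarsest) level run
#'   motion-only before LC-map estimation starts; estimating the B0 model
#'   against a still motion-corrupted image lets it absorb artifacts it then
#'   locks in, so the maps join once the motion estimates have settled
#' @param fix_first_shot keep the first shot's motion at zero (fixes the global
#'   rigid gauge: any constant pose can be absorbed into the image)
#' @param outer_tol relative data-cost change below which a level exits early
#'   (0 disables; the default keeps a fixed iteration budget)
#' @param verbose print per-outer-iteration cost
#' @param seed recorded for provenance; the solver itself is deterministic
#' @return a list of class `recon_config`
#' @export
recon_config <- function(levels = c(2, 1), outer_iters = c(45, 15),
                         cg_iters = 12, cg_iters_outer = 4, cg_tol = 1e-6,
                         lm_iters = 1, lm_damping_init = 1e-2,
                         lm_damping_up = 10, lm_damping_down = 0.5,
                         lm_fd_step = 1e-3, lm_phase_fixed = FALSE,
                         gd_iters = 1, gd_step_init = NULL,
                         gd_backtrack_factor = 0.5, gd_max_backtracks = 20,
                         gd_step_max = Inf, gd_delta_max = Inf,
                         gd_lowpass_frac = Inf, lm_step_max = Inf,
                         stabilizer_weight = 10, b0_warmup = 0,
                         continuation = FALSE, lc_block_init = FALSE,
                         gd_precondition = FALSE, lc_mask_frac = 0.1,
                         fix_first_shot = TRUE, outer_tol = 0,
                         verbose = FALSE, seed = NULL) {
  stopifnot(length(levels) == length(outer_iters),
            all(outer_iters >= 1), all(levels >= 1),
            cg_iters >= 1, cg_iters_outer >= 1, cg_tol > 0,
            lm_iters >= 1, lm_damping_init > 0, lm_fd_step > 0,
            gd_iters >= 1, gd_backtrack_factor > 0, gd_backtrack_factor < 1,
            stabilizer_weight >= 0, b0_warmup >= 0, outer_tol >= 0,
            gd_step_max > 0, gd_delta_max > 0, gd_lowpass_frac > 0,
            lm_step_max > 0,
            lc_mask_frac >= 0, lc_mask_frac < 1)
  structure(as.list(environment()), class = "recon_config")
}

# ---- image update (conjugate gradient) -------------------------------------

#' @keywords internal
normal_op <- function(ctx, x, trace, lc) {
  acc <- array(0i, ctx$d)
  for (n in seq_len(ctx$seg$n_shots)) {
    z <- trace[n, ]
    acc <- acc + shot_adjoint_n(ctx, shot_forward_n(ctx, x, z, lc, n), z, lc, n)
  }
  acc
}

#' Conjugate-gradient image solve
#'
#' Solves the normal equations `E^H E x = E^H y` of the encoding model with
#' motion and LC maps held fixed. The normal-equation residual norm is
#' non-increasing across iterations.
#'
#' @inheritParams adjoint_model
#' @param cg_iters maximum iterations
#' @param cg_tol relative residual tolerance
#' @param x0 warm start (complex array), `NULL` for zero
#' @param ctx precomputed encoding context (internal use)
#' @return complex 3D array with attribute `residuals` (per-iteration relative
#'   normal-equation residual norms)
#' @export
solve_image_cg <- function(y, trace, lc, S, seg, TE, cg_iters = 12,
                           cg_tol = 1e-6, x0 = NULL, ctx = NULL) {
  if (is.null(ctx)) ctx <- encode_ctx(S, seg, TE, y$spacing)
  b <- array(0i, ctx$d)
  for (n in seq_len(seg$n_shots))
    b <- b + shot_adjoint_n(ctx, y$y[[n]], trace[n, ], lc, n)
  bnorm <- sqrt(sum(Mod(b)^2))
  if (bnorm == 0) {
    out <- array(0i, ctx$d); attr(out, "residuals") <- numeric(0); return(out)
  }
  if (is.null(x0)) {
    x <- array(0i, ctx$d)
    r <- b
  } else {
    x <- x0
    r <- b - normal_op(ctx, x, trace, lc)
  }
  p <- r
  rs <- sum(Mod(r)^2)
  hist <- numeric(0)
  for (it in seq_len(cg_iters)) {
    Ap <- normal_op(ctx, p, trace, lc)
    if (any(!is.finite(Re(Ap))))
      stop(sprintf("non-finite operator output at CG iteration %d", it), call. = FALSE)
    alpha <- rs / Re(sum(Conj(p) * Ap))
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(Mod(r)^2)
    hist <- c(hist, sqrt(rs_new) / bnorm)
    if (sqrt(rs_new) / bnorm < cg_tol) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  attr(x, "residuals") <- hist
  x
}

# ---- motion update (Levenberg-Marquardt) -----------------------------------

# One shot's LM refinement. Returns list(z, cost, lambda, frozen).
# With lm_phase_fixed the B0 phase is evaluated at the shot's incoming pose
# and held constant while the rigid parameters move: only the geometric
# dependence enters the Jacobian, so errors still present in the LC maps
# cannot steer the pose update through the (much more sensitive) phase term.
#' @keywords internal
lm_shot <- function(ctx, yv, x, z, lc, n, cfg, lambda) {
  if (isTRUE(cfg$lm_phase_fixed) && !is.null(lc)) {
    x <- x * shot_phase(lc, z, ctx$TE)
    lc <- NULL
  }
  cache <- shot_forward_cached(ctx, x, z, lc, n)
  r0 <- as.vector(cache$y) - yv
  c0 <- sum(Mod(r0)^2)
  frozen <- FALSE
  for (it in seq_len(cfg$lm_iters)) {
    J <- matrix(0i, length(r0), 6L)
    for (j in 1:6) {
      yj <- shot_forward_stage(ctx, cache, x, lc, n, j, z[j] + cfg$lm_fd_step)
      J[, j] <- (as.vector(yj) - yv - r0) / cfg$lm_fd_step
    }
    if (any(!is.finite(Re(J))) || any(!is.finite(Im(J)))) { frozen <- TRUE; break }
    H <- Re(crossprod(Conj(J), J))
    g <- Re(crossprod(Conj(J), r0))
    ridge <- 1e-12 * max(diag(H), 1e-300) * diag(6)
    accepted <- FALSE
    repeat {
      step <- tryCatch(-solve(H + lambda * diag(diag(H)) + ridge, g),
                       error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) {
        lambda <- lambda * cfg$lm_damping_up
        if (lambda > 1e10) break
        next
      }
      step <- as.vector(step)
      if (is.finite(cfg$lm_step_max)) {
        sc <- max(abs(step)) / cfg$lm_step_max
        if (sc > 1) step <- step / sc
      }
      zt <- z + step
      cache_t <- shot_forward_cached(ctx, x, zt, lc, n)
      rt <- as.vector(cache_t$y) - yv
      ct <- sum(Mod(rt)^2)
      if (is.finite(ct) && ct < c0) {
        z <- zt; r0 <- rt; c0 <- ct; cache <- cache_t
        lambda <- lambda * cfg$lm_damping_down
        accepted <- TRUE
        break
      }
      lambda <- lambda * cfg$lm_damping_up
      if (lambda > 1e10) break
    }
    if (!accepted) break
  }
  list(z = z, cost = c0, lambda = lambda, frozen = frozen)
}

#' Per-shot Levenberg-Marquardt motion update
#'
#' Refines each shot's six rigid parameters against the shot's own k-space
#' samples, with the image and LC maps fixed. The shot subproblems are
#' independent; accepted steps never increase a shot's data-consistency cost
#' (the Marquardt damping is inflated until they do not). When LC maps are
#' given, the pose-dependent phase is part of the residual, so its dependence
#' on the trial rotations is included in the (finite-difference) Jacobian.
#'
#' @inheritParams adjoint_model
#' @param x current image estimate (complex array)
#' @param cfg a [recon_config()]
#' @param lambda per-shot Marquardt damping carried across calls (`NULL`:
#'   `cfg$lm_damping_init`)
#' @param ctx precomputed encoding context (internal use)
#' @return updated [motion_trace()] with attributes `cost` (per-shot),
#'   `lambda`, and `frozen` (shots whose Jacobian was non-finite)
#' @export
solve_motion_lm <- function(y, x, trace, lc, S, seg, TE, cfg = recon_config(),
                            lambda = NULL, ctx = NULL) {
  if (is.null(ctx)) ctx <- encode_ctx(S, seg, TE, y$spacing)
  ns <- seg$n_shots
  if (is.null(lambda)) lambda <- rep(cfg$lm_damping_init, ns)
  cost <- numeric(ns)
  frozen <- logical(ns)
  out <- unclass(trace)
  for (n in seq_len(ns)) {
    if (length(ctx$cols[[n]]) == 0L) next
    if (cfg$fix_first_shot && n == 1L) {
      cost[n] <- sum(Mod(as.vector(shot_forward_n(ctx, x, out[n, ], lc, n)) -
                           as.vector(y$y[[n]]))^2)
      next
    }
    fit <- lm_shot(ctx, as.vector(y$y[[n]]), x, out[n, ], lc, n, cfg, lambda[n])
    out[n, ] <- fit$z
    cost[n] <- fit$cost
    lambda[n] <- fit$lambda
    frozen[n] <- fit$frozen
  }
  res <- motion_trace(out)
  attr(res, "cost") <- cost
  attr(res, "lambda") <- lambda
  attr(res, "frozen") <- frozen
  res
}

# ---- LC-map update (gradient descent) --------------------------------------

# Low-pass a real volume by cropping its centered spectrum to a fraction of
# each axis (used to restrict early LC updates to smooth structure).
#' @keywords internal
lowpass_real <- function(g, frac) {
  d <- dim(g)
  keep <- pmax(2L, pmin(d, 2L * ceiling(frac * d / 2)))
  G <- cfft3(g + 0i)
  Gc <- array(0i, d)
  i1 <- center_block(d[1], keep[1]); i2 <- center_block(d[2], keep[2])
  i3 <- center_block(d[3], keep[3])
  Gc[i1, i2, i3] <- G[i1, i2, i3]
  Re(cifft3(Gc))
}

# Stabilizer: smooth hinge penalty on the per-voxel phase excursion
# 2*pi*TE*theta_max*|d| beyond pi, discouraging the optimization from crossing
# the 2*pi-periodic saddle points of the exponential phase term.
#' @keywords internal
stabilizer <- function(lc, TE, thmax, weight) {
  ap <- 2 * pi * TE * thmax[1] * abs(lc$dpitch)
  ar <- 2 * pi * TE * thmax[2] * abs(lc$droll)
  hp <- pmax(ap - pi, 0)
  hr <- pmax(ar - pi, 0)
  list(cost = weight * (sum(hp^2) + sum(hr^2)),
       gp = weight * 2 * hp * (2 * pi * TE * thmax[1]) * sign(lc$dpitch),
       gr = weight * 2 * hr * (2 * pi * TE * thmax[2]) * sign(lc$droll))
}

#' @keywords internal
lc_data_cost <- function(ctx, y, x, trace, lc) {
  cost <- 0
  for (n in seq_len(ctx$seg$n_shots)) {
    if (length(ctx$cols[[n]]) == 0L) next
    cost <- cost + sum(Mod(shot_forward_n(ctx, x, trace[n, ], lc, n) - y$y[[n]])^2)
  }
  cost
}

# Analytic gradient of the data-consistency cost with respect to the two LC
# volumes.  With u_n = P_n x (head frame) and b_n the residual back-projected
# through A^H, F^H, S^H and T^H (phase step excluded), the chain rule through
# the exponential phase gives
#   dC/ddpitch(v) = 4*pi*TE * sum_n theta_n,pitch * Im( conj(b_n(v)) u_n(v) )
# and the analogous expression with theta_n,roll for droll.  Validated against
# central finite differences in the test suite.
#' @keywords internal
lc_gradient <- function(ctx, y, x, trace, lc) {
  d <- ctx$d
  gp <- array(0, d); gr <- array(0, d)
  cost <- 0
  for (n in seq_len(ctx$seg$n_shots)) {
    if (length(ctx$cols[[n]]) == 0L) next
    z <- trace[n, ]
    if (z[4] == 0 && z[5] == 0) {
      cost <- cost + sum(Mod(shot_forward_n(ctx, x, z, lc, n) - y$y[[n]])^2)
      next
    }
    rn <- shot_forward_n(ctx, x, z, lc, n) - y$y[[n]]
    cost <- cost + sum(Mod(rn)^2)
    bn <- shot_adjoint_n(ctx, rn, z, NULL, n)
    un <- x * shot_phase(lc, z, ctx$TE)
    t <- Im(Conj(bn) * un)
    gp <- gp + (4 * pi * ctx$TE * z[4]) * t
    gr <- gr + (4 * pi * ctx$TE * z[5]) * t
  }
  list(cost = cost, gp = gp, gr = gr)
}

#' Gradient-descent update of the LC maps
#'
#' Descends the data-consistency cost plus the phase-wrapping stabilizer with
#' respect to the two voxelized LC volumes, using the analytic chain-rule
#' gradient through the exponential phase term and a backtracking line search.
#' The combined objective is non-increasing per accepted step; if the line
#' search fails the step is skipped with a warning.
#'
#' @inheritParams solve_motion_lm
#' @param lc current LC maps (the starting point of the descent)
#' @param step line-search step carried across calls (`NULL`: scaled from the
#'   first gradient)
#' @return updated [lc_maps()] with attributes `cost` (data-consistency part at
#'   the returned point), `total_cost` (including stabilizer), `step`,
#'   `grad_norm`
#' @export
solve_lc_gd <- function(y, x, trace, lc, S, seg, TE, cfg = recon_config(),
                        step = NULL, ctx = NULL) {
  if (is.null(ctx)) ctx <- encode_ctx(S, seg, TE, y$spacing)
  thmax <- c(max(abs(trace[, 4])), max(abs(trace[, 5])))
  # diagonal (Jacobi) preconditioner: the data-term curvature at voxel v is
  # approximately sum_n (2 pi TE theta_n)^2 f_n |x(v)|^2 rss^2(v), with f_n the
  # shot's sampling fraction -- without it a single global step length is
  # dictated by the brightest voxels and the LC update crawls elsewhere
  V <- prod(ctx$d)
  rss2 <- array(0, ctx$d)
  for (c in seq_len(ctx$nc)) {
    sc <- S$data[, , , c, drop = FALSE]
    dim(sc) <- ctx$d
    rss2 <- rss2 + Mod(sc)^2
  }
  fn <- vapply(ctx$cols, length, 1L) * ctx$d[1] / V
  wp <- sum((2 * pi * TE * trace[, 4])^2 * fn)
  wr <- sum((2 * pi * TE * trace[, 5])^2 * fn)
  base <- Mod(x)^2 * rss2
  pre_p <- wp * base
  pre_r <- wr * base
  pre_p <- pre_p + 1e-3 * max(pre_p, 1e-300)
  pre_r <- pre_r + 1e-3 * max(pre_r, 1e-300)
  if (!isTRUE(cfg$gd_precondition)) { pre_p[] <- 1; pre_r[] <- 1 }
  lcmask <- if (cfg$lc_mask_frac > 0) {
    mg <- Mod(x)
    mg > cfg$lc_mask_frac * stats::quantile(mg, 0.99, names = FALSE)
  } else NULL
  grad_norm <- NA_real_
  dcost <- NA_real_
  for (it in seq_len(cfg$gd_iters)) {
    g <- lc_gradient(ctx, y, x, trace, lc)
    st <- stabilizer(lc, TE, thmax, cfg$stabilizer_weight)
    f0 <- g$cost + st$cost
    dcost <- g$cost
    gp <- (g$gp + st$gp) / pre_p
    gr <- (g$gr + st$gr) / pre_r
    if (!is.null(lcmask)) { gp[!lcmask] <- 0; gr[!lcmask] <- 0 }
    if (is.finite(cfg$gd_lowpass_frac) && cfg$gd_lowpass_frac < 1) {
      gp <- lowpass_real(gp, cfg$gd_lowpass_frac)
      gr <- lowpass_real(gr, cfg$gd_lowpass_frac)
      if (!is.null(lcmask)) { gp[!lcmask] <- 0; gr[!lcmask] <- 0 }
    }
    gn2 <- sum((g$gp + st$gp) * gp) + sum((g$gr + st$gr) * gr)  # g' P^-1 g
    grad_norm <- sqrt(sum((g$gp + st$gp)^2) + sum((g$gr + st$gr)^2))
    if (gn2 == 0) break
    # the preconditioner approximates half the Gauss-Newton curvature, so a
    # unit-order step is the natural start for the line search
    if (is.null(step)) step <- if (isTRUE(cfg$gd_precondition)) 0.5 else 0.5 * f0 / gn2
    step <- min(step, cfg$gd_step_max)
    if (is.finite(cfg$gd_delta_max)) {
      gmax <- max(abs(gp), abs(gr))
      if (gmax > 0) step <- min(step, cfg$gd_delta_max / gmax)
    }
    t <- step
    accepted <- FALSE
    best_ft <- Inf
    for (bt in seq_len(cfg$gd_max_backtracks)) {
      lct <- lc_maps(lc$dpitch - t * gp, lc$droll - t * gr, lc$spacing)
      dt <- lc_data_cost(ctx, y, x, trace, lct)
      stt <- stabilizer(lct, TE, thmax, cfg$stabilizer_weight)
      ft <- dt + stt$cost
      best_ft <- min(best_ft, ft)
      if (is.finite(ft) && ft < f0) {
        lc <- lct
        dcost <- dt
        step <- min(2 * t, cfg$gd_step_max)
        accepted <- TRUE
        break
      }
      t <- t * cfg$gd_backtrack_factor
    }
    if (!accepted) {
      # at a stationary point the line search cannot strictly decrease; only
      # warn when there was a decrease to be had
      if (is.finite(best_ft) && (f0 - best_ft) > 1e-10 * abs(f0))
        warning("LC line search failed; step skipped", call. = FALSE)
      break
    }
  }
  attr(lc, "cost") <- dcost
  attr(lc, "total_cost") <- if (is.na(dcost)) NA_real_ else
    dcost + stabilizer(lc, TE, thmax, cfg$stabilizer_weight)$cost
  attr(lc, "step") <- step
  attr(lc, "grad_norm") <- grad_norm
  lc
}

# ---- LC initialization from quasi-static segments --------------------------

# Coarse-level re-initialization of the LC maps from low-pass field estimates:
# shots are grouped into quasi-static segments (consecutive poses within
# jump_tol of each other -- the interleaved design makes these the pose
# blocks), each segment's k-space is reconstructed with a few warm-started CG
# iterations, the phase of each segment image relative to the current image
# is unwrapped and converted to a frequency field, low-passed, and regressed
# voxelwise (with an intercept absorbing the shared field) on the segment's
# (pitch, roll) angles.  The result replaces the LC maps as the starting
# point of the joint descent, which otherwise has to crawl out of the
# motion-biased valley by gradient steps alone.
#' @keywords internal
init_lc_from_segments <- function(ctx, y, S, trace, x, cfg, jump_tol = 0.5) {
  tr <- unclass(trace)
  ns <- nrow(tr)
  jump <- c(0, vapply(seq_len(ns - 1), function(n)
    max(abs(tr[n + 1, ] - tr[n, ])), numeric(1)))
  grp <- cumsum(jump > jump_tol) + 1L
  ngrp <- max(grp)
  if (ngrp < 3L) return(NULL)
  d <- ctx$d
  mag <- Mod(x)
  mask <- mag > 0.15 * stats::quantile(mag, 0.99, names = FALSE)
  fields <- vector("list", ngrp)
  theta <- matrix(0, ngrp, 2)
  for (g in seq_len(ngrp)) {
    shots <- which(grp == g)
    theta[g, ] <- colMeans(tr[shots, 4:5, drop = FALSE])
    # segment-only normal equations, warm-started from the shared image
    b <- array(0i, d)
    for (n in shots) b <- b + shot_adjoint_n(ctx, y$y[[n]], tr[n, ], NULL, n)
    xg <- x
    r <- b
    for (n in shots) {
      z <- tr[n, ]
      r <- r - shot_adjoint_n(ctx, shot_forward_n(ctx, xg, z, NULL, n), z, NULL, n)
    }
    p <- r
    rs <- sum(Mod(r)^2)
    for (it in seq_len(6)) {
      Ap <- array(0i, d)
      for (n in shots) {
        z <- tr[n, ]
        Ap <- Ap + shot_adjoint_n(ctx, shot_forward_n(ctx, p, z, NULL, n), z, NULL, n)
      }
      alpha <- rs / Re(sum(Conj(p) * Ap))
      if (!is.finite(alpha)) break
      xg <- xg + alpha * p
      r <- r - alpha * Ap
      rs_new <- sum(Mod(r)^2)
      p <- r + (rs_new / rs) * p
      rs <- rs_new
    }
    fm <- extract_field_map(x, xg, ctx$TE, mask = mask)
    f <- fm$field
    f[!fm$mask] <- 0
    fields[[g]] <- lowpass_real(f, 0.4)
  }
  # voxelwise LS with intercept: field_g = dp*thp_g + dr*thr_g + c
  A <- cbind(theta, 1)
  AtA <- crossprod(A)
  if (rcond(AtA) < 1e-10) return(NULL)
  Ai <- solve(AtA)
  b1 <- array(0, d); b2 <- array(0, d); b3 <- array(0, d)
  for (g in seq_len(ngrp)) {
    b1 <- b1 + A[g, 1] * fields[[g]]
    b2 <- b2 + A[g, 2] * fields[[g]]
    b3 <- b3 + A[g, 3] * fields[[g]]
  }
  dp <- Ai[1, 1] * b1 + Ai[1, 2] * b2 + Ai[1, 3] * b3
  dr <- Ai[2, 1] * b1 + Ai[2, 2] * b2 + Ai[2, 3] * b3
  dp[!mask] <- 0; dr[!mask] <- 0
  dp <- pmin(pmax(dp, -15), 15)
  dr <- pmin(pmax(dr, -15), 15)
  lc_maps(dp, dr, ctx$spacing)
}

# ---- continuation initialization ------------------------------------------

# Joint estimation over an increasing set of quasi-static segments, mildest
# pose first.  Weakly-displaced segments are almost free of pose-dependent
# phase, so image, motion and a first LC estimate are found on them reliably;
# each stronger segment is then registered with the field its angles predict
# from the current LC maps before joining the joint solve.  This walks the
# solver into the joint basin along the pose-magnitude direction instead of
# dropping it into the fully-corrupted problem at once.
#' @keywords internal
continuation_init <- function(ctx, y, S, cfg, jump_tol = 0.5) {
  seg <- ctx$seg
  ns <- seg$n_shots
  TE <- ctx$TE
  dd <- ctx$d
  cfgLM <- cfg
  cfgLM$fix_first_shot <- FALSE
  # 1) short motion-only pass to reveal the segment structure
  trace <- identity_trace(ns)
  xh <- NULL
  lambda <- NULL
  for (ou in seq_len(8)) {
    xh <- solve_image_cg(y, trace, NULL, S, seg, TE, cg_iters = cfg$cg_iters_outer,
                         x0 = xh, ctx = ctx)
    trace <- solve_motion_lm(y, xh, trace, NULL, S, seg, TE, cfgLM,
                             lambda = lambda, ctx = ctx)
    lambda <- attr(trace, "lambda")
  }
  trm <- unclass(trace)
  jump <- c(0, vapply(seq_len(ns - 1), function(n)
    max(abs(trm[n + 1, ] - trm[n, ])), numeric(1)))
  grp <- cumsum(jump > jump_tol) + 1L
  strength <- tapply(abs(trm[, 4]) + abs(trm[, 5]) + abs(trm[, 6]), grp, max)
  ord <- order(strength)
  # 2) incremental joint solve
  trace <- identity_trace(ns)
  lc <- zero_lc_maps(dd, ctx$spacing)
  xh <- NULL
  gstep <- NULL
  active <- integer(0)
  run_joint <- function(shots, n_out, xh, trace, lc, gstep) {
    lambda <- NULL
    segs <- structure(list(n_shots = length(shots), ny = seg$ny, nz = seg$nz,
                           seed = seg$seed, shots = seg$shots[shots]),
                      class = "shot_seg")
    ys <- kspace_data(y$y[shots], segs, y$TE, y$shape, y$spacing)
    for (ou in seq_len(n_out)) {
      b <- array(0i, dd)
      for (n in shots) b <- b + shot_adjoint_n(ctx, y$y[[n]], trace[n, ], lc, n)
      xx <- if (is.null(xh)) array(0i, dd) else xh
      r <- b
      for (n in shots) {
        z <- trace[n, ]
        r <- r - shot_adjoint_n(ctx, shot_forward_n(ctx, xx, z, lc, n), z, lc, n)
      }
      p <- r
      rs <- sum(Mod(r)^2)
      for (it in seq_len(cfg$cg_iters_outer)) {
        Ap <- array(0i, dd)
        for (n in shots) {
          z <- trace[n, ]
          Ap <- Ap + shot_adjoint_n(ctx, shot_forward_n(ctx, p, z, lc, n), z, lc, n)
        }
        a <- rs / Re(sum(Conj(p) * Ap))
        if (!is.finite(a)) break
        xx <- xx + a * p
        r <- r - a * Ap
        rsn <- sum(Mod(r)^2)
        p <- r + (rsn / rs) * p
        rs <- rsn
      }
      xh <- xx
      keep <- unclass(trace)
      tr2 <- solve_motion_lm(y, xh, trace, lc, S, seg, TE, cfgLM,
                             lambda = lambda, ctx = ctx)
      lambda <- attr(tr2, "lambda")
      new <- unclass(tr2)
      inact <- setdiff(seq_len(ns), shots)
      new[inact, ] <- keep[inact, ]
      trace <- motion_trace(new)
      z1 <- unclass(trace)[1, ]
      if (cfg$fix_first_shot && any(abs(z1) > 1e-8)) {
        trace <- motion_trace(t(apply(unclass(trace), 1, compose_pose,
                                      zb = invert_pose(z1))))
        xh <- rigid_transform(xh, z1, "forward", spacing = ctx$spacing)
        phg <- shot_phase(lc, z1, TE)
        if (!is.null(phg)) xh <- xh * phg
      }
      trs <- motion_trace(unclass(trace)[shots, , drop = FALSE])
      lc <- solve_lc_gd(ys, xh, trs, lc, S, segs, TE, cfg, step = gstep)
      gstep <- attr(lc, "step")
    }
    list(xh = xh, trace = trace, lc = lc, gstep = gstep)
  }
  for (k in seq_along(ord)) {
    newshots <- which(grp == ord[k])
    if (k > 1) {
      # register the joining shots against the current image with the phase
      # their candidate angles predict; candidates: from zero and from the
      # motion-only pass, whichever explains the data better
      trz <- unclass(trace)
      trz[newshots, ] <- 0
      t0 <- solve_motion_lm(y, xh, motion_trace(trz), lc, S, seg, TE,
                            recon_config(lm_iters = 8, fix_first_shot = FALSE),
                            ctx = ctx)
      trz[newshots, ] <- trm[newshots, ]
      t1 <- solve_motion_lm(y, xh, motion_trace(trz), lc, S, seg, TE,
                            recon_config(lm_iters = 8, fix_first_shot = FALSE),
                            ctx = ctx)
      c0 <- attr(t0, "cost")[newshots]
      c1 <- attr(t1, "cost")[newshots]
      newtr <- unclass(trace)
      newtr[newshots, ] <- ifelse(rep(sum(c0) <= sum(c1), 6 * length(newshots)),
                                  unclass(t0)[newshots, ], unclass(t1)[newshots, ])
      trace <- motion_trace(newtr)
    }
    active <- c(active, newshots)
    st <- run_joint(active, if (k < length(ord)) 6L else 10L, xh, trace, lc, gstep)
    xh <- st$xh; trace <- st$trace; lc <- st$lc; gstep <- st$gstep
  }
  list(x = xh, trace = trace, lc = lc)
}

# ---- multiresolution plumbing ---------------------------------------------

# Central index block of length nc inside a centered axis of length n.
#' @keywords internal
center_block <- function(n, nc) ((n - nc) %/% 2L + 1L):((n + nc) %/% 2L)

# Crop a k-space object to a coarser grid (factor f on every axis): central
# readout rows, phase-encode points inside the coarse bounds, values scaled so
# the coarse data match the coarse orthonormal-FFT model.
#' @keywords internal
crop_kspace <- function(y, f) {
  if (f == 1) return(y)
  d <- y$shape
  dc <- d %/% f
  rows <- center_block(d[1], dc[1])
  yb <- center_block(d[2], dc[2])
  zb <- center_block(d[3], dc[3])
  scale <- sqrt(prod(dc) / prod(d))
  shots <- vector("list", y$seg$n_shots)
  yy <- vector("list", y$seg$n_shots)
  for (n in seq_len(y$seg$n_shots)) {
    mk <- y$seg$shots[[n]]
    keep <- mk[, 1] >= yb[1] & mk[, 1] <= yb[length(yb)] &
            mk[, 2] >= zb[1] & mk[, 2] <= zb[length(zb)]
    mkc <- mk[keep, , drop = FALSE]
    mkc[, 1] <- mkc[, 1] - (yb[1] - 1L)
    mkc[, 2] <- mkc[, 2] - (zb[1] - 1L)
    shots[[n]] <- mkc
    yy[[n]] <- y$y[[n]][rows, keep, , drop = FALSE] * scale
  }
  segc <- structure(list(n_shots = y$seg$n_shots, ny = dc[2], nz = dc[3],
                         seed = y$seg$seed, shots = shots), class = "shot_seg")
  kspace_data(yy, segc, y$TE, dc, y$spacing * f)
}

# Fourier-domain resampling of a complex volume to a new grid (crop or
# zero-pad the centered spectrum), amplitude-preserving for smooth content.
#' @keywords internal
resample_volume <- function(x, to_shape) {
  d <- dim(x)
  if (identical(as.integer(d), as.integer(to_shape))) return(x)
  X <- cfft3(x)
  out <- array(0i, to_shape)
  if (all(to_shape <= d)) {
    out <- X[center_block(d[1], to_shape[1]),
             center_block(d[2], to_shape[2]),
             center_block(d[3], to_shape[3]), drop = FALSE]
  } else {
    out[center_block(to_shape[1], d[1]),
        center_block(to_shape[2], d[2]),
        center_block(to_shape[3], d[3])] <- X
  }
  cifft3(out) * sqrt(prod(to_shape) / prod(d))
}

#' @keywords internal
resample_coils <- function(S, to_shape, spacing) {
  nc <- dim(S$data)[4]
  d <- dim(S$data)[1:3]
  out <- array(0i, c(to_shape, nc))
  for (c in seq_len(nc)) {
    sc <- S$data[, , , c, drop = FALSE]
    dim(sc) <- d
    out[, , , c] <- resample_volume(sc, to_shape)
  }
  coil_maps(out, spacing)
}

#' @keywords internal
resample_lc <- function(lc, to_shape, spacing) {
  lc_maps(Re(resample_volume(lc$dpitch + 0i, to_shape)),
          Re(resample_volume(lc$droll + 0i, to_shape)), spacing)
}

# ---- top-level driver ------------------------------------------------------

#' Motion- and B0-corrected image reconstruction
#'
#' Alternating estimation of the image (CG), the per-shot rigid motion
#' (Levenberg-Marquardt) and the LC maps of the pose-dependent B0 model
#' (gradient descent), over a coarse-to-fine multiresolution schedule.
#'
#' Modes:
#' \describe{
#'   \item{`"uncorrected"`}{plain SENSE: no motion or B0 modelling; all shots
#'     merged, single CG solve at full resolution.}
#'   \item{`"moco"`}{aligned SENSE: alternates image and motion only.}
#'   \item{`"moco-b0"`}{the full model: image, motion and LC maps.}
#'   \item{`"provided"`}{`trace_init` and (optionally) `lc_init` are taken as
#'     ground truth and held fixed; only the image is solved.}
#' }
#'
#' @param y a [kspace_data()] object
#' @param S [coil_maps()]
#' @param mode reconstruction arm, see Details
#' @param cfg a [recon_config()]
#' @param trace_init initial (or fixed) [motion_trace()]
#' @param lc_init initial (or fixed) [lc_maps()]
#' @return an object of class `recon_result`: list with `image` ([mr_volume()]),
#'   `trace`, `lc`, `cost_history` (data.frame: level, outer, data cost,
#'   combined cost), `mode`, `config`, and `flags`
#' @export
reconstruct <- function(y, S, mode = c("moco-b0", "moco", "uncorrected", "provided"),
                        cfg = recon_config(), trace_init = NULL, lc_init = NULL) {
  mode <- match.arg(mode)
  est_motion <- mode %in% c("moco", "moco-b0")
  est_b0 <- mode == "moco-b0"
  if (mode == "uncorrected") {
    y <- collapse_kspace(y)
    trace_init <- identity_trace(1L)
    lc_init <- NULL
  }
  if (mode == "provided" && is.null(trace_init))
    stop("mode 'provided' needs trace_init (and optionally lc_init)", call. = FALSE)
  d_full <- y$shape
  ns <- y$seg$n_shots
  trace <- if (is.null(trace_init)) identity_trace(ns) else trace_init
  use_lc <- est_b0 || (mode == "provided" && !is.null(lc_init))
  levels <- if (mode %in% c("uncorrected", "provided")) 1 else cfg$levels
  outers <- if (mode %in% c("uncorrected", "provided")) 1 else cfg$outer_iters
  x <- NULL
  lc <- NULL
  lambda <- NULL
  gd_step <- NULL
  hist <- list()
  frozen_any <- FALSE
  for (li in seq_along(levels)) {
    f <- levels[li]
    yl <- crop_kspace(y, f)
    dl <- yl$shape
    Sl <- if (f == 1) S else resample_coils(S, dl, yl$spacing)
    ctx <- encode_ctx(Sl, yl$seg, yl$TE, yl$spacing)
    if (!is.null(x)) x <- resample_volume(x, dl)
    if (use_lc) {
      lc <- if (is.null(lc)) {
        if (is.null(lc_init)) zero_lc_maps(dl, yl$spacing)
        else resample_lc(lc_init, dl, yl$spacing)
      } else resample_lc(lc, dl, yl$spacing)
    }
    if (li == 1L && est_b0 && isTRUE(cfg$continuation) && is.null(trace_init)) {
      ci <- continuation_init(ctx, yl, Sl, cfg)
      x <- ci$x
      trace <- ci$trace
      lc <- ci$lc
    }
    lambda <- rep(cfg$lm_damping_init, ns)
    gd_step <- NULL
    prev_cost <- Inf
    n_outer <- outers[li]
    cg_it <- if (mode %in% c("uncorrected", "provided")) cfg$cg_iters else cfg$cg_iters_outer
    for (ou in seq_len(n_outer)) {
      x <- solve_image_cg(yl, trace, lc, Sl, yl$seg, yl$TE,
                          cg_iters = cg_it, cg_tol = cfg$cg_tol, x0 = x, ctx = ctx)
      dcost <- NA_real_
      tcost <- NA_real_
      if (est_motion) {
        cfg_lm <- cfg
        cfg_lm$fix_first_shot <- FALSE     # gauge handled by re-centering below
        trace <- solve_motion_lm(yl, x, trace, lc, Sl, yl$seg, yl$TE, cfg_lm,
                                 lambda = lambda, ctx = ctx)
        lambda <- attr(trace, "lambda")
        frozen_any <- frozen_any || any(attr(trace, "frozen"))
        dcost <- sum(attr(trace, "cost"))
        if (cfg$fix_first_shot) {
          # re-center the rigid gauge on the first shot: compose every pose
          # with the inverse of shot 1's pose and move the head frame (image
          # and LC maps) along, so shot 1 stays exactly at zero without the
          # slow gauge drift a hard freeze induces
          z1 <- unclass(trace)[1, ]
          if (any(abs(z1) > 1e-8)) {
            zinv <- invert_pose(z1)
            tr_new <- t(apply(unclass(trace), 1, compose_pose, zb = zinv))
            at <- attributes(trace)
            trace <- motion_trace(tr_new)
            attr(trace, "cost") <- at$cost
            x <- rigid_transform(x, z1, "forward", spacing = yl$spacing)
            # changing every pose by -z1 also changes the model's B0 phase:
            # P_{theta-dz}(d) = P_theta(d) * exp(+i 2 pi d.dz TE), so the
            # image must carry the conjugate factor for the re-gauged state
            # to describe the same data (exact up to the small T-P commutator)
            if (!is.null(lc)) {
              phg <- shot_phase(lc, z1, yl$TE)
              if (!is.null(phg)) x <- x * phg
            }
            # the LC maps themselves are left untouched: they are re-estimated
            # each outer iteration and absorb the (small) residual frame shift,
            # which avoids degrading them by repeated resampling
          }
        }
      }
      if (est_b0 && li == 1L && ou == cfg$b0_warmup + 1L &&
          isTRUE(cfg$lc_block_init)) {
        lci <- init_lc_from_segments(ctx, yl, Sl, trace, x, cfg)
        if (!is.null(lci)) lc <- lci
      }
      if (est_b0 && !(li == 1L && ou <= cfg$b0_warmup)) {
        cfg_gd <- cfg
        if (f == 1) cfg_gd$gd_lowpass_frac <- Inf   # full detail at full resolution
        lc <- solve_lc_gd(yl, x, trace, lc, Sl, yl$seg, yl$TE, cfg_gd,
                          step = gd_step, ctx = ctx)
        gd_step <- attr(lc, "step")
        dcost <- attr(lc, "cost")
        tcost <- attr(lc, "total_cost")
      }
      if (is.na(dcost)) dcost <- lc_data_cost(ctx, yl, x, trace, lc)
      if (is.na(tcost)) tcost <- dcost
      hist[[length(hist) + 1L]] <- data.frame(level = li, factor = f, outer = ou,
                                              data_cost = dcost, total_cost = tcost)
      if (cfg$verbose)
        message(sprintf("level %d outer %3d: data cost %.6g", li, ou, dcost))
      if (cfg$outer_tol > 0 && is.finite(prev_cost) &&
          abs(prev_cost - dcost) < cfg$outer_tol * prev_cost) break
      prev_cost <- dcost
    }
  }
  # final image polish at full resolution with the converged motion/LC maps;
  # if the schedule stopped at a coarse level, carry the state up first
  if (!(mode %in% c("uncorrected", "provided"))) {
    if (!identical(as.integer(dim(x)), d_full)) {
      x <- resample_volume(x, d_full)
      if (!is.null(lc)) lc <- resample_lc(lc, d_full, y$spacing)
    }
    ctx <- encode_ctx(S, y$seg, y$TE, y$spacing)
    x <- solve_image_cg(y, trace, lc, S, y$seg, y$TE, cg_iters = cfg$cg_iters,
                        cg_tol = cfg$cg_tol, x0 = x, ctx = ctx)
    dcost <- lc_data_cost(ctx, y, x, trace, lc)
    hist[[length(hist) + 1L]] <- data.frame(level = length(levels), factor = 1,
                                            outer = outers[length(outers)] + 1L,
                                            data_cost = dcost, total_cost = dcost)
  }
  hist <- do.call(rbind, hist)
  attr(x, "residuals") <- NULL
  structure(list(image = mr_volume(x, y$spacing, frame = "head"),
                 trace = motion_trace(unclass(trace)[, , drop = FALSE]),
                 lc = lc,
                 cost_history = hist,
                 mode = mode,
                 config = cfg,
                 flags = list(frozen_shots = frozen_any,
                              finite = all(is.finite(hist$data_cost)))),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> mode '%s', grid %s\n", x$mode,
              paste(dim(x$image$data), collapse = " x ")))
  n <- nrow(x$cost_history)
  if (n) cat(sprintf("  data cost: %.6g -> %.6g over %d outer iterations\n",
                     x$cost_history$data_cost[1], x$cost_history$data_cost[n], n))
  invisible(x)
}
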