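---
title: "Motion-corrected reconstruction with pose-dependent B0 fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-corrected reconstruction with pose-dependent B0 fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(b0moco)
```

## The problem

Rigid head motion during a volumetric Cartesian brain acquisition corrupts
k-space because different readouts see the object in different poses.
Retrospective motion correction partitions the readouts into temporal shots,
gives each shot its own rigid state $z_n$ (three translations in mm, three
rotations in degrees: pitch about the left-right axis, roll about
anterior-posterior, yaw about foot-head), and solves jointly for the image and
the motion — the aligned-SENSE formulation, made well-posed by the redundancy
of the receive array and by a sampling order (DISORDER) that spreads every
shot incoherently over the phase-encode plane.

At ultra-high field a second mechanism appears: tissue susceptibility makes
the static field $B_0$ inhomogeneous, and because the susceptibility
distribution moves with the head, the field *changes with pose*. A frequency
offset $\omega(\mathbf r)$ multiplies the transverse magnetization by
$e^{-i 2\pi \omega(\mathbf r)\,TE}$ at the echo time, so pose-dependent fields
put shot-dependent phase structure into the data that a motion-only model
cannot explain. This package models that dependence compactly with
voxelwise **linear-coefficient (LC) maps** $d_{pitch}, d_{roll}$ (Hz/degree,
head frame):

$$\omega_n(\mathbf r) = d_{pitch}(\mathbf r)\,\theta_{n,pitch} +
  d_{roll}(\mathbf r)\,\theta_{n,roll},$$

a first-order expansion in the two rotation angles that dominate
susceptibility changes. There is no constant term — the pose-independent
field is already absorbed in the complex image. Yaw and translations do not
enter. The full encoding of shot $n$ is then

$$y_n = A_n F S T_{z_n} P_{\theta_n}(d)\, x,$$

with $P$ the diagonal phase term (applied in the head frame, before the rigid
transform: the field moves with the head), $T_{z_n}$ the rigid transform, $S$
the coil sensitivities, $F$ the centered orthonormal Fourier transform and
$A_n$ the shot's phase-encode mask inside an elliptical shutter. The joint
estimate of $(x, z_n, d)$ minimizes the summed data misfit.

## The solver

The three blocks are updated in alternation, in the order image → motion →
LC maps:

* **Image**: conjugate gradient on the normal equations
  $E^H E\, x = E^H y$ with motion and LC maps fixed. A handful of
  warm-started iterations per outer pass suffice; a longer final solve
  polishes the returned image.
* **Motion**: per-shot Levenberg–Marquardt on the six rigid parameters, with
  a finite-difference Jacobian. The phase term depends on pitch and roll, so
  its derivative is part of the Jacobian. Damping: start $10^{-2}$, times 10
  on rejection, times 0.5 on acceptance; accepted steps never increase a
  shot's misfit. An optional trust region (`lm_step_max`) bounds the
  per-iteration parameter change.
* **LC maps**: gradient descent on the two voxelized volumes with the
  analytic chain-rule gradient through the exponential phase (validated
  against finite differences in the test suite), a backtracking line search,
  and a smooth *phase-wrapping stabilizer* that penalizes per-voxel phase
  excursions $2\pi\,TE\,\theta_{max}\,|d|$ beyond $\pi$ — the exponential
  makes the objective $2\pi$-periodic in accumulated phase, and the penalty
  keeps the descent away from the wrapped branches. Updates are restricted
  to voxels with appreciable image magnitude (`lc_mask_frac`): where there is
  no signal the phase is unobservable and free parameters only absorb
  artifacts. Several optional safeguards are exposed and documented because
  the joint setting is delicate: a diagonal curvature preconditioner
  (`gd_precondition`; dramatic near the solution, destabilizing from
  scratch, hence off by default), step caps in physical units
  (`gd_delta_max`, Hz/degree per step) and in line-search length
  (`gd_step_max`), a gradient low-pass for coarse levels
  (`gd_lowpass_frac`), a motion-only warm-up (`b0_warmup`), an LC
  re-initialization from low-pass segment-field estimates
  (`lc_block_init`), and a continuation that introduces pose blocks mildest
  first (`continuation`).

Two structural devices stabilize the joint problem:

* **Gauge re-centering.** A constant pose applied to every shot can be
  absorbed into the image, so the joint cost has a near-flat direction. With
  one shot hard-frozen the gauge converges only through that shot's small
  share of the data; instead, all shots are estimated freely and after every
  motion update the whole state is re-expressed relative to shot 1 (poses
  composed with the inverse of shot 1's pose; the image transformed
  accordingly), keeping the first shot's motion exactly zero without the
  drift. The incrementally-estimated LC maps are deliberately *not*
  resampled along — they re-absorb the small frame shift at the next update,
  which avoids degrading them by repeated interpolation.
* **Multiresolution.** k-space is cropped (not image-smoothed) to half
  resolution for a first block of outer iterations, then the state moves to
  full resolution: motion is copied, LC maps are Fourier-interpolated. The
  default schedule is 45 coarse and 15 fine outer iterations; the validation
  runs in the test suite use shorter schedules (25 coarse / 3 fine on a
  48-cube joint problem, 12 coarse for the arm comparison), sized so the
  whole suite completes in a sensible desk-scale run — measured on these
  problems, deeper schedules refine the data cost but do not change the
  qualitative outcomes.

Stopping is by fixed iteration budget (a relative-change exit is available
via `outer_tol`). Everything is deterministic: no RNG is consumed during
reconstruction.

## What the synthetic generator emulates

`simulation_spec()` fixes the study conditions; the defaults are the
desk-scale analogue of a 7 T SPGR protocol: a 64-cube grid at 1.5 mm, TE =
5 ms, an elliptical shutter, 128 DISORDER shots, and an interleaved motion
design of 13 poses (contiguous shot blocks, sizes within one shot of each
other) drawn uniformly from $\pm 5$ mm and $\pm 7.5^\circ$, each decaying
geometrically toward neutral by 5% per shot — the "slow drift back" seen in
volunteer traces; the exact drift law is the package's choice, and its rate
is configurable. The first pose block is neutral by default so that the
ground-truth trace matches the reconstruction gauge (first shot pinned at
zero); `first_pose_neutral = FALSE` restores fully random blocks.

* **Phantom**: nested-ellipsoid head with deliberately asymmetric internal
  structure (off-center brain, unequal ventricles, a cerebellum-like
  compartment, a frontal air-like cavity, seeded focal structures), a smooth
  background phase, and a zero margin of 8 voxels at the default size so the
  cyclic wrap of the shear-FFT transforms never recirculates tissue. The
  phantom is band-limited to the elliptical-shutter support at construction:
  the ground truth of an acquisition lives in measured k-space, and corner
  energy the sampling can never see would otherwise put a spurious error
  floor under every reconstruction.
* **Coils**: Gaussian receive lobes on a ring around the head with gentle
  per-coil linear phase; root-sum-of-squares magnitude positive over the
  support. Eight coils by default — a desk-scale stand-in for a 32-channel
  array (32 is available but quadruples the dominant FFT cost).
* **LC maps**: a smooth base pattern antisymmetric across each rotation axis
  (opposite signs on opposite sides) plus high-magnitude lobes near a
  frontal "sinus" locus and two "ear-canal" loci, clipped to
  $[-10, 10]$ Hz/degree — the range reported for susceptibility-induced
  linear coefficients at 7 T.
* **Noise**: complex Gaussian i.i.d. in k-space, calibrated *operationally*:
  the motion-free data are reconstructed once to measure the error floor,
  the actual noise draw is pushed through the same reconstruction as a
  perturbation to measure its image-domain gain, and the standard deviation
  is solved so the uncorrected motion-free reconstruction lands on the
  target SNR (30 dB by default). The perturbation route matters: an
  iterative solve filters a pure-noise input differently from noise riding
  on signal, and calibrating on the pure-noise response leaves a visible
  bias. The measured SNR of the calibrated pipeline is reproducible to
  about 0.1 dB across seeds.

What passing on these data does *not* establish: the generator has no
spin-history or steady-state signal evolution, no pose-dependent coil
loading, no readout distortion, and its ground-truth LC maps are smooth
constructions rather than fields derived from a susceptibility model — so
agreement here validates the estimation machinery, not the biophysics of any
particular head.

## The multi-pose fitting pipeline

For data acquired (or simulated) as separate single-pose scans, LC maps are
fitted directly: the phase difference of each co-registered scan against the
reference is unwrapped (a quality-guided, magnitude-ordered region-growing
3D unwrapper built into the package), converted to frequency by
$\omega = \varphi / (2\pi TE)$, and regressed voxelwise on the known
(pitch, roll) angles by ordinary least squares; the per-voxel mean absolute
residual over poses accompanies the maps. The sign convention is pinned by a
round trip: fields applied through the package's own phase term are
recovered with positive sign. The phase difference is therefore taken as
$\arg(\text{ref}\cdot\overline{\text{moved}})$; reading the difference the
other way flips every recovered field. Voxels below 10% of the robust
magnitude maximum are excluded (no usable phase), and a singular angle
design — all angles zero, or pitch and roll collinear across poses — is
refused with the deficient direction named.

## Numerical conventions

* Centered orthonormal FFT on all axes (DC at `floor(n/2)+1`); Parseval holds
  to machine precision.
* Rigid transforms: FFT phase ramps for translations, three-pass k-space
  shears per rotation, Euler order pitch → roll → yaw about the volume
  center. Each pass multiplies by a unit-modulus phase, so the operator is
  unitary to floating point and its adjoint equals its inverse; boundary
  behavior is cyclic wrap, which the phantom margin renders harmless.
  The shear decomposition is smooth in the parameters, which the
  finite-difference Levenberg-Marquardt Jacobian needs.
* Degenerate inputs: empty shots are carried but skipped; an exactly
  reconstructed image reports infinite SNR with a flag rather than an error;
  constant images get zero mutual information with a flag; ties in the
  unwrapper's quality queue resolve in deterministic stack order.

## Known limitations

* The joint problem is nonconvex, and at desk scale the dominant failure
  mode is *registration capture under unmodeled pose-dependent phase*: with
  the true image but zero LC maps, per-shot pose refinement can walk many
  degrees away from the truth, while LC estimation in turn needs
  near-correct motion. The package's diagnostics show the truth is a stable
  attractor of the alternation (initializing at the generating state stays
  there, with LC correlation 0.9999), and each block update is individually
  validated against oracles — but from a cold start on strongly corrupted
  desk-scale data (tens of shots, 8 coils) the alternation can settle in a
  self-consistent wrong valley: the data cost decreases monotonically, yet
  recovered rotations can be degrees off and LC correlations far below 1.
  The safeguards above mitigate but do not eliminate this; the acquisition
  scale of the original framework (over a hundred shots, a 32-channel
  array, millions of voxels) is substantially better conditioned. Treat
  joint motion+B0 results from small simulations as qualitative (the arm
  ordering uncorrected < motion < motion+B0 is robust) rather than as
  parameter ground truth.
* Second-order (in angle) field terms, pose-dependent coil sensitivities and
  scanner-frame field sources are out of scope.
* The HDF5 container format common for raw k-space is not available in this
  R stack; the package serializes its documented in-memory k-space list via
  RDS with a JSON sidecar instead.
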