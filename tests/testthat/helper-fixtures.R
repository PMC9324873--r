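# Shared fixtures: tiny deterministic volumes, coils, segmentations.

rand_cvol <- function(d, seed = 1, sd = 1) {
  set.seed(seed)
  array(complex(real = rnorm(prod(d), 0, sd),
                imaginary = rnorm(prod(d), 0, sd)), d)
}

# Smooth-ish random coil maps with nonzero magnitude everywhere.
rand_coils <- function(d, n_coils, seed = 1) {
  set.seed(seed)
  coil_maps(array(complex(real = rnorm(prod(d) * n_coils, 1, 0.3),
                          imaginary = rnorm(prod(d) * n_coils, 0, 0.3)),
                  c(d, n_coils)))
}

rand_lc <- function(d, seed = 1, sd = 3) {
  set.seed(seed)
  lc_maps(array(rnorm(prod(d), 0, sd), d), array(rnorm(prod(d), 0, sd), d))
}

# A single shot covering the full phase-encode plane (no shutter).
full_seg <- function(ny, nz) {
  structure(list(n_shots = 1L, ny = ny, nz = nz, seed = 0L,
                 shots = list(as.matrix(expand.grid(ky = seq_len(ny),
                                                    kz = seq_len(nz))))),
            class = "shot_seg")
}

# Full plane split into n interleaved shots (deterministic, no shutter).
split_seg <- function(ny, nz, n) {
  pts <- as.matrix(expand.grid(ky = seq_len(ny), kz = seq_len(nz)))
  structure(list(n_shots = as.integer(n), ny = ny, nz = nz, seed = 0L,
                 shots = lapply(seq_len(n), function(s)
                   pts[seq(s, nrow(pts), by = n), , drop = FALSE])),
            class = "shot_seg")
}

# Small blocky object useful for registration tests: asymmetric, compact,
# zero near the boundary. Index ranges scale with the grid.
blocky_object <- function(d = c(16, 16, 16)) {
  x <- array(0, d)
  rng <- function(a, b, n) max(2L, round(a * n)):min(n - 1L, round(b * n))
  x[rng(.30, .72, d[1]), rng(.25, .78, d[2]), rng(.35, .68, d[3])] <- 1
  x[rng(.42, .56, d[1]), rng(.42, .56, d[2]), rng(.48, .58, d[3])] <- 2
  x[rng(.60, .70, d[1]), rng(.30, .38, d[2]), rng(.42, .46, d[3])] <- 0.5
  x + 0i
}

relerr <- function(a, b) sqrt(sum(Mod(a - b)^2) / max(sum(Mod(b)^2), 1e-300))

unit_coils <- function(d) coil_maps(array(1 + 0i, c(d, 1L)))
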