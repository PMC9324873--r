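# Quality-guided region-growing 3D phase unwrapping.
#
# Voxels are absorbed into the solved region in order of decreasing quality
# (by default the signal magnitude), each unwrapped against the already-solved
# neighbor that enqueued it.  A bucket queue over quantized quality keeps the
# whole pass O(n).  Disconnected mask components are re-seeded from their own
# best voxel; the seed keeps its wrapped value, so each component is unwrapped
# up to a (harmless, 2*pi*k) global offset anchored at its highest-quality
# voxel.

#' Unwrap a 3D phase volume
#'
#' @param phase wrapped phase, radians, 3D array
#' @param mask logical array of voxels to unwrap (default: all)
#' @param quality guidance map, higher is unwrapped earlier (default: all-ones;
#'   callers typically pass the magnitude image)
#' @param n_buckets quality quantization levels of the growth queue
#' @return 3D array: unwrapped phase inside the mask, `NA` outside
#' @export
unwrap_phase_3d <- function(phase, mask = NULL, quality = NULL, n_buckets = 128L) {
  d <- dim(phase)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (is.null(quality)) quality <- array(1, d)
  stopifnot(identical(dim(mask), d), identical(dim(quality), d))
  n <- prod(d)
  q <- as.vector(quality)
  qin <- q[as.vector(mask)]
  if (!length(qin)) return(array(NA_real_, d))
  # quantize quality into buckets (1 = best)
  br <- range(qin)
  bucket <- if (br[1] == br[2]) rep(1L, n) else {
    pmin(n_buckets, pmax(1L, as.integer(ceiling((br[2] - q) / (br[2] - br[1]) * (n_buckets - 1L))) + 1L))
  }
  ph <- as.vector(phase)
  out <- rep(NA_real_, n)
  state <- integer(n)                  # 0 unknown, 1 queued, 2 solved
  state[!as.vector(mask)] <- -1L       # outside mask: never touched
  refval <- numeric(n)                 # unwrapped value of the enqueuing neighbor
  # neighbor offsets in flat index space, with axis guards
  sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
  ix <- ((seq_len(n) - 1L) %% d[1]) + 1L
  iy <- (((seq_len(n) - 1L) %/% d[1]) %% d[2]) + 1L
  iz <- ((seq_len(n) - 1L) %/% sz) + 1L
  buckets <- vector("list", n_buckets)   # stacks of queued voxels
  bsize <- integer(n_buckets)
  push <- function(v) {
    b <- bucket[v]
    bsize[b] <<- bsize[b] + 1L
    if (length(buckets[[b]]) < bsize[b]) buckets[[b]] <<- c(buckets[[b]], integer(64L))
    buckets[[b]][bsize[b]] <<- v
  }
  remaining <- which(state == 0L)
  twopi <- 2 * pi
  while (length(remaining)) {
    seed <- remaining[which.max(q[remaining])]
    out[seed] <- ph[seed]
    state[seed] <- 2L
    frontier <- seed
    top <- 1L
    repeat {
      # enqueue unknown neighbors of newly solved voxels
      for (v in frontier) {
        nb <- c(if (ix[v] > 1L) v - sx, if (ix[v] < d[1]) v + sx,
                if (iy[v] > 1L) v - sy, if (iy[v] < d[2]) v + sy,
                if (iz[v] > 1L) v - sz, if (iz[v] < d[3]) v + sz)
        for (w in nb) {
          if (state[w] == 0L) {
            state[w] <- 1L
            refval[w] <- out[v]
            push(w)
            if (bucket[w] < top) top <- bucket[w]
          }
        }
      }
      # pop the best queued voxel
      while (top <= n_buckets && bsize[top] == 0L) top <- top + 1L
      if (top > n_buckets) break
      v <- buckets[[top]][bsize[top]]
      bsize[top] <- bsize[top] - 1L
      out[v] <- ph[v] + twopi * round((refval[v] - ph[v]) / twopi)
      state[v] <- 2L
      frontier <- v
    }
    remaining <- which(state == 0L)
  }
  array(out, d)
}
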