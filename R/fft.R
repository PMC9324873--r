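# Centered, orthonormal FFT helpers.
#
# Convention used throughout the package: the DC component sits at grid index
# floor(n/2)+1 on every axis ("centered"), and both directions carry a 1/sqrt(V)
# factor so the transform is unitary (Parseval holds exactly up to float error).

#' @keywords internal
fftshift_index <- function(n) ((seq_len(n) - 1L + n %/% 2L) %% n) + 1L

#' @keywords internal
ifftshift_index <- function(n) ((seq_len(n) - 1L + (n + 1L) %/% 2L) %% n) + 1L

#' @keywords internal
fftshift3 <- function(x) {
  d <- dim(x)
  x[fftshift_index(d[1]), fftshift_index(d[2]), fftshift_index(d[3]), drop = FALSE]
}

#' @keywords internal
ifftshift3 <- function(x) {
  d <- dim(x)
  x[ifftshift_index(d[1]), ifftshift_index(d[2]), ifftshift_index(d[3]), drop = FALSE]
}

#' Centered orthonormal 3D Fourier transform
#'
#' Image domain -> k-space. The inverse is [cifft3()]. Both are unitary:
#' `sum(abs(x)^2) == sum(abs(cfft3(x))^2)` to floating point.
#'
#' @param x complex 3D array
#' @return complex 3D array of the same shape, DC at `floor(dim/2)+1`
#' @keywords internal
cfft3 <- function(x) {
  fftshift3(fft(ifftshift3(x))) / sqrt(length(x))
}

#' @rdname cfft3
#' @keywords internal
cifft3 <- function(x) {
  fftshift3(fft(ifftshift3(x), inverse = TRUE)) / sqrt(length(x))
}

# 1D FFT along one axis of a 3D array, unnormalized and *uncentered* (DC at
# index 1).  Used by the shear passes of the rigid transform, where the
# normalization cancels between the forward and inverse pass.
#' @keywords internal
fft_axis <- function(x, axis, inverse = FALSE) {
  d <- dim(x)
  if (axis != 1L) {
    perm <- c(axis, setdiff(1:3, axis))
    x <- aperm(x, perm)
    dp <- d[perm]
  } else {
    dp <- d
  }
  dim(x) <- c(dp[1], dp[2] * dp[3])
  x <- mvfft(x, inverse = inverse)
  dim(x) <- dp
  if (axis != 1L) {
    # invert the permutation
    inv <- order(c(axis, setdiff(1:3, axis)))
    x <- aperm(x, inv)
  }
  x
}

# Centered frequency index along one axis for uncentered FFT output storage:
# entry j corresponds to frequency ((j-1+n/2) mod n) - n/2.
#' @keywords internal
freq_index <- function(n) {
  k <- seq_len(n) - 1L
  ((k + n %/% 2L) %% n) - n %/% 2L
}

# Centered spatial coordinate (voxel units) along one axis: zero at the voxel
# floor(n/2)+1, matching the DC position of the centered FFT.
#' @keywords internal
centered_coord <- function(n) seq_len(n) - (n %/% 2L + 1L)
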