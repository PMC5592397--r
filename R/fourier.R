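#' Orthonormal 2-D spatial Fourier transform, frame by frame
#'
#' Applies a unitary (1/sqrt(mn)-scaled) 2-D discrete Fourier transform to
#' each dynamic frame of a spatiotemporal image, returning k-space with the
#' DC sample at the array centre.
#'
#' @param x complex (or numeric) array, `m x n x d`.
#' @return complex array of the same shape (k-space, DC centred).
#' @seealso [spatial_ifft2()]
#' @export
spatial_fft2 <- function(x) {
  x <- as_tdim_array(x)$x
  dm <- dim(x)
  sc <- sqrt(prod(dm[1:2]))
  out <- array(0+0i, dm)
  for (t in seq_len(dm[3])) {
    out[, , t] <- shift2(stats::fft(x[, , t]) / sc, forward = TRUE)
  }
  out
}

#' Inverse orthonormal 2-D spatial Fourier transform, frame by frame
#'
#' Exact inverse (and adjoint) of [spatial_fft2()].
#'
#' @param k complex array, `m x n x d`, DC centred.
#' @return complex image array of the same shape.
#' @export
spatial_ifft2 <- function(k) {
  k <- as_tdim_array(k)$x
  dm <- dim(k)
  sc <- sqrt(prod(dm[1:2]))
  out <- array(0+0i, dm)
  for (t in seq_len(dm[3])) {
    out[, , t] <- stats::fft(shift2(k[, , t], forward = FALSE),
                             inverse = TRUE) / sc
  }
  out
}

#' Casorati matrix view of a dynamic image
#'
#' Reshapes an `m x n x d` spatiotemporal array to the `mn x d` Casorati
#' matrix (one column per dynamic frame), whose rank captures temporal
#' redundancy.
#'
#' @param x `m x n x d` array.
#' @return `mn x d` matrix.
#' @export
casorati <- function(x) {
  dm <- dim(x)
  stopifnot(length(dm) == 3L)
  dim(x) <- c(dm[1] * dm[2], dm[3])
  x
}

#' Restore a Casorati matrix to spatiotemporal shape
#'
#' @param xc `mn x d` matrix.
#' @param shape length-3 integer vector `c(m, n, d)`.
#' @return `m x n x d` array.
#' @export
uncasorati <- function(xc, shape) {
  stopifnot(length(shape) == 3L, nrow(xc) == shape[1] * shape[2],
            ncol(xc) == shape[3])
  array(xc, dim = shape)
}
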