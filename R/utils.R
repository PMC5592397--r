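#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-task seed from a global seed
#'
#' Deterministic mixing of a global seed with a stream index, kept inside
#' the 32-bit integer range required by [set.seed()].
#'
#' @param global integer global seed.
#' @param index nonnegative stream index.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(global, index) {
  g <- as.double(global) %% 2147483647
  s <- (g * 48271 + as.double(index) * 16807 + 12345) %% 2147483646
  as.integer(s + 1)
}

## circular shift of a matrix so the DC sample moves to/from the centre
shift2 <- function(x, forward = TRUE) {
  m <- nrow(x); n <- ncol(x)
  sr <- floor(m / 2); sc <- floor(n / 2)
  if (!forward) { sr <- m - sr; sc <- n - sc }
  ri <- ((seq_len(m) - 1 + m - sr) %% m) + 1
  ci <- ((seq_len(n) - 1 + n - sc) %% n) + 1
  x[ri, ci, drop = FALSE]
}

#' Frobenius norm of a numeric or complex array
#' @param x array.
#' @return nonnegative scalar.
#' @keywords internal
fnorm <- function(x) sqrt(sum(Mod(x)^2))

## coerce a time-course vector to a 1 x 1 x d array; returns list with the
## array and a function restoring the original shape
as_tdim_array <- function(x) {
  if (is.null(dim(x))) {
    arr <- array(x, dim = c(1, 1, length(x)))
    list(x = arr, restore = function(z) as.vector(z))
  } else if (length(dim(x)) == 2L) {
    arr <- array(x, dim = c(dim(x)[1], 1, dim(x)[2]))
    d <- dim(x)
    list(x = arr, restore = function(z) array(z, dim = d))
  } else if (length(dim(x)) == 3L) {
    list(x = x, restore = identity)
  } else {
    stop("expected a vector, matrix, or 3-D array with time on the last axis")
  }
}

## spatially correlated standard-normal field: white noise smoothed by a
## separable Gaussian kernel with replicate-padded boundaries
smooth_gaussian_field <- function(m, n, corr_len) {
  w <- matrix(stats::rnorm(m * n), m, n)
  if (corr_len <= 0) return(w)
  r <- max(1L, ceiling(2 * corr_len))
  g <- stats::dnorm(seq(-r, r), sd = corr_len)
  g <- g / sum(g)
  conv1 <- function(v) {
    nv <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[nv], r))
    as.numeric(stats::filter(vp, g, sides = 2))[(r + 1):(r + nv)]
  }
  w <- apply(w, 2, conv1)
  t(apply(w, 1, conv1))
}

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite scalar", name))
  }
}
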