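#' Generate ground-truth pharmacokinetic maps for a dynamic phantom
#'
#' Builds a breast-like digital object: a smooth static background, a
#' circular enhancing tumor whose voxelwise volume transfer constant
#' (Ktrans, 1/min) and extravascular-extracellular volume fraction (ve)
#' are log-normally perturbed around requested means (then renormalized so
#' the tumor means match the request), and an acquisition time grid.
#'
#' @param shape length-2 integer vector `c(m, n)` (phase encodes, readouts).
#' @param d number of dynamic frames (>= 6).
#' @param tumor_spec list with elements `center` (row, col; default image
#'   centre), `radius` (voxels), `mean_ktrans` (1/min), `mean_ve` (in
#'   (0,1]), `heterogeneity` (log-normal sdlog of the multiplicative
#'   perturbation field), and `corr_len` (spatial correlation length of the
#'   heterogeneity field, voxels; default `radius / 2`). The perturbation
#'   field is spatially smooth: intra-tumor parameter variation in real
#'   lesions is structured, not voxelwise-independent noise.
#' @param dt frame spacing in minutes.
#' @param injection_index first post-contrast frame (1-based), in
#'   `[4, d - 3]` so at least 3 baseline and 3 late frames exist.
#' @param aif_params list passed to [aif()] (`D`, `a`, `m`, `t0`); `t0`
#'   defaults to the injection time.
#' @param seed integer RNG seed; identical seeds give identical maps.
#' @return object of class `ground_truth` with fields `ktrans_map`,
#'   `ve_map`, `tumor_mask`, `background`, `time_grid`, `aif_params`,
#'   `injection_index`.
#' @export
make_ground_truth <- function(shape = c(48, 32), d = 30,
                              tumor_spec = list(), dt = 0.15,
                              injection_index = 6,
                              aif_params = NULL, seed = 1) {
  stopifnot(length(shape) == 2L, all(shape >= 4), d >= 6)
  if (injection_index < 4 || injection_index > d - 3) {
    stop("'injection_index' must lie in [4, d - 3]")
  }
  m <- shape[1]; n <- shape[2]
  ts <- list(center = c(round((m + 1) / 2), round((n + 1) / 2)),
             radius = max(3, round(min(shape) / 5)),
             mean_ktrans = 0.425, mean_ve = 0.635, heterogeneity = 0.4,
             corr_len = NULL)
  ts[names(tumor_spec)] <- tumor_spec
  if (is.null(ts$corr_len)) ts$corr_len <- ts$radius / 2
  if (ts$radius < 1) stop("tumor radius must be >= 1 voxel")
  if (ts$center[1] < 1 || ts$center[1] > m ||
      ts$center[2] < 1 || ts$center[2] > n) {
    stop("tumor centre lies outside the image")
  }
  if (ts$mean_ktrans < 0) stop("mean Ktrans must be nonnegative")
  if (ts$mean_ve <= 0 || ts$mean_ve > 1) stop("mean ve must lie in (0, 1]")

  rr <- outer(seq_len(m) - ts$center[1], rep(1, n))
  cc <- outer(rep(1, m), seq_len(n) - ts$center[2])
  dist2 <- rr^2 + cc^2
  tumor_mask <- dist2 <= ts$radius^2
  if (!any(tumor_mask)) stop("tumor lies fully outside the image")

  ## smooth static background: broad elliptical 'breast' profile
  bg <- 0.3 + 0.4 * exp(-((rr / (0.7 * m))^2 + (cc / (0.7 * n))^2) * 4)

  ktrans_map <- matrix(0, m, n)
  ve_map <- matrix(ts$mean_ve, m, n)  # benign ve outside tumor (unused)
  with_seed(seed, {
    if (ts$heterogeneity > 0) {
      zk <- smooth_gaussian_field(m, n, ts$corr_len)
      zv <- smooth_gaussian_field(m, n, ts$corr_len)
      stdz <- function(z) {
        s <- stats::sd(z[tumor_mask])
        if (!is.finite(s) || s == 0) return(z * 0)
        (z - mean(z[tumor_mask])) / s
      }
      pk <- exp(ts$heterogeneity * stdz(zk))[tumor_mask]
      pv <- exp(ts$heterogeneity * stdz(zv))[tumor_mask]
    } else {
      pk <- rep(1, sum(tumor_mask)); pv <- rep(1, sum(tumor_mask))
    }
    ktrans_map[tumor_mask] <- ts$mean_ktrans * pk / mean(pk)
    ## renormalize the ve field to the requested mean, clipping at 0.99
    vev <- ts$mean_ve * pv / mean(pv)
    for (i in 1:3) {
      vev <- pmin(vev, 0.99)
      vev <- vev * ts$mean_ve / mean(vev)
    }
    vev <- pmin(vev, 0.99)
    ve_map[tumor_mask] <- vev
  })
  if (abs(mean(ve_map[tumor_mask]) / ts$mean_ve - 1) > 0.02) {
    stop("ve specification cannot stay within (0, 1]: the requested mean ",
         "and heterogeneity push too much mass above 1")
  }

  time_grid <- (seq_len(d) - 1) * dt
  ap <- list(D = 1, a = c(3.99, 4.78), m = c(0.144, 0.011),
             t0 = time_grid[injection_index])
  if (!is.null(aif_params)) ap[names(aif_params)] <- aif_params
  if (any(ap$m < 0) || ap$D < 0) stop("AIF rate constants must be nonnegative")

  structure(list(ktrans_map = ktrans_map, ve_map = ve_map,
                 tumor_mask = tumor_mask, background = bg,
                 time_grid = time_grid, aif_params = ap,
                 injection_index = injection_index, seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth: %d x %d image, %d dynamics, %d tumor voxels>\n",
    nrow(x$ktrans_map), ncol(x$ktrans_map), length(x$time_grid),
    sum(x$tumor_mask)))
  cat(sprintf("  tumor mean Ktrans = %.4f /min, mean ve = %.4f\n",
              mean(x$ktrans_map[x$tumor_mask]),
              mean(x$ve_map[x$tumor_mask])))
  invisible(x)
}

#' Biexponential plasma (arterial) input function
#'
#' Contrast concentration in blood plasma:
#' `Cp(t) = D * (a1 exp(-m1 (t - t0)) + a2 exp(-m2 (t - t0)))` for
#' `t >= t0`, and 0 before the injection time `t0`.
#'
#' @param time_grid increasing vector of times (min).
#' @param aif_params list with `D` (dose scaling), `a` (two amplitudes),
#'   `m` (two decay rates, 1/min), `t0` (injection time, min).
#' @return nonnegative plasma concentration at each time point.
#' @export
aif <- function(time_grid,
                aif_params = list(D = 1, a = c(3.99, 4.78),
                                  m = c(0.144, 0.011), t0 = 0)) {
  if (is.unsorted(time_grid, strictly = TRUE)) {
    stop("'time_grid' must be strictly increasing")
  }
  p <- aif_params
  if (any(p$m < 0)) stop("AIF decay rates must be nonnegative")
  if (p$D < 0) stop("AIF dose scaling must be nonnegative")
  dt <- time_grid - p$t0
  cp <- numeric(length(time_grid))
  post <- dt >= 0
  cp[post] <- p$D * (p$a[1] * exp(-p$m[1] * dt[post]) +
                       p$a[2] * exp(-p$m[2] * dt[post]))
  cp
}

#' Synthesize a noiseless complex dynamic image from ground truth
#'
#' Non-tumor voxels are constant in time at their background value; tumor
#' voxel time courses follow the enhancement-proportional signal model
#' `S(x, t) = background(x) * (1 + k * C_T(x, t))` with tissue
#' concentration `C_T` from the standard Tofts-Kety model
#' ([tofts_forward()]) driven by the ground-truth plasma input.
#'
#' @param gt a [make_ground_truth()] object.
#' @param k enhancement gain converting concentration to relative signal
#'   change (dimensionless). The default 0.5 gives peak tumor enhancement
#'   around 2.5-3x baseline, typical of malignant breast lesions.
#' @param refine temporal refinement factor of the convolution quadrature.
#' @return complex `m x n x d` array (zero imaginary part before noise),
#'   with `k` and the plasma curve attached as attributes.
#' @export
synthesize_dynamic_image <- function(gt, k = 0.5, refine = 10) {
  stopifnot(inherits(gt, "ground_truth"))
  m <- nrow(gt$ktrans_map); n <- ncol(gt$ktrans_map)
  d <- length(gt$time_grid)
  cp_fn <- function(t) aif(t, gt$aif_params)
  grid <- conv_grid(gt$time_grid, cp_fn, refine = refine)
  x <- array(0+0i, c(m, n, d))
  bgv <- as.vector(gt$background)
  for (t in seq_len(d)) x[, , t] <- gt$background + 0i
  idx <- which(gt$tumor_mask)
  for (i in idx) {
    ct <- tofts_forward(gt$ktrans_map[i], gt$ve_map[i], grid)
    x[arrayInd(i, c(m, n))[1], arrayInd(i, c(m, n))[2], ] <-
      bgv[i] * (1 + k * ct)
  }
  attr(x, "k") <- k
  attr(x, "cp") <- cp_fn(gt$time_grid)
  x
}

#' Simulate fully sampled noisy k-space from a dynamic image
#'
#' Applies the orthonormal 2-D spatial Fourier transform per frame and adds
#' independent complex white Gaussian noise (standard deviation
#' `noise_sigma` on the real and imaginary parts of every k-space sample).
#'
#' @param x complex `m x n x d` dynamic image.
#' @param noise_sigma nonnegative per-sample noise standard deviation.
#' @param seed integer RNG seed for the noise; identical seeds give
#'   identical noise realizations.
#' @return complex `m x n x d` k-space array (DC centred).
#' @export
simulate_kspace <- function(x, noise_sigma = 0, seed = 1) {
  if (noise_sigma < 0) stop("'noise_sigma' must be nonnegative")
  k <- spatial_fft2(x)
  if (noise_sigma > 0) {
    nel <- length(k)
    noise <- with_seed(seed, {
      complex(real = stats::rnorm(nel, sd = noise_sigma),
              imaginary = stats::rnorm(nel, sd = noise_sigma))
    })
    k <- k + array(noise, dim(k))
  }
  k
}
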