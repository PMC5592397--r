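#' Signal-to-error ratio (dB)
#'
#' `SER = -20 log10( ||X_hat - X_fs||_F / ||X_fs||_F )`, by default on
#' magnitude images; higher is better. An exact reconstruction returns
#' `Inf`.
#'
#' @param x_hat reconstructed image array.
#' @param x_fs fully sampled reference array (nonzero).
#' @param use_magnitude compare magnitudes (default) or complex values.
#' @return SER in dB.
#' @export
ser <- function(x_hat, x_fs, use_magnitude = TRUE) {
  stopifnot(all(dim(x_hat) == dim(x_fs)) || length(x_hat) == length(x_fs))
  if (use_magnitude) {
    x_hat <- Mod(x_hat); x_fs <- Mod(x_fs)
  }
  ref <- fnorm(x_fs)
  if (ref == 0) stop("reference image is identically zero")
  err <- fnorm(x_hat - x_fs)
  if (err == 0) return(Inf)
  -20 * log10(err / ref)
}

#' Concordance correlation coefficient
#'
#' Lin's agreement coefficient between two paired vectors,
#' `2 cov(a, b) / (var(a) + var(b) + (mean(a) - mean(b))^2)` with
#' population (1/n) moments: 1 only for perfect agreement (`a == b`),
#' penalizing both dispersion and location differences. `form =
#' "as_printed"` instead uses `2 sd(a) sd(b)` in the numerator, a variant
#' that ignores the pairing; it is provided for comparison only.
#'
#' @param a,b numeric vectors of equal length (>= 2). NA pairs are dropped.
#' @param form `"lin"` (default) or `"as_printed"`.
#' @return coefficient in `[-1, 1]`.
#' @export
ccc <- function(a, b, form = c("lin", "as_printed")) {
  form <- match.arg(form)
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) stop("need at least 2 complete pairs")
  ma <- mean(a); mb <- mean(b)
  va <- mean((a - ma)^2); vb <- mean((b - mb)^2)
  if (va == 0 && vb == 0 && ma == mb) return(1)
  if (va == 0 && vb == 0) stop("both inputs are constant with unequal means")
  num <- if (form == "lin") 2 * mean((a - ma) * (b - mb)) else
    2 * sqrt(va) * sqrt(vb)
  num / (va + vb + (ma - mb)^2)
}

#' Mean of a parameter map over an ROI
#'
#' Arithmetic mean over mask voxels having a defined (non-NA) estimate.
#'
#' @param map numeric matrix (NA where no estimate exists).
#' @param tumor_mask logical matrix.
#' @return scalar mean.
#' @export
tumor_mean <- function(map, tumor_mask) {
  stopifnot(all(dim(map) == dim(tumor_mask)))
  vals <- map[tumor_mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop("no defined estimates inside the mask")
  mean(vals)
}

#' ROI signal-intensity curve differences against the reference
#'
#' Per-dynamic difference of ROI-mean magnitude signal between a
#' reconstruction and the fully sampled reference, plus (optionally) the
#' difference time course of a single voxel.
#'
#' @param x_hat,x_fs `m x n x d` image arrays.
#' @param tumor_mask logical `m x n` ROI.
#' @param voxel optional `c(row, col)` index for a single-voxel curve.
#' @return list with `mean_delta` (length-d vector) and `voxel_delta`
#'   (length-d vector or NULL).
#' @export
curve_difference <- function(x_hat, x_fs, tumor_mask, voxel = NULL) {
  if (!any(tumor_mask)) stop("ROI mask is empty")
  a <- Mod(as_tdim_array(x_hat)$x)
  b <- Mod(as_tdim_array(x_fs)$x)
  d <- dim(a)[3]
  md <- vapply(seq_len(d), function(t) {
    mean(a[, , t][tumor_mask]) - mean(b[, , t][tumor_mask])
  }, numeric(1))
  vd <- NULL
  if (!is.null(voxel)) {
    vd <- a[voxel[1], voxel[2], ] - b[voxel[1], voxel[2], ]
  }
  list(mean_delta = md, voxel_delta = vd)
}

#' Bland-Altman agreement data
#'
#' Differences `a - b_fs` against an abscissa (by default the fully sampled
#' values themselves, matching plots drawn relative to the fully sampled
#' parameter values; `abscissa = "mean"` gives the conventional pairwise
#' mean), with bias (mean difference) and 95% limits of agreement
#' `bias +/- 1.96 sd`.
#'
#' @param a parameter estimates under test.
#' @param b_fs fully sampled reference estimates (same length).
#' @param abscissa `"fs"` (default) or `"mean"`.
#' @return list with `table` (data frame: abscissa, difference), `bias`,
#'   `lower`, `upper`.
#' @export
bland_altman <- function(a, b_fs, abscissa = c("fs", "mean")) {
  abscissa <- match.arg(abscissa)
  if (length(a) != length(b_fs)) stop("'a' and 'b_fs' must have equal length")
  keep <- is.finite(a) & is.finite(b_fs)
  a <- a[keep]; b_fs <- b_fs[keep]
  diffs <- a - b_fs
  xs <- if (abscissa == "fs") b_fs else (a + b_fs) / 2
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  list(table = data.frame(abscissa = xs, difference = diffs),
       bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s)
}

#' Pairwise paired significance tests across sampling seeds
#'
#' For each pair of regularizers, a paired two-sided Wilcoxon signed-rank
#' test on the per-seed values of a metric, with Holm adjustment across
#' pairs. Identical series (all differences zero) yield p = 1.
#'
#' @param records data frame with columns `seed`, `regularizer`, and the
#'   metric column.
#' @param metric name of the metric column (e.g. `"ser_db"`).
#' @return data frame with columns `a`, `b`, `p_value`, `p_adjusted`.
#' @export
paired_compare <- function(records, metric) {
  stopifnot(all(c("seed", "regularizer", metric) %in% names(records)))
  regs <- sort(unique(records$regularizer))
  if (length(regs) < 2) stop("need at least 2 regularizers")
  seed_sets <- tapply(records$seed, records$regularizer,
                      function(s) paste(sort(s), collapse = ","))
  if (length(unique(seed_sets)) != 1) {
    stop("regularizers were not evaluated on matched seed sets")
  }
  pairs <- utils::combn(regs, 2)
  out <- data.frame(a = pairs[1, ], b = pairs[2, ],
                    p_value = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    va <- records[records$regularizer == pairs[1, i], ]
    vb <- records[records$regularizer == pairs[2, i], ]
    va <- va[order(va$seed), metric]
    vb <- vb[order(vb$seed), metric]
    dd <- va - vb
    out$p_value[i] <- if (all(dd == 0)) 1 else {
      suppressWarnings(stats::wilcox.test(va, vb, paired = TRUE,
                                          exact = FALSE)$p.value)
    }
  }
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  out
}
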