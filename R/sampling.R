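#' Generate a seeded Cartesian variable-density undersampling mask
#'
#' Per dynamic frame, a central window of `center_width` phase-encode lines
#' is always fully sampled; peripheral lines are chosen randomly such that
#' across the whole acquisition each peripheral line is sampled roughly the
#' same number of times, but at random time points. A sampled line covers
#' all readout points. The number of lines per frame is set from the target
#' acceleration: `round(n_pe / target_R)` lines in total, of which
#' `p = round(n_pe / target_R) - center_width` are peripheral.
#'
#' @param n_pe number of phase-encode lines (first mask dimension).
#' @param n_ro number of readout points (fully sampled direction).
#' @param d number of dynamic frames.
#' @param center_width number of always-sampled central lines.
#' @param target_R requested overall acceleration factor.
#' @param seed integer RNG seed; masks are bit-reproducible per seed.
#' @param mode `"balanced"` (default) distributes an even per-line quota of
#'   peripheral samples over random time points, so the per-frame line
#'   count varies slightly around `p`; `"fixed_p"` draws exactly `p`
#'   peripheral lines per frame, greedily balancing per-line totals.
#' @return object of class `mask_set` with the binary `mask` array
#'   (`n_pe x n_ro x d`), `center_width`, `target_R`, `seed`, `mode`.
#' @export
make_mask <- function(n_pe, n_ro, d, center_width = 20, target_R = 4.5,
                      seed = 1, mode = c("balanced", "fixed_p")) {
  mode <- match.arg(mode)
  if (center_width >= n_pe) stop("'center_width' must be smaller than 'n_pe'")
  if (target_R < 1) stop("'target_R' must be >= 1")
  lines_per_frame <- round(n_pe / target_R)
  p <- lines_per_frame - center_width
  if (p < 0) {
    stop("target acceleration is unreachable: the central window alone ",
         "already samples more lines than round(n_pe / target_R)")
  }
  c0 <- floor((n_pe - center_width) / 2) + 1L
  center_idx <- seq(c0, length.out = center_width)
  periph_idx <- setdiff(seq_len(n_pe), center_idx)
  np <- length(periph_idx)

  pe_sampled <- matrix(FALSE, n_pe, d)
  pe_sampled[center_idx, ] <- TRUE

  if (p > 0 && np > 0) {
    with_seed(seed, {
      if (mode == "balanced") {
        budget <- p * d
        q <- budget %/% np
        r <- budget %% np
        quota <- rep(q, np)
        if (r > 0) quota[sample.int(np, r)] <- q + 1L
        for (j in seq_len(np)) {
          if (quota[j] > 0) {
            frames <- sample.int(d, min(quota[j], d))
            pe_sampled[periph_idx[j], frames] <- TRUE
          }
        }
      } else {
        counts <- rep(0L, np)
        for (t in seq_len(d)) {
          tie <- sample.int(np)
          ord <- order(counts[tie])
          pick <- tie[ord][seq_len(p)]
          pe_sampled[periph_idx[pick], t] <- TRUE
          counts[pick] <- counts[pick] + 1L
        }
      }
    })
  }

  mask <- array(0L, c(n_pe, n_ro, d))
  for (t in seq_len(d)) {
    mask[pe_sampled[, t], , t] <- 1L
  }
  structure(list(mask = mask, center_width = center_width,
                 target_R = target_R, seed = seed, mode = mode,
                 center_idx = center_idx),
            class = "mask_set")
}

#' Achieved acceleration of a sampling mask
#'
#' Total number of k-space entries divided by the number of sampled
#' entries.
#'
#' @param maskset a [make_mask()] object, or a binary array.
#' @return acceleration factor (>= 1).
#' @export
acceleration <- function(maskset) {
  m <- if (inherits(maskset, "mask_set")) maskset$mask else maskset
  ns <- sum(m != 0)
  if (ns == 0) stop("mask has no sampled entries")
  length(m) / ns
}

#' @export
print.mask_set <- function(x, ...) {
  dm <- dim(x$mask)
  cat(sprintf(
    "<mask_set: %d PE x %d RO x %d dynamics, center %d, R = %.3f (target %.2f), seed %d>\n",
    dm[1], dm[2], dm[3], x$center_width, acceleration(x), x$target_R, x$seed))
  invisible(x)
}

#' Render a mask's phase-encode/time pattern to TSV (and optionally PNG)
#'
#' Writes the `n_pe x d` line-sampling pattern (readout collapsed, as all
#' readout points of a sampled line are acquired) as a tab-separated 0/1
#' table, and optionally as a PNG image for visual inspection.
#'
#' @param maskset a [make_mask()] object.
#' @param tsv_path output TSV path.
#' @param png_path optional PNG path (requires the \pkg{png} package).
#' @return invisibly, the `n_pe x d` binary matrix.
#' @export
render_mask <- function(maskset, tsv_path, png_path = NULL) {
  stopifnot(inherits(maskset, "mask_set"))
  pat <- maskset$mask[, 1, ]
  utils::write.table(pat, tsv_path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(png_path)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the 'png' package is required for PNG rendering")
    }
    png::writePNG(1 - pat, png_path)
  }
  invisible(pat)
}
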