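#' Write a real or complex dynamic array as NIfTI
#'
#' Real arrays are written as a single volume (dynamics on the 4th axis);
#' complex arrays as a pair of `_real` / `_imag` volumes.
#'
#' @param x 2-D/3-D numeric or complex array.
#' @param path output path (`.nii` / `.nii.gz`); for complex input the
#'   suffixes `_real` and `_imag` are inserted before the extension.
#' @return invisibly, the path(s) written.
#' @export
write_dynamic_nifti <- function(x, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the 'RNifti' package is required for NIfTI output")
  }
  if (is.complex(x)) {
    paths <- c(sub("(\\.nii(\\.gz)?)$", "_real\\1", path),
               sub("(\\.nii(\\.gz)?)$", "_imag\\1", path))
    RNifti::writeNifti(Re(x), paths[1])
    RNifti::writeNifti(Im(x), paths[2])
    return(invisible(paths))
  }
  RNifti::writeNifti(x, path)
  invisible(path)
}

#' Read a dynamic array written by [write_dynamic_nifti()]
#'
#' @param path path given at write time; if the `_real`/`_imag` pair
#'   exists, the complex array is reassembled.
#' @return numeric or complex array.
#' @export
read_dynamic_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the 'RNifti' package is required for NIfTI input")
  }
  pre <- sub("(\\.nii(\\.gz)?)$", "_real\\1", path)
  pim <- sub("(\\.nii(\\.gz)?)$", "_imag\\1", path)
  if (file.exists(pre) && file.exists(pim)) {
    re <- as.array(RNifti::readNifti(pre))
    im <- as.array(RNifti::readNifti(pim))
    out <- re + 1i * im
    dim(out) <- dim(re)
    return(out)
  }
  as.array(RNifti::readNifti(path))
}

#' Write a k-space / mask / time-grid container
#'
#' Stores complex k-space and the sampling mask as NIfTI volumes plus a
#' JSON sidecar holding the time grid and mask metadata, under a common
#' path prefix.
#'
#' @param prefix output path prefix (files `<prefix>_kspace_real.nii.gz`,
#'   `<prefix>_kspace_imag.nii.gz`, `<prefix>_mask.nii.gz`,
#'   `<prefix>_meta.json` are written).
#' @param kspace complex `m x n x d` array.
#' @param maskset [make_mask()] object (optional).
#' @param time_grid acquisition times (optional).
#' @return invisibly, the vector of files written.
#' @export
write_kspace_container <- function(prefix, kspace, maskset = NULL,
                                   time_grid = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the 'jsonlite' package is required")
  }
  files <- write_dynamic_nifti(kspace, paste0(prefix, "_kspace.nii.gz"))
  meta <- list(shape = dim(kspace))
  if (!is.null(maskset)) {
    mfile <- paste0(prefix, "_mask.nii.gz")
    write_dynamic_nifti(maskset$mask + 0, mfile)
    files <- c(files, mfile)
    meta$mask <- list(center_width = maskset$center_width,
                      target_R = maskset$target_R, seed = maskset$seed,
                      mode = maskset$mode)
  }
  if (!is.null(time_grid)) meta$time_grid <- time_grid
  jfile <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, jfile, auto_unbox = TRUE, digits = NA)
  invisible(c(files, jfile))
}

#' Read a k-space container written by [write_kspace_container()]
#'
#' @param prefix path prefix used at write time.
#' @return list with `kspace`, `mask` (or NULL), `meta`.
#' @export
read_kspace_container <- function(prefix) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the 'jsonlite' package is required")
  }
  kspace <- read_dynamic_nifti(paste0(prefix, "_kspace.nii.gz"))
  mfile <- paste0(prefix, "_mask.nii.gz")
  mask <- if (file.exists(mfile)) read_dynamic_nifti(mfile) else NULL
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  list(kspace = kspace, mask = mask, meta = meta)
}

#' Write ensemble records and summary as CSV
#'
#' One tidy CSV with a row per seed x regularizer, and one summary CSV with
#' per-regularizer statistics.
#'
#' @param result an [run_experiment()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_records_csv <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "records.csv")
  p2 <- file.path(dir, "summary.csv")
  utils::write.csv(result$records, p1, row.names = FALSE)
  utils::write.csv(result$summary, p2, row.names = FALSE)
  paths <- c(p1, p2)
  if (!is.null(result$tests)) {
    p3 <- file.path(dir, "pairwise_tests.csv")
    utils::write.csv(result$tests, p3, row.names = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}

#' Crop a rectangular region from user-supplied dynamic data
#'
#' Utility for trimming regions (for example posterior of the chest wall)
#' from an imported complex spatiotemporal array before reconstruction.
#'
#' @param x `m x n x d` array.
#' @param rows,cols integer ranges to keep.
#' @return cropped array.
#' @export
crop_dynamic <- function(x, rows, cols) {
  a <- as_tdim_array(x)$x
  a[rows, cols, , drop = FALSE]
}
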