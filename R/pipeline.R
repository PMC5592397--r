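#' Configuration of a full ensemble experiment
#'
#' Bundles the phantom specification, the sampling-mask ensemble, the set
#' of reconstruction configurations, and the pharmacokinetic fitting
#' options driving [run_experiment()].
#'
#' @param shape image dimensions `c(m, n)` (phase encodes, readouts).
#' @param d number of dynamic frames.
#' @param n_seeds number of random sampling patterns in the ensemble.
#' @param target_R requested acceleration.
#' @param center_width always-sampled central phase-encode lines. The
#'   default preserves the center fraction of the full-size protocol
#'   (20 of 128 lines) at the configured `shape`.
#' @param regularizers character vector of regularizer labels (see
#'   [recon_config()]).
#' @param noise_sigma complex-noise standard deviation per k-space sample.
#' @param tumor_spec phantom tumor specification (see
#'   [make_ground_truth()]).
#' @param dt frame spacing (min).
#' @param injection_index first post-contrast frame.
#' @param k enhancement gain of the signal model.
#' @param seed global integer seed; all per-stage seeds derive from it.
#' @param recon_overrides named list of per-regularizer [recon_config()]
#'   override lists, e.g. `list(TV = list(iter = 50))`.
#' @param ccc_population `"enhancing"` (default: all voxels enhancing in
#'   the fully sampled reference) or `"tumor"` (ground-truth tumor mask)
#'   for the primary CCC columns; the other population is reported too.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(shape = c(48, 32), d = 30, n_seeds = 10,
                              target_R = 4.5,
                              center_width = max(2, round(shape[1] * 20 / 128)),
                              regularizers = c("ZF", "FT", "WT", "TV",
                                               "TGV", "NN"),
                              noise_sigma = 0.01, tumor_spec = list(),
                              dt = 0.15, injection_index = 6, k = 0.5,
                              seed = 1, recon_overrides = list(),
                              ccc_population = c("enhancing", "tumor")) {
  stopifnot(n_seeds >= 1, length(shape) == 2)
  ccc_population <- match.arg(ccc_population)
  regularizers <- toupper(regularizers)
  bad <- setdiff(regularizers, c("ZF", "FT", "WT", "TV", "TGV", "NN"))
  if (length(bad)) stop("unknown regularizers: ", paste(bad, collapse = ", "))
  ## validate mask feasibility and sub-configs up front
  invisible(make_mask(shape[1], shape[2], d, center_width = center_width,
                      target_R = target_R, seed = 1))
  for (r in regularizers) {
    do.call(recon_config, c(list(regularizer = r),
                            recon_overrides[[r]] %||% list()))
  }
  structure(list(shape = shape, d = d, n_seeds = n_seeds,
                 target_R = target_R, center_width = center_width,
                 regularizers = regularizers, noise_sigma = noise_sigma,
                 tumor_spec = tumor_spec, dt = dt,
                 injection_index = injection_index, k = k, seed = seed,
                 recon_overrides = recon_overrides,
                 ccc_population = ccc_population),
            class = "experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full ensemble experiment
#'
#' Generates the phantom and its fully sampled noisy k-space once, computes
#' the fully sampled reference image and reference pharmacokinetic maps
#' once, then for every mask seed: generates a sampling pattern,
#' retrospectively undersamples the shared k-space, reconstructs with every
#' configured regularizer, fits voxelwise Tofts-Kety maps, and records
#' per-(seed, regularizer) evaluation rows (SER against the fully sampled
#' image, CCC of Ktrans and ve against the reference maps, tumor means,
#' achieved acceleration).
#'
#' @param config an [experiment_config()].
#' @param verbose print per-stage progress.
#' @return object of class `experiment_result`: `records` (data frame, one
#'   row per seed x regularizer), `summary` (per-regularizer statistics),
#'   `tests` (pairwise paired comparisons of SER), `gt`, `reference`
#'   (fully sampled image and maps), `config`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  gt <- make_ground_truth(shape = config$shape, d = config$d,
                          tumor_spec = config$tumor_spec, dt = config$dt,
                          injection_index = config$injection_index,
                          seed = derive_seed(config$seed, 0))
  say("phantom: %d tumor voxels", sum(gt$tumor_mask))
  X <- synthesize_dynamic_image(gt, k = config$k)
  ksp <- simulate_kspace(X, noise_sigma = config$noise_sigma,
                         seed = derive_seed(config$seed, 1))
  x_fs <- spatial_ifft2(ksp)

  say("fitting fully sampled reference maps")
  nb <- config$injection_index - 1L
  ref_maps <- fit_map(Mod(x_fs), gt, k = config$k, n_baseline = nb)
  ref_pop <- if (config$ccc_population == "enhancing") {
    ref_maps$enhancing_mask & !is.na(ref_maps$ktrans)
  } else {
    gt$tumor_mask & !is.na(ref_maps$ktrans)
  }
  if (!any(ref_pop)) stop("reference maps contain no usable voxels")

  rows <- list()
  failures <- list()
  for (s in seq_len(config$n_seeds)) {
    mseed <- derive_seed(config$seed, 100 + s)
    maskset <- make_mask(config$shape[1], config$shape[2], config$d,
                         center_width = config$center_width,
                         target_R = config$target_R, seed = mseed)
    B <- ksp * maskset$mask
    for (r in config$regularizers) {
      rc <- do.call(recon_config,
                    c(list(regularizer = r),
                      config$recon_overrides[[r]] %||% list()))
      row <- tryCatch({
        res <- reconstruct(B, maskset, rc)
        maps <- fit_map(Mod(res$image), gt, k = config$k, n_baseline = nb)
        both <- ref_pop & !is.na(maps$ktrans)
        data.frame(
          seed = s, mask_seed = mseed, regularizer = r,
          ser_db = ser(res$image, x_fs),
          ccc_ktrans = ccc(maps$ktrans[both], ref_maps$ktrans[both]),
          ccc_ve = ccc(maps$ve[both], ref_maps$ve[both]),
          tumor_mean_ktrans = tumor_mean(maps$ktrans, gt$tumor_mask),
          tumor_mean_ve = tumor_mean(maps$ve, gt$tumor_mask),
          achieved_R = acceleration(maskset),
          n_fit_failed = maps$n_failed,
          iterations = res$iterations_run)
      }, error = function(e) {
        failures[[length(failures) + 1L]] <<-
          list(seed = s, regularizer = r, message = conditionMessage(e))
        NULL
      })
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
      say("seed %d / %s: done", s, r)
    }
  }
  if (!length(rows)) stop("every (seed, regularizer) stage failed")
  records <- do.call(rbind, rows)
  structure(list(records = records,
                 summary = summarize_records(records),
                 tests = if (length(unique(records$regularizer)) > 1 &&
                             config$n_seeds > 1)
                   paired_compare(records, "ser_db") else NULL,
                 gt = gt, reference = list(x_fs = x_fs, maps = ref_maps,
                                           population = ref_pop),
                 failures = failures, config = config),
            class = "experiment_result")
}

#' Per-regularizer summary of ensemble records
#'
#' Grouped mean, median, and interquartile range of SER, CCCs, and tumor
#' means across sampling seeds, in a layout with one row per regularizer.
#'
#' @param records data frame of evaluation rows from [run_experiment()].
#' @return data frame of grouped statistics.
#' @export
summarize_records <- function(records) {
  if (!nrow(records)) stop("no records to summarize")
  metrics <- c("ser_db", "ccc_ktrans", "ccc_ve",
               "tumor_mean_ktrans", "tumor_mean_ve")
  metrics <- intersect(metrics, names(records))
  regs <- unique(records$regularizer)
  out <- lapply(regs, function(r) {
    sub <- records[records$regularizer == r, , drop = FALSE]
    row <- data.frame(regularizer = r, n = nrow(sub))
    for (mcol in metrics) {
      v <- sub[[mcol]]
      row[[paste0("mean_", mcol)]] <- mean(v)
      row[[paste0("median_", mcol)]] <- stats::median(v)
      row[[paste0("iqr_", mcol)]] <- stats::IQR(v)
    }
    row
  })
  do.call(rbind, out)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result: %d seeds x {%s}>\n",
              x$config$n_seeds,
              paste(x$config$regularizers, collapse = ", ")))
  cols <- intersect(c("regularizer", "n", "median_ser_db",
                      "median_ccc_ktrans", "median_ccc_ve"),
                    names(x$summary))
  print(x$summary[, cols], row.names = FALSE, digits = 4)
  if (length(x$failures)) {
    cat(sprintf("  %d stage failure(s) recorded\n", length(x$failures)))
  }
  invisible(x)
}
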