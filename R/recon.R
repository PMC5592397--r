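## Reconstruction parameter sets used throughout: regularization weight
## alpha, outer iteration cap, primal-dual steps sigma/tau and fidelity
## weight lambda (TV/TGV only), stopping tolerance on the relative image
## change, and inner prox iterations for TV/TGV.
.table1_defaults <- list(
  FT  = list(alpha = 0.059, iter = 35,  sigma = NA,  tau_step = NA,  lam = NA),
  WT  = list(alpha = 0.008, iter = 60,  sigma = NA,  tau_step = NA,  lam = NA),
  TV  = list(alpha = 0.5,   iter = 100, sigma = 0.2, tau_step = 0.2, lam = 0.5),
  TGV = list(alpha = 0.5,   iter = 100, sigma = 0.2, tau_step = 0.2, lam = 0.5),
  NN  = list(alpha = 0.3,   iter = 40,  sigma = NA,  tau_step = NA,  lam = NA),
  ZF  = list(alpha = 0,     iter = 1,   sigma = NA,  tau_step = NA,  lam = NA)
)

#' Reconstruction configuration for one temporal regularizer
#'
#' Returns the published tuning for each regularizer (regularization weight
#' `alpha`, outer iteration cap, and for TV/TGV the primal-dual step sizes
#' `sigma`/`tau_step` and fidelity weight `lam`), overridable field by
#' field. `ZF` denotes the unregularized zero-filled baseline.
#'
#' @param regularizer one of `"FT"`, `"WT"`, `"TV"`, `"TGV"`, `"NN"`,
#'   `"ZF"`.
#' @param ... overrides: `alpha`, `iter`, `sigma`, `tau_step`, `lam`,
#'   `tol`, `inner_iter`, `alpha1`, `alpha0`, `mode`. For TV/TGV, `mode`
#'   selects the solver: `"pd"` (default) runs a standalone Chambolle-Pock
#'   primal-dual scheme whose step sizes are the published `sigma`/`tau`
#'   (they satisfy the primal-dual step condition
#'   `sigma * tau * ||grad_t||^2 <= 1` exactly); `"fista"` runs FISTA with
#'   the TV/TGV proximal map solved inexactly by `inner_iter` primal-dual
#'   iterations.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(regularizer = c("FT", "WT", "TV", "TGV", "NN", "ZF"),
                         ...) {
  regularizer <- match.arg(toupper(regularizer[1]),
                           c("FT", "WT", "TV", "TGV", "NN", "ZF"))
  cfg <- .table1_defaults[[regularizer]]
  cfg$regularizer <- regularizer
  cfg$tol <- 1e-3
  cfg$inner_iter <- 10
  cfg$mode <- if (regularizer %in% c("TV", "TGV")) "pd" else "fista"
  ## TGV weight split: the published tuning lists a single alpha; default
  ## first-order weight alpha1 = alpha and second-order alpha0 = 2 * alpha.
  cfg$alpha1 <- cfg$alpha
  cfg$alpha0 <- 2 * cfg$alpha
  dots <- list(...)
  bad <- setdiff(names(dots), c("alpha", "iter", "sigma", "tau_step", "lam",
                                "tol", "inner_iter", "alpha1", "alpha0",
                                "mode"))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  if ("alpha" %in% names(dots) && !("alpha1" %in% names(dots))) {
    dots$alpha1 <- dots$alpha
  }
  if ("alpha" %in% names(dots) && !("alpha0" %in% names(dots))) {
    dots$alpha0 <- 2 * dots$alpha
  }
  cfg[names(dots)] <- dots
  if (cfg$alpha < 0) stop("'alpha' must be nonnegative")
  if (cfg$iter < 1) stop("'iter' must be >= 1")
  if (cfg$tol <= 0) stop("'tol' must be positive")
  if (!cfg$mode %in% c("pd", "fista")) stop("'mode' must be 'pd' or 'fista'")
  structure(cfg, class = "recon_config")
}

#' @export
print.recon_config <- function(x, ...) {
  cat(sprintf("<recon_config: %s, alpha = %g, iter = %d, tol = %g>\n",
              x$regularizer, x$alpha, x$iter, x$tol))
  invisible(x)
}

#' Rescale measured k-space so image magnitudes lie in [0, 1]
#'
#' Divides the data by the maximum magnitude of its zero-filled
#' reconstruction, returning the scaled data and the factor needed to undo
#' the scaling on reconstructed images.
#'
#' @param B measured (possibly undersampled) k-space array.
#' @param maskset optional [make_mask()] object or binary array applied
#'   before the zero-filled transform.
#' @return list with `B_scaled` and `scale_factor` (the divisor).
#' @export
rescale_to_unit <- function(B, maskset = NULL) {
  zf <- zero_filled(B, maskset)
  s <- max(Mod(zf))
  if (s == 0) stop("all-zero data cannot be rescaled")
  list(B_scaled = B / s, scale_factor = s)
}

#' Zero-filled reconstruction
#'
#' Inverse orthonormal spatial Fourier transform of the measured data with
#' unmeasured k-space entries set to zero: the unregularized baseline.
#'
#' @param B measured k-space array (`m x n x d`, DC centred).
#' @param maskset optional [make_mask()] object or binary array; when
#'   supplied, `B` is masked before the inverse transform.
#' @return complex dynamic image.
#' @export
zero_filled <- function(B, maskset = NULL) {
  if (!is.null(maskset)) {
    m <- if (inherits(maskset, "mask_set")) maskset$mask else maskset
    stopifnot(all(dim(m) == dim(B)))
    B <- B * m
  }
  spatial_ifft2(B)
}

#' Gradient of the data-fidelity term
#'
#' For `f(X) = 0.5 * ||A X - B||_F^2` with `A = M F` (sampling mask times
#' unitary spatial Fourier transform), returns `A^H (A X - B)`. Under the
#' orthonormal convention the Lipschitz constant of this gradient is 1.
#'
#' @param X current image iterate.
#' @param B measured (masked) k-space.
#' @param maskset [make_mask()] object or binary array.
#' @return complex gradient array shaped like `X`.
#' @export
data_fidelity_grad <- function(X, B, maskset) {
  m <- if (inherits(maskset, "mask_set")) maskset$mask else maskset
  spatial_ifft2(m * spatial_fft2(X) - m * B)
}

#' Accelerated proximal-gradient (FISTA) solver
#'
#' Minimizes `f(x) + g(x)` for smooth convex `f` (gradient `grad_f`,
#' Lipschitz constant `L_f`) and convex `g` given through its proximal map,
#' using the momentum sequence `t_{k+1} = (1 + sqrt(1 + 4 t_k^2)) / 2` and
#' extrapolated evaluation points. Iterations stop when the relative image
#' change drops below `tol` or after `max_iter` iterations.
#'
#' @param grad_f function of the iterate returning the gradient of `f`.
#' @param prox_g function `(x, tau)` returning the proximal map of `g` at
#'   step `tau`.
#' @param x0 starting iterate.
#' @param L_f Lipschitz constant of `grad_f` (> 0); the step is `1 / L_f`.
#' @param max_iter iteration cap.
#' @param tol relative-change stopping threshold.
#' @param objective optional function of the iterate returning the
#'   objective value, recorded per iteration; if it ever exceeds 10x its
#'   initial value the solver aborts with a divergence diagnostic.
#' @return list with `x`, `objective_trace`, `rel_change_trace`,
#'   `iterations_run`.
#' @export
fista <- function(grad_f, prox_g, x0, L_f = 1, max_iter = 100, tol = 1e-3,
                  objective = NULL) {
  if (L_f <= 0) stop("'L_f' must be positive")
  x <- x0
  y <- x0
  tk <- 1
  obj <- numeric(0)
  relch <- numeric(0)
  obj0 <- if (!is.null(objective)) objective(x0) else NA_real_
  iters <- 0L
  for (k in seq_len(max_iter)) {
    iters <- k
    xnew <- prox_g(y - grad_f(y) / L_f, 1 / L_f)
    tnew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- xnew + ((tk - 1) / tnew) * (xnew - x)
    rc <- fnorm(xnew - x) / max(fnorm(x), .Machine$double.eps)
    relch <- c(relch, rc)
    if (!is.null(objective)) {
      ov <- objective(xnew)
      obj <- c(obj, ov)
      if (is.finite(obj0) && obj0 > 0 && ov > 10 * obj0) {
        stop(sprintf(
          "FISTA diverged: objective %.3g exceeds 10x initial %.3g at iteration %d",
          ov, obj0, k))
      }
    }
    x <- xnew
    tk <- tnew
    if (rc < tol) break
  }
  list(x = x, objective_trace = obj, rel_change_trace = relch,
       iterations_run = iters)
}

## regularizer value S(X) for the objective trace (TGV uses the auxiliary
## field carried by the prox solver, giving an upper bound on TGV(X))
.reg_value <- function(X, cfg, ops, v = NULL) {
  switch(cfg$regularizer,
         FT = sum(Mod(ops$ft$forward(X))),
         WT = sum(Mod(ops$wt$forward(X))),
         TV = sum(Mod(temporal_diff(X))),
         TGV = {
           if (is.null(v)) {
             v <- array(0+0i, c(dim(X)[1:2], dim(X)[3] - 1L))
           }
           cfg$alpha1 / cfg$alpha * sum(Mod(tdiff_link(X) - v)) +
             cfg$alpha0 / cfg$alpha * sum(Mod(tdiff_link(v)))
         },
         NN = sum(svd(casorati(X))$d),
         ZF = 0)
}

## Standalone Chambolle-Pock reconstruction for TV/TGV:
## min_X  1/(2 lam) ||A X - B||_F^2 + alpha ||grad_t X||_1         (TV)
## min_X,v 1/(2 lam) ||A X - B||^2 + a1 ||grad_t X - v||_1
##                                 + a0 ||grad_t v||_1              (TGV)
## The fidelity term is handled by its exact proximal map (diagonal in
## k-space because A is a masked unitary transform); the l1 terms are
## dualized with clipped dual ascent.
recon_primal_dual <- function(Bs, msk, config, track_objective = FALSE) {
  tgv <- config$regularizer == "TGV"
  sigma <- config$sigma; tau <- config$tau_step; lam <- config$lam
  X <- zero_filled(Bs)
  Xb <- X
  d <- dim(X)[3]
  zero <- array(0+0i, dim(X))
  zerol <- array(0+0i, c(dim(X)[1:2], d - 1L))
  q <- if (tgv) array(0+0i, c(dim(X)[1:2], d - 2L)) else zero
  r <- zerol; v <- zerol; vb <- zerol
  prox_fid <- function(Y) {
    KY <- spatial_fft2(Y)
    spatial_ifft2((KY + (tau / lam) * msk * Bs) / (1 + (tau / lam) * msk))
  }
  obj <- numeric(0)
  relch <- numeric(0)
  objective <- function(X, v) {
    fid <- sum(Mod(msk * spatial_fft2(X) - Bs)^2) / (2 * lam)
    if (tgv) {
      fid + config$alpha1 * sum(Mod(tdiff_link(X) - v)) +
        config$alpha0 * sum(Mod(tdiff_link(v)))
    } else {
      fid + config$alpha * sum(Mod(temporal_diff(X)))
    }
  }
  iters <- 0L
  for (it in seq_len(config$iter)) {
    iters <- it
    if (tgv) {
      r <- dual_clip(r + sigma * (tdiff_link(Xb) - vb), config$alpha1)
      q <- dual_clip(q + sigma * tdiff_link(vb), config$alpha0)
      Xn <- prox_fid(X - tau * tdiff_link_adj(r))
      vn <- v - tau * (tdiff_link_adj(q) - r)
      vb <- 2 * vn - v
      v <- vn
    } else {
      q <- dual_clip(q + sigma * temporal_diff(Xb), config$alpha)
      Xn <- prox_fid(X - tau * temporal_diff_adjoint(q))
    }
    rc <- fnorm(Xn - X) / max(fnorm(X), .Machine$double.eps)
    relch <- c(relch, rc)
    if (track_objective) obj <- c(obj, objective(Xn, v))
    Xb <- 2 * Xn - X
    X <- Xn
    if (rc < config$tol) break
  }
  list(x = X, objective_trace = obj, rel_change_trace = relch,
       iterations_run = iters)
}

#' Reconstruct a dynamic image from undersampled k-space
#'
#' Solves the constrained reconstruction
#' `argmin_X 0.5 ||A X - B||_F^2 + alpha S(X)` by FISTA, where `S` is the
#' selected temporal regularizer: l1 norm of the temporal Fourier (`FT`) or
#' Haar wavelet (`WT`) coefficients, temporal total variation (`TV`),
#' second-order temporal total generalized variation (`TGV`), or the
#' nuclear norm of the Casorati matrix (`NN`). For TV/TGV the fidelity is
#' weighted as `1/(2 lam) ||A X - B||^2 + alpha S(X)` and the proximal
#' subproblem is solved inexactly by a primal-dual inner loop. `ZF` returns
#' the zero-filled baseline. Data are internally rescaled to unit maximum
#' zero-filled magnitude before reconstruction and un-scaled afterwards.
#'
#' @param B measured k-space (`m x n x d`, DC centred; unmeasured entries
#'   are ignored via the mask).
#' @param maskset [make_mask()] object or binary array.
#' @param config a [recon_config()].
#' @param track_objective logical; record the objective per iteration.
#' @return object of class `recon_result`: `image` (complex array in input
#'   units), `objective_trace`, `rel_change_trace`, `iterations_run`,
#'   `config`.
#' @export
reconstruct <- function(B, maskset, config, track_objective = FALSE) {
  stopifnot(inherits(config, "recon_config"))
  msk <- if (inherits(maskset, "mask_set")) maskset$mask else maskset
  stopifnot(all(dim(msk) == dim(B)))
  sc <- rescale_to_unit(B, msk)
  Bs <- sc$B_scaled * msk
  x0 <- zero_filled(Bs)

  if (config$regularizer == "ZF") {
    return(structure(list(image = x0 * sc$scale_factor,
                          objective_trace = numeric(0),
                          rel_change_trace = numeric(0),
                          iterations_run = 0L, config = config),
                     class = "recon_result"))
  }

  shape <- dim(B)
  tvtgv <- config$regularizer %in% c("TV", "TGV")
  if (tvtgv && config$mode == "pd") {
    res <- recon_primal_dual(Bs, msk, config, track_objective)
    return(structure(list(image = res$x * sc$scale_factor,
                          objective_trace = res$objective_trace,
                          rel_change_trace = res$rel_change_trace,
                          iterations_run = res$iterations_run,
                          config = config),
                     class = "recon_result"))
  }
  ops <- list(ft = op_temporal_dft(), wt = op_temporal_haar())
  L_f <- if (tvtgv) 1 / config$lam else 1
  grad_f <- if (tvtgv) {
    function(X) data_fidelity_grad(X, Bs, msk) / config$lam
  } else {
    function(X) data_fidelity_grad(X, Bs, msk)
  }

  v_state <- NULL
  prox_g <- switch(config$regularizer,
    FT = function(x, tau) prox_l1_unitary(ops$ft, x, tau * config$alpha),
    WT = function(x, tau) prox_l1_unitary(ops$wt, x, tau * config$alpha),
    NN = function(x, tau) uncasorati(
      prox_nuclear(casorati(x), tau * config$alpha), shape),
    TV = function(x, tau) tv_denoise(x, weight = tau * config$alpha,
                                     n_iter = config$inner_iter,
                                     sigma = config$sigma,
                                     tau_step = config$tau_step),
    TGV = function(x, tau) {
      out <- tgv_denoise(x, alpha1 = tau * config$alpha1,
                         alpha0 = tau * config$alpha0,
                         n_iter = config$inner_iter,
                         sigma = config$sigma, tau_step = config$tau_step)
      v_state <<- attr(out, "v")
      attr(out, "v") <- NULL
      out
    })

  objective <- if (track_objective) {
    function(X) {
      fid <- 0.5 * sum(Mod(msk * spatial_fft2(X) - Bs)^2)
      if (tvtgv) fid <- fid / config$lam
      fid + config$alpha * .reg_value(X, config, ops, v_state)
    }
  } else NULL

  res <- fista(grad_f, prox_g, x0, L_f = L_f, max_iter = config$iter,
               tol = config$tol, objective = objective)
  structure(list(image = res$x * sc$scale_factor,
                 objective_trace = res$objective_trace,
                 rel_change_trace = res$rel_change_trace,
                 iterations_run = res$iterations_run, config = config),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result: %s, %d iterations, final rel change %s>\n",
              x$config$regularizer, x$iterations_run,
              if (length(x$rel_change_trace))
                sprintf("%.2e", utils::tail(x$rel_change_trace, 1))
              else "NA"))
  invisible(x)
}
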