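## Independent brute-force minimizers used as oracles for the proximal
## operators and solvers: each nonsmooth objective is smoothed
## (|u| -> sqrt(|u|^2 + eps)) and minimized by BFGS with analytic
## gradients under an epsilon-continuation schedule. The strongly convex
## quadratic term guarantees a unique minimizer; the smoothed minimizer
## converges to it as eps -> 0.

sabs <- function(x, eps) sqrt(x^2 + eps)
dsabs <- function(x, eps) x / sqrt(x^2 + eps)

smooth_min <- function(fn, gr, par0) {
  par <- par0
  for (eps in 10^seq(-2, -14, by = -2)) {
    o <- stats::optim(par, function(p) fn(p, eps), function(p) gr(p, eps),
                      method = "BFGS",
                      control = list(maxit = 10000, reltol = 1e-16))
    par <- o$par
  }
  par
}

## prox of tau * ||u||_1 for complex vectors (entries as re/im pairs)
oracle_prox_l1_complex <- function(x, tau) {
  n <- length(x)
  xr <- Re(x); xi <- Im(x)
  fn <- function(p, eps) {
    s <- sqrt(p[1:n]^2 + p[(n + 1):(2 * n)]^2 + eps)
    tau * sum(s) + 0.5 * sum((p[1:n] - xr)^2) +
      0.5 * sum((p[(n + 1):(2 * n)] - xi)^2)
  }
  gr <- function(p, eps) {
    s <- sqrt(p[1:n]^2 + p[(n + 1):(2 * n)]^2 + eps)
    c(tau * p[1:n] / s + (p[1:n] - xr),
      tau * p[(n + 1):(2 * n)] / s + (p[(n + 1):(2 * n)] - xi))
  }
  p <- smooth_min(fn, gr, c(xr, xi))
  complex(real = p[1:n], imaginary = p[(n + 1):(2 * n)])
}

## dense complex matrix of a matrix-free operator acting on length-d
## time courses
op_matrix <- function(op, d) {
  cols <- lapply(seq_len(d), function(j) {
    e <- rep(0, d); e[j] <- 1
    as.vector(op$forward(array(e, c(1, 1, d))))
  })
  do.call(cbind, cols)
}

## prox of tau * ||F z||_1 restricted to real z (valid: the objective is
## conjugation-symmetric and strictly convex, so the minimizer of a real
## input is real)
oracle_prox_l1_transform <- function(x, tau, Fm) {
  fn <- function(p, eps) {
    cv <- as.vector(Fm %*% p)
    tau * sum(sqrt(Mod(cv)^2 + eps)) + 0.5 * sum((p - x)^2)
  }
  gr <- function(p, eps) {
    cv <- as.vector(Fm %*% p)
    s <- sqrt(Mod(cv)^2 + eps)
    tau * as.vector(Re(Conj(cv / s) %*% Fm)) + (p - x)
  }
  smooth_min(fn, gr, x)
}

## prox of tau * ||Z||_* for small real matrices
oracle_prox_nuclear <- function(X, tau) {
  dm <- dim(X)
  fn <- function(p, eps) {
    Z <- matrix(p, dm[1], dm[2])
    sv <- svd(Z)$d
    tau * sum(sqrt(sv^2 + eps)) + 0.5 * sum((Z - X)^2)
  }
  gr <- function(p, eps) {
    Z <- matrix(p, dm[1], dm[2])
    s <- svd(Z)
    G <- tau * s$u %*% (s$d / sqrt(s$d^2 + eps) * t(s$v)) + (Z - X)
    as.vector(G)
  }
  matrix(smooth_min(fn, gr, as.vector(X)), dm[1], dm[2])
}

## prox of weight * ||diff(z)||_1 (temporal TV) for real time courses
oracle_tv <- function(x, weight) {
  d <- length(x)
  fn <- function(p, eps) weight * sum(sabs(diff(p), eps)) +
    0.5 * sum((p - x)^2)
  gr <- function(p, eps) {
    g <- dsabs(diff(p), eps)
    weight * c(-g, 0) + weight * c(0, g) + (p - x)
  }
  smooth_min(fn, gr, x)
}

## joint TGV prox: minimize over z (length d) and the link-grid slope
## field v (length d - 1):
##   a1 * sum |diff(z) - v| + a0 * sum |diff(v)| + 0.5 ||z - x||^2,
## matching tgv_denoise exactly (affine z with constant v is free).
oracle_tgv <- function(x, a1, a0) {
  d <- length(x)
  stopifnot(d >= 3)
  adjdiff <- function(y) {
    ## adjoint of diff: length(y) -> length(y) + 1
    n <- length(y)
    if (n == 1) return(c(-y, y))
    c(-y[1], y[seq_len(n - 1)] - y[2:n], y[n])
  }
  fn <- function(p, eps) {
    z <- p[1:d]; v <- p[(d + 1):(2 * d - 1)]
    a1 * sum(sabs(diff(z) - v, eps)) + a0 * sum(sabs(diff(v), eps)) +
      0.5 * sum((z - x)^2)
  }
  gr <- function(p, eps) {
    z <- p[1:d]; v <- p[(d + 1):(2 * d - 1)]
    g1 <- dsabs(diff(z) - v, eps)
    g2 <- dsabs(diff(v), eps)
    c(a1 * adjdiff(g1) + (z - x), -a1 * g1 + a0 * adjdiff(g2))
  }
  p <- smooth_min(fn, gr, c(x, rep(0, d - 1)))
  list(z = p[1:d], v = p[(d + 1):(2 * d - 1)])
}

## closed-form Tofts-Kety response to the biexponential plasma input
## Cp(t) = D * sum_j a_j exp(-m_j (t - t0)) for t >= t0:
## C_T(t) = Ktrans * D * sum_j a_j (exp(-m_j u) - exp(-kep u)) / (kep - m_j)
## with u = t - t0 and kep = Ktrans / ve.
oracle_tofts_biexp <- function(ktrans, ve, time_grid, D = 1,
                               a = c(3.99, 4.78), m = c(0.144, 0.011),
                               t0 = 0) {
  kep <- ktrans / ve
  u <- pmax(time_grid - t0, 0)
  ct <- numeric(length(u))
  for (j in seq_along(a)) {
    denom <- kep - m[j]
    term <- if (abs(denom) < 1e-10) {
      u * exp(-m[j] * u)
    } else {
      (exp(-m[j] * u) - exp(-kep * u)) / denom
    }
    ct <- ct + a[j] * term
  }
  out <- ktrans * D * ct
  out[time_grid < t0] <- 0
  out
}

## dense DFT-matrix zero-filled reconstruction for tiny instances:
## undo the DC-centring shift by explicit index arithmetic, then apply the
## conjugate (inverse) orthonormal DFT matrices on both axes.
oracle_zero_filled_dense <- function(B, mask) {
  dm <- dim(B)
  m <- dm[1]; n <- dm[2]
  Wd <- function(N) exp(-2i * pi * outer(0:(N - 1), 0:(N - 1)) / N)
  Wm <- Wd(m); Wn <- Wd(n)
  ## forward shift sent row p to ((p - 1 + floor(m/2)) %% m) + 1; invert it
  unshift_idx <- function(N) ((seq_len(N) - 1 + floor(N / 2)) %% N) + 1
  ri <- unshift_idx(m); ci <- unshift_idx(n)
  out <- array(0+0i, dm)
  for (t in seq_len(dm[3])) {
    kc <- (B[, , t] * mask[, , t])[ri, ci, drop = FALSE]
    out[, , t] <- (Conj(Wm) %*% kc %*% Conj(Wn)) / sqrt(m * n)
  }
  out
}
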