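test_that("rescaling normalizes the zero-filled image to unit maximum", {
  set.seed(2)
  B <- spatial_fft2(rand_complex_array(c(8, 8, 3)))
  sc <- rescale_to_unit(B)
  expect_lt(abs(max(Mod(zero_filled(sc$B_scaled))) - 1), 1e-12)
  sc2 <- rescale_to_unit(2 * B)
  expect_equal(sc2$scale_factor, 2 * sc$scale_factor, tolerance = 1e-12)
  expect_error(rescale_to_unit(B * 0), "all-zero")
})

test_that("zero-filled reconstruction inverts full data and matches a dense oracle", {
  set.seed(3)
  x <- rand_complex_array(c(8, 8, 4))
  B <- spatial_fft2(x)
  full <- array(1L, dim(B))
  expect_lt(max(Mod(zero_filled(B, full) - x)), 1e-10)
  ## half-sampled mask against the dense DFT-matrix computation
  mask <- array(0L, dim(B))
  mask[c(1, 3, 4, 7), , ] <- 1L
  expect_lt(max(Mod(zero_filled(B, mask) -
                      oracle_zero_filled_dense(B, mask))), 1e-10)
})

test_that("the data-fidelity gradient is stationary and consistent", {
  set.seed(4)
  x <- rand_complex_array(c(6, 6, 3))
  B <- spatial_fft2(x)
  full <- array(1L, dim(B))
  g <- data_fidelity_grad(zero_filled(B, full), B, full)
  expect_lt(max(Mod(g)), 1e-12)
  ## finite-difference directional derivative
  mask <- full; mask[1:3, , ] <- 0L
  Bm <- B * mask
  X <- rand_complex_array(dim(B))
  V <- rand_complex_array(dim(B))
  f <- function(Z) 0.5 * sum(Mod(mask * spatial_fft2(Z) - Bm)^2)
  h <- 1e-6
  num <- (f(X + h * V) - f(X - h * V)) / (2 * h)
  ana <- Re(sum(data_fidelity_grad(X, Bm, mask) * Conj(V)))
  expect_lt(abs(num - ana) / max(abs(num), 1), 1e-5)
  ## gradient is linear in the residual scale
  g1 <- data_fidelity_grad(2 * X, 2 * Bm, mask)
  g2 <- data_fidelity_grad(X, Bm, mask)
  expect_equal(g1, 2 * g2, tolerance = 1e-10)
})

test_that("FISTA solves smooth and composite toy problems", {
  set.seed(5)
  ## pure quadratic: matches the normal-equations solution
  A <- matrix(rnorm(20), 5, 4)
  b <- rnorm(5)
  L <- max(eigen(crossprod(A))$values)
  r <- fista(function(x) crossprod(A, A %*% x - b), function(x, tau) x,
             rep(0, 4), L_f = L, max_iter = 2000, tol = 1e-14)
  expect_lt(max(abs(r$x - solve(crossprod(A), crossprod(A, b)))), 1e-6)
  ## l1-regularized toy problem against the brute-force oracle
  al <- 0.3
  r2 <- fista(function(x) crossprod(A, A %*% x - b),
              function(x, tau) Re(soft_threshold(x, tau * al)),
              rep(0, 4), L_f = L, max_iter = 5000, tol = 0)
  fn <- function(p, eps) 0.5 * sum((A %*% p - b)^2) + al * sum(sabs(p, eps))
  gr <- function(p, eps) as.vector(crossprod(A, A %*% p - b)) +
    al * dsabs(p, eps)
  expect_lt(max(abs(r2$x - smooth_min(fn, gr, rep(0, 4)))), 1e-5)
  ## divergence guard
  expect_error(
    fista(function(x) -(x - 5), function(x, tau) x, 0.1, L_f = 1,
          max_iter = 500, tol = 0, objective = function(x) sum(x^2)),
    "diverged")
})

test_that("reconstruction recovers noiseless fully sampled data as alpha -> 0", {
  gt <- small_gt(seed = 21, d = 8)
  x <- synthesize_dynamic_image(gt)
  B <- simulate_kspace(x, 0)
  full <- array(1L, dim(B))
  for (reg in c("ZF", "FT", "WT", "NN")) {
    cfg <- recon_config(reg, alpha = 1e-12)
    res <- reconstruct(B, full, cfg)
    expect_gt(ser(res$image, x), 100)
  }
  for (reg in c("TV", "TGV")) {
    cfg <- recon_config(reg, alpha = 1e-12)
    res <- reconstruct(B, full, cfg)
    expect_gt(ser(res$image, x), 100)
  }
})

test_that("every regularizer beats zero-filling on an undersampled phantom", {
  ## study-scale geometry with a single sampling pattern
  gt <- make_ground_truth(seed = 22)
  x <- synthesize_dynamic_image(gt)
  ksp <- simulate_kspace(x, 0.01, seed = 3)
  mk <- make_mask(48, 32, 30, center_width = 8, target_R = 4.5, seed = 5)
  B <- ksp * mk$mask
  xfs <- spatial_ifft2(ksp)
  ser_zf <- ser(reconstruct(B, mk, recon_config("ZF"))$image, xfs)
  for (reg in c("FT", "WT", "TV", "TGV", "NN")) {
    res <- reconstruct(B, mk, recon_config(reg))
    expect_gt(ser(res$image, xfs), ser_zf)
    ## deterministic given identical inputs
    res2 <- reconstruct(B, mk, recon_config(reg))
    expect_identical(res$image, res2$image)
  }
})

test_that("a static scene reconstructed with the nuclear norm is low rank", {
  gt <- small_gt(seed = 23, d = 10)
  gt$ktrans_map[] <- 0                      # static phantom
  x <- synthesize_dynamic_image(gt)
  mk <- make_mask(16, 12, 10, center_width = 4, target_R = 2, seed = 2)
  B <- simulate_kspace(x, 0) * mk$mask
  res <- reconstruct(B, mk, recon_config("NN", iter = 300, tol = 1e-10))
  sv <- svd(casorati(res$image))$d
  expect_lt(sv[2] / sv[1], 1e-6)
})

test_that("objective decreases and stronger alpha yields sparser solutions", {
  gt <- small_gt(seed = 24, d = 8)
  x <- synthesize_dynamic_image(gt)
  ksp <- simulate_kspace(x, 0.01, seed = 9)
  mk <- make_mask(16, 12, 8, center_width = 4, target_R = 2, seed = 3)
  B <- ksp * mk$mask
  for (reg in c("FT", "TV")) {
    res <- reconstruct(B, mk, recon_config(reg), track_objective = TRUE)
    tr <- res$objective_trace
    expect_gt(length(tr), 1)
    expect_lt(min(tr), tr[1] * (1 + 1e-9))
    ## running minimum is non-increasing by construction; final near best
    expect_lt(tr[length(tr)], tr[1])
  }
  ## data consistency improves over the zero image
  res <- reconstruct(B, mk, recon_config("FT"))
  resid <- function(X) sqrt(sum(Mod(mk$mask * spatial_fft2(X) - B)^2))
  expect_lt(resid(res$image), resid(array(0+0i, dim(B))))
  ## regularizer value is non-increasing in alpha (FT, 3-point sweep)
  ft <- op_temporal_dft()
  vals <- vapply(c(0.01, 0.059, 0.3), function(a) {
    r <- reconstruct(B, mk, recon_config("FT", alpha = a))
    sc <- max(Mod(zero_filled(B, mk$mask)))
    sum(Mod(ft$forward(r$image / sc)))
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-8))
})

test_that("reconstruction configs expose the published defaults", {
  expect_equal(recon_config("FT")$alpha, 0.059)
  expect_equal(recon_config("FT")$iter, 35)
  expect_equal(recon_config("WT")$alpha, 0.008)
  expect_equal(recon_config("WT")$iter, 60)
  tv <- recon_config("TV")
  expect_equal(c(tv$alpha, tv$iter, tv$sigma, tv$tau_step, tv$lam),
               c(0.5, 100, 0.2, 0.2, 0.5))
  tgv <- recon_config("TGV")
  expect_equal(c(tgv$alpha, tgv$iter, tgv$sigma, tgv$tau_step, tgv$lam),
               c(0.5, 100, 0.2, 0.2, 0.5))
  expect_equal(recon_config("NN")$alpha, 0.3)
  expect_equal(recon_config("NN")$iter, 40)
  expect_error(recon_config("FT", nonsense = 1), "unknown")
  expect_error(recon_config("TV", mode = "magic"), "mode")
})
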