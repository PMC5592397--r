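test_that("soft thresholding shrinks magnitudes and preserves phase", {
  expect_equal(soft_threshold(3 + 4i, 1), 2.4 + 3.2i)
  x <- c(-2, 0.5, 0, 3)
  expect_equal(soft_threshold(x, 0), x)
  expect_equal(soft_threshold(x, 10), rep(0, 4))
  ## exact prox of the complex l1 norm (oracle on 4 complex unknowns)
  set.seed(11)
  for (i in 1:5) {
    u <- complex(real = rnorm(4), imaginary = rnorm(4))
    tau <- runif(1, 0.1, 1)
    expect_lt(max(Mod(soft_threshold(u, tau) -
                        oracle_prox_l1_complex(u, tau))), 1e-6)
  }
  expect_error(soft_threshold(x, -1), "nonnegative")
})

test_that("box projection clamps exactly and rejects bad bounds", {
  expect_equal(project_box(0.5, 0, 1), 0.5)
  expect_equal(project_box(-0.2, 0, 1), 0)
  expect_equal(project_box(1.7, 0, 1), 1)
  expect_equal(project_box(c(-1, 0.3, 2), 0, 1), c(0, 0.3, 1))
  expect_error(project_box(1, 2, 0), "exceed")
  expect_error(project_box(1 + 1i, 0, 1), "real")
})

test_that("temporal transforms satisfy the adjoint identity and unitarity", {
  set.seed(5)
  for (op in list(op_temporal_dft(), op_temporal_haar())) {
    for (d in c(4, 7, 16)) {
      x <- rand_complex_array(c(3, 2, d))
      y <- rand_complex_array(c(3, 2, d))
      ip1 <- sum(op$forward(x) * Conj(y))
      ip2 <- sum(x * Conj(op$adjoint(y)))
      expect_lt(Mod(ip1 - ip2) / (csdce:::fnorm(x) * csdce:::fnorm(y)), 1e-12)
      expect_lt(abs(csdce:::fnorm(op$forward(x)) - csdce:::fnorm(x)) /
                  csdce:::fnorm(x), 1e-12)
      expect_lt(max(Mod(op$adjoint(op$forward(x)) - x)), 1e-10)
    }
  }
})

test_that("Haar and Fourier transforms sparsify their canonical signals", {
  ## piecewise-constant time course: only the scaling and one coarse
  ## detail coefficient survive under Haar
  x <- array(rep(c(1, 1, 1, 1, 3, 3, 3, 3), each = 1), c(1, 1, 8))
  wt <- op_temporal_haar()
  cw <- as.vector(wt$forward(x))
  expect_lte(sum(Mod(cw) > 1e-8), 2)
  ## single-frequency cosine: two DFT bins
  d <- 16
  xc <- array(cos(2 * pi * 3 * (0:(d - 1)) / d), c(1, 1, d))
  ft <- op_temporal_dft()
  cf <- as.vector(ft$forward(xc))
  expect_lte(sum(Mod(cf) > 1e-8), 2)
})

test_that("l1 prox under a unitary transform solves the prox problem", {
  set.seed(7)
  ops <- list(op_temporal_dft(), op_temporal_haar())
  for (op in ops) {
    d <- 6
    Fm <- op_matrix(op, d)
    for (i in 1:5) {
      x <- rnorm(d)
      tau <- runif(1, 0.05, 0.5)
      got <- as.vector(op$adjoint(
        soft_threshold(op$forward(array(x, c(1, 1, d))), tau)))
      ref <- oracle_prox_l1_transform(x, tau, Fm)
      expect_lt(max(Mod(got - ref)), 1e-5)
    }
    ## tau = 0 is the identity
    x <- rnorm(d)
    out0 <- as.vector(prox_l1_unitary(op, array(x, c(1, 1, d)), 0))
    expect_lt(max(Mod(out0 - x)), 1e-12)
  }
  ## constant-in-time voxel: DC survives small tau, output stays constant
  xc <- array(2, c(1, 1, 8))
  out <- Re(as.vector(prox_l1_unitary(op_temporal_dft(), xc, 0.1)))
  expect_lt(diff(range(out)), 1e-12)
  expect_gt(mean(out), 1.9)
  expect_error(
    prox_l1_unitary(linop(identity, identity, is_unitary = FALSE), 1, 0.1),
    "unitary")
})

test_that("singular value thresholding matches its closed forms", {
  set.seed(13)
  u <- rnorm(5); v <- rnorm(3)
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  s <- 2.5
  X <- s * outer(u, v)
  out <- prox_nuclear(X, 1)
  expect_equal(out, (s - 1) * outer(u, v), tolerance = 1e-10)
  expect_equal(prox_nuclear(X, 0), X, tolerance = 1e-10)
  expect_equal(prox_nuclear(X, 3), matrix(0, 5, 3))
  ## against the brute-force oracle on 4 x 2 matrices
  for (i in 1:5) {
    Z <- matrix(rnorm(8), 4, 2)
    tau <- runif(1, 0.1, 0.8)
    expect_lt(max(abs(prox_nuclear(Z, tau) - oracle_prox_nuclear(Z, tau))),
              1e-5)
  }
})

test_that("temporal difference and its adjoint are exact companions", {
  set.seed(3)
  x <- rand_complex_array(c(2, 2, 9))
  y <- rand_complex_array(c(2, 2, 9))
  ip1 <- sum(temporal_diff(x) * Conj(y))
  ip2 <- sum(x * Conj(temporal_diff_adjoint(y)))
  expect_lt(Mod(ip1 - ip2) / (csdce:::fnorm(x) * csdce:::fnorm(y)), 1e-12)
  ## constant signal has zero difference; a single step appears once
  expect_equal(max(Mod(temporal_diff(array(5, c(1, 1, 6))))), 0)
  stp <- array(c(0, 0, 0, 2, 2, 2), c(1, 1, 6))
  dd <- as.vector(temporal_diff(stp))
  expect_equal(Mod(dd), c(0, 0, 2, 0, 0, 0))
  expect_error(temporal_diff(array(1, c(2, 2, 1))), "at least 2")
})

test_that("TV denoising solves its prox problem", {
  ## weight 0 is the identity
  x <- rnorm(5)
  expect_equal(tv_denoise(x, 0), x)
  ## two-frame closed form: the difference shrinks by 2 * weight
  z <- Re(tv_denoise(c(1, 2), 0.2, n_iter = 5000, accelerate = FALSE))
  expect_equal(diff(z), 0.6, tolerance = 1e-6)
  expect_equal(mean(z), 1.5, tolerance = 1e-8)
  ## random length-5 time courses against the brute-force oracle
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(5)
    w <- runif(1, 0.1, 0.6)
    z <- Re(tv_denoise(x, w, n_iter = 20000, accelerate = FALSE))
    expect_lt(max(abs(z - oracle_tv(x, w))), 1e-5)
  }
  expect_error(tv_denoise(x, 0.1, sigma = 1, tau_step = 1), "step sizes")
})

test_that("TGV denoising preserves affine trends and generalizes TV", {
  ## constant in time: unchanged
  xc <- rep(2, 6)
  expect_lt(max(abs(Re(tgv_denoise(xc, 0.3, 0.6, n_iter = 500)) - 2)), 1e-8)
  ## a linear ramp incurs no TGV penalty, so it is exactly preserved;
  ## TV at the same weight visibly flattens it
  ramp <- seq(0, 1, length.out = 6)
  zt <- Re(tgv_denoise(ramp, 0.3, 0.6, n_iter = 4000))
  expect_lt(max(abs(zt - ramp)), 1e-3)
  ztv <- Re(tv_denoise(ramp, 0.3, n_iter = 4000, accelerate = FALSE))
  expect_gt(max(abs(ztv - ramp)), 0.05)
  ## alpha0 -> Inf forces the slope field constant; on a zero-trend input
  ## that constant is zero and TV is recovered exactly
  x <- c(0, 0, 2, 2, 0, 0)
  z1 <- Re(tgv_denoise(x, 0.3, 0.3e6, n_iter = 20000))
  z2 <- Re(tv_denoise(x, 0.3, n_iter = 20000, accelerate = FALSE))
  expect_lt(max(abs(z1 - z2)), 1e-4)
})

test_that("proximal operators are non-expansive", {
  set.seed(41)
  d <- 6
  ops <- list(
    function(x) soft_threshold(x, 0.3),
    function(x) as.vector(prox_l1_unitary(op_temporal_dft(),
                                          array(x, c(1, 1, d)), 0.3)),
    function(x) as.vector(prox_l1_unitary(op_temporal_haar(),
                                          array(x, c(1, 1, d)), 0.3)),
    function(x) Re(tv_denoise(x, 0.3, n_iter = 2000, accelerate = FALSE)),
    function(x) Re(tgv_denoise(x, 0.3, 0.6, n_iter = 2000))
  )
  for (P in ops) {
    for (i in 1:5) {
      a <- rnorm(d); b <- rnorm(d)
      expect_lte(sqrt(sum(Mod(P(a) - P(b))^2)),
                 sqrt(sum((a - b)^2)) * (1 + 1e-6))
    }
  }
  for (i in 1:5) {
    A <- matrix(rnorm(8), 4, 2); B <- matrix(rnorm(8), 4, 2)
    expect_lte(norm(prox_nuclear(A, 0.3) - prox_nuclear(B, 0.3), "F"),
               norm(A - B, "F") * (1 + 1e-9))
  }
})

test_that("operator self-test reports passing operators", {
  res <- suppressMessages(
    utils::capture.output(out <- operator_self_test(d = 6, n_pairs = 5)))
  expect_true(all(out$pass))
})
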