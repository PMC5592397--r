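test_that("ground-truth maps honor the requested tumor means", {
  gt <- make_ground_truth(seed = 2)
  tm <- gt$tumor_mask
  expect_lt(abs(mean(gt$ktrans_map[tm]) / 0.425 - 1), 0.02)
  expect_lt(abs(mean(gt$ve_map[tm]) / 0.635 - 1), 0.02)
  expect_true(all(gt$ve_map[tm] > 0 & gt$ve_map[tm] <= 1))
  expect_true(all(gt$ktrans_map >= 0))
  expect_true(all(gt$ktrans_map[!tm] == 0))
  ## custom means are hit too
  gt2 <- make_ground_truth(tumor_spec = list(mean_ktrans = 0.2,
                                             mean_ve = 0.4), seed = 2)
  expect_lt(abs(mean(gt2$ktrans_map[gt2$tumor_mask]) / 0.2 - 1), 0.02)
  expect_lt(abs(mean(gt2$ve_map[gt2$tumor_mask]) / 0.4 - 1), 0.02)
})

test_that("zero heterogeneity gives constant maps; seeds control RNG", {
  gt0 <- make_ground_truth(tumor_spec = list(heterogeneity = 0), seed = 9)
  expect_equal(diff(range(gt0$ktrans_map[gt0$tumor_mask])), 0)
  a <- make_ground_truth(seed = 4)
  b <- make_ground_truth(seed = 4)
  c3 <- make_ground_truth(seed = 5)
  expect_identical(a$ktrans_map, b$ktrans_map)
  expect_identical(a$ve_map, b$ve_map)
  expect_false(identical(a$ktrans_map[a$tumor_mask],
                         c3$ktrans_map[c3$tumor_mask]))
})

test_that("invalid phantom specifications are rejected", {
  expect_error(make_ground_truth(tumor_spec = list(center = c(100, 100))),
               "outside")
  expect_error(make_ground_truth(tumor_spec = list(mean_ve = 1.3)), "ve")
  expect_error(make_ground_truth(tumor_spec = list(mean_ve = 0.95,
                                                   heterogeneity = 0.8)),
               "ve")
  expect_error(make_ground_truth(d = 30, injection_index = 2),
               "injection_index")
  expect_error(make_ground_truth(d = 30, injection_index = 29),
               "injection_index")
})

test_that("the plasma input is zero pre-injection and biexponential after", {
  tg <- seq(0, 5, by = 0.25)
  p <- list(D = 1, a = c(3.99, 4.78), m = c(0.144, 0.011), t0 = 1)
  cp <- aif(tg, p)
  expect_true(all(cp[tg < 1] == 0))
  expect_true(all(cp >= 0))
  ## direct closed-form evaluation one minute post-injection
  expect_equal(cp[tg == 2], 3.99 * exp(-0.144) + 4.78 * exp(-0.011),
               tolerance = 1e-12)
  ## amplitude linearity
  p2 <- p; p2$a <- 3 * p$a
  expect_equal(aif(tg, p2), 3 * cp, tolerance = 1e-12)
  pbad <- p; pbad$m <- c(-0.1, 0.01)
  expect_error(aif(tg, pbad), "nonnegative")
})

test_that("synthesized images follow the enhancement-proportional model", {
  gt <- small_gt(seed = 6)
  gt0 <- gt
  gt0$ktrans_map[] <- 0
  x0 <- synthesize_dynamic_image(gt0)
  ## no uptake: every voxel constant in time
  expect_lt(max(apply(Mod(x0), c(1, 2), function(v) diff(range(v)))), 1e-12)
  x <- synthesize_dynamic_image(gt, k = 0.5)
  ## non-tumor voxels stay at background
  bgv <- which(!gt$tumor_mask, arr.ind = TRUE)[1, ]
  expect_equal(Mod(x[bgv[1], bgv[2], ]),
               rep(gt$background[bgv[1], bgv[2]], length(gt$time_grid)),
               tolerance = 1e-12)
  expect_true(all(Im(x) == 0))
  ## doubling the background doubles every signal value
  gt2 <- gt
  gt2$background <- 2 * gt$background
  x2 <- synthesize_dynamic_image(gt2, k = 0.5)
  expect_equal(x2, 2 * x, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a constant plasma input gives the saturating closed form", {
  ## Cp = c after t0 = 0 (decay rates zero); late signal approaches
  ## background * (1 + k * c * ve)
  d <- 24
  gt <- make_ground_truth(shape = c(8, 8), d = d, dt = 2, injection_index = 4,
                          tumor_spec = list(radius = 3, heterogeneity = 0),
                          aif_params = list(D = 1, a = c(1, 1), m = c(0, 0),
                                            t0 = 0),
                          seed = 1)
  x <- synthesize_dynamic_image(gt, k = 1, refine = 50)
  ctr <- round(dim(x)[1:2] / 2)
  curve <- Mod(x[ctr[1], ctr[2], ]) / gt$background[ctr[1], ctr[2]] - 1
  tgd <- gt$time_grid
  closed <- 2 * 0.635 * (1 - exp(-0.425 * tgd / 0.635))
  expect_equal(curve, closed, tolerance = 1e-3)
})

test_that("simulated k-space is unitary and its noise is calibrated", {
  set.seed(8)
  gt <- small_gt()
  x <- synthesize_dynamic_image(gt)
  k0 <- simulate_kspace(x, noise_sigma = 0)
  expect_lt(max(Mod(spatial_ifft2(k0) - x)) / max(Mod(x)), 1e-10)
  ## Parseval under the orthonormal convention
  expect_equal(sum(Mod(k0)^2), sum(Mod(x)^2), tolerance = 1e-10)
  ## Monte-Carlo check of the noise generator
  s <- 0.37
  kn <- simulate_kspace(x, noise_sigma = s, seed = 123)
  addn <- Re(kn - k0)
  expect_lt(abs(stats::sd(addn) / s - 1), 0.05)
  expect_identical(simulate_kspace(x, noise_sigma = s, seed = 123), kn)
  expect_false(identical(simulate_kspace(x, noise_sigma = s, seed = 124), kn))
})

test_that("noiseless synthesized tumor curves return the true parameters", {
  gt <- small_gt(seed = 12, d = 16)
  x <- synthesize_dynamic_image(gt, k = 1)
  cp_fn <- function(t) aif(t, gt$aif_params)
  g <- conv_grid(gt$time_grid, cp_fn, refine = 10)
  idx <- which(gt$tumor_mask, arr.ind = TRUE)
  for (i in seq_len(min(5, nrow(idx)))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    ct <- Mod(x[r, c, ]) / gt$background[r, c] - 1
    f <- tofts_fit(ct, g)
    expect_lt(abs(f$ktrans / gt$ktrans_map[r, c] - 1), 1e-3)
    expect_lt(abs(f$ve / gt$ve_map[r, c] - 1), 1e-3)
  }
})
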