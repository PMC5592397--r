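## Small phantom instances shared across tests. Built fresh per call so
## tests stay independent; sizes chosen to keep the suite fast.

small_gt <- function(seed = 3, d = 12, shape = c(16, 12), radius = 3,
                     heterogeneity = 0.3) {
  make_ground_truth(shape = shape, d = d,
                    tumor_spec = list(radius = radius,
                                      heterogeneity = heterogeneity),
                    injection_index = 4, seed = seed)
}

rand_complex_array <- function(dims) {
  array(complex(real = stats::rnorm(prod(dims)),
                imaginary = stats::rnorm(prod(dims))), dims)
}

## feasible tiny mask: 24 phase encodes, center 4, R = 3 -> 8 lines/frame
tiny_mask <- function(d = 12, seed = 1) {
  make_mask(n_pe = 24, n_ro = 16, d = d, center_width = 4, target_R = 3,
            seed = seed)
}
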