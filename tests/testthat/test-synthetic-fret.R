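test_that("forward model: acceptor equals (a + beta) * donor signal, noiseless", {
  sc <- make_fret_scene(frames = 3, engulf = integer(0), a_basal = 1,
                        bleed_through = 0.62)
  C_sig <- phagoquant:::donor_signal(sc$truth, 1000)
  for (t in 1:3) {
    V_sig <- sc$stack$acceptor[, , t] - sc$truth$background_level
    expect_equal(max(abs(V_sig - (1 + 0.62) * C_sig)), 0, tolerance = 1e-9)
  }
})

test_that("forward-model consistency: (V - beta C) / C recovers a exactly", {
  sc <- make_fret_scene(frames = 4, engulf = 2:3, a_basal = 1, a_contact = 2)
  tr <- sc$truth
  C_sig <- phagoquant:::donor_signal(tr, 1000)
  for (t in c(1, 2)) {
    V_sig <- sc$stack$acceptor[, , t] - tr$background_level
    a_hat <- (V_sig - tr$bleed_through * C_sig) / C_sig
    a_true <- tr$activation_map_series[, , t]
    expect_lt(max(abs(a_hat - a_true)[tr$cell_mask]), 1e-9)
  }
})

test_that("zero activation and zero leakage leave only background", {
  sc <- make_fret_scene(frames = 2, engulf = integer(0), a_basal = 0,
                        a_contact = 0, bleed_through = 0)
  expect_equal(diff(range(sc$stack$acceptor)), 0)
  expect_equal(sc$stack$acceptor[1, 1, 1], sc$truth$background_level)
})

test_that("drift translates frames before noise", {
  dr <- rbind(c(0, 0), c(3, 0))
  sc <- make_fret_scene(frames = 2, engulf = integer(0), drift = dr)
  shifted <- phagoquant:::shift_int(sc$stack$donor[, , 1] -
                                      sc$truth$background_level, c(3, 0))
  expect_equal(sc$stack$donor[, , 2] - sc$truth$background_level, shifted)
})

test_that("stack generation is deterministic; invalid leakage rejected", {
  a <- generate_fret_stack(fret_truth(frames = 2), noise_sd = 15, seed = 9)
  b <- generate_fret_stack(fret_truth(frames = 2), noise_sd = 15, seed = 9)
  expect_identical(a$stack$acceptor, b$stack$acceptor)
  expect_error(fret_truth(bleed_through = 1), "invalid parameter")
  expect_error(fret_truth(bleed_through = -0.1), "invalid parameter")
})

test_that("donor-only cells carry only leakage in the acceptor channel", {
  do <- generate_donor_only(2, beta = 0.5, noise_sd = 0, seed = 3)
  st <- do$stacks[[1]]
  bg <- do$truth$background_level
  V <- st$acceptor[, , 1] - bg
  C <- st$donor[, , 1] - bg
  expect_equal(V, 0.5 * C, tolerance = 1e-9)

  zero <- generate_donor_only(1, beta = 0, noise_sd = 0, seed = 3)
  expect_equal(diff(range(zero$stacks[[1]]$acceptor)), 0)

  again <- generate_donor_only(2, beta = 0.5, noise_sd = 0, seed = 3)
  expect_identical(again$stacks[[1]]$donor, do$stacks[[1]]$donor)
})

test_that("truth activation maps live exactly on the cell footprint", {
  tr <- fret_truth(frames = 3, engulf_frames = 2)
  for (t in 1:3) {
    a <- tr$activation_map_series[, , t]
    expect_identical(is.finite(a), tr$cell_mask)
  }
  # engulfment frames elevate the contact membrane relative to cytosol
  hot <- tr$activation_map_series[, , 2]
  cold <- tr$activation_map_series[, , 1]
  expect_gt(max(hot, na.rm = TRUE), max(cold, na.rm = TRUE))
})
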