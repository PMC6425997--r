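test_that("background correction subtracts the exact level and is idempotent", {
  sc <- make_fret_scene(frames = 2, engulf = integer(0))
  corr <- background_correct(sc$stack)
  inside <- sc$truth$cell_mask
  for (t in 1:2) {
    expect_equal(corr$donor[, , t][inside],
                 sc$stack$donor[, , t][inside] - sc$truth$background_level)
    expect_equal(median(corr$donor[, , t][!inside]), 0)
  }
  twice <- background_correct(corr)
  expect_equal(twice$donor, corr$donor)
})

test_that("alignment recovers generator drift exactly and moves all channels together", {
  dr <- rbind(c(0, 0), c(3, 0), c(-4, 2))
  sc <- make_fret_scene(frames = 3, engulf = integer(0), drift = dr)
  corr <- background_correct(sc$stack)
  al <- align_stack(corr)
  expect_equal(al$shifts$dx, c(0, -3, 4))
  expect_equal(al$shifts$dy, c(0, 0, -2))
  # after alignment every frame matches frame 1 on the interior
  for (t in 2:3) {
    expect_equal(al$stack$donor[20:100, 20:100, t],
                 al$stack$donor[20:100, 20:100, 1])
  }
  # identical shift applied to all three channels: particle follows donor
  expect_equal(al$stack$particle[, , 2],
               phagoquant:::shift_int(corr$particle[, , 2], c(-3, 0)))

  zero <- align_stack(background_correct(make_fret_scene(frames = 3,
                                                         engulf = integer(0))$stack))
  expect_true(all(zero$shifts$dx == 0 & zero$shifts$dy == 0))
})

test_that("smoothing is a 3x3 mean with the expected variance reduction", {
  flat <- fret_stack(array(5, c(20, 20, 1)), array(7, c(20, 20, 1)),
                     pixel_size = 0.1)
  sm <- smooth_stack(flat)
  expect_equal(sm$donor, flat$donor)

  hot <- array(0, c(21, 21, 1)); hot[11, 11, 1] <- 9
  st <- fret_stack(hot, hot, pixel_size = 0.1)
  sm2 <- smooth_stack(st)
  expect_equal(sum(abs(sm2$donor - 1) < 1e-9), 9)
  expect_equal(sum(sm2$donor), 9)

  noise <- withr::with_seed(5, array(rnorm(101 * 101), c(101, 101, 1)))
  sm3 <- smooth_stack(fret_stack(noise, noise, pixel_size = 0.1))
  ratio <- stats::var(as.vector(noise[20:80, 20:80, 1])) /
    stats::var(as.vector(sm3$donor[20:80, 20:80, 1]))
  expect_equal(ratio, 9, tolerance = 0.5)

  expect_error(smooth_stack(flat, kernel_size = 4), "odd")
})

test_that("bleed-through estimation is exact without noise and accurate with it", {
  exact <- estimate_bleedthrough(
    generate_donor_only(3, beta = 0.62, noise_sd = 0, seed = 1)$stacks)
  expect_equal(exact$beta_hat, 0.62, tolerance = 1e-6)

  none <- estimate_bleedthrough(
    generate_donor_only(3, beta = 0, noise_sd = 5, seed = 1)$stacks)
  expect_equal(none$beta_hat, 0, tolerance = 0.02)

  noisy <- estimate_bleedthrough(
    generate_donor_only(50, beta = 0.62, noise_sd = 20, seed = 1)$stacks)
  expect_lt(abs(100 * noisy$beta_hat - 62), 2)

  td <- tidy(noisy); gl <- glance(noisy)
  expect_true("donor" %in% td$term)
  expect_equal(gl$beta_pct, 100 * noisy$beta_hat)

  flat <- fret_stack(array(c(0, 1000)[1 + phagoquant:::disc_mask(64, 64, c(3.2, 3.2), 2, 0.1)],
                           c(64, 64, 1)),
                     array(100, c(64, 64, 1)), pixel_size = 0.1)
  expect_error(estimate_bleedthrough(flat), "degenerate calibration")
})

test_that("ratio map inverts the forward model and conserves NaN", {
  sc <- make_fret_scene(frames = 2, engulf = integer(0), a_basal = 1.5,
                        a_contact = 1.5)
  chain <- smooth_stack(align_stack(background_correct(sc$stack))$stack)
  rm <- suppressMessages(ratio_map(chain, beta = 0.62))
  inmask <- sc$truth$cell_mask
  expect_lt(max(abs(rm$ratio[, , 1][inmask] - 1.5)), 1e-6)

  # NaN exactly where acceptor fell below threshold or the donor was zero
  V <- chain$acceptor; C <- chain$donor
  expected_nan <- V < rm$threshold | (!(V < rm$threshold) & C == 0)
  expect_identical(is.nan(rm$ratio), expected_nan)

  # skipping the bleed-through correction leaves the leakage bias
  rm0 <- suppressMessages(ratio_map(chain, beta = 0))
  expect_equal(median(rm0$ratio[, , 1][inmask], na.rm = TRUE), 1.5 + 0.62,
               tolerance = 1e-6)
})

test_that("full noisy chain recovers the activation map and the contact contrast", {
  dr <- withr::with_seed(1, matrix(sample(-5:5, 16, TRUE), 8, 2)); dr[1, ] <- 0
  sc <- make_fret_scene(frames = 8, engulf = 3:6, noise_sd = 20, seed = 1,
                        drift = dr)
  res <- suppressMessages(fret_pipeline(sc$stack))
  for (t in c(2, 4)) {
    a_true <- sc$truth$activation_map_series[, , t]
    rel <- abs(res$ratio_map$ratio[, , t] - a_true) / a_true
    expect_lt(median(rel[sc$truth$cell_mask], na.rm = TRUE), 0.05)
  }
  A <- res$trace$activation_ratio
  expect_equal(mean(A[3:6]), 2, tolerance = 0.05)
  expect_equal(mean(A[c(1, 2, 7, 8)]), 1, tolerance = 0.05)
})

test_that("activation trace contracts: uniform map, missing frames, scale invariance", {
  sc <- make_fret_scene(frames = 3, engulf = integer(0), a_basal = 1.2,
                        a_contact = 1.2)
  res <- suppressMessages(fret_pipeline(sc$stack))
  expect_equal(res$trace$activation_ratio, rep(1, 3), tolerance = 1e-9)

  # absent particle centroid in one frame leaves that frame missing, not 0
  centroids <- track_particle(res$stack)
  centroids$x_um[2] <- NA
  masks <- phagoquant:::cell_mask_series(res$stack)
  tr2 <- activation_trace(res$ratio_map, centroids, masks)
  expect_true(is.na(tr2$activation_ratio[2]))
  expect_false(anyNA(tr2$activation_ratio[c(1, 3)]))

  # A is invariant under positive scaling of the whole ratio map
  scaled <- res$ratio_map; scaled$ratio <- scaled$ratio * 7.3
  tr3 <- activation_trace(scaled, track_particle(res$stack), masks)
  expect_equal(tr3$activation_ratio, res$trace$activation_ratio, tolerance = 1e-12)
})

test_that("heatmap rendering maps the LUT ends, clips, and blanks NaN", {
  rm <- structure(
    list(ratio = array(c(0.5, 2, 5, NaN), c(2, 2, 1)), beta_used = 0.62,
         threshold = 0, n_division_guard = 0, pixel_size = 0.1,
         frame_interval = 1),
    class = "ratio_map")
  td <- withr::local_tempdir()
  paths <- render_ratio_heatmap(rm, lut_range = c(0.5, 2), dir = td)
  img <- png::readPNG(paths[1])
  # lut minimum is blue-dominant, maximum red-dominant
  expect_gt(img[1, 1, 3], img[1, 1, 1])       # ratio 0.5 -> blue end
  expect_gt(img[2, 1, 1], img[2, 1, 3])       # ratio 2   -> red end
  expect_equal(img[1, 2, ], img[2, 1, ])      # 5 clips to the red end
  expect_equal(max(img[2, 2, ]), 0)           # NaN -> black
})
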