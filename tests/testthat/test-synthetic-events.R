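test_that("event generation is deterministic and respects the noiseless contracts", {
  a <- generate_event(event_truth("bound"), noise_sd = 12, seed = 42)
  b <- generate_event(event_truth("bound"), noise_sd = 12, seed = 42)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth, b$truth)

  # different seed moves the sampled geometry
  c_ <- generate_event(event_truth("bound"), noise_sd = 12, seed = 43)
  expect_false(identical(a$image$channels$particle, c_$image$channels$particle))

  # no particle + no noise: particle channel is flat background
  np <- make_event("no_particle")
  expect_equal(diff(range(np$image$channels$particle)), 0)
})

test_that("class geometry invariants hold for resolved truths", {
  for (seed in 1:10) {
    bd <- make_event("bound", seed = seed)$truth
    expect_equal(truth_distance(bd),
                 bd$cell_radius + bd$particle_diameter / 2, tolerance = 1e-12)

    int <- make_event("internalized", seed = seed)$truth
    expect_lte(truth_distance(int),
               int$cell_radius - int$particle_diameter / 2)

    off <- make_event("off_plane", seed = seed)$truth
    expect_gte(off$focus_blur_sigma[4], 1.0)
  }
  expect_null(make_event("no_particle")$truth$particle_center)
})

test_that("bead geometry places the bound centroid 5 um out", {
  ev <- make_event("bound", cell_radius = 3.5, particle_diameter = 3)
  expect_equal(truth_distance(ev$truth), 5.0, tolerance = 1e-12)
})

test_that("generation rejects impossible frames and bad parameters", {
  expect_error(generate_event(event_truth("bound", cell_radius = 12), seed = 1),
               "frame too small")
  expect_error(generate_event(event_truth("bound"), noise_sd = -1), ">= 0")
  expect_error(event_truth("bound", cell_radius = -1), "> 0")
})

test_that("cohorts follow the requested mixture", {
  pure <- generate_cohort(50, mixture = c(0, 0, 1, 0), noise_sd = 0, seed = 3)
  expect_true(all(pure$label == "internalized"))

  mixed <- generate_cohort(400, mixture = rep(0.25, 4), noise_sd = 0, seed = 7)
  counts <- table(factor(mixed$label,
                         levels = c("no_particle", "bound", "internalized", "off_plane")))
  sigma <- sqrt(400 * 0.25 * 0.75)
  expect_true(all(abs(counts - 100) <= 3 * sigma))

  # per-event seeds derive from the master seed: full reproducibility
  again <- generate_cohort(10, mixture = rep(0.25, 4), noise_sd = 5, seed = 21)
  once <- generate_cohort(10, mixture = rep(0.25, 4), noise_sd = 5, seed = 21)
  expect_identical(once$image[[7]]$channels, again$image[[7]]$channels)
})

test_that("invalid mixtures are rejected with the offending entry named", {
  expect_error(generate_cohort(0, rep(0.25, 4)), ">= 1")
  expect_error(generate_cohort(5, c(0.5, 0.5, 0.5, -0.5)), "off_plane")
  expect_error(generate_cohort(5, c(0.3, 0.3, 0.3, 0.3)), "sum")
})
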