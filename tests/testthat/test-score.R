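test_that("score formula identities hold", {
  expect_equal(internalization_score(R = 3.5, d = 3.5), 1)
  expect_equal(internalization_score(R = 3.5, d = 1.75), 2)
  expect_equal(internalization_score(R = 3.5, d = 0, eps = 0.33), 3.5 / 0.33)
  # scale invariance of the ratio form
  expect_equal(internalization_score(7, 3), internalization_score(14, 6))
  # monotonically non-increasing in d
  d <- seq(0, 5, by = 0.1)
  s <- internalization_score(3.5, d)
  expect_true(all(diff(s) <= 0))
  # depth reading
  expect_equal(internalization_score(3.5, 1, formula = "depth"), 2.5)
  expect_error(internalization_score(3.5, NA), "without particle")
})

test_that("classification respects threshold and gate precedence", {
  expect_equal(classify_event(2.0, TRUE), "internalized")
  expect_equal(classify_event(1.99, TRUE), "bound")
  expect_equal(classify_event(10, FALSE), "excluded_unfocused")
  expect_equal(classify_event(NA, TRUE), "no_particle")
  expect_equal(classify_event(NA, FALSE), "excluded_unfocused")
  expect_error(classify_event(1, TRUE, tau = 0), "> 0")
})

test_that("cohort summary reproduces the gating arithmetic", {
  labels <- c(rep("excluded_unfocused", 2), rep("no_particle", 3),
              rep("bound", 3), rep("internalized", 2))
  s <- summarize_cohort(labels)
  expect_equal(s$n_total, 10)
  expect_equal(s$n_focused, 8)
  expect_equal(s$pct_interacting, 62.5)
  expect_equal(s$pct_internalized, 40)

  all_np <- summarize_cohort(rep("no_particle", 5))
  expect_true(is.na(all_np$pct_internalized))

  all_int <- summarize_cohort(rep("internalized", 5))
  expect_equal(all_int$pct_interacting, 100)
  expect_equal(all_int$pct_internalized, 100)

  expect_error(summarize_cohort(character(0)), "empty")
})

test_that("gating-chain counts are monotone on arbitrary label mixes", {
  labels <- c("excluded_unfocused", "no_particle", "bound", "internalized")
  for (seed in 1:10) {
    mix <- withr::with_seed(seed, sample(labels, 30, replace = TRUE))
    s <- summarize_cohort(mix)
    expect_true(s$n_total >= s$n_focused)
    expect_true(s$n_focused >= s$n_particle_positive)
    expect_true(s$n_particle_positive >= s$n_internalized)
  }
})

test_that("time-course AUC matches hand trapezoids and is linear/additive", {
  expect_equal(auc_time_course(c(0, 1), c(0, 1)), 0.5)
  expect_equal(auc_time_course(c(0, 10), c(7, 7)), 70)
  expect_equal(auc_time_course(c(5, 10, 20, 30), c(10, 20, 40, 40)), 775)

  t <- c(5, 10, 20, 30); v <- c(10, 20, 40, 40)
  expect_equal(auc_time_course(t, 3 * v), 3 * auc_time_course(t, v))
  expect_equal(auc_time_course(t[1:2], v[1:2]) + auc_time_course(t[2:4], v[2:4]),
               auc_time_course(t, v))

  expect_error(auc_time_course(c(1, 1, 2), c(0, 0, 0)), "increasing")
  expect_error(auc_time_course(c(2, 1), c(0, 0)), "increasing")
  expect_error(auc_time_course(5, 1), ">= 2")
})

test_that("segmentation-based scores agree with ground-truth geometry", {
  for (seed in 1:8) {
    label <- if (seed %% 2) "bound" else "internalized"
    ev <- make_event(label, seed = seed)
    scored <- score_events(tibble::tibble(event_id = "e", image = list(ev$image)))
    s_truth <- internalization_score(ev$truth$cell_radius,
                                     max(truth_distance(ev$truth), 0.33))
    expect_equal(scored$score, s_truth, tolerance = 0.05)
    expect_equal(scored$label_pred, label)
  }
})

test_that("the score is invariant to rescaling pixel size and resolution", {
  tr <- event_truth("internalized", cell_center = c(10.5, 10.5),
                    particle_angle = 0.7)
  coarse <- generate_event(tr, noise_sd = 0, pixel_size = 0.33,
                           image_side = 64, seed = 5)
  fine <- generate_event(coarse$truth, noise_sd = 0, pixel_size = 0.165,
                         image_side = 128, seed = 5)
  s <- function(ev, eps) {
    sc <- score_events(tibble::tibble(event_id = "e", image = list(ev$image)),
                       eps = eps)
    sc$score
  }
  expect_equal(s(coarse, 0.33), s(fine, 0.33), tolerance = 0.05)
})
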