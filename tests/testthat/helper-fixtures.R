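# shared fixture builders; everything is generated in code at test time

# noiseless event of a given class, fixed geometry unless overridden
make_event <- function(label, seed = 1, noise_sd = 0, ...) {
  generate_event(event_truth(label, ...), noise_sd = noise_sd, seed = seed)
}

# truth-geometry centroid distance of a resolved event truth
truth_distance <- function(truth) {
  sqrt(sum((truth$cell_center - truth$particle_center)^2))
}

# small noiseless FRET scene with an engulfment window
make_fret_scene <- function(frames = 6, engulf = 3:4, noise_sd = 0, seed = 2,
                            drift = NULL, ...) {
  truth <- fret_truth(frames = frames, engulf_frames = engulf,
                      drift_series = drift, ...)
  gen <- generate_fret_stack(truth, noise_sd = noise_sd, seed = seed)
  list(truth = truth, stack = gen$stack)
}
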