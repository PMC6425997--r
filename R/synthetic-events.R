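#' Ground-truth description of a synthetic event
#'
#' Builds the ground truth for one synthetic imaging-flow-cytometry event.
#' Geometry fields left `NULL` are resolved reproducibly by
#' [generate_event()] under its seed, subject to the class invariants:
#'
#' * `bound`: particle centroid sits exactly at `cell_radius +
#'   particle_diameter / 2` from the cell centroid (touching the membrane
#'   from outside).
#' * `internalized`: particle centroid depth is drawn so the centroid
#'   distance is at most `0.4 * cell_radius` (engulfed well past the
#'   membrane, and always within `cell_radius - particle_diameter / 2`).
#' * `no_particle`: no particle is rendered.
#' * `off_plane`: bound geometry, but the particle channel carries a large
#'   defocus blur (default 1.2 um), emulating a particle outside the cell's
#'   focal plane.
#'
#' @param label one of `"no_particle"`, `"bound"`, `"internalized"`,
#'   `"off_plane"`.
#' @param cell_center optional `(x, y)` in um; default: frame centre with a
#'   small random jitter.
#' @param cell_radius cell radius in um (default 3.5, a primary B cell).
#' @param particle_diameter particle diameter in um; 1.0 emulates
#'   *S. typhimurium*, 3.0 an IgM-coated polystyrene bead.
#' @param particle_angle optional direction (radians) from cell centre to
#'   particle centre; drawn uniformly when `NULL`.
#' @param particle_center optional explicit `(x, y)` um; overrides
#'   angle/depth resolution (invariants are then checked, not imposed).
#' @param focus_blur_sigma per-channel Gaussian defocus sigma in um, length
#'   4 (brightfield, nucleus, surface, particle).  Default: 0.15 um on all
#'   channels; `off_plane` raises the particle entry to `offplane_blur`.
#' @param offplane_blur particle-channel defocus for `off_plane` events (um).
#' @return A list of class `event_truth`.
#' @export
event_truth <- function(label = c("no_particle", "bound", "internalized", "off_plane"),
                        cell_center = NULL,
                        cell_radius = 3.5,
                        particle_diameter = 1.0,
                        particle_angle = NULL,
                        particle_center = NULL,
                        focus_blur_sigma = rep(0.15, 4),
                        offplane_blur = 1.2) {
  label <- match.arg(label)
  if (cell_radius <= 0) abort("`cell_radius` must be > 0.")
  if (particle_diameter <= 0) abort("`particle_diameter` must be > 0.")
  focus_blur_sigma <- rep_len(focus_blur_sigma, 4)
  if (any(focus_blur_sigma < 0)) abort("`focus_blur_sigma` must be >= 0.")
  if (label == "off_plane") focus_blur_sigma[4] <- max(focus_blur_sigma[4], offplane_blur)
  structure(
    list(label = label, cell_center = cell_center, cell_radius = cell_radius,
         particle_diameter = particle_diameter,
         particle_angle = particle_angle, particle_center = particle_center,
         focus_blur_sigma = focus_blur_sigma, seed = NA_integer_),
    class = "event_truth"
  )
}

# fill in unresolved geometry under the current RNG state; enforce invariants
resolve_truth <- function(truth, pixel_size, image_side) {
  side_um <- image_side * pixel_size
  if (is.null(truth$cell_center)) {
    truth$cell_center <- rep(side_um / 2, 2) + stats::runif(2, -0.4, 0.4)
  }
  R <- truth$cell_radius; p <- truth$particle_diameter
  if (truth$label == "no_particle") {
    truth$particle_center <- NULL
  } else if (is.null(truth$particle_center)) {
    ang <- truth$particle_angle %||% stats::runif(1, 0, 2 * pi)
    d <- switch(truth$label,
      bound = R + p / 2,
      off_plane = R + p / 2,
      internalized = stats::runif(1, 0, min(0.4 * R, R - p / 2))
    )
    truth$particle_angle <- ang
    truth$particle_center <- truth$cell_center + d * c(cos(ang), sin(ang))
  }
  # containment: every rendered structure (incl. 3 sigma of blur) in frame
  margin <- 3 * max(truth$focus_blur_sigma)
  extents <- truth$cell_center[1] + c(-1, 1) * (R + margin)
  extents <- c(extents, truth$cell_center[2] + c(-1, 1) * (R + margin))
  if (!is.null(truth$particle_center)) {
    extents <- c(extents,
                 truth$particle_center[1] + c(-1, 1) * (p / 2 + margin),
                 truth$particle_center[2] + c(-1, 1) * (p / 2 + margin))
  }
  if (min(extents) < 0 || max(extents) > side_um) {
    abort(sprintf("frame too small: %d px at %.3g um/px cannot contain the scene.",
                  image_side, pixel_size))
  }
  truth
}

# rendering intensities (counts, 16-bit dynamic range)
event_render_defaults <- function() {
  list(brightfield_bg = 1000, brightfield_cell = 700,
       background = 100, nucleus_amp = 800, surface_amp = 600,
       particle_amp = 3000, nucleus_radius_frac = 0.55)
}

#' Generate one synthetic event image
#'
#' Renders a four-channel single-cell event (brightfield, nucleus, surface
#' marker, particle) from a ground truth, with per-channel Gaussian defocus
#' blur and additive Gaussian noise.  The same `truth`, parameters and `seed`
#' always yield a bit-identical image.
#'
#' @param truth an [event_truth()], or a label string as shorthand.
#' @param noise_sd additive Gaussian noise standard deviation, counts
#'   (applied to every channel; >= 0).
#' @param pixel_size um per pixel.
#' @param image_side image side length in pixels (square frame).
#' @param seed integer seed for geometry jitter and noise.
#' @param render list of rendering intensities, see
#'   `phagoquant:::event_render_defaults()`.
#' @return list with elements `image` ([event_image]) and `truth` (the fully
#'   resolved `event_truth`, centres in um).
#' @examples
#' ev <- generate_event(event_truth("internalized"), noise_sd = 0, seed = 1)
#' ev$truth$label
#' @export
generate_event <- function(truth = event_truth("bound"), noise_sd = 30,
                           pixel_size = 0.33, image_side = 64L, seed = 1L,
                           render = event_render_defaults()) {
  if (is.character(truth)) truth <- event_truth(truth)
  stopifnot(inherits(truth, "event_truth"))
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (pixel_size <= 0) abort("`pixel_size` must be > 0.")
  image_side <- as.integer(image_side)

  withr::local_seed(as.integer(seed))
  truth <- resolve_truth(truth, pixel_size, image_side)
  truth$seed <- as.integer(seed)

  nr <- image_side; nc <- image_side
  cell <- disc_soft(nr, nc, truth$cell_center, truth$cell_radius, pixel_size)
  nuc <- disc_soft(nr, nc, truth$cell_center,
                   render$nucleus_radius_frac * truth$cell_radius, pixel_size)

  bf <- render$brightfield_bg +
    (render$brightfield_cell - render$brightfield_bg) * cell
  nucleus <- render$background + render$nucleus_amp * nuc
  surface <- render$background + render$surface_amp * cell
  particle <- matrix(render$background, nr, nc)
  if (!is.null(truth$particle_center)) {
    pdisc <- disc_soft(nr, nc, truth$particle_center,
                       truth$particle_diameter / 2, pixel_size)
    particle <- particle + render$particle_amp * pdisc
  }

  sig <- truth$focus_blur_sigma
  chans <- list(
    brightfield = blur_um(bf, sig[1], pixel_size),
    nucleus = blur_um(nucleus, sig[2], pixel_size),
    surface = blur_um(surface, sig[3], pixel_size),
    particle = blur_um(particle, sig[4], pixel_size)
  )
  if (noise_sd > 0) {
    chans <- lapply(chans, function(m) m + rnorm(length(m), 0, noise_sd))
  }
  chans <- lapply(chans, function(m) pmax(m, 0))

  list(
    image = event_image(chans, pixel_size, event_id = sprintf("ev_s%d", seed)),
    truth = truth
  )
}

event_labels <- c("no_particle", "bound", "internalized", "off_plane")

#' Generate a ground-truthed synthetic cohort
#'
#' Draws `n` events i.i.d. from a mixture over the four ground-truth classes
#' and renders each with [generate_event()].  Per-event seeds are derived
#' deterministically from `seed`, so the whole cohort is reproducible.
#'
#' @param n number of events (>= 1).
#' @param mixture probabilities over
#'   `c(no_particle, bound, internalized, off_plane)`; must sum to 1
#'   (tolerance 1e-9).
#' @param particle_diameter particle diameter in um for particle-bearing
#'   classes (1.0 = bacterium, 3.0 = bead).
#' @inheritParams generate_event
#' @return tibble with one row per event: `event_id`, truth columns (`label`,
#'   `cell_x`, `cell_y`, `cell_radius_um`, `particle_x`, `particle_y`,
#'   `particle_diameter_um`, `blur_particle_um`, `seed`) and an `image`
#'   list-column of [event_image] objects.
#' @examples
#' cohort <- generate_cohort(8, mixture = c(0.25, 0.25, 0.25, 0.25), seed = 7)
#' table(cohort$label)
#' @export
generate_cohort <- function(n, mixture = c(0.25, 0.25, 0.25, 0.25),
                            noise_sd = 30, pixel_size = 0.33,
                            image_side = 64L, seed = 1L,
                            particle_diameter = 1.0,
                            render = event_render_defaults()) {
  if (n < 1) abort("`n` must be >= 1.")
  if (length(mixture) != 4L) abort("`mixture` must have four probabilities.")
  bad <- which(mixture < 0 | mixture > 1)
  if (length(bad)) {
    abort(sprintf("invalid mixture: probability for '%s' is %g (must be in [0, 1]).",
                  event_labels[bad[1]], mixture[bad[1]]))
  }
  if (abs(sum(mixture) - 1) > 1e-9) {
    abort(sprintf("invalid mixture: probabilities sum to %.12g, not 1.", sum(mixture)))
  }

  labels <- withr::with_seed(as.integer(seed),
    sample(event_labels, n, replace = TRUE, prob = mixture))
  seeds <- derive_seeds(seed, n)

  rows <- purrr::map(seq_len(n), function(i) {
    ev <- generate_event(
      event_truth(labels[i], particle_diameter = particle_diameter),
      noise_sd = noise_sd, pixel_size = pixel_size,
      image_side = image_side, seed = seeds[i], render = render
    )
    tr <- ev$truth
    ev$image$event_id <- sprintf("ev_%04d", i)
    tibble(
      event_id = ev$image$event_id,
      label = tr$label,
      cell_x = tr$cell_center[1], cell_y = tr$cell_center[2],
      cell_radius_um = tr$cell_radius,
      particle_x = if (is.null(tr$particle_center)) NA_real_ else tr$particle_center[1],
      particle_y = if (is.null(tr$particle_center)) NA_real_ else tr$particle_center[2],
      particle_diameter_um = tr$particle_diameter,
      blur_particle_um = tr$focus_blur_sigma[4],
      seed = seeds[i],
      image = list(ev$image)
    )
  })
  dplyr::bind_rows(rows)
}
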