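#' Ground truth for a synthetic biosensor acquisition
#'
#' Describes a single-cell RAC1 biosensor time lapse: a circular cell with a
#' basal activation level everywhere and an elevated activation level in the
#' membrane sector facing the particle contact during an "engulfment" window
#' of frames.  The elevated region is the membrane ROI the analysis
#' ([activation_trace()]) measures (same geometry helper), widened by one
#' pixel so the measured membrane-to-cytosol contrast tracks
#' `a_contact / a_basal` through the smoothing of the analysis chain.
#'
#' @param frames number of frames (>= 1).
#' @param side image side, px.
#' @param pixel_size um per pixel; default 0.102 um (63x objective with a
#'   6.45 um camera pixel).
#' @param frame_interval minutes per frame.
#' @param cell_radius um.
#' @param a_basal basal activation (ratio units) over the cell.
#' @param a_contact activation in the contact membrane sector during
#'   engulfment frames.
#' @param engulf_frames integer vector of frames carrying contact
#'   activation; default the middle half of the stack.
#' @param contact_angle direction from cell centre to the particle, radians.
#' @param bleed_through donor-to-acceptor leakage fraction in `[0, 1)`;
#'   default 0.62.
#' @param background_level counts added to every channel.
#' @param drift_series `frames x 2` matrix of per-frame `(dx, dy)` pixel
#'   translations (stage drift); default none.
#' @param membrane_width,sector_halfangle contact ROI geometry (um, degrees).
#' @param particle_diameter um.
#' @return list of class `fret_truth`, including the true
#'   `activation_map_series` (`H x W x T`, `NaN` off the cell footprint),
#'   the cell mask and the per-frame particle centres.
#' @export
fret_truth <- function(frames = 20L, side = 128L, pixel_size = 0.102,
                       frame_interval = 0.5, cell_radius = 5,
                       a_basal = 1, a_contact = 2,
                       engulf_frames = NULL, contact_angle = 0,
                       bleed_through = 0.62, background_level = 100,
                       drift_series = NULL,
                       membrane_width = 0.5, sector_halfangle = 45,
                       particle_diameter = 1.0) {
  if (frames < 1) abort("`frames` must be >= 1.")
  if (bleed_through < 0 || bleed_through >= 1) {
    abort("invalid parameter: `bleed_through` must be in [0, 1).")
  }
  frames <- as.integer(frames); side <- as.integer(side)
  engulf_frames <- engulf_frames %||%
    seq.int(max(1L, frames %/% 4 + 1L), min(frames, (3L * frames) %/% 4))
  if (is.null(drift_series)) drift_series <- matrix(0L, frames, 2)
  drift_series <- matrix(as.integer(drift_series), frames, 2)

  center <- rep(side * pixel_size / 2, 2)
  mask <- disc_mask(side, side, center, cell_radius, pixel_size)
  contact <- center + (cell_radius + particle_diameter / 2) *
    c(cos(contact_angle), sin(contact_angle))
  rois <- contact_rois(mask, center, contact, pixel_size,
                       membrane_width, sector_halfangle)
  # elevated region = measured membrane ROI plus a one-pixel rasterization
  # margin, so the analysis chain's 3x3 smoothing cannot erode the
  # constructed membrane contrast at the band's inner edge; the margin
  # leaks a few percent of activation into the adjacent cytosol ROI
  hot <- as.matrix(EBImage::dilate(EBImage::Image(rois$membrane * 1),
                                   EBImage::makeBrush(3L, "disc"))) > 0
  hot <- hot & mask

  a <- array(NaN, c(side, side, frames))
  base_map <- matrix(NaN, side, side); base_map[mask] <- a_basal
  hot_map <- base_map; hot_map[hot] <- a_contact
  for (t in seq_len(frames)) {
    a[, , t] <- if (t %in% engulf_frames) hot_map else base_map
  }

  structure(
    list(activation_map_series = a, bleed_through = bleed_through,
         background_level = background_level, drift_series = drift_series,
         cell_mask = mask, cell_center = center, cell_radius = cell_radius,
         contact_angle = contact_angle,
         particle_center_series = matrix(contact, frames, 2, byrow = TRUE),
         particle_diameter = particle_diameter,
         membrane_width = membrane_width, sector_halfangle = sector_halfangle,
         pixel_size = pixel_size, frame_interval = frame_interval,
         frames = frames, side = side, seed = NA_integer_),
    class = "fret_truth"
  )
}

# radially shaded donor emission: brighter at the cell centre, so per-pixel
# donor intensities span a range (needed for slope-based calibration)
donor_signal <- function(truth, donor_brightness) {
  g <- pixel_grid(truth$side, truth$side)
  r2 <- ((g$x * truth$pixel_size - truth$cell_center[1])^2 +
           (g$y * truth$pixel_size - truth$cell_center[2])^2) / truth$cell_radius^2
  sig <- donor_brightness * (1 - 0.4 * pmin(r2, 1))
  sig * truth$cell_mask
}

#' Generate a synthetic FRET biosensor stack
#'
#' Forward model, per pixel and frame: donor `C = C_sig + background +
#' noise` with `C_sig` the shaded cell emission; acceptor `V = (a + beta) *
#' C_sig + background + noise` where `a` is the true activation map and
#' `beta` the donor bleed-through.  Stage drift translates the signal
#' (before noise); the particle channel renders the particle disc.
#' Identical truth, parameters and seed give a bit-identical stack.
#'
#' @param truth a [fret_truth()].
#' @param donor_brightness peak donor signal, counts.
#' @param noise_sd additive Gaussian noise sd, counts.
#' @param seed integer seed.
#' @return list with `stack` ([fret_stack]) and `truth` (seed filled in).
#' @export
generate_fret_stack <- function(truth = fret_truth(), donor_brightness = 1000,
                                noise_sd = 20, seed = 1L) {
  stopifnot(inherits(truth, "fret_truth"))
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  withr::local_seed(as.integer(seed))
  truth$seed <- as.integer(seed)

  side <- truth$side; nt <- truth$frames
  bg <- truth$background_level
  beta <- truth$bleed_through
  C_sig <- donor_signal(truth, donor_brightness)

  donor <- array(0, c(side, side, nt))
  acceptor <- array(0, c(side, side, nt))
  particle <- array(0, c(side, side, nt))
  for (t in seq_len(nt)) {
    a_t <- truth$activation_map_series[, , t]
    a_t[is.nan(a_t)] <- 0
    V_sig <- (a_t + beta) * C_sig
    P_sig <- 3000 * disc_mask(side, side, truth$particle_center_series[t, ],
                              truth$particle_diameter / 2, truth$pixel_size)
    sh <- truth$drift_series[t, ]
    donor[, , t] <- shift_int(C_sig, sh) + bg
    acceptor[, , t] <- shift_int(V_sig, sh) + bg
    particle[, , t] <- shift_int(P_sig, sh) + bg
  }
  if (noise_sd > 0) {
    donor <- donor + rnorm(length(donor), 0, noise_sd)
    acceptor <- acceptor + rnorm(length(acceptor), 0, noise_sd)
    particle <- particle + rnorm(length(particle), 0, noise_sd)
  }
  list(
    stack = fret_stack(pmax(donor, 0), pmax(acceptor, 0), pmax(particle, 0),
                       pixel_size = truth$pixel_size,
                       frame_interval = truth$frame_interval),
    truth = truth
  )
}

#' Generate donor-only calibration cells
#'
#' Renders `n_cells` single-frame acquisitions of cells expressing the donor
#' fluorophore only (activation forced to zero everywhere), so the acceptor
#' channel carries nothing but the bleed-through `beta * donor` plus
#' background and noise.  These are the calibration inputs for
#' [estimate_bleedthrough()].
#'
#' @param n_cells number of cells (>= 1).
#' @param beta true leakage fraction in `[0, 1)`.
#' @param donor_brightness peak donor signal, counts.
#' @param noise_sd Gaussian noise sd, counts.
#' @param seed master seed; per-cell seeds are derived from it.
#' @param side,pixel_size,cell_radius image geometry, see [fret_truth()].
#' @return list with `stacks` (list of single-frame [fret_stack]s) and
#'   `truth` (a [fret_truth()] carrying `beta`).
#' @export
generate_donor_only <- function(n_cells, beta = 0.62, donor_brightness = 1000,
                                noise_sd = 20, seed = 1L,
                                side = 96L, pixel_size = 0.102,
                                cell_radius = 4) {
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  seeds <- derive_seeds(seed, n_cells)
  truth <- fret_truth(frames = 1L, side = side, pixel_size = pixel_size,
                      cell_radius = cell_radius, a_basal = 0, a_contact = 0,
                      bleed_through = beta)
  stacks <- lapply(seq_len(n_cells), function(i) {
    # cell-to-cell expression variation: scale brightness per cell
    b_i <- withr::with_seed(seeds[i], donor_brightness * stats::runif(1, 0.7, 1.3))
    generate_fret_stack(truth, donor_brightness = b_i,
                        noise_sd = noise_sd, seed = seeds[i])$stack
  })
  list(stacks = stacks, truth = truth)
}
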