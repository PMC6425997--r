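# membrane / cytosol ROIs around the particle contact: membrane = in-mask
# pixels within `membrane_width` (um) of the mask boundary and inside the
# angular sector facing the particle; cytosol = in-mask, in-sector pixels
# deeper than the membrane band
contact_rois <- function(mask, cell_centroid_um, particle_centroid_um,
                         pixel_size, membrane_width = 0.5,
                         sector_halfangle = 45) {
  depth_um <- mask_depth_px(mask) * pixel_size
  sector <- in_sector(nrow(mask), ncol(mask), cell_centroid_um,
                      particle_centroid_um, sector_halfangle, pixel_size)
  list(
    membrane = mask & sector & depth_um > 0 & depth_um <= membrane_width,
    cytosol = mask & sector & depth_um > membrane_width
  )
}

# per-frame cell masks from an Otsu threshold of the donor channel
cell_mask_series <- function(stack) {
  nt <- n_frames(stack)
  masks <- array(FALSE, dim(stack$donor))
  for (t in seq_len(nt)) {
    m <- otsu_mask(stack$donor[, , t])
    if (any(m)) m <- largest_component(m)$mask
    masks[, , t] <- m
  }
  masks
}

#' Background-correct a biosensor stack
#'
#' For every frame and channel, subtracts the median intensity of the pixels
#' outside the cell mask (Otsu threshold of the donor channel) and clips at
#' zero.  Idempotent on an already zero-background stack.
#'
#' @param stack a [fret_stack].
#' @return a corrected [fret_stack].
#' @export
background_correct <- function(stack) {
  stopifnot(inherits(stack, "fret_stack"))
  masks <- cell_mask_series(stack)
  out <- stack
  for (t in seq_len(n_frames(stack))) {
    bgmask <- !masks[, , t]
    for (ch in c("donor", "acceptor", "particle")) {
      fr <- stack[[ch]][, , t]
      bg <- if (any(bgmask)) median(fr[bgmask]) else 0
      out[[ch]][, , t] <- pmax(fr - bg, 0)
    }
  }
  out
}

#' Align a biosensor stack to its first frame
#'
#' Integer-pixel translation registration: each frame's donor channel is
#' cross-correlated (FFT) with frame 1, and the recovered shift is applied
#' identically to donor, acceptor and particle channels.
#'
#' @param stack a [fret_stack].
#' @return list with `stack` (aligned [fret_stack]) and `shifts` (tibble
#'   `frame`, `dx`, `dy`: the correction applied, in pixels).
#' @export
align_stack <- function(stack) {
  stopifnot(inherits(stack, "fret_stack"))
  nt <- n_frames(stack)
  ref <- stack$donor[, , 1]
  Fref <- fft(ref)
  nr <- nrow(ref); nc <- ncol(ref)
  out <- stack
  shifts <- matrix(0L, nt, 2)
  for (t in seq_len(nt)) {
    if (t > 1L) {
      cc <- Re(fft(Fref * Conj(fft(stack$donor[, , t])), inverse = TRUE))
      peak <- arrayInd(which.max(cc), dim(cc)) - 1L
      dy <- if (peak[1] > nr / 2) peak[1] - nr else peak[1]
      dx <- if (peak[2] > nc / 2) peak[2] - nc else peak[2]
      shifts[t, ] <- c(dx, dy)
      for (ch in c("donor", "acceptor", "particle")) {
        out[[ch]][, , t] <- shift_int(stack[[ch]][, , t], c(dx, dy))
      }
    }
  }
  list(stack = out,
       shifts = tibble(frame = seq_len(nt), dx = shifts[, 1], dy = shifts[, 2]))
}

#' Smooth a biosensor stack
#'
#' Applies a `k x k` uniform mean filter (default 3 x 3, replicated borders)
#' to the donor and acceptor channels of every frame to reduce noise before
#' ratioing; the particle channel is left untouched.
#'
#' @param stack a [fret_stack].
#' @param kernel_size odd kernel edge length (default 3).
#' @return a smoothed [fret_stack].
#' @export
smooth_stack <- function(stack, kernel_size = 3L) {
  stopifnot(inherits(stack, "fret_stack"))
  k <- as.integer(kernel_size)
  if (k < 1L || k %% 2L == 0L) abort("`kernel_size` must be a positive odd integer.")
  if (k == 1L) return(stack)
  kern <- matrix(1 / k^2, k, k)
  out <- stack
  for (t in seq_len(n_frames(stack))) {
    for (ch in c("donor", "acceptor")) {
      out[[ch]][, , t] <- as.matrix(
        EBImage::filter2(EBImage::Image(stack[[ch]][, , t]), kern,
                         boundary = "replicate"))
    }
  }
  out
}

#' Estimate the donor bleed-through coefficient
#'
#' Least-squares calibration of the leakage of donor (Cerulean3/CFP)
#' emission into the acceptor (Venus/YFP) channel, from cells expressing the
#' donor construct only.  Each stack is background corrected, in-cell pixels
#' are pooled across cells, and the slope of acceptor on donor intensity is
#' the bleed-through estimate.
#'
#' @param donor_only a list of single-frame [fret_stack]s (e.g. from
#'   [generate_donor_only()]), or one [fret_stack].
#' @return object of class `bleedthrough_fit` with elements `beta_hat`,
#'   `n_cells`, `n_pixels`, and the underlying `lm` fit; see [tidy()] /
#'   [glance()] methods.
#' @export
estimate_bleedthrough <- function(donor_only) {
  if (inherits(donor_only, "fret_stack")) donor_only <- list(donor_only)
  if (length(donor_only) < 1) abort("need >= 1 donor-only cell.")
  pixels <- purrr::map(donor_only, function(st) {
    st <- background_correct(st)
    masks <- cell_mask_series(st)
    keep <- which(masks)
    tibble(donor = st$donor[keep], acceptor = st$acceptor[keep])
  })
  px <- dplyr::bind_rows(pixels)
  if (nrow(px) == 0 || sd(px$donor) < 1e-12) {
    abort("degenerate calibration: donor signal is constant.")
  }
  fit <- lm(acceptor ~ donor, data = px)
  structure(
    list(beta_hat = unname(coef(fit)["donor"]),
         intercept = unname(coef(fit)["(Intercept)"]),
         n_cells = length(donor_only), n_pixels = nrow(px), fit = fit),
    class = "bleedthrough_fit"
  )
}

#' @export
print.bleedthrough_fit <- function(x, ...) {
  cat(sprintf("<bleedthrough_fit> beta_hat = %.4f (%.1f%%), %d cells, %d pixels\n",
              x$beta_hat, 100 * x$beta_hat, x$n_cells, x$n_pixels))
  invisible(x)
}

#' @rdname estimate_bleedthrough
#' @param x a `bleedthrough_fit`.
#' @param ... unused.
#' @export
tidy.bleedthrough_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname estimate_bleedthrough
#' @export
glance.bleedthrough_fit <- function(x, ...) {
  tibble(beta_hat = x$beta_hat, beta_pct = 100 * x$beta_hat,
         n_cells = x$n_cells, n_pixels = x$n_pixels,
         r.squared = summary(x$fit)$r.squared)
}

#' Default acceptor (Venus) intensity threshold
#'
#' Background median plus three times the MAD of the acceptor channel over
#' out-of-cell pixels, pooled across frames.  Pixels below this are set to
#' `NaN` in the ratio map so background noise cannot masquerade as signal.
#'
#' @param stack a [fret_stack] (background-corrected).
#' @return scalar threshold, counts.
#' @export
default_acceptor_threshold <- function(stack) {
  masks <- cell_mask_series(stack)
  bgpx <- stack$acceptor[which(!masks)]
  if (length(bgpx) == 0) return(0)
  median(bgpx) + 3 * mad(bgpx)
}

#' Bleed-through corrected Venus/Cerulean3 ratio map
#'
#' Computes `F = (V - beta * C) / C` per pixel and frame on a
#' background-corrected, aligned, smoothed stack.  The intensity threshold
#' is applied exclusively to the acceptor (Venus) channel: pixels with
#' `V < acceptor_threshold` become `NaN` in every output frame they fail in.
#' Pixels where `C = 0` are also `NaN` (division guard) and counted.
#'
#' @param stack a [fret_stack], already background corrected, aligned and
#'   smoothed (see [background_correct()], [align_stack()],
#'   [smooth_stack()]).
#' @param beta bleed-through fraction; default 0.62.
#' @param acceptor_threshold Venus threshold in counts; default
#'   [default_acceptor_threshold()].
#' @return object of class `ratio_map`: list with `ratio` (`H x W x T`,
#'   `NaN` at background), `beta_used`, `threshold`, `n_division_guard`,
#'   `pixel_size`, `frame_interval`.
#' @export
ratio_map <- function(stack, beta = 0.62, acceptor_threshold = NULL) {
  stopifnot(inherits(stack, "fret_stack"))
  if (beta < 0 || beta >= 1) abort("invalid parameter: `beta` must be in [0, 1).")
  thr <- acceptor_threshold %||% default_acceptor_threshold(stack)
  V <- stack$acceptor; C <- stack$donor
  below <- V < thr
  guard <- !below & C == 0
  ratio <- (V - beta * C) / C
  ratio[below | guard] <- NaN
  n_guard <- sum(guard)
  if (n_guard > 0) {
    message(sprintf("ratio_map: %d pixel(s) with zero donor intensity set to NaN.",
                    n_guard))
  }
  structure(
    list(ratio = ratio, beta_used = beta, threshold = thr,
         n_division_guard = n_guard, pixel_size = stack$pixel_size,
         frame_interval = stack$frame_interval),
    class = "ratio_map"
  )
}

#' @export
print.ratio_map <- function(x, ...) {
  d <- dim(x$ratio)
  cat(sprintf("<ratio_map> %d x %d px, %d frame(s), beta = %.3g, %.3g%% finite\n",
              d[1], d[2], d[3], x$beta_used,
              100 * mean(is.finite(x$ratio))))
  invisible(x)
}

#' Track the particle across frames
#'
#' Per-frame particle centroid from the particle channel (noise-floor test
#' plus Otsu threshold, largest component), for feeding
#' [activation_trace()].
#'
#' @param stack a [fret_stack].
#' @param k,min_area_px detection parameters as in [segment_particle()].
#' @return tibble `frame`, `x_um`, `y_um` (`NA` where no particle found).
#' @export
track_particle <- function(stack, k = 5, min_area_px = 3L) {
  purrr::map_dfr(seq_len(n_frames(stack)), function(t) {
    ch <- smooth3(stack$particle[, , t])
    floor_level <- median(ch) + k * mad(ch)
    cen <- c(NA_real_, NA_real_)
    if (sum(ch > floor_level) >= min_area_px) {
      m <- otsu_mask(ch) & ch > floor_level
      if (sum(m) >= min_area_px) {
        m <- largest_component(m)$mask
        cen <- weighted_centroid_um(ch, m, stack$pixel_size)
      }
    }
    tibble(frame = t, x_um = cen[1], y_um = cen[2])
  })
}

#' Membrane-versus-cytosol activation trace
#'
#' For each frame, measures the mean ratio in a membrane band near the
#' particle contact (in-mask pixels within `membrane_width` of the cell
#' boundary, inside the angular sector centred on the cell-to-particle
#' direction) against the mean ratio in the adjacent cytosol (in-mask,
#' in-sector pixels deeper than the band).  The activation ratio
#' `A(t) = membrane_mean / cytosol_mean` is `NA` whenever the particle
#' centroid is missing, an ROI is empty, or the cytosol mean is not
#' positive.  `A(t)` is invariant to scaling the whole ratio map by a
#' positive constant.
#'
#' @param rmap a [ratio_map()].
#' @param particle_centroids tibble `frame`, `x_um`, `y_um` (see
#'   [track_particle()]).
#' @param cell_masks logical `H x W x T` array of cell masks; default
#'   recomputed is not possible from the ratio map alone, so pass e.g.
#'   `phagoquant:::cell_mask_series(corrected_stack)`.
#' @param sector_halfangle degrees; default 45.
#' @param membrane_width um; default 0.5.
#' @return tibble of class `activation_trace`: `frame`, `time_min`,
#'   `membrane_mean`, `cytosol_mean`, `activation_ratio`.
#' @export
activation_trace <- function(rmap, particle_centroids, cell_masks,
                             sector_halfangle = 45, membrane_width = 0.5) {
  stopifnot(inherits(rmap, "ratio_map"))
  d <- dim(rmap$ratio)
  if (!identical(dim(cell_masks), d)) {
    abort("`cell_masks` must share the ratio map's shape.")
  }
  rows <- purrr::map_dfr(seq_len(d[3]), function(t) {
    pc <- particle_centroids[particle_centroids$frame == t, ]
    out <- tibble(frame = t, time_min = (t - 1) * rmap$frame_interval,
                  membrane_mean = NA_real_, cytosol_mean = NA_real_,
                  activation_ratio = NA_real_)
    if (nrow(pc) == 0 || is.na(pc$x_um[1])) return(out)
    mask <- cell_masks[, , t]
    if (!any(mask)) return(out)
    g <- pixel_grid(d[1], d[2])
    cen <- c(mean(g$x[mask]), mean(g$y[mask])) * rmap$pixel_size
    rois <- contact_rois(mask, cen, c(pc$x_um[1], pc$y_um[1]),
                         rmap$pixel_size, membrane_width, sector_halfangle)
    fr <- rmap$ratio[, , t]
    mem <- fr[rois$membrane]; cyt <- fr[rois$cytosol]
    mem_mean <- if (any(is.finite(mem))) mean(mem[is.finite(mem)]) else NA_real_
    cyt_mean <- if (any(is.finite(cyt))) mean(cyt[is.finite(cyt)]) else NA_real_
    out$membrane_mean <- mem_mean
    out$cytosol_mean <- cyt_mean
    if (is.finite(mem_mean) && is.finite(cyt_mean) && cyt_mean > 0) {
      out$activation_ratio <- mem_mean / cyt_mean
    }
    out
  })
  class(rows) <- c("activation_trace", class(rows))
  rows
}

#' Run the full ratiometric chain on a raw stack
#'
#' Convenience wrapper: background correction, alignment to frame 1,
#' smoothing, ratio map with bleed-through correction, particle tracking and
#' the activation trace, in the fixed order the method prescribes.
#'
#' @param stack a raw [fret_stack].
#' @param beta bleed-through fraction (default 0.62).
#' @param kernel_size smoothing kernel (default 3).
#' @param acceptor_threshold optional Venus threshold; default derived from
#'   the corrected stack.
#' @param sector_halfangle,membrane_width trace geometry.
#' @return list with `ratio_map`, `trace`, `shifts`, and the processed
#'   `stack`.
#' @export
fret_pipeline <- function(stack, beta = 0.62, kernel_size = 3L,
                          acceptor_threshold = NULL,
                          sector_halfangle = 45, membrane_width = 0.5) {
  corrected <- background_correct(stack)
  aligned <- align_stack(corrected)
  smoothed <- smooth_stack(aligned$stack, kernel_size = kernel_size)
  rmap <- ratio_map(smoothed, beta = beta,
                    acceptor_threshold = acceptor_threshold)
  masks <- cell_mask_series(smoothed)
  centroids <- track_particle(smoothed)
  trace <- activation_trace(rmap, centroids, masks,
                            sector_halfangle = sector_halfangle,
                            membrane_width = membrane_width)
  list(ratio_map = rmap, trace = trace, shifts = aligned$shifts,
       stack = smoothed)
}
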