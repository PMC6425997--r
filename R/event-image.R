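#' Single-cell event image
#'
#' Container for one multi-channel imaging-flow-cytometry event: four 2-D
#' intensity channels of equal shape (brightfield, nucleus, surface marker,
#' particle) plus the pixel calibration.  Channels are plain numeric matrices
#' indexed `[row, col]`; pixel `(x, y) = (col - 1, row - 1)` (0-based), and
#' physical positions are `pixel * pixel_size` in micrometres.
#'
#' @param channels named list of four numeric matrices with names
#'   `brightfield`, `nucleus`, `surface`, `particle`, all of one shape.
#' @param pixel_size pixel edge length in micrometres per pixel (> 0).
#' @param event_id character identifier.
#' @return An object of class `event_image`.
#' @export
event_image <- function(channels, pixel_size, event_id = "event") {
  wanted <- c("brightfield", "nucleus", "surface", "particle")
  if (!is.list(channels) || !setequal(names(channels), wanted)) {
    abort("`channels` must be a named list: brightfield, nucleus, surface, particle.")
  }
  channels <- channels[wanted]
  shapes <- vapply(channels, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) abort("all channels must share one shape.")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    abort("`pixel_size` must be a single positive number (um/px).")
  }
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    abort("channel intensities must be non-negative.")
  }
  structure(
    list(channels = channels, pixel_size = pixel_size,
         event_id = as.character(event_id)),
    class = "event_image"
  )
}

#' @export
print.event_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<event_image> %s: %d x %d px, %.3g um/px, 4 channels\n",
              x$event_id, d[1], d[2], x$pixel_size))
  invisible(x)
}

#' @export
dim.event_image <- function(x) dim(x$channels[[1]])

event_channel_order <- c("brightfield", "nucleus", "surface", "particle")

#' Write and read event images as multi-page TIFF
#'
#' Events are written one file per event, one page per channel in the fixed
#' order brightfield, nucleus, surface, particle, as 32-bit float TIFF.
#' `write_events()` also writes a `ground_truth.csv` sidecar (when truth
#' columns are present) and a `config.json` capturing the pixel size and
#' channel order; `read_events()` restores the event tibble from a directory.
#'
#' @param events tibble with columns `event_id` and `image` (list of
#'   [event_image]), as returned by [generate_cohort()]; extra columns are
#'   treated as ground-truth metadata and written to the sidecar CSV.
#' @param dir output/input directory.
#' @return `write_events()`: `dir`, invisibly.  `read_events()`: an event
#'   tibble with any sidecar ground-truth columns joined back on.
#' @export
write_events <- function(events, dir) {
  stopifnot(is.data.frame(events), all(c("event_id", "image") %in% names(events)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(events))) {
    img <- events$image[[i]]
    pages <- lapply(img$channels[event_channel_order], function(m) m / 65535)
    tiff::writeTIFF(pages, file.path(dir, paste0(events$event_id[i], ".tif")),
                    bits.per.sample = 32L)
  }
  meta <- events[setdiff(names(events), "image")]
  readr::write_csv(meta, file.path(dir, "ground_truth.csv"))
  cfg <- list(
    pixel_size = events$image[[1]]$pixel_size,
    channel_order = event_channel_order,
    intensity_scale = 65535,
    n_events = nrow(events)
  )
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_events
#' @export
read_events <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  meta <- readr::read_csv(file.path(dir, "ground_truth.csv"),
                          show_col_types = FALSE)
  scale <- cfg$intensity_scale %||% 65535
  images <- lapply(meta$event_id, function(id) {
    pages <- tiff::readTIFF(file.path(dir, paste0(id, ".tif")), all = TRUE)
    chans <- lapply(pages, function(p) p * scale)
    names(chans) <- unlist(cfg$channel_order)
    event_image(chans, pixel_size = cfg$pixel_size, event_id = id)
  })
  meta$image <- images
  as_tibble(meta)
}
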