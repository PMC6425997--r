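#' Time-lapse FRET biosensor stack
#'
#' Container for a two-camera biosensor acquisition: donor (Cerulean3),
#' acceptor (Venus FRET) and particle channels as `H x W x T` numeric
#' arrays, plus pixel calibration and frame interval.
#'
#' @param donor,acceptor,particle numeric arrays of one shape `H x W x T`
#'   (a matrix is taken as a single frame).
#' @param pixel_size um per pixel (> 0).
#' @param frame_interval minutes between frames.
#' @return object of class `fret_stack`.
#' @export
fret_stack <- function(donor, acceptor, particle = NULL, pixel_size,
                       frame_interval = 1) {
  as3d <- function(a) if (length(dim(a)) == 2L) array(a, c(dim(a), 1L)) else a
  donor <- as3d(donor); acceptor <- as3d(acceptor)
  if (is.null(particle)) particle <- array(0, dim(donor))
  particle <- as3d(particle)
  if (!identical(dim(donor), dim(acceptor)) ||
      !identical(dim(donor), dim(particle))) {
    abort("donor, acceptor and particle arrays must share one shape.")
  }
  if (pixel_size <= 0) abort("`pixel_size` must be > 0.")
  structure(
    list(donor = donor, acceptor = acceptor, particle = particle,
         pixel_size = pixel_size, frame_interval = frame_interval),
    class = "fret_stack"
  )
}

#' @export
print.fret_stack <- function(x, ...) {
  d <- dim(x$donor)
  cat(sprintf("<fret_stack> %d x %d px, %d frame(s), %.3g um/px, %.3g min/frame\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
dim.fret_stack <- function(x) dim(x$donor)

n_frames <- function(stack) dim(stack$donor)[3]

#' Write and read a FRET stack as multi-page TIFF plus JSON metadata
#'
#' Pages are interleaved per frame in channel order donor, acceptor,
#' particle; a `<stem>.json` sidecar records pixel size, frame interval,
#' channel order and the intensity scale.
#'
#' @param stack a [fret_stack].
#' @param path output TIFF path (`.tif`).
#' @return `write_fret_tiff()`: `path` invisibly; `read_fret_tiff()`: a
#'   [fret_stack].
#' @export
write_fret_tiff <- function(stack, path) {
  scale <- 65535
  pages <- list()
  for (t in seq_len(n_frames(stack))) {
    pages <- c(pages, list(stack$donor[, , t] / scale,
                           stack$acceptor[, , t] / scale,
                           stack$particle[, , t] / scale))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(pixel_size = stack$pixel_size,
               frame_interval = stack$frame_interval,
               channel_order = c("donor", "acceptor", "particle"),
               intensity_scale = scale, n_frames = n_frames(stack))
  jsonlite::write_json(meta, sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fret_tiff
#' @export
read_fret_tiff <- function(path) {
  meta <- jsonlite::read_json(sub("\\.tiff?$", ".json", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  nt <- meta$n_frames
  scale <- meta$intensity_scale %||% 65535
  d <- dim(pages[[1]])
  pick <- function(offset) {
    a <- array(0, c(d, nt))
    for (t in seq_len(nt)) a[, , t] <- pages[[3 * (t - 1) + offset]] * scale
    a
  }
  fret_stack(pick(1), pick(2), pick(3),
             pixel_size = meta$pixel_size,
             frame_interval = meta$frame_interval)
}
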