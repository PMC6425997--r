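# Internal geometry and image helpers shared by the generators and the
# analysis code.  Convention throughout: matrices are indexed [row, col] with
# (x, y) = (col - 1, row - 1) in 0-based pixel coordinates; physical
# coordinates are x_um = x_px * pixel_size.

# pixel-centre coordinate grids (0-based), each a matrix of the image shape
pixel_grid <- function(nrow, ncol) {
  list(
    x = matrix(rep(seq_len(ncol) - 1, each = nrow), nrow = nrow),
    y = matrix(rep(seq_len(nrow) - 1, times = ncol), nrow = nrow)
  )
}

# binary disc mask: centre in um (x, y), radius in um
disc_mask <- function(nrow, ncol, center_um, radius_um, pixel_size) {
  g <- pixel_grid(nrow, ncol)
  dx <- g$x * pixel_size - center_um[1]
  dy <- g$y * pixel_size - center_um[2]
  (dx * dx + dy * dy) <= radius_um^2
}

# anti-aliased disc: per-pixel area coverage in [0, 1] by ss x ss
# supersampling, so rendered centroids are not quantized to the pixel grid
disc_soft <- function(nrow, ncol, center_um, radius_um, pixel_size, ss = 4L) {
  cov <- matrix(0, nrow, ncol)
  offs <- (seq_len(ss) - 0.5) / ss - 0.5
  g <- pixel_grid(nrow, ncol)
  for (ox in offs) for (oy in offs) {
    dx <- (g$x + ox) * pixel_size - center_um[1]
    dy <- (g$y + oy) * pixel_size - center_um[2]
    cov <- cov + ((dx * dx + dy * dy) <= radius_um^2)
  }
  cov / ss^2
}

# Gaussian blur with sigma in um; returns the unblurred matrix when sigma is
# negligible relative to the pixel grid
blur_um <- function(m, sigma_um, pixel_size) {
  sigma_px <- sigma_um / pixel_size
  if (sigma_px < 0.05) return(m)
  # EBImage::gblur needs a filter smaller than the image; cap the support
  r <- min(ceiling(4 * sigma_px), floor((min(dim(m)) - 1) / 2) - 1)
  as.matrix(EBImage::gblur(m, sigma = sigma_px, radius = 2 * r + 1))
}

# Otsu foreground mask of a single channel (largest-component selection is
# left to callers).  EBImage's otsu expects intensities in [0, 1].
otsu_mask <- function(m) {
  rng <- range(m)
  if (diff(rng) <= 0) return(matrix(FALSE, nrow(m), ncol(m)))
  scaled <- (m - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256L)
  scaled > thr
}

# largest connected component of a logical mask (8-connectivity); returns a
# logical mask, all-FALSE when the input has no TRUE pixel
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  if (max(lab) == 0) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  list(mask = lab == keep, n_components = length(sizes),
       sizes_px = sizes)
}

# intensity-weighted centroid of `m` over `mask`, in um (x, y)
weighted_centroid_um <- function(m, mask, pixel_size) {
  g <- pixel_grid(nrow(m), ncol(m))
  w <- m[mask]
  w <- w - min(w)          # weights non-negative even after background shifts
  if (sum(w) <= 0) w <- rep(1, length(w))
  c(
    x = sum(g$x[mask] * w) / sum(w) * pixel_size,
    y = sum(g$y[mask] * w) / sum(w) * pixel_size
  )
}

# distance (px) from each in-mask pixel to the nearest background pixel;
# 0 outside the mask
mask_depth_px <- function(mask) {
  as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
}

# angular sector test: TRUE where the direction from `center_um` to the pixel
# lies within `halfangle_deg` of the direction from `center_um` to `toward_um`
in_sector <- function(nrow, ncol, center_um, toward_um, halfangle_deg,
                      pixel_size) {
  g <- pixel_grid(nrow, ncol)
  vx <- g$x * pixel_size - center_um[1]
  vy <- g$y * pixel_size - center_um[2]
  ux <- toward_um[1] - center_um[1]
  uy <- toward_um[2] - center_um[2]
  nu <- sqrt(ux^2 + uy^2)
  nv <- sqrt(vx^2 + vy^2)
  cosang <- (vx * ux + vy * uy) / pmax(nv * nu, .Machine$double.eps)
  cosang >= cos(halfangle_deg * pi / 180)
}

# integer-pixel translation with zero fill; shift = c(dx, dy) moves content
# +dx columns right and +dy rows down
shift_int <- function(m, shift) {
  dx <- as.integer(round(shift[1])); dy <- as.integer(round(shift[2]))
  out <- matrix(0, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  src_r <- seq_len(nr) - dy; src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# deterministic child seeds below 2^31, derived from one master seed
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

# 3x3 mean prefilter used before particle detection (noise suppression)
smooth3 <- function(m) {
  as.matrix(EBImage::filter2(EBImage::Image(m), matrix(1 / 9, 3, 3),
                             boundary = "replicate"))
}
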