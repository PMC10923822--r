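# Input standardization (resize -> grayscale -> CLAHE -> channel
# replication -> [0,1] scaling) and label-consistent geometric
# augmentation. Geometric resampling is delegated to EBImage; masks are
# always resampled nearest-neighbour so they stay binary.

rgb_to_gray <- function(x) {
  if (length(dim(x)) == 2) return(x)
  if (dim(x)[3] == 1) return(x[, , 1])
  0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
}

# EBImage stores images as (x = width, y = height); package matrices are
# (row = y, col = x), hence the transposes at the boundary.
mat_to_eb <- function(m) EBImage::Image(t(m))
eb_to_mat <- function(img) t(EBImage::imageData(img))

resize_mat <- function(m, size, nearest = FALSE) {
  img <- EBImage::resize(mat_to_eb(m), w = size, h = size,
                         filter = if (nearest) "none" else "bilinear")
  eb_to_mat(img)
}

#' Standardize a raw radiograph for the networks
#'
#' Applies, in order: resize to `size` x `size` (bilinear), grayscale
#' conversion (luminance weighting for RGB input), Contrast Limited
#' Adaptive Histogram Equalization, replication of the single channel to
#' three identical channels, and scaling by the 8-bit maximum of 255 into
#' `\[0, 1\]`.
#'
#' @param raw 2-D matrix or (H, W, C) array; 8-bit values in 0..255 or
#'   already-scaled values in \[0, 1\].
#' @param size Output side length in pixels (default 299).
#' @param clahe_clip CLAHE clip limit (default 2).
#' @param clahe_grid CLAHE tile grid (default 8, meaning 8 x 8 tiles).
#' @return A `size` x `size` x 3 array with identical channels and values
#'   in \[0, 1\].
#' @export
standardize <- function(raw, size = 299, clahe_clip = 2, clahe_grid = 8) {
  d <- dim(raw)
  if (is.null(d) || length(d) < 2 || any(d[1:2] < 2) || length(raw) == 0)
    stop("invalid input: expected a non-empty 2-D image")
  if (max(raw) > 1) raw <- raw / 255
  if (length(d) == 3) {
    chans <- lapply(seq_len(d[3]), function(c) resize_mat(raw[, , c], size))
    g <- rgb_to_gray(array(unlist(chans), dim = c(size, size, d[3])))
  } else {
    g <- resize_mat(raw, size)
  }
  g <- pmin(pmax(g, 0), 1)
  g <- clahe_mat(g, clahe_grid, clahe_clip)
  array(rep(g, 3), dim = c(size, size, 3))
}

# CLAHE via EBImage. The tile decomposition needs the side length to be a
# multiple of the grid, so the image is edge-padded up to the next multiple
# and cropped back; a constant image (no contrast to equalize) is returned
# unchanged.
clahe_mat <- function(g, grid, clip) {
  if (max(g) - min(g) < .Machine$double.eps) return(g)
  d <- dim(g)
  ph <- (grid - d[1] %% grid) %% grid
  pw <- (grid - d[2] %% grid) %% grid
  gp <- g
  if (ph > 0) gp <- rbind(gp, gp[rep(d[1], ph), , drop = FALSE])
  if (pw > 0) gp <- cbind(gp, gp[, rep(d[2], pw), drop = FALSE])
  eq <- EBImage::clahe(mat_to_eb(gp), nx = grid, ny = grid,
                       limit = clip, keep.range = TRUE)
  out <- eb_to_mat(eq)[seq_len(d[1]), seq_len(d[2])]
  pmin(pmax(out, 0), 1)
}

rotate_mat <- function(m, angle, nearest = FALSE) {
  d <- dim(m)
  img <- EBImage::rotate(mat_to_eb(m), angle,
                         filter = if (nearest) "none" else "bilinear",
                         output.dim = c(d[2], d[1]), bg.col = 0)
  eb_to_mat(img)
}

zoom_mat <- function(m, frac, nearest = FALSE) {
  d <- dim(m)
  r0 <- floor(d[1] * frac / 2) + 1
  c0 <- floor(d[2] * frac / 2) + 1
  r1 <- r0 + ceiling(d[1] * (1 - frac)) - 1
  c1 <- c0 + ceiling(d[2] * (1 - frac)) - 1
  resize_mat(m[r0:r1, c0:c1], d[1], nearest = nearest)
}

#' Label-consistent random augmentation of an image/mask pair
#'
#' Samples one geometric transform (random horizontal/vertical flips, a
#' rotation with angle drawn uniformly in \[0, max_rotation\] degrees with
#' random sign, and an optional 10 percent center zoom-in) and applies the
#' identical transform to the image (bilinear) and its mask
#' (nearest-neighbour, so labels stay binary). Any of the transform
#' arguments can be forced for reproducibility; `NULL` means "sample".
#'
#' @param image (H, W) matrix or (H, W, C) array.
#' @param mask (H, W) binary matrix with the same spatial shape.
#' @param hflip,vflip Logical or NULL (sample with probability 0.5).
#' @param angle Rotation in degrees or NULL (sample).
#' @param zoom Logical or NULL (sample with probability 0.5).
#' @param max_rotation Maximum rotation magnitude in degrees (default 10).
#' @param zoom_frac Zoom-in fraction (default 0.1: crop to 90 percent of
#'   each side, then resize back).
#' @return List with `image` and `mask`, shapes unchanged.
#' @export
augment <- function(image, mask, hflip = NULL, vflip = NULL, angle = NULL,
                    zoom = NULL, max_rotation = 10, zoom_frac = 0.1) {
  di <- dim(image); dm <- dim(mask)
  if (any(di[1:2] != dm[1:2]))
    stop("image and mask spatial shapes differ")
  if (is.null(hflip)) hflip <- stats::runif(1) < 0.5
  if (is.null(vflip)) vflip <- stats::runif(1) < 0.5
  if (is.null(angle))
    angle <- stats::runif(1, 0, max_rotation) * sample(c(-1, 1), 1)
  if (is.null(zoom)) zoom <- stats::runif(1) < 0.5

  tf <- function(m, nearest) {
    if (hflip) m <- m[, rev(seq_len(ncol(m)))]
    if (vflip) m <- m[rev(seq_len(nrow(m))), ]
    if (angle != 0) m <- rotate_mat(m, angle, nearest = nearest)
    if (zoom) m <- zoom_mat(m, zoom_frac, nearest = nearest)
    m
  }
  if (length(di) == 3) {
    out <- array(0, dim = di)
    for (c in seq_len(di[3])) out[, , c] <- tf(image[, , c], nearest = FALSE)
    image <- out
  } else {
    image <- tf(image, nearest = FALSE)
  }
  mask <- tf(mask, nearest = TRUE)
  mask <- (mask > 0.5) * 1
  list(image = image, mask = mask)
}
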