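# Synthetic chest-phantom generator. Phantoms emulate a posteroanterior
# chest radiograph at the level the segmentation/CTR pipeline needs: two
# dark elliptical lung fields with bright surroundings, one bright central
# cardiac ellipse of controllable width, an intensity gradient, additive
# Gaussian noise, and pixel-exact ground-truth masks with a known true CTR.

#' Specification of one synthetic chest phantom
#'
#' All geometric fields are fractions of the image size. The heart's
#' horizontal extent is constructed so that the mask-derived CTR (heart
#' bounding-box width over lung-union bounding-box width) equals
#' `target_ctr` up to pixelization.
#'
#' @param image_size Square image size in pixels (default 128).
#' @param lung_centers List of two (x, y) centers as fractions.
#' @param lung_semiaxes (a, b) horizontal/vertical semi-axes as fractions,
#'   shared by both lungs.
#' @param heart_center (x, y) heart center as fractions.
#' @param target_ctr Desired cardiothoracic ratio in (0, 1].
#' @param noise_sd Gaussian noise standard deviation in intensity units
#'   (default 0.05; 0 gives a noiseless phantom).
#' @param gradient_amp Amplitude of the diagonal intensity gradient
#'   (default 0.1).
#' @param ribs Add faint sinusoidal rib-like bands over the lungs
#'   (default FALSE).
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 128,
                         lung_centers = list(c(0.30, 0.48), c(0.70, 0.48)),
                         lung_semiaxes = c(0.16, 0.30),
                         heart_center = c(0.50, 0.62),
                         target_ctr = 0.55, noise_sd = 0.05,
                         gradient_amp = 0.1, ribs = FALSE, seed = 1L) {
  spec <- list(image_size = as.integer(image_size),
               lung_centers = lung_centers,
               lung_semiaxes = lung_semiaxes, heart_center = heart_center,
               target_ctr = target_ctr, noise_sd = noise_sd,
               gradient_amp = gradient_amp, ribs = ribs,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  if (spec$image_size < 16)
    stop("invalid phantom spec: image_size must be >= 16")
  if (!(spec$target_ctr > 0 && spec$target_ctr <= 1))
    stop("invalid phantom spec: target_ctr must lie in (0, 1]")
  a <- spec$lung_semiaxes[1]; b <- spec$lung_semiaxes[2]
  for (ctr in spec$lung_centers) {
    if (ctr[1] - a < 0 || ctr[1] + a > 1 || ctr[2] - b < 0 || ctr[2] + b > 1)
      stop("invalid phantom spec: lung ellipse extends outside the image")
  }
  invisible(spec)
}

ellipse_mask <- function(S, cx, cy, a, b) {
  x <- matrix(0:(S - 1), S, S, byrow = TRUE)  # column index
  y <- matrix(0:(S - 1), S, S)                # row index
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

#' Generate one synthetic chest phantom
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (S x S matrix in \[0, 1\]), `heart` and
#'   `lungs` (S x S binary masks), and `true_ctr` (the mask-derived CTR,
#'   equal to the bounding-box width ratio exactly).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  S <- spec$image_size
  a <- spec$lung_semiaxes[1] * S
  b <- spec$lung_semiaxes[2] * S
  lungs <- ellipse_mask(S, spec$lung_centers[[1]][1] * S,
                        spec$lung_centers[[1]][2] * S, a, b) |
    ellipse_mask(S, spec$lung_centers[[2]][1] * S,
                 spec$lung_centers[[2]][2] * S, a, b)
  cols <- which(colSums(lungs) > 0)
  wl <- max(cols) - min(cols) + 1
  # heart width in pixels matching the requested CTR; the horizontal
  # semi-axis is set so exactly that many integer columns are covered
  wh <- max(1L, round(spec$target_ctr * wl))
  c_left <- round(spec$heart_center[1] * S - (wh - 1) / 2)
  c_left <- min(max(c_left, min(cols)), max(cols) - wh + 1)
  ch <- c_left + (wh - 1) / 2
  ah <- (wh - 1) / 2 + 0.499
  cyh <- spec$heart_center[2] * S
  bh <- min(0.8 * ah + 0.5, cyh, S - 1 - cyh)
  heart <- ellipse_mask(S, ch, cyh, ah, max(bh, 1))
  hcols <- which(colSums(heart) > 0)
  true_ctr <- (max(hcols) - min(hcols) + 1) / wl

  set.seed(spec$seed)
  img <- matrix(0.62, S, S)
  img[lungs] <- 0.30
  if (spec$ribs) {
    y <- matrix(0:(S - 1), S, S)
    bands <- 0.06 * (sin(y / S * 10 * pi) > 0.3)
    img[lungs] <- img[lungs] + bands[lungs]
  }
  img[heart] <- 0.78
  if (spec$gradient_amp != 0) {
    x <- matrix(0:(S - 1), S, S, byrow = TRUE)
    y <- matrix(0:(S - 1), S, S)
    img <- img + spec$gradient_amp * ((x + y) / (2 * (S - 1)) - 0.5)
  }
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(S * S, 0, spec$noise_sd), S, S)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, heart = heart * 1, lungs = lungs * 1,
       true_ctr = true_ctr)
}

#' Default CTR distribution for phantom datasets
#'
#' Normal with mean 0.50 and standard deviation 0.08 (roughly the clinical
#' spread of cardiothoracic ratios), clamped to \[0.30, 0.95\].
#'
#' @param n Number of draws.
#' @return Numeric vector of CTR values.
#' @export
default_ctr_law <- function(n) {
  pmin(pmax(stats::rnorm(n, 0.50, 0.08), 0.30), 0.95)
}

#' Generate a phantom dataset on disk
#'
#' Writes 8-bit grayscale PNG images for `n_labeled + m_unlabeled`
#' phantoms, PNG masks (0/255) for the labeled ones only, and a manifest
#' CSV with columns `path`, `heart_mask`, `lungs_mask`, `true_ctr`,
#' `label`. The image-level label is cardiomegaly iff `true_ctr > pi`
#' (strict inequality); unlabeled rows carry empty mask/CTR/label fields.
#' Lung geometry and heart height are jittered slightly between phantoms.
#'
#' @param n_labeled,m_unlabeled Counts of labeled and unlabeled phantoms.
#' @param out_dir Output directory (created if needed).
#' @param ctr_law Function of `n` returning target CTR draws, or one
#'   number for a constant law (default [default_ctr_law()]).
#' @param pi Cardiomegaly decision threshold (default 0.50).
#' @param image_size Phantom size in pixels (default 128).
#' @param noise_sd,gradient_amp Passed to every [phantom_spec()].
#' @param seed Root seed; all geometry, CTR draws and image noise derive
#'   from it.
#' @return The manifest as a tibble (also written to
#'   `out_dir/manifest.csv`), invisibly carrying the attribute `dir`.
#' @export
generate_phantom_dataset <- function(n_labeled, m_unlabeled, out_dir,
                                     ctr_law = default_ctr_law, pi = 0.50,
                                     image_size = 128, noise_sd = 0.05,
                                     gradient_amp = 0.1, seed = 1L) {
  stopifnot(n_labeled >= 0, m_unlabeled >= 0)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  n_tot <- n_labeled + m_unlabeled
  if (is.numeric(ctr_law)) {
    const <- ctr_law
    ctr_law <- function(n) rep(const, n)
  }
  set.seed(seed)
  ctrs <- ctr_law(n_tot)
  jit <- matrix(stats::runif(n_tot * 6, -1, 1), n_tot, 6)
  item_seeds <- sample.int(.Machine$integer.max, n_tot)
  rows <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    spec <- phantom_spec(
      image_size = image_size,
      lung_centers = list(c(0.30 + 0.015 * jit[i, 1], 0.48 + 0.02 * jit[i, 2]),
                          c(0.70 + 0.015 * jit[i, 3], 0.48 + 0.02 * jit[i, 2])),
      lung_semiaxes = c(0.16 * (1 + 0.08 * jit[i, 4]),
                        0.30 * (1 + 0.08 * jit[i, 5])),
      heart_center = c(0.50, 0.62 + 0.02 * jit[i, 6]),
      target_ctr = ctrs[i], noise_sd = noise_sd,
      gradient_amp = gradient_amp, seed = item_seeds[i]
    )
    ph <- generate_phantom(spec)
    img_path <- sprintf("img_%04d.png", i)
    png::writePNG(ph$image, file.path(out_dir, img_path))
    labeled <- i <= n_labeled
    if (labeled) {
      hp <- sprintf("heart_%04d.png", i)
      lp <- sprintf("lungs_%04d.png", i)
      png::writePNG(ph$heart, file.path(out_dir, hp))
      png::writePNG(ph$lungs, file.path(out_dir, lp))
      rows[[i]] <- tibble::tibble(
        path = img_path, heart_mask = hp, lungs_mask = lp,
        true_ctr = ph$true_ctr,
        label = if (ph$true_ctr > pi) "cardiomegaly" else "normal")
    } else {
      rows[[i]] <- tibble::tibble(
        path = img_path, heart_mask = "", lungs_mask = "",
        true_ctr = NA_real_, label = "")
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, na = "")
  attr(manifest, "dir") <- out_dir
  invisible(manifest)
}

#' Read a phantom/radiograph manifest
#'
#' @param path Path to a manifest CSV (or a dataset directory containing
#'   `manifest.csv`).
#' @return A tibble with attribute `dir` set to the dataset directory.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(true_ctr = "numeric"), na.strings = "")
  df$heart_mask[is.na(df$heart_mask)] <- ""
  df$lungs_mask[is.na(df$lungs_mask)] <- ""
  df$label[is.na(df$label)] <- ""
  out <- tibble::as_tibble(df)
  attr(out, "dir") <- dirname(path)
  out
}

#' Read an 8-bit grayscale PNG as a matrix in \[0, 1\]
#'
#' @param path PNG file path.
#' @return Numeric matrix (rows x cols) in \[0, 1\]; RGB input is reduced to
#'   luminance.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- rgb_to_gray(x)
  x
}

#' Read a binary mask PNG
#'
#' @param path PNG file path (0/255 convention).
#' @return Binary matrix with values in {0, 1}.
#' @export
read_mask <- function(path) {
  (read_image(path) > 0.5) * 1
}
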