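# From probability maps to bounding boxes, a cardiothoracic ratio and a
# cardiomegaly/normal call. Coordinates are 0-based and boxes inclusive,
# so width = x_max - x_min + 1.

#' Binarize a probability map and keep the organ-appropriate components
#'
#' Thresholds at `threshold`, discards connected components smaller than
#' `min_area_frac` of the image area, then keeps the largest component for
#' the heart or the union of the up-to-two largest components for the
#' lungs.
#'
#' @param p Probability matrix (values in (0, 1)); an (S, S, 1) array is
#'   accepted.
#' @param organ "heart" or "lungs".
#' @param threshold Binarization threshold (default 0.5).
#' @param min_area_frac Minimum component area as a fraction of the image
#'   (default 0.001).
#' @return Binary matrix; attribute `empty` is TRUE when no component
#'   survives.
#' @export
binarize_and_select <- function(p, organ = c("heart", "lungs"),
                                threshold = 0.5, min_area_frac = 0.001) {
  organ <- match.arg(organ)
  if (length(dim(p)) == 3) p <- p[, , 1]
  bw <- (p > threshold) * 1
  lab <- eb_to_mat(EBImage::bwlabel(mat_to_eb(bw)))
  n <- max(lab)
  if (n == 0) {
    attr(bw, "empty") <- TRUE
    return(bw)
  }
  areas <- tabulate(lab[lab > 0], nbins = n)
  keep_ids <- which(areas >= min_area_frac * length(p))
  if (length(keep_ids) == 0) {
    out <- matrix(0, nrow(p), ncol(p))
    attr(out, "empty") <- TRUE
    return(out)
  }
  ord <- keep_ids[order(areas[keep_ids], decreasing = TRUE)]
  sel <- utils::head(ord, if (organ == "heart") 1L else 2L)
  out <- matrix(as.numeric(lab %in% sel), nrow(p), ncol(p))
  attr(out, "empty") <- FALSE
  out
}

#' Tightest axis-aligned bounding box of a mask
#'
#' @param mask Binary matrix.
#' @return List with `x_min`, `x_max`, `y_min`, `y_max` (0-based,
#'   inclusive; x indexes columns, y rows) and `width`/`height`.
#' @export
bounding_box <- function(mask) {
  fg <- which(mask > 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("empty mask: no bounding box")
  box <- list(x_min = min(fg[, 2]) - 1L, x_max = max(fg[, 2]) - 1L,
              y_min = min(fg[, 1]) - 1L, y_max = max(fg[, 1]) - 1L)
  box$width <- box$x_max - box$x_min + 1L
  box$height <- box$y_max - box$y_min + 1L
  box
}

#' Cardiothoracic ratio from heart and lung bounding boxes
#'
#' Maximum horizontal cardiac diameter (heart-box width) divided by the
#' maximum horizontal thoracic diameter (lung-union-box width).
#'
#' @param heart_box,lungs_box Boxes from [bounding_box()].
#' @return The CTR, a positive unitless ratio.
#' @export
compute_ctr <- function(heart_box, lungs_box) {
  if (lungs_box$width <= 0) stop("undefined CTR: lungs box has zero width")
  heart_box$width / lungs_box$width
}

#' Threshold a CTR into a cardiomegaly/normal call
#'
#' Cardiomegaly iff `ctr > pi` (strict); `ctr == pi` is normal.
#'
#' @param ctr Cardiothoracic ratio.
#' @param pi Decision threshold (0.50 by default; 0.55 under the stricter
#'   annotation protocol).
#' @return "cardiomegaly" or "normal".
#' @export
classify_ctr <- function(ctr, pi = 0.50) {
  if (!is.finite(ctr) || ctr <= 0) stop("invalid CTR value")
  if (ctr > pi) "cardiomegaly" else "normal"
}

#' CTR and classification from a pair of binary masks
#'
#' @param heart,lungs Binary masks (same shape).
#' @param pi Decision threshold.
#' @return A `ctr_result` list: `ctr`, `threshold`, `label`, `heart_box`,
#'   `lungs_box`, `valid`. An empty mask yields `valid = FALSE` and label
#'   "indeterminate".
#' @export
ctr_from_masks <- function(heart, lungs, pi = 0.50) {
  if (sum(heart) == 0 || sum(lungs) == 0) {
    return(structure(list(ctr = NA_real_, threshold = pi,
                          label = "indeterminate", heart_box = NULL,
                          lungs_box = NULL, valid = FALSE),
                     class = "ctr_result"))
  }
  hb <- bounding_box(heart)
  lb <- bounding_box(lungs)
  ctr <- compute_ctr(hb, lb)
  structure(list(ctr = ctr, threshold = pi, label = classify_ctr(ctr, pi),
                 heart_box = hb, lungs_box = lb, valid = TRUE),
            class = "ctr_result")
}

#' CTR and classification from two probability maps
#'
#' Applies [binarize_and_select()] per organ, then [ctr_from_masks()].
#'
#' @param heart_p,lungs_p Probability maps.
#' @inheritParams ctr_from_masks
#' @param threshold Binarization threshold.
#' @return A `ctr_result` (see [ctr_from_masks()]).
#' @export
ctr_from_probability_maps <- function(heart_p, lungs_p, pi = 0.50,
                                      threshold = 0.5) {
  hm <- binarize_and_select(heart_p, "heart", threshold)
  lm <- binarize_and_select(lungs_p, "lungs", threshold)
  ctr_from_masks(hm, lm, pi)
}

#' @export
print.ctr_result <- function(x, ...) {
  if (x$valid)
    cat(sprintf("CTR = %.4f (threshold %.2f) -> %s\n", x$ctr, x$threshold,
                x$label))
  else cat("CTR indeterminate (empty segmentation mask)\n")
  invisible(x)
}
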