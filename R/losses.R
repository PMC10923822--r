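# Supervised, unsupervised and combined losses, plus the Gaussian ramp-up
# schedule that weights the unsupervised term.

#' Binary cross-entropy between a mask and a probability map
#'
#' Pixel-mean of `-(y log p + (1 - y) log(1 - p))`, with p clipped to
#' \[eps, 1 - eps\] for numerical safety.
#'
#' @param y Binary mask (values in {0, 1}).
#' @param p Probability map of the same shape, values in (0, 1).
#' @param eps Clipping constant (default 1e-7).
#' @return Non-negative scalar.
#' @export
bce <- function(y, p, eps = 1e-7) {
  check_same_shape(y, p)
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Dice loss
#'
#' `1 - (2 * sum(y p) + eps) / (sum(y) + sum(p) + eps)`; zero for a perfect
#' binary prediction, close to one for disjoint masks.
#'
#' @inheritParams bce
#' @param eps Smoothing constant (default 1e-6).
#' @return Scalar in \[0, 1\] (up to smoothing).
#' @export
dice_loss <- function(y, p, eps = 1e-6) {
  check_same_shape(y, p)
  1 - (2 * sum(y * p) + eps) / (sum(y) + sum(p) + eps)
}

check_same_shape <- function(y, p) {
  dy <- dim(y) %||% length(y)
  dp <- dim(p) %||% length(p)
  if (length(dy) != length(dp) || any(dy != dp))
    stop("mask and probability map shapes differ")
  invisible(TRUE)
}

#' Supervised segmentation loss over a labeled batch
#'
#' Mean over the labeled batch of BCE + Dice loss per pair.
#'
#' @param ys List of binary masks.
#' @param ps List of probability maps (same shapes as `ys`).
#' @return Non-negative scalar.
#' @export
supervised_loss <- function(ys, ps) {
  if (length(ys) == 0) stop("empty labeled batch")
  if (length(ys) != length(ps)) stop("ys and ps lengths differ")
  mean(mapply(function(y, p) bce(y, p) + dice_loss(y, p), ys, ps))
}

#' Unsupervised cross-consistency loss
#'
#' `1 / (k * bs_u)` times the sum over unlabeled samples and perturbations
#' of the pixel-summed squared error between the main-decoder output (a
#' fixed target) and each auxiliary-decoder output. With
#' `pixel_mean = TRUE` the per-pair error is additionally averaged over
#' pixels, which puts the term on the same scale as the pixel-mean
#' supervised loss.
#'
#' @param main List of `bs_u` main-decoder probability maps.
#' @param aux List of `bs_u` lists, each holding `k` auxiliary maps.
#' @param pixel_mean Average the per-pair error over pixels (default FALSE,
#'   the literal pixel sum).
#' @return Non-negative scalar.
#' @export
unsupervised_loss <- function(main, aux, pixel_mean = FALSE) {
  bs_u <- length(main)
  if (bs_u == 0) return(0)
  k <- length(aux[[1]])
  if (length(aux) != bs_u || any(vapply(aux, length, numeric(1)) != k))
    stop("aux must hold the same number k of maps for every sample")
  tot <- 0
  for (j in seq_len(bs_u)) {
    for (p in seq_len(k)) {
      d <- (main[[j]] - aux[[j]][[p]])^2
      tot <- tot + if (pixel_mean) mean(d) else sum(d)
    }
  }
  tot / (k * bs_u)
}

#' Gaussian ramp-up weight for the unsupervised loss
#'
#' `exp(-5 (1 - t/L)^2)` for epochs `t < L`, and 1 afterwards, so the
#' unsupervised term fades in from nearly zero over the first L epochs.
#'
#' @param t Current epoch (>= 0).
#' @param L Ramp-up length in epochs (default 50).
#' @return Scalar in (0, 1].
#' @export
rampup_weight <- function(t, L = 50) {
  stopifnot(t >= 0, L >= 1)
  if (t < L) exp(-5 * (1 - t / L)^2) else 1
}

#' Combine supervised and unsupervised losses
#'
#' @param loss_s Supervised loss value.
#' @param loss_u Unsupervised loss value.
#' @param t,L Epoch and ramp-up length passed to [rampup_weight()].
#' @return A list with `supervised`, `unsupervised`, `weight` and
#'   `total = supervised + weight * unsupervised`.
#' @export
total_loss <- function(loss_s, loss_u, t, L = 50) {
  w <- rampup_weight(t, L)
  list(supervised = loss_s, unsupervised = loss_u, weight = w,
       total = loss_s + w * loss_u)
}

# Gradients of the losses w.r.t. the probability maps (used by the training
# loops; the batch-mean factors are folded in by the callers).

grad_bce <- function(y, p, eps = 1e-7) {
  pc <- pmin(pmax(p, eps), 1 - eps)
  (-y / pc + (1 - y) / (1 - pc)) / length(p)
}

grad_dice <- function(y, p, eps = 1e-6) {
  s <- sum(y) + sum(p) + eps
  num <- 2 * sum(y * p) + eps
  (-2 * y * s + num) / s^2
}
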