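# Stochastic latent-space perturbations applied before the auxiliary
# decoder during cross-consistency training. All three are pure functions
# of the latent tensor and the R random stream; each returns the perturbed
# tensor plus the multiplicative factor needed to route gradients back
# through the perturbation.

#' Perturbation parameter set
#'
#' @param k Number of perturbed versions per latent (default 3, one per
#'   perturbation family).
#' @param noise_low,noise_high Uniform support of the multiplicative noise
#'   (default -0.3, 0.3).
#' @param gamma_low,gamma_high Uniform support of the feature-drop
#'   threshold (default 0.6, 0.9).
#' @param dropout_low,dropout_high Uniform support of the dropout rate
#'   (default 0.1, 0.7).
#' @param fdrop_invert Drop the most active regions instead of keeping them
#'   (default FALSE: the mask keeps positions whose normalized channel-mean
#'   exceeds the threshold, as published).
#' @param dropout_rescale Rescale surviving activations by 1/(1-r)
#'   (default FALSE: unscaled, the literal reading).
#' @return A `perturbation_params` list.
#' @export
perturbation_params <- function(k = 3, noise_low = -0.3, noise_high = 0.3,
                                gamma_low = 0.6, gamma_high = 0.9,
                                dropout_low = 0.1, dropout_high = 0.7,
                                fdrop_invert = FALSE,
                                dropout_rescale = FALSE) {
  if (k < 1) stop("k must be >= 1")
  structure(list(k = as.integer(k), noise_low = noise_low,
                 noise_high = noise_high, gamma_low = gamma_low,
                 gamma_high = gamma_high, dropout_low = dropout_low,
                 dropout_high = dropout_high, fdrop_invert = fdrop_invert,
                 dropout_rescale = dropout_rescale),
            class = "perturbation_params")
}

#' F-Noise: multiplicative uniform noise
#'
#' `z' = z + z * N` with N drawn elementwise from U(noise_low, noise_high),
#' so each activation changes by at most 30 percent in magnitude under the
#' defaults.
#'
#' @param z Latent array.
#' @param params A [perturbation_params()] list.
#' @return List with `z` (perturbed array) and `factor` (the elementwise
#'   multiplier 1 + N, used for gradient routing).
#' @export
f_noise <- function(z, params = perturbation_params()) {
  n <- array(stats::runif(length(z), params$noise_low, params$noise_high),
             dim = dim(z))
  factor <- 1 + n
  list(z = z * factor, factor = factor)
}

#' F-Drop: threshold the normalized channel-mean activation map
#'
#' The channel-wise mean of `z` is min-max normalized to \[0, 1\]; a
#' threshold gamma ~ U(gamma_low, gamma_high) is drawn and all spatial
#' positions whose normalized mean does not exceed gamma are zeroed across
#' every channel (the published form keeps the most active regions;
#' `fdrop_invert` drops them instead). A constant latent, for which min-max
#' normalization is undefined, is treated as all-below-threshold: everything
#' is dropped.
#'
#' @inheritParams f_noise
#' @return List with `z`, `factor` (the broadcast binary mask) and `gamma`.
#' @export
f_drop <- function(z, params = perturbation_params()) {
  gamma <- stats::runif(1, params$gamma_low, params$gamma_high)
  d <- dim(z)
  zt <- apply(z, c(1, 2), mean)
  rng <- range(zt)
  if (rng[2] > rng[1]) {
    zt <- (zt - rng[1]) / (rng[2] - rng[1])
  } else {
    zt <- array(0, dim = d[1:2])  # constant latent: drop everything
  }
  keep <- zt > gamma
  if (params$fdrop_invert) keep <- !keep
  factor <- array(rep(as.numeric(keep), d[3]), dim = d)
  list(z = z * factor, factor = factor, gamma = gamma)
}

#' Random dropout with a uniformly sampled rate
#'
#' Each activation is independently zeroed with probability
#' r ~ U(dropout_low, dropout_high). Survivors are left unscaled unless
#' `dropout_rescale` is set in the parameters.
#'
#' @inheritParams f_noise
#' @return List with `z`, `factor` (the applied mask, rescaled if
#'   requested) and `rate`.
#' @export
rand_dropout <- function(z, params = perturbation_params()) {
  r <- stats::runif(1, params$dropout_low, params$dropout_high)
  mask <- array(stats::runif(length(z)) >= r, dim = dim(z)) * 1
  if (params$dropout_rescale) mask <- mask / (1 - r)
  list(z = z * mask, factor = mask, rate = r)
}

#' Apply the ordered set of k stochastic perturbations
#'
#' The default k = 3 applies F-Noise, F-Drop and random dropout once each;
#' larger k cycles through the three families with fresh random draws, and
#' k = 1 applies F-Noise only.
#'
#' @inheritParams f_noise
#' @return A list of k elements, each a list with `z`, `factor` and `type`.
#' @export
make_perturbation_set <- function(z, params = perturbation_params()) {
  if (params$k < 1) stop("k must be >= 1")
  fams <- c("noise", "drop", "dropout")
  lapply(seq_len(params$k), function(i) {
    type <- fams[(i - 1) %% 3 + 1]
    res <- switch(type,
      noise = f_noise(z, params),
      drop = f_drop(z, params),
      dropout = rand_dropout(z, params)
    )
    res$type <- type
    res
  })
}
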