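# Shared fixtures: tiny phantoms and models built in code at test time.

tiny_net_filters <- c(2, 2, 3, 3, 4)

tiny_model <- function(size = 32, mode = "supervised", seed = 1) {
  build_segmentation_model(input_size = size, organ = "heart",
                           mode = mode, filters = tiny_net_filters,
                           cbam_reduction = 2, seed = seed)
}

noiseless_spec <- function(target_ctr = 0.55, size = 128, seed = 7, ...) {
  phantom_spec(image_size = size, target_ctr = target_ctr, noise_sd = 0,
               gradient_amp = 0, seed = seed, ...)
}

disc_mask <- function(S, r = 0.3) {
  x <- matrix(0:(S - 1), S, S, byrow = TRUE)
  y <- matrix(0:(S - 1), S, S)
  (((x - (S - 1) / 2)^2 + (y - (S - 1) / 2)^2) <= (r * S)^2) * 1
}

random_latent <- function(dims = c(4, 4, 3), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(prod(dims)), dim = dims)
}

# Desk-scale training configuration shared by the learning-property
# tests: 64-px phantoms, narrow filter stack, small batches so an epoch
# holds enough optimisation steps, faster-tracking batch-norm statistics.
desk_config <- function(organ, mode, epochs, seed, batch_size = 2,
                        ramp_length = 50) {
  training_config(organ = organ, mode = mode, input_size = 64,
                  filters = c(8, 16, 16, 24, 32), epochs = epochs,
                  batch_size = batch_size, bn_momentum = 0.9,
                  ramp_length = ramp_length, seed = seed)
}

# Problem size of the semi-supervised vs supervised comparison (held in
# one place; the methods vignette documents the choice).
desk_semi_scale <- list(m_unlabeled = 60, epochs = 15, ramp = 8,
                        seeds = c(1, 2, 3))
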