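#' Encoder spatial-size chain
#'
#' The encoder halves the spatial size five times with 2x2 stride-2 max
#' pooling (valid windows, so an odd size drops its last row/column:
#' 299 -> 149 -> 74 -> 37 -> 18 -> 9).
#'
#' @param input_size Input height/width in pixels (square input).
#' @return Integer vector of length 6: input size followed by the size after
#'   each of the five pooling stages.
#' @export
encoder_shape_chain <- function(input_size) {
  input_size <- as.integer(input_size)
  if (input_size < 32L)
    stop("input_size must be at least 32 so that five 2x2 poolings leave ",
         "a non-empty latent grid")
  sizes <- integer(6)
  sizes[1] <- input_size
  for (i in 2:6) sizes[i] <- sizes[i - 1] %/% 2L
  sizes
}

#' Transposed-convolution padding pattern inverting the encoder
#'
#' Each decoder upsampling step must map the encoder size chain back up one
#' stage: "same" doubles the size (H -> 2H), "valid" gives 2H + 1. For a
#' 299-pixel input this yields the pattern same, valid, same, valid, valid
#' (9 -> 18 -> 37 -> 74 -> 149 -> 299).
#'
#' @inheritParams encoder_shape_chain
#' @return Character vector of length 5 of "same"/"valid" padding modes.
#' @export
decoder_pad_pattern <- function(input_size) {
  sizes <- encoder_shape_chain(input_size)
  pattern <- character(5)
  for (i in 1:5) {
    src <- sizes[7 - i]
    tgt <- sizes[6 - i]
    if (tgt == 2L * src) pattern[i] <- "same"
    else if (tgt == 2L * src + 1L) pattern[i] <- "valid"
    else stop("size chain cannot be inverted at stage ", i)
  }
  pattern
}

conv_block_layers <- function(c_in, filters, opts) {
  blk <- list(
    new_conv_layer(c_in, filters),
    new_bn_layer(filters, momentum = opts$bn_momentum, eps = opts$bn_eps),
    new_relu_layer()
  )
  if (opts$cbam)
    blk <- c(blk, list(new_cbam_layer(filters, opts$cbam_reduction,
                                      opts$cbam_kernel)))
  blk
}

default_net_opts <- function(cbam = TRUE, cbam_reduction = 16,
                             cbam_kernel = 7, bn_momentum = 0.99,
                             bn_eps = 1e-3) {
  list(cbam = cbam, cbam_reduction = cbam_reduction,
       cbam_kernel = cbam_kernel, bn_momentum = bn_momentum,
       bn_eps = bn_eps)
}

build_encoder_layers <- function(in_channels, filters, opts) {
  layers <- list()
  c_in <- in_channels
  for (f in filters) {
    for (b in 1:3) {
      layers <- c(layers, conv_block_layers(c_in, f, opts))
      c_in <- f
    }
    layers <- c(layers, list(new_pool_layer()))
  }
  layers
}

build_decoder_layers <- function(filters, pad_pattern, opts) {
  nf <- length(filters)           # 5 stages
  dec_filters <- rev(filters)     # e.g. 256 128 64 32 16
  up_filters <- c(dec_filters[-1], 1L)  # 128 64 32 16 1
  layers <- list()
  c_in <- dec_filters[1]
  for (s in 1:nf) {
    f <- dec_filters[s]
    for (b in 1:3) {
      layers <- c(layers, conv_block_layers(c_in, f, opts))
      c_in <- f
    }
    layers <- c(layers, list(
      new_convt_layer(c_in, up_filters[s], pad_pattern[s]),
      new_bn_layer(up_filters[s], opts$bn_momentum, opts$bn_eps),
      new_relu_layer()
    ))
    c_in <- up_filters[s]
  }
  # final 3x3 convolution to one channel, batch norm, sigmoid (the batch
  # norm placed before the sigmoid follows the published architecture
  # literally, unusual as it is)
  c(layers, list(
    new_conv_layer(c_in, 1L),
    new_bn_layer(1L, opts$bn_momentum, opts$bn_eps),
    new_sigmoid_layer()
  ))
}

#' Build a segmentation model bundle
#'
#' Constructs the shared encoder, the main decoder and (for semi-supervised
#' training) an auxiliary decoder of identical architecture. The encoder
#' stacks five stages of three convolutional blocks (3x3 convolution, batch
#' normalization, ReLU, CBAM attention) followed by 2x2 max pooling; the
#' decoder mirrors it with stride-2 transposed convolutions whose padding
#' pattern is derived from the input size so the output spatial shape equals
#' the input's.
#'
#' @param input_size Square input size in pixels (>= 32; default 299).
#' @param organ Which structure the model segments: "heart" or "lungs".
#' @param mode "supervised" (encoder + main decoder) or "semi_supervised"
#'   (adds the auxiliary decoder).
#' @param filters Number of filters per encoder stage (default the published
#'   16, 32, 64, 128, 256).
#' @param in_channels Input channels after standardization (default 3).
#' @param cbam,cbam_reduction,cbam_kernel Attention configuration.
#' @param bn_momentum Batch-normalization running-statistics momentum
#'   (default 0.99; smaller values track faster when epochs hold few
#'   optimisation steps).
#' @param seed Integer seed for weight initialization (He-uniform).
#' @return A `ctrseg_model` list with elements `encoder`, `decoder`,
#'   `aux_decoder` (possibly NULL) and `meta`.
#' @export
build_segmentation_model <- function(input_size = 299, organ = "heart",
                                     mode = c("supervised",
                                              "semi_supervised"),
                                     filters = c(16, 32, 64, 128, 256),
                                     in_channels = 3, cbam = TRUE,
                                     cbam_reduction = 16, cbam_kernel = 7,
                                     bn_momentum = 0.99, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(filters) == 5)
  filters <- as.integer(filters)
  sizes <- encoder_shape_chain(input_size)
  pattern <- decoder_pad_pattern(input_size)
  opts <- default_net_opts(cbam, cbam_reduction, cbam_kernel,
                           bn_momentum = bn_momentum)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  encoder <- build_encoder_layers(in_channels, filters, opts)
  decoder <- build_decoder_layers(filters, pattern, opts)
  aux <- if (mode == "semi_supervised")
    build_decoder_layers(filters, pattern, opts) else NULL
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  structure(list(
    encoder = encoder, decoder = decoder, aux_decoder = aux,
    meta = list(input_size = as.integer(input_size), organ = organ,
                mode = mode, filters = filters,
                in_channels = as.integer(in_channels),
                latent_size = sizes[6], latent_channels = filters[5],
                pad_pattern = pattern, cbam = cbam,
                cbam_reduction = cbam_reduction, cbam_kernel = cbam_kernel,
                seed = as.integer(seed), epoch = 0L)
  ), class = "ctrseg_model")
}

#' @export
print.ctrseg_model <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<ctrseg_model> organ=%s mode=%s input=%dpx latent=%dx%dx%d params=%s\n",
    m$organ, m$mode, m$input_size, m$latent_size, m$latent_size,
    m$latent_channels, format(count_params(x$encoder) +
      count_params(x$decoder) +
      if (is.null(x$aux_decoder)) 0 else count_params(x$aux_decoder),
      big.mark = ",")))
  invisible(x)
}

count_params <- function(layers) {
  sum(vapply(layers, function(l) sum(vapply(l$params, length, numeric(1))),
             numeric(1)))
}

#' Apply a single convolutional block
#'
#' One 3x3 convolution (stride 1, shape-preserving padding), batch
#' normalization, ReLU and CBAM attention — the unit both the encoder and
#' decoder are built from. Exposed mainly for inspection and testing.
#'
#' @param x An (H, W, C) numeric array.
#' @param filters Number of output channels.
#' @param seed Seed for the freshly initialized block weights.
#' @param cbam Apply the attention module (default TRUE).
#' @return An (H, W, filters) array.
#' @export
conv_block_apply <- function(x, filters, seed = 1L, cbam = TRUE) {
  stopifnot(length(dim(x)) == 3)
  set.seed(seed)
  blk <- conv_block_layers(dim(x)[3], as.integer(filters),
                           default_net_opts(cbam = cbam))
  net_forward(blk, list(x), training = TRUE, keep_cache = FALSE)$out[[1]]
}

#' Encode a standardized image to its latent representation
#'
#' @param model A `ctrseg_model`.
#' @param image An (S, S, C) standardized image array matching the model's
#'   input size.
#' @param training Use batch statistics (TRUE) or running statistics.
#' @return The latent activation array (s, s, C_latent); for a 299 input
#'   this is 9 x 9 x 256.
#' @export
encode_image <- function(model, image, training = FALSE) {
  check_model_input(model, image)
  net_forward(model$encoder, list(image), training = training,
              keep_cache = FALSE)$out[[1]]
}

#' Decode a latent representation to a probability map
#'
#' @param model A `ctrseg_model`.
#' @param z Latent array as produced by [encode_image()].
#' @param decoder "main" or "aux".
#' @param training Use batch statistics (TRUE) or running statistics.
#' @return An (S, S, 1) array of sigmoid probabilities in (0, 1).
#' @export
decode_latent <- function(model, z, decoder = c("main", "aux"),
                          training = FALSE) {
  decoder <- match.arg(decoder)
  layers <- if (decoder == "main") model$decoder else model$aux_decoder
  if (is.null(layers)) stop("model has no auxiliary decoder")
  net_forward(layers, list(z), training = training,
              keep_cache = FALSE)$out[[1]]
}

check_model_input <- function(model, image) {
  d <- dim(image)
  if (length(d) != 3 || d[1] != model$meta$input_size ||
      d[2] != model$meta$input_size || d[3] != model$meta$in_channels)
    stop(sprintf("expected a %dx%dx%d input, got %s",
                 model$meta$input_size, model$meta$input_size,
                 model$meta$in_channels, paste(d, collapse = "x")))
  invisible(TRUE)
}

#' Predict a segmentation probability map for one image
#'
#' Runs the shared encoder and the main decoder in inference mode.
#'
#' @inheritParams encode_image
#' @return An (S, S) matrix of probabilities.
#' @export
predict_probability_map <- function(model, image) {
  p <- decode_latent(model, encode_image(model, image))
  p[, , 1]
}

# ---- optimiser -------------------------------------------------------------

adam_init <- function(...) {
  nets <- list(...)
  lapply(nets, function(layers) lapply(layers, function(l)
    lapply(l$params, function(p) list(m = array(0, dim = dim(p) %||%
                                                  length(p)),
                                      v = array(0, dim = dim(p) %||%
                                                  length(p))))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam update for one network (list of layers). grads parallels layers.
adam_update <- function(layers, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (li in seq_along(layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (pn in names(g)) {
      st <- state[[li]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[pn]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[pn]]^2
      step <- lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      layers[[li]]$params[[pn]] <- layers[[li]]$params[[pn]] - step
      state[[li]][[pn]] <- st
    }
  }
  list(layers = layers, state = state)
}

# ---- checkpoints -----------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes the parameter arrays (RDS container) together with a JSON metadata
#' sidecar describing organ, input size, training mode, seed and epoch.
#'
#' @param model A `ctrseg_model`.
#' @param dir Directory to create/overwrite.
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(unclass(model), file.path(dir, "params.rds"))
  jsonlite::write_json(model$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir Directory written by [save_model()].
#' @return A `ctrseg_model`.
#' @export
load_model <- function(dir) {
  f <- file.path(dir, "params.rds")
  if (!file.exists(f)) stop("no checkpoint found in ", dir)
  structure(readRDS(f), class = "ctrseg_model")
}
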