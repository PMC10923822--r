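test_that("encoder shape chain halves five times and the decoder pattern inverts it", {
  expect_equal(encoder_shape_chain(299), c(299, 149, 74, 37, 18, 9))
  expect_equal(decoder_pad_pattern(299),
               c("same", "valid", "same", "valid", "valid"))
  expect_equal(encoder_shape_chain(128), c(128, 64, 32, 16, 8, 4))
  expect_equal(decoder_pad_pattern(128), rep("same", 5))
  expect_equal(encoder_shape_chain(64)[6], 2)
  # the valid transposed step gives 2s+1, the same step 2s
  sizes <- encoder_shape_chain(299)
  up <- 9
  for (i in seq_along(decoder_pad_pattern(299))) {
    up <- if (decoder_pad_pattern(299)[i] == "valid") 2 * up + 1 else 2 * up
    expect_equal(up, sizes[6 - i])
  }
  expect_error(encoder_shape_chain(31), "at least 32")
})

test_that("a convolutional block preserves spatial shape and sets the channel count", {
  x <- array(runif(9 * 9 * 256), c(9, 9, 256))
  y <- conv_block_apply(x, 256, seed = 2)
  expect_equal(dim(y), c(9, 9, 256))
  x2 <- array(runif(299 * 299 * 3), c(299, 299, 3))
  y2 <- conv_block_apply(x2, 16, seed = 2)
  expect_equal(dim(y2), c(299, 299, 16))
  expect_true(all(is.finite(y2)))
})

test_that("CBAM attention is uniform on constant activations (output proportional to input)", {
  lyr <- ctrseg:::new_cbam_layer(4, reduction = 2)
  x <- array(1, c(16, 16, 4))
  out <- ctrseg:::layer_forward(lyr, list(x), training = TRUE)$out[[1]]
  # away from the zero-padded border each channel is scaled by one constant
  for (c in 1:4) {
    inner <- out[4:13, 4:13, c]
    expect_equal(max(inner) - min(inner), 0, tolerance = 1e-12)
  }
  expect_true(all(out > 0 & out < 1))  # two sigmoid gates scale 1 downward
  # with channel-symmetric MLP weights the gates coincide across channels
  lyr$params$W1[] <- 0.3; lyr$params$W2[] <- 0.2
  lyr$params$b1[] <- 0; lyr$params$b2[] <- 0
  out2 <- ctrseg:::layer_forward(lyr, list(x), training = TRUE)$out[[1]]
  for (c in 2:4) expect_equal(out2[, , c], out2[, , 1], tolerance = 1e-12)
})

test_that("encode and decode compose to the input spatial shape", {
  model <- tiny_model(size = 64)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  z <- encode_image(model, img, training = TRUE)
  expect_equal(dim(z), c(2, 2, tail(tiny_net_filters, 1)))
  p <- decode_latent(model, z, training = TRUE)
  expect_equal(dim(p), c(64, 64, 1))
  expect_true(all(p > 0 & p < 1))
  # zero input at initialization stays finite
  z0 <- encode_image(model, array(0, c(64, 64, 3)), training = TRUE)
  expect_true(all(is.finite(z0)))
  expect_error(encode_image(model, array(0, c(32, 32, 3))), "expected")
})

test_that("main and auxiliary decoders share architecture and parameter count", {
  model <- tiny_model(size = 32, mode = "semi_supervised")
  expect_equal(length(model$decoder), length(model$aux_decoder))
  shapes <- function(layers) lapply(layers, function(l)
    lapply(l$params, dim))
  expect_equal(shapes(model$decoder), shapes(model$aux_decoder))
  expect_equal(ctrseg:::count_params(model$decoder),
               ctrseg:::count_params(model$aux_decoder))
  # but independently initialized weights
  expect_false(identical(model$decoder[[1]]$params$W,
                         model$aux_decoder[[1]]$params$W))
})

test_that("model construction is seed-deterministic and leaves the global RNG intact", {
  set.seed(500)
  before <- runif(1)
  set.seed(500)
  m1 <- tiny_model(seed = 3)
  after <- runif(1)
  expect_equal(before, after)  # building a model must not consume the stream
  m2 <- tiny_model(seed = 3)
  expect_identical(m1$encoder[[1]]$params$W, m2$encoder[[1]]$params$W)
})

test_that("checkpoints round-trip through disk", {
  model <- tiny_model(size = 32)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  p0 <- predict_probability_map(model, img)
  dir <- file.path(withr::local_tempdir(), "ckpt")
  save_model(model, dir)
  expect_true(file.exists(file.path(dir, "meta.json")))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  expect_equal(meta$organ, "heart")
  expect_equal(meta$input_size, 32L)
  m2 <- load_model(dir)
  expect_identical(predict_probability_map(m2, img), p0)
  expect_error(load_model(withr::local_tempdir()), "no checkpoint")
})

test_that("backpropagated gradients match finite differences through the whole net", {
  set.seed(6)
  S <- 32
  model <- tiny_model(size = S, seed = 11)
  xs <- list(array(runif(S * S * 3), c(S, S, 3)))
  ys <- list(array((matrix(runif(S * S), S) > 0.5) * 1, c(S, S, 1)))
  loss_fn <- function(model) {
    z <- ctrseg:::net_forward(model$encoder, xs, TRUE, FALSE)$out
    p <- ctrseg:::net_forward(model$decoder, z, TRUE, FALSE)$out
    supervised_loss(ys, p)
  }
  enc <- ctrseg:::net_forward(model$encoder, xs, TRUE)
  dec <- ctrseg:::net_forward(model$decoder, enc$out, TRUE)
  dps <- ctrseg:::supervised_grads(ys, dec$out)
  dbw <- ctrseg:::net_backward(model$decoder, dec$caches, dps)
  ebw <- ctrseg:::net_backward(model$encoder, enc$caches, dbw$dx)
  grads <- list(encoder = ebw$grads, decoder = dbw$grads)
  set.seed(21)
  for (net in c("encoder", "decoder")) {
    cand <- list()
    for (li in seq_along(model[[net]]))
      if (!is.null(grads[[net]][[li]]))
        for (pn in names(grads[[net]][[li]]))
          cand[[length(cand) + 1]] <- list(li = li, pn = pn)
    for (rep in 1:6) {
      pk <- cand[[sample.int(length(cand), 1)]]
      p <- model[[net]][[pk$li]]$params[[pk$pn]]
      i <- sample.int(length(p), 1)
      eps <- 1e-6
      m2 <- model
      m2[[net]][[pk$li]]$params[[pk$pn]][i] <- p[i] + eps
      lp <- loss_fn(m2)
      m2[[net]][[pk$li]]$params[[pk$pn]][i] <- p[i] - eps
      lm <- loss_fn(m2)
      num <- (lp - lm) / (2 * eps)
      ana <- grads[[net]][[pk$li]][[pk$pn]][i]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 5e-3)
    }
  }
})
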