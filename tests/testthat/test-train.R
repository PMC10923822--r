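test_that("batch planning follows the floor/ceiling rule with the >=1 labeled clamp", {
  p <- plan_batches(200, 1000, 16)
  expect_equal(p$delta, 75)
  expect_equal(p$bs_l, 2L)
  expect_equal(p$bs_u, 14L)
  expect_false(p$clamped)
  # equal pools split the batch evenly
  p2 <- plan_batches(64, 64, 16)
  expect_equal(p2$bs_l, 8L)
  expect_equal(p2$bs_u, 8L)
  # the heavily unlabeled regime drives the floor to zero and clamps
  p3 <- plan_batches(247, 9763, 16)
  expect_equal(p3$delta, 625.625)
  expect_true(p3$clamped)
  expect_equal(p3$bs_l, 1L)
  expect_equal(p3$bs_u, 15L)
  # labeled-only planning fills the batch with labeled samples
  p4 <- plan_batches(100, 0, 16)
  expect_equal(p4$bs_l, 16L)
  expect_equal(p4$bs_u, 0L)
  expect_error(plan_batches(3, 4, 16), "exceeds")
})

test_that("bs_l + bs_u always equals bs on a broad grid", {
  for (bs in c(4, 8, 16)) {
    for (n in seq(1, 200, by = 7)) {
      for (m in seq(0, 200, by = 11)) {
        if (bs > n + m) next
        p <- plan_batches(n, m, bs)
        expect_identical(p$bs_l + p$bs_u, as.integer(bs))
        expect_gte(p$bs_l, 1L)
      }
    }
  }
})

test_that("validation splits are exact, disjoint, reproducible and stratifiable", {
  s <- split_validation(100, 0, seed = 4)
  expect_length(s$labeled_val, 20)
  expect_length(s$labeled_train, 80)
  expect_equal(sort(c(s$labeled_train, s$labeled_val)), 1:100)
  # 247 labeled -> 49 validation under round-half-away
  s2 <- split_validation(247, 0, seed = 4)
  expect_length(s2$labeled_val, 49)
  expect_length(s2$labeled_train, 198)
  # unlabeled fraction 10%
  s3 <- split_validation(20, 150, seed = 4)
  expect_length(s3$unlabeled_val, 15)
  expect_length(s3$unlabeled_train, 135)
  # reproducible
  expect_identical(split_validation(50, 40, seed = 9),
                   split_validation(50, 40, seed = 9))
  # stratified by label
  labels <- rep(c("cardiomegaly", "normal"), c(30, 70))
  s4 <- split_validation(labels, 0, seed = 1)
  expect_equal(sum(s4$labeled_val <= 30), 6)   # 20% of each class
  expect_equal(sum(s4$labeled_val > 30), 14)
  expect_error(split_validation(1, 0), "at least 2")
})

make_tiny_data <- function(n_lab, n_unl, seed = 5) {
  dir <- file.path(tempdir(), sprintf("tinydat_%d_%d_%d", n_lab, n_unl,
                                      seed))
  if (!dir.exists(dir))
    generate_phantom_dataset(n_lab, n_unl, dir, image_size = 32,
                             noise_sd = 0.02, seed = seed)
  load_training_data(read_manifest(dir), organ = "heart", input_size = 32)
}

tiny_cfg <- function(mode, epochs = 2, seed = 3) {
  training_config(organ = "heart", mode = mode, input_size = 32,
                  filters = tiny_net_filters, epochs = epochs,
                  batch_size = 4, ramp_length = 5, bn_momentum = 0.9,
                  cbam_reduction = 2, seed = seed)
}

test_that("supervised training runs, logs history without unsupervised terms, and checkpoints", {
  dat <- make_tiny_data(8, 0)
  res <- train_supervised(dat$labeled, tiny_cfg("supervised"))
  expect_equal(nrow(res$history), 2)
  expect_true(all(is.na(res$history$loss_u)))
  expect_true(all(is.na(res$history$omega)))
  expect_true(all(is.finite(res$history$loss_s)))
  expect_true(all(res$history$val_jaccard >= 0 &
                    res$history$val_jaccard <= 1))
  # the retained checkpoint reproduces its recorded validation Jaccard
  dir <- file.path(withr::local_tempdir(), "ck")
  save_model(res$model, dir)
  m2 <- load_model(dir)
  expect_equal(m2$meta$best_val_jaccard, res$best_val_jaccard)
  expect_error(train_supervised(list(), tiny_cfg("supervised")), "empty")
})

test_that("semi-supervised training tracks the ramp-up weight and consistency loss", {
  dat <- make_tiny_data(6, 12)
  cfg <- tiny_cfg("semi_supervised")
  res <- train_semi_supervised(dat$labeled, dat$unlabeled, cfg)
  expect_equal(res$history$omega,
               vapply(1:2, rampup_weight, numeric(1), L = 5))
  expect_true(all(is.finite(res$history$loss_u)))
  expect_true(all(res$history$loss_u >= 0))
  expect_false(is.null(res$model$aux_decoder))
  expect_error(train_semi_supervised(dat$labeled, list(), cfg), "empty")
})

test_that("training histories are bit-reproducible under a fixed seed", {
  dat <- make_tiny_data(6, 12)
  cfg <- tiny_cfg("semi_supervised", seed = 17)
  r1 <- train_semi_supervised(dat$labeled, dat$unlabeled, cfg)
  r2 <- train_semi_supervised(dat$labeled, dat$unlabeled, cfg)
  expect_identical(r1$history, r2$history)
  r3 <- train_semi_supervised(dat$labeled, dat$unlabeled,
                              tiny_cfg("semi_supervised", seed = 18))
  expect_false(identical(r1$history$loss_s, r3$history$loss_s))
})
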