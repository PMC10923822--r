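blob <- function(S, r0, r1, c0, c1) {
  m <- matrix(0, S, S); m[r0:r1, c0:c1] <- 1; m
}

test_that("binarization keeps organ-appropriate connected components", {
  # a single confident blob survives unchanged
  p <- matrix(0.05, 64, 64); p[10:20, 10:20] <- 0.9
  m <- binarize_and_select(p, "heart")
  expect_equal(m, blob(64, 10, 20, 10, 20), ignore_attr = TRUE)
  # heart: only the largest of two blobs is retained
  p2 <- matrix(0.05, 64, 64)
  p2[5:29, 5:24] <- 0.9          # 500 px
  p2[50:57, 50:54] <- 0.9        # 40 px
  m2 <- binarize_and_select(p2, "heart")
  expect_equal(sum(m2), 500)
  expect_equal(sum(m2[50:57, 50:54]), 0)
  # lungs: the two largest of three blobs are kept
  p3 <- matrix(0.05, 64, 64)
  p3[2:21, 2:11] <- 0.9          # 200 px
  p3[2:21, 40:49] <- 0.9         # 200 px
  p3[50:52, 30:33] <- 0.9        # 12 px
  m3 <- binarize_and_select(p3, "lungs")
  expect_equal(sum(m3), 400)
  # components below 0.1% of the image area are discarded outright
  p4 <- matrix(0.05, 100, 100); p4[1:2, 1:3] <- 0.9  # 6 px < 10 px
  m4 <- binarize_and_select(p4, "heart")
  expect_true(attr(m4, "empty"))
  # nothing above threshold -> empty flag
  m5 <- binarize_and_select(matrix(0.2, 32, 32), "lungs")
  expect_true(attr(m5, "empty"))
})

test_that("bounding boxes are tight, 0-based and inclusive", {
  m <- matrix(0, 7, 9); m[3, 5] <- 1
  b <- bounding_box(m)
  expect_equal(b[c("x_min", "x_max", "y_min", "y_max")],
               list(x_min = 4L, x_max = 4L, y_min = 2L, y_max = 2L))
  expect_equal(b$width, 1L)
  full <- matrix(1, 7, 9)
  expect_equal(bounding_box(full)$width, 9L)
  expect_equal(bounding_box(full)$height, 7L)
  # random sparse mask against an exhaustive coordinate scan
  set.seed(13)
  rm <- matrix(0, 20, 30); rm[sample(600, 50)] <- 1
  b2 <- bounding_box(rm)
  fg <- which(rm == 1, arr.ind = TRUE)
  expect_equal(b2$x_min, min(fg[, 2]) - 1L)
  expect_equal(b2$x_max, max(fg[, 2]) - 1L)
  expect_equal(b2$y_min, min(fg[, 1]) - 1L)
  expect_equal(b2$y_max, max(fg[, 1]) - 1L)
  expect_error(bounding_box(matrix(0, 4, 4)), "empty mask")
})

test_that("CTR is the width ratio and classification is strictly greater-than", {
  hb <- bounding_box(blob(128, 60, 80, 40, 94))   # width 55
  lb <- bounding_box(blob(128, 30, 100, 10, 109)) # width 100
  expect_equal(compute_ctr(hb, lb), 0.55)
  expect_equal(compute_ctr(lb, lb), 1)
  expect_equal(classify_ctr(0.56, pi = 0.55), "cardiomegaly")
  expect_equal(classify_ctr(0.50, pi = 0.50), "normal")
  expect_equal(classify_ctr(0.49, pi = 0.50), "normal")
  expect_error(classify_ctr(NaN), "invalid")
})

test_that("CTR is invariant to vertical translation of either mask", {
  ph <- generate_phantom(noiseless_spec(target_ctr = 0.62, size = 96))
  r0 <- ctr_from_masks(ph$heart, ph$lungs)
  shift_down <- function(m, k) rbind(matrix(0, k, ncol(m)),
                                     m[1:(nrow(m) - k), ])
  r1 <- ctr_from_masks(shift_down(ph$heart, 5), ph$lungs)
  expect_equal(r1$ctr, r0$ctr)
  r2 <- ctr_from_masks(ph$heart, shift_down(ph$lungs, 3))
  expect_equal(r2$ctr, r0$ctr)
})

test_that("ground-truth phantom masks reproduce the manifest labels exactly", {
  dir <- withr::local_tempdir()
  man <- generate_phantom_dataset(12, 0, dir, image_size = 96,
                                  noise_sd = 0, seed = 77,
                                  ctr_law = function(n)
                                    runif(n, 0.35, 0.75))
  for (i in seq_len(nrow(man))) {
    h <- read_mask(file.path(dir, man$heart_mask[i]))
    l <- read_mask(file.path(dir, man$lungs_mask[i]))
    res <- ctr_from_masks(h, l, pi = 0.50)
    expect_equal(res$label, man$label[i])
    expect_equal(res$ctr, man$true_ctr[i], tolerance = 1e-12)
  }
})

test_that("empty masks yield an indeterminate result rather than a label", {
  res <- ctr_from_masks(matrix(0, 8, 8), matrix(1, 8, 8))
  expect_false(res$valid)
  expect_equal(res$label, "indeterminate")
  res2 <- ctr_from_probability_maps(matrix(0.1, 32, 32),
                                    matrix(0.9, 32, 32))
  expect_false(res2$valid)
})
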