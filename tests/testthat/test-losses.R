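test_that("binary cross-entropy matches closed forms and a per-pixel oracle", {
  y <- matrix(c(1, 0, 0, 1), 2)
  # near-perfect prediction
  p_good <- ifelse(y == 1, 1 - 1e-7, 1e-7)
  expect_lt(bce(y, p_good), 1e-5)
  # maximally uncertain prediction: ln 2 regardless of the mask
  expect_equal(bce(y, matrix(0.5, 2, 2)), log(2), tolerance = 1e-12)
  expect_equal(bce(matrix(0, 2, 2), matrix(0.5, 2, 2)), log(2),
               tolerance = 1e-12)
  # brute-force per-pixel sum on a 2x2 case
  p <- matrix(c(0.9, 0.2, 0.1, 0.8), 2)  # column-major: [0.9,0.1;0.2,0.8]
  oracle <- -mean(c(log(0.9), log(1 - 0.2), log(1 - 0.1), log(0.8)))
  expect_equal(bce(y, p), oracle, tolerance = 1e-12)
  expect_error(bce(y, matrix(0.5, 3, 2)), "shapes differ")
})

test_that("dice loss is 0 for perfect overlap, ~1 for disjoint, 1/3 for the half-confidence case", {
  y <- matrix(0, 4, 4); y[2:3, 2:3] <- 1
  expect_equal(dice_loss(y, y), 0, tolerance = 1e-6)
  disj <- matrix(0, 4, 4); disj[1, 4] <- 1
  expect_gt(dice_loss(y, disj), 0.999)
  p <- y * 0.5
  expect_equal(dice_loss(y, p), 1 / 3, tolerance = 1e-5)
})

test_that("supervised loss averages bce + dice over the batch", {
  y1 <- matrix(c(1, 0, 0, 1), 2); p1 <- matrix(c(0.9, 0.2, 0.1, 0.8), 2)
  y2 <- matrix(c(0, 1, 1, 0), 2); p2 <- matrix(c(0.3, 0.6, 0.7, 0.4), 2)
  a <- bce(y1, p1) + dice_loss(y1, p1)
  b <- bce(y2, p2) + dice_loss(y2, p2)
  expect_equal(supervised_loss(list(y1), list(p1)), a, tolerance = 1e-12)
  expect_equal(supervised_loss(list(y1, y2), list(p1, p2)), (a + b) / 2,
               tolerance = 1e-12)
  perfect <- ifelse(y1 == 1, 1 - 1e-7, 1e-7)
  expect_lt(supervised_loss(list(y1), list(perfect)), 1e-4)
  expect_error(supervised_loss(list(), list()), "empty")
})

test_that("unsupervised consistency loss follows the k x bs_u averaged pixel-sum", {
  m1 <- matrix(0.5, 3, 3)
  # aux identical to main -> zero
  expect_equal(unsupervised_loss(list(m1), list(list(m1, m1))), 0)
  # single pixel differing by d -> d^2 (bs_u = 1, k = 1)
  a <- m1; a[2, 2] <- 0.5 + 0.3
  expect_equal(unsupervised_loss(list(m1), list(list(a))), 0.09,
               tolerance = 1e-12)
  # constant offset c on an N-pixel map: per-pair pixel sum survives the
  # k*bs_u averaging -> N * c^2
  c0 <- 0.1; N <- 9
  aux <- lapply(1:2, function(j) lapply(1:3, function(p) m1 + c0))
  expect_equal(unsupervised_loss(list(m1, m1), aux), N * c0^2,
               tolerance = 1e-12)
  # permuting the k auxiliary maps of a sample leaves the loss unchanged
  set.seed(4)
  auxr <- list(lapply(1:3, function(p) m1 + matrix(runif(9), 3) * 0.1))
  perm <- list(auxr[[1]][c(3, 1, 2)])
  expect_equal(unsupervised_loss(list(m1), auxr),
               unsupervised_loss(list(m1), perm), tolerance = 1e-12)
  # pixel-mean variant divides the per-pair error by the map size
  expect_equal(unsupervised_loss(list(m1, m1), aux, pixel_mean = TRUE),
               c0^2, tolerance = 1e-12)
  expect_error(unsupervised_loss(list(m1, m1),
                                 list(list(m1), list(m1, m1))),
               "same number")
})

test_that("Gaussian ramp-up starts near zero, hits one at t = L, never decreases", {
  expect_equal(rampup_weight(0, 50), exp(-5), tolerance = 1e-12)
  expect_equal(rampup_weight(50, 50), 1)
  expect_equal(rampup_weight(120, 50), 1)
  w <- vapply(0:100, rampup_weight, numeric(1), L = 50)
  expect_true(all(diff(w) >= 0))
  expect_true(all(w > 0 & w <= 1))
})

test_that("total loss composes the ramp-up weight", {
  tl <- total_loss(1, 2, t = 0, L = 50)
  expect_equal(tl$total, 1 + 2 * exp(-5), tolerance = 1e-12)
  expect_equal(total_loss(1, 2, t = 50, L = 50)$total, 3)
  expect_equal(total_loss(1.5, 0, t = 3, L = 50)$total, 1.5)
  expect_equal(tl$weight, rampup_weight(0, 50))
})

test_that("dice and jaccard agree through J = (1 - dice)/(1 + dice) on binary masks", {
  set.seed(9)
  for (i in 1:10) {
    y <- matrix(rbinom(64, 1, 0.4), 8)
    p <- matrix(rbinom(64, 1, 0.4), 8)
    if (sum(y) + sum(p) == 0) next
    d <- dice_loss(y, p)
    expect_equal(jaccard(y, p), (1 - d) / (1 + d), tolerance = 1e-4)
  }
})
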