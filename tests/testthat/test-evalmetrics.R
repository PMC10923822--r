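test_that("jaccard handles identity, disjoint, partial overlap and empties", {
  y <- matrix(0, 4, 4); y[1:2, 1:4] <- 1          # 8 px
  expect_equal(jaccard(y, y), 1)
  z <- matrix(0, 4, 4); z[4, 1] <- 1
  expect_equal(jaccard(y, z), 0)
  yh <- matrix(0, 4, 4); yh[2:3, 1:4] <- 1        # 8 px, overlap 4
  expect_equal(jaccard(y, yh), 4 / 12, tolerance = 1e-12)
  expect_equal(jaccard(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_equal(jaccard(y, yh), jaccard(yh, y))
  expect_error(jaccard(y, matrix(0, 3, 3)), "shapes differ")
})

test_that("confusion counts tally with cardiomegaly as the positive class", {
  tr <- c("cardiomegaly", "cardiomegaly", "normal", "normal", "normal",
          "cardiomegaly")
  pr <- c("cardiomegaly", "normal", "normal", "cardiomegaly", "normal",
          "cardiomegaly")
  cc <- confusion_counts(tr, pr)
  expect_equal(cc, list(tp = 2, fn = 1, tn = 2, fp = 1))
  all_right <- confusion_counts(tr, tr)
  expect_equal(all_right$fn + all_right$fp, 0)
  swapped <- ifelse(tr == "normal", "cardiomegaly", "normal")
  cs <- confusion_counts(tr, swapped)
  expect_equal(cs$tp + cs$tn, 0)
  expect_error(confusion_counts(tr, c(pr[-6], "weird")), "labels")
})

test_that("summary metrics match the direct formulas on random counts", {
  set.seed(31)
  for (i in 1:20) {
    cnt <- list(tp = sample(0:20, 1), fn = sample(0:20, 1),
                tn = sample(0:20, 1), fp = sample(0:20, 1))
    if (cnt$tp + cnt$fn + cnt$tn + cnt$fp == 0) next
    m <- summary_metrics(cnt)
    if (cnt$tp + cnt$fn > 0)
      expect_equal(m$sensitivity, 100 * cnt$tp / (cnt$tp + cnt$fn))
    else expect_true(is.na(m$sensitivity))
    if (cnt$tn + cnt$fp > 0)
      expect_equal(m$specificity, 100 * cnt$tn / (cnt$tn + cnt$fp))
    expect_equal(m$accuracy, 100 * (cnt$tp + cnt$tn) /
                   (cnt$tp + cnt$fn + cnt$tn + cnt$fp))
    if (!is.na(m$g_mean))
      expect_equal(m$g_mean, sqrt(m$sensitivity * m$specificity))
  }
})

test_that("balanced classes make accuracy equal (Sens+Spec)/2 and AM-GM bounds G-mean", {
  cnt <- list(tp = 30, fn = 12, tn = 25, fp = 17)  # 42 vs 42
  m <- summary_metrics(cnt)
  expect_equal(m$accuracy, (m$sensitivity + m$specificity) / 2,
               tolerance = 1e-12)
  expect_lte(m$g_mean, (m$sensitivity + m$specificity) / 2)
})

test_that("hard-prediction AUC equals (Sens+Spec)/2 and matches the score AUC on 0/1 scores", {
  tr <- rep(c("cardiomegaly", "normal"), c(6, 8))
  set.seed(2)
  pr <- sample(rep(c("cardiomegaly", "normal"), c(7, 7)))
  cc <- confusion_counts(tr, pr)
  sens <- 100 * cc$tp / (cc$tp + cc$fn)
  spec <- 100 * cc$tn / (cc$tn + cc$fp)
  expect_equal(auc_binary(tr, pr), (sens + spec) / 2, tolerance = 1e-12)
  expect_equal(auc_binary(tr, tr), 100)
  expect_equal(auc_binary(tr, rep("cardiomegaly", 14)), 50)
  expect_equal(auc_binary(tr, pr),
               auc_scores(tr, as.numeric(pr == "cardiomegaly")),
               tolerance = 1e-12)
  expect_error(auc_binary(rep("normal", 4), pr[1:4]), "both classes")
})

test_that("score-based AUC equals the concordant-pair oracle and pROC", {
  set.seed(77)
  tr <- rep(c("cardiomegaly", "normal"), c(4, 6))
  sc <- round(runif(10, 0.3, 0.8), 2)
  sc[2] <- sc[6]  # force a tie across classes
  pair_auc <- function(truth, s) {
    pos <- s[truth == "cardiomegaly"]; neg <- s[truth != "cardiomegaly"]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    100 * tot / (length(pos) * length(neg))
  }
  expect_equal(auc_scores(tr, sc), pair_auc(tr, sc), tolerance = 1e-12)
  expect_equal(auc_scores(tr, seq_len(10) %in% 1:4 * 1), 100)
  expect_equal(auc_scores(tr, rep(0.5, 10)), 50)
  skip_if_not_installed("pROC")
  ref <- 100 * as.numeric(pROC::auc(pROC::roc(
    response = tr, predictor = sc, levels = c("normal", "cardiomegaly"),
    direction = "<", quiet = TRUE)))
  expect_equal(auc_scores(tr, sc), ref, tolerance = 1e-9)
})

test_that("count reconstruction inverts reported rates at table precision", {
  cnt <- reconstruct_counts(56.96, 86.54, 79, 52)
  expect_equal(cnt, list(tp = 45, fn = 34, tn = 45, fp = 7))
  m <- summary_metrics(cnt)
  expect_equal(round_half_away(m$sensitivity), 56.96)
  expect_equal(round_half_away(m$specificity), 86.54)
})

test_that("half-away rounding matches table conventions", {
  expect_equal(round_half_away(90.385), 90.39)
  expect_equal(round_half_away(70.205), 70.21)
  expect_equal(round_half_away(0.125), 0.13)
  expect_equal(round_half_away(-0.125), -0.13)
  expect_equal(round_half_away(49.4, 0), 49)
})
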