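# Segmentation and classification evaluation: Jaccard index, confusion
# counts, sensitivity/specificity/G-mean/accuracy and ROC AUC. Cardiomegaly
# is the positive class throughout; rates are reported as percentages.

#' Jaccard index (intersection over union) of two binary masks
#'
#' @param y,yhat Binary masks of identical shape.
#' @return Value in \[0, 1\]; two empty masks score 1.
#' @export
jaccard <- function(y, yhat) {
  check_same_shape(y, yhat)
  u <- sum(y > 0 | yhat > 0)
  if (u == 0) return(1)
  sum(y > 0 & yhat > 0) / u
}

#' Confusion counts for cardiomegaly detection
#'
#' @param truth,pred Character vectors over {"cardiomegaly", "normal"}.
#' @return List with `tp`, `fn`, `tn`, `fp` (cardiomegaly = positive).
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  lv <- c("cardiomegaly", "normal")
  if (!all(truth %in% lv) || !all(pred %in% lv))
    stop("labels must be 'cardiomegaly' or 'normal'")
  list(tp = sum(truth == "cardiomegaly" & pred == "cardiomegaly"),
       fn = sum(truth == "cardiomegaly" & pred == "normal"),
       tn = sum(truth == "normal" & pred == "normal"),
       fp = sum(truth == "normal" & pred == "cardiomegaly"))
}

#' Summary metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), geometric mean
#' sqrt(Sens x Spec), accuracy (TP+TN)/total, and the hard-prediction AUC
#' (Sens+Spec)/2 — all as percentages. A rate whose denominator is zero is
#' returned as NA.
#'
#' @param counts List with `tp`, `fn`, `tn`, `fp` (see
#'   [confusion_counts()]).
#' @return One-row tibble with the counts and metric percentages
#'   (unrounded; see [round_report()] for table-style 2-decimal output).
#' @export
summary_metrics <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  total <- tp + fn + tn + fp
  if (total == 0) stop("no observations")
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  gm <- if (is.na(sens) || is.na(spec)) NA_real_ else sqrt(sens * spec)
  acc <- 100 * (tp + tn) / total
  auc <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  tibble::tibble(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = sens, specificity = spec, g_mean = gm,
                 accuracy = acc, auc = auc)
}

#' Round half away from zero
#'
#' The rounding convention of the reported tables (so 90.385 prints as
#' 90.39 rather than banker's 90.38).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Round an evaluation report to table precision
#'
#' @param report A tibble from [summary_metrics()].
#' @return The report with metric columns rounded to 2 decimals, half away
#'   from zero.
#' @export
round_report <- function(report) {
  for (col in c("sensitivity", "specificity", "g_mean", "accuracy", "auc"))
    if (col %in% names(report))
      report[[col]] <- round_half_away(report[[col]], 2)
  report
}

#' Reconstruct confusion counts from reported rates and class sizes
#'
#' Given a published sensitivity/specificity pair and the evaluation set's
#' class sizes, recovers the integer confusion counts (TP = round(Sens x
#' positives), TN = round(Spec x negatives)), from which every derived
#' summary metric can be recomputed and checked against the printed table.
#'
#' @param sens_pct,spec_pct Reported sensitivity and specificity in
#'   percent.
#' @param n_pos,n_neg Number of positive (cardiomegaly) and negative
#'   (normal) samples.
#' @return List with `tp`, `fn`, `tn`, `fp`.
#' @export
reconstruct_counts <- function(sens_pct, spec_pct, n_pos, n_neg) {
  tp <- round(sens_pct / 100 * n_pos)
  tn <- round(spec_pct / 100 * n_neg)
  list(tp = tp, fn = n_pos - tp, tn = tn, fp = n_neg - tn)
}

#' ROC AUC of a hard binary predictor
#'
#' The two-point trapezoidal ROC of a hard classifier has area
#' (Sensitivity + Specificity)/2; this is the default AUC reported for the
#' thresholded CTR predictor.
#'
#' @inheritParams confusion_counts
#' @return AUC percentage.
#' @export
auc_binary <- function(truth, pred) {
  if (length(unique(truth)) < 2)
    stop("AUC undefined: both classes must be present")
  cc <- confusion_counts(truth, pred)
  sens <- 100 * cc$tp / (cc$tp + cc$fn)
  spec <- 100 * cc$tn / (cc$tn + cc$fp)
  (sens + spec) / 2
}

#' Rank-based ROC AUC of continuous scores
#'
#' Mann-Whitney formulation with midrank tie handling; scores are oriented
#' so larger values indicate cardiomegaly (e.g. the CTR itself).
#'
#' @param truth Character vector over {"cardiomegaly", "normal"}.
#' @param scores Finite numeric scores.
#' @return AUC percentage.
#' @export
auc_scores <- function(truth, scores) {
  if (length(truth) != length(scores)) stop("length mismatch")
  if (!all(is.finite(scores))) stop("scores must be finite")
  pos <- truth == "cardiomegaly"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  100 * (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
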