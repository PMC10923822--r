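# End-to-end prediction: manifest -> standardized images -> two
# probability maps -> bounding boxes -> CTR -> cardiomegaly call, plus an
# evaluation report when ground-truth labels are available.

#' Run the full CTR screening pipeline over a manifest
#'
#' Every image is standardized to the models' input size, segmented by the
#' heart and lungs models, post-processed into bounding boxes and a CTR,
#' and classified with threshold `pi`. Rows with an empty segmentation
#' mask are reported with status "indeterminate" instead of a label.
#'
#' @param manifest Manifest tibble from [read_manifest()] (or a path to
#'   one). An empty manifest yields an empty prediction table.
#' @param heart_model,lungs_model `ctrseg_model` bundles (or checkpoint
#'   directories for [load_model()]).
#' @param pi Cardiomegaly decision threshold (default 0.50).
#' @param out_dir Optional directory; when given, predictions are written
#'   to `predictions.csv` and, if truth labels exist, the evaluation
#'   report to `evaluation.csv`.
#' @return List with `predictions` (tibble: path, ctr, label, status, box
#'   coordinates) and `evaluation` (tibble from [summary_metrics()], or
#'   NULL without ground truth).
#' @export
run_pipeline <- function(manifest, heart_model, lungs_model, pi = 0.50,
                         out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(heart_model)) heart_model <- load_model(heart_model)
  if (is.character(lungs_model)) lungs_model <- load_model(lungs_model)
  if (heart_model$meta$organ != "heart" ||
      lungs_model$meta$organ != "lungs")
    stop("model/organ mismatch: check the checkpoints' metadata")
  if (heart_model$meta$input_size != lungs_model$meta$input_size)
    stop("heart and lungs models expect different input sizes")
  size <- heart_model$meta$input_size
  dir <- attr(manifest, "dir") %||% "."

  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    img <- standardize(read_image(file.path(dir, manifest$path[i])),
                       size = size)
    hp <- predict_probability_map(heart_model, img)
    lp <- predict_probability_map(lungs_model, img)
    res <- ctr_from_probability_maps(hp, lp, pi = pi)
    rows[[i]] <- tibble::tibble(
      path = manifest$path[i],
      ctr = res$ctr,
      label = if (res$valid) res$label else NA_character_,
      status = if (res$valid) "ok" else "indeterminate",
      heart_x_min = res$heart_box$x_min %||% NA_integer_,
      heart_x_max = res$heart_box$x_max %||% NA_integer_,
      heart_y_min = res$heart_box$y_min %||% NA_integer_,
      heart_y_max = res$heart_box$y_max %||% NA_integer_,
      lungs_x_min = res$lungs_box$x_min %||% NA_integer_,
      lungs_x_max = res$lungs_box$x_max %||% NA_integer_,
      lungs_y_min = res$lungs_box$y_min %||% NA_integer_,
      lungs_y_max = res$lungs_box$y_max %||% NA_integer_)
  }
  preds <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(path = character(0), ctr = numeric(0),
                   label = character(0), status = character(0))

  evaluation <- NULL
  if (nrow(preds) > 0 && "label" %in% names(manifest)) {
    has_truth <- nzchar(manifest$label) & preds$status == "ok"
    if (any(has_truth)) {
      cc <- confusion_counts(manifest$label[has_truth],
                             preds$label[has_truth])
      evaluation <- summary_metrics(cc)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE, na = "")
    if (!is.null(evaluation))
      utils::write.csv(round_report(evaluation),
                       file.path(out_dir, "evaluation.csv"),
                       row.names = FALSE)
  }
  list(predictions = preds, evaluation = evaluation)
}
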