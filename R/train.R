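# Batch planning, validation splitting and the optimisation loops for
# supervised and cross-consistency semi-supervised training.

#' Plan labeled/unlabeled batch sizes
#'
#' delta = (n + m)/bs, bs_l = floor(n/delta), bs_u = ceiling(m/delta), so
#' each mini-batch mixes labeled and unlabeled samples in proportion to
#' their pool sizes and bs_l + bs_u = bs always. When the floor drives
#' bs_l to zero (heavily unlabeled regimes, e.g. n = 247, m = 9763,
#' bs = 16), bs_l is clamped to 1 and bs_u reduced accordingly; the
#' returned plan records whether the clamp fired.
#'
#' @param n Labeled training-pool size (>= 1).
#' @param m Unlabeled training-pool size (>= 0).
#' @param bs Total batch size (default 16).
#' @return A `batch_plan` list with `bs`, `bs_l`, `bs_u`, `delta`, `n`,
#'   `m`, `clamped`.
#' @export
plan_batches <- function(n, m, bs = 16) {
  stopifnot(n >= 1, m >= 0, bs >= 2)
  if (bs > n + m) stop("batch size exceeds the total number of samples")
  delta <- (n + m) / bs
  bs_l <- floor(n / delta)
  bs_u <- ceiling(m / delta)
  clamped <- FALSE
  if (bs_l < 1) {
    bs_u <- bs_u - (1 - bs_l)
    bs_l <- 1
    clamped <- TRUE
  }
  structure(list(bs = as.integer(bs), bs_l = as.integer(bs_l),
                 bs_u = as.integer(bs_u), delta = delta,
                 n = as.integer(n), m = as.integer(m), clamped = clamped),
            class = "batch_plan")
}

#' Split labeled and unlabeled pools into training and validation sets
#'
#' 20 percent of the labeled samples and 10 percent of the unlabeled
#' samples are held out for validation by default (rounded half away from
#' zero, so 247 labeled samples give a 198/49 split). The labeled split is
#' stratified by image-level label when labels are supplied.
#'
#' @param labeled Either the labeled-pool size or a character vector of
#'   image-level labels (enables stratification).
#' @param m_unlabeled Unlabeled-pool size (default 0).
#' @param labeled_val_fraction,unlabeled_val_fraction Validation fractions
#'   (defaults 0.2 and 0.1).
#' @param seed Optional seed; identical seeds give identical splits.
#' @return List of index vectors `labeled_train`, `labeled_val`,
#'   `unlabeled_train`, `unlabeled_val` (disjoint and exhaustive per pool).
#' @export
split_validation <- function(labeled, m_unlabeled = 0,
                             labeled_val_fraction = 0.2,
                             unlabeled_val_fraction = 0.1, seed = NULL) {
  stopifnot(labeled_val_fraction > 0, labeled_val_fraction < 1,
            unlabeled_val_fraction > 0, unlabeled_val_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- if (is.character(labeled)) length(labeled) else as.integer(labeled)
  if (n < 2) stop("labeled set must hold at least 2 samples")
  if (is.character(labeled) && length(unique(labeled[nzchar(labeled)])) > 1) {
    lv <- integer(0)
    for (cl in unique(labeled)) {
      idx <- which(labeled == cl)
      nv <- max(1L, round_half_away(length(idx) * labeled_val_fraction, 0))
      lv <- c(lv, sample(idx, nv))
    }
    lv <- sort(lv)
  } else {
    nv <- max(1L, round_half_away(n * labeled_val_fraction, 0))
    lv <- sort(sample.int(n, nv))
  }
  lt <- setdiff(seq_len(n), lv)
  if (m_unlabeled > 0) {
    if (m_unlabeled < 2) stop("unlabeled set must hold at least 2 samples")
    nuv <- max(1L, round_half_away(m_unlabeled * unlabeled_val_fraction, 0))
    uv <- sort(sample.int(m_unlabeled, nuv))
    ut <- setdiff(seq_len(m_unlabeled), uv)
  } else {
    uv <- integer(0); ut <- integer(0)
  }
  list(labeled_train = lt, labeled_val = lv,
       unlabeled_train = ut, unlabeled_val = uv)
}

#' Training configuration
#'
#' @param organ "heart" or "lungs".
#' @param mode "supervised" or "semi_supervised".
#' @param input_size Network input size in pixels (default 299).
#' @param filters Encoder stage widths (default 16, 32, 64, 128, 256).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param epochs Number of epochs (default 100).
#' @param ramp_length Gaussian ramp-up length L in epochs (default 50).
#' @param batch_size Total batch size bs (default 16).
#' @param labeled_val_fraction,unlabeled_val_fraction Validation fractions.
#' @param augment Augment labeled training samples on the fly (default
#'   TRUE; unlabeled samples are never augmented).
#' @param perturb A [perturbation_params()] set for the auxiliary branch.
#' @param unsup_pixel_mean Average the unsupervised loss over pixels
#'   instead of the literal pixel sum (default TRUE, which keeps the
#'   consistency term on the scale of the pixel-mean supervised loss).
#' @param adam_beta1,adam_beta2 Adam moment decays (defaults 0.9, 0.999).
#' @param bn_momentum Batch-normalization running-statistics momentum.
#' @param cbam,cbam_reduction,cbam_kernel Attention configuration.
#' @param seed Root seed for initialization, splits, shuffling,
#'   augmentation and perturbations.
#' @param verbose Print a per-epoch summary line (default FALSE).
#' @return A `training_config` list.
#' @export
training_config <- function(organ = "heart",
                            mode = c("supervised", "semi_supervised"),
                            input_size = 299,
                            filters = c(16, 32, 64, 128, 256),
                            learning_rate = 1e-3, epochs = 100,
                            ramp_length = 50, batch_size = 16,
                            labeled_val_fraction = 0.2,
                            unlabeled_val_fraction = 0.1, augment = TRUE,
                            perturb = perturbation_params(),
                            unsup_pixel_mean = TRUE, adam_beta1 = 0.9,
                            adam_beta2 = 0.999, bn_momentum = 0.99,
                            cbam = TRUE,
                            cbam_reduction = 16, cbam_kernel = 7,
                            seed = 1L, verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(epochs >= 1, ramp_length >= 1)
  structure(as.list(environment()), class = "training_config")
}

standardize_pair <- function(image, mask, size) {
  img <- standardize(image, size = size)
  if (!is.null(mask) && any(dim(mask) != c(size, size)))
    mask <- (resize_mat(mask, size, nearest = TRUE) > 0.5) * 1
  list(image = img, mask = mask)
}

#' Load training data from a manifest
#'
#' Reads and standardizes every image; labeled rows additionally carry the
#' organ's ground-truth mask (resized nearest-neighbour if needed).
#'
#' @param manifest Tibble from [read_manifest()] (or a path).
#' @param organ "heart" or "lungs" (selects which mask column is read).
#' @param input_size Standardization size.
#' @return List with `labeled` (list of image/mask/label), `unlabeled`
#'   (list of images).
#' @export
load_training_data <- function(manifest, organ = c("heart", "lungs"),
                               input_size = 128) {
  organ <- match.arg(organ)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir <- attr(manifest, "dir") %||% "."
  mask_col <- paste0(organ, "_mask")
  labeled <- list(); unlabeled <- list()
  for (i in seq_len(nrow(manifest))) {
    img <- read_image(file.path(dir, manifest$path[i]))
    if (nzchar(manifest[[mask_col]][i])) {
      msk <- read_mask(file.path(dir, manifest[[mask_col]][i]))
      sp <- standardize_pair(img, msk, input_size)
      sp$label <- manifest$label[i]
      labeled[[length(labeled) + 1]] <- sp
    } else {
      unlabeled[[length(unlabeled) + 1]] <-
        standardize(img, size = input_size)
    }
  }
  list(labeled = labeled, unlabeled = unlabeled)
}

as_y_array <- function(mask) array(mask, dim = c(dim(mask), 1))

supervised_grads <- function(ys, ps) {
  bs_l <- length(ys)
  Map(function(y, p) (grad_bce(y, p) + grad_dice(y, p)) / bs_l, ys, ps)
}

validation_jaccard <- function(model, val_pairs) {
  if (length(val_pairs) == 0) return(NA_real_)
  xs <- lapply(val_pairs, `[[`, "image")
  z <- net_forward(model$encoder, xs, training = FALSE, keep_cache = FALSE)
  ps <- net_forward(model$decoder, z$out, training = FALSE,
                    keep_cache = FALSE)$out
  js <- mapply(function(pair, p) jaccard(pair$mask, (p[, , 1] > 0.5) * 1),
               val_pairs, ps)
  mean(js)
}

#' Train a segmentation model on labeled data only
#'
#' Encoder + main decoder optimised with the supervised BCE + Dice loss
#' (Adam, on-the-fly augmentation of labeled samples). The checkpoint with
#' the best validation Jaccard is retained.
#'
#' @param labeled List of `list(image, mask, label)` items (standardized;
#'   see [load_training_data()]).
#' @param config A [training_config()] with mode "supervised".
#' @return List with `model` (best-validation checkpoint), `history`
#'   (tibble: epoch, loss_s, loss_u, omega, val_jaccard), and
#'   `best_val_jaccard`.
#' @export
train_supervised <- function(labeled, config) {
  if (length(labeled) == 0) stop("labeled training set is empty")
  run_training(labeled, unlabeled = list(), config,
               semi = FALSE)
}

#' Train a segmentation model with cross-consistency semi-supervision
#'
#' Each step draws bs_l labeled and bs_u unlabeled samples (per
#' [plan_batches()]); all pass through the shared encoder and the main
#' decoder, while k stochastically perturbed copies of each unlabeled
#' latent pass through the auxiliary decoder. The supervised loss updates
#' the main decoder and encoder; the ramp-up-weighted consistency loss
#' (main-decoder outputs held fixed as targets) updates the auxiliary
#' decoder and encoder.
#'
#' @param labeled,unlabeled Standardized data (see
#'   [load_training_data()]).
#' @param config A [training_config()] with mode "semi_supervised".
#' @return As [train_supervised()].
#' @export
train_semi_supervised <- function(labeled, unlabeled, config) {
  if (length(labeled) == 0) stop("labeled training set is empty")
  if (length(unlabeled) == 0) stop("unlabeled training set is empty")
  run_training(labeled, unlabeled, config, semi = TRUE)
}

run_training <- function(labeled, unlabeled, config, semi) {
  set.seed(config$seed)
  labels <- vapply(labeled, function(x) x$label %||% "", character(1))
  split <- split_validation(
    if (any(nzchar(labels))) labels else length(labeled),
    length(unlabeled), config$labeled_val_fraction,
    config$unlabeled_val_fraction)
  lab_tr <- labeled[split$labeled_train]
  lab_val <- labeled[split$labeled_val]
  unl_tr <- unlabeled[split$unlabeled_train]

  model <- build_segmentation_model(
    input_size = config$input_size, organ = config$organ,
    mode = if (semi) "semi_supervised" else "supervised",
    filters = config$filters, cbam = config$cbam,
    cbam_reduction = config$cbam_reduction,
    cbam_kernel = config$cbam_kernel, bn_momentum = config$bn_momentum,
    seed = sample.int(.Machine$integer.max, 1))

  n_tr <- length(lab_tr)
  if (semi) {
    plan <- plan_batches(n_tr, length(unl_tr), config$batch_size)
    if (plan$bs_u < 1) stop("batch plan leaves no unlabeled slot")
    steps <- ceiling(length(unl_tr) / plan$bs_u)
  } else {
    bs_l <- min(config$batch_size, n_tr)
    plan <- NULL
    steps <- ceiling(n_tr / bs_l)
  }

  st_enc <- adam_init(model$encoder)[[1]]
  st_dec <- adam_init(model$decoder)[[1]]
  st_aux <- if (semi) adam_init(model$aux_decoder)[[1]] else NULL
  tstep <- 0
  best <- list(val = -Inf, model = NULL)
  hist <- vector("list", config$epochs)
  lab_queue <- integer(0)

  draw_labeled <- function(k) {
    out <- integer(0)
    while (length(out) < k) {
      if (length(lab_queue) == 0) lab_queue <<- sample.int(n_tr)
      take <- min(k - length(out), length(lab_queue))
      out <- c(out, lab_queue[seq_len(take)])
      lab_queue <<- lab_queue[-seq_len(take)]
    }
    out
  }

  for (epoch in seq_len(config$epochs)) {
    omega <- rampup_weight(epoch, config$ramp_length)
    ep_ls <- 0; ep_lu <- 0
    unl_order <- if (semi) sample.int(length(unl_tr)) else NULL
    lab_order <- if (!semi) sample.int(n_tr) else NULL
    for (step in seq_len(steps)) {
      if (semi) {
        li <- draw_labeled(plan$bs_l)
        u0 <- (step - 1) * plan$bs_u
        ui <- unl_order[(u0 + 1):min(u0 + plan$bs_u, length(unl_tr))]
      } else {
        s0 <- (step - 1) * min(config$batch_size, n_tr)
        li <- lab_order[(s0 + 1):min(s0 + min(config$batch_size, n_tr),
                                     n_tr)]
        ui <- integer(0)
      }
      pairs <- lapply(lab_tr[li], function(pr) {
        if (config$augment) {
          a <- augment(pr$image, pr$mask)
          list(image = a$image, mask = a$mask)
        } else pr
      })
      xs <- c(lapply(pairs, `[[`, "image"), unl_tr[ui])
      bs_l <- length(pairs); bs_u <- length(ui)

      enc <- net_forward(model$encoder, xs, training = TRUE)
      dec <- net_forward(model$decoder, enc$out, training = TRUE)
      ys <- lapply(pairs, function(pr) as_y_array(pr$mask))
      ps_l <- dec$out[seq_len(bs_l)]
      loss_s <- supervised_loss(ys, ps_l)

      dps <- c(supervised_grads(ys, ps_l),
               lapply(seq_len(bs_u), function(i)
                 array(0, dim = dim(dec$out[[1]]))))
      dec_bw <- net_backward(model$decoder, dec$caches, dps)
      dzs <- dec_bw$dx

      loss_u <- 0
      if (semi && bs_u > 0) {
        zs_u <- enc$out[bs_l + seq_len(bs_u)]
        targets <- dec$out[bs_l + seq_len(bs_u)]  # detached
        psets <- lapply(zs_u, make_perturbation_set, params = config$perturb)
        k <- config$perturb$k
        aux_in <- unlist(lapply(psets, lapply, `[[`, "z"), recursive = FALSE)
        aux <- net_forward(model$aux_decoder, aux_in, training = TRUE)
        aux_maps <- lapply(seq_len(bs_u), function(j)
          aux$out[(j - 1) * k + seq_len(k)])
        loss_u <- unsupervised_loss(targets, aux_maps,
                                    pixel_mean = config$unsup_pixel_mean)
        npix_div <- if (config$unsup_pixel_mean)
          length(targets[[1]]) else 1
        daux <- vector("list", bs_u * k)
        for (j in seq_len(bs_u)) for (p in seq_len(k)) {
          daux[[(j - 1) * k + p]] <-
            omega * (-2) * (targets[[j]] - aux_maps[[j]][[p]]) /
            (k * bs_u * npix_div)
        }
        aux_bw <- net_backward(model$aux_decoder, aux$caches, daux)
        for (j in seq_len(bs_u)) {
          acc <- array(0, dim = dim(dzs[[1]]))
          for (p in seq_len(k)) {
            acc <- acc + aux_bw$dx[[(j - 1) * k + p]] *
              psets[[j]][[p]]$factor
          }
          dzs[[bs_l + j]] <- dzs[[bs_l + j]] + acc
        }
        model$aux_decoder <- apply_bn_states(model$aux_decoder,
                                             aux$bn_states)
      }

      total <- loss_s + omega * loss_u
      if (!is.finite(total))
        stop(sprintf(
          "training diverged at epoch %d step %d (loss_s=%g, loss_u=%g)",
          epoch, step, loss_s, loss_u))

      enc_bw <- net_backward(model$encoder, enc$caches, dzs)
      model$encoder <- apply_bn_states(model$encoder, enc$bn_states)
      model$decoder <- apply_bn_states(model$decoder, dec$bn_states)

      tstep <- tstep + 1
      up <- adam_update(model$encoder, enc_bw$grads, st_enc,
                        config$learning_rate, tstep, config$adam_beta1,
                        config$adam_beta2)
      model$encoder <- up$layers; st_enc <- up$state
      up <- adam_update(model$decoder, dec_bw$grads, st_dec,
                        config$learning_rate, tstep, config$adam_beta1,
                        config$adam_beta2)
      model$decoder <- up$layers; st_dec <- up$state
      if (semi && bs_u > 0) {
        up <- adam_update(model$aux_decoder, aux_bw$grads, st_aux,
                          config$learning_rate, tstep, config$adam_beta1,
                          config$adam_beta2)
        model$aux_decoder <- up$layers; st_aux <- up$state
      }
      ep_ls <- ep_ls + loss_s; ep_lu <- ep_lu + loss_u
    }
    model$meta$epoch <- epoch
    vj <- validation_jaccard(model, lab_val)
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, loss_s = ep_ls / steps,
      loss_u = if (semi) ep_lu / steps else NA_real_,
      omega = if (semi) omega else NA_real_, val_jaccard = vj)
    if (config$verbose)
      message(sprintf(
        "epoch %3d  loss_s %.4f  loss_u %s  omega %.4f  val_J %.4f",
        epoch, ep_ls / steps,
        if (semi) sprintf("%.4f", ep_lu / steps) else "-", omega, vj))
    if (!is.na(vj) && vj > best$val) {
      best$val <- vj
      best$model <- model
    }
  }
  out_model <- best$model %||% model
  out_model$meta$best_val_jaccard <- if (is.finite(best$val)) best$val
    else NA_real_
  list(model = out_model, history = do.call(rbind, hist),
       best_val_jaccard = out_model$meta$best_val_jaccard)
}
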