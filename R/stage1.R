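#' Configuration for the stage-1 patch-level cancer detector
#'
#' The detector is trained from slide-level labels only, by max-pooling
#' multiple-instance learning: each epoch every candidate patch of every
#' training slide is scored, the top-1 most-suspicious patch per slide is
#' selected, and the selected patches are trained with their slide's binary
#' label (cancer = grade group >= 1). The checkpoint with the best tune-split
#' PR AUC is kept (ties: earliest epoch).
#'
#' Default schedule: SGD with initial learning
#' rate 0.01 multiplied by 0.1 every 25 epochs, momentum 0.9, weight decay
#' 1e-5, 100 epochs, batch 128, augmentation by horizontal flip, 90-degree
#' rotations and brightness/contrast/saturation/hue jitter of +/-0.1, 0.3,
#' 0.3, 0.05. [desk_stage1_config()] shortens the schedule for CPU-scale
#' runs.
#'
#' @param backbone `"small-cnn"` (4 stride-2 conv blocks, feature dimension
#'   64). `"densenet121"` (feature dimension 1024) is the full-scale
#'   configuration and requires a GPU deep-learning stack; requesting it here
#'   raises an informative error at build time.
#' @param epochs,batch_size,lr,lr_step,lr_factor,momentum,weight_decay SGD
#'   schedule.
#' @param top_k Number of highest-probability instances selected per slide
#'   per epoch (1 = canonical max-pooling MIL).
#' @param candidate_pool `"tissue"` restricts MIL candidates to tissue
#'   patches; `"all"` includes background patches as benign candidates.
#' @param benign_instance `"hard"` trains on the most suspicious patch of a
#'   benign slide (hard negative); `"random"` picks a random candidate.
#' @param augment List of augmentation amplitudes.
#' @param seed Integer seed; training is a pure function of (data, config).
#' @return A `stage1_config` list.
#' @export
stage1_config <- function(backbone = c("small-cnn", "densenet121"),
                          epochs = 100, batch_size = 128,
                          lr = 0.01, lr_step = 25, lr_factor = 0.1,
                          momentum = 0.9, weight_decay = 1e-5,
                          top_k = 1, candidate_pool = c("tissue", "all"),
                          benign_instance = c("hard", "random"),
                          augment = list(hflip = TRUE, rot90 = TRUE,
                                         brightness = 0.1, contrast = 0.3,
                                         saturation = 0.3, hue = 0.05),
                          seed = 0) {
  backbone <- match.arg(backbone)
  feature_dim <- switch(backbone, "small-cnn" = 64L, "densenet121" = 1024L)
  structure(list(backbone = backbone, feature_dim = feature_dim,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_step = as.integer(lr_step), lr_factor = lr_factor,
                 momentum = momentum, weight_decay = weight_decay,
                 top_k = as.integer(top_k),
                 candidate_pool = match.arg(candidate_pool),
                 benign_instance = match.arg(benign_instance),
                 augment = augment, seed = as.integer(seed)),
            class = "stage1_config")
}

#' Desk-scale stage-1 configuration
#'
#' The schedule used throughout the package's own experiments: the small CNN
#' backbone, 20 epochs, batch 32, otherwise the standard recipe.
#'
#' @param ... Overrides passed to [stage1_config()].
#' @export
desk_stage1_config <- function(...) {
  stage1_config(epochs = 20, batch_size = 32, ...)
}

# 4 stride-2 conv blocks 3->16->32->64->64, GAP (64-d feature tap), linear
# head to {benign, cancer}
build_stage1_layers <- function(config) {
  if (config$backbone != "small-cnn") {
    stop("backbone '", config$backbone, "' requires a GPU deep-learning ",
         "stack; the desk-scale backbone is 'small-cnn'", call. = FALSE)
  }
  list(nn_conv(3, 16, 3, stride = 2), nn_bn(16), nn_relu(),
       nn_conv(16, 32, 3, stride = 2), nn_bn(32), nn_relu(),
       nn_conv(32, 64, 3, stride = 2), nn_bn(64), nn_relu(),
       nn_conv(64, 64, 3, stride = 2), nn_bn(64), nn_relu(),
       nn_gap(), nn_linear(64, 2))
}

# ---- augmentation ----------------------------------------------------------

# color jitter in the torchvision order/convention: brightness and contrast
# as additive/blend factors, saturation as blend toward per-pixel gray, hue
# as a shift in HSV space
jitter_colors <- function(px, amp) {
  if (!is.null(amp$brightness) && amp$brightness > 0) {
    px <- px + stats::runif(1, -amp$brightness, amp$brightness)
  }
  if (!is.null(amp$contrast) && amp$contrast > 0) {
    f <- stats::runif(1, 1 - amp$contrast, 1 + amp$contrast)
    gray <- mean(0.299 * px[, 1] + 0.587 * px[, 2] + 0.114 * px[, 3])
    px <- px * f + gray * (1 - f)
  }
  if (!is.null(amp$saturation) && amp$saturation > 0) {
    f <- stats::runif(1, 1 - amp$saturation, 1 + amp$saturation)
    lum <- 0.299 * px[, 1] + 0.587 * px[, 2] + 0.114 * px[, 3]
    px <- px * f + lum * (1 - f)
  }
  px <- clamp01(px)
  if (!is.null(amp$hue) && amp$hue > 0) {
    hsv <- rgb_to_hsv_mat(px)
    hsv[, 1] <- (hsv[, 1] + stats::runif(1, -amp$hue, amp$hue)) %% 1
    px <- hsv_to_rgb_mat(hsv)
  }
  clamp01(px)
}

augment_patch <- function(patch, amp) {
  if (isTRUE(amp$hflip) && stats::runif(1) < 0.5) {
    patch <- patch[, rev(seq_len(ncol(patch))), , drop = FALSE]
  }
  if (isTRUE(amp$rot90)) {
    k <- sample(0:3, 1)
    for (r in seq_len(k)) {
      patch <- aperm(patch, c(2, 1, 3))[rev(seq_len(dim(patch)[2])), , , drop = FALSE]
    }
  }
  d <- dim(patch)
  px <- jitter_colors(matrix(patch, ncol = 3), amp)
  array(px, d)
}

# ---- model utilities -------------------------------------------------------

normalize_patches <- function(patches, norm) {
  for (ch in 1:3) {
    patches[, , ch, ] <- (patches[, , ch, ] - norm$mean[ch]) / norm$sd[ch]
  }
  patches
}

check_patch_size <- function(model, patches) {
  d <- dim(patches)
  if (length(d) != 4 || d[3] != 3 || d[1] != model$input_size || d[2] != model$input_size) {
    stop("patches must be ", model$input_size, "x", model$input_size,
         "x3xN for this model", call. = FALSE)
  }
}

# eval-mode forward returning both features (penultimate GAP output) and
# cancer probabilities
stage1_forward <- function(model, patches) {
  check_patch_size(model, patches)
  x <- normalize_patches(patches, model$norm)
  n <- length(model$layers)
  f <- net_forward(model$layers[seq_len(n - 1)], x, training = FALSE)
  logits <- linear_fw(model$layers[[n]], f$out)$out
  z <- sweep(logits, 2, apply(logits, 2, max))
  ez <- exp(z)
  probs <- sweep(ez, 2, colSums(ez), "/")
  list(features = t(f$out), cancer_prob = probs[2, ])
}

#' Extract penultimate-layer feature vectors for patches
#'
#' Deterministic evaluation-mode pass: one `feature_dim`-vector per patch,
#' tapped at the last hidden layer (the global-average-pooled conv features)
#' of the cancer detector.
#'
#' @param model A trained `stage1_model`.
#' @param patches `ps x ps x 3 x n` array at the model's input size.
#' @return `n x feature_dim` matrix.
#' @export
extract_features <- function(model, patches) {
  stage1_forward(model, patches)$features
}

#' Per-patch cancer probabilities
#'
#' @inheritParams extract_features
#' @return Numeric vector of length `n`.
#' @export
patch_cancer_probability <- function(model, patches) {
  stage1_forward(model, patches)$cancer_prob
}

#' Slide-level cancer probability by max pooling
#'
#' The slide probability of containing a cancer lesion is the maximum of its
#' patch probabilities over tissue patches.
#'
#' @param model A trained `stage1_model`.
#' @param grid A `patch_grid` from [extract_patches()], or a plain patch
#'   array (then all patches count as tissue).
#' @return Scalar probability.
#' @export
slide_cancer_probability <- function(model, grid) {
  if (inherits(grid, "patch_grid")) {
    keep <- grid$tissue[cbind(grid$coords$grid_row, grid$coords$grid_col)]
    if (!any(keep)) stop("no tissue patches on slide", call. = FALSE)
    patches <- grid$patches[, , , keep, drop = FALSE]
  } else {
    patches <- grid
    if (dim(patches)[4] < 1) stop("no tissue patches on slide", call. = FALSE)
  }
  max(patch_cancer_probability(model, patches))
}

# candidate patches of a slide for MIL and for slide scoring
slide_candidates <- function(slide, patch_size, pool = "tissue") {
  grid <- extract_patches(slide$image, patch_size)
  keep <- grid$tissue[cbind(grid$coords$grid_row, grid$coords$grid_col)]
  if (pool == "all" || !any(keep)) keep <- rep(TRUE, length(keep))
  grid$patches[, , , keep, drop = FALSE]
}

#' Train the stage-1 cancer detector by max-pooling MIL
#'
#' @param dataset A `slide_dataset` from [make_dataset()] with both benign
#'   and cancer slides in its train and tune splits.
#' @param config A [stage1_config()].
#' @param shuffle_labels Permute the training slides' binary labels before
#'   training (negative control: performance must collapse to chance).
#' @param verbose Print per-epoch progress.
#' @return A `stage1_model`: list with `layers`, `norm` (per-channel
#'   standardization constants), `config`, `feature_dim`, `input_size`,
#'   `best_epoch`, and `log` (tibble: epoch, lr, train_loss, tune_roc_auc,
#'   tune_pr_auc, best).
#' @export
train_stage1 <- function(dataset, config = desk_stage1_config(),
                         shuffle_labels = FALSE, verbose = FALSE) {
  manifest <- dataset$manifest
  tr_idx <- which(manifest$split == "train")
  tu_idx <- which(manifest$split == "tune")
  y_tr <- as.integer(manifest$grade_group[tr_idx] >= 1)
  y_tu <- as.integer(manifest$grade_group[tu_idx] >= 1)
  if (length(unique(y_tr)) < 2 || length(unique(y_tu)) < 2) {
    stop("train and tune splits must each contain benign and cancer slides",
         call. = FALSE)
  }

  with_seed(derive_seed(config$seed, "stage1"), {
    if (shuffle_labels) y_tr <- sample(y_tr)

    # candidate patches are deterministic per slide: extract once
    cand_tr <- lapply(tr_idx, function(i)
      slide_candidates(get_slide(dataset, i), dataset$patch_size,
                       config$candidate_pool))
    cand_tu <- lapply(tu_idx, function(i)
      slide_candidates(get_slide(dataset, i), dataset$patch_size,
                       config$candidate_pool))

    # normalization constants from a sample of training patches
    norm_sample <- do.call(abind4, cand_tr[seq_len(min(10, length(cand_tr)))])
    norm <- list(mean = vapply(1:3, function(ch) mean(norm_sample[, , ch, ]), 0),
                 sd = vapply(1:3, function(ch) stats::sd(norm_sample[, , ch, ]), 0))
    rm(norm_sample)

    model <- list(layers = build_stage1_layers(config), norm = norm,
                  config = config, feature_dim = config$feature_dim,
                  input_size = dataset$patch_size)
    class(model) <- "stage1_model"
    state <- sgd_init(model$layers)

    log <- NULL
    best <- list(pr_auc = -Inf, epoch = NA_integer_, layers = NULL)
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_at_epoch(epoch, config$lr, config$lr_step, config$lr_factor)

      # (a) score all candidate patches, (b) select top-k per slide
      sel_patches <- list()
      sel_labels <- integer(0)
      for (s in seq_along(tr_idx)) {
        cand <- cand_tr[[s]]
        pr <- patch_cancer_probability(model, cand)
        k <- min(config$top_k, length(pr))
        pick <- if (y_tr[s] == 0 && config$benign_instance == "random") {
          sample(length(pr), k)
        } else {
          order(pr, decreasing = TRUE)[seq_len(k)]
        }
        sel_patches <- c(sel_patches, lapply(pick, function(p) cand[, , , p]))
        sel_labels <- c(sel_labels, rep(y_tr[s], k))
      }

      # (c) train on the selected instances with the slide labels
      ord <- sample(length(sel_labels))
      losses <- numeric(0)
      for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        xb <- array(0, c(dataset$patch_size, dataset$patch_size, 3, length(b)))
        for (q in seq_along(b)) {
          xb[, , , q] <- augment_patch(sel_patches[[b[q]]], config$augment)
        }
        xb <- normalize_patches(xb, norm)
        fw <- net_forward(model$layers, xb, training = TRUE)
        model$layers <- fw$layers
        ce <- weighted_cross_entropy(fw$out, sel_labels[b] + 1L)
        if (!is.finite(ce$loss)) {
          stop("non-finite stage-1 loss at epoch ", epoch, call. = FALSE)
        }
        bk <- net_backward(model$layers, fw$caches, ce$dlogits)
        up <- sgd_step(model$layers, bk$grads, state, lr,
                       config$momentum, config$weight_decay)
        model$layers <- up$layers
        state <- up$state
        losses <- c(losses, ce$loss)
      }

      # (d) slide-level PR AUC on the tune split
      tune_scores <- vapply(seq_along(tu_idx), function(s) {
        slide_cancer_probability(model, cand_tu[[s]])
      }, 0)
      roc <- roc_auc(tune_scores, y_tu)
      pr <- pr_auc(tune_scores, y_tu)
      is_best <- pr > best$pr_auc
      if (is_best) best <- list(pr_auc = pr, epoch = epoch, layers = model$layers)
      log <- dplyr::bind_rows(log, tibble::tibble(
        epoch = epoch, lr = lr, train_loss = mean(losses),
        tune_roc_auc = roc, tune_pr_auc = pr, best = is_best))
      if (verbose) {
        message(sprintf("stage1 epoch %3d  loss %.4f  tune ROC %.3f PR %.3f%s",
                        epoch, mean(losses), roc, pr, if (is_best) " *" else ""))
      }
    }
    model$layers <- best$layers
    model$best_epoch <- best$epoch
    model$log <- log
    model
  })
}

#' @export
print.stage1_model <- function(x, ...) {
  cat("<stage1_model> ", x$config$backbone, ", feature_dim ", x$feature_dim,
      ", input ", x$input_size, "px; best epoch ", x$best_epoch,
      " (tune PR AUC ", sprintf("%.3f", max(x$log$tune_pr_auc)), ")\n", sep = "")
  invisible(x)
}

# bind patch arrays along the 4th dimension
abind4 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[4], 0))
  out <- array(0, c(d[1], d[2], d[3], n))
  at <- 0
  for (a in arrs) {
    k <- dim(a)[4]
    out[, , , at + seq_len(k)] <- a
    at <- at + k
  }
  out
}
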