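#' Configuration for the stage-2 grade-group classifier
#'
#' The grader consumes the assembled per-slide feature maps. Its front part
#' is five 1x1-convolution + batch-norm + ReLU layers that mix each
#' position's feature vector before any spatial context; the trunk is a
#' stack of residual 3x3-convolution blocks (conv-BN-ReLU-conv-BN plus
#' identity skip, ReLU after the addition); the head is global average
#' pooling and a linear map to the six classes (benign, grade groups 1-5).
#' Training minimizes class-weighted cross-entropy with weights
#' 1, 1, 1.5, 1.4, 1.7, 1.6; SGD starts at learning rate 0.1, multiplied by
#' 0.1 every 40 epochs, momentum 0.9, weight decay 1e-5, 150 epochs, batch
#' 256; augmentation is a random shift of -5..5 map positions in each axis,
#' vertical flip, and 90-degree rotations. The checkpoint with the best
#' tune-split quadratic-weighted kappa is kept. The exact layer widths of
#' the original are not published; the tapering front and width-128 trunk
#' here are a declared reconstruction, all overridable.
#'
#' @param feature_dim Channels of the incoming feature maps.
#' @param front_widths Five output widths for the 1x1 front layers; default
#'   is a geometric taper from `feature_dim` to `trunk_width`.
#' @param trunk_width,n_blocks,kernel Residual trunk geometry.
#' @param class_weights Length-6 cross-entropy weights, benign first.
#' @param epochs,batch_size,lr,lr_step,lr_factor,momentum,weight_decay SGD
#'   schedule.
#' @param canvas `c(H_f, W_f)` fixed spatial size maps are padded to.
#' @param augment List: `shift` (max absolute shift in map positions),
#'   `vflip`, `rot90`.
#' @param seed Integer seed.
#' @return A `stage2_config` list.
#' @export
stage2_config <- function(feature_dim = 64, front_widths = NULL,
                          trunk_width = 128, n_blocks = 16, kernel = 3,
                          class_weights = c(1, 1, 1.5, 1.4, 1.7, 1.6),
                          epochs = 150, batch_size = 256,
                          lr = 0.1, lr_step = 40, lr_factor = 0.1,
                          momentum = 0.9, weight_decay = 1e-5,
                          canvas = c(16, 32),
                          augment = list(shift = 5, vflip = TRUE, rot90 = TRUE),
                          seed = 0) {
  if (is.null(front_widths)) {
    front_widths <- round(exp(seq(log(feature_dim), log(trunk_width),
                                  length.out = 6)))[-1]
  }
  stopifnot(length(front_widths) == 5, length(class_weights) == 6)
  if (any(c(front_widths, trunk_width) <= 0)) {
    stop("layer widths must be positive", call. = FALSE)
  }
  structure(list(feature_dim = as.integer(feature_dim),
                 front_widths = as.integer(front_widths),
                 trunk_width = as.integer(trunk_width),
                 n_blocks = as.integer(n_blocks), kernel = as.integer(kernel),
                 n_classes = 6L, class_weights = class_weights,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_step = as.integer(lr_step), lr_factor = lr_factor,
                 momentum = momentum, weight_decay = weight_decay,
                 canvas = as.integer(canvas), augment = augment,
                 seed = as.integer(seed)),
            class = "stage2_config")
}

#' Desk-scale stage-2 configuration
#'
#' Keeps the 16-block residual trunk but narrows it to width 32, shortens
#' the schedule to 36 epochs at batch 16 with the learning-rate decay
#' interval scaled proportionally (x0.1 every 12 epochs, mirroring 40-of-150
#' at full scale — without the decay the short run never leaves the
#' high-learning-rate regime and late epochs stay noisy), and shrinks the
#' canvas to 8 x 16 map positions. Sized for single-CPU training on the
#' synthetic datasets.
#'
#' @param ... Overrides passed to [stage2_config()].
#' @export
desk_stage2_config <- function(...) {
  args <- list(...)
  defaults <- list(trunk_width = 32, epochs = 36, batch_size = 16,
                   lr_step = 12, canvas = c(8, 16))
  do.call(stage2_config, utils::modifyList(defaults, args))
}

#' Build an untrained stage-2 model
#'
#' @param config A [stage2_config()].
#' @return A `stage2_model` with randomly initialized layers (seeded from
#'   `config$seed`).
#' @export
build_stage2 <- function(config = stage2_config()) {
  layers <- with_seed(derive_seed(config$seed, "stage2-init"), {
    front <- list()
    cin <- config$feature_dim
    for (w in config$front_widths) {
      front <- c(front, list(nn_conv(cin, w, 1, pad = 0), nn_bn(w), nn_relu()))
      cin <- w
    }
    trunk <- list()
    if (cin != config$trunk_width) {
      # width adapter so the identity skips type-check; 1x1, no activation
      trunk <- list(nn_conv(cin, config$trunk_width, 1, pad = 0))
    }
    trunk <- c(trunk, lapply(seq_len(config$n_blocks),
                             function(i) nn_resblock(config$trunk_width,
                                                     config$kernel)))
    c(front, trunk, list(nn_gap(), nn_linear(config$trunk_width,
                                             config$n_classes)))
  })
  structure(list(layers = layers, config = config,
                 best_epoch = NA_integer_, log = NULL),
            class = "stage2_model")
}

#' @export
print.stage2_model <- function(x, ...) {
  cat("<stage2_model> front ", paste(x$config$front_widths, collapse = "-"),
      ", trunk ", x$config$n_blocks, "x width-", x$config$trunk_width,
      " residual blocks, canvas ", x$config$canvas[1], "x",
      x$config$canvas[2], sep = "")
  if (!is.na(x$best_epoch)) {
    cat("; best epoch ", x$best_epoch, " (tune kappa_quad ",
        sprintf("%.3f", max(x$log$tune_kappa_quad)), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

# ---- feature dataset -------------------------------------------------------

#' Convert a slide dataset to per-slide feature grids
#'
#' Runs the trained stage-1 model over every slide: extracts the patch grid,
#' computes the per-patch feature vectors and stores them as a
#' `g_h x g_w x feature_dim` array per slide together with the tissue mask.
#' Feature maps for training and prediction are assembled from these grids
#' (augmentation operates in map units).
#'
#' @param model A trained `stage1_model`.
#' @param dataset A `slide_dataset`.
#' @param verbose Print progress.
#' @return A `feature_dataset`: list with `grids` (list of feature arrays),
#'   `tissue` (list of logical matrices), `manifest`, `feature_dim`.
#' @export
featurize_dataset <- function(model, dataset, verbose = FALSE) {
  n <- nrow(dataset$manifest)
  grids <- vector("list", n)
  tissue <- vector("list", n)
  for (i in seq_len(n)) {
    s <- get_slide(dataset, i)
    pg <- extract_patches(s$image, dataset$patch_size)
    feats <- extract_features(model, pg$patches)
    g <- pg$grid
    arr <- array(0, c(g[1], g[2], ncol(feats)))
    for (k in seq_len(nrow(feats))) {
      arr[pg$coords$grid_row[k], pg$coords$grid_col[k], ] <- feats[k, ]
    }
    grids[[i]] <- arr
    tissue[[i]] <- pg$tissue
    if (verbose && i %% 25 == 0) message("featurized ", i, "/", n)
  }
  structure(list(grids = grids, tissue = tissue,
                 manifest = dataset$manifest,
                 feature_dim = model$feature_dim),
            class = "feature_dataset")
}

# place a feature grid (and its mask) on the canvas at `offset`, cropping
# content shifted off the canvas; returns H x W x C array
place_on_canvas <- function(grid_arr, tissue, canvas, offset = c(0, 0)) {
  d <- dim(grid_arr)
  out <- array(0, c(canvas[1], canvas[2], d[3]))
  rows <- seq_len(d[1]); cols <- seq_len(d[2])
  tr <- rows + offset[1]; tc <- cols + offset[2]
  keep_r <- tr >= 1 & tr <= canvas[1]
  keep_c <- tc >= 1 & tc <= canvas[2]
  if (any(keep_r) && any(keep_c)) {
    sub <- grid_arr[rows[keep_r], cols[keep_c], , drop = FALSE]
    mask <- tissue[rows[keep_r], cols[keep_c], drop = FALSE]
    sub <- sub * array(rep(as.numeric(mask), d[3]), dim(sub))
    out[tr[keep_r], tc[keep_c], ] <- sub
  }
  out
}

# random flip/rotation/shift of a feature grid, in map units
augment_grid <- function(grid_arr, tissue, canvas, amp) {
  if (isTRUE(amp$vflip) && stats::runif(1) < 0.5) {
    grid_arr <- grid_arr[rev(seq_len(dim(grid_arr)[1])), , , drop = FALSE]
    tissue <- tissue[rev(seq_len(nrow(tissue))), , drop = FALSE]
  }
  if (isTRUE(amp$rot90)) {
    k <- sample(0:3, 1)
    for (r in seq_len(k)) {
      if (dim(grid_arr)[2] > canvas[1]) break   # rotation would not fit
      grid_arr <- aperm(grid_arr, c(2, 1, 3))[rev(seq_len(dim(grid_arr)[2])), , , drop = FALSE]
      tissue <- t(tissue)[rev(seq_len(ncol(tissue))), , drop = FALSE]
    }
  }
  shift <- if (is.null(amp$shift)) c(0, 0) else {
    c(sample(-amp$shift:amp$shift, 1), sample(-amp$shift:amp$shift, 1))
  }
  place_on_canvas(grid_arr, tissue, canvas, shift)
}

# assemble a batch tensor (H, W, C, B) from feature-dataset indices
stage2_batch <- function(fdata, idx, canvas, augment = NULL) {
  C <- fdata$feature_dim
  x <- array(0, c(canvas[1], canvas[2], C, length(idx)))
  for (q in seq_along(idx)) {
    i <- idx[q]
    x[, , , q] <- if (is.null(augment)) {
      place_on_canvas(fdata$grids[[i]], fdata$tissue[[i]], canvas)
    } else {
      augment_grid(fdata$grids[[i]], fdata$tissue[[i]], canvas, augment)
    }
  }
  x
}

# ---- training --------------------------------------------------------------

#' Train the stage-2 grade-group classifier
#'
#' Minimizes the class-weighted cross-entropy on the train split and keeps
#' the epoch checkpoint with the best tune-split quadratic-weighted kappa
#' (ties: earliest epoch).
#'
#' @param fdata A `feature_dataset` from [featurize_dataset()].
#' @param config A [stage2_config()].
#' @param verbose Print per-epoch progress.
#' @return A trained `stage2_model` with a `log` tibble (epoch, lr, loss,
#'   tune accuracy, kappa, kappa_quad, best).
#' @export
train_stage2 <- function(fdata, config = desk_stage2_config(),
                         verbose = FALSE) {
  manifest <- fdata$manifest
  tr_idx <- which(manifest$split == "train")
  tu_idx <- which(manifest$split == "tune")
  y_tr <- manifest$grade_group[tr_idx]
  missing <- setdiff(0:5, unique(y_tr))
  if (length(missing)) {
    stop("class(es) absent from training data: grade group ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (fdata$feature_dim != config$feature_dim) {
    stop("feature_dim mismatch: maps have ", fdata$feature_dim,
         " channels, config expects ", config$feature_dim, call. = FALSE)
  }

  model <- build_stage2(config)
  with_seed(derive_seed(config$seed, "stage2-train"), {
    state <- sgd_init(model$layers)
    log <- NULL
    best <- list(kq = -Inf, epoch = NA_integer_, layers = NULL)
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_at_epoch(epoch, config$lr, config$lr_step, config$lr_factor)
      ord <- sample(length(tr_idx))
      losses <- numeric(0)
      for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        xb <- stage2_batch(fdata, tr_idx[b], config$canvas, config$augment)
        fw <- net_forward(model$layers, xb, training = TRUE)
        model$layers <- fw$layers
        ce <- weighted_cross_entropy(fw$out, y_tr[b] + 1L, config$class_weights)
        if (!is.finite(ce$loss)) {
          stop("non-finite stage-2 loss at epoch ", epoch, call. = FALSE)
        }
        bk <- net_backward(model$layers, fw$caches, ce$dlogits)
        up <- sgd_step(model$layers, bk$grads, state, lr,
                       config$momentum, config$weight_decay)
        model$layers <- up$layers
        state <- up$state
        losses <- c(losses, ce$loss)
      }

      tune_pred <- predict_feature_dataset(model, fdata, tu_idx)
      cm <- confusion_matrix(manifest$grade_group[tu_idx], tune_pred$predicted)
      acc <- sum(diag(cm)) / sum(cm)
      kap <- cohens_kappa(cm)$estimate
      kq <- cohens_kappa(cm, weighting = "quadratic")$estimate
      is_best <- kq > best$kq
      if (is_best) best <- list(kq = kq, epoch = epoch, layers = model$layers)
      log <- dplyr::bind_rows(log, tibble::tibble(
        epoch = epoch, lr = lr, train_loss = mean(losses),
        tune_accuracy = acc, tune_kappa = kap, tune_kappa_quad = kq,
        best = is_best))
      if (verbose) {
        message(sprintf(
          "stage2 epoch %3d  loss %.4f  tune acc %.3f k %.3f kq %.3f%s",
          epoch, mean(losses), acc, kap, kq, if (is_best) " *" else ""))
      }
    }
    model$layers <- best$layers
    model$best_epoch <- best$epoch
    model$log <- log
    model
  })
}

# evaluation-mode predictions for a subset of a feature dataset
predict_feature_dataset <- function(model, fdata, idx = seq_along(fdata$grids)) {
  probs <- matrix(0, length(idx), model$config$n_classes)
  for (q in seq_along(idx)) {
    x <- stage2_batch(fdata, idx[q], model$config$canvas)
    fw <- net_forward(model$layers, x, training = FALSE)
    z <- fw$out - max(fw$out)
    p <- exp(z) / sum(exp(z))
    probs[q, ] <- p
  }
  tibble::tibble(slide_id = fdata$manifest$slide_id[idx],
                 reference = fdata$manifest$grade_group[idx],
                 predicted = max.col(probs) - 1L,
                 probs = unname(split(probs, row(probs))))
}

#' Predict the grade group for one feature map
#'
#' @param model A trained `stage2_model`.
#' @param fmap A `feature_map` from [assemble_feature_map()] (its canvas
#'   must match the model's) or a raw `H x W x C` array.
#' @return A `grade_prediction`: list with `probabilities` (named 6-vector
#'   summing to 1) and `predicted` (grade group, argmax).
#' @export
predict_grade_group <- function(model, fmap) {
  values <- if (inherits(fmap, "feature_map")) fmap$values else fmap
  d <- dim(values)
  if (d[3] != model$config$feature_dim) {
    stop("channel mismatch: map has ", d[3], " channels, model expects ",
         model$config$feature_dim, call. = FALSE)
  }
  x <- array(values, c(d[1], d[2], d[3], 1))
  fw <- net_forward(model$layers, x, training = FALSE)
  z <- fw$out - max(fw$out)
  p <- as.numeric(exp(z) / sum(exp(z)))
  names(p) <- c("benign", paste0("gg", 1:5))
  structure(list(probabilities = p, predicted = unname(which.max(p) - 1L)),
            class = "grade_prediction")
}

#' @export
print.grade_prediction <- function(x, ...) {
  cat("<grade_prediction> grade group", x$predicted, "\n")
  print(round(x$probabilities, 4))
  invisible(x)
}
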