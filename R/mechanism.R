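#' Exact t-SNE embedding
#'
#' A faithful implementation of t-distributed stochastic neighbor embedding
#' for the feature-space separability analysis: Gaussian conditional
#' similarities calibrated per point to the target perplexity by binary
#' search, symmetrized; Student-t low-dimensional affinities; gradient
#' descent with early exaggeration (factor 4, first 100 iterations),
#' adaptive per-coordinate gains and momentum 0.5 rising to 0.8 after
#' iteration 250. Learning rate defaults to 200, matching the analysis
#' setting. Exact (quadratic-cost) computation — intended for a few thousand
#' points.
#'
#' @param x `n x d` numeric matrix of feature vectors.
#' @param perplexity Target perplexity (effective neighborhood size).
#' @param iterations Gradient-descent iterations.
#' @param learning_rate Step size.
#' @param seed Integer seed for the initial layout.
#' @return `n x 2` matrix of embedding coordinates.
#' @export
tsne_embed <- function(x, perplexity = 50, iterations = 1000,
                       learning_rate = 200, seed = 0) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 points", call. = FALSE)
  if (perplexity >= (n - 1) / 3) perplexity <- max(2, floor((n - 1) / 3))
  sumsq <- rowSums(x^2)
  d2 <- pmax(outer(sumsq, sumsq, "+") - 2 * tcrossprod(x), 0)
  if (max(d2) == 0) {
    stop("all feature vectors are identical; embedding is undefined",
         call. = FALSE)
  }

  # per-point bandwidths by binary search on the conditional entropy
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1; bmin <- -Inf; bmax <- Inf
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { bmin <- beta; beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2 }
      else { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  with_seed(seed, {
    y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    gains <- matrix(1, n, 2)
    inc <- matrix(0, n, 2)
    for (iter in seq_len(iterations)) {
      Pe <- if (iter <= 100) P * 4 else P
      ys <- rowSums(y^2)
      num <- 1 / (1 + pmax(outer(ys, ys, "+") - 2 * tcrossprod(y), 0))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% y
      mom <- if (iter <= 250) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      inc <- mom * inc - learning_rate * gains * grad
      y <- y + inc
      y <- sweep(y, 2, colMeans(y))
    }
    y
  })
}

#' Feature-space separability of Gleason patterns
#'
#' Samples cancer patches of each pattern (3, 4, 5) from a dataset, extracts
#' their stage-1 feature vectors, embeds them in 2-D by t-SNE and scores the
#' class structure by the mean silhouette over patches (on the embedding
#' coordinates). A detector that has learned pattern-specific features — even
#' though it was trained only on cancer presence — yields clearly separated
#' clouds.
#'
#' @param model A `stage1_model` (trained or not; untrained models serve as
#'   the comparison baseline).
#' @param dataset A `slide_dataset` with per-patch pattern labels.
#' @param n_per_class Patches sampled per cancer pattern; if a class has
#'   fewer, all are used with a warning.
#' @param perplexity,iterations t-SNE hyperparameters.
#' @param seed Integer seed (sampling and embedding).
#' @return An `embedding_result`: list with `points` (tibble: x, y,
#'   pattern), `centroids` (tibble), `silhouette` (mean silhouette width).
#' @export
embed_pattern_features <- function(model, dataset, n_per_class = 600,
                                   perplexity = 50, iterations = 1000,
                                   seed = 0) {
  manifest <- dataset$manifest
  # inventory of cancer patches: slide index, grid row, grid col, pattern
  inv <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    lab <- if (!is.null(dataset$slides)) {
      dataset$slides[[i]]$patch_labels
    } else {
      load_slide(manifest$path[i])$patch_labels
    }
    idx <- which(matrix(lab %in% cancer_patterns(), nrow(lab)), arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    tibble::tibble(slide = i, row = idx[, 1], col = idx[, 2],
                   pattern = lab[idx])
  })

  sel <- with_seed(derive_seed(seed, "embed-sample"), {
    purrr::map_dfr(cancer_patterns(), function(cl) {
      pool <- dplyr::filter(inv, .data$pattern == cl)
      if (nrow(pool) < n_per_class) {
        warning("only ", nrow(pool), " ", cl, " patches available (requested ",
                n_per_class, "); using all", call. = FALSE)
        pool
      } else {
        pool[sample(nrow(pool), n_per_class), ]
      }
    })
  })

  ps <- dataset$patch_size
  feats <- matrix(0, nrow(sel), model$feature_dim)
  for (si in unique(sel$slide)) {
    rows <- which(sel$slide == si)
    img <- get_slide(dataset, si)$image
    patches <- array(0, c(ps, ps, 3, length(rows)))
    for (q in seq_along(rows)) {
      ri <- (sel$row[rows[q]] - 1) * ps + seq_len(ps)
      cj <- (sel$col[rows[q]] - 1) * ps + seq_len(ps)
      patches[, , , q] <- img[ri, cj, ]
    }
    feats[rows, ] <- extract_features(model, patches)
  }

  y <- tsne_embed(feats, perplexity, iterations,
                  seed = derive_seed(seed, "embed-tsne"))
  labels <- factor(sel$pattern, levels = cancer_patterns())
  sil <- cluster::silhouette(as.integer(labels), stats::dist(y))
  points <- tibble::tibble(x = y[, 1], y = y[, 2], pattern = sel$pattern)
  centroids <- points |>
    dplyr::group_by(.data$pattern) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")
  structure(list(points = points, centroids = centroids,
                 silhouette = mean(sil[, "sil_width"])),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat("<embedding_result> ", nrow(x$points), " patches, mean silhouette ",
      sprintf("%.3f", x$silhouette), "\n", sep = "")
  invisible(x)
}

#' Proportion-sensitivity experiment by ratio-controlled slide concatenation
#'
#' Samples non-overlapping pairs of pure Gleason 3+3 and pure 4+4 slides
#' and, for each mixture ratio, horizontally concatenates the left fraction
#' of the 3+3 slide with the matching fraction of the 4+4 slide (crop
#' boundaries snap to whole patch columns so no patch straddles the
#' junction). Each synthetic mixture runs through the full two-stage
#' pipeline; the per-class output probabilities are summarized as mean and
#' sd per ratio. A proportion-sensitive grader shows the grade-group-1
#' probability falling and the group-4/5 probabilities rising along the
#' series.
#'
#' @param stage1,stage2 Trained models.
#' @param dataset A `slide_dataset` providing the slide pool; pure 3+3
#'   slides are grade-group-1 slides whose cancer is all pattern 3, pure
#'   4+4 slides grade-group-4 with all pattern 4.
#' @param n_pairs Number of non-overlapping slide pairs.
#' @param ratios Fractions of the 3+3 slide's width, descending.
#' @param seed Integer seed for pair sampling.
#' @return A `ratio_series_result`: list with `summary` (tibble: ratio,
#'   class, mean, sd), `raw` (tibble with per-pair probabilities), `pairs`.
#' @export
ratio_concatenation_experiment <- function(stage1, stage2, dataset,
                                           n_pairs = 5,
                                           ratios = c(1, 0.8, 0.6, 0.4, 0.2, 0),
                                           seed = 0) {
  manifest <- dataset$manifest
  is_pure <- function(i, cl) {
    s <- get_slide(dataset, i)
    comp <- s$composition
    sum(comp[setdiff(cancer_patterns(), cl)]) == 0 && comp[cl] > 0
  }
  gg1 <- which(manifest$grade_group == 1)
  gg4 <- which(manifest$grade_group == 4)
  gg1 <- gg1[vapply(gg1, is_pure, TRUE, cl = "gp3")]
  gg4 <- gg4[vapply(gg4, is_pure, TRUE, cl = "gp4")]
  if (length(gg1) < n_pairs || length(gg4) < n_pairs) {
    stop("slide pool too small for ", n_pairs, " non-overlapping pairs (",
         length(gg1), " pure 3+3, ", length(gg4), " pure 4+4)", call. = FALSE)
  }
  pairs <- with_seed(derive_seed(seed, "ratio-pairs"), {
    tibble::tibble(a = sample(gg1, n_pairs), b = sample(gg4, n_pairs))
  })

  ps <- dataset$patch_size
  raw <- purrr::map_dfr(seq_len(n_pairs), function(p) {
    sa <- get_slide(dataset, pairs$a[p])
    sb <- get_slide(dataset, pairs$b[p])
    purrr::map_dfr(ratios, function(r) {
      img <- concat_slides(sa$image, sb$image, r, ps)
      pred <- grade_slide_image(stage1, stage2, img, ps)
      tibble::tibble(pair = p, ratio = r,
                     class = names(pred$probabilities),
                     prob = as.numeric(pred$probabilities))
    })
  })
  summary <- raw |>
    dplyr::group_by(.data$ratio, .data$class) |>
    dplyr::summarise(mean = mean(.data$prob), sd = stats::sd(.data$prob),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$ratio))
  structure(list(summary = summary, raw = raw, pairs = pairs,
                 ratios = ratios),
            class = "ratio_series_result")
}

# horizontal concatenation: left fraction `r` (in whole patch columns) of
# image `a`, remainder from image `b`; heights are padded with background
# if they differ
concat_slides <- function(a, b, r, patch_size, background = 0.97) {
  g_w <- ncol(a) %/% patch_size
  left_cols <- round(r * g_w)
  h <- max(nrow(a), nrow(b))
  pad <- function(img) {
    if (nrow(img) == h) return(img)
    out <- array(background, c(h, ncol(img), 3))
    out[seq_len(nrow(img)), , ] <- img
    out
  }
  a <- pad(a); b <- pad(b)
  if (left_cols == g_w) return(a)
  if (left_cols == 0) return(b)
  left <- a[, seq_len(left_cols * patch_size), , drop = FALSE]
  right_cols <- g_w - left_cols
  right <- b[, seq_len(right_cols * patch_size), , drop = FALSE]
  out <- array(0, c(h, ncol(left) + ncol(right), 3))
  out[, seq_len(ncol(left)), ] <- left
  out[, ncol(left) + seq_len(ncol(right)), ] <- right
  out
}

#' Summary table of a ratio series in the conventional layout
#'
#' Rows are output classes, columns the mixture ratios, cells "mean +/- sd".
#'
#' @param x A `ratio_series_result`.
#' @return Tibble.
#' @export
ratio_series_table <- function(x) {
  x$summary |>
    dplyr::mutate(cell = sprintf("%.2f ± %.2f", .data$mean, .data$sd),
                  ratio = sprintf("%d%%:%d%%", round(100 * .data$ratio),
                                  100 - round(100 * .data$ratio))) |>
    dplyr::select("class", "ratio", "cell") |>
    tidyr::pivot_wider(names_from = "ratio", values_from = "cell")
}

#' @export
print.ratio_series_result <- function(x, ...) {
  cat("<ratio_series_result> ", nrow(x$pairs), " pairs, ",
      length(x$ratios), " ratios\n", sep = "")
  print(ratio_series_table(x))
  invisible(x)
}
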