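#' Default texture parameters for the synthetic histology generator
#'
#' Each pattern class is rendered as an abstraction of its H&E morphology:
#' benign tissue and Gleason pattern 3 as ring-shaped "glands" (large and
#' sparse vs small and numerous), pattern 4 as fused solid blobs without
#' lumina, pattern 5 as near-confluent sheets, all over a noisy pink stroma.
#' Realism is not the goal; class separability and exact controllability are.
#' Classes differ in structure count, size and foreground coverage, which is
#' what both the hand-crafted statistics oracle and the learned detector key
#' on. Colors are kept away from the \[0,1\] value-range boundaries so the
#' training-time color jitter cannot clip.
#'
#' @param separability Scalar in (0, 1]; 1 gives the default, well-separated
#'   classes. Lower values shrink the differences between class structure
#'   counts (a knob for difficulty experiments).
#' @return A `texture_params` list with one entry per pattern class plus the
#'   shared stroma parameters.
#' @export
texture_params <- function(separability = 1) {
  stopifnot(separability > 0, separability <= 1)
  list(
    stroma = list(base = c(0.82, 0.64, 0.72), noise_sd = 0.035),
    benign = list(family = "ring", n_range = c(2L, 3L),
                  radius = c(9, 12), rim = 3,
                  rim_color = c(0.48, 0.28, 0.56), lumen_color = c(0.86, 0.82, 0.86)),
    gp3 = list(family = "ring", n_range = c(8L, 11L),
               radius = c(3.2, 4.6), rim = 1.6,
               rim_color = c(0.44, 0.24, 0.52), lumen_color = c(0.86, 0.82, 0.86)),
    gp4 = list(family = "blob", n_range = c(3L, 5L),
               radius = c(4.5, 6.5), lobes = c(2L, 3L),
               fill_color = c(0.42, 0.22, 0.50)),
    gp5 = list(family = "sheet", coverage = c(0.55, 0.70),
               fill_color = c(0.38, 0.20, 0.46)),
    separability = separability
  )
}

# place n centers at least min_dist apart inside [margin, size - margin]
place_centers <- function(n, size, margin, min_dist, max_tries = 400) {
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(pts) < n && tries < max_tries) {
    tries <- tries + 1
    cand <- stats::runif(2, margin, size - margin)
    if (nrow(pts) == 0 ||
        min(sqrt(rowSums((pts - matrix(cand, nrow(pts), 2, byrow = TRUE))^2))) >= min_dist) {
      pts <- rbind(pts, cand)
    }
  }
  pts
}

# number of structures for a class, shrunk toward the overall mean when
# separability < 1
draw_count <- function(n_range, separability) {
  n <- sample(seq(n_range[1], n_range[2]), 1)
  if (separability < 1) {
    mid <- 6 # common count all classes shrink toward
    n <- max(1L, as.integer(round(mid + (n - mid) * separability)))
  }
  n
}

#' Render one synthetic tissue patch
#'
#' Draws a `patch_size` x `patch_size` RGB patch of the requested pattern
#' class. Deterministic given `(pattern, params, seed)`.
#'
#' @param pattern One of [pattern_classes()].
#' @param patch_size Edge length in pixels (>= 16).
#' @param params Texture parameters, see [texture_params()].
#' @param seed Integer seed.
#' @return Numeric array `patch_size x patch_size x 3` with values in \[0,1\].
#' @export
#' @examples
#' p <- make_patch("gp3", 64, seed = 1)
#' dim(p)
make_patch <- function(pattern, patch_size = 64, params = texture_params(),
                       seed = 0) {
  if (!pattern %in% pattern_classes()) {
    stop("unknown pattern class: ", pattern, call. = FALSE)
  }
  stopifnot(patch_size >= 16)
  with_seed(seed, {
    ps <- patch_size
    # stroma background with mild color wobble and pixel noise
    base <- params$stroma$base + stats::rnorm(3, 0, 0.02)
    img <- array(rep(base, each = ps * ps), c(ps, ps, 3))
    img <- img + array(stats::rnorm(ps * ps * 3, 0, params$stroma$noise_sd),
                       c(ps, ps, 3))

    cx <- matrix(seq_len(ps), ps, ps)          # row coordinate
    cy <- matrix(seq_len(ps), ps, ps, byrow = TRUE)
    paint <- function(mask, color) {
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[mask] <- color[ch] + stats::rnorm(sum(mask), 0, 0.02)
        img[, , ch] <<- pl
      }
    }

    pp <- params[[pattern]]
    if (pattern %in% c("benign", "gp3")) {
      n <- draw_count(pp$n_range, params$separability)
      r <- stats::runif(n, pp$radius[1], pp$radius[2])
      ctr <- place_centers(n, ps, max(r) + 1, 2 * max(r) + 2)
      for (k in seq_len(nrow(ctr))) {
        d2 <- (cx - ctr[k, 1])^2 + (cy - ctr[k, 2])^2
        rim <- d2 <= r[k]^2 & d2 > (r[k] - pp$rim)^2
        lum <- d2 <= (r[k] - pp$rim)^2
        paint(rim, pp$rim_color)
        if (any(lum)) paint(lum, pp$lumen_color)
      }
    } else if (pattern == "gp4") {
      n <- draw_count(pp$n_range, params$separability)
      r0 <- mean(pp$radius)
      ctr <- place_centers(n, ps, r0 + 2, 2.6 * r0)
      for (k in seq_len(nrow(ctr))) {
        lobes <- sample(seq(pp$lobes[1], pp$lobes[2]), 1)
        mask <- matrix(FALSE, ps, ps)
        for (l in seq_len(lobes)) {
          off <- stats::runif(2, -r0 / 2, r0 / 2)
          rr <- stats::runif(1, pp$radius[1], pp$radius[2]) * 0.8
          mask <- mask | ((cx - ctr[k, 1] - off[1])^2 +
                          (cy - ctr[k, 2] - off[2])^2 <= rr^2)
        }
        paint(mask, pp$fill_color)
      }
    } else if (pattern == "gp5") {
      cov <- stats::runif(1, pp$coverage[1], pp$coverage[2])
      # smooth random field, thresholded at the requested coverage
      field <- matrix(stats::rnorm(ps * ps), ps, ps)
      k <- rep(1 / 9, 9)
      for (i in 1:2) {
        field <- t(apply(field, 1, function(v) stats::filter(v, k, circular = TRUE)))
        field <- apply(field, 2, function(v) stats::filter(v, k, circular = TRUE))
      }
      mask <- field <= stats::quantile(field, cov)
      paint(mask, pp$fill_color)
    }
    clamp01(img)
  })
}

# foreground (epithelial) mask used by texture statistics: pixels clearly
# darker than the stroma base
patch_foreground <- function(img, cutoff = 0.62) {
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  lum < cutoff
}

#' Hand-crafted texture statistics for a patch
#'
#' Computes simple structural statistics — foreground fraction, a 4-connected
#' component count of the foreground, mean component size and mean lumen
#' brightness inside foreground bounding discs — that separate the four
#' texture classes by construction. Used to verify generator separability
#' without a learned model.
#'
#' @param img Patch array from [make_patch()].
#' @param min_size Components smaller than this many pixels are treated as
#'   noise specks and ignored.
#' @return Tibble with one row of statistics.
#' @export
patch_statistics <- function(img, min_size = 5) {
  fg <- patch_foreground(img)
  lab <- label_components(fg)
  sizes <- if (max(lab) > 0) tabulate(lab[lab > 0]) else integer(0)
  sizes <- sizes[sizes >= min_size]
  ncomp <- length(sizes)
  # interior brightness: glands have bright lumina inside dark rims
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  interior <- interior_mask(fg)
  tibble::tibble(
    fg_fraction = mean(fg),
    n_components = ncomp,
    mean_component_size = if (length(sizes)) mean(sizes) else 0,
    interior_brightness = if (any(interior)) mean(lum[interior]) else NA_real_
  )
}

# 4-connected component labelling (two-pass union-find), plain R
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j]) next
    up <- if (i > 1 && mask[i - 1, j]) lab[i - 1, j] else 0L
    lf <- if (j > 1 && mask[i, j - 1]) lab[i, j - 1] else 0L
    if (up == 0L && lf == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[i, j] <- nxt
    } else if (up == 0L || lf == 0L) {
      lab[i, j] <- max(up, lf)
    } else {
      ru <- find(up); rl <- find(lf)
      lab[i, j] <- min(ru, rl)
      parent[max(ru, rl)] <- min(ru, rl)
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

# pixels whose 4-neighbourhood is entirely enclosed by foreground rings:
# approximated as background pixels not reachable from the patch border
interior_mask <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  bg <- !fg
  lab <- label_components(bg)
  border_labels <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  border_labels <- border_labels[border_labels > 0]
  bg & !(lab %in% border_labels)
}
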