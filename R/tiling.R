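#' Extract a non-overlapping patch grid covering a slide
#'
#' Tiles the (optionally downsampled) slide with `patch_size` patches,
#' ceiling-dividing each axis so the whole area is covered; edge patches are
#' padded to full size with the background fill. A patch is marked as tissue
#' when any of its pixels is darker than the background threshold — synthetic
#' slides use a bright glass background, so intensity alone suffices.
#'
#' @param image `H x W x 3` array in \[0,1\], or a `synthetic_slide`.
#' @param patch_size Patch edge length in pixels.
#' @param downsample Integer decimation factor applied before tiling (models
#'   scanning at 40x and analysing at 10x; 1 for synthetic slides).
#' @param background Fill value for padding, and the luminance above which a
#'   pixel counts as background glass.
#' @return A `patch_grid`: list with `patches`
#'   (`patch_size x patch_size x 3 x n` array in row-major grid order),
#'   `coords` (tibble: index, grid_row, grid_col, origin_row, origin_col —
#'   0-based pixel origins), `grid = c(g_h, g_w)`, `tissue` (`g_h x g_w`
#'   logical), `patch_size`.
#' @export
extract_patches <- function(image, patch_size = 64, downsample = 1,
                            background = 0.97) {
  if (inherits(image, "synthetic_slide")) image <- image$image
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3, downsample >= 1)
  if (downsample > 1) {
    keep_r <- seq(1, nrow(image), by = downsample)
    keep_c <- seq(1, ncol(image), by = downsample)
    image <- image[keep_r, keep_c, , drop = FALSE]
  }
  h <- nrow(image); w <- ncol(image)
  if (h < patch_size || w < patch_size) {
    stop("slide (", h, "x", w, ") smaller than one ", patch_size,
         "-pixel patch after downsampling", call. = FALSE)
  }
  g_h <- ceiling(h / patch_size); g_w <- ceiling(w / patch_size)
  n <- g_h * g_w
  patches <- array(background, c(patch_size, patch_size, 3, n))
  tissue <- matrix(FALSE, g_h, g_w)
  coords <- tibble::tibble(index = seq_len(n),
                           grid_row = rep(seq_len(g_h), each = g_w),
                           grid_col = rep(seq_len(g_w), g_h),
                           origin_row = (rep(seq_len(g_h), each = g_w) - 1L) * patch_size,
                           origin_col = (rep(seq_len(g_w), g_h) - 1L) * patch_size)
  if (h == g_h * patch_size && w == g_w * patch_size) {
    # exact tiling: one reshape instead of a per-patch copy loop
    a <- array(image, c(patch_size, g_h, patch_size, g_w, 3))
    patches <- array(aperm(a, c(1, 3, 5, 4, 2)),
                     c(patch_size, patch_size, 3, n))
    lum <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    lmin <- apply(array(lum, c(patch_size, g_h, patch_size, g_w)),
                  c(2, 4), min)
    tissue <- lmin < background
  } else {
    for (k in seq_len(n)) {
      i <- coords$grid_row[k]; j <- coords$grid_col[k]
      ri <- ((i - 1) * patch_size + 1):min(i * patch_size, h)
      cj <- ((j - 1) * patch_size + 1):min(j * patch_size, w)
      patches[seq_along(ri), seq_along(cj), , k] <- image[ri, cj, ]
      lum <- 0.299 * image[ri, cj, 1] + 0.587 * image[ri, cj, 2] +
        0.114 * image[ri, cj, 3]
      tissue[i, j] <- any(lum < background)
    }
  }
  structure(list(patches = patches, coords = coords,
                 grid = c(g_h, g_w), tissue = tissue,
                 patch_size = as.integer(patch_size)),
            class = "patch_grid")
}

#' Assemble per-patch feature vectors into a spatial feature map
#'
#' Places the feature vector of patch (i, j) at canvas position
#' (i, j) + offset, so the map is the slide resized by 1/patch_size with C
#' channels. Off-tissue and padding positions hold the fill value (zeros —
#' the neutral input for the downstream convolutional classifier). The grid
#' is anchored top-left by default; translation robustness is the job of the
#' shift augmentation during grader training, not of centering.
#'
#' @param features `n x C` matrix of feature vectors, rows in the grid order
#'   of `grid$coords`.
#' @param grid A `patch_grid` (or list with `grid` and `tissue`).
#' @param canvas `c(H_f, W_f)` canvas size; must be at least the grid size.
#' @param offset 0-based `c(row, col)` placement offset of the grid inside
#'   the canvas.
#' @param fill Fill value outside tissue.
#' @return A `feature_map`: list with `values` (`H_f x W_f x C` array),
#'   `offset`, `grid`, `tissue` (canvas-aligned logical matrix), `channels`.
#' @export
assemble_feature_map <- function(features, grid, canvas = c(16, 32),
                                 offset = c(0, 0), fill = 0) {
  g <- grid$grid
  features <- as.matrix(features)
  if (nrow(features) != g[1] * g[2]) {
    stop("need one feature vector per grid cell: got ", nrow(features),
         " for a ", g[1], "x", g[2], " grid", call. = FALSE)
  }
  if (g[1] + offset[1] > canvas[1] || g[2] + offset[2] > canvas[2]) {
    stop("grid (with offset) exceeds canvas", call. = FALSE)
  }
  C <- ncol(features)
  values <- array(fill, c(canvas[1], canvas[2], C))
  tissue_canvas <- matrix(FALSE, canvas[1], canvas[2])
  for (k in seq_len(nrow(features))) {
    i <- grid$coords$grid_row[k] + offset[1]
    j <- grid$coords$grid_col[k] + offset[2]
    if (grid$tissue[grid$coords$grid_row[k], grid$coords$grid_col[k]]) {
      values[i, j, ] <- features[k, ]
      tissue_canvas[i, j] <- TRUE
    }
  }
  structure(list(values = values, offset = as.integer(offset),
                 grid = g, tissue = tissue_canvas, channels = C),
            class = "feature_map")
}

#' Gather feature vectors back from a feature map
#'
#' Inverse of [assemble_feature_map()] on tissue positions.
#'
#' @param fmap A `feature_map`.
#' @param grid The `patch_grid` it was assembled from.
#' @return `n x C` matrix; rows at non-tissue positions hold the fill value.
#' @export
gather_feature_map <- function(fmap, grid) {
  n <- grid$grid[1] * grid$grid[2]
  out <- matrix(0, n, fmap$channels)
  for (k in seq_len(n)) {
    i <- grid$coords$grid_row[k] + fmap$offset[1]
    j <- grid$coords$grid_col[k] + fmap$offset[2]
    out[k, ] <- fmap$values[i, j, ]
  }
  out
}

#' Serialize / read a feature map
#'
#' Values are stored as a flat gzip-compressed binary array next to a JSON
#' header carrying dimensions, offset, tissue mask and the source slide id.
#'
#' @param fmap A `feature_map`.
#' @param path Output path (`.fmap`); the header is written to
#'   `<path>.json`.
#' @param slide_id Optional source slide id recorded in the header.
#' @return `path`, invisibly.
#' @export
write_feature_map <- function(fmap, path, slide_id = NA_character_) {
  header <- list(dims = dim(fmap$values), offset = fmap$offset,
                 grid = fmap$grid, channels = fmap$channels,
                 tissue = fmap$tissue, slide_id = slide_id)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(fmap$values), con)
  invisible(path)
}

#' @rdname write_feature_map
#' @export
read_feature_map <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  values <- readBin(con, "numeric", prod(header$dims))
  structure(list(values = array(values, header$dims),
                 offset = as.integer(header$offset),
                 grid = as.integer(header$grid),
                 tissue = as.matrix(header$tissue),
                 channels = as.integer(header$channels)),
            class = "feature_map")
}
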