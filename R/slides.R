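#' Assemble a labeled synthetic slide
#'
#' Builds a grid-of-patches slide image whose per-patch pattern labels follow
#' the requested area composition as closely as the grid allows
#' (largest-remainder rounding). Cancer patches are laid out as a contiguous
#' run in row-major scan order, with each pattern occupying a contiguous
#' sub-run — cancer in a needle biopsy core is focal, not salt-and-pepper.
#' The stored grade group is always derived from the *realized* patch
#' composition through the rule engine, so label consistency holds by
#' construction.
#'
#' @param composition Named area-fraction vector (see
#'   [as_area_composition()]).
#' @param grid Integer vector `c(g_h, g_w)` of grid dimensions.
#' @param patch_size Patch edge length in pixels.
#' @param params Texture parameters ([texture_params()]).
#' @param seed Integer seed; every patch texture derives its own seed from it.
#' @param slide_id Optional slide identifier string.
#' @return A `synthetic_slide` object: list with `image`
#'   (`g_h*patch_size x g_w*patch_size x 3` array), `patch_labels`
#'   (`g_h x g_w` character matrix), `composition` (realized), `grade_group`,
#'   `slide_id`, `seed`, `patch_size`.
#' @export
#' @examples
#' s <- make_slide(c(benign = 0.5, gp3 = 0.25, gp4 = 0.25), grid = c(2, 4),
#'                 patch_size = 32, seed = 1)
#' s$grade_group
make_slide <- function(composition, grid = c(4, 16), patch_size = 64,
                       params = texture_params(), seed = 0,
                       slide_id = sprintf("slide_%08d", seed)) {
  comp <- as_area_composition(composition)
  g_h <- as.integer(grid[1]); g_w <- as.integer(grid[2])
  stopifnot(g_h >= 1, g_w >= 1)
  n <- g_h * g_w

  counts <- largest_remainder(comp, n)
  names(counts) <- pattern_classes()
  lost <- comp > 0 & counts == 0
  if (any(lost)) {
    warning("fraction(s) for ", paste(names(comp)[lost], collapse = ", "),
            " rounded to 0 patches on a ", g_h, "x", g_w,
            " grid; realized composition recorded", call. = FALSE)
  }

  labels_run <- with_seed(derive_seed(seed, "layout"), {
    cancer <- cancer_patterns()[counts[cancer_patterns()] > 0]
    run <- unlist(lapply(sample(cancer), function(cl) rep(cl, counts[cl])))
    n_cancer <- length(run)
    lab <- rep("benign", n)
    if (n_cancer > 0) {
      start <- sample.int(n - n_cancer + 1, 1)
      lab[seq(start, length.out = n_cancer)] <- run
    }
    lab
  })
  patch_labels <- matrix(labels_run, g_h, g_w, byrow = TRUE)

  img <- array(0, c(g_h * patch_size, g_w * patch_size, 3))
  for (i in seq_len(g_h)) for (j in seq_len(g_w)) {
    p <- make_patch(patch_labels[i, j], patch_size, params,
                    seed = derive_seed(seed, sprintf("patch_%d_%d", i, j)))
    ri <- (i - 1) * patch_size + seq_len(patch_size)
    cj <- (j - 1) * patch_size + seq_len(patch_size)
    img[ri, cj, ] <- p
  }

  realized <- composition_from_label_grid(patch_labels)
  structure(list(
    image = img,
    patch_labels = patch_labels,
    composition = realized,
    grade_group = composition_to_grade_group(realized),
    slide_id = slide_id,
    seed = as.integer(seed),
    patch_size = as.integer(patch_size)
  ), class = "synthetic_slide")
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat("<synthetic_slide> ", x$slide_id, ": ",
      nrow(x$image), "x", ncol(x$image), " px, grid ",
      nrow(x$patch_labels), "x", ncol(x$patch_labels),
      ", grade group ", x$grade_group, "\n", sep = "")
  comp <- x$composition[x$composition > 0]
  cat("  composition:", paste(sprintf("%s=%.3f", names(comp), comp),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Sample an area composition for a target grade group
#'
#' Draws a realistic slide composition whose rule-engine grade group equals
#' `grade_group`: cancer occupies 30-70% of the slide; grade group 2 has a
#' 15-45% pattern-4 share of the cancer area, grade group 3 a 55-85% share;
#' grade group 4 is pure pattern 4; grade group 5 is either pure pattern 5
#' or pattern 4 with a 20-45% pattern-5 share (Gleason 4+5). Margins keep
#' compositions away from the 1% floor and 5% secondary-rule boundaries so
#' grid rounding cannot flip the label.
#'
#' @param grade_group Integer in 0..5.
#' @param seed Integer seed.
#' @return Named area-fraction vector.
#' @export
sample_composition <- function(grade_group, seed = 0) {
  stopifnot(grade_group %in% 0:5)
  with_seed(seed, {
    if (grade_group == 0) return(c(benign = 1))
    f <- stats::runif(1, 0.3, 0.7)
    comp <- switch(as.character(grade_group),
      "1" = c(gp3 = f),
      "2" = { s <- stats::runif(1, 0.15, 0.45); c(gp3 = f * (1 - s), gp4 = f * s) },
      "3" = { s <- stats::runif(1, 0.55, 0.85); c(gp3 = f * (1 - s), gp4 = f * s) },
      "4" = c(gp4 = f),
      "5" = if (stats::runif(1) < 0.5) c(gp5 = f) else {
        s <- stats::runif(1, 0.2, 0.45)
        c(gp4 = f * (1 - s), gp5 = f * s)
      })
    c(benign = 1 - sum(comp), comp)
  })
}

#' Generate a synthetic slide dataset with a manifest
#'
#' Draws per-class slide counts from `class_mix` by largest-remainder
#' rounding, samples a composition per slide, renders the slides, and assigns
#' train/tune/validate splits stratified by grade group. The validation split
#' takes `validate_fraction` of each class; the remainder is divided
#' train:tune at `tune_ratio`:1 (default 6:1).
#'
#' @param n_slides Number of slides (>= 7 so every grade group can appear).
#' @param class_mix Length-6 non-negative weights over grade groups 0..5.
#' @param grid,patch_size,params Slide geometry and texture parameters.
#' @param seed Integer seed governing compositions, layouts and splits.
#' @param dir Optional output directory; when given, slide images are written
#'   as PNG with a JSON patch-label sidecar and `manifest.csv`, and the
#'   returned dataset references them by path instead of holding pixels in
#'   memory.
#' @param validate_fraction Fraction of each class held out for validation.
#' @param tune_ratio Train:tune ratio applied to the non-validation slides.
#' @return A `slide_dataset`: list with `manifest` (tibble: slide_id, path,
#'   grade_group, split, seed), `slides` (list of `synthetic_slide`, or NULL
#'   when written to disk), `grid`, `patch_size`, `params`, `seed`, `dir`.
#' @export
make_dataset <- function(n_slides, class_mix = rep(1, 6), grid = c(4, 16),
                         patch_size = 64, params = texture_params(), seed = 0,
                         dir = NULL, validate_fraction = 0.2, tune_ratio = 6) {
  stopifnot(n_slides >= 7, length(class_mix) == 6)
  counts <- largest_remainder(class_mix, n_slides)

  gg_seq <- rep(0:5, counts)
  slide_seeds <- vapply(seq_len(n_slides),
                        function(i) derive_seed(seed, sprintf("slide%05d", i)),
                        integer(1))

  split <- character(n_slides)
  for (g in 0:5) {
    idx <- which(gg_seq == g)
    if (!length(idx)) next
    idx <- with_seed(derive_seed(seed, paste0("split", g)), sample(idx))
    n_val <- round(length(idx) * validate_fraction)
    n_tune <- round((length(idx) - n_val) / (tune_ratio + 1))
    split[idx] <- c(rep("validate", n_val), rep("tune", n_tune),
                    rep("train", length(idx) - n_val - n_tune))
  }

  slides <- vector("list", n_slides)
  paths <- rep(NA_character_, n_slides)
  gg_real <- integer(n_slides)
  n_patches <- prod(grid)
  for (i in seq_len(n_slides)) {
    # coarse grids can round a small secondary away; resample the
    # composition until the grid realizes the requested grade group
    comp <- NULL
    for (try in seq_len(25)) {
      cand <- sample_composition(gg_seq[i],
                                 derive_seed(slide_seeds[i],
                                             paste0("comp", try)))
      counts <- largest_remainder(as_area_composition(cand), n_patches)
      realized <- composition_to_grade_group(
        stats::setNames(counts / n_patches, pattern_classes()))
      comp <- cand
      if (realized == gg_seq[i]) break
    }
    s <- suppressWarnings(
      make_slide(comp, grid, patch_size, params, seed = slide_seeds[i],
                 slide_id = sprintf("S%05d", i)))
    gg_real[i] <- s$grade_group
    if (is.null(dir)) {
      slides[[i]] <- s
    } else {
      paths[i] <- save_slide(s, dir)
    }
  }

  manifest <- tibble::tibble(
    slide_id = sprintf("S%05d", seq_len(n_slides)),
    path = paths,
    grade_group = gg_real,
    split = split,
    seed = slide_seeds
  )
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(manifest = manifest,
                 slides = if (is.null(dir)) slides else NULL,
                 grid = as.integer(grid), patch_size = as.integer(patch_size),
                 params = params, seed = as.integer(seed), dir = dir),
            class = "slide_dataset")
}

#' @export
print.slide_dataset <- function(x, ...) {
  cat("<slide_dataset> ", nrow(x$manifest), " slides, grid ",
      x$grid[1], "x", x$grid[2], ", patch ", x$patch_size, " px",
      if (!is.null(x$dir)) paste0(", on disk at ", x$dir), "\n", sep = "")
  print(dplyr::count(x$manifest, .data$grade_group, .data$split))
  invisible(x)
}

#' Write a synthetic slide to disk
#'
#' Saves the raster as PNG and the patch-label grid, composition, grade
#' group and seed as a JSON sidecar (`<slide_id>.json`).
#'
#' @param slide A `synthetic_slide`.
#' @param dir Output directory (created if missing).
#' @return The PNG path, invisibly usable in a manifest.
#' @export
save_slide <- function(slide, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(slide$slide_id, ".png"))
  png::writePNG(slide$image, path)
  side <- list(slide_id = slide$slide_id,
               patch_size = slide$patch_size,
               grade_group = slide$grade_group,
               seed = slide$seed,
               composition = as.list(slide$composition),
               patch_labels = slide$patch_labels)
  jsonlite::write_json(side, file.path(dir, paste0(slide$slide_id, ".json")),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  path
}

#' Load a synthetic slide written by [save_slide()]
#'
#' @param path Path to the PNG file (the JSON sidecar is looked up next to
#'   it).
#' @return A `synthetic_slide`.
#' @export
load_slide <- function(path) {
  img <- png::readPNG(path)
  side_path <- sub("\\.png$", ".json", path)
  if (!file.exists(side_path)) stop("missing sidecar: ", side_path, call. = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  labels <- as.matrix(side$patch_labels)
  structure(list(
    image = img,
    patch_labels = labels,
    composition = as_area_composition(unlist(side$composition)),
    grade_group = as.integer(side$grade_group),
    slide_id = side$slide_id,
    seed = as.integer(side$seed),
    patch_size = as.integer(side$patch_size)
  ), class = "synthetic_slide")
}

#' Reopen a dataset written by [make_dataset()]
#'
#' Reads `manifest.csv` and the first slide's sidecar to restore the
#' dataset geometry; slides stay on disk and are loaded on demand.
#'
#' @param dir Directory containing `manifest.csv` and the slide files.
#' @return A `slide_dataset`.
#' @export
load_dataset <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- tibble::as_tibble(utils::read.csv(path,
                                                stringsAsFactors = FALSE))
  first <- load_slide(manifest$path[1])
  structure(list(manifest = manifest, slides = NULL,
                 grid = dim(first$patch_labels),
                 patch_size = first$patch_size,
                 params = NULL, seed = NA_integer_, dir = dir),
            class = "slide_dataset")
}

#' Fetch one slide of a dataset
#'
#' @param dataset A `slide_dataset`.
#' @param i Row index or slide id.
#' @return A `synthetic_slide`, from memory or from disk.
#' @export
get_slide <- function(dataset, i) {
  if (is.character(i)) i <- match(i, dataset$manifest$slide_id)
  if (is.na(i) || i < 1 || i > nrow(dataset$manifest)) {
    stop("slide not found", call. = FALSE)
  }
  if (!is.null(dataset$slides)) return(dataset$slides[[i]])
  load_slide(dataset$manifest$path[i])
}

#' Per-grade-group slide counts and percentages of a manifest
#'
#' The bookkeeping a study table reports: per-class counts with their share
#' of the dataset, optionally split by a grouping column, plus the total row.
#'
#' @param manifest Data frame with a `grade_group` column (0..5).
#' @param by Optional additional grouping column name (e.g. `"split"`).
#' @return Tibble with columns `grade_group`, `n`, `percent` (0-100, one
#'   decimal as conventionally printed), plus `by` when requested.
#' @export
summarize_manifest <- function(manifest, by = NULL) {
  stopifnot("grade_group" %in% names(manifest))
  grp <- c(by, "grade_group")
  out <- manifest |>
    dplyr::count(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(percent = round(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::ungroup()
  out
}
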