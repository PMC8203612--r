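test_that("patch rendering is deterministic and class-structured", {
  expect_identical(make_patch("benign", 64, seed = 0),
                   make_patch("benign", 64, seed = 0))
  expect_error(make_patch("gp6", 64), "unknown pattern")
  p <- make_patch("gp3", 48, seed = 2)
  expect_equal(dim(p), c(48, 48, 3))
  expect_true(all(p >= 0 & p <= 1))

  # density ordering: small-gland pattern 3 has at least as many foreground
  # components as fused pattern 4 under matched seeds
  for (sd in 1:6) {
    n3 <- patch_statistics(make_patch("gp3", 64, seed = sd))$n_components
    n4 <- patch_statistics(make_patch("gp4", 64, seed = sd))$n_components
    expect_gte(n3, n4)
  }

  # sheet pattern 5 covers at least the configured minimum
  params <- texture_params()
  for (sd in 1:4) {
    fg <- patch_statistics(make_patch("gp5", 64, seed = sd))$fg_fraction
    expect_gte(fg, params$gp5$coverage[1] * 0.9) # clamp/noise margin
  }
})

test_that("component counts agree with an independent labelling oracle", {
  skip_if_not_installed("EBImage")
  for (sd in 1:4) {
    for (cl in c("benign", "gp3", "gp4")) {
      img <- make_patch(cl, 64, seed = sd)
      fg <- gleasonmil:::patch_foreground(img)
      mine <- gleasonmil:::label_components(fg)
      ref <- EBImage::bwlabel(fg)
      # same partition: component count and size multiset
      expect_equal(max(mine), max(ref))
      expect_equal(sort(tabulate(mine[mine > 0])),
                   sort(tabulate(ref[ref > 0])))
    }
  }
})

test_that("slides realize requested compositions by largest remainder", {
  s <- make_slide(c(benign = 0.5, gp3 = 0.25, gp4 = 0.25), grid = c(4, 16),
                  patch_size = 32, seed = 3)
  counts <- table(factor(s$patch_labels, levels = pattern_classes()))
  expect_equal(as.integer(counts), c(32L, 16L, 16L, 0L))
  # 16/16 is an exact tie: the worse pattern is primary, so 4+3 -> GG3
  expect_identical(s$grade_group, 3L)
  # an unambiguous majority of pattern 3 gives 3+4 -> GG2
  s2 <- make_slide(c(benign = 0.5, gp3 = 0.3125, gp4 = 0.1875),
                   grid = c(4, 16), patch_size = 32, seed = 3)
  expect_identical(s2$grade_group, 2L)
  expect_equal(dim(s$image), c(4 * 32, 16 * 32, 3))

  b <- make_slide(c(benign = 1), grid = c(4, 16), patch_size = 32, seed = 1)
  expect_true(all(b$patch_labels == "benign"))
  expect_identical(b$grade_group, 0L)

  g4 <- make_slide(c(gp4 = 1), grid = c(1, 8), patch_size = 32, seed = 2)
  expect_identical(g4$grade_group, 4L)

  # unreachable fraction: warning and realized composition recorded
  expect_warning(
    tiny <- make_slide(c(benign = 0.99, gp5 = 0.01), grid = c(2, 2),
                       patch_size = 32, seed = 4),
    "rounded to 0")
  expect_equal(tiny$composition[["gp5"]], 0)
  expect_identical(tiny$grade_group, 0L)

  # determinism
  expect_identical(make_slide(c(gp3 = 1), grid = c(2, 4), patch_size = 32,
                              seed = 9)$image,
                   make_slide(c(gp3 = 1), grid = c(2, 4), patch_size = 32,
                              seed = 9)$image)
})

test_that("cancer patches form contiguous runs in scan order", {
  withr::with_seed(31, {
    for (i in 1:10) {
      s <- make_slide(sample_composition(sample(1:5, 1), seed = i),
                      grid = c(4, 8), patch_size = 32, seed = i)
      scan <- as.vector(t(s$patch_labels))
      cancer <- scan %in% c("gp3", "gp4", "gp5")
      runs <- rle(cancer)
      expect_lte(sum(runs$values), 1) # a single cancer run
    }
  })
})

test_that("every generated slide satisfies label consistency", {
  ds <- make_dataset(24, seed = 11, grid = c(2, 6), patch_size = 32)
  for (s in ds$slides) {
    expect_identical(
      s$grade_group,
      composition_to_grade_group(composition_from_label_grid(s$patch_labels)))
  }
})

test_that("datasets honor class mix, splits and determinism", {
  ds <- make_dataset(70, seed = 5, grid = c(2, 4), patch_size = 32)
  expect_equal(nrow(ds$manifest), 70)
  counts <- table(factor(ds$manifest$grade_group, levels = 0:5))
  expect_true(all(counts %in% c(11, 12)))
  expect_setequal(unique(ds$manifest$split), c("train", "tune", "validate"))
  # stratification: every class present in train
  expect_setequal(unique(ds$manifest$grade_group[ds$manifest$split == "train"]),
                  0:5)

  ds7 <- make_dataset(7, seed = 5, grid = c(2, 4), patch_size = 32)
  expect_setequal(unique(ds7$manifest$grade_group), 0:5)

  m1 <- make_dataset(20, seed = 9, grid = c(2, 4), patch_size = 32)$manifest
  m2 <- make_dataset(20, seed = 9, grid = c(2, 4), patch_size = 32)$manifest
  expect_identical(m1, m2)
})

test_that("disk-backed datasets round-trip through PNG + sidecar", {
  dir <- withr::local_tempdir()
  ds <- make_dataset(8, seed = 3, grid = c(2, 4), patch_size = 32, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  s1 <- get_slide(ds, 1)
  expect_s3_class(s1, "synthetic_slide")
  mem <- make_dataset(8, seed = 3, grid = c(2, 4), patch_size = 32)
  # PNG quantizes to 8 bits; labels and grade groups are exact
  expect_identical(s1$patch_labels, mem$slides[[1]]$patch_labels)
  expect_identical(s1$grade_group, mem$slides[[1]]$grade_group)
  expect_lt(max(abs(s1$image - mem$slides[[1]]$image)), 1 / 255)

  # byte-identical manifests for identical calls (paths normalized)
  dir2 <- withr::local_tempdir()
  make_dataset(8, seed = 3, grid = c(2, 4), patch_size = 32, dir = dir2)
  expect_identical(
    gsub(dir, "", readLines(file.path(dir, "manifest.csv")), fixed = TRUE),
    gsub(dir2, "", readLines(file.path(dir2, "manifest.csv")), fixed = TRUE))
})

test_that("hand-crafted statistics separate the four classes", {
  withr::with_seed(77, {
    feats <- function(seeds) {
      purrr::map_dfr(pattern_classes(), function(cl) {
        purrr::map_dfr(seeds, function(sd) {
          st <- patch_statistics(make_patch(cl, 64,
                                            seed = derive_seed(sd, cl)))
          st$class <- cl
          st
        })
      })
    }
    train <- feats(1:30)
    test <- feats(101:130)
    vars <- c("fg_fraction", "n_components", "mean_component_size")
    mu <- train |>
      dplyr::group_by(class) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(vars), mean))
    sds <- vapply(vars, function(v) stats::sd(train[[v]]), 0)
    pred <- vapply(seq_len(nrow(test)), function(i) {
      z <- vapply(seq_len(nrow(mu)), function(j) {
        sum(((as.numeric(test[i, vars]) - as.numeric(mu[j, vars])) / sds)^2)
      }, 0)
      mu$class[which.min(z)]
    }, "")
    acc <- mean(pred == test$class)
    expect_gt(acc, 0.9)
  })
})

test_that("manifest summaries report counts and percentages", {
  m <- tibble::tibble(grade_group = rep(0:5, c(10, 4, 3, 2, 1, 0)))
  sm <- summarize_manifest(m)
  expect_equal(sm$n, c(10, 4, 3, 2, 1))
  expect_equal(sm$percent, round(100 * sm$n / 20, 1))
})
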