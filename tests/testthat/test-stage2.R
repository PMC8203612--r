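test_that("the grader accepts maps of the configured geometry", {
  cfg <- stage2_config(feature_dim = 8, trunk_width = 8, n_blocks = 2,
                       canvas = c(8, 16), seed = 61)
  m <- build_stage2(cfg)
  x <- array(stats::rnorm(8 * 16 * 8), c(8, 16, 8, 1))
  out <- gleasonmil:::net_forward(m$layers, x, training = FALSE)$out
  expect_equal(dim(out), c(6, 1))

  # all-fill map: finite logits
  zero <- array(0, c(8, 16, 8, 1))
  oz <- gleasonmil:::net_forward(m$layers, zero, training = FALSE)$out
  expect_true(all(is.finite(oz)))

  expect_error(stage2_config(front_widths = c(0, 1, 2, 3, 4)), "positive")
  expect_error(stage2_config(class_weights = c(1, 1)), "length")
})

test_that("default configuration matches the stated recipe", {
  cfg <- stage2_config()
  expect_equal(cfg$class_weights, c(1, 1, 1.5, 1.4, 1.7, 1.6))
  expect_equal(cfg$n_blocks, 16L)
  expect_equal(cfg$trunk_width, 128L)
  expect_equal(length(cfg$front_widths), 5)
  expect_equal(cfg$lr, 0.1)
  expect_equal(cfg$lr_step, 40L)
  expect_equal(cfg$epochs, 150L)
  expect_equal(cfg$batch_size, 256L)
  expect_equal(cfg$n_classes, 6L)
})

# a small feature dataset built from random grids with composition-coded
# class structure (cheap stand-in for real stage-1 features)
fake_fdata <- function(n = 20, seed = 62, feature_dim = 6) {
  withr::with_seed(seed, {
    gg <- rep(0:5, length.out = n)
    grids <- lapply(gg, function(g) {
      arr <- array(stats::rnorm(4 * 8 * feature_dim, mean = 0, sd = 0.1),
                   c(4, 8, feature_dim))
      arr[, , 1] <- arr[, , 1] + g / 5
      arr
    })
    # stratified split: the last slide of each class tunes
    split <- rep("train", n)
    for (g in 0:5) split[max(which(gg == g))] <- "tune"
    structure(list(
      grids = grids,
      tissue = replicate(n, matrix(TRUE, 4, 8), simplify = FALSE),
      manifest = tibble::tibble(
        slide_id = sprintf("F%03d", seq_len(n)),
        grade_group = gg,
        split = split),
      feature_dim = feature_dim), class = "feature_dataset")
  })
}

test_that("training requires all six classes and a matching feature_dim", {
  fd <- fake_fdata()
  fd$manifest$grade_group[fd$manifest$grade_group == 3 &
                            fd$manifest$split == "train"] <- 2
  cfg <- stage2_config(feature_dim = 6, trunk_width = 8, n_blocks = 1,
                       epochs = 1, canvas = c(8, 16))
  expect_error(train_stage2(fd, cfg), "grade group 3")
  fd2 <- fake_fdata()
  cfg_bad <- stage2_config(feature_dim = 5, trunk_width = 8, n_blocks = 1,
                           epochs = 1, canvas = c(8, 16))
  expect_error(train_stage2(fd2, cfg_bad), "feature_dim mismatch")
})

test_that("two training runs with one seed produce identical logs", {
  fd <- fake_fdata()
  cfg <- stage2_config(feature_dim = 6, trunk_width = 8, n_blocks = 2,
                       epochs = 3, batch_size = 8, canvas = c(8, 16),
                       seed = 63)
  m1 <- train_stage2(fd, cfg)
  m2 <- train_stage2(fd, cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$layers, m2$layers)
})

test_that("predictions are proper distributions and validate channels", {
  fd <- fake_fdata()
  cfg <- stage2_config(feature_dim = 6, trunk_width = 8, n_blocks = 2,
                       epochs = 2, batch_size = 8, canvas = c(8, 16),
                       seed = 64)
  m <- train_stage2(fd, cfg)
  pg <- extract_patches(array(0.4, c(64, 128, 3)), 32) # 2 x 4 grid
  fmap <- assemble_feature_map(matrix(stats::rnorm(8 * 6), 8, 6), pg,
                               canvas = c(8, 16))
  pred <- predict_grade_group(m, fmap)
  expect_equal(sum(pred$probabilities), 1, tolerance = 1e-12)
  expect_true(all(pred$probabilities >= 0))
  expect_equal(pred$predicted, unname(which.max(pred$probabilities) - 1L))

  # invariant to re-serialization of the map
  path <- tempfile(fileext = ".fmap")
  write_feature_map(fmap, path)
  pred2 <- predict_grade_group(m, read_feature_map(path))
  expect_identical(pred$probabilities, pred2$probabilities)

  bad <- assemble_feature_map(matrix(stats::rnorm(8 * 5), 8, 5), pg,
                              canvas = c(8, 16))
  expect_error(predict_grade_group(m, bad), "channel mismatch")

  # rotation invariance is not architectural: once the trunk has trained
  # spatial weights, a 180-degree-rotated map scores differently
  rot <- fmap
  rot$values <- fmap$values[8:1, 16:1, , drop = FALSE]
  pred_rot <- predict_grade_group(m, rot)
  expect_false(isTRUE(all.equal(pred$probabilities, pred_rot$probabilities)))
})

test_that("grid placement and augmentation preserve content geometry", {
  withr::with_seed(65, {
    arr <- array(stats::rnorm(3 * 5 * 2), c(3, 5, 2))
    tis <- matrix(TRUE, 3, 5)
    canvas <- c(8, 16)
    placed <- gleasonmil:::place_on_canvas(arr, tis, canvas)
    expect_equal(placed[1:3, 1:5, ], arr)
    expect_equal(sum(placed != 0), sum(arr != 0))
    shifted <- gleasonmil:::place_on_canvas(arr, tis, canvas, offset = c(2, 3))
    expect_equal(shifted[2 + 1:3, 3 + 1:5, ], arr)
    # negative shifts crop rows off the canvas edge
    cropped <- gleasonmil:::place_on_canvas(arr, tis, canvas, offset = c(-1, 0))
    expect_equal(cropped[1:2, 1:5, ], arr[2:3, , ])
    # flips/rotations preserve the value multiset
    for (i in 1:5) {
      aug <- gleasonmil:::augment_grid(arr, tis, canvas,
                                       list(shift = 0, vflip = TRUE,
                                            rot90 = TRUE))
      expect_equal(sort(as.numeric(aug)[aug != 0]), sort(as.numeric(arr)))
    }
  })
})
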