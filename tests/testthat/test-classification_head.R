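test_that("concatenation upsamples to the finest grid and stacks channels", {
  bb <- make_test_backbone(5L, channels = 4L)
  img <- array(runif(256 * 256 * 3), c(256, 256, 3))
  pyr <- extract_pyramid(img, bb)

  all5 <- build_concatenated_block(pyr, c("P3", "P4", "P5", "P6", "P7"))
  expect_identical(dim(all5), c(32L, 32L, 20L)) # 5 levels x channel width

  single <- build_concatenated_block(pyr, "P6")
  expect_identical(single[, , ], pyr$levels$P6[, , ])

  mix <- build_concatenated_block(pyr, c("P3", "P6", "P7"))
  expect_identical(dim(mix), c(32L, 32L, 12L))
  # nearest-neighbour: the P7 part is an 16x-replicated copy of the 2x2 map
  expect_equal(mix[1:16, 1:16, 9], matrix(pyr$levels$P7[1, 1, 1], 16, 16))

  expect_error(build_concatenated_block(list(levels = pyr$levels["P3"]), "P5"),
               "P5")
})

test_that("forward pass is the affine GAP map", {
  h <- classifier_head(matrix(0, 8, 2), c(0.3, -0.2), "P3", c(4L, 4L))
  fw <- head_forward(h, array(0, c(4, 4, 8)))
  expect_equal(fw$logits, c(0.3, -0.2))
  expect_equal(sum(fw$probs), 1, tolerance = 1e-9)

  # zero weights and biases: exact symmetry
  h0 <- classifier_head(matrix(0, 8, 2), c(0, 0), "P3", c(4L, 4L))
  expect_equal(head_forward(h0, random_block(c(4L, 4L), 8))$probs, c(0.5, 0.5))

  # replication invariance of mean pooling
  set.seed(1)
  blk <- random_block(c(4L, 4L), 8)
  blk2 <- fpncam:::upsample_nearest(blk, 8L, 8L)
  hr <- random_head(8, grid = c(4L, 4L))
  hr2 <- classifier_head(hr$w, hr$b, hr$levels, c(8L, 8L))
  expect_equal(head_forward(hr, blk)$logits, head_forward(hr2, blk2)$logits,
               tolerance = 1e-12)

  # affinity: logits(sum of blocks) = logits(a) + logits(b) - bias
  a <- random_block(c(4L, 4L), 8)
  b <- random_block(c(4L, 4L), 8)
  expect_equal(
    head_forward(hr, a + b)$logits,
    head_forward(hr, a)$logits + head_forward(hr, b)$logits - hr$b,
    tolerance = 1e-5
  )

  expect_error(head_forward(hr, array(0, c(5, 4, 8))), "grid")
  expect_error(head_forward(hr, array(0, c(4, 4, 7))), "channels")
})

test_that("training is seeded, head-only, and a no-op at zero learning rate", {
  st <- small_study()
  # reproducibility
  cfg <- head_config(c("P3", "P6"), seed = 9L, epochs = 50L)
  h1 <- train_head(cfg, st$train, st$backbone)
  h2 <- train_head(cfg, st$train, st$backbone)
  expect_identical(h1$w, h2$w)
  expect_identical(h1$b, h2$b)

  # zero learning rate: optimizer never moves, epochs are irrelevant
  z1 <- train_head(head_config("P6", seed = 3L, learning_rate = 0, epochs = 2L),
                   st$train, st$backbone)
  z2 <- train_head(head_config("P6", seed = 3L, learning_rate = 0, epochs = 40L),
                   st$train, st$backbone)
  expect_equal(z1$w, z2$w, tolerance = 1e-12)
  expect_equal(z1$b, z2$b, tolerance = 1e-12)
  moved <- train_head(head_config("P6", seed = 3L, epochs = 40L),
                      st$train, st$backbone)
  expect_gt(max(abs(moved$w - z1$w)), 0)

  # frozen backbone: probe features identical before and after training
  probe <- generate_sample(77L, 0L)$image
  before <- extract_pyramid(probe, st$backbone)$levels
  invisible(train_head(head_config("P7", seed = 1L, epochs = 30L),
                       st$train, st$backbone))
  expect_identical(extract_pyramid(probe, st$backbone)$levels, before)

  # degenerate datasets are refused
  one_class <- lapply(1:6, function(i) generate_sample(i, 1L))
  expect_error(train_head(head_config("P6"), one_class, st$backbone),
               "each class")
})

test_that("the trained head separates the synthetic classes", {
  st <- small_study()
  rep <- evaluate_head(st$head, st$test, st$backbone)
  expect_gte(rep$accuracy, 0.85)
  expect_identical(sum(rep$confusion), nrow(rep$per_image))
  # cached pooled features give the identical report
  fte <- precompute_features(st$test, st$backbone)
  rep2 <- evaluate_head(st$head, st$test, st$backbone, features = fte)
  expect_equal(rep$accuracy, rep2$accuracy)
  expect_equal(rep$per_image$score, rep2$per_image$score, tolerance = 1e-12)
})

test_that("evaluation metrics follow exact confusion arithmetic", {
  true <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0) # TP3 FN1 FP1 TN5
  r <- fpncam:::report_from_predictions(paste0("i", 1:10), true, pred, pred)
  expect_equal(r$accuracy, 0.8)
  expect_equal(r$f1, 0.75)
  expect_identical(as.integer(r$confusion), c(5L, 1L, 1L, 3L))

  perfect <- fpncam:::report_from_predictions(paste0("i", 1:10), true, true, true)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)

  # all predicted negative with positives present: F1 0, with a warning
  expect_warning(
    none <- fpncam:::report_from_predictions(paste0("i", 1:10), true,
                                             rep(0, 10), rep(0, 10)),
    "F1"
  )
  expect_equal(none$f1, 0)
  expect_equal(none$accuracy, 0.6)
})

test_that("head checkpoints round-trip through JSON", {
  st <- small_study()
  path <- tempfile(fileext = ".json")
  save_head(st$head, path)
  back <- load_head(path)
  expect_equal(back$w, st$head$w, tolerance = 1e-12)
  expect_equal(back$b, st$head$b, tolerance = 1e-12)
  expect_identical(back$levels, st$head$levels)
  expect_identical(back$target_grid, st$head$target_grid)
  blk <- build_concatenated_block(
    extract_pyramid(generate_sample(2L, 1L)$image, st$backbone), st$head$levels
  )
  expect_equal(head_forward(back, blk)$logits, head_forward(st$head, blk)$logits,
               tolerance = 1e-10)
  unlink(path)
})

test_that("the multi-scale head is at least as accurate as single levels", {
  # statistical ranking over seeds: mean accuracy of {P3,P6,P7} vs each
  # single-level head on datasets whose lesion spans several strides
  sets <- list("P3", "P4", "P5", "P6", "P7", c("P3", "P6", "P7"))
  accs <- matrix(0, 5, length(sets))
  for (k in 1:5) {
    man <- generate_dataset(c(73, 30), seed = 600L + k)
    bb <- make_test_backbone(800L + k, channels = 16L)
    ftr <- precompute_features(manifest_split(man, "train"), bb)
    fte <- precompute_features(manifest_split(man, "test"), bb)
    for (j in seq_along(sets)) {
      h <- train_head(head_config(sets[[j]], seed = k, epochs = 8000L),
                      manifest_split(man, "train"), bb, features = ftr)
      accs[k, j] <- suppressWarnings(
        evaluate_head(h, manifest_split(man, "test"), bb, features = fte)
      )$accuracy
    }
  }
  mean_acc <- colMeans(accs)
  for (j in 1:5) expect_gte(mean_acc[6], mean_acc[j])
})
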