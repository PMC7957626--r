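test_that("cam computes the weighted feature sum per class", {
  # single channel, unit weight: map equals the feature map
  h1 <- classifier_head(matrix(c(1, 0), 1, 2), c(0, 0), "P3", c(2L, 2L))
  f <- array(matrix(c(3, -1, 2, 0.5), 2, 2), c(2, 2, 1))
  expect_equal(cam(h1, f, 1L)$values, f[, , 1])

  # two channels, hand arithmetic
  h2 <- classifier_head(matrix(c(0.5, 1.0), 2, 1), 0, "P3", c(2L, 2L))
  blk <- array(0, c(2, 2, 2))
  blk[, , 1] <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)
  blk[, , 2] <- matrix(c(0, 2, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(cam(h2, blk, 1L)$values,
               matrix(c(0.5, 2.0, 0.0, 0.0), 2, 2, byrow = TRUE))

  expect_error(cam(h1, f, 3L), "class_index")
  expect_error(cam(h1, array(0, c(2, 2, 4)), 1L), "channels")
})

test_that("cam satisfies the completeness identity", {
  set.seed(42)
  for (rep in 1:20) {
    K <- sample(c(4L, 16L, 48L), 1)
    grid <- c(sample(2:9, 1), sample(2:9, 1))
    h <- random_head(K, grid = grid)
    blk <- random_block(grid, K)
    fw <- head_forward(h, blk)
    for (cls in 1:2) {
      expect_equal(mean(cam(h, blk, cls)$values), fw$logits[cls] - h$b[cls],
                   tolerance = 1e-5)
    }
  }
})

test_that("brute-force relevance responds only where features live", {
  set.seed(7)
  h <- random_head(6, grid = c(3L, 3L))
  zero <- array(0, c(3, 3, 6))
  expect_true(all(crm_bruteforce(h, zero)$values == 0))

  one_loc <- zero
  one_loc[2, 3, ] <- rnorm(6)
  m <- crm_bruteforce(h, one_loc)$values
  expect_gt(m[2, 3], 0)
  expect_equal(sum(m != 0), 1L)
})

test_that("closed-form relevance equals the zero-out oracle", {
  set.seed(31)
  for (rep in 1:20) {
    K <- sample(c(3L, 8L, 24L), 1)
    grid <- c(sample(2:8, 1), sample(2:8, 1))
    h <- random_head(K, grid = grid)
    blk <- random_block(grid, K)
    bf <- crm_bruteforce(h, blk)$values
    cf <- crm_closed_form(h, blk)$values
    expect_lt(max(abs(bf - cf)) / max(abs(bf)), 1e-5)
  }
})

test_that("relevance limits match the closed form", {
  set.seed(5)
  # single-location limit: CRM = sum of squared CAMs
  h <- random_head(10, grid = c(1L, 1L))
  blk <- random_block(c(1L, 1L), 10)
  cams2 <- cam(h, blk, 1L)$values^2 + cam(h, blk, 2L)$values^2
  expect_equal(crm_closed_form(h, blk)$values, cams2, tolerance = 1e-8)

  # homogeneity: scaling weights by t scales the map by t^2
  h1 <- random_head(6, grid = c(4L, 4L))
  h1$b <- c(0, 0)
  h3 <- classifier_head(3 * h1$w, h1$b, h1$levels, h1$target_grid)
  blk <- random_block(c(4L, 4L), 6)
  expect_equal(crm_closed_form(h3, blk)$values,
               9 * crm_closed_form(h1, blk)$values, tolerance = 1e-8)

  # antisymmetric two-class weights: CRM = 2 (CAM_2 / HW)^2
  wa <- matrix(rnorm(12), 6, 2)
  wa[, 1] <- -wa[, 2]
  ha <- classifier_head(wa, c(0, 0), "P3", c(4L, 4L))
  expect_equal(crm_closed_form(ha, blk)$values,
               2 * (cam(ha, blk, 2L)$values / 16)^2, tolerance = 1e-8)

  # non-negativity on random inputs
  expect_true(all(crm_closed_form(h1, blk)$values >= 0))
})

test_that("heatmap rendering thresholds, rescales and upsamples correctly", {
  m <- matrix(c(10, 5, 2.5, 1.9, 1, 0, -3, 0.4, 8), 3, 3)
  hm <- render_heatmap(fpncam:::new_saliency_map(m, "CAM", 1L), c(48L, 48L), 0.20)
  # cells below 20% of max (2) and non-positive cells are zeroed
  expect_identical(hm$feature_roi, m >= 2)
  # survivors span 1..255 with the max at 255
  surv <- hm$feature_values[hm$feature_roi]
  expect_identical(max(surv), 255L)
  expect_identical(min(surv), 1L)
  expect_true(all(hm$feature_values[!hm$feature_roi] == 0L))
  # rendered output: input resolution, max exactly 255, zero outside RoI
  expect_identical(dim(hm$values), c(48L, 48L))
  expect_identical(max(hm$values), 255L)
  expect_true(all(hm$values[!hm$roi_mask] == 0L))

  # constant positive map: everything survives at 255
  cm <- render_heatmap(fpncam:::new_saliency_map(matrix(4, 2, 2), "CAM", 1L),
                       c(8L, 8L))
  expect_true(all(cm$feature_values == 255L))

  # all non-positive map: empty RoI with a warning, not an error
  expect_warning(
    em <- render_heatmap(fpncam:::new_saliency_map(matrix(-1, 3, 3), "CAM", 1L),
                         c(12L, 12L)),
    "no positive"
  )
  expect_identical(sum(em$roi_mask), 0L)
})

test_that("lowering the threshold only grows the region of interest", {
  set.seed(12)
  for (rep in 1:10) {
    m <- matrix(rnorm(64, mean = 0.3), 8, 8)
    sm <- fpncam:::new_saliency_map(m, "CRM", "class-agnostic")
    h20 <- render_heatmap(sm, c(64L, 64L), 0.20)
    h15 <- render_heatmap(sm, c(64L, 64L), 0.15)
    expect_true(all(h15$feature_roi[h20$feature_roi]))
    expect_true(all(h15$roi_mask[h20$roi_mask]))
  }
})

test_that("RoI fractions and the CRM-vs-CAM comparison are exact ratios", {
  mk <- function(n_hot, grid = 20L) {
    m <- matrix(0, grid, grid)
    m[seq_len(n_hot)] <- 10
    render_heatmap(fpncam:::new_saliency_map(m, "CAM", 1L),
                   c(grid * 4L, grid * 4L))
  }
  expect_equal(roi_fraction(mk(100L)), 0.25)
  expect_equal(compare_roi(mk(100L), mk(100L)), 0)
  expect_equal(compare_roi(mk(80L), mk(100L)), 0.20)
  expect_message(
    expect_true(is.na(compare_roi(mk(80L), suppressWarnings(mk(0L))))),
    "undefined"
  )
})

test_that("the pointing game scores peaks against the dilated mask", {
  m <- matrix(0, 8, 8)
  m[4, 5] <- 3
  hm <- render_heatmap(fpncam:::new_saliency_map(m, "CRM", "class-agnostic"),
                       c(64L, 64L))
  mask <- matrix(FALSE, 64, 64)
  mask[25:34, 33:42] <- TRUE # covers the upsampled peak
  expect_true(pointing_game(hm, mask))
  far <- matrix(FALSE, 64, 64)
  far[1:4, 1:4] <- TRUE
  expect_false(pointing_game(hm, far))

  # an all-zero heatmap never scores a hit
  zero_hm <- suppressWarnings(
    render_heatmap(fpncam:::new_saliency_map(matrix(-1, 8, 8), "CRM", 1L),
                   c(64L, 64L))
  )
  expect_false(pointing_game(zero_hm, mask))

  expect_error(pointing_game(hm, matrix(FALSE, 64, 64)), "empty")
  expect_error(pointing_game(hm, matrix(TRUE, 10, 10)), "size")
})

test_that("heatmap PNG writers produce grayscale and overlay files", {
  st <- small_study()
  s <- get_sample(st$test, 1)
  blk <- build_concatenated_block(extract_pyramid(s$image, st$backbone),
                                  st$head$levels)
  hm <- render_heatmap(crm_closed_form(st$head, blk), dim(s$image)[1:2])
  g <- tempfile(fileext = ".png")
  o <- tempfile(fileext = ".png")
  write_heatmap_png(hm, g)
  write_heatmap_png(hm, o, image = s$image)
  expect_true(file.exists(g) && file.exists(o))
  gm <- png::readPNG(g)
  expect_identical(dim(gm), dim(hm$values))
  unlink(c(g, o))
})
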