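# GAP + fully connected softmax head over a selected / concatenated pyramid
# block, trained with a compiled SGD/Adam loop on frozen backbone features.

#' Head configuration
#'
#' @param levels Ordered subset of `P3`..`P7` (no duplicates) whose feature
#'   maps form the last convolutional block.
#' @param num_classes Number of output classes (default 2).
#' @param learning_rate SGD learning rate (default `1e-6`).
#' @param epochs Number of passes over the training split (default 20000); the
#'   returned head is the one from the best-validation epoch.
#' @param seed Seed for weight initialization, the validation split and the
#'   SGD shuffling.
#' @param val_frac Fraction of training images (at the woman level when woman
#'   ids are available) held out for best-epoch selection (default 0.2).
#' @param batch_size SGD minibatch size (default 1, i.e. stochastic
#'   gradient descent).
#' @param optimizer `"adam"` (default) or `"sgd"`. At the stated learning
#'   rate, plain SGD needs an impractical number of steps on these features;
#'   Adam's per-coordinate step normalization makes the small learning rate
#'   usable (see the methods vignette).
#' @return A `head_config` list.
#' @export
head_config <- function(levels, num_classes = 2L, learning_rate = 1e-6,
                        epochs = 20000L, seed = 1L, val_frac = 0.2,
                        batch_size = 1L, optimizer = c("adam", "sgd")) {
  optimizer <- match.arg(optimizer)
  levels <- as.character(levels)
  if (length(levels) == 0L) stop("levels must be a nonempty subset of P3..P7")
  if (anyDuplicated(levels)) stop("levels must not contain duplicates")
  level_stride(levels) # validates names
  structure(
    list(levels = levels, num_classes = as.integer(num_classes),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         seed = as.integer(seed), val_frac = val_frac,
         batch_size = as.integer(batch_size), optimizer = optimizer),
    class = "head_config"
  )
}

#' Build the concatenated last convolutional block
#'
#' Upsamples every selected pyramid level (nearest neighbour) to the spatial
#' size of the highest-resolution selected level and stacks them along the
#' channel axis in the given order. A single selected level is returned
#' unchanged.
#'
#' @param pyramid A `pyramid_features` object from [extract_pyramid()].
#' @param levels Character vector of level names to select, in stacking order.
#' @return `h x w x K` array with `K` the summed channel count; the selected
#'   level names are kept in `attr(, "levels")`.
#' @export
build_concatenated_block <- function(pyramid, levels) {
  levels <- as.character(levels)
  missing <- setdiff(levels, names(pyramid$levels))
  if (length(missing) > 0L) {
    stop("requested pyramid level(s) not present: ", paste(missing, collapse = ", "))
  }
  strides <- level_stride(levels)
  target <- levels[which.min(strides)]
  td <- dim(pyramid$levels[[target]])[1:2]
  parts <- lapply(levels, function(nm) {
    x <- pyramid$levels[[nm]]
    if (all(dim(x)[1:2] == td)) x else upsample_nearest(x, td[1], td[2])
  })
  k_tot <- sum(vapply(parts, function(x) dim(x)[3], integer(1)))
  block <- array(0, c(td[1], td[2], k_tot))
  at <- 0L
  for (p in parts) {
    kc <- dim(p)[3]
    block[, , (at + 1L):(at + kc)] <- p
    at <- at + kc
  }
  attr(block, "levels") <- levels
  block
}

#' Construct a classifier head from explicit parameters
#'
#' Builds the GAP + FC head object directly from a weight matrix and bias
#' vector, e.g. for testing saliency methods against hand-chosen weights.
#' [train_head()] is the usual way to obtain one.
#'
#' @param w `K x C` weight matrix (`w_kc`), rows = block channels, columns =
#'   classes.
#' @param b Length-`C` bias vector.
#' @param levels Pyramid level set the head expects.
#' @param target_grid `c(H_f, W_f)` spatial size of the concatenated block.
#' @return A `classifier_head`.
#' @export
classifier_head <- function(w, b, levels, target_grid) {
  w <- as.matrix(w)
  stopifnot(length(b) == ncol(w), length(target_grid) == 2L)
  structure(
    list(w = w, b = as.numeric(b), levels = as.character(levels),
         target_grid = as.integer(target_grid)),
    class = "classifier_head"
  )
}

new_classifier_head <- classifier_head

#' @export
print.classifier_head <- function(x, ...) {
  cat(sprintf(
    "<classifier_head> levels {%s}, K = %d channels, %d classes, grid %dx%d\n",
    paste(x$levels, collapse = ","), nrow(x$w), ncol(x$w),
    x$target_grid[1], x$target_grid[2]
  ))
  invisible(x)
}

# Global average pooling of a block: one mean per channel.
gap_pool <- function(block) {
  d <- dim(block)
  colMeans(matrix(block, d[1] * d[2], d[3]))
}

#' Forward pass of the GAP + FC head
#'
#' Computes `s_c = sum_k w_kc * mean_xy f_k(x, y) + b_c` followed by a
#' softmax. The pooling is the spatial mean, so the logits are invariant to
#' nearest-neighbour replication of the block.
#'
#' @param head A `classifier_head`.
#' @param block `h x w x K` feature block matching the head's `target_grid`
#'   and channel count.
#' @return List with `logits` (length C) and `probs` (softmax, sums to 1).
#' @export
head_forward <- function(head, block) {
  d <- dim(block)
  if (d[1] != head$target_grid[1] || d[2] != head$target_grid[2]) {
    stop(sprintf("block grid %dx%d does not match head target grid %dx%d",
                 d[1], d[2], head$target_grid[1], head$target_grid[2]))
  }
  if (d[3] != nrow(head$w)) {
    stop(sprintf("block has %d channels, head expects %d", d[3], nrow(head$w)))
  }
  pooled <- gap_pool(block)
  s <- as.vector(crossprod(head$w, pooled)) + head$b
  list(logits = s, probs = softmax(s))
}

#' Precompute per-level pooled features for a dataset
#'
#' Runs the backbone once per image and stores the per-level global average
#' pooled vectors, so that several head variants can be trained and evaluated
#' on one shared extraction pass. Because nearest-neighbour upsampling by an
#' integer factor preserves channel means exactly, the pooled vector of a
#' concatenated block is the concatenation of the per-level pooled vectors
#' whenever the target grid is an integer multiple of every selected level's
#' grid; [train_head()] and [evaluate_head()] verify this condition before
#' using the cache and refuse it otherwise.
#'
#' @param dataset Dataset (see [get_sample()]).
#' @param backbone Pyramid-producing callable.
#' @return A `pooled_level_features` object.
#' @export
precompute_features <- function(dataset, backbone) {
  n <- dataset_size(dataset)
  level_means <- NULL
  grids <- NULL
  y <- integer(n)
  for (i in seq_len(n)) {
    s <- get_sample(dataset, i)
    pyr <- extract_pyramid(s$image, backbone)
    if (is.null(level_means)) {
      grids <- lapply(pyr$levels, function(x) dim(x)[1:2])
      level_means <- lapply(pyr$levels, function(x) matrix(0, n, dim(x)[3]))
    }
    for (nm in names(pyr$levels)) {
      if (!all(dim(pyr$levels[[nm]])[1:2] == grids[[nm]])) {
        stop("all images in a dataset must share one size")
      }
      level_means[[nm]][i, ] <- gap_pool(pyr$levels[[nm]])
    }
    y[i] <- as.integer(s$label)
  }
  structure(
    list(level_means = level_means, grids = grids, y = y,
         ids = dataset_ids(dataset), woman_ids = dataset_woman_ids(dataset)),
    class = "pooled_level_features"
  )
}

select_pooled <- function(features, levels) {
  stopifnot(inherits(features, "pooled_level_features"))
  missing <- setdiff(levels, names(features$level_means))
  if (length(missing) > 0L) {
    stop("requested pyramid level(s) not present: ", paste(missing, collapse = ", "))
  }
  strides <- level_stride(levels)
  target <- features$grids[[levels[which.min(strides)]]]
  for (nm in levels) {
    g <- features$grids[[nm]]
    if (any(target %% g != 0L)) {
      stop("cached pooled features require integer-factor grids; ",
           nm, " grid does not divide the target grid")
    }
  }
  list(X = do.call(cbind, features$level_means[levels]), y = features$y,
       grid = target, ids = features$ids, woman_ids = features$woman_ids)
}

# Extract pooled block features for every image of a dataset. The backbone is
# called once per image; the head only ever sees the pooled vectors.
pooled_features <- function(dataset, backbone, levels) {
  n <- dataset_size(dataset)
  feats <- NULL
  grid <- NULL
  y <- integer(n)
  for (i in seq_len(n)) {
    s <- get_sample(dataset, i)
    pyr <- extract_pyramid(s$image, backbone)
    block <- build_concatenated_block(pyr, levels)
    if (is.null(feats)) {
      feats <- matrix(0, n, dim(block)[3])
      grid <- dim(block)[1:2]
    }
    if (!all(dim(block)[1:2] == grid)) {
      stop("all images in a dataset must share one size (block grids differ)")
    }
    feats[i, ] <- gap_pool(block)
    y[i] <- as.integer(s$label)
  }
  list(X = feats, y = y, grid = grid)
}

#' Train the head on frozen pyramid features
#'
#' Extracts and pools block features for every training image (the backbone
#' is fixed and never updated) and fits the fully connected softmax layer by
#' plain minibatch SGD on the cross-entropy loss over the raw pooled
#' features. A woman-level validation split selects the best epoch.
#'
#' @param config A [head_config()].
#' @param dataset Training dataset (see [get_sample()] for supported forms);
#'   must contain at least one example of each class.
#' @param backbone Pyramid-producing callable.
#' @param features Optional `pooled_level_features` from
#'   [precompute_features()] for this dataset, to share one extraction pass
#'   across several head variants.
#' @return A `classifier_head` with attributes `history` (per-epoch validation
#'   cross-entropy) and `best_epoch` (the validation-loss minimizer whose
#'   weights are returned).
#' @export
train_head <- function(config, dataset, backbone, features = NULL) {
  stopifnot(inherits(config, "head_config"))
  pf <- if (is.null(features)) {
    pooled_features(dataset, backbone, config$levels)
  } else {
    select_pooled(features, config$levels)
  }
  X <- pf$X
  y <- pf$y
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    stop("training dataset must contain at least one example of each class")
  }
  n <- nrow(X)
  K <- ncol(X)
  C <- config$num_classes

  # woman-level validation split for best-epoch selection
  wid <- if (is.null(features)) dataset_woman_ids(dataset) else pf$woman_ids
  val_idx <- with_seed(derive_seed(config$seed, 23L), {
    women <- unique(wid)
    vw <- sample(women, max(1L, round(config$val_frac * length(women))))
    which(wid %in% vw)
  })
  if (length(val_idx) == n || length(val_idx) == 0L) {
    val_idx <- seq_len(max(1L, floor(config$val_frac * n)))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(y[tr_idx])) < 2L) tr_idx <- seq_len(n)

  # Conditioning: center the pooled features and scale each channel by its
  # standard deviation, floored at 10% of the RMS channel scale. The floor
  # matters: near-constant (dead) channels would otherwise be amplified
  # enormously when the scaling is folded back into the weights, and the
  # folded weights are exactly what CAM and CRM read, so an unfloored
  # standardization corrupts the saliency maps. Centering folds into the
  # bias only.
  mu <- colMeans(X[tr_idx, , drop = FALSE])
  sdv <- apply(X[tr_idx, , drop = FALSE], 2, stats::sd)
  g <- pmax(sdv, 0.1 * max(sqrt(mean(sdv^2)), 1e-8))
  Z <- sweep(sweep(X, 2, mu), 2, g, "/")
  w0 <- with_seed(derive_seed(config$seed, 31L),
                  matrix(stats::rnorm(K * C, sd = 1e-3), K, C))
  b0 <- rep(0, C)
  res <- sgd_softmax_train(
    Z, as.integer(y), w0, b0,
    config$learning_rate, config$epochs, config$batch_size,
    as.integer(tr_idx - 1L), as.integer(val_idx - 1L),
    derive_seed(config$seed, 47L),
    if (identical(config$optimizer, "adam")) 1L else 0L
  )
  w_eff <- res$w / g
  b_eff <- as.vector(res$b - crossprod(res$w, mu / g))
  head <- new_classifier_head(w_eff, b_eff, config$levels, pf$grid)
  attr(head, "history") <- res$history
  attr(head, "best_epoch") <- res$best_epoch
  head
}

#' Evaluate a head on a dataset
#'
#' Class 1 ("not treatable") is the positive class: F1 is `2PR/(P+R)` for
#' that class, and the probability-0.5 tie predicts positive. A zero
#' denominator in precision, recall or F1 yields 0 with a warning.
#'
#' @param head A `classifier_head`.
#' @param dataset Evaluation dataset (nonempty).
#' @param backbone The same pyramid-producing callable used in training.
#' @param features Optional `pooled_level_features` cache for this dataset.
#' @return An `evaluation_report`: list with `accuracy`, `f1`, `confusion`
#'   (2x2 table, true x predicted) and `per_image` data frame
#'   (`id`, `true`, `predicted`, `score` = probability of class 1).
#' @export
evaluate_head <- function(head, dataset, backbone, features = NULL) {
  n <- dataset_size(dataset)
  if (n == 0L) stop("dataset is empty")
  pf <- if (is.null(features)) {
    pooled_features(dataset, backbone, head$levels)
  } else {
    select_pooled(features, head$levels)
  }
  s <- sweep(pf$X %*% head$w, 2, head$b, "+")
  p1 <- apply(s, 1, function(z) softmax(z)[2])
  pred <- ifelse(p1 >= 0.5, 1L, 0L)
  ids <- if (is.null(features)) dataset_ids(dataset) else pf$ids
  report_from_predictions(ids, pf$y, pred, p1)
}

report_from_predictions <- function(ids, true, pred, score) {
  confusion <- table(
    factor(true, levels = c(0, 1)),
    factor(pred, levels = c(0, 1)),
    dnn = c("true", "predicted")
  )
  tp <- confusion["1", "1"]
  fp <- confusion["0", "1"]
  fn <- confusion["1", "0"]
  tn <- confusion["0", "0"]
  accuracy <- (tp + tn) / sum(confusion)
  if (tp + fp == 0 || tp + fn == 0 || 2 * tp + fp + fn == 0) {
    if (tp == 0) {
      f1 <- 0
      warning("zero denominator in F1 (no positive predictions or no positives); reporting F1 = 0")
    } else {
      f1 <- 0
    }
  } else {
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    f1 <- 2 * prec * rec / (prec + rec)
  }
  structure(
    list(
      accuracy = as.numeric(accuracy), f1 = as.numeric(f1),
      confusion = confusion,
      per_image = data.frame(id = ids, true = true, predicted = pred,
                             score = score, stringsAsFactors = FALSE)
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d, accuracy = %.4f, F1 = %.4f\n",
              nrow(x$per_image), x$accuracy, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Save / load a head checkpoint
#'
#' Checkpoints are plain JSON (shapes plus weight values), so they survive
#' text-only round trips.
#'
#' @param head A `classifier_head`.
#' @param path File path for the JSON checkpoint.
#' @return `save_head()` returns `path` invisibly; `load_head()` returns the
#'   restored `classifier_head`.
#' @export
save_head <- function(head, path) {
  obj <- list(
    levels = head$levels, target_grid = head$target_grid,
    K = nrow(head$w), C = ncol(head$w),
    w = as.vector(head$w), b = head$b
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_head
#' @export
load_head <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_classifier_head(
    matrix(obj$w, obj$K, obj$C), obj$b, obj$levels, obj$target_grid
  )
}
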