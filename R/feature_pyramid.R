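# Pyramid-feature contract: levels P3..P7 at strides 8..128, one shared
# channel width, spatial size ceiling(input / stride) at every level.

#' Pyramid level names and strides
#'
#' The five pyramid levels used throughout the package, named `P3` to `P7`,
#' with stride `2^l` for level `l` (P3 is 8, P7 is 128). All levels of one
#' pyramid share a single channel width (256 for a full-size FPN backbone;
#' the bundled test backbone uses a smaller, configurable width).
#'
#' @return A data frame with columns `name` and `stride`.
#' @export
#' @examples
#' pyramid_level_specs()
pyramid_level_specs <- function() {
  data.frame(
    name = c("P3", "P4", "P5", "P6", "P7"),
    stride = c(8L, 16L, 32L, 64L, 128L),
    stringsAsFactors = FALSE
  )
}

level_stride <- function(name) {
  specs <- pyramid_level_specs()
  i <- match(name, specs$name)
  if (anyNA(i)) {
    stop("unknown pyramid level(s): ", paste(name[is.na(i)], collapse = ", "))
  }
  specs$stride[i]
}

#' Extract pyramid features from an image
#'
#' Runs a pyramid-producing backbone on an image and validates the result
#' against the pyramid contract: all five levels present, spatial size
#' `ceiling(input / stride)` at each level, one shared channel width.
#'
#' @param image Numeric `H x W x 3` array with values in `[0, 1]`; both sides
#'   must be at least 128 pixels so that P7 is non-empty.
#' @param backbone A pyramid-producing callable, e.g. from
#'   [make_test_backbone()]: a function taking the image and returning a named
#'   list of `h x w x channels` arrays for `P3`..`P7`.
#' @return A `pyramid_features` object: list with `levels` (named list of
#'   feature arrays), `input_size` (`c(H, W)`) and `channels`.
#' @export
extract_pyramid <- function(image, backbone) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("image must be an H x W x 3 array")
  }
  h <- dim(image)[1]
  w <- dim(image)[2]
  if (h < 128L) stop("image height ", h, " is below the 128-pixel minimum")
  if (w < 128L) stop("image width ", w, " is below the 128-pixel minimum")
  if (min(image) < 0 || max(image) > 1) {
    stop("image values must lie in [0, 1]; rescale first (see resize_longest_side)")
  }
  levels <- backbone(image)
  specs <- pyramid_level_specs()
  if (!all(specs$name %in% names(levels))) {
    stop("backbone must return all levels ", paste(specs$name, collapse = ", "))
  }
  levels <- levels[specs$name]
  ch <- vapply(levels, function(x) dim(x)[3], integer(1))
  if (length(unique(ch)) != 1L) {
    stop("all pyramid levels must share one channel width")
  }
  for (i in seq_len(nrow(specs))) {
    d <- dim(levels[[specs$name[i]]])
    eh <- ceiling(h / specs$stride[i])
    ew <- ceiling(w / specs$stride[i])
    if (d[1] != eh || d[2] != ew) {
      stop(sprintf(
        "level %s has size %dx%d, expected %dx%d (stride %d on %dx%d input)",
        specs$name[i], d[1], d[2], eh, ew, specs$stride[i], h, w
      ))
    }
  }
  structure(
    list(levels = levels, input_size = c(h, w), channels = ch[[1]]),
    class = "pyramid_features"
  )
}

#' @export
print.pyramid_features <- function(x, ...) {
  cat(sprintf(
    "<pyramid_features> input %dx%d, %d channels/level\n",
    x$input_size[1], x$input_size[2], x$channels
  ))
  for (nm in names(x$levels)) {
    d <- dim(x$levels[[nm]])
    cat(sprintf("  %s: %d x %d\n", nm, d[1], d[2]))
  }
  invisible(x)
}

#' Deterministic seeded test backbone
#'
#' A small strided convolutional stack standing in for a pretrained pyramid
#' backbone: seven 3x3 stride-2 convolutions with ReLU, emitting the feature
#' maps after layers 3..7 as levels `P3`..`P7` (strides 8..128). Weights are
#' He-initialized from `seed` and fixed: the returned closure is pure, so head
#' training can never update it.
#'
#' @param seed Integer seed fixing the weights.
#' @param channels Channel width of every emitted level (default 16; must be
#'   at least 2). Kept small so that tests run at desk scale.
#' @return A function `image -> named list of P3..P7 feature arrays`, suitable
#'   as the `backbone` argument of [extract_pyramid()].
#' @export
make_test_backbone <- function(seed, channels = 16L) {
  channels <- as.integer(channels)
  if (channels < 2L) stop("channels must be >= 2")
  cins <- c(3L, rep(channels, 6L))
  weights <- with_seed(derive_seed(seed, 101L), {
    lapply(seq_len(7L), function(i) {
      cin <- cins[i]
      list(
        w = array(stats::rnorm(9L * cin * channels, sd = sqrt(2 / (9 * cin))),
                  c(3L, 3L, cin, channels)),
        b = stats::rnorm(channels, sd = 0.05)
      )
    })
  })
  function(image) {
    x <- image
    out <- list()
    for (i in seq_len(7L)) {
      x <- relu(conv3x3_stride2(x, weights[[i]]$w, weights[[i]]$b))
      if (i >= 3L) out[[paste0("P", i)]] <- x
    }
    out
  }
}

#' Resize an image so its longer side matches a target length
#'
#' Resizes with bilinear interpolation so that the longer border equals
#' `target` pixels, preserving aspect ratio to within one pixel of rounding,
#' and rescales pixel values into `(0, 1)` (8-bit input is divided by 255).
#' Grayscale input is replicated to three channels.
#'
#' @param image `H x W x 3` array, `H x W` matrix (grayscale), or integer
#'   array with values in `[0, 255]`.
#' @param target Length in pixels of the longer output side (default 1200).
#' @return `H' x W' x 3` numeric array with values in `[0, 1]`.
#' @export
resize_longest_side <- function(image, target = 1200L) {
  if (target < 1) stop("target must be >= 1")
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  if (!is.array(image) || length(dim(image)) != 3L) {
    stop("image must be a matrix or an H x W x C array")
  }
  if (dim(image)[3] == 1L) image <- array(rep(image, 3L), c(dim(image)[1:2], 3L))
  if (dim(image)[1] == 0L || dim(image)[2] == 0L) stop("empty image")
  storage.mode(image) <- "double"
  if (max(image) > 1) image <- image / 255
  h <- dim(image)[1]
  w <- dim(image)[2]
  if (h >= w) {
    h_out <- as.integer(target)
    w_out <- max(1L, as.integer(round(w * target / h)))
  } else {
    w_out <- as.integer(target)
    h_out <- max(1L, as.integer(round(h * target / w)))
  }
  bilinear_resize_image(image, h_out, w_out)
}

#' Read an image file as an RGB array in [0, 1]
#'
#' Reads a PNG file; grayscale is replicated to three channels and any alpha
#' channel is dropped.
#'
#' @param path Path to a PNG file.
#' @return `H x W x 3` numeric array with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- png::readPNG(path)
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] == 2L) img <- array(rep(img[, , 1L], 3L), c(dim(img)[1:2], 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}
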