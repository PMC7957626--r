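# Gaussian-blur degradation harness: blur the evaluation images at a ladder
# of kernel sizes, re-run the frozen head and the saliency pipeline, and
# report how classification and localization decay.

#' Blur specification
#'
#' @param kernel Odd positive kernel side `k` (used as a `(k, k)` filter);
#'   a length-2 vector may be given but must be square.
#' @param sigma Gaussian standard deviation in pixels, or `"auto"` for the
#'   kernel-derived default `0.3 * ((k - 1) / 2 - 1) + 0.8` used by common
#'   vision libraries.
#' @return A `blur_spec` list.
#' @export
blur_spec <- function(kernel, sigma = "auto") {
  kernel <- as.integer(kernel)
  if (length(kernel) == 1L) kernel <- c(kernel, kernel)
  if (kernel[1] != kernel[2]) stop("only square kernels are supported")
  k <- kernel[1]
  if (k < 1L || k %% 2L == 0L) stop("kernel side must be odd and >= 1, got ", k)
  if (!identical(sigma, "auto")) {
    sigma <- as.numeric(sigma)
    if (!(sigma > 0)) stop("explicit sigma must be > 0")
  }
  structure(list(kernel = c(k, k), sigma = sigma), class = "blur_spec")
}

blur_sigma <- function(spec) {
  if (identical(spec$sigma, "auto")) {
    0.3 * ((spec$kernel[1] - 1) / 2 - 1) + 0.8
  } else {
    spec$sigma
  }
}

gaussian_kernel_1d <- function(k, sigma) {
  if (k == 1L) return(1)
  r <- (k - 1L) / 2L
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g / sum(g)
}

# Separable 1D convolution along rows then columns with symmetric (reflective)
# border handling; mass-conserving, so constants and total intensity are
# preserved.
convolve_separable <- function(m, g) {
  k <- length(g)
  if (k == 1L) return(m * g)
  r <- (k - 1L) / 2L
  reflect_idx <- function(n) c(r:1, seq_len(n), n:(n - r + 1L))
  # rows (vertical pass)
  pi_ <- reflect_idx(nrow(m))
  p <- m[pi_, , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_len(k)) {
    out <- out + g[j] * p[(j - 1L) + seq_len(nrow(m)), , drop = FALSE]
  }
  # columns (horizontal pass)
  pj <- reflect_idx(ncol(out))
  p <- out[, pj, drop = FALSE]
  out2 <- matrix(0, nrow(m), ncol(m))
  for (j in seq_len(k)) {
    out2 <- out2 + g[j] * p[, (j - 1L) + seq_len(ncol(m)), drop = FALSE]
  }
  out2
}

#' Gaussian-blur an image
#'
#' Separable Gaussian convolution with symmetric (reflective) borders; the
#' kernel is normalized, so constant images are unchanged and total intensity
#' is conserved. A `(1, 1)` kernel is an exact identity.
#'
#' @param image `H x W x C` array or `H x W` matrix.
#' @param spec A [blur_spec()]; its kernel must be smaller than the image.
#' @return Blurred image of the same size and shape.
#' @export
gaussian_blur <- function(image, spec) {
  stopifnot(inherits(spec, "blur_spec"))
  k <- spec$kernel[1]
  dims <- if (is.matrix(image)) dim(image) else dim(image)[1:2]
  if (k >= min(dims)) stop("kernel must be smaller than the image")
  g <- gaussian_kernel_1d(k, blur_sigma(spec))
  if (is.matrix(image)) return(convolve_separable(image, g))
  out <- image
  for (ch in seq_len(dim(image)[3])) {
    out[, , ch] <- convolve_separable(image[, , ch], g)
  }
  out
}

#' Run the quality-degradation suite
#'
#' Evaluates a head (already trained on unblurred images) on copies of the
#' dataset blurred at each requested level, re-running classification and the
#' CRM saliency pipeline, and reports per-level accuracy, F1, mean
#' pointing-game hit rate and mean RoI fraction. Levels are reported in
#' increasing kernel order; a `(1, 1)` identity level reproduces the
#' unblurred metrics exactly.
#'
#' @param head A trained `classifier_head`.
#' @param backbone The pyramid-producing callable the head was trained on.
#' @param dataset Evaluation dataset with ground-truth landmark masks.
#' @param specs List of [blur_spec()] objects.
#' @param threshold_frac Heatmap threshold (default 0.20).
#' @param tolerance_px Pointing-game tolerance (default 4).
#' @param include_saliency Compute the CRM heatmap metrics (default `TRUE`);
#'   disable for accuracy-only ladders.
#' @return A `degradation_report` data frame with one row per blur level:
#'   `kernel`, `sigma`, `accuracy`, `f1`, `hit_rate`, `mean_roi_fraction`
#'   (the last two `NA` when `include_saliency = FALSE`).
#' @export
run_degradation_suite <- function(head, backbone, dataset, specs,
                                  threshold_frac = 0.20, tolerance_px = 4,
                                  include_saliency = TRUE) {
  specs <- specs[order(vapply(specs, function(s) s$kernel[1], integer(1)))]
  n <- dataset_size(dataset)
  rows <- lapply(specs, function(spec) {
    true <- integer(n)
    pred <- integer(n)
    score <- numeric(n)
    hits <- logical(n)
    rois <- numeric(n)
    for (i in seq_len(n)) {
      s <- get_sample(dataset, i)
      img <- if (spec$kernel[1] == 1L) s$image else gaussian_blur(s$image, spec)
      pyr <- extract_pyramid(img, backbone)
      block <- build_concatenated_block(pyr, head$levels)
      fw <- head_forward(head, block)
      true[i] <- s$label
      score[i] <- fw$probs[2]
      pred[i] <- if (fw$probs[2] >= 0.5) 1L else 0L
      if (include_saliency) {
        hm <- render_heatmap(crm_closed_form(head, block), dim(img)[1:2],
                             threshold_frac)
        rois[i] <- roi_fraction(hm)
        hits[i] <- if (!is.null(s$landmark_mask)) {
          pointing_game(hm, s$landmark_mask, tolerance_px)
        } else {
          NA
        }
      } else {
        rois[i] <- NA_real_
        hits[i] <- NA
      }
    }
    rep_ <- report_from_predictions(dataset_ids(dataset), true, pred, score)
    data.frame(
      kernel = spec$kernel[1], sigma = blur_sigma(spec),
      accuracy = rep_$accuracy, f1 = rep_$f1,
      hit_rate = mean(hits, na.rm = TRUE),
      mean_roi_fraction = mean(rois)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("degradation_report", "data.frame")
  out
}
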