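# Saliency over the head's last convolutional block.
#
# CAM_c(x, y)  = sum_k w_kc f_k(x, y)                  (per class, signed)
# CRM(x, y)    = sum_c (s_c - s_c(x, y))^2             (class-agnostic, >= 0)
# where s_c(x, y) are the logits after zeroing the whole K-channel feature
# vector at location (x, y). Under mean pooling that zeroing shifts logit c by
# exactly -CAM_c(x, y) / (H_f * W_f), which gives the closed form
# CRM(x, y) = sum_c (CAM_c(x, y) / (H_f * W_f))^2, checked against the literal
# zero-out brute force in the tests.

new_saliency_map <- function(values, method, class_index) {
  structure(
    list(values = values, method = method, class_index = class_index,
         feature_grid = dim(values)),
    class = "saliency_map"
  )
}

#' Class activation map
#'
#' The per-class weighted sum of the block's feature maps using the head's
#' fully connected weights: `M_c(x, y) = sum_k w_kc f_k(x, y)`. No bias term;
#' values may be negative. Its spatial mean equals the class logit minus the
#' bias (completeness identity under mean pooling).
#'
#' @param head A `classifier_head`.
#' @param block Feature block matching the head (see [head_forward()]).
#' @param class_index Class index in `1..C` (1 = treatable, 2 = not treatable
#'   for the default two-class head).
#' @return A `saliency_map` with `method = "CAM"`.
#' @export
cam <- function(head, block, class_index) {
  d <- dim(block)
  if (d[3] != nrow(head$w)) {
    stop(sprintf("block has %d channels, head expects %d", d[3], nrow(head$w)))
  }
  C <- ncol(head$w)
  if (!(class_index %in% seq_len(C))) {
    stop("class_index must be in 1..", C)
  }
  m <- matrix(block, d[1] * d[2], d[3]) %*% head$w[, class_index]
  new_saliency_map(matrix(m, d[1], d[2]), "CAM", as.integer(class_index))
}

#' Class-selective relevance map, brute-force oracle
#'
#' Executes the relevance definition literally: for each location, zero the
#' full channel vector there, rerun the forward pass, accumulate the squared
#' logit change summed over all output classes, then restore the block. One
#' forward pass per location; intended as the oracle for
#' [crm_closed_form()].
#'
#' @inheritParams cam
#' @return A class-agnostic `saliency_map` with `method = "CRM"`.
#' @export
crm_bruteforce <- function(head, block) {
  d <- dim(block)
  base <- head_forward(head, block)$logits
  vals <- matrix(0, d[1], d[2])
  for (x in seq_len(d[1])) {
    for (y in seq_len(d[2])) {
      saved <- block[x, y, ]
      block[x, y, ] <- 0
      probed <- head_forward(head, block)$logits
      block[x, y, ] <- saved
      vals[x, y] <- sum((base - probed)^2)
    }
  }
  new_saliency_map(vals, "CRM", "class-agnostic")
}

#' Class-selective relevance map, closed form
#'
#' Exact closed form of [crm_bruteforce()] for a pure GAP + FC head:
#' `M(x, y) = sum_c (CAM_c(x, y) / (H_f * W_f))^2`.
#'
#' @inheritParams cam
#' @return A class-agnostic `saliency_map` with `method = "CRM"`.
#' @export
crm_closed_form <- function(head, block) {
  if (!inherits(head, "classifier_head")) {
    stop("closed-form CRM requires a pure GAP+FC classifier_head")
  }
  d <- dim(block)
  if (d[3] != nrow(head$w)) {
    stop(sprintf("block has %d channels, head expects %d", d[3], nrow(head$w)))
  }
  hw <- d[1] * d[2]
  cams <- matrix(block, hw, d[3]) %*% head$w # hw x C, all classes at once
  vals <- matrix(rowSums((cams / hw)^2), d[1], d[2])
  new_saliency_map(vals, "CRM", "class-agnostic")
}

#' Render a saliency map as a thresholded heatmap
#'
#' Post-processing applied at feature resolution first: values below
#' `threshold_frac` of the map maximum (and all non-positive values) are set
#' to zero, survivors are min-max rescaled to `[1, 255]` (so any survivor is
#' distinguishable from the zero background; a constant surviving set renders
#' as 255), and the result is then bilinearly upsampled to the input size and
#' rescaled so the rendered maximum is exactly 255. The feature-resolution
#' mask is kept alongside because region-of-interest statistics are defined
#' on the feature grid.
#'
#' @param map A `saliency_map`.
#' @param input_size `c(H, W)` of the original image.
#' @param threshold_frac Fraction of the map maximum kept (default 0.20; the
#'   looser alternative used for insufficient-coverage remediation is 0.15).
#' @return A `rendered_heatmap`: list with `values` (`H x W` integers in
#'   `[0, 255]`), `roi_mask` (`values > 0`), `feature_values`, `feature_roi`
#'   and `threshold_frac`.
#' @export
render_heatmap <- function(map, input_size, threshold_frac = 0.20) {
  m <- map$values
  if (!any(is.finite(m))) stop("saliency map has no finite values")
  mx <- max(m)
  if (mx <= 0) {
    warning("saliency map has no positive values; rendering an empty RoI")
    fv <- matrix(0L, nrow(m), ncol(m))
  } else {
    thr <- threshold_frac * mx
    surv <- m >= thr & m > 0
    mn <- min(m[surv])
    fv <- matrix(0L, nrow(m), ncol(m))
    fv[surv] <- if (mx > mn) {
      as.integer(round(1 + 254 * (m[surv] - mn) / (mx - mn)))
    } else {
      255L # degenerate constant surviving set
    }
  }
  up <- bilinear_resize_matrix(fv, input_size[1], input_size[2])
  if (max(up) > 0) up <- up * (255 / max(up))
  values <- matrix(as.integer(round(up)), input_size[1], input_size[2])
  structure(
    list(values = values, roi_mask = values > 0L,
         feature_values = fv, feature_roi = fv > 0L,
         threshold_frac = threshold_frac),
    class = "rendered_heatmap"
  )
}

#' RoI size statistics of rendered heatmaps
#'
#' `roi_fraction()` is the number of feature-grid cells surviving the
#' threshold divided by the total number of cells. `compare_roi()` is the
#' relative RoI-size reduction of CRM against CAM,
#' `(fraction_CAM - fraction_CRM) / fraction_CAM`: positive means the CRM
#' region is tighter.
#'
#' @param h,crm_h,cam_h `rendered_heatmap` objects; the two compared heatmaps
#'   must share the feature grid size and threshold.
#' @return A single number; `compare_roi()` returns `NA` when the CAM RoI is
#'   empty (the comparison is undefined).
#' @export
roi_fraction <- function(h) {
  sum(h$feature_roi) / length(h$feature_roi)
}

#' @rdname roi_fraction
#' @export
compare_roi <- function(crm_h, cam_h) {
  if (!all(dim(crm_h$feature_roi) == dim(cam_h$feature_roi))) {
    stop("heatmaps must share the same feature grid size")
  }
  if (crm_h$threshold_frac != cam_h$threshold_frac) {
    stop("heatmaps must share the same threshold_frac")
  }
  f_cam <- roi_fraction(cam_h)
  if (f_cam == 0) {
    message("CAM RoI is empty; RoI comparison undefined")
    return(NA_real_)
  }
  (f_cam - roi_fraction(crm_h)) / f_cam
}

#' Pointing game
#'
#' Scores whether the rendered heatmap's peak falls inside the ground-truth
#' landmark mask dilated by `tolerance_px` (Euclidean). The peak is the first
#' maximum in column-major order (deterministic tie-break); an all-zero
#' heatmap is a miss.
#'
#' @param h A `rendered_heatmap` at input resolution.
#' @param truth_mask Logical (or 0/1) matrix of the same size as `h$values`.
#' @param tolerance_px Dilation radius in pixels (default 4).
#' @return `TRUE` (hit) or `FALSE` (miss).
#' @export
pointing_game <- function(h, truth_mask, tolerance_px = 4) {
  if (!is_binary_mask(truth_mask)) stop("truth_mask must be a binary matrix")
  truth_mask <- truth_mask > 0
  if (!any(truth_mask)) stop("truth mask is empty; invalid fixture")
  if (!all(dim(truth_mask) == dim(h$values))) {
    stop("truth mask and heatmap must share the input grid size")
  }
  if (max(h$values) <= 0L) return(FALSE)
  peak <- which.max(h$values) # first maximum, column-major
  pr <- (peak - 1L) %% nrow(h$values) + 1L
  pc <- (peak - 1L) %/% nrow(h$values) + 1L
  idx <- which(truth_mask, arr.ind = TRUE)
  min(sqrt((idx[, 1] - pr)^2 + (idx[, 2] - pc)^2)) <= tolerance_px
}

#' Write a rendered heatmap to PNG
#'
#' Writes the 8-bit grayscale heatmap, or an RGBA overlay on the source image
#' with a warm colormap (higher value = warmer) when `image` is supplied.
#'
#' @param h A `rendered_heatmap`.
#' @param path Output PNG path.
#' @param image Optional `H x W x 3` image to overlay on.
#' @param alpha Overlay opacity of the heatmap inside its RoI (default 0.5).
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(h, path, image = NULL, alpha = 0.5) {
  v <- h$values / 255
  if (is.null(image)) {
    png::writePNG(v, path)
    return(invisible(path))
  }
  if (!all(dim(image)[1:2] == dim(v))) stop("image and heatmap sizes differ")
  ramp <- grDevices::colorRamp(c("blue", "cyan", "yellow", "red"))
  rgbm <- ramp(as.vector(v)) / 255
  out <- image
  a <- ifelse(h$roi_mask, alpha, 0)
  for (ch in 1:3) {
    out[, , ch] <- image[, , ch] * (1 - a) + matrix(rgbm[, ch], nrow(v)) * a
  }
  png::writePNG(out, path)
  invisible(path)
}
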