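# Synthetic two-class image generator. Each image shows a large soft-edged
# ellipse (the organ) with low-frequency shading, a dark concave disc (the
# os-like landmark), and a class-dependent structure hugging that disc:
#   class 0 ("treatable")     — a thin, smooth, faint rim;
#   class 1 ("not treatable") — a broad irregular bright annulus carrying
#                               strong fine-grained texture.
# The class signal therefore lives at one localized landmark but spans scales
# (fine texture at a few pixels, annulus geometry at tens of pixels), so
# multi-level pyramid heads have a genuine advantage and Gaussian blur
# progressively removes the evidence.

#' Generate one synthetic labelled sample
#'
#' Renders a deterministic synthetic image with a single localized
#' discriminative landmark and its ground-truth mask. The label changes only
#' the appearance of the structure around the dark central disc; all other
#' scene randomness is shared, so the two labels rendered from the same seed
#' differ only inside the dilated landmark region.
#'
#' @param seed Integer seed; fully determines the sample.
#' @param label Class label, 0 (treatable) or 1 (not treatable).
#' @param size Image side in pixels (square output, default 256, minimum 128).
#' @return A `synthetic_sample`: list with `image` (`size x size x 3` in
#'   `(0, 1)`), `label`, `landmark_mask` (logical matrix, the os-like disc),
#'   and `meta` (seed, landmark center/radius, texture parameters).
#' @export
generate_sample <- function(seed, label, size = 256L) {
  size <- as.integer(size)
  if (size < 128L) stop("size must be >= 128")
  if (!label %in% c(0L, 1L)) stop("label must be 0 or 1")

  with_seed(derive_seed(seed, 3L), {
    yy <- matrix(seq_len(size), size, size)
    xx <- matrix(seq_len(size), size, size, byrow = TRUE)

    # Shared scene randomness, drawn in a fixed order for both labels.
    lowfreq <- bilinear_resize_matrix(
      matrix(stats::rnorm(144L), 12L, 12L), size, size
    ) * 0.02
    ecy <- size * (0.5 + stats::runif(1, -0.03, 0.03))
    ecx <- size * (0.5 + stats::runif(1, -0.03, 0.03))
    ea <- size * stats::runif(1, 0.39, 0.43)
    eb <- size * stats::runif(1, 0.39, 0.43)
    ocy <- ecy + size * stats::runif(1, -0.04, 0.04)
    ocx <- ecx + size * stats::runif(1, -0.04, 0.04)
    r_os <- size * stats::runif(1, 0.05, 0.065)
    speckle <- matrix(stats::rnorm(size * size, sd = 0.002), size, size)
    # Lesion parameters are drawn for both labels (keeps the RNG stream
    # aligned); they are rendered only for label 1.
    harm_amp <- stats::runif(2, 0.5, 1.0)
    harm_phase <- stats::runif(2, 0, 2 * pi)
    tex_freq <- stats::runif(4, 0.18, 0.28)
    tex_phase <- stats::runif(2, 0, 2 * pi)
    lobe_phase <- stats::runif(1, 0, 2 * pi)
    lobe_depth <- stats::runif(1, 0.4, 1.4)

    q <- ((yy - ecy) / ea)^2 + ((xx - ecx) / eb)^2
    ellipse <- 1 / (1 + exp((q - 1) / 0.09))
    base_in <- c(0.80, 0.52, 0.50)
    base_out <- c(0.42, 0.22, 0.24)

    # the dip and rim profiles are kept wide relative to a few pixels so that
    # the class-neutral scene content is stable under moderate smoothing;
    # only the lesion carries fine structure
    d <- sqrt((yy - ocy)^2 + (xx - ocx)^2)
    os_dip <- 0.5 * exp(-(d / (1.05 * r_os))^2)

    theta <- atan2(yy - ocy, xx - ocx)
    if (label == 0L) {
      landmark <- 0.09 * exp(-((d - 1.3 * r_os) / (0.35 * r_os))^2)
    } else {
      r_out <- r_os * (2.0 + 0.25 * (harm_amp[1] * sin(2 * theta + harm_phase[1]) +
                                       harm_amp[2] * sin(3 * theta + harm_phase[2])))
      band <- (1 / (1 + exp(-(d - 1.02 * r_os) / (0.15 * r_os)))) *
        (1 / (1 + exp(-(r_out - d) / (0.15 * r_os))))
      tex <- sin(2 * pi * (yy * tex_freq[1] + xx * tex_freq[2]) + tex_phase[1]) *
        sin(2 * pi * (yy * tex_freq[3] - xx * tex_freq[4]) + tex_phase[2])
      # Three spatial scales of evidence: a smooth annular mean lift
      # (coarse), azimuthal lobes of ~20 px wavelength (medium, with a
      # per-image depth so lesions range from smooth to strongly lobed), and
      # a strong fine-grained interference texture (a few px). Gaussian blur
      # strips these progressively: a (19,19) filter removes the texture, a
      # (49,49) filter also removes the lobes. The lobe modulation averages
      # to zero over angle, so it leaves the landmark-region mean intensity
      # untouched.
      lobes <- 1 + lobe_depth * cos(6 * theta + lobe_phase)
      landmark <- band * (0.36 * lobes * exp(-((d - 1.05 * r_os) / (0.9 * r_os))^2) +
                            0.45 * tex * exp(-((d - 1.1 * r_os) / (0.5 * r_os))^2))
    }
    # hard support cutoff: the lesion amplitude at 4 r_os is below 1e-8, so
    # truncating there leaves the rendered images numerically unchanged while
    # making "identical outside the dilated landmark region" hold exactly
    landmark[d > 4 * r_os] <- 0

    lum <- lowfreq + speckle - os_dip + landmark
    img <- array(0, c(size, size, 3L))
    for (ch in 1:3) {
      img[, , ch] <- base_out[ch] + (base_in[ch] - base_out[ch]) * ellipse + lum
    }
    img[img < 0.01] <- 0.01
    img[img > 0.99] <- 0.99

    structure(
      list(
        image = img,
        label = as.integer(label),
        landmark_mask = d <= r_os,
        meta = list(
          seed = as.integer(seed), label = as.integer(label), size = size,
          os_center = c(ocy, ocx), os_radius = r_os,
          ellipse = c(ecy, ecx, ea, eb),
          harm_amp = harm_amp, harm_phase = harm_phase,
          tex_freq = tex_freq, tex_phase = tex_phase,
          lobe_phase = lobe_phase, lobe_depth = lobe_depth
        )
      ),
      class = "synthetic_sample"
    )
  })
}

#' Generate a labelled synthetic dataset with a woman-level split
#'
#' Builds a dataset manifest of lazily rendered samples (images are
#' regenerated on demand from their per-row seeds, so nothing large is held
#' in memory or on disk unless `write_dir` is given). Each image belongs to a
#' "woman"; roughly 10 percent of women contribute two images, and the
#' train/test split is carried out at the woman level so no woman appears in
#' both splits.
#'
#' @param n_per_class Integer vector `c(n_class0, n_class1)`; a single number
#'   is used for both classes. Each entry must be at least 10. The study-like
#'   default ratio is 729:304 (see [default_class_counts()]).
#' @param seed Integer seed controlling sample seeds, woman assignment and the
#'   split.
#' @param split_frac Fraction of images (per class, approximately) assigned to
#'   the training split; must be strictly between 0 and 1 (default 0.8).
#' @param size Image side in pixels passed to [generate_sample()].
#' @param write_dir Optional directory; when given, images and masks are
#'   written as PNG files and `manifest.csv` is written alongside, with
#'   `path`/`mask_path` columns added to the manifest.
#' @return A `synth_manifest` data frame with columns `id`, `woman_id`,
#'   `label`, `sample_seed`, `split` (and `path`, `mask_path` when written);
#'   the image side is stored in `attr(, "size")`.
#' @export
generate_dataset <- function(n_per_class, seed, split_frac = 0.8, size = 256L,
                             write_dir = NULL) {
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 2L)
  n_per_class <- as.integer(n_per_class)
  if (any(n_per_class < 10L)) stop("n_per_class must be >= 10 for each class")
  if (!(split_frac > 0 && split_frac < 1)) {
    stop("split_frac must be strictly between 0 and 1 (got ", split_frac,
         "); a degenerate split would leave one side empty")
  }

  build <- function(try_seed) {
    with_seed(derive_seed(try_seed, 11L), {
      rows <- list()
      woman_counter <- 0L
      for (cls in c(0L, 1L)) {
        n <- n_per_class[cls + 1L]
        n_pairs <- max(0L, round(0.09 * n))
        n_singles <- n - 2L * n_pairs
        images_per_woman <- c(rep(2L, n_pairs), rep(1L, n_singles))
        women <- paste0("w", sprintf("%05d", woman_counter + seq_along(images_per_woman)))
        woman_counter <- woman_counter + length(images_per_woman)
        # woman-level split: permute women, take train women until the train
        # image count reaches split_frac of this class's images
        ord <- sample.int(length(women))
        cum <- cumsum(images_per_woman[ord])
        n_train_women <- which(cum >= round(split_frac * n))[1]
        split_by_woman <- rep("test", length(women))
        split_by_woman[ord[seq_len(n_train_women)]] <- "train"
        widx <- rep(seq_along(women), images_per_woman)
        rows[[cls + 1L]] <- data.frame(
          woman_id = women[widx],
          label = cls,
          split = split_by_woman[widx],
          stringsAsFactors = FALSE
        )
      }
      m <- do.call(rbind, rows)
      m$id <- sprintf("img%05d", seq_len(nrow(m)))
      m$sample_seed <- vapply(seq_len(nrow(m)), function(i) {
        derive_seed(try_seed, 7000L + i)
      }, integer(1))
      m[, c("id", "woman_id", "label", "sample_seed", "split")]
    })
  }

  manifest <- build(seed)
  tries <- 0L
  while (any(table(factor(manifest$label, c(0, 1)), factor(manifest$split, c("train", "test"))) == 0L)) {
    tries <- tries + 1L
    if (tries > 20L) stop("could not produce a split with both classes on both sides")
    message("split left a class empty on one side; regenerating with reseed ", seed + tries)
    manifest <- build(seed + tries)
  }

  attr(manifest, "size") <- as.integer(size)
  class(manifest) <- c("synth_manifest", "data.frame")

  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(write_dir, paste0(manifest$id, ".png"))
    manifest$mask_path <- file.path(write_dir, paste0(manifest$id, "_mask.png"))
    for (i in seq_len(nrow(manifest))) {
      s <- generate_sample(manifest$sample_seed[i], manifest$label[i], size)
      png::writePNG(s$image, manifest$path[i])
      png::writePNG(s$landmark_mask * 1.0, manifest$mask_path[i])
    }
    utils::write.csv(as.data.frame(manifest), file.path(write_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  manifest
}

#' Study-like class counts
#'
#' The default class imbalance mirrors a 729:304 treatable/not-treatable
#' ratio; `scale` shrinks both counts proportionally (rounded).
#'
#' @param scale Multiplier applied to the full-size counts (default 1).
#' @return Integer vector `c(n_class0, n_class1)`.
#' @export
#' @examples
#' default_class_counts(0.1)
default_class_counts <- function(scale = 1) {
  as.integer(round(c(729L, 304L) * scale))
}

#' Materialize one sample from a dataset
#'
#' Datasets are either `synth_manifest` frames (samples regenerated from
#' seeds), manifest frames with `path`/`mask_path` columns (read from disk),
#' or plain lists of `synthetic_sample`-like lists.
#'
#' @param dataset A dataset in one of the supported forms.
#' @param i Row/element index.
#' @return A list with at least `image` and `label`; `landmark_mask` when
#'   masks are available.
#' @export
get_sample <- function(dataset, i) {
  if (inherits(dataset, "synth_manifest")) {
    return(generate_sample(dataset$sample_seed[i], dataset$label[i],
                           attr(dataset, "size")))
  }
  if (is.data.frame(dataset)) {
    if (!"path" %in% names(dataset)) stop("manifest data frame needs a 'path' column")
    img <- read_image(dataset$path[i])
    mask <- NULL
    if ("mask_path" %in% names(dataset) && !is.na(dataset$mask_path[i])) {
      mm <- png::readPNG(dataset$mask_path[i])
      if (length(dim(mm)) == 3L) mm <- mm[, , 1L]
      mask <- mm > 0.5
    }
    return(list(image = img, label = as.integer(dataset$label[i]),
                landmark_mask = mask))
  }
  dataset[[i]]
}

#' @rdname get_sample
#' @export
dataset_size <- function(dataset) {
  if (is.data.frame(dataset)) nrow(dataset) else length(dataset)
}

dataset_labels <- function(dataset) {
  if (is.data.frame(dataset)) {
    as.integer(dataset$label)
  } else {
    vapply(dataset, function(s) as.integer(s$label), integer(1))
  }
}

dataset_ids <- function(dataset) {
  if (is.data.frame(dataset) && "id" %in% names(dataset)) {
    dataset$id
  } else {
    sprintf("img%05d", seq_len(dataset_size(dataset)))
  }
}

dataset_woman_ids <- function(dataset) {
  if (is.data.frame(dataset) && "woman_id" %in% names(dataset)) {
    dataset$woman_id
  } else {
    dataset_ids(dataset)
  }
}

#' Split a manifest into its train and test parts
#'
#' @param manifest A manifest with a `split` column.
#' @param which `"train"` or `"test"`.
#' @return The subset manifest, preserving class and attributes.
#' @export
manifest_split <- function(manifest, which = c("train", "test")) {
  which <- match.arg(which)
  out <- manifest[manifest$split == which, , drop = FALSE]
  attr(out, "size") <- attr(manifest, "size")
  class(out) <- class(manifest)
  out
}
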