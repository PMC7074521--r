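#' Color and texture feature extraction
#'
#' `color_features()` computes, for each of the six color spaces (RGB,
#' HSV, HSI, YCbCr, YIQ, CMY), the mean and population standard deviation
#' of the three channels and of the per-pixel mean of the three channels,
#' restricted to foreground pixels: 6 spaces x 4 aggregates x 2 statistics
#' = 48 features. `texture_features()` computes the 20 GLCM statistics of
#' [glcm_features()] at the four neighborhood angles 0, 45, 90, 135
#' degrees: 80 features. `extract_features()` concatenates both families
#' into the canonical 128-feature vector.
#'
#' All statistics are computed over foreground pixels only; GLCM pairs
#' require both pixels of the pair to be foreground. Standard deviations
#' are population (divide by n) statistics.
#'
#' @param image H x W x 3 numeric array in \[0, 255\].
#' @param mask logical H x W foreground mask with at least 2 foreground
#'   pixels.
#' @param levels,distance,symmetric GLCM configuration (see
#'   [compute_glcm()]).
#' @return named numeric vector (48, 80, or 128 values).
#' @export
color_features <- function(image, mask) {
  check_mask_pixels(image, mask)
  fg <- as.vector(mask)
  out <- numeric(0)
  for (space in colorspace_ids()) {
    planes <- convert_colorspace(image, space)
    chans <- list(ch1 = as.vector(planes$ch1)[fg],
                  ch2 = as.vector(planes$ch2)[fg],
                  ch3 = as.vector(planes$ch3)[fg])
    chans$mean3 <- (chans$ch1 + chans$ch2 + chans$ch3) / 3
    for (nm in names(chans)) {
      v <- chans[[nm]]
      out[paste0(space, "_", nm, "_mean")] <- mean(v)
      out[paste0(space, "_", nm, "_std")] <- pop_sd(v)
    }
  }
  out
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

check_mask_pixels <- function(image, mask) {
  validate_image(image)
  if (!all(dim(mask) == dim(image)[1:2])) {
    abort("`mask` shape must match `image`.")
  }
  if (sum(mask) < 2) {
    abort("mask must contain at least 2 foreground pixels.")
  }
  invisible(TRUE)
}

#' @rdname color_features
#' @export
texture_features <- function(image, mask, levels = 8, distance = 1,
                             symmetric = FALSE) {
  check_mask_pixels(image, mask)
  gray <- to_gray(image)
  out <- numeric(0)
  for (angle in c(0, 45, 90, 135)) {
    g <- compute_glcm(gray, mask, levels = levels, distance = distance,
                      angle = angle, symmetric = symmetric)
    f <- glcm_features(g)
    names(f) <- paste0("glcm_", names(f), "_", angle)
    out <- c(out, f)
  }
  out
}

#' @rdname color_features
#' @export
extract_features <- function(image, mask, levels = 8, distance = 1,
                             symmetric = FALSE) {
  c(color_features(image, mask),
    texture_features(image, mask, levels = levels, distance = distance,
                     symmetric = symmetric))
}

#' Canonical feature names
#'
#' The fixed, documented order of the 128 features: 48 color features
#' (space, then aggregate ch1/ch2/ch3/mean3, then mean/std), followed by
#' 80 texture features (angle-major: all 20 GLCM statistics at 0, then
#' 45, 90, 135 degrees).
#'
#' @return character vector of length 128.
#' @export
feature_names <- function() {
  color <- as.vector(t(outer(
    colorspace_ids(),
    as.vector(t(outer(c("ch1", "ch2", "ch3", "mean3"), c("mean", "std"),
                      paste, sep = "_"))),
    paste, sep = "_")))
  texture <- as.vector(t(outer(c(0, 45, 90, 135), glcm_feature_names(),
    function(a, f) paste0("glcm_", f, "_", a))))
  c(color, texture)
}

#' Extract a feature table from a labeled image set
#'
#' Maps `extract_features()` over a dataset (as produced by
#' [generate_dataset()] or assembled by hand) and returns a tidy table:
#' one row per image, one column per feature, plus `image_id` and
#' `label`. Masks are computed with [segment_image()] when not supplied.
#'
#' @param dataset a data frame with columns `image_id`, `label`, and
#'   list-columns `image` (H x W x 3 arrays) and optionally `mask`.
#' @param min_pixels small-object threshold used when masks must be
#'   computed.
#' @inheritParams color_features
#' @return tibble with `image_id`, `label`, and 128 feature columns.
#' @export
extract_dataset <- function(dataset, levels = 8, distance = 1,
                            symmetric = FALSE, min_pixels = 100) {
  if (!all(c("image_id", "label", "image") %in% names(dataset))) {
    abort("`dataset` needs columns image_id, label, image.")
  }
  has_mask <- "mask" %in% names(dataset)
  rows <- purrr::map(seq_len(nrow(dataset)), function(k) {
    img <- dataset$image[[k]]
    msk <- if (has_mask) dataset$mask[[k]] else {
      segment_image(img, min_pixels = min_pixels)
    }
    as_tibble(as.list(extract_features(img, msk, levels = levels,
                                       distance = distance,
                                       symmetric = symmetric)))
  })
  dplyr::bind_cols(
    tibble(image_id = dataset$image_id, label = dataset$label),
    dplyr::bind_rows(rows)
  )
}

#' Frozen presets of selected discriminant features
#'
#' `"paper5"` is the published five-feature set found by the
#' cultural-algorithm wrapper: mean of the per-pixel RGB channel average,
#' mean of the per-pixel HSI channel average, GLCM sum entropy at 90
#' degrees, GLCM standard deviation at 0 degrees, and the mean of the
#' third YCbCr channel (Cr). `"paper5_alt"` replaces the HSI average with
#' the mean of the first HSI channel (hue), an alternative reading of the
#' published description.
#'
#' @param preset `"paper5"` or `"paper5_alt"`.
#' @return character vector of 5 canonical feature names.
#' @export
feature_preset <- function(preset = c("paper5", "paper5_alt")) {
  preset <- match.arg(preset)
  base <- c("RGB_mean3_mean", "HSI_mean3_mean", "glcm_sum_entropy_90",
            "glcm_standard_deviation_0", "YCbCr_ch3_mean")
  if (preset == "paper5_alt") base[2] <- "HSI_ch1_mean"
  base
}
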