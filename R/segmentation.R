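#' HSI-rule segmentation of seeds from a dark background
#'
#' A pixel is foreground (chickpea) when any of the three clauses holds on
#' the \[0, 1\]-scaled HSI planes: hue < 0.4, or saturation > 0.15, or
#' intensity > 0.07; otherwise it is background. The rule is applied
#' per pixel; blobs smaller than `min_pixels` are then discarded with
#' [remove_small_objects()].
#'
#' @param image H x W x 3 numeric array in \[0, 255\].
#' @param h_max,s_min,i_min the three clause thresholds (defaults 0.4,
#'   0.15, 0.07 on the \[0, 1\] HSI scale).
#' @return logical H x W matrix, `TRUE` = foreground.
#' @seealso [remove_small_objects()], [apply_mask()]
#' @export
hsi_threshold <- function(image, h_max = 0.4, s_min = 0.15, i_min = 0.07) {
  planes <- convert_colorspace(image, "HSI")
  planes$ch1 < h_max | planes$ch2 > s_min | planes$ch3 > i_min
}

#' Remove small foreground blobs from a binary mask
#'
#' Labels 8-connected foreground components and clears every component
#' whose pixel count is below `min_pixels`. Components with exactly
#' `min_pixels` pixels or more are kept unchanged.
#'
#' @param mask logical H x W matrix.
#' @param min_pixels minimum component area kept (default 100, the value
#'   found by trial and error in the original imaging study).
#' @return logical matrix of the same shape.
#' @export
remove_small_objects <- function(mask, min_pixels = 100) {
  if (!is.matrix(mask)) abort("`mask` must be a logical matrix.")
  if (!is.numeric(min_pixels) || min_pixels < 1) {
    abort("`min_pixels` must be a positive integer.")
  }
  lab <- label_components(mask)
  if (max(lab) == 0) return(mask & FALSE)
  area <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(area >= min_pixels)
  out <- matrix(lab %in% keep, nrow(mask))
  out
}

# 8-connected component labeling: 4-connected pass (EBImage::bwlabel),
# then union of labels that touch diagonally.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  lab <- matrix(as.integer(lab), nrow(mask))
  n_lab <- max(lab)
  if (n_lab <= 1) return(lab)
  parent <- seq_len(n_lab)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  nr <- nrow(lab); nc <- ncol(lab)
  for (shift in list(c(1, 1), c(1, -1))) {
    dr <- shift[1]; dc <- shift[2]
    rows <- seq_len(nr - 1)
    cols <- if (dc == 1) seq_len(nc - 1) else seq.int(2, nc)
    a <- lab[rows, cols, drop = FALSE]
    b <- lab[rows + dr, cols + dc, drop = FALSE]
    touching <- which(a > 0 & b > 0 & a != b)
    for (k in touching) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n_lab), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  out
}

#' Apply a binary mask to an image
#'
#' Background pixels are set to (0, 0, 0); foreground pixels pass through
#' unchanged.
#'
#' @param image H x W x 3 numeric array.
#' @param mask logical H x W matrix.
#' @return masked H x W x 3 array.
#' @export
apply_mask <- function(image, mask) {
  image <- validate_image(image)
  if (!all(dim(mask) == dim(image)[1:2])) {
    abort("`mask` shape must match `image`.")
  }
  out <- image
  bg <- !mask
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[bg] <- 0
    out[, , ch] <- plane
  }
  out
}

#' Segment an image end to end
#'
#' Convenience wrapper: HSI threshold rule followed by small-object
#' removal.
#'
#' @inheritParams hsi_threshold
#' @inheritParams remove_small_objects
#' @return logical H x W mask.
#' @export
segment_image <- function(image, min_pixels = 100, h_max = 0.4,
                          s_min = 0.15, i_min = 0.07) {
  remove_small_objects(
    hsi_threshold(image, h_max = h_max, s_min = s_min, i_min = i_min),
    min_pixels = min_pixels
  )
}
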