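#' Color-space conversions for seed images
#'
#' Images are H x W x 3 numeric arrays with channel values in \[0, 255\]
#' (8-bit RGB). `convert_colorspace()` maps an image into one of the six
#' color spaces used by the feature extractor; `to_gray()` produces the
#' luma plane used for GLCM texture analysis.
#'
#' Channel conventions:
#' \describe{
#'   \item{RGB}{input channels unchanged, \[0, 255\].}
#'   \item{HSV}{hexcone hue/saturation/value, each on \[0, 1\]; hue wraps
#'     at 1 and is 0 for achromatic pixels.}
#'   \item{HSI}{hue on \[0, 1\] (geometric definition, 0 for achromatic
#'     pixels), saturation `1 - min/mean` on \[0, 1\], intensity
#'     `(R + G + B) / (3 * 255)` on \[0, 1\]. This is the scale on which
#'     the segmentation thresholds (0.4, 0.15, 0.07) are defined.}
#'   \item{YCbCr}{ITU-R BT.601: `Y = 0.299 R + 0.587 G + 0.114 B`,
#'     `Cb = 0.564 (B - Y) + 128`, `Cr = 0.713 (R - Y) + 128`; \[0, 255\].}
#'   \item{YIQ}{NTSC: `Y` as above, `I = 0.595716 R - 0.274453 G -
#'     0.321263 B`, `Q = 0.211456 R - 0.522581 G - 0.311135 B`, on the
#'     0-255 input scale (I and Q may be negative).}
#'   \item{CMY}{`255 - R`, `255 - G`, `255 - B`.}
#' }
#'
#' @param image numeric H x W x 3 array, channels in \[0, 255\].
#' @param space one of `"RGB"`, `"HSV"`, `"HSI"`, `"YCbCr"`, `"YIQ"`,
#'   `"CMY"`.
#' @return for `convert_colorspace()`, a list of class `"color_planes"`
#'   with elements `space`, `ch1`, `ch2`, `ch3` (H x W matrices) and
#'   `channels` (channel names); for `to_gray()`, an H x W matrix in
#'   \[0, 255\].
#' @examples
#' img <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' convert_colorspace(img, "CMY")$ch1  # 0
#' to_gray(img)                        # 76.245
#' @export
convert_colorspace <- function(image, space) {
  image <- validate_image(image)
  space <- match.arg(space, colorspace_ids())
  h_px <- dim(image)[1]
  r <- matrix(image[, , 1], h_px)
  g <- matrix(image[, , 2], h_px)
  b <- matrix(image[, , 3], h_px)
  planes <- switch(space,
    RGB = list(r, g, b, c("R", "G", "B")),
    HSV = {
      hsv <- grDevices::rgb2hsv(r = as.vector(r), g = as.vector(g),
                                b = as.vector(b), maxColorValue = 255)
      list(matrix(hsv[1, ], nrow(r)), matrix(hsv[2, ], nrow(r)),
           matrix(hsv[3, ], nrow(r)), c("H", "S", "V"))
    },
    HSI = {
      i_norm <- (r + g + b) / (3 * 255)
      m <- pmin(r, pmin(g, b))
      s <- ifelse(i_norm > 0, 1 - m / (255 * i_norm), 0)
      list(hsi_hue(r, g, b), s, i_norm, c("H", "S", "I"))
    },
    YCbCr = {
      y <- 0.299 * r + 0.587 * g + 0.114 * b
      list(y, 0.564 * (b - y) + 128, 0.713 * (r - y) + 128,
           c("Y", "Cb", "Cr"))
    },
    YIQ = {
      y <- 0.299 * r + 0.587 * g + 0.114 * b
      list(y,
           0.595716 * r - 0.274453 * g - 0.321263 * b,
           0.211456 * r - 0.522581 * g - 0.311135 * b,
           c("Y", "I", "Q"))
    },
    CMY = list(255 - r, 255 - g, 255 - b, c("C", "M", "Y"))
  )
  structure(list(space = space, ch1 = planes[[1]], ch2 = planes[[2]],
                 ch3 = planes[[3]], channels = planes[[4]]),
            class = "color_planes")
}

colorspace_ids <- function() c("RGB", "HSV", "HSI", "YCbCr", "YIQ", "CMY")

# Geometric HSI hue on [0, 1]. Achromatic pixels (zero denominator) get
# hue 0 by convention; callers that need a stable hue must avoid exact
# grays (the synthetic background generator does, by construction).
hsi_hue <- function(r, g, b) {
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  cosv <- ifelse(den > 0, pmax(-1, pmin(1, num / den)), 1)
  theta <- acos(cosv) * 180 / pi
  h <- ifelse(b > g, 360 - theta, theta)
  ifelse(den > 0, h / 360, 0)
}

#' @rdname convert_colorspace
#' @export
to_gray <- function(image) {
  image <- validate_image(image)
  matrix(0.299 * image[, , 1] + 0.587 * image[, , 2] +
           0.114 * image[, , 3], dim(image)[1])
}

validate_image <- function(image) {
  if (is.matrix(image)) {
    abort("`image` must be an H x W x 3 array, not a matrix.")
  }
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort("`image` must be an H x W x 3 array.")
  }
  if (anyNA(image) || min(image) < 0 || max(image) > 255) {
    abort("image channel values must be finite and in [0, 255].")
  }
  image
}

#' Read and write 8-bit RGB images
#'
#' Thin wrappers around the png package. Grayscale and RGBA rasters are
#' promoted/truncated to 3 channels; values are rescaled to \[0, 255\].
#'
#' @param path file path.
#' @param image H x W x 3 array in \[0, 255\] (`write_image`) or H x W
#'   logical matrix (`write_mask`).
#' @return `read_image()` returns an H x W x 3 array in \[0, 255\].
#' @export
read_image <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 2) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  if (dim(raw)[3] == 4) raw <- raw[, , 1:3, drop = FALSE]
  raw * 255
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  png::writePNG(validate_image(image) / 255, path)
  invisible(path)
}

#' @rdname read_image
#' @export
write_mask <- function(image, path) {
  png::writePNG(matrix(as.numeric(image), nrow(image)), path)
  invisible(path)
}

#' @rdname read_image
#' @export
read_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  raw > 0.5
}
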