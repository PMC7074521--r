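#' Synthetic chickpea-scene generator
#'
#' Generates labeled images that emulate the imaging setup the
#' classifier was designed for: around 60 convex bright seed blobs per
#' image, possibly touching, on a dark slightly blue-tinted background.
#' Background pixels are constructed to fail all three clauses of the
#' segmentation rule (hue >= 0.4, saturation <= 0.15, intensity <=
#' 0.07), so the generator's ground-truth mask is recoverable by
#' [segment_image()]. Varieties differ in mean seed color and in the
#' grain scale/amplitude of a multiplicative texture noise, so both
#' color and GLCM texture features carry class signal.
#'
#' @param name variety name.
#' @param base_rgb mean seed color, 3 values in \[0, 255\].
#' @param color_jitter per-image standard deviation of the seed color
#'   (shared across an image's seeds; models batch-to-batch variation).
#' @param grain_scale texture grain radius in pixels (larger = coarser
#'   speckle, higher GLCM contrast at short offsets).
#' @param grain_amp multiplicative noise amplitude (relative).
#' @param axis_range semi-axis range of the seed ellipses, in pixels.
#' @return a `"variety_profile"` list.
#' @export
variety_profile <- function(name, base_rgb, color_jitter = 4,
                            grain_scale = 1, grain_amp = 0.08,
                            axis_range = c(6, 10)) {
  stopifnot(length(base_rgb) == 3, all(base_rgb >= 0 & base_rgb <= 255),
            grain_amp >= 0, grain_scale >= 0)
  structure(list(name = name, base_rgb = base_rgb,
                 color_jitter = color_jitter, grain_scale = grain_scale,
                 grain_amp = grain_amp, axis_range = axis_range),
            class = "variety_profile")
}

#' Default variety profiles
#'
#' Three profiles standing in for the Adel, Arman, and Azad cultivars:
#' beige-to-tan seed colors about 20-40 gray levels apart (well beyond
#' the per-image color jitter of 4), with fine, coarse, and intermediate
#' texture grain respectively.
#'
#' @return named list of three [variety_profile()]s.
#' @export
default_profiles <- function() {
  list(
    Adel = variety_profile("Adel", c(205, 175, 130), color_jitter = 4,
                            grain_scale = 1, grain_amp = 0.05),
    Arman = variety_profile("Arman", c(185, 148, 105), color_jitter = 4,
                             grain_scale = 3, grain_amp = 0.13),
    Azad = variety_profile("Azad", c(218, 192, 152), color_jitter = 4,
                            grain_scale = 2, grain_amp = 0.20)
  )
}

#' Scene geometry and background sampler
#'
#' @param width,height image size in pixels.
#' @param n_seeds seeds per image (default 60).
#' @param background_range range of the dark background base level `b`;
#'   a background pixel is `(b, b + 1, b + 2)`, which has blue-leaning
#'   hue about 0.58, saturation below 0.12 and intensity below 0.06 for
#'   `b` in 8..14 -- verifiably background under the segmentation rule.
#' @return a `"scene_spec"` list.
#' @export
scene_spec <- function(width = 192, height = 192, n_seeds = 60,
                       background_range = c(8, 14)) {
  stopifnot(n_seeds >= 1, width >= 16, height >= 16,
            background_range[1] >= 8, background_range[2] <= 14)
  structure(list(width = width, height = height, n_seeds = n_seeds,
                 background_range = background_range),
            class = "scene_spec")
}

#' Generate one seed-bunch image
#'
#' Dark tinted background plus `n_seeds` randomly placed (possibly
#' touching) ellipses filled with the profile color modulated by
#' smoothed multiplicative grain noise. Deterministic given `seed`.
#'
#' @param profile a [variety_profile()].
#' @param spec a [scene_spec()].
#' @param seed RNG seed.
#' @return list with `image` (H x W x 3 array in \[0, 255\]) and `mask`
#'   (logical ground-truth foreground).
#' @export
generate_image <- function(profile, spec = scene_spec(), seed = 1) {
  with_seed(seed, {
    h <- spec$height; w <- spec$width
    # background: (b, b+1, b+2) with b constant per image
    b <- resample(seq.int(spec$background_range[1],
                          spec$background_range[2]), 1)
    img <- array(0, dim = c(h, w, 3))
    img[, , 1] <- b; img[, , 2] <- b + 1; img[, , 3] <- b + 2
    mask <- matrix(FALSE, h, w)

    # per-image color shift shared by all seeds (batch variation)
    shift <- rnorm(3, 0, profile$color_jitter)
    base <- pmin(pmax(profile$base_rgb + shift, 40), 250)

    rows <- matrix(rep(seq_len(h), w), h)
    cols <- matrix(rep(seq_len(w), each = h), h)
    for (s in seq_len(spec$n_seeds)) {
      a <- runif(1, profile$axis_range[1], profile$axis_range[2])
      bb <- runif(1, profile$axis_range[1], profile$axis_range[2])
      theta <- runif(1, 0, pi)
      m <- max(a, bb)
      cx <- runif(1, 1 + m, w - m)
      cy <- runif(1, 1 + m, h - m)
      dx <- cols - cx; dy <- rows - cy
      u <- dx * cos(theta) + dy * sin(theta)
      v <- -dx * sin(theta) + dy * cos(theta)
      mask <- mask | (u^2 / a^2 + v^2 / bb^2 <= 1)
    }

    # multiplicative grain: smoothed white noise, normalized, scaled
    grain <- smooth_noise(h, w, profile$grain_scale)
    modulation <- 1 + profile$grain_amp * grain
    modulation <- pmax(modulation, 0.35)
    for (ch in 1:3) {
      plane <- img[, , ch]
      seedvals <- base[ch] * modulation[mask] +
        rnorm(sum(mask), 0, 1.5)
      plane[mask] <- pmin(pmax(seedvals, 45), 255)
      img[, , ch] <- plane
    }
    list(image = round(img), mask = mask)
  })
}

# White noise smoothed by a (2r+1) box filter via running sums, then
# re-standardized so grain_amp sets the pixel standard deviation.
smooth_noise <- function(h, w, radius) {
  z <- matrix(rnorm(h * w), h, w)
  r <- round(radius)
  if (r >= 1) {
    k <- 2 * r + 1
    z <- t(apply(z, 1, box_smooth, k = k))
    z <- apply(z, 2, box_smooth, k = k)
  }
  z / max(sd(as.vector(z)), 1e-9)
}

box_smooth <- function(v, k) {
  n <- length(v)
  pad <- c(rep(v[1], k %/% 2), v, rep(v[n], k %/% 2))
  cs <- c(0, cumsum(pad))
  (cs[(1 + k):(n + k)] - cs[1:n]) / k
}

#' Generate a labeled synthetic dataset
#'
#' @param profiles named list of [variety_profile()]s (default
#'   [default_profiles()]).
#' @param n_per_class images per variety.
#' @param spec a [scene_spec()].
#' @param seed master seed (each image gets a derived seed).
#' @return tibble with `image_id`, `label`, and list-columns `image`
#'   and `mask`.
#' @export
generate_dataset <- function(profiles = default_profiles(),
                             n_per_class = 30, spec = scene_spec(),
                             seed = 1) {
  rows <- list()
  for (p in seq_along(profiles)) {
    prof <- profiles[[p]]
    for (k in seq_len(n_per_class)) {
      gen <- generate_image(prof, spec,
                            seed = fanout_seed(seed, prof$name, k))
      rows[[length(rows) + 1]] <- tibble(
        image_id = sprintf("%s_%03d", prof$name, k),
        label = prof$name,
        image = list(gen$image), mask = list(gen$mask))
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a generated dataset to disk
#'
#' Emits one PNG per image and mask plus a `manifest.csv` with columns
#' `image_id`, `label`, `image_path`, `mask_path`.
#'
#' @param dataset from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return the manifest tibble, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- dplyr::bind_rows(lapply(seq_len(nrow(dataset)), function(k) {
    id <- dataset$image_id[k]
    ip <- file.path(dir, paste0(id, ".png"))
    mp <- file.path(dir, paste0(id, "_mask.png"))
    write_image(dataset$image[[k]], ip)
    write_mask(dataset$mask[[k]], mp)
    tibble(image_id = id, label = dataset$label[k],
           image_path = ip, mask_path = mp)
  }))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `manifest.csv`.
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  dplyr::bind_rows(lapply(seq_len(nrow(manifest)), function(k) {
    tibble(image_id = manifest$image_id[k], label = manifest$label[k],
           image = list(read_image(manifest$image_path[k])),
           mask = list(read_mask(manifest$mask_path[k])))
  }))
}
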