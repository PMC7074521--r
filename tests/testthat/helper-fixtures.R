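# Shared fixtures, built in code at test time.

# single-pixel image helper
px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))

rand_image <- function(h, w, seed = 1) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

# Brute-force GLCM oracle: explicit double loop over all pixel pairs.
glcm_oracle <- function(gray, mask, levels, distance, angle) {
  q <- floor(gray / 256 * levels) + 1
  q[q > levels] <- levels
  off <- switch(as.character(angle),
    "0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
    "135" = c(-1, -1)) * distance
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(gray))) {
    for (cc in seq_len(ncol(gray))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= nrow(gray) && c2 >= 1 && c2 <= ncol(gray) &&
          mask[r, cc] && mask[r2, c2]) {
        counts[q[r, cc], q[r2, c2]] <- counts[q[r, cc], q[r2, c2]] + 1
      }
    }
  }
  counts / sum(counts)
}

# Independent per-pixel reference for the foreground decision rule.
hsi_rule_oracle <- function(r, g, b) {
  i <- (r + g + b) / 765
  s <- if (i > 0) 1 - min(r, g, b) / (255 * i) else 0
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  h <- if (den > 0) {
    theta <- acos(max(-1, min(1, num / den))) * 180 / pi
    (if (b > g) 360 - theta else theta) / 360
  } else 0
  (h < 0.4) || (s > 0.15) || (i > 0.07)
}

# Planted-signal classification table: features 3 and 7 are jointly
# (and only jointly) informative -- f3 isolates class A, f7 class B.
make_planted_table <- function(n_per_class = 40, p = 20, seed = 1) {
  stopifnot(p >= 7)
  set.seed(seed)
  n <- n_per_class * 3
  X <- matrix(rnorm(n * p), n)
  y <- rep(c("A", "B", "C"), each = n_per_class)
  X[, 3] <- X[, 3] * 0.4 + 2 * (y == "A")
  X[, 7] <- X[, 7] * 0.4 + 2 * (y == "B")
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(p))
  df$label <- y
  tibble::as_tibble(df)
}

# Small well-separated gaussian-blob table for classifier tests.
make_blob_table <- function(n_per_class = 12, seed = 1) {
  set.seed(seed)
  centers <- list(A = c(0, 0), B = c(4, 0), C = c(0, 4))
  rows <- lapply(names(centers), function(cl) {
    data.frame(f1 = rnorm(n_per_class, centers[[cl]][1], 0.5),
               f2 = rnorm(n_per_class, centers[[cl]][2], 0.5),
               label = cl)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

small_scene <- function() scene_spec(width = 96, height = 96, n_seeds = 14)
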