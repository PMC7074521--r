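#' Gray-level co-occurrence matrix restricted to a foreground mask
#'
#' Gray values in \[0, 255\] are linearly quantized into `levels` bins;
#' pixel pairs `(p, p + offset)` are counted when both pixels lie in the
#' foreground mask, and the count matrix is normalized to sum 1. The
#' offset for angle theta at distance d is `d * (cos theta, -sin theta)`
#' in (column, row) form, i.e. the standard image-processing conventions:
#' 0 degrees looks right, 45 up-right, 90 up, 135 up-left.
#'
#' @param gray H x W numeric matrix in \[0, 255\].
#' @param mask logical H x W matrix (`NULL` = all pixels valid).
#' @param levels number of gray bins (default 8).
#' @param distance pixel offset length (default 1).
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @param symmetric if `TRUE`, pairs are counted in both directions.
#' @return `levels` x `levels` matrix of pair probabilities (sums to 1).
#' @export
compute_glcm <- function(gray, mask = NULL, levels = 8, distance = 1,
                         angle = 0, symmetric = FALSE) {
  if (!is.matrix(gray)) abort("`gray` must be a numeric matrix.")
  if (levels < 2) abort("`levels` must be at least 2.")
  if (distance < 1) abort("`distance` must be at least 1.")
  if (!angle %in% c(0, 45, 90, 135)) {
    abort("`angle` must be one of 0, 45, 90, 135.")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gray), ncol(gray))
  q <- quantize_gray(gray, levels)
  off <- glcm_offset(angle, distance)
  dr <- off[1]; dc <- off[2]
  nr <- nrow(gray); nc <- ncol(gray)
  rows <- seq_len(nr); cols <- seq_len(nc)
  src_r <- rows[rows + dr >= 1 & rows + dr <= nr]
  src_c <- cols[cols + dc >= 1 & cols + dc <= nc]
  if (length(src_r) == 0 || length(src_c) == 0) {
    abort("no valid pixel pair for this offset.")
  }
  a <- q[src_r, src_c, drop = FALSE]
  b <- q[src_r + dr, src_c + dc, drop = FALSE]
  ok <- mask[src_r, src_c, drop = FALSE] &
    mask[src_r + dr, src_c + dc, drop = FALSE]
  if (!any(ok)) abort("no valid pixel pair inside the mask.")
  idx <- (a[ok] - 1L) * levels + b[ok]
  counts <- tabulate(idx, nbins = levels * levels)
  glcm <- matrix(counts, levels, levels, byrow = TRUE)
  if (symmetric) glcm <- glcm + t(glcm)
  glcm / sum(glcm)
}

quantize_gray <- function(gray, levels) {
  q <- floor(gray / 256 * levels) + 1L
  matrix(pmin(pmax(as.integer(q), 1L), as.integer(levels)), nrow(gray))
}

# (row, col) displacement for the four standard angles.
glcm_offset <- function(angle, distance) {
  switch(as.character(angle),
    "0"   = c(0, 1),
    "45"  = c(-1, 1),
    "90"  = c(-1, 0),
    "135" = c(-1, -1)
  ) * distance
}

glcm_feature_names <- function() {
  c("contrast", "sum_of_squares", "second_diagonal_moment", "mean",
    "sum_entropy", "difference_variance", "difference_entropy",
    "imc1", "imc2", "inverse_difference", "inn", "idmn",
    "diagonal_moment", "sum_average", "variance", "sum_variance",
    "standard_deviation", "coefficient_of_variation",
    "maximum_probability", "correlation")
}

#' Texture statistics of a co-occurrence matrix
#'
#' Computes the 20 texture features used by the classifier from one
#' normalized GLCM. Logarithms are base 2 with the convention
#' `0 * log(0) = 0`. With `p` the matrix, indices `i, j` in `1..N`,
#' `p_x`/`p_y` the row/column marginals, `p_{x+y}`/`p_{x-y}` the sum and
#' absolute-difference marginals, and `mu_x, mu_y, sigma_x, sigma_y`
#' their means and standard deviations, the features are:
#' contrast `sum (i-j)^2 p`; sum of squares `sum (i-mu_x)^2 p`;
#' second diagonal moment `sum |i-j| (i-j)^2 p`; mean `mu_x`;
#' sum entropy and difference entropy (entropies of the marginals);
#' difference variance `Var(p_{x-y})`; the two information measures of
#' correlation; inverse difference `sum p / (1 + |i-j|)`; its normalized
#' forms INN `sum p / (1 + |i-j|/N)` and IDMN `sum p / (1 + (i-j)^2/N^2)`;
#' diagonal moment `sum |i-j| p`; sum average `sum k p_{x+y}`; variance
#' `sum (i-mu)^2 p` with `mu` the grand mean `(mu_x + mu_y)/2`; sum
#' variance `sum (k - SumAvg)^2 p_{x+y}`; standard deviation
#' `sqrt(variance)`; coefficient of variation `sigma/mu` (0 when
#' `mu = 0`); maximum probability `max p`; correlation
#' `sum (i-mu_x)(j-mu_y) p / (sigma_x sigma_y)` (0 when degenerate).
#'
#' @param glcm nonnegative matrix summing to 1 (see [compute_glcm()]).
#' @return named numeric vector of length 20.
#' @export
glcm_features <- function(glcm) {
  if (!is.matrix(glcm) || nrow(glcm) != ncol(glcm)) {
    abort("`glcm` must be a square matrix.")
  }
  if (any(glcm < 0) || sum(glcm) == 0) {
    abort("`glcm` must be nonnegative and nonzero.")
  }
  p <- glcm / sum(glcm)
  n <- nrow(p)
  i <- matrix(rep(seq_len(n), n), n)        # row index
  j <- t(i)                                  # column index
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(seq_len(n) * px)
  mu_y <- sum(seq_len(n) * py)
  sigma_x <- sqrt(sum((seq_len(n) - mu_x)^2 * px))
  sigma_y <- sqrt(sum((seq_len(n) - mu_y)^2 * py))
  # sum and difference marginals
  ks <- 2:(2 * n)
  p_sum <- vapply(ks, function(k) sum(p[i + j == k]), numeric(1))
  kd <- 0:(n - 1)
  p_diff <- vapply(kd, function(k) sum(p[abs(i - j) == k]), numeric(1))
  ent <- function(q) -sum(xlogx(q))
  hxy <- ent(p)
  pxy_prod <- outer(px, py)
  hxy1 <- -sum(p * log2z(pxy_prod))
  hxy2 <- -sum(xlogx2(pxy_prod))
  hx <- ent(px)
  hy <- ent(py)
  sum_avg <- sum(ks * p_sum)
  mu_g <- (mu_x + mu_y) / 2
  variance <- sum((i - mu_g)^2 * p)
  std_dev <- sqrt(variance)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  correlation <- if (sigma_x * sigma_y > 0) {
    sum((i - mu_x) * (j - mu_y) * p) / (sigma_x * sigma_y)
  } else 0
  out <- c(
    contrast = sum((i - j)^2 * p),
    sum_of_squares = sum((i - mu_x)^2 * p),
    second_diagonal_moment = sum(abs(i - j) * (i - j)^2 * p),
    mean = mu_x,
    sum_entropy = ent(p_sum),
    difference_variance = sum((kd - sum(kd * p_diff))^2 * p_diff),
    difference_entropy = ent(p_diff),
    imc1 = imc1,
    imc2 = imc2,
    inverse_difference = sum(p / (1 + abs(i - j))),
    inn = sum(p / (1 + abs(i - j) / n)),
    idmn = sum(p / (1 + (i - j)^2 / n^2)),
    diagonal_moment = sum(abs(i - j) * p),
    sum_average = sum_avg,
    variance = variance,
    sum_variance = sum((ks - sum_avg)^2 * p_sum),
    standard_deviation = std_dev,
    coefficient_of_variation = if (mu_g != 0) std_dev / mu_g else 0,
    maximum_probability = max(p),
    correlation = correlation
  )
  out[glcm_feature_names()]
}

xlogx <- function(q) ifelse(q > 0, q * log2(q), 0)
xlogx2 <- xlogx
log2z <- function(q) ifelse(q > 0, log2(q), 0)
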