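# Internal helpers shared across modules.

# Deterministic fan-out of one master seed into per-stage streams, so any
# stage can be reproduced in isolation. Kept below 2^31 - 1.
fanout_seed <- function(seed, stage, index = 0L) {
  stage_hash <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(seed) * 48271 + stage_hash * 7919 + as.numeric(index)) %%
    2147483647
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stratified index split: returns a list of disjoint index vectors covering
# seq_len(n), with per-class proportions preserved (largest-remainder
# rounding, every split gets at least one sample per class when feasible).
stratified_split <- function(labels, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  out <- lapply(fractions, function(f) integer(0))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    n_cl <- length(idx)
    sizes <- floor(fractions * n_cl)
    rem <- n_cl - sum(sizes)
    if (rem > 0) {
      frac_rem <- fractions * n_cl - sizes
      bump <- order(frac_rem, decreasing = TRUE)[seq_len(rem)]
      sizes[bump] <- sizes[bump] + 1
    }
    at <- c(0, cumsum(sizes))
    for (k in seq_along(fractions)) {
      out[[k]] <- c(out[[k]], idx[seq.int(at[k] + 1, length.out = sizes[k])])
    }
  }
  out
}

# z-score standardization fit on a training block, applied to any block.
fit_standardizer <- function(x) {
  mu <- colMeans(x)
  sigma <- apply(x, 2, sd)
  sigma[!is.finite(sigma) | sigma == 0] <- 1
  list(mu = mu, sigma = sigma)
}

apply_standardizer <- function(x, st) {
  sweep(sweep(as.matrix(x), 2, st$mu, "-"), 2, st$sigma, "/")
}

one_hot <- function(labels, classes) {
  m <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  m[cbind(seq_along(labels), match(labels, classes))] <- 1
  m
}
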