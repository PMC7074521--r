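#' Mixed integer/categorical search spaces
#'
#' A search space is an ordered list of dimensions, each either an
#' integer range or a categorical set. Optimizers work internally either
#' on continuous keys in \[0, 1\] (PSO) or directly on values (ACO, HS,
#' CA); `decode_keys()`/`encode_values()` map between the two so that
#' `decode(encode(v)) = v` for every in-domain value.
#'
#' @param ... dimensions created with [dim_integer()] / [dim_categorical()].
#' @return object of class `"search_space"`.
#' @examples
#' sp <- search_space(
#'   n1 = dim_integer(1, 25),
#'   transfer = dim_categorical(c("tansig", "logsig"))
#' )
#' @export
search_space <- function(...) {
  dims <- list(...)
  if (length(dims) == 0) abort("a search space needs at least 1 dimension.")
  if (is.null(names(dims)) || any(names(dims) == "")) {
    abort("all dimensions must be named.")
  }
  structure(dims, class = "search_space")
}

#' @rdname search_space
#' @param lo,hi inclusive integer bounds.
#' @export
dim_integer <- function(lo, hi) {
  if (hi < lo) abort("empty integer domain.")
  list(kind = "integer", lo = as.integer(lo), hi = as.integer(hi))
}

#' @rdname search_space
#' @param levels character vector of categories.
#' @export
dim_categorical <- function(levels) {
  if (length(levels) < 1) abort("empty categorical domain.")
  list(kind = "categorical", levels = levels)
}

space_size <- function(space) {
  prod(vapply(space, function(d) {
    if (d$kind == "integer") d$hi - d$lo + 1 else length(d$levels)
  }, numeric(1)))
}

# Continuous key in [0, 1] -> value, uniform over the domain.
decode_keys <- function(space, keys) {
  out <- vector("list", length(space))
  names(out) <- names(space)
  for (d in seq_along(space)) {
    dm <- space[[d]]
    k <- min(max(keys[d], 0), 1 - 1e-12)
    if (dm$kind == "integer") {
      out[[d]] <- dm$lo + as.integer(floor(k * (dm$hi - dm$lo + 1)))
    } else {
      out[[d]] <- dm$levels[1 + as.integer(floor(k * length(dm$levels)))]
    }
  }
  out
}

encode_values <- function(space, values) {
  vapply(seq_along(space), function(d) {
    dm <- space[[d]]
    if (dm$kind == "integer") {
      (values[[d]] - dm$lo + 0.5) / (dm$hi - dm$lo + 1)
    } else {
      (match(values[[d]], dm$levels) - 0.5) / length(dm$levels)
    }
  }, numeric(1))
}

random_values <- function(space) {
  decode_keys(space, runif(length(space)))
}

# Exhaustive enumeration (small spaces only; used by tests and oracles).
enumerate_space <- function(space, limit = 10000) {
  if (space_size(space) > limit) abort("space too large to enumerate.")
  grids <- lapply(space, function(d) {
    if (d$kind == "integer") seq.int(d$lo, d$hi) else d$levels
  })
  grid <- expand.grid(grids, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(r) as.list(grid[r, , drop = FALSE]))
}

new_trace <- function(seed) {
  structure(list(iteration = integer(0), best_fitness = numeric(0),
                 n_evaluations = 0L, seed = seed),
            class = "optimizer_trace")
}

#' @export
print.optimizer_trace <- function(x, ...) {
  cat("<optimizer_trace> ", length(x$iteration), " iterations, ",
      x$n_evaluations, " evaluations, best ",
      format(min(c(x$best_fitness, Inf))), "\n", sep = "")
  invisible(x)
}

#' Tidy an optimizer trace
#'
#' @param x an `"optimizer_trace"`.
#' @param ... unused.
#' @return tibble with `iteration` and `best_fitness`.
#' @export
tidy.optimizer_trace <- function(x, ...) {
  tibble(iteration = x$iteration, best_fitness = x$best_fitness)
}

# Shared evaluation wrapper: non-finite objective values are rejected
# with a warning and treated as +Inf fitness.
safe_eval <- function(objective, values) {
  f <- tryCatch(objective(values), error = function(e) {
    warn(paste0("objective error treated as infeasible: ",
                conditionMessage(e)))
    Inf
  })
  if (!is.numeric(f) || length(f) != 1 || !is.finite(f)) {
    if (!identical(f, Inf)) warn("non-finite objective value rejected.")
    f <- Inf
  }
  f
}
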