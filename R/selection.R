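#' Cultural-algorithm wrapper feature selection
#'
#' Searches subsets of the feature columns (allowed cardinalities 3, 5,
#' 9, 11 by default) with the cultural algorithm, scoring each subset by
#' the validation MSE of a fixed two-hidden-layer network (8 and 19
#' units, `tribas`/`tansig` transfers, Levenberg-Marquardt training).
#' Samples are split 70/15/15 (train/validation/test, stratified by
#' class) once per run; features are z-scored using training-split
#' statistics before entering the network. The subset with the lowest
#' validation MSE wins.
#'
#' Subsets are encoded as a fixed-length index vector plus a cardinality
#' dimension; duplicate indices are repaired deterministically (advance
#' to the next unused feature), and fitness values are cached per
#' canonical subset so revisits are free.
#'
#' @param features a data frame with feature columns and a `label`
#'   column (e.g. from [extract_dataset()]).
#' @param sizes allowed subset cardinalities (default `c(3, 5, 9, 11)`).
#' @param seed master seed (splits, network init, CA search).
#' @param feature_cols candidate columns (default: all numeric columns
#'   except `label`/`image_id`).
#' @param pop_size,n_iters CA population and iteration counts.
#' @param epochs training-epoch budget per fitness evaluation (default
#'   100).
#' @param patience early-stopping patience for fitness training.
#' @return object of class `"sv_selection"`: `features` (selected
#'   names), `size`, `mse` (best validation MSE), `trace`, `seed`.
#' @export
select_features <- function(features, sizes = c(3, 5, 9, 11), seed = 1,
                            feature_cols = NULL, pop_size = 20,
                            n_iters = 15, epochs = 100, patience = 10) {
  if (!"label" %in% names(features)) abort("`features` needs a label column.")
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                                   logical(1))],
                            c("label", "image_id"))
  }
  missing_cols <- setdiff(feature_cols, names(features))
  if (length(missing_cols) > 0) {
    abort(paste("unknown feature columns:",
                paste(missing_cols, collapse = ", ")))
  }
  labels <- as.character(features$label)
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("at least 2 classes are required.")
  X_all <- as.matrix(features[, feature_cols, drop = FALSE])
  n <- nrow(X_all)
  if (floor(0.7 * min(table(labels))) < 1 ||
      floor(0.15 * n) < 1) {
    abort("too few samples for a 70/15/15 split.")
  }

  split <- with_seed(fanout_seed(seed, "selection_split"),
                     stratified_split(labels, c(0.7, 0.15, 0.15)))
  T_all <- one_hot(labels, classes)
  net_seed <- fanout_seed(seed, "selection_net")

  cache <- new.env(parent = emptyenv())
  p <- length(feature_cols)
  fitness <- function(subset_idx) {
    key <- paste(sort(subset_idx), collapse = ",")
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    cols <- sort(subset_idx)
    st <- fit_standardizer(X_all[split[[1]], cols, drop = FALSE])
    Xtr <- apply_standardizer(X_all[split[[1]], cols, drop = FALSE], st)
    Xva <- apply_standardizer(X_all[split[[2]], cols, drop = FALSE], st)
    cfg <- mlp_config(c(8, 19), c("tribas", "tansig"),
                      train = "trainlm", learn = "learncon")
    model <- mlp_init(cfg, n_inputs = length(cols),
                      n_outputs = length(classes), seed = net_seed)
    model <- mlp_train(model, Xtr, T_all[split[[1]], , drop = FALSE],
                       Xva, T_all[split[[2]], , drop = FALSE],
                       max_epochs = epochs, patience = patience)
    f <- mlp_mse(model, Xva, T_all[split[[2]], , drop = FALSE])
    assign(key, f, envir = cache)
    f
  }

  max_size <- max(sizes)
  dims <- c(
    list(size = dim_categorical(as.character(sizes))),
    setNames(lapply(seq_len(max_size), function(i) dim_integer(1, p)),
             paste0("idx", seq_len(max_size)))
  )
  space <- do.call(search_space, dims)
  objective <- function(values) {
    fitness(decode_subset(values, p))
  }
  res <- ca_optimize(objective, space, pop_size = pop_size,
                     n_iters = n_iters,
                     seed = fanout_seed(seed, "selection_ca"))
  best_idx <- decode_subset(res$best$values, p)
  structure(list(features = feature_cols[best_idx],
                 size = length(best_idx),
                 mse = res$best$fitness,
                 trace = res$trace,
                 seed = seed,
                 classes = classes),
            class = "sv_selection")
}

# First `size` index slots, with duplicates repaired by advancing to the
# next unused feature (wrapping at p).
decode_subset <- function(values, p) {
  size <- as.integer(values$size)
  raw <- unlist(values[paste0("idx", seq_len(size))], use.names = FALSE)
  used <- logical(p)
  out <- integer(size)
  for (k in seq_len(size)) {
    v <- raw[k]
    while (used[v]) v <- (v %% p) + 1L
    used[v] <- TRUE
    out[k] <- v
  }
  sort(out)
}

#' @export
print.sv_selection <- function(x, ...) {
  cat("<sv_selection> ", x$size, " features, validation MSE ",
      format(x$mse, digits = 4), "\n  ",
      paste(x$features, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname select_features
#' @param x an `"sv_selection"`.
#' @param ... unused.
#' @export
tidy.sv_selection <- function(x, ...) {
  tibble(feature = x$features, rank = seq_along(x$features))
}

#' @rdname select_features
#' @export
glance.sv_selection <- function(x, ...) {
  tibble(n_selected = x$size, val_mse = x$mse,
         n_evaluations = x$trace$n_evaluations, seed = x$seed)
}
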