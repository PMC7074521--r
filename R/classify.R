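#' Architecture search space of the hybrid classifiers
#'
#' Candidates are fixed-length vectors: first-layer size 1-25, second
#' and third layer sizes 0-25 (0 = layer absent), three transfer names,
#' a training rule and a weight/bias learning rule. A candidate with
#' `n2 = 0` is a one-layer network regardless of `n3`.
#'
#' @return a [search_space()] over the 8 architecture dimensions.
#' @export
architecture_space <- function() {
  search_space(
    n1 = dim_integer(1, 25),
    n2 = dim_integer(0, 25),
    n3 = dim_integer(0, 25),
    t1 = dim_categorical(transfer_ids()),
    t2 = dim_categorical(transfer_ids()),
    t3 = dim_categorical(transfer_ids()),
    train = dim_categorical(mlp_trainers()),
    learn = dim_categorical(c("learngdm", "learngd", "learncon",
                              "learnh", "learnhd", "learnis", "learnk",
                              "learnlv1", "learnlv2", "learnos",
                              "learnp", "learnpn", "learnwh"))
  )
}

# Candidate values -> mlp_config (absent layers dropped).
values_to_config <- function(values) {
  neurons <- c(values$n1, values$n2, values$n3)
  transfers <- c(values$t1, values$t2, values$t3)
  present <- if (neurons[2] == 0) 1 else if (neurons[3] == 0) 1:2 else 1:3
  mlp_config(neurons[present], transfers[present],
             train = values$train, learn = values$learn)
}

#' Published optimal architectures
#'
#' The three tuned architectures reported for the hybrid classifiers,
#' loadable as fixed presets: PSO 16/9/18 (`netinv`, `satlins`,
#' `compet`) with `traingdx`; ACO 12/3/13 (`satlin`, `satlin`,
#' `poslin`) with `traingd`; HS 13/10/17 (`tansig`, `satlin`, `logsig`)
#' with `trainlm`.
#'
#' @param id `"pso"`, `"aco"`, or `"hs"`.
#' @return an [mlp_config()].
#' @export
published_architecture <- function(id = c("pso", "aco", "hs")) {
  id <- match.arg(id)
  switch(id,
    pso = mlp_config(c(16, 9, 18), c("netinv", "satlins", "compet"),
                     train = "traingdx", learn = "learnlv1"),
    aco = mlp_config(c(12, 3, 13), c("satlin", "satlin", "poslin"),
                     train = "traingd", learn = "learnlv2"),
    hs = mlp_config(c(13, 10, 17), c("tansig", "satlin", "logsig"),
                    train = "trainlm", learn = "learnp")
  )
}

#' Tune an MLP architecture with a metaheuristic
#'
#' Runs PSO, ACO, or HS over [architecture_space()]; the fitness of a
#' candidate is the validation MSE of the decoded network trained on
#' the supplied split. Inputs are assumed already restricted to the
#' selected features and standardized.
#'
#' @param x_train,y_train,x_val,y_val standardized inputs and one-hot
#'   targets.
#' @param optimizer `"pso"`, `"aco"`, or `"hs"`.
#' @param budget approximate objective-evaluation budget (population
#'   sizes and iteration counts are derived from it).
#' @param seed RNG seed.
#' @param epochs,patience per-candidate training budget.
#' @return list with `config` (best [mlp_config()]), `fitness`, `trace`.
#' @export
tune_architecture <- function(x_train, y_train, x_val, y_val,
                              optimizer = c("pso", "aco", "hs"),
                              budget = 120, seed = 1, epochs = 80,
                              patience = 10) {
  optimizer <- match.arg(optimizer)
  pop <- 12
  if (budget < pop) abort("`budget` must cover at least one population.")
  iters <- max(1, floor(budget / pop) - 1)
  objective <- function(values) {
    cfg <- values_to_config(values)
    model <- mlp_init(cfg, n_inputs = ncol(x_train),
                      n_outputs = ncol(y_train),
                      seed = fanout_seed(seed, "tune_init"))
    model <- mlp_train(model, x_train, y_train, x_val, y_val,
                       max_epochs = epochs, patience = patience)
    mlp_mse(model, x_val, y_val)
  }
  space <- architecture_space()
  res <- switch(optimizer,
    pso = pso_optimize(objective, space, n_particles = pop,
                       n_iters = iters, seed = seed),
    aco = aco_optimize(objective, space, n_ants = pop, archive_size = pop,
                       n_iters = iters, seed = seed),
    hs = hs_optimize(objective, space, harmony_memory_size = pop,
                     n_iters = max(1, budget - pop), seed = seed)
  )
  list(config = values_to_config(res$best$values),
       fitness = res$best$fitness, trace = res$trace,
       optimizer = optimizer)
}

#' Majority vote of three classifiers
#'
#' Returns the modal label when at least two classifiers agree. A
#' three-way disagreement is broken by the highest softmax confidence;
#' a confidence tie falls back to the harmony-search classifier's label
#' (the strongest single classifier).
#'
#' @param labels character vector of 3 predicted labels (PSO, ACO, HS
#'   order).
#' @param confidences numeric vector of 3 winning-class scores.
#' @return single winning label.
#' @export
majority_vote <- function(labels, confidences = c(0, 0, 0)) {
  stopifnot(length(labels) == 3)
  counts <- table(labels)
  if (max(counts) >= 2) return(names(counts)[which.max(counts)])
  best <- which(confidences == max(confidences))
  if (length(best) > 1) return(labels[3])
  labels[best]
}

#' Run the repeated-split classification experiment
#'
#' Per iteration: a fresh stratified split reserves `test_frac` of the
#' samples for testing and `val_frac` (of the total) for validation;
#' the three hybrid classifiers are trained on the remainder, predict
#' all three partitions, and the majority vote combines their test
#' predictions. Confusion matrices are pooled (summed) across
#' iterations, and per-iteration CCR and one-vs-rest AUC are recorded.
#'
#' Architectures are tuned once, on the first split, and the fixed
#' configurations are re-trained each iteration (set
#' `retune_each_iteration = TRUE` to re-run the search every split;
#' `configs` can supply fixed configurations, skipping tuning).
#'
#' @param features feature table with a `label` column.
#' @param feature_cols which feature columns to use (e.g.
#'   `feature_preset("paper5")`); default: all numeric except ids.
#' @param n_iterations number of random splits (default 1000).
#' @param test_frac test fraction (default 0.30).
#' @param val_frac validation fraction of the total (default 0.15).
#' @param seed master seed.
#' @param tune_budget evaluation budget per optimizer during tuning.
#' @param epochs,patience per-iteration training budget.
#' @param configs optional named list (`pso`, `aco`, `hs`) of
#'   [mlp_config()]s to use instead of tuning.
#' @param retune_each_iteration logical (default `FALSE`).
#' @return object of class `"sv_experiment"`: pooled confusion matrices
#'   (`pooled$<classifier>$<set>`), per-iteration metric tibble
#'   (`metrics`), tuned `configs`, and the experiment settings.
#' @export
run_experiment <- function(features, feature_cols = NULL,
                           n_iterations = 1000, test_frac = 0.30,
                           val_frac = 0.15, seed = 1, tune_budget = 60,
                           epochs = 80, patience = 10, configs = NULL,
                           retune_each_iteration = FALSE) {
  stopifnot(test_frac > 0, test_frac < 1, val_frac > 0,
            val_frac < 1 - test_frac)
  if (!"label" %in% names(features)) abort("`features` needs a label column.")
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                                   logical(1))],
                            c("label", "image_id"))
  }
  labels <- as.character(features$label)
  classes <- sort(unique(labels))
  X_all <- as.matrix(features[, feature_cols, drop = FALSE])
  T_all <- one_hot(labels, classes)
  members <- c("pso", "aco", "hs")
  fractions <- c(train = 1 - test_frac - val_frac, val = val_frac,
                 test = test_frac)

  draw_split <- function(it) {
    for (attempt in 0:24) {
      sp <- with_seed(fanout_seed(seed, "split", it * 100 + attempt),
                      stratified_split(labels, fractions))
      ok <- all(vapply(sp, function(ix) {
        length(unique(labels[ix])) == length(classes)
      }, logical(1)))
      if (ok) return(sp)
      warn("a class was absent from a split; redrawing.")
    }
    abort("could not draw a split containing every class.")
  }

  prepare <- function(sp) {
    st <- fit_standardizer(X_all[sp[[1]], , drop = FALSE])
    lapply(sp, function(ix) list(
      X = apply_standardizer(X_all[ix, , drop = FALSE], st),
      T = T_all[ix, , drop = FALSE],
      y = labels[ix]))
  }

  tune_one <- function(member, parts) {
    tune_architecture(parts[[1]]$X, parts[[1]]$T, parts[[2]]$X,
                      parts[[2]]$T, optimizer = member,
                      budget = tune_budget,
                      seed = fanout_seed(seed, paste0("tune_", member)),
                      epochs = epochs, patience = patience)$config
  }

  sp0 <- draw_split(0)
  parts0 <- prepare(sp0)
  if (is.null(configs)) {
    configs <- setNames(lapply(members, tune_one, parts = parts0), members)
  }

  set_names <- c("train", "val", "test")
  pooled <- lapply(setNames(c(members, "mv"), c(members, "mv")),
                   function(m) {
    lapply(setNames(set_names, set_names), function(s) {
      matrix(0L, length(classes), length(classes),
             dimnames = list(classes, classes))
    })
  })
  metric_rows <- list()

  for (it in seq_len(n_iterations)) {
    sp <- draw_split(it)
    parts <- prepare(sp)
    if (retune_each_iteration) {
      configs <- setNames(lapply(members, tune_one, parts = parts), members)
    }
    preds <- list(); scores <- list()
    for (m in members) {
      model <- mlp_init(configs[[m]], n_inputs = length(feature_cols),
                        n_outputs = length(classes),
                        seed = fanout_seed(seed, paste0("init_", m), it))
      model <- mlp_train(model, parts[[1]]$X, parts[[1]]$T,
                         parts[[2]]$X, parts[[2]]$T,
                         max_epochs = epochs, patience = patience)
      preds[[m]] <- lapply(parts, function(pt) {
        sc <- mlp_forward(model, pt$X)
        list(scores = sc, labels = classes[max.col(sc, "first")])
      })
    }
    # pooled matrices for the three members, all three partitions
    for (m in members) {
      for (s in seq_along(set_names)) {
        cm <- confusion_matrix(parts[[s]]$y, preds[[m]][[s]]$labels,
                               classes)
        pooled[[m]][[set_names[s]]] <- pooled[[m]][[set_names[s]]] + cm
      }
    }
    # majority vote on the test partition
    test_scores <- lapply(members, function(m) preds[[m]][[3]]$scores)
    mv_labels <- vapply(seq_len(nrow(parts[[3]]$X)), function(r) {
      lab3 <- vapply(members, function(m) preds[[m]][[3]]$labels[r], "")
      conf3 <- vapply(seq_along(members), function(k) {
        max(test_scores[[k]][r, ])
      }, numeric(1))
      majority_vote(unname(lab3), conf3)
    }, "")
    cm_mv <- confusion_matrix(parts[[3]]$y, mv_labels, classes)
    pooled$mv$test <- pooled$mv$test + cm_mv
    mv_scores <- Reduce(`+`, test_scores) / length(test_scores)

    for (m in members) {
      metric_rows[[length(metric_rows) + 1]] <- iteration_metrics(
        it, m, parts[[3]]$y, preds[[m]][[3]]$labels,
        preds[[m]][[3]]$scores, classes)
    }
    metric_rows[[length(metric_rows) + 1]] <- iteration_metrics(
      it, "mv", parts[[3]]$y, mv_labels, mv_scores, classes)
  }

  structure(list(pooled = pooled,
                 metrics = dplyr::bind_rows(metric_rows),
                 configs = configs, classes = classes,
                 feature_cols = feature_cols,
                 settings = list(n_iterations = n_iterations,
                                 test_frac = test_frac,
                                 val_frac = val_frac, seed = seed,
                                 epochs = epochs,
                                 tune_budget = tune_budget)),
            class = "sv_experiment")
}

iteration_metrics <- function(it, classifier, truth, pred, scores,
                              classes) {
  cm <- confusion_matrix(truth, pred, classes)
  aucs <- vapply(seq_along(classes), function(k) {
    roc_auc(scores[, k], truth == classes[k])
  }, numeric(1))
  tibble(iteration = it, classifier = classifier, ccr = ccr(cm),
         !!!setNames(as.list(aucs), paste0("auc_", classes)))
}

#' @export
print.sv_experiment <- function(x, ...) {
  cat("<sv_experiment> ", x$settings$n_iterations, " iterations, ",
      length(x$feature_cols), " features\n", sep = "")
  for (m in names(x$pooled)) {
    cm <- x$pooled[[m]]$test
    if (sum(cm) > 0) {
      cat(sprintf("  %-4s pooled test CCR %6.2f%%\n", m, ccr(cm)))
    }
  }
  invisible(x)
}

#' Tidy and summarize an experiment
#'
#' `tidy()` returns the per-iteration test metrics (one row per
#' iteration and classifier); `glance()` returns one row per classifier
#' with the pooled test CCR and the mean and standard deviation of the
#' per-iteration CCR and AUC values.
#'
#' @param x an `"sv_experiment"`.
#' @param ... unused.
#' @export
tidy.sv_experiment <- function(x, ...) x$metrics

#' @rdname tidy.sv_experiment
#' @export
glance.sv_experiment <- function(x, ...) {
  auc_cols <- grep("^auc_", names(x$metrics), value = TRUE)
  x$metrics |>
    dplyr::group_by(.data$classifier) |>
    dplyr::summarise(
      pooled_ccr = NA_real_,
      ccr_mean = mean(.data$ccr), ccr_sd = sd(.data$ccr),
      dplyr::across(dplyr::all_of(auc_cols), mean,
                    .names = "{.col}_mean"),
      .groups = "drop") |>
    dplyr::mutate(pooled_ccr = vapply(.data$classifier, function(m) {
      ccr(x$pooled[[m]]$test)
    }, numeric(1)))
}
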