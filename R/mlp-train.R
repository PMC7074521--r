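#' Training rules
#'
#' Implemented batch backpropagation rules: plain gradient descent
#' (`traingd`), gradient descent with momentum (`traingdm`), adaptive
#' learning rate (`traingda`), momentum plus adaptive rate (`traingdx`),
#' resilient backpropagation (`trainrp`), and Levenberg-Marquardt
#' (`trainlm`). The remaining names of the MATLAB-style vocabulary are
#' accepted and aliased to the nearest implemented rule with a warning.
#'
#' @return character vector of implemented trainer ids.
#' @export
mlp_trainers <- function() {
  c("traingd", "traingdm", "traingda", "traingdx", "trainrp", "trainlm")
}

trainer_aliases <- function() {
  c(trainbfg = "trainlm", trainbfgc = "trainlm", trainbr = "trainlm",
    traincgb = "trainrp", traincgf = "trainrp", traincgp = "trainrp",
    trainscg = "trainrp", trainoss = "trainrp", trainbuwb = "traingd",
    trainb = "traingd", trainc = "traingd", trainr = "traingd",
    trains = "traingd")
}

resolve_trainer <- function(id) {
  if (id %in% mlp_trainers()) return(id)
  al <- trainer_aliases()
  if (id %in% names(al)) {
    warn(paste0("trainer '", id, "' aliased to '", al[[id]], "'"))
    return(al[[id]])
  }
  abort(paste0("unknown trainer '", id, "'"))
}

#' Train an MLP by backpropagation with early stopping
#'
#' Full-batch training minimizing the MSE between softmax outputs and
#' one-hot targets. Training stops at `max_epochs`, when the training
#' MSE reaches `goal`, or when the validation MSE has not improved for
#' `patience` consecutive epochs (the weights of the best validation
#' epoch are restored).
#'
#' @param model an initialized [mlp_init()] model (its config's `train`
#'   id selects the rule).
#' @param x_train,y_train training inputs (matrix) and one-hot targets.
#' @param x_val,y_val validation inputs/targets (`NULL` disables early
#'   stopping).
#' @param max_epochs epoch cap (default 300).
#' @param patience validation non-improvement tolerance (default 20).
#' @param lr initial learning rate for the gradient-descent family.
#' @param momentum momentum coefficient (`traingdm`, `traingdx`).
#' @param goal training-MSE stopping goal.
#' @return the trained model, with a `record` element (class
#'   `"train_record"`): per-epoch train/validation MSE, stopping epoch
#'   and reason.
#' @export
mlp_train <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                      max_epochs = 300, patience = 20, lr = 0.01,
                      momentum = 0.9, goal = 1e-5) {
  if (nrow(x_train) == 0) abort("empty training set.")
  if (!is.null(x_val) && nrow(x_val) == 0) abort("empty validation set.")
  trainer <- model$config$train
  theta <- flatten_params(model)
  n_par <- length(theta)

  # rule state
  velocity <- numeric(n_par)
  rp_delta <- rep(0.07, n_par)
  rp_prev_g <- numeric(n_par)
  mu <- 1e-3
  lr_now <- lr
  prev_mse <- Inf

  train_mse <- numeric(0); val_mse <- numeric(0)
  best_val <- Inf; best_theta <- theta; best_epoch <- 0
  stop_reason <- "max_epochs"

  for (epoch in seq_len(max_epochs)) {
    model <- unflatten_params(model, theta)
    if (trainer == "trainlm") {
      res <- lm_step(model, x_train, y_train, theta, mu)
      theta <- res$theta; mu <- res$mu; mse_now <- res$mse
    } else {
      g <- mlp_gradient(model, x_train, y_train)
      gv <- flatten_grad(g)
      mse_now <- g$mse
      if (trainer %in% c("traingda", "traingdx")) {
        # adaptive rate: grow while improving, shrink and reject on
        # significant regression (max_perf_inc = 1.04)
        if (is.finite(prev_mse) && mse_now > prev_mse * 1.04) {
          lr_now <- lr_now * 0.7
          velocity <- velocity * 0
        } else if (mse_now < prev_mse) {
          lr_now <- lr_now * 1.05
        }
      }
      if (trainer %in% c("traingdm", "traingdx")) {
        velocity <- momentum * velocity - lr_now * gv
        step <- velocity
      } else if (trainer == "trainrp") {
        sign_change <- sign(gv) * sign(rp_prev_g)
        rp_delta <- pmin(pmax(
          ifelse(sign_change > 0, rp_delta * 1.2,
                 ifelse(sign_change < 0, rp_delta * 0.5, rp_delta)),
          1e-8), 50)
        step <- -sign(gv) * rp_delta
        rp_prev_g <- ifelse(sign_change < 0, 0, gv)
      } else {
        step <- -lr_now * gv
      }
      theta <- theta + step
      prev_mse <- mse_now
    }
    train_mse <- c(train_mse, mse_now)

    if (!is.null(x_val)) {
      vm <- mlp_mse(unflatten_params(model, theta), x_val, y_val)
      val_mse <- c(val_mse, vm)
      if (vm < best_val - 1e-12) {
        best_val <- vm; best_theta <- theta; best_epoch <- epoch
      } else if (epoch - best_epoch >= patience) {
        stop_reason <- "early_stop"
        break
      }
    } else {
      best_theta <- theta; best_epoch <- epoch
    }
    if (mse_now <= goal) {
      stop_reason <- "goal"
      if (is.null(x_val) || val_mse[length(val_mse)] <= best_val) {
        best_theta <- theta; best_epoch <- epoch
      }
      break
    }
  }
  model <- unflatten_params(model, best_theta)
  model$record <- structure(
    list(train_mse = train_mse, val_mse = val_mse,
         stop_epoch = length(train_mse), best_epoch = best_epoch,
         stop_reason = stop_reason),
    class = "train_record")
  model
}

# One Levenberg-Marquardt epoch: try damped Gauss-Newton steps, adapting
# mu until the training MSE decreases (or mu hits its cap).
lm_step <- function(model, X, T, theta, mu) {
  jac <- mlp_jacobian(model, X)
  r <- as.vector(jac$Y - T)
  mse0 <- mean(r^2)
  JtJ <- crossprod(jac$J)
  Jtr <- crossprod(jac$J, r)
  for (tries in 1:8) {
    step <- tryCatch(
      -solve(JtJ + diag(mu, ncol(JtJ)), Jtr),
      error = function(e) NULL)
    if (!is.null(step)) {
      cand <- theta + as.vector(step)
      mse1 <- mlp_mse(unflatten_params(model, cand), X, T)
      if (is.finite(mse1) && mse1 < mse0) {
        return(list(theta = cand, mu = max(mu * 0.1, 1e-12), mse = mse1))
      }
    }
    mu <- mu * 10
    if (mu > 1e10) break
  }
  list(theta = theta, mu = mu, mse = mse0)
}

#' Serialize a model to JSON (and back)
#'
#' The format stores the architecture descriptor and all weight/bias
#' arrays; a load-save-forward round trip is bit-identical.
#'
#' @param model an `"mlp_model"`.
#' @param path file path.
#' @export
mlp_save <- function(model, path) {
  # weights stored as %.17g strings: decimal text that round-trips
  # doubles bit-exactly
  payload <- list(
    config = unclass(model$config),
    n_inputs = model$n_inputs, n_outputs = model$n_outputs,
    seed = model$seed,
    W = lapply(model$W, function(w) {
      list(dim = dim(w), data = sprintf("%.17g", as.vector(w)))
    }),
    b = lapply(model$b, function(v) sprintf("%.17g", v))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname mlp_save
#' @export
mlp_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- mlp_config(unlist(p$config$neurons), unlist(p$config$transfers),
                    p$config$train, p$config$learn)
  W <- lapply(p$W, function(w) {
    matrix(as.numeric(unlist(w$data)), unlist(w$dim)[1],
           unlist(w$dim)[2])
  })
  b <- lapply(p$b, function(v) as.numeric(unlist(v)))
  structure(list(config = cfg, W = W, b = b, n_inputs = p$n_inputs,
                 n_outputs = p$n_outputs, seed = p$seed),
            class = "mlp_model")
}
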