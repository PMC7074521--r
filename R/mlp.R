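#' Multilayer perceptron with the classic MATLAB-style transfer set
#'
#' The classifier core is a fully connected feed-forward network: 1-3
#' hidden layers with per-layer transfer functions drawn from the
#' 13-name vocabulary below, and a softmax output layer (one unit per
#' class). Targets are one-hot vectors and training minimizes the mean
#' squared error between softmax outputs and targets.
#'
#' @name mlp
NULL

transfer_ids <- function() {
  c("tansig", "logsig", "purelin", "hardlim", "compet", "hardlims",
    "netinv", "poslin", "radbas", "satlin", "satlins", "softmax",
    "tribas")
}

# netinv guard: 1/x is replaced by sign(x)/eps near zero so forward
# passes stay finite.
.netinv_eps <- 1e-12

#' Transfer functions
#'
#' Applies one of the 13 named nonlinearities elementwise (`compet` and
#' `softmax` act per row vector). `netinv` is guarded near zero: inputs
#' with |x| < 1e-12 map to a large finite value instead of Inf.
#'
#' @param id transfer name (see [mlp]).
#' @param x numeric vector or matrix (rows = samples).
#' @return same shape as `x`.
#' @export
transfer <- function(id, x) {
  id <- match.arg(id, transfer_ids())
  m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  out <- switch(id,
    tansig = tanh(m),
    logsig = 1 / (1 + exp(-m)),
    purelin = m,
    hardlim = (m >= 0) * 1,
    hardlims = ifelse(m >= 0, 1, -1),
    netinv = {
      g <- ifelse(abs(m) < .netinv_eps,
                  .netinv_eps * ifelse(m < 0, -1, 1), m)
      1 / g
    },
    poslin = pmax(m, 0),
    radbas = exp(-m^2),
    satlin = pmin(pmax(m, 0), 1),
    satlins = pmin(pmax(m, -1), 1),
    tribas = pmax(0, 1 - abs(m)),
    softmax = row_softmax(m),
    compet = {
      o <- m * 0
      o[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))] <- 1
      o
    }
  )
  if (!is.matrix(out)) out <- matrix(out, nrow(m), ncol(m))
  if (is.matrix(x)) out else as.vector(out)
}

row_softmax <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# Derivative of each transfer wrt its input, given input z and output a.
# Non-differentiable transfers (hardlim, hardlims, compet) have zero
# derivative: architectures using them simply do not learn by gradient
# and are weeded out by the metaheuristic search via their fitness.
transfer_deriv <- function(id, z, a) {
  switch(id,
    tansig = 1 - a^2,
    logsig = a * (1 - a),
    purelin = z * 0 + 1,
    hardlim = z * 0,
    hardlims = z * 0,
    netinv = -1 / pmax(z^2, .netinv_eps),
    poslin = (z > 0) * 1,
    radbas = -2 * z * a,
    satlin = (z > 0 & z < 1) * 1,
    satlins = (z > -1 & z < 1) * 1,
    tribas = -sign(z) * (abs(z) < 1),
    compet = z * 0,
    softmax = NULL  # handled via full Jacobian in backprop
  )
}

#' Build an MLP architecture descriptor
#'
#' @param neurons integer vector of hidden-layer sizes (1-3 layers,
#'   first layer 1-25, later layers 1-25 when present).
#' @param transfers per-layer transfer names.
#' @param train training-rule id (see [mlp_trainers()]).
#' @param learn weight/bias learning-rule id; carried for fidelity with
#'   the MATLAB configuration idiom and recorded on the model, but batch
#'   updates are governed by `train`.
#' @return object of class `"mlp_config"`.
#' @export
mlp_config <- function(neurons, transfers, train = "trainlm",
                       learn = "learngdm") {
  neurons <- as.integer(neurons)
  if (length(neurons) < 1 || length(neurons) > 3) {
    abort("1 to 3 hidden layers are supported.")
  }
  if (any(neurons < 1) || any(neurons > 25)) {
    abort("hidden-layer sizes must be in 1..25.")
  }
  if (length(transfers) != length(neurons)) {
    abort("one transfer per hidden layer is required.")
  }
  transfers <- vapply(transfers, match.arg, "", choices = transfer_ids())
  structure(list(neurons = neurons, transfers = unname(transfers),
                 train = resolve_trainer(train), learn = learn),
            class = "mlp_config")
}

#' @export
print.mlp_config <- function(x, ...) {
  cat("<mlp_config> ", paste(x$neurons, collapse = "-"), " [",
      paste(x$transfers, collapse = ", "), "] ", x$train, "/", x$learn,
      "\n", sep = "")
  invisible(x)
}

#' Initialize network weights
#'
#' Weights are drawn uniformly from \[-r, r\] with
#' `r = sqrt(6 / (fan_in + fan_out))` (Glorot-style scaling); biases
#' start at zero. Reproducible given `seed`.
#'
#' @param config an [mlp_config()].
#' @param n_inputs number of input features.
#' @param n_outputs number of classes (softmax units, default 3).
#' @param seed integer RNG seed.
#' @return object of class `"mlp_model"`.
#' @export
mlp_init <- function(config, n_inputs, n_outputs = 3, seed = 1) {
  stopifnot(inherits(config, "mlp_config"))
  sizes <- c(n_inputs, config$neurons, n_outputs)
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1)) {
      r <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -r, r),
                       sizes[l], sizes[l + 1])
      b[[l]] <- numeric(sizes[l + 1])
    }
    structure(list(config = config, W = W, b = b, n_inputs = n_inputs,
                   n_outputs = n_outputs, seed = seed),
              class = "mlp_model")
  })
}

# Forward pass keeping intermediate activations (for backprop).
mlp_forward_full <- function(model, X) {
  transfers <- c(model$config$transfers, "softmax")
  A <- list(X); Z <- list()
  for (l in seq_along(model$W)) {
    Z[[l]] <- sweep(A[[l]] %*% model$W[[l]], 2, model$b[[l]], "+")
    A[[l + 1]] <- transfer(transfers[l], Z[[l]])
  }
  list(A = A, Z = Z)
}

#' Forward pass
#'
#' @param model an [mlp_init()] / [mlp_train()] model.
#' @param x numeric matrix (rows = samples) or a single feature vector.
#' @return matrix of class scores; each row sums to 1 (softmax output).
#' @export
mlp_forward <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_inputs) {
    abort("input dimension does not match the model.")
  }
  ff <- mlp_forward_full(model, x)
  ff$A[[length(ff$A)]]
}

mlp_mse <- function(model, X, T) {
  Y <- mlp_forward(model, X)
  mean((Y - T)^2)
}

# Gradient of mean((softmax - T)^2) wrt all weights/biases (full batch).
mlp_gradient <- function(model, X, T) {
  ff <- mlp_forward_full(model, X)
  L <- length(model$W)
  n <- nrow(X); K <- ncol(T)
  Y <- ff$A[[L + 1]]
  G <- 2 * (Y - T) / (n * K)
  dZ <- Y * (G - rowSums(G * Y))  # softmax Jacobian applied to G
  gW <- vector("list", L); gb <- vector("list", L)
  transfers <- model$config$transfers
  for (l in L:1) {
    gW[[l]] <- crossprod(ff$A[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1) {
      dA <- dZ %*% t(model$W[[l]])
      id <- transfers[l - 1]
      if (id == "softmax") {
        Aprev <- ff$A[[l]]
        dZ <- Aprev * (dA - rowSums(dA * Aprev))
      } else {
        dZ <- dA * transfer_deriv(id, ff$Z[[l - 1]], ff$A[[l]])
      }
    }
  }
  list(gW = gW, gb = gb, mse = mean((Y - T)^2))
}

flatten_params <- function(model) {
  c(unlist(model$W), unlist(model$b))
}

unflatten_params <- function(model, theta) {
  at <- 0
  for (l in seq_along(model$W)) {
    k <- length(model$W[[l]])
    model$W[[l]][] <- theta[at + seq_len(k)]
    at <- at + k
  }
  for (l in seq_along(model$b)) {
    k <- length(model$b[[l]])
    model$b[[l]][] <- theta[at + seq_len(k)]
    at <- at + k
  }
  model
}

flatten_grad <- function(g) c(unlist(g$gW), unlist(g$gb))

# Jacobian of the residual vector vec(Y - T) wrt all parameters.
# Rows ordered sample-major within each output unit block.
mlp_jacobian <- function(model, X) {
  ff <- mlp_forward_full(model, X)
  L <- length(model$W)
  n <- nrow(X); K <- model$n_outputs
  Y <- ff$A[[L + 1]]
  transfers <- model$config$transfers
  nW <- sum(vapply(model$W, length, numeric(1)))
  nb <- sum(vapply(model$b, length, numeric(1)))
  J <- matrix(0, n * K, nW + nb)
  for (k in seq_len(K)) {
    ek <- numeric(K); ek[k] <- 1
    # d y_k / d z_out per sample: y_k * (e_k - y)
    dZ <- Y * matrix(ek, n, K, byrow = TRUE) - Y * Y[, k]
    rows <- (k - 1) * n + seq_len(n)
    atW <- 0; atb <- nW
    blocksW <- vector("list", L); blocksb <- vector("list", L)
    for (l in L:1) {
      m <- ncol(dZ); p <- ncol(ff$A[[l]])
      # column order matches unlist(W[[l]]): column-major (v-1)*p + u
      blocksW[[l]] <- ff$A[[l]][, rep(seq_len(p), times = m), drop = FALSE] *
        dZ[, rep(seq_len(m), each = p), drop = FALSE]
      blocksb[[l]] <- dZ
      if (l > 1) {
        dA <- dZ %*% t(model$W[[l]])
        id <- transfers[l - 1]
        if (id == "softmax") {
          Aprev <- ff$A[[l]]
          dZ <- Aprev * (dA - rowSums(dA * Aprev))
        } else {
          dZ <- dA * transfer_deriv(id, ff$Z[[l - 1]], ff$A[[l]])
        }
      }
    }
    for (l in seq_len(L)) {
      kW <- length(model$W[[l]])
      J[rows, atW + seq_len(kW)] <- blocksW[[l]]
      atW <- atW + kW
      kb <- length(model$b[[l]])
      J[rows, atb + seq_len(kb)] <- blocksb[[l]]
      atb <- atb + kb
    }
  }
  list(J = J, Y = Y)
}
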