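test_that("transfer functions match their definitions", {
  cases <- list(
    list("tansig", 0, 0), list("logsig", 0, 0.5), list("purelin", 2.5, 2.5),
    list("hardlim", -1, 0), list("hardlim", 0, 1), list("hardlims", -0.1, -1),
    list("poslin", -2, 0), list("poslin", 3, 3), list("radbas", 0, 1),
    list("satlin", 2, 1), list("satlins", 3, 1), list("satlins", -3, -1),
    list("tribas", 0.5, 0.5), list("tribas", 2, 0), list("netinv", 4, 0.25)
  )
  for (cs in cases) {
    expect_equal(transfer(cs[[1]], cs[[2]]), cs[[3]],
                 info = paste(cs[[1]], cs[[2]]))
  }
  expect_equal(transfer("compet", c(0.1, 0.9, 0.3)), c(0, 1, 0))
  expect_equal(sum(transfer("softmax", c(1, 2, 3))), 1)
  # netinv guard: finite at zero
  expect_true(is.finite(transfer("netinv", 0)))
  expect_error(transfer("nosuch", 1))
})

test_that("initialization is reproducible and shapes follow the config", {
  cfg <- mlp_config(c(12, 17), c("tansig", "poslin"), train = "traingda")
  m1 <- mlp_init(cfg, n_inputs = 5, seed = 3)
  m2 <- mlp_init(cfg, n_inputs = 5, seed = 3)
  m3 <- mlp_init(cfg, n_inputs = 5, seed = 4)
  expect_identical(m1$W, m2$W)
  expect_false(identical(m1$W, m3$W))
  expect_equal(lapply(m1$W, dim),
               list(c(5L, 12L), c(12L, 17L), c(17L, 3L)))
})

test_that("forward pass is softmax-normalized and matches hand arithmetic", {
  cfg <- mlp_config(2, "purelin", train = "traingd")
  m <- mlp_init(cfg, n_inputs = 2, n_outputs = 3, seed = 1)
  # zero weights: uniform output
  m$W <- lapply(m$W, function(w) w * 0)
  expect_equal(as.vector(mlp_forward(m, c(1, 2))), rep(1 / 3, 3))
  # hand-computed 2-2-3 toy network
  m$W[[1]] <- matrix(c(1, 0, 0, 1), 2, 2)
  m$b[[1]] <- c(0.5, -0.5)
  m$W[[2]] <- matrix(c(1, 0, 0, 1, 1, 1), 2, 3)
  m$b[[2]] <- c(0, 0, 0)
  x <- c(0.2, 0.4)
  hidden <- c(0.7, -0.1)  # purelin(x W + b)
  z_out <- c(hidden %*% m$W[[2]])
  want <- exp(z_out) / sum(exp(z_out))
  expect_equal(as.vector(mlp_forward(m, x)), want, tolerance = 1e-12)
  # scores always sum to 1
  set.seed(2)
  scores <- mlp_forward(mlp_init(cfg, 2, 3, seed = 9), matrix(rnorm(20), 10))
  expect_equal(rowSums(scores), rep(1, 10))
  expect_error(mlp_forward(m, c(1, 2, 3)))
})

test_that("the analytic gradient matches finite differences", {
  set.seed(5)
  cfg <- mlp_config(c(4, 3), c("tansig", "logsig"), train = "traingd")
  model <- mlp_init(cfg, n_inputs = 2, n_outputs = 3, seed = 7)
  X <- matrix(rnorm(12), 6, 2)
  T <- diag(3)[sample(1:3, 6, TRUE), ]
  g <- seedvision:::mlp_gradient(model, X, T)
  gv <- seedvision:::flatten_grad(g)
  theta <- seedvision:::flatten_params(model)
  idx <- sample(length(theta), 10)
  for (i in idx) {
    e <- 1e-6
    tp <- theta; tp[i] <- tp[i] + e
    tm <- theta; tm[i] <- tm[i] - e
    fd <- (seedvision:::mlp_mse(seedvision:::unflatten_params(model, tp), X, T) -
           seedvision:::mlp_mse(seedvision:::unflatten_params(model, tm), X, T)) / (2 * e)
    expect_equal(gv[i], fd, tolerance = 1e-5)
  }
})

test_that("Levenberg-Marquardt solves XOR", {
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  T <- matrix(c(1, 0, 0, 1, 0, 1, 1, 0), 4, 2, byrow = TRUE)
  m <- mlp_init(mlp_config(4, "tansig", train = "trainlm"), 2, 2, seed = 3)
  m <- mlp_train(m, X, T, max_epochs = 100)
  expect_lt(tail(m$record$train_mse, 1), 0.05)
})

test_that("separable blobs reach high training accuracy", {
  tb <- make_blob_table(n_per_class = 15, seed = 2)
  X <- as.matrix(tb[, c("f1", "f2")])
  Tm <- diag(3)[match(tb$label, c("A", "B", "C")), ]
  m <- mlp_init(mlp_config(5, "tansig", train = "trainlm"), 2, 3, seed = 1)
  m <- mlp_train(m, X, Tm, max_epochs = 150)
  acc <- mean(c("A", "B", "C")[max.col(mlp_forward(m, X))] == tb$label)
  expect_gte(acc, 0.95)
})

test_that("zero learning rate freezes the MSE history", {
  tb <- make_blob_table(n_per_class = 5, seed = 3)
  X <- as.matrix(tb[, c("f1", "f2")])
  Tm <- diag(3)[match(tb$label, c("A", "B", "C")), ]
  m <- mlp_init(mlp_config(3, "tansig", train = "traingd"), 2, 3, seed = 1)
  m <- mlp_train(m, X, Tm, max_epochs = 10, lr = 0)
  expect_true(all(abs(diff(m$record$train_mse)) < 1e-14))
})

test_that("plain gradient descent is non-increasing at a small step", {
  # convex case: single purelin layer... the output softmax keeps it
  # smooth; at lr = 1e-4 the full-batch descent must not increase MSE
  tb <- make_blob_table(n_per_class = 8, seed = 4)
  X <- as.matrix(tb[, c("f1", "f2")])
  Tm <- diag(3)[match(tb$label, c("A", "B", "C")), ]
  m <- mlp_init(mlp_config(1, "purelin", train = "traingd"), 2, 3, seed = 2)
  m <- mlp_train(m, X, Tm, max_epochs = 60, lr = 1e-4)
  expect_true(all(diff(m$record$train_mse) <= 1e-12))
})

test_that("every implemented trainer reduces the loss on blobs", {
  tb <- make_blob_table(n_per_class = 10, seed = 6)
  X <- scale(as.matrix(tb[, c("f1", "f2")]))
  Tm <- diag(3)[match(tb$label, c("A", "B", "C")), ]
  for (tr in mlp_trainers()) {
    m <- mlp_init(mlp_config(6, "tansig", train = tr), 2, 3, seed = 5)
    m <- mlp_train(m, X, Tm, max_epochs = 120, lr = 0.05)
    expect_lt(tail(m$record$train_mse, 1), m$record$train_mse[1],
              label = paste("trainer", tr))
  }
})

test_that("unknown trainers alias with a warning, garbage errors", {
  expect_warning(cfg <- mlp_config(3, "tansig", train = "trainscg"),
                 "aliased")
  expect_equal(cfg$train, "trainrp")
  expect_error(mlp_config(3, "tansig", train = "sgd"))
})

test_that("early stopping restores the best-validation weights", {
  set.seed(10)
  X <- matrix(rnorm(80), 40, 2)
  Tm <- diag(3)[sample(1:3, 40, TRUE), ]  # pure noise: must overfit
  Xv <- matrix(rnorm(40), 20, 2)
  Tv <- diag(3)[sample(1:3, 20, TRUE), ]
  m <- mlp_init(mlp_config(c(10, 10), c("tansig", "tansig"),
                           train = "trainlm"), 2, 3, seed = 1)
  m <- mlp_train(m, X, Tm, Xv, Tv, max_epochs = 200, patience = 8)
  expect_equal(m$record$stop_reason, "early_stop")
  expect_equal(seedvision:::mlp_mse(m, Xv, Tv),
               min(m$record$val_mse), tolerance = 1e-10)
})

test_that("serialization round-trips bit-identically", {
  m <- mlp_init(mlp_config(c(7, 4), c("radbas", "satlin"),
                           train = "traingdx", learn = "learnhd"),
                n_inputs = 6, seed = 12)
  path <- withr::local_tempfile(fileext = ".json")
  mlp_save(m, path)
  m2 <- mlp_load(path)
  x <- matrix(rnorm(18), 3, 6)
  expect_identical(mlp_forward(m, x), mlp_forward(m2, x))
  expect_identical(m$W, m2$W)
  expect_equal(unclass(m$config), unclass(m2$config))
})
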