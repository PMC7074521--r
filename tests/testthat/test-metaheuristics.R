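sphere_space <- function() {
  search_space(x = dim_integer(-10, 10), y = dim_integer(-10, 10),
               z = dim_integer(-10, 10))
}
sphere <- function(v) v$x^2 + v$y^2 + v$z^2

optimizer_list <- function() {
  list(pso = function(obj, sp, seed, iters = 50)
         pso_optimize(obj, sp, n_iters = iters, seed = seed),
       aco = function(obj, sp, seed, iters = 50)
         aco_optimize(obj, sp, n_iters = iters, seed = seed),
       hs = function(obj, sp, seed, iters = 50)
         hs_optimize(obj, sp, n_iters = iters * 30, seed = seed),
       ca = function(obj, sp, seed, iters = 50)
         ca_optimize(obj, sp, n_iters = iters, seed = seed))
}

test_that("all four optimizers find the sphere optimum", {
  for (nm in names(optimizer_list())) {
    res <- optimizer_list()[[nm]](sphere, sphere_space(), seed = 11)
    expect_equal(res$best$fitness, 0, label = paste("optimizer", nm))
  }
})

test_that("identical seeds give identical results, traces are monotone", {
  for (nm in names(optimizer_list())) {
    f <- optimizer_list()[[nm]]
    r1 <- f(sphere, sphere_space(), seed = 5, iters = 15)
    r2 <- f(sphere, sphere_space(), seed = 5, iters = 15)
    expect_identical(r1$best, r2$best, label = nm)
    expect_identical(r1$trace$best_fitness, r2$trace$best_fitness,
                     label = nm)
    expect_true(all(diff(r1$trace$best_fitness) <= 0), label = nm)
  }
})

test_that("a single-candidate space returns that candidate", {
  sp <- search_space(only = dim_integer(4, 4))
  obj <- function(v) v$only
  for (nm in names(optimizer_list())) {
    res <- optimizer_list()[[nm]](obj, sp, seed = 1, iters = 3)
    expect_equal(res$best$values$only, 4, label = nm)
  }
})

test_that("optimizers track the brute-force optimum on a small space", {
  sp <- search_space(a = dim_integer(1, 10),
                     b = dim_categorical(letters[1:5]),
                     c = dim_integer(0, 3))
  obj <- function(v) {
    (v$a - 7)^2 + 3 * (match(v$b, letters[1:5]) - 2)^2 + abs(v$c - 1)
  }
  best <- min(vapply(seedvision:::enumerate_space(sp), obj, numeric(1)))
  for (nm in names(optimizer_list())) {
    wins <- sum(vapply(1:20, function(s) {
      optimizer_list()[[nm]](obj, sp, seed = s, iters = 20)$best$fitness <=
        best * 1.05 + 1e-12
    }, logical(1)))
    expect_gte(wins, 18)
  }
})

test_that("non-finite objectives are rejected with a warning", {
  obj <- function(v) if (v$x == 0) NaN else v$x^2
  sp <- search_space(x = dim_integer(-2, 2))
  w <- capture_warnings(
    res <- pso_optimize(obj, sp, n_particles = 8, n_iters = 10, seed = 2))
  expect_true(any(grepl("non-finite", w)))
  expect_true(is.finite(res$best$fitness))
  expect_gte(res$best$fitness, 1)
})

test_that("harmony search with hmcr=1, par=0 stays inside its memory", {
  sp <- search_space(q = dim_integer(0, 1000))
  obj <- function(v) -v$q
  set.seed(99)
  res <- hs_optimize(obj, sp, harmony_memory_size = 5, n_iters = 80,
                     seed = 9, hmcr = 1, par = 0)
  # reproduce the initial memory values independently
  init <- seedvision:::with_seed(9, {
    vapply(1:5, function(i) seedvision:::random_values(sp)$q, numeric(1))
  })
  expect_equal(res$best$values$q, max(init))
})

test_that("the cultural algorithm recovers a planted feature pair", {
  sp <- do.call(search_space,
                setNames(lapply(1:10, function(i) dim_integer(0, 1)),
                         paste0("f", 1:10)))
  obj <- function(v) {
    sel <- which(unlist(v) == 1)
    length(union(setdiff(sel, c(3, 7)), setdiff(c(3, 7), sel)))
  }
  res <- ca_optimize(obj, sp, n_iters = 60, seed = 2)
  expect_equal(res$best$fitness, 0)
  expect_equal(which(unlist(res$best$values) == 1), c(3L, 7L),
               ignore_attr = TRUE)
})

test_that("the belief space's normative ranges contain the best solution", {
  res <- ca_optimize(sphere, sphere_space(), n_iters = 25, seed = 7)
  for (d in names(sphere_space())) {
    nm <- res$belief$normative[[d]]
    v <- res$belief$situational[[d]]
    expect_true(v >= nm$lo && v <= nm$hi)
  }
})

test_that("search-space encoding round-trips every candidate", {
  sp <- search_space(a = dim_integer(-3, 5),
                     b = dim_categorical(c("u", "v", "w")))
  for (cand in seedvision:::enumerate_space(sp)) {
    keys <- seedvision:::encode_values(sp, cand)
    expect_identical(seedvision:::decode_keys(sp, keys), cand)
  }
})
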