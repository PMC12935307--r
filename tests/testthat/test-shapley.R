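test_that("exact Shapley satisfies the additivity and symmetry axioms", {
  # additive value function: phi_i = c_i
  cvec <- c(2, -1, 3, 0.5)
  f_add <- function(v) sum(v * cvec)
  at <- exact_shapley(f_add, x = rep(1, 4), baseline = rep(0, 4))
  expect_equal(at$phi, cvec, tolerance = 1e-9)
  # symmetric AND-like function: equal shares
  f_and <- function(v) as.numeric(v[1] > 0.5 && v[2] > 0.5)
  at2 <- exact_shapley(f_and, x = c(1, 1), baseline = c(0, 0))
  expect_equal(at2$phi[1], at2$phi[2], tolerance = 1e-9)
  expect_equal(sum(at2$phi), 1, tolerance = 1e-9)
  expect_error(exact_shapley(f_add, rep(1, 13), rep(0, 13)), "12 features")
})

test_that("exact Shapley satisfies efficiency, dummy and linearity", {
  set.seed(17)
  for (rep_ in 1:5) {
    n <- 5
    A <- matrix(rnorm(n * n), n)
    f1 <- function(v) sum(v * 1:n) + as.numeric(t(v) %*% A %*% v) / 10
    f2 <- function(v) prod(1 + abs(v[1:2]))
    x <- rnorm(n); baseline <- rnorm(n)
    a1 <- exact_shapley(f1, x, baseline)
    a2 <- exact_shapley(f2, x, baseline)
    # efficiency
    expect_equal(sum(a1$phi), a1$f_full - a1$f_baseline, tolerance = 1e-9)
    # dummy: f2 ignores features 3..n
    expect_equal(a2$phi[3:n], rep(0, n - 2), tolerance = 1e-9)
    # linearity: phi(f1 + 2 f2) = phi(f1) + 2 phi(f2)
    f12 <- function(v) f1(v) + 2 * f2(v)
    a12 <- exact_shapley(f12, x, baseline)
    expect_equal(a12$phi, a1$phi + 2 * a2$phi, tolerance = 1e-9)
  }
})

test_that("exact enumeration matches the permutation-averaging oracle", {
  set.seed(23)
  for (rep_ in 1:3) {
    n <- 4
    tab <- rnorm(2^n)  # random tabulated coalition values
    f <- function(v) {
      bits <- as.integer(v != 0)
      tab[sum(bits * 2^(seq_len(n) - 1)) + 1]
    }
    x <- rep(1, n); baseline <- rep(0, n)
    expect_equal(exact_shapley(f, x, baseline)$phi,
                 permutation_shapley(f, x, baseline), tolerance = 1e-9)
  }
})

test_that("the sampling estimator converges to the exact oracle", {
  set.seed(31)
  n <- 6
  cvec <- rnorm(n)
  B <- matrix(rnorm(n * n, sd = 0.3), n)
  f <- function(v) sum(cvec * v) + as.numeric(t(v) %*% B %*% v) / 5
  x <- rnorm(n)
  baseline <- rnorm(n)
  exact <- exact_shapley(f, x, baseline)
  approx <- approx_shapley(f, x, baseline, n_samples = 400, seed = 2)
  expect_equal(approx$phi, exact$phi, tolerance = 0.05)
  # efficiency holds for the estimator
  expect_equal(sum(approx$phi), approx$f_full - approx$f_baseline,
               tolerance = 1e-9)
  # reproducible under a fixed seed
  expect_identical(approx_shapley(f, x, baseline, n_samples = 50, seed = 3)$phi,
                   approx_shapley(f, x, baseline, n_samples = 50, seed = 3)$phi)
  # error shrinks with more samples (averaged over repeats)
  errs <- sapply(c(10, 1000), function(ns) {
    mean(sapply(1:5, function(s) {
      max(abs(approx_shapley(f, x, baseline, n_samples = ns, seed = s)$phi -
                exact$phi))
    }))
  })
  expect_lt(errs[2], errs[1])
})

test_that("backend importance aggregates and normalizes per block", {
  blocks <- list(a = c(start = 1, end = 4), b = c(start = 5, end = 6))
  phi <- c(1, 1, 1, 1, 1, 1)
  raw <- backend_importance(phi, blocks, mode = "raw")
  expect_equal(raw$normalized, c(4 / 6, 2 / 6))
  # widths 4 and 2 with sums 4 and 2 -> mean scores 1,1 -> normalized .5,.5
  mn <- backend_importance(phi, blocks, mode = "mean")
  expect_equal(mn$normalized, c(0.5, 0.5))
  # raw sums 3 and 1 -> 0.75 / 0.25
  phi2 <- c(1.5, 1.5, 0, 0, -1, 0)
  raw2 <- backend_importance(phi2, blocks, mode = "raw")
  expect_equal(raw2$normalized, c(0.75, 0.25))
  expect_equal(sum(raw2$normalized), 1)
  single <- backend_importance(phi2[1:4], list(a = c(start = 1, end = 4)))
  expect_equal(single$normalized, 1)
  expect_error(backend_importance(phi, blocks[1]), "partition")
  expect_error(backend_importance(rep(0, 6), blocks), "all importance")
})

test_that("normalized profiles are permutation-equivariant in backend order", {
  blocks <- list(a = c(start = 1, end = 2), b = c(start = 3, end = 5),
                 c = c(start = 6, end = 6))
  set.seed(4)
  phi <- rnorm(6)
  p1 <- backend_importance(phi, blocks)
  p2 <- backend_importance(phi, blocks[c(3, 1, 2)])
  expect_equal(p1$normalized[match(p2$backend, p1$backend)], p2$normalized)
})

test_that("profile aggregation averages and handles missing backends", {
  mk <- function(b, v) data.frame(backend = b, normalized = v)
  same <- aggregate_importance(list(mk(c("a", "b"), c(0.7, 0.3)),
                                    mk(c("a", "b"), c(0.7, 0.3))))
  expect_equal(same$normalized, c(0.7, 0.3))
  hot <- aggregate_importance(list(mk("a", 1), mk("b", 1)))
  expect_equal(hot$normalized, c(0.5, 0.5))
  # entity present in 3 of 5 profiles is averaged over those 3 only
  profs <- c(replicate(3, mk(c("a", "b"), c(0.6, 0.4)), simplify = FALSE),
             replicate(2, mk("a", 1), simplify = FALSE))
  agg <- aggregate_importance(profs)
  a_mean <- mean(c(0.6, 0.6, 0.6, 1, 1))
  b_mean <- 0.4
  expect_equal(agg$normalized,
               c(a_mean, b_mean) / (a_mean + b_mean))
})

test_that("residue explanations attribute a fitted model's prediction", {
  ts <- small_training_set(seed = 11, n_sequences = 8)
  # tiny feature space so the exact path is tractable
  keep <- 1:6
  fit <- paratope_mlp(ts$train$x[, keep], ts$train$y, ts$train$groups,
                      validation = list(x = ts$validation$x[, keep],
                                        y = ts$validation$y,
                                        groups = ts$validation$groups),
                      hidden = c(8), learning_rate = 1e-3, max_epochs = 10,
                      seed = 2)
  f <- function(v) predict(fit, matrix(v, nrow = 1))
  x <- as.numeric(ts$test$x[1, keep])
  baseline <- colMeans(ts$train$x[, keep])
  exact <- exact_shapley(f, x, baseline)
  approx <- explain_residue(fit, ts$test$x[, keep], row = 1,
                            background = ts$train$x[, keep],
                            n_samples = 300, seed = 1)
  expect_lt(max(abs(approx$phi - exact$phi)), 0.02)
  expect_equal(sum(exact$phi), exact$f_full - exact$f_baseline,
               tolerance = 1e-9)
})
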