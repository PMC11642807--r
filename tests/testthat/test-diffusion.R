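test_that("out-degree Laplacian matches its definition", {
  conn <- connectome(c("a", "b"), matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  L <- out_degree_laplacian(conn)
  expect_equal(unname(L), matrix(c(1, -1, 0, 0), 2, 2, byrow = TRUE))

  zero <- connectome(c("a", "b"), matrix(0, 2, 2))
  expect_equal(unname(out_degree_laplacian(zero)), matrix(0, 2, 2))

  conn5 <- rand_connectome(5, seed = 3)
  L5 <- out_degree_laplacian(conn5)
  expect_equal(unname(rowSums(L5)), rep(0, 5))
  expect_true(all(L5[row(L5) != col(L5)] <= 0))
})

test_that("zero rate or zero horizon returns the seed vector exactly", {
  conn <- rand_connectome(6, seed = 4)
  seed <- seed_spec(c("r01", "r03"))
  for (p in list(predict_spread(conn, seed, c = 0, t = 3),
                 predict_spread(conn, seed, c = 1, t = 0))) {
    expect_equal(p$value, c(1, 0, 1, 0, 0, 0))
  }
})

test_that("propagation matches Runge-Kutta integration of the linear system", {
  # 3-node directed chain with unit weights, seed at the head, c*t = 1
  A <- matrix(0, 3, 3); A[1, 2] <- 1; A[2, 3] <- 1
  conn <- connectome(c("n1", "n2", "n3"), A)
  pred <- predict_spread(conn, seed_spec("n1"), c = 1, t = 1)
  oracle <- rk4_spread(flux_generator(conn), c(1, 0, 0), T = 1)
  expect_lt(max(abs(pred$value - oracle)), 1e-8)

  # random graphs, N <= 10
  set.seed(21)
  for (i in 1:10) {
    n <- sample(3:10, 1)
    conn <- rand_connectome(n, density = runif(1, 0.3, 0.9))
    x0 <- numeric(n); x0[sample(n, 2)] <- 1
    ct <- runif(1, 0.1, 2)
    pred <- predict_spread(conn, seed_spec(conn$regions[x0 > 0]), c = ct, t = 1)
    oracle <- rk4_spread(flux_generator(conn), x0, T = ct)
    expect_lt(max(abs(pred$value - oracle)), 1e-8)
  }
})

test_that("total pathology is conserved across rates and horizons", {
  set.seed(31)
  for (i in 1:5) {
    conn <- rand_connectome(sample(4:12, 1), density = 0.5)
    seed <- seed_spec(conn$regions[1:2])
    for (ct in c(0, 0.01, 0.5, 3, 20)) {
      p <- predict_spread(conn, seed, c = ct, t = 1)
      expect_lt(abs(sum(p$value) - 2) / 2, 1e-10)
      expect_true(all(p$value >= 0))
    }
  }
})

test_that("the seed region dilutes monotonically on a strongly connected graph", {
  set.seed(41)
  A <- rand_adjacency(8, density = 1)  # complete graph: strongly connected
  conn <- connectome(sprintf("r%02d", 1:8), A)
  vals <- vapply(c(0, 0.1, 0.3, 1, 3, 10), function(ct) {
    predict_spread(conn, seed_spec("r01"), c = ct, t = 1)$value[1]
  }, numeric(1))
  # non-increasing up to numerical dust from the eigensolver (tiny damped
  # oscillations at the stationary plateau are below 1e-6)
  expect_true(all(diff(vals) <= 1e-6))
})

test_that("anterograde and retrograde agree on a symmetric matrix", {
  S <- rand_adjacency(6, density = 0.8, seed = 51)
  S <- (S + t(S)) / 2
  conn <- connectome(sprintf("r%02d", 1:6), S)
  pa <- predict_spread(directional_view(conn, "anterograde"), seed_spec("r01"), 0.7)
  pr <- predict_spread(directional_view(conn, "retrograde"), seed_spec("r01"), 0.7)
  expect_equal(pa$value, pr$value, tolerance = 1e-10)
})

test_that("long-horizon predictions approach the generator's stationary state", {
  set.seed(61)
  conn <- rand_connectome(6, density = 1)
  G <- flux_generator(conn)
  # stationary state: right null vector of the generator, unit mass
  ns <- eigen(G)
  v <- Re(ns$vectors[, which.min(Mod(ns$values))])
  v <- v / sum(v)
  p <- predict_spread(conn, seed_spec("r01"), c = 500, t = 1)
  expect_lt(max(abs(p$value - v)), 1e-6)
})

test_that("rate fitting recovers the generating rate on noiseless data", {
  w <- shared_world()
  conn <- w$gt$connectomes$retrograde
  truth <- predict_spread(conn, w$gt$seed, c = 0.5, t = 3)
  obs <- stats::setNames(truth$value, truth$region_id)
  fit <- fit_rate(obs, conn, w$gt$seed, t = 3)
  expect_lt(abs(fit$c_hat - 0.5) / 0.5, 0.01)
  expect_gte(fit$fit_r, 0.999)
  expect_gte(fit$n_used, 3)

  flat <- stats::setNames(rep(2, length(obs)), names(obs))
  expect_error(fit_rate(flat, conn, w$gt$seed), "zero variance")
})

test_that("rate fitting is scale-equivariant in the horizon", {
  w <- shared_world()
  conn <- w$gt$connectomes$anterograde
  truth <- predict_spread(conn, w$gt$seed, c = 0.4, t = 3)
  obs <- stats::setNames(truth$value, truth$region_id)
  f3 <- fit_rate(obs, conn, w$gt$seed, t = 3)
  f6 <- fit_rate(obs, conn, w$gt$seed, t = 6)
  expect_equal(f6$c_hat * 6, f3$c_hat * 3, tolerance = 1e-3)
  expect_equal(f6$fit_r, f3$fit_r, tolerance = 1e-6)
})

test_that("rate recovery tolerates multiplicative log-normal noise", {
  w <- shared_world()
  conn <- w$gt$connectomes$retrograde
  truth <- predict_spread(conn, w$gt$seed, c = 0.5, t = 3)
  base <- stats::setNames(truth$value, truth$region_id)
  set.seed(77)
  rel_err <- replicate(30, {
    obs <- base * exp(rnorm(length(base), 0, 0.25))
    f <- fit_rate(obs, conn, w$gt$seed, t = 3)
    abs(f$c_hat - 0.5) / 0.5
  })
  # smoke bound: the estimator stays in the right ballpark under noise; the
  # tighter calibration check lives in the acceptance suite
  expect_lt(median(rel_err), 0.20)
})

test_that("seed-site variants fit with the expected seed sets", {
  w <- shared_world()
  atlas <- w$gt$atlas
  conn <- w$gt$connectomes$retrograde
  hip_ids <- atlas$region_id[match(c("DG", "CA1", "CA3"), atlas$acronym)]
  truth <- predict_spread(conn, seed_spec(hip_ids), c = 0.3, t = 3)
  obs <- stats::setNames(truth$value, truth$region_id)
  fits <- single_seed_variants(obs, conn, atlas)
  expect_named(fits, c("hippocampus_only", "PTLp_only", "dual"))
  expect_length(fits$dual$seed$sites, 4)
  # data generated from the hippocampal seed: hippocampus-only must win
  expect_gte(fits$hippocampus_only$fit_r, fits$PTLp_only$fit_r)

  expect_error(single_seed_variants(obs, conn, atlas, hippocampus = "NOPE"),
               "absent")
  expect_error(seed_spec(character(0)), "non-empty")
})

test_that("predictions and fits carry tidy and glance methods", {
  w <- shared_world()
  means <- region_means(w$cohort, "WT", "Sal")
  fit <- fit_rate(means, w$gt$connectomes$retrograde, w$gt$seed)
  td <- tidy(fit)
  expect_true(all(c("region_id", "value", "observed", "used") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_used, fit$n_used)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
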