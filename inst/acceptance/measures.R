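# Acceptance measurements: each function re-runs a calibration or recovery
# experiment from scratch with the installed package and returns the
# measured quantities. Shared by tests/testthat/test-acceptance.R and
# scripts/acceptance.R. All randomness flows from the `seed` argument.

acc_child <- function(seed, k) (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L

# classical RK4 integration of dx/ds = G x: the independent oracle for the
# matrix-exponential propagation
acc_rk4 <- function(G, x0, T, h = 1e-4) {
  if (T == 0) return(x0)
  n_steps <- ceiling(T / h)
  h <- T / n_steps
  x <- x0
  for (i in seq_len(n_steps)) {
    k1 <- G %*% x
    k2 <- G %*% (x + h / 2 * k1)
    k3 <- G %*% (x + h / 2 * k2)
    k4 <- G %*% (x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  as.vector(x)
}

acc_rand_conn <- function(n, density = 0.6) {
  A <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) < density)
  diag(A) <- 0
  connectome(sprintf("r%02d", seq_len(n)), A)
}

# criterion: propagation agrees with high-resolution ODE integration, and
# conserves total pathology, on random graphs with N <= 10
measure_oracle <- function(seed, n_graphs = 50) {
  set.seed(acc_child(seed, 1))
  max_diff <- 0
  max_mass_err <- 0
  for (i in seq_len(n_graphs)) {
    n <- sample(3:10, 1)
    conn <- acc_rand_conn(n, density = runif(1, 0.3, 0.9))
    x0 <- numeric(n); x0[sample(n, sample(1:2, 1))] <- 1
    ct <- runif(1, 0.1, 2)
    pred <- predict_spread(conn, seed_spec(conn$regions[x0 > 0]), c = ct, t = 1)
    oracle <- acc_rk4(-t(out_degree_laplacian(conn)), x0, T = ct)
    max_diff <- max(max_diff, max(abs(pred$value - oracle)))
    for (cc in c(0, 0.05, 0.5, 5, 50)) {
      p2 <- predict_spread(conn, seed_spec(conn$regions[x0 > 0]), c = cc, t = 1)
      max_mass_err <- max(max_mass_err, abs(sum(p2$value) - sum(x0)) / sum(x0))
    }
  }
  list(oracle_max_abs_diff = max_diff, conservation_max_rel_err = max_mass_err,
       n = n_graphs)
}

# criterion: the diffusion rate is recovered exactly without noise and to a
# <10% median relative error under multiplicative log-normal noise
measure_rate_recovery <- function(seed, n_reps = 100, n_regions = 50,
                                  c_star = 0.5, sigma = 0.25) {
  ac <- generate_atlas_connectome(n_regions = n_regions, seed = acc_child(seed, 2))
  gt <- ground_truth(ac$atlas, ac$connectome)
  conn <- gt$connectomes$retrograde
  truth <- predict_spread(conn, gt$seed, c = c_star, t = 3)
  base <- stats::setNames(truth$value, truth$region_id)

  f0 <- fit_rate(base, conn, gt$seed, t = 3)
  noiseless_err <- abs(f0$c_hat - c_star) / c_star

  set.seed(acc_child(seed, 3))
  rel <- replicate(n_reps, {
    obs <- base * exp(rnorm(n_regions, 0, sigma))
    abs(fit_rate(obs, conn, gt$seed, t = 3)$c_hat - c_star) / c_star
  })
  list(rate_noiseless_rel_err = noiseless_err,
       rate_noisy_median_rel_err = median(rel), n = n_reps)
}

# criterion: data generated by purely anterograde spread on an asymmetric
# connectome are better fit by the anterograde than the retrograde model
measure_direction <- function(seed, n_reps = 100, n_regions = 50,
                              asymmetry = 0.6, sigma = 0.25) {
  wins <- vapply(seq_len(n_reps), function(i) {
    s <- acc_child(seed, 100 + i)
    ac <- generate_atlas_connectome(n_regions = n_regions,
                                    asymmetry = asymmetry, seed = s)
    gt <- ground_truth(ac$atlas, ac$connectome)
    truth <- predict_spread(gt$connectomes$anterograde, gt$seed, c = 0.25, t = 3)
    set.seed(s + 1L)
    obs <- stats::setNames(truth$value * exp(rnorm(n_regions, 0, sigma)),
                           truth$region_id)
    fa <- fit_rate(obs, gt$connectomes$anterograde, gt$seed, t = 3)
    fr <- fit_rate(obs, gt$connectomes$retrograde, gt$seed, t = 3)
    fa$fit_r > fr$fit_r
  }, logical(1))
  list(direction_win_rate = mean(wins), n = n_reps)
}

# criterion: the combined model recovers generating weights (0.7, 0.2, 0.1)
# as standardized betas, and the beta-ratio ordering matches the truth
measure_beta_recovery <- function(seed, n_reps = 200, n_regions = 100,
                                  sigma = 0.1) {
  ac <- generate_atlas_connectome(n_regions = n_regions, seed = acc_child(seed, 4))
  gt <- ground_truth(ac$atlas, ac$connectome)
  regions <- ac$connectome$regions
  Z <- lapply(gt$connectomes, function(cn) {
    v <- predict_spread(cn, gt$seed, c = 0.25, t = 3)$value
    lv <- log10(v + min(v[v > 0]))
    stats::setNames((lv - mean(lv)) / sd(lv), regions)
  })
  b_true <- c(0.7, 0.2, 0.1)
  set.seed(acc_child(seed, 5))
  betas <- replicate(n_reps, {
    y <- b_true[1] * Z$anterograde + b_true[2] * Z$retrograde +
      b_true[3] * Z$euclidean + rnorm(n_regions, 0, sigma)
    names(y) <- regions
    fit_combined(y, Z, transform = "none")$betas
  })
  ok <- colSums(abs(betas - b_true) <= 0.05) == 3
  mean_betas <- rowMeans(betas)
  fake <- structure(list(betas = mean_betas), class = "combined_fit")
  br <- beta_ratios(fake)
  ord_fit <- order(br$value[match(c("a:r", "e:r", "a:e"), br$ratio)])
  fake_true <- structure(list(betas = stats::setNames(b_true, names(mean_betas))),
                         class = "combined_fit")
  brt <- beta_ratios(fake_true)
  ord_true <- order(brt$value[match(c("a:r", "e:r", "a:e"), brt$ratio)])
  list(beta_recovery_fraction = mean(ok),
       beta_max_mean_abs_err = max(abs(mean_betas - b_true)),
       ratio_ordering_match = as.numeric(identical(ord_fit, ord_true)),
       n = n_reps)
}

acc_interaction_gt <- function(seed, n_regions, b_t, b_t_ptz) {
  ac <- generate_atlas_connectome(n_regions = n_regions, seed = seed)
  bt <- tibble::tibble(
    genotype = "WT", treatment = c("Sal", "PTZ"),
    b_a = 0.2, b_r = 0.6, b_e = 0.1, b_t = b_t, b_t_ptz = c(0, b_t_ptz)
  )
  ground_truth(ac$atlas, ac$connectome, beta_true = bt)
}

# criterion: the tdT-by-treatment interaction model detects a PTZ-specific
# tdT slope (power) and stays near nominal size with no interaction (type I)
measure_interaction <- function(seed, n_reps = 200, n_regions = 150,
                                n_mice = 10) {
  gt_pow <- acc_interaction_gt(acc_child(seed, 6), n_regions, b_t = 0, b_t_ptz = 0.5)
  gt_null <- acc_interaction_gt(acc_child(seed, 6), n_regions, b_t = 0.3, b_t_ptz = 0)
  preds <- lapply(gt_pow$connectomes, function(cn)
    predict_spread(cn, gt_pow$seed, c = 0.25, t = 3))

  power_hits <- vapply(seq_len(n_reps), function(i) {
    coh <- simulate_cohort(gt_pow, n_mice = n_mice, seed = acc_child(seed, 1000 + i))
    fit <- fit_tdt_interaction(coh, preds, "WT")
    ptz <- fit$slopes[fit$slopes$group == "PTZ", ]
    sal <- fit$slopes[fit$slopes$group == "Sal", ]
    ptz$p < 0.05 && abs(sal$slope) < 0.1
  }, logical(1))

  type1_hits <- vapply(seq_len(n_reps), function(i) {
    coh <- simulate_cohort(gt_null, n_mice = n_mice, seed = acc_child(seed, 2000 + i))
    fit <- fit_tdt_interaction(coh, preds, "WT")
    s <- summary(fit$model)$coefficients
    s["tdt:treatment", 4] < 0.05
  }, logical(1))

  list(interaction_power = mean(power_hits),
       interaction_type1 = mean(type1_hits), n = n_reps)
}

# draw one random seed set matched on mean pairwise centroid distance
acc_matched_set <- function(atlas, regions, true_sites, tolerance = 0.2) {
  cent <- as.matrix(atlas[match(regions, atlas$region_id), c("x", "y", "z")])
  rownames(cent) <- regions
  target <- mean(dist(cent[true_sites, ]))
  for (i in 1:10000) {
    cand <- sample(regions, length(true_sites))
    if (abs(mean(dist(cent[cand, ])) - target) <= tolerance * target &&
        !setequal(cand, true_sites)) return(cand)
  }
  stop("no matched set found")
}

# criterion: the seed-specificity percentile is uniform when the data come
# from a random matched seed set, and near 1 when they come from the true
# seed at low noise
measure_null_calibration <- function(seed, n_reps = 200, n_sets = 100,
                                     n_regions = 40, sigma = 0.25) {
  percentiles <- vapply(seq_len(n_reps), function(i) {
    s <- acc_child(seed, 3000 + i)
    ac <- generate_atlas_connectome(n_regions = n_regions, seed = s)
    gt <- ground_truth(ac$atlas, ac$connectome)
    conn <- gt$connectomes$retrograde
    set.seed(s + 1L)
    gen_sites <- acc_matched_set(gt$atlas, conn$regions, gt$seed$sites)
    truth <- predict_spread(conn, seed_spec(gen_sites), c = 0.25, t = 3)
    obs <- stats::setNames(truth$value * exp(rnorm(n_regions, 0, sigma)),
                           truth$region_id)
    nl <- suppressMessages(
      random_seed_null(obs, conn, gt$atlas, gt$seed, n_sets = n_sets,
                       tolerance = 0.2, seed = s + 2L)
    )
    nl$percentile
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(percentiles, "punif"))
  list(null_ks_p = ks$p.value, null_mean_percentile = mean(percentiles),
       n = n_reps)
}

measure_null_specificity <- function(seed, n_runs = 50, n_sets = 100,
                                     n_regions = 40, sigma = 0.1) {
  hits <- vapply(seq_len(n_runs), function(i) {
    s <- acc_child(seed, 4000 + i)
    ac <- generate_atlas_connectome(n_regions = n_regions, seed = s)
    gt <- ground_truth(ac$atlas, ac$connectome)
    conn <- gt$connectomes$retrograde
    truth <- predict_spread(conn, gt$seed, c = 0.25, t = 3)
    set.seed(s + 1L)
    obs <- stats::setNames(truth$value * exp(rnorm(n_regions, 0, sigma)),
                           truth$region_id)
    nl <- suppressMessages(
      random_seed_null(obs, conn, gt$atlas, gt$seed, n_sets = n_sets,
                       tolerance = 0.2, seed = s + 2L)
    )
    nl$percentile >= 0.95
  }, logical(1))
  list(null_specificity_rate = mean(hits), n = n_runs)
}

# criterion: brute-force Benjamini-Hochberg agreement over gridded p-vectors
measure_fdr <- function(seed, n_per_length = 200) {
  bh_brute <- function(p) {
    m <- length(p); o <- order(p); ps <- p[o]
    adj <- numeric(m)
    adj[o] <- vapply(seq_len(m), function(i) min(1, min(m * ps[i:m] / (i:m))),
                     numeric(1))
    adj
  }
  grid <- seq(0, 1, by = 0.01)
  set.seed(acc_child(seed, 7))
  max_dev <- 0
  n_checked <- 0L
  for (m in 1:8) {
    for (r in seq_len(n_per_length)) {
      p <- sample(grid, m, replace = TRUE)
      max_dev <- max(max_dev, max(abs(fdr_adjust(p) - bh_brute(p))))
      n_checked <- n_checked + 1L
    }
  }
  list(fdr_max_abs_dev = max_dev, n = n_checked)
}

# criterion: edge behavior and power of the two-tailed bootstrap comparison
measure_bootstrap_test <- function(seed, B = 1000, n_reps = 100) {
  set.seed(acc_child(seed, 8))
  x <- rnorm(B)
  p_ident <- compare_distributions(x, x)
  p_sep <- compare_distributions(runif(B, 10, 11), runif(B, 0, 1))
  ps <- replicate(n_reps,
    compare_distributions(rnorm(B, 0.5, 0.1), rnorm(B, 0.0, 0.1)))
  list(boot_p_identical = p_ident, boot_p_separated = p_sep,
       boot_gauss_detect_rate = mean(ps < 0.01), n = n_reps)
}

# criterion: the full pipeline is byte-identical under a fixed seed
measure_determinism <- function(seed, out_root = tempfile("acc_runs")) {
  cfg <- list(simulate = list(n_regions = 30, n_mice = 7),
              B = 20, n_sets = 15, rng_seed = acc_child(seed, 9))
  d1 <- file.path(out_root, "a"); d2 <- file.path(out_root, "b")
  suppressMessages(run_pipeline(c(cfg, list(out_dir = d1))))
  suppressMessages(run_pipeline(c(cfg, list(out_dir = d2))))
  files <- c("fits.csv", "betas.csv", "beta_ratios.csv", "comparisons.csv",
             "bootstrap_values.csv", "null_fits.csv", "manifest.json")
  same <- all(vapply(files, function(f) {
    identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }, logical(1)))
  unlink(out_root, recursive = TRUE)
  list(pipeline_deterministic = as.numeric(same), n = length(files))
}
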