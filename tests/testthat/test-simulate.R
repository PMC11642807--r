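test_that("the synthetic world is a pure function of its seed", {
  a <- generate_atlas_connectome(n_regions = 20, seed = 7)
  b <- generate_atlas_connectome(n_regions = 20, seed = 7)
  expect_identical(a$connectome$A, b$connectome$A)
  expect_identical(a$atlas, b$atlas)
  c <- generate_atlas_connectome(n_regions = 20, seed = 8)
  expect_false(identical(a$connectome$A, c$connectome$A))

  expect_error(generate_atlas_connectome(n_regions = 5), ">= 10")
  expect_error(generate_atlas_connectome(20, density = 0), "density")
  expect_error(generate_atlas_connectome(20, asymmetry = 2), "asymmetry")
})

test_that("asymmetry 0 gives a symmetric connectome with identical directional spread", {
  ac <- generate_atlas_connectome(n_regions = 20, asymmetry = 0, seed = 9)
  expect_equal(ac$connectome$A, t(ac$connectome$A), tolerance = 1e-12)
  s <- seed_spec(ac$connectome$regions[1:2])
  pa <- predict_spread(directional_view(ac$connectome, "anterograde"), s, 0.5)
  pr <- predict_spread(directional_view(ac$connectome, "retrograde"), s, 0.5)
  expect_equal(pa$value, pr$value, tolerance = 1e-10)
})

test_that("density 1 yields a complete graph and asymmetry scales imbalance", {
  ac <- generate_atlas_connectome(n_regions = 10, density = 1, seed = 10)
  offdiag <- ac$connectome$A[row(ac$connectome$A) != col(ac$connectome$A)]
  expect_true(all(offdiag > 0))

  imbalance <- function(asym) {
    A <- generate_atlas_connectome(30, asymmetry = asym, seed = 11)$connectome$A
    sum(abs(A - t(A))) / sum(abs(A + t(A)))
  }
  vals <- vapply(c(0, 0.3, 0.6, 1), imbalance, numeric(1))
  expect_equal(vals[1], 0)
  expect_true(all(diff(vals) > 0))
})

test_that("the generated atlas supports hierarchy aggregation and seed acronyms", {
  ac <- generate_atlas_connectome(n_regions = 30, seed = 12)
  expect_setequal(intersect(c("DG", "CA1", "CA3", "PTLp"), ac$atlas$acronym),
                  c("DG", "CA1", "CA3", "PTLp"))
  hips <- ac$atlas[ac$atlas$acronym %in% c("DG", "CA1", "CA3"), ]
  expect_equal(length(unique(hips$parent_id)), 1L)
  expect_equal(ac$atlas$acronym[ac$atlas$region_id == unique(hips$parent_id)],
               "HIP")
  leaves <- ac$atlas$region_id[ac$atlas$level == 2]
  counts <- stats::setNames(rep(1, length(leaves)), leaves)
  agg <- aggregate_hierarchy(counts, ac$atlas)
  expect_equal(agg$count[agg$region_id == "ROOT"], length(leaves))
})

test_that("noiseless single-mode cohorts are a deterministic transform of the prediction", {
  ac <- generate_atlas_connectome(n_regions = 20, seed = 13)
  bt <- tibble::tibble(genotype = "WT", treatment = "Sal",
                       b_a = 1, b_r = 0, b_e = 0, b_t = 0, b_t_ptz = 0)
  gt <- ground_truth(ac$atlas, ac$connectome, beta_true = bt,
                     noise_sigma = 0, tdt_sigma = 0)
  coh <- suppressMessages(simulate_cohort(gt, n_mice = c("WT-Sal" = 3), seed = 14))
  pred <- predict_spread(gt$connectomes$anterograde, gt$seed, 0.25, 3)
  lv <- log10(pred$value + min(pred$value[pred$value > 0]))
  z <- (lv - mean(lv)) / sd(lv)
  one_mouse <- dplyr::filter(coh, mouse_id == coh$mouse_id[1])
  one_mouse <- one_mouse[match(pred$region_id, one_mouse$region_id), ]
  # every mouse's regional log-profile is an exact affine image of the
  # anterograde prediction's standardized log profile
  expect_equal(log10(one_mouse$pathology), 1 + 0.5 * z, tolerance = 1e-10)
  mice <- split(coh$pathology, coh$mouse_id)
  expect_true(all(vapply(mice, function(v) isTRUE(all.equal(v, mice[[1]])), TRUE)))
})

test_that("simulated cohorts validate and survive the default region filter", {
  w <- shared_world()
  expect_silent(validate_cohort(w$cohort, w$gt$atlas))
  kept <- suppressMessages(filter_regions(w$cohort, 6))
  expect_length(excluded_regions(kept), 0)
  expect_identical(simulate_cohort(w$gt, n_mice = 4, seed = 1),
                   simulate_cohort(w$gt, n_mice = 4, seed = 1))
})

test_that("fitting the generating mode recovers the generating rate", {
  reps <- purrr::map_dbl(1:10, function(i) {
    ac <- generate_atlas_connectome(n_regions = 40, seed = 600 + i)
    bt <- tibble::tibble(genotype = "WT", treatment = "Sal",
                         b_a = 0, b_r = 1, b_e = 0, b_t = 0, b_t_ptz = 0)
    gt <- ground_truth(ac$atlas, ac$connectome, beta_true = bt,
                       noise_sigma = 0.05)
    coh <- suppressMessages(simulate_cohort(gt, n_mice = c("WT-Sal" = 8),
                                            seed = 700 + i))
    m <- region_means(coh, "WT", "Sal")
    f <- fit_rate(m, gt$connectomes$retrograde, gt$seed, t = gt$t)
    abs(f$c_hat - gt$c_true[["retrograde"]]) / gt$c_true[["retrograde"]]
  })
  expect_lt(median(reps), 0.35)
})

test_that("behavioral covariates carry the configured association", {
  w <- shared_world()
  beh <- simulate_behavior(w$cohort, w$gt$seed$sites, effect_r = 0.8, seed = 20)
  expect_true(all(beh$nor_percent >= 0 & beh$nor_percent <= 100))
  rac <- as.matrix(beh[, sprintf("racine_%02d", 1:15)])
  expect_true(all(rac >= 0 & rac <= 6))
  auc <- racine_auc_table(beh)
  expect_true(all(auc$value >= 0 & auc$value <= 90))

  per_mouse <- w$cohort |>
    dplyr::filter(region_id %in% w$gt$seed$sites) |>
    dplyr::group_by(mouse_id) |>
    dplyr::summarise(x = mean(log10(pathology + 1)))
  r_obs <- cor(per_mouse$x[match(beh$mouse_id, per_mouse$mouse_id)],
               beh$nor_percent)
  expect_gt(r_obs, 0.4)

  expect_error(simulate_behavior(w$cohort, w$gt$seed$sites, effect_r = 1.5),
               "effect_r")
})

test_that("null behavioral covariates keep the screen near its nominal level", {
  w <- shared_world()
  coh <- dplyr::filter(w$cohort, genotype == "5X", treatment == "PTZ")
  set.seed(21)
  fps <- purrr::map_dbl(1:10, function(i) {
    cov <- tibble::tibble(mouse_id = unique(coh$mouse_id),
                          value = rnorm(length(unique(coh$mouse_id))))
    scr <- suppressMessages(regional_correlation_screen(coh, cov, "pathology"))
    mean(scr$p < 0.05)
  })
  expect_lt(mean(fps), 0.12)
})
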