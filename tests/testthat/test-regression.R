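zpred <- function(w) {
  # z-scored log predictions under the true rates, named by region
  regions <- w$gt$connectomes$anterograde$regions
  purrr::map(w$gt$connectomes, function(cn) {
    v <- predict_spread(cn, w$gt$seed, c = 0.25, t = 3)$value
    lv <- log10(v + min(v[v > 0]))
    stats::setNames((lv - mean(lv)) / sd(lv), regions)
  })
}

test_that("an exact regressor gets beta 1 and the rest 0", {
  w <- shared_world()
  Z <- zpred(w)
  y <- Z$anterograde
  fit <- fit_combined(y, Z, transform = "none")
  expect_equal(unname(fit$betas["anterograde"]), 1, tolerance = 1e-8)
  expect_equal(unname(fit$betas["retrograde"]), 0, tolerance = 1e-8)
  expect_equal(unname(fit$betas["euclidean"]), 0, tolerance = 1e-8)
  expect_equal(fit$r, 1, tolerance = 1e-8)
  expect_lt(abs(mean(fit$residuals)), 1e-10)
})

test_that("a response orthogonal to all predictors gets zero betas", {
  w <- shared_world()
  Z <- zpred(w)
  set.seed(8)
  y0 <- rnorm(length(Z$anterograde))
  X <- cbind(1, Z$anterograde, Z$retrograde, Z$euclidean)
  y <- y0 - X %*% solve(crossprod(X), crossprod(X, y0))
  y <- stats::setNames(as.vector(y), names(Z$anterograde))
  fit <- fit_combined(y, Z, transform = "none")
  expect_true(all(abs(fit$betas) < 1e-8))
})

test_that("a single-predictor standardized beta equals the Pearson correlation", {
  set.seed(12)
  for (i in 1:5) {
    x <- stats::setNames(rlnorm(40), paste0("g", 1:40))
    y <- stats::setNames(rlnorm(40), paste0("g", 1:40))
    fit <- fit_combined(y, list(anterograde = x))
    lx <- log10(x + min(x)); ly <- log10(y + min(y))
    expect_equal(unname(fit$betas["anterograde"]), cor(lx, ly), tolerance = 1e-10)
  }
})

test_that("standardized betas are invariant to affine predictor/response rescaling", {
  w <- shared_world()
  Z <- zpred(w)
  set.seed(13)
  y <- 0.5 * Z$anterograde + 0.3 * Z$retrograde + rnorm(50, 0, 0.2)
  names(y) <- names(Z$anterograde)
  f0 <- fit_combined(y, Z, transform = "none")
  Z2 <- Z
  Z2$retrograde <- 7 * Z2$retrograde + 2
  f1 <- fit_combined(y, Z2, transform = "none")
  expect_equal(f1$betas, f0$betas, tolerance = 1e-10)
  f2 <- fit_combined(100 * y + 3, Z, transform = "none")
  expect_equal(f2$betas, f0$betas, tolerance = 1e-10)
})

test_that("generating weights are recovered up to the response scale factor", {
  # with the response z-scored, the population standardized coefficients are
  # the generating weights divided by sd(y); undoing that factor recovers
  # the weights almost exactly
  w <- shared_world()
  Z <- zpred(w)
  set.seed(14)
  err <- replicate(20, {
    y <- 0.7 * Z$anterograde + 0.2 * Z$retrograde + 0.1 * Z$euclidean +
      rnorm(50, 0, 0.1)
    names(y) <- names(Z$anterograde)
    fit <- fit_combined(y, Z, transform = "none")
    max(abs(fit$betas * sd(y) - c(0.7, 0.2, 0.1)))
  })
  expect_lt(median(err), 0.05)
})

test_that("constant predictors and constant responses are rejected", {
  w <- shared_world()
  Z <- zpred(w)
  Zc <- Z
  Zc$euclidean[] <- 0
  y <- Z$anterograde
  expect_error(fit_combined(y, Zc, transform = "none"), "constant predictor")
  yc <- stats::setNames(rep(1, 50), names(Z$anterograde))
  expect_error(fit_combined(yc, Z, transform = "none"), "constant response")
})

test_that("beta ratios follow their definition and guard zero denominators", {
  fake <- structure(list(betas = c(anterograde = 0.6, retrograde = 0.3,
                                   euclidean = 0.2)), class = "combined_fit")
  br <- beta_ratios(fake)
  expect_equal(br$value[br$ratio == "a:r"], 2)
  expect_equal(br$value[br$ratio == "e:r"], 2 / 3, tolerance = 1e-12)
  expect_equal(br$value[br$ratio == "a:e"], 3)

  fake$betas["retrograde"] <- 0
  br0 <- beta_ratios(fake)
  expect_true(br0$undefined[br0$ratio == "a:r"])
  expect_true(is.na(br0$value[br0$ratio == "a:r"]))
  expect_false(br0$undefined[br0$ratio == "a:e"])

  fake$betas[] <- 0.4
  expect_true(all(beta_ratios(fake)$value == 1))
})

test_that("tdT interaction model exposes coherent simple slopes", {
  w <- shared_world()
  preds <- purrr::map(w$gt$connectomes, predict_spread,
                      seed = w$gt$seed, c = 0.25, t = 3)
  fit <- fit_tdt_interaction(w$cohort, preds, "WT")
  cf <- coef(fit$model)
  # treatment-reference coding: Sal slope is the tdt main effect, PTZ slope
  # adds the interaction
  expect_equal(fit$slopes$slope[fit$slopes$group == "Sal"],
               unname(cf["tdt"]), tolerance = 1e-12)
  expect_equal(fit$slopes$slope[fit$slopes$group == "PTZ"],
               unname(cf["tdt"] + cf["tdt:treatment"]), tolerance = 1e-12)
  expect_true(all(fit$slopes$p >= 0 & fit$slopes$p <= 1))

  # partial residuals regressed on tdt within a group reproduce that
  # group's simple slope exactly
  for (g in c("Sal", "PTZ")) {
    pr <- dplyr::filter(fit$partial_residuals, treatment == g)
    b <- coef(lm(partial_residual ~ tdt, data = pr))[["tdt"]]
    expect_equal(b, fit$slopes$slope[fit$slopes$group == g], tolerance = 1e-10)
  }
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("tdT interaction model rejects degenerate inputs", {
  w <- shared_world()
  preds <- purrr::map(w$gt$connectomes, predict_spread,
                      seed = w$gt$seed, c = 0.25, t = 3)
  only_sal <- dplyr::filter(w$cohort, treatment == "Sal")
  expect_error(fit_tdt_interaction(only_sal, preds, "WT"), "both treatment")
  no_tdt <- dplyr::mutate(w$cohort, tdt = NA_real_)
  expect_error(fit_tdt_interaction(no_tdt, preds, "WT"), "missing")
  const_tdt <- dplyr::mutate(w$cohort, tdt = 5)
  expect_error(fit_tdt_interaction(const_tdt, preds, "WT"), "constant")
})

test_that("the configured group-specific tdT association is detected", {
  # WT ground truth: positive tdT slope under saline, none under PTZ
  w <- shared_world()
  preds <- purrr::map(w$gt$connectomes, predict_spread,
                      seed = w$gt$seed, c = 0.25, t = 3)
  hits <- purrr::map_lgl(1:20, function(i) {
    coh <- suppressMessages(simulate_cohort(w$gt, n_mice = 8, seed = 500 + i))
    fit <- fit_tdt_interaction(coh, preds, "WT")
    sal <- fit$slopes[fit$slopes$group == "Sal", ]
    ptz <- fit$slopes[fit$slopes$group == "PTZ", ]
    sal$p < 0.05 && abs(ptz$slope) < 0.1
  })
  expect_gte(mean(hits), 0.9)
})

test_that("region-wise Pearson screen matches cor.test and skips small n", {
  w <- shared_world()
  coh <- dplyr::filter(w$cohort, genotype == "WT", treatment == "Sal")
  mice <- unique(coh$mouse_id)
  region1 <- coh$region_id[1]
  cov <- coh |>
    dplyr::filter(region_id == region1) |>
    dplyr::transmute(mouse_id, value = pathology)
  scr <- suppressMessages(regional_correlation_screen(coh, cov, "pathology"))
  row1 <- scr[scr$region_id == region1, ]
  expect_equal(row1$r, 1, tolerance = 1e-12)
  expect_lt(row1$p, 1e-6)

  # independent check of one other region against stats::cor.test
  region2 <- sort(unique(coh$region_id))[5]
  d2 <- dplyr::filter(coh, region_id == region2) |>
    dplyr::inner_join(cov, by = "mouse_id")
  ct <- cor.test(d2$pathology, d2$value)
  row2 <- scr[scr$region_id == region2, ]
  expect_equal(row2$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(row2$p, ct$p.value, tolerance = 1e-12)

  # a region observed in only 2 mice is skipped
  thin <- coh |>
    dplyr::filter(!(region_id == region1 & !mouse_id %in% mice[1:2]))
  scr2 <- suppressMessages(regional_correlation_screen(thin, cov, "pathology"))
  expect_false(region1 %in% scr2$region_id)

  cov_const <- dplyr::mutate(cov, value = 1)
  expect_error(regional_correlation_screen(coh, cov_const, "pathology"),
               "constant")
})

test_that("Racine AUC is the sum of per-minute maxima", {
  expect_equal(racine_auc(rep(0L, 15)), 0)
  expect_equal(racine_auc(rep(5L, 15)), 75)
  expect_equal(racine_auc(c(0, 1, 2, 3, 4, 5, 5, 5, 4, 3, 2, 1, 0, 0, 0)), 35)
  expect_error(racine_auc(rep(1L, 14)), "15")
  expect_error(racine_auc(c(rep(1L, 14), 7L)), "0..6")
  expect_error(racine_auc(c(rep(1L, 14), -1L)), "0..6")
  expect_equal(racine_auc(rep(4L, 15), method = "trapezoid"), 60 - 4)
})
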