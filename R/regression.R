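#' Combine spread predictions (and tdT density) in a multivariate regression
#'
#' Fits the combined "Bidirectional Euclidean (tdT)" model: observed
#' regional pathology regressed on the anterograde, retrograde and
#' Euclidean-distance spread predictions, optionally with tdT+ cell
#' density, by ordinary least squares. Response and predictors are
#' log10(x + eps) transformed (eps = smallest positive value of each
#' vector) and z-scored, so the returned coefficients are standardized
#' beta weights; the residuals keep a zero mean, and with a single
#' predictor the beta equals the Pearson correlation.
#'
#' @param observed A data frame `(region_id, pathology)` or named vector.
#' @param predictions Named list of spread predictions (tibbles from
#'   [predict_spread()] / [fit_rate()]`$prediction`, or named vectors) with
#'   names among `anterograde`, `retrograde`, `euclidean`.
#' @param tdt Optional tdT density: data frame `(region_id, tdt)` or named
#'   vector.
#' @param transform `"log10"` (default) or `"none"` applied before z-scoring.
#' @param condition_warn Condition-number threshold above which a
#'   collinearity warning is emitted.
#' @return An object of class `combined_fit`.
#' @export
fit_combined <- function(observed, predictions, tdt = NULL,
                         transform = c("log10", "none"),
                         condition_warn = 1e4) {
  transform <- match.arg(transform)
  if (is.data.frame(observed)) {
    col <- if ("pathology" %in% names(observed)) "pathology" else "value"
    obs <- setNames(observed[[col]], observed$region_id)
  } else obs <- observed
  obs <- obs[!is.na(obs)]
  regions <- names(obs)
  if (is.null(regions)) abort("observed must carry region ids (names or a region_id column)")

  tf <- function(v) if (transform == "log10") log10_eps(v) else v
  X <- purrr::map(predictions, function(p) {
    v <- prediction_values(p, regions)
    tf(unname(v))
  })
  if (!is.null(tdt)) {
    tv <- if (is.data.frame(tdt)) setNames(tdt$tdt %||% tdt$value, tdt$region_id) else tdt
    keep <- regions %in% names(tv)[!is.na(tv)]
    if (sum(keep) < length(X) + 3) abort("too few regions with tdT available")
    regions <- regions[keep]
    obs <- obs[keep]
    X <- purrr::map(X, ~ .x[keep])
    X$tdt <- tf(unname(tv[regions]))
  }
  n <- length(regions)
  if (n < length(X) + 2) abort("need at least p + 2 regions")
  const <- purrr::map_lgl(X, ~ sd(.x) == 0)
  if (any(const)) {
    abort(paste0("constant predictor(s): ", paste(names(X)[const], collapse = ", ")))
  }
  if (sd(tf(unname(obs))) == 0) abort("constant response")

  Z <- purrr::map(X, zscore)
  y <- zscore(tf(unname(obs)))
  dat <- as_tibble(Z)
  dat$.y <- y

  Xm <- as.matrix(as_tibble(Z))
  kappa_ <- kappa(cbind(1, Xm), exact = TRUE)
  if (kappa_ > condition_warn) {
    warn(paste0("predictors are nearly collinear (condition number ",
                format(kappa_, digits = 3), ")"))
  }

  model <- lm(.y ~ ., data = dat)
  betas <- coef(model)[-1]
  names(betas) <- names(Z)
  r <- cor(fitted(model), y)
  tag <- if ("tdt" %in% names(Z)) "bidirectional_euclidean_tdt" else "bidirectional_euclidean"
  structure(
    list(betas = betas, intercept = unname(coef(model)[1]),
         model = model, r = r, n_regions = n, model_tag = tag,
         regions = regions, residuals = setNames(unname(residuals(model)), regions),
         transform = transform, condition_number = kappa_),
    class = "combined_fit"
  )
}

#' @export
print.combined_fit <- function(x, ...) {
  cat("<combined_fit> ", x$model_tag, ": r=", signif(x$r, 4),
      " over ", x$n_regions, " regions\n", sep = "")
  print(round(x$betas, 4))
  invisible(x)
}

#' Standardized coefficients of a combined model
#' @param x A `combined_fit`.
#' @param ... Unused.
#' @return A tibble `(term, estimate, std.error, statistic, p.value)`.
#' @export
tidy.combined_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(
    term = c("(Intercept)", names(x$betas)),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4])
  )
}

#' @export
glance.combined_fit <- function(x, ...) {
  tibble(r = x$r, r.squared = x$r^2, n_regions = x$n_regions,
         model_tag = x$model_tag, condition_number = x$condition_number)
}

#' Ratios of standardized beta weights
#'
#' Reports anterograde:retrograde, Euclidean:retrograde and
#' anterograde:Euclidean ratios of the standardized betas, the summary used
#' to compare the relative contribution of each spread mode between groups.
#' Ratios with a near-zero denominator are flagged undefined rather than
#' reported as infinite.
#'
#' @param fit A `combined_fit` with anterograde, retrograde and euclidean
#'   terms.
#' @param tol Denominator magnitude below which a ratio is undefined.
#' @return A tibble `(ratio, value, undefined)`.
#' @export
beta_ratios <- function(fit, tol = 1e-8) {
  b <- fit$betas
  need <- c("anterograde", "retrograde", "euclidean")
  missing <- setdiff(need, names(b))
  if (length(missing) > 0) {
    abort(paste0("fit lacks term(s): ", paste(missing, collapse = ", ")))
  }
  pairs <- list("a:r" = c("anterograde", "retrograde"),
                "e:r" = c("euclidean", "retrograde"),
                "a:e" = c("anterograde", "euclidean"))
  purrr::imap_dfr(pairs, function(p, nm) {
    den <- b[[p[2]]]
    if (abs(den) < tol) {
      tibble(ratio = nm, value = NA_real_, undefined = TRUE)
    } else {
      tibble(ratio = nm, value = b[[p[1]]] / den, undefined = FALSE)
    }
  })
}

#' tdT-by-treatment interaction model for one genotype
#'
#' For a single genotype, regresses regional pathology (per treatment
#' group) on the three spread predictions, tdT+ cell density, treatment,
#' and the tdT-by-treatment interaction. With treatment coded Sal = 0,
#' PTZ = 1, the tdT coefficient is the saline simple slope and the sum of
#' the tdT and interaction coefficients is the PTZ simple slope; each is
#' tested two-sided against zero. Partial residuals for the tdT term
#' (residual plus the group's fitted tdT contribution) are returned for
#' plotting pathology against tdT density while controlling for spread.
#'
#' @param cohort A cohort tibble with tdT densities.
#' @param predictions Named list with `anterograde`, `retrograde`,
#'   `euclidean` spread predictions.
#' @param genotype `"WT"` or `"5X"`.
#' @param transform `"log10"` or `"none"`.
#' @return An object of class `tdt_interaction_fit` containing the model,
#'   a `slopes` tibble (group, slope, se, p), and a `partial_residuals`
#'   tibble.
#' @export
fit_tdt_interaction <- function(cohort, predictions, genotype = c("WT", "5X"),
                                transform = c("log10", "none")) {
  genotype <- match.arg(genotype)
  transform <- match.arg(transform)
  sub <- filter(cohort, .data$genotype == !!genotype)
  levels_present <- unique(sub$treatment)
  if (!all(c("Sal", "PTZ") %in% levels_present)) {
    abort(paste0("both treatment levels required; found only: ",
                 paste(levels_present, collapse = ", ")))
  }
  means <- sub |>
    group_by(.data$treatment, .data$region_id) |>
    summarise(pathology = mean(.data$pathology, na.rm = TRUE),
              tdt = if (all(is.na(.data$tdt))) NA_real_ else mean(.data$tdt, na.rm = TRUE),
              .groups = "drop")
  if (mean(is.na(means$tdt)) > 0.5) abort("tdT missing for more than half of the regions")
  means <- filter(means, !is.na(.data$tdt), !is.na(.data$pathology))

  tf <- function(v) if (transform == "log10") log10_eps(v) else v
  regions <- means$region_id
  pv <- purrr::map(predictions, ~ prediction_values(.x, regions))
  if (sd(means$tdt) == 0) abort("constant predictor: tdt")

  dat <- tibble(
    region_id = regions,
    treatment = as.integer(means$treatment == "PTZ"),
    y = zscore(tf(means$pathology)),
    anterograde = zscore(tf(unname(pv$anterograde))),
    retrograde = zscore(tf(unname(pv$retrograde))),
    euclidean = zscore(tf(unname(pv$euclidean))),
    tdt = zscore(tf(means$tdt))
  )
  model <- lm(y ~ anterograde + retrograde + euclidean + tdt + treatment +
                tdt:treatment, data = dat)
  cf <- coef(model); V <- vcov(model)
  df_res <- model$df.residual
  slope_sal <- cf[["tdt"]]
  se_sal <- sqrt(V["tdt", "tdt"])
  slope_ptz <- cf[["tdt"]] + cf[["tdt:treatment"]]
  se_ptz <- sqrt(V["tdt", "tdt"] + V["tdt:treatment", "tdt:treatment"] +
                   2 * V["tdt", "tdt:treatment"])
  pval <- function(est, se) 2 * pt(-abs(est / se), df_res)
  slopes <- tibble(
    group = c("Sal", "PTZ"),
    slope = c(slope_sal, slope_ptz),
    se = c(se_sal, se_ptz),
    p = c(pval(slope_sal, se_sal), pval(slope_ptz, se_ptz))
  )
  group_slope <- ifelse(dat$treatment == 1, slope_ptz, slope_sal)
  partial <- tibble(
    region_id = dat$region_id,
    treatment = ifelse(dat$treatment == 1, "PTZ", "Sal"),
    tdt = dat$tdt,
    partial_residual = residuals(model) + group_slope * dat$tdt
  )
  betas <- cf[-1]
  structure(
    list(model = model, betas = betas, slopes = slopes,
         partial_residuals = partial, genotype = genotype,
         n_regions = nrow(dat), r = cor(fitted(model), dat$y),
         interaction = cf[["tdt:treatment"]],
         interaction_ci = stats::confint(model)["tdt:treatment", ],
         model_tag = "tdt_interaction", transform = transform),
    class = "tdt_interaction_fit"
  )
}

#' @export
print.tdt_interaction_fit <- function(x, ...) {
  cat("<tdt_interaction_fit> genotype=", x$genotype, ", r=", signif(x$r, 4),
      " over ", x$n_regions, " region x treatment cells\n", sep = "")
  print(as.data.frame(x$slopes), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.tdt_interaction_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.tdt_interaction_fit <- function(x, ...) {
  tibble(genotype = x$genotype, r = x$r, n = x$n_regions,
         interaction = x$interaction,
         slope_sal = x$slopes$slope[x$slopes$group == "Sal"],
         slope_ptz = x$slopes$slope[x$slopes$group == "PTZ"])
}

#' Region-wise Pearson correlation with a per-mouse covariate
#'
#' Screens every region for a correlation between the per-mouse regional
#' measure (pathology or tdT density) and a per-mouse scalar covariate such
#' as seizure-severity AUC or novel-object preference. Regions with fewer
#' than `min_n` complete pairs are skipped.
#'
#' @param cohort A cohort tibble.
#' @param covariate A data frame `(mouse_id, value)` or named vector.
#' @param measure `"pathology"` or `"tdt"`.
#' @param min_n Minimum complete pairs per region (>= 3).
#' @param adjust If `TRUE`, append Benjamini-Hochberg adjusted p-values.
#' @return A tibble `(region_id, n, r, p[, p_adj])`.
#' @export
regional_correlation_screen <- function(cohort, covariate,
                                        measure = c("pathology", "tdt"),
                                        min_n = 3, adjust = FALSE) {
  measure <- match.arg(measure)
  if (is.data.frame(covariate)) {
    cov <- setNames(covariate$value, covariate$mouse_id)
  } else cov <- covariate
  cov <- cov[!is.na(cov)]
  if (length(cov) < 3) abort("need covariate values for at least 3 mice")
  if (sd(cov) == 0) abort("covariate is constant: correlation undefined")

  per_region <- cohort |>
    filter(.data$mouse_id %in% names(cov)) |>
    mutate(cov_val = unname(cov[.data$mouse_id]))
  out <- per_region |>
    group_by(.data$region_id) |>
    dplyr::group_modify(function(d, key) {
      ok <- complete.cases(d[[measure]], d$cov_val)
      n <- sum(ok)
      if (n < min_n || sd(d[[measure]][ok]) == 0) {
        return(tibble(n = n, r = NA_real_, p = NA_real_, skipped = TRUE))
      }
      ct <- cor.test(d[[measure]][ok], d$cov_val[ok], method = "pearson")
      tibble(n = n, r = unname(ct$estimate), p = ct$p.value, skipped = FALSE)
    }) |>
    ungroup()
  n_skip <- sum(out$skipped)
  if (n_skip > 0) inform(paste0("regional_correlation_screen: skipped ", n_skip,
                                " region(s) with n < ", min_n, " or zero variance"))
  out <- filter(out, !.data$skipped) |> select(-"skipped")
  if (adjust) out$p_adj <- fdr_adjust_allow_na(out$p)
  out
}

fdr_adjust_allow_na <- function(p) {
  adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  adj[ok] <- fdr_adjust(p[ok])
  adj
}

#' Seizure-severity area under the curve from per-minute Racine maxima
#'
#' The AUC is the sum of the maximal modified Racine score (0-6) reached in
#' each of the 15 minutes following the final pentylenetetrazol
#' administration, i.e. rectangular integration with 1-minute bins; a
#' trapezoidal rule is available as an option.
#'
#' @param scores Integer vector of length 15, values in 0..6.
#' @param method `"rectangular"` (default, the plain sum) or `"trapezoid"`.
#' @return Scalar AUC in score-minutes (0 to 90 for the rectangular rule).
#' @export
racine_auc <- function(scores, method = c("rectangular", "trapezoid")) {
  method <- match.arg(method)
  if (length(scores) != 15) abort("expected 15 per-minute maximal Racine scores")
  if (any(is.na(scores)) || any(scores != round(scores)) ||
      any(scores < 0) || any(scores > 6)) {
    abort("Racine scores must be integers in 0..6")
  }
  switch(method,
    rectangular = sum(scores),
    trapezoid = sum(scores) - (scores[1] + scores[15]) / 2
  )
}
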