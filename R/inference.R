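#' Bootstrap a fit statistic over mice within a group
#'
#' Resamples mice with replacement within one genotype-by-treatment group,
#' recomputes regional means for each resample, and applies a statistic
#' function, yielding the bootstrap distribution used to compare spread
#' models or beta weights between groups. Resamples where the statistic
#' errors or returns a non-finite value are dropped and counted.
#'
#' @param cohort A cohort tibble.
#' @param genotype,treatment Group selectors.
#' @param stat_fn Function taking a regional-means tibble
#'   (`region_id`, `pathology`, `tdt`, `n`) and returning a scalar.
#' @param B Number of resamples (default 1000).
#' @param seed RNG seed for reproducibility.
#' @param statistic Label stored with the distribution.
#' @return An object of class `bootstrap_dist` with `values` (finite
#'   statistics, length <= B), `B`, `n_failed`, `seed`, `group`.
#' @export
bootstrap_statistic <- function(cohort, genotype, treatment, stat_fn,
                                B = 1000, seed = NULL, statistic = "statistic") {
  stopifnot(is_scalar_number(B), B >= 1)
  sub <- filter(cohort, .data$genotype == !!genotype, .data$treatment == !!treatment)
  mice <- unique(sub$mouse_id)
  if (length(mice) < 3) abort("group must contain at least 3 mice")
  if (!is.null(seed)) withr::local_seed(seed)

  by_mouse <- split(sub, sub$mouse_id)
  values <- numeric(0)
  n_failed <- 0L
  for (b in seq_len(B)) {
    draw <- sample(mice, length(mice), replace = TRUE)
    res <- dplyr::bind_rows(by_mouse[draw], .id = NULL)
    # duplicated mice keep separate identities so they weight the means
    res$mouse_id <- rep(seq_along(draw), times = vapply(by_mouse[draw], nrow, 0L))
    means <- res |>
      group_by(.data$region_id) |>
      summarise(
        pathology = mean(.data$pathology, na.rm = TRUE),
        tdt = if (all(is.na(.data$tdt))) NA_real_ else mean(.data$tdt, na.rm = TRUE),
        n = sum(!is.na(.data$pathology)),
        .groups = "drop"
      )
    v <- tryCatch(stat_fn(means), error = function(e) NA_real_)
    if (length(v) != 1 || !is.finite(v)) n_failed <- n_failed + 1L
    else values <- c(values, v)
  }
  if (length(values) == 0) abort("all bootstrap resamples failed")
  if (n_failed > 0) inform(paste0("bootstrap_statistic: ", n_failed,
                                  " of ", B, " resamples failed and were dropped"))
  structure(
    list(statistic = statistic, values = values, B = B, n_failed = n_failed,
         seed = seed, group = paste0(genotype, "-", treatment)),
    class = "bootstrap_dist"
  )
}

#' @export
print.bootstrap_dist <- function(x, ...) {
  cat("<bootstrap_dist> ", x$statistic, " in ", x$group, ": B=", length(x$values),
      ", median=", signif(median(x$values), 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.bootstrap_dist <- function(x, ...) {
  tibble(statistic = x$statistic, group = x$group, value = x$values)
}

#' @export
glance.bootstrap_dist <- function(x, ...) {
  q <- quantile(x$values, c(0.025, 0.5, 0.975), names = FALSE)
  tibble(statistic = x$statistic, group = x$group, B = length(x$values),
         n_failed = x$n_failed, mean = mean(x$values),
         q025 = q[1], median = q[2], q975 = q[3])
}

#' Two-tailed non-parametric comparison of two bootstrap distributions
#'
#' Computes p = 2 * min(P(delta <= 0), P(delta >= 0)) where delta pairs
#' draws from the two distributions, with a +1/(B+1) continuity correction
#' and capped at 1. The default pairing matches draws by index (requiring
#' equal lengths); `"all_pairs"` uses every cross pair. The minimum
#' attainable p under complete separation is 2/(B+1).
#'
#' @param d1,d2 `bootstrap_dist` objects or numeric vectors.
#' @param pairing `"matched"` (default) or `"all_pairs"`.
#' @return Two-sided p-value in (0, 1].
#' @export
compare_distributions <- function(d1, d2, pairing = c("matched", "all_pairs")) {
  pairing <- match.arg(pairing)
  v1 <- if (inherits(d1, "bootstrap_dist")) d1$values else as.numeric(d1)
  v2 <- if (inherits(d2, "bootstrap_dist")) d2$values else as.numeric(d2)
  if (length(v1) == 0 || length(v2) == 0) abort("empty distribution")
  if (pairing == "matched") {
    if (length(v1) != length(v2)) {
      abort("matched pairing requires equal-length distributions; use pairing = 'all_pairs'")
    }
    delta <- v1 - v2
  } else {
    delta <- as.vector(outer(v1, v2, "-"))
  }
  B <- length(delta)
  p_lo <- (sum(delta <= 0) + 1) / (B + 1)
  p_hi <- (sum(delta >= 0) + 1) / (B + 1)
  min(1, 2 * min(p_lo, p_hi))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values; monotone and capped at 1.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Seed-specificity null: random seed sets matched on spatial clustering
#'
#' Repeats the diffusion-rate fit from `n_sets` random seed sets with the
#' same number of sites as the experimental seed and a similar spatial
#' clustering, quantified as the mean pairwise centroid distance within
#' `tolerance` (a fraction) of the experimental seed's. Reports the
#' fraction of null fits that fall strictly below the experimental fit; a
#' high percentile indicates the observed pattern is specific to the true
#' seed sites rather than generic network position.
#'
#' @param observed Regional observed pathology (data frame or named vector),
#'   as for [fit_rate()].
#' @param conn A `connectome`.
#' @param atlas Atlas supplying centroids for the matching statistic.
#' @param true_seed A `seed_spec` for the experimental seed sites.
#' @param n_sets Number of matched random sets (paper-scale default 500).
#' @param tolerance Allowed fractional deviation of the matching statistic.
#' @param seed RNG seed.
#' @param t Horizon in months.
#' @param match_stat `"mean_pairwise"` (default) or `"max_pairwise"`
#'   centroid distance.
#' @param max_proposals Rejection-sampling cap before giving up.
#' @param ... Passed to [fit_rate()].
#' @return An object of class `seed_null` with `true_fit`, `null_fits`
#'   (tibble), and `percentile`.
#' @export
random_seed_null <- function(observed, conn, atlas, true_seed,
                             n_sets = 500, tolerance = 0.2, seed = NULL,
                             t = 3, match_stat = c("mean_pairwise", "max_pairwise"),
                             max_proposals = 1e6, ...) {
  match_stat <- match.arg(match_stat)
  if (is.character(true_seed)) true_seed <- seed_spec(true_seed)
  k <- length(true_seed$sites)
  regions <- conn$regions
  rows <- atlas[match(regions, atlas$region_id), ]
  if (any(is.na(rows$region_id))) abort("connectome regions missing from atlas")
  cent <- as.matrix(rows[, c("x", "y", "z")])
  rownames(cent) <- regions

  pair_stat <- function(sites) {
    d <- stats::dist(cent[sites, , drop = FALSE])
    if (match_stat == "mean_pairwise") mean(d) else max(d)
  }
  target <- if (k >= 2) pair_stat(true_seed$sites) else NA_real_

  if (!is.null(seed)) withr::local_seed(seed)
  true_key <- paste(sort(true_seed$sites), collapse = "|")
  sets <- list(); keys <- character(0)
  proposals <- 0L
  while (length(sets) < n_sets && proposals < max_proposals) {
    proposals <- proposals + 1L
    cand <- sample(regions, k)
    key <- paste(sort(cand), collapse = "|")
    if (key == true_key || key %in% keys) next
    if (k >= 2) {
      s <- pair_stat(cand)
      if (abs(s - target) > tolerance * target) next
    }
    sets[[length(sets) + 1L]] <- cand
    keys <- c(keys, key)
  }
  if (length(sets) < n_sets) {
    abort(paste0("candidate pool exhausted: only ", length(sets),
                 " matched seed sets found in ", proposals, " proposals"))
  }

  true_fit <- fit_rate(observed, conn, true_seed, t = t, ...)
  null_r <- vapply(sets, function(sites) {
    f <- tryCatch(fit_rate(observed, conn, seed_spec(sites, true_seed$amount),
                           t = t, ...),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$fit_r
  }, numeric(1))
  ok <- is.finite(null_r)
  if (sum(!ok) > 0) inform(paste0("random_seed_null: ", sum(!ok),
                                  " null set(s) unfittable and dropped"))
  null_tbl <- tibble(
    set_id = seq_along(sets),
    members = vapply(sets, paste, character(1), collapse = ","),
    fit_r = null_r
  ) |> filter(is.finite(.data$fit_r))

  structure(
    list(true_fit = true_fit, null_fits = null_tbl, n_sets = nrow(null_tbl),
         matching_tolerance = tolerance, match_stat = match_stat,
         percentile = mean(null_tbl$fit_r < true_fit$fit_r), seed = seed),
    class = "seed_null"
  )
}

#' @export
print.seed_null <- function(x, ...) {
  cat("<seed_null> true fit_r=", signif(x$true_fit$fit_r, 4),
      " beats ", signif(100 * x$percentile, 4), "% of ", x$n_sets,
      " spatially matched random seed sets\n", sep = "")
  invisible(x)
}

#' @export
tidy.seed_null <- function(x, ...) x$null_fits

#' @export
glance.seed_null <- function(x, ...) {
  tibble(true_fit_r = x$true_fit$fit_r, n_sets = x$n_sets,
         percentile = x$percentile, tolerance = x$matching_tolerance)
}
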