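#' @import ggplot2
NULL

#' Observed versus predicted pathology for a diffusion fit
#'
#' @param object A `diffusion_fit`.
#' @param ... Unused.
#' @return A ggplot: log-log scatter of observed against predicted regional
#'   pathology with the identity-free linear trend.
#' @export
autoplot.diffusion_fit <- function(object, ...) {
  d <- filter(object$prediction, .data$used)
  eps <- min(d$observed[d$observed > 0])
  d <- mutate(d, pred_l = log10(.data$value + eps),
              obs_l = log10(.data$observed + eps))
  ggplot(d, aes(x = .data$pred_l, y = .data$obs_l)) +
    geom_point(alpha = 0.6) +
    geom_smooth(method = "lm", formula = y ~ x, se = TRUE, linewidth = 0.6) +
    labs(
      x = "log10 predicted pathology (a.u.)",
      y = "log10 observed pathology",
      title = sprintf("%s spread model: r = %.3f, c = %.3g /month",
                      object$mode, object$fit_r, object$c_hat)
    )
}

#' Standardized beta weights of a combined model
#' @param object A `combined_fit`.
#' @param ... Unused.
#' @return A ggplot bar chart of standardized coefficients with 95% CIs.
#' @export
autoplot.combined_fit <- function(object, ...) {
  td <- tidy(object) |> filter(.data$term != "(Intercept)")
  ggplot(td, aes(x = .data$term, y = .data$estimate)) +
    geom_col(fill = "grey35") +
    geom_errorbar(aes(ymin = .data$estimate - 1.96 * .data$std.error,
                      ymax = .data$estimate + 1.96 * .data$std.error),
                  width = 0.2) +
    labs(x = NULL, y = "standardized beta",
         title = sprintf("%s (r = %.3f, n = %d regions)",
                         object$model_tag, object$r, object$n_regions))
}

#' Partial-residual plot for the tdT term, split by treatment
#'
#' Shows regional tau pathology (as partial residuals after removing the
#' fitted spread terms) against tdT+ cell density for each treatment group,
#' with the group simple slopes.
#'
#' @param object A `tdt_interaction_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tdt_interaction_fit <- function(object, ...) {
  pr <- object$partial_residuals
  sl <- object$slopes
  lab <- sprintf("%s: slope = %.3f (p = %.2g)", sl$group, sl$slope, sl$p)
  names(lab) <- sl$group
  ggplot(pr, aes(x = .data$tdt, y = .data$partial_residual,
                 color = .data$treatment)) +
    geom_point(alpha = 0.5) +
    geom_abline(data = sl, aes(slope = .data$slope, intercept = 0,
                               color = .data$group)) +
    labs(x = "tdT+ density (standardized log10)",
         y = "tau pathology (partial residual)",
         title = paste0(object$genotype, ": ", paste(lab, collapse = "; ")),
         color = "treatment")
}

#' Histogram of a bootstrap distribution
#' @param object A `bootstrap_dist`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bootstrap_dist <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$value)) +
    geom_histogram(bins = 40, fill = "grey40") +
    labs(x = object$statistic, y = "resamples",
         title = paste0(object$group, " (B = ", length(object$values), ")"))
}

#' Null distribution of seed-specificity fits
#'
#' Histogram of fit correlations from spatially matched random seed sets
#' with the experimental seed's fit marked.
#'
#' @param object A `seed_null`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.seed_null <- function(object, ...) {
  ggplot(object$null_fits, aes(x = .data$fit_r)) +
    geom_histogram(bins = 40, fill = "grey55") +
    geom_vline(xintercept = object$true_fit$fit_r, color = "red",
               linewidth = 0.8) +
    labs(x = "fit r (random matched seed sets)", y = "count",
         title = sprintf("experimental seed beats %.1f%% of %d null sets",
                         100 * object$percentile, object$n_sets))
}
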