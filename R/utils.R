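#' @importFrom rlang abort warn inform .data %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows distinct n pull rename across all_of
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats cor lm coef vcov pt sd setNames rnorm runif rlnorm
#'   residuals fitted p.adjust ks.test cor.test complete.cases quantile median
#' @importFrom utils head
NULL

# log10(x + eps) with eps = smallest positive value of the reference vector
# (the observation vector by default). Used for both diffusion fitting and
# the combined regressions so betas are comparable across modules.
log10_eps <- function(x, eps = NULL) {
  if (is.null(eps)) {
    pos <- x[is.finite(x) & x > 0]
    if (length(pos) == 0) abort("cannot derive epsilon: no positive values")
    eps <- min(pos)
  }
  log10(x + eps)
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("cannot z-score a constant vector")
  (x - mean(x)) / s
}

# deterministic child seeds so one pipeline seed drives many stages without
# correlated streams; kept below .Machine$integer.max
child_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483647L
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
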