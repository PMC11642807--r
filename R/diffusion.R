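#' Seed specification for diffusion
#'
#' @param sites Character vector of region ids to initialize.
#' @param amount Pathology units placed in each site (default 1, matching
#'   one unit per injection site).
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(sites, amount = 1) {
  sites <- as.character(sites)
  if (length(sites) == 0) abort("seed sites must be non-empty")
  if (anyDuplicated(sites)) abort("seed sites must be distinct")
  if (!is_scalar_number(amount) || amount <= 0) abort("seed amount must be > 0")
  structure(list(sites = sites, amount = amount), class = "seed_spec")
}

#' @export
print.seed_spec <- function(x, ...) {
  cat("<seed_spec> ", length(x$sites), " site(s) x ", x$amount, " unit(s): ",
      paste(x$sites, collapse = ", "), "\n", sep = "")
  invisible(x)
}

seed_vector <- function(seed, regions) {
  missing <- setdiff(seed$sites, regions)
  if (length(missing) > 0) {
    abort(paste0("seed site(s) absent from connectome: ",
                 paste(missing, collapse = ", ")))
  }
  x0 <- setNames(rep(0, length(regions)), regions)
  x0[seed$sites] <- seed$amount
  x0
}

#' Out-degree graph Laplacian
#'
#' L = D_out - A, with D_out the diagonal matrix of row sums of A. Every row
#' of L sums to zero and off-diagonal entries are non-positive. L generates
#' the linear diffusion dynamics used throughout the package.
#'
#' @param conn A `connectome`.
#' @return An N x N matrix.
#' @export
out_degree_laplacian <- function(conn) {
  A <- conn$A
  diag(rowSums(A)) - A
}

# Propagator for x(t) = exp(-c t L^T) x0.
#
# The flux convention: pathology leaves region i at rate proportional to its
# out-weights and arrives along edges i -> j, so the generator is -L^T and
# the all-ones vector is a left null vector -- total pathology is conserved.
# (Writing states as row vectors this is exactly x(t) = x0 exp(-cLt).)
#
# An eigendecomposition of the generator is computed once so a rate search
# costs one O(N^2) product per candidate c rather than a fresh matrix
# exponential. Falls back to a dense Pade exponential when the generator is
# close to defective.
make_propagator <- function(L) {
  G <- -t(L)
  n <- nrow(G)
  use_eigen <- FALSE
  eg <- tryCatch(eigen(G), error = function(e) NULL)
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      recon <- eg$vectors %*% (eg$values * Vi)
      err <- max(Mod(recon - G))
      scale <- max(1, max(abs(G)))
      if (is.finite(err) && err < 1e-9 * scale) use_eigen <- TRUE
    }
  }
  if (use_eigen) {
    V <- eg$vectors; lam <- eg$values
    single <- function(ct, x0) {
      y <- V %*% (exp(ct * lam) * (Vi %*% x0))
      out <- Re(y)[, 1]
      # repair rounding drift so mass is conserved to near machine precision
      drift <- sum(x0) - sum(out)
      out + drift / n
    }
    # all horizons at once: one complex matmul for a whole rate grid
    batch <- function(cts, x0) {
      w <- as.vector(Vi %*% x0)
      E <- exp(outer(lam, cts)) * w
      P <- Re(V %*% E)
      drift <- sum(x0) - colSums(P)
      sweep(P, 2, drift / n, "+")
    }
    list(single = single, batch = batch)
  } else {
    single <- function(ct, x0) {
      as.vector(Matrix::expm(ct * Matrix::Matrix(G)) %*% x0)
    }
    list(single = single,
         batch = function(cts, x0) vapply(cts, single, numeric(n), x0 = x0))
  }
}

finish_prediction <- function(values, regions, total) {
  if (any(!is.finite(values))) abort("non-finite diffusion prediction")
  neg <- values < 0
  if (any(values < -1e-8 * max(total, 1))) {
    abort("diffusion prediction has a substantially negative entry")
  }
  values[neg] <- 0
  rel_err <- abs(sum(values) - total) / total
  if (rel_err > 1e-10) {
    abort(paste0("mass conservation violated: relative error ", format(rel_err)))
  }
  setNames(values, regions)
}

#' Predict regional pathology by linear diffusion from seed regions
#'
#' Propagates the seed vector x0 for a horizon t under the linear dynamics
#' generated by the out-degree Laplacian of the connectome, x(t) =
#' exp(-cLt) x0 (states as row vectors), scaled by the diffusion rate c.
#' Total pathology is conserved; tiny negative rounding dust is clipped
#' to zero.
#'
#' @param conn A `connectome`.
#' @param seed A `seed_spec` (or character vector of sites, 1 unit each).
#' @param c Diffusion rate constant (per month), >= 0.
#' @param t Horizon in months (default 3, the post-injection interval).
#' @return A tibble `(region_id, value)` of class `spread_prediction`, with
#'   the provenance (`mode`, `seed`, `c`, `t`) stored as attributes.
#' @export
predict_spread <- function(conn, seed, c, t = 3) {
  if (is.character(seed)) seed <- seed_spec(seed)
  if (!is_scalar_number(c) || c < 0) abort("c must be a finite nonnegative scalar")
  if (!is_scalar_number(t) || t < 0) abort("t must be a finite nonnegative scalar")
  x0 <- seed_vector(seed, conn$regions)
  L <- out_degree_laplacian(conn)
  prop <- make_propagator(L)
  values <- finish_prediction(prop$single(c * t, x0), conn$regions, sum(x0))
  out <- tibble(region_id = conn$regions, value = unname(values))
  structure(out, class = c("spread_prediction", class(out)),
            mode = conn$mode, seed = seed, c = c, t = t)
}

prediction_values <- function(pred, regions) {
  if (inherits(pred, "spread_prediction") || is.data.frame(pred)) {
    v <- setNames(pred$value, pred$region_id)
  } else {
    v <- pred
  }
  missing <- setdiff(regions, names(v))
  if (length(missing) > 0) {
    abort(paste0("prediction missing region(s): ", paste(head(missing, 5), collapse = ", ")))
  }
  v[regions]
}

#' Fit the diffusion rate constant against observed pathology
#'
#' Searches for the rate c that maximizes the Pearson correlation between
#' log10-transformed predicted and observed regional pathology, the model's
#' measure of spatial fit. The search is a log-spaced grid over
#' `c_range` followed by golden-section refinement around the grid optimum,
#' and is fully deterministic.
#'
#' Zero-handling: both vectors are shifted by the smallest positive observed
#' value before the log; regions with observed pathology exactly 0 are
#' excluded from the correlation (prediction zeros are retained through the
#' shift). Seed regions are excluded by default since their values are
#' imposed rather than predicted.
#'
#' @param observed A data frame `(region_id, pathology)` (e.g. from
#'   [region_means()]) or a named numeric vector aligned to the connectome.
#' @param conn A `connectome`.
#' @param seed A `seed_spec`.
#' @param t Horizon in months. Only the product c*t is identified, so
#'   rescaling t rescales the fitted c accordingly.
#' @param transform `"log10"` (default) or `"none"` for the fit correlation.
#' @param include_seeds Keep seed regions in the correlation (default FALSE).
#' @param c_range Search interval for c (per month).
#' @param n_grid Number of log-spaced grid points.
#' @return An object of class `diffusion_fit` with elements `c_hat`,
#'   `fit_r`, `n_used`, `prediction`, `mode`, `seed`, `t`.
#' @export
fit_rate <- function(observed, conn, seed, t = 3,
                     transform = c("log10", "none"),
                     include_seeds = FALSE,
                     c_range = c(1e-4, 1e2), n_grid = 200) {
  transform <- match.arg(transform)
  if (is.character(seed)) seed <- seed_spec(seed)
  if (is.data.frame(observed)) {
    col <- if ("pathology" %in% names(observed)) "pathology" else "value"
    obs <- setNames(observed[[col]], observed$region_id)
  } else {
    obs <- observed
  }
  regions <- conn$regions
  missing <- setdiff(regions, names(obs))
  if (length(missing) > 0) {
    abort(paste0("observed vector missing region(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  obs <- obs[regions]
  x0 <- seed_vector(seed, regions)
  eligible <- !is.na(obs)
  if (transform == "log10") eligible <- eligible & obs > 0
  if (!include_seeds) eligible <- eligible & !(regions %in% seed$sites)
  n_used <- sum(eligible)
  if (n_used < 3) abort("unfittable: fewer than 3 eligible regions")
  if (sd(obs[eligible]) == 0) abort("observed pathology has zero variance: correlation undefined")

  # each vector is shifted by its own smallest positive value before the
  # log: predictions (seed-mass units) and observations (objects per mm^2)
  # live on unrelated scales, so a shared shift would flatten whichever
  # vector has the smaller dynamic range
  eps_obs <- if (transform == "log10") min(obs[eligible]) else 0
  obs_t <- if (transform == "log10") log10(obs[eligible] + eps_obs) else obs[eligible]

  prop <- make_propagator(out_degree_laplacian(conn))
  score_pred <- function(pred) {
    pred <- pred[eligible]
    pred[pred < 0] <- 0
    if (transform == "log10") {
      pos <- pred[pred > 0]
      if (length(pos) == 0) return(-Inf)
      pred_t <- log10(pred + min(pos))
    } else pred_t <- pred
    if (sd(pred_t) == 0) return(-Inf)
    cor(pred_t, obs_t)
  }
  score <- function(cc) score_pred(prop$single(cc * t, x0))

  grid <- exp(seq(log(c_range[1]), log(c_range[2]), length.out = n_grid))
  grid_preds <- prop$batch(grid * t, x0)
  vals <- vapply(seq_len(n_grid), function(i) score_pred(grid_preds[, i]),
                 numeric(1))
  if (all(!is.finite(vals))) abort("unfittable: correlation undefined at every rate")
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(n_grid, i + 1)]
  c_hat <- golden_section(score, lo, hi)
  fit_r <- score(c_hat)
  # the refined optimum can only improve on the grid point
  if (vals[i] > fit_r) { c_hat <- grid[i]; fit_r <- vals[i] }

  values <- finish_prediction(prop$single(c_hat * t, x0), regions, sum(x0))
  pred_tbl <- tibble(region_id = regions, value = unname(values),
                     observed = unname(obs), used = unname(eligible))
  structure(
    list(c_hat = c_hat, fit_r = fit_r, n_used = n_used, t = t,
         mode = conn$mode, seed = seed, transform = transform,
         prediction = pred_tbl),
    class = "diffusion_fit"
  )
}

# deterministic golden-section maximization on [lo, hi] (log scale)
golden_section <- function(f, lo, hi, tol = 1e-6, max_iter = 200) {
  phi <- (sqrt(5) - 1) / 2
  a <- log(lo); b <- log(hi)
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- f(exp(c1)); f2 <- f(exp(c2))
  for (k in seq_len(max_iter)) {
    if (b - a < tol) break
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- f(exp(c2))
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- f(exp(c1))
    }
  }
  exp((a + b) / 2)
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat("<diffusion_fit> mode=", x$mode, ": c_hat=", signif(x$c_hat, 4),
      " /month, fit_r=", signif(x$fit_r, 4), " (n=", x$n_used, ", t=", x$t,
      " months)\n", sep = "")
  invisible(x)
}

#' @export
tidy.diffusion_fit <- function(x, ...) x$prediction

#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble(mode = x$mode, c_hat = x$c_hat, fit_r = x$fit_r,
         n_used = x$n_used, t = x$t)
}

#' Compare hippocampus-only, cortex-only and dual seed sites
#'
#' Fits the same diffusion model from three seed configurations: the
#' hippocampal injection sites only, the cortical site only, and all sites
#' together (the dual model, matching the experimental injections into the
#' right dentate gyrus, CA1, CA3 and the posterior parietal association
#' area).
#'
#' @inheritParams fit_rate
#' @param atlas Atlas used to resolve acronyms to region ids.
#' @param hippocampus Acronyms of the hippocampal seed regions.
#' @param cortex Acronym(s) of the cortical seed region.
#' @param ... Passed to [fit_rate()].
#' @return Named list of `diffusion_fit`: `hippocampus_only`, `PTLp_only`,
#'   `dual`.
#' @export
single_seed_variants <- function(observed, conn, atlas, t = 3,
                                 hippocampus = c("DG", "CA1", "CA3"),
                                 cortex = "PTLp", ...) {
  resolve <- function(acrs) {
    ids <- atlas$region_id[match(acrs, atlas$acronym)]
    if (any(is.na(ids))) {
      abort(paste0("seed region(s) absent from atlas: ",
                   paste(acrs[is.na(ids)], collapse = ", ")))
    }
    ids
  }
  hip <- resolve(hippocampus); ctx <- resolve(cortex)
  list(
    hippocampus_only = fit_rate(observed, conn, seed_spec(hip), t = t, ...),
    PTLp_only = fit_rate(observed, conn, seed_spec(ctx), t = t, ...),
    dual = fit_rate(observed, conn, seed_spec(c(hip, ctx)), t = t, ...)
  )
}
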