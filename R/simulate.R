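#' Generate a synthetic region atlas and directed connectome
#'
#' Produces a toy but structurally realistic input pair: region centroids
#' uniform in a 3-D box (micrometre units), a two-level hierarchy whose
#' parents are spatial clusters of roughly `leaves_per_parent` regions, and
#' a directed weight matrix in which an edge between regions at distance d
#' is present with probability `density^(d / dbar)` (dbar = mean pairwise
#' distance, so sparser and more local as `density` falls, and complete at
#' `density = 1`) with log-normal weight magnitudes. The `asymmetry`
#' parameter mixes a shared symmetric weight component with independent
#' per-direction components: 0 gives an exactly symmetric matrix, 1 fully
#' independent directions. Weights are rescaled so the mean row sum is 1,
#' keeping the Laplacian spectrum on a common scale across sizes.
#'
#' Three regions in one spatial cluster are labeled DG, CA1 and CA3 under a
#' parent labeled HIP, and one region of another cluster is labeled PTLp,
#' providing designated hippocampal and cortical seed sites for
#' seed-variant analyses.
#'
#' @param n_regions Number of leaf regions (>= 10).
#' @param spatial_extent Box edge length in micrometres.
#' @param density Edge density parameter in (0, 1].
#' @param asymmetry Direction-independence of weights, in `[0, 1]`.
#' @param seed RNG seed.
#' @param leaves_per_parent Approximate leaves per hierarchy parent.
#' @return A list with `atlas` (tibble, leaves plus parent and root rows)
#'   and `connectome` (mode `"anterograde"`, leaves only).
#' @export
generate_atlas_connectome <- function(n_regions = 100, spatial_extent = 8000,
                                      density = 0.3, asymmetry = 0.6,
                                      seed = NULL, leaves_per_parent = 5) {
  if (!is_scalar_number(n_regions) || n_regions < 10) abort("n_regions must be >= 10")
  if (!is_scalar_number(density) || density <= 0 || density > 1) {
    abort("density must lie in (0, 1]")
  }
  if (!is_scalar_number(asymmetry) || asymmetry < 0 || asymmetry > 1) {
    abort("asymmetry must lie in [0, 1]")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  n <- as.integer(n_regions)
  cent <- matrix(runif(3 * n, 0, spatial_extent), ncol = 3,
                 dimnames = list(NULL, c("x", "y", "z")))
  ids <- sprintf("R%03d", seq_len(n))

  n_parents <- max(2L, as.integer(round(n / leaves_per_parent)))
  km <- stats::kmeans(cent, centers = n_parents, nstart = 5, iter.max = 50)
  parent_of_leaf <- sprintf("P%02d", km$cluster)

  acronym <- ids
  # designated seed sites: three co-clustered hippocampal subfields + one
  # cortical site in a different cluster
  hip_cluster <- km$cluster[1]
  hip_leaves <- which(km$cluster == hip_cluster)
  if (length(hip_leaves) < 3) {
    hip_cluster <- as.integer(names(sort(table(km$cluster), decreasing = TRUE))[1])
    hip_leaves <- which(km$cluster == hip_cluster)
  }
  acronym[hip_leaves[1:3]] <- c("DG", "CA1", "CA3")
  other <- which(km$cluster != hip_cluster)
  acronym[other[1]] <- "PTLp"

  leaf_tbl <- tibble(
    region_id = ids, acronym = acronym,
    name = paste0("synthetic region ", ids),
    hemisphere = ifelse(cent[, "x"] < spatial_extent / 2, "ipsi", "contra"),
    parent_id = parent_of_leaf,
    x = cent[, 1], y = cent[, 2], z = cent[, 3]
  )
  parent_tbl <- leaf_tbl |>
    group_by(region_id = .data$parent_id) |>
    summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
              .groups = "drop") |>
    mutate(acronym = ifelse(.data$region_id == sprintf("P%02d", hip_cluster),
                            "HIP", .data$region_id),
           name = paste0("synthetic parent ", .data$region_id),
           hemisphere = "ipsi", parent_id = "ROOT")
  root_tbl <- tibble(region_id = "ROOT", acronym = "ROOT",
                     name = "synthetic root", hemisphere = "ipsi",
                     parent_id = NA_character_,
                     x = spatial_extent / 2, y = spatial_extent / 2,
                     z = spatial_extent / 2)
  atlas <- validate_atlas(bind_rows(leaf_tbl, parent_tbl, root_tbl))

  D <- as.matrix(stats::dist(cent))
  dbar <- mean(D[upper.tri(D)])
  p_edge <- density^(D / dbar)
  mask <- matrix(runif(n * n), n, n) < p_edge
  mask[lower.tri(mask)] <- t(mask)[lower.tri(mask)]   # symmetric presence
  diag(mask) <- FALSE
  w_sym <- matrix(rlnorm(n * n, 0, 1), n, n)
  w_sym[lower.tri(w_sym)] <- t(w_sym)[lower.tri(w_sym)]
  w_dir <- matrix(rlnorm(n * n, 0, 1), n, n)
  A <- mask * ((1 - asymmetry) * w_sym + asymmetry * w_dir)
  rs <- rowSums(A)
  A <- A / mean(rs[rs > 0])

  list(atlas = atlas, connectome = connectome(ids, A, mode = "anterograde"))
}

#' Ground truth for synthetic cohorts
#'
#' Bundles everything needed to generate (and later verify recovery of) a
#' synthetic cohort: the three connectome views, the seed sites, the true
#' diffusion rate per spread mode, per-group generating weights for the
#' spread components and the tdT association, and the multiplicative noise
#' level. Defaults emulate the structure reported for the real cohorts:
#' retrograde-dominant spread in WT with an increased anterograde
#' contribution in 5X, a positive tdT association in every group except
#' PTZ-treated WT, and group sizes inside the observed 6-15 mice range.
#'
#' @param atlas,conn Output of [generate_atlas_connectome()] (`conn` is the
#'   anterograde view; retrograde and Euclidean views are derived).
#' @param seed_sites Region ids of the seed sites; default resolves
#'   acronyms DG, CA1, CA3, PTLp through the atlas.
#' @param c_true Named diffusion rates per mode (per month).
#' @param t Horizon in months.
#' @param beta_true Per-group generating weights: tibble with columns
#'   `genotype`, `treatment`, `b_a`, `b_r`, `b_e`, `b_t`, `b_t_ptz`.
#' @param noise_sigma Log10-scale SD of the per-mouse multiplicative noise.
#' @param tdt_sigma Log10-scale SD of per-mouse tdT noise around the
#'   regional tdT profile.
#' @return A list of class `ground_truth`; fully serializable.
#' @export
ground_truth <- function(atlas, conn,
                         seed_sites = NULL,
                         c_true = c(anterograde = 0.25, retrograde = 0.25,
                                    euclidean = 0.25),
                         t = 3,
                         beta_true = NULL,
                         noise_sigma = 0.25,
                         tdt_sigma = 0.2) {
  if (is.null(seed_sites)) {
    seed_sites <- atlas$region_id[match(c("DG", "CA1", "CA3", "PTLp"), atlas$acronym)]
    if (any(is.na(seed_sites))) abort("default seed acronyms not found in atlas")
  }
  if (is.null(beta_true)) {
    beta_true <- tibble(
      genotype = c("WT", "WT", "5X", "5X"),
      treatment = c("Sal", "PTZ", "Sal", "PTZ"),
      b_a = c(0.2, 0.2, 0.5, 0.5),
      b_r = c(0.6, 0.6, 0.4, 0.4),
      b_e = c(0.1, 0.1, 0.1, 0.1),
      b_t = c(0.3, 0.0, 0.3, 0.3),
      b_t_ptz = 0
    )
  }
  conns <- list(
    anterograde = directional_view(conn, "anterograde"),
    retrograde = directional_view(conn, "retrograde"),
    euclidean = euclidean_connectome(atlas, conn$regions)
  )
  structure(
    list(atlas = atlas, connectomes = conns, seed = seed_spec(seed_sites),
         c_true = c_true, t = t, beta_true = beta_true,
         noise_sigma = noise_sigma, tdt_sigma = tdt_sigma),
    class = "ground_truth"
  )
}

# z-scored log10 spread predictions for each mode under the true rates
gt_predictors <- function(gt) {
  purrr::imap(gt$connectomes, function(cn, mode) {
    pred <- predict_spread(cn, gt$seed, c = gt$c_true[[mode]], t = gt$t)
    v <- pred$value
    zscore(log10_eps(v, eps = min(v[v > 0])))
  })
}

#' Simulate a per-mouse, per-region cohort from ground truth
#'
#' Regional mean pathology per group is the inverse log10 transform of a
#' linear combination of the z-scored log-spread predictors (weights
#' `b_a`, `b_r`, `b_e`) plus the group's tdT association applied to a
#' group-specific regional activity profile; each mouse's value is the
#' regional mean times multiplicative log-normal noise, so pathology stays
#' positive and right-skewed. tdT densities are the regional activity
#' profile with independent per-mouse log-normal noise, giving the
#' configured partial tdT-pathology association within each group.
#'
#' @param gt A `ground_truth`.
#' @param n_mice Mice per group: scalar or vector named `"WT-Sal"` etc.
#' @param seed RNG seed.
#' @param base_log10 Baseline log10 pathology level (density scale).
#' @param scale_log10 Log10 units per standardized predictor unit.
#' @return A cohort tibble over the connectome's leaf regions.
#' @export
simulate_cohort <- function(gt, n_mice = 10, seed = NULL,
                            base_log10 = 1, scale_log10 = 0.5) {
  if (!is.null(seed)) withr::local_seed(seed)
  groups <- gt$beta_true
  if (length(n_mice) == 1) {
    n_mice <- setNames(rep(n_mice, nrow(groups)),
                       paste0(groups$genotype, "-", groups$treatment))
  }
  if (any(n_mice < 3)) abort("group sizes must be >= 3")
  Z <- gt_predictors(gt)
  regions <- gt$connectomes$anterograde$regions
  n_r <- length(regions)

  out <- purrr::pmap_dfr(groups, function(genotype, treatment, b_a, b_r, b_e,
                                          b_t, b_t_ptz) {
    g <- paste0(genotype, "-", treatment)
    n_g <- n_mice[[g]]
    slope <- b_t + b_t_ptz * (treatment == "PTZ")
    z_act <- rnorm(n_r)                       # regional activity profile
    eta <- b_a * Z$anterograde + b_r * Z$retrograde + b_e * Z$euclidean +
      slope * z_act
    mu_log10 <- base_log10 + scale_log10 * eta
    purrr::map_dfr(seq_len(n_g), function(i) {
      tibble(
        mouse_id = sprintf("%s_%s_m%02d", genotype, treatment, i),
        genotype = genotype, treatment = treatment, region_id = regions,
        pathology = 10^(mu_log10 + rnorm(n_r, 0, gt$noise_sigma)),
        tdt = 10^(1 + 0.4 * z_act + rnorm(n_r, 0, gt$tdt_sigma))
      )
    })
  })
  validate_cohort(out, gt$atlas)
}

#' Simulate behavioral covariates tied to regional pathology
#'
#' Builds per-mouse covariates with a configurable population correlation
#' `effect_r` to the mean (log) pathology of `target_regions` and no
#' built-in association elsewhere: a novel-object-recognition preference
#' (percent time on the novel object) and 15 per-minute maximal Racine
#' scores whose AUC tracks the same latent severity.
#'
#' @param cohort A cohort tibble.
#' @param target_regions Region ids driving the association.
#' @param effect_r Target correlation, `|effect_r| < 1`.
#' @param seed RNG seed.
#' @return A tibble with `mouse_id`, `nor_percent`, and `racine_01` ..
#'   `racine_15` integer columns.
#' @export
simulate_behavior <- function(cohort, target_regions, effect_r = 0.5,
                              seed = NULL) {
  if (!is_scalar_number(effect_r) || abs(effect_r) >= 1) {
    abort("effect_r must satisfy |effect_r| < 1")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  per_mouse <- cohort |>
    filter(.data$region_id %in% target_regions) |>
    group_by(.data$mouse_id) |>
    summarise(x = mean(log10(.data$pathology + 1), na.rm = TRUE), .groups = "drop")
  if (nrow(per_mouse) < 3) abort("need at least 3 mice with target-region data")
  z <- zscore(per_mouse$x)
  latent <- effect_r * z + sqrt(1 - effect_r^2) * rnorm(length(z))
  nor <- pmin(100, pmax(0, 50 + 15 * latent))
  # per-minute severity profile rises then falls; AUC scales with latent
  shape <- c(1, 2, 3, 4, 5, 5, 5, 4, 4, 3, 3, 2, 2, 1, 1) / 5
  racine <- t(vapply(latent, function(l) {
    sev <- pmax(0, 3 + 1.5 * l + rnorm(15, 0, 0.5))
    pmin(6L, pmax(0L, as.integer(round(sev * shape))))
  }, integer(15)))
  colnames(racine) <- sprintf("racine_%02d", 1:15)
  dplyr::bind_cols(
    tibble(mouse_id = per_mouse$mouse_id, nor_percent = nor),
    as_tibble(racine)
  )
}

#' Racine AUC for every mouse in a behavior table
#' @param behavior Output of [simulate_behavior()] (or any table with
#'   `racine_01` .. `racine_15` columns).
#' @param method Passed to [racine_auc()].
#' @return A tibble `(mouse_id, value)` suitable for
#'   [regional_correlation_screen()].
#' @export
racine_auc_table <- function(behavior, method = "rectangular") {
  cols <- sprintf("racine_%02d", 1:15)
  missing <- setdiff(cols, names(behavior))
  if (length(missing) > 0) abort("behavior table lacks 15 racine_* columns")
  tibble(
    mouse_id = behavior$mouse_id,
    value = apply(as.matrix(behavior[, cols]), 1, racine_auc, method = method)
  )
}
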