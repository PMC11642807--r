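#' Run the full spread-modelling pipeline
#'
#' Orchestrates simulate (or load) -> region filter -> per-group diffusion
#' fits for the anterograde, retrograde and Euclidean connectomes ->
#' combined regression with beta ratios -> bootstrap fit distributions with
#' pairwise FDR-adjusted comparisons -> seed-specificity null, writing
#' delimited tables, a JSON manifest and a log to the output directory.
#' Given the same configuration (including `rng_seed`) the numeric outputs
#' are byte-identical across runs.
#'
#' @param config A named list or path to a JSON/YAML file with fields:
#'   `out_dir`; either `simulate` (list passed to
#'   [generate_atlas_connectome()] plus `n_mice`) or `paths` (named list
#'   `atlas`, `connectome`, `cohort`); optional `seed_acronyms` (default
#'   DG, CA1, CA3, PTLp), `t` (3), `min_per_group` (6), `B` (200),
#'   `n_sets` (0 to skip the null), `tolerance` (0.2), `rng_seed` (1).
#' @return Invisibly, a list with the fits, comparisons and null ensemble;
#'   side effect: files under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "log.txt")
  log_lines <- c(paste0("tauspreadr pipeline, R ", getRversion()),
                 paste0("rng_seed: ", cfg$rng_seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("FAILED at stage: ", name)), log_path)
      file.create(file.path(cfg$out_dir, "FAILED"))
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  inputs <- stage("inputs", {
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      ac <- generate_atlas_connectome(
        n_regions = sim$n_regions %||% 100,
        spatial_extent = sim$spatial_extent %||% 8000,
        density = sim$density %||% 0.3,
        asymmetry = sim$asymmetry %||% 0.6,
        seed = child_seed(cfg$rng_seed, 1)
      )
      gt <- ground_truth(ac$atlas, ac$connectome, t = cfg$t)
      cohort <- simulate_cohort(gt, n_mice = sim$n_mice %||% 10,
                                seed = child_seed(cfg$rng_seed, 2))
      list(atlas = ac$atlas, conn = ac$connectome, cohort = cohort, gt = gt)
    } else {
      atlas <- read_atlas(cfg$paths$atlas)
      conn <- read_connectome(cfg$paths$connectome)
      cohort <- read_cohort(cfg$paths$cohort, atlas)
      list(atlas = atlas, conn = conn, cohort = cohort, gt = NULL)
    }
  })

  cohort <- stage("prepare", filter_regions(inputs$cohort, cfg$min_per_group))
  log_lines <- c(log_lines,
                 paste0("regions excluded by sample-size filter: ",
                        length(excluded_regions(cohort))))
  seed_ids <- stage("seeds", {
    ids <- inputs$atlas$region_id[match(cfg$seed_acronyms, inputs$atlas$acronym)]
    if (any(is.na(ids))) abort(paste0("seed acronym(s) not in atlas: ",
                                      paste(cfg$seed_acronyms[is.na(ids)], collapse = ", ")))
    ids
  })
  sspec <- seed_spec(seed_ids)
  conns <- list(
    anterograde = directional_view(inputs$conn, "anterograde"),
    retrograde = directional_view(inputs$conn, "retrograde"),
    euclidean = euclidean_connectome(inputs$atlas, inputs$conn$regions)
  )
  groups <- distinct(cohort, .data$genotype, .data$treatment)

  fits <- stage("fit", {
    purrr::pmap_dfr(groups, function(genotype, treatment) {
      means <- region_means(cohort, genotype, treatment)
      purrr::imap_dfr(conns, function(cn, mode) {
        f <- fit_rate(means, cn, sspec, t = cfg$t)
        glance(f) |> mutate(genotype = genotype, treatment = treatment,
                            .before = 1)
      })
    })
  })

  combined <- stage("combine", {
    parts <- purrr::pmap(groups, function(genotype, treatment) {
      means <- region_means(cohort, genotype, treatment)
      preds <- purrr::imap(conns, function(cn, mode) {
        cf <- fits |> filter(.data$genotype == !!genotype,
                             .data$treatment == !!treatment,
                             .data$mode == !!mode)
        predict_spread(cn, sspec, c = cf$c_hat, t = cfg$t)
      })
      obs <- setNames(means$pathology, means$region_id)
      fitc <- fit_combined(obs, preds)
      betas <- tibble(genotype = genotype, treatment = treatment,
                      term = names(fitc$betas), beta = unname(fitc$betas),
                      r = fitc$r, n_regions = fitc$n_regions)
      ratios <- beta_ratios(fitc) |>
        mutate(genotype = genotype, treatment = treatment, .before = 1)
      list(betas = betas, ratios = ratios)
    })
    list(betas = bind_rows(purrr::map(parts, "betas")),
         ratios = bind_rows(purrr::map(parts, "ratios")))
  })

  boots <- stage("bootstrap", {
    gidx <- seq_len(nrow(groups))
    purrr::map(gidx, function(i) {
      g <- groups[i, ]
      purrr::imap(conns, function(cn, mode) {
        bootstrap_statistic(
          cohort, g$genotype, g$treatment,
          stat_fn = function(m) fit_rate(m, cn, sspec, t = cfg$t)$fit_r,
          B = cfg$B, seed = child_seed(cfg$rng_seed, 10 + 3 * i +
                                         match(mode, names(conns))),
          statistic = paste0("fit_r_", mode)
        )
      })
    }) |> setNames(paste0(groups$genotype, "-", groups$treatment))
  })

  comparisons <- stage("compare", {
    rows <- purrr::imap_dfr(boots, function(bl, gname) {
      pairs <- utils::combn(names(bl), 2, simplify = FALSE)
      purrr::map_dfr(pairs, function(pr) {
        tibble(group = gname, mode_1 = pr[1], mode_2 = pr[2],
               p = compare_distributions(bl[[pr[1]]], bl[[pr[2]]]))
      })
    })
    rows |> group_by(.data$group) |>
      mutate(p_adj = fdr_adjust(.data$p)) |> ungroup()
  })

  null_ens <- NULL
  if (cfg$n_sets > 0) {
    null_ens <- stage("nullseed", {
      g <- groups[1, ]
      means <- region_means(cohort, g$genotype, g$treatment)
      random_seed_null(means, conns$retrograde, inputs$atlas, sspec,
                       n_sets = cfg$n_sets, tolerance = cfg$tolerance,
                       seed = child_seed(cfg$rng_seed, 99), t = cfg$t)
    })
  }

  stage("write", {
    readr::write_csv(fits, file.path(cfg$out_dir, "fits.csv"))
    readr::write_csv(combined$betas, file.path(cfg$out_dir, "betas.csv"))
    readr::write_csv(combined$ratios, file.path(cfg$out_dir, "beta_ratios.csv"))
    readr::write_csv(comparisons, file.path(cfg$out_dir, "comparisons.csv"))
    boot_tbl <- purrr::imap_dfr(boots, function(bl, g) {
      purrr::map_dfr(bl, tidy)
    })
    readr::write_csv(boot_tbl, file.path(cfg$out_dir, "bootstrap_values.csv"))
    if (!is.null(null_ens)) {
      readr::write_csv(tidy(null_ens), file.path(cfg$out_dir, "null_fits.csv"))
      jsonlite::write_json(glance(null_ens),
                           file.path(cfg$out_dir, "null_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("tauspreadr")),
      rng_seed = cfg$rng_seed,
      config = cfg[setdiff(names(cfg), "out_dir")],
      config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
      n_regions_used = length(unique(cohort$region_id)),
      excluded_regions = excluded_regions(cohort)
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(log_lines, "status: OK"), log_path)
  })

  invisible(list(fits = fits, betas = combined$betas,
                 ratios = combined$ratios, comparisons = comparisons,
                 bootstrap = boots, null = null_ens))
}

read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

validate_config <- function(config) {
  if (is.null(config$out_dir)) abort("config requires out_dir")
  if (is.null(config$simulate) && is.null(config$paths)) {
    abort("config requires either 'simulate' parameters or input 'paths'")
  }
  if (!is.null(config$paths)) {
    for (f in c("atlas", "connectome", "cohort")) {
      p <- config$paths[[f]]
      if (is.null(p)) abort(paste0("config paths missing '", f, "'"))
      if (!file.exists(p)) abort(paste0("config path does not exist: ", p))
    }
  }
  defaults <- list(seed_acronyms = c("DG", "CA1", "CA3", "PTLp"), t = 3,
                   min_per_group = 6, B = 200, n_sets = 0, tolerance = 0.2,
                   rng_seed = 1)
  for (nm in names(defaults)) config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  config
}
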