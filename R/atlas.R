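#' Read and validate a region atlas table
#'
#' The atlas is a headered delimited table with one row per region and
#' columns `region_id`, `acronym`, `hemisphere` (`ipsi`/`contra`, relative to
#' the injected hemisphere), `parent_id` (empty or `NA` for roots), and the
#' centroid coordinates `x`, `y`, `z` in micrometres. An optional `name`
#' column carries the full region name. Hierarchy depth (`level`, 0 at the
#' roots) is computed from the parent links.
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed by [readr::read_delim()]).
#' @return A validated atlas tibble with an added `level` column.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) abort(paste0("atlas file not found: ", path))
  raw <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  validate_atlas(raw)
}

#' Validate an atlas data frame
#'
#' Checks the atlas schema and invariants: unique region ids, parent links
#' forming a forest (no cycles, every non-root parent present), and finite
#' centroids. Hierarchy depth is (re)computed.
#'
#' @param atlas A data frame with the columns described in [read_atlas()].
#' @return The atlas as a tibble with a `level` column.
#' @export
validate_atlas <- function(atlas) {
  required <- c("region_id", "acronym", "hemisphere", "parent_id", "x", "y", "z")
  missing <- setdiff(required, names(atlas))
  if (length(missing) > 0) {
    abort(paste0("atlas is missing required column(s): ",
                 paste(missing, collapse = ", ")), class = "tauspreadr_schema_error")
  }
  atlas <- as_tibble(atlas)
  atlas$region_id <- as.character(atlas$region_id)
  atlas$parent_id <- as.character(atlas$parent_id)
  atlas$parent_id[atlas$parent_id %in% c("", "NA")] <- NA_character_

  dup <- atlas$region_id[duplicated(atlas$region_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate region_id: ", paste(unique(dup), collapse = ", ")),
          class = "tauspreadr_validation_error")
  }
  bad_hemi <- setdiff(unique(atlas$hemisphere), c("ipsi", "contra"))
  if (length(bad_hemi) > 0) {
    abort(paste0("hemisphere must be 'ipsi' or 'contra'; found: ",
                 paste(bad_hemi, collapse = ", ")), class = "tauspreadr_validation_error")
  }
  coords <- as.matrix(atlas[, c("x", "y", "z")])
  if (!all(is.finite(coords))) {
    abort("centroid coordinates must be finite", class = "tauspreadr_validation_error")
  }
  orphan <- setdiff(atlas$parent_id[!is.na(atlas$parent_id)], atlas$region_id)
  if (length(orphan) > 0) {
    abort(paste0("parent_id not present in atlas: ", paste(orphan, collapse = ", ")),
          class = "tauspreadr_validation_error")
  }

  atlas$level <- atlas_levels(atlas$region_id, atlas$parent_id)
  atlas
}

# depth of every region following parent links; aborts on cycles naming the
# regions involved
atlas_levels <- function(ids, parents) {
  parent_of <- setNames(parents, ids)
  level <- setNames(rep(NA_integer_, length(ids)), ids)
  for (id in ids) {
    chain <- character(0)
    cur <- id
    while (!is.na(cur) && is.na(level[[cur]])) {
      if (cur %in% chain) {
        abort(paste0("cycle in atlas hierarchy involving: ",
                     paste(chain[which(chain == cur):length(chain)], collapse = " -> ")),
              class = "tauspreadr_validation_error")
      }
      chain <- c(chain, cur)
      cur <- parent_of[[cur]]
    }
    base <- if (is.na(cur)) -1L else level[[cur]]
    for (k in seq_along(chain)) {
      level[[chain[length(chain) - k + 1L]]] <- base + k
    }
  }
  unname(level[ids])
}

#' Sum detected-object counts up through the region hierarchy
#'
#' Object counts are recorded at the finest atlas level; each internal
#' region's count is its own count plus the counts of all its descendants
#' (e.g. somatosensory and auditory areas roll up into isocortex).
#'
#' @param counts A data frame with columns `region_id` and `count`, or a
#'   named numeric vector. Regions absent from `counts` contribute 0.
#' @param atlas A validated atlas tibble.
#' @return A tibble `(region_id, count)` covering every atlas region.
#' @export
aggregate_hierarchy <- function(counts, atlas) {
  if (is.numeric(counts) && !is.null(names(counts))) {
    counts <- tibble(region_id = names(counts), count = unname(counts))
  }
  counts <- as_tibble(counts)
  unknown <- setdiff(counts$region_id, atlas$region_id)
  if (length(unknown) > 0) {
    abort(paste0("count given for unknown region(s): ",
                 paste(unknown, collapse = ", ")))
  }
  total <- setNames(rep(0, nrow(atlas)), atlas$region_id)
  if (nrow(counts) > 0) {
    own <- tapply(counts$count, counts$region_id, sum)
    total[names(own)] <- own
  }
  parent_of <- setNames(atlas$parent_id, atlas$region_id)
  # deepest first so each region's accumulated total flows into its parent once
  for (id in atlas$region_id[order(atlas$level, decreasing = TRUE)]) {
    p <- parent_of[[id]]
    if (!is.na(p)) total[[p]] <- total[[p]] + total[[id]]
  }
  tibble(region_id = atlas$region_id, count = unname(total[atlas$region_id]))
}

#' Read a long-format cohort table
#'
#' Expects columns `mouse_id`, `genotype` (`WT`/`5X`), `treatment`
#' (`Sal`/`PTZ`), `region_id`, `pathology` (AT8+ objects per mm^2) and
#' optionally `tdt` (tdT+ cells per mm^2, may be missing).
#'
#' @param path Path to a delimited file.
#' @param atlas Optional atlas tibble; if given, every `region_id` must exist
#'   in it.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, atlas = NULL) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  raw <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(raw, atlas)
}

#' Validate a cohort data frame
#' @inheritParams read_cohort
#' @param cohort A data frame in the long format described in [read_cohort()].
#' @return The cohort as a tibble.
#' @export
validate_cohort <- function(cohort, atlas = NULL) {
  required <- c("mouse_id", "genotype", "treatment", "region_id", "pathology")
  missing <- setdiff(required, names(cohort))
  if (length(missing) > 0) {
    abort(paste0("cohort is missing required column(s): ",
                 paste(missing, collapse = ", ")), class = "tauspreadr_schema_error")
  }
  cohort <- as_tibble(cohort)
  cohort$region_id <- as.character(cohort$region_id)
  if (!"tdt" %in% names(cohort)) cohort$tdt <- NA_real_
  bad_gt <- setdiff(unique(cohort$genotype), c("WT", "5X"))
  if (length(bad_gt) > 0) abort(paste0("unknown genotype: ", paste(bad_gt, collapse = ", ")))
  bad_tr <- setdiff(unique(cohort$treatment), c("Sal", "PTZ"))
  if (length(bad_tr) > 0) abort(paste0("unknown treatment: ", paste(bad_tr, collapse = ", ")))
  if (any(cohort$pathology < 0, na.rm = TRUE) || any(cohort$tdt < 0, na.rm = TRUE)) {
    abort("negative densities are not allowed", class = "tauspreadr_validation_error")
  }
  key <- paste(cohort$mouse_id, cohort$region_id)
  if (anyDuplicated(key)) {
    abort("duplicate (mouse_id, region_id) rows", class = "tauspreadr_validation_error")
  }
  if (!is.null(atlas)) {
    unknown <- setdiff(cohort$region_id, atlas$region_id)
    if (length(unknown) > 0) {
      abort(paste0("cohort references region(s) absent from atlas: ",
                   paste(head(unknown, 10), collapse = ", ")),
            class = "tauspreadr_validation_error")
    }
  }
  cohort
}

#' Apply the minimum-samples-per-group region filter
#'
#' A region is retained only if every genotype-by-treatment group present in
#' the cohort has at least `min_per_group` non-missing pathology values for
#' it (default 6). Excluded region ids are attached as the `"excluded"`
#' attribute and retrievable with [excluded_regions()].
#'
#' @param cohort A validated cohort tibble.
#' @param min_per_group Minimum non-missing samples per group (>= 1).
#' @return The filtered cohort tibble.
#' @export
filter_regions <- function(cohort, min_per_group = 6) {
  stopifnot(is_scalar_number(min_per_group), min_per_group >= 1)
  groups <- distinct(cohort, .data$genotype, .data$treatment)
  tallies <- cohort |>
    filter(!is.na(.data$pathology)) |>
    dplyr::count(.data$region_id, .data$genotype, .data$treatment, name = "n_obs")
  full <- tidyr::crossing(region_id = unique(cohort$region_id), groups) |>
    left_join(tallies, by = c("region_id", "genotype", "treatment")) |>
    mutate(n_obs = dplyr::coalesce(.data$n_obs, 0L))
  keep <- full |>
    group_by(.data$region_id) |>
    summarise(ok = all(.data$n_obs >= min_per_group), .groups = "drop")
  excluded <- keep$region_id[!keep$ok]
  out <- filter(cohort, !(.data$region_id %in% excluded))
  if (nrow(out) == 0) warn("all regions excluded by the sample-size filter")
  inform(paste0("filter_regions: excluded ", length(excluded), " of ",
                nrow(keep), " regions (< ", min_per_group, " samples in some group)"))
  attr(out, "excluded") <- excluded
  out
}

#' Regions removed by the last [filter_regions()] call
#' @param cohort A cohort tibble returned by [filter_regions()].
#' @return Character vector of excluded region ids.
#' @export
excluded_regions <- function(cohort) attr(cohort, "excluded") %||% character(0)

#' Per-region group means of pathology and tdT density
#'
#' Collapses a cohort to regional means, the unit at which diffusion models
#' and combined regressions are fit (mouse-level uncertainty is handled by
#' bootstrapping mice).
#'
#' @param cohort A cohort tibble, usually already filtered.
#' @param genotype,treatment Optional filters; `NULL` keeps all levels.
#' @return A tibble `(region_id, pathology, tdt, n)`.
#' @export
region_means <- function(cohort, genotype = NULL, treatment = NULL) {
  if (!is.null(genotype)) cohort <- filter(cohort, .data$genotype %in% !!genotype)
  if (!is.null(treatment)) cohort <- filter(cohort, .data$treatment %in% !!treatment)
  cohort |>
    group_by(.data$region_id) |>
    summarise(
      pathology = mean(.data$pathology, na.rm = TRUE),
      tdt = if (all(is.na(.data$tdt))) NA_real_ else mean(.data$tdt, na.rm = TRUE),
      n = sum(!is.na(.data$pathology)),
      .groups = "drop"
    )
}
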