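#' Construct a connectome object
#'
#' A connectome bundles an ordered region list with an N x N nonnegative
#' weight matrix. For tracing-based matrices, entry (i, j) is the projection
#' strength from source region i to target region j measured at the axon
#' terminals; anterograde spread uses the matrix as stored and retrograde
#' spread uses its transpose (see [directional_view()]). The `euclidean`
#' mode holds a symmetric proximity matrix derived from centroid distances.
#'
#' @param regions Character vector of region ids (length N >= 2).
#' @param A N x N numeric matrix of nonnegative weights, zero diagonal.
#' @param mode One of `"anterograde"`, `"retrograde"`, `"euclidean"`.
#' @return An object of class `connectome`.
#' @export
connectome <- function(regions, A, mode = c("anterograde", "retrograde", "euclidean")) {
  mode <- match.arg(mode)
  regions <- as.character(regions)
  A <- as.matrix(A)
  if (length(regions) < 2) abort("a connectome needs at least 2 regions")
  if (nrow(A) != length(regions) || ncol(A) != length(regions)) {
    abort("A must be square with one row/column per region")
  }
  if (any(!is.finite(A))) abort("connectivity weights must be finite (no NaN/Inf)")
  if (any(A < 0)) abort("connectivity weights must be nonnegative")
  if (any(diag(A) != 0)) abort("connectome diagonal must be exactly 0")
  dimnames(A) <- list(regions, regions)
  structure(list(regions = regions, A = A, mode = mode), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> mode=", x$mode, ", N=", length(x$regions),
      ", edges=", sum(x$A > 0), "\n", sep = "")
  invisible(x)
}

#' @export
format.connectome <- function(x, ...) {
  paste0("<connectome ", x$mode, " N=", length(x$regions), ">")
}

#' Edge list of a connectome
#'
#' @param x A `connectome`.
#' @param ... Unused.
#' @return A tibble `(from, to, weight)` of the nonzero edges.
#' @export
tidy.connectome <- function(x, ...) {
  idx <- which(x$A > 0, arr.ind = TRUE)
  tibble(
    from = x$regions[idx[, 1]],
    to = x$regions[idx[, 2]],
    weight = x$A[idx]
  ) |> arrange(.data$from, .data$to)
}

#' Read a square connectivity matrix
#'
#' The file is a delimited square matrix with a header row and a leading
#' column of region ids; rows are sources, columns targets. `NaN` entries
#' are rejected; empty cells are treated as absent edges (weight 0) and the
#' number of such entries is reported.
#'
#' @param path Path to the matrix file.
#' @param mode Direction tag to attach; under the default source-to-target
#'   convention a tract-tracing matrix is tagged `"anterograde"`.
#' @return A `connectome`.
#' @export
read_connectome <- function(path, mode = "anterograde") {
  if (!file.exists(path)) abort(paste0("connectome file not found: ", path))
  raw <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  regions <- as.character(raw[[1]])
  A <- as.matrix(raw[, -1, drop = FALSE])
  if (!identical(colnames(A), regions)) {
    abort("connectome row ids and column header must list the same regions in the same order")
  }
  if (any(is.nan(A))) abort("connectivity matrix contains NaN")
  n_missing <- sum(is.na(A))
  if (n_missing > 0) {
    inform(paste0("read_connectome: ", n_missing, " missing entries treated as 0"))
    A[is.na(A)] <- 0
  }
  connectome(regions, A, mode)
}

#' Write a connectome to a delimited file
#' @param conn A `connectome`.
#' @param path Output path (CSV).
#' @export
write_connectome <- function(conn, path) {
  df <- as.data.frame(conn$A)
  df <- cbind(region_id = conn$regions, df)
  readr::write_csv(as_tibble(df), path)
  invisible(path)
}

#' Build a Euclidean-proximity connectome from atlas centroids
#'
#' Off-diagonal weights are a decreasing function of the centroid distance
#' d_ij: `1/d` (default) or `exp(-d/lambda)`. The matrix is symmetric by
#' construction; spatially close regions get the largest weights, so
#' diffusion over this connectome models distance-based (non-axonal) spread.
#'
#' @param atlas A validated atlas tibble (centroids in micrometres).
#' @param regions Ordered region ids to include (default: all atlas rows).
#' @param kernel `"inverse"` for 1/d or `"exponential"` for exp(-d/lambda).
#' @param lambda Length scale in micrometres for the exponential kernel
#'   (default: the mean pairwise distance).
#' @return A `connectome` with `mode = "euclidean"`.
#' @export
euclidean_connectome <- function(atlas, regions = NULL,
                                 kernel = c("inverse", "exponential"),
                                 lambda = NULL) {
  kernel <- match.arg(kernel)
  regions <- regions %||% atlas$region_id
  missing <- setdiff(regions, atlas$region_id)
  if (length(missing) > 0) {
    abort(paste0("regions absent from atlas: ", paste(missing, collapse = ", ")))
  }
  if (length(regions) < 2) abort("need at least 2 regions")
  rows <- atlas[match(regions, atlas$region_id), ]
  D <- as.matrix(stats::dist(as.matrix(rows[, c("x", "y", "z")])))
  off <- D[upper.tri(D)]
  if (any(off == 0)) {
    abort("coincident centroids: zero off-diagonal distance gives infinite weight")
  }
  W <- switch(kernel,
    inverse = 1 / D,
    exponential = exp(-D / (lambda %||% mean(off)))
  )
  diag(W) <- 0
  connectome(regions, W, mode = "euclidean")
}

#' Switch a tracing-based connectome between spread directions
#'
#' With the stored convention A(i, j) = projection strength from i to j,
#' anterograde spread (soma to axon terminal) propagates along A while
#' retrograde spread (terminal to soma) propagates along its transpose.
#' Requesting the direction the connectome is already tagged with is the
#' identity; requesting the other transposes the matrix, so applying the
#' operation twice returns the original. Meaningless for the symmetric
#' Euclidean mode, which has no direction.
#'
#' @param conn A tracing-based `connectome`.
#' @param direction `"anterograde"` or `"retrograde"`.
#' @return A `connectome` tagged with `direction`.
#' @export
directional_view <- function(conn, direction = c("anterograde", "retrograde")) {
  direction <- match.arg(direction)
  if (conn$mode == "euclidean") {
    abort("directional_view is undefined for the euclidean mode (symmetric, no direction)")
  }
  if (conn$mode == direction) return(conn)
  connectome(conn$regions, t(conn$A), mode = direction)
}
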