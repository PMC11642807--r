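# Shared fixtures and independent oracles, built in code.

# small random directed nonnegative weight matrix with zero diagonal
rand_adjacency <- function(n, density = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) < density)
  diag(A) <- 0
  A
}

rand_connectome <- function(n, density = 0.6, seed = NULL, mode = "anterograde") {
  connectome(sprintf("r%02d", seq_len(n)), rand_adjacency(n, density, seed), mode)
}

# independent oracle for the diffusion propagation: classical 4th-order
# Runge-Kutta integration of dx/ds = G x from x0 over s in [0, T]
rk4_spread <- function(G, x0, T, h = 1e-4) {
  if (T == 0) return(x0)
  n_steps <- ceiling(T / h)
  h <- T / n_steps
  x <- x0
  for (i in seq_len(n_steps)) {
    k1 <- G %*% x
    k2 <- G %*% (x + h / 2 * k1)
    k3 <- G %*% (x + h / 2 * k2)
    k4 <- G %*% (x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  as.vector(x)
}

# generator matching the package's flux convention (mass-conserving)
flux_generator <- function(conn) {
  L <- out_degree_laplacian(conn)
  -t(L)
}

# brute-force Benjamini-Hochberg step-up from its definition:
# adj for the i-th smallest p is min over j >= i of m * p_(j) / j, capped at 1
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# tiny three-level atlas: root -> two parents -> leaves
toy_atlas <- function() {
  validate_atlas(tibble::tibble(
    region_id = c("ROOT", "HIP", "CTX", "DG", "CA1", "CA3", "PTLp", "VIS"),
    acronym   = c("ROOT", "HIP", "CTX", "DG", "CA1", "CA3", "PTLp", "VIS"),
    hemisphere = "ipsi",
    parent_id = c(NA, "ROOT", "ROOT", "HIP", "HIP", "HIP", "CTX", "CTX"),
    x = c(0, 100, 900, 120, 140, 160, 880, 920),
    y = c(0, 100, 100, 120, 140, 160, 120, 80),
    z = c(0, 0, 0, 10, 20, 30, 10, 20)
  ))
}

# default synthetic world at modest size, shared across tests
shared_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ac <- generate_atlas_connectome(n_regions = 50, asymmetry = 0.6, seed = 101)
      gt <- ground_truth(ac$atlas, ac$connectome)
      cohort <- suppressMessages(simulate_cohort(gt, n_mice = 8, seed = 102))
      cache <<- list(ac = ac, gt = gt, cohort = cohort)
    }
    cache
  }
})
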