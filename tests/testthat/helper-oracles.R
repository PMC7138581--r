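# Brute-force oracles, independent of the package's BFS/C++ code paths.

# Floyd-Warshall all-pairs hop distances on an adjacency matrix
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- ifelse(a == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_eglo <- function(a) {
  d <- oracle_distances(a)
  n <- nrow(a)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) s <- s + 1 / d[i, j]
    }
  }
  s / (n * (n - 1))
}

oracle_lp <- function(a) {
  d <- oracle_distances(a)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  mean(vals)
}

# explicit triangle counting
oracle_clustering <- function(a) {
  n <- nrow(a)
  C <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (x in seq_along(nb)) {
      for (y in seq_along(nb)) {
        if (x < y && a[nb[x], nb[y]] == 1) e <- e + 1
      }
    }
    C[i] <- 2 * e / (k * (k - 1))
  }
  C
}

oracle_eloc <- function(a) {
  n <- nrow(a)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) next
    vals[i] <- oracle_eglo(a[nb, nb, drop = FALSE])
  }
  mean(vals)
}

# random simple undirected graph as a plain adjacency matrix
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  ut <- which(upper.tri(a))
  a[ut[runif(length(ut)) < p]] <- 1L
  a + t(a)
}

random_binary_graph <- function(n, p, seed) {
  binary_graph(random_adjacency(n, p, seed))
}

# random symmetric "connectivity" matrix with entries in (-1, 1)
random_connectivity <- function(n, seed) {
  set.seed(seed)
  r <- matrix(runif(n * n, -0.9, 0.9), n, n)
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  diag(r) <- 0
  connectivity_matrix(r, subject_id = paste0("rand", seed))
}

# small synthetic world reused across tests: 30 regions, 6 modules, 6 hubs
small_spec <- function(n_volumes = 60L, ...) {
  ground_truth_spec(n_regions = 30L, n_volumes = n_volumes, n_modules = 6L,
                    hubs_per_module = 1L, ...)
}

fast_config <- function(...) {
  analysis_config(sparsity_step = 0.05, n_null_networks = 10L, ...)
}
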