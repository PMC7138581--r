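#' Identify hub regions for a group
#'
#' Averages the group's connectivity matrices elementwise, thresholds the
#' group-mean matrix at every grid level, averages each region's degree
#' centrality across levels, and calls a region a hub when its averaged
#' centrality is at least one (population) standard deviation above the
#' across-region mean. When the SD is zero (regular graphs) no region
#' qualifies: a strict `> mean` is then required, which never holds.
#'
#' @param group_conn_matrices list of [connectivity_matrix()] objects from
#'   one group (same region order).
#' @param grid sparsity grid (see [sparsity_grid()]).
#' @return List with `hubs` (character region labels), `centrality` (named
#'   per-region mean degree centrality) and `threshold` (mean + 1 SD).
#' @export
identify_hubs <- function(group_conn_matrices, grid = sparsity_grid()) {
  stopifnot(length(group_conn_matrices) >= 1L)
  labels <- group_conn_matrices[[1]]$region_labels
  for (cm in group_conn_matrices) {
    stopifnot(inherits(cm, "connectivity_matrix"),
              identical(cm$region_labels, labels))
  }
  rbar <- Reduce(`+`, lapply(group_conn_matrices, `[[`, "r")) /
    length(group_conn_matrices)
  mean_conn <- connectivity_matrix(rbar, labels, subject_id = "group-mean")
  graphs <- sparsity_sweep(mean_conn, grid)
  deg <- rowMeans(vapply(graphs, degree_centrality,
                         numeric(length(labels))))
  mu <- mean(deg)
  pop_sd <- sqrt(mean((deg - mu)^2))
  thr <- mu + pop_sd
  hubs <- if (pop_sd > 0) labels[deg >= thr] else labels[deg > mu]
  list(hubs = hubs, centrality = deg, threshold = thr)
}

#' Classify edges as rich-club, feeder or local
#'
#' An edge is `rich_club` when both endpoints are hubs, `feeder` when
#' exactly one is, and `local` when neither is; the three classes partition
#' the edge set.
#'
#' @param graph a [binary_graph()].
#' @param hubs character vector of hub region labels.
#' @return Data frame with columns `i`, `j` (region labels, i before j) and
#'   `class` (factor: rich_club / feeder / local).
#' @export
classify_edges <- function(graph, hubs) {
  labels <- graph$region_labels
  unknown <- setdiff(hubs, labels)
  if (length(unknown)) {
    stop("hub label(s) not in graph: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  a <- as_adjacency(graph)
  idx <- which(upper.tri(a) & a == 1L, arr.ind = TRUE)
  hub_i <- labels[idx[, 1]] %in% hubs
  hub_j <- labels[idx[, 2]] %in% hubs
  cls <- ifelse(hub_i & hub_j, "rich_club",
                ifelse(hub_i | hub_j, "feeder", "local"))
  data.frame(i = labels[idx[, 1]], j = labels[idx[, 2]],
             class = factor(cls, levels = c("rich_club", "feeder", "local")),
             stringsAsFactors = FALSE)
}

#' Per-subject connection strengths by edge class
#'
#' At each sparsity level the subject's connectivity matrix is thresholded,
#' edges are classified against the (group-level) hub set, and the strength
#' of a class is the sum of the Pearson weights of its edges; the reported
#' value per class is the mean across grid levels.
#'
#' @param conn the subject's [connectivity_matrix()].
#' @param grid sparsity grid.
#' @param hubs hub region labels (normally from [identify_hubs()] on the
#'   subject's group).
#' @return Named numeric vector `c(rich_club=, feeder=, local=)`.
#' @export
connection_strengths <- function(conn, grid = sparsity_grid(), hubs) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  graphs <- sparsity_sweep(conn, grid)
  per_level <- vapply(graphs, function(g) {
    ec <- classify_edges(g, hubs)
    w <- conn$r[cbind(ec$i, ec$j)]
    vapply(split(w, ec$class), function(x) sum(x), numeric(1))
  }, numeric(3))
  rowMeans(per_level)
}

#' Rich-club coefficient and its degree-preserving normalization
#'
#' `phi(k) = 2 E_{>k} / (N_{>k} (N_{>k} - 1))` is the density of the
#' subgraph induced by nodes of degree greater than `k`;
#' `phi_norm(k) = phi(k) / mean phi_rand(k)` over `M` Maslov-Sneppen
#' rewired nulls. Levels where fewer than two nodes exceed `k` (or where
#' every null density is zero) are undefined and returned as `NA`.
#'
#' @param graph a [binary_graph()].
#' @param k_levels integer degrees at which to evaluate (default
#'   `1..max(degree)-1`).
#' @param M null-ensemble size.
#' @param n_swaps_per_edge attempted swaps per edge per null.
#' @param seed integer seed.
#' @return Data frame with columns `k`, `phi`, `phi_rand`, `phi_norm`.
#' @export
normalized_rich_club_coefficient <- function(graph, k_levels = NULL,
                                             M = 100L, n_swaps_per_edge = 10,
                                             seed = 1L) {
  stopifnot(M >= 1L)
  a <- as_adjacency(graph)
  deg <- rowSums(a)
  if (is.null(k_levels)) {
    k_levels <- seq_len(max(1L, max(deg) - 1L))
  }
  phi_of <- function(adj, k) {
    keep <- rowSums(adj) > k
    nk <- sum(keep)
    if (nk < 2L) return(NA_real_)
    sum(adj[keep, keep]) / (nk * (nk - 1))
  }
  phi <- vapply(k_levels, function(k) phi_of(a, k), numeric(1))
  nulls <- lapply(seq_len(M), function(m) {
    cpp_rewire(a, n_swaps_per_edge, stage_seed(seed, "richclub_null", m))
  })
  phi_rand <- vapply(k_levels, function(k) {
    mean(vapply(nulls, function(nm) phi_of(nm, k), numeric(1)))
  }, numeric(1))
  phi_norm <- ifelse(is.na(phi) | is.na(phi_rand) | phi_rand == 0,
                     NA_real_, phi / phi_rand)
  data.frame(k = k_levels, phi = phi, phi_rand = phi_rand,
             phi_norm = phi_norm)
}
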