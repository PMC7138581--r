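as_adjacency <- function(graph) {
  if (inherits(graph, "binary_graph")) graph$adjacency
  else stop("expected a binary_graph", call. = FALSE)
}

#' All-pairs shortest hop distances
#'
#' Breadth-first search from every node; unreachable pairs are `Inf`,
#' the diagonal is 0.
#'
#' @param graph a [binary_graph()].
#' @return N x N numeric matrix of hop counts.
#' @export
shortest_path_matrix <- function(graph) {
  a <- as_adjacency(graph)
  d <- cpp_bfs_distances(a)
  dimnames(d) <- dimnames(a)
  d
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs, with
#' `1/Inf = 0` for unreachable pairs. Lies in `[0, 1]`; 1 for a complete
#' graph, 0 for an empty one.
#'
#' @param graph a [binary_graph()].
#' @return Scalar Eglo.
#' @export
global_efficiency <- function(graph) {
  d <- shortest_path_matrix(graph)
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal clustering coefficients and their mean
#'
#' `C_i = 2 e_i / (k_i (k_i - 1))` with `e_i` the number of edges among the
#' neighbors of `i`; `C_i = 0` when the degree is below 2. `Cp` averages
#' over all nodes (including low-degree ones).
#'
#' @param graph a [binary_graph()].
#' @return List with `nodal` (length-N vector) and `cp` (mean).
#' @export
clustering_coefficients <- function(graph) {
  a <- as_adjacency(graph)
  nodal <- cpp_clustering(a)
  names(nodal) <- rownames(a)
  list(nodal = nodal, cp = mean(nodal))
}

#' Local efficiency
#'
#' Mean, over nodes, of the global efficiency of the subgraph induced by
#' each node's neighbors (the node itself excluded); subgraphs with fewer
#' than 2 nodes contribute 0.
#'
#' @param graph a [binary_graph()].
#' @return Scalar Eloc.
#' @export
local_efficiency <- function(graph) {
  mean(cpp_local_efficiency(as_adjacency(graph)))
}

#' Characteristic path length
#'
#' Mean shortest hop distance over all unordered pairs with finite distance.
#' On a disconnected graph the unreachable pairs are excluded and the
#' `connected` flag is `FALSE` (a WARN-level log line is emitted).
#'
#' @param graph a [binary_graph()].
#' @return List with `lp` and logical `connected`.
#' @export
characteristic_path_length <- function(graph) {
  d <- shortest_path_matrix(graph)
  ut <- d[upper.tri(d)]
  finite <- is.finite(ut)
  if (!any(finite)) {
    stop("no finite node pair: characteristic path length undefined",
         call. = FALSE)
  }
  connected <- all(finite)
  if (!connected) {
    log_msg("WARN", sprintf(
      "graph at sparsity %s is disconnected; Lp averages %d of %d pairs",
      format(graph$sparsity), sum(finite), length(ut)))
  }
  list(lp = mean(ut[finite]), connected = connected)
}

#' Degree centrality
#' @param graph a [binary_graph()].
#' @return Named integer vector of node degrees.
#' @export
degree_centrality <- function(graph) {
  a <- as_adjacency(graph)
  k <- rowSums(a)
  names(k) <- rownames(a)
  k
}

graph_metrics_row <- function(graph) {
  cl <- clustering_coefficients(graph)
  lp <- characteristic_path_length(graph)
  list(eglo = global_efficiency(graph),
       eloc = local_efficiency(graph),
       cp = cl$cp,
       lp = lp$lp,
       connected = lp$connected,
       degree = degree_centrality(graph))
}

#' Per-subject metric profile over a sparsity grid
#'
#' Thresholds a connectivity matrix at every grid level and records Eglo,
#' Eloc, Cp, Lp (and, when `config$n_null_networks` nulls are requested via
#' `smallworld = TRUE`, the normalized coefficients gamma, lambda, sigma),
#' plus nodal degrees and a connectedness flag.
#'
#' @param conn a [connectivity_matrix()].
#' @param config an [analysis_config()].
#' @param smallworld compute gamma/lambda/sigma against degree-preserving
#'   nulls (costs `n_null_networks` rewired graphs per level).
#' @return A `metric_profile`: list with `subject_id`, data frame `metrics`
#'   (one row per sparsity level) and matrix `degree` (levels x regions).
#' @export
metric_profile <- function(conn, config = analysis_config(),
                           smallworld = TRUE) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  validate_config(config)
  grid <- grid_from_config(config)
  graphs <- sparsity_sweep(conn, grid)
  rows <- vector("list", length(grid))
  degrees <- matrix(NA_real_, length(grid), length(conn$region_labels),
                    dimnames = list(format(grid), conn$region_labels))
  for (g in seq_along(graphs)) {
    m <- graph_metrics_row(graphs[[g]])
    degrees[g, ] <- m$degree
    row <- data.frame(sparsity = grid[g], eglo = m$eglo, eloc = m$eloc,
                      cp = m$cp, lp = m$lp, connected = m$connected,
                      gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
    if (smallworld) {
      ens <- null_reference(graphs[[g]], M = config$n_null_networks,
                            n_swaps_per_edge = config$n_rewire_swaps_per_edge,
                            seed = stage_seed(config$seed, "smallworld",
                                              g + 1000L * string_index(conn$subject_id)))
      sw <- tryCatch(
        small_world_parameters(graphs[[g]], ens, cp = m$cp, lp = m$lp),
        error = function(e) {
          # degenerate null (e.g. triangle-free at very low sparsity):
          # record the normalization as undefined rather than aborting
          log_msg("WARN", sprintf(
            "sparsity %s: %s; gamma/lambda/sigma recorded as NA",
            format(grid[g]), conditionMessage(e)))
          list(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
        })
      row$gamma <- sw$gamma
      row$lambda <- sw$lambda
      row$sigma <- sw$sigma
    }
    rows[[g]] <- row
  }
  structure(list(subject_id = conn$subject_id,
                 metrics = do.call(rbind, rows),
                 degree = degrees),
            class = "metric_profile")
}

# stable small integer from a subject id, for substream derivation
string_index <- function(s) {
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1000L
}

#' @export
print.metric_profile <- function(x, ...) {
  cat(sprintf("<metric_profile> subject %s: %d sparsity levels\n",
              x$subject_id, nrow(x$metrics)))
  print(utils::head(x$metrics, 3))
  invisible(x)
}
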