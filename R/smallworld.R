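#' Degree-preserving rewiring (Maslov-Sneppen double-edge swaps)
#'
#' Performs `n_swaps_per_edge * E` attempted swaps: two edges `(a,b)` and
#' `(c,d)` with four distinct endpoints are picked uniformly (each with a
#' random orientation, which keeps the chain reversible) and replaced by
#' `(a,d)` and `(c,b)` iff neither proposed edge already exists. Degrees are
#' preserved exactly; self-loops and multi-edges can never arise. Swaps that
#' would violate simplicity are skipped, so graphs with no valid swap (for
#' example a triangle) are returned unchanged.
#'
#' @param graph a [binary_graph()].
#' @param n_swaps_per_edge attempted swaps per edge (default 10).
#' @param seed integer seed of this rewiring substream.
#' @return A rewired [binary_graph()] with identical degree sequence.
#' @export
rewire_degree_preserving <- function(graph, n_swaps_per_edge = 10, seed = 1L) {
  a <- as_adjacency(graph)
  if (sum(a) / 2 < 2) return(graph)
  out <- cpp_rewire(a, n_swaps_per_edge, as.integer(seed))
  binary_graph(out, sparsity = graph$sparsity,
               region_labels = graph$region_labels)
}

#' Null ensemble of rewired reference networks
#'
#' Generates `M` independent degree-preserving rewirings of `graph` (one RNG
#' substream per null index, derived from `seed`) and records each null's
#' mean clustering coefficient and characteristic path length. Disconnected
#' nulls are retained, with Lp averaged over finite pairs as in
#' [characteristic_path_length()].
#'
#' @param graph a [binary_graph()].
#' @param M ensemble size.
#' @param n_swaps_per_edge attempted swaps per edge per null.
#' @param seed integer seed for the ensemble.
#' @return A `null_ensemble`: list with `sparsity`, `M`, per-null vectors
#'   `cp` and `lp`, and their means `cp_rand`, `lp_rand`.
#' @export
null_reference <- function(graph, M = 100L, n_swaps_per_edge = 10,
                           seed = 1L) {
  stopifnot(M >= 1L)
  a <- as_adjacency(graph)
  seeds <- vapply(seq_len(M), function(m) stage_seed(seed, "null", m),
                  integer(1))
  stats <- cpp_null_ensemble(a, n_swaps_per_edge, seeds)
  structure(list(sparsity = graph$sparsity, M = as.integer(M),
                 cp = stats[, 1], lp = stats[, 2],
                 cp_rand = mean(stats[, 1]), lp_rand = mean(stats[, 2])),
            class = "null_ensemble")
}

#' Small-world coefficients
#'
#' `gamma = Cp / cp_rand`, `lambda = Lp / lp_rand`, `sigma = gamma / lambda`
#' where `cp_rand`, `lp_rand` are the mean clustering and path length of a
#' degree-matched null ensemble. `sigma > 1` is the usual small-world
#' signature: clustering well above random at near-random path length.
#'
#' @param graph a [binary_graph()].
#' @param ensemble a `null_ensemble` derived from `graph`.
#' @param cp,lp optionally precomputed Cp and Lp of `graph` (recomputed when
#'   `NULL`).
#' @return List with `gamma`, `lambda`, `sigma`.
#' @export
small_world_parameters <- function(graph, ensemble, cp = NULL, lp = NULL) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (is.null(cp)) cp <- clustering_coefficients(graph)$cp
  if (is.null(lp)) lp <- characteristic_path_length(graph)$lp
  if (!is.finite(ensemble$cp_rand) || ensemble$cp_rand <= 0) {
    stop("null ensemble has cp_rand <= 0: normalization undefined",
         call. = FALSE)
  }
  if (!is.finite(ensemble$lp_rand) || ensemble$lp_rand <= 0) {
    stop("null ensemble has lp_rand <= 0: normalization undefined",
         call. = FALSE)
  }
  gamma <- cp / ensemble$cp_rand
  lambda <- lp / ensemble$lp_rand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}
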