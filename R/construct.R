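#' Temporal cleanup of a time-series panel
#'
#' Applies the standard resting-state temporal pipeline to each region:
#' drop the first `discard_volumes` columns (magnetization equilibration),
#' remove a least-squares linear trend, and band-pass with an ideal
#' rectangular filter on the discrete Fourier transform, retaining only
#' frequencies strictly inside `(band_low_hz, band_high_hz)`. The DC bin is
#' always removed, so each output region has mean (numerically) zero.
#'
#' @param panel a [timeseries_panel()].
#' @param config an [analysis_config()].
#' @return A filtered [timeseries_panel()].
#' @export
preprocess_timeseries <- function(panel, config = analysis_config()) {
  stopifnot(inherits(panel, "timeseries_panel"))
  validate_config(config)
  d <- config$discard_volumes
  T_all <- ncol(panel$values)
  T_keep <- T_all - d
  need <- ceiling(2 / (config$band_high_hz * config$tr_seconds))
  if (T_keep < max(2L, need)) {
    stop(sprintf(
      "too few volumes after discard: %d remain, need at least %d for band up to %g Hz",
      T_keep, max(2L, need), config$band_high_hz), call. = FALSE)
  }
  x <- panel$values[, (d + 1L):T_all, drop = FALSE]
  x <- detrend_rows(x)
  x <- bandpass_rows(x, config$band_low_hz, config$band_high_hz,
                     config$tr_seconds)
  timeseries_panel(x, region_labels = panel$region_labels,
                   subject_id = panel$subject_id,
                   tr_seconds = panel$tr_seconds)
}

# least-squares removal of intercept + linear term, all rows at once
detrend_rows <- function(x) {
  T_len <- ncol(x)
  t_c <- seq_len(T_len) - (T_len + 1) / 2
  beta <- (x %*% t_c) / sum(t_c^2)
  x - rowMeans(x) - beta %*% t(t_c)
}

# ideal rectangular band-pass on the real DFT; band limits are exclusive.
# Folding is done on integer bin indices so the kept set is exactly
# conjugate-symmetric (a float fold of 1/tr - f is asymmetric in the last
# ulp, which would leak power through the final Re()).
bandpass_rows <- function(x, low_hz, high_hz, tr) {
  T_len <- ncol(x)
  k <- seq_len(T_len) - 1
  f_fold <- pmin(k, T_len - k) / (T_len * tr)
  keep <- f_fold > low_hz & f_fold < high_hz
  X <- t(apply(x, 1L, fft))
  X[, !keep] <- 0 + 0i
  out <- t(apply(X, 1L, function(row) Re(fft(row, inverse = TRUE)))) / T_len
  dimnames(out) <- dimnames(x)
  out
}

#' Pearson connectivity matrix of a panel
#'
#' Correlates every pair of regional time courses. The diagonal is stored as
#' zero: self-connections are excluded throughout.
#'
#' @param panel a [timeseries_panel()].
#' @return An object of class `connectivity_matrix` with fields
#'   `subject_id`, `region_labels` and `r` (N x N, symmetric, zero diagonal).
#' @export
correlation_matrix <- function(panel) {
  stopifnot(inherits(panel, "timeseries_panel"))
  sds <- apply(panel$values, 1L, sd)
  if (any(sds == 0)) {
    stop("zero-variance region(s): ",
         paste(panel$region_labels[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- cor(t(panel$values))
  diag(r) <- 0
  connectivity_matrix(r, panel$region_labels, panel$subject_id)
}

#' Construct a connectivity-matrix object
#' @param r symmetric numeric matrix of Pearson correlations in `[-1, 1]`.
#' @param region_labels region names (defaults to rownames or `R001..`).
#' @param subject_id subject identifier.
#' @return A `connectivity_matrix`.
#' @export
connectivity_matrix <- function(r, region_labels = NULL,
                                subject_id = "unknown") {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("matrix must be square", call. = FALSE)
  if (max(abs(r - t(r))) > 1e-10) stop("matrix must be symmetric", call. = FALSE)
  if (any(abs(r) > 1 + 1e-12)) stop("entries must lie in [-1, 1]", call. = FALSE)
  r <- (r + t(r)) / 2
  diag(r) <- 0
  if (is.null(region_labels)) {
    region_labels <- rownames(r)
    if (is.null(region_labels)) region_labels <- default_labels(nrow(r))
  }
  dimnames(r) <- list(region_labels, region_labels)
  structure(list(subject_id = subject_id,
                 region_labels = as.character(region_labels), r = r),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> subject %s: %d x %d, r in [%.3f, %.3f]\n",
              x$subject_id, nrow(x$r), ncol(x$r), min(x$r), max(x$r[upper.tri(x$r)])))
  invisible(x)
}

#' Sparsity grid
#'
#' @param start,stop,step grid limits and spacing; defaults give the 36
#'   levels 0.05, 0.06, ..., 0.40.
#' @return Strictly increasing numeric vector of sparsity levels.
#' @export
sparsity_grid <- function(start = 0.05, stop = 0.40, step = 0.01) {
  if (!(start > 0 && start <= stop && stop < 1 && step > 0)) {
    stop("require 0 < start <= stop < 1 and step > 0", call. = FALSE)
  }
  n <- floor((stop - start) / step + 1e-9)
  round(start + step * (0:n), 10)
}

grid_from_config <- function(config) {
  sparsity_grid(config$sparsity_start, config$sparsity_stop,
                config$sparsity_step)
}

#' Binary graph at one sparsity level
#' @param adjacency 0/1 symmetric matrix with zero diagonal.
#' @param sparsity the sparsity level the graph was thresholded at.
#' @param region_labels node names.
#' @return An object of class `binary_graph`.
#' @export
binary_graph <- function(adjacency, sparsity = NA_real_,
                         region_labels = NULL) {
  a <- as.matrix(adjacency)
  storage.mode(a) <- "integer"
  if (nrow(a) != ncol(a)) stop("adjacency must be square", call. = FALSE)
  if (any(a != t(a))) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(a) != 0L)) stop("adjacency must have zero diagonal", call. = FALSE)
  if (!all(a %in% c(0L, 1L))) stop("adjacency must be 0/1", call. = FALSE)
  if (is.null(region_labels)) {
    region_labels <- rownames(a)
    if (is.null(region_labels)) region_labels <- default_labels(nrow(a))
  }
  dimnames(a) <- list(region_labels, region_labels)
  structure(list(region_labels = as.character(region_labels),
                 adjacency = a, sparsity = sparsity),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges, sparsity %s\n",
              nrow(x$adjacency), sum(x$adjacency) / 2L,
              format(x$sparsity)))
  invisible(x)
}

n_edges <- function(graph) sum(graph$adjacency) / 2L

# rank positive correlations: strongest first, ties broken by (i, j) order
ranked_positive_edges <- function(r) {
  n <- nrow(r)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  w <- r[ut]
  pos <- w > 0
  ut <- ut[pos, , drop = FALSE]
  w <- w[pos]
  o <- order(-w, ut[, 1], ut[, 2])
  list(i = ut[o, 1], j = ut[o, 2], w = w[o])
}

#' Binarize a connectivity matrix at a sparsity level
#'
#' Keeps exactly `round(s * N(N-1)/2)` edges (half-up rounding): the edges
#' with the largest positive correlations, ties at the cutoff broken by
#' lexicographic node order. Negative correlations never become edges.
#'
#' @param conn a [connectivity_matrix()].
#' @param s sparsity in (0, 1).
#' @return A [binary_graph()] carrying `s`.
#' @export
threshold_by_sparsity <- function(conn, s) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  if (!(s > 0 && s < 1)) stop("sparsity must lie in (0, 1)", call. = FALSE)
  n <- nrow(conn$r)
  n_pairs <- n * (n - 1) / 2
  E <- round_half_up(s * n_pairs)
  if (E == 0) {
    stop(sprintf("sparsity %g keeps zero edges on %d nodes", s, n),
         call. = FALSE)
  }
  re <- ranked_positive_edges(conn$r)
  if (length(re$w) < E) {
    stop(sprintf(
      "infeasible sparsity %g: only %d positive correlations (max attainable sparsity %.4f)",
      s, length(re$w), length(re$w) / n_pairs), call. = FALSE)
  }
  a <- matrix(0L, n, n)
  idx <- seq_len(E)
  a[cbind(re$i[idx], re$j[idx])] <- 1L
  a <- a + t(a)
  binary_graph(a, sparsity = s, region_labels = conn$region_labels)
}

#' Threshold a connectivity matrix over a sparsity grid
#'
#' The ranking rule is shared across levels, so the returned graphs are
#' nested: the edge set at a lower level is a subset of the edge set at any
#' higher level.
#'
#' @param conn a [connectivity_matrix()].
#' @param grid numeric vector of sparsity levels (see [sparsity_grid()]).
#' @return List of [binary_graph()]s, one per level, named by level.
#' @export
sparsity_sweep <- function(conn, grid = sparsity_grid()) {
  graphs <- lapply(grid, function(s) threshold_by_sparsity(conn, s))
  names(graphs) <- format(grid)
  graphs
}
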