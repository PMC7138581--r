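#' Ground-truth specification for the synthetic cohort generator
#'
#' Describes the latent covariance world the generator samples from: 90
#' regions in 6 equal modules, 12 planted hub regions (2 per module),
#' within-module latent correlation 0.45, between-module 0.10, an additive
#' hub boost of 0.20 on hub-incident pairs, unit-variance observation noise,
#' and per-group effect multipliers. The patient-like group weakens
#' within-module clustering (factor 0.7 on within-module non-hub pairs) and
#' hub connectivity (factor 0.6 on the hub boost), which downstream should
#' surface as higher integration, weaker clustering and weaker rich-club,
#' feeder and local strengths.
#'
#' @param n_regions number of regions N.
#' @param n_volumes time points simulated per subject (210, so 200 survive
#'   the 10-volume discard).
#' @param n_modules number of equal-size modules (must divide `n_regions`).
#' @param hub_regions integer indices of planted hubs; default picks the
#'   first `hubs_per_module` regions of each module.
#' @param hubs_per_module hubs planted per module when `hub_regions` is NULL.
#' @param r_within,r_between latent correlations by module co-membership.
#' @param r_hub_boost additive correlation on hub-incident pairs.
#' @param noise_sd independent observation noise SD added to each draw.
#' @param group_effects named list of per-group multipliers
#'   `list(control = c(clustering_factor, hub_factor), patient = ...)`.
#' @return An object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(n_regions = 90L,
                              n_volumes = 210L,
                              n_modules = 6L,
                              hub_regions = NULL,
                              hubs_per_module = 2L,
                              r_within = 0.45,
                              r_between = 0.10,
                              r_hub_boost = 0.20,
                              noise_sd = 1.0,
                              group_effects = list(
                                control = c(clustering_factor = 1.0,
                                            hub_factor = 1.0),
                                patient = c(clustering_factor = 0.7,
                                            hub_factor = 0.6))) {
  n_regions <- as.integer(n_regions)
  n_modules <- as.integer(n_modules)
  if (n_regions %% n_modules != 0L) {
    stop("n_modules must divide n_regions", call. = FALSE)
  }
  per <- n_regions %/% n_modules
  module_assignment <- rep(seq_len(n_modules), each = per)
  if (is.null(hub_regions)) {
    hub_regions <- as.integer(outer(seq_len(hubs_per_module),
                                    (seq_len(n_modules) - 1L) * per, "+"))
  }
  hub_regions <- sort(as.integer(hub_regions))
  if (any(hub_regions < 1L | hub_regions > n_regions)) {
    stop("hub_regions must be region indices in 1..n_regions", call. = FALSE)
  }
  spec <- list(n_regions = n_regions, n_volumes = as.integer(n_volumes),
               module_assignment = module_assignment,
               hub_regions = hub_regions,
               r_within = r_within, r_between = r_between,
               r_hub_boost = r_hub_boost, noise_sd = noise_sd,
               group_effects = group_effects)
  class(spec) <- "ground_truth_spec"
  spec
}

#' Latent covariance matrix for one group
#'
#' Builds the target correlation matrix entry by entry: `r_within` for
#' same-module pairs, `r_between` otherwise; plus `r_hub_boost * hub_factor`
#' when either endpoint is a planted hub; then `clustering_factor` applied
#' multiplicatively to within-module pairs with no hub endpoint. The result
#' is repaired to positive semidefiniteness by clipping negative eigenvalues
#' at zero and renormalizing the diagonal to exactly 1.
#'
#' @param spec a [ground_truth_spec()].
#' @param group `"control"` or `"patient"` (any group named in
#'   `spec$group_effects`).
#' @return N x N positive-semidefinite covariance (unit diagonal).
#' @export
make_group_covariance <- function(spec, group = "control") {
  stopifnot(inherits(spec, "ground_truth_spec"))
  eff <- spec$group_effects[[group]]
  if (is.null(eff)) stop("unknown group: ", group, call. = FALSE)
  n <- spec$n_regions
  mod <- spec$module_assignment
  is_hub <- seq_len(n) %in% spec$hub_regions
  same_mod <- outer(mod, mod, "==")
  hub_pair <- outer(is_hub, is_hub, "|")
  S <- ifelse(same_mod, spec$r_within, spec$r_between)
  S <- S + spec$r_hub_boost * eff[["hub_factor"]] * hub_pair
  shrink <- same_mod & !hub_pair
  S[shrink] <- S[shrink] * eff[["clustering_factor"]]
  diag(S) <- 1
  off <- S[upper.tri(S)]
  if (any(off <= -1 | off >= 1)) {
    stop("target correlations outside (-1, 1); adjust the spec", call. = FALSE)
  }
  nearest_psd_unit_diag(S)
}

# eigenvalue clipping at 0, then diagonal rescaled back to exactly 1
nearest_psd_unit_diag <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 0) {
    S <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    d <- 1 / sqrt(diag(S))
    S <- S * tcrossprod(d)
    S <- (S + t(S)) / 2
  }
  diag(S) <- 1
  S
}

#' Simulate one subject's time series
#'
#' Volumes are i.i.d. draws from a zero-mean multivariate normal with the
#' given covariance, plus independent N(0, noise_sd^2) observation noise.
#' No temporal autocorrelation is modelled: every downstream statistic uses
#' only zero-lag correlations.
#'
#' @param cov positive-semidefinite covariance (regions x regions).
#' @param n_volumes number of time points T.
#' @param noise_sd observation noise SD.
#' @param seed integer seed; the draw is a pure function of
#'   `(cov, n_volumes, noise_sd, seed)`.
#' @param subject_id,tr_seconds metadata for the returned panel.
#' @return A [timeseries_panel()] of dimensions N x T.
#' @export
simulate_subject <- function(cov, n_volumes, noise_sd = 0, seed = 1L,
                             subject_id = "sim", tr_seconds = 2.0) {
  cov <- as.matrix(cov)
  n <- nrow(cov)
  e <- eigen(cov, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values))) {
    stop("covariance is not positive semidefinite", call. = FALSE)
  }
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n)
  x <- with_stage_seed(seed, {
    z <- matrix(rnorm(n * n_volumes), n, n_volumes)
    out <- A %*% z
    if (noise_sd > 0) out <- out + noise_sd * matrix(rnorm(n * n_volumes),
                                                     n, n_volumes)
    out
  })
  timeseries_panel(x, subject_id = subject_id, tr_seconds = tr_seconds)
}

# Clinical covariate moments (mean, sd) used by the cohort generator.
clinical_moments <- list(
  patient = list(age = c(41.00, 11.23), education = c(13.32, 2.14),
                 male_fraction = 4 / 19,
                 duration = c(4.76, 3.58), acth = c(86.10, 58.28),
                 ufc = c(659.87, 357.29),
                 cortisol_0am = c(17.03, 9.13),
                 cortisol_4pm = c(19.66, 9.09),
                 cortisol_8am = c(2.43, 13.08)),
  control = list(age = c(47.05, 13.51), education = c(13.09, 3.64),
                 male_fraction = 7 / 22)
)

rtruncnorm0 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  pmax(x, 0)
}

#' Simulate a two-group cohort
#'
#' Draws `n_patient` patient-like and `n_control` control-like subjects:
#' regional time series from each group's latent covariance
#' ([make_group_covariance()]) and clinical covariates from the reference
#' moments (age, sex, education for both groups; disease duration, ACTH,
#' UFC and diurnal cortisol for patients only, truncated at 0; control
#' clinical fields are left missing).
#'
#' @param spec a [ground_truth_spec()].
#' @param n_per_group subjects per group; either a single count or
#'   `c(patient, control)`.
#' @param seed master integer seed; panels and manifest are pure functions
#'   of `(spec, n_per_group, seed)`.
#' @param tr_seconds repetition time attached to the panels.
#' @return List with `panels` (list of [timeseries_panel()]) and `manifest`
#'   (a `subject_manifest` data frame).
#' @export
simulate_cohort <- function(spec, n_per_group = 15L, seed = 1L,
                            tr_seconds = 2.0) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  n_per_group <- as.integer(n_per_group)
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  n_pat <- n_per_group[1]
  n_con <- n_per_group[2]
  if (n_pat < 2L || n_con < 2L) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  covs <- list(patient = make_group_covariance(spec, "patient"),
               control = make_group_covariance(spec, "control"))
  ids <- c(sprintf("P%03d", seq_len(n_pat)), sprintf("C%03d", seq_len(n_con)))
  groups <- rep(c("patient", "control"), c(n_pat, n_con))
  panels <- vector("list", length(ids))
  names(panels) <- ids
  for (i in seq_along(ids)) {
    panels[[i]] <- simulate_subject(
      covs[[groups[i]]], spec$n_volumes, spec$noise_sd,
      seed = stage_seed(seed, "panel", i),
      subject_id = ids[i], tr_seconds = tr_seconds)
  }
  manifest <- with_stage_seed(stage_seed(seed, "clinical"), {
    df <- data.frame(subject_id = ids, group = groups,
                     stringsAsFactors = FALSE)
    for (g in c("patient", "control")) {
      m <- clinical_moments[[g]]
      sel <- df$group == g
      k <- sum(sel)
      df$age[sel] <- rtruncnorm0(k, m$age[1], m$age[2])
      df$sex[sel] <- ifelse(runif(k) < m$male_fraction, "M", "F")
      df$education[sel] <- rtruncnorm0(k, m$education[1], m$education[2])
      if (g == "patient") {
        for (v in c("duration", "acth", "ufc", "cortisol_0am",
                    "cortisol_4pm", "cortisol_8am")) {
          df[[v]][sel] <- rtruncnorm0(k, m[[v]][1], m[[v]][2])
        }
      }
    }
    df
  })
  list(panels = panels, manifest = as_manifest(manifest))
}

#' Reference graph constructions
#'
#' Standard graph families used as test fixtures and oracles for the
#' small-world machinery.
#'
#' @param kind one of `"ring_lattice"`, `"erdos_renyi"`, `"watts_strogatz"`,
#'   `"star"`, `"complete"`, `"path"`.
#' @param n node count.
#' @param k even neighbor count for lattice/Watts-Strogatz.
#' @param p edge probability for Erdos-Renyi.
#' @param rewire_p per-edge rewiring probability for Watts-Strogatz.
#' @param seed integer seed (random kinds only).
#' @return A [binary_graph()] (undirected, simple, zero diagonal).
#' @export
reference_graph <- function(kind = c("ring_lattice", "erdos_renyi",
                                     "watts_strogatz", "star", "complete",
                                     "path"),
                            n, k = NULL, p = NULL, rewire_p = 0.1,
                            seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 2L) stop("need n >= 2", call. = FALSE)
  a <- matrix(0L, n, n)
  if (kind %in% c("ring_lattice", "watts_strogatz")) {
    if (is.null(k) || k %% 2 != 0 || k >= n || k < 2) {
      stop("ring lattice needs even k with 2 <= k < n", call. = FALSE)
    }
    for (d in seq_len(k / 2)) {
      i <- seq_len(n)
      j <- (i + d - 1L) %% n + 1L
      a[cbind(i, j)] <- 1L
      a[cbind(j, i)] <- 1L
    }
    if (kind == "watts_strogatz") {
      a <- with_stage_seed(seed, ws_rewire(a, rewire_p))
    }
  } else if (kind == "erdos_renyi") {
    if (is.null(p) || p < 0 || p > 1) {
      stop("erdos_renyi needs p in [0, 1]", call. = FALSE)
    }
    a <- with_stage_seed(seed, {
      ut <- which(upper.tri(a))
      a[ut[runif(length(ut)) < p]] <- 1L
      a + t(a)
    })
  } else if (kind == "star") {
    a[1, 2:n] <- 1L
    a[2:n, 1] <- 1L
  } else if (kind == "complete") {
    a[] <- 1L
    diag(a) <- 0L
  } else if (kind == "path") {
    i <- seq_len(n - 1L)
    a[cbind(i, i + 1L)] <- 1L
    a[cbind(i + 1L, i)] <- 1L
  }
  binary_graph(a, region_labels = default_labels(n))
}

# Watts-Strogatz step: each lattice edge rewired with prob p by replacing
# its far endpoint with a uniform non-neighbor
ws_rewire <- function(a, p) {
  n <- nrow(a)
  edges <- which(upper.tri(a) & a == 1L, arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    if (runif(1) >= p) next
    i <- edges[e, 1]
    j <- edges[e, 2]
    candidates <- which(a[i, ] == 0L & seq_len(n) != i)
    if (!length(candidates)) next
    jnew <- candidates[sample.int(length(candidates), 1L)]
    a[i, j] <- a[j, i] <- 0L
    a[i, jnew] <- a[jnew, i] <- 1L
  }
  a
}
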