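test_that("degenerate spec gives the identity covariance", {
  spec <- ground_truth_spec(n_regions = 12L, n_modules = 3L,
                            hub_regions = integer(0), r_within = 0,
                            r_between = 0, r_hub_boost = 0)
  S <- make_group_covariance(spec, "control")
  expect_equal(S, diag(12), ignore_attr = TRUE)
})

test_that("default covariance needs PSD repair and gets exact unit diagonal", {
  spec <- ground_truth_spec()
  # independent eigendecomposition oracle on the unrepaired target
  eff <- spec$group_effects$control
  n <- spec$n_regions
  is_hub <- seq_len(n) %in% spec$hub_regions
  same <- outer(spec$module_assignment, spec$module_assignment, "==")
  hp <- outer(is_hub, is_hub, "|")
  raw <- ifelse(same, spec$r_within, spec$r_between) +
    spec$r_hub_boost * eff[["hub_factor"]] * hp
  sh <- same & !hp
  raw[sh] <- raw[sh] * eff[["clustering_factor"]]
  diag(raw) <- 1
  raw_min <- min(eigen(raw, symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(raw_min, 0) # clipping is genuinely exercised by the default spec
  S <- make_group_covariance(spec, "control")
  expect_identical(unname(diag(S)), rep(1, n))
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("patient hub shrinkage lowers hub-incident covariance", {
  spec <- ground_truth_spec()
  Sc <- make_group_covariance(spec, "control")
  Sp <- make_group_covariance(spec, "patient")
  is_hub <- seq_len(spec$n_regions) %in% spec$hub_regions
  mask <- outer(is_hub, is_hub, "|")
  diag(mask) <- FALSE
  expect_lt(mean(Sp[mask]), mean(Sc[mask]))
  # and within-module non-hub clustering is weakened too
  same <- outer(spec$module_assignment, spec$module_assignment, "==")
  wm <- same & !mask
  diag(wm) <- FALSE
  expect_lt(mean(Sp[wm]), mean(Sc[wm]))
  expect_error(make_group_covariance(spec, "nosuch"), "unknown group")
  expect_error(
    make_group_covariance(ground_truth_spec(r_within = 0.9,
                                            r_hub_boost = 0.2), "control"),
    "outside")
})

test_that("simulated draws reproduce the target covariance (Monte Carlo)", {
  # identity target: off-diagonal sample correlations vanish
  p <- simulate_subject(diag(20), 10000, noise_sd = 0, seed = 3)
  r <- cor(t(p$values))
  expect_lt(max(abs(r[upper.tri(r)])), 0.05) # 3/sqrt(T) rounded up
  # strong pair: r = 0.9 recovered within 0.02
  S <- diag(4)
  S[1, 2] <- S[2, 1] <- 0.9
  p <- simulate_subject(S, 10000, noise_sd = 0, seed = 4)
  expect_equal(cor(p$values[1, ], p$values[2, ]), 0.9, tolerance = 0.02)
  # purity: same seed, identical panels
  expect_identical(simulate_subject(S, 50, 1, seed = 9)$values,
                   simulate_subject(S, 50, 1, seed = 9)$values)
  expect_error(simulate_subject(matrix(c(1, 2, 2, 1), 2), 10), "semidefinite")
})

test_that("sampled correlations converge to the repaired target", {
  spec <- ground_truth_spec()
  S <- make_group_covariance(spec, "control")
  p <- simulate_subject(S, 10000, noise_sd = 0, seed = 21)
  r <- cor(t(p$values))
  expect_lt(max(abs(r - S)), 0.05)
})

test_that("cohorts honor group sizes, clinical moments and purity", {
  spec <- small_spec(n_volumes = 4L)
  cohort <- simulate_cohort(spec, c(19L, 22L), seed = 2)
  m <- cohort$manifest
  expect_equal(sum(m$group == "patient"), 19L)
  expect_equal(sum(m$group == "control"), 22L)
  expect_length(cohort$panels, 41L)
  expect_true(all(is.na(m$acth[m$group == "control"])))
  expect_true(all(!is.na(m$acth[m$group == "patient"])))
  expect_true(all(m$duration[m$group == "patient"] >= 0))
  # Monte-Carlo on the ACTH moments at n = 1000 patients
  big <- simulate_cohort(spec, c(1000L, 2L), seed = 6)
  acth <- big$manifest$acth[big$manifest$group == "patient"]
  expect_lt(abs(mean(acth) - 86.10), 3 * 58.28 / sqrt(1000))
  again <- simulate_cohort(spec, c(19L, 22L), seed = 2)
  expect_identical(again$manifest, m)
  expect_identical(again$panels[[1]]$values, cohort$panels[[1]]$values)
  expect_error(simulate_cohort(spec, 1L, seed = 1), "at least 2")
})

test_that("reference graphs match their closed forms", {
  k4 <- reference_graph("complete", 4)
  expect_equal(sum(k4$adjacency) / 2, 6)
  expect_equal(unname(degree_centrality(k4)), rep(3, 4))
  rl <- reference_graph("ring_lattice", 20, k = 4)
  expect_equal(unname(degree_centrality(rl)), rep(4, 20))
  # closed form C = 3(k-2)/(4(k-1)) = 0.5 at k = 4; verified by direct count
  expect_equal(clustering_coefficients(rl)$cp, 0.5)
  expect_equal(mean(oracle_clustering(rl$adjacency)), 0.5)
  expect_error(reference_graph("ring_lattice", 4, k = 4), "k")
  expect_error(reference_graph("erdos_renyi", 10, p = 1.5), "p in")
})

test_that("Erdos-Renyi edge counts match binomial moments", {
  counts <- vapply(1:200, function(s) {
    sum(reference_graph("erdos_renyi", 100, p = 0.1, seed = s)$adjacency) / 2
  }, numeric(1))
  expect_lt(abs(mean(counts) - 495), 3 * sqrt(4950 * 0.1 * 0.9))
})

test_that("watts-strogatz keeps edge count and gains shortcuts", {
  ws <- reference_graph("watts_strogatz", 90, k = 10, rewire_p = 0.1,
                        seed = 3)
  expect_equal(sum(ws$adjacency) / 2, 450)
  expect_lt(characteristic_path_length(ws)$lp,
            characteristic_path_length(
              reference_graph("ring_lattice", 90, k = 10))$lp)
})
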