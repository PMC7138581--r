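test_that("two-sample t matches the textbook formula", {
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$p, 0.0214, tolerance = 1e-2)
  expect_equal(r$df, 4)
  # symmetry: swapping flips the sign, p unchanged
  r2 <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero pooled variance")
  expect_error(two_sample_t(1, c(1, 2)), ">= 2 values")
  # cross-check both variants against stats::t.test on random data
  set.seed(5)
  a <- rnorm(10)
  b <- rnorm(12, 0.5)
  expect_equal(two_sample_t(a, b)$p,
               stats::t.test(a, b, var.equal = TRUE)$p.value)
  expect_equal(two_sample_t(a, b, welch = TRUE)$p,
               stats::t.test(a, b)$p.value)
})

test_that("BH step-up flags match hand computation and stay monotone", {
  expect_equal(fdr_correct(c(0.001, 0.02, 0.8), q = 0.05),
               c(TRUE, TRUE, FALSE))
  expect_equal(fdr_correct(rep(1, 5), q = 0.05), rep(FALSE, 5))
  expect_equal(fdr_correct(rep(0, 5), q = 0.05), rep(TRUE, 5))
  for (seed in 1:20) {
    set.seed(seed)
    p <- runif(30)^2
    flags <- fdr_correct(p, q = 0.05)
    expect_identical(flags, p.adjust(p, "BH") <= 0.05) # stats oracle
    if (any(flags)) expect_true(max(p[flags]) <= min(p[!flags][p[!flags] > max(p[flags])], Inf))
  }
})

test_that("permutation test honors the add-one convention and separation", {
  same <- permutation_test_difference(c(1, 2, 3), c(1, 2, 3), P = 50, seed = 1)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  # complete separation with n = 3 per group: only the 2 extreme splits of
  # the C(6,3) = 20 reach |delta| >= 10, so the exact permutation p is
  # 2/20 = 0.1 and p-hat = (1 + Binom(100, 0.1))/101 concentrates near it
  ps <- vapply(1:100, function(seed) {
    permutation_test_difference(c(10, 11, 12), c(0, 1, 2), P = 100,
                                seed = seed)$p
  }, numeric(1))
  expect_gte(sum(ps <= 0.2), 95)
  expect_equal(mean(ps), 11 / 101, tolerance = 0.1)
  # determinism and minimum attainable p
  r1 <- permutation_test_difference(rnorm(8), rnorm(8), P = 100, seed = 9)
  r2 <- permutation_test_difference(rnorm(8), rnorm(8), P = 100, seed = 9)
  expect_gte(r1$p, 1 / 101)
})

test_that("spearman correlation: monotone invariance and rank oracle", {
  x <- c(0.3, 1.1, 2.2, 3.5, 4.1)
  expect_equal(spearman_correlation(x, exp(x))$rho, 1)
  expect_equal(spearman_correlation(x, -x)$rho, -1)
  r <- spearman_correlation(1:5, c(3, 1, 2, 5, 4))
  # rank formula: 1 - 6*sum(d^2)/(n(n^2-1)) with sum(d^2) = 8
  expect_equal(r$rho, 1 - 6 * 8 / (5 * 24))
  expect_equal(r$rho, 0.6)
  expect_equal(r$rho, cor(1:5, c(3, 1, 2, 5, 4), method = "spearman"))
  # missing entries dropped pairwise; < 3 pairs errors
  expect_equal(spearman_correlation(c(1, 2, NA, 4, 5),
                                    c(2, 4, 9, 8, 10))$n, 4L)
  expect_error(spearman_correlation(c(1, 2, NA), c(2, NA, 3)), ">= 3")
})

test_that("demographics table: chi-square and rank-sum contracts", {
  man <- as_manifest(data.frame(
    subject_id = sprintf("S%02d", 1:40),
    group = rep(c("patient", "control"), each = 20),
    sex = rep(c("M", "F", "M", "F"), each = 10),
    age = c(1:10, 31:40, 11:30),
    education = rnorm(40, 13)))
  d <- demographics_table(man)
  sex_row <- d[d$variable == "sex", ]
  expect_equal(sex_row$statistic, 0) # balanced 10/10 vs 10/10
  expect_equal(sex_row$p, 1)
  # permuting subject order leaves every statistic unchanged
  perm <- man[sample(40), ]
  expect_equal(demographics_table(as_manifest(perm))$statistic, d$statistic)
})

test_that("Mann-Whitney U matches the rank-sum oracle on separated groups", {
  mw <- fcgraph:::mann_whitney_u(1:10, 11:20)
  expect_equal(mw$U, 0)
  expect_lt(mw$p, 0.001)
  # tie-corrected normal approximation vs stats::wilcox.test
  set.seed(2)
  a <- sample(1:8, 15, replace = TRUE)
  b <- sample(3:10, 12, replace = TRUE)
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = FALSE))
  expect_equal(fcgraph:::mann_whitney_u(a, b)$U, unname(ref$statistic))
  expect_equal(fcgraph:::mann_whitney_u(a, b)$p, ref$p.value,
               tolerance = 1e-10)
})

test_that("compare_groups produces the contracted shapes", {
  spec <- small_spec()
  cohort <- simulate_cohort(spec, 5, seed = 3)
  cfg <- fast_config(seed = 3, n_permutations = 50L)
  suppressMessages({
    conns <- lapply(cohort$panels,
                    function(p) correlation_matrix(preprocess_timeseries(p, cfg)))
    profiles <- lapply(conns, metric_profile, config = cfg, smallworld = TRUE)
    grid <- sparsity_grid(0.05, 0.4, 0.05)
    man <- cohort$manifest
    strengths <- list()
    for (g in c("patient", "control")) {
      ids <- man$subject_id[man$group == g]
      h <- identify_hubs(conns[ids], grid)
      for (sid in ids) {
        strengths[[sid]] <- connection_strengths(conns[[sid]], grid, h$hubs)
      }
    }
    sdf <- data.frame(subject_id = names(strengths),
                      rich_club = vapply(strengths, `[[`, numeric(1), 1),
                      feeder = vapply(strengths, `[[`, numeric(1), 2),
                      local = vapply(strengths, `[[`, numeric(1), 3))
    cmp <- compare_groups(profiles, sdf, man, cfg)
  })
  # 7 metric families x 8 levels, minus levels where gamma/lambda/sigma are
  # undefined (degenerate nulls on the sparsest graphs of this small world)
  expect_lte(nrow(cmp$metrics), 7 * 8)
  raw <- cmp$metrics$metric %in% c("eglo", "eloc", "cp", "lp")
  expect_equal(sum(raw), 4 * 8)
  expect_setequal(unique(cmp$metrics$metric), fcgraph:::metric_families)
  expect_true(all(cmp$metrics$p >= 0 & cmp$metrics$p <= 1))
  expect_equal(nrow(cmp$strengths), 3L)
  expect_true(all(cmp$strengths$p >= 1 / (cfg$n_permutations + 1)))
  # Spearman block: (7 metrics + 3 strengths) x 2 clinical variables
  expect_equal(nrow(cmp$spearman), 20L)
  # subject order invariance (permutation RNG keys on sorted ids)
  reord <- sample(nrow(man))
  suppressMessages({
    cmp2 <- compare_groups(profiles[reord], sdf[order(sdf$subject_id), ],
                           man[reord, ], cfg)
  })
  expect_equal(cmp2$metrics, cmp$metrics)
  expect_equal(cmp2$strengths, cmp$strengths)
})

test_that("metric families that are all NA are omitted gracefully", {
  spec <- small_spec()
  cohort <- simulate_cohort(spec, 3, seed = 4)
  cfg <- fast_config(seed = 4)
  suppressMessages({
    conns <- lapply(cohort$panels,
                    function(p) correlation_matrix(preprocess_timeseries(p, cfg)))
    profiles <- lapply(conns, metric_profile, config = cfg,
                       smallworld = FALSE)
    cmp <- compare_groups(profiles, NULL, cohort$manifest, cfg)
  })
  expect_equal(sort(unique(cmp$metrics$metric)),
               sort(c("eglo", "eloc", "cp", "lp")))
  expect_null(cmp$strengths)
  expect_equal(nrow(cmp$spearman), 4 * 2)
})
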