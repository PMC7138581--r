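test_that("preprocessing discards volumes, detrends and band-passes", {
  cfg <- analysis_config()
  set.seed(8)
  p <- timeseries_panel(matrix(rnorm(5 * 210), 5, 210), subject_id = "S")
  out <- preprocess_timeseries(p, cfg)
  expect_equal(ncol(out$values), 200L) # 210 - 10
  expect_lt(max(abs(rowMeans(out$values))), 1e-8)

  # in-band 0.04 Hz sinusoid passes through nearly unchanged
  tt <- seq_len(210)
  sine <- sin(2 * pi * 0.04 * tt * 2)
  p2 <- timeseries_panel(rbind(sine, cos(2 * pi * 0.04 * tt * 2)),
                         subject_id = "sine")
  out2 <- preprocess_timeseries(p2, cfg)
  expect_gt(cor(out2$values[1, ], sine[11:210]), 0.99)

  # a pure linear ramp is annihilated by detrending
  ramp <- rbind(seq_len(210), 2 * seq_len(210))
  out3 <- preprocess_timeseries(timeseries_panel(ramp), cfg)
  expect_lt(max(abs(out3$values)), 1e-8)

  # an out-of-band 0.2 Hz sinusoid is rejected by the ideal filter; the
  # small residual is the in-band tail of the detrending line, not leakage
  fast <- rbind(sin(2 * pi * 0.2 * tt * 2), cos(2 * pi * 0.2 * tt * 2))
  out4 <- preprocess_timeseries(timeseries_panel(fast), cfg)
  expect_lt(max(abs(out4$values)), 0.05)

  expect_error(
    preprocess_timeseries(timeseries_panel(matrix(rnorm(4 * 20), 4, 20)), cfg),
    "too few volumes")
})

test_that("band-pass retains exactly the in-band DFT bins (FFT oracle)", {
  cfg <- analysis_config()
  set.seed(9)
  x <- matrix(rnorm(2 * 210), 2, 210)
  out <- preprocess_timeseries(timeseries_panel(x), cfg)
  spec_out <- abs(fft(out$values[1, ]))
  T_len <- 200
  k <- seq_len(T_len) - 1
  f <- pmin(k, T_len - k) / (T_len * 2)
  inband <- f > 0.01 & f < 0.08
  expect_lt(max(spec_out[!inband]), 1e-8 * max(spec_out))
  expect_gt(max(spec_out[inband]), 0)
})

test_that("correlation matrices follow the Pearson contract", {
  v <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(4, 3, 2, 1), c(1, 3, 2, 4))
  conn <- correlation_matrix(timeseries_panel(v, subject_id = "S"))
  expect_equal(conn$r[1, 2], 1)
  expect_equal(conn$r[1, 3], -1)
  # brute-force Pearson formula oracle for rows (1,2,3,4) vs (1,3,2,4)
  a <- v[1, ]; b <- v[4, ]
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r_oracle, 0.8)
  expect_equal(conn$r[1, 4], r_oracle)
  expect_identical(unname(diag(conn$r)), rep(0, 4))
  expect_equal(conn$r, t(conn$r))
  flat <- rbind(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_error(correlation_matrix(timeseries_panel(flat)), "R001")
})

test_that("sparsity thresholding keeps the strongest positive edges", {
  r <- matrix(0, 4, 4)
  r[1, 2] <- 0.9; r[1, 3] <- 0.8; r[1, 4] <- 0.7
  r[2, 3] <- 0.3; r[2, 4] <- 0.2; r[3, 4] <- 0.1
  r <- r + t(r)
  conn <- connectivity_matrix(r)
  g <- threshold_by_sparsity(conn, 0.5)
  expect_equal(sum(g$adjacency) / 2, 3) # round(0.5 * 6)
  expect_equal(g$adjacency[1, 2] + g$adjacency[1, 3] + g$adjacency[1, 4], 3L)
  expect_equal(g$adjacency[2, 3] + g$adjacency[2, 4] + g$adjacency[3, 4], 0L)
  expect_equal(g$sparsity, 0.5)
})

test_that("edge count is exactly round-half-up(s * N(N-1)/2)", {
  for (seed in 1:5) {
    conn <- random_connectivity(15, seed)
    for (s in c(0.07, 0.1, 0.25, 0.33)) {
      g <- threshold_by_sparsity(conn, s)
      expect_equal(sum(g$adjacency) / 2, floor(s * 105 + 0.5))
    }
  }
})

test_that("threshold error contracts", {
  neg <- connectivity_matrix(-abs(random_connectivity(8, 1)$r))
  expect_error(threshold_by_sparsity(neg, 0.2), "infeasible")
  expect_error(threshold_by_sparsity(random_connectivity(8, 1), 0.001),
               "zero edges")
  expect_error(threshold_by_sparsity(random_connectivity(8, 1), 1.2),
               "in \\(0, 1\\)")
})

test_that("sweeps are nested with non-decreasing edge counts", {
  conn <- random_connectivity(20, seed = 6)
  grid <- sparsity_grid(0.05, 0.40, 0.05)
  graphs <- sparsity_sweep(conn, grid)
  expect_length(graphs, 8L)
  for (i in seq_len(length(graphs) - 1)) {
    a <- graphs[[i]]$adjacency
    b <- graphs[[i + 1]]$adjacency
    expect_true(all(b[a == 1L] == 1L)) # nestedness
    expect_lte(sum(a), sum(b))
  }
  # default grid on a 90-node matrix gives 36 graphs
  spec <- ground_truth_spec()
  p <- simulate_subject(make_group_covariance(spec, "control"), 60,
                        noise_sd = 1, seed = 2)
  g90 <- sparsity_sweep(correlation_matrix(p), sparsity_grid())
  expect_length(g90, 36L)
  expect_equal(dim(g90[[1]]$adjacency), c(90L, 90L))
})

test_that("thresholding is invariant to increasing transforms of r", {
  conn <- random_connectivity(15, seed = 11)
  warped <- connectivity_matrix(2 / pi * atan(conn$r) * pi / 2.5)
  for (s in c(0.1, 0.3)) {
    expect_identical(threshold_by_sparsity(conn, s)$adjacency,
                     threshold_by_sparsity(warped, s)$adjacency)
  }
  # achieved sparsity within 0.5 edge of requested
  for (s in c(0.11, 0.23)) {
    g <- threshold_by_sparsity(conn, s)
    expect_lte(abs(sum(g$adjacency) / 2 / 105 - s), 0.5 / 105)
  }
})
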