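test_that("hierarchical generator plants the requested layer structure", {
  # pure chain: 3 layers, no feedback, full density, exact weights
  net <- generate_hierarchical_coupling(3, 3, feedforward_weight = 1,
                                        feedback_weight = 0, density = 1,
                                        weight_jitter = 0, seed = 1)
  expect_equal(net$coupling, chain_coupling(3))
  expect_equal(trophic_levels(net$coupling), c(2, 1, 0))
  expect_equal(net$planted_levels, c(2, 1, 0))

  # equal reciprocal weights: symmetric coupling, zero imbalance
  net_s <- generate_hierarchical_coupling(6, 3, feedforward_weight = 0.5,
                                          feedback_weight = 0.5, density = 1,
                                          weight_jitter = 0, seed = 2)
  # build explicitly symmetric variant on its support
  C <- net_s$coupling
  S <- pmax(C, t(C))
  expect_equal(flow_degrees(S)$v, rep(0, 6))

  # determinism
  a <- generate_hierarchical_coupling(12, 4, seed = 7)
  b <- generate_hierarchical_coupling(12, 4, seed = 7)
  expect_identical(a, b)

  # planted levels decrease with layer index, network weakly connected
  expect_true(all(diff(a$planted_levels[order(a$layer_assignment)]) <= 0))
  expect_equal(max(weak_components(a$coupling)), 1)

  expect_error(generate_hierarchical_coupling(1, 1), "at least 2")
  expect_error(generate_hierarchical_coupling(5, 2, 0, 0), "all-zero")
})

test_that("uncoupled Hopf nodes match the Ornstein-Uhlenbeck variance", {
  p <- hopf_params(a = -0.5, omega = c(0, 0), sigma = 0.1)
  ts <- simulate_hopf_bold(matrix(0, 2, 2), p, n_timepoints = 50000,
                           TR = 0.5, dt = 0.05, burn_in = 30, seed = 3)
  v <- apply(ts, 1, var)
  # var = sigma^2 / (2|a|) = 0.01; batch-means standard error
  bm <- vapply(split(ts[1, ], rep(1:50, each = 1000)), var, numeric(1))
  se <- sd(bm) / sqrt(50)
  expect_true(all(abs(v - 0.01) < 3 * se + 5e-4))
  # determinism
  ts2 <- simulate_hopf_bold(matrix(0, 2, 2), p, n_timepoints = 100,
                            TR = 0.5, dt = 0.05, seed = 9)
  ts3 <- simulate_hopf_bold(matrix(0, 2, 2), p, n_timepoints = 100,
                            TR = 0.5, dt = 0.05, seed = 9)
  expect_identical(ts2, ts3)
  expect_error(simulate_hopf_bold(matrix(0, 2, 2), p, 10, TR = 0.5, dt = 0.4),
               "dt")
})

test_that("symmetric coupling gives time-reversible lagged correlations", {
  set.seed(4)
  C <- matrix(runif(16, 0, 0.05), 4)
  C <- (C + t(C)) / 2
  diag(C) <- 0
  p <- hopf_params(rep(-0.1, 4), rep(0.25, 4), 0.02)
  ts <- simulate_hopf_bold(C, p, n_timepoints = 12000, TR = 1, dt = 0.05,
                           seed = 5)
  fs_f <- empirical_shifted_correlation(ts, 1)
  fs_r <- empirical_shifted_correlation(ts, 1, reversed = TRUE)
  # forward ~ reversed up to sampling error
  expect_lt(max(abs(fs_f - fs_r)) / 2, 0.05)
})

test_that("cohort bundle is consistent, deterministic, and flattens by group", {
  cfg <- cohort_config(n_regions = 10, n_subjects_per_group = c(3, 3, 3, 3),
                       n_timepoints = 160, seed = 5)
  expect_warning(cohort_config(n_timepoints = 100), "150")
  b <- generate_cohort(cfg)
  expect_length(b$timeseries, 12)
  expect_equal(dim(b$timeseries[[1]]), c(10, 160))
  expect_equal(nrow(b$metadata), 12)
  expect_equal(rownames(b$biomarkers$amyloid), b$metadata$subject)

  # planted directedness strictly ordered across groups in the ground truth
  gm <- tapply(b$truth$directedness, b$metadata$group, mean)
  expect_true(all(diff(gm) < 0))

  # determinism
  b2 <- generate_cohort(cfg)
  expect_identical(b$timeseries, b2$timeseries)
  expect_identical(b$biomarkers, b2$biomarkers)

  # zero flattening and zero subject noise: all couplings equal the truth
  cfg0 <- cohort_config(n_regions = 8, n_subjects_per_group = c(2, 2, 2, 2),
                        flattening_per_group = rep(0, 4), noise_sd = 0,
                        n_timepoints = 150, seed = 6)
  b0 <- suppressWarnings(generate_cohort(cfg0))
  dirs <- vapply(b0$coupling_true, directedness, numeric(1))
  expect_true(all(abs(dirs - dirs[1]) < 1e-12))
})

test_that("symmetrization monotonicity holds on the generated ensemble", {
  for (s in 1:3) {
    net <- generate_hierarchical_coupling(12, 4, seed = 50 + s)
    Cs <- (net$coupling + t(net$coupling)) / 2
    d <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(l)
      directedness((1 - l) * net$coupling + l * Cs), numeric(1))
    expect_true(all(diff(d) <= 1e-10))
    expect_equal(d[5], 0)
  }
})

test_that("cohort biomarkers and cognition track the planted hierarchy", {
  cfg <- cohort_config(n_regions = 12, n_subjects_per_group = c(8, 8, 8, 8),
                       seed = 8)
  b <- generate_cohort(cfg)
  dir_true <- b$truth$directedness
  # amyloid rises as directedness falls; cognition falls with directedness
  expect_lt(cor(dir_true, b$truth$amyloid_suvr), -0.5)
  expect_gt(cor(dir_true, b$cognition$mmse), 0.5)
  expect_lt(cor(dir_true, b$cognition$adas13), -0.5)
  # gmv tracks regional hierarchy on average
  expect_gt(cor(colMeans(b$truth$trophic), colMeans(b$biomarkers$gmv)), 0.7)
})

test_that("site effects are planted with stored ground truth", {
  X <- matrix(rnorm(30 * 4), 30)
  site <- rep(c("s1", "s2", "s3"), each = 10)
  Y <- plant_site_effects(X, site, shift_sd = 0.5, scale_range = c(0.9, 1.1),
                          seed = 4)
  g <- attr(Y, "gamma"); d <- attr(Y, "delta")
  manual <- X
  for (s in unique(site)) {
    r <- site == s
    manual[r, ] <- sweep(sweep(X[r, ], 2, d[s, ], "*"), 2, g[s, ], "+")
  }
  expect_equal(unclass(Y)[1:30, ], manual, ignore_attr = TRUE)
  # identity configuration
  Y0 <- plant_site_effects(X, site, shift_sd = 0, scale_range = c(1, 1))
  expect_equal(unclass(Y0)[1:30, ], X, ignore_attr = TRUE)
})
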