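test_that("empirical FC behaves like a correlation matrix", {
  set.seed(1)
  ts <- matrix(rnorm(3 * 200), 3)
  fc <- empirical_fc(ts)
  expect_true(isSymmetric(fc))
  expect_equal(diag(fc), rep(1, 3))

  # duplicated and negated channels
  ts2 <- rbind(ts[1, ], ts[1, ], -ts[1, ])
  fc2 <- empirical_fc(ts2)
  expect_equal(fc2[1, 2], 1)
  expect_equal(fc2[1, 3], -1)

  # independent white noise: null bound 3/sqrt(T)
  set.seed(2)
  T_len <- 5000
  wn <- matrix(rnorm(2 * T_len), 2)
  expect_lt(abs(empirical_fc(wn)[1, 2]), 3 / sqrt(T_len))

  expect_error(empirical_fc(rbind(ts[1, ], rep(1, 200))), "constant")
})

test_that("lagged correlation estimator: tau=0 case, null bound, reversal identity", {
  set.seed(3)
  ts <- matrix(rnorm(4 * 500), 4)
  expect_equal(empirical_shifted_correlation(ts, 0), empirical_fc(ts),
               tolerance = 1e-12)
  # white noise at lag 1 is near zero
  expect_lt(max(abs(empirical_shifted_correlation(ts, 1))), 3 / sqrt(500))
  # reversal = transpose, exactly, for arbitrary series
  arb <- matrix(cumsum(rnorm(3 * 100)), 3)
  f <- empirical_shifted_correlation(arb, 2)
  r <- empirical_shifted_correlation(arb, 2, reversed = TRUE)
  expect_equal(r, t(f), tolerance = 1e-12)
  expect_error(empirical_shifted_correlation(ts[, 1:4], 2), "exhausts")
})

test_that("a lagging driver produces the expected asymmetry sign", {
  # x drives y with one-sample delay: FS[x, y] >> FS[y, x]
  set.seed(4)
  x <- rnorm(2000)
  y <- 0.8 * c(0, head(x, -1)) + 0.2 * rnorm(2000)
  fs <- empirical_shifted_correlation(rbind(x, y), 1)
  expect_gt(fs[1, 2], 0.5)
  expect_lt(abs(fs[2, 1]), 0.1)
})

test_that("no-op fit returns the initial coupling and converges", {
  sys <- small_hopf_system(4, seed = 8)
  target <- model_statistics(sys$C, sys$params, 3)
  stats <- target[c("fc", "fs_forward", "fs_reversal")]
  mask <- (sys$C > 0) * 1
  cfg <- fit_config(alpha = 0, varsigma = 0, patience = 5, max_iter = 50)
  fit <- fit_gec(stats, mask, sys$params, cfg, init = sys$C, tau_seconds = 3)
  expect_equal(fit$coupling, sys$C)
  expect_true(fit$converged)
})

test_that("fit respects the structural mask at every recorded state", {
  sys <- small_hopf_system(5, seed = 13)
  target <- model_statistics(sys$C, sys$params, 3)
  stats <- target[c("fc", "fs_forward", "fs_reversal")]
  mask <- (sys$C > 0.02) * 1   # sparser than the generator
  fit <- fit_gec(stats, mask, sys$params,
                 fit_config(max_iter = 300, patience = 30), tau_seconds = 3)
  expect_true(all(fit$coupling[mask == 0] == 0))
  expect_true(all(fit$coupling >= 0))
  # best-so-far error is non-increasing along the trace
  best_path <- cummin(fit$fit_trace$total)
  expect_true(all(diff(best_path) <= 0))
})

test_that("noiseless analytic targets are recovered (self-consistency)", {
  set.seed(31)
  net <- generate_hierarchical_coupling(6, 3, feedforward_weight = 0.08,
                                        feedback_weight = 0.02, density = 1,
                                        seed = 31)
  C_true <- net$coupling
  params <- hopf_params(rep(-0.1, 6), 2 * pi * runif(6, 0.02, 0.06), 0.02)
  target <- model_statistics(C_true, params, 3)
  stats <- target[c("fc", "fs_forward", "fs_reversal")]
  mask <- (C_true > 0) * 1
  fit <- fit_gec(stats, mask, params, tau_seconds = 3)
  m <- mask > 0
  expect_gt(cor(C_true[m], fit$coupling[m]), 0.95)
  expect_gt(cor(trophic_levels(C_true), trophic_levels(fit$coupling),
                method = "spearman"), 0.9)
  # determinism: identical inputs give identical output
  fit2 <- fit_gec(stats, mask, params, tau_seconds = 3)
  expect_identical(fit$coupling, fit2$coupling)
})

test_that("symmetric targets yield less asymmetric fits than directed ones", {
  set.seed(17)
  net <- generate_hierarchical_coupling(6, 3, feedforward_weight = 0.08,
                                        feedback_weight = 0.01, density = 1,
                                        seed = 17)
  C_dir <- net$coupling
  C_symm <- (C_dir + t(C_dir)) / 2
  params <- hopf_params(rep(-0.1, 6), 2 * pi * runif(6, 0.02, 0.06), 0.02)
  mask <- ((C_dir > 0) | t(C_dir > 0)) * 1
  fits <- lapply(list(C_symm, C_dir), function(Ct) {
    tg <- model_statistics(Ct, params, 3)
    fit_gec(tg[c("fc", "fs_forward", "fs_reversal")], mask, params,
            fit_config(max_iter = 1500), tau_seconds = 3)
  })
  expect_lt(asymmetry_index(fits[[1]]$coupling),
            asymmetry_index(fits[[2]]$coupling))
})

test_that("cohort fitting composes group and subject stages", {
  sys <- small_hopf_system(4, seed = 23)
  target <- model_statistics(sys$C, sys$params, 3)
  stats <- target[c("fc", "fs_forward", "fs_reversal")]
  mask <- (sys$C > 0) * 1
  cfg <- fit_config(max_iter = 200, patience = 20)
  res <- fit_cohort(list(s1 = stats, s2 = stats), mask, sys$params, cfg,
                    tau_seconds = 3)
  # identical stats give identical per-subject GECs
  expect_identical(res$subjects$s1$coupling, res$subjects$s2$coupling)
  # single subject: equals sequential group (FC-only) fit then a
  # warm-started individual fit
  res1 <- fit_cohort(list(s1 = stats), mask, sys$params, cfg,
                     tau_seconds = 3)
  gcfg <- cfg
  gcfg$varsigma <- 0
  manual_group <- fit_gec(stats, mask, sys$params, gcfg, tau_seconds = 3)
  expect_equal(res1$group$coupling, manual_group$coupling)
  manual <- fit_gec(stats, mask, sys$params, cfg,
                    init = manual_group$coupling, tau_seconds = 3)
  expect_equal(res1$subjects$s1$coupling, manual$coupling)
})
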