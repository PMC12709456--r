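test_that("Jacobian has the documented block structure and convention", {
  # single node: closed-form 2x2
  J <- build_jacobian(matrix(0, 1, 1), hopf_params(-0.5, 1, 0.1))
  expect_equal(J, matrix(c(-0.5, 1, -1, -0.5), 2))
  ev <- eigen(J, only.values = TRUE)$values
  expect_equal(sort(ev), sort(complex(real = -0.5, imaginary = c(-1, 1))))

  # zero coupling: A block is diag(a)
  p <- hopf_params(c(-0.3, -0.7), c(0.1, 0.2), 0.1)
  J0 <- build_jacobian(matrix(0, 2, 2), p)
  expect_equal(J0[1:2, 1:2], diag(c(-0.3, -0.7)))

  # column-sum convention: C[m, n] enters row n of the A block, and the
  # diagonal compensates the column sum
  C <- matrix(c(0, 0.2, 0, 0), 2, byrow = TRUE)  # 1 -> 2
  J <- build_jacobian(C, p)
  expect_equal(J[2, 1], 0.2)
  expect_equal(J[1, 2], 0)
  expect_equal(diag(J)[2], -0.7 - 0.2)
  # omega blocks unaffected by coupling strength
  J2 <- build_jacobian(2 * C, p)
  expect_equal(J2[1:2, 3:4], J[1:2, 3:4])

  # unstable configuration rejected
  expect_error(build_jacobian(matrix(0, 1, 1), hopf_params(-1e-9, 0, 1e-3)),
               NA)  # tiny negative a is still stable
  p_bad <- structure(list(a = 0.1, omega = 0, sigma = 0.1),
                     class = "hopf_params")
  expect_error(build_jacobian(matrix(0, 1, 1), p_bad), "not stable")
})

test_that("Lyapunov solve reproduces the scalar OU closed form and scales", {
  J <- build_jacobian(matrix(0, 1, 1), hopf_params(-0.5, 0, 0.1))
  K <- solve_stationary_covariance(J, 0.1)
  expect_equal(K[1, 1], 0.1^2 / (2 * 0.5))   # sigma^2 / (2|a|)
  # quadratic scaling in sigma
  K3 <- solve_stationary_covariance(J, 0.3)
  expect_equal(K3, 9 * K)
})

test_that("Lyapunov solve matches a long simulated linear SDE", {
  sys <- small_hopf_system(n = 4, seed = 5)
  J <- build_jacobian(sys$C, sys$params)
  K <- solve_stationary_covariance(J, sys$params$sigma)
  expect_true(isSymmetric(K, tol = 1e-10))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)

  # brute-force Euler-Maruyama oracle on the x-components
  set.seed(99)
  n2 <- nrow(J)
  dt <- 0.05
  n_steps <- 2e5
  x <- rep(0, n2)
  acc <- matrix(0, n2, n2)
  batch_means <- numeric(20)
  vsum <- 0
  burn <- 2000
  bsize <- (n_steps - burn) / 20
  bvals <- matrix(NA_real_, 20, n2)
  bi <- 0; cnt <- 0; bacc <- matrix(0, n2, n2)
  for (s in seq_len(n_steps)) {
    x <- x + dt * (J %*% x) + sys$params$sigma * sqrt(dt) * rnorm(n2)
    if (s > burn) {
      bacc <- bacc + tcrossprod(x)
      cnt <- cnt + 1
      if (cnt == bsize) {
        bi <- bi + 1
        bvals[bi, ] <- diag(bacc) / cnt
        acc <- acc + bacc
        bacc[] <- 0; cnt <- 0
      }
    }
  }
  K_emp <- acc / (n_steps - burn)
  se <- apply(bvals, 2, sd) / sqrt(20)
  # diagonal within 3 standard errors (batch-means SE)
  expect_true(all(abs(diag(K_emp) - diag(K)) <= 3 * se + 1e-6))
  # off-diagonals close on the covariance scale
  expect_lt(max(abs(K_emp - K)), 0.15 * max(diag(K)))
})

test_that("lagged model covariance obeys the OU closed form and limits", {
  J <- build_jacobian(matrix(0, 1, 1), hopf_params(-0.5, 0, 0.1))
  K <- solve_stationary_covariance(J, 0.1)
  ks <- lagged_model_covariance(J, K, 2)
  expect_equal(ks$KS_forward[1, 1], exp(-0.5 * 2) * K[1, 1])
  # tau = 0 recovers K
  ks0 <- lagged_model_covariance(J, K, 0)
  expect_equal(ks0$KS_forward, K)
  # reversal is the transpose
  sys <- small_hopf_system(4, seed = 2)
  J4 <- build_jacobian(sys$C, sys$params)
  K4 <- solve_stationary_covariance(J4, sys$params$sigma)
  ks4 <- lagged_model_covariance(J4, K4, 3)
  expect_equal(ks4$KS_reversal, t(ks4$KS_forward))
})

test_that("symmetric omega-homogeneous systems are time-reversible", {
  set.seed(7)
  C <- matrix(runif(16, 0, 0.05), 4)
  C <- (C + t(C)) / 2
  diag(C) <- 0
  p <- hopf_params(rep(-0.1, 4), rep(0.3, 4), 0.02)
  mod <- model_statistics(C, p, tau_seconds = 3)
  expect_equal(mod$fs_forward, mod$fs_reversal, tolerance = 1e-10)
})

test_that("normalization rescales pairs by zero-lag variances", {
  K0 <- diag(c(4, 9))
  KS <- matrix(c(4, 3, 3, 9), 2)
  FS <- normalize_shifted(KS, K0, n_regions = 2)
  expect_equal(FS, matrix(c(1, 0.5, 0.5, 1), 2))
  # joint scaling cancels
  expect_equal(normalize_shifted(5 * KS, 5 * K0, 2), FS)
  expect_error(normalize_shifted(KS, diag(c(1, 0)), 2), "variance")
})

test_that("model statistics match empirical lagged correlations of a long run", {
  sys <- small_hopf_system(4, seed = 3)
  mod <- model_statistics(sys$C, sys$params, tau_seconds = 3)
  expect_equal(diag(mod$fc), rep(1, 4))

  # exact-regime oracle: long trajectory of the linearized SDE itself,
  # sampled at a 1 s lag to keep the step count manageable
  mod1 <- model_statistics(sys$C, sys$params, tau_seconds = 1)
  set.seed(11)
  J <- mod1$J
  dt <- 0.025
  keep_every <- 1 / dt
  n_keep <- 40000
  x <- rep(0, 8)
  ts_lin <- matrix(NA_real_, 4, n_keep)
  k <- 0
  sn <- sys$params$sigma * sqrt(dt)
  n_steps <- 2000 + n_keep * keep_every
  for (s in seq_len(n_steps)) {
    x <- x + dt * (J %*% x) + sn * rnorm(8)
    if (s > 2000 && (s - 2000) %% keep_every == 0) {
      k <- k + 1
      ts_lin[, k] <- x[1:4]
    }
  }
  emp <- empirical_stats(ts_lin, tau_trs = 1)
  expect_lt(max(abs(emp$fc - mod1$fc)), 0.02)
  expect_lt(max(abs(emp$fs_forward - mod1$fs_forward)), 0.02)
  # orientation check: the empirical antisymmetric part must correlate
  # positively (and strongly) with the model's, not with its transpose
  asym_emp <- emp$fs_forward - t(emp$fs_forward)
  asym_mod <- mod1$fs_forward - t(mod1$fs_forward)
  expect_gt(cor(as.vector(asym_emp), as.vector(asym_mod)), 0.8)

  # the full nonlinear oscillator stays close to the linear prediction
  ts_nl <- simulate_hopf_bold(sys$C, sys$params, n_timepoints = 20000,
                              TR = 3, dt = 0.05, burn_in = 120, seed = 11)
  emp_nl <- empirical_stats(ts_nl, tau_trs = 1)
  expect_lt(max(abs(emp_nl$fc - mod$fc)), 0.05)
})

test_that("spectral peak estimation recovers a planted frequency", {
  set.seed(21)
  TR <- 3
  t_sec <- (0:499) * TR
  x <- sin(2 * pi * 0.05 * t_sec) + 0.1 * rnorm(500)
  y <- sin(2 * pi * 0.05 * t_sec + 1) + 0.1 * rnorm(500)
  om <- estimate_node_frequencies(rbind(x, y), TR)
  expect_equal(om, rep(2 * pi * 0.05, 2), tolerance = 0.15)
  # identical channels give identical estimates
  om2 <- estimate_node_frequencies(rbind(x, x), TR)
  expect_equal(om2[1], om2[2])
  # white noise stays within the band by construction
  wn <- matrix(rnorm(2 * 500), 2)
  om3 <- suppressWarnings(estimate_node_frequencies(wn, TR))
  expect_true(all(om3 >= 2 * pi * 0.008 - 1e-12 &
                    om3 <= 2 * pi * 0.08 + 1e-12))
  expect_error(estimate_node_frequencies(rbind(x, y), TR,
                                         band_hz = c(0.01, 0.5)),
               "Nyquist")
})
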