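# Synthetic multi-site feature table with known site effects, a covariate
# (age) slope and a group shift.
make_site_data <- function(n_per_site = 20, n_sites = 3, p = 6,
                           shift_sd = 1, scale_range = c(0.7, 1.3),
                           age_slope = -3, group_gap = 1.5, seed = 1) {
  set.seed(seed)
  n <- n_per_site * n_sites
  site <- rep(paste0("s", seq_len(n_sites)), each = n_per_site)
  age <- runif(n, 60, 90)
  group <- factor(rep(c("A", "B"), length.out = n))
  X0 <- matrix(rnorm(n * p, 10, 1), n, p)
  X0 <- X0 + age_slope * (age - 75) / 15 + group_gap * (group == "B")
  Y <- plant_site_effects(X0, site, shift_sd, scale_range, seed = seed + 1)
  list(Y = Y, clean = X0, site = site, age = age, group = group,
       gamma = attr(Y, "gamma"), delta = attr(Y, "delta"))
}

test_that("unique-site filtering drops exactly the singleton sites", {
  meta <- data.frame(site = c("A", "A", "B"))
  f <- filter_unique_sites(meta)
  expect_equal(f$kept, 1:2)
  expect_equal(f$excluded$site, "B")

  meta2 <- data.frame(site = c("A", "A", "B", "B", "C"))
  expect_equal(length(filter_unique_sites(meta2)$kept), 4)

  meta3 <- data.frame(site = c("A", "A", "B", "B"))
  expect_equal(filter_unique_sites(meta3)$kept, 1:4)

  expect_error(filter_unique_sites(data.frame(site = c("A", "B"))),
               "all sites unique")
})

test_that("planted site effects are what the generator stores", {
  d <- make_site_data(shift_sd = 0, scale_range = c(1, 1))
  expect_equal(unclass(d$Y)[seq_len(nrow(d$Y)), ], d$clean,
               ignore_attr = TRUE)
  # two sites, gamma = +-1: between-site mean gap of 2 per feature
  X <- matrix(0, 20, 3)
  site <- rep(c("s1", "s2"), each = 10)
  Y <- plant_site_effects(X, site, shift_sd = 1e-9, seed = 5)
  g <- attr(Y, "gamma")
  Y2 <- sweep(Y, 2, 0)  # planted shift only
  gap <- colMeans(Y2[1:10, ]) - colMeans(Y2[11:20, ])
  expect_equal(unname(gap), unname(g[1, ] - g[2, ]))
  expect_error(plant_site_effects(X, site, scale_range = c(0, 1)),
               "exclude 0")
})

test_that("ComBat removes planted site effects and preserves biology", {
  d <- make_site_data(seed = 42)
  cov_df <- data.frame(age = d$age, group = d$group)
  model <- fit_combat(d$Y, d$site, cov_df)
  Yh <- apply_combat(model, d$Y, d$site, cov_df)

  # site means after harmonization are nearly equal
  site_gap <- function(Y) {
    max(abs(apply(Y, 2, function(y) diff(range(tapply(y, d$site, mean))))))
  }
  expect_lt(site_gap(Yh), 0.25 * site_gap(d$Y))

  # planted group gap survives within 10%
  gap <- function(Y) mean(colMeans(Y[d$group == "B", ]) -
                            colMeans(Y[d$group == "A", ]))
  expect_lt(abs(gap(Yh) - gap(d$Y)) / abs(gap(d$Y)), 0.1)

  # age slope sign preserved per feature
  sl <- function(Y) apply(Y, 2, function(y) coef(lm(y ~ d$age))[2])
  expect_true(all(sign(sl(Yh)) == sign(sl(d$Y))))

  # recovered site locations track the planted additive effects when the
  # planted effect is purely additive (no delta confound through the mean)
  d2 <- make_site_data(scale_range = c(1, 1), seed = 43)
  m2 <- fit_combat(d2$Y, d2$site, data.frame(age = d2$age, group = d2$group))
  g_rec <- sweep(m2$gamma_hat, 2, m2$sigma, "*")   # back to original units
  g_true <- sweep(d2$gamma, 2, colMeans(d2$gamma)) # model centers site means
  expect_gt(cor(as.vector(g_rec), as.vector(g_true)), 0.95)
})

test_that("null data yield near-null site adjustments", {
  d <- make_site_data(n_per_site = 80, shift_sd = 1e-6,
                      scale_range = c(0.999, 1.001), seed = 7)
  model <- fit_combat(d$Y, d$site, data.frame(age = d$age, group = d$group))
  expect_lt(max(abs(model$gamma_star)), 0.2)
  expect_lt(max(abs(model$delta_star - 1)), 0.2)
  # near-idempotence on null-site data
  Yh <- apply_combat(model, d$Y, d$site, data.frame(age = d$age,
                                                    group = d$group))
  rel <- sqrt(mean((Yh - d$Y)^2)) / sd(d$Y)
  expect_lt(rel, 0.2)
  m2 <- fit_combat(Yh, d$site, data.frame(age = d$age, group = d$group))
  Yh2 <- apply_combat(m2, Yh, d$site, data.frame(age = d$age,
                                                 group = d$group))
  expect_lt(sqrt(mean((Yh2 - Yh)^2)) / sd(Yh), 0.01)
})

test_that("the printed harmonized-value equation is reproduced exactly", {
  # freeze gamma*/delta* and sigma = 1: y* = (y - a - Xb - g*) / d* + a + Xb
  d <- make_site_data(n_per_site = 10, n_sites = 2, p = 2, seed = 3)
  cov_df <- data.frame(age = d$age)
  model <- fit_combat(d$Y, d$site, cov_df, eb = FALSE)
  model$sigma <- rep(1, 2)
  model$gamma_star <- matrix(c(0.5, -0.5, 1, -1), 2, 2)
  model$delta_star <- matrix(c(2, 0.5, 1, 1), 2, 2)
  Yh <- apply_combat(model, d$Y, d$site, cov_df)
  X <- cbind(d$age)
  bio <- matrix(model$alpha, nrow(d$Y), 2, byrow = TRUE) +
    X %*% model$beta
  idx <- match(d$site, model$site_levels)
  manual <- (d$Y - bio - model$gamma_star[idx, ]) /
    model$delta_star[idx, ] + bio
  expect_equal(Yh, manual, ignore_attr = TRUE)
})

test_that("ComBat agrees with the reference implementation on shared data", {
  skip_if_not_installed("sva")
  d <- make_site_data(seed = 13)
  cov_df <- data.frame(age = d$age, group = d$group)
  model <- fit_combat(d$Y, d$site, cov_df)
  Yh <- apply_combat(model, d$Y, d$site, cov_df)
  mod_mat <- model.matrix(~ age + group, cov_df)
  ref <- t(suppressMessages(
    sva::ComBat(dat = t(d$Y), batch = d$site, mod = mod_mat)))
  # same adjustment up to minor implementation differences
  expect_gt(cor(as.vector(Yh), as.vector(ref)), 0.99)
  expect_lt(sqrt(mean((Yh - ref)^2)) / sd(d$Y), 0.1)
})

test_that("harmonization check flags planted shifts and passes after", {
  # strong age slope so its sign is identified despite the site noise
  d <- make_site_data(n_per_site = 30, shift_sd = 2, age_slope = -4,
                      seed = 21)
  cov_df <- data.frame(age = d$age, group = d$group)
  model <- fit_combat(d$Y, d$site, cov_df)
  Yh <- apply_combat(model, d$Y, d$site, cov_df)
  rep <- check_harmonization(d$Y, Yh, d$site, d$group, d$age,
                             n_perm = 200, seed = 3)
  expect_gte(mean(rep$site_p_post > 0.05), 0.95)
  expect_true(all(sign(rep$age_slope_pre) == sign(rep$age_slope_post)))

  expect_error(apply_combat(model, d$Y, rep("new_site", nrow(d$Y)), cov_df),
               "not in the fitted model")
})
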