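# Multi-site harmonization (ComBat-style empirical-Bayes location/scale).
#
# Feature model: y_ijv = alpha_v + X_ij beta_v + gamma_iv + delta_iv e_ijv,
# with additive (gamma) and multiplicative (delta) site effects shrunk by
# parametric empirical Bayes (normal prior on gamma, inverse-gamma on
# delta^2), and harmonized values
#   y* = sigma_v (z_ijv - gamma*_iv) / delta*_iv + alpha_v + X_ij beta_v
# so that biological covariate effects are removed before site adjustment
# and reintroduced afterwards.

#' Drop subjects whose acquisition site is unique
#'
#' Site-effect estimation needs at least two subjects per site.
#'
#' @param meta data.frame with a \code{site} column.
#' @return list with \code{kept} (row indices) and \code{excluded}
#'   (data.frame of dropped subjects with reason).
#' @export
filter_unique_sites <- function(meta) {
  if (!"site" %in% names(meta)) stop("no site column")
  tab <- table(meta$site)
  lonely <- names(tab)[tab == 1]
  if (length(lonely) == length(tab)) stop("all sites unique; nothing to harmonize")
  drop <- meta$site %in% lonely
  list(kept = which(!drop),
       excluded = data.frame(row = which(drop), site = meta$site[drop],
                             reason = rep("unique site", sum(drop))))
}

# Build the covariate design matrix (no intercept; categorical one-hot
# with reference level dropped).
combat_design <- function(covariates) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0)
    return(NULL)
  covariates <- as.data.frame(covariates)
  X <- model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  X
}

#' Fit a ComBat-style harmonization model
#'
#' Per feature: least-squares estimates of the grand mean and covariate
#' effects (site means constrained to a weighted-average zero), pooled
#' residual scale, per-site location/scale of the standardized residuals,
#' and parametric empirical-Bayes shrinkage of those site effects.
#'
#' @param Y subjects x features numeric matrix.
#' @param site per-subject site labels (>= 2 subjects per site).
#' @param covariates data.frame of biological covariates to preserve
#'   (e.g. age, gender, education, diagnosis), or NULL.
#' @param eb apply empirical-Bayes shrinkage (TRUE) or use the raw
#'   site estimates.
#' @return list of class \code{combat_model}.
#' @export
fit_combat <- function(Y, site, covariates = NULL, eb = TRUE) {
  Y <- as.matrix(Y)
  site <- droplevels(factor(site))
  if (length(site) != nrow(Y)) stop("site labels must match rows of Y")
  if (nlevels(site) < 2) stop("need >= 2 sites (run filter_unique_sites first)")
  if (any(table(site) < 2)) stop("site with a single subject; pre-filter")
  if (any(apply(Y, 2, var) == 0)) stop("zero-variance feature(s)")
  n <- nrow(Y); p <- ncol(Y)
  S <- model.matrix(~ site - 1)
  X <- combat_design(covariates)
  design <- cbind(S, X)
  if (qr(design)$rank < ncol(design)) stop("covariate design not full rank")
  B <- solve(crossprod(design), crossprod(design, Y))
  n_i <- as.vector(table(site))
  gamma_hat_ls <- B[seq_len(nlevels(site)), , drop = FALSE]
  alpha <- as.vector(crossprod(n_i / n, gamma_hat_ls))       # grand mean
  beta <- if (is.null(X)) NULL else B[-seq_len(nlevels(site)), , drop = FALSE]
  fitted_bio <- matrix(alpha, n, p, byrow = TRUE) +
    if (is.null(X)) 0 else X %*% beta
  resid <- Y - fitted_bio
  sigma <- sqrt(colMeans((Y - design %*% B)^2))              # pooled scale
  Z <- sweep(resid, 2, sigma, "/")

  g_hat <- apply(Z, 2, function(z) tapply(z, site, mean))
  d2_hat <- apply(Z, 2, function(z) tapply(z, site, var))
  g_hat <- matrix(g_hat, nlevels(site), p,
                  dimnames = list(levels(site), colnames(Y)))
  d2_hat <- matrix(d2_hat, nlevels(site), p,
                   dimnames = list(levels(site), colnames(Y)))

  if (eb && p >= 2) {
    g_star <- g_hat; d2_star <- d2_hat
    for (i in seq_len(nlevels(site))) {
      gbar <- mean(g_hat[i, ]); t2 <- var(g_hat[i, ])
      # inverse-gamma moments for the scale prior
      m <- mean(d2_hat[i, ]); v <- var(d2_hat[i, ])
      lam <- (m^2 + 2 * v) / v
      th <- (m^3 + m * v) / v
      ni <- n_i[i]
      g_new <- g_hat[i, ]; d2_new <- d2_hat[i, ]
      zi <- Z[site == levels(site)[i], , drop = FALSE]
      for (iter in 1:100) {
        g_prev <- g_new; d_prev <- d2_new
        g_new <- (ni * t2 * g_hat[i, ] + d2_new * gbar) / (ni * t2 + d2_new)
        ss <- colSums(sweep(zi, 2, g_new, "-")^2)
        d2_new <- (th + 0.5 * ss) / (ni / 2 + lam - 1)
        if (max(abs(g_new - g_prev), abs(d2_new - d_prev)) < 1e-8) break
      }
      g_star[i, ] <- g_new
      d2_star[i, ] <- d2_new
    }
  } else {
    g_star <- g_hat
    d2_star <- d2_hat
  }
  structure(list(alpha = alpha, beta = beta, sigma = sigma,
                 gamma_star = g_star, delta_star = sqrt(d2_star),
                 gamma_hat = g_hat, delta_hat = sqrt(d2_hat),
                 site_levels = levels(site),
                 covariate_names = colnames(X), eb = eb,
                 feature_names = colnames(Y)),
            class = "combat_model")
}

#' Apply a fitted ComBat model
#'
#' Standardizes by the model's biological fit, removes the (shrunk) site
#' location/scale, and reintroduces the grand mean and covariate effects.
#'
#' @param model [fit_combat()] result.
#' @param Y subjects x features matrix with the model's feature columns.
#' @param site per-subject site labels; all must be known to the model.
#' @param covariates covariate data.frame matching the fit.
#' @return harmonized matrix of the same shape as \code{Y}.
#' @export
apply_combat <- function(model, Y, site, covariates = NULL) {
  Y <- as.matrix(Y)
  site <- as.character(site)
  unseen <- setdiff(unique(site), model$site_levels)
  if (length(unseen))
    stop("site(s) not in the fitted model: ", paste(unseen, collapse = ", "))
  X <- combat_design(covariates)
  if (is.null(X) != is.null(model$beta))
    stop("covariates must match the fitted model")
  n <- nrow(Y); p <- ncol(Y)
  fitted_bio <- matrix(model$alpha, n, p, byrow = TRUE) +
    if (is.null(X)) 0 else X[, model$covariate_names, drop = FALSE] %*%
      model$beta
  Z <- sweep(Y - fitted_bio, 2, model$sigma, "/")
  idx <- match(site, model$site_levels)
  Zadj <- (Z - model$gamma_star[idx, , drop = FALSE]) /
    model$delta_star[idx, , drop = FALSE]
  sweep(Zadj, 2, model$sigma, "*") + fitted_bio
}

#' Harmonization quality report
#'
#' Checks that (1) within-group site differences are eliminated after
#' harmonization (permutation one-way ANOVA per feature, FDR-corrected)
#' and (2) the sign of the age slope is preserved.
#'
#' @param Y_pre,Y_post subjects x features matrices before/after.
#' @param site,group,age aligned per-subject vectors.
#' @param n_perm permutations for the site ANOVA.
#' @param seed integer seed.
#' @return list with per-feature site p-values pre/post (FDR-adjusted),
#'   age slope signs, and an overall \code{pass} flag.
#' @export
check_harmonization <- function(Y_pre, Y_post, site, group, age,
                                n_perm = 500, seed = 1) {
  set.seed(seed)
  site_p <- function(Y) {
    apply(Y, 2, function(y) {
      ps <- vapply(unique(group), function(g) {
        sel <- group == g
        if (length(unique(site[sel])) < 2) return(NA_real_)
        yv <- y[sel]; sv <- factor(site[sel])
        fobs <- summary(stats::aov(yv ~ sv))[[1]]$`F value`[1]
        null <- replicate(n_perm, {
          summary(stats::aov(yv ~ sample(sv)))[[1]]$`F value`[1]
        })
        (1 + sum(null >= fobs)) / (n_perm + 1)
      }, numeric(1))
      min(ps, na.rm = TRUE)   # worst group
    })
  }
  p_pre <- p.adjust(site_p(Y_pre), method = "BH")
  p_post <- p.adjust(site_p(Y_post), method = "BH")
  slope <- function(Y) apply(Y, 2, function(y) coef(lm(y ~ age))[2])
  s_pre <- slope(Y_pre); s_post <- slope(Y_post)
  pass <- all(p_post > 0.05) && all(sign(s_pre) == sign(s_post))
  list(site_p_pre = p_pre, site_p_post = p_post,
       age_slope_pre = s_pre, age_slope_post = s_post, pass = pass)
}
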