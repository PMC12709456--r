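# Inferential statistics: covariate-adjusted permutation tests,
# false-discovery-rate correction, mixed-effects ridge regression and
# cognition regressions.

#' Covariate-adjusted two-group permutation test (Freedman-Lane)
#'
#' The outcome is regressed on the covariates alone; the residuals are
#' permuted, added back to the covariate fit, and the covariate-adjusted
#' group t-statistic is recomputed for each permutation. Two-sided p-value
#' with the add-one correction.
#'
#' @param y numeric outcome.
#' @param group two-level factor (or coercible).
#' @param covariates data.frame of nuisance covariates, or NULL.
#' @param n_perm number of permutations.
#' @param seed integer seed (mandatory for reproducibility).
#' @return list with \code{statistic} (observed group t),
#'   \code{p_value}, \code{n_perm}.
#' @export
permutation_group_test <- function(y, group, covariates = NULL,
                                   n_perm = 10000, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  if (n_perm < 100) warning("fewer than 100 permutations is unreliable")
  group <- droplevels(factor(group))
  if (nlevels(group) != 2) stop("group must have exactly 2 levels")
  n <- length(y)
  if (var(y) == 0)
    return(list(statistic = 0, p_value = 1, n_perm = n_perm))
  Z <- if (is.null(covariates)) matrix(1, n, 1) else
    model.matrix(~ ., data = as.data.frame(covariates))
  if (qr(Z)$rank < ncol(Z)) stop("covariate matrix not full rank")
  g <- as.numeric(group == levels(group)[2])
  X <- cbind(Z, g = g)
  qx <- qr(X)
  p <- ncol(X)
  xtxinv_g <- chol2inv(qr.R(qx))[p, p]
  tstat <- function(Y) {   # Y: n x k matrix of outcomes
    cf <- qr.coef(qx, Y)
    res <- Y - X %*% cf
    s2 <- colSums(res^2) / (n - p)
    cf[p, ] / sqrt(s2 * xtxinv_g)
  }
  t_obs <- tstat(cbind(y))[1]
  # reduced model: covariates only
  qz <- qr(Z)
  fit0 <- qr.fitted(qz, y)
  res0 <- y - fit0
  perms <- replicate(n_perm, sample.int(n))
  Ystar <- fit0 + matrix(res0[perms], n, n_perm)
  t_null <- tstat(Ystar)
  p_val <- (1 + sum(abs(t_null) >= abs(t_obs))) / (n_perm + 1)
  list(statistic = unname(t_obs), p_value = p_val, n_perm = n_perm)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' @param p raw p-values in \[0, 1\].
#' @param q target FDR level.
#' @return list with \code{adjusted} p-values and logical \code{rejected}.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  adj <- p.adjust(p, method = "BH")
  list(adjusted = adj, rejected = !is.na(adj) & adj <= q)
}

#' Mixed-effects ridge regression with subject random intercepts
#'
#' Long-format model \eqn{y = X\beta + b_{subject} + \epsilon} with the
#' fixed effects L2-penalized and the subject intercepts estimated by
#' closed-form shrinkage, alternating until convergence. Continuous
#' predictors are standardized internally. Per-coefficient significance by
#' permuting the predictor of interest within subject.
#'
#' @param data data.frame in long format (one row per subject x unit).
#' @param outcome name of the outcome column.
#' @param predictors names of the focal predictor columns (standardized).
#' @param covariates names of covariate columns (continuous ones
#'   standardized; factors expanded).
#' @param subject name of the subject id column.
#' @param penalty ridge penalty; \code{NULL} selects it by generalized
#'   cross-validation over a log grid.
#' @param n_perm permutations per focal predictor (0 skips testing).
#' @param seed integer seed.
#' @return list of class \code{ridge_mixed} with \code{betas} (all fixed
#'   effects), \code{p_values} (focal predictors), \code{penalty},
#'   \code{intercept_variance}, \code{residual_variance}.
#' @export
ridge_mixed_fit <- function(data, outcome, predictors, covariates = NULL,
                            subject = "subject", penalty = NULL,
                            n_perm = 1000, seed = 1) {
  set.seed(seed)
  y <- data[[outcome]]
  sub <- factor(data[[subject]])
  std <- function(x) if (is.numeric(x)) zscore(x) else x
  Xd <- as.data.frame(lapply(data[, c(predictors, covariates), drop = FALSE],
                             std))
  X <- model.matrix(~ ., data = Xd)[, -1, drop = FALSE]
  if (qr(X)$rank < ncol(X)) stop("singular design after standardization")
  n <- nrow(X)

  solve_ridge <- function(Xm, yv, lam) {
    XtX <- crossprod(Xm) + diag(lam, ncol(Xm))
    drop(solve(XtX, crossprod(Xm, yv)))
  }
  backfit <- function(yv, lam, Xm = X) {
    b <- rep(0, nlevels(sub))
    names(b) <- levels(sub)
    mu <- mean(yv)
    for (iter in 1:200) {
      beta <- solve_ridge(Xm, yv - mu - b[sub], lam)
      res <- drop(yv - mu - Xm %*% beta)
      s2e <- max(1e-10, mean((res - b[sub])^2))
      bm <- as.vector(tapply(res, sub, mean))
      names(bm) <- levels(sub)
      s2b <- max(0, var(bm) - s2e / mean(table(sub)))
      ns <- as.vector(table(sub))
      shrink <- (ns * s2b) / (ns * s2b + s2e)
      b_new <- shrink * bm
      if (max(abs(b_new - b)) < 1e-8) {
        b <- b_new
        break
      }
      b <- b_new
    }
    list(beta = stats::setNames(drop(beta), colnames(Xm)), b = b, mu = mu,
         s2b = s2b, s2e = s2e)
  }

  if (is.null(penalty)) {
    grid <- 10^seq(-3, 3, length.out = 13)
    gcv <- vapply(grid, function(lam) {
      f <- backfit(y, lam)
      H_tr <- sum(diag(solve(crossprod(X) + diag(lam, ncol(X)),
                             crossprod(X))))
      resid <- y - f$mu - X %*% f$beta - f$b[sub]
      n * sum(resid^2) / (n - H_tr)^2
    }, numeric(1))
    penalty <- grid[which.min(gcv)]
  }
  fit <- backfit(y, penalty)

  p_values <- NULL
  if (n_perm > 0) {
    p_values <- vapply(predictors, function(pr) {
      cols <- grep(paste0("^", pr), colnames(X))
      obs <- sqrt(sum(fit$beta[cols]^2))
      null <- replicate(n_perm, {
        Xp <- X
        for (s in levels(sub)) {
          rows <- which(sub == s)
          Xp[rows, cols] <- Xp[rows[sample.int(length(rows))], cols]
        }
        f <- backfit(y, penalty, Xm = Xp)
        sqrt(sum(f$beta[cols]^2))
      })
      (1 + sum(null >= obs)) / (n_perm + 1)
    }, numeric(1))
  }
  structure(list(betas = fit$beta, p_values = p_values, penalty = penalty,
                 intercept_variance = fit$s2b,
                 residual_variance = fit$s2e,
                 random_intercepts = fit$b),
            class = "ridge_mixed")
}

#' Predict cognition from network trophic levels
#'
#' One multiple linear regression per (score, network) pair with the
#' requested covariates; the network-level coefficient p-values are
#' FDR-corrected across the whole family.
#'
#' @param scores data.frame of cognitive scores (one column per test).
#' @param network_levels data.frame/matrix of per-network trophic levels
#'   (one column per network), aligned by row with \code{scores}.
#' @param covariates data.frame of covariates (age, gender, education,
#'   APOE status), aligned by row.
#' @param q FDR level.
#' @return data.frame with columns \code{score}, \code{network},
#'   \code{beta}, \code{p}, \code{p_adj}, \code{significant},
#'   \code{n_used}.
#' @export
cognition_regression <- function(scores, network_levels, covariates,
                                 q = 0.05) {
  scores <- as.data.frame(scores)
  network_levels <- as.data.frame(network_levels)
  covariates <- as.data.frame(covariates)
  out <- do.call(rbind, lapply(names(scores), function(sc) {
    do.call(rbind, lapply(names(network_levels), function(nw) {
      df <- data.frame(y = scores[[sc]], x = network_levels[[nw]],
                       covariates)
      cc <- complete.cases(df)
      df <- df[cc, ]
      if (nrow(df) <= ncol(df) + 1)
        stop("fewer observations than parameters for ", sc, " ~ ", nw)
      fit <- lm(y ~ ., data = df)
      sm <- summary(fit)$coefficients
      data.frame(score = sc, network = nw, beta = sm["x", "Estimate"],
                 p = sm["x", "Pr(>|t|)"], n_used = nrow(df))
    }))
  }))
  adj <- fdr_bh(out$p, q)
  out$p_adj <- adj$adjusted
  out$significant <- adj$rejected
  rownames(out) <- NULL
  out
}
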