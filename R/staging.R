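# Binary disease-staging classifier: mRMR feature selection, logistic
# regression with nested leave-one-out grid search, Monte Carlo outer
# splits, Youden-threshold decisions, permutation significance, vertical
# ROC averaging and linear Shapley feature importance.

#' Classifier configuration
#'
#' @param nf_grid candidate numbers of selected features.
#' @param c_grid inverse regularization strengths (larger = weaker
#'   penalty); mapped to glmnet's lambda as \code{1 / (n C)}.
#' @param penalty_grid subset of \code{c("l1", "l2")}.
#' @param n_monte_carlo outer train/test splits.
#' @param train_fraction training proportion per split.
#' @param n_label_perms test-label permutations per split.
#' @param seed integer seed.
#' @return list of class \code{classifier_config}.
#' @export
classifier_config <- function(nf_grid = 5:15,
                              c_grid = c(0.01, 0.1, 1, 5, 10, 50, 100,
                                         500, 1000),
                              penalty_grid = c("l1", "l2"),
                              n_monte_carlo = 20, train_fraction = 0.75,
                              n_label_perms = 1000, seed = 1) {
  if (!length(nf_grid) || !length(c_grid) || !length(penalty_grid))
    stop("empty hyperparameter grid")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  structure(as.list(environment()), class = "classifier_config")
}

# Rank-based (Mann-Whitney) area under the ROC curve.
auc_rank <- function(probs, y) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probs)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Minimum-redundancy maximum-relevance feature ranking (FCQ)
#'
#' Greedy selection maximizing the quotient of class relevance (one-way
#' ANOVA F statistic) to redundancy (mean absolute Pearson correlation
#' with already-selected features). The greedy order is nested, so the
#' first \code{k} entries are the size-\code{k} selection.
#'
#' @param X samples x features matrix.
#' @param y binary labels.
#' @param k number of features to select.
#' @return integer vector of selected column indices, in selection order.
#' @export
mrmr_select <- function(X, y, k) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (k > p) stop("k exceeds the number of features")
  if (any(apply(X, 2, sd) == 0)) stop("constant feature(s)")
  y <- as.numeric(factor(y)) - 1
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  m1 <- colMeans(X[y == 1, , drop = FALSE])
  m0 <- colMeans(X[y == 0, , drop = FALSE])
  mall <- colMeans(X)
  ssb <- n1 * (m1 - mall)^2 + n0 * (m0 - mall)^2
  ssw <- colSums((X - matrix(ifelse(y == 1, 1, 0)) %*% t(m1) -
                    matrix(ifelse(y == 0, 1, 0)) %*% t(m0))^2)
  relevance <- (ssb / 1) / (ssw / (length(y) - 2))
  R <- abs(cor(X))
  selected <- which.max(relevance)
  while (length(selected) < k) {
    cand <- setdiff(seq_len(p), selected)
    red <- rowMeans(R[cand, selected, drop = FALSE])
    score <- relevance[cand] / pmax(red, 1e-12)
    selected <- c(selected, cand[which.max(score)])
  }
  unname(selected)
}

# Fit logistic models along the whole C grid in a single glmnet path and
# return predicted probabilities for new data: rows = newdata, cols = C.
glmnet_path_probs <- function(X, y, penalty, c_grid, newx) {
  lam <- sort(1 / (nrow(X) * c_grid), decreasing = TRUE)
  ord <- order(1 / (nrow(X) * c_grid), decreasing = TRUE)  # map back to C order
  # glmnet warns about small class counts on LOOCV folds; expected here
  fit <- suppressWarnings(
    glmnet::glmnet(X, y, family = "binomial",
                   alpha = if (penalty == "l1") 1 else 0,
                   lambda = lam, standardize = TRUE))
  pr <- predict(fit, newx = newx, s = lam, type = "response")
  out <- matrix(NA_real_, nrow(newx), length(c_grid))
  out[, ord] <- pr
  out
}

#' Nested leave-one-out grid search over (NF, C, penalty)
#'
#' For every left-out training sample, mRMR ranking is recomputed on the
#' remaining samples (no leakage); out-of-fold probabilities are pooled
#' into one ROC-AUC per grid cell and the cell with the highest AUC wins.
#' Ties prefer fewer features, then stronger regularization (smaller C),
#' then the L2 penalty.
#'
#' @param X training samples x features matrix.
#' @param y binary training labels (0/1 or two-level factor).
#' @param cfg [classifier_config()].
#' @return list with \code{nf}, \code{c}, \code{penalty}, \code{auc}, and
#'   the full \code{auc_grid} array.
#' @export
loocv_grid_search <- function(X, y, cfg = classifier_config()) {
  X <- as.matrix(X)
  y <- as.numeric(factor(y)) - 1
  if (min(table(y)) < 2) stop("need >= 2 samples per class")
  M <- nrow(X)
  nf_grid <- cfg$nf_grid[cfg$nf_grid <= ncol(X)]
  if (!length(nf_grid)) stop("all NF values exceed the feature count")
  kmax <- max(nf_grid)
  probs <- array(NA_real_,
                 c(M, length(nf_grid), length(cfg$penalty_grid),
                   length(cfg$c_grid)))
  for (m in seq_len(M)) {
    Xi <- X[-m, , drop = FALSE]; yi <- y[-m]
    if (length(unique(yi)) < 2) next
    ranking <- mrmr_select(Xi, yi, kmax)
    for (fi in seq_along(nf_grid)) {
      sel <- ranking[seq_len(nf_grid[fi])]
      for (pi in seq_along(cfg$penalty_grid)) {
        pr <- try(glmnet_path_probs(Xi[, sel, drop = FALSE], yi,
                                    cfg$penalty_grid[pi], cfg$c_grid,
                                    X[m, sel, drop = FALSE]),
                  silent = TRUE)
        if (!inherits(pr, "try-error")) probs[m, fi, pi, ] <- pr
      }
    }
  }
  auc_grid <- apply(probs, c(2, 3, 4), function(pv) {
    ok <- !is.na(pv)
    if (sum(ok) < M) return(NA_real_)
    auc_rank(pv, y)
  })
  if (all(is.na(auc_grid))) stop("no grid cell produced valid probabilities")
  best <- which(auc_grid == max(auc_grid, na.rm = TRUE), arr.ind = TRUE)
  # tie-breaks: smallest NF, then smallest C, then l2 over l1
  pen_pref <- match(cfg$penalty_grid[best[, 2]], c("l2", "l1"))
  best <- best[order(best[, 1], best[, 3], pen_pref), , drop = FALSE][1, ]
  list(nf = nf_grid[best[1]], penalty = cfg$penalty_grid[best[2]],
       c = cfg$c_grid[best[3]],
       auc = auc_grid[best[1], best[2], best[3]],
       auc_grid = auc_grid)
}

#' Decision threshold maximizing Youden's J
#'
#' \eqn{J = sensitivity + specificity - 1}, maximized over the observed
#' probabilities; ties resolved to the lowest threshold.
#'
#' @param probs predicted positive-class probabilities.
#' @param y binary labels with both classes present.
#' @return scalar threshold (classify positive when \code{prob >= thr}).
#' @export
youden_threshold <- function(probs, y) {
  y <- as.numeric(factor(y)) - 1
  if (length(unique(y)) < 2) stop("need both classes")
  thr <- sort(unique(probs))
  j <- vapply(thr, function(t) {
    pred <- as.numeric(probs >= t)
    sens <- sum(pred == 1 & y == 1) / sum(y == 1)
    spec <- sum(pred == 0 & y == 0) / sum(y == 0)
    sens + spec - 1
  }, numeric(1))
  thr[which(j == max(j))[1]]   # thresholds sorted: first max = lowest
}

#' Exact Shapley values of a linear (logit-scale) model
#'
#' Under feature independence the Shapley value of feature j for sample x
#' is \eqn{\phi_j = w_j (x_j - \bar{x}_j)} with the background mean taken
#' from the training data; contributions sum to the deviation of the
#' sample's logit from the background-mean logit.
#'
#' @param weights named coefficient vector (selected features only).
#' @param X samples x features matrix to explain (all features).
#' @param background training matrix supplying feature means.
#' @param selected indices of the selected features (others get 0).
#' @return samples x all-features matrix of Shapley values.
#' @export
linear_shap <- function(weights, X, background, selected) {
  X <- as.matrix(X)
  phi <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  mu <- colMeans(as.matrix(background)[, selected, drop = FALSE])
  phi[, selected] <- sweep(X[, selected, drop = FALSE], 2, mu) %*%
    diag(weights, length(weights))
  phi
}

# One train/test evaluation; returns metrics, ROC points, confusion
# proportions, SHAP means and the permutation p-value.
evaluate_split <- function(X, y, train_idx, cfg) {
  Xtr <- X[train_idx, , drop = FALSE]; ytr <- y[train_idx]
  Xte <- X[-train_idx, , drop = FALSE]; yte <- y[-train_idx]
  hp <- loocv_grid_search(Xtr, ytr, cfg)
  sel <- mrmr_select(Xtr, ytr, hp$nf)
  fit <- suppressWarnings(
    glmnet::glmnet(Xtr[, sel, drop = FALSE], ytr, family = "binomial",
                   alpha = if (hp$penalty == "l1") 1 else 0,
                   lambda = 1 / (nrow(Xtr) * hp$c), standardize = TRUE))
  p_tr <- drop(predict(fit, Xtr[, sel, drop = FALSE], type = "response"))
  thr <- youden_threshold(p_tr, ytr)
  p_te <- drop(predict(fit, Xte[, sel, drop = FALSE], type = "response"))
  pred <- as.numeric(p_te >= thr)

  bal_acc <- function(truth, prd) {
    mean(c(mean(prd[truth == 1] == 1), mean(prd[truth == 0] == 0)))
  }
  sens <- mean(pred[yte == 1] == 1)
  spec <- mean(pred[yte == 0] == 0)
  f1 <- {
    tp <- sum(pred == 1 & yte == 1)
    fp <- sum(pred == 1 & yte == 0)
    fn <- sum(pred == 0 & yte == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  obs_acc <- bal_acc(yte, pred)
  null_acc <- replicate(cfg$n_label_perms,
                        bal_acc(sample(yte), pred))
  p_perm <- (1 + sum(null_acc >= obs_acc)) / (cfg$n_label_perms + 1)

  # ROC by thresholding test probabilities; TPR interpolated on FPR grid
  ord <- order(p_te, decreasing = TRUE)
  tpr <- cumsum(yte[ord] == 1) / max(1, sum(yte == 1))
  fpr <- cumsum(yte[ord] == 0) / max(1, sum(yte == 0))
  fpr_grid <- seq(0, 1, by = 0.01)
  tpr_grid <- vapply(fpr_grid,
                     function(f) max(0, tpr[fpr <= f], na.rm = TRUE),
                     numeric(1))
  conf <- prop.table(table(factor(yte, levels = 0:1),
                           factor(pred, levels = 0:1)), margin = 1)

  w <- drop(coef(fit))[-1]
  phi <- linear_shap(w, Xte, Xtr, sel)
  list(metrics = c(balanced_accuracy = obs_acc,
                   auc = auc_rank(p_te, yte),
                   sensitivity = sens, specificity = spec, f1 = f1),
       p_perm = p_perm, tpr_grid = tpr_grid, confusion = conf,
       shap = colMeans(abs(phi)), hyper = hp[c("nf", "c", "penalty")],
       threshold = thr)
}

#' Monte Carlo evaluation of the staging classifier
#'
#' Repeats the full pipeline (stratified 75/25 split, nested LOOCV grid
#' search, refit, training-set Youden threshold, test evaluation,
#' test-label permutation test) over \code{cfg$n_monte_carlo} splits and
#' aggregates: mean and SD of the test metrics, median and IQR of the
#' permutation p-values, vertically averaged ROC curve, averaged
#' confusion proportions, and mean absolute Shapley importance (zero for
#' features never selected in an iteration).
#'
#' @param X samples x features matrix.
#' @param y binary labels.
#' @param cfg [classifier_config()].
#' @return list of class \code{classifier_report}.
#' @export
monte_carlo_evaluate <- function(X, y, cfg = classifier_config()) {
  X <- as.matrix(X)
  y <- as.numeric(factor(y)) - 1
  set.seed(cfg$seed)
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  n_tr1 <- round(length(idx1) * cfg$train_fraction)
  n_tr0 <- round(length(idx0) * cfg$train_fraction)
  if (n_tr1 < 2 || n_tr0 < 2 ||
      n_tr1 >= length(idx1) || n_tr0 >= length(idx0))
    stop("not enough samples for a stratified split with both classes")
  iters <- vector("list", cfg$n_monte_carlo)
  failures <- 0L
  for (b in seq_len(cfg$n_monte_carlo)) {
    train_idx <- c(sample(idx1, n_tr1), sample(idx0, n_tr0))
    res <- try(evaluate_split(X, y, train_idx, cfg), silent = TRUE)
    if (inherits(res, "try-error")) {
      failures <- failures + 1L
      next
    }
    iters[[b]] <- res
  }
  iters <- Filter(Negate(is.null), iters)
  if (!length(iters)) stop("every Monte Carlo iteration failed")
  M <- do.call(rbind, lapply(iters, `[[`, "metrics"))
  pvals <- vapply(iters, `[[`, numeric(1), "p_perm")
  roc <- colMeans(do.call(rbind, lapply(iters, `[[`, "tpr_grid")))
  conf <- Reduce(`+`, lapply(iters, `[[`, "confusion")) / length(iters)
  shap <- colMeans(do.call(rbind, lapply(iters, `[[`, "shap")))
  structure(list(metrics_mean = colMeans(M),
                 metrics_sd = apply(M, 2, sd),
                 metrics_by_iteration = as.data.frame(M),
                 perm_p_median = median(pvals),
                 perm_p_iqr = unname(quantile(pvals, c(0.25, 0.75))),
                 roc = data.frame(fpr = seq(0, 1, by = 0.01), tpr = roc),
                 confusion = conf, shap_importance = shap,
                 hyperparameters = lapply(iters, `[[`, "hyper"),
                 n_failed = failures),
            class = "classifier_report")
}
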