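# Generative effective connectivity (GEC) estimation.
#
# The anatomical connection strengths are fine-tuned by a heuristic
# pseudo-gradient so that the linearized Hopf model reproduces (i) the
# empirical functional connectivity and (ii) the forward-minus-reversed
# lagged correlation difference, the signature of time-reversal asymmetry
# that carries the directionality information:
#   C_ij <- C_ij + alpha (FC_emp - FC_mod)_ij
#               + varsigma [(FSf_emp - FSr_emp) - (FSf_mod - FSr_mod)]_ij
# restricted to anatomically existing connections and clipped at zero.

#' Fit configuration for the GEC pseudo-gradient
#'
#' @param alpha FC learning rate.
#' @param varsigma non-reversibility learning rate.
#' @param tau_trs lag in TR units for the shifted correlations.
#' @param max_iter iteration cap.
#' @param tol minimum improvement of the combined error counted as progress.
#' @param patience iterations without improvement before stopping.
#' @param nonneg clip the coupling at zero after each update.
#' @param momentum optional heavy-ball momentum on the pseudo-gradient
#'   velocity (0 = plain update, the default). Momentum can traverse the
#'   shallow plateaus cold-started fits encounter on frequency-
#'   heterogeneous systems, but makes warm-started fits stall, so it is
#'   off unless requested.
#' @return list of class \code{fit_config}.
#' @export
fit_config <- function(alpha = 5e-3, varsigma = 2.5e-3, tau_trs = 1L,
                       max_iter = 5000L, tol = 1e-7, patience = 100L,
                       nonneg = TRUE, momentum = 0) {
  if (alpha < 0 || varsigma < 0) stop("learning rates must be >= 0")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  structure(as.list(environment()), class = "fit_config")
}

#' Empirical functional connectivity
#'
#' Pearson correlation matrix of the regional time series.
#'
#' @param ts regions x timepoints matrix.
#' @return symmetric N x N correlation matrix with unit diagonal.
#' @export
empirical_fc <- function(ts) {
  if (!is.matrix(ts)) ts <- as.matrix(ts)
  if (ncol(ts) < 2) stop("need at least 2 timepoints")
  v <- apply(ts, 1, var)
  if (any(v == 0)) stop("constant channel(s): ",
                        paste(which(v == 0), collapse = ", "))
  cor(t(ts))
}

#' Empirical lagged (time-shifted) correlation
#'
#' \eqn{FS_{ij} = cov(x_i(t), x_j(t+\tau)) / \sqrt{var_i \, var_j}}; entry
#' (i, j) is large when region i leads region j. With \code{reversed=TRUE}
#' the series is flipped in time first, which for any series equals the
#' transpose of the forward estimator.
#'
#' @param ts regions x timepoints matrix.
#' @param tau_trs nonnegative integer lag in samples.
#' @param reversed estimate on the time-reversed series.
#' @return N x N matrix of lagged correlations.
#' @export
empirical_shifted_correlation <- function(ts, tau_trs = 1L, reversed = FALSE) {
  if (!is.matrix(ts)) ts <- as.matrix(ts)
  T_len <- ncol(ts)
  if (T_len <= tau_trs + 2) stop("lag exhausts the series")
  if (reversed) ts <- ts[, T_len:1, drop = FALSE]
  x <- sweep(ts, 1, rowMeans(ts))
  v <- rowSums(x^2) / (T_len - 1)
  if (any(v == 0)) stop("constant channel(s)")
  if (tau_trs == 0) {
    K <- tcrossprod(x) / (T_len - 1)
  } else {
    early <- x[, 1:(T_len - tau_trs), drop = FALSE]
    late <- x[, (1 + tau_trs):T_len, drop = FALSE]
    K <- tcrossprod(early, late) / (T_len - tau_trs - 1)
  }
  s <- sqrt(v)
  K / outer(s, s)
}

#' Empirical statistics bundle for one subject
#'
#' @param ts regions x timepoints matrix.
#' @param tau_trs lag in TR units.
#' @return list with \code{fc}, \code{fs_forward}, \code{fs_reversal}.
#' @export
empirical_stats <- function(ts, tau_trs = 1L) {
  list(fc = empirical_fc(ts),
       fs_forward = empirical_shifted_correlation(ts, tau_trs),
       fs_reversal = empirical_shifted_correlation(ts, tau_trs,
                                                   reversed = TRUE))
}

# Combined fitting error: FC correlation distance plus the mean squared
# error of the forward-minus-reversed asymmetry difference.
gec_error <- function(stats, mod) {
  off <- upper.tri(stats$fc) | lower.tri(stats$fc)
  e_fc <- 0.5 * (1 - cor(stats$fc[off], mod$fc[off]))
  d_emp <- stats$fs_forward - stats$fs_reversal
  d_mod <- mod$fs_forward - mod$fs_reversal
  e_fs <- 0.5 * mean((d_emp - d_mod)^2)
  c(total = e_fc + e_fs, fc = e_fc, fs = e_fs)
}

#' Fit a generative effective connectivity matrix
#'
#' Iterates: linearized-model statistics from the current coupling,
#' pseudo-gradient update on anatomically allowed entries, nonnegativity
#' clip, stability re-check (with step halving on instability). Stops when
#' the best combined error has not improved by \code{tol} for
#' \code{patience} iterations, or at \code{max_iter}; the best-error
#' coupling is returned.
#'
#' @param stats [empirical_stats()] bundle (or analytic target statistics).
#' @param sc_mask structural mask; entries equal to zero are never updated.
#' @param params [hopf_params()] for the model side.
#' @param cfg [fit_config()].
#' @param init initial coupling; defaults to the mask normalized to a
#'   maximum weight of 0.2.
#' @param tau_seconds model lag in seconds; defaults to
#'   \code{cfg$tau_trs * 3}.
#' @return list of class \code{gec_result} with \code{coupling},
#'   \code{fit_trace} (iteration, total/fc/fs errors), \code{converged},
#'   \code{n_iter}.
#' @export
fit_gec <- function(stats, sc_mask, params, cfg = fit_config(), init = NULL,
                    tau_seconds = cfg$tau_trs * 3) {
  if (any(!is.finite(stats$fc)) || any(!is.finite(stats$fs_forward)))
    stop("non-finite empirical statistics")
  mask <- check_coupling(sc_mask) > 0
  n <- nrow(sc_mask)
  if (is.null(init)) {
    init <- sc_mask / max(sc_mask) * 0.2
  }
  C <- init * mask
  if (any(C < 0)) stop("init must be nonnegative")
  mod <- model_statistics(C, params, tau_seconds)
  err <- gec_error(stats, mod)
  best <- list(C = C, err = err)
  trace <- matrix(NA_real_, cfg$max_iter + 1L, 3,
                  dimnames = list(NULL, c("total", "fc", "fs")))
  trace[1, ] <- err
  stall <- 0L
  it <- 0L
  d_emp <- stats$fs_forward - stats$fs_reversal
  vel <- matrix(0, n, n)
  mom <- if (is.null(cfg$momentum)) 0 else cfg$momentum
  while (it < cfg$max_iter) {
    it <- it + 1L
    step <- 1
    ok <- FALSE
    upd <- cfg$alpha * (stats$fc - mod$fc) +
      cfg$varsigma * (d_emp - (mod$fs_forward - mod$fs_reversal))
    vel <- mom * vel + upd
    for (try in 1:10) {
      C_new <- C + step * vel
      if (cfg$nonneg) C_new <- pmax(C_new, 0)
      C_new <- C_new * mask
      diag(C_new) <- 0
      mod_new <- tryCatch(model_statistics(C_new, params, tau_seconds),
                          error = function(e) NULL)
      if (!is.null(mod_new)) {
        ok <- TRUE
        break
      }
      step <- step / 2
    }
    if (!ok) {
      warning("update destabilized the Jacobian and step halving failed; ",
              "stopping at iteration ", it)
      break
    }
    if (step < 1) vel[] <- 0   # reset velocity after a forced halving
    C <- C_new
    mod <- mod_new
    err <- gec_error(stats, mod)
    trace[it + 1L, ] <- err
    if (best$err["total"] - err["total"] > cfg$tol) {
      best <- list(C = C, err = err)
      stall <- 0L
    } else {
      if (err["total"] < best$err["total"]) best <- list(C = C, err = err)
      stall <- stall + 1L
    }
    if (stall >= cfg$patience) break
  }
  structure(list(coupling = best$C,
                 fit_trace = as.data.frame(cbind(iteration = 0:it,
                                                 trace[1:(it + 1L), ,
                                                       drop = FALSE])),
                 converged = stall >= cfg$patience,
                 n_iter = it,
                 error = best$err),
            class = "gec_result")
}

#' Fit a cohort of subjects: group-level first, then per-subject
#'
#' Stage 1 fits the elementwise group-averaged empirical statistics
#' starting from the normalized structural mask; stage 2 fits each subject
#' warm-started from the group GEC. By default the group stage fits the
#' functional connectivity only (\code{group_varsigma = 0}): the shared
#' stage estimates the common anatomical connection strengths, while the
#' time-reversal asymmetry — the quantity that differs between subjects
#' and groups — is learned per subject from a symmetric starting point.
#' Carrying a group-average asymmetry into every subject's
#' initialization biases all subjects toward one directional pattern and
#' suppresses between-group directedness contrasts.
#'
#' @param subject_stats named list of [empirical_stats()] bundles.
#' @param sc_mask structural mask shared across subjects.
#' @param params [hopf_params()].
#' @param cfg [fit_config()].
#' @param tau_seconds model lag in seconds.
#' @param group_varsigma non-reversibility learning rate for the group
#'   stage; set to \code{cfg$varsigma} to propagate the group-average
#'   asymmetry into the warm start.
#' @return list with \code{group} (stage-1 \code{gec_result}) and
#'   \code{subjects} (named list of \code{gec_result}; failed fits carry
#'   the error condition instead).
#' @export
fit_cohort <- function(subject_stats, sc_mask, params, cfg = fit_config(),
                       tau_seconds = cfg$tau_trs * 3, group_varsigma = 0) {
  if (length(subject_stats) < 1) stop("need at least one subject")
  avg <- function(field)
    Reduce(`+`, lapply(subject_stats, `[[`, field)) / length(subject_stats)
  group_stats <- list(fc = avg("fc"), fs_forward = avg("fs_forward"),
                      fs_reversal = avg("fs_reversal"))
  group_cfg <- cfg
  group_cfg$varsigma <- group_varsigma
  group_fit <- fit_gec(group_stats, sc_mask, params, group_cfg,
                       tau_seconds = tau_seconds)
  subjects <- lapply(subject_stats, function(st) {
    tryCatch(fit_gec(st, sc_mask, params, cfg, init = group_fit$coupling,
                     tau_seconds = tau_seconds),
             error = function(e) e)
  })
  failed <- vapply(subjects, inherits, logical(1), "condition")
  if (any(failed))
    warning(sum(failed), " subject fit(s) failed: ",
            paste(names(subjects)[failed], collapse = ", "))
  list(group = group_fit, subjects = subjects)
}
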