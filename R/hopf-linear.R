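# Linearized Hopf (Stuart-Landau) model machinery.
#
# Each region j obeys dz_j = (a_j + i w_j) z_j - |z_j|^2 z_j
#                            + sum_m C[m, j] (z_m - z_j) + noise,
# with a_j < 0 so the origin is a stable fixed point. Linearizing there
# gives a 2N-dimensional Ornstein-Uhlenbeck process in (x, y) components
# with block Jacobian J = [[A, -Omega], [Omega, A]], whose stationary
# covariance solves the continuous Lyapunov equation J K + K J' + Q = 0
# (Q = sigma^2 I), and whose lagged covariance is exp(tau J) K.

#' Hopf model parameters
#'
#' @param a per-region bifurcation parameter (1/s); must be negative for
#'   the linearization at the fixed point to be valid.
#' @param omega per-region angular frequency (rad/s).
#' @param sigma noise amplitude (signal units / sqrt(s)).
#' @return list of class \code{hopf_params}.
#' @export
hopf_params <- function(a, omega, sigma = 0.01) {
  if (length(a) == 1) a <- rep(a, length(omega))
  if (length(omega) == 1) omega <- rep(omega, length(a))
  if (length(a) != length(omega)) stop("a and omega lengths differ")
  if (any(a >= 0)) stop("all bifurcation parameters a must be negative")
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(a = a, omega = omega, sigma = sigma), class = "hopf_params")
}

#' Per-region dominant frequencies from BOLD time series
#'
#' Welch-style averaged periodogram (Hann-windowed segments, 50% overlap);
#' returns the angular frequency of the spectral peak within the requested
#' band for each region. When a list of subject matrices is given, the
#' periodograms are pooled across subjects before peak-picking — regional
#' intrinsic frequencies are far better determined by the group-average
#' spectrum than by a single short scan.
#'
#' @param ts regions x timepoints matrix, or a list of such matrices
#'   (one per subject, same regions in the same order).
#' @param TR sampling interval in seconds.
#' @param band_hz length-2 frequency band in Hz; must sit below Nyquist.
#' @param n_segments number of Welch segments per subject.
#' @return vector of angular frequencies (rad/s), one per region.
#' @export
estimate_node_frequencies <- function(ts, TR, band_hz = c(0.008, 0.08),
                                      n_segments = 4) {
  if (is.list(ts) && !is.data.frame(ts)) {
    T_min <- min(vapply(ts, ncol, integer(1)))
    psum <- NULL
    for (m in ts) {
      p <- node_periodograms(m[, seq_len(T_min), drop = FALSE], n_segments)
      psum <- if (is.null(psum)) p else psum + p
    }
    return(pick_spectral_peaks(psum, T_min, TR, band_hz))
  }
  if (!is.matrix(ts)) ts <- as.matrix(ts)
  T_len <- ncol(ts)
  if (T_len < 64) stop("need at least 64 timepoints for frequency estimation")
  pick_spectral_peaks(node_periodograms(ts, n_segments), T_len, TR, band_hz)
}

# Welch-averaged periodograms: regions x segment-frequencies matrix.
node_periodograms <- function(ts, n_segments = 4) {
  T_len <- ncol(ts)
  if (T_len < 64) stop("need at least 64 timepoints for frequency estimation")
  seg_len <- max(32, floor(T_len / (n_segments / 2 + 0.5)))
  step <- floor(seg_len / 2)
  starts <- seq(1, T_len - seg_len + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))  # Hann
  t(apply(ts, 1, function(x) {
    rowMeans(vapply(starts, function(s) {
      seg <- x[s:(s + seg_len - 1)]
      seg <- (seg - mean(seg)) * win
      Mod(fft(seg))^2
    }, numeric(seg_len)))
  }))
}

pick_spectral_peaks <- function(psd, T_len, TR, band_hz) {
  nyq <- 1 / (2 * TR)
  if (band_hz[2] > nyq || band_hz[1] <= 0)
    stop("band must lie within (0, Nyquist = ", signif(nyq, 4), " Hz)")
  seg_len <- ncol(psd)
  freqs <- (seq_len(seg_len) - 1) / (seg_len * TR)
  in_band <- which(freqs >= band_hz[1] & freqs <= band_hz[2])
  if (!length(in_band)) stop("no Fourier frequency falls inside the band")
  omega <- apply(psd, 1, function(p) {
    i <- in_band[which.max(p[in_band])]
    if (i %in% range(in_band))
      warning("spectral peak at band edge (flat spectrum?)")
    # parabolic interpolation of the log-power peak between bins
    d <- 0
    if (i > 1 && i < seg_len && all(p[(i - 1):(i + 1)] > 0)) {
      lp <- log(p[(i - 1):(i + 1)])
      den <- lp[1] - 2 * lp[2] + lp[3]
      if (den < 0) d <- max(-0.5, min(0.5, 0.5 * (lp[1] - lp[3]) / den))
    }
    2 * pi * (freqs[i] + d / (seg_len * TR))
  })
  unname(omega)
}

#' Jacobian of the linearized Hopf model
#'
#' Block structure \code{[[A, -Omega], [Omega, A]]} with
#' \code{A[n, m] = C[m, n]} for \code{m != n} (influence of m over n enters
#' row n) and \code{A[n, n] = a_n - sum_m C[m, n]}; \code{Omega = diag(omega)}.
#'
#' @param C coupling matrix, \code{C[m, n]} = influence of m over n.
#' @param params a [hopf_params()] object matching \code{ncol(C)}.
#' @param check_stability raise if any eigenvalue real part is nonnegative.
#' @return 2N x 2N Jacobian matrix.
#' @export
build_jacobian <- function(C, params, check_stability = TRUE) {
  C <- check_coupling(C)
  n <- nrow(C)
  if (length(params$a) != n)
    stop("params dimension (", length(params$a), ") != coupling (", n, ")")
  A <- t(C)
  diag(A) <- params$a - colSums(C)
  Om <- diag(params$omega, nrow = n)
  J <- rbind(cbind(A, -Om), cbind(Om, A))
  if (check_stability) {
    ev <- eigen(J, only.values = TRUE)$values
    if (max(Re(ev)) >= 0)
      stop("Jacobian is not stable (max Re eigenvalue = ",
           signif(max(Re(ev)), 4), "); linearization invalid")
  }
  J
}

#' Stationary covariance of a stable linear SDE (Lyapunov solve)
#'
#' Solves \eqn{J K + K J^T + Q = 0} with \eqn{Q = \sigma^2 I} through the
#' eigendecomposition of J; falls back to the Kronecker-product linear
#' system when J is numerically defective.
#'
#' @param J stable square Jacobian.
#' @param sigma noise amplitude (Q = sigma^2 I).
#' @return symmetric positive semi-definite covariance matrix.
#' @export
solve_stationary_covariance <- function(J, sigma) {
  n <- nrow(J)
  Q <- diag(sigma^2, n)
  ed <- eigen(J)
  if (max(Re(ed$values)) >= 0) stop("J is not stable; no stationary covariance")
  kronecker_solve <- function() {
    # exact route for defective or ill-conditioned J:
    # vec(K) = -(I (x) J + J (x) I)^{-1} vec(Q)
    A <- kronecker(diag(n), J) + kronecker(J, diag(n))
    matrix(solve(A, -as.vector(Q)), n, n)
  }
  K <- tryCatch({
    Vi <- solve(ed$vectors)
    Qt <- Vi %*% Q %*% t(Vi)
    Y <- -Qt / outer(ed$values, ed$values, "+")
    Re(ed$vectors %*% Y %*% t(ed$vectors))
  }, error = function(e) kronecker_solve())
  K <- (K + t(K)) / 2
  resid <- max(abs(J %*% K + K %*% t(J) + Q))
  if (resid > 1e-8 * max(abs(Q))) {
    # eigenvector conditioning spoiled the spectral route; use the exact one
    K <- (function(M) (M + t(M)) / 2)(kronecker_solve())
    resid <- max(abs(J %*% K + K %*% t(J) + Q))
    if (resid > 1e-8 * max(abs(Q)))
      stop("Lyapunov residual too large: ", signif(resid, 4))
  }
  K
}

# Matrix exponential via eigendecomposition, with a scaling-and-squaring
# Taylor fallback for defective matrices.
expm_eig <- function(M, eig = NULL) {
  out <- tryCatch({
    ed <- if (is.null(eig)) eigen(M) else eig
    Re(ed$vectors %*% (exp(ed$values) * solve(ed$vectors)))
  }, error = function(e) NULL)
  if (!is.null(out)) return(out)
  s <- max(0, ceiling(log2(max(1, max(abs(M))))) + 4)
  A <- M / 2^s
  E <- diag(nrow(M)) + A
  term <- A
  for (k in 2:16) {
    term <- term %*% A / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

#' Model lagged covariances, forward and time-reversed
#'
#' For the stationary linearized model, the lag-\eqn{\tau} covariance with
#' element (i, j) = cov(x_i(t), x_j(t + tau)) is \eqn{(e^{\tau J} K)^T};
#' this orientation makes entry (i, j) large when region i drives region j,
#' matching the coupling convention \code{C[i, j]} = influence of i over j
#' and the empirical estimator. The time-reversed counterpart of a
#' stationary linear process is exactly the transpose.
#'
#' @param J Jacobian.
#' @param K0 stationary covariance from [solve_stationary_covariance()].
#' @param tau_seconds positive lag in seconds.
#' @return list with \code{KS_forward} and \code{KS_reversal} (2N x 2N).
#' @export
lagged_model_covariance <- function(J, K0, tau_seconds) {
  if (tau_seconds < 0) stop("tau must be nonnegative")
  E <- expm_eig(tau_seconds * J)
  KSf <- t(E %*% K0)
  list(KS_forward = KSf, KS_reversal = t(KSf))
}

#' Normalize a shifted covariance into correlation-like units
#'
#' Divides each pair (i, j) by \eqn{\sqrt{K0_{ii} K0_{jj}}} and restricts
#' to the first N rows/columns (the observed x-components).
#'
#' @param KS 2N x 2N (or N x N) shifted covariance.
#' @param K0 matching zero-lag covariance with strictly positive diagonal.
#' @param n_regions N; defaults to half the dimension of \code{KS}.
#' @return N x N normalized shifted correlation matrix.
#' @export
normalize_shifted <- function(KS, K0, n_regions = nrow(KS) %/% 2) {
  d <- diag(K0)
  if (any(d <= 0)) stop("zero or negative variance on the diagonal of K0")
  idx <- seq_len(n_regions)
  scale <- sqrt(d[idx])
  KS[idx, idx, drop = FALSE] / outer(scale, scale)
}

#' Analytic model functional connectivity and shifted correlations
#'
#' Convenience wrapper: builds the Jacobian, solves the Lyapunov equation
#' and returns the normalized zero-lag (FC) and lag-\eqn{\tau} forward /
#' reversed correlation matrices predicted by the linearized model.
#'
#' @inheritParams build_jacobian
#' @param tau_seconds lag in seconds (typically one TR).
#' @return list with \code{fc}, \code{fs_forward}, \code{fs_reversal}
#'   (all N x N) plus \code{J} and \code{K0}.
#' @export
model_statistics <- function(C, params, tau_seconds) {
  J <- build_jacobian(C, params)
  K0 <- solve_stationary_covariance(J, params$sigma)
  ks <- lagged_model_covariance(J, K0, tau_seconds)
  n <- nrow(C)
  list(fc = normalize_shifted(K0, K0, n),
       fs_forward = normalize_shifted(ks$KS_forward, K0, n),
       fs_reversal = normalize_shifted(ks$KS_reversal, K0, n),
       J = J, K0 = K0)
}
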