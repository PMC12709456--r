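# Trophic-level analysis of directed weighted networks.
#
# A coupling matrix C defines a directed graph where C[m, n] is the influence
# (weight) of node m over n. Trophic levels h order nodes along the global
# direction of flow: they solve the singular linear system
#   Delta h = v,   Delta = diag(u) - C - t(C),   u = d_in + d_out,
#   v = d_out - d_in,
# so sources (net out-flow) sit high and sinks low. Trophic incoherence F0
# measures the weight-normalized squared deviation of each edge's level
# increment from the ideal unit step; directedness = 1 - F0.

#' In/out flow degrees and imbalance of a directed weighted network
#'
#' @param C square nonnegative coupling matrix with zero diagonal;
#'   \code{C[m, n]} is the weight of the edge from \code{m} to \code{n}.
#' @return list with \code{d_in} (column sums), \code{d_out} (row sums),
#'   \code{u = d_in + d_out} and \code{v = d_out - d_in}.
#' @export
flow_degrees <- function(C) {
  C <- check_coupling(C)
  d_in <- colSums(C)
  d_out <- rowSums(C)
  list(d_in = d_in, d_out = d_out, u = d_in + d_out, v = d_out - d_in)
}

#' Trophic levels of a directed weighted network
#'
#' Solves the graph-Laplacian system \eqn{\Delta h = v} with
#' \eqn{\Delta = diag(u) - C - C^T} and \eqn{v = d^{out} - d^{in}} by
#' minimum-norm least squares (the Laplacian is exactly singular on a
#' connected graph), then shifts levels so the lowest node sits at zero.
#' Disconnected graphs are solved and shifted per weakly connected
#' component, with a warning; isolated nodes get level 0.
#'
#' @inheritParams flow_degrees
#' @return numeric vector of min-shifted trophic levels, one per node.
#' @export
trophic_levels <- function(C) {
  C <- check_coupling(C)
  n <- nrow(C)
  if (n < 2) stop("need at least 2 nodes")
  deg <- flow_degrees(C)
  comp <- weak_components(C)
  h <- numeric(n)
  n_comp <- max(comp)
  if (n_comp > 1)
    warning("graph has ", n_comp,
            " weakly connected components; levels solved and shifted per component")
  for (k in seq_len(n_comp)) {
    idx <- which(comp == k)
    if (length(idx) == 1) {  # isolated node
      h[idx] <- 0
      next
    }
    Delta <- diag(deg$u[idx], nrow = length(idx)) - C[idx, idx] - t(C[idx, idx])
    hk <- as.vector(MASS::ginv(Delta) %*% deg$v[idx])
    h[idx] <- hk - min(hk)
  }
  names(h) <- rownames(C)
  h
}

#' Trophic incoherence of a network given its levels
#'
#' \eqn{F_0 = \sum_{edges} w (h_{tail} - h_{head} - 1)^2 / \sum w}: a
#' weight-normalized measure of how far each edge deviates from the ideal
#' one-level drop from tail to head (the orientation whose minimizer solves
#' the Laplacian system with \eqn{v = d^{out} - d^{in}}). Zero on a
#' perfectly layered graph.
#'
#' @inheritParams flow_degrees
#' @param h trophic levels as returned by [trophic_levels()]; recomputed
#'   when missing.
#' @return scalar incoherence, \eqn{\ge 0}.
#' @export
trophic_incoherence <- function(C, h = NULL) {
  C <- check_coupling(C)
  w_tot <- sum(C)
  if (w_tot <= 0) stop("network has zero total weight; incoherence undefined")
  if (is.null(h)) h <- trophic_levels(C)
  # residual per directed edge m -> n: h[m] - h[n] - 1
  res2 <- (outer(h, h, "-") - 1)^2
  sum(C * res2) / w_tot
}

#' Trophic directedness
#'
#' One minus the trophic incoherence: 1 on a perfectly coherent (layered)
#' network, 0 on a fully symmetric one with uniform reciprocal weights.
#'
#' @inheritParams flow_degrees
#' @return scalar directedness, \eqn{\le 1}.
#' @export
directedness <- function(C) {
  1 - trophic_incoherence(C)
}

#' Frobenius asymmetry index
#'
#' Ratio of the Frobenius norm of the antisymmetric component
#' \eqn{K = (A - A^T)/2} to the Frobenius norm of the full matrix:
#' 0 for symmetric, 1 for antisymmetric matrices.
#'
#' @param A nonzero square numeric matrix.
#' @return scalar in \[0, 1\].
#' @export
asymmetry_index <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("A must be a square matrix")
  nf <- sqrt(sum(A^2))
  if (nf == 0) stop("zero matrix: asymmetry undefined")
  K <- (A - t(A)) / 2
  sqrt(sum(K^2)) / nf
}

#' Classify regions into sink / mediator / source regimes
#'
#' Z-scores the (group-mean) regional trophic levels with the population
#' standard deviation, splits the observed z-range into three equal-width
#' intervals and labels the lowest third sinks, the middle mediators and
#' the highest sources. Boundary values go to the lower interval.
#'
#' @param h numeric vector of (group-mean) trophic levels, length >= 3.
#' @return factor with levels \code{sink}, \code{mediator}, \code{source}.
#' @export
classify_regimes <- function(h) {
  if (length(h) < 3) stop("need at least 3 regions")
  lev <- c("sink", "mediator", "source")
  if (sd(h) == 0 || max(h) == min(h)) {
    warning("zero variance in levels; all regions labelled mediator")
    return(factor(rep("mediator", length(h)), levels = lev))
  }
  z <- zscore(h, ddof = 0)
  br <- seq(min(z), max(z), length.out = 4)
  lab <- cut(z, breaks = br, labels = lev, include.lowest = TRUE, right = TRUE)
  stats::setNames(factor(as.character(lab), levels = lev), names(h))
}

#' Average a regional measure within functional networks
#'
#' The mean (not the sum) is used so each region contributes equally and
#' the network value is independent of network size.
#'
#' @param x named or ordered numeric vector of regional values.
#' @param mapping character/factor vector assigning each region to one
#'   network, same length/order as \code{x}.
#' @return named numeric vector of per-network means.
#' @export
network_average <- function(x, mapping) {
  if (length(x) != length(mapping))
    stop("mapping length (", length(mapping), ") != number of regions (",
         length(x), ")")
  if (anyNA(mapping)) {
    bad <- which(is.na(mapping))
    stop("unmapped regions at positions: ", paste(bad, collapse = ", "))
  }
  tapply(x, factor(mapping), mean)
}
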