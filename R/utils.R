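#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cov var sd lm coef pf pt p.adjust rnorm runif quantile
#'   median fft predict model.matrix complete.cases setNames rbinom
#' @importFrom utils read.delim write.table head
NULL

# Validate a coupling / adjacency matrix: square, numeric, nonnegative,
# zero diagonal. Returns the matrix with dimnames preserved.
check_coupling <- function(C, nonneg = TRUE, name = "coupling") {
  if (!is.matrix(C) || !is.numeric(C))
    stop(name, " must be a numeric matrix")
  if (nrow(C) != ncol(C))
    stop(name, " must be square, got ", nrow(C), "x", ncol(C))
  if (any(!is.finite(C)))
    stop(name, " contains non-finite values")
  if (nonneg && any(C < 0))
    stop(name, " must be nonnegative")
  if (any(abs(diag(C)) > 0))
    stop(name, " must have a zero diagonal")
  C
}

# z-score a vector; ddof = 0 uses the population standard deviation.
zscore <- function(x, ddof = 1) {
  mu <- mean(x)
  n <- length(x)
  s <- if (ddof == 0) sqrt(mean((x - mu)^2)) else sd(x)
  if (s == 0) return(rep(0, n))
  (x - mu) / s
}

# Weakly connected component labels of a directed weighted matrix.
weak_components <- function(C) {
  g <- igraph::graph_from_adjacency_matrix((C + t(C)) > 0, mode = "undirected")
  igraph::components(g)$membership
}
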