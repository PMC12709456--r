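# Directed weighted graph descriptors and their relation to trophic levels.

#' Standard graph metrics of a directed weighted network
#'
#' Per region: out/in strength ratio, Fagiolo's directed weighted
#' clustering coefficient, mean shortest-path length to reachable targets,
#' and betweenness centrality. Path-based metrics use edge length
#' \code{1 / weight} so the strongest connections are the shortest routes;
#' unreachable pairs are excluded from the mean path length.
#'
#' @param C coupling matrix (\code{C[m, n]} = weight of edge m -> n).
#' @return data.frame with columns \code{out_in_ratio}, \code{clustering},
#'   \code{mean_path_length}, \code{betweenness}.
#' @export
compute_metrics <- function(C) {
  C <- check_coupling(C)
  n <- nrow(C)
  if (sum(C) == 0) stop("empty graph")
  deg <- flow_degrees(C)
  d_in <- deg$d_in
  ratio <- deg$d_out / ifelse(d_in > 0, d_in, NA)
  if (anyNA(ratio)) {
    warning("region(s) with zero in-strength; out/in ratio uses epsilon")
    eps <- min(C[C > 0]) * 1e-3
    ratio[is.na(ratio)] <- deg$d_out[is.na(ratio)] / eps
  }

  # Fagiolo (2007) directed weighted clustering:
  # CC_i = [W^(1/3) + (W')^(1/3)]^3_ii / (2 [dtot_i (dtot_i - 1) - 2 dbi_i])
  # with binary total degree dtot and bilateral degree dbi.
  W3 <- C^(1/3)
  S <- W3 + t(W3)
  num <- diag(S %*% S %*% S) / 2
  A <- (C > 0) * 1
  dtot <- rowSums(A) + colSums(A)
  dbi <- diag(A %*% A)
  denom <- dtot * (dtot - 1) - 2 * dbi
  clustering <- ifelse(denom > 0, num / denom, 0)

  g <- igraph::graph_from_adjacency_matrix(C, mode = "directed",
                                           weighted = TRUE)
  igraph::E(g)$length <- 1 / igraph::E(g)$weight
  D <- igraph::distances(g, mode = "out", weights = igraph::E(g)$length)
  diag(D) <- NA
  D[!is.finite(D)] <- NA
  mpl <- rowMeans(D, na.rm = TRUE)
  btw <- igraph::betweenness(g, weights = igraph::E(g)$length,
                             directed = TRUE)
  data.frame(out_in_ratio = ratio, clustering = clustering,
             mean_path_length = mpl, betweenness = unname(btw))
}

#' Regress trophic levels on graph metrics
#'
#' Z-scores all variables and fits an ordinary least squares model of the
#' trophic levels on the four metrics jointly; also reports per-metric
#' Pearson correlations.
#'
#' @param h per-region trophic levels.
#' @param metrics data.frame from [compute_metrics()].
#' @return list with \code{coefficients} (named, standardized scale),
#'   \code{p_values}, \code{r} (per-metric Pearson), \code{r_squared},
#'   \code{model} (the lm fit).
#' @export
regress_trophic_on_metrics <- function(h, metrics) {
  if (length(h) < 5) stop("need at least 5 regions")
  if (any(apply(metrics, 2, sd) == 0)) stop("constant metric column")
  Z <- as.data.frame(lapply(metrics, zscore))
  Z$h <- zscore(h)
  X <- as.matrix(Z[, setdiff(names(Z), "h")])
  kappa_x <- kappa(cbind(1, X))
  if (kappa_x > 1e8)
    warning("near-collinear metrics (condition number ",
            format(kappa_x, digits = 3), ")")
  fit <- lm(h ~ ., data = Z)
  sm <- summary(fit)
  list(coefficients = coef(fit)[-1],
       p_values = sm$coefficients[-1, "Pr(>|t|)"],
       r = vapply(as.data.frame(X), function(x) cor(x, Z$h), numeric(1)),
       r_squared = sm$r.squared,
       model = fit)
}
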