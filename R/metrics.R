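#' Proportion of closed triads around a node
#'
#' The local clustering coefficient used throughout the model: the number of
#' connected pairs among a node's neighbors divided by the number of possible
#' pairs. Nodes with fewer than two neighbors have no possible triads and
#' score 0, so the triad term of the utility is evaluated at `x = 0` for
#' them.
#'
#' @param net a [nidm_network].
#' @param i node id.
#' @return A value in `[0, 1]`.
#' @export
local_triad_proportion <- function(net, i) {
  i <- check_node(net, i)
  nb <- which(net$adj[i, ])
  k <- length(nb)
  if (k < 2L) return(0)
  closed <- sum(net$adj[nb, nb]) / 2
  closed / choose(k, 2)
}

#' @rdname local_triad_proportion
#' @return `local_triad_proportions()` returns the vector over all nodes.
#' @export
local_triad_proportions <- function(net) {
  vapply(seq_len(n_nodes(net)), function(i) local_triad_proportion(net, i),
         numeric(1))
}

#' Network-level clustering
#'
#' Mean of the per-node proportions of closed triads ([local_triad_proportion]).
#'
#' @param net a [nidm_network].
#' @export
network_clustering <- function(net) mean(local_triad_proportions(net))

#' Mean degree
#'
#' @param net a nonempty [nidm_network].
#' @return `2 |E| / n`.
#' @export
mean_degree <- function(net) {
  n <- n_nodes(net)
  if (n < 1L) stop("empty network")
  2 * edge_count(net) / n
}

#' Closeness index of a connected network
#'
#' Reversed, normalized mean geodesic distance:
#' `1 - (dbar - 1) / (n - 1)` with `dbar` the average shortest-path length
#' over all unordered node pairs. A complete graph scores 1; longer average
#' distances push the index towards 0.
#'
#' @param net a connected [nidm_network].
#' @export
closeness_index <- function(net) {
  n <- n_nodes(net)
  if (n < 2L) stop("closeness index needs at least two nodes")
  d <- igraph::distances(as_igraph(net))
  if (any(is.infinite(d))) stop("network must be connected")
  dbar <- sum(d[upper.tri(d)]) / choose(n, 2)
  1 - (dbar - 1) / (n - 1)
}

#' Edgewise risk-score correlation (homophily)
#'
#' Pearson correlation of risk-aversion scores across connected node pairs.
#' Each undirected edge contributes both orientations, which makes the
#' statistic symmetric in its margins. With zero score variance on a margin
#' the correlation is undefined and `NA` is returned with a warning rather
#' than a silent 0.
#'
#' @param net a [nidm_network] with at least two edges.
#' @param scores optional score vector; defaults to the scores stored in
#'   `net`.
#' @return Correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
edgewise_risk_correlation <- function(net, scores = net$score) {
  if (length(scores) != n_nodes(net)) stop("scores must cover all nodes")
  if (anyNA(scores)) stop("scores contain NA")
  el <- edge_list(net)
  if (nrow(el) < 2L) stop("need at least two edges")
  a <- c(scores[el[, 1L]], scores[el[, 2L]])
  b <- c(scores[el[, 2L]], scores[el[, 1L]])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("edgewise risk correlation undefined: zero variance on a margin")
    return(NA_real_)
  }
  stats::cor(a, b)
}
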