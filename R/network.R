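#' Simulation network
#'
#' The central state object of a game: an undirected simple graph over nodes
#' `1..n` together with per-node disease state (`"S"`, `"I"`, `"R"`), the
#' infection clock (rounds of infection remaining; positive exactly while a
#' node is infected), the risk-aversion score in `(0, 2)`, and cumulative
#' points. Internally the graph is a logical adjacency matrix, which keeps
#' the many single-tie evaluations of the agent policy cheap; conversion to
#' an [igraph::graph] is available via [as_igraph()].
#'
#' @param n number of nodes.
#' @param edges optional two-column matrix (or data.frame) of node pairs.
#' @param scores optional numeric vector of risk-aversion scores, length `n`.
#' @return An object of class `nidm_network`.
#' @examples
#' net <- nidm_network(4, rbind(c(1, 2), c(2, 3)))
#' mean_degree(net)
#' @export
nidm_network <- function(n, edges = NULL, scores = NULL) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be positive")
  adj <- matrix(FALSE, n, n)
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "integer"
    if (ncol(edges) != 2L) stop("'edges' must have two columns")
    if (any(edges < 1L | edges > n)) stop("edge endpoint outside 1..n")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    adj[edges] <- TRUE
    adj[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  if (is.null(scores)) scores <- rep(NA_real_, n)
  if (length(scores) != n) stop("'scores' must have length n")
  net <- list(
    adj = adj,
    state = rep("S", n),
    clock = integer(n),
    score = as.numeric(scores),
    points = numeric(n)
  )
  class(net) <- "nidm_network"
  net
}

#' @rdname nidm_network
#' @param net a `nidm_network`.
#' @export
n_nodes <- function(net) nrow(net$adj)

#' @rdname nidm_network
#' @export
edge_count <- function(net) sum(net$adj) %/% 2L

#' Edge list of a network
#'
#' @param net a `nidm_network`.
#' @return Integer matrix with columns `from`, `to`, one row per undirected
#'   edge with `from < to`.
#' @export
edge_list <- function(net) {
  idx <- which(net$adj & upper.tri(net$adj), arr.ind = TRUE)
  colnames(idx) <- c("from", "to")
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' @rdname nidm_network
#' @param i a node id.
#' @export
neighbors_of <- function(net, i) which(net$adj[i, ])

#' @rdname nidm_network
#' @export
degrees <- function(net) as.integer(rowSums(net$adj))

has_edge <- function(net, i, j) net$adj[i, j]

add_edge <- function(net, i, j) {
  stopifnot(i != j)
  net$adj[i, j] <- TRUE
  net$adj[j, i] <- TRUE
  net
}

remove_edge <- function(net, i, j) {
  net$adj[i, j] <- FALSE
  net$adj[j, i] <- FALSE
  net
}

check_node <- function(net, i) {
  if (!is.numeric(i) || length(i) != 1L || is.na(i) ||
      i < 1L || i > n_nodes(net))
    stop("unknown node id: ", i)
  as.integer(i)
}

#' Convert a simulation network to igraph
#'
#' Disease state, infection clock, risk score and cumulative points are
#' carried over as vertex attributes.
#'
#' @param net a `nidm_network`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(net$adj, mode = "undirected")
  igraph::V(g)$state <- net$state
  igraph::V(g)$clock <- net$clock
  igraph::V(g)$score <- net$score
  igraph::V(g)$points <- net$points
  g
}

#' @export
print.nidm_network <- function(x, ...) {
  tab <- table(factor(x$state, levels = c("S", "I", "R")))
  cat(sprintf("<nidm_network> %d nodes, %d edges | S=%d I=%d R=%d\n",
              n_nodes(x), edge_count(x), tab[["S"]], tab[["I"]], tab[["R"]]))
  if (!all(is.na(x$score)))
    cat(sprintf("  risk scores: mean %.3f, range [%.3f, %.3f]\n",
                mean(x$score), min(x$score), max(x$score)))
  invisible(x)
}

# Structural sanity used by tests and the runner.
validate_network <- function(net) {
  adj <- net$adj
  if (!isSymmetric(unname(adj))) stop("adjacency must be symmetric")
  if (any(diag(adj))) stop("self-loops are not allowed")
  if (!all(net$state %in% c("S", "I", "R"))) stop("invalid disease state")
  if (any((net$clock > 0L) != (net$state == "I")))
    stop("infection clock must be positive exactly for infected nodes")
  invisible(net)
}
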