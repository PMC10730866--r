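#' Per-round infection probability
#'
#' Probability for a susceptible node with `k` infectious neighbors to get
#' infected in one round: `1 - (1 - gamma)^k`. With the default
#' `gamma = 0.15` a single infectious neighbor implies a 15% risk.
#'
#' @param k number of infectious neighbors (nonnegative integer).
#' @param p a [nidm_params] object.
#' @return Probability in `[0, 1]`.
#' @export
infection_probability <- function(k, p = nidm_params()) {
  if (any(k < 0)) stop("'k' must be nonnegative")
  1 - (1 - p$gamma)^k
}

# number of infectious neighbors per node
infected_neighbor_counts <- function(net) {
  inf <- net$state == "I"
  if (!any(inf)) return(integer(n_nodes(net)))
  as.integer(net$adj %*% inf)
}

# Bernoulli draw of new infections from the current infectious set;
# does not modify the network.
draw_infections <- function(net, p) {
  sus <- which(net$state == "S")
  if (length(sus) == 0L) return(integer(0))
  k <- infected_neighbor_counts(net)[sus]
  at_risk <- sus[k > 0L]
  if (length(at_risk) == 0L) return(integer(0))
  pr <- infection_probability(infected_neighbor_counts(net)[at_risk], p)
  at_risk[stats::runif(length(at_risk)) < pr]
}

infect_nodes <- function(net, ids, p) {
  if (length(ids)) {
    net$state[ids] <- "I"
    net$clock[ids] <- p$tau
  }
  net
}

#' Disease transmission step
#'
#' Each susceptible node independently becomes infected with probability
#' [infection_probability()] of its current count of infectious neighbors.
#' Newly infected nodes receive an infection clock of `tau` rounds; their
#' penalty and infectiousness take effect from the next round. Uses the
#' global RNG; seed before calling for reproducibility.
#'
#' @param net a [nidm_network].
#' @param p a [nidm_params] object.
#' @return A list with the updated `net` and the integer vector `infected`
#'   of newly infected node ids.
#' @export
transmission_step <- function(net, p = nidm_params()) {
  new_inf <- draw_infections(net, p)
  list(net = infect_nodes(net, new_inf, p), infected = new_inf)
}

#' Recovery step
#'
#' Decrements the infection clock of every infected node; nodes whose clock
#' reaches zero recover permanently (state `"R"`), never to be infected
#' again.
#'
#' @param net a [nidm_network].
#' @param p a [nidm_params] object (unused fields tolerated).
#' @return A list with the updated `net` and the integer vector `recovered`.
#' @export
recovery_step <- function(net, p = nidm_params()) {
  inf <- which(net$state == "I")
  net$clock[inf] <- net$clock[inf] - 1L
  rec <- inf[net$clock[inf] <= 0L]
  if (length(rec)) {
    net$state[rec] <- "R"
    net$clock[rec] <- 0L
  }
  list(net = net, recovered = rec)
}

# Full stage 4 of a round. Ordering: the transmission draw sees the round's
# infectious set, then clocks are decremented (a node in its last infected
# round is still infectious this round), then the new infections take
# effect. A node infected at the end of round k is therefore in state I
# during rounds k+1 .. k+tau and recovered from round k+tau+1.
stage4_step <- function(net, p) {
  new_inf <- draw_infections(net, p)
  stepped <- recovery_step(net, p)
  net <- infect_nodes(stepped$net, new_inf, p)
  list(net = net, infected = new_inf, recovered = stepped$recovered)
}

#' Select the index case
#'
#' The initially infected node is the most average node: the one minimizing
#' the sum of absolute z-scores of degree, local clustering coefficient and
#' risk-aversion score. A quantity without variance contributes nothing;
#' ties break to the lowest node id.
#'
#' @param net a [nidm_network].
#' @param scores risk-aversion scores (defaults to those stored in `net`).
#' @return A node id.
#' @export
select_index_case <- function(net, scores = net$score) {
  n <- n_nodes(net)
  if (n < 1L) stop("empty network")
  if (length(scores) != n || anyNA(scores)) stop("scores must cover all nodes")
  zs <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  crit <- abs(zs(degrees(net))) + abs(zs(local_triad_proportions(net))) +
    abs(zs(scores))
  which.min(crit) # which.min takes the first (lowest id) among ties
}
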