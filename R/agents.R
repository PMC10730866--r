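# Unscaled decision utility from a node's summary position: t relations,
# closed-triad proportion x, nI infectious neighbors. The sigma bracket of
# the realized reward is replaced by the perceived infection cost for
# susceptible egos; infected egos carry the (decision-irrelevant) constant
# sigma; recovered egos are not at risk. The penalty-for-all-egos extension
# adds the perceived cost for infected and recovered egos as well.
utility_from <- function(t, x, nI, state, r, p) {
  # arithmetic of relation_value/triad_value/perceived_infection_cost,
  # inlined because this sits under every tie evaluation of the round loop
  v <- p$b1 * t - (p$c1 * t + p$c2 * t * t)
  if (p$clamp_relation_reward && v < 0) v <- 0
  base <- v + p$b2 * (1 - 2 * abs(x - p$alpha) / max(p$alpha, 1 - p$alpha))
  perceived <- function() {
    pi <- 1 - (1 - p$gamma)^nI
    p$ext_risk_weight * p$sigma^r * pi^(2 - r)
  }
  cost <- switch(state,
    S = perceived(),
    I = p$sigma + if (p$ext_penalty_all_egos) perceived() else 0,
    R = if (p$ext_penalty_all_egos) perceived() else 0
  )
  base - cost
}

#' Perceived round utility of a node
#'
#' The unscaled utility a myopic agent assigns to its current network
#' position: relation and triad terms as in the realized reward, with the
#' objective infection cost replaced by the risk-perceived cost
#' ([perceived_infection_cost()]) of the agent's current probability of
#' getting infected. Infected egos carry the constant objective severity
#' (irrelevant for comparing tie changes); recovered egos bear no infection
#' cost, unless the `ext_penalty_all_egos` extension is switched on.
#'
#' @param net a [nidm_network] with risk scores.
#' @param i node id.
#' @param p a [nidm_params] object.
#' @return Unscaled utility (multiply by `p$scale` for points).
#' @export
perceived_utility <- function(net, i, p = nidm_params()) {
  i <- check_node(net, i)
  nb <- which(net$adj[i, ])
  k <- length(nb)
  x <- if (k < 2L) 0 else (sum(net$adj[nb, nb]) / 2) / choose(k, 2)
  nI <- sum(net$state[nb] == "I")
  utility_from(k, x, nI, net$state[i], net$score[i], p)
}

#' Utility change of toggling one tie
#'
#' Perceived utility of the ego with the tie `(ego, alter)` present minus
#' with it absent, every other tie held at its current (round-start) state.
#' Positive values mean the ego prefers the tie to exist.
#'
#' @param net a [nidm_network] with risk scores.
#' @param ego,alter distinct node ids.
#' @param p a [nidm_params] object.
#' @return The utility difference (unscaled).
#' @export
tie_delta <- function(net, ego, alter, p = nidm_params()) {
  ego <- check_node(net, ego)
  alter <- check_node(net, alter)
  if (ego == alter) stop("'ego' and 'alter' must differ")
  row <- net$adj[ego, ]
  nb0 <- which(row & seq_along(row) != alter)  # neighbors without the tie
  k0 <- length(nb0)
  cp0 <- if (k0 < 2L) 0 else sum(net$adj[nb0, nb0]) / 2
  common <- sum(net$adj[alter, nb0])
  nI0 <- sum(net$state[nb0] == "I")
  st <- net$state[ego]
  r <- net$score[ego]
  x_with <- if (k0 + 1L < 2L) 0 else (cp0 + common) / choose(k0 + 1L, 2)
  x_without <- if (k0 < 2L) 0 else cp0 / choose(k0, 2)
  u_with <- utility_from(k0 + 1L, x_with, nI0 + (net$state[alter] == "I"),
                         st, r, p)
  u_without <- utility_from(k0, x_without, nI0, st, r, p)
  u_with - u_without
}

# shared action resolution: reward-seeking action from the sign of the
# delta, with the optional randomized deviation when the alter is healthy
resolve_action <- function(delta, keep_action, drop_action, status_quo,
                           alter_infected, p) {
  act <- if (delta > 0) keep_action else if (delta < 0) drop_action else
    status_quo
  if (p$ext_p_reward_seeking < 1 && !alter_infected &&
      stats::runif(1) >= p$ext_p_reward_seeking) {
    act <- c(keep_action, drop_action)[sample.int(2L, 1L)]
  }
  act
}

decision_frame <- function(net, round, stage, ego, alters, kinds, actions,
                           deltas) {
  nbI <- infected_neighbor_counts(net)
  m <- length(alters)
  # hand-built data.frame: this sits on the hot path of the round loop
  structure(
    list(round = rep.int(round, m), stage = rep.int(stage, m),
         ego = rep.int(ego, m), alter = as.integer(alters),
         kind = rep_len(kinds, m), action = rep_len(actions, m),
         perceived_delta = deltas,
         ego_state = rep.int(net$state[ego], m),
         alter_state = net$state[alters],
         alter_has_infected_neighbor = nbI[alters] > 0L),
    class = "data.frame", row.names = seq_len(m)
  )
}

#' Stage-1 decisions of an ego
#'
#' For every offered alter the ego evaluates the tie change myopically
#' against the round-start network: an existing tie is maintained when
#' [tie_delta()] is positive and dissolved when negative; a new tie is
#' proposed when the delta is positive. An exact zero resolves to the
#' status quo. With probability `1 - ext_p_reward_seeking` (and a
#' non-infected alter) the action is instead drawn uniformly between the
#' two options.
#'
#' @param ego deciding node.
#' @param alters alters offered by [select_opportunities()].
#' @param net round-start [nidm_network].
#' @param p a [nidm_params] object.
#' @param round round number recorded in the log.
#' @return A decision data.frame, one row per opportunity, with the
#'   perceived delta, both disease states and the infected-neighbor flag of
#'   the alter at decision time.
#' @export
stage1_decide <- function(ego, alters, net, p = nidm_params(), round = 1L) {
  m <- length(alters)
  kinds <- character(m); actions <- character(m); deltas <- numeric(m)
  for (k in seq_len(m)) {
    alter <- alters[k]
    deltas[k] <- tie_delta(net, ego, alter, p)
    inf <- net$state[alter] == "I"
    if (net$adj[ego, alter]) {
      kinds[k] <- "dissolve-or-maintain"
      actions[k] <- resolve_action(deltas[k], "maintain", "dissolve",
                                   "maintain", inf, p)
    } else {
      kinds[k] <- "propose-or-not"
      actions[k] <- resolve_action(deltas[k], "propose", "not-propose",
                                   "not-propose", inf, p)
    }
  }
  decision_frame(net, round, 1L, ego, alters, kinds, actions, deltas)
}

#' Stage-2 decisions on incoming proposals
#'
#' The receiving ego accepts a proposed tie exactly when its [tie_delta()]
#' is positive, evaluated against the round-start network; the same
#' randomized deviation as in stage 1 applies.
#'
#' @param ego deciding node.
#' @param proposers nodes whose proposals await a decision.
#' @param net round-start [nidm_network].
#' @param p a [nidm_params] object.
#' @param round round number recorded in the log.
#' @return A decision data.frame (zero rows when there are no proposals).
#' @export
stage2_decide <- function(ego, proposers, net, p = nidm_params(),
                          round = 1L) {
  m <- length(proposers)
  if (!m)
    return(decision_frame(net, round, 2L, 1L, 2L, "accept-or-decline",
                          "decline", 0)[0L, ])
  actions <- character(m); deltas <- numeric(m)
  for (k in seq_len(m)) {
    alter <- proposers[k]
    deltas[k] <- tie_delta(net, ego, alter, p)
    actions[k] <- resolve_action(deltas[k], "accept", "decline", "decline",
                                 net$state[alter] == "I", p)
  }
  decision_frame(net, round, 2L, ego, proposers, "accept-or-decline",
                 actions, deltas)
}

#' Apply the resolved decisions of one round
#'
#' Dissolutions are unilateral: a tie is removed when either endpoint chose
#' to dissolve it. Creations require consent: a tie appears when a proposal
#' was accepted in stage 2 or when both nodes proposed it simultaneously.
#' Dissolutions are applied before creations; the two sets concern disjoint
#' node pairs, so the order cannot create conflicts.
#'
#' @param net round-start [nidm_network].
#' @param stage1 stage-1 decision data.frame ([stage1_decide()]).
#' @param stage2 stage-2 decision data.frame ([stage2_decide()]).
#' @param auto_create matrix of reciprocally proposed pairs
#'   ([collect_stage2_opportunities()]).
#' @return The updated network.
#' @export
apply_round_decisions <- function(net, stage1, stage2 = NULL,
                                  auto_create = NULL) {
  if (NROW(stage1)) {
    dis <- stage1[stage1$action == "dissolve", , drop = FALSE]
    for (k in seq_len(nrow(dis)))
      net <- remove_edge(net, dis$ego[k], dis$alter[k])
  }
  if (!is.null(auto_create)) {
    for (k in seq_len(NROW(auto_create)))
      net <- add_edge(net, auto_create[k, 1L], auto_create[k, 2L])
  }
  if (NROW(stage2)) {
    acc <- stage2[stage2$action == "accept", , drop = FALSE]
    for (k in seq_len(nrow(acc)))
      net <- add_edge(net, acc$ego[k], acc$alter[k])
  }
  net
}
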