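# Independent oracles and fixture builders used across the test files.

# Erdos-Renyi style random test network with risk scores
random_net <- function(n, p_edge = 0.3, seed = 1, scores = NULL) {
  set.seed(seed)
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  if (is.null(scores)) scores <- stats::runif(n, 0.1, 1.9)
  nidm_network(n, pairs[keep, , drop = FALSE], scores = scores)
}

# brute-force proportion of closed triads: enumerate every neighbor pair
brute_triad_proportion <- function(net, i) {
  nb <- which(net$adj[i, ])
  if (length(nb) < 2) return(0)
  pairs <- t(utils::combn(nb, 2))
  closed <- sum(apply(pairs, 1, function(pr) net$adj[pr[1], pr[2]]))
  closed / nrow(pairs)
}

# independent evaluation of the decision utility, written directly from the
# reward formula (relation + triad - perceived infection bracket)
brute_utility <- function(net, i, p) {
  t <- sum(net$adj[i, ])
  rel <- p$b1 * t - (p$c1 * t + p$c2 * t^2)
  if (p$clamp_relation_reward) rel <- max(0, rel)
  x <- brute_triad_proportion(net, i)
  tri <- p$b2 * (1 - 2 * abs(x - p$alpha) / max(p$alpha, 1 - p$alpha))
  nI <- sum(net$state[which(net$adj[i, ])] == "I")
  pi_i <- 1 - (1 - p$gamma)^nI
  cost <- if (net$state[i] == "S") {
    p$ext_risk_weight * p$sigma^net$score[i] * pi_i^(2 - net$score[i])
  } else if (net$state[i] == "I") p$sigma else 0
  rel + tri - cost
}

# two-network comparison: the reward-seeking action on a single tie
brute_tie_choice <- function(net, ego, alter, p) {
  with_tie <- net; with_tie$adj[ego, alter] <- with_tie$adj[alter, ego] <- TRUE
  without <- net; without$adj[ego, alter] <- without$adj[alter, ego] <- FALSE
  du <- brute_utility(with_tie, ego, p) - brute_utility(without, ego, p)
  if (du > 0) "keep" else if (du < 0) "drop" else "status-quo"
}

# play n_rounds of the full four-stage loop without any infection and
# report the tie churn per offered opportunity
churn_rate <- function(net, p, n_rounds = 3, seed = 1) {
  set.seed(seed)
  n <- n_nodes(net)
  if (anyNA(net$score)) net$score <- rep(1, n)
  changed <- 0L; offered <- 0L
  for (r in seq_len(n_rounds)) {
    start <- net
    s1 <- do.call(rbind, lapply(seq_len(n), function(ego) {
      alters <- select_opportunities(ego, start, p)
      stage1_decide(ego, alters, start, p, r)
    }))
    props <- s1[s1$action == "propose", c("ego", "alter")]
    grouped <- collect_stage2_opportunities(props, start)
    s2 <- do.call(rbind, lapply(unique(grouped$stage2$ego), function(ego)
      stage2_decide(ego, grouped$stage2$alter[grouped$stage2$ego == ego],
                    start, p, r)))
    net <- apply_round_decisions(start, s1, s2, grouped$auto_create)
    offered <- offered + nrow(s1) + NROW(s2)
    changed <- changed + sum(xor(start$adj, net$adj)) / 2
  }
  changed / offered
}

expect_prints_as <- function(value, digits, printed) {
  expect_equal(format(round(value, digits), nsmall = digits), printed)
}
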