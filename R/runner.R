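#' Session schedule of the two-by-two design
#'
#' Each session holds two games. The initial clustering setting alternates
#' every session and the mixing setting every second session, giving the
#' order LO:RA, HI:RA | HI:RA, LO:RA | LO:AS, HI:AS | HI:AS, LO:AS |
#' LO:RA, ... With 48 sessions every condition is played 24 times.
#'
#' @param n_sessions number of sessions (default 48).
#' @return A data.frame with columns `session`, `game`, `clustering`,
#'   `mixing`.
#' @export
session_plan <- function(n_sessions = 48L) {
  rows <- lapply(seq_len(n_sessions), function(s) {
    mixing <- if (((s - 1L) %/% 2L) %% 2L == 0L) "RA" else "AS"
    first_lo <- s %% 2L == 1L
    data.frame(
      session = s, game = 1:2,
      clustering = if (first_lo) c("LO", "HI") else c("HI", "LO"),
      mixing = mixing, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Run one network game
#'
#' Plays a full installment: the baseline network for the condition's
#' clustering setting is generated, participants are assigned to nodes
#' according to the mixing setting, the index case is infected, and rounds
#' of (stage 1) maintain/dissolve/propose decisions, (stage 2) proposal
#' acceptance, (stage 3) point rewards and (stage 4) disease transmission
#' and recovery are played until no infectious node remains or `max_rounds`
#' is reached. Fully reproducible from `(condition, scores, seed)`.
#'
#' @param condition a [nidm_condition].
#' @param scores risk-aversion scores, one per node (default: sampled from
#'   the truncated normal of [sample_risk_scores()]).
#' @param p a [nidm_params] object. `alpha` and `omega` are overridden by
#'   the condition (`LO`/`HI` sets `alpha`, `RA`/`AS` sets `omega`).
#' @param seed integer seed; defaults to the condition's seed.
#' @param omega optional override of the similarity weight, decoupling the
#'   opportunity-selection mechanism from the condition's assignment (used
#'   to study the two mixing ingredients in isolation).
#' @param noop_agents node ids of unresponsive participants: they stay in
#'   the network but never initiate relational changes (they maintain every
#'   existing tie, propose nothing and decline every proposal).
#' @return An object of class `nidm_game`: the condition and parameters,
#'   the decision log, per-node reward log, round-start network snapshots,
#'   per-round disease states, the epidemic trace, the final network,
#'   `rounds_played` and `final_size`.
#' @export
run_game <- function(condition, scores = NULL, p = nidm_params(),
                     seed = condition$seed, omega = NULL,
                     noop_agents = integer(0)) {
  stopifnot(inherits(condition, "nidm_condition"))
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  p$alpha <- condition_alpha(condition$clustering)
  p$omega <- if (is.null(omega)) condition_omega(condition$mixing) else omega

  net <- generate_baseline(condition$clustering, seeds[1L], p,
                           report_equilibrium = FALSE)
  set.seed(seeds[2L])
  n <- n_nodes(net)
  if (is.null(scores)) scores <- sample_risk_scores(n)
  if (length(scores) != n) stop("need exactly one score per node")
  net <- assign_participants(net, scores, condition$mixing)
  assignment <- attr(net, "assignment")

  index_case <- select_index_case(net)
  net <- infect_nodes(net, index_case, p)

  snapshots <- list(edge_list(net))   # network at the start of round 1
  states <- list()
  decisions <- list()
  rewards <- list()
  trace <- list()
  infection_round <- stats::setNames(rep(NA_integer_, n), seq_len(n))
  recovery_round <- stats::setNames(rep(NA_integer_, n), seq_len(n))
  infection_round[index_case] <- 0L
  round <- 0L

  repeat {
    round <- round + 1L
    start_net <- net
    states[[round]] <- start_net$state

    # stage 1: every ego decides on its offered alters
    s1 <- vector("list", n)
    for (ego in seq_len(n)) {
      alters <- select_opportunities(ego, start_net, p)
      d <- stage1_decide(ego, alters, start_net, p, round)
      if (ego %in% noop_agents)
        d$action <- ifelse(d$kind == "dissolve-or-maintain",
                           "maintain", "not-propose")
      s1[[ego]] <- d
    }
    s1 <- do.call(rbind, s1)

    # stage 2: proposals grouped by target, reciprocal pairs auto-created
    props <- s1[s1$action == "propose", c("ego", "alter"), drop = FALSE]
    grouped <- collect_stage2_opportunities(props, start_net)
    s2 <- lapply(unique(grouped$stage2$ego), function(ego) {
      d <- stage2_decide(ego, grouped$stage2$alter[grouped$stage2$ego == ego],
                         start_net, p, round)
      if (ego %in% noop_agents) d$action <- "decline"
      d
    })
    s2 <- if (length(s2)) do.call(rbind, s2) else s1[0, ]

    net <- apply_round_decisions(start_net, s1, s2, grouped$auto_create)
    decisions[[round]] <- rbind(s1, s2)

    # stage 3: point rewards on the post-decision network
    deg <- degrees(net)
    x <- local_triad_proportions(net)
    rel <- relation_points(deg, p)
    tri <- triad_points(x, p)
    pen <- infection_penalty(net$state, p)
    net$points <- net$points + rel + tri - pen
    rewards[[round]] <- data.frame(
      round = round, node = seq_len(n), degree = deg,
      relation_points = rel, triad_points = tri, infection_penalty = pen,
      total = rel + tri - pen
    )

    # stage 4: transmission and recovery
    s4 <- stage4_step(net, p)
    net <- s4$net
    infection_round[s4$infected] <- round
    recovery_round[s4$recovered] <- round
    trace[[round]] <- data.frame(
      round = round,
      S = sum(net$state == "S"), I = sum(net$state == "I"),
      R = sum(net$state == "R")
    )
    snapshots[[round + 1L]] <- edge_list(net)

    if (!any(net$state == "I") || round >= p$max_rounds) break
  }

  res <- list(
    condition = condition, params = p, seed = as.integer(seed),
    scores = scores, assignment = assignment, index_case = index_case,
    rounds_played = round,
    snapshots = snapshots[seq_len(round)],  # round-start edge lists
    states = states,
    final_net = net,
    decisions = do.call(rbind, decisions),
    rewards = do.call(rbind, rewards),
    trace = do.call(rbind, trace),
    ever_infected = which(!is.na(infection_round)),
    infection_round = infection_round,
    recovery_round = recovery_round,
    final_size = sum(net$state %in% c("I", "R")) / n
  )
  class(res) <- "nidm_game"
  res
}

#' @export
print.nidm_game <- function(x, ...) {
  cat(sprintf("<nidm_game> %s:%s | %d rounds | final size %.3f (%d/%d ever infected)\n",
              x$condition$clustering, x$condition$mixing, x$rounds_played,
              x$final_size, length(x$ever_infected), n_nodes(x$final_net)))
  invisible(x)
}

#' Final epidemic size
#'
#' Proportion of nodes infected or recovered when the game ends. The index
#' case is always counted, so the value lies in `[1/n, 1]`.
#'
#' @param result a `nidm_game`.
#' @export
final_size <- function(result) result$final_size

#' Run a full batch of sessions
#'
#' Plays the whole experimental design: `n_sessions` sessions of two games
#' each, conditions following [session_plan()]. Risk scores are sampled
#' once per session and reused for both of its games (the same participants
#' play both). All seeds derive from the master seed, so a batch is fully
#' reproducible.
#'
#' @param p a [nidm_params] object.
#' @param master_seed integer seed for the whole batch.
#' @param n_sessions number of sessions (default 48, i.e. 96 games).
#' @param keep_games if `FALSE`, only the summary table is kept.
#' @return An object of class `nidm_batch` with the plan, the list of
#'   games and a per-game summary data.frame.
#' @export
run_batch <- function(p = nidm_params(), master_seed = 1L,
                      n_sessions = 48L, keep_games = TRUE) {
  plan <- session_plan(n_sessions)
  set.seed(as.integer(master_seed))
  session_seeds <- sample.int(.Machine$integer.max - 1L, n_sessions)
  game_seeds <- sample.int(.Machine$integer.max - 1L, nrow(plan))

  games <- vector("list", nrow(plan))
  for (s in seq_len(n_sessions)) {
    set.seed(session_seeds[s])
    scores <- sample_risk_scores(60L)
    for (g in 1:2) {
      k <- (s - 1L) * 2L + g
      cond <- nidm_condition(plan$clustering[k], plan$mixing[k],
                             session_index = s, game_index = g,
                             seed = game_seeds[k])
      games[[k]] <- run_game(cond, scores, p)
    }
  }
  summary <- cbind(plan, data.frame(
    seed = game_seeds,
    rounds_played = vapply(games, function(g) g$rounds_played, integer(1)),
    final_size = vapply(games, final_size, numeric(1)),
    ever_infected = vapply(games, function(g) length(g$ever_infected),
                           integer(1))
  ))
  structure(
    list(plan = plan, games = if (keep_games) games else NULL,
         summary = summary, master_seed = as.integer(master_seed)),
    class = "nidm_batch"
  )
}

#' @export
print.nidm_batch <- function(x, ...) {
  cat(sprintf("<nidm_batch> %d games, master seed %d\n",
              nrow(x$summary), x$master_seed))
  agg <- stats::aggregate(final_size ~ clustering + mixing, x$summary, stats::median)
  print(agg)
  invisible(x)
}

#' Proportions of decisions by decision type and disease states
#'
#' Tallies, for every combination of ego and alter disease state, the
#' proportion of opportunities that were turned into each decision type:
#' *Create* (proposals in stage 1 and acceptances in stage 2), *Not create*
#' (their complements), *Dissolve* and *Maintain* (for existing ties).
#' Create and Not create sum to one within a cell, as do Dissolve and
#' Maintain. Cells without opportunities report `NA`, not 0.
#'
#' @param decisions a decision log (`game$decisions`, possibly several
#'   games' logs row-bound).
#' @param split_alter_S if `TRUE`, susceptible alters are split by whether
#'   they had an infectious neighbor at decision time.
#' @return A data.frame with `ego_state`, `alter_state`, `type`,
#'   `n_opportunities`, `n_decisions`, `proportion`.
#' @export
decision_matrix <- function(decisions, split_alter_S = FALSE) {
  if (NROW(decisions) == 0L) stop("empty decision log")
  d <- decisions
  d$alter_cell <- d$alter_state
  if (split_alter_S) {
    s <- d$alter_state == "S"
    d$alter_cell[s] <- ifelse(d$alter_has_infected_neighbor[s],
                              "S+infected-neighbor", "S-no-infected-neighbor")
  }
  d$is_create_kind <- d$kind %in% c("propose-or-not", "accept-or-decline")
  rows <- list()
  for (es in c("S", "I", "R")) for (ac in unique(d$alter_cell)) {
    cell <- d[d$ego_state == es & d$alter_cell == ac, , drop = FALSE]
    ck <- cell[cell$is_create_kind, , drop = FALSE]
    tk <- cell[!cell$is_create_kind, , drop = FALSE]
    n_c <- nrow(ck); n_t <- nrow(tk)
    made_create <- sum(ck$action %in% c("propose", "accept"))
    made_dissolve <- sum(tk$action == "dissolve")
    rows[[length(rows) + 1L]] <- data.frame(
      ego_state = es, alter_state = ac,
      type = c("Create", "Not create", "Dissolve", "Maintain"),
      n_opportunities = c(n_c, n_c, n_t, n_t),
      n_decisions = c(made_create, n_c - made_create,
                      made_dissolve, n_t - made_dissolve),
      proportion = c(
        if (n_c) c(made_create / n_c, 1 - made_create / n_c) else c(NA, NA),
        if (n_t) c(made_dissolve / n_t, 1 - made_dissolve / n_t) else c(NA, NA)
      ),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Counterfactual rewardingness of decisions
#'
#' For every decision, recomputes the ego's stage-3 round reward with the
#' single tie toggled to the opposite of its realized state, holding all
#' other ties and the round's disease states fixed. A decision is
#' *rewarding* when the realized reward is at least (strictly above, with
#' `strict = TRUE`) the counterfactual one.
#'
#' @param game a `nidm_game`.
#' @param strict require a strictly higher realized reward.
#' @return Logical vector aligned with the rows of `game$decisions`.
#' @export
decision_rewardingness <- function(game, strict = FALSE) {
  p <- game$params
  n <- n_nodes(game$final_net)
  out <- logical(nrow(game$decisions))
  for (r in sort(unique(game$decisions$round))) {
    # post-stage-2 network of round r is the start of round r + 1
    post <- if (r < game$rounds_played) game$snapshots[[r + 1L]] else
      edge_list(game$final_net)
    net <- nidm_network(n, post)
    net$state <- game$states[[r]]
    idx <- which(game$decisions$round == r)
    for (k in idx) {
      ego <- game$decisions$ego[k]
      alter <- game$decisions$alter[k]
      realized <- round_reward(net, ego, p)$total
      toggled <- if (net$adj[ego, alter]) remove_edge(net, ego, alter) else
        add_edge(net, ego, alter)
      counterfactual <- round_reward(toggled, ego, p)$total
      out[k] <- if (strict) realized > counterfactual else
        realized >= counterfactual
    }
  }
  out
}

#' Dissolve rate of susceptible egos towards infected alters
#'
#' Share of dissolve-or-maintain opportunities with a susceptible ego and
#' an infected alter that were resolved by dissolving — the avoidance
#' behaviour at the heart of the model's individual-level predictions.
#'
#' @param decisions a decision log.
#' @return A proportion, or `NA` if no such opportunity occurred.
#' @export
dissolve_rate_SI <- function(decisions) {
  d <- decisions[decisions$kind == "dissolve-or-maintain" &
                   decisions$ego_state == "S" &
                   decisions$alter_state == "I", , drop = FALSE]
  if (!nrow(d)) return(NA_real_)
  mean(d$action == "dissolve")
}

#' Wilcoxon rank-sum test for final sizes
#'
#' Two-sided rank-sum test using the normal approximation with tie
#' correction, reporting the standardized statistic `z` alongside the
#' Mann-Whitney `U`.
#'
#' @param a,b numeric samples.
#' @return A list with `statistic` (U), `z` and `p.value`.
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    warning("rank-sum test degenerate: all observations tied")
    return(list(statistic = U, z = NA_real_, p.value = NA_real_))
  }
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  list(statistic = U, z = z, p.value = 2 * stats::pnorm(-abs(z)))
}
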