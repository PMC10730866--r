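p0 <- nidm_params()

test_that("the session schedule alternates as designed", {
  plan <- session_plan(48)
  expect_equal(nrow(plan), 96)
  # printed order: 1.1 LO:RA, 1.2 HI:RA, 2.1 HI:RA, 2.2 LO:RA, 3.1 LO:AS,
  # 3.2 HI:AS, 4.1 HI:AS, 4.2 LO:AS, 5.1 LO:RA, ...
  head9 <- paste(plan$clustering, plan$mixing, sep = ":")[1:9]
  expect_equal(head9, c("LO:RA", "HI:RA", "HI:RA", "LO:RA",
                        "LO:AS", "HI:AS", "HI:AS", "LO:AS", "LO:RA"))
  counts <- table(plan$clustering, plan$mixing)
  expect_true(all(counts == 24))
})

test_that("games terminate by epidemic extinction or the round cap", {
  g <- run_game(nidm_condition("LO", "RA", seed = 3))
  expect_lte(g$rounds_played, 20)
  expect_gte(g$final_size, 1 / 60)
  expect_lte(g$final_size, 1)
  last <- g$trace[nrow(g$trace), ]
  expect_true(last$I == 0 || g$rounds_played == 20)
  expect_equal(g$final_size, (last$I + last$R) / 60)
  # without transmission the game ends when the index case recovers
  g0 <- run_game(nidm_condition("HI", "AS", seed = 3), p = nidm_params(gamma = 0))
  expect_equal(g0$rounds_played, 4)
  expect_equal(g0$final_size, 1 / 60)
})

test_that("identical inputs reproduce a game exactly", {
  cond <- nidm_condition("HI", "AS", seed = 21)
  set.seed(1); scores <- sample_risk_scores(60)
  a <- run_game(cond, scores)
  b <- run_game(cond, scores)
  expect_identical(a$decisions, b$decisions)
  expect_identical(a$final_net$adj, b$final_net$adj)
  expect_identical(a$trace, b$trace)
  expect_identical(a$rewards, b$rewards)
})

test_that("stage-3 points are conserved in the logs", {
  g <- run_game(nidm_condition("LO", "RA", seed = 13))
  by_node <- tapply(g$rewards$total, g$rewards$node, sum)
  expect_equal(as.vector(by_node), g$final_net$points, tolerance = 1e-9)
  # reward log recomputes from the stored snapshots
  r <- 2
  net <- nidm_network(60, if (r < g$rounds_played) g$snapshots[[r + 1]] else
    edge_list(g$final_net))
  net$state <- g$states[[r]]
  rows <- g$rewards[g$rewards$round == r, ]
  for (i in c(1, 30, 60)) {
    expect_equal(rows$total[rows$node == i],
                 round_reward(net, i, g$params)$total, tolerance = 1e-9)
  }
})

test_that("decision matrices tally a hand-built log correctly", {
  log <- data.frame(
    round = 1, stage = 1,
    ego = 1:10, alter = c(2:10, 1),
    kind = c(rep("dissolve-or-maintain", 4), rep("propose-or-not", 4),
             rep("accept-or-decline", 2)),
    action = c("dissolve", "maintain", "maintain", "maintain",
               "propose", "propose", "not-propose", "not-propose",
               "accept", "decline"),
    perceived_delta = 0,
    ego_state = "S",
    alter_state = c(rep("I", 4), rep("S", 4), "S", "S"),
    alter_has_infected_neighbor = FALSE
  )
  dm <- decision_matrix(log)
  cell <- function(es, as_, type)
    dm$proportion[dm$ego_state == es & dm$alter_state == as_ & dm$type == type]
  expect_equal(cell("S", "I", "Dissolve"), 1 / 4)
  expect_equal(cell("S", "I", "Maintain"), 3 / 4)
  expect_equal(cell("S", "S", "Create"), 3 / 6)      # 2 proposals + 1 accept
  expect_equal(cell("S", "S", "Not create"), 3 / 6)
  # empty cells are undefined, not zero
  expect_true(is.na(cell("R", "I", "Dissolve")))
  # complementarity holds on a real game log
  g <- run_game(nidm_condition("HI", "RA", seed = 2))
  dmg <- decision_matrix(g$decisions)
  for (es in c("S", "I", "R")) for (as_ in c("S", "I", "R")) {
    pc <- dmg$proportion[dmg$ego_state == es & dmg$alter_state == as_]
    types <- dmg$type[dmg$ego_state == es & dmg$alter_state == as_]
    cr <- pc[types == "Create"]; ncr <- pc[types == "Not create"]
    if (!is.na(cr)) expect_equal(cr + ncr, 1)
  }
})

test_that("rewardingness compares against the counterfactual tie", {
  # synthetic one-round game around a 7-spoke ego, no disease
  net_post <- nidm_network(20, cbind(1, 2:7), scores = rep(1, 20))
  game <- list(
    params = nidm_params(),
    rounds_played = 1,
    snapshots = list(edge_list(net_post)),
    states = list(rep("S", 20)),
    final_net = net_post,
    decisions = data.frame(
      round = 1, stage = 1, ego = 1,
      alter = c(8, 2),
      kind = c("dissolve-or-maintain", "dissolve-or-maintain"),
      action = c("dissolve", "maintain"),
      perceived_delta = 0, ego_state = "S", alter_state = "S",
      alter_has_infected_neighbor = FALSE
    )
  )
  class(game) <- "nidm_game"
  # ego ended at 6 relations: having dissolved the 7th was rewarding
  # (100.01 > 97.04), maintaining one of the six also rewarding
  flags <- decision_rewardingness(game)
  expect_equal(flags, c(TRUE, TRUE))
  # flags agree with direct recomputation on a real game
  g <- run_game(nidm_condition("LO", "RA", seed = 17))
  fl <- decision_rewardingness(g)
  idx <- round(seq(1, nrow(g$decisions), length.out = 25))
  for (k in idx) {
    r <- g$decisions$round[k]
    post <- if (r < g$rounds_played) g$snapshots[[r + 1]] else
      edge_list(g$final_net)
    net <- nidm_network(60, post); net$state <- g$states[[r]]
    ego <- g$decisions$ego[k]; alter <- g$decisions$alter[k]
    realized <- round_reward(net, ego, g$params)$total
    net2 <- net
    net2$adj[ego, alter] <- net2$adj[alter, ego] <- !net$adj[ego, alter]
    expect_equal(fl[k], realized >= round_reward(net2, ego, g$params)$total)
  }
})

test_that("rank-sum test matches a permutation oracle", {
  rs <- rank_sum_test(1:10, 1:10)
  expect_gt(rs$p.value, 0.9)
  sep <- rank_sum_test(rnorm(24, 0, 0.1), rnorm(24, 10, 0.1))
  expect_lt(sep$p.value, 0.001)
  expect_warning(rank_sum_test(rep(1, 5), rep(1, 5)), "degenerate")
  # exhaustive permutation of a 5 vs 5 comparison
  a <- c(1.2, 3.4, 0.5, 2.2, 4.1); b <- c(2.0, 5.5, 4.8, 3.9, 6.1)
  obs <- rank_sum_test(a, b)
  pool <- c(a, b)
  combs <- utils::combn(10, 5)
  u_of <- function(idx) sum(rank(pool)[idx]) - 5 * 6 / 2
  us <- apply(combs, 2, u_of)
  u_obs <- u_of(1:5)
  p_perm <- mean(abs(us - 12.5) >= abs(u_obs - 12.5))
  expect_equal(obs$p.value, p_perm, tolerance = 0.1)
  expect_equal(obs$statistic, u_obs)
})

test_that("batch outputs serialize and round-trip", {
  b <- run_batch(p0, master_seed = 3, n_sessions = 2)
  expect_equal(nrow(b$summary), 4)
  dir <- withr::local_tempdir()
  write_outputs(b, dir)
  expect_true(all(file.exists(file.path(dir,
    c("network.csv", "decisions.csv", "participants.csv", "metrics.json")))))
  nw <- read.csv(file.path(dir, "network.csv"))
  g1 <- b$games[[1]]
  r1 <- nw[nw$session_id == 1 & nw$game_id == 1 & nw$round == 1, ]
  # one row per directed edge occurrence plus isolated-node rows
  n_iso <- 60 - length(unique(c(g1$snapshots[[1]])))
  expect_equal(nrow(r1), 2 * nrow(g1$snapshots[[1]]) + n_iso)
  # graphs reconstruct from the two orientations
  el <- r1[!is.na(r1$connected_node_id), c("node_id", "connected_node_id")]
  rebuilt <- nidm_network(60, as.matrix(el[el[, 1] < el[, 2], ]))
  expect_identical(rebuilt$adj, nidm_network(60, g1$snapshots[[1]])$adj)
  expect_equal(names(nw), c("session_id", "game_id", "clustering_setting",
                            "mixing_setting", "round", "node_id",
                            "disease_state", "connected_node_id"))
  pt <- read.csv(file.path(dir, "participants.csv"))
  expect_equal(nrow(pt), 2 * 60)
  expect_true(all(!is.na(pt$node_id_game1) | !is.na(pt$node_id_game2)))
})

test_that("graph exports round-trip through CSV and GraphML", {
  net <- generate_baseline("LO", 2, report_equilibrium = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  export_edgelist_csv(net, f)
  back <- read_edgelist_csv(f, n = 60)
  expect_identical(back$adj, net$adj)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), 178)
})

test_that("unresponsive agents never initiate relational changes", {
  g <- run_game(nidm_condition("LO", "RA", seed = 44), noop_agents = c(3, 9))
  d <- g$decisions[g$decisions$ego %in% c(3, 9), ]
  expect_true(all(d$action %in% c("maintain", "not-propose", "decline")))
  # their ties can still be dissolved unilaterally by others
  expect_gt(nrow(d), 0)
})

test_that("risk-seeking populations suffer at least as much infection", {
  fs <- function(r, seeds) {
    mean(vapply(seeds, function(s)
      final_size(run_game(nidm_condition("LO", "RA", seed = 7000 + s),
                          scores = rep(r, 60))), numeric(1)))
  }
  expect_gte(fs(0.3, 1:6), fs(1.7, 1:6))
})
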