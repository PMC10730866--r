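p0 <- nidm_params()          # LO defaults, alpha = 0
pH <- nidm_params(alpha = 0.67)

test_that("relation rewards peak at six relations and clamp at zero", {
  expect_equal(round(relation_points(6, p0)), 100)
  expect_equal(relation_points(6, p0), 41.88 * 2.388, tolerance = 1e-12)
  expect_equal(relation_points(0, p0), 0)
  # 12 relations: unclamped value is negative, clamped to zero
  expect_equal(relation_points(12, p0), 0)
  unclamped <- nidm_params(clamp_relation_reward = FALSE)
  expect_lt(relation_points(12, unclamped), 0)
  expect_error(relation_points(-1, p0), "nonnegative")
  # unimodal with the maximum at t = 6
  vals <- sapply(0:20, relation_points, p = p0)
  expect_equal(which.max(vals) - 1, 6)
  expect_true(all(diff(vals[1:7]) > 0))
  expect_true(all(diff(vals[7:13]) < 0))
})

test_that("triad rewards are maximal at the preferred proportion", {
  expect_equal(round(triad_points(0, p0)), 21)
  expect_equal(triad_points(0, p0), 0.5 * 41.88, tolerance = 1e-12)
  expect_equal(triad_points(1, p0), -0.5 * 41.88, tolerance = 1e-12)
  for (a in c(0, 0.3, 0.5, 0.67, 1)) {
    pa <- nidm_params(alpha = a)
    expect_equal(triad_points(a, pa), 41.88 * 0.5)
    grid <- seq(0, 1, by = 0.05)
    expect_true(all(triad_points(grid, pa) <= triad_points(a, pa) + 1e-12))
  }
  expect_error(triad_points(1.2, p0), "\\[0, 1\\]")
})

test_that("infection penalty applies to infected nodes only", {
  expect_equal(round(infection_penalty("I", p0)), 14)
  expect_equal(infection_penalty("I", p0), 0.34 * 41.88, tolerance = 1e-12)
  expect_equal(infection_penalty("S", p0), 0)
  expect_equal(infection_penalty("R", p0), 0)
  # the triad optimum is worth more than the infection penalty
  expect_gt(triad_points(0, p0), infection_penalty("I", p0))
})

test_that("round rewards compose the three terms", {
  # susceptible node with 6 relations at the triad optimum (alpha = 0)
  net <- nidm_network(8, cbind(1, 2:7))
  rw <- round_reward(net, 1, p0)
  expect_equal(rw$total, 41.88 * (2.388 + 0.5), tolerance = 1e-9)
  # infected: same position minus the penalty
  net$state[1] <- "I"; net$clock[1] <- 4L
  rwI <- round_reward(net, 1, p0)
  expect_equal(rwI$total, 41.88 * (2.388 + 0.5 - 0.34), tolerance = 1e-9)
  expect_equal(rwI$total, rwI$relation_points + rwI$triad_points -
                 rwI$infection_penalty)
  # isolated susceptible node: only the triad term at x = 0
  iso <- nidm_network(3, rbind(c(2, 3)))
  expect_equal(round_reward(iso, 1, p0)$total, 0.5 * 41.88)
})

test_that("perceived infection cost amplifies with risk aversion", {
  expect_equal(perceived_infection_cost(1, 0.15, p0), 0.34 * 0.15)
  expect_equal(perceived_infection_cost(1.3, 0, p0), 0)
  expect_equal(perceived_infection_cost(1.8, 0.15, p0),
               0.34^1.8 * 0.15^0.2, tolerance = 1e-12)
  expect_gt(perceived_infection_cost(1.8, 0.15, p0),
            perceived_infection_cost(1, 0.15, p0))
  expect_error(perceived_infection_cost(2, 0.5, p0), "open interval")
  expect_error(perceived_infection_cost(0, 0.5, p0), "open interval")
  # strictly increasing in r whenever severity exceeds the probability,
  # and strictly increasing in the probability of infection
  for (pi_ in c(0.05, 0.15, 0.2775)) {
    rs <- seq(0.2, 1.8, by = 0.2)
    vals <- sapply(rs, perceived_infection_cost, pi = pi_, p = p0)
    expect_true(all(diff(vals) > 0))
  }
  for (r_ in c(0.5, 1, 1.5)) {
    pis <- seq(0.05, 0.95, by = 0.1)
    vals <- sapply(pis, function(q) perceived_infection_cost(r_, q, p0))
    expect_true(all(diff(vals) > 0))
  }
  # the risk-weight extension scales the cost linearly
  pw <- nidm_params(ext_risk_weight = 2.5)
  expect_equal(perceived_infection_cost(1.2, 0.3, pw),
               2.5 * perceived_infection_cost(1.2, 0.3, p0))
})
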