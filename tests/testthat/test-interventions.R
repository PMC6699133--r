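test_that("selection size is round-half-up with a floor of one", {
  for (n in 7:40) {
    ids <- sprintf("p%02d", seq_len(n))
    net <- network_from_edges(paste0(ids[-1], "->", ids[1]), ids)
    sel <- selectInfluenceAgents(net, cond = condition("in_degree"))
    expect_equal(length(sel), max(1, floor(0.15 * n + 0.5)))
  }
  # n = 20 x 0.15 = 3 exactly
  ids <- sprintf("p%02d", 1:20)
  net <- network_from_edges(paste0(ids[-1], "->", ids[1]), ids)
  expect_length(selectInfluenceAgents(net, cond = condition("betweenness")), 3)
})

test_that("centrality selection takes the top k, randomizing only cutoff ties", {
  ids <- c("a", "b", "c", "d", "e", "f", "g")  # k = 1 for n = 7? 7*.15 = 1.05 -> 1
  tab <- data.frame(participant_id = ids,
                    in_degree = c(5, 4, 3, 3, 1, 0, 0),
                    betweenness = 0, closeness = 0)
  net <- network_from_edges("b->a", ids)
  expect_equal(selectInfluenceAgents(net, tab, condition("in_degree")), "a")

  # k = 2 with scores 5, 3, 3, 1: the unique max plus one of the tied pair
  ids4 <- c("a", "b", "c", "d")
  tab4 <- data.frame(participant_id = ids4, in_degree = c(5, 3, 3, 1),
                     betweenness = 0, closeness = 0)
  net4 <- network_from_edges("b->a", ids4)
  cond4 <- condition("in_degree", fraction = 0.5)  # k = 2
  picks <- replicate(40, {
    sel <- selectInfluenceAgents(net4, tab4, cond4)
    expect_true("a" %in% sel)
    expect_length(sel, 2)
    setdiff(sel, "a")
  })
  expect_setequal(unique(picks), c("b", "c"))  # both tied pupils reachable

  expect_identical(selectInfluenceAgents(net4, tab4, condition("control")),
                   character())
})

test_that("boost raises selected PAL by 17%, clamped, others untouched", {
  st <- make_states(c("a", "b", "c"), pal = c(1.00, 4.00, 2.00))
  out <- applyBoost(st, c("a", "b"), boost = 0.17)
  expect_equal(out$pal, c(1.17, 4.27, 2.00))
  expect_identical(applyBoost(st, "a", boost = 0)$pal, st$pal)
  expect_error(applyBoost(st, "zz"), "unknown agent")
})

test_that("success rate is the percent change of the class mean, day 0 to end", {
  expect_equal(successRate(c(1.0, 1.05, 1.1)), 10)
  expect_equal(successRate(rep(1.7, 365)), 0)
  expect_equal(successRate(c(1.0, 0.95, 0.9)), -10)
  expect_error(successRate(c(0, 1)), "zero")
})

test_that("null boost makes every condition identical to control, exactly", {
  co <- generateCohort(cohortSpec(n_classes = 2, seed = 8))
  res <- runExperiment(co, simConfig(),
                       conditionSet(boost = 0, random_replicates = 5L),
                       seed = 99)
  ctrl <- res$success_rate[res$condition == "control"]
  for (cond in setdiff(unique(res$condition), "control"))
    expect_identical(res$success_rate[res$condition == cond], ctrl)
})

test_that("experiment table: 5 conditions x classes, deterministic under the seed", {
  co <- generateCohort(cohortSpec(n_classes = 4, seed = 12))
  res <- runExperiment(co, simConfig(), conditionSet(random_replicates = 10L),
                       seed = 5, trajectories = TRUE)
  expect_equal(nrow(res), 4 * 5)
  expect_setequal(unique(res$condition), conditionLevels())
  expect_true(all(res$n_agents[res$condition == "control"] == 0))

  res2 <- runExperiment(co, simConfig(), conditionSet(random_replicates = 10L),
                        seed = 5)
  expect_equal(res$success_rate, res2$success_rate)

  tr <- attr(res, "trajectories")
  expect_equal(nrow(tr), 4 * 5 * 365)
  expect_equal(range(tr$day), c(0, 364))
})

test_that("replicate averaging reduces the across-seed variance of the random condition", {
  co <- generateCohort(cohortSpec(n_classes = 1, seed = 44))
  net <- buildNetworks(co)[[1]]
  st <- baselineStates(co, classId(net))
  cfg <- simConfig(days = 120)
  sr <- function(reps, seed)
    runCondition(net, st, condition("random", random_replicates = reps),
                 cfg, seed = seed)$success_rate
  seeds <- 1:30
  v1 <- stats::var(vapply(seeds, function(s) sr(1L, s), numeric(1)))
  v50 <- stats::var(vapply(seeds, function(s) sr(50L, s), numeric(1)))
  expect_lt(v50, v1)
})

test_that("conditions selecting identical agents give identical success rates", {
  co <- generateCohort(cohortSpec(n_classes = 1, seed = 3))
  net <- buildNetworks(co)[[1]]
  st <- baselineStates(co, classId(net))
  tab <- centralities(net)
  # force betweenness scores equal to in-degree: same ranking, same selection
  tab2 <- tab; tab2$betweenness <- tab$in_degree
  r1 <- runCondition(net, st, condition("in_degree"), simConfig(days = 100),
                     seed = 1, centrality_table = tab2)
  r2 <- runCondition(net, st, condition("betweenness"), simConfig(days = 100),
                     seed = 1, centrality_table = tab2)
  expect_setequal(r1$selected, r2$selected)
  expect_identical(r1$success_rate, r2$success_rate)
})
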