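#' Define an intervention condition
#'
#' Five conditions are studied: influence agents chosen by in-degree,
#' betweenness or closeness centrality, chosen at random, or no intervention
#' (control). In every intervention the top `fraction` (default 15%) of the
#' class is selected, each selected pupil's initial PAL is raised by `boost`
#' (default 17%), and the simulation then runs with no further interference.
#' The random condition is replicated (default 100 times) and its success
#' rates averaged into a single outcome value.
#'
#' @param name one of `"in_degree"`, `"betweenness"`, `"closeness"`,
#'   `"random"`, `"control"`.
#' @param fraction selection proportion in (0, 1).
#' @param boost relative initial PAL increase (>= 0).
#' @param random_replicates replicate count for the random condition.
#' @return a list of class `"condition"`.
#' @export
condition <- function(name = c("in_degree", "betweenness", "closeness",
                               "random", "control"),
                      fraction = 0.15, boost = 0.17,
                      random_replicates = 100L) {
  name <- match.arg(name)
  stopifnot(fraction > 0, fraction < 1, boost >= 0, random_replicates >= 1L)
  structure(list(name = name, fraction = fraction, boost = boost,
                 random_replicates = as.integer(random_replicates)),
            class = "condition")
}

#' The full set of five study conditions
#'
#' @param fraction,boost,random_replicates shared condition parameters, see
#'   [condition()].
#' @return a named list of five conditions.
#' @export
conditionSet <- function(fraction = 0.15, boost = 0.17, random_replicates = 100L) {
  nm <- c("control", "random", "in_degree", "betweenness", "closeness")
  out <- lapply(nm, condition, fraction = fraction, boost = boost,
                random_replicates = random_replicates)
  names(out) <- nm
  out
}

# round-half-up with a floor of one selected agent
.selectionSize <- function(n, fraction) max(1L, as.integer(floor(n * fraction + 0.5)))

#' Select influence agents for a condition
#'
#' Centrality conditions take the top `k = max(1, round(fraction * n))` pupils
#' by the named measure; when pupils above and below the cutoff share the
#' cutoff score, the remaining slots are filled by uniform random choice among
#' the tied pupils. The random condition samples `k` pupils uniformly without
#' replacement. The control condition selects nobody. Selection consumes the
#' current RNG stream; seed it for reproducibility.
#'
#' @param network a [ClassNetwork-class].
#' @param centrality_table output of [centralities()] for this network.
#' @param cond a [condition()].
#' @return a character vector of selected participant ids (empty for control).
#' @export
selectInfluenceAgents <- function(network, centrality_table = centralities(network),
                                  cond = condition("in_degree")) {
  ids <- roster(network)
  n <- length(ids)
  if (cond$name == "control") return(character())
  if (n < 1L) stop("cannot select influence agents from an empty class")
  k <- .selectionSize(n, cond$fraction)
  if (cond$name == "random") return(sample(ids, k))
  scores <- centrality_table[[cond$name]]
  names(scores) <- centrality_table$participant_id
  scores <- scores[ids]
  cutoff <- sort(scores, decreasing = TRUE)[k]
  sure <- ids[scores > cutoff]
  tied <- ids[scores == cutoff]
  need <- k - length(sure)
  picked <- if (need > 0) sample(tied, need) else character()
  c(sure, picked)
}

#' Boost the initial PAL of selected agents
#'
#' Multiplies each selected agent's PAL by `1 + boost`, clamped to the PAL
#' bounds; all other agents are unchanged.
#'
#' @param states a states data.frame (`participant_id`, `pal`, ...).
#' @param agents ids of the selected influence agents.
#' @param boost relative increase (0.17 = +17%).
#' @param palBounds clamp range.
#' @return the states data.frame with boosted `pal`.
#' @export
applyBoost <- function(states, agents, boost = 0.17, palBounds = c(0.1, 4.27)) {
  unknown <- setdiff(agents, states$participant_id)
  if (length(unknown)) stop("unknown agent id(s): ", paste(unknown, collapse = ", "))
  idx <- states$participant_id %in% agents
  states$pal[idx] <- pmin(pmax(states$pal[idx] * (1 + boost), palBounds[1]),
                          palBounds[2])
  states
}

#' Success rate of a simulated intervention
#'
#' Percent change of the class mean PAL from day 0 (the post-boost state) to
#' the final simulated day:
#' `100 * (meanPAL(last) - meanPAL(0)) / meanPAL(0)`.
#'
#' @param trajectory a [Trajectory-class], or a numeric vector of daily mean
#'   PAL values.
#' @return the success rate in percent (negative when the class mean fell).
#' @export
successRate <- function(trajectory) {
  m <- if (is(trajectory, "Trajectory")) meanPal(trajectory) else as.numeric(trajectory)
  if (m[1] == 0) stop("day-0 mean PAL is zero; success rate undefined")
  100 * (m[length(m)] - m[1]) / m[1]
}

#' Run one condition on one class
#'
#' Applies selection and boost, runs the (deterministic) diffusion model, and
#' measures the success rate. Centrality and control conditions are single
#' runs; the random condition runs `random_replicates` independent selections
#' (all replicates evolved simultaneously) and averages their success rates.
#'
#' @param network a [ClassNetwork-class].
#' @param baseline_states states data.frame from [baselineStates()] (pre-boost).
#' @param cond a [condition()].
#' @param config a [SimConfig-class].
#' @param seed integer seed for selection randomness (tie-breaks, random
#'   agents); logged in the result.
#' @param centrality_table optional precomputed [centralities()] table.
#' @return a list: `class_id`, `condition`, `success_rate`, `selected`
#'   (ids; for the random condition, of the first replicate), `n_agents`,
#'   `seed`, and `mean_trajectory` (daily class mean PAL, averaged over
#'   replicates for the random condition).
#' @export
runCondition <- function(network, baseline_states, cond, config = simConfig(),
                         seed = 1L, centrality_table = NULL) {
  ids <- roster(network)
  n <- length(ids)
  pal0 <- .statesVector(baseline_states, ids)
  env <- .statesField(baseline_states, "env", ids, 1)
  theta <- .statesField(baseline_states, "threshold", ids, config@threshold)
  M <- .influenceMatrix(network)
  anchor <- config@palRef * (2 - env) / 2
  set.seed(seed)

  boostVec <- function(sel) {
    p <- pal0
    p[sel] <- pmin(pmax(p[sel] * (1 + cond$boost), config@palBounds[1]),
                   config@palBounds[2])
    p
  }

  if (cond$name == "control") {
    res <- .evolve(M, matrix(pal0, ncol = 1), anchor, theta, config)
    sel <- character(); n_agents <- 0L
    sr <- successRate(res$means[, 1])
    traj <- res$means[, 1]
  } else if (cond$name == "random") {
    k <- .selectionSize(n, cond$fraction)
    sels <- lapply(seq_len(cond$random_replicates), function(i) sample(ids, k))
    P0 <- vapply(sels, boostVec, numeric(n))
    res <- .evolve(M, P0, anchor, theta, config)
    sr <- mean(apply(res$means, 2, successRate))
    sel <- sels[[1]]; n_agents <- k
    traj <- rowMeans(res$means)
  } else {
    ct <- if (is.null(centrality_table)) centralities(network) else centrality_table
    sel <- selectInfluenceAgents(network, ct, cond)
    res <- .evolve(M, matrix(boostVec(sel), ncol = 1), anchor, theta, config)
    sr <- successRate(res$means[, 1])
    n_agents <- length(sel)
    traj <- res$means[, 1]
  }
  list(class_id = classId(network), condition = cond$name, success_rate = sr,
       selected = sel, n_agents = n_agents, seed = seed,
       mean_trajectory = traj)
}

# deterministic child seed, kept below 2^31
.childSeed <- function(master, class_index, cond_index) {
  as.integer((as.numeric(master) * 7919 + class_index * 1009 +
                cond_index * 131) %% 2147483647)
}

#' Run the full simulated experiment
#'
#' All five conditions on every class of a cohort: builds the class networks,
#' computes centralities, applies selection/boost/simulation per condition,
#' and collects the per-class success rates. Child seeds for every class x
#' condition are derived deterministically from the master seed and logged in
#' the results table, so any single run can be replayed.
#'
#' @param cohort a [Cohort-class] (or a list with `participants` and
#'   `nominations` tables).
#' @param config a [SimConfig-class].
#' @param conditions a list of conditions, see [conditionSet()].
#' @param seed master seed.
#' @param trajectories also return the long-format daily mean-PAL table.
#' @return a data.frame `class_id`, `condition`, `success_rate`, `n_agents`,
#'   `seed` (one row per class x condition; the random condition enters as its
#'   replicate average). When `trajectories = TRUE`, a long data.frame
#'   (`class_id`, `condition`, `day`, `mean_pal`) is attached as
#'   `attr(, "trajectories")`.
#' @export
runExperiment <- function(cohort, config = simConfig(),
                          conditions = conditionSet(), seed = 1L,
                          trajectories = FALSE) {
  networks <- buildNetworks(cohort)
  rows <- list(); trows <- list()
  for (ci in seq_along(networks)) {
    net <- networks[[ci]]
    ct <- centralities(net)
    states <- baselineStates(cohort, classId(net), config)
    for (ki in seq_along(conditions)) {
      cond <- conditions[[ki]]
      r <- runCondition(net, states, cond, config,
                        seed = .childSeed(seed, ci, ki), centrality_table = ct)
      rows[[length(rows) + 1L]] <- data.frame(
        class_id = r$class_id, condition = r$condition,
        success_rate = r$success_rate, n_agents = r$n_agents, seed = r$seed)
      if (trajectories)
        trows[[length(trows) + 1L]] <- data.frame(
          class_id = r$class_id, condition = r$condition,
          day = seq_along(r$mean_trajectory) - 1L, mean_pal = r$mean_trajectory)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (trajectories) {
    tr <- do.call(rbind, trows)
    rownames(tr) <- NULL
    attr(out, "trajectories") <- tr
  }
  out
}

#' Write the experiment results table to CSV
#'
#' @param results output of [runExperiment()].
#' @param dir output directory.
#' @return invisibly, the path.
#' @export
writeResults <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "results.csv")
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
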