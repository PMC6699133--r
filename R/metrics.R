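#' Individual centralities of a class network
#'
#' Computed on the unweighted digraph of nomination presence (published
#' in-degree descriptives are integer nomination counts, so edge presence, not
#' weight, is the individual-level currency; weights are reserved for the
#' simulation):
#' \itemize{
#'   \item `in_degree`: number of distinct nominators (incoming edges).
#'   \item `betweenness`: directed shortest-path betweenness, normalized by
#'     `(n-1)(n-2)`.
#'   \item `closeness`: incoming-distance closeness (how quickly a pupil is
#'     reached by peers), in the Wasserman-Faust form for possibly
#'     disconnected graphs: with `r` peers able to reach the node and `S` the
#'     sum of their distances, `closeness = (r / (n-1)) * (r / S)`; 0 when
#'     nobody reaches the node.
#' }
#'
#' @param network a [ClassNetwork-class] with at least 2 nodes.
#' @return a data.frame: `participant_id`, `in_degree`, `betweenness`,
#'   `closeness`.
#' @export
centralities <- function(network) {
  stopifnot(is(network, "ClassNetwork"))
  n <- length(roster(network))
  if (n < 2L) stop("centralities are undefined for a single-node network")
  g <- asIgraph(network, weighted = FALSE)
  indeg <- igraph::degree(g, mode = "in")
  btw <- igraph::betweenness(g, directed = TRUE, weights = NA)
  if (n > 2L) btw <- btw / ((n - 1) * (n - 2))
  dm <- igraph::distances(g, mode = "in", weights = NA)  # dm[i, j] = d(j -> i)
  clo <- apply(dm, 1, function(dr) {
    dr <- dr[is.finite(dr)]           # includes the 0 self-distance
    r <- length(dr) - 1L
    s <- sum(dr)
    if (r <= 0L || s == 0) 0 else (r / (n - 1)) * (r / s)
  })
  data.frame(participant_id = roster(network),
             in_degree = as.numeric(indeg),
             betweenness = as.numeric(btw),
             closeness = as.numeric(clo),
             row.names = NULL)
}

#' Density of a directed class network
#'
#' Realized directed ties divided by the `n(n-1)` possible ties.
#'
#' @param network a [ClassNetwork-class] with at least 2 nodes.
#' @return a fraction in [0, 1].
#' @export
networkDensity <- function(network) {
  stopifnot(is(network, "ClassNetwork"))
  n <- length(roster(network))
  if (n < 2L) stop("density is undefined for fewer than 2 nodes")
  nrow(edgeTable(network)) / (n * (n - 1))
}

# normalized centrality scores + the directed-star theoretical maximum of
# sum(Cmax - Ci) under the same normalization, per measure
.centralizationParts <- function(table, measure, n) {
  scores <- switch(measure,
    in_degree = table$in_degree / (n - 1),
    betweenness = table$betweenness,
    closeness = table$closeness,
    stop("unknown centralization measure: ", measure))
  tmax <- switch(measure,
    # inward star: hub in-degree n-1 (normalized 1), leaves 0
    in_degree = n - 1,
    # bidirectional star: hub lies on all (n-1)(n-2) leaf-to-leaf paths
    betweenness = n - 1,
    # bidirectional star: hub closeness 1; leaf distances 1 + 2(n-2)
    closeness = (n - 1) * (n - 2) / (2 * n - 3),
    )
  list(scores = scores, tmax = tmax)
}

#' Freeman centralization of a class
#'
#' The class-level skewness of a centrality distribution:
#' `sum_i (Cmax - C_i)` divided by the theoretical maximum of that sum for a
#' graph of the same size, taken over directed star graphs under the same
#' normalization as the centrality itself. The inward star attains 1 for
#' in-degree; the bidirectional star attains 1 for betweenness and closeness;
#' perfectly equal centralities give 0. Scores are normalized, so
#' centralizations are comparable across class sizes.
#'
#' @param table a centrality table from [centralities()].
#' @param measure one of `"in_degree"`, `"betweenness"`, `"closeness"`.
#' @param n class size (defaults to the number of rows of `table`).
#' @return a score in [0, 1].
#' @export
centralization <- function(table, measure = c("in_degree", "betweenness", "closeness"),
                           n = nrow(table)) {
  measure <- match.arg(measure)
  parts <- .centralizationParts(table, measure, n)
  if (n < 3L || parts$tmax <= 0) return(0)
  sum(max(parts$scores) - parts$scores) / parts$tmax
}

#' Class-level structure table
#'
#' Density and the three Freeman centralizations for every class network.
#'
#' @param networks a list of [ClassNetwork-class] objects (see
#'   [buildNetworks()]).
#' @return a data.frame: `class_id`, `density`, `centralization_in_degree`,
#'   `centralization_betweenness`, `centralization_closeness`.
#' @export
classStructure <- function(networks) {
  rows <- lapply(networks, function(net) {
    tab <- centralities(net)
    data.frame(class_id = classId(net),
               density = networkDensity(net),
               centralization_in_degree = centralization(tab, "in_degree"),
               centralization_betweenness = centralization(tab, "betweenness"),
               centralization_closeness = centralization(tab, "closeness"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlations among pooled individual centralities
#'
#' Pearson correlations (with two-sided p-values) among in-degree, betweenness
#' and closeness centrality over all individuals pooled across classes.
#'
#' @param tables a list of centrality tables (one per class) or a single
#'   pooled table.
#' @return a list with matrices `r` and `p` (3 x 3); entries are `NA` where a
#'   centrality is constant (undefined correlation).
#' @export
centralityCorrelations <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  pooled <- do.call(rbind, tables)
  if (nrow(pooled) < 3L) stop("need at least 3 pooled individuals")
  vars <- c("in_degree", "betweenness", "closeness")
  r <- p <- matrix(NA_real_, 3, 3, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in 1:2) for (j in (i + 1):3) {
    x <- pooled[[vars[i]]]; y <- pooled[[vars[j]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # undefined, not an error
    ct <- stats::cor.test(x, y)
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p)
}

#' Write class-structure and centrality tables to CSV
#'
#' Emits `class_structure.csv` (class-level density and centralizations) and
#' `centrality.csv` (individual centralities with class ids).
#'
#' @param networks list of [ClassNetwork-class] objects.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeMetrics <- function(networks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  struct <- classStructure(networks)
  cent <- do.call(rbind, lapply(networks, function(net) {
    cbind(class_id = classId(net), centralities(net))
  }))
  rownames(cent) <- NULL
  paths <- file.path(dir, c("class_structure.csv", "centrality.csv"))
  utils::write.csv(struct, paths[1], row.names = FALSE)
  utils::write.csv(cent, paths[2], row.names = FALSE)
  invisible(paths)
}
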