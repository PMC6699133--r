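#' Build the weighted directed network of one class
#'
#' Collapses nomination records into one directed graph. For each ordered pair
#' `(u, v)` the edge weight is the number of distinct sociometric questions
#' (out of 6) on which `u` nominated `v` in any wave, divided by 6; duplicate
#' nominations (same nominator, nominee and question in different waves) are
#' omitted, so weights are quantized to `{1/6, ..., 6/6}` and a pair can
#' accumulate at most 6 nominations across all 4 waves. Pairs with no
#' nomination carry no edge. The node set is the roster, not the nomination
#' table: pupils who never nominate or are never nominated stay in the graph
#' as isolated nodes (their activity still evolves through the environment
#' term of the simulation).
#'
#' @param nominations data.frame with columns `nominator_id`, `nominee_id`,
#'   `question_id` (1..6) and `wave` (1..4).
#' @param roster character vector of participant ids; every nominator and
#'   nominee must be on it.
#' @param class_id identifier stored on the network.
#' @return a [ClassNetwork-class].
#' @export
#' @examples
#' noms <- data.frame(nominator_id = "A", nominee_id = "B",
#'                    question_id = c(1, 2, 3, 1), wave = c(1, 1, 2, 3))
#' net <- buildClassNetwork(noms, roster = c("A", "B", "C"), class_id = "demo")
#' edgeTable(net)  # one edge A -> B with weight 3/6 (duplicate question 1 dropped)
buildClassNetwork <- function(nominations, roster, class_id = "class") {
  stopifnot(is.character(roster) || is.factor(roster))
  roster <- as.character(roster)
  nm <- nominations
  need <- c("nominator_id", "nominee_id", "question_id", "wave")
  stopifnot(all(need %in% names(nm)))
  if (nrow(nm)) {
    off <- setdiff(c(nm$nominator_id, nm$nominee_id), roster)
    if (length(off))
      stop("nomination ids not on the roster: ", paste(unique(off), collapse = ", "))
    if (any(nm$nominator_id == nm$nominee_id))
      stop("self-nominations are not allowed")
    if (!all(nm$question_id %in% 1:6)) stop("question_id must be in 1..6")
    if (!all(nm$wave %in% 1:4)) stop("wave must be in 1..4")
    # dedup on (nominator, nominee, question) across all waves
    key <- paste(nm$nominator_id, nm$nominee_id, nm$question_id, sep = "\r")
    nm <- nm[!duplicated(key), , drop = FALSE]
    counts <- stats::aggregate(question_id ~ nominator_id + nominee_id,
                               data = nm, FUN = length)
    edges <- data.frame(from = counts$nominator_id, to = counts$nominee_id,
                        weight = counts$question_id / 6)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(), weight = numeric())
  }
  new("ClassNetwork", classId = as.character(class_id), roster = roster,
      edges = edges)
}

#' Build one network per class from cohort tables
#'
#' @param cohort a [Cohort-class], or a list with `participants` and
#'   `nominations` data.frames (as returned by [readCohortTables()]).
#' @return a named list of [ClassNetwork-class] objects, one per class.
#' @export
buildNetworks <- function(cohort) {
  if (is(cohort, "Cohort"))
    cohort <- list(participants = participants(cohort),
                   nominations = nominations(cohort))
  p <- cohort$participants; nm <- cohort$nominations
  cls <- unique(p$class_id)
  out <- lapply(cls, function(cl) {
    ids <- p$participant_id[p$class_id == cl]
    buildClassNetwork(nm[nm$nominator_id %in% ids, , drop = FALSE], ids, cl)
  })
  names(out) <- cls
  out
}

#' Mutual dyads of a class network
#'
#' Unordered pairs connected by edges in both directions (each nominated the
#' other on at least one question).
#'
#' @param network a [ClassNetwork-class].
#' @return a data.frame with columns `a`, `b` (a < b), possibly empty.
#' @export
mutualDyads <- function(network) {
  stopifnot(is(network, "ClassNetwork"))
  e <- edgeTable(network)
  if (!nrow(e)) return(data.frame(a = character(), b = character()))
  key <- paste(e$from, e$to, sep = "\r")
  rev <- paste(e$to, e$from, sep = "\r")
  both <- e[key %in% rev & e$from < e$to, c("from", "to"), drop = FALSE]
  out <- data.frame(a = both$from, b = both$to)
  rownames(out) <- NULL
  out
}

#' Convert a class network to an igraph object
#'
#' @param network a [ClassNetwork-class].
#' @param weighted keep connection weights as an edge attribute (`TRUE`) or
#'   return the unweighted digraph of nomination presence (`FALSE`). Individual
#'   centralities are defined on the unweighted digraph; the simulation uses
#'   the weights.
#' @return an igraph directed graph whose vertices are the full roster.
#' @export
asIgraph <- function(network, weighted = TRUE) {
  stopifnot(is(network, "ClassNetwork"))
  e <- edgeTable(network)
  g <- igraph::graph_from_data_frame(e, directed = TRUE,
                                     vertices = data.frame(name = roster(network)))
  if (!weighted && nrow(e)) g <- igraph::delete_edge_attr(g, "weight")
  g
}

#' Weighted adjacency matrix of a class network
#'
#' Row `u`, column `v` holds the connection weight of `u -> v` (0 when absent).
#'
#' @param network a [ClassNetwork-class].
#' @return a square numeric matrix with roster ids as dimnames.
#' @export
adjacencyMatrix <- function(network) {
  ids <- roster(network)
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  e <- edgeTable(network)
  if (nrow(e)) W[cbind(e$from, e$to)] <- e$weight
  W
}

#' Export a class network as GraphML
#'
#' @param network a [ClassNetwork-class].
#' @param file output path.
#' @return invisibly, the path.
#' @export
exportGraphML <- function(network, file) {
  igraph::write_graph(asIgraph(network), file, format = "graphml")
  invisible(file)
}
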