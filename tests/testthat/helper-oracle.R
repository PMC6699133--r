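# Brute-force graph oracles, independent of igraph: Floyd-Warshall distances
# plus dynamic-programming shortest-path counting. Used to validate the
# centrality implementations on small digraphs.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# sigma[s, t]: number of distinct shortest s -> t paths
oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  diag(S) <- 1
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      preds <- which(A[, t] > 0 & D[s, ] + 1 == D[s, t])
      S[s, t] <- sum(S[s, preds])
    }
  }
  S
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  S <- oracle_path_counts(A, D)
  bw <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || s == v || t == v || !is.finite(D[s, t])) next
    if (D[s, v] + D[v, t] == D[s, t] && S[s, t] > 0)
      bw[v] <- bw[v] + S[s, v] * S[v, t] / S[s, t]
  }
  if (n > 2) bw / ((n - 1) * (n - 2)) else bw
}

# Wasserman-Faust incoming closeness from the distance matrix
oracle_closeness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  vapply(seq_len(n), function(v) {
    d <- D[, v]
    d <- d[is.finite(d)]
    r <- length(d) - 1L
    s <- sum(d)
    if (r <= 0L || s == 0) 0 else (r / (n - 1)) * (r / s)
  }, numeric(1))
}

oracle_in_degree <- function(A) colSums(A > 0)

# random simple digraph as a ClassNetwork (weights all 1/6; centralities only
# use edge presence)
random_class_network <- function(n, p_edge, id = "rnd") {
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p_edge
  e <- pairs[keep, , drop = FALSE]
  noms <- data.frame(nominator_id = e$from, nominee_id = e$to,
                     question_id = rep(1L, nrow(e)), wave = rep(1L, nrow(e)))
  buildClassNetwork(noms, ids, id)
}

# tiny network from an edge list given as c("a->b", "b->c", ...); weight = k/6
# where k = number of questions, via distinct question ids per repetition
network_from_edges <- function(edges, roster, weights = NULL, id = "toy") {
  if (!length(edges)) {
    return(buildClassNetwork(
      data.frame(nominator_id = character(), nominee_id = character(),
                 question_id = integer(), wave = integer()), roster, id))
  }
  parts <- strsplit(edges, "->", fixed = TRUE)
  from <- vapply(parts, `[`, "", 1)
  to <- vapply(parts, `[`, "", 2)
  if (is.null(weights)) weights <- rep(1 / 6, length(edges))
  k <- round(weights * 6)
  noms <- do.call(rbind, lapply(seq_along(edges), function(i) {
    data.frame(nominator_id = from[i], nominee_id = to[i],
               question_id = seq_len(k[i]), wave = 1L)
  }))
  buildClassNetwork(noms, roster, id)
}

# flat states helper
make_states <- function(ids, pal, env = 1, threshold = 0) {
  data.frame(participant_id = ids, pal = pal, env = env, threshold = threshold)
}
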