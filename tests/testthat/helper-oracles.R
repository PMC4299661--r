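# Brute-force graph oracles, independent of igraph's algorithms: distances
# by Floyd-Warshall, shortest-path counts by dynamic programming, components
# by flood fill. Used to validate the package's metric computations on small
# random graphs.

# adjacency matrix (0/1) from an edge data frame a,b over given node names
oracle_adjacency <- function(edges, nodes) {
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges$a[i], edges$b[i]] <- 1
    A[edges$b[i], edges$a[i]] <- 1
  }
  A
}

# Floyd-Warshall all-pairs distances
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# number of shortest paths between every pair: sigma[s,t] =
# sum over neighbours u of t with D[s,u] = D[s,t]-1 of sigma[s,u]
oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  diag(S) <- 1
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      for (u in which(A[, t] > 0)) {
        if (is.finite(D[s, u]) && D[s, u] == D[s, t] - 1) {
          S[s, t] <- S[s, t] + S[s, u]
        }
      }
    }
  }
  S
}

# unnormalized betweenness: sum over unordered pairs s<t (s,t != v) of the
# fraction of s-t shortest paths through v
oracle_betweenness <- function(A) {
  D <- oracle_distances(A)
  S <- oracle_path_counts(A, D)
  n <- nrow(A)
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
        b[v] <- b[v] + S[s, v] * S[v, t] / S[s, t]
      }
    }
  }
  names(b) <- rownames(A)
  b
}

# flood-fill component labels
oracle_components <- function(A) {
  n <- nrow(A)
  lab <- rep(NA_integer_, n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (!is.na(lab[v])) next
    cur <- cur + 1L
    frontier <- v
    while (length(frontier) > 0) {
      lab[frontier] <- cur
      nxt <- unique(unlist(lapply(frontier, function(u) which(A[u, ] > 0))))
      frontier <- nxt[is.na(lab[nxt])]
    }
  }
  lab
}

# Wasserman-Faust component-scaled closeness from the distance matrix
oracle_closeness <- function(A) {
  D <- oracle_distances(A)
  lab <- oracle_components(A)
  n <- nrow(A)
  out <- numeric(n)
  for (v in seq_len(n)) {
    members <- which(lab == lab[v])
    k <- length(members)
    if (k == 1) { out[v] <- 0; next }
    out[v] <- (k - 1) / sum(D[v, members]) * (k - 1) / (n - 1)
  }
  names(out) <- rownames(A)
  out
}

oracle_state_metrics <- function(A) {
  D <- oracle_distances(A)
  lab <- oracle_components(A)
  finite <- D[upper.tri(D)][is.finite(D[upper.tri(D)]) &
                              D[upper.tri(D)] > 0]
  list(
    n_edges = sum(A) / 2,
    n_components = max(lab),
    giant_size = max(tabulate(lab)),
    avg_shortest_path = if (length(finite) > 0) mean(finite) else 0,
    diameter = if (length(finite) > 0) max(finite) else 0
  )
}

# random Erdos-Renyi graph as (igraph, adjacency) with letter names
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                      stringsAsFactors = FALSE)
  g <- igraph::make_empty_graph(0, directed = FALSE) +
    igraph::vertices(nodes)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, as.vector(t(as.matrix(edges))))
  }
  list(graph = g, adjacency = oracle_adjacency(edges, nodes),
       nodes = nodes, edges = edges)
}

# adjusted Rand index between two label vectors
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c / choose(n, 2)
  maxi <- (b + c) / 2
  (a - expected) / (maxi - expected)
}

# small igraph from a formula-like edge string "a-b,b-c"
toy_graph <- function(edge_string, isolated = character(0)) {
  pairs <- strsplit(strsplit(edge_string, ",", fixed = TRUE)[[1]], "-",
                    fixed = TRUE)
  nodes <- unique(c(unlist(pairs), isolated))
  g <- igraph::make_empty_graph(0, directed = FALSE) +
    igraph::vertices(nodes)
  igraph::add_edges(g, unlist(pairs))
}
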