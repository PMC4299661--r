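#' Node centralities of the interactome
#'
#' Degree, exact (unnormalized) shortest-path betweenness, and closeness
#' centrality. Closeness uses the Wasserman-Faust component-scaled form so
#' values remain comparable across components of a disconnected graph: for a
#' node in a component of size \eqn{k} within a graph of \eqn{n} nodes,
#' \deqn{C = \frac{k-1}{\sum_j d_{ij}} \cdot \frac{k-1}{n-1},}
#' which lies in \[0,1\]; an isolated node has closeness 0 by convention.
#' Betweenness is left unnormalized because all downstream use is rank-based.
#'
#' @param g An `igraph` interactome.
#' @return Data frame `protein`, `degree`, `betweenness`, `closeness`.
#' @export
centralities <- function(g) {
  stopifnot(igraph::vcount(g) > 0)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  comp <- igraph::components(g)
  d <- igraph::distances(g)
  clo <- numeric(n)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    k <- length(members)
    if (k == 1) { clo[members] <- 0; next }
    sumd <- rowSums(d[members, members, drop = FALSE])
    clo[members] <- (k - 1) / sumd * (k - 1) / (n - 1)
  }
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  data.frame(protein = nm, degree = as.integer(deg),
             betweenness = unname(btw), closeness = clo,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Integrity metrics of a (node-depleted) graph
#'
#' Computes the structural state of the induced subgraph on the nodes that
#' remain after deleting `removed`: surviving edge count, number of
#' components, giant-component size, average shortest path over connected
#' pairs, and diameter (largest shortest path over all components). Removed
#' identifiers not present in the graph are ignored and counted. An empty
#' remaining graph returns all-zero metrics with `empty = TRUE`.
#'
#' @param g An `igraph` interactome.
#' @param removed Character vector of node names to delete.
#' @param paths If `FALSE`, skip the all-pairs path metrics (`NA` returned);
#'   useful when only edge/component counts are needed over many replicates.
#' @return One-row data frame: `n_nodes`, `n_edges`, `n_components`,
#'   `giant_size`, `avg_shortest_path`, `diameter`, `n_removed`,
#'   `n_outside`, `empty`.
#' @export
state_metrics <- function(g, removed = character(), paths = TRUE) {
  nodes <- igraph::V(g)$name
  removed <- unique(removed)
  inside <- removed[removed %in% nodes]
  n_outside <- length(removed) - length(inside)
  h <- if (length(inside) > 0) igraph::delete_vertices(g, inside) else g
  n <- igraph::vcount(h)
  if (n == 0) {
    return(data.frame(n_nodes = 0L, n_edges = 0L, n_components = 0L,
                      giant_size = 0L, avg_shortest_path = 0,
                      diameter = 0, n_removed = length(inside),
                      n_outside = n_outside, empty = TRUE))
  }
  comp <- igraph::components(h)
  asp <- NA_real_; diam <- NA_real_
  if (paths) {
    asp <- if (igraph::ecount(h) > 0) {
      igraph::mean_distance(h, unconnected = TRUE)
    } else 0
    diam <- igraph::diameter(h, unconnected = TRUE)
  }
  data.frame(n_nodes = n, n_edges = igraph::ecount(h),
             n_components = comp$no, giant_size = max(comp$csize),
             avg_shortest_path = asp, diameter = as.numeric(diam),
             n_removed = length(inside), n_outside = n_outside,
             empty = FALSE)
}

#' Pairwise rank-sum comparisons with FDR control
#'
#' Two-sided Mann-Whitney U test for each requested pair of groups, with
#' Benjamini-Hochberg adjustment across the requested pairs. Exact p-values
#' are used for small tie-free samples and the tie-corrected normal
#' approximation otherwise (the default behaviour of [stats::wilcox.test()]).
#'
#' @param values Named list mapping group label to numeric vector.
#' @param tests List of length-2 character vectors naming the pairs to test;
#'   default all pairs.
#' @return Data frame `group_a`, `group_b`, `statistic` (U for group_a),
#'   `p_raw`, `p_fdr`.
#' @export
compare_groups <- function(values, tests = NULL) {
  stopifnot(is.list(values), length(values) >= 2)
  if (any(vapply(values, length, integer(1)) < 2)) {
    stop("every group needs at least 2 values")
  }
  if (is.null(tests)) {
    cmb <- utils::combn(names(values), 2)
    tests <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  res <- lapply(tests, function(pair) {
    w <- suppressWarnings(
      stats::wilcox.test(values[[pair[1]]], values[[pair[2]]],
                         alternative = "two.sided", exact = NULL))
    data.frame(group_a = pair[1], group_b = pair[2],
               statistic = unname(w$statistic), p_raw = w$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p_raw, method = "BH")
  out
}

#' Spearman correlation between node centrality and damage frequency
#'
#' Correlates each centrality metric with the per-protein count of damaged
#' individuals, restricted to proteins observed damaged at least once
#' (frequency >= 1), mirroring how observed-frequency spectra are built.
#'
#' @param cent Centrality table from [centralities()].
#' @param freq Frequency table from [frequency_table()].
#' @param mode Which frequency column to use: `"hom"` (both alleles) or
#'   `"het_or_hom"` (at least one allele).
#' @return Data frame `metric`, `rho`, `p`, `n`; `rho` is `NA` (flagged) for
#'   constant inputs.
#' @export
centrality_frequency_correlation <- function(cent, freq,
                                             mode = c("hom", "het_or_hom")) {
  mode <- match.arg(mode)
  col <- if (mode == "hom") "n_hom" else "n_het_or_hom"
  m <- merge(cent, freq, by = "protein")
  m <- m[m[[col]] >= 1, ]
  if (nrow(m) < 3) stop("need at least 3 proteins with nonzero frequency")
  out <- lapply(c("degree", "betweenness", "closeness"), function(metric) {
    x <- m[[metric]]; y <- m[[col]]
    if (length(unique(x)) < 2 || length(unique(y)) < 2) {
      return(data.frame(metric = metric, rho = NA_real_, p = NA_real_,
                        n = nrow(m), stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    data.frame(metric = metric, rho = unname(ct$estimate),
               p = ct$p.value, n = nrow(m), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Distribution of affected proteins across closeness quartiles
#'
#' Bins interactome proteins into four regions by the quartiles of the
#' closeness distribution, then computes, for each individual, the
#' proportion of that individual's affected proteins falling in each bin.
#' Each bin's proportions across individuals are compared with the uniform
#' expectation of 0.25 by a one-sample Wilcoxon signed-rank test.
#'
#' @param cent Centrality table from [centralities()].
#' @param profiles Profile table from [build_profiles()].
#' @param states Which affection states count (default all).
#' @return List with `proportions` (individuals x 4 matrix), `tests` (per
#'   quartile: mean proportion, p-value vs 0.25) and `breaks`.
#' @export
quartile_damage_distribution <- function(cent, profiles,
                                         states = c("affected", "het_affected",
                                                    "both_alleles_affected")) {
  stopifnot(nrow(cent) >= 4)
  qs <- stats::quantile(cent$closeness, probs = c(0.25, 0.5, 0.75))
  bin <- findInterval(cent$closeness, qs, left.open = TRUE) + 1L
  names(bin) <- cent$protein
  samples <- unique(profiles$sample)
  prop <- matrix(NA_real_, length(samples), 4,
                 dimnames = list(samples, paste0("Q", 1:4)))
  for (s in samples) {
    aff <- affected_proteins(profiles, s, states)
    aff <- aff[aff %in% names(bin)]
    if (length(aff) == 0) next
    tb <- tabulate(bin[aff], nbins = 4)
    prop[s, ] <- tb / length(aff)
  }
  prop <- prop[stats::complete.cases(prop), , drop = FALSE]
  tests <- data.frame(
    quartile = paste0("Q", 1:4),
    mean_proportion = colMeans(prop),
    p = vapply(1:4, function(j) {
      x <- prop[, j]
      if (length(unique(x)) < 2 && all(x == 0.25)) return(1)
      suppressWarnings(stats::wilcox.test(x, mu = 0.25)$p.value)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(proportions = prop, tests = tests, breaks = qs)
}
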