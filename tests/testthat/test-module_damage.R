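two_cliques <- function(k = 6) {
  # two k-cliques joined by a single bridge edge
  g1 <- igraph::make_full_graph(k)
  igraph::V(g1)$name <- paste0("a", seq_len(k))
  g2 <- igraph::make_full_graph(k)
  igraph::V(g2)$name <- paste0("b", seq_len(k))
  g <- igraph::disjoint_union(g1, g2)
  igraph::add_edges(g, c("a1", "b1"))
}

test_that("community detection recovers planted cliques and drops small ones", {
  g <- two_cliques(6)
  for (alg in c("walktrap", "infomap")) {
    part <- detect_modules(g, alg, seed = 1)
    expect_equal(length(part$modules), 2)
    sets <- lapply(part$modules, sort)
    expect_true(any(vapply(sets, identical, logical(1), sort(paste0("a", 1:6)))))
    expect_true(any(vapply(sets, identical, logical(1), sort(paste0("b", 1:6)))))
  }
  # a lone 4-clique component falls below the 5-protein minimum
  g4 <- igraph::make_full_graph(4)
  igraph::V(g4)$name <- paste0("c", 1:4)
  gg <- igraph::disjoint_union(g, g4)
  part <- detect_modules(gg, "walktrap", seed = 1)
  expect_equal(length(part$modules), 2)
  expect_equal(sum(is.na(part$membership)), 4)
  # a single 8-clique is one module of 8
  g8 <- igraph::make_full_graph(8)
  igraph::V(g8)$name <- paste0("d", 1:8)
  part8 <- detect_modules(g8, "walktrap", seed = 1)
  expect_equal(vapply(part8$modules, length, integer(1)),
               c(M1 = 8L))
  expect_error(detect_modules(g8, "leiden"), "arg")
})

test_that("module graph connects modules iff an interaction spans them", {
  g <- two_cliques(6)
  part <- detect_modules(g, "walktrap", seed = 1)
  mg <- module_graph(g, part)
  expect_equal(igraph::vcount(mg$graph), 2)
  expect_equal(igraph::ecount(mg$graph), 1)
  # no spanning edges: isolated module nodes
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c("a1", "b1")))
  part2 <- detect_modules(g2, "walktrap", seed = 1)
  mg2 <- module_graph(g2, part2)
  expect_equal(igraph::ecount(mg2$graph), 0)
  expect_true(all(mg2$closeness == 0))
})

test_that("a planted module chain ranks middle modules as most central", {
  # 4 cliques connected in a chain: closeness on the 4-node path graph
  gs <- lapply(1:4, function(i) {
    gi <- igraph::make_full_graph(5)
    igraph::V(gi)$name <- paste0("m", i, "_", 1:5)
    gi
  })
  g <- Reduce(igraph::disjoint_union, gs)
  g <- igraph::add_edges(g, c("m1_1", "m2_1", "m2_2", "m3_1", "m3_2", "m4_1"))
  part <- detect_modules(g, "walktrap", seed = 1)
  expect_equal(length(part$modules), 4)
  mg <- module_graph(g, part)
  clo <- mg$closeness
  chain_pos <- vapply(names(clo), function(m) {
    as.integer(substr(part$modules[[m]][1], 2, 2))
  }, integer(1))
  expect_true(min(clo[chain_pos %in% c(2, 3)]) >
                max(clo[chain_pos %in% c(1, 4)]))
})

test_that("mid-rank percentile formula hits its anchor points", {
  # observation above every null value
  expect_equal(midrank_percentile(10, 1:8), 1)
  # observation at the median of an even-length tie-free null
  expect_equal(midrank_percentile(5, c(1, 2, 4, 6, 8, 9)), 0.5)
  # all null values tied with the observation
  expect_equal(midrank_percentile(3, rep(3, 10)), 0.5)
  expect_equal(midrank_percentile(0, 1:10), 0)
})

test_that("relative damage matches exhaustive enumeration on a 6-node toy", {
  # 2 modules of 3; universe of 6; 2 affected proteins
  g <- toy_graph("x1-x2,x2-x3,y1-y2,y2-y3,x1-y1")
  part <- structure(list(
    modules = list(MX = c("x1", "x2", "x3"), MY = c("y1", "y2", "y3")),
    membership = NULL, algorithm = "manual", min_size = 3, seed = 1),
    class = "module_partition")
  universe <- c("x1", "x2", "x3", "y1", "y2", "y3")
  affected <- c("x1", "x2")

  rd <- relative_damage(part, affected, universe, exhaustive = TRUE)

  # independent oracle: enumerate all C(6,2)=15 placements directly
  combos <- combn(universe, 2)
  for (mod in c("MX", "MY")) {
    members <- part$modules[[mod]]
    obs <- sum(affected %in% members) / 3
    null <- apply(combos, 2, function(s) sum(s %in% members) / 3)
    want <- (sum(null < obs) + 0.5 * sum(null == obs)) / 15
    expect_equal(unname(rd[mod]), want)
  }
  expect_true(all(rd >= 0 & rd <= 1))

  # sampled permutations approach the exhaustive value
  rs <- relative_damage(part, affected, universe, n_perm = 4000, seed = 2)
  expect_equal(unname(rs["MX"]), unname(rd["MX"]), tolerance = 0.05)

  # min-max rescaling stays in bounds and agrees at the extremes
  rm_ <- relative_damage(part, affected, universe, exhaustive = TRUE,
                         method = "minmax")
  expect_true(all(rm_ >= 0 & rm_ <= 1))
  expect_equal(unname(rm_["MX"]), 1)  # 2/3 observed is the null maximum

  # empty affected set: every module at the null median, flagged
  r0 <- relative_damage(part, character(0), universe)
  expect_true(all(r0 == 0.5))
  expect_true(attr(r0, "empty_profile"))
})

test_that("relative damage is bounded, centred under uniform placement, and conserves counts", {
  spec <- synth_spec(n_proteins = 150, n_modules = 5, seed = 31)
  net <- generate_interactome(spec)
  part <- detect_modules(net$graph, "walktrap", seed = 1)
  universe <- igraph::V(net$graph)$name
  set.seed(8)
  vals <- c()
  for (i in 1:30) {
    aff <- sample(universe, 12)
    rd <- relative_damage(part, aff, universe, n_perm = 200, seed = i)
    expect_true(all(rd >= 0 & rd <= 1))
    # conservation: sum over modules of size x observed proportion equals
    # the number of affected proteins assigned to retained modules
    op <- attr(rd, "observed_proportion")
    sizes <- vapply(part$modules, length, integer(1))
    assigned <- sum(vapply(part$modules, function(m) sum(aff %in% m),
                           integer(1)))
    expect_equal(sum(sizes * op), assigned)
    vals <- c(vals, rd)
  }
  # under unbiased placement the pooled mean sits at 0.5 within 3 SE
  expect_lt(abs(mean(vals) - 0.5), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("population damage matrix averages individuals and feeds clustering", {
  m <- matrix(c(0.2, 0.8, 0.4,
                0.6, 0.4, 0.4), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("M1", "M2")))
  man <- data.frame(sample = c("s1", "s2", "s3"),
                    population = c("A", "A", "B"))
  dm <- damage_matrix(m, man)
  expect_equal(dm["M1", "A"], 0.5)
  expect_equal(dm["M1", "B"], 0.4)
  # single individual: matrix equals that individual's vector
  dm1 <- damage_matrix(m[3, , drop = FALSE], man[3, ])
  expect_equal(unname(dm1[, "B"]), unname(m[3, ]))

  # identical columns merge at height zero; an outlier merges last
  mm <- cbind(A = c(0.1, 0.2, 0.3, 0.4), B = c(0.1, 0.2, 0.3, 0.4),
              C = c(0.9, 0.8, 0.1, 0.05))
  rownames(mm) <- paste0("M", 1:4)
  cl <- cluster_profiles(mm, "populations")
  expect_equal(min(cl$hclust$height), 0)
  expect_equal(cl$cophenetic["A", "B"], 0)
  expect_true(cl$cophenetic["A", "C"] > cl$cophenetic["A", "B"])
  expect_match(cl$newick, "^\\(")
  # three items with pairwise distances (1,1,10): the close pair merges first
  m3 <- cbind(a = 0, b = 1, c = 10); rownames(m3) <- "M1"
  cl3 <- cluster_profiles(rbind(m3, m3 * 0), "populations")
  first_merge <- -cl3$hclust$merge[1, ]
  expect_equal(sort(cl3$hclust$labels[first_merge]), c("a", "b"))
})

test_that("module centrality-damage correlation recovers planted sign", {
  clo <- c(M1 = 0.1, M2 = 0.3, M3 = 0.5, M4 = 0.7, M5 = 0.9)
  mg <- list(closeness = clo)
  dmg_down <- c(M1 = 0.9, M2 = 0.7, M3 = 0.5, M4 = 0.3, M5 = 0.1)
  r <- centrality_damage_correlation(mg, dmg_down)
  expect_equal(r$rho, -1)
  r2 <- centrality_damage_correlation(
    mg, stats::setNames(rev(unname(dmg_down)), names(clo)))
  expect_equal(r2$rho, 1)
  expect_true(is.na(centrality_damage_correlation(
    mg, stats::setNames(rep(0.5, 5), names(clo)))$rho))
  expect_error(centrality_damage_correlation(list(closeness = clo[1:2]),
                                             dmg_down[1:2]))
})
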