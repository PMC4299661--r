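#' Detect interactome modules by random-walk community detection
#'
#' Partitions the interactome into communities with Walktrap (random walks of
#' length 4, its common default) or Infomap (two-level, default settings).
#' Communities with fewer than `min_size` proteins are discarded and their
#' proteins marked unassigned; such proteins still belong to the permutation
#' universe of [relative_damage()] but to no scored module.
#'
#' @param g An `igraph` interactome.
#' @param algorithm `"walktrap"` or `"infomap"`.
#' @param min_size Minimum community size retained.
#' @param seed Integer seed (Infomap is stochastic; Walktrap deterministic,
#'   seeded anyway for uniformity).
#' @return Object of class `module_partition`: list with `modules` (named
#'   list module id -> character vector of proteins), `membership` (named
#'   vector, `NA` for unassigned), `algorithm`, `min_size`, `seed`.
#' @export
detect_modules <- function(g, algorithm = c("walktrap", "infomap"),
                           min_size = 5, seed = 1) {
  algorithm <- match.arg(algorithm)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cl <- switch(algorithm,
    walktrap = igraph::cluster_walktrap(g, steps = 4),
    infomap = igraph::cluster_infomap(g)
  )
  memb <- igraph::membership(cl)
  nm <- igraph::V(g)$name
  names(memb) <- nm
  sizes <- table(memb)
  keep_ids <- names(sizes)[sizes >= min_size]
  memb_out <- ifelse(as.character(memb) %in% keep_ids,
                     as.character(memb), NA_character_)
  names(memb_out) <- nm
  # stable relabelling M1, M2, ... by decreasing size then first member
  ord <- order(-as.integer(sizes[keep_ids]), keep_ids)
  relabel <- stats::setNames(paste0("M", seq_along(keep_ids)), keep_ids[ord])
  memb_out[!is.na(memb_out)] <- relabel[memb_out[!is.na(memb_out)]]
  modules <- split(nm[!is.na(memb_out)], memb_out[!is.na(memb_out)])
  modules <- modules[order(as.integer(sub("M", "", names(modules))))]
  structure(list(modules = modules, membership = memb_out,
                 algorithm = algorithm, min_size = min_size, seed = seed),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition:", length(x$modules), "modules (",
      x$algorithm, ", min_size =", x$min_size, ")\n")
  cat("  sizes:", paste(vapply(x$modules, length, integer(1)),
                        collapse = " "), "\n")
  cat("  unassigned proteins:", sum(is.na(x$membership)), "\n")
  invisible(x)
}

#' Module-level graph and module closeness
#'
#' Collapses the interactome to a graph whose nodes are retained modules;
#' two modules are connected when at least one interaction spans proteins of
#' the two. Module closeness is the Wasserman-Faust component-scaled
#' closeness computed on this module graph.
#'
#' @param g An `igraph` interactome.
#' @param part A `module_partition` from [detect_modules()].
#' @return List with `graph` (module-level `igraph`) and `closeness`
#'   (named numeric per module).
#' @export
module_graph <- function(g, part) {
  stopifnot(inherits(part, "module_partition"))
  ids <- names(part$modules)
  el <- igraph::as_edgelist(g)
  ma <- part$membership[el[, 1]]
  mb <- part$membership[el[, 2]]
  span <- !is.na(ma) & !is.na(mb) & ma != mb
  pairs <- unique(cbind(pmin(ma[span], mb[span]), pmax(ma[span], mb[span])))
  mg <- igraph::make_empty_graph(0, directed = FALSE) +
    igraph::vertices(ids)
  if (length(pairs) > 0 && nrow(pairs) > 0) {
    mg <- igraph::add_edges(mg, t(pairs))
  }
  clo <- if (length(ids) > 0) {
    ct <- centralities(mg)
    stats::setNames(ct$closeness, ct$protein)
  } else stats::setNames(numeric(0), character(0))
  list(graph = mg, closeness = clo[ids])
}

#' Mid-rank empirical percentile
#'
#' Fraction of null draws strictly below the observation plus half the
#' fraction tied with it. An observation at the median of an even-length
#' tie-free null maps to exactly 0.5.
#'
#' @param obs Observed value.
#' @param null_values Numeric vector of null draws.
#' @return A value in \[0,1\].
#' @export
midrank_percentile <- function(obs, null_values) {
  (sum(null_values < obs) + 0.5 * sum(null_values == obs)) /
    length(null_values)
}

#' Relative damage of each module for one individual
#'
#' The observed statistic per module is the proportion of its proteins
#' affected in the individual. The null re-places the same number of
#' affected proteins uniformly at random over the whole interactome node
#' universe (every protein equally likely, including proteins of discarded
#' small communities) and recomputes the per-module proportion; relative
#' damage is the mid-rank empirical percentile of the observed proportion
#' within its module's null distribution,
#' \deqn{RD = \frac{\#\{null < obs\} + 0.5\,\#\{null = obs\}}{n_{perm}},}
#' which lies in \[0,1\] and equals 0.5 when the observation sits at the
#' median of a tie-free null. With `exhaustive = TRUE` (feasible only for
#' tiny universes) all \eqn{\binom{n}{k}} placements are enumerated instead
#' of sampled, making the percentile exact.
#'
#' @param part A `module_partition`.
#' @param affected Character vector of affected proteins for one individual
#'   (typically [affected_proteins()] with the states matching the chosen
#'   zygosity interpretation).
#' @param universe Character vector of interactome node names (the placement
#'   universe). Affected proteins outside it are ignored.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param exhaustive If `TRUE`, enumerate all placements exactly.
#' @param method `"percentile"` (default, the mid-rank percentile above) or
#'   `"minmax"`: the observed proportion min-max rescaled against the range
#'   of its null distribution, clamped to \[0,1\]. The percentile is the
#'   canonical statistic; min-max is provided to probe sensitivity to the
#'   rescaling convention.
#' @return Named numeric vector of relative damage per module, with
#'   attribute `observed_proportion` (named numeric) and `n_affected`. When
#'   `affected` is empty every module gets 0.5 and attribute
#'   `empty_profile = TRUE` is set.
#' @export
relative_damage <- function(part, affected, universe, n_perm = 1000,
                            seed = 1, exhaustive = FALSE,
                            method = c("percentile", "minmax")) {
  method <- match.arg(method)
  stopifnot(inherits(part, "module_partition"))
  ids <- names(part$modules)
  sizes <- vapply(part$modules, length, integer(1))
  affected <- unique(affected[affected %in% universe])
  k <- length(affected)
  obs <- vapply(part$modules, function(p) sum(affected %in% p),
                numeric(1)) / sizes
  if (k == 0) {
    out <- stats::setNames(rep(0.5, length(ids)), ids)
    attr(out, "observed_proportion") <- obs
    attr(out, "n_affected") <- 0L
    attr(out, "empty_profile") <- TRUE
    return(out)
  }
  idx_universe <- seq_along(universe)
  mod_idx <- lapply(part$modules, function(p) match(p, universe))
  if (exhaustive) {
    stopifnot(choose(length(universe), k) <= 1e5)
    combos <- utils::combn(idx_universe, k)
    null_prop <- matrix(NA_real_, ncol(combos), length(ids))
    for (j in seq_len(ncol(combos))) {
      sel <- combos[, j]
      null_prop[j, ] <- vapply(mod_idx, function(mi) sum(mi %in% sel),
                               numeric(1)) / sizes
    }
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    null_prop <- matrix(NA_real_, n_perm, length(ids))
    in_mod <- matrix(FALSE, length(universe), length(ids))
    for (m in seq_along(ids)) in_mod[mod_idx[[m]], m] <- TRUE
    for (j in seq_len(n_perm)) {
      sel <- sample.int(length(universe), k)
      null_prop[j, ] <- colSums(in_mod[sel, , drop = FALSE]) / sizes
    }
  }
  out <- vapply(seq_along(ids), function(m) {
    if (method == "percentile") {
      midrank_percentile(obs[m], null_prop[, m])
    } else {
      rng <- range(null_prop[, m])
      if (rng[2] == rng[1]) return(0.5)
      min(1, max(0, (obs[m] - rng[1]) / (rng[2] - rng[1])))
    }
  }, numeric(1))
  names(out) <- ids
  attr(out, "observed_proportion") <- obs
  attr(out, "n_affected") <- k
  out
}

#' Relative damage for every individual of a cohort
#'
#' Runs [relative_damage()] per individual with the affection states implied
#' by `zygosity_mode` (`any_allele`: any state counts; `recessive`: only
#' both-alleles-affected proteins count). Per-individual seeds are derived
#' from `seed` so the cohort is reproducible as a whole.
#'
#' @param part A `module_partition`.
#' @param profiles Profile table from [build_profiles()].
#' @param zygosity_mode `"any_allele"` (default, one damaged allele marks a
#'   protein affected) or `"recessive"`.
#' @param n_perm,seed As in [relative_damage()].
#' @return Matrix samples x modules of relative damage values, with the
#'   manifest (`sample`, `population`) as attribute `samples`.
#' @export
relative_damage_cohort <- function(part, profiles,
                                   zygosity_mode = c("any_allele",
                                                     "recessive"),
                                   n_perm = 1000, seed = 1) {
  zygosity_mode <- match.arg(zygosity_mode)
  states <- if (zygosity_mode == "recessive") "both_alleles_affected" else {
    c("affected", "het_affected", "both_alleles_affected")
  }
  samples <- attr(profiles, "samples")
  universe <- attr(profiles, "proteins")
  stopifnot(!is.null(samples), !is.null(universe))
  ids <- names(part$modules)
  out <- matrix(NA_real_, nrow(samples), length(ids),
                dimnames = list(samples$sample, ids))
  for (i in seq_len(nrow(samples))) {
    aff <- affected_proteins(profiles, samples$sample[i], states)
    out[i, ] <- relative_damage(part, aff, universe, n_perm = n_perm,
                                seed = seed + i)
  }
  attr(out, "samples") <- samples
  out
}

#' Modules x populations relative-damage matrix
#'
#' Aggregates per-individual relative damage to population level by the
#' arithmetic mean over the individuals of each population.
#'
#' @param per_individual Samples x modules matrix from
#'   [relative_damage_cohort()].
#' @param manifest Data frame `sample`, `population`; defaults to the
#'   matrix's `samples` attribute.
#' @return Modules x populations numeric matrix.
#' @export
damage_matrix <- function(per_individual, manifest = NULL) {
  if (is.null(manifest)) manifest <- attr(per_individual, "samples")
  stopifnot(!is.null(manifest))
  pops <- unique(manifest$population)
  out <- sapply(pops, function(p) {
    s <- manifest$sample[manifest$population == p]
    colMeans(per_individual[rownames(per_individual) %in% s, , drop = FALSE])
  })
  out <- matrix(out, nrow = ncol(per_individual),
                dimnames = list(colnames(per_individual), pops))
  out
}

#' Correlation between module centrality and module damage
#'
#' Spearman correlation of module closeness (from [module_graph()]) against
#' one population's relative damage column. A negative coefficient means
#' damage accumulates in peripheral modules; positive, in central ones.
#'
#' @param mg List from [module_graph()].
#' @param damage Named numeric of relative damage per module (one column of
#'   the damage matrix).
#' @return One-row data frame `rho`, `p`, `n`; `rho` is `NA` for constant
#'   input.
#' @export
centrality_damage_correlation <- function(mg, damage) {
  ids <- intersect(names(mg$closeness), names(damage))
  stopifnot(length(ids) >= 3)
  x <- mg$closeness[ids]; y <- damage[ids]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(data.frame(rho = NA_real_, p = NA_real_, n = length(ids)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  data.frame(rho = unname(ct$estimate), p = ct$p.value, n = length(ids))
}

#' Hierarchical clustering of damage profiles
#'
#' Agglomerative clustering on Euclidean distances between the columns
#' (populations) or rows (modules) of the relative-damage matrix, arranging
#' items by the resemblance of their damage patterns.
#'
#' @param m Modules x populations matrix from [damage_matrix()].
#' @param axis `"populations"` (cluster columns) or `"modules"` (rows).
#' @param linkage `"complete"` (default) or `"average"`.
#' @return List with `hclust`, `newick` (dendrogram serialized as a Newick
#'   string), `cophenetic` (distance matrix), and `merge_order` (labels in
#'   order of first merge).
#' @export
cluster_profiles <- function(m, axis = c("populations", "modules"),
                             linkage = c("complete", "average")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  x <- if (axis == "populations") t(m) else m
  stopifnot(nrow(x) >= 2)
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, newick = newick,
       cophenetic = as.matrix(stats::cophenetic(hc)),
       merge_order = hc$labels[hc$order])
}
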