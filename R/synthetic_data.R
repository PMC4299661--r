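#' Specification for synthetic interactome cohorts
#'
#' Bundles every knob of the synthetic-data generators. The defaults
#' describe a desk-scale modular interactome — a planted-partition graph of
#' 400 proteins in 8 modules, dense within modules and sparse between, with
#' module 1 acting as a better-connected core so that closeness varies
#' across the graph — and a two-population cohort of 20 individuals each
#' whose per-protein deleterious-variant carrier probability depends on
#' closeness rank with sign and strength `placement_bias`.
#'
#' @param n_proteins Number of proteins (nodes).
#' @param n_modules Number of planted modules.
#' @param intra_module_edge_prob Edge probability within a module.
#' @param inter_module_edge_prob Edge probability between chain-adjacent
#'   peripheral modules (see [generate_interactome()] for the topology).
#' @param hub_fraction Strength of the core module's extra attachment to the
#'   rest of the graph: module 1's between-module edge probability is
#'   `inter_module_edge_prob + hub_fraction * intra_module_edge_prob`.
#' @param populations Character vector of population labels.
#' @param n_individuals Individuals per population (recycled).
#' @param placement_bias Signed bias \eqn{\beta \in [-1,1]} (recycled per
#'   population): a protein at closeness rank fraction \eqn{r \in (0,1)}
#'   carries a deleterious variant with probability
#'   \eqn{rate \cdot (1 + \beta (2r - 1))}, so \eqn{\beta < 0} concentrates
#'   damage in peripheral proteins and \eqn{\beta > 0} in central ones.
#' @param carrier_rate Baseline per-protein carrier probability.
#' @param hom_fraction Fraction of carrier genotypes made homozygous
#'   alternative (the rest are heterozygous).
#' @param benign_fraction Fraction of proteins also given a benign missense
#'   variant (fails the deleteriousness rules).
#' @param synonymous_fraction Fraction of proteins given a synonymous
#'   variant (for mutation-spectrum readouts).
#' @param preserve_connectivity If `TRUE`, each individual's homozygous
#'   removal set is rejection-sampled so that deleting it strands at most
#'   `max_excess_disconnection` nodes beyond the deleted ones — emulating
#'   damage combinations that preserve interactome connectivity.
#' @param max_excess_disconnection Tolerated number of additionally
#'   disconnected nodes under `preserve_connectivity`.
#' @param seed Integer seed; all generators are pure functions of
#'   (spec, seed).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_proteins = 400, n_modules = 8,
                       intra_module_edge_prob = 0.12,
                       inter_module_edge_prob = 0.004,
                       hub_fraction = 0.1,
                       populations = c("POP1", "POP2"),
                       n_individuals = 20,
                       placement_bias = -0.5,
                       carrier_rate = 0.05,
                       hom_fraction = 0.3,
                       benign_fraction = 0.5,
                       synonymous_fraction = 0.5,
                       preserve_connectivity = FALSE,
                       max_excess_disconnection = 2,
                       seed = 1) {
  stopifnot(n_proteins >= n_modules * 2,
            intra_module_edge_prob >= 0, intra_module_edge_prob <= 1,
            inter_module_edge_prob >= 0, inter_module_edge_prob <= 1,
            all(abs(placement_bias) <= 1),
            hom_fraction >= 0, hom_fraction <= 1)
  structure(list(
    n_proteins = n_proteins, n_modules = n_modules,
    intra_module_edge_prob = intra_module_edge_prob,
    inter_module_edge_prob = inter_module_edge_prob,
    hub_fraction = hub_fraction,
    populations = populations,
    n_individuals = rep_len(n_individuals, length(populations)),
    placement_bias = rep_len(placement_bias, length(populations)),
    carrier_rate = carrier_rate, hom_fraction = hom_fraction,
    benign_fraction = benign_fraction,
    synonymous_fraction = synonymous_fraction,
    preserve_connectivity = preserve_connectivity,
    max_excess_disconnection = max_excess_disconnection,
    seed = seed
  ), class = "synth_spec")
}

#' Generate a modular synthetic interactome
#'
#' Planted-partition graph of `n_modules` equal-size blocks. Each block's
#' internal subgraph is scale-free-ish (static fitness model, power-law
#' exponent 2.5) with expected edge density `intra_module_edge_prob`, giving
#' the heavy low-degree tail typical of curated interactomes. Between
#' blocks the topology is a core-and-chain: block 1 (the core) attaches to
#' every other block with elevated density
#' `inter_module_edge_prob + hub_fraction * intra_module_edge_prob`, while
#' peripheral blocks are chained to their index neighbours at
#' `inter_module_edge_prob`; between-module edges attach preferentially to
#' within-module hubs. Closeness therefore declines from the core toward
#' the chain ends at both the protein and the module level. Vertices are
#' named `P0001`, `P0002`, ... Deterministic given `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return List with `graph` (`igraph`) and `true_modules` (named character
#'   vector of planted block labels).
#' @export
generate_interactome <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$n_proteins; B <- spec$n_modules
  sizes <- rep(n %/% B, B)
  sizes[seq_len(n %% B)] <- sizes[seq_len(n %% B)] + 1L
  block_of <- rep(seq_len(B), sizes)
  names_v <- sprintf("P%04d", seq_len(n))

  # within-block subgraphs are scale-free-ish (fitness model, exponent 2.5)
  # so the degree distribution has the heavy low-degree tail of curated
  # interactomes and node removal can strand peripheral proteins
  el <- matrix(integer(0), 0, 2)
  for (b in seq_len(B)) {
    idx <- which(block_of == b)
    s <- length(idx)
    m_b <- round(spec$intra_module_edge_prob * s * (s - 1) / 2)
    if (m_b > 0) {
      gb <- igraph::sample_fitness_pl(s, m_b, exponent.out = 2.5)
      el <- rbind(el, matrix(idx[as.vector(igraph::as_edgelist(gb))],
                             ncol = 2))
    }
  }
  deg_w <- tabulate(as.vector(el), nbins = n) + 1  # hub-preferential gluing

  # core block 1 attaches to every block; peripheral blocks form a chain,
  # so closeness declines from the core toward the chain ends
  core_p <- min(1, spec$inter_module_edge_prob +
                  spec$hub_fraction * spec$intra_module_edge_prob)
  for (i in seq_len(B - 1)) for (j in (i + 1):B) {
    p_ij <- if (i == 1) core_p else {
      if (j == i + 1) spec$inter_module_edge_prob else 0
    }
    if (p_ij <= 0) next
    ii <- which(block_of == i); jj <- which(block_of == j)
    m_ij <- stats::rbinom(1, length(ii) * length(jj), p_ij)
    if (m_ij == 0) next
    a <- sample(ii, m_ij, replace = TRUE, prob = deg_w[ii])
    bb <- sample(jj, m_ij, replace = TRUE, prob = deg_w[jj])
    el <- rbind(el, cbind(a, bb))
  }

  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  g <- igraph::simplify(g)
  igraph::V(g)$name <- names_v
  labels <- paste0("B", block_of)
  names(labels) <- names_v
  n_singleton <- sum(igraph::degree(g) == 0)
  if (n_singleton > 0.05 * n) {
    warning(n_singleton, " isolated proteins; edge probabilities may be too sparse")
  }
  list(graph = g, true_modules = labels)
}

#' Generate a multi-population genotype cohort over an interactome
#'
#' For every protein, draws one deleterious missense variant (SIFT below
#' 0.05 and PolyPhen above 0.95) and, for random subsets of proteins, a
#' benign missense variant (scores failing both rules) and a synonymous
#' variant. Each individual carries the deleterious variant of protein
#' \eqn{i} with probability monotone in the protein's closeness rank (sign
#' and strength from the population's `placement_bias`), with a fraction
#' `hom_fraction` of carrier genotypes homozygous. With
#' `preserve_connectivity` the homozygous set of each individual is
#' rejection-sampled to strand almost no nodes beyond those deleted.
#'
#' @param interactome Result of [generate_interactome()] (or an `igraph`).
#' @param spec A [synth_spec()].
#' @param dir Optional directory: when given, writes `cohort.vcf`,
#'   `annotation.tsv` and `manifest.tsv` there.
#' @return List with `variants` (annotation data frame carrying a
#'   `genotypes` dosage-matrix attribute), `manifest`, `truth` (per-protein
#'   carrier probabilities per population plus realized `n_hom` /
#'   `n_het_or_hom` counts), `files` (paths or `NULL`) and `seed`.
#' @export
generate_population <- function(interactome, spec, dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  g <- if (igraph::is_igraph(interactome)) interactome else interactome$graph
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 1L)

  cent <- centralities(g)
  prot <- cent$protein
  n <- length(prot)
  r <- (rank(cent$closeness, ties.method = "average") - 0.5) / n

  manifest <- do.call(rbind, lapply(seq_along(spec$populations), function(pi) {
    data.frame(
      sample = sprintf("%s_I%03d", spec$populations[pi],
                       seq_len(spec$n_individuals[pi])),
      population = spec$populations[pi], stringsAsFactors = FALSE)
  }))

  # deleterious variant per protein; benign / synonymous for subsets
  n_benign <- round(spec$benign_fraction * n)
  n_syn <- round(spec$synonymous_fraction * n)
  benign_prot <- sample(prot, n_benign)
  syn_prot <- sample(prot, n_syn)
  variants <- rbind(
    data.frame(protein = prot, consequence = "missense",
               sift = stats::runif(n, 0, 0.04),
               polyphen = stats::runif(n, 0.96, 1),
               phastcons = stats::runif(n, 250, 600), class = "deleterious",
               stringsAsFactors = FALSE),
    data.frame(protein = benign_prot, consequence = "missense",
               sift = stats::runif(n_benign, 0.2, 1),
               polyphen = stats::runif(n_benign, 0, 0.9),
               phastcons = stats::runif(n_benign, 0, 150), class = "benign",
               stringsAsFactors = FALSE),
    data.frame(protein = syn_prot, consequence = "synonymous",
               sift = NA_real_, polyphen = NA_real_,
               phastcons = stats::runif(n_syn, 0, 300), class = "synonymous",
               stringsAsFactors = FALSE)
  )
  variants$chrom <- "1"
  variants$pos <- seq_len(nrow(variants)) * 10L
  variants$ref <- "A"
  variants$alt <- "G"
  variants <- variants[, c("chrom", "pos", "ref", "alt", "protein",
                           "consequence", "sift", "polyphen", "phastcons",
                           "class")]

  gmat <- matrix(0L, nrow(variants), nrow(manifest),
                 dimnames = list(NULL, manifest$sample))
  del_rows <- which(variants$class == "deleterious")
  carrier_prob <- matrix(NA_real_, n, length(spec$populations),
                         dimnames = list(prot, spec$populations))
  for (pi in seq_along(spec$populations)) {
    beta <- spec$placement_bias[pi]
    p <- spec$carrier_rate * (1 + beta * (2 * r - 1))
    carrier_prob[, pi] <- pmin(pmax(p, 1e-4), 0.95)
  }
  for (si in seq_len(nrow(manifest))) {
    pi <- match(manifest$population[si], spec$populations)
    draw <- function() {
      carrier <- stats::runif(n) < carrier_prob[, pi]
      hom <- carrier & stats::runif(n) < spec$hom_fraction
      list(dos = ifelse(hom, 2L, ifelse(carrier, 1L, 0L)),
           removal = prot[hom])
    }
    d <- draw()
    if (spec$preserve_connectivity) {
      best <- d
      best_excess <- .excess_disconnection(g, d$removal)
      for (try in seq_len(50)) {
        if (best_excess <= spec$max_excess_disconnection) break
        d <- draw()
        ex <- .excess_disconnection(g, d$removal)
        if (ex < best_excess) { best <- d; best_excess <- ex }
      }
      d <- best
    }
    gmat[del_rows, si] <- d$dos
  }
  # background genotypes at benign/synonymous sites, unbiased low frequency
  other_rows <- which(variants$class != "deleterious")
  for (i in other_rows) {
    carrier <- stats::runif(nrow(manifest)) < spec$carrier_rate
    hom <- carrier & stats::runif(nrow(manifest)) < spec$hom_fraction
    gmat[i, ] <- ifelse(hom, 2L, ifelse(carrier, 1L, 0L))
  }

  # realized ground-truth frequencies from the generator's own bookkeeping
  truth_freq <- do.call(rbind, lapply(spec$populations, function(pp) {
    cols <- manifest$sample[manifest$population == pp]
    sub <- gmat[del_rows, cols, drop = FALSE]
    data.frame(population = pp, protein = variants$protein[del_rows],
               n_het_or_hom = as.integer(rowSums(sub > 0)),
               n_hom = as.integer(rowSums(sub == 2)),
               n_total = length(cols), stringsAsFactors = FALSE)
  }))

  files <- NULL
  ann <- variants[, setdiff(names(variants), "class")]
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(vcf = file.path(dir, "cohort.vcf"),
                  annotation = file.path(dir, "annotation.tsv"),
                  manifest = file.path(dir, "manifest.tsv"))
    .write_vcf(variants, gmat, files$vcf)
    utils::write.table(ann, files$annotation, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(manifest, files$manifest, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  attr(ann, "genotypes") <- gmat
  list(variants = ann, manifest = manifest,
       truth = list(carrier_prob = carrier_prob, frequencies = truth_freq,
                    deleterious_proteins = variants$protein[del_rows],
                    variant_class = variants$class),
       files = files, seed = spec$seed)
}

# nodes stranded beyond the deleted ones when `removal` is cut out
.excess_disconnection <- function(g, removal) {
  n <- igraph::vcount(g)
  giant0 <- max(igraph::components(g)$csize)
  if (length(removal) == 0) return(0L)
  h <- igraph::delete_vertices(g, removal)
  giant1 <- max(igraph::components(h)$csize)
  (giant0 - length(removal)) - giant1
}

.write_vcf <- function(variants, gmat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gmat)), collapse = "\t")
  ), con)
  gt <- matrix(c("0/0", "0/1", "1/1")[gmat + 1L], nrow(gmat))
  rows <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
            variants$alt[i], ".", "PASS", ".", "GT", gt[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(rows, con)
}

#' Generate a MITAB 2.5 fixture with known curation outcome
#'
#' Writes interaction evidence rows with planted detection-method
#' multiplicities and interaction types — one row per (pair, method)
#' evidence — and returns the exactly expected post-curation edge set, so
#' parsing and curation can be verified round trip.
#'
#' @param path Output MITAB file path.
#' @param n_pairs Number of distinct protein pairs to plant.
#' @param method_counts Integer vector (recycled) of distinct detection
#'   methods per pair.
#' @param types Character vector (recycled) of interaction-type labels per
#'   pair.
#' @param min_methods Curation threshold used to compute the expected edges.
#' @param seed Integer seed.
#' @return List with `path`, `planted` (pair, n_methods, type) and
#'   `expected_edges` (data frame `protein_a`, `protein_b` after curation
#'   at `min_methods` and physical-association type).
#' @export
generate_mitab <- function(path, n_pairs = 10,
                           method_counts = c(1L, 2L, 2L, 3L),
                           types = "physical association",
                           min_methods = 2, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  methods_vocab <- c("psi-mi:MI:0018(two hybrid)",
                     "psi-mi:MI:0019(coimmunoprecipitation)",
                     "psi-mi:MI:0055(fluorescent resonance energy transfer)",
                     "psi-mi:MI:0114(x-ray crystallography)",
                     "psi-mi:MI:0096(pull down)")
  type_term <- function(lbl) {
    switch(lbl,
           "physical association" = "psi-mi:MI:0915(physical association)",
           "colocalization" = "psi-mi:MI:0403(colocalization)",
           paste0("psi-mi:MI:0000(", lbl, ")"))
  }
  acc <- sprintf("Q%05d", sample.int(99999, 2 * n_pairs))
  pair_a <- acc[seq_len(n_pairs)]
  pair_b <- acc[n_pairs + seq_len(n_pairs)]
  counts <- rep_len(as.integer(method_counts), n_pairs)
  type_lbl <- rep_len(types, n_pairs)
  lines <- character(0)
  for (i in seq_len(n_pairs)) {
    ms <- methods_vocab[seq_len(counts[i])]
    for (m in ms) {
      f <- c(paste0("uniprotkb:", pair_a[i]), paste0("uniprotkb:", pair_b[i]),
             "-", "-", "-", "-", m, "-", "pubmed:12345678",
             "taxid:9606(human)", "taxid:9606(human)",
             type_term(type_lbl[i]), "psi-mi:MI:0469(IntAct)",
             paste0("intact:EBI-", i), "-")
      lines <- c(lines, paste(f, collapse = "\t"))
    }
  }
  writeLines(lines, path)
  keep <- counts >= min_methods & type_lbl == "physical association"
  expected <- data.frame(protein_a = pmin(pair_a, pair_b)[keep],
                         protein_b = pmax(pair_a, pair_b)[keep],
                         stringsAsFactors = FALSE)
  list(path = path,
       planted = data.frame(protein_a = pair_a, protein_b = pair_b,
                            n_methods = counts, type = type_lbl,
                            stringsAsFactors = FALSE),
       expected_edges = expected)
}
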