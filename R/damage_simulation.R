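#' Per-individual interactome damage
#'
#' Builds each individual's interactome by deleting the proteins with both
#' alleles affected by a deleterious variant (including compound
#' heterozygotes) and measures the structural state of what remains.
#'
#' @param g An `igraph` interactome.
#' @param profiles Profile table from [build_profiles()], recessive mode.
#' @param paths Passed to [state_metrics()]; set `FALSE` to skip the
#'   all-pairs path metrics over large cohorts.
#' @return Data frame, one row per individual: `sample`, `population`,
#'   `n_removed` plus the [state_metrics()] columns.
#' @export
observe_damage <- function(g, profiles, paths = TRUE) {
  samples <- attr(profiles, "samples")
  stopifnot(!is.null(samples))
  out <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples$sample[i]
    rem <- affected_proteins(profiles, s, states = "both_alleles_affected")
    m <- state_metrics(g, rem, paths = paths)
    cbind(data.frame(sample = s, population = samples$population[i],
                     stringsAsFactors = FALSE), m)
  })
  do.call(rbind, out)
}

#' Simulate node-removal null ensembles
#'
#' Generates `n_sim` randomly damaged interactomes. For each draw a removal
#' count \eqn{k} is resampled from the multiset of counts observed in the
#' population, then \eqn{k} distinct proteins are deleted:
#'
#' * `uniform`: every protein equally likely (sampling without replacement),
#'   the expectation of random damage for a given removal count;
#' * `frequency_weighted`: proteins sampled successively without replacement
#'   with probability proportional to their observed population damage
#'   frequency, so simulated individuals only carry damage in proteins that
#'   are damaged in real individuals, but in random combinations. The pool is
#'   restricted to proteins with `n_hom > 0` and weights are pseudo-counted
#'   as `n_hom + 1` within that pool.
#'
#' @param g An `igraph` interactome.
#' @param observed_k Integer vector of removal counts observed in the
#'   population (resampled per draw).
#' @param model `"uniform"` or `"frequency_weighted"`.
#' @param weights Frequency table from [frequency_table()]; required for the
#'   weighted model.
#' @param n_sim Number of draws.
#' @param seed Integer seed; same seed and inputs reproduce the ensemble
#'   bit for bit.
#' @param paths Passed to [state_metrics()].
#' @return Data frame of `n_sim` rows of state metrics, with attributes
#'   `model`, `seed`, `n_sim`.
#' @export
simulate_null <- function(g, observed_k,
                          model = c("uniform", "frequency_weighted"),
                          weights = NULL, n_sim = 1000, seed = 1,
                          paths = TRUE) {
  model <- match.arg(model)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  stopifnot(length(observed_k) > 0, all(observed_k >= 0),
            all(observed_k <= n))
  if (model == "frequency_weighted") {
    stopifnot(!is.null(weights))
    pool <- weights$protein[weights$n_hom > 0]
    pool <- pool[pool %in% nodes]
    if (length(pool) == 0) stop("weighted model needs >=1 positive-weight protein")
    w <- weights$n_hom[match(pool, weights$protein)] + 1
    if (max(observed_k) > length(pool)) {
      stop("fewer positive-weight proteins than the largest removal count")
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draws <- vector("list", n_sim)
  for (i in seq_len(n_sim)) {
    k <- observed_k[sample.int(length(observed_k), 1)]
    rem <- if (k == 0) character(0) else if (model == "uniform") {
      nodes[sample.int(n, k)]
    } else {
      pool[sample.int(length(pool), k, prob = w)]
    }
    draws[[i]] <- state_metrics(g, rem, paths = paths)
  }
  out <- do.call(rbind, draws)
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  attr(out, "n_sim") <- n_sim
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Compare real individual damage against a null ensemble
#'
#' Per metric, a two-sided Mann-Whitney test of the per-individual real
#' values against the per-draw null values, with Benjamini-Hochberg
#' adjustment across all requested metric comparisons (pool comparisons for
#' several null models into one call to adjust across metrics x models).
#'
#' @param obs Data frame from [observe_damage()].
#' @param nulls Named list of data frames from [simulate_null()] (names are
#'   model labels), or a single such data frame.
#' @param metrics Character vector of metric columns to compare.
#' @return Data frame `metric`, `model`, `real_mean`, `null_mean`,
#'   `statistic`, `p_raw`, `p_fdr`.
#' @export
test_real_vs_null <- function(obs, nulls,
                              metrics = c("n_edges", "n_components",
                                          "giant_size")) {
  if (is.data.frame(nulls)) {
    lbl <- attr(nulls, "model")
    nulls <- stats::setNames(list(nulls), if (is.null(lbl)) "null" else lbl)
  }
  rows <- list()
  for (model in names(nulls)) {
    for (metric in metrics) {
      x <- obs[[metric]]; y <- nulls[[model]][[metric]]
      stopifnot(length(x) > 0, length(y) > 0)
      w <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided"))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, model = model,
        real_mean = mean(x), null_mean = mean(y),
        statistic = unname(w$statistic), p_raw = w$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p_raw, method = "BH")
  out
}
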