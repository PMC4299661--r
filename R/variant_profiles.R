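#' Classify variants as deleterious
#'
#' Applies the deleteriousness rules used throughout the pipeline. Only
#' protein-affecting consequence classes are considered: `missense`,
#' `stop_gain`, `stop_loss` and `splice_disrupting`; everything else
#' (synonymous, other) is excluded outright. Stop and splice variants are
#' damaging when their conservation score exceeds `phastcons_thr` (the
#' conservation score is taken as given in the annotation input; the default
#' threshold of 200 assumes a scaled, not raw \[0,1\], phastCons score).
#' Missense variants are damaging when SIFT is at or below `sift_thr`
#' (comparator configurable via `sift_cmp`) or PolyPhen is above
#' `polyphen_thr`; a missing score fails its own clause but does not block
#' the other.
#'
#' The SIFT comparator defaults to `"le"` (\eqn{\le}): published benchmark
#' calls at exactly SIFT = 0.05 are damaging, which a strict `<` cannot
#' reproduce.
#'
#' @param variants Data frame with columns `consequence` (character, one of
#'   `missense`, `stop_gain`, `stop_loss`, `splice_disrupting`, `synonymous`,
#'   `other`), `sift`, `polyphen` (numeric in \[0,1\] or `NA`) and
#'   `phastcons` (non-negative numeric or `NA`).
#' @param sift_cmp `"le"` (default) or `"lt"`: whether SIFT at exactly the
#'   threshold counts as damaging.
#' @param sift_thr,polyphen_thr,phastcons_thr Numeric thresholds.
#' @return The input with two added columns: logical `deleterious` and
#'   character `rule_fired` (one of `sift`, `polyphen`, `conservation`,
#'   `none`, `excluded_consequence`).
#' @export
classify_variants <- function(variants, sift_cmp = c("le", "lt"),
                              sift_thr = 0.05, polyphen_thr = 0.95,
                              phastcons_thr = 200) {
  sift_cmp <- match.arg(sift_cmp)
  stopifnot(all(c("consequence", "sift", "polyphen", "phastcons") %in%
                  names(variants)))
  cons <- variants$consequence
  considered <- cons %in% c("missense", "stop_gain", "stop_loss",
                            "splice_disrupting")
  stopclass <- cons %in% c("stop_gain", "stop_loss", "splice_disrupting")

  sift_hit <- if (sift_cmp == "le") {
    !is.na(variants$sift) & variants$sift <= sift_thr
  } else {
    !is.na(variants$sift) & variants$sift < sift_thr
  }
  poly_hit <- !is.na(variants$polyphen) & variants$polyphen > polyphen_thr
  cons_hit <- !is.na(variants$phastcons) & variants$phastcons > phastcons_thr

  rule <- rep("none", nrow(variants))
  rule[!considered] <- "excluded_consequence"
  rule[considered & !stopclass & sift_hit] <- "sift"
  rule[considered & !stopclass & !sift_hit & poly_hit] <- "polyphen"
  rule[stopclass & cons_hit] <- "conservation"

  variants$deleterious <- rule %in% c("sift", "polyphen", "conservation")
  variants$rule_fired <- rule
  variants
}

#' Read variants and genotypes from a multi-sample VCF plus annotation table
#'
#' Parses a VCF 4.x file (GT format field required), splits multi-allelic
#' records per alternative allele, and joins each (chrom, pos, ref, alt)
#' allele to its row in the annotation TSV, which must have columns `chrom`,
#' `pos`, `ref`, `alt`, `protein`, `consequence`, `sift`, `polyphen`,
#' `phastcons`. Alleles without an annotation row are dropped with a count.
#'
#' Genotypes are reduced per allele to `0` (no copy of this alt), `1` (one
#' copy), `2` (two copies) or `NA` (missing), so for a multi-allelic site
#' each split allele carries its own dosage.
#'
#' @param vcf_path Path to the VCF file (plain or bgzipped).
#' @param annotation_path Path to the annotation TSV.
#' @return A data frame of variants (columns `chrom`, `pos`, `ref`, `alt`,
#'   `protein`, `consequence`, `sift`, `polyphen`, `phastcons`) with a
#'   `genotypes` attribute: an integer matrix, variants x samples, of alt
#'   allele dosages.
#' @export
read_variant_calls <- function(vcf_path, annotation_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))

  rows <- list(); dosages <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (ai in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[ai], stringsAsFactors = FALSE
      )
      dosages[[length(dosages) + 1L]] <- .gt_dosage(gt_raw[i, ], ai)
    }
  }
  var <- do.call(rbind, rows)
  gmat <- do.call(rbind, dosages)
  colnames(gmat) <- colnames(gt_raw)

  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  idx <- match(key(var), key(ann))
  dropped <- sum(is.na(idx))
  keep <- !is.na(idx)
  out <- cbind(var[keep, , drop = FALSE],
               ann[idx[keep], c("protein", "consequence", "sift", "polyphen",
                                "phastcons"), drop = FALSE])
  rownames(out) <- NULL
  attr(out, "genotypes") <- gmat[keep, , drop = FALSE]
  attr(out, "n_unannotated") <- dropped
  out
}

# per-sample dosage of the ai-th alt allele from GT strings like "0/1", "1|1"
.gt_dosage <- function(gt, ai) {
  vapply(gt, function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(x, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles == as.character(ai))
  }, integer(1), USE.NAMES = FALSE)
}

#' Read a merged annotated variant TSV
#'
#' Alternative single-file input: one row per variant allele with columns
#' `chrom`, `pos`, `ref`, `alt`, `protein`, `consequence`, `sift`,
#' `polyphen`, `phastcons` followed by one genotype column per sample coded
#' as alt-allele dosage (0/1/2, empty or NA for missing).
#'
#' @param path Path to the TSV.
#' @return Same shape as [read_variant_calls()].
#' @export
read_merged_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  fixed_cols <- c("chrom", "pos", "ref", "alt", "protein", "consequence",
                  "sift", "polyphen", "phastcons")
  stopifnot(all(fixed_cols %in% names(df)))
  samples <- setdiff(names(df), fixed_cols)
  gmat <- as.matrix(df[, samples, drop = FALSE])
  mode(gmat) <- "integer"
  out <- df[, fixed_cols]
  attr(out, "genotypes") <- gmat
  out
}

#' Reduce deleterious calls to per-individual protein affection states
#'
#' For each individual and each interactome protein, determines whether the
#' protein is unaffected, affected in one allele, or affected in both
#' alleles. In `recessive` mode a protein has both alleles affected when the
#' individual is homozygous alternative for at least one deleterious variant
#' of that protein, or heterozygous for two or more distinct deleterious
#' variants of it (compound heterozygote under the unphased assumption);
#' exactly one heterozygous deleterious variant gives `het_affected`. In
#' `any_allele` mode a single deleterious allele marks the protein affected.
#' Missing genotypes contribute nothing. Proteins absent from the interactome
#' are dropped and counted.
#'
#' @param variants Classified variant table from [classify_variants()], with
#'   its `genotypes` attribute (or `genotypes` supplied separately).
#' @param interactome `igraph` whose vertex names are protein accessions.
#' @param manifest Data frame with columns `sample`, `population`.
#' @param zygosity_mode `"recessive"` (default) or `"any_allele"`.
#' @param genotypes Optional variants x samples dosage matrix overriding the
#'   attribute.
#' @param lenient If `TRUE`, genotype columns absent from the manifest are
#'   skipped instead of raising.
#' @return Long-format data frame (`sample`, `population`, `protein`,
#'   `state`) listing only affected proteins; states are `het_affected` or
#'   `both_alleles_affected` (`any_allele` mode uses `affected`). Attributes:
#'   `samples`, `proteins` (the interactome node universe), `zygosity_mode`,
#'   `n_dropped_proteins`.
#' @export
build_profiles <- function(variants, interactome, manifest,
                           zygosity_mode = c("recessive", "any_allele"),
                           genotypes = NULL, lenient = FALSE) {
  zygosity_mode <- match.arg(zygosity_mode)
  if (is.null(genotypes)) genotypes <- attr(variants, "genotypes")
  stopifnot(!is.null(genotypes), nrow(genotypes) == nrow(variants))
  if (!"deleterious" %in% names(variants)) {
    stop("variants must be classified first (see classify_variants)")
  }
  samples <- colnames(genotypes)
  unknown <- setdiff(samples, manifest$sample)
  if (length(unknown) > 0) {
    if (!lenient) {
      stop("samples in genotypes absent from manifest: ",
           paste(unknown, collapse = ", "))
    }
    samples <- setdiff(samples, unknown)
  }
  nodes <- igraph::V(interactome)$name
  del <- which(variants$deleterious)
  in_net <- variants$protein[del] %in% nodes
  n_dropped <- length(unique(variants$protein[del][!in_net]))
  del <- del[in_net]

  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    s <- samples[si]
    dos <- genotypes[del, s]
    carried <- !is.na(dos) & dos > 0
    if (!any(carried)) next
    prot <- variants$protein[del][carried]
    dos <- dos[carried]
    if (zygosity_mode == "any_allele") {
      state <- data.frame(protein = unique(prot), state = "affected",
                          stringsAsFactors = FALSE)
    } else {
      n_hom <- tapply(dos == 2, prot, sum)
      n_het <- tapply(dos == 1, prot, sum)
      both <- n_hom > 0 | n_het >= 2
      st <- ifelse(both, "both_alleles_affected", "het_affected")
      state <- data.frame(protein = names(n_hom), state = unname(st),
                          stringsAsFactors = FALSE)
    }
    state$sample <- s
    state$population <- manifest$population[match(s, manifest$sample)]
    out[[si]] <- state
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out) > 0) {
    do.call(rbind, out)[, c("sample", "population", "protein", "state")]
  } else {
    data.frame(sample = character(), population = character(),
               protein = character(), state = character(),
               stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  attr(res, "samples") <- manifest[manifest$sample %in% samples,
                                   c("sample", "population")]
  attr(res, "proteins") <- nodes
  attr(res, "zygosity_mode") <- zygosity_mode
  attr(res, "n_dropped_proteins") <- n_dropped
  res
}

#' Proteins affected in one individual
#'
#' @param profiles Profile table from [build_profiles()].
#' @param sample Sample identifier.
#' @param states Which states count; default all present states.
#' @return Character vector of protein accessions.
#' @export
affected_proteins <- function(profiles, sample,
                              states = c("affected", "het_affected",
                                         "both_alleles_affected")) {
  unique(profiles$protein[profiles$sample == sample &
                            profiles$state %in% states])
}

#' Per-protein population damage frequencies
#'
#' Counts, for every protein of the interactome universe carried by the
#' profile table, how many individuals have it affected in at least one
#' allele (`n_het_or_hom`) and in both alleles (`n_hom`). Proteins never
#' affected get explicit zero rows.
#'
#' @param profiles Profile table from [build_profiles()] (recessive mode for
#'   a meaningful `n_hom`).
#' @return Data frame `protein`, `n_het_or_hom`, `n_hom`, `n_total`.
#' @export
frequency_table <- function(profiles) {
  proteins <- attr(profiles, "proteins")
  samples <- attr(profiles, "samples")
  stopifnot(!is.null(proteins), nrow(samples) > 0)
  n_total <- nrow(samples)
  any_aff <- table(factor(profiles$protein, levels = proteins))
  hom <- profiles[profiles$state %in% c("both_alleles_affected"), ]
  n_hom <- table(factor(hom$protein, levels = proteins))
  data.frame(
    protein = proteins,
    n_het_or_hom = as.integer(any_aff),
    n_hom = as.integer(n_hom),
    n_total = n_total,
    stringsAsFactors = FALSE
  )
}

#' Per-protein ratio of non-synonymous to synonymous variant counts
#'
#' A crude per-protein selective-pressure readout. Proteins with no
#' synonymous variant get `NA` (undefined, excluded from downstream
#' correlation) rather than infinity.
#'
#' @param variants Variant table (pre-classification; must include
#'   synonymous calls) with columns `protein` and `consequence`.
#' @return Data frame `protein`, `n_ns`, `n_s`, `ratio`.
#' @export
ns_s_ratio <- function(variants) {
  ns_classes <- c("missense", "stop_gain", "stop_loss", "splice_disrupting")
  prot <- unique(variants$protein)
  n_ns <- vapply(prot, function(p) {
    sum(variants$protein == p & variants$consequence %in% ns_classes)
  }, integer(1))
  n_s <- vapply(prot, function(p) {
    sum(variants$protein == p & variants$consequence == "synonymous")
  }, integer(1))
  data.frame(
    protein = prot, n_ns = n_ns, n_s = n_s,
    ratio = ifelse(n_s > 0, n_ns / n_s, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
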