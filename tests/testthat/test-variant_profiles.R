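mkvar <- function(consequence, sift = NA_real_, polyphen = NA_real_,
                  phastcons = NA_real_, protein = "P1") {
  data.frame(protein = protein, consequence = consequence, sift = sift,
             polyphen = polyphen, phastcons = phastcons,
             stringsAsFactors = FALSE)
}

test_that("missense deleteriousness follows the SIFT-or-PolyPhen rule", {
  cases <- rbind(
    cbind(mkvar("missense", sift = 0, polyphen = 0.999),
          want = TRUE, rule = "sift"),
    cbind(mkvar("missense", sift = 0.37, polyphen = 0.001),
          want = FALSE, rule = "none"),
    cbind(mkvar("missense", sift = NA, polyphen = 0.314),
          want = FALSE, rule = "none"),
    cbind(mkvar("missense", sift = NA, polyphen = 0.991),
          want = TRUE, rule = "polyphen"),
    cbind(mkvar("missense", sift = 0.05, polyphen = 0.042),
          want = TRUE, rule = "sift"),     # boundary: <= comparator
    cbind(mkvar("synonymous", sift = 0, polyphen = 1),
          want = FALSE, rule = "excluded_consequence"),
    cbind(mkvar("other"), want = FALSE, rule = "excluded_consequence")
  )
  got <- classify_variants(cases)
  expect_equal(got$deleterious, cases$want)
  expect_equal(got$rule_fired, cases$rule)
  # strict comparator flips only the boundary case
  strict <- classify_variants(cases, sift_cmp = "lt")
  expect_false(strict$deleterious[5])
  expect_equal(strict$deleterious[-5], cases$want[-5])
})

test_that("stop and splice variants gate on the conservation score", {
  cases <- rbind(
    cbind(mkvar("stop_gain", phastcons = 350), want = TRUE),
    cbind(mkvar("stop_gain", phastcons = 150), want = FALSE),
    cbind(mkvar("stop_loss", phastcons = 201), want = TRUE),
    cbind(mkvar("splice_disrupting", phastcons = 200), want = FALSE),
    cbind(mkvar("splice_disrupting", phastcons = NA), want = FALSE),
    # SIFT/PolyPhen never rescue a low-conservation stop variant
    cbind(mkvar("stop_gain", sift = 0, polyphen = 1, phastcons = 10),
          want = FALSE)
  )
  got <- classify_variants(cases)
  expect_equal(got$deleterious, cases$want)
  expect_equal(got$rule_fired[1], "conservation")
})

test_that("classification is monotone in the damage scores", {
  set.seed(1)
  base <- mkvar("missense", sift = runif(50), polyphen = runif(50))
  got <- classify_variants(base)
  # lowering SIFT or raising PolyPhen never flips deleterious -> benign
  lowered <- base; lowered$sift <- lowered$sift * 0.5
  raised <- base; raised$polyphen <- 1 - (1 - raised$polyphen) * 0.5
  expect_true(all(classify_variants(lowered)$deleterious >= got$deleterious))
  expect_true(all(classify_variants(raised)$deleterious >= got$deleterious))
})

test_that("reference benchmark of 20 published variants is reproduced", {
  ref <- reference_variants()
  expect_equal(nrow(ref), 20)
  v <- data.frame(protein = ref$gene, consequence = "missense",
                  sift = ref$sift, polyphen = ref$polyphen,
                  phastcons = NA_real_, stringsAsFactors = FALSE)
  got <- classify_variants(v, sift_cmp = "le")
  expect_equal(ifelse(got$deleterious, "D", "ND"), ref$prediction)
  expect_equal(sum(!got$deleterious), 8)
  expect_equal(sum(got$deleterious), 12)
})

prof_fixture <- function(gmat, proteins, zygosity_mode = "recessive",
                         deleterious = rep(TRUE, length(proteins))) {
  v <- data.frame(protein = proteins, consequence = "missense",
                  sift = ifelse(deleterious, 0.01, 0.5),
                  polyphen = 0.1, phastcons = NA_real_,
                  stringsAsFactors = FALSE)
  attr(v, "genotypes") <- gmat
  g <- toy_graph("A-B,B-C,C-D")
  manifest <- data.frame(sample = colnames(gmat),
                         population = "POP", stringsAsFactors = FALSE)
  build_profiles(classify_variants(v), g, manifest,
                 zygosity_mode = zygosity_mode)
}

test_that("zygosity reduction: hom, compound het and single het states", {
  # rows = variants (proteins A, B, B), columns = samples
  gmat <- matrix(c(2L, 0L, 0L,   # A: hom in s1
                   0L, 1L, 0L,   # B site 1: het in s2
                   0L, 1L, 1L),  # B site 2: het in s2 (compound) and s3
                 nrow = 3, byrow = TRUE,
                 dimnames = list(NULL, c("s1", "s2", "s3")))
  pr <- prof_fixture(gmat, c("A", "B", "B"))
  expect_equal(pr$state[pr$sample == "s1" & pr$protein == "A"],
               "both_alleles_affected")
  expect_equal(pr$state[pr$sample == "s2" & pr$protein == "B"],
               "both_alleles_affected")
  expect_equal(pr$state[pr$sample == "s3" & pr$protein == "B"],
               "het_affected")
  # any_allele mode: a single damaged allele marks the protein affected
  pr2 <- prof_fixture(gmat, c("A", "B", "B"), zygosity_mode = "any_allele")
  expect_true(all(pr2$state == "affected"))
  # recessive both-alleles set is a subset of the any_allele affected set
  for (s in c("s1", "s2", "s3")) {
    expect_true(all(affected_proteins(pr, s, "both_alleles_affected") %in%
                      affected_proteins(pr2, s)))
  }
})

test_that("benign variants, missing genotypes and off-network proteins are inert", {
  gmat <- matrix(c(2L, 2L, NA_integer_, 2L), nrow = 4,
                 dimnames = list(NULL, "s1"))
  # row2 benign, row3 missing genotype, row4 protein outside the interactome
  pr <- prof_fixture(gmat, c("A", "B", "C", "Z"),
                     deleterious = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(pr$protein, "A")
  expect_equal(attr(pr, "n_dropped_proteins"), 1)
  # unknown sample: strict raises, lenient skips
  v <- data.frame(protein = "A", consequence = "missense", sift = 0.01,
                  polyphen = 0.1, phastcons = NA_real_)
  attr(v, "genotypes") <- matrix(2L, 1, 1, dimnames = list(NULL, "ghost"))
  g <- toy_graph("A-B")
  man <- data.frame(sample = "s1", population = "POP")
  expect_error(build_profiles(classify_variants(v), g, man), "ghost")
  pr3 <- build_profiles(classify_variants(v), g, man, lenient = TRUE)
  expect_equal(nrow(pr3), 0)
})

test_that("frequency table counts individuals exactly, with explicit zeros", {
  gmat <- matrix(c(2L, 2L, 2L,    # A hom in all three
                   1L, 0L, 2L),   # B het in s1, hom in s3
                 nrow = 2, byrow = TRUE,
                 dimnames = list(NULL, c("s1", "s2", "s3")))
  pr <- prof_fixture(gmat, c("A", "B"))
  f <- frequency_table(pr)
  expect_setequal(f$protein, c("A", "B", "C", "D"))
  expect_equal(f$n_hom[f$protein == "A"], 3)
  expect_equal(f$n_het_or_hom[f$protein == "A"], 3)
  expect_equal(f$n_hom[f$protein == "B"], 1)
  expect_equal(f$n_het_or_hom[f$protein == "B"], 2)
  expect_equal(f$n_het_or_hom[f$protein == "C"], 0)  # never affected
  expect_true(all(f$n_hom <= f$n_het_or_hom & f$n_het_or_hom <= f$n_total))
})

test_that("frequency table matches the synthetic generator's bookkeeping", {
  spec <- synth_spec(n_proteins = 120, n_modules = 4, n_individuals = 15,
                     populations = "POP1", seed = 21)
  net <- generate_interactome(spec)
  pop <- generate_population(net, spec)
  pr <- build_profiles(classify_variants(pop$variants), net$graph,
                       pop$manifest)
  f <- frequency_table(pr)
  truth <- pop$truth$frequencies
  m <- merge(f, truth, by = "protein")
  expect_gt(nrow(m), 100)
  expect_equal(m$n_hom.x, m$n_hom.y)
  expect_equal(m$n_het_or_hom.x, m$n_het_or_hom.y)
})

test_that("NS/S ratio is exact and guards division by zero", {
  v <- rbind(mkvar("missense", protein = "A"), mkvar("missense", protein = "A"),
             mkvar("stop_gain", protein = "A"), mkvar("missense", protein = "A"),
             mkvar("synonymous", protein = "A"), mkvar("synonymous", protein = "A"),
             mkvar("synonymous", protein = "B"), mkvar("synonymous", protein = "B"),
             mkvar("synonymous", protein = "B"),
             mkvar("missense", protein = "C"), mkvar("missense", protein = "C"))
  r <- ns_s_ratio(v)
  expect_equal(r$ratio[r$protein == "A"], 2)      # 4 NS / 2 S
  expect_equal(r$ratio[r$protein == "B"], 0)      # 0 NS / 3 S
  expect_true(is.na(r$ratio[r$protein == "C"]))   # 2 NS / 0 S -> undefined
})

test_that("VCF + annotation input reproduces in-memory genotypes", {
  d <- withr::local_tempdir()
  spec <- synth_spec(n_proteins = 60, n_modules = 3, n_individuals = 4,
                     intra_module_edge_prob = 0.25, seed = 5)
  net <- generate_interactome(spec)
  pop <- generate_population(net, spec, dir = d)
  v <- read_variant_calls(pop$files$vcf, pop$files$annotation)
  expect_equal(nrow(v), nrow(pop$variants))
  expect_equal(unname(attr(v, "genotypes")),
               unname(attr(pop$variants, "genotypes")))
  expect_equal(v$protein, pop$variants$protein)
  # merged-TSV route gives the same variants
  ft <- file.path(d, "merged.tsv")
  merged <- cbind(pop$variants, as.data.frame(attr(pop$variants, "genotypes")))
  utils::write.table(merged, ft, sep = "\t", row.names = FALSE, quote = FALSE)
  v2 <- read_merged_tsv(ft)
  expect_equal(unname(attr(v2, "genotypes")),
               unname(attr(pop$variants, "genotypes")))
})

test_that("multi-allelic records are split with per-allele dosages", {
  d <- withr::local_tempdir()
  vcf <- file.path(d, "m.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT\t1/2\t2/2",
    "1\t200\t.\tC\tG\t.\tPASS\t.\tGT\t./.\t0/1"), vcf)
  ann <- file.path(d, "a.tsv")
  writeLines(c("chrom\tpos\tref\talt\tprotein\tconsequence\tsift\tpolyphen\tphastcons",
               "1\t100\tA\tG\tPA\tmissense\t0.01\t0.5\tNA",
               "1\t100\tA\tT\tPB\tmissense\t0.01\t0.5\tNA",
               "1\t200\tC\tG\tPC\tmissense\t0.5\t0.5\tNA"), ann)
  v <- read_variant_calls(vcf, ann)
  gm <- attr(v, "genotypes")
  expect_equal(nrow(v), 3)
  expect_equal(unname(gm[v$protein == "PA", ]), c(1L, 0L))
  expect_equal(unname(gm[v$protein == "PB", ]), c(1L, 2L))
  expect_equal(unname(gm[v$protein == "PC", ]), c(NA_integer_, 1L))
})
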