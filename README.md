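# netload

Network analysis of deleterious mutational load on the human protein
interaction network.

Healthy genomes carry hundreds of variants predicted to destroy protein
function, many in homozygosis, yet their carriers are well. `netload`
implements the systems-level explanation pipeline: deleterious damage is
tolerated when it lands on the **periphery** of the interactome, in
**combinations that preserve connectivity**, and is pathogenic when it
concentrates in **central** proteins and modules. The package is aimed at
computational biologists who have a curated (or curatable) protein–protein
interaction network and multi-sample annotated variant calls, and want to
quantify where a cohort's mutational load sits in that network.

## What it computes

1. **Interactome curation** — pool PSI-MI TAB 2.5 / edge-list evidence per
   protein pair; keep edges with ≥ 2 distinct detection methods and a
   physical-association record (`parse_mitab()`, `curate()`).
2. **Deleteriousness classification** — missense: SIFT ≤ 0.05 or
   PolyPhen > 0.95; stop/splice: scaled conservation score > 200
   (`classify_variants()`).
3. **Affection states** — per individual and protein: heterozygous,
   or both-alleles-affected via homozygosity or compound heterozygosity
   (`build_profiles()`).
4. **Damage simulation** — each individual's interactome is the graph minus
   their both-alleles-affected proteins; cohorts are tested (Mann–Whitney,
   BH-adjusted) against a *uniform* removal null and a
   *frequency-weighted* null that removes only population-damaged proteins
   in random combinations (`observe_damage()`, `simulate_null()`,
   `test_real_vs_null()`).
5. **Module relative damage** — communities from Walktrap/Infomap
   (≥ 5 proteins); per module and individual, the mid-rank percentile of
   the observed affected proportion against `n_perm` uniform re-placements,

   RD = (#{null < obs} + ½·#{null = obs}) / n_perm ∈ [0, 1],

   with 0.5 at the null median; population profiles are clustered on
   Euclidean distances (`detect_modules()`, `relative_damage()`,
   `damage_matrix()`, `cluster_profiles()`). The headline statistic is
   Spearman's ρ between module closeness and relative damage: ρ < 0 means
   peripherally concentrated damage, ρ > 0 centrally concentrated.
6. **Synthetic cohorts with ground truth** — a modular, scale-free-ish
   interactome and genotype cohorts whose per-protein carrier probability
   depends on closeness rank with signed strength β, so every stage is
   testable without data downloads (`synth_spec()`,
   `generate_interactome()`, `generate_population()`, `generate_mitab()`).

## Worked example

A synthetic cohort of 50 individuals on a 1,000-protein modular
interactome, with damage planted peripherally (β = −0.8) in
connectivity-preserving combinations:

```r
library(netload)
report <- run_pipeline(list(
  synth = list(n_proteins = 1000, n_modules = 10, n_individuals = 50,
               populations = "POP1", placement_bias = -0.8,
               intra_module_edge_prob = 0.035, carrier_rate = 0.07,
               preserve_connectivity = TRUE),
  damage = list(n_sim = 500, paths = FALSE),
  modules = list(n_perm = 500),
  seed = 1))
report
#> netload pipeline report (seed 1)
#>   interactome: 1000 proteins, 2760 interactions
#>   individuals: 50; deleterious variants: 1000
#>   modules scored: 11
#>   module damage vs centrality [POP1]: rho = -0.446, p = 0.169

report$correlations
#>        metric        rho             p   n
#> 1      degree -0.5259845  1.369288e-66 920
#> 2 betweenness -0.5432257  9.472958e-72 920
#> 3   closeness -0.6367285 9.489194e-106 920

subset(report$damage$tests, metric %in% c("n_edges", "n_components"))
#>         metric              model real_mean null_mean statistic        p_raw        p_fdr
#> 1      n_edges            uniform   2674.54  2645.934   19794.5 9.861458e-12 5.916875e-11
#> 2 n_components            uniform     25.98    26.848    8586.5 1.716545e-04 5.149636e-04
#> 4      n_edges frequency_weighted   2674.54  2670.836   13545.5 3.293205e-01 4.939807e-01
#> 5 n_components frequency_weighted     25.98    26.032   12619.0 9.094370e-01 9.671664e-01
```

Reading the output: the planted peripheral bias is decisively visible at
the protein level — damage frequency falls with closeness
(ρ = −0.64, p ≈ 10⁻¹⁰⁵). Real individuals keep significantly more edges
and fragment into fewer components than equally sized *uniform* random
damage (p ≈ 10⁻¹¹ and 10⁻⁴), while the *frequency-weighted* null — random
combinations of genuinely damaged proteins — sits between the real cohort
and the uniform null, the signature of combination-level selection. The
module-level Spearman ρ is negative as planted but, with only ~11 modules,
a single run has limited power (p = 0.169 here); the seed-fixed
desk-scale experiments in `tests/testthat/test-acceptance.R` show the
sign recovered with p ≤ 0.05 under both Walktrap and Infomap partitions.

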