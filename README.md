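# metqtl

Stability genetics for multi-environment trials (METs) of inbred germplasm
panels, in one reusable R pipeline.

Breeders and diversity researchers evaluating a germplasm collection — the
motivating case is a core collection of traditional tomato accessions
genotyped by GBS and field-phenotyped in four locations — need to answer, for
each trait: how much variation is genetic versus environmental versus
genotype-by-environment interaction (G×E); which accessions are stable; and
which loci control the trait mean (meanQTLs), its stability (stbQTLs), and
its environment-specific response (QTIs, QTL-by-environment interactions).
`metqtl` implements that analysis end to end, plus the diversity and
core-collection tooling used to build such a panel in the first place.

## The models

* **Variance decomposition** — REML fit of
  `Y_ijk = mu + G_i + E_j + (GxE)_ij + e_ijk` with all factors random;
  per-component likelihood-ratio tests; BLUPs of genotype (BLUPg) and
  interaction (BLUPge) from the environment-fixed parametrization; and
  broad-sense heritability `H2 = s2g / (s2g + s2ge + s2e)`.
* **Stability indices** — WAASB (weighted average of absolute IPCA scores
  from the SVD of BLUPge) for replicated traits, and the GGE biplot's
  average-environment-coordination (AEC) ordinate projection for
  accession-mean traits. Lower = more stable.
* **Association** — identity-by-state kinship; exact per-marker REML
  mixed-model scans (EMMA-style, OLS-equivalent at K = identity) on trait
  means, stability indices, and two-stage GWEIS interaction effects;
  multiple testing by the Li–Ji effective number of tests with a Šidák
  cutoff.
* **QTL architecture** — LD candidate regions (r² above the
  interchromosomal baseline, < 2 Mb), loci merged within 100 kb, QTL
  grouping with co-localization labels; additive / dominant / recessive /
  overdominant classification from allelic-class contrasts
  (`a = (AA-BB)/2`, `d = AB-(AA+BB)/2`); QTI typing into magnitude change
  (QTL3), conditional neutrality (QTL4), and antagonistic pleiotropy (QTL5).
* **Haplotypes** — D′ via EM over phase-ambiguous genotypes, solid-spine
  blocks, per-accession haplotype assignment, and haplotype–trait
  association (two-way ANOVA + Tukey HSD; χ² with standardized Pearson
  residuals).
* **Diversity & core selection** — π, MAF, MDS/PCoA on IBS distances, and a
  mixed-strategy core-collection selector (maximin genetic sub-core,
  phenotypic extremes, geographic fill, nearest-neighbour replacement) with
  representativeness diagnostics.

A synthetic-data generator (`scenario_spec()`, `gen_genotypes()`,
`gen_met_phenotypes()`, `gen_qualitative_trait()`) emulates the panel
structure — blockwise LD with exact pairwise r² control, inbred-like
heterozygosity, planted QTLs with known gene action and environment-response
profiles — so the whole pipeline is testable offline with known truth. See
`vignettes/metqtl-methods.Rmd` for the models, assumptions, and limits.

## Worked example

```r
library(metqtl)

sc <- scenario_spec(n_accessions = 120, n_snps = 300, n_chromosomes = 3,
                    seed = 42,
                    qtls = list(planted_qtl(40, "T1", a = 1.5, d = 0),
                                planted_qtl(200, "T1", a = 1,
                                            env_multipliers = c(1, 0, 0, 0))))
g   <- gen_genotypes(sc)          # 120 accessions x 300 markers, 3% missing
sim <- gen_met_phenotypes(g, sc)  # 4 environments x 3 plants

fit <- fit_met_mixed(sim$met, "T1")
fit$vc
#>    component sigma2 percent lrt_stat     lrt_p
#>     genotype  6.370    71.2    464.9 4.20e-103
#>  environment  0.506     5.7     99.9  1.56e-23
#>          gxe  1.059    11.8    303.9  4.76e-68
#>     residual  1.012    11.3       NA        NA
fit$H2
#> 0.755
```

Genetic variance dominates (71% of total), interaction and residual split
the rest, and every component is LRT-significant; `H2 = 0.755` says
three-quarters of the across-environment phenotypic variance among accession
means is genetic. Stability and association:

```r
waasb(fit$blup_ge)$ranking[1:3]          # most stable accessions
#> "ACC096" "ACC053" "ACC049"

flt <- filter_snps(g)                    # 25%/25%/5%/5% filter cascade
K   <- kinship(flt$genotypes)            # IBS, additive heterozygotes
thr <- significance_threshold(flt$genotypes)
c(thr$meff, thr$cutoff)
#> 120.0  0.000427

gw <- gweis_two_stage(sim$met, "T1", flt$genotypes, K, method = "approx")
head(gw$mean_scan[order(gw$mean_scan$p), c("marker", "chrom", "pos", "beta", "p")], 3)
#>  marker chrom     pos  beta        p
#>  S00040 chr01 2041819 -1.52 1.68e-06
#>  S00039 chr01 2021804 -1.13 5.94e-04
#>  S00036 chr01 1898967 -0.97 3.69e-03
```

The planted additive QTL (marker 40, `a = 1.5`) is the top mean-scan hit,
with its LD-block neighbours trailing; the slope −1.52 per alternate-allele
copy recovers the planted effect. Gene action on the BLUPg response:

```r
gene_action(fit$blup_g, flt$genotypes$codes[, "S00040"])[c("mode", "a")]
#> mode: "additive"   a: 1.4
```

(`d` is untestable here: an inbred panel leaves fewer than the required >3
heterozygous accessions, so the dominance class is dropped — the result is
flagged additive-by-default.)

The full chain — filter → ANOVA/BLUP → stability → GWAS/GWEIS → loci/QTLs →
gene action — is `run_pipeline(run_config(seed = 1))`, or from the shell:

```sh
exec/metqtl simulate --out runs/demo --seed 1
exec/metqtl run      --out runs/demo --seed 1   # writes TSVs + summary.json
```

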