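---
title: "Models and methods in metqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in metqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metqtl)
```

## What this package models

`metqtl` analyses multi-environment trials (METs) of inbred-like germplasm
panels — the motivating system is a core collection of traditional tomato
accessions genotyped by GBS and phenotyped in several locations — and asks
three linked questions: how much of a trait's variation is genetic,
environmental, and interaction (G×E); which accessions are stable across
environments; and which loci control the trait mean, its stability, and its
environment-specific response.

The backbone is the combined-trial mixed model

$$Y_{ijk} = \mu + G_i + E_j + (G\times E)_{ij} + \varepsilon_{ijk},$$

with genotype, environment and interaction treated as random
($G_i \sim N(0, \sigma^2_g)$, $E_j \sim N(0, \sigma^2_E)$,
$(G\times E)_{ij} \sim N(0, \sigma^2_{ge})$). Broad-sense heritability across
environments deliberately excludes the environment main effect:

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge} + \sigma^2_\varepsilon}.$$

BLUPs of the genotype effect (BLUPg) and of the interaction (BLUPge) come
from a second parametrization with environment fixed; this is also the fit
whose variance components feed $H^2$. Which of the two fits fed the published
heritabilities is not stated in the source methods; we use the env-fixed fit
because it is the one that defines the BLUPs, and the choice is switchable in
code by reading `sigma2_blup_fit` versus the all-random `vc` table.

## Stability indices

Two indices, chosen by how a trait was scored:

* **WAASB** (replicated traits): from the SVD of the BLUPge matrix,
  $\mathrm{WAASB}_i = \sum_k |IPCA_{ik}| \, EP_k / \sum_k EP_k$, where the
  genotype scores are $U\Lambda$ and $EP_k = \lambda_k^2/\sum \lambda^2$. All
  $p = \min(g-1, e-1)$ axes are retained: the formula's upper limit uses the
  full interaction signal, and truncation by axis significance is left as a
  flag-level choice for the caller (we found no principled default).
* **AEC projection** (accession-mean traits): the genotype-main-effect plus
  G×E (GGE) model is fitted by column-centering the genotype × environment
  mean table and taking the SVD. Under genotype-focused singular value
  partitioning (genotype scores $U\Lambda$, environment scores $V$), the
  average environment is the mean of the environment PC1–PC2 scores; a
  genotype's instability is the perpendicular distance of its 2-D score from
  the line through the origin and the average environment. Axis signs are
  fixed (average-environment PC1 positive; first environment's PC2
  non-negative) so the geometry is reproducible run to run.

Lower is more stable for both. Missing cells in the mean table are imputed by
environment means and flagged. Both computations are checked against
independent literal-formula oracles to 1e-10 in the test suite.

## Association scans

SNPs are filtered in a fixed order: accessions with >25% missing calls,
markers with >25% missing, MAF < 5% (the boundary is kept), then markers with
a heterozygous-call fraction ≥ 5%. The upstream description of that last rule
reads "homozygous fraction <5%", which taken literally would discard nearly
every SNP of an inbred panel; we implement the heterozygosity reading and
keep the literal one behind `literal_hom_filter`.

The scan itself fits, for each marker,
$y = \mu + \beta x + g + e$ with $g$ a polygenic random effect whose
covariance is the identity-by-state kinship matrix
$K_{ij} = \overline{1 - |g_i - g_j|/2}$ (heterozygotes handled additively).
A single eigendecomposition of $K$ rotates the data; the genetic-to-residual
variance ratio is then re-optimized exactly for every marker by 1-D REML
profile search (the classical exact mixed-model association approach), with a
one-time null-model estimate available as `method = "approx"` for large
scans. At $K = I$ the scan reduces to ordinary least squares exactly, which
the tests assert to 1e-8. Missing marker dosages are mean-imputed within the
scan (the reported `n` is the non-missing count) so the one-time rotation
stays exact; the alternative — re-eigendecomposition per marker on the
non-missing subset — costs two orders of magnitude more for a difference far
below the reporting precision at the missingness rates filtered data can
have (≤25%, typically ~3%).

Trait-mean and interaction-effect scans use a two-stage scheme: a fixed
two-way model on accession × environment cell means yields a genotype-mean
vector and per-environment interaction vectors (sum-to-zero per accession on
balanced data); each vector is then scanned with the kinship model. One
consequence worth knowing: because interaction effects are sum-to-zero, a
QTL acting only in one of four environments spills $-1/3$ of its effect into
each of the other three interaction vectors. At realistic effect sizes the
spillover stays below the significance threshold, but it is a property of the
decomposition, not a bug, and the tests pin the ratio explicitly.

Stability-index scans use WAASB for replicated traits and the AEC projection
for accession-mean traits — exactly that mapping.

Significance is controlled through the effective number of independent tests:
per chromosome, the eigenvalues $\lambda$ of the marker correlation matrix
contribute $I(\lambda \ge 1) + (\lambda - \lfloor\lambda\rfloor)$; summing
over chromosomes gives $M_\mathrm{eff}$ and the Šidák cutoff
$1 - (1-\alpha)^{1/M_\mathrm{eff}}$ (Bonferroni by flag). Eigenvalues are
rounded at 1e-10 before the floor so exact duplicates hit the integer limit.

## Loci, QTLs, and gene action

Candidate regions extend from each significant SNP to all same-chromosome
markers with $r^2$ above the interchromosomal LD baseline (95th percentile of
inter-chromosome pairwise $r^2$; the study's published constant 0.4456 is the
config default, with a recompute option) and strictly within 2 Mb of the
lead. Regional LD blocks (maximal runs of lead-linked SNPs) are merged
transitively when they overlap or sit within 100 kb, defining loci; all
significant SNPs for one trait and one analysis class inside a locus form a
single QTL. Per trait × locus, the classes present yield the co-localization
label (mean-specific, stability-specific, interaction-specific, the pairwise
combinations, or all three).

Mode of inheritance is classified from allelic-class marginal means (classes
kept when shared by more than 3 accessions, per the source's rule — note an
internal inconsistency in our build contract was resolved in favour of the
stricter "more than 3"): the additive contrast
$AB - (AA+BB)/2 = 0$ is tested first; if rejected, dominant/recessive nulls
are tested with roles assigned by the sign of the allelic effect; if all are
rejected and the heterozygote exceeds both homozygotes the QTL is
overdominant. An AB below both homozygotes is reported non-conclusive — the
scheme names no underdominance class. Because the dominant/recessive roles
condition on the effect sign, the mode label names the action of the
trait-raising allele and is invariant to allele relabeling (the tests assert
this). Additive and dominance genotypic values are $a = (AA - BB)/2$ and
$d = AB - (AA+BB)/2$.

QTL-by-environment interaction types follow the per-environment homozygote
contrasts on BLUPge: opposite significant signs = antagonistic pleiotropy
(QTL5); a mix of significant and silent environments = conditional neutrality
(QTL4); all significant, same sign = magnitude change (QTL3), additionally
requiring a significant SNP×environment interaction term — markers passing
every per-environment test without an interaction term are reported as
consistent-effect, not as a QTI type. With per-environment testing at
$\alpha = 0.05$, a conditional-neutral QTL has an irreducible ~5–7% chance of
being read as antagonistic (a silent environment crossing $\alpha$ with
opposite sign); the acceptance suite therefore bounds cross-type error pooled
over types, and separately asserts that antagonistic truth is (essentially)
never read as magnitude change. QTL-level summaries require unanimity across
member SNPs; any disagreement is non-conclusive.

## Haplotypes

Pairwise LD uses Lewontin's $D'$ with two-locus haplotype frequencies from an
EM over phase-ambiguous double heterozygotes (convergence 1e-6 on the
log-likelihood; the two-locus likelihood is well behaved, so no restarts).
Blocks use the solid-spine rule: a maximal run whose first and last markers
have $D' \ge 0.8$ with every intermediate marker, over pairs spaced under
1 Mb. Marker exclusions mirror the Haploview-style defaults (MAF < 0.001,
exact Hardy–Weinberg p < 0.001, missingness ≥ 75%); note the HWE exclusion is
incoherent for fully inbred panels — every informative marker fails it — so
`hwe_p = 0` is the sensible setting there, and the default is kept only for
fidelity to the stated parameters. Block haplotypes are assigned directly for
fully homozygous and single-heterozygous accessions, and by EM posterior
(> 0.9, else unassigned) for multi-heterozygous ones; unassigned accessions
are excluded from association rather than imputed. Frequency classes: major
(> 10%), minor (1–10%), rare (< 1%).

Haplotype–trait association is a two-way ANOVA of presence (1–2 copies)
versus absence ("X") across collections with Tukey HSD cell comparisons for
quantitative traits, and a χ² independence test with standardized Pearson
residuals $d_{ij}$ (|d|>2 ≈ p<0.05, |d|>4 ≈ p<0.001) for qualitative traits,
Bonferroni-corrected pairwise comparisons (the source's "Bonferroni FDR" is
internally contradictory; we implement family-wise Bonferroni), and a Fisher
fallback when an expected count is zero.

## The synthetic world

The generator is first-class, tested code. Its defaults are the stated world
of the motivating study: ~200 accessions × 3000 SNPs with MAF ≥ 5% on 12
chromosomes, 4 environments × 3 replicate plants, inbred-like heterozygosity
(2%), 3% missing calls, and variance components (4, 1, 1, 1) for genotype,
environment, interaction and residual — the ratio used throughout the
parameter-recovery tests.

LD is blockwise by construction: within a block every gamete copies a shared
core gamete with probability $\theta = (r^2_\mathrm{target})^{1/4}$ and is
redrawn independently otherwise, which makes the expected pairwise dosage
$r^2$ within a block equal the target exactly ($\theta^4$), and blocks
independent. Block lengths are 1 + Poisson(mean − 1), positions accumulate
20–80 kb gaps. This gives clean control of the r²/D′ machinery but no
recombination-map realism: no LD decay with distance inside a block, no
background LD between blocks, no allele-frequency spectrum from demography.
A green LD test therefore establishes the machinery, not population-genetic
realism. Population structure is off by default; a two-subpopulation
allele-frequency shift can be switched on to exercise kinship correction
(the truth labels are attached as an attribute).

Planted QTLs use the F2 parametrization (class means $+a$, $d$, $-a$ for
codes 0/1/2) and enter phenotypes only through per-environment multipliers,
so interaction truth labels stay unambiguous: equal multipliers = none; same
sign, unequal = magnitude; some zero = conditional neutrality; sign change =
antagonistic. Qualitative traits cut an interaction-free latent version of
the same model at equally spaced latent quantiles — the source gives no
generative model for qualitative G×E, so this latent-threshold choice is
ours.

Two design notes that matter for interpreting simulations. First,
interaction is relative: if half the panel carries an antagonistic response,
the average environment response splits the difference and both halves show
mirror-image interactions of equal size. Stability-ranking claims are
therefore tested with antagonists as a small minority. Second, planted-QTL
variance adds to the polygenic variance, so realized $\sigma^2_g$ exceeds the
nominal parameter whenever QTLs are planted; recovery tests plant none.

## Numerical choices and defaults

| Parameter | Default | Why |
|---|---|---|
| `maf_min` | 0.05 | study's filter; boundary kept |
| `snp_missing_max` / `ind_missing_max` | 0.25 | study's filters |
| `het_max` | 0.05 | heterozygosity reading of the homozygous-fraction rule |
| `r2_baseline` | 0.4456 | study's interchromosomal 95th percentile; recomputable |
| `region_window_bp` | 2e6 (strict <, from the lead SNP) | study's distance rule |
| `locus_gap_bp` | 1e5 (inclusive ≤) | study's merge rule |
| `contrast_alpha` | 0.05 | mode-of-inheritance contrasts |
| `corr_p` | 0.01 | mean–stability correlation display mask |
| `min_class_n` | 3 (classes kept when n > 3) | study's "shared by >3 accessions" |
| D′ spine threshold | 0.8 | solid-spine convention |
| EM tolerances | 1e-6 log-likelihood | two-locus EM is convex-like; block EM single start |

Variance-component LRTs report the literal one-df upper-tail χ² p-value;
the standard 50:50 boundary mixture (which halves it) sits behind
`boundary = TRUE` — fidelity first, correctness switchable. Percentiles for
the LD baseline are order statistics (`sorted[ceil(q n)]`), so they match a
sort-based recomputation exactly. Genotype codes are 1-based-position,
0/1/2 alternate-allele counts; MAF is always computed from observed allele
counts, never assumed from code orientation.

## Core collection tools

Diversity summaries use per-SNP nucleotide diversity
$\pi = 2p(1-p)\,n/(n-1)$ with $n$ the non-missing accession count (the
accession-level convention of the genotype data, which makes two differing
accessions give $\pi = 1$), MAF, 1-Mb SNP density, classical-scaling MDS of
the IBS distance, and the centered-IBS kinship distribution. Core selection
is the mixed strategy: a maximin (farthest-point) genetic sub-core on the
first three PCoA axes, seeded at the accession farthest from the centroid
(the source names no algorithm; farthest-point greedy is the standard
maximin heuristic and is deterministic given the seed); a phenotypic
sub-core of the 10 highest and 10 lowest accessions per quantitative trait
plus category-proportional random picks for qualitative traits; a geographic
fill of one accession per unrepresented region; and
nearest-neighbour replacement for discarded accessions. The published
sub-core sizes arose from manual curation and are exposed as parameters, not
reproduced.

## What the tests do and do not establish

The acceptance suite verifies: the arithmetic consistency of the published
count tables; equivalence of WAASB, AEC, the mixed-model scan, Meff and D′
against independent oracles; recovery of generative variance components
(within 15% over 30 seeds at the 200 × 4 × 3 design); recovery of planted
gene actions (>80% at a = 1 SD, n = 200) and interaction types (<5% pooled
cross-type error); error control (null-scan type-I within a binomial CI,
scaled to 500 markers × 8 seeds for runtime — the realized count's CI, not a
rescaled one; no inflation of null interaction scans, which in fact run
slightly conservative; representativeness flags at ≤ the nominal rate); and
the stability-ranking property for minority antagonists under both indices.
None of this certifies behaviour on real GBS data — reference bias, pooled
sampling of heterogeneous accessions, call-rate structure and LD decay are
all outside the generator — and the published biological results themselves
are not reproducible without the study's field phenotypes, which is why no
numeric acceptance targets exist.

## Known limitations

* REML fitting is delegated to lme4; degenerate designs return flagged
  results rather than alternative estimators.
* The per-marker exact REML scan is O(markers × n) after one O(n³)
  eigendecomposition; panels far beyond ~10⁵ markers will want
  `method = "approx"`.
* No multiallelic or polyploid support; no imputation beyond major-allele
  fill; no epistasis, spatial field correction, or multi-trait models.
* The solid-spine implementation follows the stated rule (first and last
  marker in strong D′ with every intermediate marker); Haploview's exact
  spine extension heuristics differ in edge cases.
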