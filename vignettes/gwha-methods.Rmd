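---
title: "Gene-based haplotype association in inbred panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based haplotype association in inbred panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwhap)
```

## The problem

Conventional single-SNP genome-wide association scans report markers, not
genes. In strongly inbred crop panels (rice accessions, for example) the
SNPs inside one annotated gene segregate as a small number of discrete
allele strings — haplotypes — because the accessions are essentially
homozygous and recombination within a gene body is rare in the panel's
history. A *gene-based haplotype association* (GWHA) scan exploits this:
every gene's body SNPs are collapsed into haplotype classes, and the gene
is tested as a single categorical factor against each quantitative trait.
A significant gene is then re-examined with a within-gene single-SNP scan,
and the lowest-p SNP is nominated as the gene's *key natural variant* — a
candidate functional polymorphism and a ready-made selection marker.

gwhap implements this pipeline end-to-end for quantitative multi-trait
panels (the package defaults are named for the motivating use case: the
17 grain amino-acid contents, in % dry weight, of a diverse rice panel of
164 accessions in two subspecies groups).

## The association model

For gene $g$ with haplotype classes $1, \dots, k$ (after rare-class
exclusion) and trait $y$, the model is ordinary least squares:

$$ y_i = \mu + \sum_{q=1}^{Q} \gamma_q \, \mathrm{PC}_{qi}
       + \sum_{c=2}^{k} \beta_c \, \mathbb{1}[h_i = c] + \varepsilon_i $$

where $h_i$ is accession $i$'s haplotype class (class 1, the most
frequent, is the reference) and $\mathrm{PC}_q$ are principal components
of the genome-wide dosage matrix included to absorb population
stratification. The gene-level statistic is the F-test of the joint null
$\beta_2 = \dots = \beta_k = 0$, comparing the full model against the
PCs-only reduced model:

$$ F = \frac{(\mathrm{RSS}_0 - \mathrm{RSS}_1)/\mathrm{df}_1}
            {\mathrm{RSS}_1/\mathrm{df}_2}, \qquad
   \mathrm{df}_1 = k - 1, \quad \mathrm{df}_2 = n - k - Q. $$

A gene-trait pair is called significant at a fixed $\alpha = 10^{-4}$; no
multiplicity correction is layered on top, matching the practice this
pipeline reproduces. Both thresholds are configurable
(`scan_config()`).

Degenerate inputs are flagged rather than silently dropped: a trait that
is constant on the used accessions yields no call; a perfect fit
(residual variance numerically zero) reports a p-value at the smallest
positive double with a `degenerate` flag; a design made singular by
confounding between classes and PCs has its collinear columns dropped
via QR rank detection and is flagged `collinear` (df then reflect the
retained columns).

## Parameters that matter

* `Q` (PC covariates, default **2**): the panels targeted split into two
  subpopulations, and structure enters the model through PCs rather than
  a Bayesian admixture Q-matrix. Two PCs absorb a two-group split; raise
  `Q` for more finely structured panels.
* `alpha` (default **1e-4**): the gene-level significance threshold.
* `min_class_count` (default **5** accessions): haplotype classes rarer
  than this are excluded, not pooled — a pooled "other" class has no
  biological identity and inflates the class factor's df with noise.
* `maf_min` = **0.05**, `miss_max` = **0.20**: SNPs with minor allele
  frequency below 0.05 or missing-call rate above 20% are removed before
  haplotype construction (boundaries inclusive: `maf >= 0.05` passes).
  MAF is computed on called alleles only, counting a het as one of each
  allele.
* `spacing_bp` (default **50000**): structure and kinship use SNPs
  thinned to an approximately even grid by a deterministic greedy
  left-to-right rule (~50 kb matches an even genome-wide marker grid on
  a real rice panel; synthetic fixtures are much denser and use a
  proportionally smaller spacing).

## Haplotype construction rules

Hom-ref and hom-alt calls map to the reference and alternate base; an
accession with a heterozygous *or* missing call at any gene SNP is
excluded for that gene. Residual heterozygosity in an inbred panel is
treated as noise, not a third allele, and missing calls are not imputed
— imputation could fabricate haplotype classes that exist in no plant.
Classes are labelled `Hap1, Hap2, ...` in descending accession count,
ties broken by first occurrence, which makes class labels deterministic.

## Population structure and kinship

PCA is computed by SVD of the column-centered dosage matrix (missing
dosages mean-imputed per SNP), with a deterministic sign convention
(largest-magnitude loading positive). Subpopulation labels come from
k-means on the leading PCs with a fixed seed, label 1 being the largest
cluster. Bayesian MCMC clustering was deliberately not reimplemented:
the association model consumes PCs, not admixture proportions, and PCA +
k-means recovers the same two-group story the panels of interest show.

Kinship is centered identity-by-state with VanRaden-style scaling,
$K = WW^{\top} / \sum_l 2 p_l (1 - p_l)$ with $W$ the column-centered
dosages. The exact scaling used by legacy toolkits for "centered IBS" is
not published precisely; this normalization is documented, standard, and
the kinship is diagnostic output only — the headline test corrects
structure through PCs, and mixed-model association is an explicit
non-goal.

## What the synthetic generator emulates

`simulate_panel()` produces an inbred panel of two subpopulations
(default 40 + 124 = 164 accessions) whose genes carry *planted founder
haplotypes*: each gene draws $H$ founder allele strings (default 2–8)
and every accession inherits one founder string homozygously. This
reproduces the empirically observed handful of haplotype classes per
gene; independent per-SNP draws would instead give almost every
accession a private string for multi-SNP genes. Consequences:

* `divergence` (default 0.3) is applied **per gene**: with that
  probability the two subpopulations draw independent founder-frequency
  vectors (Dirichlet), otherwise they share one. The stratified-null
  property this knob exists for — trait shifts along the subpopulation
  split inflate $\lambda_{GC}$ unless PCs are included — holds by
  construction.
* Per-SNP target minor allele frequencies are drawn uniformly on
  (0.05, 0.5) and realized by choosing the founder subset whose total
  frequency is closest to the target, so realized MAFs track the
  spectrum up to founder granularity.
* SNPs within a gene are forced to *distinguishable* founder carrier
  patterns: a new SNP's carrier subset must differ from every earlier
  pattern (and from its complement — complementary patterns segregate
  identically up to sign) by at least 0.05 of founder-frequency mass.
  Two SNPs segregating near-identically are one variant pattern, not
  two. Note the hard combinatorial limit: a gene with $H$ haplotypes
  supports at most $2^{H-1}-1$ distinct SNP bipartitions, so genes with
  many more SNPs than haplotypes unavoidably contain perfect-LD
  duplicates (as real genes do); when the pattern space is exhausted the
  generator allows them. Power and key-variant recovery claims are
  therefore benchmarked on causal genes whose SNP count is within the
  distinguishable range (4–6 SNPs on 4–8 haplotypes), because "the
  causal SNP is recovered" is only well-posed when the causal SNP is
  statistically distinguishable from its neighbours.
* Calls are corrupted with per-call missingness (default 2%) and
  residual heterozygosity (default 0.5%), typical of inbred accession
  panels.
* Traits are baseline 1.0 (% scale) + an optional subpopulation shift
  (`structure_effect`, default 0.2 in the structured-null scenarios,
  i.e. one noise SD) + Gaussian noise (`noise_sd` default 0.2) + planted
  causal effects. The effect scale is solved so that the *realized*
  explained variance — the sample $R^2$ of the trait on the causal
  effect — equals the target exactly, accounting for the sampling
  covariance between effect and background. (Scaling the variance
  *share* instead leaves the realized $R^2$ swinging by roughly
  $\pm 2\,\sqrt{f}\,(1-f)/\sqrt{n}$, about $\pm 0.07$ at $n = 164$ for a
  25% target, which would make power statements about "a gene explaining
  25%" systematically untrue of the generated data.)

What the generator does **not** emulate: linkage disequilibrium decay
between genes, recombination within genes, selection, and realistic
allele-frequency spectra shaped by demography. A green simulation test
therefore establishes algorithmic correctness and statistical
calibration under the stated generative model — not performance on any
particular real panel.

## Numerical and design choices

* All model fitting is QR-based; the test suite checks F, df and
  p-values against an independent explicit normal-equations solver to
  1e-8 relative error.
* Genomic inflation is the median-based
  $\lambda_{GC} = \mathrm{median}(\chi^2_{obs}) / 0.4549$.
* Key-variant ties (identical p-values within a gene) are broken by
  smaller genomic position — deterministic, and honest about the fact
  that perfectly collinear SNPs are statistically indistinguishable.
* The accessions used are re-intersected per gene × trait (class-
  assigned ∩ trait-present ∩ PC rows), maximizing n per test.
* Gene position on Manhattan plots is the annotated interval midpoint.
* Pipeline configs are flat JSON; every stage logs counts into a run
  manifest, and no exclusion (SNP, accession, class, gene) is silent.
* Display rounding of totals is half-up to 2 decimals (matching how
  published totals are printed); internal arithmetic is full precision.
* Trait tables are stored in % (g/100 g); `read_trait_table()` converts
  g/kg input by /10 behind a units flag.

## Known limitations

* No mixed-model (kinship-based) association; strong family structure
  beyond a two-group split may leave residual inflation.
* Haplotype construction excludes rather than imputes; panels with high
  missingness lose accessions quickly in SNP-dense genes (the exclusion
  counts are reported per gene).
* The single-SNP scan is OLS with PC covariates, chosen to keep the
  gene-level and SNP-level scans comparable; it is not a replacement for
  a dedicated GWAS toolkit on outbred material.
* Upstream/downstream regulatory SNPs are out of scope by design: only
  gene-body (annotated span, UTRs and introns included) SNPs are used,
  a choice supported by key variants found in UTRs.
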