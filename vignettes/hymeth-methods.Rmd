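---
title: "Methods: methylation divergence, cis/trans classification and inheritance in F1 hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation divergence, cis/trans classification and inheritance in F1 hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(hymeth))
```

# The analysis in one paragraph

`hymeth` analyses whole-genome bisulfite sequencing of two hybridising
species — labelled COL and PIE throughout — and their F1 hybrids, sampled in
five tissues (brain, heart, kidney, liver, testis). From per-CpG counts of
methylated and unmethylated reads it computes coverage-filtered methylation
levels, metagene profiles and methylation–expression correlations, calls
differentially methylated regions (DMRs) between tissues and species,
quantifies interval enrichment by Monte Carlo shuffling, estimates
allele-specific methylation in hybrids at fixed-difference marker loci and
classifies each locus into one of seven cis/trans divergence categories, and
classifies promoter inheritance in hybrids into six modes. A synthetic-data
generator emulates the full sampling design so every stage is testable
without sequencing data.

# Methylation level

The level of one CpG in one sample is the proportion of methylated reads
mapping to both strands of the dinucleotide, $x_m / (x_m + x_u)$. A region's
level is the *unweighted mean* of per-site proportions over its CpGs. Sites
are used only when their strand-collapsed coverage lies in $[6, 200]$: the
lower bound limits sampling noise at shallow sites, the upper bound protects
against collapsed repeats attracting mismapped reads. A region with no
passing site has an *undefined* level, propagated as `NA` — never as 0,
which is a legitimate fully-unmethylated value. The coverage filter is
applied after strand collapsing, on the summed total.

Internally all positions live in 1-based `GRanges`; Bismark coverage files
keep their native 1-based convention on disk, and BED output is 0-based
half-open. The conversions happen only in the I/O layer.

# Metagene profiles

Profiles use 199 bins per gene: 50 fixed 100-bp bins covering 5 kb upstream
of the TSS, 99 gene-body rank bins, and 50 fixed bins downstream of the TTS,
all oriented 5'→3' by strand. Gene bodies are cut into 100-bp segments from
the 5' end (the shorter 3'-terminal segment is kept so short genes do not
lose their termini) and each segment is assigned rank
$\lceil 99 \cdot m / L \rceil$ where $m$ is the segment midpoint's relative
position and $L$ the gene length. The midpoint rule with ties to the lower
rank was chosen because it is deterministic and independent of processing
order; an edge-based rule would differ only for segments straddling rank
boundaries. Correlation profiles report the Spearman rank correlation across
genes between a bin's methylation and per-gene expression, requiring at
least 3 complete pairs; all-tied bins are undefined. Expression categories
(L/M/H) partition genes exactly 20/60/20 by rank.

# DMR calling

A CpG enters a comparison only if at least two samples *per group* cover it
with $\ge 2$ reads. Group mean levels are computed per CpG, and their
difference is smoothed along each chromosome with a Nadaraya–Watson
triangular-kernel smoother (bandwidth 500 bp). Candidate regions are maximal
runs of consecutive CpGs — runs break at gaps over 1 kb, a free parameter
that prevents regions from spanning CpG deserts — whose smoothed difference
lies beyond the comparison-wide 0.01/0.99 quantiles of the smoothed
difference, one tail at a time. Candidates become DMRs when they span at
least 3 CpGs and their mean *raw* difference is at least 0.1 in absolute
value. `mean_diff` is signed group1 − group2; "hyper" and "hypo" are
relative terms within a comparison. By construction a fully null comparison
places about 2% of CpGs inside pre-filter candidate runs (the two 1%
tails), which the test suite verifies.

The quantile thresholds are deliberately applied to the smoothed *methylation
difference*, not to a t-like statistic; the smoother itself is tool-internal
and configurable, and the suite checks that planted differential blocks are
recovered and null genomes produce the designed tail mass, which is the
behaviour the downstream criteria depend on.

Tissue-specific DMRs (tsDMRs) for a focal tissue are regions differentially
methylated against *all four* other tissues — matched across comparisons by
at least 25% reciprocal overlap — and not matched by any DMR of a comparison
that does not involve the focal tissue. Directional bias of a DMR set is the
fraction hypermethylated with a two-sided exact binomial test against 0.5.

# Monte Carlo interval enrichment

The observed statistic is the total bp overlap between a query set (e.g.
DMRs) and an annotation set. The null distribution shuffles the query 1000
times: each interval is independently re-placed uniformly over every genomic
start position that keeps it on one chromosome (chromosomes weighted by
their number of valid placements), preserving lengths and permitting
overlaps among placed intervals. No regions are excluded by default. The
empirical p-value is exactly $r/n$ — with $r$ the replicates at least as
extreme in the reported tail — so $p = 0$ is attainable; an optional
$(r+1)/(n+1)$ smoothing is provided for users who prefer it. Both tails are
always computed and the reported tail is chosen by comparing the observed
overlap with the replicate mean. Families of tests are controlled with
Bonferroni at a family-wise error rate of 0.1, and enrichment strength is
the odds ratio
$\frac{\mathrm{overlap}/L_{query}}{L_{annotation}/L_{genome}}$.

# Allele-specific methylation and cis/trans classification

At fixed differences between the species, hybrid reads can be assigned to
their parental allele; methylation is then measured in the 200-bp window
centred on the marker (read-level allele splitting is upstream of this
package; the generator emits allele-resolved counts directly). To equalise
information between hybrids and parents, hybrid allele coverage is capped at
its 0.9 quantile, parental samples are randomly downsampled to 3 individuals
and their coverage capped at the 0.45 quantile (each parental read carries
one allele, a hybrid read only half as often). Caps rescale counts
proportionally with half-to-even rounding.

Four contrasts are tested per locus with a beta regression: parental
(COL vs PIE parents), hybrid (COL vs PIE allele within hybrids), and two
trans-effect tests comparing the same allele between its parental and hybrid
cellular environment. The regression fits a beta likelihood with logit mean
$\mu = \mathrm{logit}^{-1}(\beta_0 + \beta_1 g)$ and common precision
$\phi$ by maximum likelihood (analytic-gradient L-BFGS-B; the logit link was
chosen as the standard link for proportion GLMs). Boundary values are shrunk
with $y' = (y(N-1)+0.5)/N$. The Wald statistic for $\beta_1$ is referred to
a $t$ distribution on $N-3$ degrees of freedom: at $n = 3$ per group the ML
precision estimate is biased upward and the normal reference is strongly
anti-conservative (empirical type-I error ≈ 0.19 at $\alpha = 0.05$),
whereas the residual-df $t$ reference calibrates to ≈ 0.05, which the
acceptance suite verifies against the band $[0.03, 0.08]$.

Benjamini–Hochberg q-values are computed across loci separately within each
of the four test families, and a locus is classified at FDR 0.1:

| category | parental | hybrid | trans | extra condition |
|---|---|---|---|---|
| ambiguous | — | — | — | any group without data |
| conserved | ns | ns | — | |
| cis | sig | sig | ns | same sign of both contrasts |
| trans | sig | ns | sig | |
| cis+trans | sig | sig | sig | trans component and hybrid contrast same sign |
| cis×trans | sig | sig | sig | opposite signs |
| compensatory | ns | sig | sig | cis and trans cancel between species |

Patterns matching no rule are reported as `unclassified` rather than forced
into a category. The trans effect is called, by default, when *either*
allele's environment contrast is significant; a single-test mode using only
the PIE contrast is available, since either convention equalises the number
of null hypotheses needed across categories. The sign of the trans
component is $\mathrm{sign}(\Delta_P - \Delta_H)$, the standard
decomposition in which the parental difference is the sum of cis and trans
parts.

Inheritance geometry over loci is summarised with major axis (model II)
regression of the COL parental−hybrid difference on the PIE
parental−hybrid difference; the closed-form slope is the leading principal
axis, and significance comes from the correlation test. Pure-cis loci
cluster at the origin (alleles insensitive to the cellular environment);
pure-trans loci spread along the slope −1 additive axis because both hybrid
alleles converge to the midparent.

# Promoter inheritance in hybrids

Each promoter is placed at $x = M_H - M_{COL}$, $y = M_H - M_{PIE}$. If the
same hybrid value is used on both axes then under independence
$\mathrm{cov}(x, y) = \mathrm{var}(M_H)$, which inflates the apparent over-
and underdominance (the diagonal directions). The correction draws two
distinct hybrid replicates, one per axis; with uniform noise this reduces
the covariance from $1/12$ to ≈ 0, which the suite verifies by Monte Carlo
at $n = 10^5$. Parental terms use group means: the artifact comes only from
the shared hybrid term, and means minimise parental noise.

Points with radius below 0.1 are conserved. The remaining plane is split
into eight $\pi/4$-wide sectors whose boundaries sit $\pi/8$ on either side
of the axes and diagonals (eight slices of width $\pi/8$ around each
half-axis cannot tile the plane, so the boundaries-at-odd-multiples-of-$\pi/8$
reading is used). Sector centres map to categories by the meaning of the
axes: $x = y > 0$ is overdominant, $x = y < 0$ underdominant, $x = -y$
additive (hybrid between parents), $x \approx 0$ collared-dominant (hybrid
at the COL value), $y \approx 0$ pied-dominant. Boundaries are half-open
with the counter-clockwise sector inclusive, for determinism. The suite
checks that the sector map is a partition, behaves correctly under point
reflection, and modally recovers all six generated modes at noise SD 0.02
and effect 0.3.

# Association statistics

**BCA.** Between-groups PCA R² is the between-group sum of squares of the
samples (size-weighted group means after column centring) over the total sum
of squares — the sample-score definition. Significance is by label
permutation (999 by default, p = (exceed+1)/(nPerm+1)). With a control
grouping the matrix is first centred within each control stratum and labels
permute within strata, implementing "between species controlled for
tissue"; R² is then invariant to any stratum-constant offset.

**PEM.** The preferential expression measure of gene $g$ in tissue $t$ is
$\log_{10}(x_{gt} / \bar{x}_{g\cdot})$. Its upper bound is $\log_{10} T$
(≈ 0.699 for five tissues); a "−∞ to 1" range only holds for ten tissues,
so the bound is documented as panel-dependent rather than silently changed.
Genes silent in all tissues are excluded; zero expression in one tissue
gives −∞, treated as missing by the rank tests. tsDMR–expression
association uses a chi-square test on the focal tissue's PEM rank
(tsDMR genes vs genes without a promoter tsDMR anywhere), followed by
Wilcoxon rank-sum tests on mean PEM run separately for over- (PEM > 0) and
under-expressed (PEM < 0) genes.

**DE association.** DE and non-DE genes are compared with paired t-tests
whose pairing unit is the profile bin (20 promoter bins or 99 gene-body
bins) — the natural unit when the compared quantities are per-bin set
means; the sign of the mean difference is reported alongside p.

**Fst–Mdiff.** Per profile bin, the Spearman correlation across genes
between binned genetic differentiation (Fst, split into CpG and non-CpG
site classes, supplied as input) and absolute methylation differentiation
$M_{diff} = |\bar{m}_{COL} - \bar{m}_{PIE}|$.

# The synthetic-data generator

The generator emulates the design the downstream statistics assume, not a
real genome:

* **Geometry.** Two 1-Mb chromosomes by default; background CpGs as a
  geometric spacing process (rate 0.01/bp ≈ vertebrate-like density), dense
  runs (mean spacing 8 bp) at CpG islands; non-overlapping genes of 2–8 kb
  with 2-kb promoters; 60% of promoters seeded with an island; marker loci
  as 200-bp windows in intergenic space, each with a dense CpG run so the
  windows are measurable.
* **Counts.** Coverage is negative binomial (mean 30, size 5 — matching the
  study's median depth range); methylated counts are beta-binomial with
  precision $\phi = 30$. The original data are empirical, so no noise model
  is prescribed anywhere; beta-binomial is the standard overdispersed count
  model for bisulfite data and its parameters are free. Per-site
  heterogeneity draws site means from a beta distribution around the
  configured level, so with all effects zero the genome-wide mean equals the
  configured base level exactly in expectation.
* **Effects.** Tissue and species shifts act on the logit of the mean (the
  natural scale for proportion models); architecture and inheritance
  effects are specified on the proportion scale (default 0.3) because the
  downstream cutoffs (0.1 radius, 0.1 mean difference) live there. Hybrid
  bulk samples mix the two allele means 50:50, the autosomal diploid
  expectation. Cis loci keep the allele difference in both environments;
  trans loci converge hybrid alleles to the midparent; compensatory loci
  have equal parents but split hybrid alleles; cis+trans and cis×trans
  combine a hybrid (cis) difference with a reinforcing or opposing trans
  shift.
* **Expression.** Negative-binomial counts whose log2 mean couples to the
  sample's promoter methylation (default slope −3, i.e. repression); 10% of
  genes are truth-DE with a 1 log2-unit species shift. The Fst track couples
  CpG-context Fst to the per-gene methylation divergence three times more
  strongly than non-CpG Fst.
* **Reproducibility.** One RNG stream per sample column derived from the
  master seed, so output is identical under a fixed seed and insensitive to
  evaluation order.

What the generator does **not** emulate — and therefore what green tests do
not certify about real data: read-level artefacts (mapping bias, incomplete
bisulfite conversion, M-bias), linked genetic variation and LD structure,
realistic gene/TE architecture, sex-chromosome dosage, and biological
covariance between tissues of one individual beyond the shared site means.

# Problem sizes and numerical choices

The test and acceptance runs use deliberately desk-scale problems chosen to
keep Monte Carlo error well inside the asserted tolerances: $10^5$ points
for the covariance identity, 500 loci per class (coverage 30×, $n = 3$,
effect 0.3) for architecture recovery, 2000 null loci for Wald calibration,
200 null runs × 200 shuffles for enrichment calibration, and a 2 × 1 Mb
five-tissue study (6 + 5 + 3 individuals) for the end-to-end run. Degenerate
inputs are handled explicitly: zero-coverage sites and empty regions are
undefined (`NA`), all-tied correlations are undefined, non-converged beta
fits make a locus ambiguous, an axis-aligned major-axis scatter has an
undefined slope, and classification functions never return values outside
their closed vocabularies.

# Known limitations

* The DMR caller's kernel smoother is a deliberate, documented replacement
  for a local-likelihood smoother; absolute DMR counts depend on the
  smoother and its bandwidth, while the acceptance properties (planted-block
  recovery, null tail mass, criteria enforcement) do not.
* The CGI detector is a desk-scale distance-clustering method (median
  spacing threshold, negative-binomial cluster p, BH 0.05, min 50 bp), not
  a re-implementation of any specific published tool.
* With three hybrids, the decorrelated inheritance axes still share
  replicates across promoters; the correction targets the dominant
  shared-term covariance only.
* Beta regression is unweighted by coverage (levels are already capped and
  filtered); a coverage-weighted variant is a possible extension.
* The Z-vs-autosome contrast is a partition by a chromosome-class column;
  no dosage model is attempted.
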