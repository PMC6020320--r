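---
title: "Methods: integrative eQTL mapping, hotspot detection and stratified co-expression networks"
author: "eqtlHotspots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative eQTL mapping, hotspot detection and stratified co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`eqtlHotspots` implements an integrative expression quantitative trait locus
(eQTL) analysis of the kind used to dissect complex traits in livestock and
human cohorts: genome-wide association between SNP dosages and gene
expression, classification of associations as local (cis) or distant
(trans), detection of trans-eQTL *hotspots* (single variants associated
with the expression of many genes, suggesting a shared regulator such as a
transcription factor in the region), permutation tests for overlap between
eQTL-derived regions and previously reported QTL regions, ANOVA of hotspot
genotypes on phenotypes, scanning of target-gene promoters for
transcription-factor binding sites (TFBS), and genotype-stratified weighted
co-expression networks whose module eigengenes are correlated with the
phenotypes.

Because the motivating setting is a cattle muscle cohort whose individual
level data are not public, the package ships a synthetic-data generator
that plants all of the structure the analysis is designed to find: cis
effects, one TF-mediated trans hotspot, fixed-effect covariates
(contemporary group, sequencing lane, age), module-coupled traits, and
promoter motif occurrences. Every downstream stage is therefore testable
end to end, and the test suite asserts recovery of the planted truth
rather than cohort-specific counts.

# The association model

Each variant--gene pair is tested with ordinary least squares

$$ y_g = \mu + X\alpha + \beta \, d_v + \varepsilon,\qquad
   \varepsilon \sim N(0, \sigma^2 I), $$

where $y_g$ is the gene's expression across samples, $d_v \in \{0,1,2\}$
the alternate-allele dosage (additive coding) and $X$ the fixed-effect
design: dummy-coded contemporary group and lane plus age as a numeric
covariate. The reported statistic is the two-sided Student $t$ for
$\hat\beta$ with residual degrees of freedom.

The genome-wide scan (`mapEqtl()`) residualises the expression matrix and
the mean-imputed dosage matrix on $X$ once and recovers each pair's
$\hat\beta$, standard error, $t$ and $p$ from cross-products. This is
algebraically identical to fitting every pair separately (the
Frisch--Waugh--Lovell theorem); the test suite asserts equality with
`fitAdditiveModel()` to $10^{-10}$.

A pair is **cis** when the variant lies on the gene's chromosome within
1 Mb of the gene span (distance 0 inside the span, else distance to the
nearest span boundary; exactly 1 Mb is still cis, reading "within" as
inclusive), otherwise **trans**. Distances are span-based rather than
TSS-based -- the choice matters little at desk scale and is stated here
because either convention is defensible. Benjamini--Hochberg FDR is applied
separately within the cis and the trans stream (a pooled mode is available
via `pooled_fdr = TRUE`), and significance means $q \le 0.05$ by default.

Variant QC mirrors standard chip filters: variants with call rate
$\le$ 95% or MAF $\le$ 5% are removed (strictly greater survives), as are
sex-chromosome and unmapped variants.

# Hotspot detection

A hotspot candidate is a variant whose number of *distinct* significant
trans target genes reaches a permutation threshold. The null model
reassigns every significant association to a variant drawn uniformly with
replacement from all tested variants; the per-permutation statistic is the
**maximum** per-variant distinct-target count, and the threshold is the
ceiling of the 95th percentile of 1000 such maxima. Using the maximum
gives family-wise control over the most extreme variant; a pooled
alternative (95th percentile of all per-variant counts) is available via
`null = "pooled"`. The published analysis this emulates does not state
which variant it used; the maximum is the stricter default. For toy
instances `exhaustive = TRUE` enumerates all assignments, which the tests
use to check the null distribution exactly.

Candidates over threshold are refined by linkage disequilibrium: sorted by
target count (ties: smaller minimum p, then position), each accepted
anchor absorbs remaining candidates with dosage $r^2 \ge 0.5$ (no
published merge threshold exists; 0.5 -- "half the variance shared" -- is
the package default and a parameter). The anchor keeps its own target
list; absorbed ids are recorded. Each call gets a 4 Mb window (2 Mb each
side of the anchor, clipped at chromosome ends with a flag).

LD itself is computed two ways: $r^2$ as the squared Pearson correlation
of dosages, and $D'$ from haplotype frequencies estimated by EM on the
3x3 genotype table (only double heterozygotes are phase-ambiguous;
100 iterations or $\Delta < 10^{-10}$), with
$D' = |D| / D_{\max}$ and the usual sign-dependent $D_{\max}$.

# Region overlap

`permutationOverlapTest()` measures the basewise overlap (in Mb, after
reducing each set to its union so nothing is double-counted) between a
query region set and a reference set, and compares it with overlaps of
size- and chromosome-matched random regions (one uniform placement per
template interval; placements may overlap each other -- a
`no_self_overlap` mode exists). The p-value is the add-one estimator
$(1 + \#\{perm \ge obs\})/(1 + N)$, so it is bounded below by $1/(N+1)$.
Overlapping pairs are also classified into four categories -- `AinB`
(query contained in reference; ties count as containment), `BinA`,
`AleftB`, `ArightB` -- on the unmerged inputs.

# Hotspot--phenotype ANOVA

Each hotspot anchor is tested against each phenotype with a fixed-effects
ANOVA: trait ~ contemporary group + lane + age + genotype, genotype
entered last so its sequential F is the covariate-adjusted test. Genotype
is an unordered factor over dosage classes (AA/AB/BB); levels with fewer
than 2 observations are dropped, reflecting that alternate homozygotes are
often too rare to compare. For a two-level genotype the F equals the
square of the OLS $t$ -- asserted in tests, tying this module to the eQTL
fitter. BH is applied across traits within each hotspot (a global mode is
available). Phenotypes used in correlation analyses are covariate-adjusted
by the same fixed-effects residualisation (`adjustPhenotype()`); the
external adjustment procedure cited by the motivating study is not
published in reproducible form, so residualisation on the same covariates
is the package's documented choice.

# Promoter TFBS scanning

Position frequency matrices (JASPAR text format) are converted to PSSMs
with a pseudocount of 0.25 per cell and a uniform background by default:
$p_{bj} = (c_{bj} + 0.25)/(n_j + 1)$, scores are $\log_2(p/\pi_b)$ summed
over positions, and `N` bases contribute 0 (the background expectation).
Promoters are 1500 bp; scanning covers every window on both strands.

Score significance is *exact*: the distribution of the score of a random
background L-mer is computed by dynamic-programming convolution of the
per-position score distributions -- exactly (merging duplicate sums) while
the state space is enumerable, and on a discretised grid of at most
$10^{-3}$ bits for long motifs. The per-window p-value is the tail
probability $P(S \ge s)$; tests assert equality with full enumeration for
all motif lengths $\le 6$ to $10^{-9}$. Hits are windows with
$p \le 0.05$ per window, uncorrected within a promoter (matching the
per-site usage this emulates); a per-promoter Bonferroni mode exists. The
scanner here is a standard PSSM scanner with exact p-values -- it is not a
reimplementation of the length-aware alignment tool used in the motivating
study, whose training data are external; the published ~98% target-promoter
hit rate is therefore not a quantity this package tries to reproduce.

# Genotype-stratified co-expression networks

For a hotspot anchor, samples are split into AA (dosage 0) and AB
(dosage 1) groups; rare BB samples are excluded with a count. Within each
group the unsigned weighted network is built on covariate-adjusted
expression: adjacency $a_{ij} = |\mathrm{cor}(x_i, x_j)|^6$ (soft power 6,
the conventional default at which the scale-free fit index is expected to
be high; `scaleFreeFit()` reports $R^2$ of the log-log degree-frequency
regression and its slope), topological overlap

$$ \mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}
   {\min(k_i, k_j) + 1 - a_{ij}},\qquad
   \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}, $$

and average-linkage clustering of $1 - \mathrm{TOM}$. Module detection is
the *tree* variant of dynamic tree cut: a static cut at a deep-split
controlled fraction of the maximum merge height (0.99/0.985/0.98/0.97/0.96
for deep split 0..4; default 2), keeping branches with at least 30 leaves
as modules and labelling the rest grey. The PAM-refinement stage of the
hybrid algorithm is intentionally out of scope: all assertions are about
planted-block recovery (adjusted Rand index), not exact module
boundaries.

Module eigengenes are the leading right-singular vectors of the
standardised member expression (unit norm over samples), sign-oriented so
the mean member correlation is positive -- a convention required for
reproducibility since the sign is otherwise arbitrary. Modules whose
eigengenes correlate above 0.75 (dissimilarity below 0.25) are merged
iteratively to a fixed point. To make the smaller genotype group's TOM
comparable with the larger group's, it is raised elementwise to
$\log q_{ref} / \log q_{small}$ so the two 95th percentiles agree.

Module--trait association uses Pearson correlation of eigengenes with
covariate-adjusted traits and the Student asymptotic p-value
($t = |r|\sqrt{n-2}/\sqrt{1-r^2}$). Modules with $p < 0.1$ for at least
three distinct traits are selected for enrichment; gene significance
(|cor| with trait) and module membership (signed cor with eigengene) rank
genes, and the top 20 by |MM| are reported as hubs.

# Gene-set enrichment

Over-representation of user-supplied gene sets (GMT) in selected module
gene lists uses the upper-tail hypergeometric test with the network's own
genes as the background, BH-corrected across sets within each module;
sets with fewer than 3 in-background members are skipped.

# The synthetic-data generator

`simulateStudy()` emulates the study conditions:

* **Genotypes** -- two haplotypes per sample, first-order Markov allele
  copying along each chromosome with probability `ld_copy_prob` (default
  0.9), giving tunable LD decay and Hardy--Weinberg genotypes in
  expectation; alternate-allele frequencies uniform in `maf_range`
  (default 0.1--0.5; the Markov marginal is a convex combination of
  upstream frequencies, so it stays inside the range).
* **Expression** -- per-gene baselines $N(8, 2^2)$ on an arbitrary
  log-like scale (the pipeline never interprets units); planted cis pairs
  add `cis_beta` x dosage of the nearest unused same-chromosome variant;
  the hotspot variant raises a nearby TF gene, whose centred expression
  drives `hotspot_n_targets` trans genes with slope `target_gamma`
  (targets are drawn from other chromosomes so every hotspot association
  is trans). Centring the TF signal keeps per-gene baselines
  interpretable and changes nothing downstream. Contemporary-group and
  lane effects (one $N(0,1)$ draw per level) plus a linear age effect are
  added to every gene and trait and stored in the truth bundle so
  adjustment can be verified exactly.
* **Phenotypes** -- each of 15 traits (the motivating study's panel size)
  loads on the mean standardised expression of the hotspot-target group
  plus covariates and noise.
* **Promoters** -- 1500 bp i.i.d.-uniform sequences; a configurable
  fraction of target promoters receives one motif occurrence sampled from
  the PSSM at a recorded offset and strand.
* **Determinism** -- one master seed expands to per-component child seeds
  by fixed offsets; every generator is a pure function of (config, seed).

Defaults (300 samples, 3 chromosomes of 10 Mb, 300 variants, 150 genes,
cis effect 1 against residual SD 1, 40 hotspot targets) describe a
desk-scale study at which planted cis pairs are recoverable with high
power and the hotspot is unambiguous. What the generator does **not**
emulate: read-level RNA-seq noise, realistic recombination maps, pedigree
or population structure, non-Gaussian expression. Passing tests therefore
demonstrate correctness of the statistical machinery on data satisfying
its assumptions, not robustness to everything real cohorts do.

The empirical-FDR evaluation simulates genotypes in linkage equilibrium
(`ld_copy_prob = 0`): under LD, neighbours of a planted variant are
genuinely associated with the target gene, and counting them as false
positives would misstate the error rate.

# Numerical and design notes

* Missing dosages are mean-imputed per variant at analysis time, never at
  I/O time, so QC filters see the true call rate. Multi-allelic VCF
  records are rejected rather than split (chip data are biallelic).
* Chromosome names are taken verbatim; coordinate conventions are 1-based
  inclusive everywhere, with only BED I/O converting.
* `bhFdr()` delegates to `stats::p.adjust(method = "BH")`; `NA` p-values
  propagate with a warning.
* ANOVA exact fits (residual SS numerically zero) report the F as
  infinite and the p below machine floor, flagged `exact_fit`.
* Candidate ordering, hub ranking and module labels are all given
  deterministic tie-breaks so identical inputs give identical outputs.
* Expression entering the networks is covariate-adjusted; otherwise
  shared contemporary-group/lane effects induce a global correlation
  component that swallows all genes into one module.
* Problem sizes in tests and in `scripts/acceptance.R` (hundreds of
  samples, hundreds of variants, 100--200 genes, 500--1000 permutations)
  are the package's chosen desk-scale study conditions; all statistical
  assertions are calibrated properties (uniform null p-values, FDR
  control, recovery rates), not cohort-specific counts.

# Known limitations

* No mixed-model/kinship correction: the motivating cohort reported no
  stratification, and the model is fixed-effects only.
* The tree-variant module detection is coarser than the hybrid dynamic
  tree cut; very close modules may merge or split differently.
* $D'$ from EM assumes random mating within the sample; tiny or highly
  inbred samples can bias the haplotype frequency estimates.
* The exact PSSM p-value is per window; promoter-level error control is
  optional and off by default.
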