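---
title: "Methods: models, estimators and design choices in maluspop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in maluspop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`maluspop` re-implements, as a tested and reusable pipeline, the standard
analysis battery applied to SNP panels from clonally propagated crop
germplasm collections — apple being the motivating system: ploidy
screening from heterozygosity, clone and first-degree relationship
networks from identity by descent, ancestry deconvolution of a
domesticated population against two wild progenitors, genome scans for
selection, kinship-corrected association for binary traits, and a
homozygosity resampling test. Because real collection genotypes cannot
ship with the package, a synthetic-data generator with full ground truth
stands in for them; every downstream stage is validated against that
truth.

## The synthetic panel

The generator is a *stated world*, not a tuning dial: its defaults are
fixed once and the test suite asserts recovery under them.

**Founders.** Per-variant ancestral allele frequencies are drawn
Uniform(0.05, 0.95). Two wild progenitor populations A and B drift
independently under the Balding–Nichols model: each population frequency
is Beta(p(1−F)/F, (1−p)(1−F)/F) with `drift_f = F = 0.2` by default. The
downstream analyses (Fst, reference PCA, f3) only require this minimal
differentiation structure; no effective population sizes or divergence
times are estimated, so `drift_f` is a free parameter. A note on scale:
the multi-locus (ratio-of-sums) Weir–Cockerham estimate between samples
of the two populations tracks `drift_f` closely (0.194 at F = 0.2 in the
suite), whereas the *mean of per-site ratios* is biased low (~0.14) —
this is the familiar Jensen-type bias of averaging noisy ratios, which
is why `global_fst()` uses the ratio-of-sums form.

**Admixture.** Derived ("domesticated") haplotypes are mosaics of
contiguous ancestry blocks with exponential lengths (mean 2 Mb), each
block originating from progenitor A with probability `admixture_alpha`
(default 0.5, since both wild relatives contribute ancestry to the
domesticated population being emulated). Blocks — rather than per-site
i.i.d. ancestry — give haplotype-based scans realistic local LD.

**Pedigree.** Offspring receive one recombinant gamete per parent;
crossover counts per chromosome are Poisson(1.5). The default 55
offspring mirror the size of the known parent–offspring calibration set
the analysis style relies on.

**Artifacts.** Clones copy a source genotype with per-site call error
(default 0.01), errors being redrawn from Hardy–Weinberg proportions at
the panel frequency. Triploids are represented the way a diploid caller
reports them: a third allele is drawn from the derived-population
frequency and the 0–3 dosage collapses as 0→0, {1,2}→1, 3→2, which
inflates apparent heterozygosity — the signature the ploidy screen
exploits. Missing calls are inserted uniformly (default 2%). Default
counts (8 triploids among 60 derived founders, ~13%) match the triploid
fraction reported for apple collections.

**Sweep and trait.** Within a 1 Mb interval, 90% of the target
population's haplotypes are replaced by one fixed haplotype, the
canonical post-sweep configuration XP-EHH is designed to detect. A
binary trait is driven by one causal variant (penetrance 0.9,
background rate 0.05 by default; recovery tests use 1/0).

**What the generator does not emulate:** coalescent gene genealogies,
empirical recombination maps, sequencing depth/quality, imputation
error, and the species mislabelling the real curation step corrects. A
green recovery test therefore establishes correctness of the estimators
under the stated model, not robustness to every artefact of real GBS
data.

## Ploidy screen

Per-individual heterozygosity is the fraction of heterozygous calls
among non-missing calls; samples with zero calls are flagged undefined
rather than scored 0. Group differences between ploidy labels are tested
by one-way ANOVA with Tukey HSD. The default flagging threshold 0.21 is
*panel-specific* (it was calibrated on a particular collection); because
simulated panels have different baseline heterozygosity, a data-driven
`"midpoint"` mode (midway between the 2x- and 3x-labelled group means)
is provided and used by the pipeline on simulated data. Tetraploids are
treated as diploid-like: their collapsed calls do not show the 3x
heterozygosity excess. Classification is by heterozygosity alone,
regardless of label, matching how the screen is used in practice.

## Identity by descent

`estimate_ibd()` is a PLINK-style method-of-moments estimator. For each
pair, IBS0/1/2 site counts over jointly non-missing sites are equated
with their expectations under IBD states 0/1/2. Per-site expected IBS
probabilities use allele frequencies from the **full analysed sample**
(a documented knob: founder-frequency misspecification biases pi-hat
upward in structured panels) with unbiased small-sample corrections —
products of frequencies are estimated by sampling allele counts without
replacement. The triangular system is solved sequentially, negative
estimates are clipped to zero and the probabilities renormalised;
pi-hat = z1/2 + z2.

Two numerical consequences are worth knowing. First, clipping leaves a
positive O(m^(−1/2)) bias on pi-hat for truly unrelated pairs (~0.02 at
5,000 sites, shrinking with more sites). Second, for parent–offspring
pairs IBS0 = 0 forces z0 = 0, and sampling noise that pushes z1 above 1
is renormalised back to exactly 1, so a large fraction of
parent–offspring pi-hat values sit at exactly 0.5 — the calibrated
first-degree range therefore brackets 0.5 inclusively.

## Clone groups and the relationship network

Pairs with pi-hat > 0.9 define the clonal graph. A connected component
is accepted as a group only if *every* within-component pair exceeds the
threshold; otherwise it is split by complete-linkage agglomeration on
1 − pi-hat, cut just below 1 − threshold, which guarantees the all-pairs
rule on the output. The retained representative is the
lexicographically smallest id — determinism matters more than any
particular choice.

The first-degree range is calibrated from known parent–offspring pairs.
The default drop rule removes low outliers below Q1 − 1.5·IQR (presumed
mislabels); a fixed-count mode (`drop_n = 2`) is available to replicate
the drop-two-lowest convention, which is panel-specific. Edges inside
the range are typed `first_degree` only: parent–offspring, full sibs and
equivalent relationships are indistinguishable from genotype moments.

## Ancestry

**Projection PCA.** Axes are fitted on *equal-sized* reference panels
from the two progenitors (the larger set is down-sampled
deterministically — first k ids in sorted order — so reruns are exact);
unequal reference sizes would let the better-sampled population dominate
the axis. Genotypes are centred by 2p̂ and scaled by sqrt(p̂(1−p̂)), with
p̂ estimated from the references with pseudocount 1/(2n+2). Other
samples are projected by least squares over their observed entries,
which reduces to the plain loading inner product when nothing is
missing and does not shrink scores toward the origin under missingness.
Component signs follow the largest-|loading|-positive convention.

**Rank-sum comparison.** Mann–Whitney U on a chosen component, exact for
tie-free groups of ≤20, otherwise normal approximation with tie
correction — the threshold is an implementation choice; only the test
itself is prescribed.

**f3.** The per-variant term (ĉ−â)(ĉ−b̂) − ĉ(1−ĉ)/(n_c−1) subtracts the
unbiased estimate of the target frequency's sampling variance, so an
unadmixed target gives mean ≈ 0 rather than spuriously negative values.
The statistic is the unweighted mean over usable variants; the standard
error is a leave-one-block-out jackknife over contiguous physical blocks
(default 5 Mb — a knob, since no genetic map is assumed).

## Selection scans

**Fst.** Per-site Weir–Cockerham θ̂ = a/(a+b+c) from the two-population
variance components; negative estimates are retained, undefined sites
(zero denominator, or a group with <2 called samples) are excluded from
quantile calls.

**XP-EHH.** EHH at distance d from a core is Σ_k C(n_k,2)/C(n,2) over
haplotype groups extended to d. Per population the *combined-allele*
curve (all haplotypes, both core alleles) is integrated by trapezoid
over physical distance, left plus right; the walk stops below EHH = 0.05,
at chromosome ends (truncation permitted), or at inter-variant gaps
above 1.5 Mb — both defaults taken from the cited scan software's
options and configurable. The raw score ln(iHH_A/iHH_B) is standardised
genome-wide. Unphased input is rejected rather than heuristically
phased; statistical phasing is out of scope and the generator supplies
truth phase.

**Candidate calls.** `fst_top` flags the top 5% of defined Fst values;
`xpehh_top` flags the top 5% *of positive* standardised scores
(`high_tail`, homozygosity excess in population A) — implemented
literally as the top ⌈q·n⌉ by rank so the flagged count is deterministic.
The `low_tail` direction (homozygosity excess in population B) is the
mirror image: the bottom 5% of *negative* values.
Overlap candidates carry both flags. An optional region merge within
100 kb is provided for reporting only; the distance is arbitrary and
documented as such.

**Genes and enrichment.** A gene qualifies only if its *entire* span
lies within ±50 kb of a candidate variant. Term enrichment is a plain
one-sided hypergeometric test with Benjamini–Hochberg adjustment — a
deliberate semantic simplification of hierarchy-aware term-weighting
algorithms, which are out of scope.

## Association

The kinship matrix is the standardised-genotype cross-product Z Z'/m.
Note that centring by sample frequencies forces the off-diagonal mean
toward −1/(n−1); "near zero" for unrelated panels means at that scale.

`lmm_scan()` fits y = Xβ + g·β_g + u + e with u ~ N(0, σ²_g K). Binary
phenotypes are modelled as 0/1 quantitative responses (matching common
GWAS tooling; a logistic mixed model is out of scope). The variance
ratio δ = σ²_e/σ²_g is estimated once on the null model by REML via the
eigendecomposition of K and reused for every variant (the
population-parameters-previously-determined shortcut), followed by
per-variant generalised least squares and Wald t tests. With K = I the
procedure is *exactly* ordinary least squares, which the suite asserts
to 1e-8. Significance is Bonferroni at α = 0.05 over tested variants.

`mlmm_stepwise()` adds the current top variant as a fixed cofactor,
refits, and records EBIC = −2·logLik_ML + k·log n + 2γ·log C(m,k) with
γ = 1, the most conservative standard choice. The EBIC-optimal model's
scan is returned with cofactors excluded from their own test.

The homozygosity resample draws k accessions without replacement
`n_draws` times and reports the all-homozygous fraction next to the
exact hypergeometric product ∏(K−i)/(N−i), its analytic limit.

## Numerical and degenerate-input policy

Dosages outside {0,1,2}, inconsistent dimensions, unsorted variant
positions and non-topological pedigrees are rejected at construction.
Samples with no calls yield flagged undefined statistics, never silent
zeros. Standardisation of a constant track is an error, not NaN.
All randomness flows from explicit seeds (one per simulation config, one
per pipeline run); reruns are byte-identical, which the suite asserts on
emitted VCF/TSV/JSON artifacts.

## Known limitations

- pi-hat inherits the clipping bias described above and, in structured
  panels, an upward bias from using pooled allele frequencies; no
  correction for genotyping error or uneven SNP density is applied.
- The LMM treats binary traits linearly; rare traits with strong
  case–control imbalance would warrant a logistic model.
- XP-EHH power depends on marker density inside the swept region; the
  generator's uniform marker placement is favourable compared to sparse
  reduced-representation data.
- Enrichment ignores term-hierarchy structure, so broad terms can appear
  enriched through their specific children.
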