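---
title: "Models and methods behind chromdyn"
author: "chromdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromdyn)
```

# Scope

`chromdyn` implements a comparative-epigenomics toolkit for plant genomes
analysed at fixed 200-bp bin resolution: chromatin-state segmentation with a
multivariate-Bernoulli hidden Markov model (HMM), binomial-test calling of
differentially methylated regions (DMRs) and their coupling to state
switches, tissue-pair state-switching statistics, classification of
open-chromatin peaks into distal and proximal regulatory elements (DRE/PRE)
with chromatin-loop gene categories, and conservation/divergence statistics
across a multi-variety panel.  A hidden-state-driven synthetic-epigenome
generator with planted truth makes every stage testable end to end without
any sequencing data.

This vignette records the models, their assumptions, the tunable parameters
and the numerical choices, in the package's own words.  It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

# Chromatin-state segmentation

## Binarization

Each mark's per-bin read count is reduced to presence/absence with a Poisson
upper-tail test.  The expectation in bin $b$ is

$$\lambda_b = \hat\mu_{bg}\,\max\!\left(\frac{i_b}{\bar i},\, 1\right),$$

where $i_b$ is the input (control) count and $\hat\mu_{bg}$ the mark's
global *background* rate.  A bin is called present when
$P(X \ge c_b \mid \lambda_b) \le 10^{-4}$ (the conventional threshold for
this style of binarization).  Two numerical choices matter:

* **Background-rate estimation.** The naive genome-wide mean count is
  contaminated by the signal itself: for a broad mark occupying 20--25% of
  the genome the mean approaches the foreground rate and sensitivity
  collapses.  `binarizeTrack()` therefore estimates $\hat\mu_{bg}$ by
  iterative Poisson trimming — bins above the 99.9% Poisson quantile of the
  current estimate are discarded and the mean recomputed (4 rounds or until
  stable).  On mixture counts this converges onto the background component.
* **Input floor.** The input ratio is floored at 1 so a locally *depleted*
  input can never make a bin easier to call; an all-zero input falls back to
  the global background rate with a warning.

## The hidden Markov model

States $k = 1..K$ emit each mark $m$ independently with Bernoulli
probability $E_{km}$; the state sequence follows a first-order Markov chain
along the bins of each chromosome, and chromosomes (or tissues, when
training is concatenated) are independent sequences.  `fitStateHMM()` runs
Baum-Welch EM with:

* scaled forward-backward recursions in compiled code (per-bin emission
  likelihoods are max-shifted before exponentiation, so no underflow at any
  $K$ or mark count);
* several random restarts (default 5) seeded from the master seed, keeping
  the best final log-likelihood;
* convergence when the relative log-likelihood gain drops below `tol`
  (default `1e-4`), with monotonicity asserted at every iteration;
* the `K = 1` boundary case degenerating to column means, as it must.

Decoding uses the forward-backward posterior by default (per-bin argmax,
ties to the lower state id — documented and deterministic); Viterbi is
available via `rule = "viterbi"`.  The posterior decoder is tested against
exhaustive enumeration of all state paths at $K = 2$, 12 bins.

Model selection across $K$ is deliberately left to the user: `fitStateHMM()`
reports the log-likelihood trace and can be called over a range of $K$; no
automatic criterion is imposed, mirroring how state counts are chosen by
inspection in this field.

## State annotation

`annotateStates()` reports per-state genome coverage, bp-level fold
enrichment over feature classes (TSS, TTS, exon, intron, intergenic, TE
families), and an emission-based category.  Because published state
categories are assigned by inspecting emission heat maps, automation needs an
explicit rule; the defaults in `stateCategoryRules()` are: *Quies* when all
emissions are below 0.1; *inactive* when H3K9me2 emission is at least 0.3
(flagged bivalent when H3K4me1 is also at least 0.3 — the
heterochromatin-bivalent archetype); *repressive* when H3K27me3 is the
maximal emission and at least 0.3; *active* otherwise.  All thresholds are
configurable.

# DMR calling

Per-cytosine calls (chrom, pos, strand, context, methylated, total) are
filtered at coverage $\ge 3$; levels are methylated/total.  For each 200-bp
bin with at least 2 qualifying cytosines in *both* samples (singleton bins
are too unstable to test), the pooled counts of sample A are tested against
sample B's pooled level with an exact two-sided binomial test (minimum-
likelihood rule, identical to `binom.test`).  $\hat p_B \in \{0, 1\}$ is
clamped to $[1/(n_B + 2),\, 1 - 1/(n_B + 2)]$.  BH adjustment runs within
context across tested bins only — CG, CHG and CHH levels live on different
scales and are not mixed into one family.  A bin is a DMR iff

1. $|\bar\ell_A - \bar\ell_B| \ge 0.6$, where $\bar\ell$ is the *unweighted*
   mean of per-cytosine levels (the region-averaging convention), and
2. BH-adjusted $q \le 0.05$.

The effect-size condition uses mean levels while the significance condition
uses pooled counts: the two conditions deliberately measure different
things.  The direction of the test is an interpretive choice (a "binomial
test" between two samples is underdetermined); the symmetric test (B against
A's level) is reported in a QC column so the asymmetry is auditable.

`dmrStateCoupling()` counts DMR bins per (state in A, state in B) cell,
divides by the genome-wide count of bins making that transition (cells with
no transitions are masked — a ratio over zero transitions is meaningless),
row-normalizes, and reports log10 with zeros as missing.

# State dynamics across tissues

`switchMatrix()` tallies bins per (state in A, state in B), symmetrizes by
adding the transpose, and row-normalizes into switching probabilities.  The
"enrichment" view divides each probability by the genome fraction of the
*target* state pooled over the two inputs — a row-normalized probability is
otherwise dominated by target-state abundance.  Both the raw probability and
the enrichment (with log10) are emitted, since a published "log10 ratio" can
be read either way.  `combineSwitchMatrices()` sums raw counts across tissue
pairs before re-normalizing, which is exactly equivalent to pooling all bin
pairs.

`differentialRegions()` is a documented *substitute* for a negative-binomial
differential test (the full machinery is out of scope here): counts are
summed per region, normalized with median-of-ratios size factors, and the
two conditions compared with the exact conditional test of two Poisson
rates (count of A binomial out of the regional total with success
probability equal to A's share of the inverse size factors).  The
fold-change threshold defaults to 1.5 on the natural scale with an explicit
`fcScale = "log2"` switch, because fold-change conventions differ between
RNA and mark analyses and a silent choice would be worse than a flag.

`tissueSpecificClusters()` z-scores each region across tissues (constant
rows dropped and flagged), runs seeded k-means with restarts, and orders
clusters by the tissue of maximal mean signal so labels are reproducible.

# Regulatory elements

`classifyFaire()` applies two rules to open-chromatin peaks: *PRE* when the
nearest TSS is within 1 kb or the peak overlaps a promoter window
(TSS − 1000 .. TSS + 500 by default); *DRE* when the peak overlaps neither a
gene body nor a promoter window *and* its mean CG methylation is at most
0.1.  "Low methylation" is not a standardized number; 0.1 is the
conventional cutoff for unmethylated regulatory regions and is a config
key, as are the promoter window and the proximal distance.  Peaks matching
neither rule stay unclassified with an explicit reason
(`genic`, `high_methylation`, `no_methylation_data`) rather than being
silently dropped.  DRE and PRE are mutually exclusive by construction, and
no DRE can overlap a gene body (asserted in tests).

`geneLoopCategories()` scores three predicates per gene — own-promoter PRE,
loop participation, loop-partner PRE — and maps them onto six categories
(1: own∧looped∧partnerPRE … 6: ¬own∧¬looped).  This decision table is an
interpretation reconstructed from published category contrasts, flagged as
such in the function documentation; the two combinations with a PRE partner
but no loop are unreachable by construction and asserted so.

# Variety panel

`conservedFraction()` calls a bin conserved for state $s$ when *every*
variety labels it $s$, and normalizes by the mean per-variety bin count of
$s$ — so an identical panel scores exactly 1 per occupied state and
abundance bias is removed.  `subgroupSwitch()` requires unanimity within
each subgroup and disagreement between them; the switch matrix is
normalized by the *source*-state genome fraction (the normalization
denominator is genuinely ambiguous in the field's phrasing; source-state is
the default and the raw counts are also returned, so either alternative can
be recomputed).  Third-group similarity is majority-vote agreement over the
consensus bins.

`snpProfile()` counts SNPs per 10-bp unit over 2-kb flanks with the peak
body rescaled to 20 units; the boundary mode profiles only the 1 kb before
the peak in 20 units, which removes peak-length interference.
`saturationCurve()` draws random variety orderings and reports the union
genome coverage per prefix (asserted non-decreasing — a union cannot
shrink) and, when supplied, the mean pairwise differential fraction within
the prefix.  `epigenomeDistance()` delegates to Bray-Curtis
(`vegan::vegdist`) or 1 − Spearman, with an optional seeded non-metric MDS
ordination — the ordination is labelled non-deterministic in spirit and
therefore seeded.

# The synthetic-epigenome generator

Everything downstream is validated against this generator, so its design is
the central testing decision: a single hidden state path per
tissue/variety *drives* marks, methylation, expression and SNPs, which
gives every analysis stage recoverable planted truth from one coherent
object.

* **Genome**: 2 chromosomes × 2 Mb at 200-bp bins (20,000 bins) — small
  enough for fast tests, large enough for stable frequencies.
* **States**: default 15-state emission matrix over H3K4me3, H3K27ac,
  H3K4me1, H3K27me3, H3K9me2, RNAPII and FAIRE, with rows for the
  archetypes recurrent in plant epigenomes (promoter, bivalent promoter,
  transcription, TTS, intergenic-active, open chromatin, Polycomb,
  bivalent heterochromatin, heterochromatin, quiescent); smaller $K$ uses a
  most-distinct-first subset.  State paths are run-length Markov chains with
  self-transition 0.95 (multi-bin domains, as real segmentations show), and
  the jump chain is weighted by category (Quies 3 : inactive 1.5 :
  repressive 0.8 : active 0.5) so the genome is mostly quiescent and
  heterochromatic and each mark's genome-wide presence stays in the
  realistic 10–20% range.
* **Reads**: counts are Poisson with mean $d\,(bg + fg\cdot present)$ at
  depth $d = 30$ reads/bin and $fg/bg = 20$; the input library is Poisson
  at full depth.  An overdispersion knob switches to negative binomial; the
  Poisson default matches the binarization model.
* **Methylome**: cytosines at densities CG 0.05, CHG 0.03, CHH 0.10 per bp
  (a rice-like context mix), per-cytosine levels set by the bin's state
  category (active low, heterochromatin high-CG) with small jitter;
  coverage Poisson (default mean 20); both samples re-drawn binomially
  around the same levels except in the planted DMR bins, where the level is
  shifted by exactly the planted delta (default 0.7 in CG over 100 bins).
  Planted hypomethylated valleys extend one bin beyond distal elements so
  bin-level methylation over an element is not contaminated by flanking
  heterochromatin.
* **Expression**: FPKM log-normal with the mean set by the promoter-state
  category per tissue, so repressed and heterochromatic promoters are
  mostly below 1 FPKM.
* **Panel**: 20 varieties in the five subpopulation groups (9 Xian/Indica,
  2 Geng/Japonica, 2 Aus, 2 aromatic, 5 intermediate); subgroup consensus
  paths diverge from the base by segment re-draws at the between rate
  (default 0.1), varieties from their consensus at the within rate
  (default 0.02), with 50 bins planted as fixed Xian-vs-Geng differences;
  SNP rates depend on state category with a 3× boost in the flanking bins
  of heterochromatin runs.
* **Determinism**: every component draws from a named substream of the
  master seed (`substreamSeed()`), so adding a component never perturbs the
  draws of another, and identical seeds give identical epigenomes.

What the generator does *not* emulate — and hence what passing tests do not
demonstrate about real data — includes: read-level artifacts (mappability,
GC bias, duplicates), spatially correlated noise, realistic sequence
content, partially methylated domains, overlapping/nested genes, and any
dependence structure between marks beyond what the hidden state induces.
Recovery rates measured here are upper bounds for real libraries.

# Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use the generator at these
scales, chosen as the package's own desk-scale study conditions: HMM
recovery at $K = 5$, 7 marks, $10^5$ bins; binarization oracle at $10^4$
bins; DMR calibration on $2\times 10^4$ bins at coverage 20 (null) and 30
(planted, 100 bins at $|\Delta| = 0.7$); switching-matrix independence at
$10^5$ bins; element recovery with clean margins (methylation 0.02 vs
state-driven, TSS distance < 500 bp for PREs vs > 3 kb for DREs); panel
recovery at zero within-group divergence.  `runPipeline()` executes the
whole chain on the default configuration under one seed and writes every
declared output file.

# Known limitations

* The binomial DMR test ignores within-bin level heterogeneity (pooling
  counts assumes exchangeable cytosines); smoothing-based callers are out
  of scope.
* The differential-region test is a Poisson substitute: it does not model
  biological overdispersion and will be anti-conservative on noisy real
  replicates (the package's synthetic data are Poisson by construction).
* The six loop categories implement a reconstructed decision table; other
  readings of the published contrasts are possible.
* Emission-based state categories depend on configurable thresholds; for
  borderline emission profiles the category is a judgement call, as it is
  when done by eye.
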