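---
title: "Methods: expression and sequence divergence of paralog pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression and sequence divergence of paralog pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paradiverge)
```

# Scope and data model

`paradiverge` analyzes *paralogous gene pairs* — two genes in one genome
descended from a duplication — under a stress time-course design: four
stresses (drought `Dr`, cold `Cd`, fungal infection `Bc`, herbivory `Pr`),
three time points each, each condition with treated and control samples.
The unit of analysis is always the pair.

Inputs are (a) codon-aligned, gap-free CDS pairs in FASTA
(`>pairID|geneID`, two records per pair), (b) an FPKM-like expression
matrix whose column names encode `stress_time_rep[_ctrl]`, (c) a
differential-expression table (gene × condition with log2FC, adjusted p,
expressed flag) as produced by an upstream DE tool, and (d) a plain-text
transcription-factor list. Alignment of the CDS pairs is deliberately a
caller responsibility: requiring pre-aligned, gap-free input avoids
committing to an aligner and an unstated gap policy, and makes the site
counting below well defined. For the same reason ambiguity codes (N etc.)
are rejected rather than skipped — Nei–Gojobori site counting is undefined
for them — and stop codons are rejected anywhere in the frame-0
translation, so terminal stops must be stripped before import.

# Differential-expression patterns

A gene is *called DE* in a condition iff it is expressed, padj < 0.05 and
|log2FC| > 1 — strict inequalities, exactly as the thresholds are usually
printed; a missing record means not DE. Per condition a pair is **FF**
(both genes DE), **FP** (exactly one) or **PP** (neither); the three
classes partition the pairs.

Two derived labelings:

* **Stress-sharing clusters.** Using one analysis time point per stress
  (default: the third, i.e. the strongest/latest phase; configurable), a
  pair with the focal pattern (FF or FP) under a set of stresses is
  assigned: all four → `all_four`; exactly {Dr, Cd} → `abiotic_shared`;
  exactly {Bc, Pr} → `biotic_shared`; a singleton → that stress's specific
  cluster. The remaining Venn regions (e.g. {Dr, Bc}) belong to none of the
  seven named clusters; they are assigned an explicit `other` label and
  counted rather than silently dropped.
* **Trajectories.** Per stress, the pattern sequence over the three time
  points is ranked PP = 0, FP = 1, FF = 2. A course is *enhancing* when
  non-decreasing, ending at FF and not starting there (PP → FP → FF and its
  partial variants), *decreasing* in the mirrored case, *stable* when
  constant — a flat FF course implies no change, so it is stable, not
  enhancing — and *mixed* otherwise. Reversing time swaps
  enhancing ↔ decreasing and fixes stable/mixed, which the tests verify
  exhaustively over all 27 rank triples.

# Ka/Ks estimation (Nei–Gojobori 1986)

For each codon position, the fraction of the three possible
single-nucleotide changes that preserve the amino acid contributes to the
synonymous site count S (changes to stop codons count as nonsynonymous), so
S + N equals the sequence length; site counts are averaged between the two
sequences, the standard NG86 convention. Differences are counted per codon:
a single-position difference is classed directly; codons differing at k = 2
or 3 positions average the synonymous/nonsynonymous step counts over all k!
substitution orders. Pathways passing through a stop codon are excluded
unless every pathway is blocked, in which case all are included — the
common NG86 practice.

Both proportions are Jukes–Cantor corrected,
d = −(3/4)·ln(1 − (4/3)·p), defined for p < 0.75. Saturation (p ≥ 0.75)
makes the distance undefined; `compute_ka_ks` reports it as `NA` with
selection class `undefined` rather than raising an error, and downstream
regressions and summaries exclude such pairs with a reported count.
Ka/Ks > 1 is classed *positive*, < 1 *negative* (purifying), equality
within 1e-9 *neutral*; the ratio is undefined when Ks is zero or
saturated. The implementation is cross-checked against a brute-force codon
enumeration oracle to 1e-10 on S, N, Sd and Nd over hundreds of random
pairs.

NG86 was chosen as the concrete counting method because it is what the
commonly used `dnds`-style routines default to; maximum-likelihood dN/dS
(codeml-style) and sliding windows are out of scope.

# Expression divergence and its regression on Ks

Within-pair correlation r is the Pearson product-moment correlation of
log(FPKM + 1) across treated samples (all stresses, or one). The log scale
matches the generator's lognormal model and the usual variance
stabilization of FPKM data; zero variance yields an undefined correlation
(`NA`), excluded and counted. Expression divergence is measured by the
rescaled coefficient

r′ = ln(1 + r) / (1 − r),

implemented exactly as printed in the formula this package follows; the
Fisher transform reading ln((1 + r)/(1 − r)) is selectable
(`rescale_mode = "fisher"`) since both are strictly monotone on (−1, 1) and
therefore give identical sign conclusions for the regression. r′ is
undefined at r = 1, another reason zero-noise data cannot be analyzed.
Ordinary least squares of r′ on Ks (via `lm`) gives the slope, its
t-test p-value and R²; a negative slope means pairs with greater
synonymous divergence are less correlated — i.e. expression divergence
rises with sequence divergence. No multiple-testing correction is applied
across stresses for these per-fit p-values.

# Randomized-pair null and rank tests

To ask whether, say, FF pairs have unusually low median Ka/Ks, the observed
statistic is compared with `n_reps` statistics computed on equally sized
sets of pairs drawn uniformly *without replacement within a replicate*
(independently across replicates) from the full paralog pool. The
empirical p uses the add-one correction
p = (#{null as-or-more extreme} + 1)/(n_reps + 1), so p is never exactly 0
and p < 10⁻⁴ is only reportable with at least 10,000 replicates — the
default. The summary statistic is the median (the quantity boxplots
display), with the mean selectable. Calibration is verified: when the
observed set is itself a uniform draw, empirical p is approximately
Uniform(0, 1).

The Mann–Whitney U test uses midranks for ties; the two-sided p is exact
(from the exact U distribution) when the smaller sample has ≤ 8
observations and there are no ties, and otherwise uses the normal
approximation with tie correction (complete overlap of identical samples
gives p = 1). The exact branch is tested against full enumeration of all
labelings for every sample-size split with n₁ + n₂ ≤ 10.

# Co-expression network

Adjacency between selected genes (DE paralogs and TFs) is the WGCNA-style
soft threshold |r|^β with β = 10. The published display filters are then
applied in order: edges with weight < 0.3 removed first, then nodes whose
maximum |r| to any retained neighbor is < 0.5 (iterated to a fixed point,
which makes the operation idempotent; a node whose only strong edge was
weight-filtered drops out too). A scalar node threshold is otherwise
undefined in WGCNA terms, so "max correlation with any other retained
node" is this package's reading. WGCNA's blockwise module detection
(`minModuleSize = 30`, `mergeCutHeight = 0.25`) is *not* reimplemented;
those two values are carried in the run configuration for provenance only.
TF ranking counts, per TF (optionally aggregated by caller-supplied family
labels such as MYB/ERF/bHLH), the number of DE-paralog neighbors, and
DEP–TF edge counts are compared between enhancing and decreasing subsets.

# Synthetic-data generator

The generator defines the conditions under which the pipeline is validated.

* **Sequences.** Ancestors are uniform random sense codons. Each
  descendant lineage evolves by iterated single-nucleotide proposals:
  proposals creating stops are rejected outright; for ω ≤ 1 synonymous
  proposals fix with probability 1 and nonsynonymous with probability ω,
  while for ω > 1 synonymous proposals fix with probability 1/ω. This
  acceptance-ratio scheme, rather than a full codon rate matrix, is
  sufficient to set the Ka/Ks expectation that NG86 estimates, and is
  transparent to test. Divergence is split symmetrically: each lineage
  stops once its realized synonymous substitutions per NG86 synonymous
  site (S updated incrementally as the sequence changes) reach
  target_ks/2, with a saturation guard at 50 × L proposals. Recovery
  holds where the correction is accurate: at Ks = 0.5 the median estimated
  Ka/Ks over 200 pairs falls in [0.4, 0.6] for ω = 0.5 and well above 1
  for ω = 2. Near saturation the estimate is biased low — at Ks = 1.8,
  Ka/Ks ≈ 1 per-site nonsynonymous divergence — because real codons offer
  fewer than the four equally exchangeable states Jukes–Cantor assumes;
  the package reports what the estimator sees.
* **Expression.** For each pair the two genes' latent log-expression
  values per treated sample are bivariate normal with unit variances and
  correlation ρ = exp(−λ·Ks) — monotone, bounded in (0, 1], and yielding
  the negative r′-on-Ks slope structure the analysis targets — plus
  independent measurement noise (`noise_sd`, default 0.2, a typical
  RNA-seq replicate variability on the log scale), then exponentiation to
  an FPKM-like scale. The noise term is essential, not cosmetic: without
  it λ = 0 makes every sample correlation exactly 1, where r′ is
  undefined, and there would be no estimation problem left. Controls are
  independent baseline draws.
* **DE table.** Per gene × condition a Bernoulli(de_fraction) flag decides
  DE; DE records draw padj ~ U(0, 0.049) and |log2FC| = 1 + Exp(mean
  effect_mu − 1) with random sign, non-DE records padj ~ U(0.05, 1) and
  |log2FC| ~ U(0, 1), so the threshold structure (padj < 0.05,
  |log2FC| > 1) is exactly reproduced at the boundaries. padj is generated
  directly rather than via simulated counts and a DE test: the classifier
  consumes calls, so only the threshold structure matters. Pairs planted
  as *enhancing* follow neither/one/both DE over the three time points in
  every stress (*decreasing* mirrored), giving exact ground truth for
  trajectory recovery; both fractions are configurable because both labels
  need validation.
* **What it does not emulate.** Real count noise and mean–variance
  structure, correlated conditions, library-size effects, unexpressed
  genes, gene families larger than two, codon-usage bias and
  transition/transversion asymmetry. Passing tests therefore demonstrate
  the correctness and calibration of the estimators and classifiers under
  the stated model, not biological conclusions about any real genome.

A fixed `simulation_config` (including seed) reproduces byte-identical
FASTA/TSV outputs.

# Numerical and design choices

* Strict inequalities at every printed threshold (padj < 0.05,
  |log2FC| > 1, r > 0.5).
* "Not expressed or differentially expressed" in the FP/PP definitions is
  read as "not expressed or *not* differentially expressed"; the literal
  reading would contradict the FF definition.
* Undefined quantities (saturated distances, zero-variance correlations,
  r = 1 rescalings) are signaled as `NA` and excluded with logged counts,
  never silently imputed.
* Result tables are written with 6 significant digits; data formats
  (expression, DE tables) at full double precision so write → read round
  trips are exact to 1e-12.
* Ties in the Ks histogram mode resolve to the smallest midpoint; bins are
  left-closed with width 0.1.
* The pipeline's permutation stage derives per-class seeds from the run
  seed so FF and FP tests are reproducible yet independent.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
each check has clear statistical margin: oracle equivalence on 500 random
pairs of ≤ 30 codons; ω-recovery on 200 pairs of 100 codons; slope-sign
structure over 100 replicates of 300 pairs; permutation calibration over
200 trials × 500 replicates; Mann–Whitney calibration over 2,000
simulations. Genome-scale quantities (thousands of pairs, real Ks peaks,
co-expressed percentages of a particular species) depend on external
genome-scale data and are out of scope.

# Known limitations

* NG86 with JC correction underestimates divergence near saturation
  (Ks ≳ 1.5) and returns `NA` beyond p ≥ 0.75; ML methods would extend the
  usable range.
* The r′ = ln(1 + r)/(1 − r) default is asymmetric in r; sign conclusions
  match the Fisher reading, but magnitudes are not comparable between
  modes.
* The network node filter is a display heuristic, not module detection;
  biological module claims require WGCNA proper.
* The simulator's ω acts on fixation probability only; it does not model
  site-to-site rate variation.
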