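---
title: "Quantifying ribozyme switching: models and methods"
author: "CleaveSeqR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ribozyme switching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CleaveSeqR)
```

## The assay this package models

Hammerhead-ribozyme biosensors (aptazymes) couple an aptamer to a
self-cleaving ribozyme so that ligand binding modulates cleavage. A
sequencing-based cleavage assay distinguishes cleaved from uncleaved
molecules by their 5' prefix: molecules that did not cleave keep the original
prefix ("W"), while cleaved molecules have their lost 5' end regenerated with
a new prefix ("Z") by a ligation step. After PCR with prefix-specific
primers, condition barcodes and sequencing, the read counts per (sequence,
prefix, condition) quantify cleavage for every sequence in a mixed library
simultaneously. A companion in vitro selection alternates rounds that amplify
cleaved molecules (no ligand present) with rounds that amplify uncleaved
molecules (ligand present), enriching sequences whose cleavage responds to
the ligand.

`CleaveSeqR` implements the full desk side of this workflow: read processing
into count tables, cleavage and switching quantification with uncertainty,
a stochastic model of the selection dynamics, dose-response and
surface-plasmon-resonance (SPR) fitting for downstream characterization,
reporter-assay normalization, mutation-effect maps, and synthetic-data
generators with known ground truth for all of it.

## From reads to counts

Read pairs are merged by overlap (`mergePairs()`): among candidate overlaps
of at least `min_overlap` bases whose mismatch fraction does not exceed
`max_mismatch_frac`, the lowest-mismatch overlap wins, ties resolving toward
the longer merged product; disagreeing overlap positions keep the
higher-quality base. Barcode demultiplexing (`demultiplex()`) and prefix
classification (`classifyPrefix()`) default to exact matching — amplicon ends
are primer-derived and high quality — with one-mismatch tolerance as an
opt-in. A read matching two conditions under mismatch tolerance is discarded
as ambiguous and tallied, never guessed. `tabulateReads()` groups identical
cores (prefix, suffix and barcodes stripped) and assigns stable accession
integers in lexicographic order, so the table is invariant to read order.

PCR mutations during library preparation can hand a sliver of an abundant
sequence's reads to a spurious near-identical sequence.
`misassignmentFilter()` flags any core whose total count is at least
`abundance_ratio` (default 100) times lower than that of another core within
Levenshtein distance `max_distance` (default 1); flagged cores stay in the
table but are excluded from hit calling. `N` bases never match anything in
these comparisons.

## Cleavage fraction and fold change

With $r_{P,s}$ the reads of sequence $s$ carrying prefix $P$ and $r_{P,ref}$
the reads of the spike-in references carrying $P$, the cleavage fraction is

$$c_s = \frac{r_{Z,s}/r_{Z,ref}}{r_{W,s}/r_{W,ref} + r_{Z,s}/r_{Z,ref}}.$$

Each prefix population is amplified and sequenced separately, so raw W and Z
counts are not on a common scale; dividing by the same-prefix reference
counts (references enter every sample at a known fixed concentration, 18 pM
each in the fixture scheme) cancels the per-prefix depth. The same
references give an absolute scale: `referenceScale()` returns pM per read as
total reference concentration over total reference reads for a prefix.

Switching between a $-$ligand and a $+$ligand condition is summarized by the
fold change of the *uncleaved* fraction,

$$f_s = k\,\frac{1 - c_{s,+}}{1 - c_{s,-}},$$

because only uncleaved transcripts express a downstream gene, making $f_s$
the in vivo-relevant quantity; $f_s > 1$ means the ligand suppresses
cleavage (an ON switch). The factor $k$ absorbs condition-level differences
unrelated to the ligand and is set so the median $f_s$ over qualifying
sequences in a run is exactly 1, on the rationale that only a small minority
of sequences respond to any one ligand. Qualification requires `min_reads`
(default 30) in both conditions; for an even number of sequences the median
is the mean of the two central order statistics.

## Uncertainty, replicates and hit calling

**Bootstrap intervals.** `bootstrapCI()` redraws the per-sequence prefix
cells and the reference cells from multinomials with the observed totals and
proportions, recomputes $\hat c_s$ (and $\hat f_s$) for each of $B = 1000$
samples, and reports the 5th/95th percentiles. Reference cells are resampled
by default (`resample_refs`), since references are sequenced reads like any
others; a resampled reference count of zero is clamped to one read to keep
the estimator defined, which matters only at implausibly low reference
depth. On simulated data (true $c = 0.7$, 200 reads, 500 replications) the
5–95% interval covers the truth for 90% of runs, as the percentile method
should.

**Tests.** The non-switching null ($c_{s,-} = c_{s,+}$) and replicate
concordance are both two-sided tests of equal proportions on the 2×2
cleaved/uncleaved count table. The test family is a deliberate choice: an
exact conditional (Fisher) test at small counts — typical after library
constriction — switching to the normal-approximation two-proportion test
when any cell exceeds $10^4$ reads, where the exact test is slow and the
approximation is excellent. Replicate comparison uses a family-wise
Bonferroni threshold `family_alpha / N` (`bonferroniThreshold()`), with
`family_alpha = 0.1` and a 100-read minimum; switching uses
`family_alpha = 1` (i.e. an expected one false positive per run) and a
30-read minimum.

**Hits.** `callHits()` flags a sequence as a candidate sensor when
$f_s > 2.0$, the non-switching null is rejected at $1/N$, and the sequence
is not a misassignment suspect. Hit calling uses $f_s$ in the stated
direction only; screening the opposite polarity is a matter of passing
$1/f_s$.

## The selection model

`simulateRound()` multiplies each library member's abundance by its survival
weight — $c_-$ on a cleaved-selection round, $1 - c_+$ on an
uncleaved-selection round — and renormalizes. PCR amplification factors and
transcription yields scale every member alike, affecting yield but not
composition, so they are out of the model. Stochastic mode resamples $M$
molecules multinomially after each round; expectation mode is deterministic
and equals the analytic product of weights.

Against the empirically ubiquitous background of ligand-insensitive
sequences that cleave about half the time in either condition (and therefore
survive every round with weight 0.5), the per-round enrichment of a
phenotype over one alternating cycle is the geometric mean
$\sqrt{(c_-/0.5)\,((1-c_+)/0.5)}$ (`maxEnrichment()`). A perfect switch
($c_- = 1$, $c_+ = 0$) attains the ceiling of 2×/round; a good realistic
switch ($c_- = 0.8$, $c_+ = 0.2$) enriches at 1.6×/round, which still
compounds past $10^{12}$ within 60 rounds — the throughput of a multi-day
automated run at 8–12 rounds/day.

`constrict()` models the dilution bottleneck used before sequencing a
high-diversity round: the molecule count is Poisson around
$C \cdot N_A \cdot V$ (about 5,000 molecules per µl at 8 fM;
Avogadro fixed at $6.022\times10^{23}$), drawn multinomially by abundance.

`estimateEnrichment()` fits $\log f_n$ against round $n$ by weighted least
squares, with delta-method weights from the binomial standard deviation of
each fraction estimate ($\mathrm{var}(\log f) \approx \mathrm{var}(f)/f^2$);
rounds with zero observed reads are dropped, not imputed. The enrichment
rate is $\eta = e^{\text{slope}}$ and the round-0 intercept back-extrapolates
the starting fraction $f_0$. Whether to weight the fit was an open choice;
weighting is used because read depths differ strongly across rounds, and on
noiseless trajectories the weights are irrelevant (the fit is exact).

Library combinatorics: with designs of $d$ degenerate positions the space is
$\sum_d 4^d$ (`librarySpace()`), and a fixed $k$-mer leaves $4^{d-k}$
contexts (`contexts()`). Orders of magnitude are reported as
$\mathrm{round}(\log_{10})$, the convention that matches how such sizes are
quoted (e.g. $4^{43} \approx 7.7\times10^{25}$ is "~$10^{26}$").

## Dose-response and SPR

`fitEC50()` fits a four-parameter logistic in $\log_{10}$ concentration by
weighted least squares. The functional form is a choice (the assay literature
standard), with the no-ligand condition anchoring the starting bottom
asymptote. An EC50 landing outside the measured range is reported as a
one-sided bound, and a flat response as unbounded, rather than as a number.
Concentrations are molar internally; `parseConcentration()` accepts
nM/µM/mM suffixes.

`fitKinetics()` fits the closed-form 1:1 Langmuir model — association
$RU(t) = R_{eq}(1 - e^{-(k_{on}C + k_{off})t})$ with
$R_{eq} = R_{max}C/(C + K_D)$, exponential dissociation — globally across
concentrations with shared $(k_{on}, k_{off}, R_{max})$. Rates are optimized
on the log scale (positivity) from a small grid of starting points, with
$k_{off}$ pre-estimated from the dissociation tail. Single-cycle data
(consecutive associations on one surface) need no special casing: segments
chain their boundary response automatically. $K_D$(kinetic)
$= k_{off}/k_{on}$ by definition. `fitEquilibrium()` averages the final 5 s
of each association phase and fits the Langmuir isotherm
$R_{max}C/(C+K_D)$ — a fixed-slope sigmoid in log concentration whose
inflection is $K_D$; the isotherm is used because the binding model itself
dictates the shape. `flagMeasurable()` marks fits whose
time-to-95%-of-transition $\ln(20)/k$ falls below 2 s in either phase as
non-measurable (the boundary counts as non-measurable), reflecting
instrument response limits. Mass-transport limitation and multivalent
binding models are out of scope.

## Reporter assays

Gel densitometry: band intensity is proportional to molar amount times
product length, so
$f = \frac{(I_c - I_{bg})/L_c}{(I_c - I_{bg})/L_c + (I_u - I_{bg})/L_u}$
(`gelFraction()`); negative background-subtracted intensities are clamped to
zero with a warning. The gel fold change is $(1-f_+)/(1-f_-)$.

Flow cytometry: per-cell GFP/mCherry ratios over events passing the
transformation gates (mCherry $> 10^{3.2}$, GFP $> 10^{3.1}$, linear-scale
raw units, configurable) are averaged arithmetically — the mean of ratios,
taken literally — and scaled so the inactive-ribozyme control reads exactly
100 RFU; the activation ratio is RFU(+ligand)/RFU($-$ligand).
Viability/singlet scatter gating happens upstream of this package: synthetic
events represent already-gated cells.

## Mutation-effect maps and families

`editScript()` decomposes a variant into a minimal Levenshtein script
against its parent (Rcpp dynamic program). Positions are 1-based on the
core; insertions are indexed by the gap after parent position $p \in
\{0..L\}$. Equal-cost scripts (indels in homopolymer runs) resolve to the
leftmost edit and are flagged ambiguous, since no convention is inherent in
the data. `effectMatrix()` arranges single-edit effects into position ×
mutation matrices (substitutions + deletion over $L$ positions, insertions
over $L+1$ gaps), aggregating duplicate cells by read-weighted mean with a
flag. `clusterFamilies()` groups hit sequences by average-linkage
hierarchical clustering on Levenshtein distance, cut at 25% of the core
length by default (both configurable; no principled value is dictated by the
data), with lexicographic tie-breaking so input order never matters.

## Synthetic data: what it does and does not emulate

The generators draw molecule counts multinomially by abundance, cleave each
molecule as a Bernoulli trial with the condition-appropriate probability,
inject reference reads with expected share
$\frac{\sum \text{ref conc}}{\text{library conc} + \sum \text{ref conc}}$
(18 pM × 15 references against a 2 nM library input by default, the share a
real run would see), apply uniform substitution errors, and split amplicons
into overlapping read pairs with flat qualities. They are bit-reproducible
under a fixed seed, and every truth file suffices to compute expected
pipeline outputs analytically.

They deliberately omit: PCR amplification bias and chimeras, indel
sequencing errors (available as an opt-in stress mode), quality-score
structure, cluster-density artefacts, and ligation-efficiency bias between
prefixes. Passing round-trip tests therefore demonstrates correctness of
the estimators under the assay's sampling statistics, not robustness to
every laboratory artefact; the misassignment filter and replicate test are
the package's defenses against the most consequential real-world deviation
(read misassignment), and they are exercised with planted perturbations.

The fixture `defaultScheme()` mirrors the structure of a real scheme — three
distinguishable A-rich prefixes, an A-rich suffix spacer, prefix-free
variable-length barcodes, 15 references spanning five lengths and three
prefixes at 18 pM — with synthetic sequences; real runs supply their own
scheme as YAML/JSON.

## Numerical choices and test scales

Degenerate inputs are mapped to explicit outcomes rather than errors where a
value is representable (zero-read sequences give `NA` fractions; $c_- = 1$
gives `NA` fold change; flat dose responses give unbounded flags) and to
errors where a run is unusable (no reference reads for a prefix/condition).

The test suite verifies, among others: exact recovery of planted counts from
an error-free synthetic FASTQ run; planted cleavage fractions within 3
binomial standard deviations for ≥ 99% of 1,000 sequences at ~10⁴
reads/sequence, with planted $\rho \ge 3$ switchers called at ≥ 95%
sensitivity; 90% ± 3% bootstrap coverage (B = 1000, 500 replications);
enrichment rates 1.2–1.6 recovered to machine precision on noiseless
trajectories and within the fitted CI on stochastic ones; Langmuir rates to
0.1% on noiseless sensorgrams and $K_D$ to 10% at 2% noise (with phase
durations matched to the simulated off-rate, as a real protocol would be);
EC50 to 10% at 1% noise; and edit-script soundness on 10⁴ random mutants.
These problem sizes are the package's chosen simulation scales; larger runs
only narrow the sampling error around the same expectations.

## Known limitations

* The pipeline quantifies relative cleavage within a run; absolute
  concentrations inherit any error in the nominal spike-in concentrations.
* The selection simulator treats phenotypes as fixed (c_minus, c_plus)
  pairs; sequence-explicit mutation is modelled only as abundance mass
  moving to phenotype-perturbed variants, enough to reproduce
  below-library-frequency $f_0$ estimates but not sequence-level epistasis.
* The Langmuir fitter assumes 1:1 binding; systems with mass-transport
  limitation or avidity will fit poorly and should be flagged by residual
  inspection, which the package reports but does not judge.
* The exact-test/normal-approximation switch at $10^4$ reads per cell
  introduces a negligible but nonzero discontinuity in p-values at the
  boundary.
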