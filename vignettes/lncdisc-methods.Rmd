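---
title: "Methods: feature-based classification of disease-related lncRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature-based classification of disease-related lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncdisc)
```

## The problem

Long non-coding RNAs (lncRNAs) are transcripts longer than ~200 nt that do
not encode protein. A minority of them are implicated in disease —
dysregulation and mutation of specific lncRNAs contribute to cancers and
other complex conditions — and experimentally mapping lncRNA–disease
associations is slow and expensive. `lncdisc` implements a supervised
alternative: given a set of transcripts labelled disease-related or not, it
learns a classifier over features computed from the transcript sequence, its
genomic annotation, and its predicted secondary structure, and evaluates
that classifier under stratified ten-fold cross-validation.

The package is organised as a pipeline of independently usable stages:

1. redundancy filtering of the transcript set (`greedy_cluster`),
2. sequence featurization (`featurize_sequences`),
3. structure featurization (`featurize_structures`),
4. assembly of the design matrix (`assemble_features`),
5. importance-based feature selection (`select_features`),
6. model fitting and cross-validated evaluation (`fit_model`,
   `evaluate_cv`), wrapped end-to-end by `run_pipeline`.

## Redundancy filtering

Sequence sets harvested from association databases contain near-duplicate
transcripts; without redundancy removal, close homologs of a training
sequence can appear in the test fold and inflate every metric. The filter is
a greedy incremental clustering in the CD-HIT style: sequences are sorted
longest-first (ties broken lexicographically by id, making the run
deterministic), each sequence joins the first retained representative whose
identity with it reaches the threshold, and otherwise founds a new cluster.
Only representatives survive.

Identity between two sequences is defined as the number of identical aligned
columns in the optimal global alignment with match = 1, mismatch = 0 and gap
= 0, divided by the length of the shorter sequence. Under this scoring the
optimal column count is exactly the length of the longest common
subsequence, which the package computes by an $O(nm)$ dynamic programme in
C++. A composition bound (identical columns can never exceed the summed
per-letter minimum counts of the two sequences) is used to skip provably
hopeless alignments; it cannot change the result, and the tests assert
equality with the prefilter disabled.

One consequence of this gap-free identity deserves emphasis: for two
*unrelated* uniform-random sequences of equal length the expected identity
is already ≈ 0.65 (the four-letter longest-common-subsequence constant), so
a 60% cutoff — sensible for real transcript sets, where identity reflects
homology — collapses random synthetic data into a single cluster. The
default threshold remains 0.6 for real data; the synthetic benchmarks in
this package exercise clustering at 0.9, where only constructed
near-duplicates merge, and run the modelling stages without the redundancy
filter.

## Sequence features (110 columns)

* **k-mer frequencies** (k = 2: 16 columns; k = 3: 64 columns). A sequence
  of length $L$ has $L-k+1$ overlapping windows; windows containing `N` are
  skipped and the remaining counts normalised to sum to 1. Orderings are
  lexicographic over A < C < G < U, fixed so that column names are stable.
* **Pseudo dinucleotide composition** (26 columns at the default
  $\lambda = 10$). The parallel-correlation form: with per-property
  standardised values $P_q$ over the 16 dinucleotides, the correlation
  between dinucleotides $R_1, R_2$ is
  $\Theta(R_1,R_2) = \tfrac1{n_p}\sum_q \big(P_q(R_1)-P_q(R_2)\big)^2$, the
  tier-$j$ factor $\theta_j$ averages $\Theta$ over all position pairs $j$
  apart, and the feature vector is
  $d_u = f_u/(1+w\sum_j\theta_j)$ for $u \le 16$ and
  $d_{16+j} = w\,\theta_j/(1+w\sum_j\theta_j)$, with $f$ the normalised
  dinucleotide frequencies. Defaults $\lambda = 10$, $w = 0.05$. The vector
  is non-negative and sums to 1; both properties are tested. Positions whose
  dinucleotide contains `N` are skipped in both the frequency and the
  correlation sums. A property with zero variance across dinucleotides
  standardises to all zeros rather than dividing by zero; a constant table
  therefore reduces the vector to plain dinucleotide frequencies padded with
  zeros.
* **Conservation** (1 column): per-exon mean of per-base conservation
  scores, then the unweighted mean over exons. Exons with no covered base
  are dropped from the outer mean; a transcript with no coverage at all
  scores 0 with a warning. Scores are on the phastCons scale, $[0,1]$.
* **GC content** (1 column), computed from the transcript sequence with `N`
  excluded from numerator and denominator. (Computing GC from the sequence
  rather than from a genome-browser table is a deliberate, documented
  choice: it requires no external download and is exact for the sequence
  actually featurised.)
* **Protein-interaction count** (1 column): the size of the transcript's
  protein partner set, keyed at gene level because interaction databases
  are gene-keyed; the count is broadcast to the gene's transcripts.
* **Mutation count** (1 column): the number of noncoding-variant records
  falling inside the transcript's exons. Each record counts once,
  duplicates included.

Coordinates are 0-based half-open throughout (BED convention); DNA input is
normalised to RNA (`T`→`U`) on read, and IUPAC ambiguity codes other than
`N` collapse to `N` with a warning.

## Structure features (10 columns)

Secondary structures arrive as RNAfold-style dot-bracket files
(`read_dotbracket`), or from the package's own folder. From each structure
the pipeline extracts:

* **Minimum free energy** (1 column) — taken from the RNAfold output when
  supplied; see the caveat below for the fallback path.
* **Base-pair type counts** (6 columns): each pair $(i,j)$, $i<j$, is
  classified *directionally* by its 5′ and 3′ bases into AU, GC, GU, UA,
  CG, UG. The directional reading is deliberate: both A-U and U-A are
  listed as distinct categories. Non-canonical pairs (including anything
  with `N`) are not counted; their number is kept as an attribute and the
  conservation "six counts + ignored = total pairs" is tested.
* **Unpaired-base class counts** (3 columns): every dot belongs to the loop
  closed by its nearest enclosing pair. A loop with no interior pairs is a
  hairpin; exactly one interior pair with unpaired bases on exactly one
  side is a bulge; internal loops (both sides), multibranch loops, and
  exterior (unenclosed) bases count as "other". The three-way split of a
  structure's loop taxonomy is underspecified in common usage; assigning
  exterior bases to "other" is this package's documented convention. The
  three counts always sum to the number of dots.

### The fallback folder

For a dependency-free path the package includes a Nussinov-style dynamic
programme that maximises total weighted canonical pairing (GC = 3, AU = 2,
GU = 1) with hairpins forced to enclose at least `min_hairpin = 3` unpaired
bases — the standard steric constraint. Traceback is deterministic: the 5′
base of an interval pairs with its smallest admissible partner whenever
pairing attains the optimum. The reported `mfe` is the *negated pair
weight*, a surrogate stability score flagged `surrogate = TRUE` and
propagated into the feature-matrix metadata; it is **not** a thermodynamic
energy, and production analyses should feed true RNAfold output instead.
The folder is exact for its own objective — tests compare it against an
exhaustive enumeration of all nested pairings for sequences up to length
12 — and cubic in sequence length, so the pipeline truncates sequences
beyond `max_fold_len = 300` nt for this path only, with a warning.

## Feature selection

`select_features` fits a random forest (50 trees, depth cap 11 by default)
on the labelled matrix, normalises the resulting importances to sum to 1,
and keeps the features whose importance reaches the threshold — the mean
importance by default, the usual select-from-model rule. Two backend notes,
both deliberate:

* R's `randomForest` splits on Gini impurity and offers no entropy
  criterion; the `criterion` argument is recorded in the result for
  provenance but the split rule is Gini. At the granularity of "which
  features carry signal", the two impurity measures rank features near
  identically; the package treats Gini as its impurity choice.
* `randomForest` caps tree size by `maxnodes`, not depth; a depth cap $d$
  is enforced as `maxnodes` $= 2^d$ (further bounded by the sample count).

Selection placement matters. The leakage-free default (`selection =
"per_fold"` in `evaluate_cv`/`run_pipeline`) refits the selection inside
every training fold, so test rows never influence which columns the model
sees; the report records, per fold, how many rows the selection was fit on.
`selection = "once"` reproduces the common shortcut of selecting once on
the full data before cross-validation — kept available explicitly for
comparison, since published results are often produced that way.

## Models

* **SVM** (`e1071`): linear kernel, `C = 0.1`, `gamma = 0.001` — the tuned
  values for this task; gamma is inert for the linear kernel but recorded.
* **Random forest** (`randomForest`): 130 trees, depth cap 9.
* **Extreme learning machine** (implemented here): a single hidden layer of
  22 sigmoid units whose input weights $W$ and biases $b$ are drawn once
  from $\mathcal U[-1,1]$ under the seed; only the output weights are fit,
  by the ridge-regularised least-squares solve
  $\beta = (H^\top H + 10^{-6} I)^{-1} H^\top y$ with
  $H = \sigma(XW + b)$. The ridge term exists purely for numerical
  stability when $H^\top H$ is near-singular; at $10^{-6}$ it is far below
  the scale of any signal. Classification thresholds the continuous output
  at 0.5.

Features are z-scored for the SVM and the ELM (margin- and
activation-scale-sensitive) and left raw for the forest (scale-invariant).
Scaling parameters are always fit on the training split only and applied to
the test split; a test asserts that held-out columns are *not* mean-zero
unit-variance in general, which is exactly the point.

## Evaluation protocol

`stratified_folds` deals each class's shuffled members round-robin into $k$
folds, so per-fold class counts deviate from exact proportionality by at
most one sample. Per fold, the held-out confusion counts give accuracy,
precision $TP/(TP+FP)$, recall $TP/(TP+FN)$ and F1 (their harmonic mean),
reported for the positive (disease-related) class. Ratios with zero
denominators are reported as 0. The ROC curve is a score-threshold sweep
(ties collapsed to one operating point) with trapezoidal AUC; per-fold
curves are kept and summarised as min/mean/max AUC, and a fold whose test
split happens to contain one class records a missing AUC with a warning.
All randomness — fold shuffling, forest fitting, ELM weights, per-fold
selection — derives deterministically from one master seed, and rerunning a
pipeline configuration reproduces the report exactly (tested).

`grid_search` evaluates each candidate specification by mean cross-validated
F1 and returns the first maximiser, so ties resolve by grid order.

## The synthetic benchmark

`generate_dataset` builds labelled data whose class signal flows through the
same channels the real task uses: positive-class sequences over-emit chosen
k-mers (default: `GGC` at excess rate 0.15 per position on a uniform ACGU
background), exonic mutation counts are Poisson with class means 8 vs 1,
protein-partner counts Poisson 6 vs 2, and positive-class conservation is
shifted up by 0.25 (clipped to $[0,1]$). Default class sizes are 60 + 60
with transcript lengths 150–300 nt — large enough for stable ten-fold
stratified CV, small enough that the full three-model benchmark runs in
seconds. Each transcript receives 1–4 exons on its own synthetic chromosome
whose lengths sum to the sequence length, so the conservation and variant
readers are exercised exactly as with real annotation. `null_dataset`
neutralises every one of those differences while keeping the marginal
distributions, giving a negative control whose cross-validated F1 should
sit near chance; the null comparisons in the acceptance script use 250 per
class to keep the fold-mean metrics tight. An optional `duplicate_fraction`
replaces a tail of each class with 2%-point-mutated copies of earlier
members to exercise the redundancy filter.

What the generator does *not* emulate: real lncRNA base composition and
length distributions, splice-structure statistics, mutation hotspot
spectra, the gene-level sharing of interactions across transcripts, or any
thermodynamically meaningful structure signal. Passing the synthetic
benchmark therefore demonstrates that the pipeline's plumbing, contracts
and statistical protocol are sound — recovery of planted signal, chance
behaviour on the null — not that the features transfer to real transcripts
with the performance reported on curated datasets.

### The physicochemical table

The pseudo-composition needs six base-step properties (tilt, rise, roll,
slide, twist, shift) per dinucleotide. The table shipped at
`inst/extdata/dinuc_properties_synthetic.csv` is a constructed stand-in
with realistic shape and variation, labelled synthetic in its filename: it
is not a measured reference set. Because every property is standardised to
zero mean and unit variance across the 16 dinucleotides before use, the
encoding is invariant to per-property affine changes (tested), and all
structural contracts — dimension, non-negativity, normalisation — hold for
any table of the right shape. Users with a preferred measured table can
pass it via the `props` argument.

## Numerical choices and degenerate inputs

* Ambiguity handling is consistent: `N` never matches, never pairs, and is
  excluded from GC and k-mer/psednc windows that touch it.
* An all-`N` window set returns a zero k-mer vector with a warning; an
  all-`N` sequence is an error for GC.
* Empty annotation inputs impute conservation/interaction/mutation features
  as 0 with a warning, so the assembled matrix never contains missing
  values.
* `pairwise_identity` on empty sequences, folds with a class smaller than
  $k$, single-class training labels, and `n_hidden < 1` are errors with
  explicit messages.
* Tie-breaks are all documented and deterministic: cluster representatives
  (length, then id), fold traceback (smallest admissible partner), grid
  search (first maximiser).

## Problem sizes used by the shipped checks

The test-suite and acceptance-script runs use: 200 random sequences of
length ≤ 12 for folder-vs-enumeration equivalence, 50 random pairs for the
alignment oracle, 1,000 random sequences for the normalisation invariants,
60 + 60 strong-signal and 250 + 250 null transcripts for the
cross-validation behaviour, and 20 selection seeds for planted-feature
recovery. These sizes were chosen as the smallest that make the stochastic
bands stable.

## Known limitations

* The surrogate fold score is a pairing-count proxy; MFE-derived
  conclusions require true RNAfold input.
* The gap-free identity measure saturates near 0.65 for unrelated
  sequences, so thresholds below ~0.7 are only meaningful for sets with
  real homology structure.
* Feature selection and the forest classifier are seeded but not
  platform-independent beyond R's RNG guarantees.
* No oversampling or class re-weighting is implemented; with the roughly
  balanced classes this pipeline targets, stratified CV plus F1 reporting
  is adequate.
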