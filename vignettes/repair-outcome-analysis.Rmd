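---
title: "Modelling Cas9 repair outcomes across DNA-repair knockouts"
author: "cas9repair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Cas9 repair outcomes across DNA-repair knockouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas9repair)
```

## The problem

When Cas9 cuts DNA, the cell's double-strand-break (DSB) repair machinery —
chiefly non-homologous end joining (NHEJ) and microhomology-mediated end
joining (MMEJ) — converts the break into a distribution of insertion and
deletion outcomes that is highly reproducible for a given target sequence,
but shifts systematically when repair genes are knocked out. This package
implements the computational side of a knockout-screen analysis of that
phenomenon: outcome canonicalization and classification, screen filtering
and fold-change profiling, clustering of knockout response profiles,
exponential modelling of microhomology-deletion kinetics, and a
per-cell-line softmax predictor of outcome frequencies. A synthetic screen
generator with exported ground truth stands in for the original sequencing
data, so every stage can be tested end to end against known truth.

## Coordinates and the canonical indel

All coordinates are 0-based. A target carries a protospacer and an NGG PAM;
the blunt cut sits between `cut_index - 1` and `cut_index`, three bases
upstream of the PAM. The base 5' of the cut is the *PAM-distal* flank, the
base 3' of it the *PAM-proximal* flank.

An outcome is an edit record: a half-open deleted interval plus an inserted
string. Because deletions flanked by repeated sequence (microhomology) and
insertions inside repeats can be written at several coordinates while
producing the same molecule, every outcome is reduced to the representative
with the smallest deletion start (maximal 5' shift) by `canonicalize()`.
The microhomology length of a deletion is the largest `k` with
`sequence[a:a+k] == sequence[b:b+k]` on the canonical form, which equals
the number of equivalent deletion windows minus one:

```{r}
ts <- target_site("demo", "AATCGATCGTAGGTACGATCGTAGGAC", 0, 10)
canonicalize(ts, indel(3, 7))
mh_length(ts, indel(2, 6))
```

One numerical subtlety: inside homopolymer runs the window degeneracy can
exceed the deletion size (the two homology copies overlap). `mh_length()`
reports the raw degeneracy minus one, because that is the quantity the
window-counting oracle defines; classified outcomes and the
microhomology-kinetics tabulation cap it at the deletion size so that the
inter-homology distance `d = size - mh` is never negative.

## The ten outcome categories

`classify_outcome()` stratifies outcomes into ten categories: 1bp and 2bp
deletions (`D1`, `D2`); medium (3–9bp) and long (10bp+) deletions split by
presence of microhomology (`D3_9[_MH]`, `D10P[_MH]`); 1–2bp cut-site
insertions matching the PAM-distal or PAM-proximal flank (`I12_DIST`,
`I12_PROX`); and remaining insertions, including compound
insertion–deletions, split by whether the insert is templated from the
10bp flanking the edit (`OTHER_I_MH`, `OTHER_I`).

Three choices here were genuinely open and are exposed as arguments:

* the microhomology threshold for the `_MH` split is `mh_threshold = 1`,
  the smallest nontrivial value, configurable for sensitivity analyses;
* 1–2bp insertions matching *both* flanks are counted with `I12_DIST`
  (`both_as_distal = TRUE`), since the staggered-cut fill-in mechanism that
  produces distal-matching insertions dominates; the `flank_match` flag is
  kept separately so both-matching insertions can still be analysed on
  their own;
* templated insertions are searched within a 10bp window per flank with a
  minimum insert length of 2 (`templated_window`), since shorter matches
  are uninformative.

`directionality()` summarises where a deletion lost sequence relative to
the cut: with `L` bases removed PAM-distal and `R` PAM-proximal, the
statistic is `max(L, R) / (L + R)`; any deletion confined to one side —
in particular every cut-adjacent 1bp deletion — scores exactly 1, and a
symmetric deletion scores 0.5.

## The screen pipeline

Counts live in a long table keyed by (cell line, replicate, timepoint,
target, outcome). The standard pipeline mirrors the screen's processing
order exactly: coverage filtering on raw per-sample profiles (every sample
profile of a retained target needs ≥ 100 mutated reads), removal of
outcomes with a single read summed over all samples, then pooling of
replicates and timepoints:

```{r, eval = FALSE}
ds <- pool_samples(drop_singletons(filter_guides(raw, min_reads = 100)))
# equivalently: standard_pipeline(raw)
```

Frequencies are fractions of mutated reads per (line, target). Log2 fold
changes versus control use a frequency pseudocount of 0.1% — the one value
the source analysis states for this purpose — applied uniformly to all LFC
computations (`pseudocount = 0.001`, configurable). Both a category-level
mean-over-targets view and a per-outcome view (the clustering input) are
available through `lfc()`.

Profile comparisons use Kullback–Leibler divergence in bits (log base 2
throughout, matching the log2 fold-change convention). The directed form
`D(measured ‖ predicted)` is the model loss; the symmetrised form is used
when comparing replicates, where no direction is natural. A 0.5-read
pseudocount keeps divergences finite on disjoint supports.

## Clustering response profiles

Rows are (target, outcome) pairs retained by the screen's noise rule —
present in the control and in at least 10 knockout lines — with their
per-outcome LFC vector across knockouts. `embed_outcomes()` offers UMAP
(through the Python `umap-learn` package, `n_neighbors = 50`,
`min_dist = 0`, fixed `random_state`) and a PCA alternative that is fully
deterministic and has no external dependency. Grouping uses seeded k-means
with `k = 7` by default; the upstream analysis names no algorithm, so the
simplest reproducible reading was adopted, with Ward clustering behind a
flag. Composition tables are the two renormalizations of one
cluster-by-category contingency table; knockout enrichment z-scores each
knockout's LFC column before averaging within clusters, so values are
comparable across knockouts with different global effect sizes.

## Microhomology kinetics

For every pure deletion with microhomology `s ≥ 2`, the inter-homology
distance is `d = deletion size − s` (the unique sequence lost between the
homology copies; by the window geometry `d + s = size` always holds, and
it is asserted). Frequencies are averaged within `(s, d)` bins, and
`y = A e^{B d}` is fitted per MH size (2–15) and cell line by
Levenberg–Marquardt nonlinear least squares on the raw frequencies
(`minpack.lm::nlsLM`, the R analogue of SciPy's `curve_fit`), initialised
from a log-linear regression on the positive bins. Bins supported by fewer
than 3 observations are excluded by default; fits need at least 3 distinct
distances. If the initialiser already fits to machine precision (noiseless
data, constant `y`), it is accepted directly rather than risking a
singular-gradient failure. Unweighted least squares on raw `y` follows the
cited curve-fitting usage; the log-linear fit is only ever an initialiser.

## The outcome-frequency predictor

The candidate space of a target is every deletion of up to 30bp whose
window spans *or touches* the cut (a blunt cut damages both junctions, so
boundary windows are standard candidates; `strict_span` restores strict
spanning) and every 1–2bp insertion within 3bp of the cut, canonicalized
and deduplicated. Before deduplication there are exactly 495 deletion and
140 insertion windows.

Features are binary, organised in documented families — outcome type,
deletion-size one-hots and bins, boundary offsets from the cut,
microhomology length, insertion length and sequence identity, flank-match
flags, nucleotide identity around the cut and at deletion junctions, and
declared pairwise products (deletion size × microhomology, insertion
length × flank match) — 389 features in schema `v1`. This is a versioned
reconstruction of the families that FORECasT-class predictors use; the
external 3,633-dimension count is deliberately not a conformance target.

One model is fitted per cell line. A target's predicted profile is the
softmax of the candidates' linear scores; training minimises the summed
KL divergence between measured profiles (0.5 reads added to every
candidate, then normalised) and predictions, plus an L2 penalty
(`lambda = 1e-3` by default), with L-BFGS-B. The KL direction is
measured-first, which penalises missing mass on observed outcomes; the
optimizer, regulariser and direction are package decisions, exposed as
arguments. Targets are split into train and test sets at the target level
(`test_frac = 0.1`) so no target contributes outcomes to both sides.
Observed outcomes outside the candidate space (compound indels) are
dropped, and their read fraction is logged per fit. Evaluation reports
per-target divergences and Pearson correlations at three levels:
individual outcomes, outcome categories, and the per-target in-frame
fraction (summed frequency of outcomes whose net length change is a
multiple of 3).

## The synthetic screen generator

The generator defines the study conditions for all tests. Its defaults
were fixed once to emulate the reported structure of the screen:

* 2,838 targets by default (tests and examples use smaller libraries),
  each a uniform-random 20bp protospacer with forced NGG PAM inside a
  fixed 30bp context shared by the library;
* microhomology deletions carry *absolute* probability `A_s e^{B d}` with
  `A_s = min(0.040 e^{0.35 s}, 0.12)` and `B = −0.13` per bp, so exact
  generative parameters are recoverable by the kinetics module; on
  repeat-rich targets where this family would exceed 90% of the mass it is
  rescaled down (flagged per distribution);
* 1bp insertions follow a 16-row flank-pair table whose defaults encode
  the reported propensities: T/A-distal targets about three times as
  insertion-prone as G/C-distal ones (0.29 vs 0.097) and proximal
  fractions spanning ~0.5% (T/G) to ~56% (G/T);
* remaining mass goes to non-MH deletions with size-decaying weight plus
  a flat long-deletion tail, off-cut/non-matching insertions, 2bp
  insertions, and a small compound tail that deliberately falls outside
  the predictor's candidate space (so dropped-fraction logging is
  exercised);
* read depths are log-normal (median 1,500 mutated reads per sample
  profile), two replicates, one timepoint by default — timepoints are
  i.i.d. when requested, since the screen pooled them after finding them
  highly correlated;
* knockout effects are per-category log2 fold changes applied
  multiplicatively before renormalization. Presets ship for the screen's
  18 knockouts with signs following the reported directions (e.g. `Nbn`
  suppressing 3bp+ deletions, `Lig4`/`Xrcc5`/`Xlf` depleting small indels,
  `Prkdc`/`Polm` specifically depleting PAM-proximal insertions at −2.3
  and −1.5 with −0.3 on distal ones); magnitudes without a printed value
  are free settings, not measurements.

Because frequencies are compositional, a planted per-category effect is
not exactly the fold change that survives renormalization; the ground
truth therefore stores the *realized* post-normalization LFCs computed on
the exact probabilities (with the same 0.1% pseudocount profiling uses),
and recovery tests compare against those.

The generator emulates multinomial sampling structure, flank-dependent
insertion propensities, the MH decay law and category-level knockout
effects. It does not emulate sequencing error, guide dropout, alignment
artefacts, outcome-level (within-category) effect heterogeneity, or
between-replicate overdispersion. Tests passing on this generator
demonstrate correctness of the analysis machinery under the stated
generative assumptions, not performance on real screens.

## Numerical choices and scales

Problem sizes in the test suite were chosen to exercise each claim at
desk scale: the microhomology oracle is checked on 1,000 random 60-mers
(all deletions up to 12bp), exponential-law recovery on a 50-target screen
with about 10^6 pooled reads (decay rate recovered within 5%), LFC
recovery on 200 targets at 5×10^4 reads per target (within ±0.15 of
realized truth for categories at ≥5% control frequency), and the
predictor comparison on a 500-target screen with an `Nbn`-like effect,
where the knockout-trained model must beat the control-trained model on
held-out targets (paired sign test) and sit within twofold of the
replicate–replicate divergence floor. Archetype-recovery clustering keeps
outcomes at ≥1% control frequency, because rarer outcomes carry almost no
fold-change signal through the 0.1% pseudocount and would only add noise
rows.

## Known limitations

* The softmax model's additive feature families cannot represent
  arbitrary per-candidate variation (by design); even a single-target
  unregularized fit retains a small capacity-limited residual.
* UMAP embeddings are reproducible only for a fixed seed,
  single-threaded; PCA is provided where strict determinism matters.
* The generator's compound-outcome tail is small and fixed per target;
  analyses specific to complex indel structure would need a richer tail.
* Strand-flipped (CCN-PAM) targets and ambiguity codes are out of scope;
  libraries are assumed pre-oriented.
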