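---
title: "Methods: fingerprint-based virtual screening for platelet-production inducers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprint-based virtual screening for platelet-production inducers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mkscreen)
```

## The screening problem

Radiation-induced thrombocytopenia calls for compounds that push
megakaryocytes (MKs) toward differentiation, maturation and platelet
release. Experimentally screening large libraries for this activity is slow,
so the package implements a ligand-based virtual screen: a binary classifier
is trained on known inducers and non-inducers, then used to rank an
unlabeled library by predicted activity. Training data of this kind is
heavily imbalanced — tens of confirmed inducers against hundreds of
inactives — and that imbalance, not model capacity, is usually the limiting
factor. The pipeline therefore couples three preprocessing ideas with a
hybrid neural classifier:

1. **SMILES enumeration** expands the minority class: each molecule admits
   many valid SMILES spellings, and a sequence-encoded model treats each
   spelling as a distinct training example. `augment_positives()` expands
   the positives 20-fold by default (38 inducers become 760 records).
2. **Tanimoto/MaxMin balancing** removes redundancy: within each class,
   `maxmin_select()` greedily keeps the molecules most dissimilar from those
   already kept (distance `1 - Tanimoto`), cutting both classes to the same
   size (500 per class by default).
3. **Dual fingerprints** feed the models: MACCS keys (167-slot convention)
   for the convolutional branch, Morgan/circular bits (radius 2, 2048 bits)
   for the dense branch.

## Model architectures

Three classifiers share one training protocol:

* **CNN** — the 167 MACCS bits are treated as a token sequence over the
  vocabulary {0, 1}. An embedding layer (width 32 by default) maps each bit
  to a dense vector; dropout 0.2; a 1-D convolution with 330 filters, window
  16 and stride 1 (valid padding, hence 167 − 16 + 1 = 152 output
  positions) with ReLU; global max pooling over positions; a dense ReLU
  layer of 128 units; dropout 0.2; a single sigmoid output.
* **DNN** — the 2048 Morgan bits pass through dense ReLU layers of 2048, 64
  and 16 units with dropout 0.2 between them, then a sigmoid output.
* **HCD** — both trunks minus their sigmoid heads; the 128-d and 16-d
  penultimate representations are concatenated (144-d) and a single sigmoid
  head is trained on top. The whole network is optimized end to end in one
  pass — no branch pretraining or freezing — which mirrors treating the
  hybrid as a single model invocation.

Training uses binary cross-entropy with Adam (learning rate 0.001, no
amsgrad, no decay), 20 epochs, batch size 32, the training order reshuffled
every epoch. Eighty percent of the data (stratified, floor convention) is
used for fitting and the remaining 20% for testing; each model is trained
three times with derived seeds and every downstream score is the arithmetic
mean over the replicates. There is no early stopping and no internal
validation holdout: with a fixed 20-epoch budget the entire 80% partition is
used for fitting.

### Numerical choices

The convolution, pooling and large dense products run in single precision
(the convention of the deep-learning frameworks this protocol comes from);
everything else is double. Weights use Glorot-uniform initialization, the
embedding uniform(−0.05, 0.05), biases zero, matching common framework
defaults. Adam uses β₁ = 0.9, β₂ = 0.999, ε = 1e-7. Global max pooling
breaks ties toward the first position; its gradient flows only through the
argmax. Dropout is the inverted variant, so inference needs no rescaling.
With a fixed seed the training history is reproducible on one machine; the
replicate seeds are derived from the master seed and the replicate index, so
per-molecule augmentation streams and replicate initializations are
independent of record order.

### Classification and screening conventions

A compound is called active when its replicate-mean score is **strictly
greater than** 0.5; a score of exactly 0.5 is inactive. Ranked screening
sorts by descending score with ties kept in input order. Raising the
threshold can therefore never increase the active count.

## Metrics

`confusion_counts()` and `classification_metrics()` implement ACC, PRE,
recall, F-value and the Matthews correlation coefficient with the standard
square-root denominator; a metric whose denominator is zero is reported as 0
and flagged as degenerate rather than raising, so evaluation survives a
degenerate replicate. `auroc()` integrates the ROC curve trapezoidally over
distinct score thresholds, which equals the pair-counting estimator with
ties counted half; `auprc()` uses the average-precision step convention.
Both refuse single-class label vectors.

## Diversity selection

`tanimoto()` is set overlap `|a∧b| / |a∨b|`; the undefined all-zero/all-zero
case is defined as 0, while the similarity matrix keeps a unit diagonal.
MaxMin picks its first molecule uniformly at random under the run seed and
then repeatedly adds the candidate whose minimum distance to the selected
set is largest, breaking ties by lowest input index. The greedy procedure is
the field's standard, but it is a heuristic: because the first element is
picked at random, it frequently does not attain the optimum an exhaustive
subset search finds even on small pools (three collinear points already
show why: starting from the middle point caps the achievable separation).
What greedy does guarantee on a metric distance is at least half the
optimal minimum distance — the classical dispersion approximation bound —
and the test suite asserts that bound while also reporting the (expectedly
imperfect) comparison against the exhaustive optimum. Selection runs per class
rather than jointly, because the goal is two balanced sets, each internally
diverse. The similarity fingerprint behind the distances is Morgan-2048
(configurable): it is the finer-grained descriptor and the conventional
choice for diversity picking.

Because enumerated spellings of one molecule have identical fingerprints,
an augmented pool contains exact duplicates at Tanimoto 1. MaxMin picks
distinct structures first, but once every distinct structure is selected the
remaining picks are forced duplicates; the mean-similarity reduction
achievable on such a pool is bounded by the underlying structural diversity
of the parents.

## SMILES enumeration

`enumerate_smiles()` re-roots the molecular graph at a random atom and
emits a depth-first traversal with randomized branch order, writing
explicit-hydrogen bracket atoms with kekulized bond orders. Every emitted
spelling is verified to canonicalize back to the parent structure. Distinct
spellings are preferred (up to 50 redraws per variant); tiny or highly
symmetric molecules that exhaust the redraw budget pad with duplicates, so
the requested count is always returned — an exact k-fold expansion
tolerates duplicates by design. The first spelling returned is always the
canonical one. Stereochemistry is not preserved by the enumerator and no
salt stripping or charge standardization is applied anywhere:
canonicalization is the only normalization.

## The synthetic benchmark

No public dataset ships with the package; `generate_library()` builds
labeled libraries from a curated pool of chain-compatible SMILES fragments
(ring systems, linkers, decorations) concatenated at random — guaranteeing
parseability — with a planted substructure rule: every active contains a
catechol-ester motif (`C(=O)Oc1ccc(O)c(O)c1`, a nod to the caffeoyl
chemotype of known hits; purely a fixture choice with no pharmacological
claim), and every inactive is verified motif-free by SMARTS matching. The
fragment pool includes decoys (bare catechol, simple aliphatic esters) so
the negative class shares partial features with the motif. Defaults mirror
the study conditions: 38 actives versus 743 inactives, label noise off
(enable `noise_rate` only for robustness experiments). At zero noise the
motif is perfectly informative — a substructure lookup achieves AUROC 1.0 —
so the benchmark measures whether a model can recover a clean rule from
fingerprints, not whether it can denoise labels. Real SAR data is noisier
and its actives share no single perfect substructure; passing these checks
shows the pipeline's machinery is sound, not that comparable accuracy would
be reached on experimental data.

`generate_screening_library()` produces an unlabeled library with a known
number of spiked motif-bearing actives and returns the hidden truth
separately, so enrichment (spiked actives recovered among the top ranks)
can be measured end to end.

## Problem sizes used in the checks

The packaged checks run the pipeline constants at the full study sizes
(38 positives × 20 = 760; MaxMin to 500 + 500; split 1000 → 800/200). The
learning and enrichment checks train on a 500-molecule planted library
(400 train / 100 test, balanced) — large enough for every architecture to
reach held-out AUROC ≥ 0.95 under the default protocol while keeping a full
three-architecture comparison quick on a laptop; the enrichment check
screens 200 molecules with 10 spikes using a three-replicate HCD ensemble.
The acceptance script (`scripts/acceptance.R`) instead runs the whole
pipeline at the study's 38/743 imbalance through augmentation, balancing,
training and screening, and writes every computed quantity as JSON.

## Known limitations

* Canonicalization, fingerprints and SMARTS matching are delegated to Open
  Babel (via ChemmineOB); MACCS keys match the published catalogue, while
  Morgan bit *positions* are hash-dependent and not interchangeable with
  other toolkits' (bit patterns are internally consistent, which is all the
  models need).
* The enumerator drops stereochemistry; molecules whose activity depends on
  configuration are represented only by their connectivity.
* Forced-duplicate augmentation of very small molecules slightly reduces
  effective augmentation diversity.
* The classifier offers no uncertainty estimate beyond replicate spread;
  screening scores are ranking devices, not calibrated probabilities.
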