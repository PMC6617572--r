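---
title: "Pairwise-input neural networks for compound-protein interaction prediction: models and methods"
author: "pinnCPI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise-input neural networks for CPI prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling problem

Proteochemometric (PCM) models predict whether a small molecule interacts
with a protein target from the *pair* of entities, rather than building one
model per target.  Because both the compound and the protein are inputs,
one trained model can score novel compounds against novel targets.  The
package implements a family of pairwise-input neural networks (PINNs) for
binary compound-protein interaction (CPI) classification, together with
the featurization, training, evaluation, ranking and transfer-learning
protocols that such a study needs, and a synthetic data generator that
makes the whole pipeline exercisable at desk scale.

## Representations

Both entity types get *low-level* and *high-level* representations:

* **Low-level (sequence) channels.**  SMILES strings and amino-acid
  sequences are tokenized into single characters (SMILES is
  case-sensitive: aromatic `c` and aliphatic `C` differ; amino acids are
  upper-cased).  `buildVocabulary()` enumerates the corpus alphabet,
  ordered lexicographically by character code so the index map is
  reproducible; `encodeSequence()` produces a fixed-length one-hot matrix
  (reference lengths 100 for SMILES, 700 for proteins), truncating from
  the end and zero-padding at the end -- padding is the all-zero row, not a
  token.  The vocabulary is conventionally extracted from the union of the
  corpora a model will see; this leaks the test alphabet, so a train-only
  vocabulary is available simply by passing the training corpus (unknown
  characters then raise an encoding error naming the character and
  position).

* **Circular fingerprints.**  `ecfpFingerprint()` produces ECFP-style
  binary vectors (reference: diameter 4, 1024 bits).  SMILES parsing is
  delegated to OpenBabel (via ChemmineOB/ChemmineR); the package computes
  the Morgan relaxation itself: a per-atom invariant (element, degree,
  bond-order sum) is iteratively re-hashed with the sorted (bond order,
  neighbour invariant) multiset, one iteration per radius step, and
  identifiers are folded modulo the bit width.  Identifier values are
  specific to this package's hash, exactly as they are specific to any
  fingerprint toolkit; symmetry-equivalent atoms receive equal
  identifiers.  One deliberate convention: environments are computed on
  *kekulized* connection tables, so heteroaromatic rings can split
  symmetry classes that aromatic-bond perception would keep merged.

* **Sentence embeddings.**  Molecules and proteins are treated as
  sentences: words are Morgan-substructure identifiers per atom and radius
  (`compoundToWords()`, default radii 0 and 1) and shifted non-overlapping
  N-grams (`proteinToWords()`, default n = 3; the sentence concatenates
  the n shifted N-gram lists so every residue context appears).
  `trainWordEmbeddings()` provides a compact skip-gram with negative
  sampling for desk-scale corpora (single-threaded, deterministic per
  seed); externally trained tables load from word2vec text format
  (`readWord2vec()`).  The reference hyperparameters for full-scale
  protein embeddings are dimension 300, window 35, minimum count 2.
  Entities without sequence information map to the zero vector -- the
  default out-of-vocabulary policy (an error policy is available for
  strict pipelines).

### Sentence aggregation

A sentence of word vectors $w_1..w_N$ is reduced to one vector by one of

$$S^{sum} = \sum_{i=1}^{N} w_i, \qquad
  S^{mean} = \frac{1}{N}\sum_{i=1}^{N} w_i, \qquad
  S^{tfidf} = \sum_{i=1}^{N} t_{w_i}\, w_i,$$

where $t_w$ is the word's TF-IDF weight.  The TF-IDF variant is the
smoothed formulation $idf(w) = \ln\!\big((1+n_{docs})/(1+df(w))\big) + 1$
with raw term counts and *no* normalization of the weights: the printed
weighted "average" is in fact a weighted sum, and that is the reference
behaviour here; a `normalize` flag divides by $\sum t_w$ and a
`sublinearTf` flag switches to $1+\log tf$ for sensitivity analysis.
Words never seen by the fitted model receive the maximal smoothed idf.
The TF-IDF corpus is the task's own dataset (for synthetic runs, the
synthetic sentences themselves), matching the practice of weighting within
the modelled document collection rather than the embedding corpus.

Useful algebraic identities (enforced by tests): $S^{sum} = N\,S^{mean}$;
duplicating every word $k$ times leaves $S^{mean}$ unchanged and scales
$S^{sum}$ by $k$; unit weights collapse $S^{tfidf}$ to $S^{sum}$; idf is
non-increasing in document frequency.

## Architecture

A PINN gives every channel its own *separated* dense stack -- no
cross-connections before the merge -- concatenates the channel outputs, and
classifies through a *concatenated* dense stack ending in a single sigmoid
unit.  Because each channel contributes exactly its last separated width
to the merge, the architecture balances feature ratios regardless of raw
input dimension (a 1024-bit fingerprint and a 300-dimensional embedding
meet as equals), and it needs roughly half the parameters of a plain
feed-forward network on the concatenated input (`countParameters()` /
`ffnnParameterCount()` make this auditable; the reference-width
configuration lands at a ratio of about 0.52).

Channels (`channelConfig()`):

* **dense** -- a precomputed feature vector, passed through.
* **dilated_cnn** -- token embedding (dimension 16), stacked 1-D
  convolutions with 16 filters, kernel 12, valid padding and per-layer
  dilation, then global max pooling.  The dilation schedule is a design
  choice: 3 layers `(1, 2, 4)` for SMILES (receptive field
  $1 + 11(1+2+4) = 78 \le 100$) and 4 layers `(1, 2, 4, 8)` for proteins
  (receptive field 166 $\le$ 700).  Configurations whose receptive field
  exceeds the fixed length are rejected with the computed field.  No
  residual connections are used: dilation alone provides the long-range
  context, and the skip-free stack keeps the parameter count and the
  backward pass simple.  Global max pooling is the sequence-to-vector
  reduction because all-zero padding rows can never win a maximum over a
  genuine activation pattern.
* **lstm / blstm** -- recurrent stacks with 256 units emitting the final
  state (both directions concatenated for blstm); the one-hot input is
  consumed directly through the input weight matrix, and the forget-gate
  bias starts at 1.

Dense layers use ELU ($\alpha = 1$; the identity for non-negative inputs,
$\alpha(e^x-1)$ below zero) and Lecun-uniform initialization
($\pm\sqrt{3/fan_{in}}$).  Dropout is 10% on the initial (input) layer and
50% on hidden dense layers in the reference configuration; both rates are
tunable, and desk-scale experiments in this package use 0-0.2 because
50% dropout removes most of the capacity of a 32-unit layer.  Reference
widths: two separated layers (1024, 256) per channel for single-channel
models, one (256) for multi-channel models, one concatenated layer of 256.
The fifteen named feature-pair presets (`SC_1`..`SC_6`, `MC_1`..`MC_9`)
encode the compound-feature x protein-feature grid
(SMILES/ECFP/Mol2vec x AA-sequence/ProtVec, and their multi-channel
combinations).

The network engine is implemented natively in R on BLAS matrix operations,
with hand-derived backpropagation for every layer kind; a finite-difference
gradient check over all layer types is part of the test suite.

## Training

`trainPinn()` minimizes class-weighted binary cross-entropy with Adam
(reference settings: learning rate 5e-4, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, mini-batch 1024 -- scaled down for desk-scale runs).
*Weight decay* (1e-5) follows the convention of decaying the learning rate
over updates, $lr_t = lr/(1 + decay\,t)$; a conventional L2 penalty is
available separately.  Class weights default to the balanced heuristic
$w_{neg} = 1$, $w_{pos} = n_{neg}/n_{pos}$.  High-level feature channels
are standardized to zero mean and unit variance with statistics of the
training split only (population variance; zero-variance features map
to 0).  Early stopping monitors validation MCC -- the primary metric
throughout -- with a default patience of 20 epochs (validation curves
plateau slowly here, so a generous window avoids premature stops); the
returned model carries the best-validation weights.  The epoch budget is
400 for cross-validation protocols and 500 for final training; both are
plain config fields.  Training histories record loss, validation MCC/ROC
and wall-clock per epoch, and are the substrate for the initial-performance
(epoch-1 metric) and convergence-speed (first epoch reaching 98% -- or 95%
for finetuning -- of the run's best) readouts.  `crossValidate()` runs
label-stratified k-fold (default 5) evaluation over the validation portion
with seed-reproducible fold assignment.

## Evaluation and model ranking

`mcc()`, `rocAuc()` and `prcAuc()` implement the three metrics: MCC with
the zero-denominator convention (0) and a 0.5 hard-label threshold on
probabilities; ROC AUC by the rank (Mann-Whitney) formulation with
average ranks for ties; PRC AUC by the step-wise average-precision rule
without interpolation, where tied scores form a single operating point (a
constant scorer therefore scores the prevalence -- the reason PRC is the
metric of choice for strongly imbalanced tasks).  All three are verified
against brute-force oracles in the tests.

`zscoreRanking()` compares models the way multi-model studies are usually
summarized: metric values are standardized *across models* within each
(replicate, metric) slice (population standard deviation, so each slice
has mean 0 and unit variance; a pooled variant is available), averaged per
model, and reported with the SEM over replicates, plus pairwise paired
t tests and variance-ratio F tests (degenerate comparisons -- identical or
constant values -- report p = 1 rather than failing).

## Transfer learning

`pretrainWithCheckpoints()` trains on a source task and snapshots the full
model every 5 epochs (reference schedule: 140 pretraining epochs), with
`pm_0` saved before any update; checkpoints restore bit-identically.
`finetune()` applies one of four standard strategies expressed as
freeze/re-initialization masks over the layer manifest: (1) finetune
everything; (2) re-initialize the top, finetune everything; (3) freeze the
bottom, finetune the top; (4) freeze the bottom, re-initialize and train
the top -- the setting matching a small, dissimilar test task, which is the
regime studied here.  "Top" means the concatenated stack plus output
layer, where task-specific representations concentrate; channel
featurizers and separated stacks are "bottom".  Frozen layers receive no
optimizer updates and are verified bit-identical through finetuning.
Each finetune starts a fresh optimizer (each is an independent run);
re-drawn layers use Lecun-uniform initialization.  The target-task budget
is 200 epochs with early stopping, and test-set MCC and PRC are recorded
every epoch.  `comparePretraining()` reports, per checkpoint, initial
performance, epochs to 95% of best, and highest test metric, with paired
t tests against `pm_0`.

## The synthetic data generator

The generator emulates the *shape* of the two dataset regimes that matter
for this class of study -- a balanced bioactivity corpus (54.7% positives)
and a strongly imbalanced toxicology corpus (7.49% positives; 75th length
percentiles of 63 characters for SMILES and, scaled down, 120 residues
for proteins) -- while remaining fully self-contained and deterministic
per seed.

* **Compounds** are assembled from a fragment grammar (alkyl chains,
  aromatic and saturated rings, carbonyl/amine/ether units) whose every
  unit can legally follow an atom, so all concatenations parse; target
  lengths are log-normal with the 75th percentile calibrated to the spec.
* **Proteins** draw residues at typical globular-protein frequencies with
  log-normal lengths.
* **Labels** come from a low-rank latent interaction rule.  Each compound
  receives $u_c = P_c z_c$ where $z_c$ is its centered 1024-bit circular
  fingerprint -- substructure composition exactly as a fingerprint channel
  observes it -- and each protein $v_p = P_p z_p$ with $z_p$ its
  standardized amino-acid composition.  The projections are random
  Gaussian maps *keyed per word* by a seeded hash, so two tasks can share
  or blend rules regardless of corpus vocabularies.  Pair logits are the
  standardized dot products $\langle u_c, v_p\rangle$ times
  `interactionScale`, plus optional Gaussian noise (`noiseSd`) and an
  intercept calibrated by bisection so the realized positive rate hits the
  target within half a percentage point.

Design rationale, where choices were genuinely open: the latents are
functions of *observable composition* rather than free random draws --
otherwise no model could ever learn the task and model-quality tests would
be meaningless.  The rank is 2 and the default scale is 20 (an effectively
deterministic rule; label stochasticity is controlled separately by
`noiseSd`), chosen so that the generator's learnability contract -- a
fingerprint-channel PINN reaching validation MCC $\ge$ 0.7 on the default
20,000-pair dataset within 50 epochs -- holds with margin on a single CPU;
signal placed in variance-standardized rare substructure bits turned out
to be unlearnable spikes, which is why composition is centered but not
variance-scaled on the compound side.  Centering common bits rather than
rare ones keeps the decision boundary in densely populated feature
directions.

For transfer experiments, `generateTaskPair()` blends the target's
projection as $sim \cdot P^{src} + \sqrt{1-sim^2}\cdot P^{indep}$:
similarity 1 reproduces the source rule, similarity 0 an unrelated one,
and the latent scale is preserved in between; the target defaults to the
imbalanced positive-rate regime.

What the generator does *not* emulate: chemically realistic bioactivity
(no binding physics, no target-class structure, no activity cliffs),
realistic protein domain architecture, assay noise structure, or the
scale of public bioactivity corpora.  Passing the end-to-end tests
therefore demonstrates that the machinery -- featurization, architecture,
optimization, transfer -- works and recovers a recoverable signal; it does
not certify predictive performance on real chemogenomic data.

## Desk-scale experiment configuration

Two desk-scale conventions in the tests deserve explanation:

* **Unigram protein words with mean aggregation.**  At full scale,
  3-gram words are the convention.  A desk-scale corpus of 200 proteins
  cannot support a 20^3-word vocabulary (most 3-grams occur once or
  never), and sum/tf-idf aggregation scales with sequence length, which
  confounds composition.  Mean-aggregated unigram embeddings are an
  invertible linear image of amino-acid composition whenever the embedding
  dimension is at least 20, so the protein channel provably carries the
  generator's protein signal.  Tests and example experiments therefore use
  `n = 1`, `scheme = "mean"`, `d = 32`.
* **Reduced widths, dropout and batch size.**  Experiments use separated
  widths (64, 32), concatenated (64, 32), dropout 0-0.2, batch 128 and
  learning rate 2e-3; the reference values remain the documented
  defaults.  Problem sizes in the test suite: the end-to-end experiment
  uses the full default generator (2,000 compounds x 200 proteins, 20,000
  pairs); transfer experiments use 400 x 80 entities and 4,000 pairs over
  5 seeds; unit tests use a few hundred pairs.

## Numerical choices and degenerate inputs

* MCC returns 0 when any denominator factor vanishes; ROC requires both
  classes, PRC at least one positive (errors otherwise).
* The weighted-loss gradient divides by the batch size, not the summed
  weights, matching the usual class-weight semantics.
* Skip-gram batch updates aggregate per-word *means*; summed updates
  overshoot catastrophically when a small vocabulary makes words recur
  hundreds of times per batch.
* Training stops with an error naming the epoch if the loss goes
  non-finite.
* Positive-rate bisection operates on the realized uniform draws, so the
  intercept search is monotone and lands within half a point (tolerance
  `max(5e-4, 2/n)`) or errors after 100 steps.
* Zero-variance features standardize to 0; the normalizer is affine and
  invertible on the remaining features.
* Sequence padding: encoding pads with all-zero rows; the CNN channel
  convolves over them (valid padding bounds the receptive field), the
  LSTM consumes zero input vectors for padded steps.

## Known limitations

* The engine is CPU-bound, single-threaded R: the reference full-scale
  configuration (1024-batch, 500 epochs, 700-length protein CNNs) is out
  of desk-scale reach; the package targets method development and
  desk-scale studies, not production-scale training.
* Morgan identifiers on kekulized structures can split heteroaromatic
  symmetry classes (documented above); multi-character SMILES tokens
  (e.g. `Cl` as one token) are deliberately not supported in the
  character channels.
* The skip-gram trainer is for small corpora; for full-scale embeddings,
  train externally and load the word2vec text file.
* Recurrent channels are markedly slower than convolutional ones in this
  engine and are exercised at small sequence lengths in the tests.
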