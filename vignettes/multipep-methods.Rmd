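---
title: "Label-embedding Transformers for multi-label peptide function prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-embedding Transformers for multi-label peptide function prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Therapeutic peptides are short amino-acid sequences (roughly 5–50 residues)
with bioactivities such as anti-microbial (AMP), toxic (TXP), anti-bacterial
(ABP), anti-viral (AVP) or cell-penetrating (CPP) action. A single peptide
frequently carries several of these functions at once, and the functions are
far from independent: anti-bacterial peptides are usually anti-microbial,
toxic and anti-cancer activity co-occur, and so on. Treating each function as
an isolated binary classification problem discards this correlation
structure; `multipep` instead treats the task as a single multi-label
problem over a function vocabulary of C classes (C = 15 by default) and
builds the correlations directly into the architecture.

Two practical complications shape the design:

* **Long-tail label distribution.** Public annotations are heavily
  imbalanced — a few functions have thousands of labelled examples while
  others have fewer than two hundred. We stratify evaluation into many-shot
  (> 1000 positives), medium-shot (200–1000) and few-shot (< 200) groups,
  with thresholds configurable because the absolute numbers only make sense
  at full benchmark scale.
* **Incomplete annotation (weak labels).** A peptide labelled only "AMP"
  may simply never have been assayed for anything else. We model this as a
  *weak-label ratio* r: a fraction r of a function's true positives is
  recorded as negative. The classifier-retraining strategy below is designed
  to stay robust in this regime.

## Model

Each peptide is encoded as a fixed-shape residue feature matrix
$X^s \in \mathbb{R}^{L \times 40}$ with $L = 50$: columns 1–20 are the
one-hot residue identity (alphabetical order `ACDEFGHIKLMNPQRSTVWY`),
columns 21–40 the PSI-BLAST PSSM log-odds profile when available (zeros or
BLOSUM62 rows otherwise). Sequences shorter than $L$ are zero-padded at the
end; longer sequences keep their first and last $L/2$ residues, preserving
both termini. The candidate functions enter as a one-hot token matrix
$X^t = I_C$.

The network is a standard post-layer-norm Transformer used asymmetrically:

* the **encoder** (2 layers at desk scale) runs over residues after a linear
  lift $f_{enc}: \mathbb{R}^{40} \to \mathbb{R}^{d}$, scaled by
  $\sqrt{d_{model}}$ in the standard Transformer convention, plus sinusoidal
  positional encodings
  $PE(pos, 2i) = \sin(pos / 1000^{2i/d})$,
  $PE(pos, 2i+1) = \cos(pos / 1000^{2i/d})$ — note the base constant 1000
  used by this model family rather than the common 10000 (configurable).
  Without the $\sqrt{d_{model}}$ embedding scale the unit-amplitude
  positional encodings drown the content signal roughly 8:1 at $d = 64$;
* the **decoder** (2 layers) runs over the C function tokens after
  $f_{dec}: \mathbb{R}^{C} \to \mathbb{R}^{d}$, *without* positional
  encodings: functions are an unordered set, and the forward pass is exactly
  equivariant under permutation of the function tokens.

Attention is scaled dot-product attention,
$\mathrm{softmax}(QK^\top / \sqrt{d_{model}})\,V$, with the full
$\sqrt{d_{model}}$ scale in every head (the form this model family
publishes, rather than the per-head $\sqrt{d_k}$), and conventional
$d_{model}/h$ head slices. Three attention roles fall out of the
architecture and are all recorded for interpretation: residue–residue
(encoder self-attention), function–function (decoder self-attention, the
channel through which correlated functions exchange information), and
function–residue (decoder cross-attention, which grounds each function
token in sequence evidence). Padded positions are excluded from attention
keys, so padding can never influence the output.

The decoder output is the function representation matrix
$Z \in \mathbb{R}^{C \times d}$, one row per function. Two classifier forms
sit on top:

* a **single shared classifier** $\hat y = \sigma(Z w + b)$, which forces
  all functions into one output space;
* **function-specific classifiers** $\hat y_i = \sigma(w_i \cdot z_i + b_i)$,
  giving each function its own decision boundary.

Calls use the fixed threshold 0.5 (strictly greater; a probability of
exactly 0.5 is not called).

## Two-phase training

Training the function-specific heads from scratch would let every function
pull its representation into a private output space, defeating the purpose
of the shared label embedding. Training therefore proceeds in two phases:

1. **Phase 1** trains the sequence-embedding module, the label-embedding
   module and the shared classifier jointly with multi-label binary
   cross-entropy (probabilities clipped to $[10^{-7}, 1-10^{-7}]$; the loss
   is the conventional *negated* log-likelihood, so lower is better), using
   AdamW.
2. **Phase 2** freezes the label-embedding module — bit-exactly: freezing is
   implemented as index masking on a flat parameter vector, so frozen
   coordinates are never touched — initialises each $(w_i, b_i)$ from the
   phase-1 $(w, b)$, and trains only the specific heads. By default the
   sequence-embedding module is frozen too; with the whole backbone fixed,
   the representations $Z$ are computed once and the C heads are trained on
   the cached values, which is mathematically identical to running the full
   network and substantially faster. A configuration flag leaves the
   sequence embeddings trainable, which routes phase 2 through the full
   backpropagation path instead.

Hyperparameters are configuration inputs with a grid-search helper
(`grid_search()`) that trains every combination and returns the one with
minimal final validation loss. Experiments are run across several seeds
(default 5) and metrics averaged arithmetically, with per-seed values
retained.

## Classifier retraining for weak labels (MCRT)

After full training, each function's classifier can be retrained alone on a
class-rebalanced bootstrap of the training data, with the embeddings and all
other classifiers frozen. For function c with $n_{c,pos}$ positives among N
training samples, each of N draws first picks the positive class with the
square-root probability
$$p_{c,pos} = \frac{\sqrt{n_{c,pos}}}{\sqrt{n_{c,pos}} + \sqrt{N - n_{c,pos}}},$$
then a uniform member of the chosen class (with replacement). The
complement is computed as $1 - p_{c,pos}$, which equals the same formula
applied to the negative count and guarantees the two probabilities sum to
exactly 1 in floating point. Square-root sampling sits deliberately between
the natural rate ($n_{c,pos}/N$) and a fully balanced draw ($1/2$): it
boosts minority positives enough to counteract missing labels without
letting individual (possibly mislabeled) samples dominate. Because only
$(w_c, b_c)$ is updated, the predictions of every other function are
bit-identical before and after — per-function sub-seeds are derived from
the global seed by function index, so even the processing order is
irrelevant to the result.

## The synthetic benchmark

Real curated benchmarks cannot ship with a package, so `multipep` includes
a generator whose output has the statistical structure the method relies
on, with defaults chosen to emulate a realistic study at desk scale:

* **2000 peptides over C = 8 functions**, lengths uniform on 15–50,
  uniform background residue composition (configurable to an empirical
  composition);
* **long-tail counts**: per-function base weights decay as
  $\mathrm{rank}^{-1.5}$, giving a max/min positive-count ratio above 20;
* **correlated multi-labels**: label sets are drawn from weighted templates
  (singletons plus adjacent pairs and triples), so 1–4 labels per sample and
  a non-trivial label co-occurrence Pearson matrix — independent per-label
  coin flips would make the label-embedding machinery untestable;
* **learnable signal**: each function owns a distinct 4-mer motif written
  into its positive sequences at a uniformly random non-overlapping
  position with probability 0.9. The signal is strong but deliberately not
  perfect: ~10% of positives carry no motif, which caps attainable recall
  near 0.9 and keeps the task honest.

What the generator does *not* emulate: homology structure between sequences
(no redundancy reduction is needed), real PSSM profiles (profile columns are
zero-filled unless supplied), empirical residue composition, and the exact
count spectrum of any curated dataset. Passing the learnability tests
therefore demonstrates that the implementation can extract sequence–label
signal with the assumed statistical shape — not that it reproduces any
particular published benchmark figure.

An 8:1:1 train/validation/test split is drawn with a seed; stratification is
best-effort (every function with any positives gets at least one into
training). Weak-label experiments degrade training and validation labels
only; the test split always keeps its true labels.

## Numerical and design choices

* **Permutation equivariance, bit-wise.** Floating-point softmax sums over
  keys in storage order, so a permuted token set would normally produce
  last-ulp differences. Decoder self-attention therefore accumulates its
  softmax normalizer and its weights×values contraction in sorted order,
  which is permutation-invariant; the equivariance contract holds exactly,
  not approximately. The cost is negligible because the function-token set
  is small.
* **Initialisation.** Weights are seeded uniform fan-in draws,
  $U(\pm 1/\sqrt{fan_{in}})$; the output projections of the residual
  branches (attention output and second feed-forward matrix) are
  additionally scaled by 0.25. Post-layer-norm Transformers are known to
  start far from the identity map, and at desk scale the plain fan-in
  initialisation left rare functions at zero recall for tens of epochs;
  the scaled initialisation keeps each sublayer near-identity at the start
  and removes most of that warmup burden.
* **Optimisation.** AdamW with $\beta = (0.9, 0.98)$, decoupled weight
  decay $10^{-3}$, linear warmup (100 steps), then either cosine decay to
  zero (the default schedule) or a constant rate. The second-moment
  constant 0.98 (rather than 0.999) speeds up adaptation to the
  rare-function gradients that arrive only a few times per epoch. The
  desk-scale experiments hold the rate constant after warmup: at their
  epoch budget the model is still in the improving regime, where decaying
  the rate early costs accuracy. All of these are configuration inputs.
* **Desk-scale problem sizes.** The test-suite and acceptance runs use the
  2000-sample benchmark with d_model = 64, 4 heads, 2+2 layers, d_ff = 128,
  dropout 0.1, batch size 16, 35 phase-1 epochs, 10 phase-2 epochs and
  5 seeds. At this scale phase 2 is run with the sequence-embedding module
  left trainable (the configuration flag the freeze policy exposes): the
  35-epoch encoder has not fully converged, and a short joint fine-tune
  under the specific heads recovers the remaining accuracy while the label
  embeddings stay frozen either way. The weak-label robustness experiment
  uses the same model with a shorter protocol (10 phase-1 epochs, then 8
  epochs of frozen-backbone head training), which is already deep enough for
  the retraining comparison it supports. These are the package's desk-scale
  study sizes; all of them are plain configuration values.
* **Eq-of-record for the loss.** The training objective is the standard
  negated binary cross-entropy (lower is better), summed over functions and
  averaged over the batch.
* **Empty-label convention.** Example-based accuracy uses
  $|\,L \cap \hat L\,| / |\,L \cup \hat L\,|$; a sample with both sets
  empty counts as 1 (perfectly predicted absence) and is flagged, since
  curated data always carries at least one label.
* **Macro-F1 zero-division.** A function with no positives and no positive
  predictions contributes F1 = 0 and is counted in a `degenerate`
  attribute.
* **AUC ties.** The rank (Mann–Whitney) formulation with half credit for
  ties; AUC is reported missing when only one class is present.
* **RkCC.** Gorodkin's K-category correlation coefficient; for K = 2 it
  equals the Matthews correlation coefficient, which is asserted in the
  test suite over random tables.
* **PSSM handling.** The PSI-BLAST ASCII parser keeps raw log-odds scores
  (no squashing) and reorders columns from PSI-BLAST's `ARNDCQEGHILKMFPSTWYV`
  to the package's alphabetical order. Running PSI-BLAST or CD-HIT is out
  of scope; only their outputs are consumed.
* **Non-standard residues** (B, J, O, U, X, Z) are rejected in strict mode
  and encoded as all-zero rows otherwise.
* **Weak-label flips** use half-up rounding of $r \cdot n_{pos}$ and
  per-function sub-seeds derived from one global seed; samples that lose
  all labels are retained as all-negative — in the weak-label regime they
  are legitimate "no known function" examples.

## Known limitations

* The compiled core is CPU-only and single-threaded by design; it is sized
  for desk-scale experiments, not for training on hundreds of thousands of
  sequences.
* Dropout defaults to 0 (fully deterministic training given the seed); the
  desk-scale experiments enable 0.1, which measurably reduces rare-function
  overfitting — the motif task is clean enough that an unregularised model
  starts memorising individual rare-class sequences.
* The attention-recording path keeps full-length matrices while the
  training path drops padded positions; the two agree mathematically but
  may differ in the last floating-point digit (padded keys carry exactly
  zero weight on both paths).
* Grid search is exhaustive over the supplied space; there is no early
  pruning.
* The synthetic benchmark's motif model makes signal strength an explicit
  dial. Results on it quantify implementation correctness and the relative
  benefit of classifier retraining, and do not transfer numerically to any
  real peptide corpus.
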