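---
title: "Methods: text contours, contour classifiers, and layered explanations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: text contours, contour classifiers, and layered explanations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and
procedure, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, the
numerical choices, and the design decisions taken where the design was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## 1. The pipeline

Mental-health text classification is treated as a set of independent
binary tasks (condition vs. control) over social-media-style posts. The
pipeline has four stages:

1. **Annotation.** Sentence splitting, tokenization, coarse POS tagging
   (a fixed 12-tag set), rule lemmatization and syllable counting. The
   bundled `"rules"` backend is deterministic and dependency-free; the
   original analysis used a full parser toolkit, but every downstream
   quantity here needs only token-level counts, and a reproducible
   fallback makes all tests bit-exact with no model downloads. Alternative
   backends can be registered at run time
   (`register_annotation_backend()`).
2. **Contour extraction.** A window of `w` sentences (default `w = 1`,
   i.e. per-sentence values — the indexing the dense-matrix construction
   implies; `w` is configurable) slides with stride 1. Each of 192 general
   linguistic features is scored per window into a dense `W × 192` matrix;
   each of 306 lexicon-based features produces a sparse 3-tuple
   `(feature id, window id, score)` iff its score is non-zero. For the
   combined model the two blocks are concatenated along the feature axis
   (width 498).
3. **Classification.** A stacked BiLSTM over the standardized contour
   sequence, or a compact attention encoder over raw tokens, optionally
   with multi-task fusion heads.
4. **Explanation.** LIME and SP-LIME (model-agnostic), AGRAD
   (attention-gradient, model-specific), top-k unigram extraction and
   lexicon-category coverage.

## 2. The feature catalogue and its scoring rules

The catalogue's *shape* is fixed — 192 GLFs in five groups
(morphosyntactic 48, lexical 45, readability 13, cohesion 30, stylistic
56) and 306 LBFs over seven lexicon slots (ANEW 6 norms, ANEW-Emo 5
categories, GI 178, GALC 38, LIWC 64, EmoLex 10, SenticNet 5 norms) — but
the per-feature inventory inside each group is this package's documented
default, since only the group-level composition is a hard constraint. Each
feature name resolves to a scorer in `R/glf.R`; highlights:

* *Readability* (13 published indices): Flesch Reading Ease,
  Flesch–Kincaid grade (`0.39·W/S + 11.8·Sy/W − 15.59`), Gunning Fog,
  SMOG, ARI, Coleman–Liau, LIX, RIX, Dale–Chall, Linsear Write, FORCAST,
  Strain, Spache. The two vocabulary-based indices use a compact bundled
  familiar-word list (`default_easy_words()`), a stand-in for the long
  published lists.
* *Cohesion*: adjacent-sentence lemma overlap (Jaccard, containment,
  Dice; per word class), lag-2 and cumulative overlap, connective rates
  by class, repetition and givenness proxies. These scorers see the
  sentence(s) preceding the window: adjacent-sentence overlap is
  undefined without the neighbour, so cohesion columns are
  context-dependent by construction (sentence-permutation equivariance
  holds for the other four groups and is tested there).
* *Stylistic*: for each of 4 registers × {unigram, bigram} × 7 statistics
  of register frequency/rank (mean/sd/max log frequency with +1
  smoothing, OOV rate, mean/median log rank, top-quartile share), against
  register n-gram tables in a generic TSV format (the published tables
  are proprietary; synthetic tables ship via the generator).
* *LBF scoring* (the source gives no formula; flagged for sensitivity
  analysis): categorical lexicons score hit counts — surface or lemma
  match, plus bigram entries — normalized by window token count, which
  removes the length confound and makes "add one occurrence" weakly
  monotone; norm lexicons score the mean norm value over matched words.
  A window with no match scores 0, which is exactly the sparsity rule
  for tuple emission.

Scores are computed on raw values. Per-feature z-standardization uses
**training-split statistics only** (population SD; zero-variance features
pin to 0), applied at model-input assembly — contour figures show
z-standardized curves, and fitting statistics on evaluation data would
leak. Cubic b-spline smoothing (`standardize_and_smooth(smooth = TRUE)`)
is length-preserving and for visualization only.

Degenerate windows (under ~3 tokens) are handled by guarded formulas that
floor denominators at 1, never returning NaN — classifier input must stay
finite.

## 3. Classifiers

**BiLSTM (contour models).** Default 3 layers, hidden dimension 512 per
direction, matching the published architecture; the classifier head takes
`[h→₃ | h←₃]` through two ReLU layers (width `head_dim`, default 64) and
a sigmoid. Sparse LBF inputs are densified at batch assembly; sequences
are padded to the batch maximum with masking; documents with zero windows
are excluded with a warning. Training: Adam, learning rate 1e-3 (the
source states rates only for the transformer; 1e-3 is the standard Adam
default for recurrent nets of this size), weight decay 1e-5, batch 32, 8
epochs, keeping the checkpoint with the highest validation accuracy.
Tests and examples use scaled-down configurations (1 layer, hidden 16,
learning rate 3e-3) so the suite fits a 1-CPU budget; the scaled runs
separate a d = 2 planted effect perfectly, which is what they are asked
to show.

**Attention encoder.** The pretrained domain transformer is out of scope
(no weight downloads); in its place a compact trainable encoder honours
the same training contract: word-level vocabulary built from the training
split, truncation at `max_tokens = 512`, batch 32, 8 epochs, best
validation accuracy kept. Architecture: learned word + position
embeddings, `n_layers` blocks of multi-head self-attention with residual
connections (no layer norm — at this scale it is unnecessary and its
omission keeps the hand-written backward pass small and auditable),
masked mean pooling, sigmoid heads. Defaults: 2 layers, 4 heads,
dimension 128.

Both networks and their gradients are hand-written base-R matrix code:
no deep-learning framework is available in the target environment, and
AGRAD needs `∂L/∂α` for post-softmax attention weights, which frameworks
do not expose. The backward passes are verified against central finite
differences in the test suite (BiLSTM through the masked multi-layer
stack, encoder through attention, embeddings and heads).

**Fusion.** `L_tot = λ·L_MHC + (1−λ)·L_SEC` per batch, with `L_SEC` the
unweighted mean of the active secondary-task losses (mean binary
cross-entropy over the 6 emotion or 4 personality outputs — the simplest
symmetric choice; the source does not specify one). λ defaults to 0.5
("tunable" in the source, no value given); tune on validation accuracy
over a {0.1, …, 0.9} grid if desired. Silver labels threshold predicted
probabilities at 0.5 with ties mapping to 1. The λ ∈ {0, 1} boundary
identities and the loss decomposition (`total = λ·primary +
(1−λ)·secondary` per epoch, to 1e-6) are tested; at λ = 1 the primary
learning curve is bit-comparable to a single-task run because shared
parameters are initialized before task heads consume the RNG.

## 4. Explanations

**LIME.** Perturbs a document in bag-of-unigrams space (Bernoulli-0.5
masks over distinct unigrams, the instance itself always included),
queries the model, and fits a ridge surrogate (penalty 1, intercept
unpenalized) weighted by `exp(−(100·d_cos)²/25²)` — the reference
implementation's text defaults (cosine distance on a 0–100 scale, kernel
width 25), since the source names none. 1000 samples by default; fewer
than 10 is rejected.

**SP-LIME.** For contour models, the local surrogate masks *feature
columns* to 0 — the standardized training mean — and each instance's
surrogate is sparsified to its top-K weights (K = 20), mirroring
reference LIME's K-feature selection. This sparsification matters: a
dense ridge surrogate carries noise weight in every coefficient, so
summed group importance would grow with group *cardinality* rather than
model reliance. Instances (budget `min(50, n)`) are picked greedily by
submodular coverage gain with global feature importance
`I_j = sqrt(Σ_i |W_ij|)`; picked instances' absolute weights are summed
per feature group and normalized to 100 %. Group importance columns
therefore sum to 100 by construction (tested to ±0.01).

**AGRAD.** For an attention model, the importance of attention position
`i` is `A_i = −(∂L/∂α_i)·α_i` over post-softmax weights: a negative loss
gradient (loss-reducing position) yields positive importance. Unstated
aggregation choices, made configurable: final encoder layer, summed over
heads and query positions; the word-level vocabulary makes sub-token
aggregation the identity. The analytic `∂L/∂α` is validated against a
finite-difference oracle that re-runs the forward pass from an overridden
attention tensor (relative error < 1e-4 in the acceptance suite).

**Coverage and correlations.** Top-k unigrams (k = 10) per document,
ties broken by earlier position, short documents contributing all their
unigrams; category coverage = percentage of selected word tokens in a
lexicon category (unigram entries only, multi-category words counted once
per category; empty selections report 0 with a warning). Gold-silver
label association uses the Pearson coefficient, with constant vectors
reported as 0 and flagged — matching the 0.00 convention of the published
correlation tables.

## 5. The synthetic-data generator: the stated world

The generator emulates the *statistical structure* the analysis assumes —
not natural language. Documents are template sentences ("the" + content
words + ".") over a closed vocabulary of consonant–vowel pseudo-words
whose syllable counts (1–4) and character lengths are exact by
construction, so feature-level ground truth is computable by hand. The
vocabulary, register tables (Zipf frequencies, the designated
high-frequency half taking the top ranks) and the seven lexicons are a
fixed world depending only on vocabulary size; the run seed governs
sampling. Defaults: 400 documents, balanced classes, Poisson(8) sentences
per document, Gaussian(10, 3) tokens per sentence — a short
social-media-style post.

Planted signals:

* **Lexicon plant**: each content-word slot is replaced by a planted
  lexicon word (the "sadness" categories of the emotion slots) with
  probability `p_case = 0.3` vs. `p_control = 0.05` (the rates the
  framework's own calibration example states). Planted words are also
  ordinary vocabulary, so empirical rates sit ~2 points above the
  nominal probability; the ±0.03 calibration check covers this.
* **GLF plant**, effect size `d` (default 2 — the strong-signal regime
  the module examples describe; chosen once, before any outcome was
  measured). Two mechanisms: `"morphosyntactic"` shifts case sentence
  lengths by `d` standard deviations; `"stylistic"` biases case word
  draws toward the high-frequency vocabulary half with log-odds `d`
  (halves matched on syllables, so nothing leaks into length-based
  features).
* **Auxiliary labels**: 6 emotion and 4 personality binary labels drawn
  from the 2×2 contingency construction that fixes the phi (= Pearson on
  binaries) correlation with the condition label; infeasible targets for
  the given marginals raise an error naming the feasible range, and
  |r| = 1 with matched marginals degenerates to label cloning. Default
  targets r = (0.6, 0.3, 0.2, 0.1, 0, 0) and (0.3, 0.2, 0.1, 0) give a
  gradient from strongly to un-associated labels, the structure the
  correlation analysis expects.

**Group identifiability (a design decision).** Piloting during design
showed the sentence-length mechanism is *not* attributable to a single
feature group: words-per-sentence terms appear in readability formulas,
and per-sentence register-bigram statistics are length-driven, so an
explanation method that spreads importance across those groups is being
*correct*, not failing. The planted-group recovery experiments therefore
use the frequency-bias plant, whose signal lands in exactly one group
(plus two lexical sophistication features, an accepted 56-vs-2
imbalance), with the lexicon plant disabled (`p_case = p_control`) to
keep the experiment single-mechanism. The sentence-length mechanism
remains the generator default for end-to-end classification tests, where
identifiability is not at issue.

**What a green test does not establish.** The generator has no topical
content, no discourse structure, no register variation beyond the planted
frequencies, no label noise and no class imbalance beyond configuration.
Green recovery tests establish that the pipeline recovers signals *of the
planted kind at the planted strength*; they say nothing about
effect sizes in real clinical corpora, which are far smaller and
confounded.

## 6. Published-table arithmetic

The published benchmark tables (model performance, group importance,
fusion performance, one external baseline) ship as plain TSV under
`inst/extdata/` and are treated as *inputs*: the package verifies the
aggregation arithmetic over them — Total I-scores as row sums, F1 gaps as
best-interpretable minus reference, infusion gains as fusion minus
baseline accuracy — at the printed precision. The cells themselves derive
from restricted corpora and are not recomputed. One printed total
(readability, stated as 98.28) conflicts with its own row (which sums to
77.35, while 98.28 equals the lexical row's total); the row-sum
definition is authoritative here and that value is not used as a check.

Metrics rows report accuracy, precision, recall and F1 in percent.
Averaging is macro over the two classes with F1 defined as the harmonic
mean of macro precision and macro recall — the one macro definition under
which the printed-table identity `F1 = 2PR/(P+R)` holds row-wise —
with a `"positive"`-class mode as the configurable alternative.
Zero-division cells report 0 and are flagged. Rounding is half-up to two
decimals at report time only.

## 7. Numerical choices and limitations

* Population (not sample) SD everywhere a z-score is defined; zero
  variance maps to zero scores.
* Ridge systems are solved directly (`solve` on the
  penalized normal equations); surrogate dimensions stay ≤ 500.
* Probabilities are clipped at 1e-9 inside cross-entropy.
* Seeds: every stochastic routine takes a seed and restores the caller's
  RNG state; two runs with the same seeds agree bitwise on the same
  platform/BLAS.
* Known limitations: the rule tagger and lemmatizer are approximate on
  real English (by design, they are exact on the synthetic vocabulary);
  the attention encoder is a desk-scale stand-in, so absolute accuracies
  are not comparable to pretrained-transformer results; LIME's
  bag-of-unigrams perturbation ignores word order; training is
  single-threaded CPU.
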