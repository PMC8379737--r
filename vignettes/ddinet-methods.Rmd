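---
title: "Multi-modal Siamese attention networks for DDI prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal Siamese attention networks for DDI prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

A drug–drug interaction (DDI) dataset consists of $N$ drugs, $T$ similarity
matrices $S_1, \dots, S_T \in [0,1]^{N \times N}$ — one per data *modality*
(chemical structure, targets, side effects, pathways, …) — and a symmetric
binary label matrix marking the known interacting pairs among the
$K = \binom{N}{2}$ unordered drug pairs. A pair's input is the pair of
vector sets $u_a = \{S_1^{d_a}, \dots, S_T^{d_a}\}$ and
$u_b = \{S_1^{d_b}, \dots, S_T^{d_b}\}$, where $S_t^{d}$ is drug $d$'s row
of matrix $t$: each drug is described by how similar it is to every other
drug, once per modality. The task is binary: will the pair interact?
Absent labels are not verified negatives — an unobserved interaction may
simply be unreported — which is one reason ranking metrics (AUPR in
particular, given prevalences between roughly 1.5% and 32%) are the
primary yardstick.

`ddinet` implements this model family end to end: similarity construction,
pair-level dataset assembly, the Siamese multi-head self-attention encoder
with its joint classification + contrastive objective, stratified
cross-validation with validation-AUPR model selection, and two modality
attribution procedures.

## Similarity construction

**Jaccard.** Binary drug-feature matrices (drug × feature indicators) are
converted to similarities by the Jaccard score
$J(u_a, u_b) = M_{11} / (M_{01} + M_{10} + M_{11})$ over the feature
positions set in one or both vectors. Two conventions are fixed: an
all-zero pair of vectors scores 0 off the diagonal (empty supports share
nothing), while the diagonal is always 1, so the matrix remains a valid
similarity with unit diagonal.

**GIP.** The Gaussian Interaction Profile kernel treats drug $a$'s row
$y_a$ of the label matrix as its interaction profile and sets
$\mathrm{GIP}(a,b) = \exp(-\gamma_g \lVert y_a - y_b \rVert^2)$ with
bandwidth $\gamma_g = s \big/ \frac{1}{N} \sum_a \lVert y_a \rVert^2$.
The normalisation by the mean squared profile norm is the standard
construction; because bandwidth conventions vary across implementations
the scale $s$ is exposed (`bandwidth_scale`, default 1). A label matrix
with no positives degenerates to the identity matrix.

**GIP and label leakage.** GIP is built from the very labels the model is
trained to predict. Computing it on the full matrix lets test-pair labels
leak into the input features. The default (`gip = "train"`) therefore
zeroes held-out pairs' label entries before building the kernel, fold by
fold; `gip = "full"` reproduces the whole-matrix construction for
comparability with the conventional evaluation protocol.

## The encoder

Each drug's $T$ modality vectors are processed by a shared-weight
(Siamese) encoder; the two drugs of a pair never see each other until the
classifier. One encoder unit applies, in order: multi-head scaled
dot-product self-attention over the $T$ vectors, a residual add + layer
normalisation, a position-wise feed-forward network
($W_2\,\mathrm{ReLU}(W_1 x + b_1) + b_2$ with hidden width $\xi d'$), and
a second residual add + layer normalisation. $E$ units are stacked, after
which a *feature attention* layer scores each transformed vector against a
learned context vector $c$, $\psi_t \propto \exp(c^\top \tilde g_t /
\sqrt{d'})$, and pools $z = \sum_t \psi_t \tilde g_t$ — one fixed-length
representation per drug. Attention rows and $\psi$ are probability
vectors by construction, which the test suite asserts on every trace.

Three design points were genuinely open and were resolved as follows:

* **Model dimension $d'$.** The architecture defines
  $W_{query}, W_{key}, W_{value} \in \mathbb{R}^{d' \times d}$ without
  fixing $d'$. It is a required configuration field (default 128).
* **First residual with $d \ne d'$.** The first unit's residual sums the
  attention output ($d'$) with the input vector ($d$). A learned affine
  input projection $d \to d'$ is applied before the first unit so all
  residuals are dimension-consistent; every attention projection is then
  $d' \times d'$.
* **Feed-forward residual.** The unit description labels both
  normalisations "Add + Normalize", while the layer equations write the
  second normalisation without an explicit residual term. The default
  keeps the residual, $\tilde g_t = \mathrm{LayerNorm}(g_t + \tilde r_t)$;
  `ff_residual = FALSE` selects the literal no-residual reading.

Dropout placement is the standard Transformer one (after the unified
attention output and after the feed-forward output), rate per
configuration. Parameters initialise uniformly in $\pm 1/\sqrt{fan_{in}}$
from a recorded seed. `pooling_mode` offers `mean` and `max` pooling as
alternatives to feature attention, which remains the reference setting.

## Classifier and objective

The classifier concatenates $[z_a; z_b; \mathrm{Dist}(z_a, z_b)]$ —
euclidean or cosine distance — and maps it through one affine transform
and a softmax to the two-class probability. The training objective is

$$L^{Total} = \gamma L^C + (1 - \gamma)\, L^{Dist} +
\tfrac{\lambda}{2} \lVert \theta \rVert_2^2,$$

with $L^C$ the class-weighted binary cross-entropy (weights inversely
proportional to class frequency, normalised to unit mean; probabilities
clamped at $10^{-12}$) and $L^{Dist}$ the contrastive loss: $d^2/2$ for
interacting pairs and $\max(\mu - d, 0)^2/2$ for non-interacting ones.
The printed form of the dissimilar-pair term applies the max *after*
squaring, which is vacuous since squares are nonnegative — and, taken
literally, would also penalise pairs already beyond the margin; the hinge
is therefore the default and the literal form is available as
`contrastive_literal = TRUE`. The L2 penalty is part of the objective
(not optimizer-coupled decay), so it appears in the reported loss and its
gradient. Class weighting applies to the NLL term only by default
(`weight_contrastive` extends it).

Because the concatenation $[z_a; z_b; d]$ is order-dependent and pairs
are unordered, training uses the canonical $i < j$ order and prediction
averages the class probabilities over both orders, making
$\mathrm{score}(a,b) = \mathrm{score}(b,a)$ exact at no extra training
cost.

**Optimisation.** The optimizer family is not pinned down by the
architecture; Adam with learning rate $10^{-3}$ (package default) is
used, with one global seed driving initialisation, batch shuffling and
dropout. Mini-batch losses use inverse-frequency class weights rather
than resampling. After each epoch the model is scored on a stratified
validation split (10% of the training portion); the parameters of the
best-validation-AUPR epoch are kept, earliest epoch on ties. All of the
encoder/classifier gradients are analytic and hand-derived; the test
suite checks them against central finite differences to a relative
tolerance of $10^{-4}$.

**Variants.** `attention_only` drops the Siamese split: the pair's $2T$
vectors form a single input set to one encoder, whose pooled output feeds
an affine head directly (no distance, hence no contrastive term — the
loss reduces to weighted NLL + L2). `feedforward_only` additionally drops
attention: the $2T$ vectors are concatenated into one long input for a
one-hidden-layer MLP (hidden width $\xi d'$, ReLU).

## Evaluation

AUC is computed as the Mann–Whitney statistic (ties counted ½), AUPR as
the step-wise area under the precision–recall curve — the
average-precision convention, with tied scores grouped at one threshold
and no linear interpolation between PR points; conventions differ across
libraries, so this one is fixed and tested against hand-computed curves.
Cross-validation reports both the mean over folds (primary) and pooled
metrics over all test predictions. Thresholded confusion summaries report
undefined rates as missing, never as 0.

Folds are stratified at the *pair* level: drugs are not held out, so both
members of a test pair typically occur in training pairs. This matches
the reference protocol and is the easier transductive setting; per-drug
generalisation claims would need drug-wise splits, which are out of scope
here.

## Modality attribution

Two procedures, designed to be compared:

1. **Attention aggregation.** Per drug, the $T \times T$ self-attention
   matrices are averaged over heads and units and premultiplied by the
   feature-attention row vector:
   $\mathrm{ModalityImp}^{Attn} = featAttn \cdot
   (\frac{1}{E} \sum_e \frac{1}{H} \sum_h Attn^{[h,e]})$ — a probability
   vector over modalities when the inputs are row-stochastic. A pair's
   vector is the arithmetic mean of its two drugs' vectors (the
   aggregation across the two Siamese branches is not otherwise
   specified), and the report averages over all test pairs of all folds.
2. **Masking ablation.** For each modality, the cross-validated model is
   fully retrained with that modality removed from the input set (same
   fold plan and seeds), and the per-fold relative change
   $(m_{base} - m_{masked})/m_{base}$ in AUC and AUPR — plus their
   average — is reported. Retraining, rather than zeroing at test time,
   is the reference reading of the ablation ("a base model that had
   access to all modalities"); test-time zeroing is offered as a cheap
   alternative (`method = "zero"`).

GIP counts as an ordinary modality in both procedures. Agreement between
the rankings is summarised as top-$k$ overlap.

## The synthetic generator

No benchmark data ships with the package, so everything is exercised on
synthetic fixtures built by `synth_ddi()`. The generator emulates the
statistical shape of the benchmarks — $T$ similarity matrices in $[0,1]$,
symmetric with unit diagonal, derived from binary feature matrices, and a
symmetric label matrix at a requested prevalence — via planted co-feature
structure:

* Drugs are assigned to latent groups. Within-group pair blocks, then
  randomly ordered cross-group blocks, are greedily designated as
  interacting until the target prevalence is reached; the greedy
  construction with ~`n_latent_groups` blocks of fine granularity lands
  within ±0.5 percentage points, after which labels are thinned or
  boosted at random if needed, and optional label noise flips pairs at
  `noise_flip_rate`.
* In each *informative* modality, every interaction unit (each group and
  each designated cross-group block) owns a dedicated feature block that
  its member drugs carry with probability `signal_strength` against a
  background rate of $(1 - \mathrm{signal})/4$. Interacting drugs
  therefore share features, making them Jaccard-similar — the premise
  (shared neighbourhoods predict shared interactions) that also motivates
  the GIP kernel. Non-informative modalities are feature noise
  (rate 0.15), similar for no drug subset in particular.

Defaults (200 drugs, 20 latent groups, 3 modalities of 250 features, two
of them informative, signal 0.9, prevalence 7%, no label noise) mirror a
mid-sized benchmark with moderate imbalance. `synth_benchmark_config()`
reproduces the four benchmark geometries (548 drugs / 8 modalities / ~32%;
707 / 1 / ~7%; 807 / 7 / ~1.5% and ~6%), optionally scaled down.

What the fixtures do *not* emulate: real chemistry or pharmacology,
heavy-tailed feature frequencies, correlated modalities, or the biased
missingness of curated DDI labels. Passing the recovery experiments shows
the pipeline can learn planted structure through the full model path — it
does not certify benchmark-level accuracy on real data, which requires
the external datasets (supported as inputs, but not shipped).

## Reference experiments and problem sizes

The package's own reference experiments (run by `scripts/acceptance.R`
and mirrored in the test suite) use sizes chosen to exercise the full
pipeline at desk scale: the recovery study trains 10-fold CV on the
200-drug default fixture with a $d' = 48$, $H = 2$, $E = 1$ model for 25
epochs (batch 1000, Adam 2·10⁻³, dropout 0.3, $\gamma = 0.05$, $\mu = 1$,
$\lambda = 10^{-6}$), alongside a label-shuffled null and the
`feedforward_only` ablation; the attribution study uses a 120-drug,
4-modality fixture (2 informative + 2 noise, no GIP so the feature
modalities are attributed in isolation) with 3-fold CV and full
retraining per masked modality. The per-dataset hyperparameter presets are available as
`ddinet_preset()` for full-scale runs on the real benchmarks.

## Numerical notes and limitations

* Layer-norm uses biased variance with an $\epsilon$ floor; a constant
  vector normalises to the shift $\beta$.
* Cosine distance returns 0 when either representation has zero norm;
  euclidean gradients guard the $1/d$ factor at $d = 0$.
* AUPR-tie handling on epoch selection keeps the earliest best epoch.
* Training is CPU-only, dense, base-R matrix algebra — adequate for
  $N \lesssim 10^3$ drugs; a GPU-backed implementation would be the
  better tool for large-scale hyperparameter sweeps.
* The model is transductive over drugs (similarity rows have length $N$);
  adding a new drug changes the input dimension and requires refitting.
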