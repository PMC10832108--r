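---
title: "Hint-based teacher-student adaptation for drug-target interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hint-based teacher-student adaptation for drug-target interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hintdti)
```

## The problem and the model

Binary drug-target interaction (DTI) prediction asks, for a pair consisting
of a small molecule (a SMILES string $x_{\mathrm{drug}}$) and a protein (an
amino-acid sequence $x_{\mathrm{target}}$), whether the two bind. The model
is a mapping $f(x_{\mathrm{drug}}, x_{\mathrm{target}}) \to [0,1]$ trained
on thresholded dissociation constants: a pair with $K_d$ strictly below 30
(units as distributed with the source data, passed through untransformed)
is a positive.

Large pretrained protein language models encode rich "general knowledge"
of protein sequences but are expensive to fine-tune: the attention cost
grows quadratically with sequence length and the models run to hundreds of
millions of parameters. The architecture implemented here sidesteps
fine-tuning by combining:

* a **frozen teacher** protein encoder, whose class-token (CLS) output for
  a given sequence never changes and can therefore be **cached once**
  before training;
* a small trainable **student** protein encoder (two transformer layers,
  otherwise matching the teacher's width);
* a trainable **drug encoder** over atom-level SMILES tokens;
* a learnable scalar **adaptation gate** $\lambda$ that mixes the two
  protein views,

$$
z_{\mathrm{target}} \;=\; \lambda\, g\!\big(\mathrm{LN}(x^{\mathrm{student}}_{\mathrm{class}})\big)
  \;+\; (1-\lambda)\, h\!\big(\mathrm{LN}(x^{\mathrm{teacher}}_{\mathrm{class}})\big),
$$

where $g$ and $h$ are affine projections into a shared mixing space and
$\mathrm{LN}$ is layer normalization. The drug side is analogous with a
single projection, $z_{\mathrm{drug}} = f(\mathrm{LN}(x_{\mathrm{class}}))$.
The concatenation $(z_{\mathrm{drug}}, z_{\mathrm{target}})$ — drug first —
feeds a prediction head of three fully connected blocks (GeLU activation,
dropout 0.1) and a final linear layer producing one logit. Training
minimizes binary cross-entropy computed on the logit (mathematically
identical to probability-space cross-entropy, but stable), with AdamW and a
cosine-annealed learning rate; after each epoch the model is scored on the
validation split and the checkpoint with the highest validation AUPRC is
kept, the earliest epoch winning ties. AUPRC drives selection because the
data are heavily imbalanced and AUROC saturates; no imbalance sampler is
used anywhere.

At full scale the teacher is a 30-layer, 1024-wide encoder with a
40,000-slot position table and a pooler (419,931,136 parameters; 420 M
rounded) and the student is its 2-layer counterpart (25,785,344; 26 M).
The package computes both counts in closed form from the architecture
description, and the tests verify the closed form against enumeration over
instantiated weights. The ratio quoted for the pair, 6.2%, is the ratio of
the *rounded* millions (26/420); the raw ratio is 6.14%.

## Resolving the mixing-dimension ambiguity

The description of the target branch places the class-token mixing in the
encoder width (1024) while the head consumes a 512-dimensional target
feature. The package adopts one consistent resolution: $g$ and $h$ map
$1024 \to 1024$, and a separate affine reduction maps the mixed vector
$1024 \to 512$. The alternative reading — $g, h$ projecting straight to
512 with no reduction — is available via `direct_mix = TRUE` in
`dti_model()`.

## Ablation modes are structural

The two ablations are built as *different models*, not as a full model
with $\lambda$ pinned:

* `teacher_only` contains no student encoder at all and freezes the drug
  encoder, so training updates only the projections and the head. This is
  linear probing of the cached teacher features; its performance reflects
  the teacher's existing knowledge.
* `student_only` contains no teacher branch and no $\lambda$.

This guarantees the unused branch receives no optimizer updates (AdamW
moments would otherwise still evolve) and makes the parameter-group
assertions in the test suite exact.

## Choices the source description leaves open

Decisions that had to be made, and the defaults chosen:

* **$\lambda$ is raw and unconstrained.** Only its initialization,
  $\lambda \sim U[0,1)$, is specified; no sigmoid or clamping is applied,
  values may leave $[0,1]$ during training, and the per-epoch trajectory
  is recorded as-is in the run history.
* **SMILES tokenizer.** A self-contained atom-level regular expression
  (bracket atoms, two-letter elements, `%NN` ring closures and stereo
  marks as single tokens) with a fixed alphabet; out-of-alphabet tokens
  map to UNK, never dropped. `tokenize_smiles()` accepts a user tokenizer
  function for fidelity runs against a pretrained checkpoint vocabulary.
* **Protein vocabulary.** Thirty entries: five specials plus the 20
  canonical amino acids and X, U, B, Z, O, the convention of large
  pretrained protein encoders.
* **Maximum lengths count every slot** including CLS/SEP: 512 for drugs,
  545 for targets at full scale.
* **Student position table** spans 545 slots — the only value that
  reconciles the printed 26 M student count.
* **Whether the drug encoder is fine-tuned** is not stated; the default is
  trainable (`drug_trainable = TRUE`), switchable by flag. `teacher_only`
  mode forces it frozen to keep the linear-probing reading exact.
* **Optimizer details.** AdamW weight decay 0.01 applied to weight
  matrices only (biases, layer norms and $\lambda$ exempt); cosine
  annealing spans the full epoch budget with floor 0 and no restarts or
  warmup; no gradient clipping.
* **Initialization.** Truncated normal, sd 0.02, clipped at two standard
  deviations; layer-norm epsilon $10^{-12}$.
* **Threshold conventions.** A score of exactly 0.5 counts as a predicted
  positive; a $K_d$ of exactly 30 is a negative; AUROC credits tied
  scores one half; AUPRC is non-interpolated average precision under a
  stable ordering (ties broken by original position).
* **Precision.** All computation is double precision. The training
  configuration carries a `mixed_precision` flag for interface
  completeness, but only `FALSE` is accepted — R has no reduced-precision
  arithmetic, and double precision is what makes the bit-reproducibility
  guarantees in the test suite possible.
* **Cache persistence.** The teacher cache is a single RDS file holding
  one full-precision vector per digest of the exact token-id list (so the
  truncation policy is part of the key) plus a fingerprint of the teacher
  configuration and weights; a store created under a different teacher is
  refused rather than silently reused.

## The synthetic benchmark

Public DTI benchmarks require downloads and GPU-scale training, so the
package ships a generator whose corpora exercise every pipeline stage at
desk scale. Drugs are random token strings over a SMILES-like alphabet;
targets are random residue strings. A drug motif (`[Se][Se]`) is planted
in 30% of drugs and a target motif (`HWH`) in 30% of targets, and the true
interaction rule is the AND of the two motif-presence indicators,
evaluated on the actual strings (so rare chance assembly of a motif
counts). Labels flip with probability $\varepsilon$ (default 0.05), and
each record receives a $K_d$ drawn log-uniformly from a class-consistent
range — positives from $[0.1, 30)$, negatives from $[30, 10^4]$ — so
thresholding $K_d$ reconstructs the noisy label exactly and the labeling
path is exercised non-trivially.

The motif AND-rule mirrors the knowledge split of the architecture: the
target motif is exactly the kind of general sequence property a frozen
teacher can expose — the `motif_oracle` mock teacher embeds k-mer-presence
indicators, making the target side linearly separable — while the drug
motif must be learned from scratch by the trainable path. The
`random_frozen` mock is a small seeded encoder used frozen, for tests
where the teacher must have real transformer weights (freezing and
caching checks).

Default study conditions: pools of 200 drugs and 120 targets, 2,000 pairs,
motif prevalences 0.3/0.3 (positive prevalence about 9% before noise,
emulating the imbalance of public $K_d$-derived benchmarks), noise 0.05.
What the generator does *not* emulate: chemical validity or physical
binding energetics, homology structure among proteins, and the long-tail
entity-degree distributions of curated benchmarks. Passing the synthetic
tests therefore demonstrates that the architecture, optimization and
bookkeeping are correct and that the model can extract a planted
signal — not that any particular benchmark performance is reproduced.

## The desk-scale profile

`tiny_profile()` shrinks the architecture so the full pipeline runs in
minutes on one CPU core: hidden width 32, 2 heads, feed-forward width 64,
a 1-layer drug encoder and a 2-layer student (preserving the
shallow-student design), a 24-dimensional mock teacher, 32-wide drug and
target features into a 64→128→64→32→1 head, batch size 32, ten epochs.
The learning rate is 2e-3 rather than the full-scale 1e-4: the tiny model
has roughly three orders of magnitude fewer parameters and one fifth the
epochs, and small transformers train at correspondingly larger rates.
These sizes are the package's chosen desk-scale operating point; the
acceptance script and the heavier tests train this profile on 2,000-pair
corpora, several seeds deep, in a few minutes each.

## Known limitations

* The transformer stack is implemented directly in R with hand-derived
  gradients. It is exact (finite-difference checks hold to $10^{-4}$
  relative error) and fast enough at desk scale, but it is not a vehicle
  for training the full-scale 87 M-parameter model; reproducing published
  benchmark numbers additionally requires the external datasets and
  pretrained teacher checkpoints, which are out of scope here.
* Pretrained checkpoint weights are not bundled; the teacher is either a
  seeded frozen encoder or the motif oracle. The caching, freezing and
  mixing machinery treats all teachers identically, so swapping in real
  checkpoint weights is a data question, not a code change.
* Entity identity is exact string equality; no SMILES canonicalization or
  sequence clustering is applied to the cold-split definitions.
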