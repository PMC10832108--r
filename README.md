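# hintdti

Drug–target interaction (DTI) prediction with hint-based teacher–student
knowledge adaptation, implemented as an R package.

## The problem and the method

Binary DTI prediction maps a pair — a small molecule given as a SMILES
string and a protein given as an amino-acid sequence — to a binding
probability. Labels come from dissociation constants: Kd strictly below 30
(source units) is a positive. Large pretrained protein language models
carry strong general sequence knowledge but are too expensive to
fine-tune routinely, so this package implements a lightweight alternative:

- a **frozen teacher** protein encoder whose class-token (CLS) features
  are **cached once** and looked up thereafter (it is never updated, so
  its outputs never change);
- a small trainable **student** protein encoder (2 transformer layers at
  the teacher's width) and a trainable drug encoder over atom-level
  SMILES tokens;
- a learnable scalar gate λ mixing the two protein views,

  z_target = λ · g(LN(x_class_student)) + (1 − λ) · h(LN(x_class_teacher)),

  with g, h affine projections and LN layer normalization; the drug side
  uses z_drug = f(LN(x_class));
- a concatenation head (z_drug, z_target) → 2048 → 1024 → 512 → 1 with
  GeLU and dropout 0.1, producing one binding logit.

Training is AdamW (lr 1e-4 at full scale) with cosine annealing, binary
cross-entropy on logits, batch size 32, and checkpoint selection by
validation AUPRC (robust under heavy class imbalance; ties go to the
earliest epoch). Ablations are structural constructions: `teacher_only`
is linear probing of cached teacher features (only projections + head
update), `student_only` has no teacher branch at all.

At full scale the architecture description yields 25,785,344 student
parameters (26 M) versus 419,931,136 for the teacher (420 M) — computed
in closed form by `count_parameters()` and verified against weight
enumeration in the tests. The complete transformer stack, including the
backward pass, is implemented in vectorized R and validated against
finite differences, so the whole pipeline runs and is testable on one CPU
at desk scale.

Because public benchmarks (DAVIS, BindingDB, BIOSNAP) require downloads
and GPU-scale training, the package ships a synthetic benchmark: corpora
with a planted motif AND-rule (drug motif AND target motif, labels
flipped with noise ε, Kd values consistent with labels), plus mock
teachers — `motif_oracle` exposes k-mer presence linearly, mirroring a
teacher whose general knowledge is predictive, and `random_frozen` is a
seeded frozen encoder.

## Worked example

```r
library(hintdti)

spec   <- synthetic_spec(n_pairs = 600, seed = 42)   # planted-rule corpus
corpus <- generate_synthetic_corpus(spec)
bundle <- split_dataset(corpus$records, seed = 42, provenance = "synthetic")
#> <split_bundle> synthetic: train 420 / valid 60 / test 120

teacher <- make_mock_teacher("motif_oracle", dims = 24, seed = 42)
profile <- tiny_profile(epochs = 5, seed = 42)       # desk-scale architecture
cache   <- precompute_teacher_cache(unique(corpus$records$sequence), teacher,
                                    max_len = profile$max_target_len)
#> <teacher_cache> 120 cached targets, max_len 60

model  <- profile_model(profile, mode = "adaptation", seed = 42)
config <- profile$train; config$seed <- 42
run    <- fit_dti(model, bundle, config, cache = cache)
glance(run)
#> # A tibble: 1 × 6
#>   mode       epochs best_epoch best_valid_auprc final_train_loss final_lambda
#> 1 adaptation      5          2            0.390            0.433        0.999

evaluate_split(run, bundle$test, cache = cache)
#> # A tibble: 1 × 7
#>   auroc auprc sensitivity specificity n_pos n_neg threshold
#> 1 0.731 0.287           0           1    16   104       0.5
```

Five epochs on 600 pairs already lift test AUPRC (0.287) well above the
positive prevalence (16/120 ≈ 0.13), i.e. the model has started to
recover the planted rule; the low sensitivity at threshold 0.5 reflects
an early, poorly calibrated checkpoint, which is why model selection uses
AUPRC rather than thresholded metrics. Longer runs at the default study
conditions (2,000 pairs, 10 epochs) separate the classes far more
strongly — see the acceptance script below. `tidy(run)` returns the
per-epoch history (loss, validation AUROC/AUPRC, λ) and `autoplot(run)`
plots it. `extract_cold_subsets()` / `evaluate_cold_splits()` evaluate
cold-drug, cold-target and cold-binding generalization.

A YAML-manifest command-line interface wraps the same pipeline
(`inst/cli/hintdti.R` with subcommands `simulate | cache | train |
evaluate`).

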