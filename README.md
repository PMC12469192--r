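# aivive

In vitro to in vivo extrapolation (IVIVE) of toxicogenomic expression
profiles: a cycle-consistent, label-conditioned generative adversarial
network (GAN) that translates rat primary-hepatocyte transcriptomic
profiles into synthetic animal-liver profiles, refined by per-module
**local optimizers** that restore biologically important low-signal genes
(such as the cytochrome P450 family, whose expression collapses in
hepatocyte culture). The package is aimed at computational toxicologists
who want to prototype, stress-test and evaluate this class of translator
without access to a full toxicogenomics repository: it ships a synthetic
study generator with known ground truth, the complete evaluation suite,
and an end-to-end pipeline.

## The model

Let `x ∈ [0,1]^G` be a min–max-scaled in vitro profile over a gene panel
of size `G`, and `s, t ∈ {0,1}^16` one-hot label vectors (system, dose,
time slot, replicate) for the source and target experiments. The forward
generator

```
ŷ = F([x | s | t | z]),   z ~ N(0, I_G)
```

is a fully connected network (hidden widths 8192/7168/7168/4096/4096,
LeakyReLU 0.2, dropout 0.8/0.8/0.8/0.4, sigmoid output of width `G`;
widths scale by a configurable factor). Domain discriminators `D_vivo`,
`D_vitro` (256/64 ReLU units, dropout 0.5, BCE loss, SGD lr 1e-4 momentum
0.9) provide the adversarial signal, and a reverse generator `R` closes
the cycle. The generator objective is

```
L = BCE(D_vivo(F(x)), 1) + BCE(D_vitro(R(y)), 1)
    + λ · ( ‖R(F(x)) − x‖₁ + ‖F(R(y)) − y‖₁ ),    λ = 10
```

After training, per-module refiners are fitted on the translator's scaled
outputs (input: module genes + target label; one hidden layer of 4× the
module size), and a refiner is kept only if it strictly improves
module-level RMSE on a held-out compound-level validation split. Applied
refiners overwrite exactly their module's coordinates.

Evaluation follows the field's conventions: cosine/RMSE/MAPE against
baseline (cross-treatment) and replicate (within-treatment) controls with
Welch's t-test; DEG calling at |log2 fold change| > 1 against time-matched
controls with triplet-union synthetic DEG sets and overlap ratio
|real ∩ synthetic|/|real|; hypergeometric pathway over-representation with
Bonferroni correction and tie-aware top-k comparison; percent-error grids
`(real − synthetic)/real × 100` for adverse-outcome-pathway genes; and an
XGBoost necrosis classifier (100 trees, η = 0.1, depth 10) on
replicate-averaged treatment features.

## Worked example

A complete desk-scale run — simulate a 12-compound, 100-gene paired study,
train the translator at 1/64 width, fit and accept local optimizers,
evaluate on the held-out compounds, and classify necrosis:

```r
library(aivive)
res <- run_pipeline(run_config(seed = 42), out_dir = "run1")
str(res$summary)
```

prints (abridged):

```
$ n_train_pairs              : int 7200
$ n_test_pairs               : int 1440
$ best_epoch                 : int 31
$ cosine_model               : num 0.993
$ cosine_baseline            : num 0.992
$ cosine_replicate           : num 0.998
$ rmse_model                 : num 0.747
$ rmse_baseline              : num 0.798
$ modules_selected           : int 8
$ modules_accepted           : int 4
$ necrosis_accuracy_real     : num 94.7
$ necrosis_accuracy_synthetic: num 94.7
```

Reading the numbers: the model group (synthetic vs matched real profile)
beats the baseline control on cosine similarity (0.9925 vs 0.9922) and
RMSE (0.747 vs 0.798) while staying below the replicate-control ceiling
(0.9982) — the ordering the method must produce. Four of eight candidate
modules pass the strict-improvement acceptance rule, and the
gradient-boosted classifier is far above the 50% balanced-chance level on
both real and synthetic test features. At this miniature scale the
translator mostly captures per-gene conditional means, so DEG-level
overlap stays small; the vignette discusses what desk-scale runs can and
cannot show.

The same pipeline is scriptable from a shell via the thin CLI:

```sh
Rscript exec/aivive run-all --config config.yaml --out run1
```

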