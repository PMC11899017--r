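# sadasnet

Particle-swarm-driven neural architecture search (NAS) for convolutional
image classifiers, built for multi-class dermoscopy (skin lesion)
classification in the HAM10000 style — seven classes: actinic keratoses
(akiec), basal cell carcinoma (bcc), benign keratosis (bkl),
dermatofibroma (df), melanocytic nevi (nv), vascular lesions (vasc) and
melanoma (mel). The package is aimed at researchers who want automated,
hardware-aware discovery of compact CNNs instead of hand design or
transfer learning, and at anyone who needs the surrounding machinery:
class-imbalance oversampling, stratified protocol splits, and full
multiclass evaluation reports.

## The method

Each candidate architecture is a fixed-length *genome*
`P ∈ [0, 1]^D`. Genes are grouped into macro slots — a convolution group,
a pooling group — plus fully connected slots. Within each group a
*control gene* selects the variant: serial convolution vs. an
inception-style multi-branch block (branch *i* uses kernel `2i − 1`,
outputs concatenated channel-wise), pooling present/absent and max/avg,
hidden FC present/absent. Continuous genes map to integer
hyperparameters by bounded denormalization

    V_i = round(L_i + (U_i − L_i) · P_i)

with the default ranges: serial conv FS ∈ [2, 8], NF ∈ [8, 512],
S ∈ [1, 3]; multi-branch NB ∈ [2, 4], NF ∈ [4, 128]; pool FS ∈ [1, 7],
S ∈ [1, 3]; FC neurons NN ∈ [10, 512]. Decoded architectures are
*repaired* (layers that cannot be applied to the current feature-map
size are removed), checked against hardware budgets (parameter count,
peak activation cells), trained under a fixed protocol (SGD with
momentum 0.9, initial learning rate 1e-4 dropped 20% every 5 epochs,
batch 32, L2 1e-4), and scored by the loss

    L = 1 − A_model

which the particle swarm minimizes with the standard updates

    V(t+1) = ω V(t) + c1 r1 (P_best − X(t)) + c2 r2 (G_best − X(t))
    X(t+1) = X(t) + V(t+1)

Search runs a two-stage protocol: candidates are screened with short
trainings on a 200-per-class subsample; the winner is retrained in full
and reported with confusion matrix, per-class/macro precision, recall,
F1, specificity, one-vs-rest ROC-AUC and Cohen's kappa.

A compiled (RcppArmadillo) CNN backend — SAME-padded convolutions,
VALID-padded pooling, global-average-pool classifier head, softmax
cross-entropy — makes the whole loop self-contained and deterministic
under a seed.

## Worked example

Reconstruct the published best 224×224 model (`CNN224_5_40`, named
`CNN{input}_{particles}_{iterations}`) from its hyperparameters via the
inverse mapping and inspect its accounting:

```r
library(sadasnet)
ref <- cnn224_5_40()
cmd_describe(ref$arch)
#>  no                           layer        type out_h out_w out_c ... parameters
#>   1           multibranch 1/3 (1x1) conv_branch   224   224    87           348
#>   2           multibranch 2/3 (3x3) conv_branch   224   224    87          2436
#>   3           multibranch 3/3 (5x5) conv_branch   224   224    87          6612
#>   4          max pool 1x1, stride 2        pool   112   112   261             0
#>   5 conv 6x6, 112 filters, stride 2        conv    56    56   112       1052464
#>  ...
#>  20         fc, 7 classes (softmax)      output     1     1     7           595
#> total parameters: 4,465,082
```

The first block is a 3-branch convolution with 87 filters per branch
(3 × 87 = 261 concatenated channels); the 1×1 branch over the RGB input
costs 1·1·3·87 + 87 = 348 learnable values; the final classifier maps
the 84 globally pooled channels to 7 classes (84·7 + 7 = 595).

Run a complete desk-scale search on generated data (seconds on one CPU):

```r
cfg <- desk_run_config(seed = 1)   # synthetic 4-class 16x16, swarm 4 x 6
rdir <- cmd_search(cfg, out_dir = "runs")
res <- attr(rdir, "result")
print(res$best_arch)
#> <arch_spec> input 16x16x3, 4 classes, 4 layer(s) + head
#>  ...
#> total parameters: 17,083
print(res$report)
#> <eval_report> n = 80 | accuracy 1.0000 | macro F1 1.0000 | macro AUC 1.0000 | kappa 1.0000 | loss 0.0000
```

The run directory contains `config.json`, `architecture.json`,
`convergence.csv`, `report.json`, `confusion.csv`, per-class ROC CSVs
and `run.log`, so any artifact can be regenerated from the snapshot.

A thin CLI wraps the same functions
(`inst/cli/sadasnet search|describe|evaluate|synth`), configured by a
YAML file (see `?read_run_config`); real image folders are read from a
HAM10000-style metadata CSV (`image_id`, `dx`) with
`load_image_folder()`.

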