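---
title: "Selective and adaptive CNN architecture search: model, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective and adaptive CNN architecture search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sadasnet)
```

## The problem and the model

Hand-designing a CNN for multi-class dermoscopy classification couples
two hard choices: the macro-architecture (how serial convolutions,
inception-style multi-branch blocks, pooling and fully connected layers
are arranged) and the per-layer hyperparameters (kernel sizes, filter
counts, strides, neuron counts). This package treats both as a single
continuous optimization problem. A candidate is a *genome*
$P \in [0,1]^D$; a particle swarm moves a population of genomes through
the unit hypercube, and each position decodes to a concrete,
trainable network.

**Encoding.** The genome is laid out as one contiguous gene group per
*macro slot* — seven convolution genes (a control gene plus the serial
parameters FS, NF, S and the multi-branch parameters NB, FS, NF) and
four pooling genes (control, type, FS, S) — followed by two genes
(control, NN) per fully connected slot. The control genes make the
encoding *selective*: conv control 1 reads the serial genes, 2 reads the
multi-branch genes; pool and FC controls toggle their layers. Genes not
selected by a control still travel with the particle ("silent genes"),
which keeps $D$ fixed — a requirement for swarm arithmetic — and is the
standard indirect-encoding treatment of conditional search spaces. With
the default 13 macro slots and one FC slot, $D = 13 \cdot 11 + 2 = 145$.

**Denormalization.** A gene $P_i$ maps to its integer hyperparameter by
$V_i = \mathrm{round}\!\left(L_i + (U_i - L_i)\,P_i\right)$ over the
bounds $[L_i, U_i]$ of its range. We round half *away from zero* (for
these nonnegative quantities, `floor(x + 0.5)`): base R's half-to-even
would map e.g. the exact midpoint of an odd-width range down, and the
chosen rule is the common reading of "round" in numeric software; it is
fixed here so that decoded architectures are bit-reproducible. The
inverse map `normalize_value()` makes the quantization exact: every
integer in a range round-trips, which is also how the published
reference model `cnn224_5_40()` is reconstructed from its printed
hyperparameters.

**Default ranges.** Serial convolutions: control $\in [1,2]$,
FS $\in [2,8]$, NF $\in [8,512]$, stride $\in [1,3]$. Multi-branch:
NB $\in [2,4]$, FS $\in [2,8]$, NF $\in [4,128]$ per branch. Pooling:
control $\in [0,1]$, type $\in [1,2]$ (max/average), FS $\in [1,7]$,
stride $\in [1,3]$. Fully connected: control $\in [0,1]$,
NN $\in [10,512]$. All are user-overridable per run.

## Decoding conventions

Several conventions are underdetermined by the encoding alone; the
package fixes them as follows, chosen so that the reconstructed
reference model's per-layer parameter counts come out exactly:

* **Multi-branch kernels.** Branch $i$ uses kernel $2i-1$ (1, 3, 5, 7),
  stride 1, and the branch outputs are concatenated channel-wise, so a
  block emits $NB \times NF$ channels. This 1/3/5/7 ladder is the only
  pattern consistent with the reference model's branch tables. The
  multi-branch FS gene is therefore decoded and stored
  (`decoded_filter_size`) but does not influence the kernels; it is
  retained in the genome so the layout is stable if a future variant
  gives it meaning.
* **Activations and normalization.** Every convolution carries biases
  and is followed by ReLU; there is no batch normalization. Parameter
  counts of the reference model match bias-carrying convolutions with
  no normalization parameters, so none are introduced.
* **Classifier head.** Global average pooling to $1 \times 1 \times C$,
  then (optional hidden FC layers, ReLU), then an FC layer to the class
  count with softmax. The reference classifier's 595 parameters equal
  $C \cdot K + K$ with $C = 84$, $K = 7$, which implies the spatial
  collapse.
* **Padding.** Convolutions use SAME zero padding
  ($\text{out} = \lceil \text{in}/s \rceil$; matches the reference
  model's 110 → 55 at stride 2); pooling uses VALID padding
  ($\lfloor(\text{in} - FS)/s\rfloor + 1$; matches 26 → 12 with FS 4,
  stride 2). One printed pooling row of the reference table (a 1×1
  window halving 224 to 110) is inconsistent with any standard
  convention; since pooling carries no parameters, this affects only
  the printed spatial trace, not the accounting.
* **Repair.** A pooling window larger than the remaining spatial extent
  makes a layer inapplicable; such layers are removed in order and
  propagation resumes. Repair always succeeds (a classifier-only model
  is valid), is idempotent, and logs removals.
* **Feasibility.** "Fits the hardware" is proxied by two budgets —
  total learnable parameters and peak activation cells
  ($\max H \cdot W \cdot C$ over input and all layer outputs) — so the
  check is hardware-independent and testable. Defaults (2e7 parameters,
  5e7 cells) comfortably admit the 224-scale reference model; failing
  candidates are assigned worst-case fitness 1 and never trained.

## The swarm

Velocities and positions follow the canonical updates
$V^{t+1} = \omega V^t + c_1 r_1 (P_{best} - X^t) + c_2 r_2 (G_{best} - X^t)$,
$X^{t+1} = X^t + V^{t+1}$, minimizing the training loss
$L = 1 - A_{model}$. Parameters the swarm literature leaves open are
set to widely used, stable values, all configurable:

* $\omega$ decays linearly 0.9 → 0.4 over the run; $c_1 = c_2 =
  1.49445$ (constriction-adjacent values).
* $r_1, r_2 \sim U(0,1)$ are drawn per particle per iteration as
  scalars applied to all coordinates, matching the scalar notation of
  the update rule; a per-coordinate variant is available
  (`per_coordinate_r = TRUE`).
* Velocities are clamped elementwise to ±0.2 (20% of the unit range) to
  prevent bound-bouncing in the hypercube; initial velocities are
  uniform within the clamp.
* Positions are clipped into $[0,1]$ after each move and the clipped
  coordinate's velocity is zeroed — this keeps the denormalization
  precondition satisfied without rejection sampling.
* Ties: on equal fitness the earlier-evaluated candidate keeps the
  personal/global best, making runs deterministic under a seed.
* Termination: a fixed iteration budget, or early when the global best
  reaches `stop_threshold` (default 0, i.e. a perfect candidate).
  Population × iterations is the evaluation budget: 5 × 40 and 10 × 20
  both spend 200 trainings.

## Training protocol and fitness

Candidates train with SGD with momentum 0.9, initial learning rate
1e-4, batch 32, L2 1e-4, and a piecewise schedule that multiplies the
rate by 0.8 every 5 epochs — "reduced by 20% every 5 epochs" is read
multiplicatively, the only reading that composes over repeated drops.
Validation accuracy/loss are recorded every 50 iterations. The data
protocol is an 80/20 stratified train/test split with 10% of the
training pool held out for validation. Search uses two stages:
screening trains each candidate 5 epochs on a 200-per-class subsample;
the winner retrains 50 epochs on the full data.

Stage-1 fitness is measured on the test split, which follows the
protocol this package reimplements but leaks test information into the
search; `fitness_split = "validation"` is provided and recommended when
the final test estimate must be unbiased.

The compiled backend applies L2 to weights only (biases are
unregularized, the common framework default), initializes with
He-normal draws, computes softmax cross-entropy with log-sum-exp
stabilization, and runs single-threaded in single precision — all
randomness (weight init, batch order, swarm draws) flows from R's RNG,
so equal seeds give bit-equal runs. Per-class accuracy in reports is
one-vs-rest accuracy $(TP + TN)/N$; ROC-AUC uses the midrank
(Mann–Whitney) statistic, equivalent to the trapezoidal ROC integral
with ties at midranks; Cohen's kappa is $(p_o - p_e)/(1 - p_e)$.

## Class balancing

Dermoscopy datasets are heavily imbalanced (the seven-class reference
corpus ranges from 6705 nevi down to 115 dermatofibromas).
`balance_plan()` targets the majority count; `balance_dataset()` fills
each deficit with flagged-synthetic images. The default strategy
oversamples originals with label-preserving transforms (flips,
right-angle rotations, intensity jitter). A conditional generator — for
instance a trained conditional GAN, which is what a full-scale run
would use — plugs into the same seat as any
`function(class_index, n)` returning images; training such a generator
is out of scope here, so the pipeline stays testable without
adversarial training. Balancing before the split mirrors the reference
protocol but lets augmented kin of one image land on both sides of the
train/test boundary; balancing only the training side (split first,
then balance) avoids that and is the stricter option. Both orders are
supported (`balance = "before_split"` / `"none"` plus manual
balancing of any subset).

## The synthetic generator

`generate_synthetic()` is the desk-scale stand-in for dermoscopy
photographs. Class $k$'s images share a deterministic pattern — oriented
stripes whose angle and spatial frequency are keyed to $k$, a Gaussian
blob at a class-specific position, and a class-specific channel mix —
scaled by `separability`, plus i.i.d. Gaussian pixel noise
(`noise_sigma`, default 8 intensity units), clipped to 0–255 and
quantized. At `separability = 1` a small CNN reaches near-perfect test
accuracy; as separability approaches 0 the pattern vanishes under the
noise and accuracy falls to $1/K$. The generator emulates the *format*
and class-conditional structure of the real task, not its substance: it
has none of the intra-class variability, class overlap, acquisition
artifacts or long-tailed difficulty of real lesions. Passing tests on
it therefore validate the machinery — encoding, decoding, training,
search dynamics, reporting — and say nothing about clinical
performance.

## Desk-scale configuration

`desk_run_config()` is the package's self-contained demonstration and
test workload, sized to run in seconds on a single CPU core: 4 classes
of 100 synthetic 16×16 images, a 3-macro-slot search space with filter
counts capped at 32 (serial) / 16 (per branch) and hidden layers at 64
neurons — a 16-pixel input cannot use 13 downsampling stages, and the
caps keep candidate FLOPs proportionate to the image size — a
4-particle × 6-iteration swarm, 3-epoch screening, 10-epoch final
training, and budgets of 2e5 parameters / 2e4 activation cells. The
learning rate is 0.01: the full-scale protocol's 1e-4 is tuned to long
schedules on large data, while tiny networks on small images need a
conventional small-CNN rate to move in a 3–10-epoch schedule. These
sizes are also what the heavier tests use (e.g. the end-to-end search
property runs three seeds of this configuration; the
backend-vs-accounting equivalence sweeps 100 random genomes of this
space).

## Known limitations

* The training backend is a compact single-threaded CPU implementation;
  it is exact and deterministic but not fast enough for 224-scale
  corpora — full-scale runs would swap in a GPU backend behind the same
  `net_plan()`/weights interface.
* The search space has no skip/residual connections, attention or
  depthwise convolutions, by design.
* FLOP accounting (`count_flops()`) uses the documented
  2-FLOPs-per-MAC convention with pooling at zero; published FLOP
  figures for comparable models vary by convention, so cross-paper FLOP
  comparisons need care.
* No early stopping is implemented; the validation trace is recorded
  but only monitors training.
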