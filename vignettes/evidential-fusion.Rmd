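---
title: "Evidential fusion of texture and deep classifiers for mammographic mass phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidential fusion of texture and deep classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsmammo)
```

## The problem

Mammographic mass diagnosis is a three-way decision: a mass is *benign*,
*malignant*, or the evidence does not support either call — the *ignorant*
class, which this package (following common CAD practice for normal tissue)
trains on mass-free images. Benign masses present smooth, uniform margins;
malignant masses present sharp, spiculated ("needle-like") margins. A single
classifier gives a point probability for each class but no account of how
much of its probability is really commitment versus confusion. `dsmammo`
runs two deliberately different classifiers — a multilayer perceptron (MLP)
over gray-level co-occurrence matrix (GLCM) texture statistics, and a small
convolutional network (CNN) over the pixels — and combines their
probability triples with Dempster–Shafer (DS) evidence theory, which models
the ignorant share of belief explicitly and rewards agreement between
independent sources.

## The evidence model

Each classifier's output for one image is a probability triple
$(p_B, p_M, p_I)$. It is mapped, unchanged (no discounting), to a basic
probability assignment $m$ over the focal elements $\{B\}$, $\{M\}$ and
"ignorance". Two readings of ignorance are implemented because the frame
can be set up either way:

* **`disjoint_singleton`** (default): ignorance is a third, pairwise
  disjoint hypothesis. Every cross-class product conflicts, so for two
  masses $m_1, m_2$ the conflict is
  $k = 1 - \sum_x m_1(x)\,m_2(x)$ and the combined mass is
  $m(x) = m_1(x)\,m_2(x) / (1-k)$.
* **`classical_ds`**: ignorance is the whole frame
  $\Theta = \{B, M\}$. Only $\{B\}\times\{M\}$ products conflict,
  $m(B) \propto m_1(B)m_2(B) + m_1(B)m_2(\Theta) + m_1(\Theta)m_2(B)$
  (likewise for $M$), $m(\Theta) \propto m_1(\Theta)m_2(\Theta)$, and the
  vacuous mass $(0,0,1)$ is the identity of the rule.

In both variants $K = 1/(1-k)$ renormalizes the agreement mass, and the
decision is the argmax of the combined masses, with ties broken by the fixed
class order (benign, malignant, ignorance) and flagged. At $k = 1$
(total conflict) Dempster's rule is undefined; per-sample fusion flags the
sample and falls back to the more confident single source so the pipeline
still emits a decision.

The choice to ship *both* variants rather than pick one is deliberate: with
three singleton classes the combination degenerates to a product rule, while
the classical reading gives ignorance its usual role as uncommitted belief;
which one a study intends is often ambiguous, and the two differ exactly in
how ignorance interacts with the committed masses.

```{r ds-example}
m1 <- mass_function(0.8, 0.1, 0.1)
m2 <- mass_function(0.6, 0.3, 0.1)
ds_combine(m1, m2, ds_frame("disjoint_singleton"))
ds_combine(m1, m2, ds_frame("classical_ds"))
```

## Preprocessing

* **Median filter** (`median_filter`): 3×3 window by default, replicate
  border padding so no artificial dark rim appears at the edge. Removes the
  salt-and-pepper impulses typical of digitized film.
* **Histogram equalization** (`equalize`): with histogram $h(x)$,
  density $p(x) = h(x)/N$ and cumulative $c(x) = \sum_{k\le x} p(k)$, the
  transfer is $f(x) = x_0 + (x_{L-1} - x_0)\,c(x)$ over the full dynamic
  range $[0, L-1]$, rounded half-up and clipped. The transfer is monotone
  nondecreasing by construction. (A commonly printed variant of this
  formula with a `+` in place of the `-` is dimensionally inconsistent and
  cannot map onto the stated range; the standard form is used.)
* **ROI extraction** (`extract_roi`): binarize (Otsu's threshold unless
  overridden), erode with a flat diamond structuring element of city-block
  radius 3, keep the largest 8-connected component, zero the background.

## Texture features

`compute_glcm` counts co-occurrences of quantized gray levels at distance
$d$ (default 1) along the four standard angles, symmetrizes and normalizes.
Intensities are uniformly re-binned to 16 levels first — full 8-bit
resolution makes small-image matrices too sparse for stable statistics.
`haralick_features` evaluates 22 scalar statistics (contrast
$\sum (i-j)^2 P_{ij}$, energy $\sum P_{ij}^2$, entropy
$-\sum P_{ij}\log P_{ij}$, homogeneity, correlation in its two standard
computational forms, cluster shade/prominence, the sum/difference
histogram statistics, the two information measures of correlation, and the
inverse-difference family), with the $0\log 0 = 0$ convention. Features are
averaged over the four angles by default (rotation-robust); concatenation
per angle is available. A sometimes-quoted figure of 59 MLP inputs cannot
be reconstructed from any standard feature list, so the feature dimension
is deliberately configuration-driven and the MLP input size follows the
feature table (22 by default).

## The two classifiers

**MLP** (`train_mlp`): two hidden layers of 10 sigmoid units, sigmoid
output units, trained by full-batch backpropagation on mean squared error
against one-hot targets. Features are z-scored with training-set statistics.
The three output activations are renormalized to sum to one, giving the
probability-triple contract that fusion needs. Defaults: 600 epochs,
learning rate 0.8 on standardized features; backpropagation is verified
against central finite differences in the test suite.

**CNN** (`train_cnn`): four convolution blocks — 16, 32, 32, 64 filters
with 28×28, 14×14, 7×7 and 4×4 kernels, stride 1, 'same' padding — each
followed by batch normalization, ReLU and 2×2 stride-2 pooling (max in
blocks 1–3, average in block 4), then a 100-unit fully-connected layer, a
3-unit output layer and softmax, trained with cross-entropy. Grayscale
input is replicated to three channels. Three numerical choices matter:

* *Input scale.* The nominal 512×512 input is desk-scaled to 32×32, and by
  default the central half of the field is cropped before resizing
  (`crop_frac = 0.5`). Mass-classification CAD conventionally works on a
  patch around the lesion rather than the whole field; the phantoms place
  the mass centrally, so the centered crop plays that role and halves the
  downscaling that the margin detail must survive.
* *Augmentation.* Each training batch is passed through a random dihedral
  transform (flips/right-angle rotations). With ~120 training images per
  fold the network otherwise memorizes; the mass phenotypes are invariant
  under these transforms, so the augmentation is label-preserving.
* *Normalization statistics.* After the last epoch the batch-normalization
  statistics are recomputed as population statistics over the full training
  set (each block computed from the previous blocks' population-normalized
  outputs). With few, small batches an exponential running average is far
  from the statistics the trained weights assume, and inference accuracy
  collapses; the population pass removes that mismatch exactly.

Defaults (10 epochs, minibatch 8, SGD momentum 0.9, learning rate 0.01)
were fixed once against a held-out phantom split and are documented rather
than tuned per run. Training is bit-deterministic given the config seed.

## The phantom generator

`generate_phantom` builds, in order: smoothed-uniform background texture
(correlation length 8 px, mean ≈ 90, s.d. ≈ 18 intensity units), the
class-specific mass (benign: disc of radius `image_size/8` Gaussian-blurred
with $\sigma = r/4$; malignant: sharp disc plus ≥ 4 radial spicules of
length $1.5r$; ignorant: background only), additive Gaussian noise
($\sigma = 6$), then salt-and-pepper impulses (2 % of pixels). Noise is
always last. The defaults are the package's study conditions; they were
chosen once as plausible desk-scale analogues of digitized-film mammograms
and are not adjusted per experiment.

What the phantoms do emulate: the margin-sharpness contrast between the
two mass classes (verified by a Sobel ring statistic in the tests), textured
background that gives GLCM features nontrivial values, and film-like noise.
What they do not: breast anatomy, pectoral muscle, calcifications,
location variability of masses, intensity calibration of real mammograms.
Passing tests therefore demonstrate that the pipeline's machinery works and
that fusion behaves as the theory predicts — not that any particular
accuracy transfers to clinical data.

`simulate_source_pair` generates aligned probability triples from two
pseudo-classifiers with controllable top-class accuracies and error
correlation (comonotone-uniform coupling; correlation 1 with equal
accuracies makes the two sources err on exactly the same samples). Triples
are Dirichlet draws concentrated on the assigned class; if the draw's
argmax lands elsewhere the two entries are swapped, so realized accuracy
equals nominal accuracy exactly rather than merely in expectation.
Erroneous outputs are drawn at a third of the concentration. This mirrors
real classifiers, whose errors are low-margin, and it is what makes
decision-level fusion worthwhile at all: if wrong answers were as confident
as right ones, the triples would carry no information beyond the argmax and
no combination rule could beat the better single source.

## Evaluation

`kfold_split` builds stratified k-folds by dealing each class's shuffled
indices round-robin with a rotating starting fold, so fold sizes differ by
at most one overall and within each class (115 samples in 5 folds gives
exactly 23 per fold). `run_cv_experiment` trains both classifiers per fold,
fuses the test-fold probability triples, and pools test predictions into a
single confusion matrix per method. Sensitivity and specificity are
reported one-versus-the-other-mass-class with ignorant/normal truths
excluded, mirroring how mammographic studies report their benign/malignant
cohorts; zero-denominator ratios are `NA`, never 0. ROC curves use the
positive class's probability (for the fused method, its combined mass —
a documented convention, since a hard-decision fusion has no canonical
score) with a fixed "higher is positive" direction.

## Problem sizes and runtime choices

The shipped experiments use 150 phantoms (50 per class) at 128×128 with
5-fold cross-validation, CNN input 32×32 and 10 epochs — sizes chosen so a
full run completes in minutes on one core while keeping ≥ 110 training
images per fold. The fusion-gain simulation uses 10,000 samples, where
binomial noise on an accuracy is ± 0.5 percentage points.

## Known limitations

* The CNN is a faithful but small re-implementation in R; it is adequate
  for phantom-scale studies, not for 512×512 clinical images.
* The identity mapping from classifier probabilities to masses performs no
  source discounting; a systematically overconfident source can drag the
  fusion down, which is visible when one classifier is much weaker than
  the other.
* The disjoint-singleton variant reduces Dempster's rule to a normalized
  product; its "ignorance" class is then just a third label, not
  uncommitted belief.
* Phantom realism is a fixture property: no claim about clinical data
  follows from the synthetic results.
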