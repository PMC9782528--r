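---
title: "Self-supervised class decomposition for irregular image data"
author: "ClassDecomp package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised class decomposition for irregular image data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Medical image classification tasks — colorectal histology patches, brain
MRI — routinely combine three data irregularities: *class imbalance*
(tumour epithelium outnumbers stroma three to one), *within-class
multimodality* (one nominal class contains several distinct appearance
modes), and *between-class morphological overlap* (adipose and stroma
share texture statistics near the class boundary). A classifier trained on
the nominal labels must carve a single decision region per class around a
multimodal, overlapping distribution, and the minority modes are the first
casualties.

ClassDecomp implements a transfer-learning pipeline that attacks these
irregularities on two fronts:

1. **A self-supervised pretext task.** A convolutional autoencoder (CAE)
   is trained on a large unlabelled pool of related images by minimising
   the reconstruction error
   $\mathrm{MSE}(\theta) = \frac{1}{2n}\sum_{i=1}^n \lVert x_i - \hat
   x_i\rVert^2$. Its latent representation is clustered by DBSCAN, the
   cluster ids become *pseudo-labels*, and a small CNN is pretrained
   (deep-tuning mode) to classify them. This warms up the convolutional
   body without a single manual annotation.
2. **Class decomposition.** Each labelled class is split into sub-classes
   by affinity propagation (AP) over cosine similarities of PCA-reduced
   backbone features. The classifier is then fine-tuned on the sub-class
   label space $C = \{l_{11}, \dots, l_{1c}, l_{21}, \dots\}$, which turns
   each appearance mode into its own (much more compact) decision region.
   At prediction time the sub-class softmax mass is *composed* back:
   $P(\text{class } p) = \sum_{j \in \text{children}(p)} P(l_{pj})$, and
   the arg-max over parents is the final prediction.

Grad-CAM heatmaps computed against the sub-class or composed-class scores
explain which pixels drove a prediction.

## Stage by stage

### Pseudo-labelling

The Eps radius for DBSCAN is chosen by the k-nearest-neighbour heuristic:
the mean over all points of the distance to their MinPts-th nearest
neighbour (`estimateEps()`, which also exposes the full sorted k-distance
curve). MinPts defaults to twice the feature dimension capped at 10, a
common rule of thumb that the data never contradicted at desk scale. The
closed neighbourhood convention is used: a point counts itself, so
`minPts = 1` makes every point core. Border points join the first cluster
that claims them in scan order; noise points are dropped from pretext
training by default (they can be kept as an explicit `pseudo_noise`
class).

### Decomposition

Per class — never globally, so that one class's dominant variance cannot
mask another's modes — backbone features are centred and reduced by PCA to
the smallest number of leading components reaching 95% explained
variance, and clustered by AP with damping $\lambda = 0.9$, at most 1000
iterations and a 50-iteration convergence window. The message updates are

$$\rho(i,k) = s(i,k) - \max_{k' \neq k}\{a(i,k') + s(i,k')\}, \qquad
a(i,k) = \min\Big(0,\ \rho(k,k) + \sum_{i' \notin \{i,k\}}
\max(0, \rho(i',k))\Big),$$

each damped as $\lambda \cdot \text{old} + (1-\lambda) \cdot
\text{new}$; exemplars are the points with $\rho(k,k) + a(k,k) > 0$, and
ties are always broken toward the lowest index so runs are bit
reproducible. A fixed-k k-means baseline (`kmeansDecompose()`, k = 2, ten
seeded Lloyd restarts via `stats::kmeans`) reproduces the behaviour of
earlier decomposition-based models.

Two choices here deserve explanation:

* **Preference.** The textbook default for AP's diagonal preference is
  the median off-diagonal similarity. On cosine similarities of compact,
  well-separated sub-clusters we found the median preference reliably
  *splits* genuine clusters (an 80-point planted cluster with
  within-cluster cosine ≈ 0.95 against between-cluster ≈ −0.46 splits
  40/40) — the preference is simply too generous on a bounded similarity.
  The default is therefore one off-diagonal spread below the minimum,
  $2\min(s) - \max(s)$, which only pays for an exemplar when real
  structure supports it; `"median"` and `"min"` remain selectable, and
  median is still the sensible choice for unbounded negative
  squared-Euclidean similarities.
* **Feature readout.** The decomposition features default to orderless
  texture statistics — the spatial mean and standard deviation of every
  convolutional activation map — rather than the raw penultimate dense
  activation. Dense activations at small image sizes are sensitive to
  where a texture happens to sit in the patch, which stretches each
  appearance mode into a curve that clustering fragments; pooled map
  statistics are (near-)invariant to that nuisance. Raw single-layer
  features remain available (`backboneClassFeatures(..., spatialStats =
  FALSE)`).

Cosine similarity is the vector form $\langle x_i, x_j\rangle /
(\lVert x_i\rVert\,\lVert x_j\rVert)$; a set-intersection reading of the
similarity is sometimes written in the literature but is not meaningful
for real-valued feature vectors and is not implemented.

### Training and composition

`tuneConfig()` encodes the three tuning modes: *shallow* (head only),
*fine* (top `trainableLayers` body layers plus head) and *deep*
(everything). Defaults follow the downstream regime of the method: body
learning rate $10^{-4}$, head $10^{-2}$, step decay ×0.95 every 5
epochs, momentum 0.9, weight decay 0.01, mini-batches of 50, 50 epochs.
When the dataset carries sub-class labels, epoch selection uses the
validation accuracy of the *composed* parent-level prediction
(`trainClassifier(..., composeWith = map)`): sub-class validation
accuracy penalises confusions between siblings that the composition
erases, and selecting on it measurably destabilises the final model.

The engine behind both the CAE and the CNN is a small, fully seeded
implementation of convolution (im2col + BLAS), 2×2 max-pooling with
first-claim tie-breaking, nearest-neighbour upsampling and dense layers,
trained by momentum SGD. Three numerical choices matter: weights start
uniform in $\pm\sqrt{6/\text{fan-in}}$; images enter the network centred
at zero (a pure reparameterisation — the reconstruction objective is
unchanged); and gradients are clipped to a global norm of 5, without which
the first large momentum steps kill every rectifier unit on some seeds.
Convolution uses "same" zero padding so the activation grid matches the
image grid, and the decoder may optionally tie its kernels to the
spatially flipped, channel-swapped encoder kernels (`tiedWeights`); by
default the decoder is learned independently. One bias per output map is
used throughout.

### Explanation

`gradCAM()` differentiates the **pre-softmax** class score (softmax
probabilities saturate and shrink gradients) with respect to the last
convolutional activation, pools the gradient spatially into one weight
per map, $\phi_d = \frac{1}{m}\sum_{ij} \partial x_c / \partial
A^d_{ij}$, and rectifies the weighted sum $\mathrm{ReLU}(\sum_d \phi_d
A^d)$. The map is upsampled bilinearly to the image grid and min-max
normalised; the raw values are kept alongside. Composed-class
explanations take the element-wise maximum over the parent's children so
that no child's evidence is lost.

## The synthetic study system

Real histology and MRI collections are large, external and GPU-scale; the
package instead ships a generator whose datasets exhibit the same
irregularities at desk scale. Every class is a mixture of planted
sub-clusters; every sub-cluster is a parametric texture motif — an
oriented sinusoidal grating (whole cycles per patch, orientations
equispaced over $[0, \pi)$) plus a field of Gaussian blobs at fixed
per-motif positions. Imbalance is declared directly through per
sub-cluster sample counts. Between-class overlap convexly blends each
class's motif parameters toward one shared bank: overlap 0 gives disjoint
appearance, overlap 1 collapses all classes onto the shared bank.

Per-image variability (grating phase over ±1.2 rad, orientation wobble,
blob placement) scales linearly with the noise level so that `noiseSd =
0` renders every motif deterministically — planted sub-clusters are then
recoverable exactly by nearest centroid on raw pixels, which the tests
assert. At the default `noiseSd = 0.05` sub-clusters are genuine texture
populations: without this structural variability every sub-cluster is a
stack of near-identical templates, plain supervised training saturates,
and no method comparison is informative.

Two named fixtures define the study conditions: `standardFixture()` (600
images, 3 classes, planted sub-cluster counts 4/2/3, no overlap) for
recovery checks, and `irregularFixture()` (360 images, class sizes
180/60/120 — 3:1 imbalance — with overlap 0.5) for the end-to-end
comparison. Splits are always 60/20/20 train/validation/test, stratified
per class. What the generator does **not** emulate: staining variation,
anatomical shape priors, scanner artefacts, label noise. Passing the
package's checks therefore demonstrates that the machinery works as
specified on data with planted irregular structure, not that it will
reproduce any particular clinical accuracy.

## Desk-scale problem sizes

The shipped checks use 16×16-pixel images; at that resolution the CAE
fixtures use a single convolutional block of 3 filters (latent 8×8×3 =
192 < 256 pixels — the encoder must compress). The two-block 64/32
configuration of `caeConfig()` remains the default for full-size
images, where it is a compression; at 16 px it would expand and is
rejected. The pipeline checks train the CAE for 30 epochs (batch 32,
learning rate 0.001), the pretext CNN for 10 epochs and the downstream
CNN for 20 epochs on a 300-image pool and the fixtures above; the full
paired comparison over five seeds completes in a few minutes on one CPU.

## The end-to-end comparison

`runPipeline()` executes pseudo-labels → pretext training →
decomposition → downstream fine-tuning → composition → metrics, persists
every intermediate artifact under a run directory with an md5 manifest,
and is byte-reproducible from one master seed (all stage seeds are
derived from it). `runBaseline()` is the comparison arm: identical data,
split and downstream configuration, but trained from random
initialisation with the identity decomposition — i.e., plain supervised
training of the same backbone, the conventional comparator for this
family of methods. The headline quantity is the median, over five paired
seeds, of (full pipeline accuracy − baseline accuracy) on the test
split of the irregular fixture.

If a sub-class emerges whose members all fall outside the training split,
it is merged into its class's largest training sub-cluster before
training (`ensureTrainCoverage`); classifier training requires every
label to be trainable, and a sub-class that cannot be trained cannot be
composed either.

## Known limitations

* The engine is plain R; it is sized for desk-scale images (tens of
  pixels), not 224×224 production runs — the pipeline is
  backbone-agnostic by design, and the registry accepts a trained model
  in place of the built-in small CNN.
* AP's cluster count is governed by the preference; no automatic
  preference/damping selection is attempted, and on diffuse feature
  clouds AP can still split a planted mode (the recovery checks aggregate
  by median over seeds for this reason).
* Sensitivity/specificity are macro-averaged one-vs-rest; with heavy
  imbalance micro-averages can differ, and both conventions exist in the
  literature.
* The DBSCAN implementation is the quadratic textbook algorithm — right
  for hundreds of points, wrong for millions.
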