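---
title: "Methods: convolutional sparse coding of histopathology tiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convolutional sparse coding of histopathology tiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Hematoxylin-and-eosin (H&E) pathology slides differ from natural
photographs in both spectral range (a two-stain purple/pink palette) and
spatial structure (nuclei, membranes, stroma at characteristic scales), so
feature dictionaries trained on natural images are unlikely to be optimal
for them. **histosparse** instead learns its features directly from
unlabeled tissue tiles by convolutional sparse coding, and feeds the
resulting representations to deliberately shallow classifiers so the
discriminative power of the representation itself is what is measured.

The representation of an image $I$ is the set of feature maps $a$ that
minimizes

$$E(I, \phi, a) = \tfrac{1}{2}\,\lVert I - \phi * a \rVert^2
  + \lambda \lVert a \rVert_1,$$

where $\phi$ is a dictionary of square convolutional kernels replicated
across the image at a fixed stride, $\phi * a$ is the transposed-convolution
superposition of kernels weighted by coefficients, and $\lambda$ trades
reconstruction fidelity against sparsity. With the default geometry —
512 kernels of $32 \times 32 \times 3$ pixels at stride 4 — a
$2048 \times 2048$ RGB tile maps to $512$ feature maps of $512 \times 512$
coefficients, of which only a few percent are nonzero.

### Inference: the Locally Competitive Algorithm

`encode()` minimizes $E$ over $a$ with a convolutional Locally Competitive
Algorithm (LCA). Internal membrane potentials $u$ integrate the residual
drive in leaky fashion,

$$u \leftarrow u + \frac{dt}{\tau}\Big(\Phi^\top (I - \phi * a) + a - u\Big),
  \qquad a = \mathrm{soft}(u, \lambda),$$

where $\Phi^\top(\cdot)$ is the stride-matched correlation of the residual
with every kernel and $\mathrm{soft}$ is the shrinkage operator
$\operatorname{sign}(u)\max(|u| - \lambda, 0)$, the proximal map of the L1
penalty. This residual form never materializes the lateral-competition
Gram matrix, which would be prohibitively large for convolutional
dictionaries. Because the objective is the convex (for fixed $\phi$)
convolutional LASSO, the fixed points of these dynamics are its global
minimizers; the test suite verifies on batches of random instances that
the final LCA energy matches an independent FISTA solver run on an
explicitly materialized convolution matrix to well under 1%.

Numerical choices that matter:

* **Step size** `dt_over_tau`: default 0.05 (0.1 is still safely stable
  for every geometry used here). The energy trace is asserted
  non-increasing after a 5-step burn-in in every synthetic test.
* **Stopping**: iteration ends at `n_iterations` (default 400) or when the
  relative energy change drops below `tolerance` (default `1e-4`). The
  check only engages once at least one coefficient has activated and one
  membrane time constant ($\lceil \tau/dt \rceil$ steps) has elapsed:
  before the first threshold crossing the energy is exactly flat while
  potentials are still charging, and a naive plateau test would return the
  all-zero code.
* **$\lambda$** (default 0.15 for `[0,1]` inputs): exposed everywhere; the
  nonzero fraction is asserted monotone non-increasing over the grid
  $\{0.05, 0.1, 0.2, 0.4\}$.
* **Input normalization**: the per-tile, per-channel mean is subtracted
  before encoding (no whitening). Kernels must be unit-norm;
  `encode()` refuses unnormalized dictionaries rather than silently
  rescaling the effective $\lambda$ per atom.
* **Padding**: zero-padded "same"-style placement so the map side is
  $\lceil H/s \rceil$ — this is what makes 2048 px at stride 4 give exactly
  512, rather than the 505 of a valid convolution. The padding offset is
  $\lfloor (k - s)/2 \rfloor$.

### Dictionary learning

`train_dictionary()` alternates LCA inference with a Hebbian stochastic
gradient step: each kernel moves along the correlation of the
reconstruction residual with its own active coefficients — the exact
negative gradient of $\tfrac12 \lVert I - \phi * a\rVert^2$, verified in
tests against central finite differences. Because that gradient is a sum
over every map position, its magnitude grows with image area; the step is
therefore normalized by the code's total activation power $\sum a^2$,
making the learning rate dimensionless — the same value is stable on a
32 px planted image and a full-size tile, where the raw gradient at any
fixed rate either diverges or stalls depending on scale. Updates are
applied per tile (true SGD), the normalized learning rate decays as
$1/\text{epoch}$ from a default of
0.5, and kernels are renormalized to unit norm after every update
(`normalize_every` exposes batched renormalization). Unit-norm
renormalization removes the scale drift that the L1/L2 alternation would
otherwise allow (kernels growing while coefficients shrink). Learning is
unsupervised by construction — the training API has no label argument —
and, mirroring common practice for generic feature learning, the default
workflow allows training tiles to include eventual test tiles; a clean
split can be enforced simply by passing disjoint tile lists.

Kernels are initialized from a seeded standard normal and unit-normalized.
On planted instances (known random smooth dictionary, exact-sparsity codes,
images synthesized as $\phi * a$ plus optional noise) training with 8 atoms
on 200 clean $32 \times 32$ images recovers every planted atom with
absolute cosine similarity above 0.8 under sign/permutation matching; for
these recovery runs a smaller $\lambda$ (0.05) and a larger step (1.0) over
20 epochs work noticeably better than the encoding defaults — with
$\lambda$ at 0.15 an atom can stay dormant (never crossing threshold, hence
never updated) while its energy is absorbed by correlated neighbors.
Recovery quality degrades smoothly as planted noise grows through
$\{0, 0.05, 0.1\}$.

### ROI extraction

Slides arrive as multi-level `slide_image` pyramids (flat PNG/TIFF rasters
are one-level slides). Selection runs on the lowest-resolution level:
Rec. 709 luminance, Otsu binarization (threshold maximizing between-class
variance over a 256-bin histogram; constant images raise a
`degenerate histogram` error), then the tissue fraction of every candidate
window via zero-padded FFT convolution with a box kernel. Densities are
rounded to 12 decimals before ranking so the FFT path agrees bit-for-bit
with direct counting; ties in the greedy argmax break toward the smallest
row-major index. Selection is greedy: take the global maximum, invalidate
every overlapping position, repeat; windows below a density floor of 0.05
are never selected, which is what makes "non-empty regions only"
a testable contract. Chosen windows are lifted to level 0, clamped to the
slide extent by shifting inward (never shrinking, so the tile size stays
constant), cropped, and resampled so the tile equals the target size at
the target magnification (crop side $= \text{target} \cdot
\text{objective power}/\text{target power}$; area averaging for integer
downscales, bilinear otherwise). The low-resolution window side is the
lifted side divided by the level downsample — the full-scale default of
four 2048 px tiles per slide at 20X falls out of these rules.

### Pooling and classification

`average_pool()` reduces each feature map to its plain mean — zeros
included, so the value mixes activation frequency with amplitude — giving
one 512-element vector per tile that is invariant to spatial permutations
of each map. Max pooling (signed maximum of $|a|$) and per-feature
histograms of nonzero coefficients (16 uniform bins over $\pm 3\sigma$ of
training-set nonzeros) are provided as controls. On real histology data
average pooling has been observed to classify better than the
alternatives; the synthetic generator cannot reproduce that ordering —
its class signal is a nucleus *count*, which per-feature activation
histograms capture directly, so histogram pooling is at least as accurate
there by construction. The suite therefore asserts that every pooling
variant yields a clearly learnable representation on synthetic data, and
leaves the ranking of variants to real data.

Two classifiers consume the pooled vectors, split 5:1 train:test
(`split_spec(test_fraction = 1/6)`): a linear SVM (libsvm, hinge loss,
train-set standardization) and a one-hidden-layer MLP — 512 ReLU units by
default, a dropout layer (rate 0.5) active only during training, and a
2-way softmax trained with cross-entropy (Adam, batch 32, at most 100
epochs, early stopping on a 10% stratified validation carve-out). The MLP
is implemented in plain matrix algebra inside the package so that dropout,
determinism-under-seed, and early stopping behave exactly as documented.
`error_reduction()` converts an accuracy pair into the fraction of
baseline error eliminated: for the published pair (85.48, 93.32) it gives
53.99 ≈ 54%.

The default split treats tiles as independent samples even when several
come from one slide/patient; `group_aware = TRUE` keeps whole groups on
one side. Per-patient leakage can inflate tile-level accuracy, so grouped
evaluation is the honest choice when group structure exists — the default
merely mirrors the common tile-as-sample convention, and both are tested.

## What the synthetic generator emulates — and what it does not

`generate_slide()` renders the gross statistics the pipeline relies on: a
near-white background (≥ 0.95 before noise), several soft-edged dark
tissue disks filled with pink stroma texture (low-pass-filtered Gaussian
noise over the eosin tone) and anti-aliased dark-purple nuclear dots of
2–5 px radius, plus additive Gaussian pixel noise (sd 0.02). The two
classes differ only in nucleus density: 5 (normal) versus 15 (tumor) dots
per 1000 px², a deliberately planted 3× separability. Tiles from one
synthetic "patient" share a base placement seed (four tiles per group,
matching four ROIs per slide), enabling grouped-split experiments. Pixel
values are floating point in `[0, 1]` throughout; quantization to 8 bits
happens only at PNG I/O.

This emulation is statistical, not histological: there is no tissue
architecture, no stain covariation, no pen marks, folds, blur or scanner
artifacts, and the class signal is a single univariate knob rather than
the diffuse morphological differences of real tumors. Passing the
end-to-end tests therefore shows that the machinery — density-based ROI
selection, energy minimization, pooling, classification — transmits a
planted signal faithfully; it does not certify any particular accuracy on
real slides, and published TCGA-scale accuracies (in the 84–93% range)
are explicitly not reproduced here, as they depend on thousands of
real-patient ROIs.

## Problem sizes used in the shipped checks

Chosen as the smallest sizes at which each property is cleanly
measurable: solver-versus-FISTA comparisons on twenty $32 \times 32$
instances with 8 kernels; planted recovery from 200 such images; the
end-to-end run with 100 tiles per class at $256 \times 256$ px and a
reduced 64-kernel, 16 px dictionary (50 LCA iterations), which lands MLP
accuracy well above 90% against a 50% chance rate and collapses to chance
under label shuffling; and a single full-geometry encode of a
$2048 \times 2048$ tile against the default 512-kernel dictionary to pin
the 512×512×512 map shape. `scripts/acceptance.R` reruns the pipeline at
50 tiles per class and writes every quantity it computes as JSON.

## Known limitations

* SVS/pyramidal slide reading is out of scope; bring PNG/TIFF levels.
* Dead atoms are not pruned or reseeded during dictionary learning.
* The LCA is the soft-threshold (L1) variant only; hard-threshold,
  non-negative and topographic variants are not implemented.
* Dictionaries serialize via R's RDS; the in-memory layout
  (`kernels[kh, kw, channels, n_features]`, `stride`, `normalized`) is
  documented for interoperability rather than using a cross-language
  binary container.
* Accuracy is the only evaluation metric, matching the design's focus on
  representation quality; ROC/calibration analysis is left to the caller.
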