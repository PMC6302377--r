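# histosparse

Convolutional sparse coding of histopathology tiles, with shallow
classification of the resulting representations.

## What problem this solves, and for whom

Whole-slide H&E pathology images are huge, non-uniform, mostly empty, and
scarcely labeled, and their color/texture statistics differ sharply from
the natural photographs that standard pretrained CNN features were
optimized for. For researchers who want tumor/non-tumor discrimination
without supervised feature learning, **histosparse** implements the
alternative: learn an overcomplete dictionary of convolutional feature
kernels *directly from unlabeled tissue tiles* by sparse-coding energy
minimization, infer each tile's sparse feature maps, pool them to a
fixed-length descriptor, and hand that to a deliberately shallow
classifier (linear SVM, or a one-hidden-layer MLP with dropout and
softmax). The shallow head makes the representation itself — not extra
nonlinear modeling — carry the discriminative load.

The pipeline:

1. **ROI extraction** — `extract_slide_rois()`: Otsu binarization of the
   low-resolution level, per-window tissue density by FFT convolution,
   greedy selection of the darkest non-overlapping square windows, lifting
   to full resolution and resampling to a fixed tile size (default
   2048 px at 20X equivalent, four ROIs per slide).
2. **Sparse inference** — `encode()`: minimize
   `E(I, φ, a) = ½‖I − φ∗a‖² + λ‖a‖₁` over feature maps `a` with a
   convolutional Locally Competitive Algorithm (membrane potentials driven
   by the residual correlation, soft-thresholded activations). Default
   geometry: 512 kernels of 32×32×3 at stride 4, so a 2048² tile yields
   512 feature maps of 512×512, a few percent nonzero.
3. **Dictionary learning** — `train_dictionary()`: alternate LCA inference
   with Hebbian SGD on the kernels (the negative reconstruction-error
   gradient, activation-power normalized, unit-norm kernels). Entirely
   unsupervised.
4. **Pooling & classification** — `pool_features()` (average pooling by
   default), `split_dataset()` (5:1 train:test), `train_linear_svm()` /
   `train_mlp()`, `evaluate()`, and `error_reduction()` for comparing
   classifiers by the fraction of baseline error they eliminate.

A synthetic data module (`generate_slide()`, `generate_tile_dataset()`,
`generate_planted()`) renders stain-like imagery — white background, dark
tissue blobs, pink stroma, purple nucleus dots whose density separates
the two classes — plus planted-dictionary instances with known ground
truth, so the whole pipeline is testable end to end without slide data.

## Worked example

Synthetic two-class tiles, a briefly trained reduced dictionary, sparse
codes, pooled features, both classifiers:

```r
library(histosparse)

ds  <- generate_tile_dataset(30, tile = 64, seed = 7)   # 60 tiles, 2 classes
cfg <- train_config(n_features = 16, kernel = 8, stride = 4, lambda = 0.3,
                    learning_rate = 0.5, n_epochs = 2, seed = 3)
lca <- lca_config(lambda = 0.3, dt_over_tau = 0.1, n_iterations = 60)

fit   <- train_dictionary(ds$tiles[1:20], cfg, lca = lca)  # unsupervised
codes <- lapply(ds$tiles, encode, dict = fit$dictionary, cfg = lca)
feats <- pool_features(codes, ds$manifest)                 # 16-element vectors

parts <- split_dataset(feats, split_spec(seed = 1))        # 5:1 split
glance(evaluate(train_linear_svm(parts$train), parts$test))
#> # A tibble: 1 × 5
#>   classifier accuracy chance_rate n_train n_test
#>   <chr>         <dbl>       <dbl>   <int>  <int>
#> 1 svm             100          50      50     10
glance(evaluate(train_mlp(parts$train, hidden = 64, seed = 2), parts$test))
#> # A tibble: 1 × 5
#>   classifier accuracy chance_rate n_train n_test
#>   <chr>         <dbl>       <dbl>   <int>  <int>
#> 1 mlp             100          50      50     10
```

Both classifiers reach 100% on held-out tiles against a 50% chance rate:
the synthetic classes differ by a planted 3× nucleus-density gap, and the
sparse representation transmits it cleanly. `autoplot(fit$dictionary)`
shows the learned kernel mosaic, `autoplot(sparsity_stats(codes))` the
per-feature sparsity histogram, and `autoplot(fit$log)` the training
energy curve. On label-shuffled data the same pipeline collapses to
chance — the suite asserts this.

For published-scale context: with accuracies of 85.48% (fine-tuned
ImageNet CNN baseline) and 93.32% (sparse-coding features + MLP),

```r
error_reduction(85.48, 93.32)
#> [1] 53.99449
```

i.e. the sparse-coding MLP removes ~54% of the baseline's error.

Command-line wrappers for each stage live in `inst/cli/`
(`extract_rois.R`, `learn_dict.R`, `encode_tiles.R`,
`train_classifier.R`).

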