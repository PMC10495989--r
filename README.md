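# teaspec

Cultivar identification and germination-period classification for oolong tea
(*Camellia sinensis*) from five-band multispectral canopy imagery.

Plantations grow many visually similar cultivars, and telling them apart —
or placing a cultivar in its phenological earliness class (early,
mesophytic or late species) — normally takes expert judgement. `teaspec`
implements a machine-vision pipeline for that task and a seeded synthetic
canopy generator that makes every stage testable without field data:

1. **Calibration** — in-scene reference panel, per band
   `R_i = DN_i · R_s / mean(DN_s)`.
2. **Segmentation** — excess-green-minus-excess-red contrast
   `ExGR = (2G − R − B) − (1.4R − G)` thresholded by Otsu's method
   (between-class-variance maximisation), background and panel masked out.
3. **Features** — an 86-indicator registry per image: 9 colour values
   (r, g, b, h, s, v, L\*, a\*, b\*) and 7 colour indices, 8 grey-level
   co-occurrence (GLCM) and 7 local-binary-pattern (LBP) texture
   statistics, 5 band reflectance means and 50 vegetation indices.
4. **Screening** — uninformative variable elimination (UVE): variables must
   beat the PLS regression-coefficient reliability `mean(b)/sd(b)` of
   appended random noise; then LASSO with cross-validated λ; VIP importance
   scores (`mean(VIP²) = 1` by construction).
5. **Classification** — RBF soft-margin SVM (one-vs-one), 6:2:2 stratified
   train/test/validation split, with the penalty `c` and kernel width `g`
   tuned by a genetic algorithm, particle swarm optimisation, or the grey
   wolf optimizer against 5-fold cross-validation accuracy, plus an
   exhaustive log-grid oracle and dataset-scale/per-class-reduction
   ablations.
6. **Germination period** — Fisher discriminant analysis
   (`S_b w = λ (S_w + γI) w`, two axes) of 15 cultivar-mean indicators,
   nearest-class-centre classification, alongside a fixed published
   two-function reference model.

See `vignettes/teaspec-methods.Rmd` for the models, parameter meanings,
the synthetic study conditions and their limitations.

## Worked example

```r
library(teaspec)

spec     <- synthetic_spec(images_per_cultivar = 15, image_size = c(48, 48), seed = 42)
dataset  <- generate_dataset(spec)          # 18 cultivars, ground-truth masks
features <- extract_features(dataset)       # calibrate + segment + 86 indicators

sel <- uve_lasso(features, seed = 7)        # UVE -> LASSO cascade
res <- tuned_svm_pipeline(features, optimizer = "gwo", agents = 12, iters = 15,
                          seed = 5, variables = sel$final_names)

cm     <- cultivar_means(features)          # 15 indicators, one row per cultivar
fisher <- fit_fisher(cm$means, cm$stages)
germ   <- germination_report(fisher)
```

This prints (abridged):

```
<synthetic_dataset> 270 images, 18 cultivars (75/75/120 stages)
<feature_table> 270 samples x 86 indicators, 18 cultivar(s)
<selection_report> cascade 86 -> 79 -> 54 indicators
<optimizer_run> GWO: best c=13.7631 g=0.0100 fitness=0.9630 (192 evals)
<eval_report> accuracy: train 100.00%, test 98.15%, validation 96.30%
            predicted
actual       early mesophytic late
  early          5          0    0
  mesophytic     0          5    0
  late           0          0    8
```

Reading the output: the screening cascade shrinks the 86 indicators to 54
informative ones; the grey-wolf search settles on penalty `c ≈ 13.8` and
kernel width `g = 0.01` with a cross-validated fitness of 96.3%; the tuned
SVM then classifies held-out test images of 18 cultivars at 98.1% accuracy;
and the Fisher discriminant places all 18 cultivars in their correct
germination stage (the all-diagonal 5/5/8 confusion matrix).

`run_pipeline(run_config(...))` chains the same stages under one master
seed and writes CSV/JSON outputs plus a hash manifest;
`compare_optimizers()` races GA, PSO and GWO on identical splits and folds.

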