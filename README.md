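# rrfdetect

Automatic recognition of **ragged red fibers (RRFs)** — the histological
hallmark of mitochondrial myopathy — in light-microscopy images of Gomori
trichrome-stained skeletal muscle.

RRFs appear as a red, granular subsarcolemmal rim around an otherwise
blue-green muscle fiber. `rrfdetect` implements a tile-level recognition
pipeline for 20x acquisitions (nominally 1653 × 1239 px):

1. **Tiling** — each acquisition is cut into a 15 × 11 grid of 110 × 110 px
   tiles (165 per field), labelled `ragged`, `not_ragged` or `waste`
   (artifacts/connective tissue).
2. **Features** — every tile is summarised by 134 named features:
   * 39 colour: 13 first-order statistics (mean, median, min, max, range,
     variance, MAD, RMS, skewness, kurtosis, energy, entropy, uniformity)
     per HSV channel;
   * 43 texture: 21 gray-level co-occurrence (GLCM, offset δ = 1 averaged
     over θ ∈ {0°, 45°, 90°, 135°}), 11 run-length (GLRLM) and 11 size-zone
     (GLSZM, 8-connected zones) features on a 32-level quantized luminance
     image;
   * 52 wavelet: the 13 first-order statistics per subband of a one-level
     2D DWT with the 8-tap least-asymmetric Daubechies orthonormal filter.
3. **Cascade classification** — a double-step binary cascade: stage 1
   separates waste from tissue (positive = tissue), stage 2 separates
   ragged from not-ragged among tissue tiles (positive = ragged). At each
   stage random forest (`ranger`), gradient boosting (`xgboost`) and an
   RBF SVM (`e1071`) are tuned by random search under stratified 10-fold
   cross-validation on an 80% training split (best mean F1 wins a draw),
   and the learner with the highest test-set AUC is selected. Features are
   z-scored with statistics fitted on training rows only.
4. **Evaluation** — confusion matrices; SEN, SPE, FPR, FNR, PPV, NPV, ACC,
   F1; exact threshold-sweep ROC curves whose trapezoidal AUC equals the
   Mann–Whitney ranking probability.

Because no public RRF tile dataset exists, the package also ships a
**synthetic tile generator** (Voronoi fiber mosaics, red speckled rims,
pale artifact fields) with a separation dial `s ∈ [0, 1]`: at `s = 0` all
three class generators are identical (an honest permutation null), at
`s = 1` the classes are cleanly separable. It makes every pipeline stage
testable end-to-end.

## Worked example

```r
library(rrfdetect)

ds  <- generate_dataset(40, 30, 30, cfg = synthetic_config(1), seed = 11)
ft  <- extract_feature_table(ds$tiles)        # 100 × 136 tibble
cas <- train_cascade(ft, learners = default_learners(n_draws = 3), seed = 42)
cas
#> <rrf_cascade> two-stage tile classifier
#>   stage 1 (waste/tissue):      random_forest, test AUC 1.000
#>   stage 2 (ragged/not_ragged): random_forest, test AUC 1.000
#>   trained on 80 tiles, tested on 20 (seed 42)

tidy(cas)
#> # A tibble: 6 × 7
#>   stage             algorithm         cv_f1 cv_acc test_auc test_acc selected
#>   <chr>             <chr>             <dbl>  <dbl>    <dbl>    <dbl> <lgl>
#> 1 waste_tissue      random_forest     1      1            1    1     TRUE
#> 2 waste_tissue      gradient_boosting 0.989  0.988        1    1     FALSE
#> 3 waste_tissue      svm_rbf           1      1            1    1     FALSE
#> 4 ragged_not_ragged random_forest     1      1            1    1     TRUE
#> 5 ragged_not_ragged gradient_boosting 0.967  0.975        1    1     FALSE
#> 6 ragged_not_ragged svm_rbf           0.827  0.868        1    0.917 FALSE

predict_cascade(cas, ft) |> head(3)
#> # A tibble: 3 × 4
#>   tile_id     p_tissue p_ragged label
#>   <chr>          <dbl>    <dbl> <chr>
#> 1 sim01_t0001        0       NA waste
#> 2 sim01_t0002        0       NA waste
#> 3 sim01_t0003        0       NA waste
```

Each row of `tidy()` is one candidate learner at one stage: its winning
cross-validated F1 and accuracy, its test-set AUC after refitting, and
whether it was selected for the cascade. `predict_cascade()` reports the
stage-1 tissue probability, the stage-2 ragged probability (absent when
stage 1 already called the tile waste — the gating rule), and the final
three-class label. `autoplot(cas)` draws the per-stage test ROC curves.

A thin command-line interface over the same functions ships at
`inst/cli/rrf.R` with subcommands `simulate`, `tile`, `extract`, `train`,
`predict`, `evaluate`.

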