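# mcsd — multi-class compressed-sensing detector for subtype classification

`mcsd` classifies disease subtypes from one or several expression data types
measured on the same samples — the motivating case being tumour subtyping
(e.g. the four transcriptional classes of glioblastoma: pro-neural, neural,
classical, mesenchymal) from a miRNA panel and a genome-wide mRNA array
combined.  Single data types often cannot separate all subtypes; cascading
the profiles and classifying in a *learned* compressed space can.

## The method

Given training blocks `x_1, x_2, ...` (probes × samples) with class labels,
the detector:

1. **cascades** the blocks into one profile per sample,
   `x = [x_1; x_2; ...]` (N probes total);
2. **normalizes** every probe row to `[0, 1]` by its training min/max;
3. **scores** every probe with five group statistics
   `V_i = (MeanStd, StdStd, StdMean, MeanCorr, StdCorr)` — low within-class
   spread, high between-class spread, high and stable correlation with
   class membership — and keeps the best `m` by rank-sum;
4. **learns** a sparse compress matrix `Φ ∈ R^{m×N}` by basis pursuit:
   row `j` solves `min ‖φ‖₁ s.t. Sᵀφ = (Yᵀ)_j`, where `S` is the
   normalized training matrix and `Y` its selected-probe submatrix
   (homotopy/least-angle path solver, deterministic, with per-row
   diagnostics);
5. **classifies** a compressed observation `y = Φx` with a Bayesian ideal
   observer: Gaussian class densities `N(Φs_k, σ²ΦΦᵀ)` and the
   maximum-expected-utility rule
   `argmax_l Σ_k U[l,k] P_k p(y | g = π_k)`, which with the default
   identity utility and equal priors is exactly maximum likelihood.

Everything is exercised end-to-end by a synthetic multi-block generator
with planted class-discriminative probes, so no external data are needed.
See the methods vignette (`vignettes/mcsd-methods.Rmd`) for the model,
numerical choices and limitations.

## Worked example

```r
library(mcsd)

cfg <- synthetic_config(effect_size = 2, seed = 42)  # 4 classes, 2 blocks
d   <- generate_synthetic(cfg)

fit <- mcsd(d$train$blocks, d$train$labels, m = 40, seed = 42)
fit
#> Multi-class compressed-sensing detector (MCSD)
#> Call: mcsd(x = d$train$blocks, labels = d$train$labels, m = 40, seed = 42)
#>   classes (4): class_1, class_2, class_3, class_4
#>   training data: 2150 probes x 60 samples in 2 blocks (miRNA, mRNA)
#>   compressed dimension: 40 (Phi 0.16% non-zero)
#>   noise sigma (pooled): 0.1822
#>   utility: identity; priors: 0.25, 0.25, 0.25, 0.25
#>   training accuracy: 100.0%

pred <- predict(fit, d$test$blocks)
acc  <- accuracy(pred, d$test$labels)
sprintf("test accuracy: %.1f%% (%d/56)", percent_accuracy(acc), 56 * acc)
#> [1] "test accuracy: 96.4% (54/56)"

table(truth = d$test$labels, predicted = pred)
#>          predicted
#> truth     class_1 class_2 class_3 class_4
#>   class_1      13       0       1       0
#>   class_2       1      13       0       0
#>   class_3       0       0      14       0
#>   class_4       0       0       0      14
```

The fitted object prints the pipeline's key numbers: the cascaded dimension
(150 miRNA + 2000 mRNA probes), the compressed dimension `m = 40` with a
very sparse `Φ` (0.16% non-zero entries), and the pooled within-class noise
scale estimated on the selected probes.  At a planted effect of 2σ the
detector recovers 54 of the 56 test samples; at 4σ recovery is essentially
perfect, and with no planted signal accuracy sits at chance (25%).

Other entry points: `stability_experiment()` repeats balanced random
train/test splits and reports mean ± sd accuracy; `sweep_features()` traces
accuracy against the number of selected features; `write_mcsd()` /
`read_mcsd()` serialize models to plain-text directories; and
`inst/cli/mcsd.R` wraps train / predict / sweep / simulate for shell use:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mcsd.R", package="mcsd"))')" \
    train --blocks miRNA.tsv,mRNA.tsv --labels labels.tsv --m 40 --out model/
```

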