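# accsym

Motion-symmetry analysis of paired left/right accelerometer recordings from
rehabilitation exercises.

## The problem

Rehabilitation protocols — for example core-muscle exercises prescribed
before abdominal surgery — should be performed symmetrically: both sides of
the body moving with the same vigour and rhythm. A smartphone accelerometer
strapped to each limb records that motion as a 3-axis time series at
~100 Hz. `accsym` turns one recording per body side into:

1. a scalar **global symmetry criterion** quantifying how different the two
   sides' motion features are, and
2. **classification reports** measuring how reliably a classifier can tell
   left segments from right segments — an independent probe of the same
   asymmetry.

It is aimed at researchers in human-movement analysis and biomedical signal
processing who need a tested, reproducible implementation of this pipeline,
together with a synthetic-data generator whose asymmetry is known by
construction.

## The method

Each recording is trimmed, reduced to the magnitude channel
`sqrt(ax² + ay² + az²)`, and split into `M` segments (default one per
repetition, `M = 10`). Left and right segments form the columns of a signal
matrix `D` (`N × Q`, `Q = 2M`). Every segment is described by time-domain
features (mean, sample standard deviation) and frequency-domain features:
the relative DFT band power

    E_q(i) = Σ_{k ∈ band i} |g_q(k)|² / Σ_{k=1}^{N/2} |g_q(k)|²,

computed on mean-removed segments (default bands `[0.5, 3)` and `[3, 10)`
Hz). For each feature `r` and left/right segment pair `q`, the symmetry
index

    c_q(r) = 50 · |F_L − F_R| / (F_L + F_R)   ∈ [0, 50]

is averaged over the `M` pairs and over a feature set Ψ (presets:
`"frequency"` = band powers, `"mixed"` = band powers + standard deviation)
to give the global criterion `C`; 0 means perfect feature symmetry.
Segments are additionally classified as left vs. right with an RBF-kernel
SVM, equal-prior Gaussian naive Bayes, and a two-layer neural network
(sigmoid hidden layer, softmax output, full-batch gradient descent on
cross-entropy), evaluated by leave-one-out cross-validation with
sensitivity/specificity/accuracy (TPR/TNR/AC) and the misclassification
rate CV.

## Worked example

```r
library(accsym)

# a synthetic pair whose right side moves 30% harder than the left
cfg  <- synth_config(asym_amp = 0.3, noise_sd = 0.2, seed = 42)
pair <- generate_pair(cfg)

sm   <- build_signal_matrix(pair$L, pair$R, M = 10)
fset <- build_feature_set(sm)

global_criterion(fset, psi = "mixed")
#> <symmetry_result> C = 5.9 over 10 pair(s) x 3 feature(s)

loocv("nn", fset, seed = 42, psi = c("std", "bandpower[0.5,3)"))
#> <classification_report> nn: AC 100.0%, TPR 1.00, TNR 1.00, CV 0.00 (n = 20)
```

The injected 30% amplitude asymmetry scores `C = 5.9`; the same generator
with `asym_amp = 0` and the same noise scores `C = 2.5` (the noise floor),
and the neural network separates the asymmetric pair's sides perfectly —
large criterion values and high left/right classifiability go together.

The published 16-individual × 8-exercise reference table ships with the
package, with all summaries recomputed from the cells:

```r
reference_symmetry()
#>       E1  E2  E3  E4  E5  E6  E7  E8 Mean
#> 1    1.5 1.7 2.1 2.4 2.3 7.7 1.0 5.7  3.0
#> ...
#> 15   1.0 1.0 2.0 1.0 1.3 0.4 0.8 1.3  1.1
#> 16   1.4 1.7 4.0 3.6 0.6 1.7 1.3 5.5  2.5
#> Mean 2.2 2.8 3.0 3.3 2.4 3.4 2.4 3.0
#> Std  1.4 1.8 1.9 1.9 1.6 2.4 1.7 2.0
```

Exercise E6 (body cross-motion) is the hardest to perform symmetrically
(column mean 3.4, std 2.4); individual 15 is the most symmetric mover (row
mean 1.1).

End-to-end runs go through a manifest plus `run_pipeline()`:

```r
cohort <- generate_cohort(2, list(c(0, 0), c(0.4, 0)),
                          synth_config(noise_sd = 0.1, seed = 1))
res <- run_pipeline(cohort, pipeline_config(seed = 1))
write_pipeline_outputs(res, "out/")   # symmetry + report CSV/JSON, config hash
```

A thin CLI over the same functions lives at `inst/cli/accsym.R`
(`simulate | features | symmetry | classify | run | report`). The methods
vignette (`vignettes/motion-symmetry.Rmd`) documents the model, parameter
defaults, generator assumptions, and numerical choices.

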