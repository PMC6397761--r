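# miace

Weakly supervised classification of tree crowns from airborne hyperspectral
imagery, using the multiple instance adaptive cosine estimator (MI-ACE) with
a one-vs-one voting scheme.

## The problem

Crown-level species labels are cheap; pixel-level labels are not. A
delineated tree crown yields dozens of pixel spectra, but overlapping
canopies, shadow, ground and neighbouring trees mean that an unknown subset
of those pixels does not belong to the labeled species. This is a multiple
instance learning (MIL) problem: each crown is a *bag* of instances
(pixel spectra) carrying a single bag-level label, with the only guarantee
that at least one pixel in the crown is genuinely of the labeled class.

`miace` is for remote-sensing ecologists and image analysts who have
per-pixel reflectance tables grouped by crown (genus + species label per
crown) and want crown-level species predictions without pixel-level ground
truth or parameter tuning.

## The method

**ACE detector.** With a background model (mean μ_b, covariance Σ_b with
eigensystem Σ_b = U D Uᵀ), a pixel x is scored against a target signature s
by the adaptive cosine estimator

    D_ACE(x, s) = ŝᵀ x̂ / (‖ŝ‖ ‖x̂‖),   x̂ = D^{-1/2} Uᵀ (x − μ_b)

— the cosine between the whitened signature and the whitened,
mean-subtracted pixel, in [−1, 1] and invariant to positive scaling of the
pixel's offset from the background mean.

**MI-ACE signature estimation.** Given positive bags B⁺ (target-class
crowns) and negative bags B⁻, the discriminative signature maximizes

    (1/N⁺) Σ_{j∈B⁺} D_ACE(x*_j, s)  −  (1/N⁻) Σ_{j∈B⁻} (1/N_j) Σ_i D_ACE(x_ji, s)

where x*_j is the instance of bag j with the largest detection statistic.
Optimization alternates instance selection with a closed-form signature
update (the objective is linear in the whitened unit signature once
selections are fixed), so the objective is non-decreasing and convergence is
exact when the selected set stabilizes. No tuning parameters.

**One-vs-one multiclass.** For every pair of classes a binary MI-ACE
classifier is trained (background statistics from the non-target class's
pixels) plus a decision threshold chosen by scanning midpoints of the sorted
training bag confidences (a bag's confidence is its mean pixel ACE
statistic). At test time each classifier casts one vote per crown; the
majority class wins. Hierarchical mode classifies genus first, then routes
the crown to that genus's species-level one-vs-one model.

**Evaluation.** Confusion matrices, rank-1 accuracy, per-class
accuracy/specificity/precision/recall/F1, and mean cross entropy with
ε-softening of crisp probabilities (ε* = (1 − a)/(C − 1) in closed form).

## Worked example

Simulate a two-genus hierarchy (AC with one species, PI with three, the
within-genus signatures deliberately similar), train hierarchically, and
predict:

```r
library(miace)

cfg <- synth_config(n_bands = 30, bags_per_class = 10,
                    signature_scale = 0.5, seed = 42)
x <- simulate_two_level(list(AC = "ACRU", PI = c("PIEL", "PIPA", "PITA")),
                        cfg, similarity = 0.4)
x
#> bag_set: 40 crowns, 841 pixels, 30 bands (400-2500 nm)
#> genus counts: AC=10, PI=30
#> species counts: ACRU=10, PIEL=10, PIPA=10, PITA=10

model <- miace_ovo(x, level = "genus", hierarchical = TRUE)
summary(model$hierarchy$PI)
#> one-vs-one MI-ACE model: 3 classes (species level), 3 classifiers (mode 'one')
#> classes: PIEL, PIPA, PITA
#>   target background objective threshold train_acc
#> 1   PIEL       PIPA    0.9902    0.2444         1
#> 2   PIEL       PITA    0.9847    0.2424         1
#> 3   PIPA       PITA    0.9786    0.2471         1

p <- predict_hierarchical(model, x, seed = 1)
p
#> miace_predictions: 40 crowns over 4 species classes; 0 tie(s)
#> rank-1 accuracy vs ground truth: 1.0000
confusion_matrix(p)
#>       predicted
#> truth  ACRU PIEL PIPA PITA
#>   ACRU   10    0    0    0
#>   PIEL    0   10    0    0
#>   PIPA    0    0   10    0
#>   PITA    0    0    0   10
```

Each classifier's `objective` is the final value of the MI-ACE criterion
(close to 1 = the selected target pixels are almost perfectly aligned with
the signature while negatives are orthogonal); `threshold` is the trained
bag-confidence cut; test-on-train rank-1 accuracy is 1 because the planted
signatures are well separated. `optimal_epsilon(0.864, 9)` returns `0.017`:
the softening that minimizes cross entropy for crisp predictions at 86.4 %
accuracy over 9 classes.

A config-driven workflow (`run_train()`, `run_predict()`, `run_evaluate()`,
`run_cv()`, `run_simulate()`) and a thin command-line front-end
(`inst/cli/miace.R`, subcommands `simulate/train/predict/evaluate/cv`)
operate on CSV instance tables with the band axis in the header
(`crown_id,genus,species,b383,...`); models persist as a directory of JSON
files.

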