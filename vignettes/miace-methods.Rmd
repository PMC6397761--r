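---
title: "Methods: multiple instance ACE for crown classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiple instance ACE for crown classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miace)
```

## The generative model and its assumptions

A crown is a bag of pixel spectra with one genus and one species label. The
model behind both the detector and the synthetic generator is Gaussian
background plus scaled additive target: a background pixel is
`x ~ N(mu_b, sigma1^2 * Sigma_b)`, and a target-bearing pixel is
`x ~ N(alpha * s + mu_b, sigma1^2 * Sigma_b)` with abundance `alpha != 0`.
A positive bag is only guaranteed to contain *at least one* target pixel;
negative bags contain none. The assumptions that matter in practice:

* background variability is stationary within a training pair of classes
  (one mean and covariance describe all non-target pixels);
* the target enters additively and scaled, so after whitening the target
  component is a fixed *direction* — which is why a cosine statistic is the
  right detector and why it is invariant to `alpha`;
* pixel noise is uncorrelated across pixels (no spatial structure).

## The ACE statistic and whitening

`fit_background()` estimates `mu_b`, the sample covariance, and its
eigensystem `Sigma_b = U D U'`. `whiten()` applies
`x_hat = D^{-1/2} U' (x - mu_b)`; under the background law the whitened
covariance is the identity (a property the test suite checks empirically on
20,000 draws). `ace_statistic()` is the cosine between the whitened unit
signature and the whitened unit pixel, bounded in [-1, 1].

Because rare classes can have fewer pixels than bands, the covariance is
always ridge-regularized as `S + lambda * (tr(S)/d) * I`. The default
`lambda = 1e-6` is relative to the mean eigenvalue scale: it is negligible
for well-conditioned backgrounds yet guarantees a positive definite model
for rank-deficient ones. If `tr(S) = 0` (a degenerate constant background)
the scale falls back to 1 so the ridge alone defines the model.

## MI-ACE optimization

`mi_ace()` maximizes the mean selected-instance statistic over positive bags
minus the mean statistic over all negative instances. Design choices where
the procedure is genuinely open:

* **Signature update.** With the per-bag selections fixed the objective is
  linear in the whitened unit signature, so its exact maximizer is the
  normalized difference between the mean selected positive direction and the
  mean negative direction. We use that closed form rather than a gradient
  step; each iteration therefore cannot decrease the objective (asserted
  per-iteration in the tests).
* **Initialization.** Every positive instance is evaluated as a candidate
  signature and the best one seeds the iteration. This is deterministic —
  no random restarts, no seed — and starts from a direction that is already
  discriminative.
* **Convergence.** The selected-instance set is the only discrete state, so
  iteration stops exactly when it repeats; `max_iter = 1000` is a safety
  bound, not a tuning parameter (typical runs converge in fewer than five
  iterations). Ties in instance selection break to the lowest index.
* **Background.** Each pairwise classifier whitens with the statistics of
  its own non-target class, so the "background" adapts to the opposing
  class; a pre-fit global background can be passed instead.

## One-vs-one training, thresholds, voting

For `C` classes, `miace_ovo()` trains one classifier per unordered pair
(`pairs_mode = "one"`, target = lexicographically first class) or per
ordered pair (`"two"`); the one-classifier mode is the default since both
modes give near-identical predictions when the pairwise problems separate
(a property the tests assert). A bag's confidence under a classifier is the
mean pixel statistic — averaging before thresholding is what suppresses
mislabeled pixels. The threshold scans midpoints of consecutive sorted
training confidences plus one candidate below the minimum and one above the
maximum, keeps the candidate with the best training accuracy (strict `>`
decides for the target), and breaks accuracy ties by the widest margin to
the nearest confidence, then by the smallest threshold — determinism plus
robustness.

Vote ties in prediction are broken uniformly at random among the tied
classes. The random stream is derived from the user seed *and the crown
id*, so predictions are invariant to bag order; a deterministic
alternative (largest mean signed margin over the tied class's classifiers)
is available via `tie_break = "margin"`. Hierarchical prediction classifies
genus first; single-species genera map directly to their species, and only
multi-species genera consult a species-level sub-model (trained within the
genus only).

## Metrics and epsilon-softening

Crisp 0/1 probabilities give infinite cross entropy as soon as one crown is
wrong. `soften()` assigns `eps` to every non-predicted class and
`1 - (C-1) * eps` to the predicted class; for crisp predictions at rank-1
accuracy `a` the softened cross entropy is
`c(eps) = -[a log(1 - (C-1) eps) + (1-a) log(eps)]`, convex on
`(0, 1/(C-1))` with minimizer `eps* = (1-a)/(C-1)` (`optimal_epsilon()`;
the tests confirm the closed form against a grid search). The reference
operating point used by `scripts/acceptance.R` takes `C = 9` scored species
classes (8 named species plus the out-of-vocabulary class) at `a = 0.864`,
i.e. 108 of 125 crowns correct. Per-class precision, recall and F1 report 0
with an explicit `*_undefined` flag when a denominator is empty, keeping
aggregate tables stable.

## The synthetic generator

`simulate_bags()` draws data from exactly the generative model above, so
passing tests demonstrate that the estimator recovers what the model
plants — not that real crowns satisfy the model. Defaults, chosen once as a
plausible desk-scale analogue of crown tables:

| parameter | default | rationale |
|---|---|---|
| `n_bands` | 50 | enough dimensionality for whitening to matter, fast tests; the real 426-band geometry is reachable via `wavelengths` |
| `bags_per_class` | 25 | order of a modest field campaign per class |
| `instances_per_bag` | 10–30 | "a crown usually contains dozens of pixels" |
| `target_fraction` | 0.5 | crown polygons are mostly but not purely the labeled tree |
| `abundance` | U(0.5, 1.5) | `alpha != 0` is the only model requirement; a unit-centered range keeps target strength comparable across draws |
| `bg_sd`, `rho` | 0.05, 0.9 | smooth, strongly band-correlated reflectance noise around a vegetation-like mean curve |
| `signature_scale` | 0.15 | moderate separability: reflectance contrasts of a few percent per band |

`sigma1sq` is a free noise multiplier: the model's variance term is defined
through the observed pixel in the detection context and cannot be used
generatively, so the generator treats it as an independent dial.
`contamination_fraction` replaces background pixels with another class's
target pixels, emulating mislabeled crown pixels; the guaranteed target
instance of each positive bag is never displaced. `simulate_two_level()`
mixes per-species directions with a shared genus direction
(`similarity` in [0, 1)), reproducing the field situation where congeneric
species are far harder to separate than genera — the tests verify that
species accuracy degrades toward chance as `similarity` approaches 1 while
genus accuracy stays high.

What the generator does **not** emulate: radiative-transfer structure,
spatially correlated pixels within a crown, sensor artifacts, or the
water-band sentinel values of real tables (water-band removal is exercised
on the wavelength grid directly).

## When averaging beats selection

A finding from this package's own experiments, worth stating because it
bounds what the MIL machinery buys: at very sparse targets (one target
pixel in ten), MI-ACE's *signature estimate* is far better than the naive
mean of all positive pixels (whitened cosine to the planted direction
around 0.98 vs 0.77 in the test suite's paired comparison — the selection
step is doing its job), but crown-level *accuracy* is then limited by the
bag-mean aggregation, whose noise affects any signature equally; a naive
mean-signature classifier run through the same aggregation and threshold
pipeline is not reliably worse. The robustness test therefore asserts
graceful accuracy degradation plus the signature-recovery comparison,
which is the quantity the selection mechanism actually controls.

## Problem sizes and numerical tolerances

The test suite runs entirely on generated data: bag sets of 20–60 crowns
with 6–30 pixels each over 10–50 bands, Monte-Carlo checks with 10,000 to
50,000 draws, 200 randomized threshold problems, and 10-seed paired
comparisons; the whole suite completes in well under a minute. Objective
monotonicity is asserted to 1e-12; whitened-covariance identity to a
Frobenius distance of 0.05 at n = 20,000–50,000; planted-signature recovery
at cosine 0.95.

## Known limitations

* No out-of-vocabulary rejection: every crown is forced into one of the
  trained classes, so unknown species inflate off-diagonal counts (the
  `OTHERS` crowns are dropped from training for the same reason).
* Classifiers are equally weighted in the vote; no pairwise probability
  coupling is attempted, so probabilities are crisp unless softened.
* Thresholds maximize training accuracy and can overfit when a class has
  very few crowns; cross-validation (`crossval_ovo()`) is the honest
  estimate, and classes with a single crown are excluded from it.
* Bag confidences average over *all* pixels; for crowns that are mostly
  non-target the aggregation dilutes the detection signal (see the
  averaging-vs-selection note above).
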