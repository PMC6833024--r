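# fundusseg

Segmentation of the optic disc (OD) and optic cup (OC) in retinal fundus
photographs, and the glaucoma-screening statistics computed from the two
masks.  The package is aimed at researchers in ophthalmic image analysis
who want a fully inspectable, dependency-light R implementation of:

* **MSMKU** — a U-shaped fully-convolutional network with an image-pyramid
  input (levels at W, W/2, W/4, W/8 fused additively in the contracting
  path), multi-kernel residual modules (three parallel 3×3 convolutions
  plus a branch of two successive 4×4 convolutions, concatenated, fused by
  1×1 convolution + ReLU + batch norm, with an additive short connection),
  strided convolutions instead of pooling, and an expanding path of
  convolution + bilinear up-sampling stages with additive skips; sigmoid
  output thresholded at 0.5.
* **MMLM training** — mixed maximum loss minimization.  Each round *t*
  ranks all training pairs by their current Dice loss
  ℓ(P,G) = 1 − 2ΣPG / (ΣP² + ΣG²) under the frozen start-of-round weights,
  then minimises
  L_t = λ₁ Σᵢ ℓ(f(Xᵢ),Yᵢ) + λ₂ Σₖ Σⱼ ℓ(f(Rₖ(X̄ⱼ)), Rₖ(Ȳⱼ)),
  where the second sum runs over the N_t hardest pairs replicated under
  K_t random rotation/translation augmentations, with schedules
  N_t = min(max(N_max − t, N_min), m) and
  K_t = max(K_max − ⌊0.25 t⌋, K_min).  λ₂ = 0 degenerates exactly to
  average-loss training (ALM); λ₁ = 0 with identity augmentation gives
  top-k maximal-loss training (MLM).
* **The two-stage pipeline** — disc segmentation at 384², square ROI
  detection around the disc mask, cup segmentation at 256² inside the ROI,
  and restoration of the cup mask to source coordinates.
* **Screening** — vertical cup-to-disc ratio (VCDR = VCD/VDD), quadrant
  rim widths with the ISNT rule (I > S > N > T in healthy eyes), a
  screening score, and exact rank-based ROC-AUC.
* **A phantom generator** — deterministic fundus-like images with exact
  elliptical disc/cup masks, vessels, noise, and an imbalanced mix of
  typical and rare styles (extremely small cups, barely visible cup
  contrast), giving analytic ground truth for every mechanism.

The network — convolution forward/backward passes, batch normalization,
up-sampling and Adam — is implemented natively (RcppArmadillo), with
gradients verified against finite differences in the test suite.  No
external deep-learning runtime is required.

## Worked example

Train a small cup-aware network on phantoms and inspect one screening
record:

```r
library(fundusseg)

ds <- generate_dataset(12, rare_fraction = 0.25, side = 64, seed = 7)
pairs <- lapply(ds$items, function(it) list(image = it$image, mask = it$od_mask))
fit <- msmku_fit(pairs, msmku_config(64, 4, seed = 7),
                 mmlm_config(n_max = 6, n_min = 2, k_max = 3, k_min = 1,
                             epochs = 10, learning_rate = 3e-3, seed = 7),
                 strategy = "mmlm")
print(fit)
#> MSMKU fit (MMLM), 10 rounds on side-64 inputs
#> final round: mean Dice loss 0.1444, mean F 0.9302, min F 0.8959

it <- ds$items[[1]]
screening_record(it$od_mask, it$oc_mask)
#> VCDR 0.400 (VCD 8 / VDD 20); rim I/S/N/T = 7.3/7.5/9.9/5.9; ISNT 1
```

The fit history shows the round, the schedule values N_t and K_t, and the
mean/min training F-score measured under the frozen start-of-round
weights; here the mean Dice loss fell from 0.99 (random initialisation) to
0.14 in ten rounds.  The screening record reads: the cup spans 8 of the
disc's 20 vertical pixels (VCDR 0.40, below the 0.6 screening threshold),
and one of the three ISNT inequalities holds.  `predict(fit, image)`
returns the probability map or the thresholded mask;
`segment_fundus(image, od_net, oc_net)` runs the full two-stage pipeline
on an arbitrary-size photograph.

A command-line front end (`generate`, `train`, `segment`, `evaluate`,
`screen`, `crossval`) ships in `inst/cli/fundusseg.R`.

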