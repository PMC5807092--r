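# liquidperc

Midlevel shape features and the visual perception of liquid viscosity.

People judge how runny a liquid is by eye, and keep judging it consistently
when the same liquid is poured, stirred, or squeezed through holes — scenes
whose images have almost nothing in common. `liquidperc` implements, as
tested R code, the computational account behind that constancy: observers
first estimate a small set of *midlevel* shape and motion features
(spreading vs clumping, irregularity, rectilinearity, dynamics), and
perceived viscosity is a weighted linear readout of those latent factors.
Because the factors generalize across scenes, so does the readout.

The package is aimed at visual psychophysicists and computational
neuroscientists who want to run, probe, or extend this model family without
the original stimulus corpus: a synthetic-stimulus simulator and simulated
observers with known ground truth stand in for the deposited data.

## The model

For a stimuli × features rating matrix `X` (repetition-averaged, slider
units):

1. **Factor count** — Horn's parallel analysis: retain eigenvalues of
   `cor(X)` exceeding the 95th percentile of eigenvalues of same-shape
   standard-normal data.
2. **Factor model** — maximum-likelihood factor analysis on the feature
   correlation matrix: loadings `Λ`, uniquenesses (unrotated by default).
3. **Scores** — Harman's idealized-variable weights `W = Λ(ΛᵀΛ)⁻¹` applied
   to the standardized data (`W` is a left inverse of `Λᵀ`).
4. **Readout** — OLS: `v̂ = β₀ + S β`.
5. **Transfer** — the frozen `(Λ, W, β)` applied to a new context's
   ratings, standardized within the new dataset; generalization is the
   regression of observed on predicted, df `(1, n − 2)`.

Around this core the package provides a viscosity-controlled height-field
liquid simulator with mesh export and silhouette rendering; four bespoke 3D
mesh metrics (shape-index-weighted curvature, surface flatness,
center-of-mass height, total absolute Gaussian curvature); twenty 2D
silhouette statistics and dense pyramidal Lucas–Kanade optical flow;
representational dissimilarity analysis in factor space; and pixel- vs
feature-space PCA.

## Worked example

Fit the perceptual model on the 192-stimulus pouring set and transfer it,
frozen, to the 56-stimulus eight-scene set:

```r
library(liquidperc)

truth <- make_ground_truth(set1_design(), seed = 42)   # known 4-factor ground truth
feats <- generate_feature_ratings(truth, repetitions = 4, seed = 42)
visc  <- generate_viscosity_ratings(truth, repetitions = 4, seed = 42)

m <- visc_model(feats, visc)    # factor count chosen by parallel analysis
m
#> Perceptual viscosity model: 4 factors from 20 features
#> Training fit: R^2 = 0.984, F(4, 187) = 2925.83, p = 2.27e-167, n = 192

truth2 <- make_ground_truth(set2_design(), loadings = truth$loadings,
                            beta = truth$regression_weights, seed = 43)
out <- evaluate_transfer(m,
  generate_feature_ratings(truth2, 4, seed = 43),
  generate_viscosity_ratings(truth2, 4, seed = 43))
out$report
#> R^2 = 0.979, F(1, 54) = 2571.70, p = 3.11e-47, n = 56
```

Parallel analysis finds the four generating factors; the training fit uses
them at the design's degrees of freedom `(4, 187)`; and the frozen model
predicts viscosity ratings in eight scenes it never saw at `R² = 0.98` with
`df = (1, 54)` — no new parameters. `summary(m)` prints the loading matrix
and regression weights; `plot(m)` shows observed vs predicted ratings.

Higher-level drivers reproduce whole workflows:
`run_forward_study()` (train on pouring → transfer to scenes),
`run_reverse_study()` (the reverse direction plus the forward-vs-reverse RDM
comparison), and `run_measurement_model_comparison()` (optical flow, 2D
silhouette statistics, and 3D mesh metrics vs the simulated percepts, with
weights fixed across contexts or free per scene).

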