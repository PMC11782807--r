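# cinefuse

Non-invasive estimation of pulmonary hemodynamics — mean pulmonary artery
pressure (mPAP, mmHg), pulmonary artery wedge pressure (PAWP, mmHg), and
pulmonary vascular resistance (PVR, Wood units) — from four-view cardiac MR
cine series, with built-in model explainability. The package is aimed at
researchers in cardiac image analysis who want an attention-based
multi-view fusion regressor whose internal reasoning (which frames, views,
phases, and chambers matter) can be inspected, and a fully synthetic cine
phantom generator so every analysis runs end-to-end without clinical data.

## The model

An examination is four cine series — two-chamber (2CH), four-chamber
(4CH), right-ventricular long-axis (RVLA), and a mid short-axis slice
(SAX) — of 20 phases each, preprocessed to 256 × 256 pixels at
0.94 mm/pixel with intensities clipped at the 3rd/97th percentile and
mapped to [0, 1]. Three shared components produce a scalar prediction:

1. a shared **frame encoder** maps each of the 80 frames to a feature
   *f* ∈ ℝᴰ;
2. a shared **Attention Feature Fusion Block** fuses any set
   {*f*₁…*f*ₙ}: raw scores *aᵢ* = *wᵀfᵢ* + *b*, normalised weights
   α = softmax(*a*), fused feature Σᵢ αᵢ *fᵢ* (dimension-preserving);
3. **two-stage fusion**: per phase over its 4 views → 20 spatial
   summaries; per view over its 20 phases → 4 temporal summaries; then
   one fusion of all 24 summaries → the final feature, which a shared
   affine **regression layer** maps to the target.

Training minimises MSE with Adam (defaults: learning rate 10⁻⁴, weight
decay 10⁻⁸, batch size 10, ≤1000 epochs, early stopping on validation
loss). Because the regression layer applies to *any* feature and every
fusion call emits attention weights, the model explains itself three ways:
per-feature predictive performance (105 features), mean attention weights
per fusion group, and chamber mask/paste perturbation with
Gaussian-dilated masks (σ = 4 px, radius 16 px). Evaluation uses MAE, the
Pearson correlation coefficient (PCC), R² = 1 − SS_res/SS_tot (can be
negative), Bland–Altman limits of agreement, and the precapillary-PH rule
mPAP > 20 mmHg, PVR > 2 WU, PAWP ≤ 15 mmHg.

## Worked example

Generate a labelled phantom cohort (signal planted in the right ventricle
on the short-axis view), train the small-profile mPAP model, and inspect
it:

```r
library(cinefuse)

ds    <- generate_dataset(phantom_config(), n_train = 90, n_val = 20,
                          n_test = 30, seed = 7)
feats <- encode_dataset(ds, cinefuse_config())
model <- train_model(feats, cinefuse_model(cinefuse_config(), seed = 7),
                     small_train_config(seed = 7))

pred <- predict(model, feats, split = "test")
regression_report(pred$truth, pred$prediction)
#> # A tibble: 1 × 4
#>       n   mae   pcc    r2
#>   <int> <dbl> <dbl> <dbl>
#> 1    30 0.491 0.999 0.998
```

The held-out mPAP error is ~0.5 mmHg with PCC 0.999 — the phantom's
planted area signal is essentially noiseless after pooling, so this is a
pipeline check, not a clinical claim. Agreement and attention:

```r
bland_altman(pred$truth, pred$prediction)
#> # A tibble: 1 × 5
#>     bias sd_diff loa_lower loa_upper     n
#>    <dbl>   <dbl>     <dbl>     <dbl> <int>
#> 1 -0.146   0.592     -1.31      1.01    30

aw <- mean_attention_weights(model, feats, split = "test")
round(colMeans(aw$mean$view_wise), 3)
#>   2CH   4CH  RVLA   SAX
#> 0.042 0.036 0.054 0.868
```

The view-wise attention concentrates on SAX — the view carrying the
planted signal. Per-view performance agrees:

```r
fi <- per_feature_performance(model, feats, split = "test")
fi[fi$level == "temporal_summary", c("view", "pcc", "r2", "weight_final")]
#> # A tibble: 4 × 4
#>   view      pcc      r2 weight_final
#>   <chr>   <dbl>   <dbl>        <dbl>
#> 1 2CH   0.0653  -15.3        0.00347
#> 2 4CH   0.00420  -6.57       0.00288
#> 3 RVLA  0.0125  -11.6        0.00455
#> 4 SAX   0.997     0.860      0.0676
```

Only the SAX temporal summary predicts the target on its own (PCC 0.997);
the other views are noise by construction. `chamber_importance(model, ds)`
completes the picture: masking the RV on SAX collapses the test PCC while
pasting only that region preserves it. `autoplot()` methods exist for
histories, importance tables, attention summaries, and perturbation grids;
`tidy()`/`glance()` summarise fitted models.

A thin command-line front-end (`inst/scripts/cinefuse`) wraps the same
functions as `synth`, `train`, `predict`, `evaluate`, and `explain`
subcommands.

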