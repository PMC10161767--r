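# fiborient

Fast recovery of three-dimensional nanofiber orientation from wide-angle
X-ray diffraction (WAXD) azimuthal intensity profiles.

Hierarchically structured biological materials — the chitin networks of
mantis-shrimp (stomatopod) cuticle are the motivating example — contain
two groups of textured nanofibers: an in-plane twisted-plywood (Bouligand)
group and an out-of-plane pore-canal group. A single azimuthal profile
I(χ) of the chitin (110) diffraction ring encodes both groups' 3D
orientation statistics. `fiborient` recovers the nine orientation
parameters

- per group: plane tilts α, β (degrees), mean in-plane fiber angle γ,
  in-plane fan spread Δγ,
- plus the quantity ratio λ₁/λ₂,

from one I(χ) curve, using a forward diffraction simulator (Ewald-circle /
pole-circle intersection on the (110) reciprocal shell) and a fully
connected neural network trained with mean-absolute-error loss and Adam on
simulated curves. Three ingredients make the simulation-trained model
robust on measured data with detector gaps:

1. **Data corruption** of the training set — Poisson counting noise,
   circular blockwise masking (default ratio 0.3, blocks may wrap the
   ±180° seam), and ±5 % random scaling of the maximum;
2. a **periodic label codec** — each angle is doubled onto the unit
   circle, (cos 2θ, sin 2θ), removing the ±90° jump discontinuity, with
   group order canonicalized by the larger γ;
3. **reconstruction-based evaluation** — predictions are scored by
   regenerating the curve with the forward model and comparing it with
   the observation (RMSE, matched-peak Pearson correlations), which also
   works on experimental curves that have no ground-truth labels.

KNN, random-forest and SVR baselines, gradient saliency maps, curve/config
I/O and a command-line interface round out the pipeline.

## Worked example

```r
library(fiborient)

# 1. Sample 5000 orientation labels and build a corrupted training set
labels  <- sample_labels(5000, seed = 42)
dataset <- build_dataset(labels, seed = 42)

# 2. Train the network (a small funnel for the example)
model <- train_fcnn(dataset, fcnn_config(
  hidden = c(256, 128, 64), lr = 2e-3, lr_decay = 0.97,
  batch_size = 64, epochs = 30, patience = 5, seed = 1
))

# 3. Evaluate on the held-out test split by reconstruction
report <- evaluate(model, dataset, phase = "phase1")
glance(report)
#> # A tibble: 1 × 7
#>   phase  n_curves n_repetitions rmse_mean rmse_sd pearson_location pearson_intensity
#>   <chr>     <int>         <int>     <dbl>   <dbl>            <dbl>             <dbl>
#> 1 phase1      500             1     0.141  0.0763            0.998             0.664

# 4. Predict orientation parameters for one masked curve
curve <- ichi_curve(dataset$curves[3, ], valid_mask = dataset$masks[3, ])
predict_orientation(model, curve)
#> # A tibble: 1 × 9
#>   alpha1  beta1 gamma1 dgamma1 alpha2 beta2 gamma2 dgamma2 lam_ratio
#>    <dbl>  <dbl>  <dbl>   <dbl>  <dbl> <dbl>  <dbl>   <dbl>     <dbl>
#> 1 -0.559 0.0919   62.5    66.2 -0.855 -1.36  -47.6    83.1     0.907
```

(The true parameters for this curve were γ₁ = 60.1, Δγ₁ = 44.4,
γ₂ = −49.4, Δγ₂ = 108.2, λ₁/λ₂ = 0.76 — the in-plane angles are recovered
within a few degrees at this small training size.)

`rmse_mean` is the mean root-mean-square difference between each observed
(corrupted) test curve and the curve regenerated from its predicted
parameters, both unit-max normalized on the shared valid bins — 0 would be
a perfect fit, and the corruption noise floor at these settings is about
0.02. `pearson_location`/`pearson_intensity` correlate matched diffraction
peak positions and heights between observed and reconstructed curves; peak
locations (which track γ) are recovered almost perfectly, peak heights
(which track λ and Δγ) are harder. The predicted tibble shows the nine
decoded parameters for one curve.

A shell interface wraps the same steps
(`simulate | corrupt | train | predict | evaluate | saliency`):

```sh
Rscript inst/cli/fiborient simulate --n 20000 --seed 7 --out ds.rds
Rscript inst/cli/fiborient train    --data ds.rds --algo fcnn --seed 1 --out model.rds
Rscript inst/cli/fiborient evaluate --model model.rds --data ds.rds --phase 1 --out report.json
```

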