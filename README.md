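# cinefuse

3D left-ventricular motion estimation from multi-view 2D cine cardiac MR
by per-view diffeomorphic tracking, cyclic-dynamics unscented Kalman
smoothing, and maximum-likelihood track-to-track fusion.

## The problem

Routine cine CMR is two-dimensional: a stack of short-axis slices 8–10 mm
apart plus a handful of long-axis views. The myocardium, however, moves in
3D, and every single 2D sequence is blind to the motion component normal
to its own plane. `cinefuse` reconstructs 3D trajectories of myocardial
points — and regional wall-motion classifications built on them — by
combining the views so that each plane's blind direction is covered by
another plane. It is aimed at researchers working on cardiac motion
analysis who have standard cine acquisitions (no tagging, no DENSE) plus
a first-frame myocardial delineation per sequence.

## What it computes

For each view the package:

1. **tracks** contour points between adjacent frames with a diffeomorphic
   moving-mesh registration: the transformation φ is parameterized by a
   monitor function μ (its prescribed Jacobian determinant, mean 1) and a
   curl field γ, obtained by solving the div–curl system
   div ρ = μ − 1, curl ρ = γ, ρ|∂Ω = 0, and integrating the flow of
   ν_t = ρ/(t + (1−t)μ); `det J_φ ≈ μ > 0` prevents folding;
2. **lifts** pixel tracks to the patient frame via the DICOM plane
   geometry (Image Position/Orientation (Patient), Pixel Spacing);
3. **smooths** each 3D track with an unscented Kalman smoother on a cyclic
   state model: per axis a harmonic oscillation about a mean position with
   transition block
   `F = [1, 0, 0; 1−cos ωT, cos ωT, sin(ωT)/ω; ω sin ωT, −ω sin ωT, cos ωT]`
   and the angular frequency ω itself in the 10-component state;
4. **fuses** per-view estimates of the same point by maximum likelihood,
   `s = P_b(P_a+P_b)⁻¹ s_a + P_a(P_a+P_b)⁻¹ s_b`, with fused covariance
   `(P_a⁻¹+P_b⁻¹)⁻¹` (information form for more than two views).

A deforming-ellipsoid phantom with analytic single-harmonic ground truth,
regional features (Shannon differential entropy of normalized radial
distance and segment area over the 4/6/6 apical/mid/basal AHA slice
segments), Bhattacharyya separability, and a leave-one-subject-out naive
Bayes classifier complete the toolchain. See the methods vignette
(`vignettes/multiview-fusion-methods.Rmd`) for the full model account.

## Worked example

A six-view phantom run (three short-axis planes, three long-axis planes,
K = 20 frames, 0.5 mm observation noise):

```r
library(cinefuse)
spec <- phantom_spec(K = 20, noise_sd = 0.5, seed = 11)
res  <- run_pipeline(list(phantom = spec, seed = 11))
round(res$report$view_rmse_multi_mm, 3)
#>   SA1   SA2   SA3   LA1   LA2   LA3
#> 3.438 4.116 4.797 0.412 0.404 0.410
round(res$report$fused_rmse_multi_mm, 3)
#> [1] 0.33
```

Reading the numbers: single short-axis views err by 3.4–4.8 mm because
base-to-apex shortening (up to ~14 mm at the base) is invisible to them;
long-axis views do better (~0.41 mm) since their blind direction carries
only the small twist component. Fusing the views drops the 3D RMSE of the
shared points to 0.33 mm — below every single view. RMSE is evaluated on
the first half of the cycle, at the points seen in at least two views
(18 of 36 here). The smoothed angular frequency is also recovered:

```r
oms <- sapply(res$fused, function(f)
  median(sapply(f$states, function(s) s$s[10])))
round(median(oms), 3); round(res$gt$omega, 3)
#> [1] 6.406
#> [1] 6.283
```

(median over tracks of the per-track median smoothed ω, against the true
2π rad/s at 60 bpm.)

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/cinefuse.R phantom --out phantom_out --seed 3
Rscript inst/scripts/cinefuse.R run --config config.json --out run_out
```

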