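# geniculate

Reconstruction and order metrics for thalamocortical projection columns.

Focal injections of retrograde tracer into primary visual cortex (V1) label a
*projection column* in the dorsal lateral geniculate nucleus (dLGN): the set
of relay neurons converging on one cortical site. When the labelled cells of
many animals are registered into a common standardized nucleus space, the
columns can be compared quantitatively: how cells are distributed along and
around each column, how the population of columns twists and expands on its
way from the pial surface to the ventral border, how well neighbourhood
relations are preserved within the nucleus and relative to V1, and how many
independent depth-varying factors underlie all of those profiles. This
package implements that full analysis chain for anyone working with
registered point clouds of labelled neurons — together with a seeded
synthetic-data generator, so every stage can be exercised and benchmarked
without histological data.

## The analysis

* **Column model** — each animal's 3D cell cloud is summarised by a
  piecewise-quadratic spline (degree 2, five uniformly spaced interior
  breaks) per coordinate, extrapolated to its intersections with the nucleus
  boundary mesh. The *unit column* maps arc length between the pial (t = 0)
  and ventral (t = 1) crossings onto [0, 1]; each cell gets a depth `t` and a
  perpendicular distance `r` from the trajectory. Depth profiles (cells per
  5% bin; mean radial spread, volume-corrected across groups) and a
  closed-form Rayleigh scale MLE, σ̂ = √(Σr²/2n), summarise the cloud.
* **Map stack** — at each 5th-percentile depth the columns' iso-percentile
  points are projected onto a total-least-squares plane, giving 21 2D maps.
  Neighbouring maps are registered with a constrained similarity transform
  (expansion E ∈ [0.1, 10], rotation θ ∈ (−π, π], translation), initialized
  at and checked against the closed-form 2D similarity Procrustes solution;
  cumulative rotation Σθ and expansion ΠE are anchored at the pial plane.
* **Order metrics** — the topographic product of Bauer & Pawelzik scores
  rank preservation between two matched point configurations:
  P = (1/N(N−1)) Σ_j Σ_k log[(Π_{l≤k} Q₁Q₂)^{1/2k}], with Q₁, Q₂ the
  cross-space distance ratios of the k-th nearest neighbours. The package
  normalizes |P| by its mean over random relabellings — 0 is perfect order,
  ≈1 complete disorder — and attaches a Monte-Carlo permutation p-value,
  p = (1 + #{|P_perm| ≤ |P_obs|}) / (1 + n_perm). This is applied between
  neighbouring depth maps (topology), between the pial and ventral end maps,
  and between the V1 injection configuration and every depth map
  (topography).
* **Latent model** — count, spread, topology and topography profiles are
  standardized to zero mean/unit variance per row and stacked into a
  metric × depth matrix; an autoassociative PLS scan (NIPALS) reports
  cumulative explained variance and a column-split cross-validated
  reconstruction error as functions of the number of latents.
* **Synthetic data** — ellipsoidal nucleus meshes with a labelled pial cap;
  curved columns with prescribed rotation/expansion fields, Poisson bin
  counts, Rayleigh scatter and a controllable fraction of scrambled
  injection pairings; profile matrices of known rank. Ground truth is
  recorded for every generated quantity.

## Worked example

```r
library(geniculate)

sim <- simulate_dataset(seed = 42)          # 16 columns, ~1700 cells
rec <- reconstruct_columns(sim$cells, sim$mesh)
stack <- percentile_maps(rec$paths)
traj <- cumulative_trajectory(align_stack(stack))
tail(traj, 1)
#> # A tibble: 1 × 3
#>   depth cum_rotation_rad cum_expansion
#>   <dbl>            <dbl>         <dbl>
#> 1     1            0.842          1.37

ee <- end_to_end_order(stack, n_perm = 199, seed = 1)
ee[c("norm_pt", "p_value", "n_points")]
#> # A tibble: 1 × 3
#>   norm_pt p_value n_points
#>     <dbl>   <dbl>    <int>
#> 1   0.131    0.02       16
```

The generator's defaults prescribe a cumulative rotation of 0.8 rad and
expansion of 1.4 between the pial and ventral ends; the reconstructed stack
recovers 0.842 rad and 1.37 from the noisy cells. The end-to-end normalized
topographic product of 0.13 with p = 0.02 says the ventral map is far more
similar in neighbourhood structure to the pial map than random relabellings
are — the columns stay ordered across the depth of the nucleus. A fraction
`scramble = 1` of re-paired injections drives the topography profile to ≈1
(complete disorder) instead.

`run_pipeline(list(seed = 42, out_dir = "results"))` chains all stages and
writes per-stage CSV tables plus a deterministic `summary.json`;
`plot_depth_profile()`, `plot_map_stack()`, `plot_trajectory()`,
`plot_order_profile()` and `autoplot()` on a latent scan give ggplot views
of each result type.

## Vignette

`vignettes/projection-columns.Rmd` documents the models, the numerical
choices (spline span, gauge fixing, tie handling, CV scheme) and what the
synthetic benchmarks do and do not establish about histological data.
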