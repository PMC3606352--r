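# veingraft

Rule-based (agent-based) simulation of early intimal remodeling in
arterialized vein grafts.

When a vein is used as an arterial bypass graft, its wall adapts to the
new pressure and flow by intimal hyperplasia: smooth muscle cells (SMC)
proliferate, die by apoptosis, and deposit extracellular matrix (ECM),
while monocytes infiltrate the wall and amplify matrix synthesis. The
balance of these events is governed by local wall shear stress — low-flow
grafts thicken far more than high-flow grafts — and sets the stage for
late graft failure. `veingraft` is for vascular-biology and
computational-physiology researchers who want a mechanistic, cell-level
sandbox for this process: a stochastic cellular automaton whose rules are
calibrated from in-vivo labeling kinetics rather than fitted growth
curves.

## The model in brief

SMC, ECM and monocyte elements (7 µm × 7 µm) occupy columns of a lattice
that grows from a fixed outer boundary toward the lumen. Each hour, every
SMC draws against a division and an apoptosis probability built from
labeling kinetics:

- BrdU-positive fraction: `BrdU(τ*, t) = A · S(τ*) · exp(−B t)` with
  A = 44 %, B = 0.16 /day, and shear factor `S(τ*) = exp(−τ*)`
  (τ* = τ/10 dynes cm⁻²); TUNEL mirrors it with E = 5 %, F = 0.32 /day.
- Labeling indices convert to per-hour probabilities through an
  asynchronous cell-cycle model (2 h BrdU availability, 24 h cycle,
  S-phase-only incorporation, harvest 24 h after injection):
  `p = b / (2000 − 24 b)` for an index of `b` percent.
- Depth profiles `C*(t)·exp(−D·d_lumen)` (D = 27.3 /mm, division at the
  luminal surface) and `G*(t)·exp(−H·d_outer)` (H = 6.7 /mm, apoptosis at
  the outer wall) are renormalized every step so they integrate to the
  space-averaged probabilities over the local intimal thickness.
- Matrix rules: each daughter cell produces one ECM element 24 h after
  division and a second 24 h later unless it re-divides; each apoptotic
  death removes the four nearest ECM elements; monocyte influx
  `J · S(τ*) · exp(−K t)` (J = 175 /(mm²·h), K = 0.16 /day) drives a
  burst of `[2·M̃]` extra ECM per daughter at division.
- A redistribution rule moves the top element of a column to its
  neighbor whenever adjacent columns differ by more than two elements,
  producing a smooth luminal contour.

One-dimensional (single column from a single SMC) and two-dimensional
(mixed 25 % SMC / 75 % ECM initial layer) algorithms are provided, along
with ensemble execution, a focal-stenosis scenario driven by a
longitudinal shear field, synthetic input generators, and least-squares
calibration of the labeling coefficients from data tables. The hourly
event loop runs in compiled code; a 28-day, 100-column run takes about
10 ms. See `vignette("veingraft-methods")` for the full model account.

## Worked example

Ensemble growth under chronic low shear (1.8 dynes/cm², the low-flow limb
of a bilateral graft construct):

```r
library(veingraft)
library(dplyr)

cfg <- sim_config(duration = 28, mode = "2d", n_columns = 100, tau = 1.8)
ens <- run_ensemble(cfg, n_runs = 50, base_seed = 1)
ens
#> <vg_ensemble> 50 runs, 28 days (2d)
#>   final area_mm2: 0.2947 (SD 0.0945)
#>   final smc_fraction: 0.222 (SD 0.0105)

filter(ens$summary, metric == "area_mm2", time_days %in% c(7, 14, 28))
#> # A tibble: 3 × 4
#>   time_days metric     mean     sd
#>       <dbl> <chr>     <dbl>  <dbl>
#> 1         7 area_mm2 0.0824 0.0191
#> 2        14 area_mm2 0.188  0.0531
#> 3        28 area_mm2 0.295  0.0945
```

The intimal cross-section grows sigmoidally to ~0.29 mm² — note the
steepest rise falls in the second week, the hallmark of the
thickness-renormalized division profile — while the wall composition
settles near 22 % SMC, inside the 20–40 % range reported for graft
intima. The kinetic layer is directly accessible; for example, the
per-hour division probability implied by the labeling surface at day 7
under low shear:

```r
mean_division_prob(brdu_fraction(tau_star = 0.18, t = 7))
#> [1] 0.007000754
```

and calibration recovers known coefficients from a noisy synthetic
labeling table:

```r
d <- generate_labeling_dataset(amp = 44, decay = 0.16, sigma = 0.1,
                               replicates = 4, seed = 42)
tidy(fit_labeling_surface(d))
#> # A tibble: 2 × 3
#>   term  estimate std.error
#>   <chr>    <dbl>     <dbl>
#> 1 amp     45.3     0.862
#> 2 decay    0.153   0.00596
```

`autoplot()` methods display trajectories, ensembles, grids and shear
fields; `stenosis_run()` simulates growth around a focal stenosis from a
`generate_stenosis_field()` table, and a thin command-line front end
lives in `inst/cli/vgsim.R`.

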