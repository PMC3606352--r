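---
title: "Methods: a rule-based model of vein graft intimal remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a rule-based model of vein graft intimal remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(veingraft)
library(dplyr)
```

## The model

When a vein segment is implanted into the arterial circulation, its wall
adapts to the new hemodynamic environment by thickening of the intima:
smooth muscle cells (SMC) proliferate, undergo apoptosis, and deposit
extracellular matrix (ECM), while monocytes enter from the blood and
amplify matrix synthesis. `veingraft` simulates this process as a
stochastic cellular automaton. The intima is a rectangular lattice of
7 µm × 7 µm elements — the footprint of one SMC — organized as columns of
contiguous stacks that grow from a fixed outer boundary toward the lumen.
Each element is an SMC, an ECM element, or a monocyte.

Every hour, each SMC faces a division probability and an apoptosis
probability that depend on three things: the local normalized wall shear
stress $\tau^* = \tau/\tau_{ref}$ (with $\tau_{ref} = 10$ dynes/cm²,
the pre-ligation reference), the time since implantation, and the
element's depth within the intima. The surfaces are anchored in labeling
data: the fraction of BrdU-positive nuclei (an S-phase proliferation
marker) and TUNEL-positive cells (an apoptosis marker) are modelled as

$$\mathrm{BrdU}(\tau^*, t) = A\,S(\tau^*)\,e^{-Bt}, \qquad
  \mathrm{TUNEL}(\tau^*, t) = E\,S(\tau^*)\,e^{-Ft},$$

with amplitudes $A = 44\%$ and $E = 5\%$ and decay constants
$B = 0.16$/day and $F = 0.32$/day obtained by regression against graft
labeling data. $S(\tau^*)$ is a shear-response factor discussed below.

### From labeling index to division probability

A BrdU index is not a division probability: BrdU is metabolically
available for only `brdu_window` = 2 h after injection, it is incorporated
only during S-phase, both daughters of a labeled cell inherit the label,
and the population grows during the `T_B` = 24 h between injection and
harvest. We model the population as asynchronous: with per-hour division
probability $p$, a fraction $\phi = p\,T_c$ of cells is actively cycling
(cycle time $T_c = 24$ h, G1/S/G2M in equal thirds), uniformly distributed
in phase. A cell dividing at cycle time $T$ was in S-phase during
$[T - 2T_c/3,\, T - T_c/3]$ and acquires label iff that interval overlaps
the availability window. Counting labeled nuclei at harvest gives, at the
default constants,

$$\mathrm{BrdU}(p) = \frac{2000\,p}{1 + 24\,p}\ [\%],
  \qquad\text{hence}\qquad
  p = \frac{b}{2000 - 24\,b}$$

for a measured index $b$ in percent (`label_fraction_forward()` and
`mean_division_prob()`; the latter is the exact algebraic inverse of the
former, and both are checked against an independent population
Monte-Carlo in the test suite). The model saturates when every cell
cycles ($\phi = 1$), at $b \approx 41.7\%$; larger indices are clamped
with a warning. The same correlation, with the apoptotic-cell residence
time `T_D` = 24 h in place of `T_B`, converts a TUNEL index into a
per-hour apoptosis probability (`mean_apoptosis_prob()`).

An alternative forward model we considered — memoryless per-hour division
of each individual cell, with S-phase assigned retrospectively — caps at
roughly 31% labeled nuclei and therefore cannot represent the fitted
amplitude of 44%; the asynchronous-population model has no such defect
and is exactly linear in $p$ at small rates, so it was adopted as the
normative definition.

### Depth structure

Proliferation concentrates at the luminal surface and apoptosis at the
outer boundary. Both are exponential profiles,

$$P_{division}(x) = C^*(t)\, e^{-D\,d_{lumen}}, \qquad
  P_{apoptosis}(x) = G^*(t)\, e^{-H\,d_{outer}},$$

with spatial decays $D = 27.3$/mm and $H = 6.7$/mm. The amplitudes
$C^*(t)$ and $G^*(t)$ are not free parameters: at every step and in every
column they are renormalized so that the profile integrates over the
local intimal thickness $IT$ to the space-averaged probability,

$$C^* = \bar{P}\,\frac{IT \cdot D}{1 - e^{-D\cdot IT}}$$

(`spatial_normalizer()`; evaluated with `expm1` and a series fallback for
$D \cdot IT \to 0$, and agreeing with numeric quadrature to $10^{-9}$
relative error). Element depths are measured from the element's center,
$d = (i + 1/2) \times 7\,\mu m$, which keeps $d_{lumen} + d_{outer} = IT$
exactly and avoids a zero-distance singularity at the surface. With
midpoint depths the element-weighted mean of the profile matches the
space average to well under 1% for columns of five or more elements.
This normalization has an important dynamic consequence: as a column
thickens, the same average probability is concentrated into the
superficial elements, so division activity scales with local wall mass.
This is the mechanism behind the accelerating (sigmoid) growth phase at
low shear. Probabilities are clipped to $[0, 1]$ after evaluation; the
simulator counts clip events and they do not occur at the default
parameters.

### The shear-response factor

The shear dependence is exposed as a configurable factor with two
presets: the default exponential form $S(\tau^*) = e^{-\tau^*}$ and an
inverse form $S(\tau^*) = 1/\tau^*$. The exponential default was chosen
because the labeling surfaces are exponential in their other argument and
the fitted amplitudes remain below the labeling-model ceiling across the
physiologic shear range (1–15 dynes/cm²), where the inverse form diverges
as $\tau^* \to 0$. Low shear enhances proliferation, apoptosis labeling
and monocyte entry under both forms. All kinetic operations and the
calibration routine honor the configured form.

### Matrix rules

ECM is produced on a post-division schedule: each daughter cell deposits
one matrix element 24 h after the division and a second one 24 h later
unless it divides again in the interval, so one division yields up to
four matrix elements. Cells that have never divided hold no production
schedule — production follows division. When an SMC dies, the four ECM
elements nearest to it (Euclidean distance in grid-index space, over the
whole grid, ties broken at random) are removed; if fewer than four exist,
all are removed with a warning. New elements are inserted into one of the
adjacent lattice slots (two in 1-D, four in 2-D, uniformly at random) and
displaced elements advance toward the lumen, reflecting the fixed outer
boundary and fixed graft length; removals collapse outward so stacks stay
contiguous.

### Monocytes

Monocyte entry follows the proliferation surface's form,
$INFLUX_M = J\,S(\tau^*)\,e^{-Kt}$ with $J = 175$/(mm²·h) and
$K = 0.16$/day. Two modelling choices required judgment:

* **Normalization of the matrix burst.** At division each daughter
  deposits $N_m = [\,2\tilde{M}\,]$ ECM elements (round-half-up), where
  $\tilde{M}$ is the entry rate normalized to the *normal condition*. We
  take the normal condition to be the maximal rate $J$ (unit shear
  factor) at time zero, so $\tilde{M} = S(\tau^*)e^{-Kt}$. At the
  low-shear condition of 1.8 dynes/cm² this gives $\tilde{M} \approx
  0.84$ and $N_m = 2$ at early times — each daughter cell creating two
  ECM elements — decaying to zero by about two weeks. Normalizing
  instead by the rate *at normal shear* would multiply the drive by
  $e^{1} \approx 2.7$ and make every early division deposit five
  elements per daughter, which is inconsistent with the two-per-daughter
  behavior the rule is meant to encode. A `same_time` option cancels the
  time decay for sensitivity analyses.

* **What the per-mm² rate multiplies.** Monocytes cross the endothelium,
  so the default treats the rate as a flux through each column's luminal
  surface patch (7 µm × 7 µm), independent of wall thickness
  (`influx_coupling = "surface"`). This keeps the monocyte content of the
  simulated wall at the few-percent level that matches its physiologic
  baseline. The alternative (`"area"`) multiplies by the growing
  cross-sectional area; entry then compounds with thickness and monocytes
  accumulate to ~20% of the wall by four weeks, an order more than
  observed. Entries are realized as per-column Poisson draws and placed
  at uniform random positions within the column; monocytes persist
  indefinitely and neither divide nor die. At time zero, monocytes equal
  to 5% of the initial element count are scattered through the wall.

### The event loop

Each step of `dt` = 1 h executes, in a fixed, documented order: (1)
per-column shear lookup; (2) division draws for every SMC, each division
inserting the new daughter adjacent to the parent, resetting both
daughters' production timers, and depositing the monocyte burst; (3)
scheduled 24/48-h matrix production; (4) apoptosis draws (a cell that
divided or was born this step is exempt — at `dt` = 1 h a double event
has negligible probability and the exemption removes the ambiguity),
each death removing the cell and its four nearest ECM; (5) monocyte
influx; (6) redistribution (2-D only). The internal order of the
published flow chart is not recoverable from the text; a fixed order was
chosen for reproducibility. Probabilities use the time at the start of
the step; per-column thickness is re-read by each phase.

Redistribution moves the top (lumen-most) element of the taller column to
the shorter one whenever adjacent columns differ by more than two
elements, sweeping left-to-right then right-to-left to a fixed point —
deterministic given the grid, conserving elements, and strictly
decreasing the sum of squared heights with every move, which guarantees
termination. Moved elements carry their production timers with them.

All randomness flows through R's RNG (also inside the C++ core), so a
`(config, seed)` pair reproduces a run event-for-event; ensembles draw
per-run seeds from the base seed.

## Domains and outputs

The 1-D model is a single column started from one SMC — the baseline
thickness of a healthy venous intima. The 2-D model starts from a single
layer, one element per column, each independently SMC with probability
0.25 (the 1:3 cell-to-matrix ratio of the normal vein wall). Trajectories
report element counts, composition fractions, mean intimal thickness and
intimal area; the 1-D "equivalent area" multiplies the thickness by a
configurable 100 equivalent columns, mirroring how a single-column
simulation is compared with a 2-D one.

For composition we report the *pooled* fractional SMC volume of an
ensemble — total SMC elements over total elements — because that is the
morphometric meaning of a tissue volume fraction. The unweighted per-run
mean is dominated, in the 1-D model, by runs whose founder cell happens
never to divide (a one-element graft with "fraction 1"), and measures
founder-division probability rather than composition.

## Synthetic inputs

Two generators make every stage testable without external data:

* `generate_stenosis_field()` emulates the shear environment of a focal
  lumen narrowing: a Gaussian throat elevation with amplitude
  $(1 - \text{area reduction})^{-3/2}$ (the Poiseuille scaling of shear
  with lumen area; an 80% area reduction elevates throat shear about
  11-fold), a distal depression of relative depth equal to the area
  reduction (the low-shear recirculation zone), and exponential
  relaxation of the whole disturbance toward baseline over time. This is
  a deliberately simple parametric stand-in for a CFD-computed field —
  computing the flow itself is out of scope — so its magnitudes are
  structural, not quantitative, truths: elevated throat, depressed distal
  segment, recovery over weeks.
* `generate_labeling_dataset()` samples the labeling surface at a
  factorial design of shear levels and times with mean-one multiplicative
  log-normal noise, providing ground truth for
  `fit_labeling_surface()`, which recovers the amplitude and time decay
  by least squares (log-linear start, `nls` refinement; the refinement is
  skipped when the start already fits exactly, since `nls` cannot iterate
  on zero residuals).

Stenosis simulations seed the same flat initial layer as the plain 2-D
model and read their per-column shear from the supplied field (columns
mapped linearly onto the field's position range, nearest-neighbor lookup,
refreshed every 7 days); the lumen-profile geometry itself is not
modelled.

What passing tests on these fixtures show — and what they do not: the
generators share the model's own functional forms, so calibration tests
demonstrate estimator correctness, not that the exponential surfaces are
the right description of real grafts; and the stenosis scenario
demonstrates the qualitative shear–growth coupling, not agreement with
any measured lumen profile.

## Problem sizes and numerical choices

The package's standard experiment sizes, used by its tests and the
bundled acceptance script, are chosen so a complete desk-scale
reproduction runs in about a minute on one core: 1,000 replicate 1-D runs
for composition statistics, 200 replicates per arm for the
monocyte-effect contrast on a 100-column 2-D domain, and 50 replicates
for growth-curve contrasts. The hourly loop over 28 days (672 steps) runs
in compiled code; a 2-D run takes on the order of 10 ms. Internally time
is in hours and lengths in micrometres; per-day decay coefficients and
per-mm spatial decays are converted at the interface, and `dt` must
divide 24 h so the production schedule's 24/48-h marks fall exactly on
steps.

## Limitations

The model grows the intima only: lumen remodeling, wall tension, SMC
migration from the media/adventitia and progenitor influx are outside its
scope, as is any computation of the flow field. Constant-shear runs do
not update shear as the lumen narrows (an option exists for shear-field
runs, refreshed every 7 days). The labeling inversion assumes a steady
asynchronous population over the 24 h labeling window, monocytes are
inert occupants once placed, and the exact algebraic shear response is a
configurable modelling choice rather than a measured quantity.
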