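---
title: "Quantifying single-cell glucose dynamics from ratiometric biosensor imaging"
author: "glucoFRET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell glucose dynamics from ratiometric biosensor imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucoFRET)
```

## The measurement problem

Genetically encoded FRET glucose sensors report cytosolic glucose as the
ratio of acceptor ("yellow", 545/55 nm) to donor ("blue", 475/50 nm)
emission. In brain-slice two-photon experiments, a field of 5–8
sensor-expressing astrocytes is imaged at 256×256 pixels while the
perfusion steps through a protocol of extracellular glucose levels and
drugs: a 5 mM baseline, a transient 25 mM step, washout, a cytochalasin-B
"transport-stop" epoch in which membrane glucose transport is blocked so
the cytosolic decline reports glycolytic consumption alone, and terminal
aglycemia (0 mM) used as a one-point calibration of the sensor.

From each cell's ratio trace the pipeline extracts: the raw basal ratio,
the minimum-normalized basal level, the rise rate and amplitude of the
response to the glucose step, and the transport-stop consumption rate.
Groups of cells (nested in slices, nested in animals) are then compared
with a linear mixed model.

Because no raw imaging data are bundled, every stage is validated against
a biophysical simulator that renders matched two-channel recordings with
known ground truth: parameter recovery takes the place of reference
datasets.

## The simulator

### Cytosolic glucose balance

Each cell integrates

$$\frac{d[Glc]_i}{dt} = T + X - C,$$

with facilitated transport through a symmetric carrier
$T = V_{max,T}\left(\frac{[Glc]_o}{K_{m,T}+[Glc]_o} -
\frac{[Glc]_i}{K_{m,T}+[Glc]_i}\right)$ (zeroed while cytochalasin B is
present), a lumped gap-junctional exchange with the astrocyte network
$X = g_{net}([Glc]_{net} - [Glc]_i)$ (zeroed while carbenoxolone is
present; $[Glc]_{net}$ is a fixed scene-level constant), and
Michaelis–Menten consumption $C = V_{hk}\,[Glc]_i/(K_{m,hk}+[Glc]_i)$.
The symmetric carrier is the simplest saturable, bidirectional transport
model; the small consumption half-saturation (default
$K_{m,hk} = 0.05$ mM, hexokinase-like) keeps the transport-stop decline
quasi-linear, matching the linear-slope read-out. Integration uses
`deSolve::lsoda` per epoch (tolerances 1e-10/1e-12), with drug action
instantaneous at epoch boundaries in the ground truth; the finite
bath-exchange time is handled on the analysis side by skipping a
configurable wash-in interval (default 1 min).

```{r physics}
p <- standardProtocol()
epochs(p)
phys <- cellPhysiology(VmaxT = 0.35, Vhk = 0.12, glc0 = 1.2)
traj <- simulateCellGlucose(phys, p, dt = 0.05)
range(traj@glc)
```

### Sensor and rendering

The sensor is a single-site binding curve
$R(g) = R_{min} + (R_{max}-R_{min})\,g/(K_d+g)$ with defaults
$K_d = 0.7$ mM (the construct's nominal affinity), $R_{min} = 1.0$,
$R_{max} = 2.2$. These are conventions, not in-situ measurements — the
in-situ constants of the sensor in astrocytes are not published — and all
are overridable. Cells are rendered as uniform disks (radius 6 px) whose
pre-noise donor and acceptor signals split a per-cell brightness $B$ as
$B/(1+R)$ and $B\,R/(1+R)$, so the summed channels conserve $B$ exactly.
A background offset (20 counts) is added to both channels, the frame is
rigidly translated along a clipped Gaussian random-walk drift path
(0.15 px/frame, ±6 px), and Poisson shot noise plus Gaussian read noise
(sd 2 counts) are applied. The default frame period is 2 s, making the
11-frame smoothing window span 22 s — short against the minutes-long
epochs.

What the generator deliberately omits: photobleaching, spectral
bleed-through, intracellular metabolite compartments, non-rigid tissue
deformation and 3-D optics. Passing recovery tests therefore demonstrates
correctness of the estimators under rigid drift and shot/read noise, not
robustness to those further artifacts.

## The analysis pipeline

1. **Motion correction.** Per-frame rigid shifts are estimated by
   cross-correlating the summed-channel image (higher SNR; both channels
   share the motion) against a template averaged from reference frames
   (default the first 10), after mean subtraction. The integer peak is
   refined to 1/10 px by sampling the correlation surface on an upsampled
   grid via a matrix-multiply DFT; ties break toward the smaller shift.
   Both channels receive the identical transform, preserving ratios;
   pixels entering from outside the frame are marked invalid and excluded
   from every downstream mean (never zero-filled).
2. **Temporal smoothing.** A centered 11-frame boxcar applied to the
   registered images. The window shrinks symmetrically at the stack
   boundaries, so no padding values are invented and the DC gain is
   exactly 1. A trace-level smoothing mode exists for speed and agrees
   with image-level smoothing for fully valid ROIs.
3. **Ratiometry.** For each ROI and frame, the ratio is
   mean(yellow)/mean(blue) over the valid ROI pixels — channel means
   first, division second. This "mean-then-divide" convention minimizes
   numerical error relative to averaging per-pixel ratios; the two differ
   (for a 2-pixel ROI with (yellow, blue) = (10, 5) and (2, 2) they give
   12/7 vs 3/2), and the package's tests pin the former. Frames with
   fewer than half of their ROI pixels valid are marked missing and are
   excluded from fits, never interpolated. No background subtraction is
   applied by default.
4. **One-point calibration.** Each trace is divided by its mean over the
   last 2 min of the aglycemia epoch, so normalized traces average
   exactly 1 there and all levels and rates are in dimensionless
   minimum-normalized units (rates in min⁻¹).
5. **Kinetics.** The rise rate is the straight-line slope between the
   first crossings of 20% and 80% of the baseline-to-plateau excursion
   (the published figures show only dashed fit lines, so the 20–80%
   window is a declared convention, configurable); the glucose increase
   is plateau minus baseline window means; the consumption rate is the
   OLS slope over [epoch start + 1 min, + 5 min] of the cytochalasin-B
   epoch, returned signed with fit diagnostics. A flat trace yields a
   "not estimable" flag rather than a zero rate.

```{r pipeline}
ex <- simulateExperiment("ctrl", nCells = 5, nSlices = 1, nAnimals = 1,
                         seed = 1, frameShape = c(96, 96))
cells <- analyzeExperiment(ex)
round(cells[, c("cell", "normBasal", "deltaGlc", "consumptionRate")], 4)
```

## Calibrated consumption presets

The two genotype presets pin the simulator to the published group-mean
transport-stop rates: 0.030 min⁻¹ for controls and 0.079 min⁻¹ for the
GLUT1-deleted genotype. `calibrateConsumptionPreset()` first forms the
chain-rule tangent estimate
$\mathrm{slope} \approx R'(g_b)\,V_{hk}\,S_{hk}(g_b)/R_{min}$ and then
refines $V_{hk}$ by root-finding so that the OLS slope of the noiseless,
minimum-normalized trace over the actual fit window equals the target
exactly. Two properties of the measurement made the refinement necessary
rather than cosmetic:

* Over a 5-min window a 0.079 min⁻¹ decline traverses roughly a third of
  the sensor's dynamic range, and the binding curve steepens as glucose
  falls, so the read-out is visibly curved; the tangent formula alone
  misses by more than the 2% the package demands of itself.
* The measured ratio includes the unsubtracted background offset in both
  channels, which compresses the apparent excursion by ~15–20% at the
  default brightness. The noiseless reference trace therefore goes
  through the same measurement model the pipeline applies (background
  offset, channel-wise boxcar, quotient of means;
  `noiselessPipelineTrace()`), so the preset is defined operationally —
  "the value the pipeline reads out" — not in sensor-ideal units.

The read-out is also non-monotone in $V_{hk}$: at very high consumption
the glucose pool empties inside the fit window and the fitted slope
collapses, so the root search brackets the rising branch only and reports
targets beyond the peak as unreachable. Transport capacity is co-adjusted
with $V_{hk}$ so every preset rests at the same baseline cytosolic
glucose (1.2 mM at 5 mM extracellular, a typical astrocyte operating
point below the transport equilibrium); consistently, the knockout preset
carries proportionally higher transport capacity, mirroring the higher
membrane glucose permeability that accompanies its higher glycolytic
rate.

```{r presets}
physiologyPreset("ctrl")
physiologyPreset("cko")
```

## Biological variability and the nested design

`simulateExperiment()` partitions cells into slices and animals (fields
of at most 8 cells; slices holding 9 are imaged as two fields) and draws
log-normal variability factors with unit mean at the animal (sd 0.04),
slice (0.04) and cell (0.10) levels. Because group dispersion for this
assay is reported on the measured-rate scale (group means ± SEM of the
fitted slopes), the factors are applied on that scale: each cell's
target rate is factor × group rate, and the cell's consumption capacity
is calibrated to that drawn rate through the calibration curve
(transport capacity co-adjusted, so every cell still rests at the same
baseline). Had the factors instead scaled the capacities directly, the
super-linear capacity-to-slope mapping (local elasticity ≈ 1.3 in the
control regime, ≈ 2 in the knockout regime) would have inflated and
skewed the knockout group's rate dispersion relative to the control's.
The sds were chosen once so the simulated knockout group SEM reproduces
the published ±0.003 min⁻¹; control dispersion comes out somewhat
cleaner than published — real traces carry sources of cell-to-cell
scatter the generator does not model. Custom physiology templates
without a calibrated target fall back to multiplicative capacity
scaling.

Group inference uses a linear mixed model with a fixed genotype effect
and random intercepts for animal and slice-within-animal, the two
nesting levels named by the design. The two-sided test of the fixed
effect uses the t statistic with Satterthwaite degrees of freedom (a
Wald-type test; the exact df method is an open choice and a plain normal
reference would be anticonservative at 5–6 animals per group). If a
variance component collapses, the model is refitted without it and the
result annotated; if fitting fails outright, a seeded hierarchical
bootstrap (animals, then slices, then cells; 2000 draws) takes over and
is recorded in the output.

```{r stats}
d <- rbind(
  data.frame(value = rnorm(20, -0.030, 0.005), genotype = "ctrl",
             slice = rep(1:4, each = 5), animal = rep(1:2, each = 10)),
  data.frame(value = rnorm(20, -0.079, 0.008), genotype = "cko",
             slice = rep(5:8, each = 5), animal = rep(3:4, each = 10)))
fitNestedComparison(d, value = "value")
summarizeGroups(d, value = "value")$foldChange
```

## Morphometry

`shollProfile()` re-implements plugin-style Sholl analysis on binarized
masks: circles start at 4 µm with 2 µm steps, each circle is sampled at
arc steps of at most 0.5 px with nearest-pixel lookup, and an
intersection is a maximal contiguous foreground run along the closed
circle (a run wrapping the seam counts once) — run semantics, so a thick
process counts once regardless of width.

`infarctVolume()` integrates edema-corrected infarct areas over the
anterior–posterior positions of the coronal sections by the trapezoidal
rule ("linear integration"; a sum × spacing mode is provided for
uniformly spaced sections). The edema correction direction is genuinely
ambiguous in common methods wording; the package defaults to the
conventional contralateral/ipsilateral scaling (shrinking swollen
sections), implements the inverse reading explicitly, and records the
mode in the output rather than guessing silently. Section positions are
required input — they are not standardized.

## Numerical choices and limitations

* ODE integration: `lsoda`, rtol 1e-10 / atol 1e-12; trajectories are
  clamped at zero and an overshoot beyond −1e-6 mM aborts with advice to
  reduce `dt`; `dt` must not exceed a tenth of the shortest epoch.
* Registration search is bounded (default ±20 px, automatically reduced
  for small frames); correlation ties break toward the smaller shift;
  structureless frames inherit the previous shift with a warning and a
  low-confidence flag.
* Boxcar windows must be odd — an even window has no center.
* All estimators drop missing frames; windows that end up empty raise
  errors rather than silently shrinking.
* Normalization is idempotent: renormalizing a normalized trace is the
  identity.
* Test and validation problem sizes: the full-design recoveries run at
  128×128 frames (a 2× spatial down-sampling of the acquisition format)
  with the full 36-min protocol at 2-s frames; registration property
  checks use 100 random drift paths on short stacks; the null-calibration
  study for the nested model uses 500 replicates of a reduced 8-animal
  design. These sizes keep the whole validation suite within minutes on
  one CPU while leaving every estimator exercised at realistic SNR.
* Rates are reported in minimum-normalized ratio units per minute
  throughout; whether published deltas are in raw or normalized units is
  not always stated — normalized is used here, and raw-unit read-outs
  can be derived from `normFactor`.
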