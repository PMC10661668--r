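---
title: "stimchip: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stimchip: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimchip)
```

This vignette documents the two computational strands of the package — the
analytic dosimetry of a microfluidic dcEF stimulation chamber, and the
calcium-imaging analysis pipeline — together with the modelling choices,
defaults and limitations a user should know before trusting either.

## 1. Chamber dosimetry

### The one-dimensional field model

An electrolyte-filled rectangular microchannel of length $L$, width $w$ and
height $h$ behaves as a uniform conductor: its resistance is Pouillet's law
$R = L/(\sigma w h)$, and a current $i$ confined to it produces a uniform
field $E = i/(\sigma w h)$ along the channel axis. This replaces a full
finite-element treatment with a one-dimensional resistor approximation; it is
accurate where the channel cross-section is constant and current is confined,
and it deliberately says nothing about fringe fields near junctions or about
the field inside tissue that partially occludes the channel.

A chamber with parallel branches is modelled as a directed resistor
multigraph with one ideal current source (`ResistorNetwork`). Branch
currents come from nodal analysis: the node-conductance (weighted Laplacian)
matrix is assembled, the source exit node is grounded, the drive current is
injected, and the dense symmetric system is solved with `solve()`. Networks
of interest have tens of nodes, so numerical conditioning and sparsity are
non-issues; Kirchhoff's current law holds at every node to below
$10^{-9}\,i_\mathrm{in}$ (property-tested on random networks), and a
two-branch divider reproduces $i_1 = i\,R_2/(R_1+R_2)$ to $10^{-12}$
relative.

Because only relative branch resistances of the original chamber are
published, the concrete topology is a **configuration input**, never a baked
constant. `inst/extdata/example_chamber.yaml` encodes one interpretation:
three identical sections (10 mm × 7.7128 mm × 0.8 mm, σ = 1.5 S/m) in a
cascade of current dividers whose bypass resistances are chosen so that
43.5 µA realizes the 4.7 / 2.7 / 1.0 mV/mm design point. Treat it as a
worked example of the schema, not as measured geometry.

### Electrode charge budget

For stimulation protocols the package computes delivered charge
($Q = i\,t$ for DC; $Q = i\,t_\mathrm{on}\,n$ for pulsed trains — off
intervals carry no current, matching the usual budget arithmetic), the
current density on a disk electrode $j = i/(\pi (d/2)^2)$, and the capacitive
window $t = C\,\Delta V/i$: the time a constant current can be supplied
purely from double-layer charge before the usable voltage window $\Delta V$
is exhausted and faradaic reactions (with their pH, ROS and dissolution
by-products) must carry the current. When $C$ and $\Delta V$ are unknown
separately, an observed window pins their product $C\,\Delta V = t\,i$
(`capacitiveChargeBudget()`).

### Capacitance estimators

Two standard estimators are implemented:

* **Slow CV** (`capacitanceFromCV`): for a sweep at rate $v$ over window
  $\Delta V$, $C = \oint |i|\,dV / (2 v \Delta V)$ by trapezoidal
  integration. The supplied trace covers one sweep branch (strictly
  increasing potential); the loop integral is twice the branch integral, so
  the factor 2 cancels. On an ideal rectangular CV this reduces to
  $C = i_c/v$, and the round trip recovers a synthetic capacitor to well
  under 1% at ≤1 mV steps.
* **Constant-current excursions** (`analyzeExcursion`): a purely capacitive
  interface charges linearly, $dV/dt = i/C$, so the initial-segment slope
  gives $C_\mathrm{eff} = i/\mathrm{slope}$. The best two-segment
  piecewise-linear fit (breakpoint by exhaustive search over sample indices)
  detects slope collapse. The published classification is by eye; here it is
  made operational and configurable: a trace whose fitted initial rise is
  below 5% of its voltage scale is *faradaic-dominant* from the start (the
  non-polarizable-electrode case; no capacitance is reported); a ≥10%
  residual improvement from the two-segment fit with a second-segment slope
  under half the first is a *faradaic onset*, reported with the breakpoint as
  the transition time; everything else is *capacitive*, with a warning when
  the initial segment's $R^2$ falls below 0.99. At a corner that lies exactly
  on both segments, splits on either side are equally optimal and the first
  minimum is taken — the reported transition is accurate to one sample.

Units are SI throughout the API; conversions (µA, mV/mm, mC, µA/cm²) are
applied only when printing.

## 2. Synthetic two-channel calcium movies

The generator (`simulateCalciumMovie`) is first-class, tested code: it
defines the conditions under which the pipeline's recovery is demonstrated.
Defaults mirror the reference acquisition — 128 × 128 px, 120 ms frame
interval, 1000 frames (2 min), 8-bit intensities (the detection default
threshold of 100 counts presumes an 8-bit scale).

* **Cells** are non-overlapping disks (radius 3–5 px by default, i.e. areas
  ≈ 28–79 px, comfortably above the 20 px area filter), placed by rejection
  sampling fully inside the frame; the rasterized disks are the ground-truth
  mask, pixel-exact.
* **Activity** combines synchronized network events — one shared Poisson
  process (default 6 events/min), joined by each cell with probability 0.8 —
  and neuron-specific events (independent Poisson, 2/min). Transients rise
  instantaneously and decay exponentially with τ = 0.4 s, a GCaMP6f-like
  kernel and the simplest shape that exercises detection.
* **Nuisance**: multiplicative exponential bleaching with time constant
  defaulting to 10× the movie duration (a mild trend that the rolling-median
  detrend must remove), additive Gaussian read noise (σ = 5 counts), optional
  Poisson shot noise. The default amplitude (0.3 · F₀ on baselines of
  90–130 counts) against σ = 5 gives transient SNR ≈ 5–8.
* The nuclear channel is static disks plus noise — the idealization that
  justifies detecting cells on its temporal mean.

What the generator does **not** emulate: dendrites and neuropil
contamination, overlapping or moving somata, photon-transfer noise
statistics, spatially varying illumination. Passing recovery tests therefore
demonstrates the pipeline's correctness under its own assumptions, not its
performance on arbitrary real recordings.

## 3. The imaging pipeline

### Cell detection

On the nuclear-channel temporal mean, in order: median blur (3 px default;
the original size is unstated), grayscale morphological opening with a 32 px
kernel to estimate background, background subtraction clipped at zero, a
second 2 px opening to sharpen contours, binary threshold at 100 counts,
connected components, rejection of components with area ≤ 20 px (strictly
greater-than: a 21 px component survives, a 20 px one does not), and
relabeling 1..K in raster order of each component's first pixel so labels
are deterministic. Structuring elements are square by default ("kernel size
k" is read as a k × k footprint), configurable to discs; connectivity
defaults to 8 (4 available). EBImage supplies the filtering and morphology;
component labeling is implemented in the package because the EBImage
labeller is fixed at 4-connectivity, and is tested against it in that
regime. Because a flat structuring element commutes with constant offsets,
detections are invariant to uniform background shifts — property-tested.

`maxProjectRoiMean` implements the generic staining quantifier: per-pixel
maximum over a z-stack, then the mean over an ROI (or the whole frame).

### Traces, ΔF/F₀ and spikes

Per-ROI traces are spatial means over the label's pixels in every frame,
held in a `SummarizedExperiment` subclass (`TraceSet`) with assays `raw`,
`trend` and `dff`. The trend is a centered rolling median, window 20 frames,
with windows shrinking at the edges so the trend exists at every frame
(centering avoids the phase lag of a trailing window; the even window sits
half a sample off exact centre, which matters only on steep ramps). The
normalization reads $\Delta F/F_0(t) = (F(t) - \mathrm{trend}(t)) /
\overline{\mathrm{trend}}$ — dividing by the mean of the trend is the only
reading that yields a dimensionless trace, and it makes ΔF/F₀ exactly
invariant to rescaling the raw fluorescence. `stats::runmed` requires odd
windows, so the rolling median is implemented directly and tested index-by-
index against an $O(nw)$ brute-force oracle.

Spikes are called at a per-ROI threshold of mean + k·SD of the full
processed trace (k = 3 by default; computing the SD over the full trace,
events included, is deliberate — it makes the threshold adaptive to activity
level at the cost of some conservatism in very active cells). Each
contiguous supra-threshold run yields one call at its peak frame; runs
separated by fewer than 2 frames are merged (at 120 ms sampling a single
transient spans several frames). A zero-variance trace yields no calls by
contract. Spike counts are non-increasing in k, and rates are normalized by
the baseline-session mean of the same culture, so 1.0 means "unchanged".

### Group comparison

Rates are compared neuron-level with a classical unpaired t-test (Welch by
default, pooled available). The statistic is computed in the package so the
degenerate zero-variance case can return the contractual $p = 1$ instead of
an error, and it is cross-checked against `stats::t.test` to $10^{-10}$ in
the tests. Because neurons within a culture are correlated, the
grouping-aware check resamples **cultures** with replacement within each
condition and recomputes the neuron-weighted mean difference — a cluster
bootstrap with a percentile CI and sign-flip p-value, deterministic under a
seed. This replaces mixed-model fitting as the package's clustering-aware
contract: the conclusion ("does the effect survive accounting for
per-culture clustering?") is what matters, and the bootstrap makes its
assumptions explicit; a thin optional adapter (`mixedModelCheck`, via the
suggested lme4) fits `value ~ condition + (1 | culture)` as an independent
confirmation. With few cultures (< ~6 per condition) the percentile
bootstrap CI undercovers somewhat — a known property of cluster bootstraps,
worth remembering when culture counts are small.

## 4. Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` demonstrate recovery at the
reference acquisition size (128 × 128 × 1000 frames, 30 cells): ten seeded
movies for segmentation recall/precision, two full pipeline runs for spike
F1, $10^4$ null replicates (n = 20 per group) for t-test calibration, and
four small sessions run twice for bit-identical determinism. These sizes
were chosen to make the statistical claims stable across seeds while keeping
a full run in minutes. Other numerical choices: trapezoidal CV integration
(refine the potential step if the voltammogram is strongly curved);
breakpoint search is exhaustive, $O(n^2)$ in samples, fine for digitized
traces; the network solver is dense LU; all simulation randomness flows from
a single master seed with fixed sub-seed offsets.

## 5. Known limitations

One-dimensional dosimetry ignores fringe and tissue-interior fields; the
chamber topology is user-supplied, so field values inherit the config's
geometry assumptions. The detection chain has no watershed splitting —
touching cells merge into one ROI. Spike calling reports calcium events, not
deconvolved action potentials, and applies no neuropil or motion correction.
The capacitance estimators assume ideally polarizable behaviour over the
fitted window and do not decompose capacitive from pseudocapacitive storage.
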