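# stimchip

Dosimetry and calcium-imaging analysis for microfluidic direct-current
electric-field (dcEF) stimulation of neural tissue on a chip.

Weak dcEFs (a few mV/mm, the regime of transcranial direct current
stimulation) can be delivered to cultured brain tissue by driving a constant
ionic current through an electrolyte-filled microchannel. Because the channel
confines the current, the field in each rectangular section follows directly
from Ohm's and Pouillet's laws,

    E = i / (σ·w·h)        [V/m, equivalently mV/mm]

where `i` is the section's current, `σ` the electrolyte conductivity (S/m)
and `w·h` the channel cross-section. A chamber with parallel channel branches
is a current divider: one drive current produces several graded field doses
at once. `stimchip` models the chamber as a resistor network solved by nodal
analysis, and budgets the electrode side of the stimulation: delivered charge
(`Q = i·t_on`), disk current density (`j = i/(π(d/2)²)`), the capacitive
window of an electrode (`t = C·ΔV/i`, the time a current can be sourced from
double-layer charge before faradaic chemistry must take over), capacitance
from slow cyclic voltammetry, and the classification of constant-current
voltage excursions into capacitive vs faradaic regimes.

The package's imaging side implements a calcium-imaging pipeline for
two-channel recordings (GCaMP-type functional channel plus a static nuclear
channel): cell detection on the nuclear-channel temporal mean (median blur →
morphological-opening background subtraction → small sharpening opening →
threshold → connected components → area filter), per-ROI trace extraction,
rolling-median detrending to ΔF/F₀, spike calling at mean + 3·SD, and
comparison of baseline-normalized spike rates between conditions with an
unpaired t-test plus a culture-level cluster bootstrap (neurons from one
culture are not independent). A seeded synthetic movie generator with ground
truth — non-overlapping somata, synchronized network events, neuron-specific
events, bleaching and noise — exercises the whole pipeline end to end.

## Worked example

```r
library(stimchip)

## Dosimetry: solve the example three-section chamber at 43.5 uA
cfg <- readChamberConfig(system.file("extdata", "example_chamber.yaml",
                                     package = "stimchip"))
round(sectionFields(cfg$network, cfg$electrolyte), 2)
#>  s1  s2  s3
#> 4.7 2.7 1.0                      # mV/mm in the three stimulation sections

deliveredCharge(dcProtocol(43.5e-6, 600)) * 1e3
#> [1] 26.1                         # mC delivered by 10 min of DC drive

## Imaging: simulate a 128x128, 1000-frame movie and run the pipeline
res <- runPipeline(seed = 7)
res$mask
#> LabelMask: 128 x 128 px, 30 cells
head(spikeRates(res$spikes), 3)
#>    roi n_spikes rate_per_min
#> 1 roi1        9          4.5
#> 2 roi2       11          5.5
#> 3 roi3       13          6.5
unlist(scoreSpikes(res))[c("precision", "recall", "f1")]
#> precision    recall        f1
#> 1.0000000 0.9867021 0.9933066   # calls vs ground-truth spikes, +/- 2 frames
```

The section fields are read off the solved resistor network (1 mV/mm =
1 V/m); the spike scores compare the pipeline's calls against the
simulation's ground-truth spike trains.

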