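---
title: "Methods: fingerprinting enteric circuits from calcium imaging, motility maps and morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprinting enteric circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enscircuit)
```

# Scope and model

`enscircuit` analyzes how myenteric neurons of the mouse large intestine are
wired, using five linked measurements:

1. **Transient fingerprinting.** A focal electrode on an interganglionic
   fiber tract is stimulated twice; every neuron's Ca^2+^ transient is
   summarized by its dF/F0 amplitude per stimulus and by the amplitude ratio
   ES2/ES1. Ratios near 1 mean a stable synaptic drive; a missing second
   response means the drive was blocked (e.g. by hexamethonium).
2. **Spatial mapping** of responder classes relative to the electrode along
   the oral-aboral axis.
3. **Motility mapping**: spatiotemporal diameter maps of the whole colon and
   detection of migrating motor complex (CMMC)-like propagating
   contractions.
4. **Wiring arithmetic**: regional ratios of neuron density (#N), fibers per
   tract (#F) and responders (#R), against the monosynaptic prediction of
   two activated neurons per stimulated fiber.
5. **Projection morphometry**: orientation classes and a two-component
   Gaussian mixture of axonal projection lengths whose density trough
   separates short from long projecting neurons; plus voxel-level
   quantification of varicosity contact onto soma surfaces.

No recordings are distributed with the package; a synthetic-data module
generates every input with ground truth, so each analysis can be validated
by parameter recovery.

# Transient measurement

For each ROI (an axis-aligned ellipse, axes stored as full diameters) the
trace is the mean intensity over pixels whose centers fall inside the
ellipse, boundary included. Each stimulation epoch has its own baseline
window - the `baseline_frames = 10` frames (5 s at 2 Hz) preceding the
epoch onset - so slow drift between epochs cannot bias the amplitude ratio.
F0 is the baseline mean; the amplitude is

> max(F_i/F0 over the response window) − mean(F_i/F0 over the baseline window),

with a response window of `response_window_s = 10` s from stimulus onset:
the 2 s train plus five decay time constants (tau = 2 s) of a GCaMP-like
transient.

A neuron *responded* when its amplitude exceeds
`max(responder_floor, responder_k * baseline_sd)` with defaults
`responder_floor = 0.05` dF/F0 and `responder_k = 5`. These two constants
are config-exposed because published analyses typically report responders
without stating a numeric criterion.

## Classification

Responders are classified per stimulation pair:

| Type | Pattern | Rule |
|------|---------|------|
| I    | blocked | responded to ES1 only |
| II   | reduced | both, ratio < 0.8 |
| III  | unchanged | both, 0.8 <= ratio <= 1.2 |
| IV   | increased | both, ratio > 1.2 |
| V    | new | responded to ES2 only |

Boundary ratios (exactly 0.8 or 1.2) are assigned to the closed "unchanged"
interval: a neuron on the boundary is the least surprising case and should
not count as changed. Neurons silent in both epochs are excluded before
classification. Ratio histograms use half-open bins of width 0.2 starting
at 0, pool ratios >= 2.4 in a top bin, and carry "blocked" and "new" as
categorical bins so that percentages over all records sum to 100.

# Synthetic movies: what they emulate and what they do not

`generate_movie()` renders a 1.7 x 1.3 mm field (5 um pixels, 2 Hz) with 30
ganglion centers and 60 somas by default: lognormal soma areas with mean
175 um^2 (between the regional means of ~173 and ~183 um^2 reported for
responding neurons), two stimulus epochs, and per-neuron transients with
instantaneous rise at stimulus onset and exponential decay (tau = 2 s) on a
normalized baseline of 1.0, scaled to uint16 counts.

Free parameters the literature does not constrain are fixed once and
documented here:

* class proportions I/II/III/IV/V = 0.05/0.20/0.50/0.20/0.05 for a
  control-like pair;
* reference (ES1) amplitudes ~ Normal(0.40, 0.05^2) truncated to
  [0.25, 0.60] dF/F0;
* true ratios II ~ U(0.35, 0.65), III ~ U(0.90, 1.10), IV ~ U(1.35, 1.90) -
  uniform laws inside each class interval, kept away from the 0.8/1.2
  boundaries so that a noise-free pipeline must recover classes exactly and
  misclassification under noise reflects measurement error, not boundary
  ambiguity of the truth itself;
* two epochs 60 s apart rather than the experimental 10 min: the gap length
  does not enter any statistic.

Spatial bias is a per-neuron Bernoulli draw on the sign of the axial offset
from the central electrode (e.g. P(aboral | Type I) = 0.9 by default), with
the magnitude uniform over the half-field. When a drawn position collides
with an already placed soma, only the position within the chosen half is
resampled - resampling the sign as well would let crowding push neurons
toward the emptier side and bias the realized aboral fraction below the
configured probability.

The noise model is additive i.i.d. Gaussian per pixel and frame, in
baseline-normalized units. `noise_sd_for_snr(config, snr)` returns the
pixel noise at which the mean amplitude over the pixel noise SD equals
`snr`; because a soma covers ~10 pixels at the default resolution, ROI-mean
traces are roughly sqrt(10)-fold cleaner. This per-pixel convention is the
level the generator actually controls; it matters because amplitude is a
max statistic, whose ratio noise is about sqrt(2)/SNR at trace level - at
trace SNR 10 that is +/-0.14, enough to push even a perfectly "unchanged"
neuron across the 0.8/1.2 boundaries ~15% of the time, so no classifier
could stay above 95% accuracy under that reading.

Not emulated: optics (PSF), photobleaching, motion, glial signals,
overlapping somas, segmentation error (ground-truth ROIs are the exact
rendered ellipses). Passing recovery tests therefore validates the
*estimators*, not robustness to those real-data nuisances.

# Spatial analysis

ROI centers are transformed rigidly into an electrode-anchored frame with
the axial coordinate positive in the aboral direction. The aboral fraction
counts `rel_axial >= 0` (the measure-zero boundary is assigned aborally);
the electrode band is interpreted as *total* width `band_width_um = 500`,
i.e. +/-250 um around the electrode, boundary inclusive - the phrase
"500 um oral-aboral band" is ambiguous between half- and full-width, so
the choice is explicit and configurable. Soma areas use
pi * long/2 * short/2 with axes as full diameters, and "large" somas are
strictly above 200 um^2.

# Motility analysis

Diameter maps come either from the generator or from silhouette videos:
per frame and per column along the gut axis, diameter = silhouette pixel
count x pixel size, with one intensity threshold per video chosen by a
histogram-valley rule (minimum of the kernel density between the two
dominant modes; manual override available).

Event detection uses a per-position temporal median as baseline - robust as
long as contractions occupy less than half of the recording at any
position. Cells with diameter below `(1 - contraction_depth) x baseline`
(default depth 0.3) form 8-connected components in the (position, time)
grid; components spanning >= 5 mm are events. Two contractions merging in
space-time count as one event, as event identity is otherwise undefined.
Initiation is the most oral contracted position at component onset; speed
is the least-squares slope of the leading front (earliest contracted time
per position), signed aboral-positive.

The generator schedules `round(rate x duration)` onsets quasi-regularly
with 20% jitter, so a noise-free map at 0.4 events/min over 15 min contains
exactly 6 bands and the recovered frequency is exactly 0.4 per min; over
60 min at the physiological proximal rate of 0.38 per min the recovered
frequency is within one event per recording of the generative rate.

# Wiring arithmetic

`consistency_report()` compares the observed responder ratio
#R_dis/#R_prox with the product of the neuron-density and fiber ratios, and
the observed responder counts with the `fanout x fibers` prediction
(default fanout 2: one antidromic plus one synaptic activation per
stimulated fiber). Two modes are always reported, because multiplying
conventionally rounded ratios (0.85 x 0.50 = 42.5%) differs from the raw
quotient product (42.9%): `raw` divides the raw regional means; `paper`
rounds the density ratio to two decimals and divides whole-fiber counts
(35.9/18.2 fibers are reported as 36/18, giving 0.50 rather than 0.507).
Printing both avoids silently disagreeing with either convention.

# Projection mixture

`fit_bimodal()` is a two-component 1D Gaussian EM with 10 restarts
(median-split initialization plus per-restart jitter from a private RNG
stream; best log-likelihood wins), components ordered by mean. The trough
is the argmin of the fitted density on a 0.01 mm grid between the means. A
fit is only called bimodal when (a) the means are at least one larger
component SD apart and (b) the density minimum is interior - condition (b)
matters because EM on a unimodal sample happily splits it into two
overlapping components that can pass the separation rule while the fitted
density still has no trough at all. Orientation classes partition the
0-180 degree range at 45 and 135 degrees (boundaries inclusive toward
oral/aboral); the angular rule is a package convention, as category labels
alone do not define one. Lengths at the cutoff are assigned to "long".
Regional proportions are compared with a 2x2 chi-square test without
continuity correction (Yates optional).

The pooled projection-length fit is the supported analysis path; per-region
fits are possible by subsetting but regional samples (tens of neurons) are
small for mixture estimation.

# Contact quantification

Surface voxels are mask voxels with a face-adjacent (6-connectivity)
background or out-of-volume neighbor. A soma surface voxel is "in contact"
when a varicosity voxel lies within `contact_distance_vox` in Chebyshev
distance (default 1, the 26-neighborhood - on the integer grid exactly the
voxels within Euclidean sqrt(3)). Commercial surface-contact tools do not
publish their criterion, so ours is explicit and configurable; results are
comparable across datasets analyzed with the same criterion but only
qualitatively with other tools. Distances are counted in voxels; for
anisotropic stacks this under- or over-weights the coarse axis, which is a
documented limitation (a physical-distance mode can be emulated by
resampling masks to isotropic voxels upstream).

The phantom generator records realized coverage computed by
nearest-neighbor distances, an independent evaluation of the same
criterion, so generator and analysis cross-check each other.

# Numerical choices and problem sizes

* Pixel membership uses pixel centers; boundary ties are included.
* Movies are stored as 16-bit TIFF; integer counts round-trip exactly, and
  amplitude quantization error is below 2/F0 (~0.2% dF/F0 at the default
  gain).
* EM tolerance 1e-8 on the log-likelihood, at most 500 iterations, SDs
  floored at 1e-6 mm.
* Validation workloads are sized for interactive runs: 60-neuron movies
  (one noise-free, twenty noisy seeds), 300-neuron layouts for spatial
  recovery, 15- and 60-minute motility maps at 0.5 mm / 1 s resolution,
  2000-draw mixture samples, and 48^3 contact phantoms.

# Known limitations

* ROI segmentation, motion correction and deconvolution are out of scope;
  the pipeline consumes ROI tables and masks as given.
* The responder criterion and response window are conventions, not fitted
  quantities; sensitivity to them should be explored via `run_config()`.
* The wiring model is deliberately simplistic (monoaxonal neurons, one
  synaptic partner); its value is as a null against which excess
  connectivity is quantified, not as a mechanistic simulation.
* Generated movies cannot stand in for tissue-level statistics (regional
  responder counts, amplitude differences, blocked fractions under
  nicotinic blockade); those require recordings and are validated here only
  through parameter recovery on synthetic data.
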