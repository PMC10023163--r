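---
title: "Methods: quantifying calcium-channel-defined vesicle pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying calcium-channel-defined vesicle pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synapsepools)
```

At nematode neuromuscular junctions, two classes of voltage-gated calcium
channels release distinct synaptic-vesicle pools: CaV2 channels sit in a
dense ~250 nm cluster at the dense projection and fuse vesicles docked
immediately adjacent to it, while dispersed CaV1 channels, coupled to
ryanodine receptors (RyR) that amplify calcium from internal stores, fuse a
lateral pool. This package implements the five quantitative analyses that
establish that picture — single-molecule localization microscopy (SMLM)
cluster geometry, nearest-neighbour colocalization, channel counting from
blink statistics, quantal decomposition of miniature currents, and
docked-vesicle fusion profiling from electron micrographs, plus the
supporting locomotion metrics — together with synthetic-data generators that
plant known ground truth for every stage.

This vignette is the package's account of the models behind each analysis,
the tunable parameters and their defaults, what the generators emulate (and
do not), and the numerical choices made where the design was genuinely open.

## Localization tables and synapse windows

A localization is one blink: one detected emission of a single fluorophore,
with lateral position (nm), photon count, frame index, and a Cramér–Rao
lower-bound precision (nm). Tables are delimited text with a header; a
*dialect* registry maps vendor exports (column names and length units) onto
the canonical schema `x_nm, y_nm, z_nm, photons, frame, precision_nm,
probe`, so deposited particle files can be consumed by declaring a dialect
rather than editing files.

Standard filtering keeps blinks localized to 80 nm or better. The threshold
is *inclusive* (`precision_nm <= 80`): inclusivity only affects records
exactly at the boundary and an inclusive rule is idempotent and simplest to
state. The axial coordinate is discarded before any geometry
(`flatten_z()`): chromatic aberration between channels makes z unreliable,
so all distances here are 2D.

A synapse window (ROI) is the set of localizations, over all probes, within
700 nm of a dense-projection fiducial cluster centre (ELKS is the fiducial
throughout). The 700 nm half-width brackets the ~580 nm average synapse
size. Windows are anchored on fiducial *cluster centres*, not nearest
fiducial localizations — centres are far more stable; a localization within
reach of two centres joins the nearer (ties to the lower ROI id). The 700 nm
window is applied to all probes alike: per-probe windows would make the
denominators of pooled fractions incomparable. One practical caveat the
analysis scripts demonstrate: at ~1 µm synapse spacing, probes whose clouds
extend ~450 nm from their centres (CaV1, RyR) bleed into neighbouring
windows, so per-synapse geometry of dispersed probes should use isolated
(en-face selected) synapses.

## Cluster geometry on the inter-centre axis

Each probe's cluster is reduced to its unweighted centre of mass. For a
probe pair, the *axis* runs from the origin probe's centre (ELKS, mapped to
0) to the target's centre, and every localization is collapsed to its
signed scalar projection on that axis. All spread statistics are computed on
these signed axial coordinates:

* **Binned profile** — half-open bins `[33k, 33(k+1))` anchored at 0,
  reported as fractions. The 33 nm width matches the electron-microscopy
  section thickness so light and EM profiles share bins.
* **Diameter** — the width of the central 95% interval (97.5th minus 2.5th
  percentile, linear interpolation). Read as a spread measure it can be
  compared across probes and matches the printed ~294–297 nm diameters of
  Gaussian-like clusters (for a Gaussian, diameter = 3.92 σ). A
  radial-distance definition was rejected: radii cannot be negative and
  would halve widths.
* **Within-cluster fraction** — the fraction of origin-probe localizations
  inside the target's central 95% interval on the shared axis, pooled over
  synapses (per-synapse averaging is available but pooling is the default).

Planted-parameter consistency: Gaussian clouds with sd 75 nm (ELKS) and
77.4 nm offset by 124 nm reproduce both the printed diameters (294 nm and
297 nm) and the printed 62% ELKS-within-CaV2 fraction —
`pnorm(271/75) - pnorm(-23/75) = 0.620` — so those quantities are mutually
consistent measurements of one geometry, and the acceptance tests recover
all of them through the full pipeline from a synthetic cord.

Cord-level cluster detection projects a probe's localizations onto their
first principal component (the cord axis), links runs separated by gaps of
at most 250 nm, and keeps clusters of at least 20 localizations; spacing is
the consecutive-centre distance and density is (n−1)/span. The 250 nm gap
and minimum size 20 are package defaults (nothing is printed for either);
closely spaced fiducial pairs can merge under gap linking, which surfaces as
a missing cluster in the planted-truth tests.

## Nearest-neighbour colocalization

For each source-probe localization, the 2D distance to the nearest
target-probe localization (first neighbour only), computed within a synapse
window and pooled across synapses; the headline statistic is the fraction
within 100 nm (inclusive). The relation is intentionally asymmetric
(RyR→CaV1 differs from CaV1→RyR). The implementation uses a bucket-grid
with ring expansion (exact; verified against an O(n²) oracle in the tests);
sources far outside the target cloud fall back to a vectorized scan.

## Counting channels from blink statistics

A fluorophore blinks several times per session, so blinks overestimate
channels. The counting model:

* **Grouping** — blinks within 60 nm of each other are assumed to come from
  one channel (density clustering, core threshold 2, i.e. connected
  components of the 60 nm neighbourhood graph); lone blinks are still
  channels (singlet promotion). 60 nm reflects the achieved ~40 nm image
  resolution with headroom under the 80 nm precision filter.
* **Blink law** — blinks per *observed* channel is modelled zero-truncated
  Poisson (a channel that never blinks is unobservable). The estimator fits
  the plain Poisson maximum-likelihood mean m on observed counts — the
  sample mean — with no truncation correction; the truncation lives in the
  generator, keeping generator and estimator consistent at the observed
  mean m = 2.7 (underlying rate λ solving λ/(1−e^{−λ}) = 2.7, ≈ 2.472).
* **Estimators** — per synapse: total blinks / m; total photons / pooled
  mean photons per grouped channel (pooled across all synapses — a
  per-synapse mean would be degenerate); and total blinks / (6 blinks
  min⁻¹ × duration) when channels cannot be resolved at all (the dense CaV2
  cluster). Photon modes are computed on 50-photon bins (bin centre
  reported); note that with the photon law below the two bins flanking the
  mode carry nearly equal mass, so the binned mode needs ~10⁶ blinks to be
  stable.
* **Packing bounds** — geometric capacity of a circular cluster: published
  optimal circle-in-circle packing ratios for N ≤ 20 (60 nm footprints in a
  250 nm cluster: 12), and a centre-anchored, fixed-orientation hexagonal
  lattice count for large N (20 nm channels in 250 nm: 121). The lattice is
  a reproducible construction rather than an optimality search; printed
  capacities near 120 depend on the unstated construction, so the tests
  accept 119–121.

## The synapse generator

`simulate_synapse()` is the validation instrument for the counting chain.
Per channel: a position from the placement model; a zero-truncated Poisson
blink count; per blink: a log-normal photon count with mode 575 and mean
765 (log-normal is the minimal right-skewed two-parameter law matching
both; meanlog = log(mode) + σ², σ² = ⅔·log(mean/mode)); a precision of
c/√photons with c = 426 nm·photons^½, calibrated so a bright 806-photon
blink is localized to 15 nm (the photon mode then maps to ~17.8 nm, within
the 15–29 nm range typical of these recordings); and a position error drawn
isotropically with that precision. Frames are uniform over the 60 s, 50 Hz
session — no photobleaching kinetics are modelled. A dark-channel fraction
(default 0) supports bias studies. Every blink is ledgered to its channel.

Placement presets:

* **CaV2** — 101 channels uniform in a 250 nm disc (the dense projection
  cluster). Blink mean 569/101 ≈ 5.63, so a synapse shows ~569 blinks per
  minute, matching the printed observable; dividing by the nominal 6
  blinks/min rate then yields ~95 channels, the same ~6% shortfall the
  printed numbers carry (569/6 = 94.8 against a best estimate of 101).
* **CaV1** — 79 channels by hard-core random sequential adsorption
  (exclusion 100 nm) in a 1400 nm field. The field is deliberately the
  window size rather than the probe's printed pooled localization spread
  (869 nm): blink-statistics counting presupposes channels resolvable at
  the 60 nm grouping radius plus localization jitter, and 79 channels
  packed into 869 nm sit ~93 nm apart at best, where grouping merges
  neighbours wholesale (measured: ~20–32 recovered groups of 79). The
  printed spread is a *localization* statistic pooled over synapses, not a
  placement parameter; the separate geometry preset below reproduces it.
  Under the chosen placement the full pipeline recovers a mean ~77.5 of 79
  (the ~2% residual shortfall is the honest merge/split balance of
  grouping at this density).
* **RyR** — 29 channels, same hard-core model in an 869 nm field
  (no RyR extent is printed; the varicosity scale is used); recovery ~28.7
  of 29.

`simulate_cord()` generates probe *localization clouds* (not blinking
channels) for the geometry analyses: ELKS fiducials every 1.10 ± 0.16 µm
along the cord, each with optional Gaussian target clouds at planted axial
offsets. The geometry preset plants the measured values: CaV2 offset 124 nm
with 95% diameter 297 nm; CaV1 offset 262 nm, diameter 869 nm; RyR offset
393 nm. The channel-placement and localization-cloud presets describe the
same proteins at different fidelity for different questions: counting needs
the blink process per channel; geometry needs only the pooled spatial law
of localizations.

What the generators do *not* emulate: camera noise, PSF shape, drift,
chromatic offsets, photobleaching decay, background staining (the high
background that made RyR photon flux unusable in practice), or true channel
positions correlated with other active-zone proteins. Passing tests
therefore show the estimators are correct *given the statistical model*,
not that real images satisfy the model.

## Quantal decomposition of miniature currents

The modal amplitude of miniature postsynaptic currents is the
single-vesicle response; k simultaneous fusions sum to ≈ k × mode.
Amplitudes are binned at 1 pA (half-open, anchored at 0) and the histogram
is fit by nonlinear least squares with a sum of three Gaussian terms. The
term-k mean is box-constrained to k·mode ± k pA (the printed 7±1, 14±2,
21±3 pattern: both centre and latitude scale with k); widths and amplitudes
are free apart from positivity. Fitting targets raw counts, unweighted (the
fractions are invariant to count rescaling). Nine deterministic starts
(mean offsets −0.5k/0/+0.5k × width scales 0.5k/k/2k) make the fit
reproducible; the best residual is kept. Per-term areas come from trapezoid
integration at 0.1 pA over the histogram support; the multiquantal fraction
is 1 minus the first term's area fraction.

Generator presets: `nemadipine` (CaV1 blocked; mode 7 pA, weights 0.67 /
0.18 / 0.15) and `dantrolene_nemadipine` (CaV1+RyR blocked; mode 6 pA,
weights 0.75 / 0.15 / 0.10), with class-k amplitudes Normal(k·mode,
σ₁√k), σ₁ = 2 pA — a generator default, since no component width is
printed — truncated at 0.

Two numerical caveats, both visible in the tests. First, a symmetric
component centred on an integer splits its mass evenly between two 1 pA
bins, so the empirical modal bin of a 20 000-event preset sample can land at
mode−1; the constrained fit tolerates this (the truth remains inside the
boxes) but scripted analyses should treat a near-tie as ambiguous. Second,
the upper components overlap, so a single 20 000-event fit determines the
third mean only to ~±1.5 pA; recovery is therefore assessed as the average
over replicate fits (which is unbiased to ±0.2 pA and ±2 percentage
points), and the acceptance checks report replicate-averaged fractions.

## Docked-vesicle fusion profiles

Docked vesicles (in membrane contact) are tabulated by distance from the
dense projection in the same 33 nm bins. The synapse is the statistical
unit: per-bin means are taken across synapses within a condition, and
fusion is the unstimulated mean minus the stimulated mean per bin — vesicles
lost to stimulation. Negative differences (apparent docking increase) are
reported and flagged, never clipped. Three zones summarize the profile:
adjacent (0–33 nm), intermediate (33–165 nm) and lateral (165–594 nm);
zone release probability is fusion over unstimulated docking on zone
totals, undefined (flagged) for empty zones.

The generator draws independent synapse cohorts per condition with
per-bin Poisson docked counts around a default profile (1.8·e^{−k/4} + 0.2
vesicles per bin, ~12 docked per synapse) and thins each stimulated vesicle
independently with its bin's depletion probability. Depletion presets
encode the genotype logic (wild type uniform 0.5; CaV2-null sparing the
adjacent zone; RyR-null sparing everything but the adjacent zone; CaV1
hypomorph reduced throughout; double mutant zero). With 120 synapses per
condition the zone probabilities are recovered to ~±0.1; low-occupancy
bins are noisy, so recovery tests use 3-SEM bounds (delta method on the
ratio of means) rather than fixed tolerances.

## Locomotion metrics

Tracks are centroid positions at 8 frames/s for 5 min. Filtering discards
animals leaving the field of view within the first 3 min and animals whose
assay-mean speed, pauses excluded, is below 100 µm/s. A reversal is a
maximal backward run lasting strictly more than 4 frames (> 500 ms — the
two printed forms of the rule agree at 8 fps). Direction labels come from
the tracker or generator; head–tail inference is out of scope. Pauses are
frames labelled paused, or — when labels are absent — frames slower than
20 µm/s (no printed threshold exists; 20 µm/s is the package default and is
configurable). Metrics per worm: total path distance (mm), mean speed over
non-pause frames (µm/s), reversals per minute, forward-run distance and
duration between reversals, and reverse distance and duration per bout.

The bout generator alternates forward runs (mean 15 s), reversals (mean
2.2 s, probability 0.8 after a forward run) and pauses (mean 12 s),
with bout speeds near 300 µm/s forward / 250 µm/s backward and a small
heading random walk. These values were chosen once to land near healthy
wild-type crawling (~295 µm/s moving speed, ~1.9 reversals/min, ~75 mm per
assay) and are not fit to anything downstream.

## Problem sizes and determinism

All simulations are deterministic under a fixed seed. The validation suite
uses: 1000 synapses per counting preset (the blink-mean estimator's
cross-synapse sd is ~2, so the mean is determined to ±0.07); 10⁴ channels
for the Poisson blink-mean recovery; 2 × 10⁴ events per quantal fit with
replicate-averaged recovery; 26-synapse cords for geometry (matching the
reported pooling); 500 synapses per condition for EM thinning recovery; and
8–12 worms for locomotion. On one CPU the whole suite runs in well under a
minute apart from the two 1000-synapse counting experiments (~15 s each).

## Known limitations

* The counting presets guarantee channel resolvability by construction;
  they quantify estimator behaviour, not how severe grouping bias is in
  real dense arrangements (for that, the CaV2 preset shows the failure mode:
  one giant group).
* The photon-flux and blink-mean estimators share one grouping, so their
  cohort means coincide exactly here; the printed values differ (75 vs 79)
  because the study pooled the two statistics over different subsets.
* The quantal model fixes the number of terms at three; it does not select
  model order, and the third component is weakly identified in single
  samples (see above).
* Packing bounds are capacity statements about circles, not biophysics: the
  60 nm "footprint" encodes a resolution argument, not channel size.
* EM distances are consumed as annotated; no re-projection along the
  membrane is attempted.
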