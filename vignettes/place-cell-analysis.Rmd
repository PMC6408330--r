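---
title: "Methods: rate maps, replay decoding, theta sequences and reactivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rate maps, replay decoding, theta sequences and reactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placeseq)
```

`placeseq` implements the full analysis stack used to characterise
hippocampal place-cell ensembles recorded on a square track with flanking
rest sessions: spatial rate maps, brain-state and population-event
detection, cell-pair reactivation, Bayesian replay decoding with linear
trajectory fitting and shuffle nulls, theta-sequence scoring, and
single-cell phase precession. Because suitable recordings are rarely
shareable, every stage is paired with a synthetic-session generator whose
ground truth the analyses must recover; this vignette explains the models,
the tunable parameters, the numerical choices, and what the recovery tests
do and do not establish.

## Data model and conventions

A session (`ps_session`) holds spike times per sorted unit, tracked
position at a fixed rate (50 Hz by default, matching head-mounted LED
tracking), one or more LFP channels, and metadata. All times are seconds
from session start, all positions cm. Trials are 15 minutes in the
emulated protocol; tests and examples use shorter sessions (2-12 minutes)
purely to keep computation proportionate, and every problem size used by
the test suite is stated in the tests themselves.

The square track (62.5 cm arms for pups, 100 cm for adults) is handled as
a circular 1D coordinate: position 0 at the corner nearest the origin,
increasing along (0,0) to (side,0) first, on the half-open range
`[0, perimeter)`. Positive displacement along this path is labelled CW.
Linearization snaps each 2D sample, by its angle about the centroid of
the four corners, to the nearest of a set of perimeter points 0.25 cm
apart; the centre and nearest-arc rule are choices this package fixes
because "radial binning" alone does not determine them.

Running speed is the centred finite difference of the trajectory after a
400 ms boxcar - a standard treatment for LED jitter; downstream analyses
do not depend on the estimator beyond epoch edges. Immobility (< 2.5
cm/s) is excised before any rate map is built; a sample at exactly
2.5 cm/s is movement. A filtered session keeps its per-sample speeds, so
re-filtering is a no-op.

## Rate maps

Open-field maps use 2.5 x 2.5 cm bins with adaptive smoothing: for each
bin a circle grows until `r >= alpha / (d * sqrt(s))` with `alpha = 200`,
`d` the dwell (s) and `s` the spike count inside the circle, and the rate
is `s/d`. The candidate radii are the sorted distances of bin centres
from the target bin, so the expansion is exact on binned data. Until at
least one spike is enclosed the criterion is treated as unsatisfiable;
if it is still unmet at the environment diagonal, a bin with dwell is
rated 0 (silent cells keep maps) and a bin without dwell is unvisited.

Track maps are built per running direction from epochs of at least 5 s of
constant-direction running at >= 2.5 cm/s. Dwell and spike counts in
2.5 cm circular bins are smoothed with a wrapped Gaussian (sd 5 cm,
truncated at +/- 3 sd and renormalised - stated support makes the kernel
reproducible bit-for-bit) and divided. Smoothing before division, rather
than after, preserves total dwell and spike mass. A sigma = 8 cm Gaussian
field smoothed this way has its peak scaled by `8/sqrt(8^2 + 5^2)`
(about 0.85); parameter-recovery tests compare against that closed form,
not against the unsmoothed peak.

Spatial information is the Skaggs estimator
`sum_i p_i (lambda_i/lambda_bar) log2(lambda_i/lambda_bar)` in bits per
spike; place-field similarity (PFS) is the Pearson correlation of two
maps over jointly visited bins (at least 10 required).

## Brain states, ripples, MUA bursts, theta cycles

State classification computes a multitaper PSD (DPSS tapers, NW = 2.5,
4 tapers, computed from the symmetric tridiagonal formulation and cached
per window length) in 1.6 s windows overlapping by 0.8 s. Theta (5-11 Hz)
and delta (1.5-4 Hz) peak frequencies are located on the whole-trial FFT
spectrum - theta slows in young animals, so the bands are anchored per
session - and window band powers integrate the PSD over peak +/- 1.5 Hz
(theta) and +/- 1 Hz (delta), clipped to the nominal bands. Rest is
speed < 2.5 cm/s with theta/delta < 2; waking movement is ratio > 2 with
speed > 2.5; everything else is `other`, so a window can never be rest
while the animal moves. Without EMG, rest and slow-wave sleep are not
distinguished; a single rest state is used everywhere.

Ripples: each channel is band-passed 100-250 Hz (zero-phase order-4
Butterworth), enveloped by a 7 ms RMS, and the channel with the highest
envelope SD defines events as 100 ms windows around suprathreshold local
peaks, thresholded at the 99th percentile of that envelope over the whole
trial. By construction ~1% of samples exceed threshold on any input, so
spurious noise peaks are expected; downstream analyses rely on the
SWR-MUA conjunction, not on ripples alone. Overlapping windows are merged
keeping the stronger peak, preventing one ripple from counting twice.

MUA bursts: the 1 ms-binned ensemble spike train is smoothed with a 10 ms
Gaussian; excursions above mean + 3 SD lasting 100-750 ms (bounds at the
threshold crossings) are events, and only bursts overlapping a ripple
window - even partially - become candidate replay events.

Theta cycles: phase comes from the analytic signal of the LFP filtered at
the session theta peak +/- 2 Hz, with 0 degrees at the filtered-LFP peak. The
preferred ensemble phase is the 5-degree bin with maximal ensemble spiking in
movement epochs, and cycle boundaries are crossings of the phase 180 degrees
opposite - cycles are anchored where the population is quietest.

## Bayesian decoding, linear-band fits, shuffle nulls

Decoding uses the standard Poisson population form with a uniform prior:
`P(pos) proportional to prod_i f_i(pos)^{n_i} * exp(-tau * sum_i f_i(pos))`,
computed in log space with a log-sum-exp normalisation so zero-spike
windows decode to the prior-weighted term rather than failing. Rates are
floored at 0.01 Hz inside the decoder only, so log rates stay finite
without altering the maps elsewhere.

Candidate events are decoded in 20 ms windows stepped by 10 ms spanning
the MUA burst. The trajectory fit maximises summed posterior probability
inside a 25 cm band around `pos(t) = start + slope*t`, over starts every
2.5 cm and signed slopes -2500..2500 cm/s in 50 cm/s steps, wrapping the
band circularly; CW and CCW posteriors are fitted independently and the
better wins. Ties break toward lower |slope|, then lower start. The scan
is implemented in C++ (`src/band_fit.cpp`) because the shuffle null
re-runs it a thousand times per event. Reported speed is |slope| and
distance is speed x MUA burst duration. Note that for a short event a
delta-thin posterior line is genuinely ambiguous: any slope whose line
stays within the 12.5 cm half-band over the event duration ties at the
maximal score, and the tie-break resolves toward slower slopes. The
noiseless recovery tests therefore use band-shaped posteriors over >=
0.4 s, where the maximum is unique.

Significance: 500 shuffles re-decode and re-fit the event with either the
cell-to-map assignment permuted (`cell_id`) or each map circularly offset
by an independent amount (`map`); CW and CCW map sets are shuffled
independently and each shuffle contributes its best fit across
directions. An event is significant when its real score exceeds the 95th
percentile of its own shuffle scores. RNG is seeded per event
(`seed + event index`) so results are reproducible and parallelisable.

The session gate mirrors the source protocol: more than 25 cells firing
more than 75 RUN spikes each (after immobility filtering), and a median
online decoding error below 10 cm, measured in non-overlapping 300 ms
windows against the rat's circular-mean position. Awake replay applies
the identical machinery to RUN epochs with speed < 1 cm/s.

## Theta sequences and phase precession

RUN spiking in qualifying epochs is decoded in 20 ms windows sliding by
5 ms; each posterior is recentred so the rat's position is 0 cm with the
axis pointing along travel (CCW posteriors reversed), truncated at
+/- 50 cm (covering the 30 cm sequence extents seen in development, with
margin). Each window receives its fraction of elapsed time through the
current theta cycle by linear interpolation between successive cycle
boundaries; windows are averaged within 10 equal theta-time bins.

The theta sequence score is the probability-weighted circular-linear
correlation between relative position and theta angle
(`2*pi*(k - 0.5)/10` for bin k - bin centres avoid within-bin bias):
`rcl = sqrt((rXC^2 + rXS^2 - 2 rXC rXS rCS)/(1 - rCS^2))` with the three
coefficients computed as posterior-weighted Pearson correlations. The
same formula, unweighted, with spike theta phase as the circular variable
and in-field position as the linear one, scores single-cell phase
precession. Two properties of this coefficient are worth keeping in
mind: it is nonnegative (direction-blind), and it reaches exactly 1 only
when the linear variable depends sinusoidally on the angle - a perfectly
linear 320-degree phase advance scores about 0.89, which is why the tests
assert a high ceiling rather than unity for that case.

Speed matching discards the fastest or slowest decode windows one at a
time, whichever moves the median toward the 10.6 cm/s target, stopping
when no single removal improves it; if the target lies outside the
observed range the best achievable median is returned with a warning.

Main fields are contiguous bins around the map peak, extended until the
rate falls below 20% of the peak or a local minimum under 50% of the
peak intervenes; the direction whose main field holds the most spikes is
analysed. Cells enter the precession analysis only with spatial
information above 0.15 bits/spike and more than 25 in-field spikes.

## Reactivation

Per cell pair: PFS from the RUN maps; SWR co-firing as the Pearson
correlation of per-event spike counts within the 100 ms ripple windows
(the only per-event window the protocol defines), requiring at least 10
events and defined variance; theta-cycle co-firing as the correlation of
per-cycle counts, with the number of jointly active cycles and the
pair's spikes within them. Plasticity is the POST minus PRE SWR
correlation; pairs from the same tetrode are not distinguished (the
package has no tetrode bookkeeping). Coupling across pairs is summarised
by Pearson r with `SE = sqrt((1 - r^2)/(n - 2))`; PRE vs POST coupling is
compared by Fisher z - the underlying protocol names no test, so this is
an explicit assumption of the package. Plasticity curves bin pairs by a
co-activity measure (log-spaced edges 1, 2, 4, ... by default; the source
axes are not machine-readable) and report the smallest bin whose mean is
significantly positive by one-sample t-test.

## The synthetic generator

`ground_truth()` fixes everything the analyses must recover. Defaults
describe a young-rat session: a 62.5 cm track, 40 cells with evenly
spaced circular-Gaussian fields (sigma 8 cm, 10 Hz peak), 7 Hz theta, 50 Hz
tracking, 1000 Hz LFP. The seed fully determines every sample.

Running alternates CW/CCW bouts (20 s at 15 cm/s, 3 s pauses). Firing is
inhomogeneous Poisson on a 1 ms grid: spatial tuning evaluated at a
*represented* position that sweeps from behind to ahead of the animal
within each theta cycle (extent `theta_compression * sweep_half_cm * 2`),
multiplied by a von Mises theta modulation (unit temporal mean, so
spatial rates are preserved) whose preferred phase advances with distance
into the field at `precession_slope_deg_cm`. Directional remapping is
built in: CCW field centres are a decorrelated permutation of the CW
tiling, as opposite-direction fields remap in real recordings - this also
matters statistically, because the replay null takes the best fit across
independently shuffled CW and CCW map sets, and degenerate identical maps
would bias that null conservative. The sweep is anchored to the phase of
maximal ensemble firing so its wrap coincides with the demarcated cycle
boundaries. One honest limitation: when both the sweep and precession are
enabled at once their wraps interact nonlinearly and the combined
alignment shifts; each mechanism alone produces the canonical
behind-to-ahead sweep, and the recovery tests exercise them separately.

Rest sessions are immobile, with delta-plus-noise LFP and a
Gaussian-windowed 150 Hz burst at every event - sufficient for a
band-power detector without pretending to biophysics. Replay events emit
spikes along `pos = start + slope*(t - t0)` through the tuning curves;
stationary events co-activate cells with centres within 10 cm; noise
events emit homogeneous Poisson spikes at a gain (default 5) times each
cell's track-average rate - the gain makes bursts detectable above the
0.2 Hz rest background and cancels out of the cell-identity shuffle null,
which remains exact by construction. Event rates during rest in young
animals are not constrained by the source, so event times and counts are
free parameters of each scenario.

What passing recovery tests show: the pipeline recovers tuning peaks,
field positions, slopes, sequence structure and coupling that are
actually present, and stays at chance when they are absent. What they do
not show: robustness to non-Poisson spiking, electrode drift, sorting
errors, multimodal fields, or realistic LFP nonstationarity - none of
which the generator emulates.

## Numerical choices

- Decoder rate floor 0.01 Hz; posteriors normalised in log space (rows
  sum to 1 within 1e-9).
- Band-fit discretisation: a line's bin offset is `round(slope*t/bin)`;
  bins whose centre falls within 12.5 cm of the line are in-band (11 bins
  at 2.5 cm).
- Adaptive smoothing radii are the sorted bin-centre distances; the cap
  is the environment diagonal.
- The track-map kernel is truncated at +/- 3 sd and renormalised; the MUA
  kernel likewise.
- Butterworth order 4, zero-phase (`filtfilt`), for ripple and theta
  bands; the theta band for phase is the session peak +/- 2 Hz.
- DPSS tapers: NW = 2.5, K = 4, eigendecomposition cached per window
  length.
- Quantiles use R's default (type 7) definition; the SWR threshold and
  the shuffle significance percentile both inherit it.
- Degenerate inputs are flagged, not imputed: zero-variance correlations
  are missing, zero-variance t-tests are `degenerate`, empty direction
  maps make downstream operations refuse.

## Problem sizes

The test suite and the acceptance script generate everything they use at
run time. Sessions range from 20 s (round-trip IO) through 120-300 s
(event detection, sequences) to 720 s (peak-rate recovery, ~16 passes per
field); the null calibration uses 120 events in the test suite and 200 in
`scripts/acceptance.R`, each with 500 cell-identity shuffles at 25 cells
and 40 position bins. These sizes were chosen so each check has the
statistical resolution its assertion needs.
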