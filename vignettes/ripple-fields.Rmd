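---
title: "Detecting replay without ripples, and mapping ripple fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting replay without ripples, and mapping ripple fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hippocampal replay — brief epochs during immobility in which the decoded
population activity traces a spatially extended trajectory at compressed
speed — is conventionally detected by first finding sharp-wave ripples
(transient 100–220 Hz LFP oscillations) or population spiking bursts and
then asking whether the spiking inside those windows is sequential. That
construction makes it impossible, by design, to observe replay *without*
ripples or bursts. `ripplefields` implements the converse pipeline: replay
is detected purely from the smoothness and compactness of the decoded
position trajectory, with no reference to ripple power or spike density, and
ripple occurrence is then analysed *conditional on the replayed location*.
The central object of that analysis is the **ripple field**: a spatial map,
over the locations depicted by replay, of mean instantaneous ripple power
normalized by replay occupancy.

## The detector

Spikes from all place cells are decoded with a memory-less Bayesian decoder
over sliding windows (duration `tau` = 80 ms, stride 5 ms), assuming Poisson
spiking, cell independence and a uniform spatial prior:

$$P(\mathbf{x}_j \mid \vec k) \propto \prod_i f_i(\mathbf{x}_j)^{k_i}
  e^{-\tau f_i(\mathbf{x}_j)}$$

with $f_i$ the smoothed rate map of cell $i$ on a 2 cm grid. Each window is
summarized by its posterior center of mass $\mathbf{x}_{cm}$, spread $m$ and
COM jump $\delta$ to the next window. A window is *valid* when the rat is
still ($\nu_{rat} < 5$ cm/s at the window center), the posterior compact
($m < 10$ cm) and the trajectory smooth ($\delta < 20$ cm). Maximal runs of
valid windows form candidates; neighbouring runs merge across gaps of at
most 50 ms and 20 cm. A candidate is accepted as replay when

* its duration exceeds 100 ms,
* its spatial dispersion $D$ (RMS distance of the COM path from its mean
  location) exceeds 12 cm, which also rejects stationary reactivations, and
* it beats a place-cell-ID shuffle: the event is re-decoded 100 times with
  the cell-to-field assignment permuted, and both the mean spread and mean
  jump must be smaller than all but at most 5% of the shuffles.

### Numerical conventions

* **Posterior spread.** The default spread is the square root of the trace
  of the posterior covariance, $m^2 = \sum_j (\|\mathbf{x}_j -
  \mathbf{x}_{cm}\|^2) P_j$, which is in cm and therefore directly
  comparable with the 10 cm gate. A product-moment variant
  ($m^2 = \sum_j (x_j - x_{cm})^2 (y_j - y_{cm})^2 P_j$, units cm²) is
  available via `convention = "product"` in `posterior_summaries()`.
* **Dispersion.** The default is the RMS form
  $D^2 = \frac1M \sum_t \|\mathbf{x}_{cm}^t - \langle \mathbf{x}_{cm}
  \rangle\|^2$. A variant that averages unsquared norms is available via
  `form = "literal"` in `dispersion()`; note that under that form $D$ has
  $\sqrt{\text{cm}}$ units and cannot exceed ~8 inside a 90 cm arena, so
  the 12 cm acceptance gate is only meaningful under the RMS form.
* **Rate floor.** A floor of $10^{-4}$ Hz is added to rates inside the
  likelihood so the log-likelihood is defined at unvisited bins.
* **Windows.** Timestamps are window centers; windows truncated at interval
  edges are dropped so every decoded bin shares the same `tau`. The jump
  gate invalidates the earlier of the two windows it spans, and only when
  the later window itself passes the speed and spread gates.
* **Filtering.** Position and speed smoothing use zero-phase second-order
  Butterworth filters with *normalized* cutoffs (0.1 and 0.02 as fractions
  of Nyquist, matching the common filter-design convention for those
  printed values), applied with odd-reflection padding so that no lag or
  edge transient leaks into the timing analyses.

## Event detection and labeling

Ripple power is the band-passed (100–220 Hz) LFP's analytic-signal
magnitude, smoothed with an 80 ms SD Gaussian (1 s kernel) and z-scored with
statistics computed from stopping periods only; the tetrode-averaged variant
averages smoothed envelopes across tetrodes *before* z-scoring. Population
spike density sums all clusters' spikes in 1 ms bins and receives the same
smoothing and z-scoring. Threshold events require z > 2 SD for ≥ 15 ms
(ripples; adjacent events merged when boundaries are < 50 ms apart) or
z > 3 SD for ≥ 50 ms (bursts; no merging). Event boundaries extend outward
to the first return to the mean, taken as the z = 0 crossing since the
z-scored mean is 0 by construction.

A replay is *ripple/burst-less* only if (1) no ripple or burst event's peak
time lies inside it and (2) its peak ripple power and peak spike density do
not exceed the 95th percentile of 100 random replay-length snippets drawn
uniformly from stopping periods outside all replay intervals. The snippet
criterion is applied as non-exceedance for bursts as well as ripples,
keeping the two tests symmetric. The per-tetrode analysis counts tetrodes
whose ripple events peak inside a replay; `min_confident_detectors(64,
0.11)` gives the smallest count (11) that chance detections at an 11%
per-tetrode false rate would reach with 95% probability.

## Ripple fields

The z-scored signal is interpolated to each replay path's timestamps;
per 2 cm bin, samples over all replay visits are summed and divided by the
replay occupancy, then smoothed with an 8 cm SD Gaussian kernel
renormalized over occupied bins. Bins never visited by replay are invalid.
Significance of spatial information, split-half stability (chronological
first vs second half of replays) and correlations against reference maps
comes from circular permutation: the concatenated per-replay signal samples
are rotated by a random offset, preserving the signal's autocorrelation and
multiset exactly while destroying its alignment with replayed location.
Because the paths are sampled at 200 Hz (the decoder's 5 ms stride), the
signal is interpolated at that native resolution by default; a coarser
20 Hz option is provided (`sample_hz` in `compute_event_field()`).

Two conventions deserve note. Spatial information of a z-scored field
floors negative values at zero (a field with no positive mass has zero
information); the same flooring applies to every shuffle, so the null
comparison is unaffected. For display, fields may be z-scored across bins;
that transform is never used in statistics.

Field zones resample the field as a discrete distribution (10,000 draws)
and cluster the samples with DBSCAN semantics (radius 3 bins, minimum 250
neighbors, clusters with ≥ 1000 samples kept). Since all samples fall on
bin centers, the clustering is computed exactly on per-bin counts. A zone's
boundary is the level set of its (lightly smoothed) sample density at 0.3
of peak. Directional tuning takes every replay crossing with ≥ 30 cm of
in-zone path, assigns it the circular mean of its segment angles and a
has-ripple flag (event peak during the crossing), and compares the mean
vector length of ripple-bearing directions against nulls built by
circularly shifting ripple times within the concatenated replay timeline.

Barrier dissimilarity convolves each session's barrier-overlapping bins
with a 10 cm SD Gaussian into a potential $b(\mathbf{x})$ and evaluates
$BD(\mathbf{x}_i) = \sqrt{\sum_{l=1}^{4} (b^I_l - b^J_l)^2} / \|2h\| - 1$
over the four nearest bins, where $\|2h\|$ is the Euclidean norm of twice
the kernel — the largest attainable numerator — so that $BD = -1$ wherever
the local barrier structure is identical. Trajectory dissimilarity
histogramms movement-segment angles within 8 cm of each bin and reports the
negative correlation of the two sessions' histograms.

## The synthetic session generator

Every stage above is validated against sessions from `make_session()`,
whose ground truth includes the planted fields, replay paths, ripple zones
and injected transient times. The generator emulates:

* **Environment.** A 90 × 90 cm arena with 9 wells and transparent barriers
  in 6 of 12 canonical slots (choose(12, 6) = 924 configurations). Barrier
  segments stop 5 cm short of wall junctions — they are free-standing
  "jail bars" the animal can pass around — so every configuration remains
  fully traversable.
* **Behavior.** Alternating stops at wells (stationary, 5–12 s) and run
  bouts along shortest barrier-avoiding paths with triangular speed
  profiles peaking at 30–60 cm/s, sampled at 200 Hz.
* **Place cells.** 150 Gaussian tuning curves (8 cm SD, log-normal peak
  rates around 15 Hz, 0.2 Hz baseline), uniform centers by default with an
  over-representation knob (`field_bias`).
* **Replays.** Constant-speed straight paths reflecting at the walls.
  Speeds are log-normal around 400 cm/s — twenty times a typical run speed,
  the compression conventionally reported for replay — and durations
  log-normal with ~300 ms median, clipped to 0.2–1 s. Replay spikes are
  Poisson draws from the fields at the *replayed* position with gain 2.5.
* **Quiet background and reallocation.** During immobility, cells fire
  diffusely at 20% of their field's spatial mean rate, independently of the
  rat's position; inside replay epochs this background is suppressed so
  replay re-expresses, rather than adds to, population spiking. Stationary
  "reactivation frames" (Poisson process, ~1.5/s during stopping, ~280 ms,
  at the replay gain but at a fixed location) give stopping periods
  replay-scale spike-density fluctuations. This reproduces the empirical
  signature that trajectory-less reactivations and ripple-less replays show
  spike density comparable to the stopping-period background — which is
  exactly what makes the burst/snippet labeling a calibrated test — while
  the dispersion gate rejects the stationary frames themselves.
* **LFP and ripple zones.** Per-tetrode 1/f background noise plus 150 Hz
  Hann-windowed transients (~80 ms) injected at the midpoint of every
  crossing of a designated ripple zone (two 12 cm disks by default).
  Transient amplitude is calibrated by `calibrate_ripple_amplitude()`,
  which runs the analysis pipeline's own envelope computation on reference
  noise and on a unit transient and solves for the amplitude reaching a
  target post-smoothing z-score (6 by default). Replay spiking is boosted
  6× while the path is inside a zone, so bursts and ripples co-localize in
  replayed space, as observed in recordings. Replays that never enter a
  zone receive no transient; their fraction is the session's designed
  ripple/burst-less fraction.

A single session seed is expanded into fixed per-component substreams
(`substream()`), so components are reproducible independently.

What the generator does **not** emulate: theta sequences and phase
precession during run, biophysical LFP content beyond a 1/f background and
the injected band transients, spike sorting noise, forward/reverse replay
structure, replay initiation biased toward the rat's location, and
multi-session cell tracking beyond a stable/unstable relocation flag.
Passing tests therefore demonstrate that the pipeline recovers the
structure it assumes, at realistic rates and noise levels — not that real
recordings satisfy those assumptions.

## Validation problem sizes

The acceptance-style tests run at sizes chosen to exercise the full
pipeline comfortably on a single CPU: detector recovery on three 5-minute
sessions with 150 cells and 20 planted replays each (aggregate sensitivity
≥ 0.8 at a false-detection fraction ≤ 0.2); ripple/burst-less fraction
recovery on one 15-minute, 200-replay session (±5 percentage points);
null calibration of the field-information shuffle over 200 runs with
location-independent signal (empirical false-positive rate in [0.02, 0.10]
at α = 0.05); and zone recovery on twenty 8-minute, 100-replay sessions
(both zone centers within 8 cm and field-to-truth correlation ≥ 0.7, where
the truth map is the zone indicator smoothed with the same 8 cm analysis
kernel, in at least 18 of 20 seeds).

## Known limitations

* The decoded COM path is a temporally smoothed version of the true
  trajectory; short events therefore have compressed dispersion, and
  planted replays shorter than ~200 ms at typical speeds fall below the
  12 cm gate. This mirrors the detector's intrinsic bias toward longer,
  straighter events.
* The quiet-background level trades off chance candidates (higher
  background concentrates spurious posteriors) against burst-test
  exchangeability; the defaults resolve this with sparse diffuse background
  plus stationary frames, but other operating points are possible through
  `synthetic_config()`.
* `field_null()` assumes replays are long enough that a circular rotation
  decorrelates signal from location; with very few, very short replays the
  null is conservative.
* Dissimilarity maps are descriptive; no significance machinery is attached
  to them beyond the generic field correlation null.
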