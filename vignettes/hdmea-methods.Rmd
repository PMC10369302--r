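---
title: "Methods: single-neuron analysis of high-density MEA recordings"
author: "hdmea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-neuron analysis of high-density MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdmea)
```

`hdmea` analyzes extracellular voltage recordings from high-density
CMOS microelectrode arrays: lattices of square electrodes so dense that a
single soma covers several of them and an axon is sampled along its whole
length. This vignette documents the models and procedures each stage
implements, the parameters that matter, what the bundled synthetic-data
generator does and does not emulate, and the numerical choices made where
the methods left freedom.

## Geometry and containers

An `ElectrodeGrid` is a regular rectangular lattice described by its row
and column counts, center-to-center pitch (default 11.47 µm = 11.22 µm
electrode side + 0.25 µm separation) and electrode side. Indexing is
row-major; all distances are Euclidean distances between stored centers,
and adjacency throughout the package is the 8-neighborhood (corner
electrodes have 3 neighbors, edges 5, interior 8). The full-array
constants live in `HDMEA_ARRAY`; `electrodeDensity()` reproduces the
91.9% metal-coverage figure from 236,880 × (11.22 µm)² over 5.5 × 5.9 mm.
Two slightly different printed sensing-area figures exist (5.5 × 5.9 and
5.51 × 5.91 mm); both are kept as constants and the coverage arithmetic
uses the former. The stated 14-block × 33,840-electrode readout layout
does not multiply back to the total electrode count; the package treats
block structure as opaque metadata and never derives geometry from it.

A recording is a plain electrodes × samples matrix in µV plus sampling
rate and grid. The on-disk container is a single serialized bundle with
`voltage`, `grid` and `meta` fields; the reader validates the schema,
names any missing field in its error, and accepts an equivalent in-memory
list so containers produced by other tools can be adapted without
touching files. Round trips are bit-exact.

## Signal conditioning

**Detrending.** Offset drift is removed by least-squares detrending in
consecutive 500-sample blocks (a trailing partial block is fitted the
same way). Constants and single-block ramps are absorbed exactly.

**Spike band.** 100–3000 Hz, as a causal cascade of a 2nd-order
Butterworth high-pass at 100 Hz and a 2nd-order Bessel low-pass at
3000 Hz. `signal` provides the Butterworth design and the bilinear
transform; the Bessel analog prototype (poles of s² + 3s + 3, −3 dB point
prewarped to the corner) is computed in-package because `signal` has no
Bessel designer. When the sampling rate cannot carry the 3000 Hz corner
(rate ≤ 6000 Hz — true for 5 kHz recordings) the corner is clipped to
0.45 × rate with a warning, mirroring what any implementation must do at
that rate.

**LFP bands.** Gamma (30–100 Hz) and ripple (150–250 Hz) extraction uses
a windowed-sinc (Hamming) FIR band-pass run forward and backward
(`filtfilt`), so passband peak times are preserved exactly. The order is
3 × rate / low-edge rounded to even — long enough for ≥ 40 dB stopband
in the configurations used here, and capped by the signal length.

**Wavelets.** The scalogram is the magnitude of
W(b, a) = (1/a) ∫ f(t) G((t − b)/a) dt with the complex Morlet
G(x) = (π F_B)^(−1/2) exp(−x²/F_B) exp(2πi F_C x), F_B = 5, F_C = 1, and
scale a = 1/frequency. Discretization is direct convolution with the
sampled mother wavelet under zero padding; the Gaussian envelope is
truncated where it falls below ~10⁻⁸ of its peak. The frequency grid is
logarithmic (120 points over 0.1–250 Hz by default; both range and
resolution are arguments). Cells within one wavelet support of either
signal edge are flagged in a cone-of-influence mask rather than silently
reported — tests only assert on interior cells.

**SNR.** Peak |v| over the whole trace divided by the noise level of a
user-chosen quiet window (≥ 0.1 s). "Noise level" is taken as the quiet
window's standard deviation, the convention consistent with quoting
hardware noise in µV rms. A warning fires if the global maximum sits
inside the supposed quiet window.

## Spike detection and unit formation

Spikes are detected on detrended, spike-band traces wherever |v| crosses
a ± threshold (80 µV default for cortical cultures; 100 µV for sensory
neurons; 200 µV for organoid and soma-locus work — all arguments).
Within one threshold excursion the timestamp is placed at the extremum of
the *leading lobe* — the lobe containing the first crossing, i.e. the
sink of a biphasic extracellular spike. The simpler absolute-extremum
rule was tried first and rejected: the causal filter cascade's rebound
occasionally overshoots the sink, and the timestamp then jumps ~1 ms to
the source lobe, which destroys sample-level timing against ground
truth. A 1 ms dead time suppresses double counts.

Electrodes are merged into single-neuron units by the firing-pattern
rule: each electrode's spike train is binned into 1 ms histograms, and
adjacent electrodes (8-neighborhood) with cosine similarity ≥ 0.3 are
linked; connected components become neurons (`igraph` provides the
component search; a brute-force transitive closure is the test oracle).
All-zero histograms are defined to have similarity 0, so silent
electrodes never merge. The unit's train is the union of member spike
times deduplicated within the 1 ms bin; its centroid is the mean member
position. Raising the similarity threshold can only refine the
partition, which the tests assert as monotonicity.

For sensory-neuron cultures, somata are located without thresholds by
the neighborhood waveform-similarity map: for every interior electrode,
the mean cosine similarity between its full raw trace and its eight
neighbors' traces. Electrodes above mean + 2 SD of the map (a documented
choice; the method itself states no cutoff) are grouped by adjacency
into soma calls.

Activity summaries report per-unit firing-rate bands over
{0, (0, 0.1), [0.1, 0.5), [0.5, 1), [1, 2), [2, 5), [5, 10), ≥ 10} Hz,
electrodes-per-soma histograms, and electrode-level totals (active
count, active fraction of a contact mask, per-5-ms firing-electrode
histograms).

## Burst analytics

**Network bursts** follow the four-step ISI method: pool and sort all
unit spikes; group runs with inter-spike intervals ≤ `isiThMs`; merge
groups separated by strictly less than `ibiThMs`; keep groups with at
least `minSpikes` spikes from at least `minUnits` units. The method
names these thresholds without printing values; the defaults here
(100 ms, 300 ms, 5 spikes, 2 units) follow common MEA practice and are
all arguments. The exact-threshold case does not merge (strict
inequality), which a boundary test pins down.

**Single-neuron bursts** use the Poisson-Surprise statistic
S = −ln P(N ≥ n) for N ~ Poisson(rT), with r the unit's overall mean
rate. Candidate groups are maximal runs of ISIs below the train's mean
ISI; within each, the contiguous sub-window maximizing S is kept when
S ≥ 10 (natural log) and it has ≥ 3 spikes. S is evaluated through the
upper-tail log-probability (`ppois(..., lower.tail = FALSE, log.p =
TRUE)`), which the tests check against independent direct tail summation
to 10⁻⁸ relative (absolute 10⁻¹² where S itself is at double-rounding
scale). On homogeneous Poisson trains the detector averages well under
one burst per 100 s.

**Parameter table.** Twelve parameters per condition: total spikes,
burst count, inter-burst interval, duration, spikes per burst, max
frequency (MF: the peak 10-ms-bin count of the intra-burst histogram,
expressed in Hz), inter-MF interval (anchored at the MF bins' centers —
the anchor is not defined by the method and is a documented choice), and
coefficients of variation of the last five. Entries that need bursts are
flagged NA when there are none; CVs need at least two bursts.
`normalizeToVehicle()` expresses a condition as percent of vehicle
(= 100%), NA where the vehicle value is zero. Significance testing on
the normalized tables (ANOVA/Dunnett) is left to standard routines.

## Surrogate connectivity

For an ordered unit pair (i, j), the synchronized-spike count is the
number of j spikes in the half-open window (t, t + 100 ms] after each i
spike — simultaneous (deduplicated) spikes are not self-counted. The
null is built per pair from 100 surrogates of the *target* train that
keep the first spike time and permute the ISI multiset, preserving
count, span and the ISI distribution exactly; a flag shuffles both
trains for users who prefer a symmetric null, at double cost.
Z = (real − surrogate mean) / surrogate SD; when the surrogate SD is
zero, Z is 0 if the real count equals the surrogate value and undefined
(NA, never ±∞) otherwise. Pairs with Z ≥ 3 are classified excitatory and
Z ≤ −3 inhibitory; a strictness flag switches to strict inequalities,
since the method's prose uses both. Ordered pairs are counted in the
network-level percentages, and the per-unit excitability connection rate
is ECR = 100 · |{j ≠ i : Z_ij ≥ 3}| / (n − 1). Calibration on
independent stationary Poisson pairs keeps the excitatory call rate
under 2.5%, and planted couplings with probability ≥ 0.3 at 1 Hz over
150 s are detected in over 80% of draws — both are fixed-seed test
properties.

## Axonal conduction

Candidate conduction electrodes are selected by synchronous firings: in
each 50 ms window, each electrode's maximum-|v| time is found, and an
electrode scores when ≥ 4 of its 8 neighbors peak within 1 ms of it.
The soma locus is the largest connected component of selected electrodes
whose amplitude reaches 200 µV (smaller hotspots are reported as
secondary candidates); its spike train is detected on its peak
electrode. Spike-triggered averaging over ±3 ms then suppresses noise by
√n-of-triggers, making the ~40 µV axonal signal dominant.

Front tracking walks the averaged map in 0.1 ms frames: an electrode
"fires" at its first crossing below −5× its own noise level (per-row MAD
of the averaged map — the method does not define firing on an averaged
map, so the criterion is explicit and configurable), and each frame
selects the firing electrode farthest from the soma centroid, skipping
empty frames and excluding the soma component. Cumulative straight-line
distance between consecutive selections is the conduction distance; its
least-squares slope against time (mm/ms) is the velocity in m/s, with R²
reported, alongside the endpoint ratio distance/time that matches how
such velocities are quoted from printed distance/time pairs (the two
differ slightly by construction, and both are exposed). Backward frames
(t < 0) are tracked identically.

A trigger counts as backpropagating when ≥ 5 path electrodes fire in the
pre-soma window [−3, 0) ms in distal-to-proximal order; order is
enforced as a Spearman rank correlation ≤ −0.9 between fire time and
distance. A looser "any negative correlation" rule was tried and
produced chance-level false positives when exactly five noisy electrodes
crossed threshold; the near-monotone requirement reproduces the
generator's planted backpropagation probability exactly on the bundled
fixture. Velocity time-courses are reported as percent of the baseline
(= 100%) with SEM across wells.

## LFP propagation

Events in a region are detected on the rectified amplitude envelope (a
centered running maximum of |v| over 10 ms): an event spans contiguous
frames in which at least `minElectrodes` region electrodes reach the
threshold (default 5× the per-electrode quiet-period SD — the event
threshold is not stated by the method). The envelope matters: an
oscillatory event crosses zero twice a cycle, and raw thresholding
fragments one wave into dozens of events. The propagated area is the
distinct active-electrode footprint times the lattice cell area (pitch²,
in mm²; a flag switches to bare metal area), and the areal velocity is
area over event duration (mm²/s) — area is thus frame-rate invariant by
construction. Inter-region synchrony counts event pairs whose onsets
fall within a window (50 ms default) of each other.

## Evoked-response clustering

Each unit's response is its spike-count histogram in 100 × 100 ms bins
over the 10 s after administration. Vectors are clustered as raw counts
(magnitude is part of the response; a normalization flag exists,
default off) by Ward-linkage agglomerative clustering on Euclidean
distances (`hclust`, `ward.D2`), cut at k = 5 by default or at a given
height. Per-cluster summaries report the peak rate and peak time of the
cluster-mean profile and its 10 s mean, plus per-condition cluster
ratios that sum to 100%. The peak is read off a 3-bin moving average of
the mean profile: the raw argmax of a 100-bin noisy profile is biased
upward (it is the maximum of a hundred fluctuating values), and light
smoothing removes most of that selection bias while flattening genuine
peaks by well under a percent; the window is an argument (`smoothBins`,
1 disables).

## The synthetic-recording generator

All stages are validated on `simulateRecording()`, which composes, on a
chosen grid and sampling rate: soma units (biphasic negative-first
templates, 1 ms sink + 1 ms half-amplitude source lobe, amplitude
decaying with distance d from the centroid as 1/(1 + d/pitch), footprint
= electrodes within a radius in pitches), Poisson or two-state bursting
base trains, directed couplings (excitatory: target fires with
probability p at a uniform latency in (0, 100 ms]; inhibitory: target
spikes in the window are deleted with probability p), axonal conduction
(arc length / velocity latency per path electrode, a narrower 0.5 ms
waveform of 40 µV default, and per-spike mirrored pre-soma injection
with the backpropagation probability), radially expanding Hann-windowed
LFP sinusoids whose disc grows linearly in area (the expansion rate is
the areal-velocity ground truth), five evoked-response templates, and
additive Gaussian noise of 9.43 µV rms by default. Everything is keyed
to one integer seed; identical seeds give bit-identical voltage
matrices. Ground truth (trains, memberships, couplings, per-electrode
latencies, backpropagating spike indices, wave extents, template labels)
is returned alongside.

Generator choices worth knowing:

- The axonal waveform is also injected on the electrodes flanking the
  path at 0.8× amplitude with the nearest path electrode's latency. A
  signal confined to a one-electrode-wide line would leave path
  electrodes with fewer than 4 signal-bearing neighbors, making the
  ≥ 4-of-8 synchronous-firing selection unsatisfiable by construction —
  and a real axon is in any case sensed by the flanking rows.
- The `axon` preset samples at 20 kHz so the 0.1 ms tracking step is an
  integer number of samples and first-crossing times resolve below the
  step; culture-style presets use 5 kHz, the slice preset 1 kHz.
- Evoked templates are gamma-shaped rate bumps
  (t/t_p)^k exp(k(1 − t/t_p)) with per-cluster shape k ∈ {—, 1.5, 2.5,
  2, 9} and peak times {—, 1.5, 1.5, 1.3, 1.2} s; amplitude and baseline
  are solved exactly on the discrete bin grid so that each template's
  discrete peak rate and 10 s mean equal the per-cluster statistics
  (20.7/7.7, 35.8/9.4, 52.8/13.2, 80.2/8.2 Hz), with cluster 1 a flat
  1 Hz baseline and cluster 5's k = 9 giving the sharp decay. Spikes are
  drawn as an inhomogeneous Poisson process on the bins.
- What is *not* modeled: biophysical membrane dynamics, volume
  conduction and electrode impedance, waveform variability between
  spikes of one neuron, overlapping-unit waveform superposition beyond
  linear summation, electrode drift, and correlated (non-white) noise.
  Passing recovery tests on this generator therefore demonstrates that
  the estimators are correct under their stated assumptions, not that
  they are robust to every artifact of real tissue.

## Test and validation scale

The suite runs the full chain at deliberately modest sizes — grids of
144–900 electrodes, 2–60 s of signal, 20 kHz at most — chosen so each
recovery property is well-powered while the whole suite completes in a
couple of minutes on one core; all statistical assertions use fixed
seeds. Quantitative recovery results under those conditions: tracked
conduction velocity within 5% (R² ≥ 0.99) at 0.5–2 m/s under 9.43 µV rms
noise; surrogate excitatory-call rate below 2.5% on 500 independent
Poisson pairs with ≥ 80% detection of p ≥ 0.3 couplings; 20-unit merge
recovery with membership Jaccard ≥ 0.9; wavelet magnitudes within 1% of
direct numerical integration; evoked-cluster matched-label agreement
≥ 0.9 (matched-label accuracy: the fraction of responses correctly
assigned under the best one-to-one cluster-to-template matching) with
the cluster-4 template's peak recovered within 10% and one bin.

## Known limitations

- The recording container holds the voltage matrix in memory; at the
  full 236,880-electrode, 5 kHz scale a recording does not fit, and the
  analysis functions would need a chunked backend. All algorithms are
  per-electrode or per-window streamable, so this is a container, not an
  algorithm, limitation.
- `detectNetworkBursts` pools spikes; extremely active single units can
  dominate a "network" burst. The `minUnits` filter is the guard.
- The surrogate null assumes stationary firing; strong slow rate drift
  inflates Z for both members of a pair. The both-sides shuffle flag
  mitigates but does not remove this.
- Ward clustering of raw counts weights high-rate responses more; for
  rate-normalized phenotypes set `normalize = TRUE`.
- The front tracker assumes one dominant axonal arbor per soma; branch
  points yield the farthest-branch composite path.
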