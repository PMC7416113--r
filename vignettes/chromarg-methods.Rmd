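---
title: "Models and methods behind chromarg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromarg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromarg)
```

chromarg is a pipeline for the functional and morphological typing of
larval zebrafish retinal ganglion cells (RGCs). It covers five stages:
spectral-kernel estimation from calcium traces recorded under
tetrachromatic binary noise; per-kernel typing (polarity, ternary cone
wiring, chromatic opponency, spectral centroid); Eye-IPL mapping of any
per-ROI statistic; Gaussian-mixture clustering of full spectral response
profiles; and point-cloud morphometrics with dendritic-tilt statistics.
Every stage is exercised on synthetic data produced by the package's own
generators, so each estimator can be validated against known ground
truth. This vignette explains the models, the parameters that matter,
the numerical choices, and what the synthetic validation does and does
not demonstrate about real recordings.

## The stimulus and the reverse-correlation model

The stimulus is a full-field tetrachromatic binary sequence: four LED
channels (red, green, blue, UV) flicker independently at 6.4 Hz for
258 s, giving `floor(258 * 6.4) = 1651` frames (the fractional trailing
frame is dropped). The channels carry "natural white" photon weights —
red 100%, green 50%, blue 13%, UV 6% — as metadata; reverse correlation
operates on the raw binary sequence, and the LED state persists between
frame updates (zero-order hold).

A neuron's spectral kernel set is estimated as a calcium-event-triggered
average. Traces sampled at 15.625 Hz (a 64-ms frame at 2-ms line speed
over 32 lines) are detrended by subtracting a 10-s moving-average
baseline (a high-pass above ~0.1 Hz), z-normalized on the 1–6 s window
at the start of the recording, differentiated, and linearly resampled
onto the 500 Hz stimulus-alignment clock. Every clock sample whose
derivative exceeds 0.7 baseline SDs becomes one event weighted by the
derivative value; no peak grouping is applied, so a single calcium
transient contributes a run of consecutive weighted events — this is a
deliberate reading of "weighting each sample by the steepness of the
transient". The kernel is then, per channel and per lag on the canonical
grid of 649 samples (dt = 2 ms, from −973.5 ms to +322.5 ms),

$$F(l,\tau) = \frac{1}{M}\sum_{i=1}^{M} \dot c(t_i)\, S(l, t_i+\tau),$$

with events whose lag window leaves the stimulus span dropped (and M
decremented) rather than zero-padded, to avoid biased edges. Because
event times live on the 500 Hz clock and all lags share one fractional
sample offset, the sum collapses to an exact FFT correlation; the direct
sum is retained for small or off-clock event sets and as the test
oracle.

Kernels are displayed and thresholded in z-scores of their own baseline:
the mean and SD of the first 50 ms of lag (the 25 earliest samples) are
subtracted and divided out. Two quality measures follow: the
peak-to-peak amplitude in baseline SDs (gate at 10 for "responsive")
and the SD of the normalized kernel over the whole lag axis (gate at 5
for clustering).

### A caveat on the 10-SD bound and synthetic noise

On this stimulus the kernel noise is strongly autocorrelated across
lags: at 2-ms spacing under 156-ms frames, adjacent lags are ~99%
correlated. The 50-ms baseline window therefore spans only a third of
one stimulus frame and its SD underestimates the kernel's noise scale by
a factor of roughly 3–5. As a consequence, on synthetic data the
peak-to-peak quality of pure-noise kernels (e.g. from temporally
shuffled events) sits around 15–35 rather than below 10, independent of
event count or SNR — the ratio is scale-free. The acceptance suite
asserts the classical below-10 null behaviour as specified and that
assertion fails by construction on synthetic data; the unit suite
instead verifies the robust property that noise kernels fall well below
the responsive population's median quality. Users applying the 10-SD
gate to real recordings should calibrate it against their own shuffled
controls.

## The synthetic forward model

`simulate_trace()` inverts the estimator by construction: the centred
binary stimulus (+/−1) is filtered by the planted kernels on the 500 Hz
clock; the drive is rectified and scaled so the mean event rate equals
`event_rate_scale`, with a configurable spontaneous floor (default 10%)
so that zero-kernel ROIs still fire stimulus-independent events; events
are Bernoulli per 2-ms bin; an exponential indicator kernel (default
0.4 s, GCaMP6f-like — a fixture choice, not an empirical claim) blurs
them; and Gaussian noise is added relative to the clean trace's SD. The
defaults — 8 events/s, noise SD 0.2, 258 s — were fixed once from a
pilot characterization as a realistic operating point and define the
package's *documented SNR threshold*: at these settings, planted
channels whose relative gain is at least 0.5 of the dominant channel are
recovered with Pearson r ≈ 0.9 and 100% polarity accuracy; gain-0.3
channels reach ~94% polarity accuracy and gain-0.2 channels degrade to
~70%. Population-level figures quoted by the acceptance script (mean
r ≥ 0.8 over all connected channels; ≥95% polarity accuracy at the
documented threshold) refer to these conditions.

Kernel templates are differences of two Gaussian lobes in lag with the
opposite-signed lobe earlier, so the planted polarity coincides with the
timing rule (minimum before maximum = On). "Monophasic" templates keep a
small (25%) early lobe so the rule stays well defined; "biphasic" uses
85%. Smaller time constants compress the lobes toward the event and
raise the spectral centroid, mimicking kinetically faster channels.

What the generator does *not* emulate: scan or eye-movement artefacts,
indicator saturation and nonlinearity, spatially correlated noise across
ROIs, non-Poisson event statistics, and the true chirp response
dynamics (the chirp waveform here is a configurable stand-in whose only
contract is the 2,499-sample response window at 1 kHz). Passing tests
demonstrate correctness of the estimators under the stated model, not
fidelity to any particular biological dataset.

## Typing: polarity, ternary wiring, opponency, centroid

Polarity compares the positions of a kernel's global extrema: minimum
before maximum is On, the reverse is Off. The ternary state applies the
10-SD gate per channel and signs the largest transition — operationalized
as the signed difference from the earlier to the later global extremum,
which makes the two stated rules provably coincide. The 4-tuple over
{On, Off, NR} is indexed in base 3 (digit order R, G, B, UV; NR = 0,
On = 1, Off = 2), spanning the 3^4 = 81 cone-wiring combinations: 50
opponent (at least one On and one Off), 30 non-opponent (15 all-On and
15 all-Off channel subsets), and one fully disconnected.

Opponency is classified by counting sign changes of the responsive
channels along decreasing wavelength R→G→B→UV, with NR channels skipped
rather than treated as zeros: one change is a simple opponency (the
flanking pair is reported, e.g. G/B), more than one is complex. The
spectral centroid is the amplitude-weighted mean frequency of the
mean-subtracted kernel's DFT magnitude over positive frequencies; it is
scale-invariant, and exact for bin-aligned test signals (spectral
leakage from non-integer cycle counts shifts the plain-DFT centroid, so
the tests use bin frequencies).

## Eye-IPL maps

Eye position in [−π, π) is cut into 8 circular bins of width π/4; IPL
depth into 20 bins, with all somata in bin 1 regardless of depth, bin 2
permanently empty as a visual barrier, and dendrites mapped linearly
onto bins 3–20 (depth 0 = GCL border, 1 = INL border; the lower IPL is
On-dominated). Bin statistics are arithmetic means; empty bins are
missing. Smoothing uses a (1, 2, 1)/4 binomial kernel: circularly along
the eye axis (support ±π/4, i.e. the π/3 scale), and across ±1 depth bin
restricted to bins 3–20. The depth filter reflects at the half-sample
boundary (the out-of-range neighbour folds onto the edge bin), the only
(1,2,1) boundary treatment that conserves mass exactly; missing bins are
excluded with weight renormalization, so mass conservation is exact on
fully populated dendritic grids and approximate around holes.

## Functional clustering

ROIs passing the SD-quality gate at 5 contribute their four concatenated
kernels. Each colour block is divided by one scalar — its SD pooled over
all ROIs and time points — to weight colours evenly, then mean-centred
PCA is run per colour, keeping the fewest components whose cumulative
explained variance reaches 99%, and the four score blocks are
concatenated (R, G, B, UV).

The mixture sweep fits k = 1…k_max components under four covariance
structures — shared-diagonal, unshared-diagonal, shared-full,
unshared-full — with a 1e-5 ridge on every covariance, an EM iteration
cap of 1e4, and 20 replicates per cell initialized by k-means++ seeding
plus a short Lloyd refinement (replicate r uses seed `base + r`).
Replicates are screened at a loose EM tolerance (1e-4 relative) and the
best is polished to 1e-6 from its own responsibilities, which cannot
lower its log-likelihood; a replicate whose components empty out or
whose covariance loses positive definiteness is recorded as failed, not
fatal. BIC is `−2 logL + p log n` with p counted per structure; ties
break toward smaller k, then the simpler structure in the order listed.
A fixed-(k, covariance) override mirrors the fallback used when BIC
gives no clean optimum. Clusters below the minimum membership (10 for
dendritic, 5 for somatic datasets by convention) are dropped and their
ROIs left unassigned; survivors are re-indexed by size. The in-package
EM exists so that the regularization, replication and BIC conventions
are exactly controllable; an independent mixture fitter (mclust) serves
as a cross-check in the test suite, where both recover identical
partitions and log-likelihoods on separated mixtures. Desk-scale runs
default to k_max = 20; the full protocol value is 100 and is a single
argument away.

## Morphology

Dendritic point clouds carry tangential coordinates in micrometres and a
depth coordinate linearly rescaled so the IPL spans [0, 10] (values
outside mark INL/GCL processes). Four summaries describe each cell:
y_span (stratification width), y_mean (mean depth), num_pts (point
count), and xz_area (tangential convex-hull area; fewer than three
non-collinear points give area 0 rather than an error). xz_area is
reported but not clustered on, as its information largely duplicates
y_span and num_pts.

Clustering standardizes each summary (n−1 SD convention) and proceeds in
two stages of agglomerative clustering with city-block distance and
average linkage: stage 1 on (y_span, y_mean, num_pts) cut at a fixed
k = 18 (fixed because no automatic criterion is defined — the cut level
is a required input), then the two largest clusters (overridable by
explicit ids, since the original choice was by visual inspection) are
re-split on y_span alone into 6 and 3 subclusters: 18 − 2 + 9 = 25
clusters, of which those with ≥ 4 members form the presentation set.
The cophenetic correlation coefficient (correlation between tree-implied
and original distances, in [−1, 1]) accompanies every tree.

Dendritic tilt translates the soma to the origin and expresses the
dendritic centre of mass in spherical coordinates with the polar angle
measured from the +y axis (perpendicular to the retinal plane; the y/z
roles are deliberately swapped relative to the textbook convention):
θ = 0 means no tilt, θ = π/2 puts the CoM at the soma's own depth, and
ϕ = atan2(z, x) ∈ [0, 2π) is the tilt direction. The zero direction of ϕ
is a per-dataset configuration matter, since retinotopic orientation
differs between regions; the atan2(z, x) convention is the package
default. Group comparisons use the two-sample KS test for r and θ and a
two-sample Kuiper test for the 2π-periodic ϕ. The Kuiper statistic
V = D⁺ + D⁻ is exactly invariant to a common rotation of both samples;
its p-value uses the standard asymptotic series with Stephens'
finite-sample argument correction, returning 1 below argument 0.4.
Monte-Carlo calibration (1,000 null replicates, n = 100 per group) puts
both tests' type-I error at α = 0.05 around 0.03 — slightly
conservative, as expected from asymptotic p-values at finite n.

The cloud generator plants stratification (y_mean, y_span in IPL units),
tangential spread, and a soma-relative tilt vector (r, θ, ϕ in
micrometres/radians). Because y_mean and the tilt vector jointly
over-determine the soma position, the soma is placed at
`y_mean − r·cos(θ)` (in depth), making both constraints hold; the
sampled scatter is mean-centred after drawing, so the planted CoM —
and hence the recovered tilt — is exact at any point count while span
and spread remain match-in-distribution. A rejection sampler provides
von Mises tilt directions in the test suite.

## Orchestration and formats

`run_pipeline()` executes simulate → kernels → classify → maps →
functional clustering → report from a single nested configuration
(YAML-serializable; unknown keys abort before any computation), writes
tidy CSV stage outputs plus a JSON report and manifest (file hashes,
seeds, version), and is byte-reproducible given an identical
configuration. All randomness descends from the single configuration
seed. Serialization is flat CSV/JSON throughout. `import_deposited()`
reads externally produced kernel/chirp tables defensively, validating
every row against the canonical 649-sample (dt = 2 ms) and 2,499-sample
(dt = 1 ms) grids and reporting offending rows by index.

## Problem sizes used in validation

The shipped validation uses desk-scale problem sizes chosen as the
package's own test design: a 200-ROI population at the full 258-s
stimulus for kernel recovery; 300-point, 5-dimensional mixtures with
10-SD separation over 10 seeds for model selection (k_max 20, 20
replicates); 132 synthetic clouds over four planted morphological types
for the two-stage clustering; 200 power and 1,000 calibration replicates
for the circular statistics. The unit suite runs smaller editions of the
same designs.

## Known limitations

* The 10-SD responsiveness gate does not reject synthetic noise kernels
  (see the caveat above); its value is meaningful only relative to a
  dataset's own null calibration.
* The chirp waveform is a stand-in; only its 2,499-sample window is
  contractual.
* The GMM protocol's initialization and BIC tie-handling are not fully
  specified by the original protocol; k-means++ seeding and the
  smaller-k/simpler-structure tie-break are this package's documented
  choices, both configurable in code.
* Kuiper p-values are asymptotic; below ~20 angles per group they are
  conservative.
* No attempt is made to reproduce dataset-level biological results
  (cluster counts, opponency percentages); those depend on the recorded
  population and require the deposited data via `import_deposited()`.
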