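---
title: "Models and methods behind tauaggr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tauaggr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tauaggr)
```

This vignette records the models the package implements, the parameter
choices that matter, what the synthetic-data generators emulate (and what
they do not), and the numerical decisions taken where the design was
genuinely open. The companion test suite and `scripts/acceptance.R`
compute every empirical claim made here; nothing below is asserted that
the code does not itself measure.

## The scientific setting

Soluble hyperphosphorylated tau (0N4R tau carrying on the order of 10–19
phosphate groups after sequential kinase treatment) self-assembles into
small amorphous aggregates, in contrast to the micron-scale fibrils that
heparin induces from unmodified tau. Characterizing these species and
their effects requires: measuring aggregate size below and around the
diffraction limit; counting phosphate groups on an intact protein from
native mass spectra in which small-ion adducts (≈23 Da) confound the 80 Da
phosphate ladder; and quantifying the calcium transients, ROS production,
membrane permeabilization, cytotoxicity and gene-expression changes the
aggregates cause in cells. Each stage below is an independent module with
explicit parameters, and each is validated end-to-end against simulated
data with known ground truth.

## Diffraction-limited morphometry

**Model.** A frame-averaged TIRF image is bandpass filtered with a
difference of Gaussians (default sigmas 1 px and 20 px — the narrow one
suppresses pixel noise, the wide one removes slowly modulated background),
lightly blurred (sigma 1 px) and thresholded: a pixel is foreground when
its filtered value exceeds 2% of the image's median intensity (the
background estimate). Because both the filtered signal and the median
scale linearly with the image, segmentation is exactly invariant to
intensity rescaling. Components of fewer than 3 px (configurable; not a
protocol value) are discarded as noise.

**Lengths.** Two measures are computed per particle:

* *Skeleton length* (`particle_length()`): the mask is thinned
  (Zhang–Suen two-subiteration thinning) to a one-pixel skeleton and the
  length is the longest geodesic path with 8-connectivity steps (1 px
  axial, √2 px diagonal) at 107.2 nm/px. This is digitization-exact on
  one-pixel-wide structures (a 10 px bar measures 9 × 107.2 = 964.8 nm; a
  10 px 45° line measures 9√2 × 107.2 ≈ 1364.4 nm).
* *Moment length* (`moment_length()`): the principal second moments of the
  background-subtracted intensity give λ₁ = L²/12 + σ² and λ₂ = σ² for a
  segment of length L under a Gaussian PSF of width σ, hence
  L = √(12(λ₁ − λ₂)), with no dependence on the (unknown) PSF width.

The skeleton measure carries a structural negative bias on
diffraction-limited masks: thinning erodes roughly 1–1.5 px from each
rounded cap, and at 107.2 nm/px with a PSF sigma near one pixel a 500 nm
fibril's threshold mask is nearly isotropic, so its skeleton collapses. We
measured ≈ −60% mean bias at 500 nm and ≈ −15% at 2000 nm for the
skeleton measure under the simulation conditions below, while the moment
measure recovers 300–2000 nm fibrils within +0.2% to +3% and reports
≈ 100 nm for 100 nm-radius isotropic blobs. `dl_analyze()` therefore
reports both columns and summarizes fields on the moment measure; the
skeleton measure remains the right tool on the super-resolution grid,
where caps are small relative to the structure (next section).

**Corrected intensity.** Per-pixel SBR = (I − B)/B with B the image
median, summed over the particle; additive over disjoint masks and
undefined (an error) when B = 0.

**Simulation conditions** (chosen once as representative of the real
acquisitions, and used by all DL validation tests): EMCCD-like background
of 500 counts, Poisson shot noise, Gaussian read noise of 3 counts,
50-frame averaging, PSF sigma 120 nm, aggregate peak brightness 150
counts above background (SBR 0.3). A 2%-above-median criterion is only
meaningful when the background level is large compared to the averaged
noise floor — at these values the threshold (10 counts) sits ≈ 10× above
the post-averaging noise — which mirrors why the protocol thresholds
work on real data.

## The SMLM pipeline

**Stages.** (1) Quality filter: signal strength ≥ 3 and localization
precision ≤ 30 nm. (2) Fiducial removal: localizations are linked at
15 nm; a linked site occupied in more than 500 distinct frames *and*
spatially tight (r.m.s. radius ≤ 15 nm) is a fiducial marker and is
removed. The tightness condition is our resolution of the open question
of what "the same location" means: a densely labeled aggregate chains
into an extended cluster at 15 nm linkage and must not be mistaken for a
marker, while a real marker jitters by far less than the localization
precision. (3) Burst grouping: DBSCAN on (x, y) with ε = 15 nm and
minPts = 3, then DBSCAN on time within each spatial cluster with
ε = 21 ms and at least 2 localizations. With 20 ms frames this makes
adjacent frames neighbors and breaks bursts at gaps of two or more
frames, removing single-frame localizations. (4) Aggregate clustering:
DBSCAN on burst centroids with ε = 200 nm and at least 20 bursts.

DBSCAN uses standard semantics (minPts counts the point itself); for
determinism, border points join the cluster of their lowest-index core
neighbor and cluster ids follow ascending core index. The implementation
(grid-bucketed exact neighbor search) is checked against an independent
brute-force oracle (full distance matrix plus graph components) on
hundreds of random tables in the test suite.

**Cluster length.** Burst centroids in camera-pixel units (107.2 nm) are
scaled 8× and rounded, giving a 13.4 nm grid; the occupancy image is
morphologically closed with a disc of radius 2 grid units, thinned, and
the longest geodesic path is converted back to nm. Two defaults here are
ours: the base pixel (we use the camera pixel; a much finer base grid
would defeat the closing step, because morphological closing — unlike
dilation — cannot connect a sparse point set), and the structuring
element (radius 2; the protocol does not state it; radius 2 bridges the
inter-burst gaps seen at realistic burst densities while keeping blobs
compact).

**What the generator emulates.** Transient dye binding produces bursts:
a binding site drawn uniformly on the aggregate support, a geometric
burst duration (mean 3 frames), one localization per burst frame with
isotropic Gaussian error (the precision), and fiducials emitting every
frame. Burst counts scale with fibril length (0.5 bursts/nm in the
validation studies, minimum 30 — the regime of the real clusters, which
carried tens to thousands of bursts each). Not emulated: dye photophysics
beyond geometric blinking, stage drift (beyond the fixed fiducials),
astigmatism or 3-D effects, and background localizations. Recovery tests
therefore demonstrate correctness of the grouping/measurement chain under
its stated assumptions, not robustness to drift or dense background.
Under these conditions fibrils of 200–2000 nm are recovered with mean
|bias| < 10% and 100 nm-radius blobs always measure < 300 nm.

**Temporal collisions.** At high burst rates two bursts at distant sites
can overlap in time within one percolating spatial cluster and merge into
a single burst whose centroid is a convex combination of the sites. For
convex supports (segments, discs) such centroids remain on the support,
which is why length recovery is insensitive to this merging; it does
reduce the recovered burst count below the generated one.

## Fourier ring correlation

Localizations are split into two random halves (Bernoulli per
localization, seeded), each half is rendered as a 10 nm histogram on a
common square grid, and FRC(q) is the ring-averaged normalized
cross-spectrum with single-bin rings and no spurious-correlation
correction. The resolution is 1/q* at the first crossing below 1/7
(linearly interpolated between bins); a curve that never crosses reports
"not determined" — which is also the self-correlation answer, since
FRC ≡ 1 when both halves are the same image. On simulated dense
structures the resolution tracks the localization precision
(≈ 2.5–3 × σ: 30 nm at σ = 10 nm, ≈ 57 nm at σ = 20 nm) and is monotone
in it.

## Phospho-stoichiometry from native mass spectra

**Model.** A deconvolved (zero-charge) spectrum in the 40–44 kDa window
is explained by states (p, a): p phosphate groups of 80 Da and a
small-ion adducts of 23 Da (sodium and ammonium are not distinguished —
both fall within the integration window) on a base mass M₀ = 39,900 Da
(the unmodified full-length tau peak). The weight of a state is the
trapezoidal area of the spectrum within the 10 Da window centered on its
mass, floored at 10⁻⁶ of the total area so that log-weights are finite;
priors are uniform with p, a < 50. The posterior is sampled with an
affine-invariant ensemble (six walkers × 3000 steps, 800 burn-in, thin
100), mixing Goodman–Weare stretch moves with differential-evolution
moves (half the proposals); the DE moves are what lets walkers hop
between lattice-separated modes of a multi-peaked spectrum. Walkers are
initialized by sampling states proportional to their windowed area (with
within-cell jitter), i.e. from regions that carry mass.

**Noise floor.** Summing window areas over ~2500 candidate states means
that even low-level baseline noise, integrated over every empty window,
can outweigh the true peaks. Intensities below 3× the robustly estimated
noise scale (from the 90th percentile of all intensities; q90 = 1.28 σ
for zero-truncated Gaussian noise) are therefore zeroed before
integration — the same threshold-of-3 philosophy as the acquisition's
noise setting. A noise-free spectrum passes through unchanged. The
threshold was calibrated on the recovery study: at 1% peak-height noise
it leaves the windowed-area mean within ±0.1 phosphate of truth, while
lower thresholds leak baseline area and bias the mean toward the grid
center.

**Degeneracy.** 2 × 80 ≈ 7 × 23 (160 vs 161 Da), so states (p, a) and
(p − 2, a + 7) are mass-degenerate to within 1 Da: on a wide-open adduct
grid a single peak is intrinsically ambiguous in p. Mode-recovery
validation therefore runs on a grid sized to the simulated state space
(adduct counts 0–5); the ambiguity is a property of the measurement, not
of the sampler, and the exhaustive-enumeration cross-check
(`enumerate_states()`) makes it visible. The MCMC marginal agrees with
enumeration within total-variation 0.02 on 5×5 grids at ≥ 5000 retained
samples, noise-free single states are recovered exactly (including with
adducts disabled), and the posterior mean at 1% noise is within ±0.4 of
the generating mean.

**Direct peak reading.** `phosphate_count_from_peak()` rounds
(peak − base)/80 to the nearest integer; an exact half-integer (e.g. a
40.5 kDa peak over 39.9 kDa: 7.5) is a tie, reported with `tie = TRUE`
and rounded down. Mean and mode of the posterior are both reported and
neither is forced to agree with the other — broad spectra legitimately
have a mean above the modal peak.

## Calcium and ROS traces

Frames are background-subtracted (5th percentile per frame — the
protocol says only "background subtraction"; a low percentile is robust
to sparse bright cells), flat-field corrected when a flat-field is
supplied, and Gaussian smoothed. Cells are local maxima (with
non-maximum suppression at twice the cell radius so a noisy flat-topped
cell yields one candidate) linked frame-to-frame by nearest neighbor
within one cell radius; tracks with positional s.d. above half the cell
radius, or spanning under 25% of the movie, are discarded, and survivors
are frozen at their mean position. Traces are disk means (radius 5 px by
default) at those fixed positions, smoothed along time (σ = 1.5 frames)
and normalized to the pre-stimulus baseline, making the spike threshold
unitless.

Spikes are called where the first difference of the normalized trace
exceeds the threshold; candidates within a 3-frame refractory window
merge; each event's amplitude is peak minus pre-onset level and its
duration the frames above half-amplitude; events failing the minimum
amplitude or duration are dropped. The threshold is deliberately a
required setting, calibrated on synthetic traces: at a derivative
threshold of ≈ 5× the baseline derivative noise (0.1 on normalized
traces with 4% noise), detection achieves recall and precision ≥ 0.95 on
isolated transients of amplitude 25× the noise s.d. and produces zero
false calls on 1000 flat noisy traces. ROS percent change uses 50-frame
windows before the stimulus and before ionomycin, and is exactly
invariant to rescaling the trace.

The movie generator places non-overlapping disc cells on a lattice with
peak-shaped transients (1-frame rise, 20-frame exponential decay) at
known times and a linear ROS ramp for responding cells. It does not
emulate cell migration, focus drift, bleaching or spectral crosstalk; the
tracking tests therefore validate the stationary-cell analysis the
protocol assumes, with the jitter-discard rule covering moving objects.

## Assay formulas

The three closed forms are implemented exactly as stated, with guards:
influx requires F_ionomycin > F_background (vesicles failing it are
excluded with a reason; out-of-range percentages are flagged, never
clipped); LDH corrects 490 nm absorbance by the 680 nm background per
well and requires the corrected maximum to exceed spontaneous; relative
expression uses the arithmetic mean of the housekeeping Cts (GAPDH and
18S), the mean ΔCt of the PBS reference group per gene, and fold change
2^(−ΔΔCt) — the efficiency-2 assumption is recorded in the output's
metadata. Gain rescaling cancels exactly in the first two by
construction; the qPCR inverse-construction test recovers designed fold
changes {0.5, 1, 4} exactly.

## Numerical and validation choices

* Problem sizes in the default test run are chosen for a few-minute
  suite: 3–4 simulated replicates per fibril length, 200 + 1200 traces
  for the spike study, 27-state subsample for mode recovery in the
  acceptance script (the test suite runs all 156).
* Skeleton path lengths use double Dijkstra sweeps per component (exact
  on trees; thinning output is a tree up to rare small cycles, where the
  sweep can only under-measure, and in practice does not at these sizes).
* All generators and samplers are pure functions of (parameters, seed);
  RNG state is saved and restored around seeded sections, so seeded calls
  do not perturb the caller's RNG stream.
* Known limitations: the DL skeleton measure's cap-erosion bias
  (quantified above; use the moment measure near the diffraction limit);
  the p vs (p − 2, a + 7) mass degeneracy on wide adduct grids; no drift
  correction (fiducials are removed, not used for correction — exposed as
  a non-default option was considered and rejected as out of the
  validated scope); temporal burst merging at very high burst rates; and
  the FRC noise floor at low localization counts, which reports "not
  determined" rather than a number.
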