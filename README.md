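# tauaggr

Quantitative analysis of soluble, hyperphosphorylated tau aggregates and of
the cellular responses they provoke. Hyperphosphorylated tau (e.g. tau
sequentially phosphorylated by PKA and GSK-3β or SAPK4) self-assembles into
small amorphous aggregates that permeabilize lipid membranes and trigger
TLR4-dependent calcium transients, ROS production and cytokine expression
in human macrophages. Characterizing those species requires a chain of
quantitative procedures that this package implements as tested, reusable R
code, together with synthetic-data generators that produce every input with
known ground truth:

* **Diffraction-limited morphometry** — pFTAA-type TIRF image stacks are
  frame-averaged, bandpass filtered (difference of Gaussians) and
  thresholded at 2% above the image median; particle lengths are measured
  both by boundary thinning (one-pixel skeleton, longest 8-connected
  geodesic path, steps of 1 or √2 pixels at 107.2 nm/pixel) and by
  intensity second moments (for a segment of length *L* under a Gaussian
  PSF, λ₁ = L²/12 + σ², λ₂ = σ², so *L* = √(12(λ₁ − λ₂))); intensities are
  background-corrected as per-pixel signal-to-background ratios,
  SBR = (I − B)/B, summed over the particle.
* **SMLM pipeline** — ThX blinking localizations are quality filtered
  (signal strength ≥ 3, precision ≤ 30 nm), cleaned of fiducial markers
  (sites occupied in > 500 frames at the same location), grouped into
  bursts by staged DBSCAN (spatial ε = 15 nm / minPts 3, then temporal
  ε = 21 ms / ≥ 2 frames), clustered into aggregates (ε = 200 nm, ≥ 20
  bursts), and each cluster's length is measured by 8× coordinate scaling,
  morphological closing, skeletonization and 8-connectivity path traversal.
* **Fourier ring correlation** — localizations are split into random
  halves, rendered, and the image resolution is 1/q at the first spatial
  frequency where the ring-averaged cross-correlation drops below 1/7.
* **Phospho-stoichiometry by MCMC** — a deconvolved native mass spectrum is
  explained by states (p, a) with mass M₀ + 80·p + 23·a (p phosphates,
  a small-ion adducts), each weighted by the spectral area in its 10 Da
  window; an affine-invariant ensemble sampler (six chains × 3000 steps,
  800 burn-in, thinned by 100) yields the posterior over phosphate counts
  with mean ± s.d. An exhaustive enumeration of the same weights serves as
  an exact cross-check.
* **Calcium / ROS trace analysis** — cells are tracked as stationary local
  maxima, disk-averaged traces are extracted at fixed positions, calcium
  spikes are called from the first derivative of the baseline-normalized
  trace, and ROS percent change is 100·(F_final − F_initial)/F_initial over
  50-frame windows.
* **Closed-form assays** — vesicle calcium influx
  100·(F_sample − F_background)/(F_ionomycin − F_background), LDH
  cytotoxicity 100·(LDH_s − LDH_spont)/(LDH_max − LDH_spont) with 680 nm
  background correction, and ΔΔCt relative expression (fold change
  2^(−ΔΔCt) against housekeeping genes and a PBS reference group).

## Worked example

Simulate a field holding one 600 nm fibril, one 80 nm-radius amorphous
blob and a fiducial marker, then run the full SMLM pipeline:

```r
library(tauaggr)

truth <- ground_truth(
  aggregates = data.frame(shape = c("segment", "blob"),
                          x_nm = c(2000, 5000), y_nm = c(2000, 5000),
                          size_nm = c(600, 80), orientation = c(0.9, 0)),
  fiducials = data.frame(x_nm = 500, y_nm = 6000), seed = 12)
locs <- gen_smlm_stream(truth, emitter_model(precision_nm = 15),
                        n_frames = 10000, n_bursts = c(300L, 60L))
res <- smlm_analyze(locs)
res
#> smlm_result: 1463 localizations, 1 fiducial(s), 269 bursts, 2 clusters
#>   cluster lengths: 118-581 nm (mean 350 nm)
res$clusters
#>   id n_bursts length_nm total_skeleton_nm
#> 1  1      220  580.9615         1164.6166
#> 2  2       49  118.3009          118.3009
```

The fiducial was recognized and removed; the fibril comes back at 581 nm
(−3% of truth) and the sub-diffraction blob at 118 nm, i.e. the pipeline
separates fibrillar from amorphous morphology. Assign phosphate
stoichiometry to a simulated deconvolved spectrum whose peaks sit on the
80/23 Da ladder around a 39.9 kDa base mass:

```r
spec <- gen_spectrum(state_weights = c("10,0" = 0.6, "10,1" = 0.3,
                                       "11,0" = 0.1))
post <- run_assignment(spec, state_grid(max_phos = 26, max_adduct = 6),
                       seed = 1)
post
#> phospho_posterior: 132 retained samples (6 walkers)
#>   phosphates: mode 10, mean 10.08 +/- 0.28 (s.d.)
#>   acceptance fraction 0.60
```

The posterior mode (10 phosphates) matches the dominant simulated state
and the mean reflects the 10/11 mixture. The counterpart worked directly
from peak masses:

```r
phosphate_count_from_peak(40.7, 39.9)$count   # 10 phosphates (g-tau peak)
phosphate_count_from_peak(41.4, 39.9)$count   # 19 phosphates (s-tau peak)
```

## Command line

A thin CLI over the same functions ships in `inst/scripts/tauaggr.R` with
subcommands `simulate`, `dl-analyze`, `smlm-analyze`, `frc`, `ms-assign`,
`traces` and `assay`, reading/writing CSV, TIFF and JSON.
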