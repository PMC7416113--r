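# chromarg

Spectral-temporal typing and morphometrics of larval zebrafish retinal
ganglion cells (RGCs), as a tested, reusable R pipeline.

Larval zebrafish are tetrachromats: their retinal output combines red,
green, blue and UV cone signals, and how each RGC wires these channels
(On, Off, or not at all — 3^4 = 81 possible states, of which 50 are
colour-opponent) varies systematically with position in the eye and with
dendritic depth in the inner plexiform layer (IPL). chromarg implements
the analysis chain used to characterize this organization:

* **Kernel estimation.** From a calcium trace recorded under
  tetrachromatic binary noise (6.4 Hz, 258 s), the pipeline detrends,
  z-normalizes (1–6 s baseline), thresholds the 500-Hz-resampled
  derivative at 0.7 baseline SDs, and computes the event-triggered
  average stimulus
  `F(l, tau) = (1/M) * sum_i dc(t_i) * S(l, t_i + tau)`
  on a 649-sample lag grid (dt = 2 ms, from −973.5 ms), normalized to
  z-scores of the first 50 ms of lag.
* **Typing.** Kernel polarity by extremum timing (min before max = On);
  ternary wiring states with a 10-SD responsiveness gate; chromatic
  opponency by zero crossings along R→G→B→UV (simple vs complex);
  On-Off index `OOi = (nOn − nOff)/(nOn + nOff)`; spectral centroid of
  the kernel's Fourier magnitude spectrum.
* **Eye-IPL maps.** Any per-ROI statistic binned on an 8 (eye position)
  × 20 (IPL depth) grid — somata in bin 1, bin 2 an empty barrier,
  dendrites in bins 3–20 — with circular binomial smoothing.
* **Functional clustering.** Per-colour scaling, per-colour ≥99%-variance
  PCA, then a Gaussian-mixture sweep (k = 1…k_max × four covariance
  structures, 20 replicates each, 1e-5 regularization) selected by BIC,
  with a fixed-k fallback and minimum-member filtering.
* **Morphology.** Point-cloud summaries (y_span, y_mean, num_pts,
  convex-hull xz_area), two-stage hierarchical clustering (city-block /
  average linkage, 18 clusters, the two largest re-split 6 + 3 → 25)
  with cophenetic validation, and dendritic tilt in soma-centred
  spherical coordinates (polar angle from the retinal normal), compared
  across regions with two-sample KS tests and a two-sample Kuiper test
  for the circular tilt direction.

Everything runs on synthetic data with known ground truth: the package
ships generators for the noise stimulus, linear-nonlinear calcium
responses with planted kernels, planted-cluster populations, and
dendritic point clouds with planted stratification and tilt — so every
estimator is validated by parameter recovery. Deposited experimental
tables (kernels 4 × 649 at dt = 2 ms; chirps 2,499 samples at 1 ms) can
be imported with `import_deposited()`.

## Worked example

```r
library(chromarg)

# simulate a small population of 12 ROIs from 3 functional archetypes
stim <- noise_stimulus(duration_s = 120, seed = 101)
cfg  <- sim_config(n_rois = 12, seed = 101, duration = 120)
pop  <- make_population(cfg, default_cluster_spec(3), stim = stim)

# estimate spectral kernels for every ROI and classify them
kt  <- estimate_population_kernels(pop, stim)
cls <- classify_rois(kt, threshold = 10)
dplyr::count(cls, category)
#> # A tibble: 3 × 2
#>   category             n
#>   <chr>            <int>
#> 1 complex_opponent     5
#> 2 non_opponent_on      2
#> 3 simple_opponent      5

glance(kt$kernel_set[[1]])
#> # A tibble: 1 × 7
#>   n_events quality_R quality_G quality_B quality_UV quality_max quality_sd_max
#>      <int>     <dbl>     <dbl>     <dbl>      <dbl>       <dbl>          <dbl>
#> 1    12463      28.7      491.      106.       330.        491.           134.
```

The first ROI's kernel set was estimated from 12,463 weighted calcium
events; its green channel swings ~491 baseline SDs peak-to-peak
(strongly responsive), red only ~29. The opponency split reflects the
planted archetypes: the red/green-On versus blue-Off type carries a
UV-On lobe as well, so its wiring state (On, On, Off, On) has two
spectral zero crossings and reads as a complex opponent. `autoplot()` on a
`kernel_set` or an `eye_ipl_map`, and `tidy()`/`glance()` on every
result type, give ggplot figures and tidy tables; `run_pipeline()`
executes the whole chain from one configuration and writes tidy CSVs, a
JSON report and a manifest.

The wiring-space combinatorics print directly:

```r
attr(enumerate_wiring_space(), "counts")[c("total", "opponent", "non_opponent")]
#> $total
#> [1] 81
#> $opponent
#> [1] 50
#> $non_opponent
#> [1] 30
```

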