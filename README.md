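# meoct

Quantitative analysis of handheld middle-ear optical coherence tomography
(OCT), for researchers and engineers working on point-of-care imaging of
retrotympanic masses. OCT can see through the tympanic membrane (TM) into
the middle ear; with repeated B-scans it can also map vascularity. This
package turns such volumes into comparable numbers:

* **Speckle-variance angiography**: per pixel over N consecutive B-scans,
  `SV = (1/N) * sum_i (I_i - Ibar)^2` on linear intensity — static tissue
  gives SV near 0, flowing blood decorrelates the speckle and SV rises.
* **ROI intensity ratios**: structural ratio = mean display intensity over
  the mass / mean over a TM box (normal ears measure the aerated
  mesotympanum instead, landing near 0.1 vs ~0.4-0.6 for soft-tissue
  masses); angiography ratio = mean SV over the mass / mean SV over the
  malleus lateral process (vascular-strip reference). Both are invariant to
  image rescaling.
* **Depth calibration**: OCT measures optical path; physical depth = path /
  refractive index (air 1.0, tissue assumed 1.4, so 1 mm optical in tissue
  is 0.714 mm), with signed uncertainty bounds over the plausible tissue
  index range 1.33-1.45.
* **Mass-to-membrane gap**: per-A-line air gap between the TM inner surface
  and the mass top surface, converted with n = 1.0.
* **Group statistics**: mean +/- SE summaries and unpaired two-sample
  t-tests (pooled Student's by default, Welch by flag), computable either
  from raw per-ear ratios or directly from published (n, mean, SE) triples.
* **Synthetic phantoms**: a ground-truthed middle-ear generator (curved TM
  with umbo, malleus with lateral process, incudostapedial joint,
  promontory, optional masses with Beer-Lambert shadowing, exponential
  speckle, and AR(1) flow decorrelation) emulating four presentations:
  normal, glomus tumor, cholesteatoma, facial nerve schwannoma.

## Worked example

Reconstruct a two-group comparison from published summary statistics alone:

```r
library(meoct)
g  <- group_summary(n = 6, mean = 0.620, se = 0.095, label = "glomus")
ch <- group_summary(n = 4, mean = 0.558, se = 0.153, label = "cholesteatoma")
ttest_from_summary(g, ch)
#> <ttest_result pooled> t=0.3658 df=8 p=0.724
```

The structural ratios of the two mass classes are statistically
indistinguishable (p = 0.72): structural OCT detects *that* a soft-tissue
mass is present, not which kind. Simulate one vascular-mass ear and run the
whole measurement chain on it:

```r
ear <- simulate_ear("glomus", seed = 42, grid_shape = c(32, 96, 192))
res <- run_ear_analysis(ear)
res$ratios[, c("class", "kind", "ratio", "gap_max_mm")]
#>    class       kind     ratio gap_max_mm
#> 1 glomus structural 0.4362667 0.08333333
#> 2 glomus      angio  0.5955191 0.08333333
```

The structural ratio (0.44) sits far above the normal-ear regime (~0.07),
and the angiography ratio (0.60) far above avascular classes (~0.02); the
designed mass-TM air gap of 0.069 mm is recovered as 0.083 mm — within one
axial pixel (0.021 mm at this grid). `build_cohort(seed = 1)` simulates the
full 17-ear study-arm cohort and `run_report(cohort, "out/")` writes the
ratios CSV, pairwise tests CSV, overlay PNGs, a markdown summary, and a
digest manifest.

```r
optical_to_physical_depth(1.0, "tissue")
#> [1] 0.7142857
```

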