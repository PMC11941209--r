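---
title: "Quantitative middle-ear OCT: speckle-variance angiography, ROI ratios, and synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative middle-ear OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meoct)
```

## The problem

Handheld optical coherence tomography (OCT) can image through the tympanic
membrane (TM) into the middle ear, resolving the ossicular chain and the
cochlear promontory, and — with repeated B-scans — can map tissue
vascularity. Two quantities turn such volumes into numbers a clinician can
compare across ears:

1. a **structural ratio**: the mean pixel intensity of a region of interest
   (ROI) over the suspected mass (or, in normal ears, the aerated
   mesotympanum at a comparable depth), normalized to the mean pixel
   intensity of a TM ROI on the same cross-section; and
2. an **angiography ratio**: the mean speckle variance (SV) in a mass ROI of
   an en-face SV map, normalized to an ROI over the malleus lateral process,
   whose overlying vascular strip provides a reproducible flow reference.

A highly vascular glomus tumor gives a large angiography ratio; an avascular
cholesteatoma a small one; a schwannoma sits between. All mass classes give
structural ratios far above the near-noise ratio of an air-filled middle
ear. This package implements the full chain — angiography, projection and
cross-section geometry, ROI ratios, depth calibration, gap measurement, and
group statistics — and, because clinical volumes of this kind are not
publicly deposited, ships a ground-truthed synthetic phantom generator to
exercise it end to end.

## Speckle-variance angiography

At each slow-axis position, `N` consecutive B-scans are acquired. For every
pixel, with intensities $I_1,\dots,I_N$ and mean $\bar I$:

$$\mathrm{SV} = \frac{1}{N}\sum_{i=1}^{N}\left(I_i - \bar I\right)^2.$$

Static tissue reproduces its speckle pattern so SV $\approx 0$; moving blood
decorrelates the speckle and SV rises toward $\mu^2(N-1)/N$ for mean
intensity $\mu$. Choices worth stating:

* **Population (1/N) normalization** is the default, matching the classic
  speckle-variance OCTA formulation; `1/(N-1)` is available via
  `norm = "n-1"`.
* SV is computed on **linear intensity**. Variance of log-compressed data
  mixes brightness with flow; display compression is strictly a rendering
  step here.
* The implementation is a **centered two-pass sum**, so SV is invariant to a
  constant intensity offset at machine precision (the one-pass
  $E[I^2]-E[I]^2$ shortcut is not, and is deliberately avoided).
* No bulk-motion correction is applied; the clinical acquisition this models
  is fast enough that motion artifacts were tolerated uncorrected, and the
  phantom does not inject them by default.
* Overlays tint above-threshold pixels red on the structural base; the
  default threshold is the 95th percentile of SV inside a static TM mask of
  the same volume (self-normalizing — no absolute SV scale is assumed). The
  en-face SV reduction is a mean projection by default; `reduce = "max"` is
  available, with no claim about which variant any particular clinical
  rendering used.

## ROI ratios and their conventions

Structural ratios are measured on the **8-bit log-compressed display
image** (40 dB window by default), because that is the rendering on which
such measurements are made interactively in practice (e.g. in Fiji); the
linear-domain ratio is recorded alongside for comparison. Display rendering
is `clip(10*log10(I/I_max) + DR, 0, DR) * 255/DR`, rounded half-up — stated
explicitly so ratio regressions are bit-stable.

Clinical ROI sizes are quoted on the clinical grids: a 100×100 mass box and
50×50 lateral-process box on the 417×1280 en-face grid, and the structural
boxes on 1280×2048 B-scans. On smaller synthetic grids the boxes are scaled
proportionally per axis (`scale_roi_size()`), and the scaling is recorded in
the ROI provenance string of every result row. The structural ROI size is
not fixed by any published convention; the defaults (100×100 mass, 20×50
TM, clinical pixels) are explicit config values, not constants baked into
the measurement.

Landmarks (umbo, malleus lateral process) are **supplied**, either from
phantom ground truth or from a per-ear YAML config; no automatic landmark
detector is claimed, mirroring the fact that clinical landmarking is human.
For cholesteatomas the ROI may sit in the posterior mesotympanum or the
epitympanum; `derive_rois()` records which plane it chose.

## Depth calibration and the mass-TM gap

OCT measures optical path length. Physical depth is optical path divided by
the refractive index: $n = 1.0$ in air (so 1 mm optical = 1 mm physical)
and an assumed $n = 1.4$ in soft tissue (1 mm optical = $1/1.4 \approx
0.714$ mm). Because soft-tissue and tumor indices realistically span
1.33–1.45, converting with 1.4 carries a relative depth uncertainty of
$n_{assumed}/n - 1$, i.e. $+5.3\%$ to $-3.4\%$ at the range endpoints
(`depth_uncertainty()` reports both signed bounds and their maximum, on the
order of the commonly quoted ~3%–5%).

The air gap between a mass and the TM inner surface is measured per A-line
as the surface-index difference times the axial pixel spacing, converted
with $n = 1.0$ since the gap is aerated; A-lines where the mass surface
lies above the TM inner surface are flagged and excluded with a count. The
summary reports the minimum and maximum over the footprint.

## Group statistics

Groups are summarized as mean ± standard error (sample SD over $\sqrt n$);
a single-ear group is reported descriptively with no SE. The two-sample
test is the **pooled (equal-variance) unpaired Student's t**, reconstructed
from summaries via $s^2 = se^2 n$:

$$t = \frac{m_1 - m_2}{s_p\sqrt{1/n_1 + 1/n_2}},\qquad
s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}.$$

Pooled is the default because it exactly reproduces the published p-values
this package's statistics module is validated against (0.72 for the
structural glomus-vs-cholesteatoma comparison; 0.67 for the angiography
cholesteatoma-vs-normal comparison) from the printed (n, mean, SE) triples
alone; that is a numerical-agreement argument, not a claim about which
spreadsheet option the original analysts clicked. Welch's variant is
available by flag. Tests are two-tailed, $\alpha = 0.05$, with no
multiple-testing correction; `compare_all()` reports how many uncorrected
comparisons it ran.

## The synthetic phantom

`scene_preset()` builds a parametric middle ear: a Gaussian-bump TM whose
apex is the umbo (edge standoff ~0.8 mm, sag ~1 mm, thickness 0.12 mm), the
malleus handle as a capsule from the lateral process to the umbo on the
medial TM face, the incudostapedial joint, and the promontory as a domed
deep wall. Expected intensity follows single-backscatter Beer–Lambert
attenuation per A-line, `mu = b * exp(-2 * sum_above(a dz)) + noise_floor`,
so any soft-tissue mass shadows the promontory beneath it. Speckle is fully
developed: intensity is exponential with mean `mu` (the squared modulus of
a circular complex Gaussian field).

Temporal decorrelation across repeated B-scans is a **first-order
autoregressive complex-Gaussian process**: $E_{i+1} = \rho E_i +
\sqrt{1-\rho^2}\,\xi_i$, giving lag-$k$ field correlation $\rho^k$ and
intensity correlation $\rho^{2k}$ — the simplest flow model with a tunable,
analytically checkable correlation (no physical flow model is implied by
the clinical description this emulates). The number of consecutive B-scans
is not dictated by any published protocol; the default is `n_repeats = 4`,
a common speckle-variance choice, and it is configurable. The sampler also
accepts an additive detection-noise field that is independent across
repeats; the phantom passes its noise floor there, because a noise floor
folded into a perfectly static ($\rho = 1$) field would make SV exactly
zero in all static tissue and leave the angiography ratio undefined.

Preset optics (relative backscatter / attenuation mm$^{-1}$ / field
correlation $\rho$): TM 1.0/2.0/1.0; malleus 1.0/4.0/0.65 (the reduced
$\rho$ stands in for the vascular strip overlying the handle — the reason
the lateral process works as an angiography reference); incudostapedial
joint 1.1/4.0/1.0; promontory 0.9/3.0/1.0; glomus mass 0.8/2.5/0.15–0.30;
cholesteatoma 0.9/3.0/1.0 (avascular); schwannoma 0.7/2.2/0.75
(intermediate vascularity — chosen so the designed ordering glomus ≫
schwannoma ≫ cholesteatoma holds with margin under the per-ear jitter).
The noise floor (1.5e-3 relative intensity) is set so the normal preset's
structural ratio lands in the ~0.1 regime of a healthy air-filled middle
ear. Masses are **molded beneath the membrane**: over the apposition
footprint the mass top surface is `tm_inner + gap_mm * min(1, (r/0.8)^2)`
in normalized footprint radius, so the designed air gap runs from 0 at the
contact apex up to `gap_mm` on the outer plateau — the per-A-line gap
"ranges from 0 to the designed maximum", and the plateau makes maximum-gap
recovery a fair one-pixel discretization test rather than an artifact of
sampling the footprint rim.

Per-ear jitter (when enabled, as in `build_cohort()`) varies the TM sag and
standoff, mass position, footprint, gap (glomus gaps drawn from
0.02–0.18 mm), backscatter (±9%), and glomus vascularity, all from the ear
seed. All randomness flows from a single master seed through deterministic
sub-seeds, so cohorts reproduce exactly.

**Problem sizes.** The default single-scene grid is 64×256×512
(slow × fast × depth) over a 6×8×4 mm field of view. The shipped 17-ear
cohort (6 normal / 6 glomus / 4 cholesteatoma / 1 schwannoma, the study-arm
sizes) uses 32×96×192 per ear — the package's chosen desk-scale size, at
which the full cohort simulates and quantifies in well under a minute while
every ROI still spans hundreds of voxels. Full clinical size
(417×1280×2048) is accepted via `grid_shape` for users with the patience.

## What the phantom does and does not emulate

It emulates: curved-membrane geometry with correct landmark relations,
Beer–Lambert shadowing, fully developed exponential speckle, AR(1) flow
decorrelation, per-class vascularity contrast, designed mass-TM gaps, and
study-arm cohort structure. It does **not** emulate: physical
interferometer optics (sweep, dispersion, k-space resampling), bulk motion
(an optional global-shift injector is the only concession), blood-vessel
microarchitecture (vascularity is a uniform $\rho$ per mass, not a vessel
tree), ear-canal optics, or — importantly — the **noise-dominated SV
baseline of real data**: in clinical angiography the avascular classes
still show ratios around 0.6–0.7 because system noise decorrelates
everything a little, whereas the clean phantom puts avascular ratios near
0.01–0.02. Passing the cohort tests therefore demonstrates correct
*ordering and separation* of the classes under the model, not that the
synthetic ratio magnitudes match clinical ones — the published group means
derive from patient volumes that are not deposited and are not reproducible
from synthetic data.

## Numerical choices and degenerate inputs

* `speckle_variance` rejects fewer than 2 repeats; assembly rejects gaps,
  duplicates, and shuffled slow indices.
* Display rounding is half-up (`floor(x + 0.5)`), not banker's rounding.
* Ratio denominators must be strictly positive; zero-mean reference ROIs
  are an error, not an NaN.
* `ttest_from_summary` refuses n < 2 or zero SE; `compare_all` routes
  single-ear groups to a descriptive listing instead.
* 16-bit volumes round-trip TIFF exactly; float volumes (SV) are stored as
  32-bit float scaled into [0, 1] with the scale in the JSON sidecar, since
  the TIFF reader clamps float samples to that range.
* A missing sidecar defaults pixel spacing to 1 mm with a warning and a
  provenance flag rather than failing.

## A worked example

```{r example, eval = FALSE}
coh <- build_cohort(seed = 1)          # 17 ears, study-arm sizes
rep <- run_report(coh, "report_out")
rep$comparisons$structural$summaries
rep$comparisons$angio$tests

# published-summary mode: reconstruct a printed comparison
g <- group_summary(n = 6, mean = 0.620, se = 0.095, label = "glomus")
c <- group_summary(n = 4, mean = 0.558, se = 0.153, label = "cholesteatoma")
ttest_from_summary(g, c)    # t = 0.366, df = 8, p = 0.724
```

## Known limitations

Landmarks come from truth or config, never from detection; the statistics
module assumes approximate normality of per-ear ratios (defensible at these
group sizes only as convention — the published analysis it reproduces made
the same assumption); the phantom's absolute intensity scale is arbitrary
(all ratios are scale-invariant by construction, which is the point); and
the type-I-error check of the pooled test uses Gaussian equal-variance null
samples at the study's group sizes, not full phantom cohorts.
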