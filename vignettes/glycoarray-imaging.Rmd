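---
title: "Characterizing printed glycan microarrays with ToF-SIMS and SPR imaging"
author: "glycosims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing printed glycan microarrays with ToF-SIMS and SPR imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycosims)
```

## The problem

Printed carbohydrate microarrays immobilize glycans (here, a maltose
conjugated to 2,6-diaminopyridine, "GDAP") on amine-reactive
oligo(ethylene glycol) self-assembled monolayers (OEG/SAM) on gold.
Array performance depends on where the glycan actually sits and whether
it is bioavailable, but neither is observable from a fluorescence
endpoint alone. Two imaging modalities answer complementary halves of
the question:

* **ToF-SIMS** rasters a primary ion beam over a 500 × 500 µm window at
  3.9 µm/pixel, collecting a full positive-ion mass spectrum at each of
  the 128 × 128 = 16,384 pixels. Fragment ions report chemistry: GDAP
  fragments mark the glycan, C~x~H~y~O/S fragments mark the monolayer,
  Au-containing ions mark the substrate, and hydrocarbon/salt ions mark
  contamination.
* **SPRi** follows lectin (Concanavalin A) binding in real time as a
  reflectance change, reported in pixel-intensity units, and shows where
  the printed glycan is *functional*.

`glycosims` implements the full analysis chain for both modalities, plus
simulators that generate co-registered synthetic data from a shared
ground truth so that every stage can be validated against known answers.

## ROI-based PCA of SIMS spectra

The discovery workflow reduces each cube to a small spectrum matrix and
lets PCA separate spot from background chemistry:

1. **Peak picking.** Channels whose summed-spectrum intensity is at
   least `k = 3` times the per-channel background are kept, within the
   m/z 1–350 window; the boundary is inclusive ("greater than or
   equal"). The background is an explicit input: real analyses derive it
   from the spectral noise floor between peaks, and
   `background_from_roi()` offers the median intensity of a blank region
   when one exists. On synthetic cubes every channel hosts a planted
   species, so the pipeline supplies the generator's stray-count floor
   (`signatures$background × n_pixels`) — a spatial background ROI would
   contain the monolayer and gold signal itself, which is chemistry, not
   noise.
2. **ROI spectra.** Three 100 × 100 µm ROIs per image — upper-left (I),
   center (II, on the spot), lower-right (III) — over five replicate
   images give 15 mean spectra. Pixels belong to an ROI iff their
   centers fall in its half-open rectangle; the same rule is used by
   every module.
3. **Normalization.** Each spectrum is divided by its total intensity
   over the selected peaks (composition, not raw yield), then each peak
   is mean-centered across spectra. The order — normalize first, center
   second — is stated explicitly because the two operations do not
   commute; centering then acts on compositional contrasts, the standard
   practice for SIMS PCA.
4. **PCA.** Full SVD of the centered matrix (deterministic and cheap at
   15 × ~900; iterative NIPALS would buy nothing). Scores are the data
   projected on unit-norm loadings; variance fractions are squared
   singular values over their total.
5. **Orientation and selection.** PCA fixes components only up to sign,
   so `orient_pc1()` flips PC1 jointly in scores and loadings until the
   designated background ROIs score positive — the convention that
   positive PC1 means substrate/background and negative PC1 means
   glycan. Ions with |PC1 loading| ≥ 0.03 are selected, boundary
   inclusive (the threshold is a convention; inclusivity is declared
   here so tests are deterministic).
6. **Separation testing.** Welch's unequal-variance *t*-test compares
   PC1 scores between the stated contrasts (spot vs pooled background;
   background I vs III), rather than an omnibus test. Welch is chosen
   because spot and background ROI classes have no reason to share a
   variance. Two all-constant, equal-mean groups return p = 1 by
   definition.

Hydrocarbon and salt ions are assigned, then removed before
normalization and PCA, mirroring how adventitious contaminants are
handled in practice; QC maps of them remain available behind an
explicit flag.

## Fragment masses

`fragment_mz()` returns the theoretical monoisotopic mass of a fragment
composition minus one electron mass (0.00055 Da — invisible at two
decimals, but stated for exactness), for singly charged cations from
{C, H, N, O, S, Na, K, Au}. Of the 33 published reference assignments,
22 printed m/z values equal the computed cation mass at two decimals;
the remaining 11 differ by 0.005–0.02 Da, consistent with printed
values being observed centroids rather than theoretical masses. The
calculator deliberately reports computed values and leaves the
discrepancy visible instead of reproducing the outliers.

## Ion maps and spot morphology

Category ion maps sum counts over a category's channels, are min-max
normalized for display, and binarized. The binary threshold is Otsu's
criterion on a 256-bin histogram by default — deterministic and
parameter-free — with a fixed-level override. On bimodal images the
between-class-variance objective is flat across the empty gap between
modes; any plateau threshold is a valid maximizer, and the test suite
checks attained objective rather than a particular tie-break.
Red/green/blue composites use the conventional assignment GDAP/OEG-SAM/
gold. Morphology (`spot_metrics()`) reports area, equivalent-circle
diameter, centroid and moment-based eccentricity of the largest
8-connected component (8-connectivity is the blob-analysis convention;
the labeling is implemented in-package because the available library
routine is 4-connected), plus the Dice overlap `2|A∩B|/(|A|+|B|)`
against the planted mask when ground truth is available.

## SPRi sensorgrams, ROI sweeps and kinetics

Sensorgrams average consecutive frames in blocks of 30 (the instrument
convention) before taking the spatial mean and standard deviation over
the ROI. `roi_sweep()` evaluates five concentric square ROIs — by
default interpolating 50 → 200 µm, since only the range of the
conventional sweep is fixed — at the 11-minute readout near maximal
binding, and normalizes to the maximum mean response across the sweep
(the reference for "normalized response" is otherwise unstated; this
choice is declared). Two regimes emerge on synthetic spots exactly as
on printed ones: ROIs larger than the spot dilute the response with
non-glycan background, and spatial standard deviation grows with ROI
area once within-spot heterogeneity and then the spot boundary enter
the ROI.

Kinetic fitting uses the 1:1 Langmuir model
$$R(t) = d \cdot R_\max \frac{C}{C + K_D}\left(1 - e^{-(C k_{on} + k_{off}) t}\right),
\qquad K_D = k_{off}/k_{on},$$
with exponential decay at rate $k_{off}$ after the association phase
ends, where $d$ is the local glycan density. `fit_langmuir()` runs
Levenberg–Marquardt in log-parameter space (which enforces positivity)
with hand-derived analytic Jacobians, from five deterministic starts
whose $k_{on}$ seeds span two decades either side of a data-derived
estimate; $k_{off}$ is seeded from the log-linear slope of the
dissociation tail. Deterministic multi-start was preferred over random
restarts so fits are reproducible without a seed. Note that the fitted
$R_\max$ is the *effective* saturation response of the ROI — it absorbs
the mean glycan density under the ROI, so only an ROI at density 1
recovers the generator's nominal value.

## What the simulators emulate — and what they do not

`make_ground_truth()` encodes the study conditions shared by both
simulators; its defaults are fixed once and used by the entire test
suite:

| parameter | default | rationale |
|---|---|---|
| field / pixel | 500 µm / 3.9 µm | instrument geometry; grid = floor(500/3.9) = 128 |
| spot diameter | 200 µm | middle of the 150–250 µm range typical of contact printing |
| spot density | 0.8 | sub-saturated coupling, leaves headroom for the ring |
| center dip | 0.15 | evaporation-driven microheterogeneity: density rises parabolically from center to rim |
| ring | +25% on a rim annulus 10% of diameter wide, clipped at 1 | "coffee-stain" deposition ring |
| wash tail | off (opt-in) | exponentially decaying half-strip beyond the rim; a rinse artifact seen in SIMS but carrying no bioavailable glycan in SPRi |
| category yields | GDAP 25–60, OEG/SAM 20–50, Au 15–40, hydrocarbon 10, salt 8 counts/pixel; floor 0.2 | heterogeneous yields typical of low-mass secondary ions; chosen so the weakest channel's compositional contrast clears the 0.03 loading threshold with a ~2.5× analytic margin |
| kinetics | k~on~ 10^5^ /M/s, k~off~ 10^-3^ /s, C 100 nM, R~max~ 100, association 900 s | moderate-affinity lectin binding (K~D~ = 10 nM); 11-min readout falls near maximal binding |

The SIMS simulator draws independent Poisson counts per pixel and
channel: glycan means scale with density, OEG/SAM and gold means with
(1 − density) because immobilized glycan masks the monolayer from the
~2 nm SIMS sampling depth, and contaminants are density-independent.
The SPRi simulator evaluates the closed-form Langmuir curve scaled by
the (tail-free) density with additive Gaussian read noise. Both draw
from RNG streams keyed by (seed, object kind), so running either
simulator alone is reproducible.

Deliberately **not** modeled: primary-ion beam optics, charge
compensation, matrix effects, detector dead time, mass-calibration
drift, mass-transport-limited SPR kinetics, bivalent binding, BSA
blocking, and replicate-to-replicate printing variability. Passing
tests therefore demonstrate that the analysis chain recovers what it
should from data with realistic geometry, counting statistics and
artifact structure — not that it is robust to every instrument
pathology of real surfaces.

## Numerical choices and degenerate inputs

* Pixel coordinates are 0-based, row-major, origin top-left; a pixel
  covers a half-open square and belongs to a region iff its center
  does. One convention, used by SIMS, SPRi and co-registration alike.
* Peak channels are discrete bins; formula-to-channel matching uses a
  0.02 Da tolerance, matching 2-decimal reporting.
* `normalize_spectra()` refuses all-zero rows ("empty spectrum in
  ROI"); `fit_pca()` refuses uncentered (column means above 1e-8
  relative) and rank-0 matrices; `orient_pc1()` refuses an exactly-zero
  background mean (orientation undefined); `normalize_image()` refuses
  constant images ("degenerate contrast"); identity co-registration
  refuses mismatched grids rather than resampling silently.
* imzML I/O is implemented in-package (continuous mode, shared 64-bit
  m/z axis, 32-bit float intensities — exact for counts below 2^24);
  files are validated against the reference pyimzML parser in the test
  suite. SPRi stacks are stored as 32-bit float TIFF with an affine
  [0, 1] mapping recorded in a JSON sidecar, because baseline TIFF
  stores only unit-range samples faithfully.
* `response_at()` uses the nearest sampled time when it is within 60 s
  and linear interpolation otherwise.

## Problem sizes used by the test suite

The suite exercises full-size 128 × 128 × 33 cubes where the claim is
about the pipeline (ion discovery, Dice recovery, imzML round-trip) and
smaller 50 × 50 fields where it is about arithmetic, keeping the whole
suite under ~2 minutes. Kinetic recovery uses 300-point sensorgrams and
100 noisy replicates; the Welch calibration uses 1,000 null
simulations.

## Known limitations

* Agreement between SIMS and SPRi maps is quantified (Dice, Jaccard,
  Pearson) on shared-ground-truth synthetic pairs; for real surfaces the
  two instruments must analyze *duplicate* arrays (ToF-SIMS is
  destructive), so replicate-to-replicate printing variability — which
  the generator does not model — bounds the achievable agreement, and no
  single headline number is reported.
* The fragment-mass calculator covers the eight elements seen in this
  chemistry; it is not a general formula parser.
* Only positive-ion, continuous-mode data are supported; there is no
  mass calibration, isotope deconvolution or dead-time correction.
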