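---
title: "Methods: lung densitometry, histomorphometry and the synthetic phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lung densitometry, histomorphometry and the synthetic phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the quantitative model behind fibrocast, the
assumptions baked into each stage, the parameters worth knowing about, and
the design decisions that were genuinely open — together with what the
synthetic phantom does and does not establish about real data.

## The densitometric model

All lung readouts derive from four primitives measured over a segmented
lung mask in a calibrated volume at a respiratory phase $p \in
\{\mathrm{P01}, \mathrm{P02}\}$ (end-inspiration, end-expiration):

$$N_p,\qquad V_p = N_p \cdot v,\qquad
\mathrm{MLA}_p = \frac{1}{N_p}\sum_{i=1}^{N_p} \mathrm{HU}_i,\qquad
\mathrm{Gas}_p = \frac{V_p\,\mathrm{MLA}_p}{-1000},$$

where $v$ is the voxel volume (the product of the header spacings, in mm³ —
no hidden unit conversion anywhere). The gas-content formula is the usual
air-fraction argument on the HU scale: a voxel at $-1000$ HU is pure air,
one at $0$ HU is airless, and the affine interpolation in between makes
$\mathrm{Gas}_p$ the air-equivalent volume of the lung. Two consequences are
used as internal invariants:

* $\%\mathrm{Gas}_p = \mathrm{Gas}_p \cdot 100 / V_p = -\mathrm{MLA}_p/10$
  whenever $\mathrm{MLA}_p \in [-1000, 0]$ — the test suite checks this to
  $10^{-9}$ on random volumes;
* $\mathrm{Tissue} + \mathrm{Gas}_{P02} = V_{P02}$ exactly, since
  $\mathrm{Tissue}$ is *defined* as $V_{P02} - \mathrm{Gas}_{P02}$
  (computed at end-expiration, where the structural, non-gas component is
  least diluted by inflation).

If $\mathrm{MLA}_p > 0$ (possible with a badly drawn mask over soft
tissue), $\mathrm{Gas}_p$ goes negative. It is reported unclamped and
flagged (`gas_negative`): the formula carries no guard, and surfacing the
pathology is more useful than hiding it.

### Aeration compartments

The HU axis over the lung window is partitioned into normo-aerated
$[-860, -435]$, hypo-aerated $(-435, -121)$ and non-aerated $[-121, 121]$.
The bracket semantics are honoured literally — $-435$ HU is normo, $-121$
HU is non — because the printed interval notation is the only specification
of the boundaries there is. Voxels outside $[-860, 121]$ stay in $N$, $V$,
MLA and Gas but fall into an explicit *unclassified* bucket for the
percentages, so the four percentages always sum to 100; nothing in the
compartment definition licenses silently discarding voxels. Compartment
percentages are computed per phase; the default reporting phase is P02
(fibrotic consolidation is conventionally read at end-expiration), with P01
selectable.

The HU frequency histogram uses equal-width bins on the display window
$[-860, +121]$ with 163 bins by default. 163 equal bins over a 981-HU span
give a non-integer width of ≈6.02 HU; we deliberately do not round to an
integer width, since equal-width bins on the printed window are the only
defensible reading. The right edge is closed so a voxel at exactly $+121$
HU is counted, and bin counts conserve the in-range masked voxel total.

## HU calibration

Grey levels are mapped to HU with the two-anchor linear model: the grey
level of air maps to $-1000$ HU and that of water to $0$ HU, giving
$\text{slope} = 1000/(g_w - g_a)$ and $\text{intercept} = -1000 -
\text{slope}\cdot g_a$. Anchors may be given directly or as mean grey
levels inside air/water reference masks — how the references were sampled
on the original scanner is not specifiable from outside, so both routes are
supported, and the model can be fit once per study or per scan. No clamping
happens at this stage; range handling belongs to the compartment logic.
Double calibration is a hard error rather than a silent no-op.

## Lung segmentation

The published workflows here are operator-in-the-loop ("semiautomatic");
fibrocast substitutes a deterministic pipeline validated against phantom
truth: background air (below `body_hu_lower`, default −500 HU, 6-connected
to the grid border) is removed; aerated candidates (below
`aerated_hu_upper`, default −200 HU) are labelled by connected components;
components below `min_component_mm3` (default 1 mm³) are dropped and the
two largest kept (left and right lobes can disconnect at the carina);
finally a morphological closing with physical radius `closing_radius_mm`
(default 0.3 mm) folds dense fibrotic pockets back into the *total* lung
map. All defaults are exposed; none is claimed to reproduce any specific
operator. A volume with no aerated candidates raises an explicit
empty-segmentation error — the cue for the manual-mask path
(`accept_manual_mask`), which binarises (any nonzero is foreground),
checks congruence and passes the mask through unchanged.

The parameter screen enforces `body_hu_lower <= aerated_hu_upper`: the
background-air threshold must sit at or below the aerated threshold for the
body-extraction step to make sense.

Connected components (6-connectivity) and the dilation/erosion pair behind
the closing are implemented in compiled code (Rcpp); the closing element is
an ellipsoidal ball in voxel units derived from the physical radius and the
(possibly anisotropic) spacing. Erosion treats out-of-grid neighbours as
foreground so image edges do not erode structures by themselves.

## The synthetic phantom

The phantom emulates exactly what the densitometry needs and nothing more:
two lung ellipsoids inside a soft-tissue cylinder surrounded by background
air, identical geometry across the two phases, Gaussian parenchymal HU per
phase, and patchy lesions obtained by thresholding a Gaussian-smoothed
white-noise field inside the lung at the quantile that yields the requested
lesion fraction. That construction gives blob-like consolidation with a
single length scale (`lesion_blob_scale`, default 3 voxels) and makes the
realised lesion fraction exact up to threshold ties.

Defaults (all config-exposed): grid 96³ voxels at 0.1 mm isotropic spacing,
`lung_fraction` 0.15 (≈1.3 × 10⁵ lung voxels, a realistic ~130 mm³ mouse
lung), parenchyma $N(-750, 30)$ HU at P01 and $N(-650, 30)$ at P02
(inspiration more aerated by construction), lesions $N(-250, 40)$ HU —
centred in the hypo-aerated band and spilling into non-aerated, the
radiological pattern of interest — body +40 HU, background −1000 HU. No
published HU statistics exist for healthy vs fibrotic murine parenchyma
beyond the compartment boundaries themselves, so these are generator
conventions chosen once to place the three compartments in realistic
relative positions, not measured values.

Because every lung voxel's generating distribution is known, the expected
compartment percentages are closed-form masses of the two-component
Gaussian mixture under the normal CDF, and recovery tests compare the
pipeline's output against them. HU values are kept floating point by
default (`quantize = FALSE`) so these analytic identities stay exact.

**What passing phantom tests shows — and does not.** They establish that
the arithmetic, boundary semantics, masking and segmentation logic are
correct on data whose truth is known. They do not establish robustness to
beam hardening, respiratory motion, reconstruction artefacts, airway trees,
cardiac borders, or operator variability in real murine scans: the phantom
has none of these (deliberately — see Non-goals in the function
documentation).

The histology fixture generator follows the same philosophy: field scores
drawn from a requested mild/moderate/severe mix (uniform within class),
stain-positive masks thresholded at the exact target fraction, and junction
polylines that are parallel (thickness exact by construction) or
sinusoidally wavy (thickness validated against a brute-force oracle
instead).

## Histomorphometry decisions

* **Severity classes.** Mild is score 0–3, moderate exactly 4, severe 5–8
  — a partition of the 0–8 scale. The phrase "mean score" in severity
  grouping is ambiguous between per-field and per-animal-mean
  classification; frequency distributions are naturally over fields, so
  per-field is the default and `per_animal_mean = TRUE` classifies each
  animal's rounded mean instead.
* **Layer thickness** is the mean over arc-length-uniform samples on the
  upper junction of the minimum point-to-polyline distance to the lower
  junction (200 samples by default). This is robust to boundary waviness
  and reduces exactly to the perpendicular separation for parallel
  boundaries. Crossing boundaries (a negative layer) are a validation
  error. The dermal layer is taken as epidermal-dermal junction →
  dermal-subcutaneous junction; published phrasing of the dermal
  definition is sometimes elliptical ("mean distance between the
  epidermal-dermal junction"), and this completion is the assumption made
  here.
* **Stain quantification** operates on binary positive/tissue masks from
  any upstream classifier; detection (e.g. a trained collagen-fiber
  classifier) is out of scope, quantification is in scope. Positive pixels
  outside the tissue mask warn and are ignored.
* **Fold increase** divides each treated value by the control-group mean;
  a non-positive control mean is an error, not an NA.

## Statistics

Group summaries are exact sample means and SDs ($n-1$ denominator);
single-observation cells report a mean and an `NA` SD, and empty cells of
the full group × day × measure grid are reported as missing rather than
zero. The ANOVA decomposition is delegated to the classical fixed-effects
machinery (`stats::aov`) — re-deriving sums of squares by hand in
production code would add risk, not value — but the test suite checks it
against an explicit between/within decomposition written independently, on
randomised designs, to 10⁻⁸ relative. Post hoc procedures go through
emmeans: Tukey or Sidak on all pairwise contrasts, Dunnett-style
comparisons against a designated control. For two-way designs
(group × day), post hoc contrasts compare groups within each day. The
Shapiro–Wilk statistic is reported per cell as a screening column and never
used to switch tests automatically: a reported check is reproducible, an
unstated decision rule is not. The simulated type-I error of the omnibus
test at α = 0.05 under the null (three N(0,1) groups of five, 1000
replicates) is checked to lie within ±0.02 of nominal.

Dose arithmetic reports two numbers deliberately: the nominal dose uses the
pump fill volume (20 mg/mL × 100 µL / 20 g = 100 mg/kg — the equivalence
implies the fill basis), while the delivered volume at 0.5 µL/h over 7 days
is only 84 µL of the 100 µL fill. Reporting both keeps the discrepancy
visible instead of resolving it silently.

## Numerical and I/O choices

* Internal axis convention: arrays stay in storage order with
  `spacing[i]` bound to `dim[i]`; the phantom emits (z, y, x). No stage
  ever transposes, which removes the classic silent-transpose failure
  mode between segmentation and densitometry.
* Masks are written as unsigned 8-bit; any nonzero value is foreground on
  read (tolerant of tools that write 255).
* NIfTI headers store pixdim as float32, so spacing round-trips to ~10⁻⁷
  relative; tests account for this. MetaImage (.mha/.mhd + raw,
  uncompressed little-endian) is parsed directly since no installed R
  package reads it.
* CSV tables serialise doubles at 17 significant digits so numeric round
  trips are bit-exact.
* Phantom determinism: a fixed seed produces bit-identical volumes, and
  the generator saves/restores the caller's RNG state.
* The histogram's rightmost bin is closed; `findInterval` with
  `rightmost.closed` handles the $+121$ HU edge case.

## Problem sizes

The validation suite runs small phantoms (48³, ≈1.6 × 10⁴ lung voxels) for
unit tests and full-size phantoms (96³, ≈1.3 × 10⁵ lung voxels) for the
recovery and acceptance checks across lesion fractions 0–0.5; the ANOVA
null simulation uses 1000 replicates of a 3 × 5 design; histogram
uniformity is checked at 10⁶ voxels. These sizes make every property
statistically decisive (multinomial/binomial error well below the asserted
tolerances) while keeping the whole suite in tens of seconds.

## Known limitations

Segmentation is a deterministic stand-in validated only against phantom
truth, not against expert manual segmentations of real scans. The phantom's
lesion HU distribution is a convention; absolute compartment percentages on
real data depend on scanner calibration and reconstruction. DICOM series
assembly, lobe labelling, airway extraction, registration between phases
and learning-based detection are out of scope. BALF cytometry and
immunofluorescence cell segmentation are upstream of this package: only
their downstream arithmetic (% area, fold change) is implemented.
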