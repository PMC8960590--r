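---
title: "Methods: synaptome mapping and tripartite synapse quantification"
author: "synaptomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synaptome mapping and tripartite synapse quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Excitatory synapses in spinal cord tissue can be mapped at scale by
imaging a fluorescently tagged postsynaptic scaffold protein (PSD95):
each suprathreshold fluorescent punctum is one postsynaptic density
(PSD), a proxy for one excitatory synapse. Adding a presynaptic marker
(VGLUT2) and a marker of perisynaptic astrocytic processes (PAPs —
p-Ezrin or EAAT2) lets each synapse be classified as *tripartite*
(contacted by an astrocytic process) or *non-tripartite*. Aggregating
puncta over an atlas of the Rexed laminae (I–II, III–IV, V, VI, VII,
VIII, IX, X) produces a laminae-resolved synaptome map; comparing case
and control cohorts region by region produces percent-of-control heat
maps. At the nanoscale, gated-STED imaging of the same PSD95 label
resolves each PSD into one or more nanoclusters (NCs) of roughly
100–150 nm diameter, and the number of NCs per PSD defines synapse
subtypes (1 NC, 2 NC, 3+ NC).

`synaptomap` implements this entire measurement chain, plus a
ground-truthed synthetic-micrograph generator, so that every stage can
be validated against known truth without access to any image archive.

## The forward model (synthetic data)

The generator emulates the statistical structure the analysis assumes,
not tissue biology:

* **Geometry.** PSD centres are placed by a homogeneous spatial Poisson
  process within each atlas region at the region's density; counts are
  Poisson with mean `density × area / 100 µm²`. An optional hard minimum
  centre-to-centre spacing supports oracle tests that need
  well-separated objects; it is off by default so that densities stay
  exactly Poisson. Each synapse carries a presynaptic punctum centre
  200 nm from the PSD centre (apposed, partially overlapping at the
  rendered sizes) and, with probability `tripartite_fraction`, a PAP
  punctum centre 100 nm away — close enough that the rendered masks
  always share at least one pixel, the operational definition of
  contact.
* **Nanostructure.** Each PSD draws a NC count from
  `nc_count_distribution` (default 0.45, 0.32, 0.15, 0.08 over 1–4,
  giving a mean of 1.86 NCs per PSD and a 23% 3+NC fraction, a plausible
  control-like configuration). NC centres are laid out on a randomly
  rotated, randomly dilated regular polygon whose chord length never
  falls below `nc_spacing_nm`; this guarantees the minimum spacing
  exactly, which the resolution tests rely on. The PSD's ground-truth
  centre is the constellation centroid.
* **Optics.** Every fluorophore site becomes an isotropic Gaussian spot
  with FWHM equal to the larger of the PSF FWHM and the physical
  structure size. Confocal optics default to a 320 nm FWHM (the stated
  lateral resolution of the mapping instrument); STED optics default to
  70 nm — a module parameter chosen inside the usual gated-STED
  operating range, because super-resolution instruments are typically
  specified only as "sub-diffraction". Under confocal optics the NCs of
  one PSD blur into a single diffraction-limited blob; under STED optics
  they resolve individually. This dichotomy — one confocal object, many
  STED objects — is exactly what the nanostructure analysis exploits.
* **Noise.** Poisson shot noise on (signal + constant background),
  scaled by a photons-per-intensity-unit factor, followed by additive
  Gaussian read noise. Both terms can be switched off independently, so
  noise-free renderings are available as exact oracles.
* **Artifacts.** Bright saturating discs of 3–6 µm diameter emulate
  lipofuscin aggregates; their footprints are recorded in ground truth
  so size-filter tests can verify their exclusion.
* **Pixel sizes.** 100 nm/px for confocal-resolution mapping fields and
  20 nm/px for STED-scale fields (Nyquist-adequate for the respective
  FWHMs); both configurable.

What the generator does **not** emulate: tissue autofluorescence
gradients, antibody binding chemistry, optical sectioning and z-blur,
photobleaching, chromatic mis-registration, or spatial correlation
between synapse properties and anatomy beyond the per-region densities.
Passing tests therefore demonstrate that the *analysis chain* is
correct and well calibrated on data satisfying its assumptions — not
that those assumptions hold in any particular tissue.

Densities default to 20–40 puncta per 100 µm² across the laminae. Real
per-lamina densities for this tissue are not published; these defaults
are order-of-magnitude placeholders chosen once for plausibility, and
every density is configurable.

## Detection

`detect_puncta()` reproduces the standard FIJI-style particle analysis:

1. **Background subtraction** — the background is estimated as the
   grayscale morphological opening of the image by a flat disc
   (default radius 50 px) and subtracted, clamping at zero. Structures
   narrower than the disc cannot survive the opening, so puncta are
   preserved while smooth background is removed. (EBImage's grayscale
   morphology clips intensities to [0, 1]; the implementation
   normalises by the image maximum first — opening commutes with
   positive scaling, so this is exact.)
2. **Gaussian smoothing** — normalised kernel, default σ = 1 px.
3. **Thresholding** — either the automatic moment-preserving
   ("Moments") threshold or a manual intensity value. The Moments
   threshold computes the target below-threshold pixel fraction `p0`
   from the first three gray-level moments of the histogram (the two
   representative levels are the roots of the moment-determined
   quadratic) and returns the smallest gray level whose cumulative
   histogram reaches `p0`. Histograms use the native bit-depth grid
   (256 or 65,536 bins); intensities are never rescaled first. Pixels
   strictly above the threshold are foreground; a constant image has no
   threshold and errors.
4. **Labelling** — 8-connected components (the ImageJ
   Analyze-Particles convention). EBImage's labeller is 4-connected,
   so diagonal adjacencies are merged with a union–find pass.
5. **Size filtering** — components with area outside
   `[min_area_um2, max_area_um2]` (inclusive) are discarded: the
   minimum rejects few-pixel specks, the maximum rejects
   lipofuscin-scale aggregates. Border-touching puncta are kept by
   default (hemisection maps are tiled; excluding border objects would
   bias densities) and a flag reverses this.

Punctum records carry the mask, centroid, area in µm², mean intensity
measured on the processed (pre-threshold) plane, and the equivalent
circular diameter `2·sqrt(area/π)`.

### Threshold profiles and their tradeoffs

Manual thresholds are expressed on the processed-intensity scale. A
default-brightness punctum (peak 200) reaches ≈130 after PSF blur and
1 px smoothing, so:

* `immuno` (threshold 60) — sensitive, completeness-first; used where
  missing dim puncta matters more than mask size.
* `analyze_scene()` defaults — presynaptic channel at 65 (half-peak:
  masks reach the structure's FWHM, so the 200 nm presynaptic
  apposition reliably yields ≥ 1 px overlap), PSD and PAP channels at
  100 (compact masks). The tighter PSD/PAP cut is deliberate: at
  mapping densities, generous PAP masks chance-overlap several percent
  of non-tripartite PSDs, and because the conversion rate scales with
  PAP density it differs between groups with different astrocytic
  coverage — a systematic bias in class-resolved densities. Compact
  masks suppress both this and the fusion of adjacent PSD masks, at
  the cost of missing the dimmest puncta. When the quantity of interest
  is a class *fraction* rather than a between-group contrast, the
  sensitive profile on all channels is the better choice; the test
  suite exercises both configurations for exactly these reasons.
* `sted` / `confocal_nano` — STED-scale profiles (manual threshold at
  half the typical peak, smaller size filters for `sted`), so that the
  measured equivalent diameter of a nanocluster is the full width at
  half maximum of its rendered spot.
* `mapping` (Moments, automatic) — for single-channel PSD95-only maps,
  where an unsupervised threshold is preferable. On sparse synthetic
  fields the Moments threshold sits high in the blob intensity range
  (most of the histogram is background), so it is not the default for
  the multi-channel workflows, mirroring the practice of thresholding
  immunolabelled channels manually.

## Colocalisation and classification

Colocalisation is strictly object-based: two puncta colocalise iff
their binarised masks share at least one pixel. No intensity
correlation, no distance rule. In `triple` mode a PSD overlapping ≥ 1
presynaptic punctum is a synapse; among synapses, those also
overlapping ≥ 1 PAP punctum are tripartite; PSDs with no presynaptic
overlap yield no record. In `psd_pap` mode (two-channel human-tissue
style data) every PSD is a synapse and is classed by PAP overlap alone.
Tripartite status requires PSD–PAP overlap specifically (not
presynaptic–PAP); a punctum may match several partners and all matches
are recorded. Tripartite + non-tripartite = synapses, always and
exactly.

## Regional mapping

Each punctum or synapse is assigned the region of the atlas pixel
containing its centroid; boundary pixels belong to whichever region
owns them, and centroid membership (rather than any-overlap) prevents
double counting. Densities are reported per 100 µm² — the choice of
unit is internal, and all comparisons are unit-free. Heat-map tables
use subject means as the analysis unit: per region,
`(case mean − control mean) / control mean × 100`, undefined where the
control mean is zero. The astrocytic-coverage analysis correlates, over
regions, the control percentage of synapses classified tripartite with
the signed percent difference in tripartite density (Pearson, two-sided
p); it requires at least three regions with defined values and errors
on zero variance. The "loss" axis is the signed percent difference, so
a positive correlation means regions with more astrocytic contact lose
fewer tripartite synapses.

## Nanostructure

Confocal-resolved objects are whole PSDs; STED-resolved objects are
NCs. Each NC is assigned to the PSD whose mask contains its centroid;
failing that, to the overlapping PSD with maximal shared pixels (ties:
nearer PSD centroid, then lower id); otherwise it is an orphan. The
assignment rule is a documented package choice — no standard exists.
PSDs with zero assigned NCs are excluded from subtype frequencies and
reported separately, as an undetectable-NC artifact. Subtypes are
binned 1 / 2 / 3+, with raw counts retained so other binnings are
recomputable.

The STED-scale generator default spaces NCs ≥ 220 nm apart (just over
three STED FWHM). With 140 nm-diameter NCs rendered at
`max(70, 140) = 140` nm FWHM, threshold segmentation separates NC pairs
reliably from about 200 nm; at the biologically tighter 150 nm default
spacing of the mapping-scale generator, two NCs render as a single
dumbbell-shaped object that thresholding cannot split — a physical
limitation of object segmentation at that scale, not a software one.

## Statistics

Thin wrappers with a uniform result record: two-way ANOVA
(genotype × region, type-II sums of squares, subject-level
observations — the subject, not the punctum, is the analysis unit),
Šidák (`1 − (1 − p)^m`) and Tukey (studentized range) post-hoc
comparisons, Pearson chi-squared on subtype count tables (no
continuity correction), Student's pooled-variance two-sample t (with a
Welch flag; pooled df matches the convention used for reporting),
Pearson correlation and Shapiro–Wilk. Degenerate inputs have defined
behaviour: identical cell means with zero noise give F = 0 / p = 1;
one observation per cell drops the inestimable interaction and fits
the additive model; empty cells, single groups, and zero-variance
statistics raise informative errors.

The underlying computations are delegated to R's standard machinery
(`lm`/`car::Anova`, `chisq.test`, `t.test`, `cor.test`,
`shapiro.test`, `ptukey`); the tests verify them against hand-computed
sums of squares, closed forms, and null-simulation calibration
(type-I error within [0.03, 0.07] at α = 0.05).

## Problem sizes used by the test suite

Simulated studies run at desk scale, chosen once: mapping subjects are
single 256 × 256 px fields at 100 nm/px (≈ 185 synapses each, 8 laminae
bands), cohort checks use 5 control vs 5 case subjects with 100
replicate cohorts, nanostructure checks accumulate ≈ 2,000 PSDs over
640 × 640 px STED-scale fields, and statistical calibration uses 2,000
null simulations. A hemisection-scale map (~45,000 PSDs) is simply a
larger field with the same parameters.

## Known limitations

* Object-overlap colocalisation has a chance-coincidence floor that
  grows with marker density and mask size; the package reduces it by
  mask compactness but does not model or subtract it.
* 2D only, single optical sections; no 3D connectivity, no axial PSF.
* No image registration: paired confocal/STED planes are assumed
  co-registered.
* The Moments threshold assumes a meaningfully bimodal histogram;
  sparse fields push it toward the bright end, which is why the
  multi-channel profiles are manual.
* Sub-resolution NC spacing is unresolvable by thresholding, as in any
  object-based analysis at these scales.
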