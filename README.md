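# synaptomap

Quantitative synaptome mapping and tripartite synapse analysis for
multi-channel fluorescence micrographs of spinal cord tissue.

Excitatory synapses can be counted and measured at scale by imaging the
postsynaptic scaffold protein PSD95: every suprathreshold fluorescent
punctum is one postsynaptic density (PSD). With a presynaptic marker
(VGLUT2) and a perisynaptic-astrocyte marker (p-Ezrin or EAAT2), each
synapse classifies as **tripartite** (its PSD mask overlaps a PAP-marker
mask by at least one pixel) or non-tripartite. Aggregated over an atlas
of the Rexed laminae (I–II … X), this yields laminae-resolved densities,
case-versus-control heat maps, and the correlation between regional
astrocytic coverage and tripartite synapse loss. Paired confocal/g-STED
imaging of the same PSD95 label additionally resolves each PSD into
nanoclusters (NCs, ~140 nm), defining synapse subtypes by NCs per PSD.

The package implements the full measurement chain:

* **Detection** — FIJI-style punctum segmentation: morphological
  (rolling-ball style) background subtraction, Gaussian smoothing,
  Tsai moment-preserving ("Moments") automatic thresholding or manual
  thresholds, 8-connected component labelling, min/max size filters
  (rejecting few-pixel specks and lipofuscin-scale aggregates).
* **Colocalisation** — object-based, binarised-mask overlap with the
  ≥ 1 shared pixel criterion; tripartite / non-tripartite
  classification in three-channel or PSD+PAP-only mode.
* **Regional mapping** — centroid-based region assignment, densities
  per 100 µm², subject-mean percent-of-control heat-map tables,
  contact-fraction vs loss correlation.
* **Nanostructure** — NC-to-PSD assignment (centroid containment, then
  maximal overlap), NC equivalent diameters, 1/2/3+ subtype
  frequencies, mean NCs per PSD.
* **Statistics** — two-way ANOVA (genotype × region, type-II SS) with
  Šidák or Tukey post-hoc tests, Pearson chi-squared on subtype
  tables, pooled or Welch t-tests, Pearson correlation, Shapiro–Wilk.
* **Synthetic data** — a ground-truthed micrograph generator (Gaussian
  PSF forward model, Poisson + read noise, confocal vs STED optics,
  laminae atlas, lipofuscin-like aggregates) that makes the entire
  pipeline testable against known truth.

## Worked example

Simulate one subject's field, run the three-channel pipeline, and map
tripartite synapses onto the laminae atlas:

```r
library(synaptomap)

params <- scene_params(seed = 42)          # 256 x 256 px at 100 nm/px
atlas  <- build_region_atlas(params$field_size_px, params$pixel_size_nm,
                             "bands")
scene  <- sample_scene(params, atlas)
scene
#> <ground_truth_scene> 202 entities (43 tripartite), 370 nanoclusters, 0 aggregates

records <- analyze_scene(scene)            # render -> detect x3 -> classify
records
#> <synapse_records> 162 synapses (triple mode, PAP marker p-Ezrin): 35 tripartite, 127 non-tripartite

stats <- compute_region_stats(records, atlas, subject = "mouse1",
                              genotype = "control")
head(subset(stats, class == "tripartite",
            select = c(region, n, density_per_100um2)), 4)
#>  region n density_per_100um2
#>    I-II 6           7.324219
#>  III-IV 8           9.765625
#>       V 4           4.882812
#>      VI 4           4.882812
```

202 synapses were planted (43 of them tripartite, i.e. carrying a PAP
contact); the pipeline recovers 162 as synapses (PSD + presynaptic
overlap) and classifies 35 tripartite — the compact-mask thresholds
trade a little recall for unbiased class contrasts (see the methods
vignette). Densities are counts per 100 µm² of each lamina band.

Paired confocal/STED nanostructure analysis of one STED-scale field:

```r
np     <- do.call(scene_params, c(nano_scene_defaults(), list(seed = 7)))
natlas <- build_region_atlas(np$field_size_px, np$pixel_size_nm, "bands")
pair   <- detect_nano_pair(sample_scene(np, natlas))
subtype_distribution(pair$assignment)
#> <subtype_distribution> n = 26 PSDs (+0 with 0 NCs excluded), mean 1.77 NCs/PSD
#>   1: 42.3%
#>   2: 38.5%
#>   3+: 19.2%
```

Each confocal-resolved PSD is matched with the nanoclusters the STED
plane resolves inside it; subtype frequencies are over PSDs with at
least one NC.

A full case/control study (5 vs 5 subjects, 40% of tripartite synapses
removed in cases) runs from a config:

```r
run_pipeline(list(workflow = "mapping", seed = 1,
                  n_control = 5, n_case = 5,
                  tripartite_removal = 0.4), "out/")
# writes region_stats.csv, heatmap_*.csv, anova_*.csv with provenance headers
```

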