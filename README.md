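# srsmi — single-cell metabolic analysis of hyperspectral SRS images

`srsmi` is an R package for single-cell metabolic phenotyping from
hyperspectral stimulated Raman scattering (SRS) microscopy, aimed at the
question of platinum (cisplatin/carboplatin) resistance in cancer cells.
Resistant cells rewire their metabolism from glucose-driven anabolism
toward fatty-acid (FA) uptake and beta-oxidation; with isotope- and
alkyne-tagged Raman probes (glucose-d7, palmitic acid-d31, oleic acid-d34,
17-octadecynoic acid/ODYA) these two fluxes become visible as C–D
(~2050–2350 cm⁻¹) and C≡C (~2100 cm⁻¹) bands in each cell's SRS spectrum.

The package implements the full analysis chain:

1. **Hyperspectral I/O and montage stitching** — multi-page TIFF stacks
   with a JSON wavenumber-calibration sidecar; large-area tiling (e.g. a
   5 × 5 grid of 400 × 400-pixel tiles) with feathered or first-wins
   blending (`read_stack`, `write_stack`, `stitch_montage`).
2. **Spectral-phasor segmentation** — each pixel's spectrum `I_k`
   (k = 0…N−1) is embedded at

       g = Σ I_k cos(2πk/N) / Σ I_k,   s = Σ I_k sin(2πk/N) / Σ I_k,

   the first-harmonic Fourier phasor. Non-negative spectra land in the
   unit disc, mixtures lie on chords, and brightness cancels out, so
   chemically similar pixels cluster regardless of intensity. Clusters
   (Gaussian mixture, k-means, or polygon gates) map back to component
   images — nuclei, lipid, C–D, C≡C (`phasor_transform`, `cluster_phasor`,
   `map_clusters_to_images`), with least-squares dual-probe unmixing as
   the linear alternative (`unmix_dual_probe`).
3. **Cell segmentation** — nuclei by thresholding + distance-transform
   watershed; cells by nucleus-seeded region growing over the whole-cell
   foreground; lipid droplets as size-filtered particles assigned to the
   cell containing their centroid (`segment_nuclei`, `outline_cells`,
   `detect_droplets`).
4. **Single-cell metrics** — per-cell integrated intensity, mean
   intensity, signal area fraction, droplet count and size
   (`quantify_cells`), histograms, and BIC-selected Gaussian-mixture
   detection of the lipid-poor / lipid-rich subpopulations
   (`classify_subpopulations`, `compare_populations`).
5. **Metabolic index** — the core statistic

       M = F / (F + G) ∈ [0, 1],

   with `F` the FA-uptake signal (PA-d31/OA-d34 C–D, or ODYA C≡C) and `G`
   the glucose-anabolism signal (glucose-d7 C–D), per cell and averaged
   per sample with SEM (`compute_index`, `index_from_dual_probe`,
   `aggregate_sample`). Higher M tracks platinum resistance.
6. **Resistance statistics** — 4-parameter logistic IC50 fitting on log10
   dose, index–IC50 linear regression, ROC analysis (rank AUC, Youden
   threshold), and assay arithmetic: OCR slopes, FAO rate
   (OCR_total − OCR_etomoxir), Seahorse respiration metrics, ΔCt, caliper
   tumor volume, Student's t tests (`fit_dose_response`, `linear_fit`,
   `roc_analysis`, …).
7. **Synthetic data with ground truth** — hyperspectral cell phantoms
   (cells, nuclei, droplets with distinct component spectra and
   shot-like noise), bimodal intensity populations, 4PL dose–response
   tables, and sensitive/resistant cohorts (`generate_cell_phantom`,
   `generate_population_intensities`, `generate_dose_response`,
   `generate_cohort`), so every stage is testable end to end against
   known truth.

## Worked example

```r
library(srsmi)

# a synthetic field of 12 cells, half lipid-poor, half lipid-rich (10x droplets)
ph   <- generate_cell_phantom(phantom_spec(n_cells = 12, seed = 7))
f    <- phasor_transform(ph$stack)
axis <- ph$stack$wavenumbers
comps <- default_components()
prot <- make_component_spectrum(comps$CH_protein, axis)
lip  <- make_component_spectrum(comps$CH_lipid,  axis)
refs <- list(nuclei = prot, cytoplasm = 0.7 * prot + 0.3 * lip, lipid = lip)

cl    <- cluster_phasor(f, method = "gmm", k = 3, seed = 1, references = refs)
imgs  <- map_clusters_to_images(cl, f)
nuc   <- segment_nuclei(imgs$nuclei, min_area = 10)
cells <- outline_cells(f$dc, nuc)
dro   <- detect_droplets(imgs$lipid, cells)
tab   <- quantify_cells(cells, list(CH = imgs$lipid),
                        droplet_to_cell = dro$droplet_to_cell)
head(tab[, c("cell_id", "area_px", "integrated_CH", "mean_CH",
             "area_fraction_CH", "droplet_count")], 4)
#>   cell_id area_px integrated_CH mean_CH area_fraction_CH droplet_count
#> 1       1     805          2007   18.93           0.1317             4
#> 2       2     763          2668   18.92           0.1848             5
#> 3       3     800         36851  188.98           0.2437             7
#> 4       4     716         22670  188.91           0.1676             4
```

Cells 1–2 are lipid-poor, 3–4 lipid-rich (mean lipid intensity ~19 vs
~189 — the generator's 10× droplet scaling recovered by the pipeline).
On per-cell intensity populations the mixture model finds the two
subpopulations and their proportions:

```r
pop <- generate_population_intensities(c(0.5, 0.5), log_means = c(1, 3.3),
                                       log_sd = 0.3, n = 500, seed = 7)
classify_subpopulations(pop$intensity)
#> <subpop_fit> k = 2 by BIC
#>   weights: 0.486 0.514
#>   log-means: 1.015 3.284
```

And a cohort of 7 sensitive (mean index 0.30) and 4 resistant (0.52)
samples is perfectly separated by the per-sample mean index:

```r
coh <- generate_cohort(7, 4, mean_s = 0.30, mean_r = 0.52, sd = 0.04,
                       cells_per_sample = 30, seed = 1)
roc_analysis(coh$samples$mean_index, coh$samples$label)
#> <roc_result> AUC = 1.000; threshold = 0.41 (sens 1.00, spec 1.00)
```

The AUC of 1 and unit sensitivity/specificity reproduce the behaviour of
the index on well-separated patient cohorts; the Youden threshold falls
between the two group means.

## Vignette

`vignettes/srs-metabolic-index.Rmd` documents the model and its
assumptions, the phasor geometry, all tunable parameters with defaults
and units, what the phantom generator does and does not emulate, and the
package's numerical conventions.
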