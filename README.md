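# tamorph

Morphometry and peritumoral spatial analysis of tumor-associated
macrophages (TAMs) in resected colorectal liver metastases.

## The problem

CD163+ macrophages at the invasive margin of a liver metastasis are
heterogeneous, and their **cell size** carries prognostic information:
patients whose TAMs are large ("L-TAMs", mean cell area at or above a
ROC-derived cutoff of 151.38 µm²) relapse much earlier after hepatectomy
than patients with small TAMs ("S-TAMs"). `tamorph` implements the full
analysis chain behind that observation as a tested, reusable R pipeline,
for pathologists and biostatisticians working with digital-pathology
annotation exports:

1. **Morphometry** — per-cell area (shoelace formula) and perimeter
   (edge sum) of manually traced outlines; the reading protocol samples
   7 macrophages in each of 3 non-contiguous invasive-margin zones
   (21 cells/slide) and the per-patient value is the *mean of the three
   zone means*, A̅ = (A̅₁ + A̅₂ + A̅₃)/3.
2. **Classification** — empirical ROC of mean TAM area vs recurrence
   (positive test: area ≥ threshold), AUC with DeLong or bootstrap 95% CI,
   Youden-optimal cutoff J = max(se + sp − 1), and the S-TAM/L-TAM split.
3. **Survival** — Kaplan–Meier product-limit DFS/OS curves, the 3-year DFS
   readout S(36 mo), the log-rank (Mantel–Cox) test, a Table-style
   univariate screen (χ²/Fisher, Mann–Whitney U), and a multivariate Cox
   model λ(t|x) = λ₀(t)·exp(βᵀx) (Efron ties) with patient-level bootstrap
   percentile CIs and an optimism-corrected concordance index.
4. **Spatial statistics** — a 500-µm peritumoral band (outward offset of
   the tumor contour), density maps whose pixels count L-TAM centroids
   within a fixed radius, detection of L-TAM *foci* (8-connected raster
   regions with ≥ 100 L-TAMs within 200 µm), and an exact Mann–Whitney
   comparison of total foci area between prognostic-extreme patients.
5. **Synthetic cohorts** — no real dataset ships with the package; a
   generator emulates the cohort structure (two lognormal slide-mean area
   components with medians 150.4/217.0 µm², exponential
   proportional-hazards DFS with HR = 5 for the large class, uniform
   censoring, Thomas-clustered vs Poisson L-TAM point patterns) so every
   stage runs, and is tested, end to end.

Inputs for real data: GeoJSON FeatureCollections (one polygon feature per
traced cell with `cell_id`/`zone_id` properties, a `role: "tumor"` contour
feature; micrometre coordinates, or pixels with a microns-per-pixel scale
factor) plus a cohort CSV with DFS/OS times (months) and event flags.

## Worked example

```r
library(tamorph)
res <- run_pipeline(pipeline_config(seed = 1), generator_config(seed = 1),
                    measure = "slides")
print(res)
```

```
<tam_pipeline: 84 patients, cutoff 174.88 um^2 (ROC-derived)>
  ROC AUC 0.647 (0.503-0.791), sens 95% / spec 39%
  3-year DFS: S-TAM 60.0%, L-TAM 2.7% (log-rank p = 0.042)
  Cox (multivariate) L-TAM HR 2.86 (0.88-9.33), p = 0.081
  Foci contrast (6 vs 6): Mann-Whitney p = 0.0022
```

Reading this: on this simulated 84-patient cohort the Youden-optimal area
cutoff landed at 174.9 µm²; patients classified L-TAM had essentially no
3-year disease-free survival (2.7%) versus 60% for S-TAM; the multivariate
Cox hazard ratio for L-TAM is attenuated relative to the generating value
(HR 5) by measurement-noise misclassification near the cutoff — see the
methods vignette; and the six early-recurrence slides (clustered L-TAMs)
carried significantly larger high-density foci than the six favorable
slides (dispersed L-TAMs).

The numbered scripts under `analysis/` run the same stages one at a time
(`01_simulate.R` … `05_spatial.R`), narrate what they find, and write
their tables under `results/`.

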