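# isoforage

Continuous-surface dual-isotope assignment of nesting sea turtles to their
foraging areas, with population-level foraging and reproductive importance
indices and rank-based hotspot comparisons.

## The problem

Females nesting on a beach can be sampled by the hundreds, but their
foraging grounds are spread across an ocean basin. Tissue stable-isotope
ratios (δ¹³C, δ¹⁵N, in ‰) record where an animal fed before migrating, so a
calibration set of known-origin animals lets you infer foraging origins for
every *unknown* female — not by forcing her into one of a few discrete
regions, but as a continuous probability surface over the whole shelf.
`isoforage` is for movement ecologists and sea-turtle biologists who want
that workflow end to end: isoscape fitting, per-individual assignment
surfaces, cohort-level importance maps, hotspot contribution tables, and the
accompanying hypothesis tests, plus a fully seeded synthetic-study generator
for validating the machinery against known ground truth.

## The model

1. **Isoscapes.** For each element, ordinary kriging of calibration tissue
   values (WLS-fitted exponential variogram, great-circle distances) yields a
   prediction raster μ(c) and a standard-error raster se(c) on a shared
   ocean grid.
2. **Per-cell error model.** Each cell gets a bivariate normal
   N(μ(c), Σ(c)) with

   Σ(c) = [ v̄_C + se_C(c)²,   r̄√(v̄_C v̄_N) ;
            r̄√(v̄_C v̄_N),   v̄_N + se_N(c)² ]

   where v̄ and r̄ are the among-individual tissue variances/correlation
   averaged over the six broad calibration foraging areas.
3. **Assignment surfaces.** For female *i* with epidermis-equivalent values
   xᵢ, the density φ₂(xᵢ; μ(c), Σ(c)) is evaluated at every ocean cell (in
   log space) and the raster is rescaled by its maximum: values in [0, 1],
   most-probable cells exactly 1.
4. **Population summaries.** Surfaces are summed by season (foraging
   importance), weighted by eggs or emergents (reproductive importance), and
   ratioed into emergence-success surfaces; hotspot × year tables are zonal
   sums over seven hotspot polygons.
5. **Tests.** Friedman rank-sum tests (years as blocks, hotspots as
   treatments) with Conover all-pairs post-hoc comparisons,
   Benjamini–Hochberg adjustment, and compact letter displays.

## Worked example

```r
library(isoforage)

scn <- defaultScenario(seed = 1L)   # a nine-season synthetic study
res <- runPipeline(scn, quiet = TRUE)

res$validation$median               # 0.943 — surface value at true cells
res$tests$female$friedman
#> Friedman chi-squared = 25.38, df = 6, p = 0.0002902
res$tests$female$posthoc@letters
#> N_Hatteras S_Hatteras      SC_GA       E_FL    Bahamas    FL_Keys       W_FL
#>       "ab"        "b"        "b"        "c"        "a"       "ab"        "b"
round(rowMeans(res$shareTable@values), 3)
#> N_Hatteras S_Hatteras      SC_GA       E_FL    Bahamas    FL_Keys       W_FL
#>      0.113      0.137      0.158      0.242      0.092      0.114      0.144

rec <- recoveryDiagnostics(res, scn)
rec$maxRateError                    # 0.044 — emergence-rate recovery
```

Reading the output: the calibration median of 0.943 says that known-origin
animals' surfaces carry high support at their true cells. The Friedman test
rejects uniform hotspot use across the nine seasons; the letter display
shows the east-Florida hotspot (`E_FL`, letter `c`) separated from all
others — it also carries the largest nine-year average contribution (0.242).
Per-hotspot emergence rates are recovered within 0.044 of the generating
probabilities.

`runPipeline(scn, outDir = "out/")` additionally writes the input CSVs,
contribution tables, overall index rasters (ESRI ASCII grid), rank-test JSON
and a run manifest. File-driven (real-data) runs go through
`readPipelineConfig()` + `runPipelineFromFiles()`.

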