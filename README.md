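# hrdcc

High-resolution differential cell counts (HRDCCs) for longitudinal
dairy-cow immunomonitoring.

Somatic cells in raw milk are largely immune cells that entered the
mammary gland, so flow cytometry can resolve them — and the leukocytes of
matched blood samples — into subpopulations whose percentages track udder
and systemic health far more specifically than a plain somatic cell
count. `hrdcc` implements that analysis end to end for a longitudinal
study design (an eight-cow herd sampled in milk and blood twice weekly to
100 days in milk, weekly thereafter, over a 291–305-day lactation):

* a **synthetic study generator** producing event-level FCS 3.1 cytometry
  samples (scatter, 12 markers, viability dye, debris/doublet/dead
  nuisance events) together with serum biomarkers (haptoglobin, calcium,
  NEFA, β-HBA, bilirubin, GLDH) and retained ground truth;
* the **HRDCC gating hierarchy** — CD45⁺ split by side scatter into
  granulocytes (eosinophils by autofluorescence, immature granulocytes by
  low CD11b), monocytes/macrophages (CD14 × CD16 quadrant; blood
  cM/intM/ncM, milk cMac and CD14⁺/⁻CD16⁺ ncMac), and lymphocytes (NK,
  γδ T, CD4⁺ T, CD8⁺ T, B), plus viability and milk MECs (panCK⁺ among
  CD45⁻) — in a fixed-threshold *reference* mode and a density-valley
  *auto* mode, with regression-based concordance between the two
  (n pairs, Pearson r, slope, intercept);
* **longitudinal statistics**: FDR-controlled robust outlier flagging
  (rate Q), cubic and 4-knot spline trends, per-cow mean/SD summaries,
  and haptoglobin-defined inflammation episode detection with in/out
  rank-sum contrasts of the milk T-cell subsets;
* **multivariate phase analysis**: six 50-DIM lactation phases, PCA (SVD
  of the standardised feature matrix), a from-scratch sparse PLS-DA
  (NIPALS with soft-thresholded loadings, `keepX` features per
  component), one-vs-rest Mann–Whitney AUROCs and top-feature ranking.

Everything is tidyverse-native: functions take and return tibbles, fitted
objects have `tidy()`/`glance()`/`augment()`/`autoplot()` methods, and a
`run_pipeline()` orchestrator (plus a thin `inst/scripts/hrdcc` CLI)
writes every table as CSV with JSON schema sidecars and a run manifest.

## Worked example

```r
library(hrdcc)
library(dplyr)

cfg   <- study_config(n_animals = 2, n_events = 10000)
study <- simulate_study(cfg, seed = 7)
#> <hrdcc_study>
#>   2 animals, 214 samples, 1 true episodes, seed 7

res <- run_study_hrdcc(study, mode = "reference")

animal_summaries(res) |> filter(node == "CD4T", matrix == "blood")
#> # A tibble: 2 × 6
#>   animal_id matrix node   mean    sd     n
#> 1 cow1      blood  CD4T   34.6  2.83    53
#> 2 cow2      blood  CD4T   24.0  2.86    54
```

Blood CD4⁺ T percentages (of lymphocytes) sit in a narrow band around a
cow-specific level — the named `cow1` profile is parameterised at 34.7%
(SD 2.9) and is recovered by the full simulate-then-gate round trip.

```r
ea <- study_episode_analysis(res, study$biomarkers, hapto_threshold(cfg))
ea$episodes
#> # A tibble: 1 × 5
#>   animal_id start_dim end_dim peak_hapto n_visits
#> 1 cow2             33      47       2.62        4
```

A haptoglobin run above baseline + 3 SD on ≥ 2 consecutive visits is an
inflammation episode; the paired contrast table reports how milk γδ T and
CD4⁺ T percentages shift inside episodes.

```r
pm  <- assemble_matrix(res, study$biomarkers, scope = "milk")
fit <- fit_splsda(pm, n_components = 2, keepX = 5)
phase_aurocs(fit, pm)
#> # A tibble: 6 × 2
#>   phase auroc
#> 1     1 0.968
#> ...
#> 6     6 0.986

top_features(fit, 3)
#>    rank feature        loading1 loading2
#> 1     1 milk_viability   -0.682    0.761
#> 2     2 milk_CD4T        -0.469    0
#> 3     3 milk_gdT          0.426    0.274
```

Early and late lactation separate almost perfectly on milk HRDCC
features; the strongest discriminators are milk viability, CD4⁺ T and
γδ T cells — the populations with the clearest lactation trends.

See `vignettes/hrdcc-methods.Rmd` for the models, parameter meanings,
defaults and their rationale.

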