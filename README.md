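# pbsi — person-based similarity indices for brain morphometry

`pbsi` quantifies how similar each person's brain-structure profile is to
the profiles of the other members of their diagnostic group.  It is aimed at
psychiatric-neuroimaging studies asking whether a patient group (e.g.
schizophrenia or bipolar disorder) is neuroanatomically *heterogeneous*:
group-mean contrasts cannot answer that, but within-group similarity can.

## The index

Each subject contributes an ordered profile of regional measures of one
modality — typically 64 cortical-thickness (CT) and 18 subcortical-volume
(SV) measures from a FreeSurfer table export.  Within one cell (diagnostic
group × site × modality, *n* subjects),

    PBSI_i = (1 / (n − 1)) · Σ_{j ≠ i} ρ(P_i, P_j)

with ρ = Spearman's rank correlation.  The index captures the relative
inter-regional pattern and is invariant to global scale and to monotone
per-subject transforms.  Around it the package provides:

* a synthetic multi-site cohort generator with a per-group heterogeneity
  knob (`cohort_spec()`, `generate_cohort()`, `inject_dominant_region()`);
* regional-contribution diagnostics: leave-one-out mean |ΔPBSI| per region
  and random-subset resampling (`contribution_report()`);
* the non-parametric comparison battery: Mann–Whitney U with tie-corrected
  Z (exact p for small tie-free samples), Cliff's delta, the Feltz–Miller
  test for equality of coefficients of variation, Spearman associations,
  Benjamini–Hochberg FDR (`compare_pbsi()`, `cv_equality_test()`, ...);
* an end-to-end, byte-reproducible pipeline with a CLI
  (`run_pipeline()`, `inst/cli/pbsi.R`).

## Worked example

```r
library(pbsi)

spec <- cohort_spec(
  n_per_group = c(HC = 40, SZ = 40),
  groups = c("HC", "SZ"), sites = "siteA",
  within_group_dispersion = c(HC = 0.45, SZ = 0.6),  # SZ more heterogeneous
  seed = 42)
cohort <- generate_cohort(spec)

scores <- compute_pbsi_table(cohort$table)
aggregate(pbsi ~ group + modality, scores, function(v) round(mean(v), 3))
#>   group modality  pbsi
#> 1    HC       CT 0.807
#> 2    SZ       CT 0.703
#> 3    HC       SV 0.745
#> 4    SZ       SV 0.657

compare_pbsi(scores, "SZ", "HC", "CT")[, c("subset", "n_a", "n_b", "U", "Z", "p_raw", "cliffs_d")]
#>    subset n_a n_b U         Z        p_raw cliffs_d
#> 1     all  40  40 0 -7.693192 1.435085e-14       -1
#> 2 trimmed  38  40 0 -7.592470 3.138651e-14       -1
```

The higher-dispersion group has lower mean similarity in both modalities.
Negative Z and delta mean the first-listed group (SZ) is stochastically
smaller; the comparison is always reported untrimmed and after Tukey-fence
outlier removal.  Note the synthetic world is deliberately clean — here the
dispersion gap separates the score distributions completely (d = −1);
published real-cohort effects are far smaller (|d| ≈ 0.4).

Is any single region driving the index?

```r
cr <- contribution_report(cohort$table, run_subsets = FALSE)
ct <- subset(cr$loo, modality == "CT" & group == "SZ")
head(ct[order(-ct$mean_abs_delta), c("region", "mean_abs_delta")], 3)
#>       region mean_abs_delta
#> 117 region35     0.01211901
#> 105 region23     0.01140992
#> 129 region47     0.01060777
```

Leave-one-out deltas of ~0.01 on scores near 0.7 say no region dominates
(plant one with `inject_dominant_region(cohort, "ct__region05", 20)` and it
tops this table).

The same analysis end-to-end, from a YAML config with contrasts, covariate
associations, CV tables and FDR families:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/pbsi.R", package = "pbsi"))')" \
  run --config inst/extdata/example_run.yaml
```

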