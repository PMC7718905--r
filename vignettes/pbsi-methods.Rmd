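---
title: "Person-based similarity indices: model, diagnostics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Person-based similarity indices: model, diagnostics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The index

Group-mean case–control differences say nothing about how *alike* the
members of a group are.  The person-based similarity index (PBSI) turns that
question into a per-subject score.  Each subject $i$ contributes an ordered
profile $P_i = (x_{i1}, \dots, x_{ip})$ of regional measures of one modality
— cortical thickness (CT, mm) or subcortical volume (SV, mm³).  Within one
*cell* (one diagnostic group at one site, one modality, $n$ subjects),

$$\mathrm{PBSI}_i = \frac{1}{n-1}\sum_{j \ne i} \rho\!\left(P_i, P_j\right),$$

where $\rho$ is Spearman's rank correlation with midranks for ties.  High
scores mean the subject's inter-regional pattern resembles the rest of the
group; a drop in a patient group's scores relative to controls is the
operational signature of neuroanatomical heterogeneity.

Because $\rho$ uses only within-subject ranks, the index is invariant to any
strictly increasing transform of a subject's profile, and to adding a
constant to or positively rescaling all profiles.  Global measures
(intracranial volume, mean thickness) therefore cannot drive it, and no
pre-normalisation of raw measures is needed — which is why the pipeline
correlates raw values.

Scoring is *strictly within cell*: pooling groups (e.g. merging two patient
groups into one) is an explicit `pool_groups` flag, never a default, and
cross-site contrasts require an explicit `cross_site` override.  No
harmonisation across sites is applied by design; replication across sites is
the intended robustness check.

## Regional-contribution diagnostics

A useful similarity index should not be an alias for one or two regions.
Two checks:

* **Leave-one-out.**  For each region $r$, recompute each subject's score
  without $r$ and report $\overline{|\Delta \mathrm{PBSI}|}$ per region and
  cell.  A region with an outsized mean absolute delta is driving the index
  (the synthetic `inject_dominant_region()` fixture plants exactly such a
  region to prove the diagnostic detects it).
* **Subset resampling.**  Recompute scores on random region subsets —
  CT: sizes 10 to 60 in steps of 10; SV: half the regions — 100 times per
  size, and summarise agreement with the full-profile scores per size by
  (a) the Spearman correlation across subjects and (b) the mean absolute
  difference.  The published analysis does not state which agreement
  criterion it used, so both are emitted and neither is privileged.

With 18 SV regions, "half" is 9; the source analysis prints 8 (half of 16).
We use `floor(p/2)`, which reproduces 8 for a 16-region schema and 9 for an
18-region schema; the grid is configurable either way.

## Inferential toolkit

Scores within a cell are bounded, often skewed, and have no reason to be
normal, so the comparison battery is rank-based:

* **Mann–Whitney U** with midranks; $Z = (U - n_A n_B/2)/\sigma_U$ with the
  tie-corrected $\sigma_U$ and a continuity correction of $1/2$; exact
  enumeration of the null distribution of $U$ when $n_A n_B \le 400$ and
  there are no ties, the normal approximation otherwise.  Whether published
  $Z$ values used a continuity correction is typically unstated; at
  realistic $n$ the difference is negligible, and exact reproduction of any
  published $Z$ from raw data is not claimed.
* **Cliff's delta** $d = [\#\{x_i > y_j\} - \#\{x_i < y_j\}]/(n_A n_B)$,
  computed through pooled midranks in $O(n\log n)$ but equal to the
  all-pairs count *exactly* (midrank sums are half-integers, exact in binary
  floating point).  Sign convention, fixed package-wide: the first-listed
  group is the reference, and negative $Z$ or $d$ means that group is
  stochastically smaller.
* **Coefficient-of-variation equality** across groups per region, by the
  Feltz–Miller asymptotic statistic
  $\sum_i m_i (c_i - \bar c)^2 / [\bar c^2(0.5 + \bar c^2)]$ on
  $\chi^2_{k-1}$, with $c_i = s_i/\bar x_i$, $m_i = n_i - 1$ and pooled
  $\bar c = \sum m_i c_i / \sum m_i$.  CV requires strictly positive means;
  non-positive means are an error, not a silent NaN.
* **Kolmogorov–Smirnov screen** against a normal with estimated mean/sd,
  used only to route between the $t$-test and Mann–Whitney (all headline
  comparisons here are rank-based regardless).  With estimated parameters
  the p-value is conservative; it is never reported as a result.
* **Benjamini–Hochberg FDR**, implemented directly (step-up, clipped at 1,
  restored to input order) and adjusted *within explicitly declared
  families* — e.g. all group contrasts of one run form one family, covariate
  associations another — mirroring the distinction between corrected and
  uncorrected results in typical reports.  Families are never inferred.
* **Outlier robustness.**  The published analyses state that excluding
  outliers did not change conclusions but never define the rule.  We use
  Tukey fences at 1.5×IQR per cell (the same convention as the boxplot
  summaries, linear-interpolation quantiles, R type 7) and always report the
  trimmed comparison next to the untrimmed one rather than choosing.

## The synthetic cohort generator

No morphometry tables are deposited with the source study, so every
downstream stage is exercised on synthetic cohorts whose generative truth is
known.  The generator states a deliberately minimal world:

$$x_{ir} = T_r + u_m\left[\beta_r (a_i - \bar a) + \gamma_r \mathbf{1}[s_i = F]
  + \sigma_g\,\varepsilon_{ir}\right], \qquad \varepsilon_{ir} \sim N(0,1)
  \text{ i.i.d.}$$

* $T$ — a template profile shared by everyone, drawn once per modality with
  spread `between_region_sd` (default 1 standardized unit).  The template
  *is* the signal: rank correlations between subjects are high exactly in
  so far as the template's region-ordering survives the noise.
* $u_m$ — the affine map from standardized units to measurement units:
  0.25 mm per unit around a 2.5 mm baseline for CT, 400 mm³ around 4000 mm³
  for SV.  Both baselines sit 10 units above zero, so volumes (and
  thicknesses) are positive *by construction* rather than by truncation —
  truncating would distort the rank structure the index lives on.  Rank
  statistics are invariant to this map, so the knobs below mean the same
  thing in both modalities.
* $\sigma_g$ — `within_group_dispersion`, the per-group heterogeneity knob:
  the SD of subject-level idiosyncratic noise in standardized units.
  Default 0.5 (half the between-region spread: subjects clearly resemble the
  template but are far from copies).  Mean within-group PBSI is
  monotonically decreasing in $\sigma_g$; this is the property the
  heterogeneity-recovery tests certify.
* $\beta, \gamma$ — per-region age slopes and female-offsets, default 0.
  Note a *region-constant* covariate effect shifts a profile uniformly and
  is invisible to ranks; covariate effects reach the index only through
  region-*varying* vectors, which is what the covariate-propagation test
  uses.
* Ages uniform on `age_range` (default 18–65), sexes alternating F/M within
  each cell.  The reference samples are not balanced; balance here isolates
  the statistics under test from composition effects.
* Reproducibility: one master seed, split into per-subject streams keyed by
  (site, group, subject index) through a pure-arithmetic 31-bit hash, so
  enlarging a cohort never perturbs previously generated subjects, and every
  subset-resampling draw is keyed by (cell, size, repetition) and
  individually recoverable.

What the generator does **not** emulate: empirical inter-regional
covariance (no atlas-based covariance structure — noise is independent
across regions given the template), scanner/site batch effects beyond a site
label, non-Gaussian tails, missingness mechanisms, and any clinical-score
structure.  A green simulation test therefore establishes that the
*machinery* is correct under the stated world, not that real cohorts behave
this way; in particular the published effect sizes are not reproducible
desk-side and are not asserted anywhere in the test suite.

## Numerical choices

* **Exact rank kernel.**  Midranks of a length-$p$ profile always sum to
  $p(p+1)/2$, so centring by $(p+1)/2$ is exact; pairwise sums of products
  of centred midranks are sums of quarter-integers, also exact.  The
  correlation matrix of a cell is computed once as a crossproduct of the
  centred rank matrix, normalised by $\sqrt{S_{ii}S_{jj}}$ computed as one
  product (in IEEE round-to-nearest $\sqrt{\mathrm{fl}(S\cdot S)} = S$), so
  identical profiles correlate at exactly 1 and rank-reversed profiles at
  exactly −1.  That is what lets the analytic-limit tests assert equality,
  not closeness.
* **Order-exact averaging.**  Each subject's $n-1$ correlations are summed
  in sorted order, making the score exactly invariant to subject input
  order (floating-point addition is not associative).
* **Degenerate inputs.**  A constant profile has zero rank variance and an
  undefined $\rho$; the subject is excluded from the cell with a warning and
  reported as `NA` — imputing $\rho = 0$ would silently bias every peer's
  mean.  A comparison whose pooled values are all tied has $\sigma_U = 0$
  and returns $Z = 0$, $p = 1$.  A CV test with all-zero CVs returns
  statistic 0.
* **Missing data.**  The analysis needs complete position-wise profiles, so
  subjects with any missing region value are dropped at ingest with a
  logged count, never imputed.
* **Determinism.**  Every output file is a pure function of (config, seed);
  reports carry a provenance block and deliberately no timestamps, so two
  runs with the same config are byte-identical — asserted, not assumed.

## Limitations

The generator's independence assumption means region-contribution results on
synthetic data are easier than on real data, where correlated regions share
their contribution.  The default 64 + 18 region schema is a reconstructed
Desikan-style listing, not a copy of any study's supplementary table, and is
marked as such.  The `cv_equality_test` is asymptotic; its type-I behaviour
is verified at $n = 50$ per group but small-sample behaviour is not
certified.  Region counts are not hard-coded: any schema with at least two
regions per modality is accepted.
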