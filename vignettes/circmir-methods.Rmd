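---
title: "Methods: circulating miRNA signature analysis in circmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circulating miRNA signature analysis in circmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circmir)
```

`circmir` analyzes low-density qPCR array (TLDA) profiles of circulating
microRNAs to find and evaluate a disease signature — the setting is
vulnerable coronary artery disease, where plasma of unstable angina (UA)
patients is compared with stable angina (SA) patients and non-cardiac
chest-pain controls. This vignette is the package's account of the
underlying models, the parameters that matter, the numerical choices, and
what the synthetic-data tests do and do not establish.

## The measurement model

A TLDA card reports a cycle threshold `Ct` per (miRNA, sample) well;
lower Ct means higher abundance, and the instrument reports
`Undetermined` when no amplification crosses threshold within 40 cycles.
Three modeling commitments follow:

* **Detection is strict.** A well is detected only when `Ct < ct_max`
  (default 40 cycles). A value exactly at the ceiling is treated as
  undetected, which makes the expression filter ("detected in at least 21
  of 26 samples") well defined at the boundary. Undetected wells
  propagate as missing values and are never imputed by the preprocessing
  layer; each downstream stage declares its own missing-data policy.
* **Quantification is relative.** Expression is
  `2^-(Ct[miRNA] - Ct[ref])` against a stable endogenous reference — U6
  for plasma profiles, hsa-miR-24 for microparticle RNA. The reference
  must be detected in every sample (hard error otherwise, naming the
  offending samples). Adding any constant to all Ct values of one sample
  (a pipetting/efficiency offset) cancels exactly.
* **Analysis happens on `log10(2^-dCt)`.** Group statistics, ROC
  cut-offs, logistic units and correlations use the log scale, where qPCR
  noise is approximately additive; fold changes are reported on the
  linear scale as ratios of arithmetic group means. The measurement
  model does not fix this pairing; it is the conventional one, and the
  geometric-mean alternative is exposed as
  `fold_changes(method = "geometric")` because published fold-change
  tables cannot be regenerated without fixing the choice.

## SAM: selection of the deregulated signature

The signature is selected by a two-class unpaired significance analysis
of microarrays, implemented from scratch:

1. **Score.** `d_i = (mean_case - mean_control) / (s_i + s0)` with `s_i`
   the pooled standard error
   `sqrt((1/n1 + 1/n2) * SS_within / (n1 + n2 - 2))` on log10
   expression. A miRNA enters calling only when each group has at least
   two defined values; group means are pairwise-available.
2. **Fudge factor.** `s0` stabilizes `d` for low-variance miRNAs.
   Candidates are the percentiles 0, 5, ..., 100 of the `s_i`
   distribution; the winner minimizes the coefficient of variation of
   `mad(d)` computed inside 10 `s_i`-quantile windows, with ties broken
   toward the smaller candidate. The procedure is deterministic; if all
   `s_i` are equal it returns 0 with a notice. At least 20 miRNAs with a
   defined score are required — below that the window statistics are
   meaningless.
3. **Permutation null.** Balanced relabelings assign the case label to
   `n1` of the `n` samples. When `choose(n, n1)` does not exceed the
   permutation budget (default 1000) all relabelings are enumerated —
   at 3 + 3 that is `C(6,3) = 20`, and the result is seed-independent;
   otherwise distinct relabelings are sampled without replacement under
   the configured seed (`C(26,13) ≈ 1.04e7` is far beyond enumeration).
   Each permutation recomputes `d` with the same `s0` and stores the
   sorted vector; the elementwise mean is the expected order-statistic
   vector of SAM's diagnostic plot.
4. **q-values.** For each candidate threshold `t` (every observed
   `|d_i|`), `FDR(t) = pi0 * median_b #{|d_null,b| >= t} / #{|d_obs| >= t}`,
   with `pi0` the fraction of observed scores inside the interquartile
   range of the null divided by 0.5, capped at 1. A miRNA's q-value is
   the minimum FDR over all thresholds at which it is called, which
   enforces monotonicity in `|d|` by construction; ties in `|d|` share a
   q-value exactly. The median (not mean) over permutations makes the
   top calls robust: a strongly separated signature yields `q = 0`
   because most relabelings produce no exceedance.
5. **Calling rule.** Fold change strictly greater than 8 (or below 1/8)
   *and* q-value below `1e-6`. The published threshold "q < 0.0001%" is
   read literally as a percentage, i.e. `1e-6` as a proportion; with a
   1000-permutation null this is operationally `q = 0`.

Assumptions worth stating: exchangeability of samples under the null
(the permutation argument), additive noise on the log scale, and no
between-array normalization beyond the reference gene (the panel design
measures all miRNAs of a sample on one card).

## Evaluation layer

* **Clustering** uses `stats::dist`/`stats::hclust` (Euclidean, average
  linkage by default) on both axes; `stats::dist` rescales distances
  computed from pairwise-complete coordinates when cells are missing.
  An all-constant matrix is rejected ("zero variance").
* **PCA** reduces samples to `k = 3` centered, unscaled components.
  Missing cells are imputed with the miRNA's cohort mean (after the
  detection filter at most a handful of cells per retained miRNA are
  missing, so mean imputation perturbs the decomposition little). Sign
  convention: the largest-magnitude loading of each component is
  positive, which fixes `prcomp`'s sign indeterminacy for reproducible
  output. Reports of PCA "correct classification"
  percentages in this literature rarely define the classifier; the package's default
  rule — documented, swappable, and the open design decision here — is
  leave-one-out nearest group centroid in the 3-dimensional score space.
  Percentages scored by visual cluster assignment are therefore
  rule-dependent and not hard targets.
* **ROC.** AUC by midranks (equal to Mann–Whitney `U/(n1*n2)`, handling
  ties as half-concordances), Hanley–McNeil variance for the 95% CI,
  normal approximation of `U` for the p-value against AUC = 0.5, and the
  Youden-optimal cut-off (`max(sens + spec - 1)`) over midpoints between
  adjacent observed values, ties broken toward higher specificity, then
  toward the higher cut-off. Polarity is "case high": positive calls are
  values at or above the cut-off. Constant markers degrade to AUC 0.5
  with a warning rather than an error.
* **Logistic adjustment.** `stats::glm(binomial)` — IRLS with tolerance
  `1e-8`, at most 100 iterations. The odds ratio is per unit of
  `log10(2^-dCt)`, i.e. per 10-fold expression change, matching the
  cut-off scale. Perfect separation or non-convergence is *flagged*
  (infinite-OR sentinel) rather than raised, so a screening loop over
  miRNAs survives degenerate markers; missing covariate values are a
  named hard error at fit time, not at load time.
* **Two-group tests.** Continuous: Shapiro–Wilk at `alpha = 0.05` in
  each group gates t-test (pooled, two-sided) versus Mann–Whitney —
  "as appropriate" needs an explicit rule, and this is it. Constant
  groups cannot reject normality and identical constant groups return
  `t = 0, p = 1` directly. Categorical: Pearson chi-squared without
  continuity correction, switching to two-sided Fisher when any
  expected cell is below 5.

## Coexpression networks

Per group, Pearson correlations over pairwise-complete samples (minimum
overlap 3) with two-sided p-values from
`t = r * sqrt((m - 2)/(1 - r^2))` on `m - 2` degrees of freedom. Edges
require `r >= 0.79` and `p < 0.02` — positive correlations only, reading
the threshold pair as a one-sided magnitude rule; `use_abs = TRUE`
switches to `|r|` thresholding since "weighted and undirected" does not
settle sign handling, and both choices change node/edge counts. Nodes
are endpoints of surviving edges (degree >= 1) — the node universe that
makes finite node counts arise from a 754-assay panel; this convention is a
documented choice rather than a target. Subnetworks take a seed set (the validated
signature) plus direct neighbors with induced edges; comparisons are
exact set operations on unordered node-pair keys. Exports (SIF, GraphML
with `r`/`p` attributes via igraph, edge-list TSV) use stable
lexicographic edge order so reruns diff cleanly.

## Microparticle quantification

Flow-cytometry event tables carry three boolean flags per event (inside
the 0.1–1 µm size gate, Annexin V+, CD31+). Bead calibration:
`concentration = (#matching gated events / bead events) * (beads per
tube / test volume)`. The CD31+/CD31− subtypes partition the Annexin V+
concentration exactly at event level, and the partition propagates to
group means. MP-RNA expression is normalized to hsa-miR-24 and divided
by the sample's MP concentration; the package adjusts to the *total*
Annexin V+ count by default — "adjusted to MP counts" admits several readings,
and total Annexin V+ is the least specific one; any
other count vector can be passed explicitly. Gate geometry is consumed
as flags: reconstructing scatter gates from raw FCS intensities is out
of scope.

## The synthetic cohort generator

The generator emits the exact data structures the pipeline consumes and
defines the study conditions under which the package's statistical
properties are tested:

* 754 assays plus a stable U6 row (Ct 25, SD 0.15); baseline Ct
  `N(28, 3)` across miRNAs; within-miRNA between-sample SD 0.6 cycles
  (real TLDA replicate dispersion is not published; this is a documented
  free parameter);
* two groups of 13 (derivation) or 45/31/37 (validation preset, 7-assay
  panel, within SD 1.5 cycles for single-assay PCR on a heterogeneous
  cohort);
* a planted signature of 30 miRNAs with linear fold changes drawn from
  `[8.702, 24.2]` — fold-change extremes typical of a strong plasma
  signature —
  applied as `-log2(FC)` Ct shifts in the case group, so linear fold
  changes are exact in expectation. The lower end deliberately sits
  above the strict 8-fold calling boundary: planting effects exactly on
  a strict decision threshold would make "recovery" a coin flip by
  construction;
* logistic detection dropout, `P(detect) = plogis((37 - Ct)/3.5)`. The
  two calibration anchors for this model (centered near Ct 37; roughly
  5–15% of assays failing the 21-of-26 filter under the baseline
  distribution) jointly force a fairly shallow slope; the cost is a few
  percent dropout even at moderate Ct, which is more than real TLDA
  cards show but exercises the missing-data paths meaningfully;
* latent-factor correlation blocks per group: members load
  `sqrt(block_cor)` on a shared per-sample factor, giving pairwise
  correlation `block_cor` (default 0.9). The block parameter is defined
  as the *target correlation*, not the loading: a loading of 0.9 would
  give pairwise correlation 0.81, for which recovering >= 80% of
  within-block pairs at the `r >= 0.79` edge threshold with 13 samples
  is unattainable, while correlation 0.9 makes it hold. Default blocks
  overlap the planted signature (indices 16–30 in both groups, 31–45
  UA-only), reflecting that deregulated miRNAs in this setting are
  cluster/family members that are coexpressed — and giving the seeded
  subnetwork comparison non-trivial shared links;
* covariates drawn marginally from per-group frequencies of a typical
  angina/control cohort (sex, age, hypertension, dyslipidemia, diabetes,
  smoking, statin, anti-platelet use). Covariates are generated
  *independently* of expression, so logistic-adjustment tests verify
  invariance under orthogonal covariates, not correction of real
  confounding;
* the MP study: per-sample CD31+/CD31− concentrations drawn around
  group means 4318/895 (UA) and 1646/594 (control) events/µL with SDs
  reconstructed from printed SEMs (`SD = SEM * sqrt(5)`), converted to
  Poisson event counts through fixed bead parameters, plus Annexin V−
  and out-of-gate nuisance events; MP-RNA Ct back-calculated so
  count-adjusted expression carries a planted 2-fold case/control ratio
  with log10 SD 0.12.

Everything is a deterministic function of the spec and its seed; the
caller's RNG stream is saved and restored.

**What passing tests on this generator do not show.** The generator is
Gaussian on the Ct scale with a single reference, clean balanced
designs, independent covariates, and dropout that depends only on the
true Ct. Real plasma profiles carry hemolysis and platelet-contamination
artifacts, batch and card effects, heavy-tailed outliers, correlated
covariates, and reference-gene instability — none of which are emulated.
Recovery of a planted signature here validates the machinery, not the
biology.

## Numerical choices and degenerate inputs

* Ct files are written with 17 significant digits so read-write round
  trips are bit-exact; delimiter auto-detection compares tab and comma
  counts in the header; decimal parsing is dot-only regardless of
  locale.
* `d = 0/0` (identical constant groups with `s0 = 0`) is defined as 0.
* Fold changes with an undefined or nonpositive control mean are set
  missing and excluded from selection, with a message.
* Correlations of constant rows are missing; exact linear relations get
  `p = 0` rather than a negative value from floating-point `1 - r^2`.
* A planted-zero Annexin V+ concentration is floored at 1/µL only for
  the Ct back-calculation in the generator; the analysis layer instead
  drops zero-count samples from the adjusted-expression stage with a
  message, and errors on nonpositive counts passed explicitly.
* Hierarchical clustering ties (equal merge heights) follow `hclust`'s
  deterministic order; tests assert tie-robust properties only.

## Problem sizes used by the test suite

The suite exercises the full 754-assay, 26-sample derivation design once
end-to-end (1000 permutations), and runs the distributional properties
at 200 assays: type-I control over 20 seeds, power at FC 16/log10 SD
0.25 over 10 seeds, block recovery over 10 seeds, MP power over 10
seeds. These sizes keep the whole suite in the half-minute range on one
core while leaving every Monte-Carlo margin wide; all seeds are fixed in
the test code.

## Known limitations

* Exact reproduction of score/fold-change tables produced by other SAM
  implementations depends on their unstated defaults (permutation
  count, the pi0 estimator, the fold-change scale) and on the network
  sign and node-universe conventions; the package documents each choice
  and exposes the alternatives rather than guessing silently.
* The permutation q-value floor is `0` below one exceedance per
  permutation set; q-values between 0 and ~1e-3 are not resolvable at
  the default 1000 permutations.
* DeLong AUC confidence intervals and multi-marker composite scores are
  not implemented (Hanley–McNeil and single-marker evaluation match the
  reference workflow).
* GEO series-matrix ingestion is not built in; converting a downloaded
  matrix to the package's TSV dialect is a one-liner in any scripting
  language, and `run_config(ct_path =, annotation_path =)` takes it from
  there.
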