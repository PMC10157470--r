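---
title: "Methods: two-sample MR for gut inflammation and cortical structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR for gut inflammation and cortical structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexmr)
```

## The causal question and the design

Two-sample Mendelian randomization uses genetic variants as instruments:
SNP–exposure associations come from one GWAS, SNP–outcome associations from
another, and under the instrumental-variable assumptions (relevance,
independence from confounders, no path to the outcome except through the
exposure) the ratio of outcome to exposure effects estimates a causal
effect. `cortexmr` implements this design for a study grid of
gut-inflammation exposures (IBD, Crohn's disease, ulcerative colitis, IL-6,
IL-6 receptor subunit alpha) against 70 cortical phenotypes: global surface
area and thickness plus the 34 Desikan–Killiany regions in both measures.
Outcome GWAS of that kind are supplied pre-adjusted ("global-weighted");
the package performs no covariate adjustment of its own.

The pipeline per exposure–outcome pair is fixed and mirrors standard
practice: instrument selection, harmonization, MR-PRESSO outlier removal
*before* estimation, the three-estimator battery, the sensitivity battery,
and tier classification.

## Instrument selection

Four screens apply in order, each only ever removing SNPs:

1. **Significance.** SNP–exposure p below `p_threshold` (default
   `5e-8`). The threshold is a per-exposure setting: an exposure with a
   single genome-wide-significant locus (the IL-6 situation) can be
   re-screened at `5e-6` while keeping the F floor, via a per-exposure
   `selection_config()`.
2. **LD independence.** Greedy clumping at `r2 < 0.001` within
   10000 kb: the smallest-p SNP becomes an index, correlated neighbours
   drop, repeat. LD comes from a user-supplied pairwise r² table — the
   algorithm is the standard one but no reference-panel genotypes or PLINK
   dependency are required; absent pairs mean r² = 0. Ties on p break by
   lexicographic SNP id, so output never depends on input order.
3. **Confounder exclusions.** A user-supplied list of SNPs associated with
   secondary phenotypes that could open confounding paths (obesity,
   hyperlipemia, hypertension, neurodegenerative and neuropsychiatric
   disease, smoking, alcohol), with a reason per SNP. Look-ups against a
   genotype–phenotype catalogue happen outside the package; the exclusion
   file is the interface.
4. **Strength.** Per instrument, `R2 = 2·MAF·(1−MAF)·β²` (or the
   `β²/(β² + Se²·n)` fallback when frequencies are missing) and
   `F = (R2/(1−R2))·((n−k−1)/k)`. The weak-instrument screen uses the
   per-SNP F (`k = 1`): the set-size-`k` variant of the same formula
   divides every per-SNP F by roughly `k`, which at 50 instruments would
   label every member of a strong set "weak" — a per-SNP screen is the
   only reading under which the screen does its job. The set-level
   statistic (summed R², `k` = set size, mean n) is computed and reported
   separately by `set_strength()`, matching the convention of quoting F
   both per variant and per instrument set.

## Harmonization

Outcome records are aligned to the exposure's effect allele: direct allele
matches pass through, swapped matches negate the outcome beta, strand
complements resolve the same way after complementing. Palindromic SNPs
(A/T, C/G) carry no strand information in their letters, so they are kept
only when both allele frequencies sit on the same side of 0.5 and both
minor-allele frequencies are below `palindrome_eaf_limit = 0.42` —
prevailing two-sample MR practice; SNPs failing this, or with missing
frequencies, drop as `palindromic-ambiguous`. Harmonization never changes a
magnitude, only signs, and every shared SNP ends up in exactly one of the
kept or dropped tables. Within one file, duplicate SNP ids keep the
smallest p-value; indels and multi-allelic records are rejected at read
time as out of scope.

## Estimators

With `w_j = 1/se_yj²`:

- **IVW (fixed):** `beta = Σ w β_x β_y / Σ w β_x²`,
  `se = sqrt(1/Σ w β_x²)` — algebraically the inverse-variance-weighted
  mean of Wald ratios.
- **IVW (multiplicative random effects, primary):** same estimate;
  `se` multiplied by `sqrt(max(1, Q/(J−1)))`. The floor at 1 means the
  random-effects SE never undercuts the fixed-effects SE — the
  conservative convention, matching the rationale for preferring the
  multiplicative random-effects form in the presence of possible
  heterogeneity. p-values are standard normal, two-sided.
- **Wald ratio:** a single-instrument pair returns `β_y/β_x` with
  first-order delta SE `se_y/|β_x|` (second-order term deliberately
  omitted), so sparsely instrumented exposures still flow through the
  pipeline; they can reach at most the nominal tier.
- **Weighted median:** ratios sorted ascending; standardized cumulative
  weights `s_j = (Σ_{i≤j} w_i − w_j/2)/Σw` with weights `β_x²/se_y²`;
  linear interpolation at `s = 0.5`, clamping to the extreme ratio outside
  `[s_1, s_J]`. The SE is a parametric bootstrap (default `n_boot = 1000`,
  seed required for reproducibility): each resample redraws
  `(β_x, β_y)` from normals at the observed values with the observed SEs.
  The estimator is exact for equal weights and odd J (the sample median).
- **MR-Egger:** SNPs oriented so `β_x ≥ 0` (results are invariant to
  per-SNP sign flips), weighted least squares with intercept, SEs scaled
  by `sqrt(max(1, RSS_w/(J−2)))`, t reference with `J−2` df — the
  originating method's convention, requiring at least three instruments.

## Sensitivity battery

- **Cochran's Q** on Wald ratios with weights `β_x²/se_y²`, chi-square
  with `J−1` df; identical by algebra to the weighted RSS of the
  origin-forced regression at the fixed-effects solution. When
  `Q p < 0.05` the report marks that only the multiplicative
  random-effects IVW should be read as primary.
- **Egger intercept test:** the intercept above, with p < 0.05 flagging
  directional pleiotropy.
- **MR-PRESSO:** observed residual sum
  `Σ_j w_j (β_yj − b_(−j) β_xj)²` with leave-one-out IVW fits `b_(−j)`,
  compared to `n_sim` parametric simulations (β_x* at the observed values,
  β_y* at the leave-one-out fitted values, observed SEs). Per-SNP
  contributions give one-sided outlier p-values, Bonferroni-corrected over
  J by default (the correction is switchable, since the bare
  p < 0.05 rule is also in circulation); flagged SNPs are removed before
  estimation and the distortion test compares the cleaned estimate with
  the all-SNP estimate against random same-size removals. Defaults
  `n_sim = 1000`, `outlier_alpha = 0.05`; a fixed seed gives bit-identical
  results. A global p of zero exceedances is reported as below `1/n_sim`.
- **Leave-one-out:** every J−1 subset refit with the primary IVW; a pass
  requires every refit significant at `loo_threshold` (default 0.05) and
  sign-stable. For results aiming at the significant tier the natural
  stricter reading re-evaluates at the Bonferroni threshold; both
  thresholds are plain config keys, and the reported verdict uses 0.05 —
  the published tables' "Yes/No" column is reproducible under either
  reading for clear-cut cases.
- **Funnel data:** per-SNP ratio against precision `|β_x|/se_y`, emitted
  as a table; `funnel_plot()` renders it but plotting is not part of the
  tested contract.

## Classification

`classify_pair()` implements the three-tier rule. *Significant* requires
IVW p below the level threshold (Bonferroni: 0.05/68 regional, 0.05/2
global), weighted-median p < 0.05, directional concordance of weighted
median and Egger with IVW, and — under the default strict reading — Q and
intercept p at or above 0.05 plus a leave-one-out pass. The published
footnote enumerates only the first three ("consistency") criteria while
every published significant row also clears the sensitivity gates, so both
readings are supported via `require_sensitivity_gates`; the strict one is
the default. *Nominal* is IVW p < 0.05 without the full battery; everything
else is *null*. The rule is monotone: improving any single criterion never
demotes a pair. Pairs that cannot be evaluated (no shared SNPs, selection
failure) are reported as `not_evaluable` with the cause.

## The synthetic-data generator

`simulate_pair()` draws, per SNP: `maf ~ U(maf_range)`; a true exposure
effect of magnitude `sqrt(h2_per_snp/(2·maf·(1−maf)))` (each instrument
explains a fixed share of a unit-variance exposure) with random sign by
default; a direct outcome effect per pleiotropy regime (none; balanced,
mean 0; directional, mean μ; InSIDE-violating, proportional to the
instrument effect); the true outcome effect `c = θ·b + a`; and observed
effects from normals with `se = 1/sqrt(2·maf·(1−maf)·n)` — the standard
summary-statistic approximation, with the two samples independent (the
two-sample design; the few-percent sample overlap a real pairing may have
is not simulated). Outliers displace `c` by a stated number of outcome
SEs. Alleles are assigned so a configurable fraction is palindromic and a
fraction is written allele-swapped in the outcome file, so harmonization
is genuinely exercised; optional LD blocks give clumping realistic input
and emit the matching r² table. All randomness flows through one seed, and
a binary exposure differs from this continuous-scale model only by the
labelling of units (log-odds), not by any computation on summary data.

Defaults are fixed at the motivating study's scale and are not tuned per
test: J = 50 instruments, exposure GWAS n = 60,000 (an IBD meta-analysis
scale), outcome n = 51,665 (the brain-imaging consortium scale), maf in
[0.05, 0.5], and `h2_per_snp = 0.004`, i.e. per-instrument F around 240 —
top-locus strength for a well-powered meta-analysis, and comfortably past
the genome-wide screen the pipeline itself applies. What the generator
does *not* emulate: realistic minor-allele spectra, liability-scale
case-control effects, polygenic backgrounds, or winner's-curse selection
of instruments.

## Numerical and design notes

- **Weak-instrument dilution.** Noise in `β_x` attenuates regression-based
  estimators: relatively `≈ 1/F̄` for IVW (about 0.4% at these defaults)
  and `V/(V+S)` for the with-intercept Egger slope (V the weighted
  variance of true effects, S the mean squared exposure SE). The
  validation suite tests recovery against these first-order corrections
  rather than pretending the effect away.
- **Weighted-median robustness testing** uses invalid instruments whose
  direct effects are balanced in sign (ratio offsets ~N(0, 0.8) on 40% of
  instruments). A common directional offset far beyond the ratio SE
  instead biases any median-type estimator by about one ratio SE (the 50%
  weight point falls at the ~83rd percentile of the valid cluster), which
  no confidence procedure centred on the point estimate can cover at
  nominal rates — a real limitation of the estimator worth knowing, not a
  defect of the implementation.
- **Determinism.** Estimation itself is closed-form; all simulation-based
  components (weighted-median bootstrap, MR-PRESSO, the generator) take
  seeds, and `run_study()` derives per-pair seeds from one master seed, so
  whole study reports rerun byte-identically.
- **Degenerate inputs.** Zero exposure effects make Wald ratios undefined
  and raise a named error; `se ≤ 0`, out-of-range frequencies or p-values
  are rejected at read time with row numbers; empty SNP intersections and
  all-dropped harmonization raise errors naming the inputs.
- **Problem sizes in the validation suite** (chosen as a desk-scale study
  in their own right): 200 oracle sets, 1000 null replicates for size,
  500 replicates for recovery and robustness, 200 for outlier detection,
  and 200 all-null single-exposure studies of 68 outcomes (J = 20,
  `n_sim = 200`, `n_boot = 200`) for the family-wise error check.
  The acceptance script repeats the same computations, with 100 null
  studies.

## Known limitations

- LD handling is table-driven; there is no reference-panel processing, no
  liftover, no VCF ingestion.
- No mode-based, MR-RAPS, contamination-mixture or multivariable
  estimators, and no bidirectional or mediation analysis: the pipeline
  implements exactly the three-estimator design it models.
- Confounder screening relies on a user-curated exclusion list, not a live
  catalogue query.
- Passing every synthetic-data test shows the machinery is correct under
  the stated generative model; real GWAS bring selection effects,
  stratification and overlap that the generator deliberately does not
  model.
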