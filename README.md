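# targetmr

Two-sample, summary-level Mendelian randomization (MR) of lipid traits and
lipid-modifying **drug-target gene regions** against a binary disease
outcome, with the full sensitivity stack the field expects: MR-Egger,
weighted-median and mode estimators, a simulation-based pleiotropy outlier
test, Bayesian colocalization, two-step mediation through an intermediate
trait, and Benjamini–Hochberg FDR across targets. A synthetic GWAS
summary-statistics generator with known ground truth makes every stage
testable without access to consortium data.

Everything is tidyverse-native: functions take data frames and return
tibbles, fitted objects have `tidy()`/`glance()` methods, and each result
type has ggplot2 visualizations.

## The statistics at the core

For a variant *g* with effects *β̂X(g)* on the exposure and *β̂Y(g)* on the
outcome, the Wald ratio *β̂Y/β̂X* estimates the causal effect. The package
pools ratios by inverse-variance weighting with multiplicative
random-effects inflation:

```
β_IVW = Σ wᵢ rᵢ / Σ wᵢ,   wᵢ = β̂Xᵢ²/se(β̂Yᵢ)²,
se    = (Σ wᵢ)^(-1/2) · max(1, √(Q/(k−1)))        (Cochran's Q, k ratios)
```

alongside MR-Egger (weighted regression with a free intercept; the
intercept tests directional pleiotropy), the weighted median
(consistent if ≥50% of weight is valid), simple/weighted modes
(consistent if the largest homogeneous cluster is valid), multivariable
IVW, leave-one-out, and an MR-PRESSO-style global/outlier/distortion test.

Instrument strength uses
`R² = (2·EAF(1−EAF)β²)/(2·EAF(1−EAF)β² + 2·EAF(1−EAF)·N·SE²)` and
`F = R²(N−2)/(1−R²)` with the conventional `F > 10` cut. Drug-target
instruments come from a ±250 kb gene window at genome-wide significance,
clumped at `r² < 0.2`; cis-eQTL instruments at `r² < 0.1`.

Colocalization enumerates the single-causal-variant hypotheses H0–H4 from
per-variant Wakefield approximate Bayes factors (all in log space, so
posteriors down to ~1e-300 are exact) and reports the conditional
probability `H4/(H3+H4)`. Mediation decomposes a target's total effect as
`indirect = β1·β2` (target→mediator times mediator→outcome),
`direct = total − indirect`, with a product delta-method SE.

## Worked example

A fully synthetic study in the shape of the real design — three null lipid
traits, four causal drug targets (one protective), a vitamin-D-like
mediator — runs end to end in one call:

```r
library(targetmr)
library(dplyr)

cfg <- simulate_study(seed = 1)   # a complete study_config with known truth
bundle <- run_study(cfg)

bundle$target_mr |> filter(method == "ivw_re") |>
  select(unit, n_snp, beta, or_point, or_low, or_high, pvalue, q_fdr)
#> # A tibble: 4 × 8
#>   unit  n_snp   beta or_point or_low or_high   pvalue    q_fdr
#>   <chr> <int>  <dbl>    <dbl>  <dbl>   <dbl>    <dbl>    <dbl>
#> 1 LDLR      3  0.703    2.02   1.80    2.27  2.61e-32 1.04e-31
#> 2 LPL       2  0.664    1.94   1.62    2.32  4.45e-13 5.94e-13
#> 3 CETP      3  0.197    1.22   1.03    1.44  2.08e- 2 2.08e- 2
#> 4 HMGCR     3 -0.808    0.446  0.383   0.519 3.13e-25 6.26e-25
```

The generating truth put log-odds effects of 0.66, 0.62, 0.25 and −0.97 on
LDLR, LPL, CETP and HMGCR: all four are recovered with the right sign and
magnitude, all four survive FDR (`q_fdr < 0.05`), and the odds ratios read
directly as disease risk per 1-SD lipid shift through each target.
Downstream tables follow automatically for the FDR-significant targets:

```r
bundle$mediation |>
  select(target, total_effect, indirect_effect, direct_effect, proportion_pct)
#> # A tibble: 4 × 5
#>   target total_effect indirect_effect direct_effect proportion_pct
#>   <chr>         <dbl>           <dbl>         <dbl>          <dbl>
#> 1 CETP          0.197          0.0123         0.185           6.23
#> 2 HMGCR        -0.808          0.0466        -0.855          -5.77
#> 3 LDLR          0.703          0.0350         0.668           4.97
#> 4 LPL           0.664         -0.0223         0.686          -3.37
```

The LDLR row recovers its generating mediation structure
(β1 = −0.091 through vitamin D, ~5% mediated); the negative proportions on
HMGCR (true β1 = 0) and LPL illustrate why out-of-range and
sign-discordant decompositions are flagged rather than suppressed —
ratio-of-estimates arithmetic is noisy. `bundle$coloc`, `bundle$eqtl_mr`,
`bundle$trait_mvmr` and `bundle$sensitivity` complete the six result
tables; `write_results_bundle(bundle, dir)` writes them as deterministic
TSVs.

Individual pieces compose just as well: `read_summary_stats()` →
`select_drug_target_instruments()` → `harmonize()` → `mr_all_methods()` /
`mr_presso()` / `coloc_abf()` / `two_step_mediation()`, with
`plot_mr_scatter()`, `plot_mr_forest()`, `plot_leave_one_out()` and
`autoplot()` for figures. See the vignette in `vignettes/` for the methods
and their assumptions.

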