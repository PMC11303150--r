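---
title: "Drug-target Mendelian randomization with colocalization and mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with colocalization and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
library(dplyr)
```

## The problem this package addresses

Observational associations between circulating lipids, lipid-lowering drugs
and male infertility are vulnerable to confounding and reverse causation.
Two-sample Mendelian randomization (MR) sidesteps both by using germline
genetic variants as instrumental variables: a variant that raises LDL-C from
birth is a tiny, randomized, lifelong "trial" of LDL-C exposure.
Drug-target MR sharpens the question from "does the lipid matter?" to "does
pharmacological modulation of this protein matter?" by restricting
instruments to variants in or near the drug's target gene (HMGCR for
statins, PCSK9, CETP, LDLR, LPL, and so on), so the instrumented exposure
proxies the drug's mechanism rather than the lipid at large.

`targetmr` implements that full workflow for summary-level GWAS data:
instrument selection, allele harmonization, the causal estimator stack with
its sensitivity analyses, Bayesian colocalization, two-step mediation
through an intermediate trait (serum vitamin D in the motivating analysis),
and false-discovery-rate control across targets — plus a synthetic
summary-statistics generator with known ground truth, so every stage can be
validated end to end without access to the original GWAS consortia data.

## Instrument selection

Trait-level instruments pass four filters, in order:

1. genome-wide significance, `p < 5e-8` (strict inequality);
2. minor-allele frequency `min(eaf, 1 - eaf) > 0.01`;
3. greedy LD clumping: repeatedly keep the remaining variant with the
   smallest p-value and discard variants within 10,000 kb on the same
   chromosome with `r² >= 0.001` against it;
4. instrument strength: per-variant variance explained
   `R² = (2·EAF(1−EAF)β²) / (2·EAF(1−EAF)β² + 2·EAF(1−EAF)·N·SE²)` and
   `F = R²(N−2)/(1−R²)`, keeping instruments with `F > 10` (strict).

Drug-target instruments use the same machinery restricted to a window of
250 kb on each side of the gene (a *closed* interval in base pairs — the
permissive reading, since the boundary convention is rarely stated), with
clumping relaxed to `r² < 0.2` within 250 kb because a single cis region
cannot supply many independent variants. cis-eQTL instruments for expression
exposures use `p < 5e-8` and `r² < 0.1`. Windows are measured from the gene
boundaries, not the transcription start site; for target pairs that share a
locus (ABCG5/ABCG8) the union of the two gene windows is the intended
configuration. All of these are arguments, not constants.

Clumping ties on p-value break by position, then lexicographic variant id,
so the kept set never depends on input row order. Variants absent from the
supplied LD matrix are treated as uncorrelated, with a warning — synthetic
runs always supply complete matrices, but user-supplied reference panels
are often incomplete, and silently dropping those variants would be worse.

## Harmonization

`harmonize()` intersects exposure and outcome on variant id and aligns the
outcome to the exposure's effect allele, negating the outcome beta and
complementing its allele frequency when the coding is swapped. Palindromic
variants (A/T, C/G) cannot be oriented from alleles alone; the default
policy drops them outright. An `infer` policy is available that orients
them by comparing allele frequencies across the two traits and drops only
those with minor-allele frequency above 0.42 (too close to 0.5 to call);
it is an extension, not the default, because the motivating workflow
removes palindromes unconditionally. Alleles are compared on the given
strand only — no reverse-complement matching is attempted beyond the
palindrome classification itself. Duplicate variant ids resolve
first-occurrence-wins and every drop is counted: the counts
(`flipped`, `dropped_palindromic`, `dropped_unmatched`) always sum with the
retained count to the size of the id intersection.

## The estimator stack

Per-variant Wald ratios `βY/βX` carry first-order delta-method standard
errors `seY/|βX|`; the exposure-side uncertainty is ignored, the standard
choice when instruments have passed a genome-wide significance filter (the
no-measurement-error assumption).

**IVW (random effects).** The inverse-variance-weighted mean of the ratios.
The fixed-effect standard error `1/sqrt(Σw)` is inflated multiplicatively by
`max(1, sqrt(Q/(k−1)))`, Cochran's Q being the weighted heterogeneity
statistic. The multiplicative (rather than additive) random-effects flavor
matches common two-sample MR practice; under-dispersion never shrinks the
standard error below its fixed-effect value. The estimate is algebraically
identical to the slope of a no-intercept weighted regression of outcome on
exposure effects with weights `1/seY²` — a property the test suite checks
to 1e-10.

**MR-Egger.** The same weighted regression with a free intercept, after
orienting every instrument to a positive exposure effect. The slope is the
causal estimate under the InSIDE assumption; the intercept estimates average
directional pleiotropy and its test (t reference, k−2 df, multiplicative
overdispersion floored at 1) is the Egger intercept test.

**Weighted median.** Order the ratios; the estimate interpolates linearly
at cumulative normalized weight 0.5 (midpoint convention). Consistent when
valid instruments carry at least half the weight. The standard error comes
from a parametric bootstrap redrawing each ratio from
`Normal(ratio, se_ratio)` — always explicitly seeded.

**Mode estimators.** Gaussian-kernel density over the ratios, weights
uniform (simple) or inverse-variance (weighted), with a Silverman-type
bandwidth `φ · 0.9 · min(sd, mad) · k^(−1/5)` (`φ` = `bandwidth_factor`,
default 1 — modal tuning is rarely reported, so it is exposed rather than
hidden) and the argmax taken on a dense fixed grid spanning the ratio range
padded by three bandwidths. All ratios equal is not an error: the common
ratio is returned.

**Multivariable IVW** regresses outcome effects on several exposures'
effects jointly (no intercept, weights `1/seY²`), one conditional estimate
per exposure. An exposure with all-zero effects is excluded with a warning
and reported as `NA` — the nuisance-free limit — while genuine collinearity
among non-trivial exposures is an error naming the offending columns.

Estimates against a binary outcome convert to odds ratios with 95% Wald
intervals; a per-target `flip` re-signs the estimate first so that the
exposure unit is the drug's action (a 1-SD *decrease* in LDL-C for an
LDL-lowering target) rather than the raw lipid increase. The flip is
declared in configuration per target because it is a pharmacological fact,
not something inferable from the data.

## Sensitivity stack

`mr_leave_one_out()` refits IVW omitting each variant; a variant is flagged
when its omission flips significance at 0.05 or moves the estimate by more
than the full-set fixed-effect standard error. The fixed-effect scale is
used deliberately: a gross outlier inflates the random-effects standard
error so much that its own removal would otherwise look unremarkable.

`mr_presso()` implements the simulation-based pleiotropy
residual-sum-of-squares test. The observed statistic sums each variant's
weighted squared residual from the IVW fit computed *without* it; the null
distribution redraws both effect sizes from normal distributions centred on
the leave-one-out predictions at the reported standard errors. P-values use
the `(1 + count)/(n_sim + 1)` estimator, so they are never exactly zero;
per-variant outlier p-values carry a Bonferroni-style correction before the
0.05 cutoff, and outliers are only declared when the global test itself is
significant. When outliers are removed, a distortion test compares the
before/after shift against shifts from removing random subsets of the same
size. Variants are processed in canonical id order so the entire result is
invariant to input row order and bit-reproducible under a fixed seed. The
default `n_sim = 10000` stabilizes tail p-values; the tests use 1000, the
minimum the function accepts.

## Bayesian colocalization

An MR signal at a drug-target locus can be an artifact of LD: the lipid
association and the disease association may be driven by *different* causal
variants that happen to be correlated. Colocalization addresses this by
enumerating, under a single-causal-variant assumption, the five hypotheses
H0 (no association), H1/H2 (one trait only), H3 (both, different variants),
H4 (both, one shared variant). Each variant's association evidence enters
as a Wakefield approximate Bayes factor `sqrt(1−r)·exp(z²r/2)` with
`r = W/(se² + W)`; the prior effect standard deviation `W^0.5` defaults to
0.15 for quantitative traits and 0.2 (log-odds) for case-control traits,
and per-configuration priors default to `p1 = p2 = 1e-4`, `p12 = 1e-5` —
the conventional values for this methodology, stated here because they are
assumptions, not estimates. The headline summary is the conditional
probability `H4/(H3+H4)`: the probability of a shared variant given that
the outcome is associated at all. It is reported as undefined (with a flag,
not an error) when H3 + H4 underflows to zero.

All hypothesis accumulation happens in log space with log-sum-exp; H3's
off-diagonal pair sum is computed as the full product-sum minus the
diagonal via a stable log-difference. This matters: realistic regions
produce posteriors far below 1e-250, which are zero in linear space. The
exhaustive configuration-enumeration oracle in the test suite agrees with
the implementation to 1e-8 on regions of up to six variants, and posterior
vectors sum to one to 1e-8.

## Two-step mediation

For targets with an FDR-significant effect, the package decomposes the
total effect on the outcome through a mediator: β1 (target → mediator, MR
with the target's cis instruments), β2 (mediator → outcome, univariable IVW
with the mediator's own genome-wide instruments), indirect effect `β1·β2`,
direct effect `total − indirect`, proportion mediated `indirect/total`.
β2 is estimated *unconditionally* on the exposure — plain two-step MR — with
a multivariable variant available but not default. The indirect-effect
standard error uses the product delta method
`sqrt(β1²·se2² + β2²·se1²)`, ignoring the β1–β2 covariance because the two
steps come from non-overlapping samples. Closure (`direct + indirect =
total`, `proportion·total = indirect`) holds by construction to machine
precision; a proportion outside [0, 1] or an indirect effect opposing the
total is flagged, never silently corrected, because both occur legitimately
with noisy ratio-of-estimates arithmetic.

## FDR and orchestration

`run_study()` executes the whole design: trait-level MR for each lipid
exposure (all five estimators plus sensitivity), multivariable MR adjusting
for configured covariates, drug-target MR across the configured targets,
Benjamini–Hochberg correction (via `stats::p.adjust`) of the per-target
primary (IVW or Wald) p-values — the FDR family is the set of drug-target
tests, while trait-level MR reports raw p-values — cis-eQTL MR where
expression data are supplied, colocalization and mediation for the
FDR-significant targets. A stage with no usable instruments produces a
flagged row, never an abort, and an un-instrumentable target simply does
not join the FDR family. Every run decision (drops, flips, flags,
instrument counts) is logged, and output tables contain no timestamps, so
re-running a configuration reproduces every file byte for byte.

## The synthetic generator: what it does and does not show

`simulate_two_sample()` generates summary statistics directly — no
individual-level genotypes — matching the two-sample design in which the
pipeline only ever sees summary data. Effect-allele frequencies are uniform
on 0.05–0.95; standard errors follow `1/sqrt(2·eaf(1−eaf)·n)` for a
standardized trait; sample sizes default to the scale of the motivating
consortia (≈187,000 exposure, ≈120,000 outcome). Latent exposure effects
are `Normal(0, 0.02)` rejection-sampled to genome-wide significance — the
rejection is on the *latent* effect, so there is no winner's curse — and
reported without sampling noise, which keeps instrument strength exact and
the first-order ratio standard error correctly calibrated. Outcome effects
add the causal contribution, an optional horizontal-pleiotropy effect for a
configurable fraction of instruments, and sampling noise at the outcome
standard error.

`simulate_mediation_chain()` extends this with a mediator. The generating
equations alone (mediator effects `β1·γ`, outcome effects
`(direct + β1·β2)·γ`) would leave β2 unidentifiable by two-step MR — the
exposure instruments see only the *total* path ratio — so the generator
also emits an equal number of mediator-specific instruments with no
exposure effect. That is exactly the structure the real workflow relies on:
the mediator GWAS contributes its own instruments.

`simulate_coloc_region()` draws causal variants per hypothesis, smears the
causal z-score over neighbours with AR(1) correlation `ld_rho`, adds
standard normal noise, and back-computes betas at `se = 1/sqrt(n)`. AR(1)
is the only LD structure offered; block structures are out of scope. The
documented confounding-by-LD behavior — H3 regions with highly correlated
adjacent causal variants inflating the H4 posterior — is reproducible with
`ld_rho` near 1 and is precisely the failure mode colocalization guards
the MR results against.

What passing tests on these generators do **not** show: robustness to
realistic allele-frequency spectra, imputation noise, sample overlap
between exposure and outcome GWAS, winner's curse from in-sample instrument
selection, or multi-causal-variant loci. Those caveats transfer to any
real-data application.

## Numerical choices and problem sizes

- Log-space accumulation with log-sum-exp wherever posteriors can
  underflow; `(1 + count)/(n_sim + 1)` for all simulation p-values;
  p-values produced by the generator are floored at 1e-300 to respect the
  `(0, 1]` record invariant.
- Overdispersion scales (IVW, Egger, multivariable IVW) are floored at 1.
- Clumping tie-break: p-value, then position, then variant id.
- Degenerate inputs produce classed conditions
  (`targetmr_degenerate_error`, `targetmr_insufficient_error`,
  `targetmr_empty_error`, `targetmr_collinear_error`) or flags, as the
  situation warrants: a zero exposure effect in a Wald ratio is an error,
  a zero-bandwidth mode returns the common ratio, an undefined conditional
  colocalization probability is `NA` with a flag.
- The validation suite calibrates IVW coverage and the Egger intercept
  test on 1000 replicates at 30 instruments, the outlier test on 200
  replicates at 10 instruments with 1000 simulations each, and
  colocalization recovery on 200 replicates per hypothesis at 50 variants
  — sizes chosen to give stable empirical rates while keeping a full
  validation run in the low minutes on a single core.

## Worked example

```{r example, eval = FALSE}
library(targetmr)

cfg <- simulate_study(seed = 1)
bundle <- run_study(cfg)

bundle$target_mr |>
  dplyr::filter(method == "ivw_re") |>
  dplyr::select(unit, beta, or_point, pvalue, q_fdr)
bundle$coloc
bundle$mediation

plot_mr_forest(bundle$target_mr |> dplyr::filter(method == "ivw_re"),
               label = "unit")
```

## Known limitations

- Single-causal-variant colocalization only; no SuSiE-style multi-signal
  decomposition, no conditional analysis on LD, no fine-mapping.
- No proxy-variant lookup, genome-build liftover, or VCF ingestion; inputs
  are delimited text with a column map.
- The ratio standard error ignores exposure-side uncertainty (second-order
  options exist in the literature but are not the default here).
- The outlier test promises distributional agreement with the established
  simulation-based procedure, not its exact random-number stream.
- Estimates for binary outcomes inherit the non-collapsibility of odds
  ratios; effects are reported on the scale the outcome GWAS used.
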