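---
title: "Methods: two-sample MR screening of serum metabolites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening of serum metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(metabomr)
```

## The model and its assumptions

metabomr implements a two-sample Mendelian randomization (MR) screen:
genetic variants are used as instrumental variables for a continuous
exposure (a serum metabolite level, measured in one GWAS cohort) to
estimate its causal effect on a binary outcome (e.g. sepsis, measured in a
second, non-overlapping cohort), from summary statistics alone. The three
instrumental-variable assumptions are the usual ones: each instrument is
(1) associated with the exposure, (2) independent of confounders of the
exposure–outcome relation, and (3) affects the outcome only through the
exposure. Assumption (1) is enforced empirically (p-value and F-statistic
filters); (2) is taken on the genetics; (3) is probed, not guaranteed, by
the pleiotropy diagnostics.

Per instrument $j$, the exposure association $\hat\gamma_j$ (SE
$\sigma_{Xj}$) and the allele-aligned outcome association $\hat\Gamma_j$
(SE $\sigma_{Yj}$, log-odds scale) give the Wald ratio
$\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ with first-order SE
$\sigma_{Yj}/|\hat\gamma_j|$. All multi-variant estimators treat
$\hat\gamma_j$ as fixed (the NOME approximation); the consequences of that
approximation at finite instrument strength are discussed under
*Limitations*.

## Pipeline stages and their parameters

**Instrument selection** (`build_instrument_set()`): keep variants with
exposure $p <$ `p_threshold` (default 1e-5, the usual metabolite-GWAS
discovery threshold — strict inequality); greedily clump so that no
retained pair on one chromosome within `window_kb` (500) has LD
$r^2 \ge$ `r2_max` (0.01), always keeping the lowest-p variant (ties broken
by chromosome then position, so selection is deterministic); compute
per-variant variance explained
$$R^2 = \frac{2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2}
{2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2 +
 2\,\mathrm{EAF}(1-\mathrm{EAF})\,N\,\mathrm{se}(\beta)^2}$$
and $F = \frac{N-K-1}{K}\cdot\frac{R^2}{1-R^2}$ with $K = 1$, and drop
variants with $F <$ `f_min` (10, strict: $F = 10$ is kept). $F$ is computed
per variant, with that variant's $R^2$, because the weak-instrument
exclusion is applied per instrument. LD is supplied as a pluggable pairwise
$r^2$ table; a pair the clumping rule needs but cannot look up is an error,
never a silent zero, so an incomplete panel cannot fake independence.

**Harmonization** (`harmonize()`): outcome effects are re-expressed per copy
of the exposure's effect allele, complementing strand-flipped
representations and negating swapped ones. Palindromic variants (A/T, C/G)
follow an explicit policy; the default `infer_by_eaf` aligns by
allele-frequency agreement and drops the variant when either study's EAF is
within 0.08 of 0.5 (no strand information in frequency there). The source
studies do not state how palindromes were handled, so the policy is a
configurable design choice rather than a guess; the exposure EAF stays
authoritative for $R^2$/F, the outcome EAF is used only for palindrome
inference. Every exclusion is logged with a reason
(`missing_in_outcome`, `palindromic_ambiguous`, `allele_mismatch`), and
retained + dropped always partitions the instrument set. No proxy variants
are substituted.

**Estimators** (`mr_ivw()`, `mr_egger()`, `mr_weighted_median()`,
`mr_presso()`): the forms are the standard ones (inverse-variance weighting
through the origin; Egger regression with a free intercept after orienting
$\hat\gamma_j \ge 0$; the interpolated weighted median with midpoint
cumulative positions $p_j = \sum_{i\le j} w_i - w_j/2$; PRESSO's simulated
leave-one-out residual-sum-of-squares test). Conventions fixed here:

* *Random-effects IVW* (the screen's primary estimator) uses multiplicative
  overdispersion floored at 1: the fixed-effect SE is multiplied by
  $\max(1, \sqrt{Q/(J-1)})$, so heterogeneity can widen but never shrink the
  interval. Egger uses the same floor with $J-2$ df and t inference (J is
  small); all other p-values are two-sided normal.
* *Weighted-median SE* comes from a parametric bootstrap (default 1000
  draws) resampling $\hat\gamma_j$ and $\hat\Gamma_j$ from normals with
  their reported SEs; the seed is mandatory, so results are reproducible.
* *MR-PRESSO* (default 1000 simulations, seed mandatory): the observed
  statistic is $\mathrm{RSS} = \sum_j w_j(\hat\Gamma_j -
  \hat\beta_{(-j)}\hat\gamma_j)^2$ with leave-one-out IVW slopes
  $\hat\beta_{(-j)}$ and $w_j = 1/\sigma_{Yj}^2$. Null datasets draw
  $\Gamma^*_j \sim N(\hat\beta_{(-j)}\hat\gamma_j, \sigma_{Yj})$ and the
  leave-one-out slopes are *refit on each simulated dataset* before the RSS
  is recomputed. The refit choice matches the published algorithm; we
  verified the alternative (reusing the observed slopes) yields a
  non-uniform null p distribution. Global and per-variant p-values use the
  $+1/(n_{sim}+1)$ continuity correction; outlier p-values are
  Bonferroni-adjusted over $J$ and flagged at 0.05; the corrected estimate
  is the random-effects IVW without flagged variants, and a distortion test
  compares the raw-vs-corrected change against random same-size removals.

**Sensitivity and screening** (`sensitivity_report()`,
`screen_candidates()`): Cochran's Q uses the Wald ratios with first-order
weights, centered on the fixed-effect IVW estimate, $\chi^2_{J-1}$. A
candidate passes the screen when (1) IVW $p < 0.05$; (2) no pleiotropy
flag — Egger-intercept $p \ge 0.05$ *and* PRESSO global $p \ge 0.05$; and
(3) the IVW, Egger, weighted-median and PRESSO estimates agree in sign
(PRESSO's outlier-corrected estimate is used whenever outliers were
removed; a zero estimate counts as inconsistent). Heterogeneity
(Q $p < 0.05$) is reported as a flag but is *not* exclusionary by default:
screens of this design have retained mildly heterogeneous candidates, so
exclusion is opt-in via `strict_heterogeneity = TRUE`. The Bonferroni tier
uses threshold $\alpha/m$ (default 0.05/486 ≈ 1.03e-4); the alternative
reading of a "p·(1/m)" correction — multiplying the p-value — would declare
everything significant and is rejected. Reverse MR (`reverse_mr()`) re-runs
selection, harmonization and all four estimators with the outcome as
exposure; a forward finding is supported when the reverse IVW and the three
complementary methods are concordantly non-significant at 0.05 (the
concordance rule is a documented choice; "non-significant" is not otherwise
defined for the reverse direction).

**Pathway over-representation** (`over_representation()`): one-sided
hypergeometric upper tail $P(X \ge k)$ for $k$ hits of an $n$-compound query
in an $m$-compound pathway over an $N$-compound background; expected overlap
$nm/N$. The pathway-topology "impact" score is a relative-betweenness
centrality computed by external tools on KEGG graphs; it is consumed as an
optional input column (significance requires $p < 0.05$ and impact $> 0.1$
when supplied) and never computed here. When no impact is supplied the
significance call is by $p$ alone. The background metabolome defaults to
the library's declared background; because the exact background of the
original web-tool analysis is unstated, validation parameterizes
(background, query) to match the printed expected counts rather than
guessing.

## The synthetic-data generator

`simulate_pair()` emulates the statistical shape of the real screen without
any downloads: a continuous exposure GWAS of $N_X = 7824$, a binary outcome
GWAS of $N_Y = 486{,}484$ with case fraction $11{,}643/486{,}484 \approx
0.024$, and 7–37 instruments per exposure (drawn uniformly unless fixed).
Per variant: MAF $\sim U(0.1, 0.45)$; the true effect magnitude is drawn
from $|N(0, \texttt{gamma\_sd})|$ and resampled until the *expected*
per-variant F, $N_X R^2/(1-R^2)$ with $R^2 = 2f(1-f)\gamma^2$, exceeds
`f_expected_min`; observed effects add $N(0, \sigma)$ noise with the
standard standardized-trait SEs $\sigma_{Xj} = 1/\sqrt{2f_j(1-f_j)N_X}$ and
$\sigma_{Yj} = 1/\sqrt{2f_j(1-f_j)N_Y u(1-u)}$ (the normal approximation to
a logistic GWAS on the log-odds scale — no individual-level genotypes are
simulated). True outcome effects are $\Gamma_j = \beta\gamma_j + \alpha_j$
with $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha)$ the horizontal-pleiotropy
direct effect, optionally inflated by `outlier_scale` outcome-SEs (random
sign) for planted PRESSO outliers. Variants are laid out on two synthetic
chromosomes 2 Mb apart (mutually independent under the 500 kb window), with
optional LD decoys 10 kb from a parent instrument to exercise clumping.
All randomness flows from one integer seed (per-exposure seeds in
`simulate_batch()` are base + index), so every table is bit-reproducible.

Default choices and why:

* `gamma_sd = 0.15`: gives per-variant $R^2$ of roughly 0.5–2% and mean
  per-variant F near 100 — the regime of metabolite GWAS instruments
  selected at $p <$ 1e-5, where even the weakest retained instrument has F
  in the tens. Chosen once from a design-time calibration and not tuned.
* `f_expected_min = 20`: with a floor of 10 on the *expected* F, realized
  F falls below 10 for a few percent of variants (noise around the floor),
  contradicting both the intended regime (realized minimum F well above 10)
  and the downstream F-filter's expectations. A floor of 20 keeps ≥ 99% of
  realized F above 10.
* Effect alleles are oriented to the exposure-increasing allele
  ($\gamma_j > 0$). With randomly signed effects, a directional pleiotropy
  mean $\mu_\alpha \ne 0$ would be unidentifiable: MR-Egger's
  $\hat\gamma \ge 0$ orientation would flip the sign of $\alpha_j$ for half
  the variants and average the direction away. Orienting the generator
  makes `pleiotropy_mean` mean what it says.

What the generator does *not* emulate: winner's curse (effects are not
selected on observed significance), sample overlap, population
stratification, LD beyond the planted decoy pairs, allele-frequency
discrepancies between studies, strand ambiguity (only non-palindromic
allele pairs are generated), and real LD-panel uncertainty. Passing tests
on synthetic data therefore validate the *algorithms* under the stated
sampling model, not robustness to those real-data complications.

## Numerical choices

* p-values are floored at the smallest positive double so they stay in
  (0, 1]; z-based p-values use the normal, Egger uses t with $J-2$ df.
* Degenerate inputs raise typed errors rather than returning NA: Wald ratio
  with $\gamma = 0$; IVW with $J < 2$ (random) / $< 1$ (fixed); Egger and
  weighted median with $J < 3$; PRESSO with $J < 4$; variance explained at
  EAF ∈ {0, 1}; F with $N \le K+1$.
* Clumping tie-break: equal p-values resolve by (chromosome, position).
* The weighted-median interpolation clamps to the extreme ratios when 0.5
  falls outside the midpoint positions.
* If PRESSO flags all but fewer than two variants, the corrected estimate
  is reported as undefined (with a warning), never silently substituted.
* Simulation problem sizes used by the validation suite: 500 replicates for
  null-calibration, parameter-recovery and outlier-flagging studies
  (J = 20–30, PRESSO at 1000 simulations), 100 replicates for the
  module-level pleiotropy scenarios, and a 50-exposure screen with three
  causal exposures — sizes chosen so the whole suite runs in minutes while
  keeping Monte-Carlo error well below the tested tolerances.

## Known limitations

Two finite-instrument-strength effects are worth understanding because the
validation suite measures both:

* **Weak-instrument dilution of IVW.** With noisy $\hat\gamma_j$, the IVW
  slope is attenuated by a factor $\approx 1/(1 + 1/\bar F)$; at
  $\bar F \approx 100$ that is a ~1% shrinkage (≈ 0.003 at $\beta = 0.3$).
  It is a property of the estimator, not a bug, and is below any
  scientifically relevant threshold here, but a simulation with several
  hundred replicates resolves it: the mean IVW estimate sits measurably,
  slightly, below the true effect.
* **Exposure-noise heterogeneity at large effects.** The first-order weights
  ignore the $\beta^2\sigma_{Xj}^2$ term in the Wald-ratio variance. Under
  this generator $\sigma_{Yj}^2/\sigma_{Xj}^2 = N_X/(N_Y u(1-u)) \approx
  0.69$, so Q and the PRESSO global statistic are inflated by
  $\approx 1 + 1.45\beta^2$ — independent of instrument strength. At
  $\beta = 0.5$ that is ~36%, and the pleiotropy gates then reject a truly
  non-pleiotropic causal exposure roughly a fifth of the time. Screens
  that gate candidates on these tests therefore lose power against their
  strongest true positives; the heterogeneity flag-only default mitigates
  but does not remove this (the PRESSO global gate remains).

Other limitations: no mode-based or multivariable estimators, no Steiger
filtering, no FDR alternative to Bonferroni, no LD computation from
genotypes or proxy-variant lookup, and no KEGG client or fuzzy
name-to-compound mapping — compound identifiers must be supplied through an
exact lookup table.
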