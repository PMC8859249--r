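---
title: "Two-sample Mendelian randomization with mrtwosample: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrtwosample}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtwosample)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect
$\theta$ of an exposure on an outcome from two independent sets of GWAS
summary statistics.  For each of $J$ independent SNPs we observe the
SNP-exposure association $\hat\gamma_j$ with standard error
$\sigma_{xj}$ and the SNP-outcome association $\hat\Gamma_j$ with
standard error $\sigma_{yj}$.  Under the three instrumental-variable
assumptions (relevance, independence from confounders, and exclusion
restriction) the generative model is

$$\hat\gamma_j \sim N(\gamma_j, \sigma_{xj}^2), \qquad
  \hat\Gamma_j \sim N(\theta\,\gamma_j + \alpha_j, \sigma_{yj}^2),$$

where $\alpha_j$ is the direct (pleiotropic) effect of SNP $j$ on the
outcome, zero for a valid instrument.  Each SNP supplies a Wald ratio
$\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ with first-order standard
error $\sigma_{yj}/|\hat\gamma_j|$ and weight
$w_j = \hat\gamma_j^2/\sigma_{yj}^2$.  For a binary outcome the betas
are log-odds ratios and estimates are reported as OR per SD of
exposure.

## Instrument construction

`select_instruments()` reproduces the conventional four-stage pipeline:

1. genome-wide significance, $p < 5\times10^{-8}$ (strict inequality —
   a SNP at exactly the threshold fails);
2. minor-allele frequency QC, MAF $> 0.01$;
3. palindromic-SNP handling: A/T and C/G variants carry no strand
   information in their allele codes; they are retained only when MAF
   $< 0.42$ (strict), since near 0.5 the minor allele cannot be
   identified reliably.  Palindromes with missing allele frequency are
   treated as not inferrable and removed — the conservative reading;
4. greedy LD clumping at $r^2 < 0.001$ within a 10,000 kb window,
   visiting SNPs in ascending p-value order (ties broken
   lexicographically by rsID for determinism).  Pairs absent from the
   user-supplied LD table count as $r^2 = 0$ with a warning tally;
   cross-chromosome or out-of-window pairs are never pruned;
5. optionally, exclusion of SNPs carrying a genome-wide-significant
   annotation to a confounder trait (an offline stand-in for manual
   PhenoScanner-style lookups).

Every stage records (n_in, n_removed, removed ids), and the audits
reconcile by construction.  Duplicated rsIDs on ingest keep the row
with the smallest p-value; indel alleles are dropped and counted —
source GWAS rarely document how they resolve these, so the package
makes its policy explicit and logs it.

## Harmonization

`harmonize()` aligns the outcome onto the exposure's effect-allele
frame by rsID.  Swapped allele orientation flips the sign of the
outcome beta and complements its allele frequency.  For palindromic
SNPs the strand is inferred from allele frequencies: the SNP is kept
only when the MAF is below the cutoff in the exposure *and* (by
default) the outcome, and the effect allele lies on the same side of
0.5 in both datasets; otherwise it is dropped.  Applying the frequency
cutoff to both datasets (`palindrome_mode = "both"`) is the
conservative standard; `"exposure-only"` reproduces pipelines that
apply the rule to the instrument dataset alone.  Matching is by rsID
only: chr:pos fallback invites build mismatches and both major source
dialects carry rsIDs.

## The estimator battery

* **IVW, fixed effect** — $\hat\theta = \sum w_j\hat\beta_j / \sum
  w_j$, $SE = (\sum w_j)^{-1/2}$; equivalent to weighted least squares
  of $\hat\Gamma$ on $\hat\gamma$ through the origin with the residual
  variance forced to 1.
* **IVW, multiplicative random effect** — same point estimate; the SE
  is inflated by $\max(1, \sqrt{Q/(J-1)})$ with $Q$ Cochran's
  heterogeneity statistic at the estimate.  The floor at 1 means
  under-dispersion never shrinks the SE below the fixed-effect value.
* **Penalized IVW** — each weight is multiplied by $\min(1, 20 p_j)$,
  $p_j$ the upper-tail $\chi^2_1$ p-value of that SNP's Q
  contribution, and the estimate re-solved iteratively (tolerance
  1e-10, max 100 iterations).  The constant 20 is the canonical
  choice.
* **Robust IVW** — bisquare M-regression through the origin (tuning
  constant 4.685, prior weights $1/\sigma_{yj}^2$), SEs from the
  robust fit with the same multiplicative scaling.  Penalized robust
  combines both.
* **Maximum likelihood** — profiling the per-SNP true effects out of
  the joint Gaussian likelihood leaves the one-dimensional objective
  $f(\theta)=\sum_j (\hat\Gamma_j-\theta\hat\gamma_j)^2 /
  (\sigma_{yj}^2+\theta^2\sigma_{xj}^2)$, minimized by BFGS from the
  fixed-effect IVW start; the SE comes from the curvature of $f$ at
  the optimum ($f$ is $-2\log L$ up to a constant).  As
  $\sigma_{xj}\to 0$ this reduces analytically to fixed-effect IVW,
  which the tests exploit as an oracle.
* **Simple and weighted median** — consistent when (weighted) half the
  instruments are valid.  The weighted median interpolates the sorted
  ratios against standardized cumulative weights at 0.5.  SEs are
  parametric-bootstrap (default 10,000 replicates, seeded): each
  replicate redraws both betas at their claimed SEs and recomputes the
  estimator.  Bootstrap rather than analytic SEs follow the
  methodology the estimator originates from.
* **MR-Egger** — after orienting every SNP so $\hat\gamma_j > 0$,
  weighted regression of $\hat\Gamma$ on $\hat\gamma$ *with* an
  intercept.  Under InSIDE (pleiotropy independent of instrument
  strength) the slope is a pleiotropy-robust estimate and a non-zero
  intercept indicates directional pleiotropy.  SEs carry
  $\max(1, \hat\sigma)$ scaling with $\hat\sigma$ the weighted
  residual SD.

P-values are two-sided normal throughout; with $J$ over 100 the
difference from t-based inference is negligible, and the choice keeps
every method on the same footing.  Whether the penalized/robust
variants should also carry multiplicative SE scaling is not pinned
down by common usage; the package defaults to scaled (`model =
"random"`) with `model = "fixed"` available.

## Diagnostics

`pleiotropy_report()` bundles Cochran's Q, the Egger intercept test,
MR-PRESSO, the leave-one-out series, and funnel data.

MR-PRESSO follows the residual-sum-and-outlier recipe: observed RSS
$\sum_j w_j(\hat\beta_j - \hat\theta_{(-j)})^2$ with leave-one-out IVW
estimates, compared against a parametric null rebuilt by simulation
(default `n_sim = 1000`); per-SNP outlier tests Bonferroni-adjusted
across $J$; an outlier-corrected IVW; and a distortion test that
compares the raw-vs-corrected shift against removals of random subsets
of the same size.  Two numerical facts matter in practice:

* empirical p-values carry a $+1/(n_{sim}+1)$ continuity correction,
  so they are never exactly zero, and
* the Bonferroni-adjusted outlier p-value cannot fall below
  $J/(n_{sim}+1)$ — with `n_sim` too small relative to $J$ no SNP can
  ever be flagged.  Keep `n_sim` $\gtrsim 20\,J$ at the 0.05 level.

Note the spec-level identity used throughout: outcome-scale residuals
$(\hat\Gamma_j - \theta\hat\gamma_j)^2/\sigma_{yj}^2$ equal
ratio-scale contributions $w_j(\hat\beta_j-\theta)^2$, so the global
RSS and Cochran's Q are two views of the same quantity.

The funnel "symmetry" check (mean ratio of the higher- vs
lower-precision half) is exploratory only and is labeled as such; no
formal asymmetry test is implied.

## Multivariable MR

`assemble_mvmr()` harmonizes the outcome and each covariate onto the
exposure's allele frame and keeps the row-complete SNP intersection;
the instrument is *not* re-selected for covariate significance — it
stays the primary-exposure instrument.  `mvmr_ivw()` regresses the
outcome betas on all exposure-beta columns jointly (no intercept,
weights $1/\sigma_{yj}^2$), giving the direct effect of the primary
exposure adjusted one covariate at a time (general $K$ is accepted).
An all-zero covariate column is dropped from the fit (coefficient
reported `NA`) so the primary estimate reduces *exactly* to the
univariable IVW — the natural continuity requirement.  Attenuation of
the primary coefficient is the only mediation-flavoured statement the
package makes; no formal mediation test is implemented.

## Power

For a binary outcome, `mr_power_binary()` uses the standard
non-centrality approximation $\lambda = n\,r^2\,k(1-k)\log(OR)^2$ and
$\mathrm{power} = \Phi(\sqrt\lambda - z_{1-\alpha/2}) +
\Phi(-\sqrt\lambda - z_{1-\alpha/2})$, where $r^2$ is the variance of
the exposure explained by the instrument and $k$ the case fraction.
At $OR = 1$ the power equals $\alpha$ exactly and the formula is
symmetric in $OR \leftrightarrow 1/OR$.  The closed form is validated
against Monte-Carlo simulation of the score statistic rather than
against any published power figure, because published figures rarely
print the assumed $r^2$.

## The synthetic-data generator

`simulate_pair()` emulates the two-sample setting the package is built
for: a strongly instrumented continuous exposure (a cognitive trait
measured in SD units, GWAS of order $10^5$–$10^6$ samples) against a
binary cardiovascular outcome on the log-OR scale.  Defaults: $J =
121$ instruments, $\theta = \log(0.76) \approx -0.274$,
$\gamma_j \sim N(0, 0.025^2)$ truncated at $|\gamma_j| \ge
0.1\,\gamma_{sd}$, outcome SEs 0.012–0.018 sized so the fixed-IVW SE
lands near 0.054.  Pleiotropy regimes: `balanced` ($\alpha \sim
N(0,\sigma_\alpha^2)$), `directional` (non-zero mean), and
`inside_violating` ($\alpha = c\,\gamma + $ noise, correlating direct
effects with instrument strength).  Gross outliers shift the outcome
beta by a configurable multiple of its SE.  Allele codes include a
configurable fraction of palindromic pairs; both tables share strand
and orientation, so harmonization stress tests construct their own
flips.

Two deliberate design points:

* **Exposure SEs default to 0.0008–0.0015**, i.e. mean instrument
  F-statistic of order 500.  First-order Wald ratios suffer regression
  dilution of order $\overline{\sigma_x^2}/\overline{\gamma^2}$; at a
  more literal exposure-GWAS noise level ($\sigma_x \approx 0.003$)
  that dilution is about 2% of $\theta$ — visible at 2000-replicate
  Monte-Carlo resolution — and the default scenario doubles as the
  estimator-unbiasedness testbed, where weak-instrument regimes are an
  explicit configuration extension rather than the default.  Users
  studying weak-instrument behaviour should raise `se_exp_range`.
* **Binary-outcome betas are generated directly on the log-OR scale**
  (no liability-threshold simulation).  That is adequate for
  validating summary-level estimators, which is all the generator is
  for; it does not emulate case-control ascertainment, sample overlap,
  LD between instruments (LD enters only through the separate
  block-structured fixture generator), or allele-frequency-dependent
  power.  A green simulation test therefore establishes estimator
  correctness under the stated model, not robustness to those realism
  gaps.

`simulate_ld_table()` takes an already-simulated table rather than a
bare configuration because LD blocks only mean something relative to
concrete SNP ids and positions: it rewrites block members' positions
to sit inside the clump window (1 kb spacing) and moves singletons to
private chromosomes, returning the LD table and the repositioned
association table together.

## Numerical choices and degenerate inputs

* Strict inequalities at the significance (5e-8) and palindrome-MAF
  (0.42) boundaries; boundary values fail.
* Clump distance is $|pos_a - pos_b|$ in base pairs against
  `window_kb * 1000`.
* Penalized-IVW iteration: tolerance 1e-10 on $\theta$, max 100
  iterations; ML optimizer: BFGS, relative tolerance 1e-14, hard error
  on non-convergence or non-positive curvature.
* Wald ratios hard-error on any $\hat\gamma_j = 0$, naming the SNP;
  the generator's truncation keeps ratios well-defined by default.
* Exact-fit Egger data (residual SD 0) cannot divide by the residual
  scale: unscaled SEs are computed from the normal equations directly.
* Empirical p-values (PRESSO) are floored by construction, never 0;
  simulated GWAS p-values are floored at 1e-300 so extreme z-scores
  survive the `(0,1]` ingest invariant.
* Estimator-level determinism: all simulation-based quantities (median
  bootstrap, MR-PRESSO) take explicit seeds and restore the caller's
  RNG state.

## Known limitations

* Criterion-style recovery claims for MR-PRESSO's outlier correction
  hold only when every instrument carries a non-trivial weight share:
  with Normal-distributed true effects the weakest instruments make
  "corrected closer to truth than raw" approach a coin flip whenever
  the outlier lands on them (analysis in the test suite's comments).
* The Egger intercept test's type-I error is calibrated under balanced
  pleiotropy with InSIDE; under InSIDE violation the slope (and the
  test) are biased — by design, that regime is what the
  `inside_violating` generator mode is for.
* No proxy-SNP lookup, genome-build lift-over, VCF ingestion, or
  individual-level analysis; LD information must be supplied as a
  table.
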