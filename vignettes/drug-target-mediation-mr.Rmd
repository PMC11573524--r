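---
title: "Drug-target Mendelian randomization with mediation: models, defaults and design decisions"
author: "targetmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The causal question and its assumptions

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from two independent GWAS: one supplying SNP-exposure
associations $\hat\gamma_j \pm \sigma_{\gamma j}$, the other SNP-outcome
associations $\hat\Gamma_j \pm \sigma_{\Gamma j}$. Valid instruments must be
(1) associated with the exposure, (2) independent of confounders of the
exposure-outcome relation, and (3) affect the outcome only through the
exposure. The package asserts (1) through the significance and F-statistic
filters, approximates (2) through a user-supplied confounder-SNP blocklist,
and probes (3) through the pleiotropy diagnostics.

In the *drug-target* variant, instruments are restricted to a cis window
around the gene encoding a drug's target, so that the exposure is not the
biomarker per se but its modulation through that specific protein — e.g.
triglyceride-lowering through LPL as a proxy for LPL agonism. The mediation
extension decomposes the total effect $\alpha$ of the exposure on the
outcome into an indirect part flowing through a molecular mediator
($\beta_1$: exposure to mediator; $\beta_2$: mediator to outcome) and a
direct remainder.

## Instrument selection

Cis selection keeps SNPs on the target gene's chromosome with position in
the inclusive window $[\mathrm{start} - f, \mathrm{end} + f]$ ($f$ = 100 kb
by default, measured from the gene ends, not its midpoint), $p$ strictly
below $5\times10^{-8}$, and effect-allele frequency strictly above 0.01.
Two conventions deserve note:

* The EAF filter is applied to the *stored* effect-allele frequency, taking
  the published rule at its word; a strict minor-allele-frequency mode
  (`strict_maf = TRUE`) is available but off by default. With the default
  generator's frequency range the two modes coincide.
* Window boundaries are inclusive on both ends; positions are 1-based. All
  internal interval arithmetic uses the same inclusive convention and is
  tested at exact boundary positions.

Clumping is greedy: SNPs are ranked by ascending p-value (ties broken by
position, then lexicographic id, making the output invariant to input row
order), and a SNP is kept only when its $r^2$ with every already-kept SNP
within the clumping window is at or below the threshold. The adaptive rule
runs at $r^2 < 0.3$ and, when fewer than three SNPs survive, reruns from
scratch at $r^2 < 0.4$. A survivor count of exactly three at the primary
threshold stands — the fallback triggers only strictly below three. The
threshold actually applied is recorded with the result, and every retained
pair is re-checked exhaustively in the test suite. LD is always consumed as
an input matrix (square or triplet format); missing entries are an error
rather than an assumed zero, because silently treating unknown LD as
independence would admit correlated instruments. pQTL instruments use the
preset $p < 5\times10^{-6}$, $r^2 < 0.001$, 10,000 kb window.

A caveat implied by the greedy algorithm: monotonicity of the survivor
count in the $r^2$ threshold holds on block-structured LD (constant
within-block correlation, zero between blocks), which is what the
simulator generates and the tests assert; on arbitrary LD matrices a
looser threshold can admit an index SNP that blocks several others, so no
general monotonicity is claimed.

## Harmonization

Outcome effects are re-expressed per copy of the exposure's effect allele:
matching alleles pass through, swapped alleles negate the outcome beta and
reflect its allele frequency, and strand flips are resolved by
complementation. Palindromic SNPs (A/T, C/G) carry no strand information in
their labels; the default policy infers orientation from allele frequency
when both studies report an EAF and both minor-allele frequencies are below
0.42, and drops the SNP otherwise (including whenever an EAF is missing).
The 0.42 cutoff is configurable; it trades retained SNPs against the risk
of silently mis-orienting common palindromes, and the source analyses this
package follows do not state their own convention, so the conservative
frequency-inference default of standard two-sample MR practice is used.
Harmonization is idempotent, the double allele swap is an involution, and
the shared-SNP count always equals retained plus dropped with per-reason
counts — all asserted as properties.

Input p-values of exactly zero (common in very large GWAS exports) are
replaced by the smallest positive double and logged, preventing downstream
log-zero failures while preserving ordering.

## Estimators

With weights $w_j = \hat\gamma_j^2/\sigma_{\Gamma j}^2$ and ratios
$b_j = \hat\Gamma_j/\hat\gamma_j$:

* **IVW**: $\hat\beta = \sum w_j b_j / \sum w_j$,
  $\mathrm{se} = (\sum w_j)^{-1/2}$. This weight convention ignores
  second-order (exposure-side) terms, so the ratio-space estimator
  coincides exactly with weighted least squares of $\hat\Gamma$ on
  $\hat\gamma$ through the origin with weights $1/\sigma_{\Gamma j}^2$ —
  an equivalence the tests verify against an independent `lm()` oracle at
  $10^{-10}$. The multiplicative-random-effects variant multiplies the SE
  by $\sqrt{\max(1, Q/(J-1))}$; the floor at 1 means heterogeneity can
  widen but never narrow the interval.
* **MR-Egger** orients $\hat\gamma_j \ge 0$ first (the fit is invariant to
  joint sign flips), regresses with a free intercept, and reports the
  intercept as the directional-pleiotropy test. Under the
  multiplicative-random-effects mode both SEs scale by
  $\sqrt{\max(1, Q_E/(J-2))}$.
* **Weighted median**: normalized weights $w'_j$, ordered ratios, cumulative
  midpoints $p_j = S_{j-1} + w'_j/2$, linear interpolation at $p = 0.5$.
  When 0.5 falls at or below the first midpoint (or at or above the last)
  the extreme ratio is returned without extrapolation. The SE is the
  standard deviation of the estimate over `n_boot` (default 1000)
  parametric-bootstrap replicates drawing per-SNP independent normals,
  seeded for exact reproducibility.

All p-values are two-sided from the standard normal, including the Egger
intercept: no small-sample t correction is applied, following the usual
multiplicative-random-effects normal approximation. With a single
instrument every path delegates to the Wald ratio
($\hat\beta = \hat\Gamma/\hat\gamma$, first-order
$\mathrm{se} = \sigma_\Gamma/|\hat\gamma|$).

The headline analysis is fixed-effect IVW escalated automatically to the
multiplicative-random-effects form when Cochran's Q has $p < 0.05$
(configurable via `q_alpha`). This escalation-on-heterogeneity rule is a
package default chosen to match how drug-target analyses typically handle
heterogeneous positive controls; both modes are callable directly.

## Sensitivity battery

* **Cochran's Q** on the IVW basis ($df = J-1$) and the Egger basis
  ($df = J-2$, the weighted residual sum of squares about the Egger fit).
* **Leave-one-out**: J re-estimates, flagging omissions that flip whether
  the CI excludes zero or move the estimate by more than half the full-set
  CI half-width (fraction configurable).
* **Simulation-based outlier detection**: the observed residual sum of
  squares about leave-one-out IVW fits is compared with `n_sim` parametric
  simulations; per-SNP two-sided empirical p-values are Bonferroni-scaled
  by J; a distortion test compares the estimate shift after outlier removal
  against removal of equally many random SNPs. Empirical p-values use
  $+1/(n_{\mathrm{sim}}+1)$ smoothing and therefore can never be exactly
  zero — a consequence worth knowing: the smallest achievable adjusted
  outlier p is $2J/(n_{\mathrm{sim}}+1)$, so `n_sim` must exceed roughly
  $40J$ before any outlier can reach the 5% level. The default `n_sim` is
  1000. Detection and removal run as a single detect → remove →
  re-estimate pass with both passes reported, mirroring how a detected
  outlier in a positive-control analysis is handled in practice.

Under the null the global test and the Egger intercept hold their size:
the test suite measures rejection frequencies over 500 seeded replicates
and requires them to lie in [0.02, 0.09] at the nominal 5% level.

## Mediation

The product-of-coefficients decomposition: indirect effect $\beta_1\beta_2$
with Sobel SE $\sqrt{\beta_1^2 s_2^2 + \beta_2^2 s_1^2}$, proportion
mediated $\beta_1\beta_2/\alpha$ with a first-order delta SE treating
$(\beta_1, \beta_2, \alpha)$ as independent, and direct effect
$\alpha - \beta_1\beta_2$. The identities
`direct + indirect == alpha` and `proportion * alpha == indirect` hold
bitwise on the stored floats. Independence is an approximation: in real
two-sample designs the $\alpha$ and $\beta_1$ fits share the exposure GWAS,
so the proportion's SE is mildly optimistic; this covariance is documented
rather than modelled.

When estimating $\beta_2$ (mediator to outcome), mediator instruments that
are also exposure instruments — or in LD at $r^2 > 0.001$ with one — are
excluded by default (`overlap_policy = "drop-shared"`), preventing the
exposure pathway from contaminating the mediator effect; the simulator
shows the contamination this guards against, since cis SNPs of the exposure
gene reach mediator-GWAS significance through $\beta_1$ yet carry the full
total effect to the outcome. The policy is selectable because the exclusion
sentence it operationalizes is ambiguous in the source design.

Bonferroni families take their size `m` explicitly: thresholds $0.05/m$
with strict inequality, and a warning (not an error) when `m` is smaller
than the number of member tests, since published families sometimes use a
denominator that differs from the member count. Mediation chains are only
computed along links that pass their respective families, mirroring the
screen-then-mediate flow.

`pval_from_or_ci()` back-calculates a two-sided p from a printed OR and
95% CI. Reconciling published forest rows this way reproduces most rows
within a few percent; one published row (MMP-1: OR 0.837, CI 0.764–0.918,
p 1.534E-05) is internally inconsistent under the normal approximation
(back-calculation gives about 1.5E-04) and is treated as a probable typo,
excluded from reconciliation checks.

## What the simulator emulates — and what it does not

`simulate_study()` generates summary statistics directly under the
structural model

$$\delta_j = \beta_1\gamma_j + m_j, \qquad
  \Gamma_j = (\alpha_{\mathrm{direct}} + \beta_1\beta_2)\gamma_j
             + \beta_2 m_j + \theta_j,$$

with $\gamma_j$ the true effects of exposure cis SNPs, $m_j$ those of
mediator pQTLs, and $\theta_j$ optional pleiotropy (balanced or
directional). This is the minimal model under which the
product-of-coefficients decomposition is exact, and the true total effect
is exactly $\alpha_{\mathrm{direct}} + \beta_1\beta_2$. Standard errors
follow $1/\sqrt{2np(1-p)}$ for standardized quantitative traits and
$1/\sqrt{2p(1-p)\,n\,\phi(1-\phi)}$ for a binary outcome with case
fraction $\phi$, so rarer alleles and smaller studies get proportionally
noisier estimates.

Defaults encode the study setting the package targets: exposure GWAS
n = 441,016; mediator pQTL study n = 14,824; binary outcome n = 1,030,836
with case fraction 0.0588; total effect $\log(0.854) = -0.158$ split as
$\beta_1 = \log(0.817)$, $\beta_2 = \log(1.075)$ and
$\alpha_{\mathrm{direct}} = -0.1432$, giving a true mediated proportion of
0.0926. True instrument magnitudes are uniform on [0.05, 0.15] SD per
allele with random sign — strong cis effects (F well above 100 at these
sample sizes) of the kind drug-target windows are chosen for — and
allele frequencies uniform on [0.1, 0.9]. Thirty cis SNPs in six LD blocks
(within-block correlation 0.6, stored as $r^2 = 0.36$) make the adaptive
clumping rule do real work, reducing them to six independent instruments.

Simulation is summary-level, not genotype-level: sufficient because every
estimator consumes only summary statistics, and binary-outcome effects are
generated directly on the log-odds scale without a liability-threshold
conversion so the truth stays interpretable against OR-scale results. The
generator draws noise independently across the three tables (perfect
two-sample separation). Features of real data it deliberately does not
model: winner's curse from in-sample instrument selection, participant
overlap between GWAS, reference-panel LD estimation error, population
stratification, and allele-frequency mismatch between studies. Passing
recovery and calibration tests therefore demonstrates correctness of the
estimators under the assumed model, not robustness to those artefacts.

## Validation problem sizes

The test suite validates at sizes chosen to make Monte-Carlo bounds tight
while keeping the default run quick: oracle equivalence on 100 random
fixtures (tolerance $10^{-10}$); IVW recovery and CI coverage over 500
replicates at J = 50 strong instruments (coverage required in
[0.93, 0.97]); mediated-proportion recovery over 200 replicates (mean
within ±0.02 of truth); null calibration of the Egger intercept and the
simulation-based global test over 500 replicates at `n_sim` = 500;
outlier detection of a 10-standard-error displacement in 100 replicates
(required in at least 95%).

## Known limitations

* No multivariable MR, reverse-direction MR, Steiger filtering, or
  mode-based/robust estimators beyond the three implemented.
* LD must be supplied; there is no reference-panel computation, no PLINK
  fileset parsing, and no remote queries of any kind.
* The proportion-mediated SE ignores the $\alpha$–$\beta_1$ covariance
  (shared exposure sample), as noted above.
* Coordinates are consumed as given; no liftover between genome builds.
* The packaged drug-target gene table contains approximate GRCh37 spans
  intended for windowing, not authoritative gene models.
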