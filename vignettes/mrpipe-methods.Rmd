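---
title: "Methods: two-sample MR, multivariable MR and cross-trait LDSC in mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, multivariable MR and cross-trait LDSC in mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

# Scope and model

`mrpipe` implements summary-statistic causal inference between complex
traits: two-sample Mendelian randomisation (MR) with a battery of
pleiotropy-robust estimators, multivariable MR (MVMR) with a
mediation/attenuation decomposition, outlier-robust sensitivity stages,
cross-trait LD score regression (LDSC), and a power calculator — together
with a synthetic-data generator that realises the generative model all of
these methods assume, so every estimator in the package can be exercised
against a known truth.

The core identity is the instrumental-variable ratio. For a variant $j$
with association $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) on an exposure $X$
and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) on an outcome $Y$, measured in two
non-overlapping samples, the per-variant causal estimate is the Wald
ratio $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$, with first-order
standard error $\sigma_j = \sigma_{Yj}/|\hat\beta_{Xj}|$ (a second-order
delta-method SE that also propagates $\sigma_{Xj}$ is available via
`se_order = "second"`). All univariable estimators are functions of
$(\hat\theta_j, \sigma_j)$ or of the harmonized coefficient pairs:

* **Fixed-effect IVW**: $\hat\theta = \sum w_j\hat\theta_j / \sum w_j$
  with $w_j = \sigma_j^{-2}$ and $SE = (\sum w_j)^{-1/2}$. A
  multiplicative random-effects variant inflates the SE by
  $\max(1, \sqrt{Q/(J-1)})$, $Q$ being Cochran's statistic.
* **MR-Egger**: weighted regression of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$ with a free intercept after orienting all
  $\hat\beta_{Xj} > 0$; the slope is the causal estimate under InSIDE and
  the intercept measures average directional pleiotropy. SEs are scaled
  by $\max(1, \hat\sigma)$ (multiplicative over-dispersion, never
  under-dispersion).
* **Weighted median**: the 50th percentile of the standardized
  cumulative-weight distribution of sorted ratios, linearly interpolated;
  consistent while valid instruments carry $>50\%$ of the weight. SE by
  parametric bootstrap, $\hat\theta_j^* \sim N(\hat\theta_j, \sigma_j)$.
* **Mode-based estimate**: argmax of the weighted normal-kernel density
  of the ratios, consistent under the zero-modal-pleiotropy assumption.
  Bandwidth is $\phi \times 0.9\,\min(sd, mad)\,J^{-1/5}$ (the
  mode-based-estimation variant of Silverman's rule); the density is
  evaluated on a fixed 512-point grid spanning
  $[\min\hat\theta_j - 3\max\sigma_j,\ \max\hat\theta_j + 3\max\sigma_j]$
  and ties at the argmax resolve to the smaller grid value, so the
  estimate is deterministic. SE by the same parametric bootstrap; the
  bootstrap argmaxes are evaluated on the point estimate's grid, which
  leaves the argmax unchanged up to grid resolution while allowing all
  resamples to be computed in one vectorised pass.
* **Penalised IVW**: each variant's heterogeneity contribution
  $Q_j = w_j(\hat\theta_j - \hat\theta_{IVW})^2$ is referred to a
  $\chi^2_1$ upper tail $q_j$ and the weight multiplied by
  $\min(1, 20\,q_j)$ — variants consistent with the consensus
  ($q_j \ge 0.05$) are untouched, outliers are smoothly suppressed.

Point-estimate p-values are two-sided normal tails of $\hat\theta/SE$
throughout (bootstrap SEs included), and every stochastic stage takes an
explicit integer seed that is recorded in its output.

# Harmonization rules

`harmonize()` aligns each instrument's outcome association to the
exposure's effect allele before any estimation. Matching precedence is
exact match, swapped alleles (sign flip), strand complement, swapped
complement (sign flip); anything else is dropped as `allele_mismatch`.
Two exclusions implement standard instrument hygiene:

* **Palindromic variants** (A/T, C/G) are excluded unconditionally — no
  allele-frequency rescue is attempted, because a frequency-based rescue
  fails exactly where it matters (frequencies near 0.5).
* **Direct-effect instruments**: variants whose outcome association is
  itself genome-wide significant ($P < 5\times10^{-8}$ by default) are
  excluded, since they plausibly act on the outcome through a pathway of
  their own. When the outcome p-value is missing it is recomputed as the
  two-sided normal tail of $\hat\beta/\hat{se}$.

Every exclusion is logged as a `(variant_id, reason)` pair and
harmonization fails loudly (with the reason tally) only when nothing
survives. One caveat this package's own simulations make visible: under a
strong true causal effect with strong instruments, *truly mediated*
outcome associations can reach $5\times10^{-8}$, so the direct-effect
filter would preferentially delete the most informative valid
instruments. The recovery and coverage studies below therefore disable
that filter (`direct_effect_p = 0`) while the pipeline default keeps it —
in real data the filter's target is pleiotropy, not mediation through the
exposure itself.

# Instrument selection

`clump()` performs greedy LD clumping: candidates with
$P < 5\times10^{-8}$ are ranked by p-value and the best remaining variant
repeatedly retained, removing remaining variants on the same chromosome
within 1 Mb and with $r^2 \ge 0.2$ against it. Ties on p-value break by
(chromosome, position) then variant id, making the retained set invariant
to input row order. The window is centred ($\pm$ 1 Mb); a one-sided
variant is available because "within a window of 1 Mb" is genuinely
ambiguous between the two conventions. Variants absent from the LD
reference are treated as unlinked with a warning rather than an error —
the permissive default is logged so it cannot pass silently. Instrument
strength is summarised per variant by $F \approx (\hat\beta/\hat{se})^2$,
the large-sample squared-z identity.

# Outlier-robust stages

`presso()` is a residual-sum-of-squares pleiotropy test in the MR-PRESSO
mould: for each variant the leave-one-out IVW fit gives an expected
outcome coefficient, the squared residual is recorded, and both the
global sum and the per-variant residuals are referred to a parametric
null (coefficients redrawn from their sampling distributions around the
leave-one-out fitted values) with $(r+1)/(n+1)$-corrected empirical
p-values; per-variant flags use a Bonferroni threshold $\alpha/J$. The
distortion test of the original procedure is deliberately out of scope —
downstream, only the exclusion list is consumed, via
`refit_after_exclusion()`. One known behaviour worth naming: a single
gross outlier contaminates every leave-one-out fit, so neighbouring valid
variants can also cross the flag threshold (masking). The planted-outlier
checks therefore assert that the planted variant is flagged and is the
most extreme contributor, not that it is the only flag.

`conmix()` is a contamination-mixture estimator: at each candidate
$\theta$ on a 401-point grid spanning
$[\min\hat\theta_j - 2\max\sigma_j,\ \max\hat\theta_j + 2\max\sigma_j]$,
each variant contributes the larger of a valid log-likelihood
$N(\hat\theta_j; \theta, \sigma_j^2)$ and an invalid one
$N(\hat\theta_j; 0, \sigma_j^2 + \psi^2)$; the profile maximum gives the
estimate, the grid points within $\chi^2_{1,0.95}/2 = 1.92$ of it give
the 95% set (reported as its convex hull with a multimodality flag when
disjoint), and the argmax assignment yields the valid-variant list. The
invalid-component scale defaults to $\psi = 1.5\,sd(\hat\theta_j)$.
Because the per-variant maximum is taken independently, the grid argmax
provably equals the exhaustive maximum over all $2^J$ valid/invalid
assignments at each grid point — a property the test suite verifies by
brute force at $J = 8$.

# Multivariable MR and mediation

`mvmr_joint()` regresses $\hat\beta_{Yj}$ on all $K$ exposures'
coefficient columns jointly (weights $\sigma_{Yj}^{-2}$, no intercept:
with instruments oriented freely an intercept is a pleiotropy term, and
$K = 1$ must reduce exactly to IVW). `mvmr_residualized()` implements the
two-stage variant in which the outcome is first residualized on the
non-target exposures and the residual regressed on the target. With
`residualize_target = TRUE` this reproduces the joint coefficient exactly
(Frisch–Waugh–Lovell); with `FALSE` — residualizing the outcome only — it
does not when exposure columns are correlated. Both are provided because
the outcome-only form is what a pipeline following the two-stage verbal
description would compute; the package treats the joint fit as the
primary result and the outcome-only form as a diagnostic, and the test
suite pins down their algebraic relationship with a projection-matrix
oracle.

`mediation()` is the difference method on the MR scale: total effect $C$
from univariable IVW of the exposure on the outcome, direct effect $C'$
from the exposure's MVMR coefficient adjusting for the mediator, indirect
effect $C - C'$ and percent mediated $100\,(C - C')/C$ (denominator the
univariable estimate). The difference is only *labelled* mediation when
both legs of the path hold at level $\alpha$: exposure→mediator (A path)
and mediator→outcome (B path), each by univariable MR; otherwise the row
is labelled attenuation. The B path needs the mediator's own instruments:
estimating it from the pooled joint set would let a direct
exposure→outcome path masquerade as a mediator effect through the
exposure's instruments (visible in the $\theta_{MY} = 0$ test). The
function therefore accepts a dedicated mediator→outcome harmonized set,
and `simulate_mediation_chain()` emits it alongside the three sets of the
standard signature; without it, the fallback restricts the joint set to
variants genome-wide significant for the mediator.
`attenuation_table()` tabulates, per added covariate, the change of the
exposure's estimate relative to the univariable base row, with a full
(all-covariate) model last.

# Cross-trait LD score regression

The LD score of variant $j$ is
$\ell_j = \sum_k [r^2_{jk} - (1 - r^2_{jk})/(n_{ref} - 2)]$ over a
genomic window, the small-sample-adjusted estimator with a self term of
exactly 1. Under the polygenic model,
$E[\chi^2_j] = 1 + n\,h^2\,\ell_j/m$, so `univariate_ldsc()` regresses
$z_j^2$ on $\ell_j$ and rescales the slope by $m/n$; the intercept
absorbs confounding and sample structure. For two traits,
$E[z_{1j} z_{2j}] = \rho_{int} + \sqrt{n_1 n_2}\,\rho_g\,\ell_j/m$, and
`cross_trait_ldsc()` regresses the z-product on $\ell_j$, rescales the
slope to genetic covariance, and normalises by the univariate
heritabilities to the genetic correlation
$r_g = \widehat{gencov}/\sqrt{\hat h^2_1 \hat h^2_2}$; the bivariate
intercept (freely estimated, since cohorts may overlap) is retained.

Numerical choices: regression weights default to $1/\max(\ell_j, 1)$, a
simple heteroscedasticity proxy (the cited software's full iterative
weighting is out of scope; plain OLS is a switch). Standard errors are
delete-a-block jackknives over 200 contiguous equal-size blocks in input
order — a stand-in for genomic blocks that is exact for the exchangeable
synthetic data the package generates. The intercept is estimated in a
first step restricted to $\chi^2 < 30$ and then held fixed (the
two-step convention). That restriction matters in simulation: when
$n h^2 \ell/m$ is large, most of the *true-signal* $\chi^2$ mass exceeds
30 and the truncation biases the fit; the package's recovery studies
therefore either run at sample sizes where the signal per SNP is
realistic for the cutoff ($n = 2000$ with $m = 5000$,
$h^2 = 0.4$), or pass `two_step_cutoff = Inf` when the simulated
intercept is exactly 1. $|r_g| > 1$ is reported with a warning flag, and
non-positive heritability leaves $r_g$ missing with a reason rather than
producing a complex number. rg p-values are two-sided Wald on
$r_g/SE_{jack}$.

# The synthetic-data generator

`simulate_two_sample()` realises the exact generative model the MR
estimators assume, so that recovery failures indict the estimator and
not the fixture. Traits sit on a directed acyclic causal matrix $A$
(entry $(i,j)$ = direct effect of trait $i$ on trait $j$, the last trait
being the outcome; acyclicity is enforced by a nilpotency check). Each
exposure owns $J$ unlinked instruments with true per-allele effects drawn
uniformly in magnitude from $[0.05, 0.15]$ with random sign; marginal
true effects propagate through $(I - A)^{-1}$. Horizontal pleiotropy adds
a direct variant→outcome effect to a configurable fraction of
instruments, drawn $N(\mu, \sigma)$ *on the exposure-increasing allele*
— defining directionality relative to orientation is what makes a
nonzero $\mu$ detectable as an Egger intercept; defined on the coded
allele it would wash out under random instrument signs. Observed
coefficients add independent noise with the standard GWAS standard error
$1/\sqrt{2\,n\,f_j(1 - f_j)}$ for allele frequency
$f_j \sim U(0.05, 0.5)$ on the unit-variance trait scale; exposure and
outcome samples are non-overlapping.

Default magnitudes are chosen once for realism: at $n = 10^5$ the
effect-size floor of 0.05 gives per-variant $F \gtrsim 23$ (typically far
higher), matching the strong-instrument regime reported for published
BMI instruments ($F \ge 27$), and binary traits are treated on the
log-odds scale without liability conversion. A configurable fraction of
variants receives strand-ambiguous (A/T, C/G) allele pairs to exercise
the palindromic filter; the default is 0 so that recovery fixtures keep
their nominal $J$.

What the generator deliberately does *not* emulate: LD between
instruments (instruments are post-clumping by construction; LD enters
only the clumping and LDSC fixtures via `simulate_ld_panel()`), winner's
curse from instrument discovery in the exposure sample, sample overlap
between exposure and outcome GWAS, MAF-dependent effect-size
architecture, and population stratification (LDSC intercepts are 1 by
construction). Passing recovery tests on this generator therefore shows
internal correctness of the estimators under their assumed model — not
robustness to the violations real GWAS data carry.

`simulate_mediation_chain()` wires the three-trait chain
X→M→Y plus a direct X→Y path; with path coefficients
$(\theta_{XM}, \theta_{MY}, \theta_{XY})$ the true percent mediated is
$100\,\theta_{XM}\theta_{MY}/(\theta_{XY} + \theta_{XM}\theta_{MY})$.
`simulate_ldsc_z()` draws z-pairs from the bivariate LDSC model with
variances $1 + n_i h^2_i \ell_j/m$ and covariance
$\sqrt{n_1 n_2}\,\rho_g \ell_j/m$, rejecting configurations whose implied
per-variant covariance is not positive semidefinite.

# Orchestration, thresholds and power

`run_pair()` chains instrument selection → harmonization → estimator
battery → outlier stages → re-fit on the altered set → consistency
verdict, with all seeds and thresholds carried in the result. The
consistency rule mirrors the forest-plot convention: a pair is consistent
when at least two methods are nominally significant and all point
estimates share a sign. `bidirectional()` runs both directions with each
trait's own instruments; the direct-effect filter then guarantees no
instrument used for A→B is genome-wide significant for B, an invariant
asserted on every run's drop log. Raw p-values are always reported next
to the Bonferroni flag ($\alpha/n_{tests}$, default $0.05/9 \approx
5.6\times10^{-3}$ matching the nine-test family of the motivating
analysis); $n_{tests}$ is configurable because that family is
analysis-specific.

`mr_power()` uses the two-sided normal approximation on unit-variance
scales,
$\Phi(|\theta|\sqrt{n r^2} - z_{1-\alpha/2}) +
 \Phi(-|\theta|\sqrt{n r^2} - z_{1-\alpha/2})$,
which returns exactly $\alpha$ at $\theta = 0$; the test suite checks it
against a Monte-Carlo simulation of the single-instrument ratio test.

# Problem sizes used by the test and acceptance runs

The shipped checks run entirely on synthetic data at sizes chosen to
balance Monte-Carlo resolution against a single-CPU run: coverage of the
five estimators uses 500 replicates per effect size at $J = 100$,
$n = 10^5$, with 200 bootstrap resamples for the median/mode SEs (the SE
of a 200-resample bootstrap SD is about 5%, immaterial at the 90%
coverage margin); outlier-test calibration uses 200 null replicates of
300 simulations each; mediation recovery 50 chains at $J = 150$; LDSC
recovery $m = 5000$ with 200 jackknife blocks. The acceptance script
(`scripts/acceptance.R`) re-derives the same quantities from scratch at
comparable sizes under a caller-supplied seed.

# Known limitations

* Proxy-variant lookup, genome-build liftover and VCF ingestion are out
  of scope; instruments missing from the outcome table are dropped and
  logged, not proxied.
* The MR-PRESSO-style stage implements the global and per-variant outlier
  tests but not the distortion test; conmix confidence sets are reported
  as convex hulls with a multimodality flag.
* LDSC here is the plain (unpartitioned) regression with simple inverse-
  LD weights and input-order jackknife blocks; it is not a drop-in
  replacement for the reference software on real, stratified data.
* Binary traits are handled on the log-odds scale throughout; no
  liability-scale conversions are applied.
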