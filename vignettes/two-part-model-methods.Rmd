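---
title: "Modeling weekly gambling losses with a Bayesian two-part gamma hurdle mixed model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling weekly gambling losses with a Bayesian two-part gamma hurdle mixed model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The data and why a hurdle model

Timeline-followback gambling (TLFB-G) data report day-by-day net losses in
SEK. In a treatment-seeking sample these series have two salient features:
a large point mass at zero (days and whole weeks with no gambling at all)
and strongly right-skewed positive amounts when gambling does occur —
often binge episodes followed by long abstinence runs. Neither a Gaussian
nor a single-family GLM describes such *semicontinuous* data well.

`gamblehurdle` models the participant-week average daily loss
$Y_{ij} \ge 0$ (subject $i$, week $j$) with a two-part mixture:

* an **occurrence part**: $Z_{ij} \sim \mathrm{Bernoulli}(p_{ij})$ with
  $\mathrm{logit}(p_{ij}) = x_{ij}^\top\beta^{(o)} + b_i^{(o)}$, where
  $Z_{ij} = 1$ means any gambling that week
  ($Y_{ij} > 0$ exactly when $Z_{ij} = 1$);
* an **amount part**: $Y_{ij} \mid Z_{ij}=1 \sim
  \mathrm{Gamma}(\nu, \nu/\mu_{ij})$ with
  $\log \mu_{ij} = x_{ij}^\top\beta^{(a)} + b_i^{(a)}$ (mean–shape
  parameterization, so $\mathrm{E}[Y\mid Z=1] = \mu_{ij}$).

The subject intercepts $(b_i^{(o)}, b_i^{(a)})$ are bivariate normal with
SDs $\sigma_o, \sigma_a$ and correlation $\rho$: a person who gambles more
often typically also loses more when they do, and the correlation lets the
two parts share that information. Logit and log are the canonical links
for this family.

Averaging daily records into one weekly value (`aggregate_weekly`) keeps
the meaning of zero identical across the baseline month, the weekly
treatment reports and the monthly follow-up recalls. The average is over
*observed* days only; a week with no observed days is missing, not zero.

## Time, the treatment-start jump, and the shared baseline

Time (in weeks from treatment start) enters as a restricted cubic spline
with three knots at the 10th/50th/90th percentiles of the observation-level
week variable — a parsimonious curvature model for a small trial. The
basis (`rcs_basis`) is the standard truncated-power construction, scaled
by $(k_3-k_1)^2$ and linear beyond both boundary knots; both columns are
centered to equal 0 at week 0.

Because most participants stop gambling abruptly when treatment starts, a
0/1 dummy (`post`) separates the baseline week from all post-baseline
weeks, giving the fitted curve a discontinuity at treatment start.

Randomization makes the arms exchangeable at baseline, so the design
constrains the week-0 mean to be identical across arms: the treatment arm
(CBT, with BCT as reference) enters only through interactions with the
post-baseline columns, all of which are identically zero at week 0. This
holds *exactly*, draw by draw — `arm_contrast(fit, 0)` is 0 with a
degenerate interval, by construction rather than estimation. Whether arm
interacts with the post dummy only or also with both spline columns is not
determined by the scientific question alone; the default is all three
(`arm_interactions = c("post", "lin", "nonlin")`), with a switch, since
that is the least restrictive shape for a differential trajectory.

The default week map places the baseline month at week 0, calendar weeks
from treatment start at 1, 2, …, (so the 10 treatment modules span weeks
1–10 and the post-treatment assessment month ends at week 12), and the
months recalled at the 3- and 6-month follow-ups around weeks 25 and 38.
Follow-up observations enter the same continuous spline rather than being
treated as separate categorical points.

## Priors, sampling and numerical choices

Priors (all configurable via `twopart_priors`):

* fixed effects: Normal(0, 10²) — effectively flat on the logit/log scale;
* random-intercept SDs: half-Student-t(3, 0, 2.5);
* intercept correlation: uniform on [−1, 1];
* gamma shape: half-Normal(0, 5).

Sampling is Gibbs/slice MCMC via JAGS. Two implementation details matter
for mixing:

1. **QR orthogonalization.** The spline columns are nearly collinear with
   each other and with the post dummy, which cripples componentwise
   samplers. The sampler therefore works on coefficients of the
   QR-orthogonalized design (columns scaled to norm $\sqrt{N}$), with the
   independent Normal(0, 10²) prior placed on the rotated coefficients,
   and draws are rotated back to the design scale afterwards. With the
   rotated columns orthonormal and the prior this flat, the induced prior
   on the design-scale coefficients remains non-informative; the gain in
   effective sample size per iteration is roughly an order of magnitude.
   A rank-deficient design (possible in the questionnaire models when an
   arm-by-timepoint cell is empty) cannot be rotated; such fits fall back
   to the identity basis and the unidentified coefficient follows its
   prior, with the empty cells named in a warning.
2. **Marginal–conditional intercepts.** The bivariate normal intercepts
   are sampled as $b^{(o)} \sim N(0, \sigma_o^2)$ and
   $b^{(a)} \mid b^{(o)} \sim N(\rho (\sigma_a/\sigma_o) b^{(o)},
   \sigma_a^2 (1 - \rho^2))$ — the same joint distribution, but univariate
   nodes that slice-sample efficiently.

Defaults are 4 chains of 1000 retained draws after 500 adaptation and 500
burn-in iterations, a fixed seed (required — identical seed and
configuration reproduce draws bit for bit), and a convergence gate of
split R-hat < 1.01 at these full-length settings. Simulation studies use
shorter chains with a correspondingly relaxed gate (reported, never
silent). JAGS's samplers have no divergence diagnostic; convergence is
judged on R-hat and effective sample size. Initial values are neutral
(zero coefficients except the amount intercept at the log mean positive
loss, unit SDs, zero correlation) rather than prior draws, which avoids
occasional wild starting points under the flat coefficient priors.

Degenerate inputs fail loudly: an all-zero outcome vector leaves the gamma
part unidentified and is an error; fewer than three distinct week values
cannot support the spline; negative losses are rejected unless the ingest
step's documented clamp (each clamp counted and reported) is active.

## Marginal summaries and contrasts

All effect summaries are posterior medians with equal-tailed 2.5–97.5%
percentile intervals. The overall money lost at a design point averages
over the two parts, $p \cdot \mu$, computed per draw with the subject
intercepts set to zero rather than integrated over — the result reads as
the average daily loss per week *for an individual with a median amount of
losses*, which is deliberately not the population-averaged mean (the
log/logit links make those differ). `arm_contrast` reports CBT − BCT
differences of this quantity and within-arm changes from baseline;
requested weeks outside the fitted range are computed but flagged as
extrapolation.

## Questionnaire models

NODS, PHQ-9 and GAD-7 totals are analyzed per instrument and role with a
Gaussian linear mixed model: categorical time (pre, post, 3- and 6-month;
pre as reference), arm, arm-by-time interactions and a subject random
intercept, sharing the hurdle model's priors. A Gaussian likelihood on
bounded sum scores is a deliberate simplification — the familiar "ordinary
linear mixed model" for such outcomes. Unlike the TLFB model, the baseline
arm difference is *freely estimated* here (the output tables carry a
pre-treatment difference row); only the gambling-loss model carries the
exact baseline constraint. NODS is gambler-only.

Scoring follows the published band tables: PHQ-9 0–4/5–9/10–14/15–19/20–27,
GAD-7 0–4/5–9/10–14/15–21, AUDIT hazardous-use flags strictly above 7
(men) and 5 (women), PGSI problem-gambling threshold at a total of 8 or
more. The NODS maps its 17 yes/no probes onto 10 DSM-IV criteria; the
gated pairs (withdrawal, loss of control, lying) require both probes,
criteria with alternative probes any one. The PGSI bands below the trial's
threshold (0 / 1–2 / 3–7) are the standard population bands, included for
synthetic-roster realism; only the ≥ 8 rule plays a role in eligibility.
AUDIT with unspecified sex returns an `NA` flag rather than a silent
`FALSE`. Missing per-protocol data never enter the likelihood — the
missing-at-random assumption under which likelihood-based Bayesian
inference remains valid.

## Posterior predictive checks and the coverage harness

`simulate_replicates` draws replicate datasets from the posterior
predictive — each replicate uses one retained draw's fixed effects, shape
*and* subject intercepts, on exactly the observed design shape. Four
statistics summarize fit: the proportion of exact zeros, the median and
maximum weekly loss, and the sample variance, computed on the pooled
weekly losses (the stratification is a free choice; pooled is the
default). Two-sided tail probabilities use
$2\min(P(\text{rep} \ge \text{obs}), P(\text{rep} \le \text{obs}))$ with
ties counted half and an add-one convention, so an observed value beyond
every replicate reports $2/(n_{\text{rep}}+1)$, never zero.

`run_coverage` is the frequentist audit of the Bayesian machinery:
simulate trials from known parameters with `generate_from_model`, refit,
and record how often each fixed effect's 95% credible interval contains
the truth, with the binomial Monte Carlo standard error
$\sqrt{c(1-c)/n}$. Replicates failing the convergence gate are excluded
and counted, never imputed. The gate applied per replicate inspects the
fixed-effect R-hats by default — the parameters whose intervals the study
assesses — because the random-effect SD and correlation mix slowest at
small n and would otherwise discard replicates whose fixed-effect
inference is sound.

`baseline_ttest` reproduces the summary-statistics two-sample comparison
used for baseline tables: pooled variance with $df = n_1+n_2-2$ by
default, Welch via a switch, since a printed "independent samples t test"
can mean either.

## The synthetic-trial generators

Two generators with different jobs:

* `generate_from_model` inverts the inference model exactly — correlated
  intercepts from the 2×2 covariance, Bernoulli week indicators, gamma
  amounts. It powers parameter recovery, coverage and MAR studies, where
  the generating truth must be *the model's own*.
* `generate_trial` builds a behaviorally structured trial: 18 gambler/CSO
  pairs by default, randomized 1:1 as pairs; an eligible-by-construction
  roster (gambler PGSI ≥ 8, CSO below the problem threshold, adults,
  relationship ≥ 3 months); daily losses from alternating geometric
  abstinence runs and binge episodes with lognormal amounts (default
  median binge day ≈ 1500 SEK), with the gambling hazard and amounts
  multiplied down after treatment start — by the same factor in both arms
  by default, since the emulated trial found no between-arm difference; a
  CSO-rated parallel series with multiplicative lognormal noise; and
  questionnaire items allocated to match drawn totals around configured
  cell-mean trajectories (the defaults trace the published pattern of
  both gambler arms improving while BCT CSOs improve more than CBT CSOs).

`apply_dropout` adds monotone missingness with a per-week hazard that
depends only on arm, week and the last *observed* weekly loss — missing
at random by construction. The published trial reports attrition only
qualitatively, so the default hazards are illustrative, not calibrated.

What the behavioral generator does **not** emulate: digit preference and
recall heaping in self-reported amounts, within-week day-of-week
structure, informative (non-MAR) dropout, therapist-contact effects, or
item-level response styles in questionnaires (items are allocated to match
totals, nothing more). Passing end-to-end tests on these data therefore
show that the pipeline is internally correct and robust to this flavor of
misspecification — not that the model is correct for any real trial.

## Problem sizes used in the validation suite

The package's simulation studies are sized for a single CPU: coverage uses
100 replicates of an 18-subject × 14-week trial with 2 chains of 500
retained draws (250 adaptation + 250 burn-in); parameter recovery uses 20
replicates at 200 subjects × 14 weeks with one short chain (bias needs
medians, not intervals); the posterior-predictive self-consistency study
uses 100 pseudo-observed datasets against 100 replicates each from one
fitted posterior; the MAR study uses 20 replicates at 30 subjects. These
sizes keep Monte Carlo error within each check's stated tolerance.

## Known limitations

* No frequentist/MLE path, no random slopes (intercepts only, matching
  the intended analysis), no model-comparison machinery.
* The marginal summaries condition on median random effects; population-
  averaged marginals would require integrating over the intercepts.
* The Gaussian questionnaire model ignores floor effects near recovery.
* The gamma hurdle excludes exact zeros by design; losses under 1 SEK
  recorded as fractional are treated as gambling weeks.
* Week mapping assumes the calendar anchors above; trials with different
  assessment schedules must supply their own `week_map`.
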