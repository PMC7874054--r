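---
title: "Deriving informative DDM priors from pooled parameter estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving informative DDM priors from pooled parameter estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

The diffusion decision model (DDM) decomposes two-choice response times and
accuracy into interpretable parameters: drift rate $v$, boundary separation
$a$, starting point $z$ (or bias $z_r = z/a$), non-decision time $T_{er}$,
and the across-trial variabilities $s_v$, $s_z$ (or $s_{z_r} = s_z/a$) and
$s_{T_{er}}$. Hundreds of published fits exist, which makes an empirical
characterization of plausible parameter values possible — most usefully in
the form of informative prior distributions for Bayesian fitting, but also
as starting values and box constraints for maximum-likelihood optimization.

Pooling published estimates is not a matter of concatenating numbers.
Articles differ in conventions that change the *scale* of every reported
value, and `ddmpriors` exists to undo those conventions, pool what remains,
and fit candidate densities to the pooled distributions:

* **Diffusion scaling.** One accumulation parameter must be fixed for
  identifiability; almost always the moment-to-moment drift variability
  $s$, set to $0.1$ (DMAT, and one prominent lab tradition) or $1$ (HDDM,
  fast-DM). Accumulation-scaled parameters ($v$, $a$, $z$, $s_v$, $s_z$)
  are proportional to $s$; $T_{er}$-type parameters and the dimensionless
  ratios are not.
* **Measurement unit.** RTs are fit in seconds or milliseconds, and
  articles essentially never say which; worse, $T_{er}$ is sometimes
  printed in milliseconds while everything else is in seconds.
* **Parameterization.** Starting points appear as absolute $z$ or relative
  $z_r$; drift rates appear accuracy-coded (positive = correct) or
  response-coded (sign tied to an arbitrary response assignment).
* **Design structure.** A parameter held fixed across an article's
  conditions is one estimate, not three; individual-participant estimates
  must be averaged before entering a pool in which every study counts
  equally.

# The canonical scale and the stage order

Estimates are canonicalized to $s = 1$, seconds, relative starting point,
accuracy-coded drift. The pipeline applies stages in a fixed order:

1. resolve $s$ (explicit value → software default → optional per-article
   rule); rows whose scale cannot be recovered are excluded with a logged
   count,
2. infer RT units per article (below), falling back to the declared or
   software-default unit when a step cannot run,
3. convert milliseconds to seconds,
4. re-scale to $s = 1$,
5. map $z, s_z$ to $z_r, s_{z_r}$ using the matching $a$ of the same
   article/study/condition (and participant, for individual rows),
6. accuracy-code drift by taking absolute values,
7. screen for implausibility ($a \le 0$, $T_{er} < 0$, ratios outside
   $[0,1]$, negative variabilities) and exclude with a logged count,
8. deduplicate constrained parameters (one representative per
   article/study/participant/kind/constraint group, first after a
   deterministic sort on article, study, condition),
9. average individual estimates within study and condition,
10. mirror $z_r$ at pooling time.

Unit inference must precede the $s$ re-scaling because the magnitude
thresholds below were designed for values as printed; mirroring must follow
averaging so that participant means are taken over directed bias values.
Every surviving row carries a `transform_log` listing the stages applied to
it, and the audit table accounts for every excluded row.

## Unit inference

Two magnitude rules assign units per parameter, not per article:

* $T_{er}$ (and $s_{T_{er}}$) are in seconds iff the reported $T_{er}$ is
  below 5 — no plausible non-decision time reaches 5 s, and none measured
  in milliseconds falls below 5 ms. With several $T_{er}$ rows per article
  the median is compared (robust to one contaminated row).
* The remaining parameters are in seconds iff the rough expected decision
  time $E(RT) = (a - z)/v$ is below 10, using the minimum across the
  article's conditions — the conservative choice against misclassifying
  slow designs; $z$ is reconstructed as $z_r \cdot a$ where only bias is
  reported.

## The millisecond conversion of accumulation parameters

Dividing times by $k = 1000$ while holding the diffusion coefficient $s$
fixed forces $v, s_v \mapsto v\sqrt{k}, s_v\sqrt{k}$ and
$a, z, s_z \mapsto a/\sqrt{k}, z/\sqrt{k}, s_z/\sqrt{k}$. This is the
unique linear rescaling of the evidence axis that maps a Wiener process
with drift $v$ and coefficient $s$ per millisecond onto one with the same
$s$ per second, so first-passage distributions (and hence fits) are
preserved; a closed-form mean-exit-time oracle verifies this in the test
suite. It follows that $E(RT)$ after conversion equals $E(RT)/k$ before,
which keeps the two unit-inference rules mutually consistent.

## Mirroring and accuracy coding

Which response sits at which boundary is arbitrary and cannot be
reconciled across articles, so the direction of bias carries no pooled
information. The pooled $z_r$ sample contains $x$ and $1-x$ for every
reported value: symmetric by construction, mean exactly $0.5$, with the
spread — the informative part — preserved. The same arbitrariness motivates
accuracy coding of drift: pooled drifts are $|v|$; a user wanting
response-coded priors mirrors the fitted prior around 0 instead.

# Candidate densities and model selection

Pooled samples are characterized by parametric densities respecting the
kinds' bounds: on $[0, \infty)$ the truncated normal, lognormal, gamma,
Weibull and truncated Student-$t$ (location, scale and degrees of freedom
all free, $df < 1$ permitted); on $[0, 1]$ (for $z_r$, $s_{z_r}$) the
truncated normal and truncated $t$. Outlier contamination from non-standard
tasks and populations inflates tails beyond any of these, so two-component
mixtures are added: gamma + gamma, and truncated normal with gamma,
lognormal, or another truncated normal (the same pairs, truncated to
$[0,1]$, for the bias kinds). Truncated densities are renormalized by the
parent mass of the interval; truncation bounds are fixed constants of the
kind and never free parameters.

Fitting is by maximum likelihood in an unconstrained reparameterization
(log for scales, shapes and $df$, logit for the mixture weight):
Nelder-Mead from 20 starts — one moment-matched, the rest Latin-hypercube
perturbations of it — with relative convergence tolerance $10^{-8}$, all
seeded. Numerical safeguards:

* A sample point with zero density under a family's support for *every*
  parameter value (an exact 0 under the lognormal, gamma or Weibull, whose
  support is open at the origin) eliminates the candidate rather than
  being jittered: the data are never edited, and exact zeros do occur
  (empirical lower bounds of $T_{er}$, $s_v$, $s_{T_{er}}$ are 0).
* Mixture likelihoods are unbounded as one component collapses onto a data
  point, so component scales are floored at 1% of the sample standard
  deviation — the conventional spike guard.
* Failed restarts are recorded, never raised; a candidate with no
  successful restart is flagged non-converged and receives Akaike weight 0.

Model selection uses Akaike weights,
$w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)$ with
$\Delta_i = AIC_i - \min AIC$, over the converged candidates. Free-parameter
counts: 2 for the two-parameter families, 3 for the truncated $t$,
$k_1 + k_2 + 1$ for mixtures. Exact ties go to the model with fewer
parameters, then to candidate enumeration order. When a mixture wins, the
proposed prior is its dominant component — the one with the larger weight
(components are relabeled after fitting so the reported weight is at least
0.5; at an exact 0.5 the smaller-variance component is taken, with a
message). The location of mirrored $z_r$ is fitted freely rather than
pinned at 0.5: the symmetry of the data forces it there, and the fitted
deviation doubles as a convergence diagnostic.

Kinds with fewer than `min_n = 10` pooled values (configurable) are
reported unfit-able: a nine-candidate comparison on a handful of points is
noise.

# The synthetic-corpus generator

Because the deposited literature corpus is an external download, every
stage is validated against generated corpora with known ground truth. The
generator draws canonical values from configurable true priors — defaulting
to the reference specifications in `default_true_priors()` — and then
*inverts* the canonicalization per article according to sampled reporting
conventions. The default conditions are chosen to resemble the published
literature:

| setting | default | rationale |
|---|---|---|
| `n_articles` | 100 | order of magnitude of the published corpus |
| `conditions_per_study` | 2–4 | typical factorial designs |
| `fraction_s01` | 0.4 | DMAT plus the $s = 0.1$ lab tradition are a large minority |
| `fraction_ms` | 0.10 | all-milliseconds articles are rare |
| `fraction_ter_ms_only` | 0.15 | the mixed dialect is the more common anomaly |
| `fraction_individual` | 0.05 | individual estimates are reported by few studies |
| `fraction_absolute_z` | 0.3 | absolute vs relative starting point both common |
| `fraction_response_coded` | 0.2 | signed drifts appear regularly |
| `constrained_kinds` | $T_{er}$, $s_v$, $s_{z_r}$, $s_{T_{er}}$ | variability parameters and $T_{er}$ are the usual constraints |
| `outlier_rate`, `outlier_scale` | 0.02, 3 | minimal multiplicative contamination producing the heavy tails that motivate mixtures |

Bias is drawn with a random direction per study so mirroring is exercised
nontrivially. The generator emulates reporting *conventions*, not
everything real corpora contain: no typographic errors, no digitization
noise from figure extraction, no correlation between parameters within a
study, and contamination is a single multiplicative mechanism. Passing
round-trip and recovery tests therefore validates the transform algebra and
the fitting machinery, not the field's reporting quality.

With `outlier_rate = 0` the full pipeline inverts the generator exactly
(discrepancy below $10^{-9}$; observed at machine precision), and the unit
rules sit far from their thresholds ($T_{er}$ near 0.44 s vs 440 ms against
a threshold of 5), so unit recovery across seeds exceeds 99%.

# What the tests compute, at what sizes

The suite fits single families to $10^4$ draws (20 seeded replications,
5% relative recovery), checks density normalization by quadrature to
$10^{-6}$, verifies truncated densities against an independent
quadrature-renormalization oracle to $10^{-9}$, and runs the full pipeline
on a 200-article corpus (about 600 pooled values for the free kinds, 200
for the constrained ones) asking the generating family — or a mixture
dominated by it — to win the Akaike comparison for at least 6 of 7 kinds.
These sizes keep the whole suite in the minutes range on one CPU.

A known limitation surfaces in that last check. Samples from a narrow,
heavy-tailed truncated-$t$ (e.g. $T_{er}$: scale 0.08, $df$ 1.32) are
often better characterized, *by AIC*, by a two-component normal mixture
than by the generating $t$ — even on pure $t$ data at $n = 5000$, and even
though the fitted $t$ sits at its global optimum (checked against the
likelihood at the true parameters). The reason is structural: the $t$'s
expected likelihood advantage over a narrow-plus-wide normal mixture is
concentrated in ultra-extreme draws, many tens of scale units out, that
usually do not materialize in a finite sample; absent them, the flexible
5-parameter mixture wins the realized comparison and the 4-point AIC
penalty does not close the gap. Among *single* families the $t$ wins
decisively with accurately recovered parameters. Consequently the
family-recovery count on a 200-article corpus depends on the seed (typical
values 4–6 of 7), with misses concentrated in $t$-vs-normal(-mixture)
confusions; users interpreting a selected mixture should read its dominant
component, whose location and scale track the generating density closely
in all these cases.

# Prior-predictive simulation

`prior_predictive_rt()` propagates parameter draws through an Euler
discretization of the accumulation process (increments
$\mathcal{N}(v\,dt,\, s^2 dt)$ from $z_r a$ until absorption at 0 or $a$,
plus $T_{er}$), with `dt = 1e-4` s by default and discretization bias of
order `dt`. It is a sanity tool for inspecting what a prior implies about
behavior — mean RT, accuracy, RT quantiles — not a fitting engine. In the
noiseless limit it reproduces $T_{er} + (a-z)/v$ exactly, and with noise it
matches the closed-form Wiener mean first-passage time within Monte-Carlo
error (both are tested).

# Design choices that were genuinely open

* **Stage order** is not dictated by the transforms themselves beyond the
  constraints above; the implemented order is the one that keeps every
  rule operating on the scale it was designed for.
* **Dedup representative**: the first row in (article, study, condition)
  order, after sorting — reproducible regardless of file row order.
* **$z$ without a matching $a$** in the same study/condition cannot be
  converted to bias ($z_r$ is only defined relative to $a$) and is
  excluded, logged.
* **Unknown-resolution order for $s$** ends at an optional user-supplied
  per-article rule rather than a hard-coded author heuristic: the corpus
  schema carries no author field, so lab-convention knowledge enters as
  data (`author_rules`), not code.
* **Equal weighting** of pooled estimates is deliberate: the uncertainty
  information needed for precision weighting is almost never reported, and
  sample size trades off against trials per participant in a way that
  makes equal weights defensible.
* **Minimum pool size 10** before fitting is attempted; below that the
  row is reported rather than fitted.

# Limitations

Univariate priors ignore the (likely substantial) correlations between
parameters across participants and studies; nothing here models
between-study heterogeneity hierarchically; and the mirrored bias prior
deliberately overstates variability relative to a task-specific analysis
in which directions can be reconciled. Task- and population-specific
pooling (`task =`, `population =` filters) is supported and reduces prior
spread when enough tagged estimates exist, but the package does not decide
when a subset is "enough" beyond the minimum-pool rule.
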