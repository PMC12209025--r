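---
title: "Novel exploration growth: models, simulation and decision rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Novel exploration growth: models, simulation and decision rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measure

The elevated plus maze (EPM) reads a rodent's anxiety-like behaviour
(ALB) off the conflict between exploring the exposed open arms and
sheltering in the walled closed arms.  The conventional outcomes —
latency to first open-arm entry, number of open-arm entries, time in the
open arms — are temporally and spatially coarse: an early shallow peek
scores "less anxious" than a later, committed exploration.

Novel exploration growth (NEG) replaces them with one spatio-temporal
curve.  Each arm is divided along its length into segments of
`grid_resolution` cm (1 cm by default) spanning the full arm width; the
square centre zone holds no segments and is excluded from every
calculation, because animals are placed there.  The first visit to a
segment is *naive exploration* and increments the curve; any revisit is
*informed preferencing* and does not.  NEG at time $t$ for a scope $S$
(open arms, closed arms, or the whole maze) is

$$\mathrm{NEG}_S(t) = 100 \cdot \frac{|\{ \text{segments of } S \text{ first visited by } t \}|}{|S|}.$$

Flat spells therefore read as avoidance (or preferencing elsewhere),
growth spells as exploration, and the composite identity
$\mathrm{NEG}_{total}\cdot|S_{total}| = \mathrm{NEG}_{open}\cdot|S_{open}| +
\mathrm{NEG}_{closed}\cdot|S_{closed}|$ holds at every second.  If the
closed arms are fully explored while half of the equally sized open
scope has been visited, total NEG is 75%.

## Discretisation choices

* Depth intervals are half-open $[d, d+\mathrm{res})$ with the final
  interval closed at the arm tip, so segment assignment is a total,
  unambiguous function; the centre square takes precedence on its
  boundary.
* Frames are binned into 1-s windows starting at the first tracking
  sample; a segment is visited in second $k$ if any frame or
  interpolated path point in $[k, k+1)$ touches it.
* Linear interpolation between consecutive samples further apart than
  one grid unit is on by default: at 25 frames/s a rat moving faster
  than ~25 cm/s skips segments, and samples above that (configurable)
  speed are flagged in a warning.  Position is genuinely under-resolved
  at such speeds; the package mitigates, but cannot remove, that
  limitation of point tracking.
* Open-arm *entries* are counted at frame level as every ingress into an
  open-arm segment from a non-open zone, so a full exploration of both
  open arms through the centre counts two entries.  Open-arm *time*
  uses the modal zone per second (ties resolved toward the previous
  second).  Latency is the first second whose occupancy contains an
  open-arm segment, or the test duration if none does.

## Simulated phenotypes

Three behavioural phenotypes define the study conditions.  Each arm
type's expected curve is a zero-anchored logistic,
$\mu(t) = A\,(F(t) - F(0))/(1 - F(0))$ with
$F(t) = (1 + e^{-k(t - t_0)})^{-1}$, anchored because nothing has been
explored at placement.  Defaults (300-s test):

| phenotype   | closed arms              | open arms                  |
|-------------|--------------------------|----------------------------|
| exploratory | $k=0.1$/s, $t_0=30$ s    | same distribution as closed |
| delayed     | $k=0.1$/s, $t_0=30$ s    | $k=0.1$/s, $t_0=150$ s (test mid-point) |
| avoidant    | $k=0.1$/s, $t_0=30$ s    | $k = t_0 = 0$: identically zero |

Between-subject variability draws each subject's $k$ and $t_0$ from
truncated Gaussians with sd 0.02/s and 15 s — a spread that keeps
individual curves recognisably phenotypical while making cohorts of ten
animals realistically heterogeneous.  These values, and the
conventional-measure distributions below, are package defaults chosen
once to reproduce the qualitative study design; they are not published
estimates, and all are exposed in the configuration.

Noise enters as a *binomial first-visit hazard*: in each second every
still-unvisited segment is first visited with probability
$q_t = (\mu_t - \mu_{t-1})/(n - \mu_{t-1})$, so the count path is
monotone by construction and its expectation equals $\mu(t)$ exactly.
(A running maximum over independent binomial draws around $\mu(t)$ —
the obvious alternative — is biased upward and was rejected for
breaking mean-correctness.)

Conventional measures are drawn from Gaussians truncated to
$[0, 300]$ s by inverse-CDF sampling, 1000 repetitions per phenotype:
latency 30 ± 20 s (exploratory), 160 ± 30 s (delayed), pinned at 300 s
(avoidant); entries 8 ± 3 and open-arm time 90 ± 30 s shared by
exploratory and delayed, identically zero for avoidant.  Only latency
separates exploratory from delayed — the designed contradiction among
the conventional measures.

`simulate_trajectory()` converts per-arm curves into coordinates.  It
schedules each arm-type block at its curve onset; within a block the
animal enters arm 1, reaches each newly scheduled segment on time
(idling at the frontier otherwise), crosses through the centre and
completes arm 2 — the full-exploration-then-exit heuristic, which makes
exactly two open-arm entries for any fully explored open pair.
Crossing between arms blacks out roughly $\tau = (\ell + c)/v$ seconds
of schedule (arm length $\ell$, centre size $c$, speed $v$), so the
generator banks about $r\tau/2$ segments around the crossing (peak
demand $r = Ak/4$ segments/s); round-trip fidelity within ~2 segments
therefore needs $v \gtrsim r(\ell + c)/4$, and schedules that slip
further than `max_lag` raise a generation error.  Because one animal
cannot grow two arm-type curves at the same instant, phenotypes with
overlapping phases (exploratory) are serialised: the trajectory mode is
exact for separated or single phases, and the `"heuristic"` policy
reproduces only the conventional-measure behaviour.

## Change-point phase models

Whether exploration happened in one phase or two is decided by Bayesian
sigmoid change-point regression on the NEG series.  The mean curve is a
sum of one or two zero-anchored logistics with total amplitude at most
100%; the dual-phase model parameterises the second inflexion as
$t_{02} = t_{01} + \delta,\ \delta > 0$, which enforces ordering and
removes the label switching that plagues unconstrained multi-sigmoid
fits.

Observations are modelled by default with the *conditionally binomial
increment* likelihood: over any interval $(s, t]$, the count of newly
visited segments among the $n - K_s$ still unvisited is binomial with
the hazard $(M_t - M_s)/(n - M_s)$ implied by the mean curve.  This is
the exact likelihood of the first-visit process: bounded by
construction, invariant under time thinning, and factorising over
increments, which makes pointwise log-likelihoods for LOO well defined.
Under simulated data its 95% HDIs cover the generating $(k, t_0)$ at
nominal rates, whereas a logit-normal curve model (retained as an
option for non-count data) is badly over-confident on monotone count
series — plateau observations drive its noise scale toward zero.

Priors: amplitudes uniform on the admissible range, inflexions uniform
on $[0, \text{duration}]$, $\log k \sim N(\log 0.05, 1.6^2)$ — a rate
scale spanning rise times from seconds to the whole test, checked by a
prior predictive that flags absurd rates (10–90% rise under 2 s).
Sampling uses JAGS with 4 chains and 1000 warmup + 1000 kept draws by
default; fits pass diagnostics only when every Rhat lies in
$[0.9, 1.1]$, every effective sample size exceeds 1000, and the
posterior predictive envelope covers at least 80% of the observed
series.  JAGS samplers have no divergence diagnostic; failure is
expressed through this gate.

Group-level fits *stack* all subjects' observations (the default of
`pool_neg()`) rather than averaging them: the mean of subject sigmoids
with spread inflexions is not itself a sigmoid, and fitting the
averaged curve with its tiny apparent noise makes the dual-phase model
win spuriously for every phenotype.  Stacked fits recover the expected
pattern — single phase for exploratory and avoidant, dual for delayed.

Model selection uses PSIS-LOO (implemented in the package: importance
ratios smoothed by a generalised Pareto tail fitted with the
Zhang–Stephens profile posterior, cross-checked against exact
leave-one-out refits).  The higher elpd_loo wins; differences within
$\max(4,\ 2\,\mathrm{SE})$ — the usual negligibility guidance for
elpd differences — count as equivalent, and the most parsimonious of
the equivalent set is selected.

## Effects over time and equivalence decisions

Effects of phenotype (and of arm type within phenotype) on NEG are
estimated from visited-count data with binomial-logit models carrying
subject random intercepts, fitted with `mgcv` under a quasibinomial
family; posterior coefficient draws come from the Gaussian
approximation $N(\hat\beta, V_p)$, the Bayesian reading of the
penalised fit.  When the change-point stage found every relevant series
single-phase, the mean structure is parametric group × time (a single
logistic phase is linear on the logit scale); if any series is
multiphase, each group gets a thin-plate smooth of time (basis size 10,
configurable — basis choice genuinely affects fit and interpretation).
Groups that never explore a scope (avoidant open arms) give divergent
logits with unbounded variance, so counts carry a Haldane–Anscombe
+0.5 continuity correction.

Contrasts are evaluated on a 1-s grid as differences of the
inverse-linked group curves, marginal over subjects (random intercepts
excluded, the usual marginal-effect convention).  Each timepoint is
summarised in the SeXiT style: posterior median, 95% HDI, probability
of direction, and the fraction of the posterior inside the region of
practical equivalence.  For growth models the ROPE is ±0.18 on the
proportion scale — ±18 NEG percentage points, the ROPE band drawn in
the package's effect plots; for conventional measures it is
$\pm 0.1\,\mathrm{SD}_y$.  More than 97.5% of posterior mass inside the
ROPE declares the effect equivalent to zero, less than 2.5% declares it
not equivalent, anything between is undecided — an exact three-way
partition.  `decision_landmarks()` extracts the onset of significance,
the return to equivalence, and time spent per state.

Conventional measures are analysed with Bayesian linear regression
(conjugate normal–inverse-$\chi^2$ posterior under the reference
prior), pairwise phenotype contrasts summarised the same way.  With the
default distributions this reproduces the designed pattern: avoidant
differs from both other phenotypes on all three measures; delayed and
exploratory differ only in latency.

## Phenotype classification and ALB grading

`classify_phenotype()` maps the fitted evidence to a label: open-arm
NEG never exceeding 5% (configurable) means no open-arm exploration —
avoidant, graded maximal ALB; a dual-phase total-maze selection with
open exploration confined to the later phase means delayed; open
exploration in the first phase means exploratory.  A dual-phase
selection whose arm contrast never leaves equivalence is conflicting
evidence and returns an undecided call.  Within the exploratory band
(low to moderately-low) and the delayed band (moderately-low to
moderately-high) the grade is refined by the end-of-test depth gap
between closed- and open-arm NEG, with cutpoints at 25/50/75 percentage
points; the gap mapping is monotone, so deeper open-arm exploration
never raises the grade.  The cutpoints are package defaults — the
ordering of the bands is the fixed part, the boundaries are not
published values.

## Problem sizes, tolerances, degenerate inputs

Simulation studies in the package's tests use cohorts of 10 subjects
per phenotype, 300-s tests on the default 50-cm/1-cm geometry, 20
seeded replicates for the selection-accuracy, HDI-coverage and
classifier checks, and thinned (5–10-s) time grids for the MCMC fits —
time thinning is exact under the increment likelihood, and these sizes
keep the full suite in a few minutes without changing any conclusion.
Equivalence-timeline checks assert the qualitative ordering of the
landmarks; with cohorts of ten and marginal (population-level)
contrasts the posterior is tight, so onset/return times fall somewhat
earlier than they would under wider, subject-predictive posteriors —
an inference-population choice documented here deliberately.

Degenerate inputs are handled explicitly: empty tracks and non-monotone
or out-of-range NEG series are errors; flat all-zero series fit with
amplitude near zero; saturated increments (no unvisited segments)
carry no information and are dropped from the likelihood; a zero `sd_y`
is rejected when building the linear ROPE; exact decision ties report a
probability of direction of 0.5.

## Known limitations

The trajectory generator serialises overlapping arm-type phases; the
binomial increment model assumes exchangeable segments within a scope
(no spatial gradient of hazard along an arm) and, like the effect
models, treats counts as conditionally binomial — real data with
extra-binomial variation would need an overdispersed extension.  The
effect models carry subject random intercepts only.  Automatic zone
estimation from raw tracking values (clustering) is not implemented;
zones come from the configured geometry.  Multi-point (head) tracking,
secondary behaviours and non-plus-maze arenas are out of scope.
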