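---
title: "Estimating hidden-population prevalence from chain-referral samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating hidden-population prevalence from chain-referral samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdsprev)
```

## The problem

Populations defined by stigmatized behaviour — here, illegal drug use among
regular tobacco and alcohol users — have no sampling frame. Respondent-driven
sampling (RDS) reaches them through their own social ties: a handful of
*seeds* are interviewed and each respondent receives up to five referral
coupons for acquaintances who meet the eligibility criteria. The referral
chains grow wave by wave; each participant's position is recorded by a
referral code such as `F001-1100000000` (seed `F001`, second wave). The
resulting sample is not a random draw — well-connected people and people
whose friends resemble them are over-represented — so the raw (crude) sample
proportion is a biased prevalence estimate. This package implements the
machinery that corrects for that: the recruitment Markov chain, its
equilibrium, degree weighting, a chain-respecting bootstrap, and the
convergence diagnostics, together with a synthetic generator of the whole
field procedure.

## The model

Write \(S_{ab}\) for the probability that a recruiter in group \(a\) (say,
ketamine users) recruits someone in group \(b\). Under the RDS assumption
that referral probabilities depend only on the recruiter's group, the group
labels along a referral chain form a Markov chain with transition matrix
\(S\), estimated by row-normalizing the observed recruiter-to-recruit pair
counts (seeds recruit but are never recruits). After enough waves the chain
forgets its seeds and the sample composition approaches the stationary vector
\(\pi\) with \(\pi S = \pi\): the *equilibrium proportion*.

Equilibrium composition still over-counts well-connected groups, because a
random walk visits a node proportionally to its degree. With \(\hat D_g\)
the harmonic ("multiplicity") mean of reported network degrees in group
\(g\), \(\hat D_g = n_g / \sum_{i \in g} 1/d_i\), the *RDS-adjusted*
prevalence is

\[
\hat P_g \;=\; \frac{\pi_g / \hat D_g}{\sum_h \pi_h / \hat D_h},
\]

the reciprocity (RDS-I) estimator. For two groups this reduces to
\(\hat P_A = S_{BA}\hat D_B / (S_{AB}\hat D_A + S_{BA}\hat D_B)\), an
identity the test suite verifies on random instances; with equal degrees it
collapses to \(\pi\). The harmonic mean is the canonical choice because the
inclusion weight of an individual is proportional to its degree, so the
group weight is the harmonic mean of individual weights; an arithmetic mean
is available behind `mean_type = "arithmetic"` for sensitivity analysis.

Standard errors come from a dependent bootstrap: each replicate regrows a
pseudo-sample of the original size by Markov draws from the observed recruit
pools conditional on the recruiter's group, then re-runs the full estimator
(its own transition counts and degree means). Percentile 2.5/97.5 bounds
give the 95% interval. Contrasts between strata use the Wald statistic
\(z = (p_1 - p_2)/\sqrt{se_1^2 + se_2^2}\), reported unadjusted for
multiplicity (one test per table row), and stratified results are summarized
by the prevalence ratio rounded half away from zero to one decimal, the
convention of printed epidemiological tables.

## Equilibrium diagnostics

Two diagnostics assess whether the chains ran long enough. The *cumulative
trace* plots, for each wave \(w\), the trait proportion among all
participants recruited at waves \(\le w\); it is declared converged at the
smallest wave from which every adjacent-wave difference stays below the
tolerance (`detect_equilibrium`). "Stays below" is deliberate: the rule asks
for *consistently* small discrepancies, not a first crossing, so a late
excursion pushes the detected wave past it. The *recursion* diagnostic
(`waves_to_equilibrium`) iterates the seed composition through \(\hat S\)
and counts the waves until every group is within tolerance of \(\pi\). The
default tolerance is 0.02 (the 2% working rule); 0.05, the classic RDSAT
default, is a common looser choice. Both diagnostics are monotone in the
tolerance, which the property tests check.

## What the synthetic generator emulates

Because field data of this kind are confidential, the package ships a
simulator of the whole design, and the default scenario
(`scenario_default()`) encodes the emulated study: 47 seeds (35 community,
12 hospital drug-rehabilitation, the latter oversampling hard-drug users),
referral of up to five friends with most respondents passing on one to
three coupons, about eight recruitment waves, and four yearly rounds
targeting 144/328/350/293 participants — 1115 in total — drawn from the same
population and pooled, mirroring the repeated yearly implementation of the
emulated survey.

The population is a degree-corrected block model over
user/non-user × onset-stratum blocks: members get a log-normal degree
weight (meanlog `log(10) - 0.32`, sdlog 0.8, mean degree ≈ 10 — the true
degree distribution of such populations is unreported, so this is an
assumption, not a fact), ties are sampled by a fast weighted Chung–Lu
scheme with within-block odds multipliers (`homophily_user_odds`, default
2; `homophily_stratum_odds`, default 1.3), and drug users' weights are
multiplied by `degree_user_multiplier` (default 1.3) to reflect their
denser substance-using networks. Homophily slightly reskews realized
degrees relative to the weights; this is harmless because the estimator
consumes *realized* degrees. Traits are drawn hierarchically — onset
stratum (early with probability 0.58), any-drug use conditional on stratum
(0.318 early / 0.152 late), individual drugs conditional on being a user,
past-year use conditional on lifetime — with magnitudes chosen to match
the stratified composition of the emulated study's published tables.
Recruitment is a random walk without replacement: uniform choice among
eligible unrecruited neighbours, a coupon count drawn from a distribution
over 0–5 with mode 1–3, stopping at the wave cap or the round target. A
`recruit_preference` parameter lets users preferentially refer non-users,
reproducing the masking bias (crude prevalence pulled downward) discussed
in the RDS literature.

What the generator does **not** emulate: refusal and non-response,
incentive effects, temporal drift across the four years (rounds are
exchangeable draws from one fixed population), reporting error in traits,
and geographic structure. Passing tests on synthetic data therefore
demonstrate the correctness and calibration of the estimation machinery
under the model's assumptions — not that those assumptions hold in any
particular field sample.

## Numerical and design choices

* **Zero recruitment rows.** A group that never recruited has an undefined
  transition row; the default policy spreads it uniformly (a self-loop
  variant exists), and the affected groups are always reported, never
  silently patched. A chain whose support has several closed communicating
  classes (e.g. perfectly assortative recruitment) has no unique stationary
  vector and raises a degeneracy error naming the absorbing classes.
* **Stationary solve.** \(\pi\) is obtained from the linear system
  \(\pi(S - I) = 0,\ \sum\pi = 1\) via QR, not power iteration, so periodic
  but irreducible chains are handled; the test suite checks the result
  against brute-force matrix powering.
* **Seeds in denominators.** Proportions include seeds; the transition
  matrix never counts a seed as a recruit. Whether the original analyses
  did likewise is not documented; both facts are stated here so the choice
  is explicit.
* **Transition smoothing.** Reciprocity smoothing
  (\(c^*_{ab} = c^*_{ba} = (c_{ab}+c_{ba})/2\)) is implemented but off by
  default, since whether it was active in the emulated analysis is unknown.
* **Bootstrap details.** Replicate chains start from a uniformly chosen
  observed recruit; an empty recruit pool triggers a logged restart draw
  and that non-conditional step is excluded from the replicate's transition
  counts. B defaults to 1000; all replicates come from one seeded RNG
  stream, so results are bit-reproducible given a seed.
* **Degrees of 0 or missing** are retained in proportions but excluded
  from degree means, with the exclusion counted and surfaced.
* **Stratified estimation** uses the induced subforest of each stratum;
  a recruit whose recruiter sits in the other stratum becomes a
  pseudo-root. The alternative (dropping cross-stratum edges' recruits
  entirely) discards data for no clear benefit.
* **Referral-code dialect.** The published coding shows only first-recruit
  chains (`F001-1100000000`); digit positions here carry the recruit's
  sibling index 1–5, which keeps codes unique and encodes the full tree
  path while remaining consistent with the published examples. Ten digit
  positions bound the representable depth at 10 waves; simulated runs with
  a deeper wave cap widen the digit field.
* **Use patterns.** `single`, `poly_no_hard` and `poly_hard` are mutually
  exclusive and exhaustive over users, with all participants of the
  stratum as the denominator. The emulated study's printed pattern cells
  do not sum consistently under any single denominator convention, so this
  package documents its own convention rather than reverse-engineering
  the published one.

## Problem sizes used in the shipped checks

The test suite exercises parameter recovery on 200 simulated surveys of
n = 1000 (population 10 000, true prevalence 0.20, users' degrees doubled,
homophily odds 3): the adjusted estimator's mean lands within 0.02 of the
truth while the crude estimate is biased upward by more than 0.03.
Bootstrap calibration uses 500 surveys of n = 300 with B = 200 in the
neutral regime (no homophily, trait-independent degrees) — deliberately,
because coverage there isolates the bootstrap's variance estimate from
estimator bias; coverage must fall in 92–98%. Chain-bootstrap intervals
are known to undercover when strong homophily biases the point estimate,
which is a property of the estimator, not of the interval machinery.

## Limitations

RDS-I inherits the with-replacement random-walk assumptions; at large
sample fractions the without-replacement field process deflates true
variance relative to the bootstrap. Successive-sampling estimators
(Volz–Heckathorn RDS-II, Gile's SS) are out of scope for this version.
P-values are unadjusted for multiplicity. The simulator's block-model
homophily is a coarse summary of real network clustering.
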