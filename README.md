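# rdsprev

Prevalence estimation for hidden populations sampled by chain referral
(respondent-driven sampling, RDS).

Populations such as illegal drug users among regular tobacco and alcohol
users have no sampling frame. RDS surveys reach them through their social
ties: seed participants each refer up to five eligible acquaintances, who
refer others in turn, and every participant's chain position is recorded by
a referral code (`F001-1100000000` = seed `F001`, second wave). The raw
sample over-represents well-connected and homophilous groups, so `rdsprev`
implements the estimator family that corrects for this:

* the recruitment **transition matrix** `S` — group-to-group referral
  probabilities, treated as a Markov chain over recruiter→recruit pairs;
* its **equilibrium** (stationary) composition `π`, with `πS = π`;
* the degree-weighted **RDS-adjusted** prevalence (reciprocity / RDS-I
  estimator), with `D̂_g` the harmonic-mean reported degree of group `g`:

  ```
  P̂_g = (π_g / D̂_g) / Σ_h (π_h / D̂_h)
  ```

* a **dependent chain bootstrap** for standard errors and 95% percentile
  intervals, Wald contrasts between strata, and printed-table prevalence
  ratios;
* **equilibrium diagnostics**: cumulative per-wave trait proportions and
  the waves-to-equilibrium recursion, both under the 2% adjacent-wave rule;
* a **synthetic generator** of the whole field procedure (block-model
  population with homophily and trait-dependent degrees, seed sources,
  coupon counts, wave caps, yearly rounds), so every estimator is testable
  without confidential field data.

## Worked example

Simulate the default study design — 47 seeds (35 community, 12 hospital),
four yearly rounds totalling 1115 participants, at most 8 waves — and fit
the estimators for lifetime ketamine use:

```r
library(rdsprev)
cfg <- scenario_default()
sim <- simulate_study(cfg, seed = 7)
sim$forest
#> Recruitment forest: 1115 participants, 47 seeds, 1068 referral edges, max wave 5

fit <- rds_estimate(sim$forest, "trait:ketamine:lifetime", B = 500, seed = 7)
fit
#> RDS prevalence fit for 'trait:ketamine:lifetime' (n = 1115, 1068 referral pairs)
#>
#>                    trait    group         kind proportion n_contributing     se  ci_lo  ci_hi
#>  trait:ketamine:lifetime     user        crude     0.1659            185 0.0121 0.1381 0.1857
#>  trait:ketamine:lifetime non-user        crude     0.8341            930 0.0121 0.8143 0.8619
#>  trait:ketamine:lifetime     user  equilibrium     0.1622            185 0.0122 0.1382 0.1858
#>  trait:ketamine:lifetime non-user  equilibrium     0.8378            930 0.0122 0.8142 0.8618
#>  trait:ketamine:lifetime     user rds_adjusted     0.1733            185 0.0183 0.1337 0.2048
#>  trait:ketamine:lifetime non-user rds_adjusted     0.8267            930 0.0183 0.7952 0.8663
#>
#> Waves to equilibrium from seed composition: 0
```

Reading the output: 185 of 1115 sampled participants reported lifetime
ketamine use (crude 16.6%). The equilibrium estimate (16.2%) is what the
recruitment chain converges to regardless of the seeds; the RDS-adjusted
estimate (17.3%, 95% CI 13.4–20.5%) additionally down-weights
well-connected groups by their harmonic-mean degree and is the headline
prevalence. The seed composition here already matches the equilibrium, so
zero further waves were needed — the chains ran long enough.

`run_analysis()` scales this up to every drug, composite (any illegal /
club / hard drug) and use pattern, each window (lifetime, past-year),
overall and stratified by tobacco-onset age with early/late prevalence
ratios and Wald contrasts; `write_report()` persists the tables.
`plot(fit)` draws the cumulative wave trace.

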