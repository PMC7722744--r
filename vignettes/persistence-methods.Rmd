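---
title: "Assessing the persistence of circadian call-activity rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the persistence of circadian call-activity rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callrhythm)
```

## The question and the model

A person's telephone activity follows a daily cycle: almost no calls
overnight, characteristic peaks at individually preferred hours. `callrhythm`
asks, for each individual in a population of call detail records (CDRs),
whether that daily pattern is *persistent* — maintained across successive
observation periods with a distinctiveness that separates it from the rest of
the population — and attaches an exact p-value to the answer.

The procedure treats the rhythm of individual $i$ in period $T_k$ as a
24-bin empirical probability distribution over hour-of-day,
$f_i(t) = n_i(t) / \sum_{t=0}^{23} n_i(t)$. Two distributions are compared
with the square-root Jensen–Shannon divergence
$d(P, Q) = \sqrt{\tfrac12 KL(P \| M) + \tfrac12 KL(Q \| M)}$,
$M = (P+Q)/2$, a metric bounded in $[0,1]$ with base-2 logarithms. The
intra-individual dissimilarity $y_i = d(P_i^{T_1}, P_i^{T_2})$ is ranked
against the $2n-2$ inter-individual dissimilarities
$x_{i,j}^{T_k} = d(P_i^{T_k}, P_j^{T_k})$, $j \ne i$, $k \in \{1,2\}$: each
comparison is a success when $x < y_i$ strictly, and under the null
hypothesis that a success has probability $q$ the success count
$N_i^+$ is $\mathrm{Binomial}(2n-2,\, q)$. The reported p-value is the exact
lower tail $P(X \le N_i^+)$: persistence shows as *few* successes. With
$q = 1/2$ (the default, a median test) and $n = 26$, the smallest attainable
p-value is $0.5^{50} \approx 8.9\times10^{-16}$.

For $N_T > 2$ periods, each consecutive pair is tested at level $\alpha$ and
the binary outcomes form $v \in \{0,1\}^{N_T-1}$; a second exact sign test —
upper tail of $\mathrm{Binomial}(N_T-1, 1/2)$ at $\sum v$ — asks whether
persistent pairs dominate. Short sequences have little power by construction:
$v = (1,1,1)$ gives $p = 0.125$, and at $\alpha = 0.05$ a fully persistent
sequence is only significant from $N_T \ge 6$ periods
($0.5^{N_T-1} < 0.05$).

## Parameters that matter

* `q` (unitless, default 0.5): the null success probability. 0.5 makes the
  test a median test on the reference sample of dissimilarities; no other
  value has an established interpretation here, and the default is used
  throughout.
* `alpha` (default 0.05): per-individual significance level. Results are
  reported per individual without multiplicity correction by default,
  mirroring per-individual reporting practice; `adjust = "BH"` switches the
  verdict column to Benjamini–Hochberg-adjusted p-values within a mode.
* `base` (default 2): logarithm base of the divergence. The choice only
  rescales all dissimilarities by a common factor, so $z_i$, $N_i^+$ and the
  p-value are invariant to it (this is property-tested); base 2 is the
  default because it bounds the distance in $[0,1]$.
* Direction mode (`outgoing`, `incoming`, `total`): the three analyses are
  run separately, since the social meaning of placing versus receiving calls
  differs and the published behavior of the test can differ by mode.

## Conventions and numerical choices

* **Half-open intervals everywhere.** Periods are $[\mathrm{start},
  \mathrm{end})$ and hour slots are $[h, h+1)$ (floor of the timestamp's
  hour), so boundary instants are assigned unambiguously.
* **Local civil time.** Timestamps are used exactly as recorded, with no
  time-zone or DST normalization: CDR hours are provider-local and the hour
  label is what carries the circadian signal.
* **Raw empirical fractions.** No smoothing and no pseudo-counts. KL terms
  with $p(t) = 0$ contribute zero; bins where both rhythms are zero are
  skipped (there $M(t) = 0$ too). Distributions are validated to sum to 1
  within $10^{-6}$ on input; computed rhythms sum to 1 within $10^{-12}$.
* **Exact tails.** Binomial tails are summed term by term in log space
  (`lchoose`), never approximated; the test suite checks agreement with
  direct pmf summation for every $N^+ \le N_{comp} \le 64$.
* **Ties are failures.** The success indicator is the strict
  $1\{y_i - x > 0\}$, which is conservative for declaring persistence.
  Exact ties essentially occur only with degenerate (point-mass) rhythms.
* **Degenerate inputs.** An individual with zero calls in some period has no
  defined rhythm there and is excluded from that direction mode *entirely* —
  as focal individual and as comparator — so the two periods' reference
  samples stay balanced and $N_{comp}$ shrinks to $2(n_{incl})-2$. Zero-
  duration calls (e.g. missed calls) are retained: the event and its hour,
  not its length, define the rhythm.

## The synthetic-data generator

`generate_dataset()` emulates the study design the method targets: 26
individuals, two 182-day periods (a 12-month window halved), and a few
hundred calls per individual per period. Each individual draws a base hourly
profile from a Dirichlet law with parameter
`profile_concentration * 24 * template`, where the template is a fixed
diurnal shape with very little overnight mass; the defaults
(`profile_concentration = 5`, `mean_calls_per_period = 300`) produce
individually distinctive but realistic rhythms and Poisson call volumes.
Calls then sample hours from the profile, dates uniformly within the period,
and direction as a fair coin. A fraction `drift_fraction` (default 0.15) of
individuals are non-persistent: at each period change their profile moves
toward a freshly drawn one with weight `drift_strength`. The default
`drift_strength = 1` is a complete redraw — the cleanest "not persistent"
ground truth, and the natural null when applied to everyone.

What the generator does *not* emulate: weekday/weekend structure, bursty
within-hour autocorrelation, social-network structure among peers, and
seasonal volume trends. Passing recovery tests on this generator therefore
shows that the statistic detects stable-versus-redrawn multinomial rhythms
at realistic volumes; it does not certify behavior on real CDRs, whose
dependence structure is richer.

Simulation sizes in the test suite and acceptance script (26 individuals,
20 replicates, one direction mode for the stochastic checks) were chosen to
give at least 500 individual-replicates per rate estimate, keeping the
Monte-Carlo standard error of a rate near 0.01.

## Calibration: a known limitation

The binomial null treats the $2n-2$ comparisons as independent, but they all
share the same $y_i$. The package quantifies the consequence with a null
simulation (`drift_fraction = 1, drift_strength = 1`: every profile redrawn
independently each period, so nobody is truly persistent). Under this null
the empirical rate of $p < 0.05$ is far above 0.05 — around 0.3–0.4 in the
packaged calibration check — rather than near the nominal level. The reason
is structural: with fully exchangeable profiles, $F_i(y_i)$ (the fraction of
the reference distribution below $y_i$) is uniformly distributed, so
$N_i^+ \approx (2n-2) \cdot U$ with $U \sim \mathrm{Uniform}(0,1)$, and the
lower-tail test rejects whenever $U$ lands below the critical quantile
($\approx 0.37$ for $N_{comp} = 50$), not with probability 0.05. The
corresponding check in the test suite is left failing by design: it measures
the method as defined, and the inflation is a property of the statistic, not
of the implementation. Practically, a significant result should be read as
"$y_i$ sits in the lower tail of the reference dissimilarities", and very
small p-values (e.g. $N^+ = 0$, $p \approx 9\times10^{-16}$) remain far more
convincing than ones near $\alpha$; cross-individual error control should
not be taken at face value from the nominal level.

## Other open choices made here

* **Tail sidedness.** The pairwise test is one-sided lower-tail: published
  result tables of this procedure are only consistent with
  $P(X \le N^+)$ (e.g. $N^+ = 0 \mapsto 0.5^{50}$ and
  $N^+ = 31 \mapsto 0.968$ at $N_{comp} = 50$), and persistence is a
  directional claim.
* **Sequence-test null.** The second-level sign test uses
  $\mathrm{Binomial}(N_T-1, 1/2)$, upper tail, mirroring the default $q$;
  the per-pair events are dependent through the shared population, so its
  p-value inherits the same caveat as above.
* **Pluggable dissimilarity.** `js_divergence()` / `rhythm_distance()` are
  the only measure implemented; the downstream test depends on the
  dissimilarities only through their ordering, so any strictly monotone
  transform of the measure leaves every verdict unchanged (tested).

## A minimal run

```{r example, eval = FALSE}
sim <- generate_dataset(simulation_config(n_individuals = 26, seed = 1))
res <- analyze_population(sim$records, simulation_partition(sim))
dplyr::filter(res, mode == "total")

rhythms <- daily_rhythms(assign_periods(sim$records, simulation_partition(sim)))
autoplot(rhythms, owners = c("A", "B"))
autoplot(assess_pair(rhythms, "A"))
```
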