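---
title: "Estimating pregnancy-related mortality from dual informant networks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pregnancy-related mortality from dual informant networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method in one page

Two village informant networks — neighbourhood-unit heads (RT) and health
volunteers (kaders) — independently list deaths of women of reproductive age
(WRA) over a defined reference window. Listings are deduplicated within each
network, matched across networks, and every likely pregnancy-related death
(PRD) receives a follow-up household visit that verifies whether it is an
*eligible* PRD (a confirmed death, pregnancy-related, inside the window and
study area). In villages covered by both networks, each verified eligible PRD
is known to have been captured by RT only, kader only, or both — the
sufficient statistic `(n_A, n_B, m)` of two-source capture–recapture. The
Lincoln–Petersen estimate `T = n_A n_B / m` then yields the stratum total and
the per-network capture probabilities `p_A = m/n_B`, `p_B = m/n_A`; strata
covered by kaders alone are scaled up by the dual-stratum kader capture
probability. Dividing by live births (fertility rates applied to census
population) gives the MMR.

Four assumptions carry the analysis: (1) a closed set of events; (2) correct
matching of deaths captured twice; (3) independence of the two networks'
captures; (4) homogeneous capture probability across deaths. The verification
visit is what makes (2) tenable in practice, and the simulator in this
package exists to quantify what happens when (2)–(4) fail.

## The Bayesian model

The source study reported a posterior mean and 95% interval for the combined
total but not its model. This package's model is the minimal hierarchy
consistent with the published logic (a kader capture probability shared
between strata):

* Dual stratum, total `N_d`: capture indicators are independent Bernoulli
  per network, so the observed cells (both, RT-only, kader-only) are
  multinomial conditional on capture by at least one network, and the number
  captured at all is `Binomial(N_d, 1 - (1-p_A)(1-p_B))`.
* Kader-only stratum, total `N_s`: the verified kader count is
  `Binomial(N_s, p_B)`, sharing `p_B` with the dual stratum. This sharing is
  exactly the extrapolation step, now with uncertainty attached.
* Priors: `p_A, p_B ~ Beta(1, 1)`; `N_d`, `N_s` discrete-uniform from the
  observed count to `cap_multiplier` (default 20) times it. The cap is a
  pragmatic bound on the prior support: at the study's counts the posterior
  mass near the cap is negligible, and doubling the multiplier moves the
  posterior mean by far less than the Monte-Carlo error.

`bayesian_total()` samples this posterior by Gibbs. Both conditionals are
exact: the capture probabilities are conjugate Beta updates, and the number
of uncaptured deaths `N - observed` has a negative-binomial conditional
(`size = observed + 1`), drawn with rejection at the prior cap. Four chains
of 15,000 post-warmup draws (the default) take about a second; a split-chain
scale-reduction diagnostic above 1.05 attaches a warning to the fit rather
than failing silently.

Because the Beta priors integrate out analytically, the joint posterior over
`(N_d, N_s)` is also available in closed form up to a finite sum;
`crc_grid_posterior()` evaluates it exactly. The test suite compares the
sampler's N-marginal (Rao-Blackwellized over the sampled capture
probabilities) against this grid in total variation on every dual
configuration with counts up to 8, and at the study scale. At the study's
counts the exact posterior mean of the combined total is ~629 with 95%
interval (565, 713): about 0.3% above the published 627 (560–711), a
discrepancy consistent with model-reconstruction uncertainty, which is why
the package documents the model rather than claiming fidelity to an
unpublished one.

One printed value required interpretation: the source table derives the kader
capture probability as "73/121" yet prints 0.71, while 73/121 = 0.60. The
package implements `p_kader = m / n_RT = 73/103 = 0.709`, the only reading
that reproduces both the printed 0.71 and the printed extrapolation
353/0.71 = 498 (which itself only reproduces with the *unrounded*
probability — `extrapolate_single_network()` therefore refuses to consume
pre-rounded inputs by taking the probability, not a two-decimal string).

## Record matching

The matcher is deliberately simple and transparent, sized for village-scale
listings (tens of records):

* **Blocking** by village: informants report within their own village, so
  cross-village candidates are never generated.
* **Score**: a weighted mean (name 0.5, age 0.25, date 0.25) of token-set
  name similarity (greedy best pairing of normalized tokens by edit-distance
  similarity, a fuzzy Dice coefficient), age proximity (full credit within 2
  years, linear to zero at 10) and date proximity (full credit within 30
  days, linear to zero at 365). A missing age or date contributes a neutral
  0.5 so incomplete forms are not penalized relative to complete ones.
* **Resolution**: greedy descending-score selection under a one-to-one
  constraint, with deterministic lexicographic tie-breaks. Pairs confirmed by
  the follow-up visit are forced in or out regardless of score. Greedy rather
  than optimal assignment is a documented simplification: at village scale
  the two coincide except on contrived ties, and greedy decisions are easy to
  audit in the field.
* **Thresholds**: pairs scoring below 0.5 are never proposed; pairs at or
  above 0.85 can be accepted without adjudication; the band between is routed
  to confirmations — mirroring how the follow-up visit resolves ambiguous
  pairs in practice. Listing-only (unverified) analyses accept only
  auto-accept pairs, since no visit adjudicates the band; this is one of the
  two mechanisms behind the listing-only overestimate below.
* **Within-network duplicates** (two informants reporting one death) are
  merged by the same scorer at the auto-accept threshold before cross-network
  matching. The source describes only that the listing meeting resolved these
  by discussion; applying the matcher is this package's choice.

## The simulator

`simulate_informant_study()` generates villages in three strata (urban,
rural, rural-remote), a latent death roster, per-network capture, informant
PRD assignment, and noisy listing forms; `simulate_capture()` is the
capture-only core for estimator experiments. Defaults encode the study
conditions where published — capture probabilities 0.71/0.85, urban villages
dual-covered, 10% of rural villages dual-covered, a two-year window,
assignment sensitivity 0.92 and specificity 0.951 — and field-realistic
choices where not: Poisson mean 4 WRA deaths per village per window (a
two-district population of a few million spread over ~700 villages), 13% of
WRA deaths pregnancy-related (the pilot's 25/189), a 10% rate of out-of-period
deaths recalled as in-period, 2% fabricated listings, a 10% chance of a
character-level name perturbation, and recall noise of 1 year / 10 days (SD)
on age and date. These defaults were fixed once from the descriptive record,
not tuned to any test outcome.

Assumption violations are single dials, all off by default:

* dependence: kader capture odds shift by `exp(delta)` when RT captured the
  death;
* heterogeneity: per-death Beta-distributed capture probabilities with a
  common quantile across networks, so hard-to-capture deaths are hard for
  both (independent per-network frailty would not bias the estimator, and is
  deliberately not what this dial does);
* early-pregnancy under-reporting: a shared multiplicative odds factor on
  flagged deaths — the concrete mechanism the field literature gives for
  heterogeneity;
* attendance thinning per network, for exploring the pilots' 90% vs 52%
  informant attendance rates, which are *not* folded into the default
  capture probabilities since the published 0.71/0.85 already absorb them.

False positives are generated predominantly as real but out-of-period deaths
whose *listed* date falls inside the window (recall error, corrected by the
visit), plus a small share of pure fabrications attached to a single
informant's form. This matters: out-of-period deaths cannot be filtered by
the listed date, which is exactly why the verification visit, not a date
filter, removes them.

What the simulator does not model — spatial structure, informant social
networks, within-window mortality trends, shared surnames within families —
bounds what passing tests show: they validate the estimation machinery under
the stated generative model, not the field performance of informant networks.

## Validation experiments and problem sizes

The test suite runs four simulation experiments, sized to keep the full suite
in a few minutes while leaving Monte-Carlo error well inside the asserted
margins:

* calibration: 1,000 capture replicates at the study operating point
  (N = 121, p = 0.85/0.71); Lincoln–Petersen relative bias is asserted below
  3%, Bayesian 95% interval coverage within [90%, 98%];
* sampler correctness: the exhaustive small-configuration sweep (204
  configurations, 24,000 draws each) against the exact grid, total variation
  below 0.02;
* bias directions: dependence (`delta = 1`) and heterogeneity (`kappa = 4`)
  each drive the mean estimate below the true total over 400 replicates;
* listing-only bias: with false positives and matching noise on, the
  unverified estimate exceeds the verified one in at least 95% of replicates
  (in practice, all of them — the mean inflation at the default rates is
  more than twofold); with noise only, the overlap deflates and the estimate
  still inflates; with all bias sources off, the two analyses coincide
  exactly. The source study's specific listing-only figures are not
  reproducible because the underlying unverified counts were never published;
  the direction properties are the testable content of that comparison.

## Numerical and reporting conventions

* All arithmetic at full precision; integer rounding (half away from zero,
  `round_half_out()`) only at report time. Summing strata happens on the
  unrounded scale, then rounds once.
* `m = 0` makes Lincoln–Petersen a division by zero: it is a hard error
  pointing at `chapman()` (defined at zero overlap) and `bayesian_total()`,
  never a silent fallback.
* Accuracy metrics with zero denominators are explicit `undefined`, never 0;
  every reported percentage carries its numerator/denominator pair so it can
  be re-derived exactly.
* In the per-network accuracy stratification a death captured by both
  networks contributes to both rows, each with that network's own assigned
  status — the only convention under which the published per-network row
  sizes (141 + 156 > 189) are consistent. Year and area stratifications
  partition deaths uniquely. One published cell prints an inconsistent
  denominator (urban NPV "98.6 (70/76)", where 70/76 = 92.1 but 70/71 =
  98.6); the packaged synthetic pilot fixture reconstructs the value with
  the corrected denominator.
* The published cost table's line items disagree with its own phase totals
  by ±1–3 dollars (rounding in the source); unit costs are computed from the
  printed totals, and the allocation test asserts conservation exactly but
  the printed phase totals only to that slack.
* Eligibility windows are closed on both ends; boundary handling was not
  specified in the source and had to be fixed somewhere.
* Residence-based exclusion is exposed as a config flag (honoured when a
  `resident` column is present) but defaults to excluding nothing: the
  listing form requests residence, yet no published rule says how
  non-residents were handled, so the package does not invent one silently.
* The dual-network stratum is taken from the study design
  (`pipeline_config(dual_villages = ...)`) when provided; otherwise it is
  inferred as the villages with at least one RT record, which misclassifies
  a dual village only in the unlikely case RT operated there and captured
  nothing.

## Known limitations

* Exactly two sources: no log-linear multi-list models, and no
  dependence-adjusted estimators — dependence is a simulator scenario with a
  documented bias direction, not a correction the package applies.
* No probabilistic record linkage (Fellegi–Sunter) or language-specific
  phonetic matching; the matcher is a scored deterministic linkage sized for
  village listings adjudicated by home visits.
* Live births are a required input, not an output: the companion population
  survey (stratified PPS cluster sampling) is out of scope, and only its
  product — fertility rates — is consumed. The live-birth figure used in the
  MMR consistency check (~144,470) is back-derived from published summary
  numbers and shipped only as a documented test fixture.
* Accuracy metrics come without confidence intervals, matching the source
  tables; cause-of-death assignment from verbal autopsy is out of scope.
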