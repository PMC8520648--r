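---
title: "Methods: comparing ordinal and binary analyses of vascular event outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing ordinal and binary analyses of vascular event outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordvasc)
```

## The question and the design

Prevention trials of vascular disease usually analyse event outcomes as
dichotomies. Events have severities, though, and a treatment that works
typically reduces both how often events occur and how severe they are.
`ordvasc` quantifies how much statistical efficiency the dichotomy throws
away: it runs fifteen analysis methods on the same two-arm comparator
dataset, ranks their p-values within the dataset (rank 1 = smallest), and
asks — across many datasets — whether the methods that use the severity
ordering systematically achieve smaller ranks than the methods that use only
the dichotomy.

A "comparator dataset" is one treatment-versus-control comparison; a
multi-arm trial contributes one per comparison, sharing its control arm
(`expand_comparisons()`). Because real participant-level data of this kind
are not shareable, the package's synthetic generator stands in for them, and
every empirical claim in the test suite is a claim about data from that
generator.

## Outcome construction

An `ordinal_scale` orders severity categories with level 0 = "none" and the
top level fatal. `ordinalise()` is deterministic: no event maps to 0, a
fatal event to the top level, and a non-fatal event to the level named by
its severity tag; an unmapped tag is an explicit error naming the tag
(silent misclassification would corrupt every downstream rank).
Coding "higher = worse" makes one direction uniform across trend tests,
cumulative-logit models and the win ratio. The built-in scales (3-, 4-, 5-
and 8-level stroke, 3-level MI, 3/4/5-level bleeding, 3-level composite) are
plausible severity ladders, not canonical definitions — real applications
should define their own via `read_scales()`.

## The synthetic generator

`simulate_comparator()` draws the ordinal outcome from a cumulative-logit
model. With baseline (control, covariate-average) category probabilities
$\pi_0,\dots,\pi_{k-1}$ and cumulative splits $S_j = P(Y \ge j)$, participant
$i$ has

$$\mathrm{logit}\, P(Y_i \ge j) = \mathrm{logit}\, S_j + \eta_i, \qquad
\eta_i = \beta_T T_i + \gamma' (x_i - \bar x),$$

so the treatment log odds ratio $\beta_T$ (`treatment_logOR`, negative =
benefit) is exactly common to all cumulative splits — the proportional-odds
assumption holds by construction — and centred covariates shift individual
cumulative odds without moving the marginal category frequencies far from
baseline. Event times are exponential (`event_rate_hazard`, per day),
truncated at `followup_days` for participants whose drawn outcome is an
event, so the outcome and the time-to-event fields never contradict each
other; participants without an event are censored at follow-up end.

Defaults, chosen once as typical of large prevention trials: `n_per_arm =
2000` (a quarter-million participants over ~59 comparisons in the study
design this emulates gives ~2000/arm), ~10% any-event probability over
follow-up with severity mass decreasing towards fatal, age ~ N(65, 10) years,
46% female, 20% diabetes history, covariate log odds 0.025/year of age,
−0.2 for female sex, +0.5 for diabetes, `followup_days = 730`.

Two deliberate design points:

- **Single effect parameter.** The treatment effect is applied once on the
  cumulative scale rather than separately to occurrence and severity: one
  parameter encodes "alters both risk and severity". A consequence worth
  knowing: with ~90% of probability mass at "none", the severity tail
  carries little extra Fisher information under this model —
  $1-\sum \bar\pi_i^3$ is dominated by the "none" category — so ordinal
  tests beat the binary chi-square only modestly in these simulations. Real
  trial data, where treatments often shift severity more strongly than
  proportional odds predicts, show larger ordinal advantages. The generator
  therefore also offers `severity_logOR`, an additional shift applied to the
  severity splits only ($j \ge 2$): the documented severity-informative
  alternative used in the power-ordering and assumption-check property
  tests. What passing tests show is that the machinery detects and ranks
  effects correctly under these generating mechanisms — not that ordinal
  analyses will beat binary ones by any particular margin on a given real
  trial.
- **Null datasets.** `simulate_null()` forces the treatment effect to zero
  and assigns the arm label by an independent fair coin per participant
  (rather than permuting a real label), so any arm difference is chance.

Randomness: one root seed; sub-streams via the documented counter scheme
`derive_seed(root, counter)` (a Lehmer-style multiply-and-reduce modulo
$2^{31}-1$), so battery results do not depend on execution order.

## The fifteen-method battery

All methods return a two-sided p-value. Choices that the sources of this
design leave open, fixed here:

- Regression p-values are Wald, not likelihood ratio (the convention of the
  standard commercial software these analyses are usually run in, and
  uniformly two-sided-comparable).
- Pearson chi-squares are computed without continuity correction.
- The Cox models use the Efron tie approximation — ties are massive when
  times accompany category-coded events — on time to first event.
- The t-test pools variances; the linear model uses integer scores 0..k−1.
- The Mann–Whitney U test uses mid-ranks and the tie-corrected normal
  approximation without continuity correction. The tie-corrected mean and
  variance equal the exact permutation moments (an identity the tests
  verify); the *p-value* is still an approximation, and at 5–10 per arm it
  can differ from the exact permutation p by far more than 0.01 in the
  centre of the distribution (discrepancies of 0.05–0.3 are routine under
  heavy ties; even untied data exceed 0.01). Below ~10 events per arm the
  approximation should not be trusted for fine distinctions.
- Mood's median test splits at "> overall median" vs "≤ median"; when one
  side is empty (common when most participants are at level 0) the method is
  degenerate with p = 1. With a median of 0 the split coincides with
  event/no-event and MT equals CSB — visible in the examples.
- Win ratio: every treatment–control pair is compared down the severity
  hierarchy (equivalently, by level); the estimate is wins/losses. The
  p-value uses a normal approximation on $\log(N_w/N_l)$ with the win and
  loss proportions' variances and covariance estimated by the two-sample
  U-statistic projection (Hájek) estimator — the matched-pairs variance
  would be anticonservative for unmatched arms. With any count below 10 the
  approximation gives way to a within-arm bootstrap; with no losses at all,
  a binomial count test on the discordant pairs.
- Bootstrap mean-rank test: the statistic is the treatment−control
  difference in mean mid-rank over the pooled ranking; within-arm
  multinomial resampling gives its bootstrap distribution $\hat F$ (centred
  at the observed difference), and $p = \max\{2/B,\ 2\min(\hat F(0),
  1-\hat F(0))\}$ — percentile-interval inversion. $B \ge 100$ is enforced;
  the default is 500. The rank difference is reported descriptively only.
- Degenerate-method policy: a method whose statistic is undefined on the
  data (no events, missing time column, inestimable effect) returns p = 1
  with a `degenerate` flag and a reason, so that every dataset still ranks
  all 15 methods.

The proportional-odds assumption check is an efficient score test: the
constrained (common-slope) cumulative-logit model is fitted, and the score
of the unconstrained model (a separate slope per cumulative split) is
evaluated there, $U' I^{-1} U \sim \chi^2_{(k-2)p}$. Derivatives are taken
numerically on the weighted pattern-collapsed likelihood; with two occupied
levels the assumption is vacuous and the test reports not-applicable.

## Ranking, Friedman, Duncan

P-values are ranked within each dataset with mid-ranks for ties, conserving
the row sum $k(k+1)/2$. The Friedman statistic uses the tie-correction
divisor $C = 1-\sum(t^3-t)/(nk(k^2-1))$; with untied rows it equals the
classical statistic, under perfect untied agreement it equals $n(k-1)$, and
with fully tied rows it is defined as 0 with p = 1. The p comes from
$\chi^2_{k-1}$: on very small matrices (4 blocks) that approximation is
accurate near the significance gate — the only place the pipeline consumes
it, since Duncan grouping runs only when Friedman is significant — but in
the centre of the null distribution it can be off by 0.1–0.3, as any
chi-square approximation at n = 4 is.

Duncan's multiple range test runs on the method mean ranks with the error
variance from the two-way (dataset × method) rank ANOVA, $df = (n-1)(k-1)$ —
row means are constant by rank-sum conservation, so the residual reduces to
deviations from column means. A range of $p$ ordered means is significant
when its span exceeds $q_{1-\alpha_p}(p, df)\sqrt{MSE/n}$ with the classic
protection level $\alpha_p = 1-(1-\alpha)^{p-1}$; ranges inside a
non-significant range are protected. Letters mark maximal non-significant
spans; the rating table flags the "top group" — methods sharing a letter
with the best-rated method. The omnibus 2×k chi-square's p is ranked as-is
alongside the two-sided p-values; comparisons sharing a control arm are
treated as independent in the ranking (a known simplification, flagged in
reports).

## Type-I error by bootstrap

`assess_type1_error()` draws B resamples with replacement from a null
dataset and counts p < α per method. One subtlety discovered in
implementation and worth stating plainly: resampling rows *with their arm
labels* preserves whatever chance arm–outcome association the one observed
dataset carries, so the significant count then tracks the observed statistic
rather than the null (a null dataset that happens to sit at z ≈ 1.3 yields
~37% significant resamples, not 5%). For the count to be binomial around
$B\alpha$ — the property the assessment is meant to check — the dummy arm
label must itself be re-randomized within every resample, and that is the
default (`reassign_arm = TRUE`); the association-preserving variant remains
available for studying bootstrap behaviour around an observed dataset.

## Sample sizes and multipliers

Four formulas, all two-sided with equal allocation and results rounded up to
even totals: binary comparison of proportions (unpooled variance); the
Whitehead proportional-odds formula
$N = 12 z^2 / ((\log OR)^2 (1-\sum\bar\pi_i^3))$, whose constant is pinned
by requiring the two-category collapse at $\bar\pi = (0.5, 0.5)$ to equal
the binary log-odds-ratio sample size exactly (the published forms differ in
per-group versus total conventions); Noether's formula for the Mann–Whitney
test, with ties entering only through the probabilistic index itself; and
the pooled-variance t-test size. Defaults α = 0.05, power = 0.90, both
configurable. Each formula's returned N is validated by simulation at the
formula's own alternative (power within ±3 points of nominal in 2000
simulated trials). `estimate_effects()` supplies the formula inputs from a
dataset: arm event proportions, the unadjusted cumulative-logit odds ratio,
the probabilistic index by direct pairwise counting, score mean difference
and pooled SD, and mean category probabilities.

Multipliers divide each method's N by the binary N and round to the printed
convention of the source table (two significant figures below 0.1, two
decimals otherwise); summaries are medians and type-7 quartiles of the
rounded per-row multipliers.

## Problem sizes used by the test suite

Chosen as the package's own scaled-down study conditions: the qualitative
replication property runs 100 pipeline replicates of 30 simulated 4-level
stroke/TIA datasets at 2000 per arm and generating OR 0.8, asserting that
the Duncan top group contains MWU and adjusted OLR and excludes the
fatal-event chi-square in at least 90 replicates; the type-I assessment uses
1000 resamples per scale at 2000 per arm; parameter-recovery runs 60
replicates at 20 000 per arm; the score-test level check 300 replicates at
500 per arm; power calibrations 2000 simulated trials each. Enumeration
oracles (exact rank-sum permutation distributions, all-pairs win counting,
all $(3!)^4$ Friedman row permutations) are kept to sizes where full
enumeration is exact.

## Known limitations

- The generator draws first/worst events only — no recurrent events,
  competing risks, or per-participant event histories.
- Under the pure proportional-odds mechanism at ~10% event rates the
  ordinal-versus-binary efficiency gap is small (see above); the large
  published sample-size reductions correspond to effect patterns where
  severity shifts exceed the proportional-odds prediction.
- Small-sample p-values of the MWU and Friedman chi-square approximations
  are approximations; exact-permutation alternatives are implemented here
  only as test oracles.
- The win ratio ignores event times ("wins" are decided by severity alone),
  and the covariate-adjusted extensions of MWU and the win ratio are out of
  scope.
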