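---
title: "Methods: simulating and analysing stealth cognitive screening from exergame telemetry"
author: "exerscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stealth cognitive screening from exergame telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Exergaming platforms for older adults record raw telemetry — completion
times, counts of gathered or missed targets, path deviations, remaining
lives — while the user trains. Because users experience play rather than
testing, these *in-game metrics* are candidates for stealth assessment of
cognitive status: screening embedded in an intervention, free of the
stress and test–retest constraints of clinic-administered instruments such
as the MMSE or MoCA.

`exerscreen` implements the full analysis chain for such a study on a
three-group cohort — cognitively normal (CN), mild cognitive impairment
(MCI) and mild dementia (MD) — together with a calibrated synthetic cohort
generator. The original trial data are not publicly deposited, so the
generator is a first-class component: it reproduces the cohort's published
group structure and summary statistics, and every downstream method is
validated on it plus independent mathematical oracles.

```{r, eval = FALSE}
library(exerscreen)
cfg     <- cohort_config(seed = 60928L)
cohort  <- generate_cohort(cfg)
plays   <- simulate_cohort_sessions(cohort, cfg)
scores  <- score_sessions(plays)
feats   <- build_feature_matrix(scores, cohort)
```

# The cohort generator

## What it emulates

* **Group structure.** 38 CN, 64 MCI and 14 MD participants (116 total),
  each with age, sex, education, MMSE, MoCA and Trail Making A/B times
  drawn per-group from the published means and SDs
  (`default_group_params()`).
* **Training schedule.** 3 sessions/week for 8 weeks (24 sessions;
  both ranges 3–4 and 7–8 are configurable). Difficulty is promoted at
  sessions 7, 13 and 19, giving six sessions at each of the four levels —
  an equal-exposure default chosen so that per-level trend fits are
  estimable; the fitness-test-driven promotion of the original protocol is
  replaced by this configurable schedule.
* **Within-session telemetry.** Each session plays one representative game
  per physical domain (aerobic, strength, flexibility, balance) and all
  five high-resolution monitoring games (HRMG: Apple Tree, Arkanoid,
  Fishing, Mini Golf, Ski Jump), plus three manual heart-rate readings,
  blood pressure, and a Borg exertion rating (6–20 scale).

## Distributional choices

Published calibration targets come as mean ± SD only, so each continuous
quantity is modelled as a normal draw **winsorized at its instrument
bounds** (MMSE/MoCA on [0, 30], game scores on [0, 10], Borg on [6, 20],
heart rate on [40, 180] bpm). Winsorizing shifts the mean of a bound-adjacent
quantity — the CN Borg target of 6.9 sits 0.75 SD above the scale floor — so
the location parameter of every draw is solved numerically
(`calibrate_location()`) such that the *post-clipping* expectation equals
the published mean. The cost is a mildly compressed SD near bounds; the
benefit is that group sample means converge to the printed table values,
which is the property the calibration is meant to guarantee (and the one
the acceptance script measures).

A clipped draw was preferred over resampling-style truncation because all
of a participant's quantities share one latent factor (below), and
clipping preserves that correlation structure without distorting the
joint draw.

## The shared cognitive factor

The published table gives no within-group covariance between
neuropsychological scores and game ability. The generator therefore uses a
single per-participant latent factor *z* ~ N(0, 1): cognitive instruments
(MMSE, MoCA) and game-domain baselines load with +√ρ, timed Trail Making
tests with −√ρ (longer = worse), and demographics/vitals/Borg do not load.
Any two loaded quantities then correlate at ρ (default 0.6, configurable).
This is a free modelling choice; it produces moderate positive HRMG–MMSE/MoCA
correlations and modest negative TMT correlations of the kind the screening
analysis is meant to detect, but the exact correlation magnitudes on real
data are not recoverable from published summaries.

## Session trends and telemetry emission

The latent expected score of domain *d* in the session with within-level
ordinal *t* is

```
score(t) = clip( baseline_d + slope_group * (t - 1) + N(0, sigma_d), 0, 10 )
```

so the **session-1 expectation equals the calibrated baseline** (the
published table does not say whether game baselines are session-1 scores
or early-period means; session-1 calibration was chosen and the
alternative differs only by a few hundredths given the small slopes).
Default learning slopes are small (0.05/0.03/0.02 points/session for
CN/MCI/MD) because the original analysis found no significant group
differences in slopes — the simulator preserves that near-null structure
rather than injecting a strong trend signal. Session noise defaults to
0.6–0.8 score points for game domains, 4 bpm for heart rate and 0.8 for
Borg; these within-subject values are not published and were fixed once at
magnitudes a trial of this kind would plausibly show.

The play ability is `score(t) / 10`, and raw metrics are emitted so the
**expected unit score of each game equals the ability** — count metrics are
binomial (e.g. `caught_fish ~ Binomial(10, ability)`), continuous ratios
use a Binomial(100)/100 fraction. One subtlety: the Mini Golf scorer
zeroes its time term when the ball is not scored, so a naive emission
would have expectation `0.9a + 0.1a²`; the path-term success probability
is therefore inflated by `(a − a²)/7`, which keeps the overall expectation
exactly `a` while staying a valid probability on [0, 1].

Reproducibility: one root seed; each participant's draws come from a
substream keyed by a stable hash of the participant id, so a participant's
data do not depend on cohort order or size.

# Scoring

Each game has a weighted scoring equation over its raw metrics, with
weights summing to 1 so perfect play scores exactly 1 before the linear
mapping to the 10-point scale:

| game | unit score |
|---|---|
| aerobic (cycling/hiking) | distance travelled / total distance |
| strength / flexibility / balance | correct / total iterations |
| Apple Tree | 0.8 · time term + 0.2 · apples / total |
| Arkanoid | 0.4 · hits / targets + 0.6 · lives / total lives |
| Fishing | caught / total fish |
| Mini Golf | 0.7 · path term + 0.2 · ball scored + 0.1 · time term |
| Ski Jump | distance / maximum possible |

Three conventions resolve dimensional ambiguities in the published
equation table:

* **Time terms** enter as remaining-time fractions,
  `(limit − elapsed)/limit` clipped to [0, 1] — raw seconds cannot enter a
  unit score, and faster completion must score higher.
* **The golf path term** is `optimal / max(travelled, optimal)`: travelled
  distance is at least the optimal path, and deviation from the optimal
  path must penalize.
* **The golf time term** is 0 when the ball is never scored.

Out-of-range raw values are clipped rather than rejected (robustness to
telemetry noise). Per session, a domain's score is the unweighted mean of
its games' normalized scores (no within-session weighting is published);
heart rate and Borg are averaged per session as pseudo-domains. Domains
without plays are absent from the output, never zero. Balance is scored
but excluded from the default feature set, since the published aggregate
lists aerobic, resistance, flexibility and HRMG; `domains =` restores it.

# Trend features

For each domain, `fit_trend()` summarizes the session-by-session scores as
mean, OLS slope *a* and intercept *b* of `y = ax + b` — over the whole
training period (`Total`, global session index) and within each difficulty
level (`Level1..4`). Per-level fits use the **within-level ordinal**
(1, 2, …) as x, so a level's intercept estimates level-entry performance
and intercepts are comparable across levels; the total fit keeps the
global index. Feature names follow `<Domain><Statistic><Period>`
(`HRMGMeanTotal`, `HeartRateSlopeLevel3`, …), plus `Age`. Levels a
participant never reached yield `NA` features; missing values are
mean-imputed inside each training fold during classification, keeping all
participants usable without leaking test-fold information.

# The statistical battery

* **Kruskal–Wallis** (tie-corrected, chi-square approximation) per
  feature, with the rank effect size ε² = H/(n−1). ε² lies in [0, 1]; note
  its maximum is attained only when every group is a distinct singleton,
  not for every perfect separation (three separated triplets give
  ε² = 0.9). An all-identical sample is reported as H = 0, p = 1 rather
  than the indeterminate tie-correction ratio.
* **Pairwise comparisons** are Dunn's z-tests on the pooled ranks,
  two-sided, Bonferroni-multiplied by the number of pairs and capped at 1
  — the convention matching a Bonferroni-adjusted "Kruskal–Wallis pairwise
  comparison" in standard statistics suites. Worth knowing: with three
  perfectly separated groups, the adjacent pairs do not reach adjusted
  significance below about 10 per group; this is a property of the z
  formula, not a power defect of the implementation.
* **Pearson correlations** of an HRMG feature (default `HRMGMeanTotal`,
  since the published correlation does not name a specific feature)
  against MMSE, MoCA and TMT A/B, with the t-transform p-value.
* **Normality annotation** via Shapiro–Wilk or the Lilliefors-corrected
  Kolmogorov–Smirnov test (the "KS test" of SPSS-style pipelines tests
  against a *fitted* normal, which is Lilliefors).

# Feature selection and classification

**CFS merit.** A subset S of k features scores
`merit(S) = k·r̄cf / sqrt(k + k(k−1)·r̄ff)`, rewarding high mean
feature–class association r̄cf and low mean feature–feature association
r̄ff. Associations are symmetric uncertainties after equal-frequency
discretization into 5 bins (class kept categorical) — deterministic and
scale-free.

**Best-first search** starts from the empty set, keeps a priority queue of
evaluated subsets, expands the best unexpanded one by single-feature
additions, and stops after 5 consecutive non-improving expansions
(configurable `stale_limit`); ties break lexicographically, making the
search deterministic. On association structures realized from data the
search recovers the exhaustive optimum for small feature counts; on
arbitrary adversarial matrices a larger patience may be needed — the test
suite demonstrates both regimes.

**Classifier.** A one-hidden-layer feedforward network with sigmoid units
and one-hot targets, trained by per-sample stochastic gradient descent
with momentum — the classic configuration of the WEKA-style multilayer
perceptron the study design implies: hidden units
⌈(features + classes)/2⌉, learning rate 0.3, momentum 0.2, 500 epochs,
inputs z-standardized per training fold, seeded initialization and
shuffling for exact reproducibility. Class probabilities are the
normalized output activations; with zero weights every class gets 1/k.

**Cross-validation.** Stratified tenfold; imputation and (optionally)
selection re-run inside each training fold. Two selection protocols are
reported side by side: *once* (selection on all data before CV — the
protocol a single published ranked feature list implies, optimistic
because selection has seen the test folds) and *nested* (leakage-free).
Neither is asserted as the original study's, which does not state the
nesting. Out-of-fold predictions are pooled into the confusion matrix;
per-class TP/FP rates, sensitivity, specificity and one-vs-rest
trapezoidal ROC areas follow, with the identities sensitivity = TP rate
and specificity = 1 − FP rate holding by construction.

# MCI screening ROC

`mci_screening()` restricts to MCI (positive, n = 64) vs CN (negative,
n = 38) and compares ROC/AUC of: the in-game score — either the
classifier's out-of-fold MCI probability or the raw `HRMGMeanTotal` — and
the MMSE and MoCA. ROC curves place one operating point per distinct score
value; ties contribute diagonal segments; AUC is the trapezoidal area,
identical to tie-corrected rank-sum concordance. Game and instrument
scores flag impairment at the *lower* end (`lower_is_positive`);
probabilities at the higher end. Instrument cutoffs default to the
conventional MMSE < 27 and MoCA < 26 (the original publication cites
"corresponding cut-off scores" without numbers; both are overridable). The
in-game screen reports both the raw accuracy convention
((TP+TN)/n: 24/38 + 54/64 correct would give 76.47%) and balanced
(mean-recall) accuracy, since published single-figure accuracies do not
always state their weighting.

# Numerical and testing notes

* Degenerate inputs: zero-variance vectors raise errors in correlation and
  normality checks; empty groups and single-class training folds raise
  errors; single-session trend fits return `NA` slope/intercept.
* Problem sizes: the test suite validates generator moments at n = 5000
  participants, type-I error of the omnibus test over 10,000 null
  simulations at the trial's group sizes, OLS and AUC oracles over
  500–1000 random instances, and emission invariants over thousands of
  draws per game — sizes chosen to give decisive checks at desk scale.
* Determinism: every stochastic component takes a seed; identical seeds
  give byte-identical cohorts, folds and network weights.

# What passing tests do and do not show

The generator reproduces the published *marginal* group summaries, a
plausible correlation structure, near-null learning slopes, and telemetry
whose expected scores equal the latent abilities. Real trial data would
additionally contain adherence gaps and dropout, fatigue and day-of-week
effects, nonlinear learning curves, instrument ceiling effects beyond
simple truncation, and unknown cross-quantity covariances. Consequently,
green tests certify the *methods* — scoring equations, trend extraction,
test statistics, selection, classifier and ROC machinery — and the
generator's calibration; they do not certify that the original study's
headline accuracies would replicate on new clinical data, which is exactly
the question only the unavailable trial data could answer.
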