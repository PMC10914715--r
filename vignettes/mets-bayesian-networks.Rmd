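---
title: "Modeling the dynamic progression of metabolic syndrome with discrete Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the dynamic progression of metabolic syndrome with discrete Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsbn)
library(dplyr)
```

## The problem

Metabolic syndrome (MetS) is not a one-way street. Between two survey
waves a few years apart, a person can accumulate abnormal metabolic
components — central obesity, elevated blood pressure, elevated fasting
glucose, high triglycerides, low HDL cholesterol — or shed them. `metsbn`
models this bidirectional process in middle-aged and older cohorts with
discrete Bayesian networks: a directed acyclic graph (DAG) over
categorical risk factors and a transition outcome, quantified by one
conditional probability table (CPT) per node, on which exact probabilistic
inference answers both *causal* questions (fix a risk factor, watch the
outcome) and *evidential* ones (fix the outcome, watch the risk factors).

## Disease staging and transitions

Each subject wave is classified against five harmonized component
criteria (sex-specific waist and HDL cutoffs; treatment of hypertension,
hyperglycemia or low HDL counts as abnormal regardless of the measured
value; boundary values equal to a `>=` cutoff qualify, the HDL comparison
is strictly `<`). The component count maps to four ordered states —
FMD (0), MMD (1), SMD (2), MetS (3+) — and the pair of states across
waves yields the transition label: *forward* when the follow-up state is
strictly worse, *reverse* when strictly better, *unchanged* otherwise.
Any jump counts; the ordering alone decides. Subjects with an unevaluable
criterion in either wave are excluded from staging (complete-case), which
mirrors the strict exclusion a survey analysis would apply.

`cohort_summary()` then reports the descriptive backbone: cumulative MetS
incidence among those at risk at baseline, and the split of all state
changes into forward and reverse shares.

Two analysis populations follow from the staging. The progression model
uses subjects who could still progress (baseline below MetS), with
outcome levels unchanged/forward; the recovery model uses subjects who
could recover (baseline above FMD), with outcome levels
unchanged/reverse. Subjects whose change runs in the opposite direction
are excluded from that model rather than folded into "unchanged" — the
outcome then cleanly encodes "moved in the studied direction versus
stayed". This at-risk definition is a design choice of the package
(`run_pipeline()` applies it automatically); it is the reading we find
most defensible because it keeps each outcome variable binary and its
denominator interpretable.

## Structure learning

The network structure is learned by greedy hill-climbing over single-arc
moves (add, delete, reverse), scored by the decomposable BIC for
categorical data,

$$\mathrm{BIC} = \sum_i \sum_{j,k} N_{ijk}\log\frac{N_{ijk}}{N_{ij}}
  \;-\; \frac{\log N}{2}\sum_i q_i\,(r_i-1),$$

starting from the whitelist-only graph and never violating the blacklist,
removing a whitelisted arc, or creating a cycle. BIC is the score because
it is the default of the software family this kind of analysis is usually
run with; the scoring function is a single internal routine, so a
different decomposable score can be swapped in.

Two determinism decisions matter more than they look:

* **Ties are broken lexicographically, with a numeric tie band.** The two
  orientations of a fresh arc between two so-far unconnected nodes are
  score-equivalent; in floating point their deltas differ by noise of
  order $10^{-8}$. If that noise picks the orientation, the search can
  wander into a genuinely worse local optimum (orient an arc out of a
  collider and the search must later add a compensating arc between the
  parents). Deltas within $10^{-6}$ of the incumbent best are therefore
  treated as equal and the first move in lexicographic (from, to, move
  type) order wins. The same constant is the minimal improvement required
  to keep climbing.
* **No restarts.** Plain hill-climbing is used, as named; the bootstrap
  layer below, not restarting, is the guard against local optima. A
  single run can and sometimes will return a local optimum.

Robustness comes from nonparametric bootstrap model averaging:
`bootstrap_arc_strengths()` resamples the rows `B` times (each replicate
seeded as master seed + replicate counter, so extending `B` never changes
earlier replicates), learns a network per replicate, and records per node
pair the *strength* (fraction of replicates containing the arc in either
direction) and *direction* (fraction of those supporting the
orientation). `averaged_network()` keeps arcs with strength at or above
0.85 — the threshold is inclusive — oriented where the directional
fraction exceeds 0.5, following the convention that the strength
threshold applies to the undirected arc and the direction threshold to
its orientation. Exact directional ties go to the lexicographically
smaller source node. The averaged graph is forced acyclic by dropping
cycle-inducing arcs in increasing strength order.

## Parameter learning

Given the DAG, CPTs are estimated as Dirichlet posterior means with a
uniform prior of total imaginary sample size `iss` spread over every CPT
cell ($\alpha_{ijk} = iss/(r_i q_i)$, BDeu-style):

$$\hat\theta_{ijk} = \frac{N_{ijk} + \alpha_{ijk}}{N_{ij} + \sum_k \alpha_{ijk}}.$$

The default `iss = 1` mirrors the default of the toolkit family this
analysis is normally run in; the source analysis names the Dirichlet
estimator but not its prior strength, so the choice is flagged here. At
cohort scale (thousands of rows) the estimates are insensitive to any
reasonable `iss`; the prior's real job is keeping every cell strictly
inside (0, 1) so downstream evidence can never hit a hard zero that the
data merely failed to observe. Missing values are handled complete-case
per node family (a row is dropped only for the tables it cannot inform),
switchable to whole-row exclusion.

## Exact inference and the two reasoning modes

`bn_query()` computes posteriors exactly by variable elimination with a
min-degree elimination order (ties lexicographic; the order changes
speed, never values). Evidence is hard instantiation at 100%; soft
evidence is out of scope. Evidence sets of probability zero raise a
dedicated error rather than returning NaNs. The brute-force
`enumerate_posterior()` — full-joint enumeration, capped at 15 nodes — is
kept as a first-class function precisely so the elimination engine can be
property-tested against an implementation too simple to be wrong; the
suite checks agreement to $10^{-12}$ on a thousand random networks.

`causal_reasoning()` instantiates each level of each risk factor and
tabulates the outcome posterior against the no-evidence prior;
`evidential_reasoning()` conditions on an outcome level and tabulates
each factor's posterior with an up/down marker. The two are linked by
Bayes' rule, $P(f \mid o) = P(o \mid f) P(f) / P(o)$, and the suite
asserts that identity to $10^{-12}$ on every table produced. Reported
tables round percentages to 2 decimals (whole percents in prose-style
summaries); unrounded values are always kept alongside.

## The published networks as fixtures

`build_published_fixture()` reconstructs the two reported networks from
their printed tables: root marginals and the outcome CPTs (progression:
outcome given hyperuricemia and BMI level; recovery: outcome given high
HbA1c and BMI level). One printed recovery row sums to 100.30% — printed
tables rounded to two decimals can do that — and is renormalized at
construction; more generally the `bnet()` constructor silently
renormalizes rows within $10^{-6}$ of 1 and rejects anything further off.
Rows already within the validation tolerance of $10^{-9}$ are left
bit-untouched so that JSON serialization round-trips reproduce
`joint_probability()` exactly.

The printed record does not include the intermediate CPTs
(hyperuricemia given gender; BMI given age and exercise, or gender and
exercise). These are synthetic, and built as *marginal-preserving tilts*:
additive deltas with zero weighted sum, so the printed marginals are
reproduced exactly (to $10^{-6}$ and better) while the arcs carry mild
dependence in the epidemiologically expected direction (male
hyperuricemia prevalence about twice female; little exercise and older
age shifting mass from normal weight to overweight). The headline
posterior queries are unaffected by the tilt sizes: every reported query
involves only the outcome, its two parents, and their exact marginals.
The nodes the printed figures connect only among covariates are omitted
from the fixtures; reproducing the printed posteriors confirms they are
separated from the outcome given the described arcs.

## The synthetic cohort generator

`generate_cohort()` emulates the *discrete* structure the analysis
consumes, not the physiology of any real survey. Covariates are drawn
independently from the printed marginal distributions (smoke, drink and
functional loss, whose marginals are not printed, default to 38%, 33%
and 16% prevalence — plausible for a middle-aged and older Chinese
cohort). Baseline biomarkers are sex-specific log-normals shifted
multiplicatively by BMI level; their medians and spreads are invented
plumbing, labeled as such, and tuned once so every component prevalence
lands in a plausible 10–50% band. Hyperuricemia and high HbA1c are
generated directly as binary flags at their printed prevalences (8.41%
and 7.28%) rather than from serum values, matching the binary coding of
the node definitions.

The between-wave transition is drawn from the configured transition CPT
(defaults: the printed outcome tables) given the model's two direct
parents, and follow-up biomarkers are then *constructed* to realize the
drawn transition: components that keep their status are redrawn on the
same side of their threshold (nudged from baseline), a forward move
pushes one randomly chosen normal component across its cutoff, a reverse
move pulls enough abnormal untreated components back to reach the next
state down. Treatment flags persist only while the component stays
abnormal. Because follow-up values are built side-constrained rather
than resampled and tested, reclassification agrees with the drawn
transition for 100% of subjects (the contract asks for at least 99%),
and the generator needs no retry loops. What this generator does *not*
emulate: sampling weights, attrition, measurement error, correlated
covariates, or multi-component jumps — so passing tests certify the
analysis machinery, not realism of any single biomarker distribution.

## Numerical choices, problem sizes, defaults

* CPT validation tolerance $10^{-9}$; constructor renormalization band
  $10^{-6}$; inference cross-checks at $10^{-12}$.
* Hill-climb tie band and minimal improvement $10^{-6}$ (see above).
* Bootstrap defaults `B = 200` in the pipeline; the averaging thresholds
  default to 0.85/0.5. The reference analysis used `B = 10{,}000`;
  strengths of strong arcs are already degenerate (at or near 1) by a few
  hundred replicates, so the package's own consistency checks run the
  bootstrap at `B = 200` on 10,000-row cohorts and the test suite sizes
  its cohorts between 1,500 and 100,000 rows depending on what the check
  needs to resolve.
* `count_dags()` uses Robinson's recurrence with exact limb arithmetic;
  counts beyond $2^{53}$ (from 10 nodes) are returned as exact decimal
  strings. The recurrence as printed in the source text is typographically
  corrupted (its terms are non-integer and the recursion argument does
  not depend on the summation index), so the standard recurrence is
  implemented and validated against brute-force enumeration instead of
  guessing at the typo.
* `hill_climb()` takes no seed: given data, constraints and the tie rule
  it is a deterministic function, and the package treats that as part of
  its contract.

## Worked example

```{r example}
net <- build_published_fixture("progression")
bn_query(net, "progression")
bn_query(net, "progression", c(hyperuricemia = "yes"))
evidential_reasoning(net, "progression", "forward",
                     c("hyperuricemia", "bmi")) |>
  mutate(across(c(prior, posterior, delta), ~ round(100 * .x, 2)))
```

And end to end on synthetic data:

```{r pipeline, eval = FALSE}
out <- run_pipeline(list(out_dir = "mets-run", n = 20000, seed = 7,
                         boot = 200))
out$summary
```

## Known limitations

* Hard evidence only; no likelihood weighting, MCMC, MAP queries, or
  interventional calculus beyond conditioning on instantiated causes.
* Discrete variables only; no continuous or temporal (dynamic) networks.
* Plain hill-climbing without restarts; the bootstrap layer is the
  intended mitigation, and single-run graphs should be read with that in
  mind.
* The synthetic generator draws covariates independently; learned
  covariate–covariate arcs on synthetic cohorts are expected to be
  absent, unlike in real survey data.
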