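---
title: "peerspread: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{peerspread: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peerspread)
```

## What the package simulates

School-based social network interventions recruit a small set of pupils —
*influence agents* — train them to adopt a target behavior, and rely on peer
influence to diffuse that behavior through the class. The open design question
is the selection criterion: which pupils make the best influence agents?
Answering it with field experiments is expensive, so this package answers it
*in silico*: it builds weighted sociometric networks for a cohort of school
classes, seeds an agent-based diffusion model of physical activity with five
different selection rules, and compares the class-level outcomes
statistically.

The five conditions are selection by **in-degree centrality** (most
nominated), **betweenness centrality** (bridges on shortest paths),
**closeness centrality** (quickly reached by everyone), **random** selection,
and a no-intervention **control**. In every intervention the top 15% of the
class is selected and receives a one-off 17% increase of its initial physical
activity level (PAL); the class then evolves for a year (days 0–364), and the
outcome is the *success rate*: the percent change of the class mean PAL from
day 0 (post-boost) to day 364.

## Measurements feeding the model

Each agent carries two inputs.

* **PAL** — daily step counts are filtered (first and last day of each
  measurement wave discarded; days with fewer than 1440 worn minutes or fewer
  than 1000 steps discarded), waves with at least 3 valid days are averaged,
  and steps are rescaled as `PAL = steps / 10000 * 1.53`. A pupil's baseline
  is the mean over their observed waves; pupils with no valid wave get the
  class mean. This per-participant mean imputation replaces model-based
  imputation deliberately: the simulator consumes exactly one baseline value
  per pupil, and the imputation machinery is orthogonal to every hypothesis
  the simulation tests.
* **env** — the family-affluence item sum (0–13) is reflected and rescaled to
  `env = (13 - sum) / 6.5`, clamped to [0, 2]; higher values mean lower
  affluence. The published description fixes only the [0, 2] range, not the
  divisor; 6.5 is the unique divisor that maps the printed sum range onto the
  printed score range, so it is used here.

Sociometric nominations (6 questions, 4 waves, no self-nominations) collapse
into one static directed network per class: the weight of edge `u -> v` is
the number of *distinct* questions on which `u` ever nominated `v`, divided
by 6. Duplicates across waves are dropped, so weights live on the grid
`{1/6, ..., 1}`. Rosters, not nomination tables, define the node set: pupils
who never nominate or get nominated remain in the class and still respond to
their environment.

## The three-phase daily update

For agent $i$ with PAL $P_i$, environment score $e_i$ and threshold
$\theta_i$, one simulated day applies, synchronously for all agents:

1. **Social influence.** $S_i = \sum_j w_{ij} P_j / \sum_j w_{ij}$ over the
   peers $j$ that $i$ nominated (out-neighbors): agents are influenced by
   those they attend to. An agent with no out-neighbors feels no social pull
   ($S_i = P_i$). The nomination direction is a modeling choice the data do
   not settle; the out-edge reading (nomination = attention) is used because
   it makes the most-nominated pupils the most *listened to*, which is the
   premise of nomination-based interventions.
2. **Socio-environmental influence.** The social pull is mixed with an
   environmental anchor into one target,
   $T_i = (1-\lambda) S_i + \lambda \, a(e_i)$, with
   $a(e) = \mathrm{palRef}\,(2-e)/2$: affluent environments ($e \to 0$)
   anchor at high activity, deprived ones ($e \to 2$) at zero. The signed
   pull is $\Delta_i = T_i - P_i$.
3. **Threshold gate.** If $|\Delta_i| > \theta_i$ the agent moves a fraction
   $\eta$ of the pull, $P_i \leftarrow P_i + \eta\,\Delta_i$, clamped to the
   PAL bounds; otherwise nothing changes.

The model is fully deterministic — no stochastic transmission across ties —
so every trajectory is a pure function of network, initial states and
configuration. All randomness in the study lives in cohort generation and
agent selection, each driven by explicit seeds.

## Default parameters and how they were chosen

| parameter | default | meaning |
|---|---|---|
| `days` | 365 | simulated horizon, days 0–364 |
| `eta` | 0.05 /day | fraction of the pull applied per day |
| `lambdaEnv` | 0.01 | weight of the environmental anchor |
| `threshold` | 0.005 | minimal pull that triggers change |
| `palBounds` | (0.1, 4.27) | clamp range for PAL |
| `palRef` | 4.8 | anchor PAL at env = 0 |

`eta`, `lambdaEnv` and `palRef` are calibration constants of the simulator,
not empirical claims, and they interact tightly. Three regime requirements
pin them down:

* **Plateau.** Trajectories must settle within the year. The slowest mode of
  the linearized dynamics decays at rate $\eta\lambda$ per day, and the
  threshold gate freezes agents whose residual pull falls below $\theta$, so
  with $\eta = 0.05$, $\lambda = 0.01$ the day-to-day change of the class
  mean is far below $10^{-4}$ by day 364.
* **Persistence.** The fraction of the initial condition surviving to day
  364 is roughly $e^{-365\,\eta\lambda}$. The success rate divides by the
  *post-boost* day-0 mean, so an intervention only beats control if the boost
  is *amplified* through the network — which requires high persistence
  ($\approx 0.83$ at the defaults) and is precisely what makes centrally
  placed agents matter: their boost carries more weight in the consensus the
  class converges to.
* **Neutral drift.** With env averaging $\approx 1.38$ in the generated
  cohorts, `palRef = 4.8` centers the mean anchor `palRef (2-env)/2` on the
  baseline mean PAL ($\approx 1.5$), so the control condition drifts only
  mildly and individual anchor pulls largely cancel in the class mean.

A stronger environmental pull (larger $\lambda$, e.g. 0.2) looks attractive
because it produces large control-condition increases, but it also collapses
every class onto a boost-independent attractor: the day-0 boost then washes
out, and all interventions score *below* control through the denominator
alone. That configuration contradicts the qualitative result the simulation
exists to probe, so the weak-anchor regime is the default. A consequence
worth stating plainly: success-rate magnitudes under these defaults are of
order 1–3%, smaller than the double-digit rates a strong-drift configuration
would print; the package's tests assert the *ordering* of conditions, which
is robust, and make no claim about absolute magnitudes. All four constants
are exposed in `simConfig()`, so other anchor/mixing choices can be swapped
in without touching code.

Per-agent thresholds are supported (a `threshold` column in the state table);
the default is a single global value, 0.005 — small enough not to block the
social phase, large enough to freeze the late-time anchor creep.

## The synthetic cohort

No empirical dataset ships with the package; `generateCohort()` emulates the
published structure of the study sample:

* 26 classes of 10–30 pupils (all fully observed — the >60% participation
  filter of the field study is not simulated);
* baseline PAL: truncated normal, mean 1.50, SD 0.55 on [0.45, 4.27]; daily
  steps are *derived* from latent PAL (steps = PAL/1.53 × 10⁴ plus day-level
  noise sized so the pooled daily-step SD matches 5,730) and pushed through
  the real measurement pipeline, including invalid days and missing waves.
  The published step mean (10,505) and PAL mean (1.50) are mutually
  inconsistent under the published rescaling (10,505 steps ↔ PAL 1.607); the
  generator anchors on the PAL side, which is what the simulation consumes;
* family-affluence sums: rounded normal, mean 4.01, SD 1.52, clamped to
  0–13;
* nominations: a latent-popularity model. Each pupil gets a log-normal
  popularity weight; the per-question nomination probability is proportional
  to it, scaled per class (by root finding) so the expected density hits a
  target drawn from 0.46–0.90. The popularity dispersion (log-SD drawn from
  0.2–1.0 per class) controls how star-like the class is, which lets the
  cohort span the published in-degree-centralization range. Duplicate
  nominations across waves are injected on purpose so the deduplication rule
  is exercised.

What the generator does **not** emulate: reciprocity beyond chance,
transitivity/clustering, subgroup (clique) structure, sex homophily, and any
correlation between popularity and activity. A green ordering test therefore
establishes that the selection-criterion ranking is robust across the
density/centralization envelope of the generator — not that it survives every
social structure real classes exhibit.

## Statistical evaluation

The per-class success rates (the random condition entering as its 100-replicate
average) are analyzed as in the study design:

* a linear mixed-effects model `success_rate ~ condition + (1 | class)`
  (REML) with four orthogonal planned contrasts — interventions vs control,
  centrality vs random, betweenness+closeness vs in-degree, closeness vs
  betweenness — coded so each coefficient *is* the corresponding difference
  of condition means;
* Satterthwaite degrees of freedom, implemented in-package from the dense
  REML criterion (hessian of −2·logLik via numerical differentiation; the
  asymptotic covariance of the variance parameters feeds the classical
  two-moment approximation). In balanced designs this reproduces the
  classical $(I-1)(J-1)$ df, which the tests assert. At boundary fits
  (class variance ≈ 0) the hessian is singular; the code then falls back to
  the residual df and flags the row — reported, never dropped;
* a one-way repeated-measures ANOVA over conditions with Mauchly's test and
  Huynh–Feldt correction (epsilon clamped at 1, standard practice);
* moderation models adding each standardized structure measure (density and
  the three Freeman centralizations) and its interactions with the planned
  contrasts;
* a 4×4 Pearson correlation matrix of per-class success rates against
  structure measures.

## Numerical and convention choices

* **Centralities are unweighted and directed.** Published in-degree
  descriptives are integer nomination counts, so individual centralities use
  edge presence only; weights act in the simulation. Closeness uses
  *incoming* distances (being reached), in the Wasserman–Faust form for
  disconnected graphs: `(r/(n-1)) · (r/S)` with `r` reached-by peers and `S`
  their distance sum, 0 for unreachable nodes.
* **Freeman centralization** divides `Σ(Cmax − Ci)` by the directed-star
  maximum under the same normalization: the inward star for in-degree, the
  bidirectional star for betweenness (hub betweenness 1) and closeness
  (denominator `(n-1)(n-2)/(2n-3)`). All three scores stay in [0, 1] for
  every class size; the inward star attains exactly 1 for in-degree at any
  *n*.
* **Selection ties.** `k = max(1, round_half_up(0.15 n))`; pupils strictly
  above the cutoff score are always selected, remaining slots are drawn
  uniformly among those tied at the cutoff.
* **Day-0 convention.** Row 1 of a trajectory is the post-boost day-0 state;
  a 365-row trajectory spans days 0–364 with 364 updates. The success-rate
  denominator is that post-boost mean, so the statistic measures diffusion,
  not the boost itself.
* **Exact null-boost equivalence.** With `boost = 0` every condition equals
  control bit for bit; replicate batches are evolved column by column so the
  floating-point path is identical to a single run.
* **Determinism and seeds.** One master seed drives cohort generation;
  per-class × per-condition child seeds are derived arithmetically and logged
  in the results table, so any single run can be replayed in isolation.
* **Clamps.** PAL is clamped to its bounds at every update and after the
  boost; env is clamped to [0, 2] against floating-point drift.

## Known limitations

* The diffusion mechanism is gradual weighted averaging; contagion-style
  threshold-count adoption (a peer changes only after *k* peers changed) is
  out of scope and would plausibly reorder the conditions.
* The one-year success-rate magnitudes are calibration-dependent (see above);
  only condition orderings and their statistics should be interpreted.
* Cohort realism is limited to the descriptive envelope listed above; no
  attempt is made to fit real nomination processes.
* Moderation analyses inherit the generator's structure distributions;
  correlations between moderators (e.g. density and centralization are
  negatively related by construction) are not deconfounded.
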