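---
title: "An evolutionary agent-based model of P-hacking and the significance threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An evolutionary agent-based model of P-hacking and the significance threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phacksim)
```

## The question

Would moving the conventional significance threshold from *P* < 0.05 to
*P* < 0.005 reduce the false-positive rate of the published literature, given
that researchers respond to publication incentives?  `phacksim` addresses this
with an evolutionary agent-based model: a fixed-size population of simulated
researchers who run experiments, test one or more hypotheses, publish any
nominally significant finding, and whose methods spread through selective
replacement — successful publishers are imitated by the researchers who
replace retirees.

A closed-form benchmark frames the question.  Among significant results, the
expected false-positive fraction is

$$\mathrm{FPR} = \frac{\alpha}{\alpha + \text{power} \times \text{odds}},$$

where *odds* is the prior odds of the alternative hypothesis.  At prior odds
1:10 and power 1 this gives 33% at $\alpha = 0.05$ and about 5% at
$\alpha = 0.005$ (`analytic_fpr()`).  The agent-based model asks what happens
when power, hypothesis counts and effort are not fixed but evolve under
publication pressure.

## The model

**Agents.** Each researcher carries effort $E$, a hypothesis count $k$, a
cumulative publication count ("value", the fitness currency), an age, a
personal effect-size scale $d_i$, and tallies of true- and false-positive
publications.

**Effort and productivity.** In each discrete time step a researcher
completes an experiment with probability
$p = \exp(-\eta\,[E - E_{\min}])$ (`experiment_probability()`): effort slows
you down.  It also helps you: effort doubles as the per-group sample size of
a balanced two-sample *t*-test, so an experiment has $2E - 2$ degrees of
freedom and a true effect $d$ yields a noncentrality parameter
$\lambda = d\sqrt{E/2}$.  Because effort mutates continuously, $E$ and the
degrees of freedom are real-valued; the noncentral *t* is defined for
non-integer df, so no rounding is applied.

**Simulated truth.** True Cohen's $d$ effect sizes are exponential:
$P[d \le x] = 1 - \exp(-x/d_0)$.  An effect at or below the minimally
relevant size $d_{\min}$ counts as a true null, so the null prior is
$P[H_0] = 1 - \exp(-d_{\min}/d_0)$, and conversely
$d_0 = -d_{\min}/\ln(1 - P[H_0])$ (`scale_from_prior()`); with
$d_{\min} = 0.2$ and $P[H_0] = 0.8$, $d_0 = 0.1243$.

**Hierarchical effect scales.** Each researcher receives a personal scale
$d_i$, itself an exponential draw at scale $d_0$, and their per-hypothesis
effects $d_{ij}$ are exponential at scale $d_i$.  This is the default
(`hierarchical_effects = TRUE`).  A flat mode ($d_i \equiv d_0$ for everyone)
is available; under it the null-prior formula is exact per test, whereas the
hierarchical marginal of $d_{ij}$ is heavier-tailed.  Both modes produce the
same qualitative scenario ordering.

**Testing and publication.** An experiment draws $k$ effects, then $k$
statistics from the noncentral *t*.  The researcher publishes if *any*
statistic exceeds the uncorrected two-sided critical value at $\alpha$ —
this unadjusted multiplicity is the modelled P-hacking.  Privately, the
simulator scores the outcome a true positive only when some single test has
both $d_{ij} \ge d_{\min}$ and a statistic beyond the Šidák-corrected
critical value at $\alpha_S = 1 - (1-\alpha)^{1/k}$ (`sidak_alpha()`,
`classify_outcome()`).  Any published outcome failing that joint condition is
a false positive.  Rejection is two-sided by default (`two_sided = TRUE`);
effects are non-negative, so the upper tail dominates, and a one-sided
reading is available through the flag.  Ties at the critical value reject on
strict inequality — a probability-zero event for continuous statistics.
Publication uses only the uncorrected threshold; the corrected one exists
solely for the simulator's truth bookkeeping, even when an agent's $k$
changes over its career.

**Evolution.** After the experiments of a step resolve (synchronously,
against beginning-of-step state), each researcher independently retires with
probability $p_{\text{retire}}$.  Each vacancy is filled by a new researcher
who copies $(E, k)$ from a parent drawn uniformly from the top
$\lceil LM \cdot N \rceil$ survivors ranked by value (ties broken at
random), then mutates: $E$ by $\mathcal{N}(0, \sigma_E)$ clipped to
$[e_{\min}, e_{\max}]$, $k$ by $\mathcal{N}(0, \sigma_k)$ rounded to the
nearest integer (a symmetric rule, needed because $k$ is integral) and
clipped to $[k_{\min}, k_{\max}]$.  Entrants get value 0, age 0 and a fresh
$d_i$ — effect-size luck is not heritable, only methods are.  No
within-lifetime imitation is modelled; selection acts through replacement
alone, the simplest mechanism consistent with imitation of high publishers.
Survivors age one step whether or not they experimented.

## Parameters

| Parameter | Meaning | Default |
|---|---|---|
| `N` | number of researchers | 2000 |
| `e0` | initial effort (all researchers) | 20 |
| `k0` | initial hypotheses per experiment | 1 |
| `emin`, `emax` | effort bounds | 5, 500 |
| `kmin`, `kmax` | hypothesis-count bounds | 1, 50 |
| `sigma_E` | effort mutation sd | 10 |
| `sigma_k` | hypothesis-count mutation sd | 2 |
| `prior_null` | prior probability of a true null | 0.8 |
| `dmin` | minimally relevant effect size (Cohen's d) | 0.2 |
| `eta` | effort cost on the experiment rate | 0.01 |
| `p_retire` | per-step retirement probability | 0.002 |
| `LM` | top fraction eligible as parents | 0.1 |

`phack_params()` validates the set and derives `d0`.  Three scenarios are
compared (`phack_scenario()`): `single` (each researcher tests exactly one
hypothesis, $\alpha = 0.05$), `multi_05` (multiple hypotheses,
$\alpha = 0.05$) and `multi_005` (multiple hypotheses, $\alpha = 0.005$).

## Scales, seeds and numerical choices

The full design is 50000 steps and 100 replicates per scenario–prior cell at
N = 2000.  The package's standard working scale is the `reduced` preset —
N = 200, 5000 steps, 20 replicates — which preserves the scenario ordering
and the approximate locations of the final false-positive-rate distributions
while running a three-scenario comparison in minutes on one core; the test
suite and the bundled acceptance script both use it.  One caveat comes with
the preset: evolution advances at roughly `p_retire * n_steps` population
turnovers per run — about 10 at the reduced scale against 100 at the full
design — so the reduced run samples the dynamics mid-transient.  In
particular the pooled false-positive rate of the uncorrected multiple-testing
scenario is still rising at the reduced preset's final step (inspect
`run$summary$pooled_fp_rate`), and reduced-scale medians sit below the
plateau that longer runs of the same model reach.  Reduced-scale values are
therefore read as directional, not asymptotic.

Each replicate seeds R's Mersenne–Twister generator once
(`replicate_seed()` derives a distinct 32-bit seed per scenario × prior ×
replicate cell from one base seed) and consumes draws in fixed agent order,
making every run bit-reproducible and every cell re-runnable in isolation.
Per-step summaries are symmetric functions of agent state, hence invariant
to agent ordering.

Degenerate inputs are validated at the boundary: $\alpha$ strictly inside
$(0,1)$, effort above 1 so degrees of freedom stay positive (the clip bound
`emin = 5` keeps the engine far from that edge), and populations that lose
all members before replacement raise an error rather than silently
continuing.

## What the summaries report

Two false-positive-rate notions are deliberately distinct:

* **Trajectory panels** (`median_trajectory(records, "median_fp_frac")`)
  track the median across living agents of each agent's career ratio
  FP/(TP+FP), excluding agents who have not yet published.  The pooled
  running ratio is also recorded (`pooled_fp_rate`).
* **Final-step histograms** (`final_histograms()`, `cumulative_fp_rate()`)
  use the replicate-level pooled ratio: total false positives over total
  publications of the researchers alive at the final step.  Replicates with
  zero publications are excluded from histograms and counted.

The hypothesis-count histogram uses unit-width integer bins; the
false-positive-rate histogram defaults to bin width 0.025, fine enough to
resolve a cluster between 0.875 and 0.9.

## What the generator does and does not emulate

All data are self-generated: the model emulates idealized null-hypothesis
testing with correctly computed *t* statistics, honest (if unadjusted)
analyses, and truth known to the simulator.  It does not emulate the garden
of forking paths, data peeking or exclusion, publication lag, peer review
errors, replication attempts, or heterogeneous journals.  Passing tests
therefore demonstrate properties of this incentive model — not estimates of
any real literature's false-positive rate.

## Limitations

* Evolution acts only through replacement; a within-lifetime imitation rule
  could speed or alter convergence.
* The parent-selection rule (uniform over the top `LM` fraction by value) is
  the simplest reading of imitation of "better" methods; rank-proportional
  selection would concentrate it further.
* Whether a retiree's successor should inherit the retiree's effect-size
  scale is an open modelling choice; the package draws fresh scales.
* The reduced preset trades asymptotic convergence for runtime, as noted
  above.

## A worked comparison

```{r, eval = FALSE}
params <- preset_params("reduced", prior_null = 0.8)
grid <- run_experiment_grid(
  params, scenarios = c("single", "multi_05", "multi_005"),
  priors = 0.8, base_seed = 1)
grid          # prints per-scenario median final FP rates
final_histograms(grid$runs[grep("^multi_05", names(grid$runs))])
```

The same comparison is scripted in `scripts/acceptance.R` and available from
the shell via the `phacksim` executable (`run`, `grid`, `analytic`, `plot`
subcommands).
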