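# phacksim

An evolutionary agent-based model of P-hacking researchers, built to ask a
policy question in metascience: **if journals redefine statistical
significance from P < 0.05 to P < 0.005, what happens to the false-positive
rate of the published literature when researchers adapt?**

The audience is methodologists and modellers studying publication incentives
and questionable research practices, and anyone who wants a reproducible
sandbox for significance-threshold interventions.

## The model

A fixed population of `N` researchers evolves over discrete time steps.
Each researcher carries effort `E`, a hypothesis count `k`, a cumulative
publication count ("value", the fitness currency), and a personal
effect-size scale.

* **Effort trades productivity for power.** An experiment completes in a
  step with probability `p = exp(-eta * (E - Emin))`; but effort doubles as
  the per-group sample size of a balanced two-sample t-test, giving
  `df = 2E - 2` and noncentrality `lambda = d * sqrt(E / 2)` for a true
  effect `d`.
* **Truth is simulated.** True Cohen's d effects are exponential,
  `P[d <= x] = 1 - exp(-x / d0)`; effects at or below a minimally relevant
  size `dmin` count as true nulls, so the null prior is
  `P[H0] = 1 - exp(-dmin / d0)` and conversely
  `d0 = -dmin / ln(1 - P[H0])` (0.1243 at `dmin = 0.2`, `P[H0] = 0.8`).
* **P-hacking is unadjusted multiplicity.** A researcher tests `k`
  hypotheses and publishes if *any* statistic beats the uncorrected
  critical value at `alpha`.  The simulator privately scores a true
  positive only when some single test has both `d >= dmin` and a statistic
  beyond the Šidák-corrected critical value at
  `alpha_S = 1 - (1 - alpha)^(1/k)`; every other publication is a false
  positive.
* **Methods evolve.** Researchers retire at rate `p_retire`; replacements
  copy `(E, k)` from a parent drawn from the top `LM` fraction by value and
  mutate both with Gaussian noise, clipped to bounds.

Three scenarios are compared: `single` (one hypothesis, alpha 0.05),
`multi_05` (multiple hypotheses, alpha 0.05) and `multi_005` (multiple
hypotheses, alpha 0.005).

A closed-form benchmark accompanies the simulation: among significant
results the expected false-positive fraction is
`alpha / (alpha + power * odds)`, which at prior odds 1:10 and power 1
gives 33% at alpha 0.05 and about 5% at 0.005.

## Worked example

```r
library(phacksim)

round(scale_from_prior(0.2, 0.8), 4)
#> [1] 0.1243
analytic_fpr(c(0.05, 0.005), power = 1, prior_odds_alt = 0.1)
#> [1] 0.33333333 0.04761905

p <- phack_params(N = 100, n_steps = 1000, n_replicates = 4)
g <- run_experiment_grid(p, scenarios = c("single", "multi_05", "multi_005"),
                         priors = 0.8, base_seed = 1)
g
#> <phack_grid> 12 runs across 3 scenario x prior cells
#>   scenario prior_null median_fp_rate
#>  multi_005        0.8      0.3265339
#>   multi_05        0.8      0.5389269
#>     single        0.8      0.4490285

g$runs[["multi_05|0.8|1"]]
#> <phack_run> multi_05 (alpha = 0.05), prior_null = 0.8, seed 5120, 1000 steps
#>   final cumulative FP rate 0.491 (4091 FP / 8334 publications)
```

`median_fp_rate` is, per scenario, the median across replicates of the
cumulative false-positive publication rate — total false positives divided
by total publications of the researchers alive at the final step.  Even in
this very short demonstration run the uncorrected multiple-testing scenario
(`multi_05`) already publishes the most false positives, and the stricter
threshold (`multi_005`) suppresses them; longer runs separate the scenarios
much further as hypothesis counts and effort evolve.  Use
`median_trajectory()` and `final_histograms()` for time courses and
end-of-run distributions, and `preset_params("reduced")` for the standard
working scale (N = 200, 5000 steps, 20 replicates).

From the shell:

```sh
exec/phacksim analytic --alpha 0.05 0.005 --power 1.0 --odds 0.1
exec/phacksim run --scenario multi_005 --prior 0.8 --seed 1 --preset reduced --out out/
exec/phacksim plot --dir out/
```

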