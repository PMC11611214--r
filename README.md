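# transmix

Group-level **transmission assortativity** from who-infected-whom chains.

When an outbreak spreads through a structured population — patients and
healthcare workers on a ward, residents and staff in a care home, school
classes — a recurring question for outbreak investigators is whether groups
transmit preferentially within themselves (assortative), towards other groups
(disassortative), or indifferently (homogeneous mixing). Given a transmission
chain (a line list with group labels, symptom-onset days and infector links)
and a census of group sizes, `transmix` answers this with a closed-form
estimator and an exact confidence interval, with no model fitting.

## The estimator

For group *a* of relative size *f_a*, the assortativity coefficient γ_a is
the multiplicative excess of within-group over between-group transmission
(γ = 1: homogeneous; γ = ∞: transmissions never leave the group). It is
reported on the rescaled scale δ = (γ − 1)/(γ + 1) ∈ [−1, 1], with 0 at
homogeneous mixing. From the chain, count τ_{a←a} (within-group pairs emitted
by *a*) and τ_{·←a} (all pairs emitted by *a*); with
π̂ = τ_{a←a} / τ_{·←a},

    δ̂_a = (π̂ − f_a) / (π̂ + f_a (1 − 2π̂))

and the Clopper-Pearson (exact binomial) interval on π̂ maps through the same
strictly increasing formula to an interval on δ̂_a.

The package also ships the two tools needed to know when to trust the
estimate: a discrete-time, group-structured branching-process outbreak
simulator (per-group R0 and true δ, daily force-of-infection kernel over a
generation-time distribution, binomial infections, multinomial infector
attribution, permanent immunity), and a simulation-study harness measuring
bias, CI coverage, sensitivity and specificity over scenario ensembles, with
analysis windows defined relative to each group's epidemic peak (the peak
coefficient ε; ε = 1 analyses up to the peak).

## Worked example

Simulate a ward outbreak with known truth — patients (census 120) assortative
at δ = 0.6, healthcare workers (census 80) mixing homogeneously — then
estimate each group's δ from the chain analysed up to its own epidemic peak:

```r
library(transmix)

ward <- scenario(group_sizes = c(120, 80), delta = c(0.6, 0),
                 r0 = c(2, 1.5), imports = c(1, 0),
                 labels = c("patient", "hcw"))
ll <- simulate_outbreak(ward, seed = 1)   # 149 cases
estimate_assortativity_peak(ll, scenario_group_table(ward), epsilon = 1)
#> # Transmission assortativity estimates (alpha = 0.05)
#> # A tibble: 2 × 14
#>   group   n_emitted tau_within fraction pi_hat gamma_hat delta_hat ci_low
#>   <chr>       <int>      <int>    <dbl>  <dbl>     <dbl>     <dbl>  <dbl>
#> 1 patient        89         72      0.6  0.809      2.82     0.477  0.244
#> 2 hcw             5          2      0.4  0.4        1        0     -0.846
#>   ci_high alpha status first_case_day peak_day window_end
#>     <dbl> <dbl> <chr>           <dbl>    <dbl>      <dbl>
#> 1   0.673  0.05 ok                  4       57         57
#> 2   0.794  0.05 ok                 27       32         32
```

Reading the output: by their peak, patients emitted 89 transmissions of which
72 stayed among patients — more than the 60% their census share would imply
under homogeneous mixing — giving δ̂ = 0.48 with a 95% CI of (0.24, 0.67)
that excludes 0: significantly assortative, consistent with the simulated
truth of 0.6. The healthcare workers emitted only 5 transmissions by their
peak, so their interval (−0.85, 0.79) is compatible with almost anything —
exactly the sample-size caveat the simulation study quantifies.
`tidy()`, `glance()` and `autoplot()` work on estimates and on study reports;
`estimate_assortativity_trees()` pools the estimator over a posterior sample
of uncertain trees.

A full performance study over an ensemble of nosocomial scenarios:

```r
spec <- ensemble_spec(n_scenarios = 200, n_replicates = 50, base_seed = 1)
report <- run_study(spec, epsilons = c(0.5, 1), alphas = 0.05)
glance(report)
```

A thin command-line wrapper (subcommands `simulate`, `estimate`, `evaluate`)
is installed at `inst/cli/transmix.R`; see `?transmix_cli`.

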