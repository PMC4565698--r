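# aggrank

Dominance rank inference and strategic-aggression statistics for directed
aggression networks.

## The problem

In many social species, dominance hierarchies emerge from dyadic aggression
without any simple cue — body size, markings, spatial position — that could
tell an individual where anyone ranks. Detailed observation studies of
newly formed captive groups (e.g. of monk parakeets) record every
displacement "win" as a timestamped actor → target event, and ask: when
does aggression become *strategic*, i.e. structured by rank over and above
what the rank order itself requires, and what locally observable signals
could individuals be using to infer rank?

`aggrank` implements that complete analysis for R users in behavioral
ecology and animal social network analysis:

* **Power scores and ranks.** The directed win-count matrix `d` is
  row-normalized with a regularizer,
  `t_ij = (d_ij + ε) / Σ_{k≠i} (d_ik + ε)`, and power is scored by
  eigenvector centrality: the stationary distribution `v` of the chain
  `t` (`vᵀ t = vᵀ`). High centrality = low power: an individual has low
  power if it receives much aggression from individuals who themselves
  have low power. Breadth (Weighted Simple Consensus: incoming events ×
  distinct aggressors) and David's Score are included for comparison, with
  event-bootstrap uncertainty for scores and ranks.
* **A hierarchy-constrained null model.** Random aggression networks that
  reproduce the observed power scores *on average* and every individual's
  total outgoing aggression *exactly*, but are otherwise unstructured.
  Deviations of the data from this null isolate behavior that the rank
  order alone cannot explain.
* **Rank-aggression profiles.** Average rank aggression
  `R(Δ) = Σ_i d_{iΔ} / (N_Δ T_obs)` — per-individual, per-unit-time
  aggression at targets exactly Δ ranks away — with ±1-rank smoothing,
  bootstrap bands, and the above-null ratio of aggression at targets one
  to five ranks below.
* **Aggression-chain motifs.** Over all directed paths of `n` nonzero
  edges with distinct individuals: weighted rank difference `W(n)` (how
  much a chain tells an observer about the rank gap between its ends) and
  fractional transitivity `T(n)` (whether the chain's originator attacks
  the terminal individual more or less than its baseline), both with null
  bands. Enumeration is depth-first in C++ and is cross-checked against a
  naive all-tuples reference implementation.
* **A synthetic event-stream generator** with latent ranks and a
  configurable rank-difference attack kernel (nearby-below focus,
  far-below avoidance, downward bias, and an unstructured early phase), so
  the whole pipeline is testable end to end with no field data.

## Worked example

```r
library(aggrank)

sim <- simulate_events(generator_config(N = 20, total_events = 1200,
                                        phase_change_day = 6, seed = 42))
log <- apply_win_cooldown(sim$log, cooldown = 60)
m   <- build_matrix(log)
network_density(m)
#> [1] 0.8263158

ec  <- ec_power(normalize_aggression(m, epsilon = 0.01))
ord <- rank_order(ec)
head(sort(ord), 3)
#> B03 B06 B18
#>   1   2   3
rank_agreement(ec, wsc_power(m))$signed_r2
#> [1] 0.8937493

kernel <- fit_null_kernel(ec)
ens    <- sample_null_ensemble(kernel, rowSums(m), B = 200, seed = 1)
prof   <- rank_aggression(m, ord, log$t_obs_min)
res    <- above_null_ratio(prof, ens, ord, log$t_obs_min, delta_range = c(1, 5))
sprintf("nearby-rank aggression: %.2f x null (p = %.3f)", res$ratio, res$p)
#> [1] "nearby-rank aggression: 1.87 x null (p = 0.005)"

chain_statistics_suite(m, ord, ens, max_n = 3)[, c("n", "W", "W_null_mean", "T", "T_null_mean")]
#>   n        W W_null_mean          T T_null_mean
#> 1 1 1.352500    1.987625         NA          NA
#> 2 2 1.724310    1.981877 0.24860381   0.1731641
#> 3 3 1.870564    1.980442 0.03047883   0.1701393
```

Reading the output: the group's rank order is recovered from the win
network (here `B03` is the most dominant individual); depth-based EC and
breadth-based WSC rankings agree strongly (signed r² 0.894); aggression at
targets one to five ranks below the actor runs 1.87× the
hierarchy-constrained null expectation (empirical p = 0.005), the
signature of rank-focused strategic aggression; and `W(n)` rises with
chain length while the null stays flat, i.e. aggression chains carry rank
information that unstructured networks with the same power scores would
not.

The full pipeline — ingest, cooldown filter, exclusions, study-quarter
windows, all three scorings with bootstrap, null ensembles, profiles,
chain statistics, covariate signals, tidy CSVs and a JSON run manifest —
runs from one config:

```r
run_analysis(list(events_csv = "events.csv", rng_seed = 1), out_dir = "out/")
# or from YAML:  run_analysis("config.yaml", out_dir = "out/")
```

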