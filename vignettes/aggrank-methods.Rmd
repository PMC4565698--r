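---
title: "Methods: rank inference and strategic-aggression statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank inference and strategic-aggression statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`aggrank` analyses timestamped dyadic aggression logs from animal social
groups. This vignette is the package's account of its models and the
design decisions behind them. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## Data model and filtering

The raw observable is a *win event*: at time `t`, actor `i` displaces
target `j`. A log couples the ordered event table with a fixed roster and
the total observation time `T_obs` (minutes). Three filters reflect
standard field protocol:

* **Win cooldown** (`apply_win_cooldown`, default 60 s). Actors often
  deliver strings of rapid sub-attacks; a win is scored only after a
  cessation of at least the cooldown toward that target. The clock resets
  from the last *retained* event of the ordered pair, so a continuous
  barrage yields one win per cooldown period. Resetting from the last raw
  event would let a sustained barrage score a single win forever, which
  contradicts the "one full win per target per minute" reading of the
  protocol; it was rejected. The rule is applied per ordered pair (actor
  toward target), not per actor across all targets, which is the literal
  reading of "cessation of aggression from the actor toward the target".
* **Windows** (`split_windows`, default 6 days, i.e. study quarters of a
  24-day observation). Windows are half-open `[start, end)` in event
  time; an event at a boundary belongs to the later window. The study
  duration must be an exact multiple of the window length unless forced.
* **Exclusions** (`exclude_individuals`). Individuals whose incoming
  aggression is reactive rather than strategic (e.g. a bird whose
  persistent affiliation attempts provoke rebuffs) can be dropped; all
  their events are removed, the roster shrinks, `T_obs` is unchanged.

Network density is reported over *ordered* pairs by default. The dyadic
(unordered) convention is available by flag; the directed convention is
the natural one for a directed network and the two differ only in a known
factor for symmetric presence patterns.

## Power scores

Win counts `d_ij` are normalized with a regularizer ε:

    t_ij = (d_ij + ε) / Σ_{k≠i} (d_ik + ε),   t_ii = 0.

The eigenvector-centrality power score is the stationary distribution of
the chain `t`: the unique probability vector with `v_i = Σ_j v_j t_ji`.
Centrality accrues through incoming aggression, recursively: an
individual has low power if it receives much aggression from individuals
who themselves have low power, and high score therefore equates to low
power. Note that the row-wise averaging fixed point `v_i = Σ_j t_ij v_j`
is degenerate for a row-stochastic matrix — its only solution is the
uniform vector — so it cannot express this recursion; the stationary
equation is the orientation that does, and the two coincide under a
transposed index convention. This choice is flagged here prominently
because it is easy to implement the degenerate version by accident.

Numerical choices: ε defaults to 0.01, well below typical row totals
(tens of events per individual) yet sufficient to make the chain
irreducible; results should always be reported with the ε used, and the
`rank_profile`/pipeline outputs carry it in the manifest. The stationary
distribution is computed by dense eigen-decomposition of the transpose
for N ≤ 64 and by power iteration (tolerance 1e-12, cap 1e5 iterations)
above. With ε = 0 a reducible chain produces an error advising
regularization rather than a silent wrong answer. Rank 1 is the most
dominant individual (lowest EC score); ties break by stable roster order
and the policy is recorded on the rank vector. The regularizer is added
only off-diagonal; adding it on the diagonal too would lazily self-loop
the chain without changing the stationary distribution's ordering, and
was not done.

Two further scorings serve as comparisons: Weighted Simple Consensus
(incoming events × distinct aggressors; breadth only) and David's Score
(dyadic win proportions accumulated two steps into the network). Both are
exact arithmetic on the matrix; agreement between scorings is summarized
as signed coefficients of determination `sign(r)·r²`, a convention that
keeps anticorrelated scorings visibly negative. Whether such r² values
are Pearson- or Spearman-based is ambiguous in parts of the literature;
both are emitted.

Bootstrap uncertainty resamples events with replacement at the observed
event count and re-scores end to end; 1σ score ranges are mean ± sd over
replicates. For rank-aggression profiles the bootstrap re-derives ranks
per replicate (full-pipeline bootstrap) by default.

## The hierarchy-constrained null model

A group of N individuals has N(N−1) free parameters in its aggression
network but only N−1 are needed to specify power scores: scores are a
lossy compression, and many networks share one hierarchy. The null model
samples from that larger set — networks that preserve the observed power
scores *on average* and each individual's total outgoing aggression
*exactly*, but carry no other structure.

Construction (`fit_null_kernel`): initialize the kernel as an
independence model `t_ij ∝ v_j` (zero diagonal, rows normalized), then
iterate: compute the stationary distribution `w`; rescale column `j` by
`v_j / w_j`; zero the diagonal; renormalize rows; stop when
`max_j |w_j − v_j| < 1e-8` (cap 10 000 iterations; infeasible targets —
e.g. any two-individual chain with unequal scores, whose kernel is forced
to the alternating matrix — error out with the achieved residual).
The construction injects no structure beyond the stationary constraint:
given the kernel, every individual's targets are conditionally
independent categorical draws. Sampling (`sample_null_ensemble`)
redistributes each individual's observed outgoing total as one
multinomial draw per row, so row totals are conserved exactly in every
sample while individual samples fluctuate around the target scores with
multinomial noise — only the ensemble mean is constrained, which is what
"on average the same v" licenses. Exact uniform sampling from the fiber
of matrices whose EC equals `v` exactly is a measure-zero problem and a
non-goal. Whether incoming totals or dyad presence should also be
preserved is a genuinely open question; this construction preserves
outgoing totals only, and the kernel, residual, iteration count and seed
are always recorded so results are auditable.

Null statistics hold ranks at the *observed* ordering rather than
re-ranking each sample: the null preserves the power scores by
construction, so re-ranking would only permute near-ties and add noise.
Empirical p-values are one-sided with the finite-sample correction
`p = (1 + #{null at least as extreme}) / (B + 1)`; samples on which a
statistic is undefined are dropped and counted.

## Rank-aggression profiles and the above-null ratio

Average rank aggression is

    R(Δ) = Σ_i d_{iΔ} / (N_Δ · T_obs),   N_Δ = N − |Δ|,

where `d_{iΔ}` is the aggression individual `i` directs at the individual
*exactly* Δ ranks away (one target per actor per Δ; the within-Δ reading
would not reproduce `N_Δ = N − |Δ|`), Δ > 0 pointing down the hierarchy.
The internal unit is events per individual per minute; figures
conventionally rescale to per-1000-minutes at presentation time only. The
identity `Σ_Δ R(Δ)·N_Δ·T_obs = total events` holds exactly on unsmoothed
profiles and is asserted in tests. Presentation smoothing averages ±1
rank with no phantom values at the gaps.

The headline effect size is the ratio of observed to null-expected
aggression at targets one to five ranks below
(`above_null_ratio`, `delta_range = c(1, 5)`), with its one-sided
empirical p. A ratio of 1.49 reads "49% above null".

## Chain statistics W(n) and T(n)

An aggression chain of length n is a directed path of n nonzero edges
whose n+1 individuals are pairwise distinct; n counts *edges*, so a
2-chain is `i → j → k`. Chains are weighted by the product of their edge
counts.

* `W(n)`: chain-weighted mean of `rank(terminal) − rank(origin)`. It
  measures how much the observation of a chain tells a watcher about the
  rank gap between its ends; `W(1)` is the dyadic weighted mean rank
  difference of aggression.
* `T(n)`: chain-weighted mean of `(d_{origin,terminal} − d̄) / d̄`, where
  the baseline `d̄` is the origin's mean aggression toward all
  individuals other than the chain's interior members. Positive values
  mean chain terminals attract above-baseline aggression from the
  origin; negative values mean they are avoided.

For n = 2 the baseline excludes exactly the intermediate `j`. For longer
chains the published 2-chain rule does not determine the generalization,
so both are implemented: excluding all interior members (default) and
excluding only the first intermediate (the literal extension); they
coincide at n = 2 and results report the variant used. Chains whose
baseline is zero are excluded from the T sums and counted; an additive
ε-regularized baseline is available instead.

Enumeration is depth-first over nonzero edges with a visited mask,
implemented in C++; cost grows as `N!/(N−n−1)!`, a dense 21-individual
network at n = 6 (≈ 4.8 × 10⁸ chains) completes in well under a minute,
and a configurable visit cap aborts with a clear error beyond that. A
deliberately naive all-tuples reference (`chain_stats_naive`, pure R,
sharing no code with the optimized path) is exported; equality to 1e-12
on random small matrices is part of the acceptance surface. Both
statistics are invariant to scaling the whole matrix by a positive
constant, and chains with repeated individuals provably contribute
nothing — both properties are asserted in tests.

The suite (`chain_statistics_suite`) reports each statistic with its null
mean, 1σ band and one-sided empirical p in the direction of the observed
deviation, by default to `max_n = 4` in pipelines (null samples are
denser than observed matrices, and enumerating B null samples at n = 6
costs ~10¹⁰ visits; single-matrix n = 6 is routine).

## Simpler signals of rank

Two covariate analyses test whether rank could be read off cheaper cues.
Morphometrics (wing chord, culmen depth, culmen width, mass) are
correlated per trait with ordinal rank, reported as signed r² with
two-sided p. Nearest-neighbour scan samples build the dyadic table of
"times i was j's nearest neighbour" over ordered pairs (undirected
pooling by flag) against `|Δrank|`; a strongly negative signed r² would
mean spatial proximity encodes rank. Degenerate inputs (constant traits,
a single scan) are flagged, not fatal.

## The synthetic generator

`simulate_events` draws a marked point process: uniform event times over
the study period, actors at configurable rates (uniform by default), and
targets from a rank-difference kernel — uniform before `phase_change_day`
(default day 6, emulating the unstructured first week of a newly formed
group), structured after. The structured kernel has three knobs on the
signed rank distance Δ = rank(target) − rank(actor):

| knob | region | default | role |
|---|---|---|---|
| `focus_strength` | 1 ≤ Δ ≤ `focus_width` (5) | 3 | rank-focused aggression at nearby-below targets |
| `avoidance_strength` | Δ > `focus_width` | 3 | avoidance of far-below targets |
| `upward_penalty` | Δ < 0 | 8 | downward bias of wins |

Defaults (N = 20, 1200 events, 24 days) match the scale of the captive
study the data model emulates. The downward bias exists because events
are displacement *wins*: with symmetric up/down weighting the incoming
aggression profile is hump-shaped in rank and eigenvector centrality
cannot recover the latent order, whereas real win networks are strongly
down-biased. At the defaults the latent order is recovered with Spearman
correlation ≥ 0.9 (asserted in tests). Focus and avoidance are separate
knobs because rank focus and far-below avoidance are distinct behavioral
signatures — one produces the nearby-rank aggression excess, the other
the preference inversion in T(n) — and a single dial cannot vary them
independently. Setting all three knobs to 1 makes the structured kernel
exactly uniform.

What the generator deliberately does not emulate: the cognitive feedback
loop itself (agents updating rank beliefs from observations — the kernel
is fixed within a phase), observer effort variation, missing-data
patterns, affiliative behavior, or within-day activity rhythms. Passing
tests therefore show that the *measurement pipeline* recovers structure a
rank-dependent kernel puts in; they do not validate any cognitive
mechanism on real data.

`simulate_scans` and `simulate_morphometrics` provide covariate tables
with configurable coupling to latent rank (zero coupling reproduces the
no-simple-cues regime), at scales plausible for a small parrot.

## Demonstration sizes and estimator choices

The acceptance checks run at these sizes, chosen to balance statistical
resolution against desk-scale runtimes:

* Oracle equivalence: 50 random matrices, N ≤ 7, n ≤ 5, tolerance 1e-12.
* Null validity: N = 10 hierarchy, B = 200 samples; ensemble-mean EC
  within 0.01 (max norm) of target, row totals exact in every sample.
* Rank-focus recovery: one structured group at the study scale
  (focus 3, N = 20, 1200 events), B = 200; ratio ≥ 1.5, p < 0.05.
* Null consistency of the unstructured phase: 50 seeds, B = 50; pooled
  2σ-band coverage over all of R(Δ), W(1..3), T(2..3) ≥ 0.90. Coverage is
  pooled over (seed, statistic) pairs because ~40 statistics are tested
  jointly per seed and marginal 2σ coverage is ≈ 95%; demanding every
  statistic inside for 90% of seeds would fail even for data drawn from
  the null itself.
* Chain signatures: means over a campaign of six replicate groups of
  2400 events (the pooled multi-window scale at which the inversion
  analysis is run). Weighted-chain statistics are dominated by a handful
  of heavy chains and are noticeably heavy-tailed on single groups —
  T(3) in particular has mean ≈ −0.08 and sd ≈ 0.04 under strong
  avoidance, so a single group flips sign a few percent of the time; the
  campaign mean is the appropriate estimator for a qualitative-signature
  claim. The W demonstration uses mild avoidance (1.5): strong avoidance
  truncates chains' down-hierarchy reach and weakens the growth of W with
  n, while the inversion demonstration uses the saturated
  strong-avoidance regime (30; the statistic is flat in this knob beyond
  ~30). The two regimes correspond to the two distinct findings the
  signatures formalize.

## Known limitations

* The EC orientation (stationary distribution) and the T(n > 2) baseline
  generalization are documented choices where the source conventions are
  ambiguous; both alternatives are either implemented or explained above.
* The null kernel's column-rescaling iteration has no global convergence
  proof; it converges in a handful of iterations for every hierarchy the
  generator produces, and failure is loud (residual in the error).
* Monotonicity of EC in incoming aggression is a sanity expectation, not
  a theorem — centrality is global, and adding incoming aggression can in
  principle rearrange the whole stationary distribution. It is not
  asserted in tests.
* Profile bootstrap bands and null bands treat events as exchangeable;
  serial dependence within observation sessions is not modeled.
* The n = 3 preference inversion is intrinsically weak at study scale
  under a static kernel; real data with behaviorally driven avoidance may
  show stronger effects than the generator can produce.
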