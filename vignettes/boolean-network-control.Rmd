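---
title: "Driving Boolean networks with pinned seed sets: the model behind boolcontrol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driving Boolean networks with pinned seed sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolcontrol)
```

## The problem

A Boolean network is a set of $N$ binary variables $\sigma_i(t) \in \{0,1\}$,
each updated by a fixed lookup table $F_i$ of the states of its regulators:
$\sigma_i(t) = F_i(\vec\sigma_{\mathcal{N}_i}(t-1))$. Under synchronous
update the dynamics is deterministic, and every trajectory is absorbed by an
attractor — a fixed point or limit cycle. In models of gene regulation the
attractors play the role of cell fates, so a central question is: **which
small set of nodes must be held fixed (pinned) so that the system reaches a
desired attractor from any initial condition?** Exhaustive answers require
the state-transition graph (STG) over all $2^N$ configurations and are
limited to very small networks; `boolcontrol` implements a mean-field
route that scales to larger sparse networks and validates it against the
exhaustive one.

## The individual-based mean-field approximation

Instead of a binary state, each node carries an activation probability
$s_i(t) = P(\sigma_i(t) = 1)$. Neglecting dynamical correlations between
regulators, the probability of each regulator configuration factorises into
marginals, and the update sums the lookup-table rows whose output is 1:

$$
s_i(t) \;=\; \sum_{\{n_j\}} \delta_{1,\,F_i(\vec n)}
\prod_{j \in \mathcal{N}_i} s_j(t-1)^{n_j}\,[1 - s_j(t-1)]^{1-n_j}.
$$

This *individual-based mean-field approximation* (IBMFA, `ibmfa_run()`)
is specific to one quenched network — one wiring, one rule set — unlike
annealed-ensemble mean-field theories, which average over network
ensembles. Two exactness properties anchor the approximation and are
enforced by tests:

* if the initial state is fully deterministic ($s_i(0) \in \{0,1\}$), the
  IBMFA trajectory coincides bit-for-bit with the exact synchronous
  trajectory;
* on networks whose regulators never share ancestry (trees), the IBMFA
  marginals equal the exact marginals at every time.

Elsewhere it is an approximation; its quality is measured by the mean
squared error $e(t)$ of `ibmfa_mse()` against the ensemble mean of $R$
exact simulations, compared with the leave-one-out variance baseline
$b(t)$ of `baseline_variance()` — the error an observer of a single run
would make. Per step the IBMFA costs $O(\sum_i 2^{k_i} k_i)$: linear in
$N$, exponential only in the in-degree.

## Influence of a pinned seed set

A seed set $\mathcal{X} = \{(i, \hat\sigma_i)\}$ pins each of its nodes to
a fixed state for all $t \ge 0$ (`seed_set()`). Its dynamical influence is
measured by the residual uncertainty left in the network when only the
seeds are known: start from $s_i(0) = \hat\sigma_i$ for seeds and
$s_i(0) = 1/2$ for all other nodes, iterate the IBMFA to a horizon $T$,
and evaluate the normalized entropy

$$
H(\vec s) = \frac{1}{N} \sum_{i=1}^N h_2(s_i), \qquad
h_2(s) = -s\log_2 s - (1-s)\log_2(1-s),
$$

(`residual_entropy()`). $H = 1$ means every free node is maximally
uncertain; $H = 0$ means the long-term configuration is fully determined —
the seed set is a *driver set*. Pinned nodes contribute zero entropy but
stay in the denominator $N$, exactly as the formula is written, so
$H(t{=}0) = (N - |\mathcal{X}|)/N$. Because the formula assumes
independent nodes, it upper-bounds the true normalized joint entropy when
evaluated on exact marginals; for the approximate mean-field marginals no
bound holds in general, which is why the package also ships the exact
references `exact_marginal_entropy()` and `exact_joint_entropy()` for
networks small enough to enumerate.

## Greedy driver-set selection

`greedy_unconstrained()` builds a seed set one tuple at a time: at each
stage every candidate `(node, state)` not yet pinned is scored by the
residual entropy it would leave, and the minimizer is added. The search
stops when $H \le \varepsilon$. `greedy_constrained(net, target)` is the
same search with candidates restricted to the states the target fixed
point prescribes, so convergence means control *toward that attractor*.
The overall cost scales as $O(N^3 \, 2^{k_{\max}})$.

Because greedy selection is sub-optimal, a converged set is post-processed
by `prune_driver_set()`: tuples are removed one at a time (in addition
order, with repeated passes) whenever removal keeps the entropy at zero.
The result is single-removal minimal and the procedure is idempotent.

Design choices that the underlying method leaves open, fixed here once:

* **Convergence of the constrained search.** Zero residual entropy means
  the mean-field limit is *some* frozen configuration, not necessarily the
  target: on the yeast network three targets freeze elsewhere. The
  constrained search therefore only declares convergence when additionally
  $|s_i(T) - \tilde\sigma_i| \le \varepsilon$ for every node, and pruning
  preserves the same predicate. The unconstrained search keeps the plain
  $H \le \varepsilon$ criterion.
* **Tie-breaking.** Candidates whose entropies differ by less than
  $10^{-12}$ are resolved by lowest node index, then state 0 before 1;
  this makes every search bit-reproducible.
* **Horizon.** $T = 10$ by default: on the bundled networks the entropy
  trajectories plateau at $t \simeq 10$ and the ranking of seed sets is
  stable beyond it. $T$ is exposed everywhere for re-checking.
* **Zero-entropy tolerance.** $\varepsilon = 10^{-4}$ normalized bits; the
  method converges geometrically, and the acceptance tests re-run the
  headline scan at $10^{-3}$ and $10^{-6}$ to confirm the classification
  of controllers does not move.
* **Pruning order.** Addition order with repeated passes; the method
  description does not fix an order, and this one is deterministic and
  idempotent.

Validation against the exact dynamics is independent of the mean field:
`validate_driver_set()` pins the seeds and either enumerates every
compatible initial configuration (small $N$) or samples them (large $N$),
reporting the fraction absorbed by the target.
`brute_force_minimal_driver()` enumerates all candidate seed sets of
increasing size and returns the provably minimal drivers — the ground
truth the greedy result is judged against.

## Exhaustive machinery and its limits

`build_stg()`/`find_attractors()` enumerate at most $2^{22}$ states
(configurable cap) and return attractors with exact basin sizes that
partition the enumerated space. For larger networks, `fixed_points()`
enumerates fixed points through a feedback vertex set: any fixed point is
determined by its values on an FVS of the regulatory graph, so
$2^{|\mathrm{FVS}|}$ candidate assignments, propagated through the acyclic
remainder in topological order and checked for self-consistency, find all
fixed points. This works for the 60-node parasegment model (FVS of 12)
but says nothing about limit cycles; `simulate_trajectory()` and the
sampling mode of `validate_driver_set()` cover those. The constrained
search itself is restricted to fixed-point targets: a pinned seed set
freezes marginals, which cannot represent phase information on a limit
cycle.

## Update schemes

All results above use synchronous update. For robustness studies,
`simulate_trajectory()` also implements deterministic-asynchronous
(ascending index within a round), stochastic-asynchronous ($N$ uniformly
random substeps per time unit, seeded) and block-deterministic
(user-supplied ordered partition) schemes — the standard definitions, as
the method source does not pin them down. Fixed points are invariant
across schemes (tested); basin sizes are not. The mean-field update
itself is synchronous only; an asynchronous mean field would be an
experimental extension and is not used by any shipped analysis.

## What the generators and fixtures emulate

`make_rbn()` builds the classic homogeneous-in-degree random Boolean
ensembles: a directed ring for $k = 1$, an undirected ring for $k = 2$,
uniform random wiring (resampled until no node is isolated) for
$k \ge 3$, and i.i.d. output bits with bias $p$ (default $1/2$, the
chaotic regime for $k \ge 2$). These are the stated test conditions of
the method's accuracy experiments ($N = 100$, $R = 100$ initial
configurations drawn with $s_i(0) = 1/2$); they emulate homogeneous
sparse regulation and none of the degree heterogeneity, canalization or
effective-connectivity structure of curated biological models — so a
green test on RBNs establishes correctness of the machinery, not
biological realism.

Three published gene-regulatory models are bundled as plain-text
fixtures and re-verified at test time by recomputing their published
invariants:

* `spn17` — the single-cell *Drosophila* segment-polarity network
  ($N = 17$; the three external signals SLP, nWG, nHH are frozen
  inputs). Recomputed: 10 attractors, all fixed points; exactly three
  seed sets of size 3 (and none smaller) have zero residual entropy.
* `yeast12` — the budding-yeast cell-cycle threshold network
  ($N = 12$ including the frozen cell-size signal; activating/inhibiting
  unit weights, ties retain state except for the five self-degrading
  nodes). Recomputed: 11 attractors, all fixed points; the cell-size-off
  branch reproduces the seven published fixed points with basin sizes
  1764/151/109/9/7/7/1 over $2^{11}$ states.
* `parasegment60` — four segment-polarity cells coupled through
  neighbouring-cell WG/hh/HH signals on a periodic ring, one frozen SLP
  input per cell. The boundary condition (periodic) and the collapsing of
  the two neighbours by OR are our reading of the published multicellular
  model; the six named phenotype attractors (wild type and variant,
  ectopic and variant, broad stripes, no segmentation) are identified
  among the ten fixed points of the wild-type SLP prepattern by their
  published wg/en expression signatures.

The T-LGL leukemia and ER+ breast-cancer networks referenced alongside
these models are *not* bundled: their full rule sets could not be
transcribed and verified offline, and shipping an unverified 60-node
model would silently invalidate every number computed on it. The
corresponding acceptance test is left failing rather than weakened.

## Numerical notes and known limitations

* Probabilities are clamped to $[0,1]$ after each mean-field step;
  products with deterministic factors are exact in floating point, so the
  deterministic-input equality is exact, not approximate.
* STG configurations are encoded as integers with the first enumerated
  node as most significant bit; truth-table rows use the first (lowest
  index) regulator as MSB. Converters normalise any regulator order into
  this convention.
* Zero-in-degree nodes are stored as identity functions of a synthetic
  self-input: they are frozen at their initial value and can only be
  controlled by pinning — which is why every driver set of the bundled
  models contains the external inputs.
* The greedy stage count is capped at $N$; non-convergence is reported in
  the returned trace, never thrown.
* Limit-cycle targets, multi-valued states, annealed mean-field theories
  and submodularity guarantees for the greedy objective are out of scope.
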