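---
title: "Dense modules in random networks: models, solvers, and the dense percolation transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense modules in random networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qclique)
```

## The model

A *γ-quasi-clique* is a vertex subset $S$, $|S| = k$, of a simple
undirected graph whose induced edge count satisfies
$$|E(S)| \;\ge\; \left\lceil \gamma \tfrac{k(k-1)}{2} \right\rceil,
\qquad \gamma \in (0,1].$$
The threshold γ is a *fixed fraction*, independent of $k$: if the required
density were allowed to vanish with growing $k$, a "dense" cluster would
degenerate into an ordinary connected component. γ = 1 is the clique;
γ = 0 would be trivially satisfied by any subset and is excluded. The
definition deliberately does **not** require connectivity: the unconnected
variant is simpler to analyze and every bound stated below transfers to
the largest *connected* quasi-clique, because that largest connected
quasi-clique is sandwiched between the maximum clique and the maximum
(unconstrained) quasi-clique. `qc_spec(connected = TRUE)` switches the
membership predicate to the connected variant when an application wants
it.

The *(λ,γ)-quasi-clique* (γ-core) additionally requires every member to
have at least $\lceil \lambda (k-1) \rceil$ neighbours inside $S$. Every
(λ,γ)-quasi-clique is a γ-quasi-clique; the converse fails (a star-like
member can carry the density while a leaf has a single internal link).
With $\lambda \ge 1/2$ any two members share a neighbour inside the
cluster, so the induced diameter is at most 2 — the robustness property
that makes γ-cores attractive as functional modules. The package keeps
the two notions as *verification predicates* (`is_gamma_quasi_clique()`,
`is_lambda_gamma_quasi_clique()`); the solver engines optimize the
γ-density objective only. That separation is deliberate: the density
constraint drives all of the asymptotics and the experiments, while the
degree-side constraint is a per-subset check that does not change the
search machinery and would complicate every pruning bound.

### Exact thresholds

γ and λ are parsed from decimal strings into exact integer fractions
(`qc_rational("0.85")` → 17/20), and every feasibility decision reduces to
an integer comparison: $2b\,|E(S)| \ge a\,k(k-1)$ for γ = a/b. Floating
point would misclassify boundary cases — `ceiling(0.85 * 10)` in double
arithmetic is 9 only by luck of rounding, and `ceiling(0.7 * 210)`
evaluates to 148 although $0.7 \cdot 210 = 147$ exactly. The unit tests
exercise the pass/fail boundary for all $k \le 1000$.

By convention a single vertex has density 1 and is always a
quasi-clique; a pair needs an edge whenever γ > 0. These conventions keep
*quasi-heredity* true down to $k = 1$: removing a minimum-degree vertex
from a size-$k$ quasi-clique leaves a size-$(k-1)$ quasi-clique, so the
feasible sizes always form a prefix $1, \dots, k_{\max}$. Quasi-heredity
is what lets the solvers search sizes upward and stop at the first
infeasible size.

## First-moment analytics

In the Erdős–Rényi model $G(n,p)$ the number $Y_k$ of γ-quasi-cliques of
size $k$ has expectation
$$\mathrm{E}[Y_k] \;=\; \binom{n}{k}\,
\Pr\!\left[\mathrm{Bin}\!\left(\tfrac{k(k-1)}{2},\,p\right) \ge
\left\lceil \gamma \tfrac{k(k-1)}{2} \right\rceil\right],$$
computed in log space (`lchoose` plus the log binomial tail) so that
$n = 10^{12}$ poses no overflow problem. The *critical size* $k^*$ is the
largest $k$ with $\mathrm{E}[Y_k] \ge 1$; since the unit crossing
generically falls between integers, the integerization "largest $k$ with
$\mathrm{E}[Y_k] \ge 1$, ascending scan from 2" is this package's
deterministic convention (`critical_size_k_star()`).

For $p < \gamma$ the maximum quasi-clique size $\omega_\gamma(n)$ obeys,
asymptotically and almost surely,
$$\frac{2 \ln n}{\ln(1/p)} \;\lesssim\; \omega_\gamma(n) \;\lesssim\;
\frac{2 \ln n}{D(\gamma \| p)}, \qquad
D(\gamma\|p) = \gamma \ln\frac{\gamma}{p} +
(1-\gamma)\ln\frac{1-\gamma}{1-p}.$$
The lower bound is the classical maximum-clique size (a clique is a
γ-quasi-clique); the upper bound is the leading term of the first-moment
calculation, and the two coincide at γ = 1. Only the leading term is
implemented: the lower-order corrections sit inside $o(\cdot)$ terms, and
the $n = 100$ reference table is reproduced at two decimals by the
leading term alone. At moderate $n$ those corrections are *not* small —
at $n = 10^6$, γ = 0.9, $p = 0.5$ the exact $k^* = 58$ sits 23% below the
main term $2\ln n/D = 75.07$, with the ratio climbing to 0.86 by
$n = 10^{12}$ — so the tests pin the exact integer values and the
monotone convergence of the ratio rather than a fixed percentage.

Two tail estimators accompany the exact binomial tail
(`binom_tail_exact()`, a thin stable wrapper over the upper-tail
distribution function):

* `chernoff_tail_bound()` — the relative-entropy Chernoff bound
  $\Pr[\mathrm{Bin}(m,p) \ge \gamma m] \le e^{-m D(\gamma\|p)}$, a true
  bound, tight in the exponent, equal to the exact tail $p^m$ at γ = 1
  and vacuous (1) for γ ≤ p. The tests verify dominance over exact tails
  on the full grid $m \le 30$, $p \in \{0.1,\dots,0.9\}$, γ > p.
* `mckay_tail_approx()` — a normal-based large-deviation *estimate*
  (not a bound): with $g = k/m$, $y = \sqrt{2 m D(g\|p)}$,
  $$\Pr[\mathrm{Bin}(m,p) \ge k] \;\approx\;
  \frac{g(1-p)\sqrt{2 D(g\|p)}}{(g-p)\sqrt{g(1-g)}}\;
  \Phi^c(y),$$
  which agrees with the lattice Bahadur–Rao asymptotic when $\Phi^c$ is
  replaced by its tail expansion but is more accurate at moderate
  deviations. Measured relative error at $p = 0.3$, $k = 0.45m$: 2.1%
  at $m = 100$, 0.6% at $m = 400$, 0.15% at $m = 1600$. It requires
  $k > mp$ and degrades toward the bulk of the distribution.

## The dense percolation transition

As $p$ grows past γ the maximum quasi-clique jumps from $O(\log n)$
vertices to all $n$ *at one point*: the limiting relative size is a step
function — 0 for $p < \gamma$, 1 for $p > \gamma$ — a *first-order*
transition, unlike the continuous emergence of the giant connected
component. `step_function_reference()` emits this limiting curve; the
boundary value at exactly $p = \gamma$ is emitted as 1, a documented
convention for a probability-zero point whose limiting classification is
a delicacy of the asymptotics, not something finite experiments can
resolve.

`sweep_density()` runs the finite-$n$ experiments: for each $p$ it draws
`reps` graphs with seeds `seed_base + 1, …, seed_base + reps`, solves
each, and aggregates mean/min/max sizes. Seeds are mandatory everywhere,
and p-grid values travel as decimal strings so output keys never suffer
float drift; identical invocations produce byte-identical TSVs. A
whole-graph shortcut ($m \ge \lceil\gamma\binom{n}{2}\rceil$ means the
entire vertex set is feasible) makes the dense phase cheap for every
engine.

At finite $n$ the step is smoothed from the left: just below γ,
fluctuation-driven quasi-cliques occupy a non-vanishing fraction of the
graph (at $n = 2000$, γ = 0.9, $p = 0.88$ the heuristic still finds
relative sizes above 0.4), and the curves steepen as $n$ grows — the
finite-size signature of the first-order limit that the test suite
checks over $n \in \{500, 1000, 2000\}$.

## Solver designs

**Brute force** (`max_quasi_clique_bruteforce()`) enumerates $k$-subsets
in lexicographic order for $k = n, n-1, \dots$; the first feasible subset
is a maximum quasi-clique, and with vertices pre-sorted by label the
reported optimum is the lexicographically smallest one — a deterministic
oracle for the other engines. Refuses $n > 22$ unless `k_cap` bounds the
search.

**Branch and bound** (`max_quasi_clique_exact()`) searches target sizes
upward and stops at the first infeasible size (valid by quasi-heredity).
Within a size-$k$ search, vertices are ordered by descending degree
(dense candidates first, the standard ordering for clique-family
searches) and a partial set $S$ ($s$ vertices, $e$ internal edges,
$r = k - s$ to pick) is pruned when
$$e + \binom{r}{2} + \sum_{\text{top-}r \text{ candidates}} d_S(v)
\;<\; \left\lceil \gamma \tfrac{k(k-1)}{2} \right\rceil .$$
An optional node budget returns the incumbent with
`is_optimal = FALSE` and a warning when exhausted. The engine is
comfortable at $n \approx 100$ on sparse graphs (the 100-replicate
experiment below takes seconds) — consistent with exact methods for this
NP-hard problem topping out around $n \sim 10^2$.

**MIP** (`build_mip()`/`solve_mip()`) implements the linearization: $n$
binaries $x_i$, $\binom{n}{2}$ continuous $w_{ij} \in [0,1]$ with
$w_{ij} \le x_i$, $w_{ij} \le x_j$, $w_{ij} \ge x_i + x_j - 1$,
$w_{ij} \ge 0$, and one density row cleared of denominators with the
exact rational γ = a/b:
$\sum_{(i,j)\in E} (b-a) w_{ij} - \sum_{(i,j)\notin E} a\, w_{ij} \ge 0$,
so backend feasibility tolerances cannot misclassify boundary densities.
The backend is a pluggable function, not a hard dependency — the shipped
one calls Python's `scipy.optimize.milp` (HiGHS) through a subprocess —
and every solution is rounded at 0.5 and re-verified through the
membership predicate before being returned. The reported constraint
count, $4\binom{n}{2} + 1$, counts all four linearization inequalities;
the LP-format serialization (`write_lp()`, deterministic variable naming
`x_<label>`, `w_<l1>_<l2>` in sorted label order) carries $w \ge 0$ as
variable bounds, the equivalent idiom of that format.

**GRASP** (`max_quasi_clique_grasp()`) is the scalable heuristic for
$n \sim 10^3$–$10^4$, where exact search is hopeless. Each of
`iterations` (default 100) starts builds a full greedy permutation: the
next vertex is drawn uniformly from the restricted candidate list — the
top `rcl_alpha` fraction (default 0.2) of candidates ranked by edges into
the current set, ties broken by static degree so that hubs seed the
search. Scoring the *whole* permutation and keeping its largest feasible
prefix is a full-lookahead variant of feasible growth: quasi-cliques are
not hereditary upward, so a temporarily infeasible prefix must be allowed
whenever a later prefix recovers feasibility. Local search then applies
single-vertex adds and strictly edge-increasing swaps that preserve
feasibility (strict increase guarantees termination), and the best set
across starts is returned — re-verified, with `is_optimal = FALSE`, and
with the non-decreasing best-so-far trace attached. On enumerable
instances ($n \le 14$) GRASP with 200 iterations matched the brute-force
optimum on 100% of 50 random instances (the regression guard asserts
≥ 90%), and it recovers planted dense modules ($n = 200$, $p = 0.05$,
$k = 12$, γ = 0.9, 50 iterations) in 100% of 20 seeds (guard: ≥ 95%).
The heuristic's internal design is this package's own; no equivalence
with any particular published GRASP implementation is claimed.

## Synthetic data and what the tests show

All inputs are generated in code. `sample_gnp()` draws each of the
$\binom{n}{2}$ pairs independently (seeded, deterministic);
`plant_dense_subset()` tops up a random $k$-subset of a sparse background
with uniformly chosen missing pairs until it meets
`required_edges(k, gamma)`, giving a certified-feasible target for solver
recovery tests. These fixtures emulate the mean-field regime the theory
addresses: independent links, homogeneous degrees. Real interaction
networks are degree-heterogeneous, clustered and noisy, so passing tests
demonstrate correctness of the algorithms and the mean-field
phenomenology — not that a particular biological network has dense
modules at any given γ.

Experiment sizes are chosen for desk-scale runtimes while keeping every
qualitative regime visible: the bound-vs-experiment table at $n = 100$
with 100 replicates per cell (its two reference cells reproduce at
sampling precision: mean 3.08 vs 3.10 at $p = 0.05$, 4.09 vs 3.97 at
$p = 0.09$, both within three standard errors of the replicate mean);
transition curves with GRASP at $n \in \{500, 1000, 2000\}$ and a few
tens of iterations. Larger $n$ sharpens the curves but changes nothing
qualitative; the asymptotic statements themselves are exercised through
the analytics, not through simulation at unreachable scales.

## Degenerate inputs, ties, limitations

* Empty subsets, unknown labels and self-loops are hard errors; duplicate
  edges in input files collapse with a warning (tolerant of real-world
  exports, where duplicated interaction records are routine).
* Isolated vertices survive edge-list round trips via the
  `# vertices:` header — $n$ matters to every relative-size statistic.
* Brute force breaks ties lexicographically; B&B, MIP and GRASP return
  an arbitrary optimum (tests compare sizes, not sets).
* `quasi_clique_size_bounds()` refuses $p \ge \gamma$: in the dense phase
  the logarithmic bounds are meaningless (the whole graph is w.h.p.
  feasible).
* The exact engines are exponential-time; beyond $n \approx 100$–150 use
  GRASP, which carries no optimality certificate.
* The CLI `solve` subcommand exposes the γ objective only; λ and
  connectivity are available through `verify`, mirroring the
  predicate/solver separation above.
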