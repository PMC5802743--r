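---
title: "Locating the source of a spread from observer arrival times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the source of a spread from observer arrival times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmla)
```

## The problem

An epidemic, a rumor, or a piece of malware starts at one node of a network
and spreads along its edges. We do not see the spread itself; we only
monitor a subset of nodes — *observers* — each of which records the time at
which the spread first reached it. Nothing else is available: in particular,
observers do not know which neighbor infected them. From the pairs
$(o_k, t_k)$ alone we want to identify the origin, the "patient zero".

This package implements three locators for that setting:

* **PTVA-LI** — the Pinto–Thiran–Vetterli maximum-likelihood locator
  restricted to limited information (arrival times only). It scores *every*
  node of the network as a candidate source.
* **GMLA** — the Gradient Maximum Likelihood Algorithm. It keeps only the
  $K_0$ earliest-reporting observers and scores only a small, adaptively
  chosen suspect set, following the likelihood gradient outward from the
  earliest observer. On large scale-free networks it is both much faster
  than the full scan and (because far observers carry hub-degraded
  information) often more accurate.
* a **baseline** that simply declares the earliest-reporting observer to be
  the source; under uniform random placement at density $\rho$ its accuracy
  estimates $\rho$.

## Spread model and delay algebra

The spread is a discrete-time Susceptible–Infected (SI) process. At each
step every infected node independently attempts each susceptible neighbor
with probability $\beta$ (the infection rate). The number of steps needed to
pass one edge is therefore geometric, with

$$\mu = \frac{1}{\beta}, \qquad
  \sigma^2 = \frac{1-\beta}{\beta^2}, \qquad
  \lambda = \frac{\mu}{\sigma} = \frac{1}{\sqrt{1-\beta}},$$

where $\lambda$, the *propagation ratio*, measures how deterministic the
spread is ($\lambda \to \infty$ as $\beta \to 1$). `delay_moments()` returns
these quantities; the default working point throughout the package is
$\beta = 0.5$, i.e. $\lambda = \sqrt 2$.

The update is synchronous: all attempts of a step are evaluated against the
susceptible set at the start of the step, so several nodes can share an
arrival step, and a node's arrival time is the index of the step of its
first successful exposure. Arrival times are integers; the Gaussian
likelihood below consumes them as reals, and no jitter is added.

## The score

Candidate sources are ranked by a Gaussian likelihood of the *observed
delays*. Fix the earliest-reporting observer $o_1$ ("observer one") and let
$d_k = t_{k+1} - t_1$. If $s$ were the source and the spread travelled along
shortest paths, observer $k$ would be reached after about
$\mu\,\mathrm{dist}(s, o_k)$ steps. Because the true propagation tree is
unknown, a breadth-first-search (BFS) tree rooted at $s$ stands in for it.
With per-edge delays i.i.d. $(\mu, \sigma^2)$,

* the expected delay vector is
  $[\mu_s]_k = \mu\,(\mathrm{depth}(o_{k+1}) - \mathrm{depth}(o_1))$ with
  depths taken in the BFS tree rooted at $s$;
* the delay covariance is
  $[\Lambda_s]_{ik} = \sigma^2 \times$ (number of edges shared by the tree
  paths $o_1 \to o_{i+1}$ and $o_1 \to o_{k+1}$), whose diagonal is
  $\sigma^2$ times the tree-path length from $o_1$.

The score of a candidate is the Gaussian log-density up to an additive
constant,

$$\phi(s) = -\tfrac12 \log\det \Lambda_s
            -\tfrac12 (d-\mu_s)^{\mathsf T} \Lambda_s^{-1} (d-\mu_s),$$

computed and compared in log space so that scans with hundreds of observers
do not underflow. A determinant-free *linearized* form
$\mu_s^{\mathsf T}\Lambda_s^{-1}(d - \tfrac12 \mu_s)$ is available via
`form = "linearized"` in every scoring entry point; the Gaussian density is
the default because it is the proper likelihood of the delay model and
penalizes candidates whose covariance inflates to absorb the residual. The
two forms can disagree on ranking; the benchmark harness can run either.

### Numerical choices

* **BFS tie-breaking.** BFS trees are not unique and $\Lambda_s$ depends on
  the tree. The frontier is processed in ascending vertex id, so each node's
  parent is its smallest-id neighbor at the previous depth. This makes every
  score deterministic and testable; it is a documented dialect choice where
  the method itself is silent, and a known source of (small) divergence from
  any implementation that breaks ties differently.
* **Covariance construction.** The compiled kernel derives shared-edge
  counts from pairwise lowest-common-ancestor depths
  ($|P(o_1,a) \cap P(o_1,b)| = \tfrac12(d_T(o_1,a)+d_T(o_1,b)-d_T(a,b))$ on
  a tree); the reference R implementation intersects explicit edge lists.
  The two routes are checked against each other to $10^{-9}$ relative
  tolerance in the tests.
* **Singular covariances** are regularized by adding
  $\varepsilon\,\sigma^2 I$ with $\varepsilon = 10^{-8}$ before a second
  Cholesky attempt; candidates whose covariance still fails to factor score
  $-\infty$, as do candidates from which some observer is unreachable. This
  lets scans run on any connected component without special-casing.
* **Tied report times** are ordered by ascending node id, both in report
  assembly and at the $K_0$ cutoff, again purely for determinism.

## GMLA

`gmla()` restricts the report to the $K_0$ earliest observers
(`select_nearest()`), scores the neighbors of observer one, jumps to the
best-scoring neighbor, and keeps expanding while some neighbor of the
current node scores at least the running maximum. Every score is cached; a
node is expanded at most once. The expand-at-most-once rule guarantees
termination even on score plateaus (where a literal "greater than or equal"
walk could cycle) and coincides with the plain gradient walk on tie-free
instances. When several neighbors tie, the smallest id is expanded first.
Observers are eligible candidates and expansion nodes. The suspected set
$V_s$ is exactly the set of scored nodes, so the true source can be missed
($P(s^* \in V_s) < 1$); the rank metric charges such misses the full
network size $N$.

The one tunable that matters is $K_0$. Too few observers starve the
likelihood; too many cost time and, on hub-rich networks, import noisy
information. `default_k0()` uses $K_0 = 0.5\sqrt N$ (rounded, floored at 2),
which tracks the accuracy-optimal count on preferential-attachment networks
at moderate observer density; for a fixed real network a hand-picked
constant (e.g. $K_0 = 30$ at $N \approx 6300$) is equally sensible.
`sweep_k0()` estimates the optimal $K_0^{\ast}$ — the smallest grid value
whose mean accuracy is within one standard error of the grid maximum, with
the paired-difference standard error since all grid values share the same
realizations — and fits $K_0^{\ast} = b N^a$ by Gauss–Newton least squares
(`fit_power_law()`, started from the log–log linear fit; exact fits are
returned in closed form because zero-residual data stalls the Gauss–Newton
step).

## Quality measures

For a single realization with true source $s^*$ and top-scorer set
$V_{top}$:

* **accuracy** $a_i = 1/|V_{top}|$ if $s^* \in V_{top}$, else 0 — ties share
  the credit;
* **rank**: position of $s^*$ in the descending score list, with ties
  resolved pessimistically ($s^*$ below all tied peers), and $N$ when $s^*$
  was never scored;
* **distance error**: mean hop distance from $s^*$ to the members of
  $V_{top}$.

Aggregation reports mean accuracy with standard errors, median and quartiles
for rank, and mean distance error. The baseline assigns no scores, so its
rank is undefined by construction and requesting it raises an error.

## Hubs and noisy observers

On scale-free networks, nodes with degree $k \ge \sqrt N$ are treated as
hubs. An observer is *noisy* ("behind a hub") with respect to a source if it
is itself a hub or if every shortest path from the source to it passes
through a hub as an intermediate node — arrival-time information that has
crossed a hub is badly degraded, because the hub's many outgoing edges
randomize which path the spread actually took. Where multiple shortest
paths exist the definition is ambiguous; `classify_noisy()` defaults to
"every shortest path is blocked" (information cannot bypass hubs), with the
laxer "some shortest path passes a hub" variant behind `rule = "any"` for
sensitivity checks. `hub_noise_experiment()` rebuilds the curated
15-observer, 2-hop designs (all-noisy, all-non-noisy, mixed, quickest) and
shows the all-noisy sets collapsing the full-scan accuracy; the "mixed" set
draws each of the 15 slots from either pool with equal probability, one
concrete reading of "a random mixture". Sources whose 2-hop neighborhood
cannot supply 15 eligible observers are redrawn up to a budget and counted
as skips.

## What the generators emulate — and what they do not

The benchmark harness (`run_quality_benchmark()`) reproduces the canonical
study conditions: Erdős–Rényi graphs parameterized by mean degree
($\langle k\rangle = 6$; the method papers report $\langle k\rangle$, never
$p$), Barabási–Albert graphs with attachment parameter $m = 3$ (so
$\langle k\rangle \to 2m = 6$) grown from a small complete core, infection
rate $\beta = 0.5$, observer density $\rho = 0.2$ placed uniformly at
random, and $K_0 = 0.5\sqrt N$. Synthetic instances are not conditioned on
connectedness; every experiment runs on the largest connected component,
mirroring how real snapshots (e.g. peer-to-peer crawls) are handled. The
simulator stops once all observers are reached — arrival times of reported
observers are unaffected, and the harness needs nothing else.

These generators capture degree heterogeneity and hub effects but not
clustering, community structure, degree correlations, or temporal/weighted
edges of real contact networks; passing benchmarks here demonstrates
correctness of the machinery and the qualitative hub phenomenology, not
field performance. Multi-source spreads, SIR-type recovery and
continuous-time dynamics are out of scope.

## Determinism and problem sizes

Every generator, simulator and experiment takes an explicit seed; harness
replicates draw child seeds from a single master stream (`child_seeds()`),
so each experiment is reproducible from one integer, and the package
restores the caller's RNG state. The shipped test suite runs the size-quality
comparison at $N = 1000$ with 300 replicates per topology, the $K_0$ sweep
on sizes 250–2000 with 200 replicates per cell, and the suspect-set scaling
on sizes 250–8000 with 250 replicates — deliberate desk-scale choices (a
few minutes each on one core). At these replicate counts the $K_0^{\ast}$
power-law exponent carries a wide confidence interval: the accuracy curves
flatten near their maximum, so the one-standard-error rule locates
$K_0^{\ast}$ only coarsely. Sharpening that exponent requires
thousand-replicate cells, which is a scale, not a correctness, question.

## Known limitations

* $\Lambda_s$ built from candidate-rooted BFS trees is itself a heuristic
  stand-in for the unknown propagation tree; with heavy ties (small graphs,
  large $\beta$) different tie rules give slightly different rankings.
* The gradient walk can terminate in a local maximum of the score
  landscape; this is intrinsic to the method, and is what the rank-$N$
  convention for missed sources accounts for.
* At $\beta = 1$ the delay variance vanishes and the Gaussian score is
  degenerate; the simulator still runs (arrival = graph distance), but
  likelihood locators need $\beta < 1$.
* The observer-subset stop rule assumes the component containing the source
  eventually reaches every observer; unreached observers are dropped from
  reports with a warning rather than given infinite times.
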