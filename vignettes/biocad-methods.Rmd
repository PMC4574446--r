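---
title: "Methods: multi-objective design and identifiability analysis of constraint-based metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-objective design and identifiability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biocad)
```

# Scope

`biocad` is a workbench for constraint-based metabolic models built around
four pieces: a flux-balance-analysis (FBA) core, the optBioCAD stochastic
multi-objective evolutionary optimizer with an epsilon-dominance
post-analysis, protein-abundance design (PADMO), and two analysis layers —
identifiability analysis of flux scans (ACE/MOTA) with a disease-stage
classifier, and sensitivity screening (Morris elementary effects,
one-at-a-time robustness, first-order Sobol indices).  This vignette
records the model assumptions, the tunable parameters and their defaults,
and the design and numerical choices that were genuinely open.

# The FBA core

A model is a stoichiometric matrix $S$ (metabolites $\times$ reactions)
with flux bounds $lb \le v \le ub$ (all fluxes in
$\mu$mol min$^{-1}$ gDW$^{-1}$).  FBA computes
$\max_v\, w^\top v$ subject to $S v = 0$ and the bounds.  Exchange
pseudo-reactions carry a single coefficient $-1$, so negative flux is an
uptake and positive flux a production rate.

The LPs are solved by a bounded-variable primal simplex implemented in
C++ (two phases, Bland's pivoting rule throughout).  Bland's rule costs
extra iterations but guarantees termination on the heavily degenerate
LPs that pinned-flux scans produce, and makes every solve bit-for-bit
reproducible.  Numerical choices:

* mass-balance tolerance: an optimal flux vector must satisfy
  $\|S v\|_\infty \le 10^{-6}\max(1, \|v\|_\infty)$ (asserted in tests);
* reduced-cost tolerance $10^{-9}$, phase-1 feasibility tolerance
  $10^{-7}$;
* infinite bounds are replaced by a finite stand-in ($10^7$);
  unboundedness is detected by re-solving with the stand-in enlarged
  tenfold and comparing objectives;
* degenerate optima: any optimal vertex may be returned.  Every
  downstream contract is written against the objective *value*, which is
  unique, never against a particular flux vector (except where a scan
  pins fluxes explicitly).

The solver is cross-checked in the test suite against three independent
routes: `boot::simplex` on randomly generated LPs, an exhaustive
basic-feasible-solution enumeration on networks small enough to
enumerate, and (for the SBML path) a reference COBRA implementation
reading the same file.

# The toy mitochondrion

`toy_mitochondrion(seed)` generates the deterministic 18-reaction,
10-metabolite fixture used by tests and examples: eight exchange
reactions (glucose, O$_2$, two amino-acid-like substrates,
3-hydroxybutyrate, lactate, CO$_2$, NADH), lumped glycolysis and TCA
reactions producing NADH, a lactate-overflow route, a lumped electron
transport chain (NADH + 0.5 O$_2$ $\to$ 2.5 ATP), two biomass component
reactions and an ATP drain.  The seed jitters each uptake capacity by
$\pm 5\%$; everything else is fixed.

The capacities are sized deliberately:

* NADH supply at full uptake ($\approx 115$ units) exceeds the
  respiratory capacity ($2 \times 50 = 100$), so maximal ATP is
  **oxygen-limited**: closing the O$_2$ exchange strictly lowers ATP, and
  the O$_2$ bound dominates a Morris screening of the uptake capacities.
* The supply-over-capacity slack ($\approx 15$) is smaller than the NADH
  export ceiling (30), so exporting NADH beyond the slack competes with
  respiration — a genuine ATP-versus-NADH trade-off with a knee at the
  slack and slope $-2.5$ beyond it.

What the toy does *not* emulate: genome-scale redundancy (thousands of
alternate pathways), compartment transport costs, cofactor bookkeeping
beyond NADH/ATP, and realistic biomass composition.  Tests passing on
the toy therefore validate the algorithms' contracts, not predictions
about any real mitochondrion.

# optBioCAD

Each candidate is a real vector $x$ within a box, with self-adaptive
step sizes $\sigma$ and an age $\tau$.  One generation executes, in
order: copying, local search, global search, evaluation, age update,
age-based diversity enforcing with archival, archive union, selection.

Parameters and defaults (`opt_config()`): population $d = 20$, copies
$dup = 2$, age limit $\tau_B = 50$, local-search rate parameter
$\rho = 1$, global-search rate parameter $\beta = 7$, archive capacity
$s_a = 160$.  The operators:

* **Local search** fires per candidate with probability
  $\alpha = e^{-\rho F}$ and mutates one uniformly chosen coordinate:
  $\sigma_i \leftarrow \sigma_i e^{\gamma N(0,1) + \gamma' N_i(0,1)}$
  with $\gamma = \gamma' = 1/(2n)$, then
  $x_i \leftarrow x_i + \sigma_i N(0,1)$, clipped to the box.  Initial
  $\sigma_i = 0.4\,(x_i^{max} - x_i^{min})/n$.  The classical
  evolution-strategy rates $1/\sqrt{2n}$, $1/\sqrt{2\sqrt n}$ are
  available behind `classical_es_rates` but default off.
* **Global search** fires with probability $\alpha = e^{-F}/\beta$ and
  blends one coordinate with a donor value taken from a random other
  position of a random other pool member (resampled once on a tie):
  $x_i \leftarrow (1-\gamma) x_i + \gamma x_k$, $\gamma \sim N(0,1)$.
  The Gaussian weight makes the blend occasionally non-convex; the
  result is clipped to the box rather than resampled.
* **Fitness** is $F = \frac{1}{r}\sum_i f_i / f^{max}_i$ clamped to
  $[0,1]$, with $f^{max}$ tracked globally over all generations.  A
  coordinate of $f^{max}$ that is not yet positive is replaced by 1 so
  that $F$ is defined from the start.  The *unclamped* value is kept for
  selection tie-breaking — without it, single-objective problems with
  negative objectives (e.g. a negated squared error) would collapse to
  $F = 0$ everywhere and selection would lose its gradient.
* **Selection** sorts parents and mutants by: feasible before
  infeasible, feasible by fitness, infeasible by violation, and keeps
  the best $d$; a deficit is filled from the archive, then with fresh
  uniform candidates.  A literal "lowest objective value" reading for
  feasible pairs is available behind `literal_min_selection`.
* **Constraints**: a candidate is feasible when $g(x) \le \theta$.  For
  FBA-backed evaluators $g$ is a *graded* steady-state infeasibility
  (the optimal $\ell_1$ mass-balance slack given the candidate's
  bounds), so infeasible candidates can still be ranked and selection
  can walk back to the feasible region.
* **Stop condition**: the generation budget `t_final`; an optional
  stagnation window (generations without front change) can be enabled,
  since a pure "until no improvement" rule is not well defined for a
  stochastic front.

The running **front** records every feasible candidate evaluated so far
that is not weakly dominated.  Dominance comparisons in this store carry
a relative tolerance of $10^{-8}$: LP optima computed under different
active sets differ by $\sim 10^{-12}$, and without the tolerance such
noise keeps weakly dominated points (e.g. along a flat face of the
attainable region) on the reported front.  Duplicates in objective space
are stored once.

## The ATP/NADH front-recovery experiment

The benchmark experiment maximizes ATP production and NADH export
simultaneously on the seed-42 toy.  The searched input flux is the NADH
exchange itself (pinned to the decision value, box $[-5, 30]$), with the
other uptakes at their wild-type capacities; each candidate is scored by
one FBA solve maximizing ATP.  The attainable objective region is then
convex and its true front is computable by a weighted-sum LP sweep,
which the recovered front matches within a 5% range-normalized
Hausdorff distance in at least 8 of 10 seeded runs of 60 generations.

This design is deliberate.  The scalarized fitness $F$ concentrates the
population at the fitness-optimal end of the front, and coverage of the
rest comes from the cumulative evaluation history.  When additional
inputs are optimized simultaneously (e.g. the O$_2$ capacity), those
inputs become selection-neutral on parts of the front (oxygen beyond the
respiratory knee), the history no longer passes near the knee, and 60
generations cannot reach 5% coverage — a real limitation of
single-scalarization evolutionary search that users should keep in mind
when choosing decision sets.

# Decision encodings

* `input_fluxes`: per-target mappings `uptake_delta` (adds $x_i \ge 0$
  to the nominal uptake capacity; the default box is +33% of nominal,
  and the zero vector reproduces the wild type), `uptake_cap` (sets the
  capacity directly), and `pin` ($lb = ub = x_i$).  Uptake magnitudes
  are clipped at 1000 $\mu$mol min$^{-1}$ gDW$^{-1}$.
* `internal_fluxes`: the decision vector is a flux vector; objectives
  are linear functionals of it and the constraint value is
  $\|S v\|_\infty$.  The companion operator
  `mutate_internal_fluxes()` keeps search inside the steady-state
  manifold: $k \sim U\{1..C\}$ fluxes are redrawn within bounds
  (irreversible reactions never receive negative draws), pinned, and the
  rest repaired by an LP feasibility solve; after $N$ failed trials the
  parent is kept.  $C$ and $N$ have no canonical values; the shipped
  defaults $C = 5$, $N = 20$ are package choices.
* `abundance` (PADMO): the decision vector is a per-reaction protein
  abundance $y \ge 0$ (wild type 1) mapped to flux bounds through the
  multiplier $f(y) = 1 + \ln y$ for $y > 1$, $1/(1+|\ln y|)$ for
  $0 < y < 1$, $f(1) = 1$, $f(0) = 0$.  Bounds are always scaled from
  the stored wild-type bounds, so scaling is idempotent, and $y = 0$
  closes a reaction — restricting $y$ to $\{0, 1\}$ reduces PADMO to a
  knockout search, which the tests verify against exhaustive
  enumeration.  The logarithmic growth of $f$ already discourages
  runaway abundances; the search box still needs a ceiling, and
  `y_max = 100` (multiplier $\approx 5.6$) is the package default.  Each
  objective is evaluated by its own FBA solve on the scaled model, so a
  front point is both an objective-space optimum and a concrete
  abundance array.

# Identifiability analysis

`disease_scan()` pins one reaction to each value of a grid
($lb = ub = g$; an inequality would not give the network state *given*
that flux) and stores each optimal flux vector as a column; infeasible
pins become flagged all-missing columns and are dropped listwise before
analysis.

`ace()` estimates optimal transformations $\hat\alpha(x_i) =
\sum_{j\ne i}\hat\beta_j(x_j)$ by alternating conditional expectations,
from the start $\alpha = x_i/\|x_i\|$, $\beta_j = 0$, with $\alpha$ kept
at unit variance; $r^2 = 1 - \overline{(\alpha - \sum\beta_j)^2}$.
Convergence: change of squared residual below $10^{-6}$, at most 100
iterations; non-convergence is flagged and the last iterate returned.

The conditional expectations use Friedman's super-smoother
(`stats::supsmu`).  A fixed-bandwidth local-linear kernel smoother was
implemented first and is still available (`smoother = "kernel"`), but
the alternation then drifts towards rough noise-eigenfunctions of the
smoother composition and overstates $r^2$ badly (e.g. 0.96 for a pair
whose true maximal correlation is 0.71); the cross-validated span of the
super-smoother suppresses exactly those directions, and with it the
planted-relation benchmarks (linear, quadratic, three-variable sum,
independent null) are all recovered at their theoretical values.  With
`supsmu` the residual trace is non-increasing only up to the smoother's
span re-selection (fluctuations $\sim 10^{-6}$), which is what the
invariant test asserts.

`mota_groups()` takes every non-constant variable once as response,
ranks predictors by the variance of their fitted $\hat\beta_j$, and
reports the smallest top-ranked prefix whose ACE refit reaches
`r2_threshold` (default 0.8) with at most `max_group_size` (default 10)
members.  A member set recovered from two or more of its members as
response is flagged *strong*.  Each member is annotated with its
coefficient of variation as a practical-identifiability hint; no hard
cv cutoff is applied because none is canonical.

`classify_stage()` labels a condition by ATP relative to the normal
optimum: $\le 33\%$ disease, $\le 66\%$ inflammation, otherwise healthy
(boundaries inclusive downwards, a total partition of $[0,\infty)$).
`characterize_disease()` combines scan, staging (ATP-based, or explicit
flux breakpoints; half-open intervals include the endpoint nearer the
healthy side, in either grid direction) and per-stage MOTA grouping.  A
stage with fewer than `min_samples` (default 30) feasible columns is
reported empty with a warning rather than an error.

# Sensitivity screening

Morris trajectories operate on the unit-scaled input box (without the
scaling, mean effects would not be comparable across inputs and ranking
would be meaningless): $p$-level grid ($p = 4$), step
$\Delta = p/(2(p-1))$, $r = 20$ trajectories by default, elementary
effect $[y(x + \Delta e_i) - y(x)]/\Delta$.  On an affine model every
effect equals the unit-scaled coefficient exactly and $\sigma = 0$.
Inputs are ranked by $\mu^*$, ties by $\sigma$, then input order.
Failing trajectories are resampled, up to $3r$ attempts.
`local_robustness()` perturbs one input at a time uniformly within a
relative step and reports the fraction of draws keeping the output
within a relative tolerance of nominal (absolute fallback at zero
nominal).  `sobol_first_order()` uses the pick-freeze estimator
$S_i = \overline{y_B (y_{AB_i} - y_A)} / \widehat{Var}(y)$, clamped to
$[-0.05, 1]$, with $n \ge 256$ base samples.

# Problem sizes in the shipped tests

The test suite runs the optimizer benchmarks at desk scale: 10 seeded
runs of 60 generations (population 20) for the front-recovery check,
a 25-generation binary PADMO run against an exhaustive 56-configuration
knockout oracle, ACE/MOTA benchmarks at 500–1000 samples and 4–6
variables, Morris with 8–30 trajectories, Sobol at 4096 base samples,
and $10^4$ seeded internal-flux mutations.  These sizes were chosen so
the whole suite exercises every contract in about a minute on one core.

# Known limitations

* The optimizer's scalarized fitness concentrates the population; front
  coverage relies on the evaluation history (see above).  No crowding or
  hypervolume mechanism is provided by design.
* FBA degeneracy means scan columns are one optimal vertex among
  possibly many; couplings inferred by MOTA are relative to the
  deterministic vertex the solver selects.
* The SBML reader targets the constraint-based subset (species,
  reactions, stoichiometry, fbc or kinetic-law bounds); kinetics, rules
  and annotations are ignored.
* The simplex is dense and intended for desk-scale models (tens to a
  few hundred reactions), not genome-scale networks.
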