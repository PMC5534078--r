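---
title: "Hybrid simulation of biochemical networks with hpnsim: models, algorithms, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid simulation of biochemical networks with hpnsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpnsim)
```

## The modelling formalism

`hpnsim` represents a reaction network as a generalised hybrid Petri net:
a bipartite graph of *places* (species) and *transitions* (reactions).
Discrete places hold non-negative integer token counts (molecule numbers,
channel states); continuous places hold non-negative reals
(concentrations). Transitions come in five kinds — stochastic
(exponentially distributed waiting time at the current propensity),
continuous (deterministic flow at the rate-law value), immediate,
deterministically delayed, and scheduled — and are wired to places by six
arc kinds. Standard arcs move tokens or mass; read, inhibitor, equal and
modifier arcs only constrain enabledness or expose a place to a rate
expression; reset arcs clear a place on firing.

Rate laws follow the *bio-semantics* convention: the user supplies
ordinary kinetic rate expressions (mass action, Hill-type ratios, …) and
the continuous regime is simply the ODE system
$\dot y_i = \sum_k s_{ik}\, v_k(y, d)$ over the deterministic transitions
$k$, with the discrete marking $d$ entering the rates as a constant that
is frozen for the duration of one integration span. `MassAction(k)`
expands at each transition into $k \prod_p p^{w_p}$ over its standard and
read input places. The same expression serves both regimes; a
per-transition `combinatorial` flag switches the discrete expansion to
falling factorials $x(x-1)\cdots(x-w+1)$ for exact chemical-master-
equation propensities. We chose the plain product as the default because
one rate expression must serve both regimes and kinetic rate constants
are conventionally calibrated against the power law.

Two structural rules keep the hybrid semantics sound, and `validate_hpn()`
reports their violations as data rather than errors: a continuous
transition may touch a discrete place only through non-consuming arcs
(continuous flow must never corrupt an integer marking), and any species
written by both regimes must be classed continuous. Species classes are
derived from the partition: continuous iff declared continuous or written
by any deterministic-regime transition.

## The synchronisation algorithms

All hybrid algorithms alternate ODE integration spans with stochastic
firings; they differ in how the firing time is located and how much
solver work is discarded at each firing.

**Exact jump equation.** Draw $r \sim U(0,1)$; augment the ODE system
with $\dot g = \sum_j a_j^s(x(t))$ over the slow reactions and integrate
until the root $g = -\log r$. The firing reaction is selected with
probabilities proportional to the propensities *at the root time* — this
is required for exactness, because the propensity mix may have drifted
during the span. The accumulator integrand clamps each slow rate at zero
and carries the enabling conditions on continuous inputs as indicator
factors; enabling conditions on discrete inputs are resolved once per
span, since the discrete marking is frozen.

**Accelerated.** The waiting time solves
$\sum_j a_j^s(x)\,\Delta\tau = -\log r$ with propensities evaluated at the
post-event state; the span is then integrated without any root function.
The state at which the propensity sum is evaluated is pinned to the state
immediately after the previous event: the alternative (continuously
refreshed) reading would re-introduce the very coupling the method
removes. The method is exact when slow propensities do not read
continuous species and documented as approximate otherwise. Reactions are
classified once per partition: a reaction is *dependent* iff its firing
changes a continuous species or a place read by a deterministic rate.
Only dependent firings reinitialise the solver.

**Improved HRSSA.** A fluctuation interval
$[x(1-\delta),\, x(1+\delta)]$ per species (widened to at least a floor,
see below) yields per-reaction propensity bounds
$[\underline a_j, \overline a_j]$ by interval arithmetic over the rate
AST. Candidates arrive at exponential rate $\overline a_0$; the candidate
reaction is drawn proportional to $\overline a_j$ and accepted with
probability $a_j(x)/\overline a_j$, with the standard squeeze shortcut
(auto-accept when $u\,\overline a_j \le \underline a_j$, which avoids
evaluating the exact propensity at all). A rejected candidate redraws a
fresh exponential time; re-drawing versus re-using the residual budget is
distribution-preserving either way, and re-drawing keeps the loop simple.
During integration, root functions $y_i - \overline x_i$ and
$y_i - \underline x_i$ monitor only the continuous species that some slow
rate reads; an exit rebuilds the interval and bounds. Accepted firings
follow the accelerated reinitialisation rule, which is what makes this
the "improved" combination.

**Dynamic partitioning** reuses the HRSSA loop and re-partitions at every
fluctuation-interval exit: a reaction is deterministic iff its current
propensity is at least `lambda_prop` *and* every substrate marking is at
least `n_substrate`; `partition_hint` pins a transition regardless. When
a re-partition reclassifies a previously-continuous species as discrete,
its value is rounded to the nearest integer — the formalism offers no
other consistent choice, and the error is at most half a molecule at a
point where the species is by construction abundant or inert.

**Degenerate regimes.** When the deterministic regime is empty the jump
integrand is constant between events, so the root is taken in closed form
(τ = −log r / a₀) instead of invoking the integrator; the exact and
accelerated methods then reduce *identically* to the Gillespie direct
method, sharing its draw sequence — the test suite asserts bit-identical
event logs under a shared random stream. With zero stochastic
transitions, every hybrid algorithm equals the pure ODE mode.

**Timed transitions.** Immediate, delayed and scheduled transitions are
handled by a time-ordered event queue. At every span boundary immediate
transitions fire to quiescence (at most $10^4$ iterations, then an error),
with conflicts resolved by a weight-proportional draw; then due scheduled
and delayed firings execute in (time, id) order. Simultaneity ordering is
immediate > timed > stochastic, ties broken by id — the deterministic
replay contract requires *some* fixed order and the formalism does not
prescribe one. A delayed transition schedules its expiration when it
becomes enabled and cancels it when disabled before expiry.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `rtol`, `atol` | 1e-6, 1e-9 | relative/absolute integrator tolerances (CVODE-style conventions) |
| `root_tol` | 1e-8 | tolerance used when comparing event times |
| `delta` | 0.1 | relative half-width of the fluctuation interval |
| `fi_floor` | 2 | minimum absolute half-width for discrete species (molecules) |
| `cont_floor` | 1e-4 | minimum absolute half-width for continuous species |
| `lambda_prop` | 10 | dynamic partitioning: propensity threshold (events/time) |
| `n_substrate` | 100 | dynamic partitioning: minimum substrate count (molecules) |
| `grid_points` | 1000 | uniform output grid points |

`delta` and `fi_floor` trade propensity-update frequency against
rejection rate; 0.1 and 2 are common rejection-sampling practice. The
continuous floor exists because a species sitting at zero would otherwise
get a zero-width interval and force a rebuild at every step; 1e-4 is far
below any concentration of interest in the bundled models and only
affects how soon a *growing* species triggers its first rebuild.
Candidate selection uses a linear cumulative-sum scan: the stochastic
sets in hybrid models are small, and a tree structure would add constant
overhead without measurable gain at these sizes.

The ODE backend is deSolve's `lsodar` — adaptive multistep with automatic
stiff/non-stiff switching and built-in root localisation. The
`stiff`/`nonstiff` preference is recorded in the configuration; both map
to the switching solver, and the session wrapper (`ode_session()`,
`ode_integrate()`, `ode_reinitialise()`) is the boundary behind which any
integrator with adaptive steps, dense output and root finding could be
substituted. The wrapper counts reinitialisations — deliberate history
discards after a discrete jump — because that counter is the observable
mechanism behind the accelerated method's speed-ups.

## Numerical choices and degenerate inputs

* Continuous markings that round off slightly negative are clamped to
  zero when above $-10\,\mathrm{atol}$ and raise an error beyond that;
  rates are evaluated with the state clamped at zero so mass-action terms
  cannot turn negative.
* Propensity evaluations clamp tiny negatives (≥ −1e−9) to zero; larger
  negative rates are modelling errors and raise.
* Inhibitor arcs are strict: a transition is enabled iff the place
  marking is *below* the weight, so weight 2 blocks at exactly 2 — the
  reading that makes "at most two copies" constraints work.
* Reset and equal arcs are restricted to discrete places; on reals both
  are ill-defined (equality of floats, resetting a flowing concentration).
* Interval bounds are exact for products of non-negative monomials (the
  mass-action case) and valid but possibly loose for non-monotone
  expressions — the rejection machinery needs validity, not tightness.
* Output traces are sampled right-continuously: a grid point that
  coincides with a firing time records the post-firing state.
* A grid point inside an integration span takes its continuous values
  from the solver's dense output at exactly that time.

## Coloured nets and unfolding

Colour sets are finite integer ranges and products of ranges — enough for
channel indices and spatial grids. A coloured transition's instances are
the guard-satisfying total assignments of its variables, enumerated in
canonical lexicographic order by vectorised constraint filtering over the
domain product (a pruned search; a general CSP solver is unnecessary at
these sizes, and the enumeration refuses domains beyond 5·10⁶
candidates). Flat names follow `base__c1_c2`, which is collision-free,
reversible, and regex-friendly for result views. Colour arithmetic that
lands outside the place's colour set is a hard error naming the
transition and binding — the guard must exclude it; silently wrapping or
clamping a neighbour index would corrupt a diffusion topology invisibly.
Unfolded instance counts and names are independent of declaration order,
and a net whose colour sets are all singletons unfolds to the base net up
to renaming.

The bundled spatial calcium generator (`make_coloured_calcium()`) models
grid diffusion with source-cell variables plus offset variables
`dx, dy ∈ [-1..1]` under the guard `|dx|+|dy| = 1` with in-range target
coordinates. This enumerates 9 candidate offsets per cell rather than all
cell pairs and yields exactly one instance per directed 4-neighbour edge:
$2(2WH - W - H)$, i.e. 39,600 on the default 100 × 100 grid, alongside
one pump instance per cell and a single inflow instance (its arc colours
are constant at the cluster cell).

## What the fixtures emulate — and what they do not

The fixture generators are first-class, deterministic model builders:

* `make_single_channel_calcium()` — the gated-channel model: two discrete
  channel states, stochastic flips, continuous calcium with inflow
  proportional to the open state. Linear, so the stationary ensemble mean
  of calcium is exactly $k_{in} p_{open}/k_{pump}$ with
  $p_{open} = k_{open}/(k_{open}+k_{close})$ (first-moment equation).
* `make_immigration_death()` — Poisson stationary law (mean = variance =
  $k_{in}/k_{out}$); the workhorse for statistical-exactness checks.
* `make_decay()`, `make_ab_equilibrium()` — closed-form exponential decay
  and a conservation invariant.
* `make_decoupled_hybrid()` — immigration–death beside an uncoupled
  continuous decay: both stochastic reactions are independent, so the
  accelerated and rejection-based algorithms should never reinitialise
  the solver while the exact method must do so at every event.
* `make_coloured_calcium()` — the spatial model above.

Rate constants are free parameters with package defaults chosen so that
channel flips and calcium relaxation share an O(1) time scale; the
models' published form does not fix numerical values, and none of the
package's claims depend on a particular choice. These fixtures are
linear or near-linear by design, which is what makes closed-form
references available; passing tests therefore demonstrate correctness of
the *algorithms* (waiting-time laws, selection probabilities, moment
recovery, conservation, reinitialisation bookkeeping), not fidelity to
any particular biological parameterisation, stiff nonlinear kinetics, or
spatial geometry beyond 4-neighbour diffusion.

## Problem sizes used by the checks

The statistical tests use sizes chosen to give decisive 3-standard-error
verdicts at desk scale: 10⁴ weakly correlated stationary samples per
algorithm for the Poisson law (one long trajectory, samples every 2 time
units, batch-means standard errors), 2,000-run ensembles per parameter
setting for the gated-channel first moment (per-run time averages over
the stationary tail), 10³-event streams for exact/accelerated event-time
agreement, and 10⁵ draws for waiting-time and selection-frequency laws.
Unfolding checks run the full 100 × 100 model; ODE conservation checks
use 6 × 6 and 8 × 8 grids, where the invariant is already exercised by
thousands of coupled equations' worth of arithmetic at negligible cost.

## Reproducibility contract

Randomness flows exclusively through explicit stream objects wrapping
R's L'Ecuyer-CMRG generator. Ensemble run $i$ receives substream $i$
derived by `parallel::nextRNGStream` *before* dispatch, so traces, their
averages and exported CSVs are bit-identical for any worker count, and a
fixed seed replays event sequences exactly. CSV export prints doubles
with `%.17g`, which round-trips IEEE doubles bit-exactly.

## Known limitations

* Reversible SBML reactions are split only when the kinetic law is a
  top-level difference; other algebraic forms raise an error rather than
  guessing.
* SBML export drops enabledness-only arc kinds (read becomes a modifier;
  inhibitor/equal/reset raise), timed transition kinds, and the hybrid
  partition itself — SBML Level 2 has no notion of any of them.
* Deterministic-regime transitions need constant standard-arc weights
  (state-dependent stoichiometry has no ODE reading here).
* The net-description dialect is compatible in spirit with the
  ANDL-style formats used by Petri-net tools, but it is this package's
  own documented grammar, not a byte-compatible clone of any tool's
  unpublished one.
* Only `MassAction` is predefined as a kinetic-law helper; other rate
  laws are written as explicit expressions.
* Tau-leaping, next-reaction, DAE/delay dynamics and steering are out of
  scope.
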