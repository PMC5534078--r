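# hpnsim — hybrid stochastic/deterministic simulation of (coloured) hybrid Petri nets

Many biochemical reaction networks are genuinely multiscale: a handful of
molecules (genes, ion channels, transcription factors) whose fluctuations
drive the system, coupled to abundant species (metabolites, calcium) that
are far more efficiently treated as continuous concentrations. Pure
stochastic simulation of such models is prohibitively slow; pure ODE
simulation throws away the fluctuations that matter. `hpnsim` is an R
package for scientists who need the middle ground: it represents a model
as a **generalised hybrid Petri net** — discrete and continuous places
(species), stochastic, continuous, immediate, delayed and scheduled
transitions (reactions), six arc types — and executes it with exact and
accelerated hybrid algorithms. Large spatial or repetitive models are
written once as **coloured** hybrid Petri nets and unfolded automatically.

## The algorithms

Let a partition split the reactions into a slow (stochastic) set with
propensities $a_j^s(\mathbf{x})$, $j = 1,\dots,N$, and a fast
(deterministic) set integrated as ODEs. With $r \sim U(0,1)$:

* **Exact jump-equation hybrid** (Haseltine–Rawlings). The next stochastic
  firing time $\tau$ solves

  $$\int_t^{t+\tau} \sum_{j=1}^{N} a_j^s(\mathbf{x}(t'))\,dt' = -\log r,$$

  integrated together with the ODE system; the firing time is captured as
  an event root, reaction $j$ fires with probability
  $a_j^s(\mathbf{x}(t+\tau))/\sum_k a_k^s(\mathbf{x}(t+\tau))$, and the
  solver is reinitialised.

* **Accelerated hybrid.** Replaces the integral by
  $\sum_j a_j^s(\mathbf{x})\cdot\Delta\tau = -\log r$ with propensities
  held at the last event, and classifies stochastic reactions as
  *dependent* (their firing changes the state seen by the ODE solver) or
  *independent*; only dependent firings reinitialise the solver. Exact
  whenever slow propensities do not read continuous species.

* **Improved HRSSA.** Rejection-based selection: a fluctuation interval
  $[\underline{x}, \overline{x}]$ around the state yields propensity
  bounds $[\underline{a}_j, \overline{a}_j]$ by interval arithmetic;
  candidate firings arrive at rate $\overline{a}_0$ and are accepted with
  probability $a_j(\mathbf{x})/\overline{a}_j$ against the exact state.
  The deterministic regime is interrupted only at candidate times or when
  the state leaves the interval; the accelerated reinitialisation rule is
  reused.

* **Dynamic partitioning.** The HRSSA loop repartitions reactions whenever
  the state leaves the fluctuation interval, classing a reaction
  deterministic iff its propensity and all substrate counts exceed
  thresholds.

* **Pure SSA** (Gillespie direct method) and **pure ODE** modes, plus
  deterministic parallel ensembles (run `i` uses substream `i` of the
  seed; results are bit-identical for any worker count).

All three hybrid algorithms are statistically exact on decoupled models;
the accelerated and rejection-based variants differ from the exact method
only in how much solver reinitialisation they avoid.

## A worked example

The introductory model: one calcium channel flipping stochastically
between `close` and `open`, gating a continuous calcium pool
(`dCa/dt = k_in * open − k_pump * Ca`).

```r
library(hpnsim)

net <- make_single_channel_calcium(k_open = 1, k_close = 1, k_in = 4, k_pump = 1)
net
#> <hpn> single_channel_calcium: 3 places (2 discrete), 4 transitions (2 stochastic), 7 arcs, 4 parameters

tr <- simulate_hpn(net, "accelerated", t_end = 25, grid_points = 51, seed = 42)
glance(tr)
#> # A tibble: 1 × 9
#>   algorithm    seed   run t_end n_grid events reinits rejects timed_fired
#>   <chr>       <int> <int> <dbl>  <int>  <int>   <int>   <int>       <int>
#> 1 accelerated    42     1    25     51     19      19       0           0
tail(tr, 3)
#> # A tibble: 3 × 4
#>    time close  open    Ca
#>   <dbl> <dbl> <dbl> <dbl>
#> 1  24       1     0 0.450
#> 2  24.5     0     1 0.803
#> 3  25       0     1 2.06
```

Nineteen channel flips occurred (`events`); each one reinitialised the
ODE solver (`reinits`) because the inflow rate reads the channel state.
An ensemble recovers the stationary first moment
`k_in * p_open / k_pump = 4 * 0.5 / 1 = 2`:

```r
ens <- simulate_hpn(net, "accelerated", t_end = 25, grid_points = 51,
                    seed = 42, runs = 500)
m <- ens$mean
mean(m$Ca[m$time >= 12.5])
#> [1] 2.004
autoplot(ens)   # ggplot of the ensemble-mean trajectories
```

Traces are tibbles; `tidy()` pivots them long, `glance()` summarises the
run, `export_csv()` writes full-precision CSV. Models can be written to
and read from a plain-text dialect (`write_andl()` / `parse_andl()`) or
an SBML Level 2 Version 4 subset (`export_sbml()` / `import_sbml()`).

A spatial coloured model — three channels feeding a 100 × 100 diffusion
grid — is built by `make_coloured_calcium()` and unfolds to 10,006 places
and 49,607 transitions:

```r
flat <- unfold(make_coloured_calcium())
flat
#> <hpn> coloured_calcium: 10006 places (6 discrete), 49607 transitions (6 stochastic), ...
```

## Command line

A thin wrapper ships in `inst/cli/hpnsim`:

```sh
hpnsim simulate model.andl --algorithm hrssa --t-end 100 --runs 16 --workers 4 \
       --seed 1 --output trace.csv --view '^Ca__' --aggregate sum
hpnsim unfold calcium.candl --output flat.andl
hpnsim validate model.andl
hpnsim fixtures coloured_calcium n_channels=3 --output calcium.candl
```

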