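#' Single-channel calcium model
#'
#' The introductory hybrid model: a two-state calcium channel (discrete
#' places `close`/`open` flipped by stochastic transitions `ch_open` and
#' `ch_close` with mass-action rates) gating a continuous calcium pool
#' (place `Ca`) filled by the continuous transition `Ca_inflow` at rate
#' `k_in * open` and drained by `Ca_pump` at rate `k_pump * Ca`. Because
#' the model is linear, the stationary ensemble mean of `Ca` is
#' `k_in * p_open / k_pump` with `p_open = k_open / (k_open + k_close)`.
#'
#' Rate constants are free parameters of the fixture; the defaults are
#' chosen so that channel flips and calcium relaxation happen on the same
#' O(1) time scale.
#'
#' @param k_open,k_close Channel opening/closing rate constants.
#' @param k_in Calcium inflow rate constant (per open channel).
#' @param k_pump Calcium extrusion rate constant.
#' @return An [hpn()] with 3 places (2 discrete) and 4 transitions
#'   (2 stochastic, 2 continuous).
#' @export
make_single_channel_calcium <- function(k_open = 1, k_close = 1, k_in = 5,
                                        k_pump = 1) {
  hpn("single_channel_calcium",
      parameters = c(k_open = k_open, k_close = k_close,
                     k_in = k_in, k_pump = k_pump)) |>
    add_place("close", "discrete", initial = 1) |>
    add_place("open", "discrete", initial = 0) |>
    add_place("Ca", "continuous", initial = 0) |>
    add_transition("ch_open", "stochastic", rate = "MassAction(k_open)") |>
    add_transition("ch_close", "stochastic", rate = "MassAction(k_close)") |>
    add_transition("Ca_inflow", "continuous", rate = "MassAction(k_in)") |>
    add_transition("Ca_pump", "continuous", rate = "MassAction(k_pump)") |>
    add_arc("close", "ch_open") |>
    add_arc("ch_open", "open") |>
    add_arc("open", "ch_close") |>
    add_arc("ch_close", "close") |>
    add_arc("open", "Ca_inflow", kind = "read") |>
    add_arc("Ca_inflow", "Ca") |>
    add_arc("Ca", "Ca_pump")
}

#' Immigration-death process
#'
#' `0 -> X` at constant rate `k_in`, `X -> 0` at rate `k_out * X`. The
#' stationary law of the chemical master equation is Poisson with mean and
#' variance `k_in / k_out`; the transient ensemble mean from `X(0) = 0` is
#' `(k_in/k_out) * (1 - exp(-k_out * t))`.
#'
#' @param k_in,k_out Immigration and per-capita death rate constants.
#' @param x0 Initial count.
#' @return An [hpn()].
#' @export
make_immigration_death <- function(k_in = 10, k_out = 1, x0 = 0) {
  hpn("immigration_death", parameters = c(k_in = k_in, k_out = k_out)) |>
    add_place("X", "discrete", initial = x0) |>
    add_transition("immigrate", "stochastic", rate = "k_in") |>
    add_transition("die", "stochastic", rate = "MassAction(k_out)") |>
    add_arc("immigrate", "X") |>
    add_arc("X", "die")
}

#' Exponential decay
#'
#' `X -> 0` at rate `k * X`; closed form `X(t) = x0 * exp(-k t)` under the
#' deterministic semantics.
#'
#' @param k Decay rate constant.
#' @param x0 Initial amount.
#' @param kind Place kind (`"continuous"` by default; use `"discrete"` with
#'   an integer `x0` for stochastic decay).
#' @return An [hpn()].
#' @export
make_decay <- function(k = 1, x0 = 100, kind = c("continuous", "discrete")) {
  kind <- match.arg(kind)
  hpn("decay", parameters = c(k = k)) |>
    add_place("X", kind, initial = x0) |>
    add_transition("decay", if (kind == "continuous") "continuous" else "stochastic",
                   rate = "MassAction(k)") |>
    add_arc("X", "decay")
}

#' Reversible isomerisation A <-> B
#'
#' Mass-action forward/backward reactions; `A + B` is a stoichiometric
#' invariant under every simulation algorithm.
#'
#' @param kf,kr Forward/backward rate constants.
#' @param a0,b0 Initial amounts.
#' @param kind Place kind for both species.
#' @return An [hpn()].
#' @export
make_ab_equilibrium <- function(kf = 1, kr = 1, a0 = 100, b0 = 0,
                                kind = c("continuous", "discrete")) {
  kind <- match.arg(kind)
  tkind <- if (kind == "continuous") "continuous" else "stochastic"
  hpn("ab_equilibrium", parameters = c(kf = kf, kr = kr)) |>
    add_place("A", kind, initial = a0) |>
    add_place("B", kind, initial = b0) |>
    add_transition("fwd", tkind, rate = "MassAction(kf)") |>
    add_transition("rev", tkind, rate = "MassAction(kr)") |>
    add_arc("A", "fwd") |> add_arc("fwd", "B") |>
    add_arc("B", "rev") |> add_arc("rev", "A")
}

#' Decoupled hybrid fixture: stochastic immigration-death + continuous decay
#'
#' The stochastic regime (immigration-death on the discrete species `X`)
#' neither reads nor writes the continuous species `C`, whose deterministic
#' decay `dC/dt = -k_dec * C` runs alongside. Both stochastic reactions are
#' therefore *independent*: the accelerated and rejection-based algorithms
#' never need to reinitialise the ODE solver, while the exact jump-equation
#' method restarts it at every event. With constant slow propensity totals
#' per state, the accelerated waiting times coincide with the exact ones.
#'
#' @inheritParams make_immigration_death
#' @param k_dec Continuous decay rate constant.
#' @param c0 Initial continuous amount.
#' @return An [hpn()].
#' @export
make_decoupled_hybrid <- function(k_in = 10, k_out = 1, x0 = 0, k_dec = 0.3,
                                  c0 = 50) {
  hpn("decoupled_hybrid",
      parameters = c(k_in = k_in, k_out = k_out, k_dec = k_dec)) |>
    add_place("X", "discrete", initial = x0) |>
    add_place("C", "continuous", initial = c0) |>
    add_transition("immigrate", "stochastic", rate = "k_in") |>
    add_transition("die", "stochastic", rate = "MassAction(k_out)") |>
    add_transition("c_decay", "continuous", rate = "MassAction(k_dec)") |>
    add_arc("immigrate", "X") |>
    add_arc("X", "die") |>
    add_arc("C", "c_decay")
}

#' Coloured spatial calcium model
#'
#' A cluster of `n_channels` two-state channels (colour set `chCS =
#' [1..n_channels]`) feeds calcium into one cell of a `width x height`
#' grid (`Grid2D = [1..width] x [1..height]`) at the cluster position; the
#' continuous transition `Ca_inflow` has a single unfolded instance
#' (constant arc colours) with rate `k_in` times the total number of open
#' channels. Calcium diffuses to the four grid neighbours (transition
#' `diffuse`, one instance per directed 4-neighbour cell pair, guarded by
#' offset variables `dx, dy in [-1..1]` with `|dx|+|dy| = 1` and in-range
#' target coordinates) and is extruded per cell by `Ca_pump`. With the
#' defaults the unfolded net has `2 n_channels + width*height` places and
#' `2 n_channels + 1 + width*height + n_edges` transitions, where
#' `n_edges = 2(2 width height - width - height)`.
#'
#' @inheritParams make_single_channel_calcium
#' @param n_channels Number of channels in the cluster (0 for none).
#' @param width,height Grid dimensions.
#' @param cluster Integer `c(x, y)` cluster position.
#' @param D Diffusion rate constant (per directed edge).
#' @param ca_init Optional named numeric of per-cell initial calcium,
#'   names like `"50_50"`.
#' @return A [coloured_hpn()].
#' @export
make_coloured_calcium <- function(n_channels = 3, width = 100, height = 100,
                                  cluster = c(50, 50), D = 1, k_pump = 1,
                                  k_in = 5, k_open = 1, k_close = 1,
                                  ca_init = NULL) {
  stopifnot(width >= 1, height >= 1, n_channels >= 0,
            cluster[1] >= 1, cluster[1] <= width,
            cluster[2] >= 1, cluster[2] <= height)
  net <- coloured_hpn("coloured_calcium",
                      parameters = c(k_open = k_open, k_close = k_close,
                                     k_in = k_in, k_pump = k_pump, D = D)) |>
    add_colourset("GX", 1, width) |>
    add_colourset("GY", 1, height) |>
    add_colourset("OS", -1, 1) |>
    add_colourset_product("Grid2D", c("GX", "GY")) |>
    add_coloured_place("Ca", "continuous", colset = "Grid2D", initial = 0,
                       initial_at = ca_init)
  if (n_channels > 0) {
    net <- net |>
      add_colourset("chCS", 1, n_channels) |>
      add_coloured_place("closed", "discrete", colset = "chCS", initial = 1) |>
      add_coloured_place("open", "discrete", colset = "chCS", initial = 0) |>
      add_coloured_transition("ch_open", "stochastic", rate = "MassAction(k_open)",
                              variables = c(m = "chCS")) |>
      add_coloured_transition("ch_close", "stochastic", rate = "MassAction(k_close)",
                              variables = c(m = "chCS")) |>
      add_coloured_arc("closed", "ch_open", colour = list("m")) |>
      add_coloured_arc("ch_open", "open", colour = list("m")) |>
      add_coloured_arc("open", "ch_close", colour = list("m")) |>
      add_coloured_arc("ch_close", "closed", colour = list("m"))
  }
  inflow_rate <- if (n_channels > 0) "k_in * colsum(open)" else "0"
  net <- net |>
    add_coloured_transition("Ca_inflow", "continuous", rate = inflow_rate) |>
    add_coloured_arc("Ca_inflow", "Ca",
                     colour = list(cluster[1], cluster[2]))
  if (n_channels > 0)
    net <- add_coloured_arc(net, "open", "Ca_inflow", kind = "modifier",
                            colour = list("all"))
  guard <- sprintf(
    "abs(dx) + abs(dy) == 1 & x + dx >= 1 & x + dx <= %d & y + dy >= 1 & y + dy <= %d",
    as.integer(width), as.integer(height))
  net |>
    add_coloured_transition("Ca_pump", "continuous", rate = "MassAction(k_pump)",
                            variables = c(x = "GX", y = "GY")) |>
    add_coloured_arc("Ca", "Ca_pump", colour = list("x", "y")) |>
    add_coloured_transition("diffuse", "continuous", rate = "MassAction(D)",
                            variables = c(x = "GX", y = "GY", dx = "OS", dy = "OS"),
                            guard = guard) |>
    add_coloured_arc("Ca", "diffuse", colour = list("x", "y")) |>
    add_coloured_arc("diffuse", "Ca", colour = list("x + dx", "y + dy"))
}

#' Emit a fixture by name
#'
#' Used by the `fixtures` command-line subcommand.
#'
#' @param name One of `"single_channel_calcium"`, `"immigration_death"`,
#'   `"decay"`, `"ab_equilibrium"`, `"decoupled_hybrid"`,
#'   `"coloured_calcium"`.
#' @param ... Passed to the fixture generator.
#' @return An [hpn()] or [coloured_hpn()].
#' @export
make_fixture <- function(name, ...) {
  switch(name,
         single_channel_calcium = make_single_channel_calcium(...),
         immigration_death = make_immigration_death(...),
         decay = make_decay(...),
         ab_equilibrium = make_ab_equilibrium(...),
         decoupled_hybrid = make_decoupled_hybrid(...),
         coloured_calcium = make_coloured_calcium(...),
         stop_hpn(paste0("unknown fixture `", name, "`"), "hpn_config_error"))
}
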