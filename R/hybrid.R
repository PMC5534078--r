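#' Simulation configuration
#'
#' Bundles the algorithm choice, horizon, output grid, random seed,
#' ensemble settings, integrator tolerances and the rejection/dynamic
#' partitioning knobs.
#'
#' Algorithms: `hr_exact` integrates the jump equation
#' `integral of the total slow propensity = -log(r)` together with the ODE
#' system and captures the stochastic firing time as an event root
#' (Haseltine-Rawlings); `accelerated` solves the algebraic approximation
#' `a0 * dtau = -log(r)` with propensities held at the last event and
#' reinitialises the ODE solver only after *dependent* firings; `hrssa`
#' selects candidate firings from propensity upper bounds over a
#' fluctuation interval and accepts by rejection against the exact state,
#' switching regimes only at candidate times or when the state leaves the
#' interval; `dynamic` is `hrssa` with state-driven repartitioning at every
#' fluctuation-interval exit; `pure_ssa` / `pure_ode` ignore the partition
#' and run everything with the Gillespie direct method / as one ODE system.
#'
#' @param algorithm One of `"hr_exact"`, `"accelerated"`, `"hrssa"`,
#'   `"dynamic"`, `"pure_ssa"`, `"pure_ode"`.
#' @param t_start,t_end Simulation window (`t_end > t_start`).
#' @param grid_points Number of uniformly spaced output points.
#' @param seed Integer seed for the run (or ensemble master seed).
#' @param runs,workers Ensemble size and worker processes; results are
#'   bit-identical for any `workers`.
#' @param method,rtol,atol,max_step,root_tol See [integrator_config()].
#' @param delta,fi_floor,cont_floor Fluctuation-interval half-width
#'   (relative), and minimum absolute half-widths for discrete/continuous
#'   species; see [make_fluctuation_interval()].
#' @param lambda_prop,n_substrate Dynamic-partitioning thresholds; see
#'   [dynamic_partition()].
#' @param select Place ids to record (default: all places).
#' @param record_firings Also record cumulative firing counts of
#'   stochastic/timed transitions as trace columns.
#' @param record_events Attach an `event_log` attribute (tibble of firing
#'   times and transition ids) to the trace.
#' @return An `hpn_sim_config` list.
#' @export
sim_config <- function(algorithm = c("hr_exact", "accelerated", "hrssa", "dynamic",
                                     "pure_ssa", "pure_ode"),
                       t_start = 0, t_end = 10, grid_points = 1000,
                       seed = 1L, runs = 1L, workers = 1L,
                       method = "stiff", rtol = 1e-6, atol = 1e-9,
                       max_step = Inf, root_tol = 1e-8,
                       delta = 0.1, fi_floor = 2, cont_floor = 1e-4,
                       lambda_prop = 10, n_substrate = 100,
                       select = NULL, record_firings = FALSE, record_events = FALSE) {
  algorithm <- match.arg(algorithm)
  if (t_end <= t_start) stop_hpn("t_end must exceed t_start", "hpn_config_error")
  if (runs < 1) stop_hpn("runs must be >= 1", "hpn_config_error")
  structure(list(algorithm = algorithm, t_start = t_start, t_end = t_end,
                 grid_points = as.integer(grid_points), seed = as.integer(seed),
                 runs = as.integer(runs), workers = as.integer(workers),
                 ode = integrator_config(method, rtol, atol, max_step, root_tol),
                 delta = delta, fi_floor = fi_floor, cont_floor = cont_floor,
                 lambda_prop = lambda_prop, n_substrate = n_substrate,
                 select = select, record_firings = record_firings,
                 record_events = record_events),
            class = "hpn_sim_config")
}

# ---------------------------------------------------------------------------
# engine plumbing: recorder, timed transitions, shared state environment

setup_engine <- function(net, cfg) {
  cm <- compile_hpn(net, check = TRUE)
  E <- new.env(parent = emptyenv())
  E$cm <- cm
  E$cfg <- cfg
  E$state <- cm$init
  E$t <- cfg$t_start
  E$grid <- seq(cfg$t_start, cfg$t_end, length.out = cfg$grid_points)
  sel <- cfg$select %||% cm$place_ids
  bad <- setdiff(sel, cm$place_ids)
  if (length(bad)) stop_hpn(paste0("unknown places in select: ",
                                   paste(bad, collapse = ", ")), "hpn_config_error")
  E$sel <- sel
  E$fcount <- setNames(numeric(length(cm$tid)), cm$tid)
  E$fsel <- if (isTRUE(cfg$record_firings)) cm$tid else character()
  E$out <- matrix(NA_real_, length(E$grid), length(sel) + length(E$fsel),
                  dimnames = list(NULL, c(sel, E$fsel)))
  E$gi <- 1L
  E$events <- 0L
  E$rejects <- 0L
  E$timed_fired <- 0L
  E$reinits <- 0L
  E$elog_t <- double()
  E$elog_j <- character()
  init_timed(E)
  E
}

log_event <- function(E, t, j) {
  if (isTRUE(E$cfg$record_events)) {
    E$elog_t <- c(E$elog_t, t)
    E$elog_j <- c(E$elog_j, j)
  }
}

# Fill pending output-grid points up to t_to with the current state (and
# dense continuous values from `segment`). With `open_end` the point exactly
# at t_to stays pending, so a later fill records the post-event state there:
# sampled traces are right-continuous at firing times.
rec_fill <- function(E, t_to, segment = NULL, open_end = FALSE) {
  eps <- 1e-12 * max(1, abs(t_to))
  if (open_end) eps <- -eps
  n <- length(E$grid)
  if (E$gi > n || E$grid[E$gi] > t_to + eps) return(invisible())
  last <- E$gi
  while (last < n && E$grid[last + 1L] <= t_to + eps) last <- last + 1L
  idx <- E$gi:last
  base <- matrix(rep(c(E$state[E$sel], E$fcount[E$fsel]), each = length(idx)),
                 nrow = length(idx),
                 dimnames = list(NULL, c(E$sel, E$fsel)))
  if (!is.null(segment) && nrow(segment) > 1L) {
    cols <- intersect(colnames(segment), E$sel)
    for (cn in cols)
      base[, cn] <- stats::approx(segment[, "time"], segment[, cn],
                                  xout = E$grid[idx], rule = 2)$y
  }
  E$out[idx, ] <- base
  E$gi <- last + 1L
  invisible()
}

record_fire <- function(E, tid) {
  E$fcount[[tid]] <- E$fcount[[tid]] + 1
}

init_timed <- function(E) {
  cm <- E$cm
  sched <- list()
  for (tid in cm$tid[cm$tkind == "scheduled"]) {
    s <- cm$tr[[tid]]$sched
    sched[[tid]] <- list(times = if (s[2] > 0) seq(s[1], s[3], by = s[2]) else s[1],
                         ptr = 1L)
  }
  E$sched <- sched
  E$pending <- setNames(rep(NA_real_, sum(cm$tkind == "deterministic_delay")),
                        cm$tid[cm$tkind == "deterministic_delay"])
  E$has_timed <- length(sched) > 0 || length(E$pending) > 0 ||
    any(cm$tkind == "immediate")
}

refresh_delays <- function(E) {
  for (tid in names(E$pending)) {
    en <- enabled_cm(E$cm, E$cm$tr[[tid]], E$state)
    if (en && is.na(E$pending[[tid]]))
      E$pending[[tid]] <- E$t + E$cm$tr[[tid]]$delay
    else if (!en)
      E$pending[[tid]] <- NA_real_
  }
}

next_timed_time <- function(E) {
  cand <- Inf
  for (tid in names(E$sched)) {
    s <- E$sched[[tid]]
    if (s$ptr <= length(s$times)) cand <- min(cand, s$times[s$ptr])
  }
  p <- E$pending[!is.na(E$pending)]
  if (length(p)) cand <- min(cand, min(p))
  cand
}

# fire all immediate transitions to quiescence; conflicts resolved by a
# weight-proportional draw. Returns the set of changed places.
fire_immediates <- function(E, rng) {
  cm <- E$cm
  imm <- cm$tid[cm$tkind == "immediate"]
  changed <- character()
  if (!length(imm)) return(changed)
  for (it in seq_len(10000L)) {
    en <- imm[vapply(imm, function(tid) enabled_cm(cm, cm$tr[[tid]], E$state),
                     logical(1))]
    if (!length(en)) return(changed)
    j <- if (length(en) == 1L) en else {
      w <- vapply(en, function(tid) cm$tr[[tid]]$imm_weight, double(1))
      en[select_index(w, draw_uniform(rng) * sum(w))]
    }
    ct <- cm$tr[[j]]
    old <- E$state
    E$state <- fire_cm(cm, ct, E$state)
    record_fire(E, j)
    E$timed_fired <- E$timed_fired + 1L
    changed <- union(changed, names(old)[old != E$state])
  }
  stop_hpn("immediate transitions did not reach quiescence after 10000 firings",
           "hpn_livelock")
}

# fire timed (scheduled / delayed) transitions due at the current time, in
# (time, id) order; then immediates. Returns changed places.
fire_due_timed <- function(E, rng) {
  eps <- 1e-9 * max(1, abs(E$t))
  due <- list()
  for (tid in names(E$sched)) {
    s <- E$sched[[tid]]
    if (s$ptr <= length(s$times) && s$times[s$ptr] <= E$t + eps)
      due[[length(due) + 1L]] <- list(time = s$times[s$ptr], id = tid, type = "sched")
  }
  for (tid in names(E$pending)) {
    if (!is.na(E$pending[[tid]]) && E$pending[[tid]] <= E$t + eps)
      due[[length(due) + 1L]] <- list(time = E$pending[[tid]], id = tid, type = "delay")
  }
  if (!length(due)) return(character())
  ord <- order(vapply(due, `[[`, double(1), "time"),
               vapply(due, `[[`, character(1), "id"))
  changed <- character()
  for (d in due[ord]) {
    tid <- d$id
    if (d$type == "sched") E$sched[[tid]]$ptr <- E$sched[[tid]]$ptr + 1L
    else E$pending[[tid]] <- NA_real_
    if (enabled_cm(E$cm, E$cm$tr[[tid]], E$state)) {
      old <- E$state
      E$state <- fire_cm(E$cm, E$cm$tr[[tid]], E$state)
      record_fire(E, tid)
      E$timed_fired <- E$timed_fired + 1L
      changed <- union(changed, names(old)[old != E$state])
    }
  }
  union(changed, fire_immediates(E, rng))
}

# gated slow-propensity integrand for the jump equation: transitions
# disabled by frozen discrete places drop out; enabling conditions on
# continuous species become indicator factors; rates are clamped at 0.
build_slow_call <- function(cm, slow, state, cont_species) {
  terms <- list()
  for (tid in slow) {
    ct <- cm$tr[[tid]]
    gates <- list()
    skip <- FALSE
    for (k in seq_along(ct$pre_place)) {
      p <- ct$pre_place[k]
      w <- if (ct$pre_const) ct$pre_wnum[[k]] else
        stop_hpn("jump-equation gating needs constant enabling arc weights",
                 "hpn_config_error")
      if (p %in% cont_species) {
        op <- switch(ct$pre_kind[k], standard = , read = ">=",
                     inhibitor = "<", equal = "==")
        gates[[length(gates) + 1L]] <- call("(", call(op, as.name(p), w))
      } else {
        ok <- switch(ct$pre_kind[k],
                     standard = , read = state[[p]] >= w,
                     inhibitor = state[[p]] < w,
                     equal = state[[p]] == w)
        if (!ok) { skip <- TRUE; break }
      }
    }
    if (skip) next
    e <- call("max", ct$rate, 0)
    for (g in gates) e <- call("*", g, e)
    terms[[length(terms) + 1L]] <- e
  }
  if (!length(terms)) return(quote(0))
  as.call(c(quote(c), terms))
}

# shared finishing: wrap the recorder output as a trace
finish_trace <- function(E, algorithm, run = 1L) {
  rec_fill(E, E$grid[length(E$grid)])
  tr <- tibble::as_tibble(as.data.frame(E$out))
  tr <- dplyr::bind_cols(tibble(time = E$grid), tr)
  structure(tr, class = c("hpn_trace", class(tr)),
            algorithm = algorithm, seed = E$cfg$seed, run = run,
            events = E$events, reinits = E$reinits, rejects = E$rejects,
            timed_fired = E$timed_fired, model = E$cm$net$name,
            event_log = if (isTRUE(E$cfg$record_events))
              tibble(time = E$elog_t, transition = E$elog_j) else NULL)
}

frozen_data <- function(cm, state, cont_species) {
  c(cm$params, as.list(state[setdiff(names(state), cont_species)]))
}

# ---------------------------------------------------------------------------
# pure modes

#' Pure stochastic and pure deterministic runs
#'
#' `pure_ssa_run()` ignores the partition and executes every rate-bearing
#' transition with the Gillespie direct method (all species must carry
#' integer markings); `pure_ode_run()` treats every rate-bearing transition
#' deterministically and integrates a single ODE system over all species.
#'
#' @inheritParams add_place
#' @param config An [sim_config()].
#' @param rng Optional `hpn_rng`; defaults to a stream seeded from
#'   `config$seed`.
#' @return An `hpn_trace` tibble (time plus one column per recorded place)
#'   with metadata attributes (`algorithm`, `seed`, `events`, `reinits`).
#' @export
pure_ssa_run <- function(net, config = sim_config("pure_ssa"), rng = NULL) {
  rng <- rng %||% random_stream(config$seed)
  E <- setup_engine(net, config)
  cm <- E$cm
  if (any(!is_whole(E$state)))
    stop_hpn("pure stochastic simulation needs integer markings on every place",
             "hpn_config_error")
  stoch <- cm$tid[cm$tkind %in% c("stochastic", "continuous")]
  repeat {
    fire_immediates(E, rng)
    refresh_delays(E)
    tnt <- next_timed_time(E)
    if (tnt <= E$t + 1e-12) { fire_due_timed(E, rng); next }
    span_end <- min(config$t_end, tnt)
    ps <- propensity_state(cm, E$state, stoch)
    st <- direct_method_step(ps, rng)
    if (isTRUE(st$no_event) || E$t + st$tau > span_end) {
      E$t <- span_end
      rec_fill(E, span_end, open_end = TRUE)
      if (E$t >= config$t_end - 1e-12) break
    } else {
      E$t <- E$t + st$tau
      rec_fill(E, E$t, open_end = TRUE)
      E$state <- fire_cm(cm, cm$tr[[st$j]], E$state)
      record_fire(E, st$j)
      E$events <- E$events + 1L
      log_event(E, E$t, st$j)
    }
  }
  finish_trace(E, "pure_ssa")
}

#' @rdname pure_ssa_run
#' @export
pure_ode_run <- function(net, config = sim_config("pure_ode"), rng = NULL) {
  rng <- rng %||% random_stream(config$seed)
  E <- setup_engine(net, config)
  cm <- E$cm
  rb <- cm$tid[cm$tkind %in% c("stochastic", "continuous")]
  partition <- derive_partition(net, character(), rb)
  partition$continuous_species <- cm$place_ids
  partition$discrete_species <- character()
  sys <- build_ode_system_cm(cm, partition)
  ses <- ode_session(sys, y0 = E$state[sys$species], t0 = E$t, config = config$ode)
  repeat {
    fire_immediates(E, rng)
    refresh_delays(E)
    tnt <- next_timed_time(E)
    if (tnt <= E$t + 1e-12) {
      ch <- fire_due_timed(E, rng)
      if (length(ch)) ode_reinitialise(ses, E$state[sys$species], E$t)
      next
    }
    span_end <- min(config$t_end, tnt)
    if (length(sys$species) > 0 && span_end > E$t) {
      res <- ode_integrate(ses, span_end, times = E$grid,
                           frozen = frozen_data(cm, E$state, sys$species))
      E$state[sys$species] <- res$y_stop
      E$t <- res$t_stop
      rec_fill(E, E$t, segment = res$segment, open_end = TRUE)
    } else {
      E$t <- span_end
      rec_fill(E, E$t, open_end = TRUE)
    }
    if (E$t >= config$t_end - 1e-12) break
  }
  E$reinits <- ses$reinits
  finish_trace(E, "pure_ode")
}

# ---------------------------------------------------------------------------
# exact jump-equation hybrid (Haseltine & Rawlings)

#' Hybrid simulation runs
#'
#' `hr_exact_run()` implements the exact jump-equation hybrid scheme: a
#' uniform draw `r` sets the target `-log(r)`; the ODE system is augmented
#' with the accumulator `dg/dt = sum_j a_j(x(t))` over the slow
#' (stochastic-regime) reactions and integrated until the event root
#' `g = -log(r)`, at which point reaction `j` fires with probability
#' proportional to its propensity *at the event time*, the solver is
#' reinitialised and the accumulator resets. `accelerated_run()` replaces
#' the integral by the algebraic waiting time `dtau = -log(r) / a0` with
#' propensities evaluated at the previous event, and skips solver
#' reinitialisation for independent reactions (see
#' [build_dependency_graph()]). `hrssa_run()` draws candidate firings from
#' propensity upper bounds over a fluctuation interval and accepts them by
#' rejection against the exact state, recomputing bounds only when the
#' state leaves the interval; accepted firings reuse the accelerated
#' reinitialisation rule. `dynamic_run()` additionally repartitions the
#' reactions (see [dynamic_partition()]) at every fluctuation-interval
#' exit.
#'
#' When the deterministic regime is empty the jump integrand is constant
#' between events and the root is taken in closed form, so all three
#' hybrid algorithms reduce exactly to the direct method.
#'
#' @inheritParams pure_ssa_run
#' @param partition An [make_partition()] result (defaults to the partition
#'   implied by transition kinds).
#' @return An `hpn_trace`; see [pure_ssa_run()].
#' @export
hr_exact_run <- function(net, partition = NULL, config = sim_config("hr_exact"),
                         rng = NULL) {
  rng <- rng %||% random_stream(config$seed)
  partition <- partition %||% make_partition(net)
  E <- setup_engine(net, config)
  cm <- E$cm
  slow <- partition$stochastic
  sys <- build_ode_system_cm(cm, partition)
  zero_dim <- length(sys$species) == 0L
  ses <- if (!zero_dim)
    ode_session(sys, y0 = E$state[sys$species], t0 = E$t, config = config$ode)
  else NULL
  target <- NA_real_
  repeat {
    fire_immediates(E, rng)
    refresh_delays(E)
    tnt <- next_timed_time(E)
    if (tnt <= E$t + 1e-12) {
      ch <- fire_due_timed(E, rng)
      if (length(ch) && !zero_dim) ode_reinitialise(ses, E$state[sys$species], E$t)
      next
    }
    span_end <- min(config$t_end, tnt)
    if (zero_dim) {
      ps <- propensity_state(cm, E$state, slow)
      if (is.na(target) && ps$a0 > 0) target <- -log(draw_uniform(rng))
      t_fire <- if (ps$a0 > 0 && !is.na(target)) E$t + target / ps$a0 else Inf
      if (t_fire <= span_end) {
        E$t <- t_fire
        rec_fill(E, E$t, open_end = TRUE)
        j <- slow[select_index(ps$a, draw_uniform(rng) * ps$a0)]
        E$state <- fire_cm(cm, cm$tr[[j]], E$state)
        record_fire(E, j)
        E$events <- E$events + 1L
        log_event(E, E$t, j)
        E$reinits <- E$reinits + 1L  # an attached solver would restart here
        target <- NA_real_
      } else {
        if (!is.na(target)) target <- target - ps$a0 * (span_end - E$t)
        E$t <- span_end
        rec_fill(E, E$t, open_end = TRUE)
        if (E$t >= config$t_end - 1e-12) break
      }
    } else {
      if (is.na(target)) target <- -log(draw_uniform(rng))
      slow_call <- build_slow_call(cm, slow, E$state, sys$species)
      nS <- length(sys$species)
      res <- ode_integrate(ses, span_end, times = E$grid,
                           events = list(function(t, y) y[nS + 1L] - target),
                           frozen = frozen_data(cm, E$state, sys$species),
                           slow_call = slow_call, g0 = 0)
      E$state[sys$species] <- res$y_stop
      E$t <- res$t_stop
      rec_fill(E, E$t, segment = res$segment, open_end = TRUE)
      if (res$stop == "event") {
        ps <- propensity_state(cm, E$state, slow)
        if (ps$a0 > 0) {
          j <- slow[select_index(ps$a, draw_uniform(rng) * ps$a0)]
          E$state <- fire_cm(cm, cm$tr[[j]], E$state)
          record_fire(E, j)
          E$events <- E$events + 1L
          log_event(E, E$t, j)
        }
        ode_reinitialise(ses, E$state[sys$species], E$t)
        target <- NA_real_
      } else {
        target <- target - res$g_stop
        if (E$t >= config$t_end - 1e-12) break
      }
    }
  }
  if (!zero_dim) E$reinits <- ses$reinits
  finish_trace(E, "hr_exact")
}

# ---------------------------------------------------------------------------
# accelerated hybrid

#' @rdname hr_exact_run
#' @export
accelerated_run <- function(net, partition = NULL,
                            config = sim_config("accelerated"), rng = NULL) {
  rng <- rng %||% random_stream(config$seed)
  partition <- partition %||% make_partition(net)
  E <- setup_engine(net, config)
  cm <- E$cm
  slow <- partition$stochastic
  dg <- build_dependency_graph_cm(cm, partition)
  det_reads <- unique(unlist(lapply(partition$deterministic,
                                    function(tid) cm$tr[[tid]]$dep_places)))
  sys <- build_ode_system_cm(cm, partition)
  zero_dim <- length(sys$species) == 0L
  ses <- if (!zero_dim)
    ode_session(sys, y0 = E$state[sys$species], t0 = E$t, config = config$ode)
  else NULL
  repeat {
    fire_immediates(E, rng)
    refresh_delays(E)
    tnt <- next_timed_time(E)
    if (tnt <= E$t + 1e-12) {
      ch <- fire_due_timed(E, rng)
      if (length(ch) && !zero_dim &&
          length(intersect(ch, union(sys$species, det_reads))))
        ode_reinitialise(ses, E$state[sys$species], E$t)
      next
    }
    span_end <- min(config$t_end, tnt)
    ps <- propensity_state(cm, E$state, slow)
    t_fire <- if (ps$a0 > 0) E$t - log(draw_uniform(rng)) / ps$a0 else Inf
    stop_t <- min(span_end, t_fire)
    if (!zero_dim && stop_t > E$t) {
      res <- ode_integrate(ses, stop_t, times = E$grid,
                           frozen = frozen_data(cm, E$state, sys$species))
      E$state[sys$species] <- res$y_stop
      E$t <- res$t_stop
      rec_fill(E, E$t, segment = res$segment, open_end = TRUE)
    } else {
      E$t <- stop_t
      rec_fill(E, E$t, open_end = TRUE)
    }
    if (stop_t == t_fire) {
      j <- slow[select_index(ps$a, draw_uniform(rng) * ps$a0)]
      E$state <- fire_cm(cm, cm$tr[[j]], E$state)
      record_fire(E, j)
      E$events <- E$events + 1L
      log_event(E, E$t, j)
      if (!zero_dim && dg$dependent[[j]])
        ode_reinitialise(ses, E$state[sys$species], E$t)
    } else {
      if (E$t >= config$t_end - 1e-12) break
    }
  }
  if (!zero_dim) E$reinits <- ses$reinits
  finish_trace(E, "accelerated")
}

# ---------------------------------------------------------------------------
# improved hybrid rejection-based simulation (HRSSA) and dynamic mode

hrssa_engine <- function(net, partition, config, rng, dynamic = FALSE) {
  E <- setup_engine(net, config)
  cm <- E$cm
  if (dynamic)
    partition <- dynamic_partition_cm(cm, E$state, config$lambda_prop,
                                      config$n_substrate)
  ctx <- new.env(parent = emptyenv())
  ctx$ses <- NULL
  rebuild_regime <- function(first = FALSE) {
    carried <- if (!is.null(ctx$ses)) ctx$ses$reinits else 0L
    repart_with_ode <- !first && !is.null(ctx$ses)  # rebuilding discards history
    ctx$slow <- partition$stochastic
    ctx$dg <- build_dependency_graph_cm(cm, partition)
    ctx$det_reads <- unique(unlist(lapply(partition$deterministic,
                                          function(tid) cm$tr[[tid]]$dep_places)))
    ctx$sys <- build_ode_system_cm(cm, partition)
    ctx$zero_dim <- length(ctx$sys$species) == 0L
    ctx$ses <- if (!ctx$zero_dim) {
      s <- ode_session(ctx$sys, y0 = E$state[ctx$sys$species], t0 = E$t,
                       config = config$ode)
      s$reinits <- carried + if (repart_with_ode) 1L else 0L
      s
    } else NULL
    ctx$carried <- carried
    # species whose value influences any slow propensity
    ctx$rel <- unique(unlist(lapply(ctx$slow, function(tid) cm$tr[[tid]]$dep_places)))
    ctx$rel_cont <- intersect(ctx$rel, ctx$sys$species)
  }
  rebuild_regime(first = TRUE)
  rebuild_fi <- function() {
    ctx$fi <- make_fi_cm(cm, E$state, config$delta, config$fi_floor, ctx$slow,
                         config$cont_floor)
  }
  rebuild_fi()
  fi_ok <- function() {
    rel <- ctx$rel
    if (!length(rel)) return(TRUE)
    all(E$state[rel] >= ctx$fi$lo[rel] & E$state[rel] <= ctx$fi$hi[rel])
  }
  on_bounds_exit <- function() {
    if (dynamic) {
      new_part <- dynamic_partition_cm(cm, E$state, config$lambda_prop,
                                       config$n_substrate)
      if (!setequal(new_part$stochastic, partition$stochastic) ||
          !setequal(new_part$deterministic, partition$deterministic)) {
        # reclassified continuous -> discrete species snap to integers
        back <- intersect(new_part$discrete_species, partition$continuous_species)
        if (length(back)) E$state[back] <- round(E$state[back])
        partition <<- new_part
        rebuild_regime()
      }
    }
    rebuild_fi()
  }
  exit_events <- function() {
    evs <- list()
    sp <- ctx$sys$species
    for (p in ctx$rel_cont) {
      i <- match(p, sp)
      hi <- ctx$fi$hi[[p]]; lo <- ctx$fi$lo[[p]]
      evs[[length(evs) + 1L]] <- local({
        ii <- i; hh <- hi
        function(t, y) y[ii] - hh
      })
      if (lo > 0) evs[[length(evs) + 1L]] <- local({
        ii <- i; ll <- lo
        function(t, y) y[ii] - ll
      })
    }
    evs
  }
  repeat {
    fire_immediates(E, rng)
    refresh_delays(E)
    tnt <- next_timed_time(E)
    if (tnt <= E$t + 1e-12) {
      ch <- fire_due_timed(E, rng)
      if (length(ch)) {
        if (!ctx$zero_dim &&
            length(intersect(ch, union(ctx$sys$species, ctx$det_reads))))
          ode_reinitialise(ctx$ses, E$state[ctx$sys$species], E$t)
        if (!fi_ok()) on_bounds_exit()
      }
      next
    }
    span_end <- min(config$t_end, tnt)
    fi <- ctx$fi
    t_cand <- if (fi$abar0 > 0) E$t - log(draw_uniform(rng)) / fi$abar0 else Inf
    stop_t <- min(span_end, t_cand)
    if (!ctx$zero_dim && stop_t > E$t) {
      res <- ode_integrate(ctx$ses, stop_t, times = E$grid,
                           events = exit_events(),
                           frozen = frozen_data(cm, E$state, ctx$sys$species))
      E$state[ctx$sys$species] <- res$y_stop
      E$t <- res$t_stop
      rec_fill(E, E$t, segment = res$segment, open_end = TRUE)
      if (res$stop == "event") {  # fluctuation-interval exit
        on_bounds_exit()
        next
      }
    } else {
      E$t <- stop_t
      rec_fill(E, E$t, open_end = TRUE)
    }
    if (stop_t == t_cand) {
      u <- draw_uniform(rng, 2L)
      j <- fi$transitions[select_index(fi$a_hi, u[1] * fi$abar0)]
      accept <- u[2] * fi$a_hi[[j]] <= fi$a_lo[[j]]
      if (!accept) {
        a_exact <- prop_cm(cm, cm$tr[[j]], E$state)
        accept <- u[2] * fi$a_hi[[j]] <= a_exact
      }
      if (accept) {
        E$state <- fire_cm(cm, cm$tr[[j]], E$state)
        record_fire(E, j)
        E$events <- E$events + 1L
        log_event(E, E$t, j)
        if (!ctx$zero_dim && ctx$dg$dependent[[j]])
          ode_reinitialise(ctx$ses, E$state[ctx$sys$species], E$t)
        if (!fi_ok()) on_bounds_exit()
      } else {
        E$rejects <- E$rejects + 1L
      }
    } else {
      if (E$t >= config$t_end - 1e-12) break
    }
  }
  E$reinits <- if (!is.null(ctx$ses)) ctx$ses$reinits else ctx$carried
  finish_trace(E, if (dynamic) "dynamic" else "hrssa")
}

#' @rdname hr_exact_run
#' @export
hrssa_run <- function(net, partition = NULL, config = sim_config("hrssa"),
                      rng = NULL) {
  rng <- rng %||% random_stream(config$seed)
  partition <- partition %||% make_partition(net)
  hrssa_engine(net, partition, config, rng, dynamic = FALSE)
}

#' @rdname hr_exact_run
#' @export
dynamic_run <- function(net, config = sim_config("dynamic"), rng = NULL) {
  rng <- rng %||% random_stream(config$seed)
  hrssa_engine(net, make_partition(net), config, rng, dynamic = TRUE)
}

# ---------------------------------------------------------------------------
# front door and ensembles

run_one <- function(net, algorithm, partition, config, rng) {
  switch(algorithm,
         hr_exact = hr_exact_run(net, partition, config, rng),
         accelerated = accelerated_run(net, partition, config, rng),
         hrssa = hrssa_run(net, partition, config, rng),
         dynamic = dynamic_run(net, config, rng),
         pure_ssa = pure_ssa_run(net, config, rng),
         pure_ode = pure_ode_run(net, config, rng),
         stop_hpn(paste0("unknown algorithm `", algorithm, "`"), "hpn_config_error"))
}

#' Simulate a hybrid Petri net
#'
#' Tidy front door over the run functions: builds the configuration,
#' derives the default partition, runs a single trajectory (`runs = 1`) or
#' a deterministic parallel ensemble (`runs > 1`, see [run_ensemble()]).
#'
#' @inheritParams hr_exact_run
#' @param algorithm See [sim_config()].
#' @param ... Passed to [sim_config()].
#' @return An `hpn_trace` (single run) or `hpn_ensemble` (ensemble).
#' @examples
#' net <- make_immigration_death(10, 1)
#' tr <- simulate_hpn(net, "pure_ssa", t_end = 5, grid_points = 51, seed = 1)
#' dplyr::glimpse(tr)
#' @export
simulate_hpn <- function(net, algorithm = "hr_exact", partition = NULL, ...) {
  config <- sim_config(algorithm = algorithm, ...)
  if (config$runs > 1L) return(run_ensemble(net, config, partition))
  run_one(net, algorithm, partition, config, random_stream(config$seed))
}

#' Deterministic parallel ensembles
#'
#' Runs `config$runs` independent trajectories; run `i` uses substream `i`
#' of the master seed (see [random_stream()]), so the result is
#' bit-identical for any `workers` count. The averaged trace is the
#' pointwise mean over the shared output grid.
#'
#' @inheritParams hr_exact_run
#' @return An `hpn_ensemble`: list with `mean` (an `hpn_trace` of pointwise
#'   means), `runs` (list of per-run traces) and `config`.
#' @export
run_ensemble <- function(net, config, partition = NULL) {
  stopifnot(inherits(config, "hpn_sim_config"))
  master <- random_stream(config$seed)
  seeds <- vector("list", config$runs)
  s <- master$state
  for (i in seq_len(config$runs)) {
    seeds[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  one <- function(i) {
    rng <- new.env(parent = emptyenv())
    rng$state <- seeds[[i]]
    class(rng) <- "hpn_rng"
    run_one(net, config$algorithm, partition, config, rng)
  }
  traces <- if (config$workers > 1L) {
    parallel::mclapply(seq_len(config$runs), one, mc.cores = config$workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(config$runs), one)
  }
  err <- vapply(traces, function(x) inherits(x, "try-error") || is.null(x), logical(1))
  if (any(err)) stop_hpn("ensemble worker failure", "hpn_ensemble_error")
  cols <- setdiff(names(traces[[1]]), "time")
  acc <- matrix(0, nrow(traces[[1]]), length(cols), dimnames = list(NULL, cols))
  for (tr in traces) acc <- acc + as.matrix(tr[cols])
  avg <- dplyr::bind_cols(tibble(time = traces[[1]]$time),
                          tibble::as_tibble(as.data.frame(acc / length(traces))))
  class(avg) <- c("hpn_trace", class(avg))
  attr(avg, "algorithm") <- config$algorithm
  attr(avg, "seed") <- config$seed
  attr(avg, "run") <- NA_integer_
  attr(avg, "events") <- sum(vapply(traces, function(x) attr(x, "events"), integer(1)))
  attr(avg, "reinits") <- sum(vapply(traces, function(x) attr(x, "reinits"), integer(1)))
  attr(avg, "model") <- net$name
  structure(list(mean = avg, runs = traces, config = config),
            class = "hpn_ensemble")
}

#' @export
print.hpn_ensemble <- function(x, ...) {
  cat("<hpn_ensemble> ", length(x$runs), " runs of `", x$config$algorithm,
      "`, seed ", x$config$seed, "\n", sep = "")
  print(x$mean, ...)
  invisible(x)
}
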