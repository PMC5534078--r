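#' Integrator configuration
#'
#' Settings for the deterministic engine. The backend is deSolve's
#' `lsodar`, an adaptive multistep solver with automatic switching between
#' stiff (BDF) and non-stiff (Adams) methods and built-in root finding;
#' `method` records the user's preference and is carried in trace metadata
#' (the switching solver serves both regimes). Any integrator offering
#' adaptive steps, dense output and root localisation can be substituted
#' behind [ode_integrate()].
#'
#' @param method `"stiff"` or `"nonstiff"` preference.
#' @param rtol,atol Relative/absolute tolerances (> 0).
#' @param max_step Maximum step size (default unrestricted).
#' @param root_tol Tolerance used when comparing event times.
#' @return An `hpn_ode_config` list.
#' @export
integrator_config <- function(method = c("stiff", "nonstiff"), rtol = 1e-6,
                              atol = 1e-9, max_step = Inf, root_tol = 1e-8) {
  method <- match.arg(method)
  if (rtol <= 0 || atol <= 0 || root_tol <= 0)
    stop_hpn("tolerances must be positive", "hpn_ode_error")
  structure(list(method = method, rtol = rtol, atol = atol,
                 max_step = max_step, root_tol = root_tol),
            class = "hpn_ode_config")
}

#' Build the ODE system of the deterministic regime
#'
#' One state entry per continuous species; the right-hand side is
#' `dy_i/dt = sum_k s_ik v_k(y, d)` over the deterministic transitions `k`
#' with stoichiometry `s` and rate law `v`, where `d` is the discrete
#' marking held frozen during an integration span (e.g. a channel-state
#' place read by an inflow rate). The right-hand side is side-effect free.
#'
#' @inheritParams add_place
#' @param partition An [make_partition()] result.
#' @return An `hpn_ode_system`: list with `species` (continuous state
#'   order), `det` (deterministic transition ids), a stoichiometry matrix
#'   and the compiled rate call.
#' @export
build_ode_system <- function(net, partition = NULL) {
  partition <- partition %||% make_partition(net)
  cm <- compile_hpn(net, check = FALSE)
  build_ode_system_cm(cm, partition)
}

build_ode_system_cm <- function(cm, partition) {
  species <- intersect(cm$place_ids, partition$continuous_species)
  det <- partition$deterministic
  nD <- length(det)
  nS <- length(species)
  rate_call <- if (nD > 0)
    as.call(c(quote(c), lapply(det, function(tid) cm$tr[[tid]]$rate)))
  else NULL
  # stoichiometry matrix over continuous species (constant weights required
  # on deterministic standard arcs; expression weights would make S state-
  # dependent, which the deterministic regime does not support)
  S <- NULL
  if (nD > 0) {
    ii <- integer(0); jj <- integer(0); xx <- double(0)
    for (k in seq_len(nD)) {
      ct <- cm$tr[[det[k]]]
      if (ct$stoich_dyn)
        stop_hpn(paste0("deterministic transition `", ct$id,
                        "` needs constant standard-arc weights"), "hpn_ode_error")
      st <- ct$stoich
      for (p in names(st)) {
        i <- match(p, species)
        if (is.na(i))
          stop_hpn(paste0("deterministic transition `", ct$id, "` writes `", p,
                          "`, which is not a continuous species of the partition"),
                   "hpn_ode_error")
        ii <- c(ii, i); jj <- c(jj, k); xx <- c(xx, st[[p]])
      }
    }
    S <- if (nS * nD > 40000L)
      Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nS, nD))
    else {
      m <- matrix(0, nS, nD)
      m[cbind(ii, jj)] <- xx
      m
    }
  }
  structure(list(species = species, det = det, S = S, rate_call = rate_call,
                 cm = cm), class = "hpn_ode_system")
}

# rhs factory: returns function(t, y, parms) for deSolve. `frozen` is the
# named list of discrete markings + parameters; `slow_call` optionally adds
# the jump-equation accumulator dg/dt = sum of slow propensities (clamped
# at 0, so the jump event root only increases).
make_rhs <- function(sys, frozen, slow_call = NULL) {
  species <- sys$species
  nS <- length(species)
  S <- sys$S
  rate_call <- sys$rate_call
  force(frozen)
  function(t, y, parms) {
    data <- frozen
    if (nS > 0) data[species] <- pmax(y[seq_len(nS)], 0)
    dy <- if (!is.null(rate_call)) {
      v <- eval(rate_call, data, baseenv())
      as.numeric(S %*% v)
    } else numeric(nS)
    if (!is.null(slow_call)) {
      g <- sum(pmax(eval(slow_call, data, baseenv()), 0))
      list(c(dy, g))
    } else list(dy)
  }
}

#' Create an ODE solver session
#'
#' A session carries the current `(t, y)` state and a reinitialisation
#' counter. Integration spans continue seamlessly from the current state;
#' [ode_reinitialise()] discards the solver history after a discrete jump
#' has modified the state and increments the counter, which is the
#' observable behind the accelerated algorithm's reinitialisation-avoidance
#' mechanism.
#'
#' @param system An [build_ode_system()] result.
#' @param y0 Named numeric initial continuous state (defaults to the net's
#'   initial marking restricted to the system's species).
#' @param t0 Start time.
#' @param config An [integrator_config()].
#' @return An `hpn_ode_session` environment.
#' @export
ode_session <- function(system, y0 = NULL, t0 = 0, config = integrator_config()) {
  stopifnot(inherits(system, "hpn_ode_system"))
  y0 <- y0 %||% system$cm$init[system$species]
  e <- new.env(parent = emptyenv())
  e$sys <- system
  e$t <- t0
  e$y <- setNames(as.double(y0), system$species)
  e$reinits <- 0L
  e$config <- config
  class(e) <- "hpn_ode_session"
  e
}

#' Integrate a session forward with optional event (root) detection
#'
#' Adaptive-step integration from the session's current time to `t1`,
#' stopping early when any scalar event function crosses zero. The state at
#' the stop time comes from the solver's dense output. Small negative
#' continuous markings from round-off are clamped to zero (beyond
#' `10 * atol` they raise an error).
#'
#' @inheritParams ode_session
#' @param session An [ode_session()].
#' @param t1 Span end (> current time).
#' @param times Optional output time points inside the span.
#' @param events Optional list of functions `f(t, y) -> numeric` with
#'   sign-change semantics.
#' @param frozen Named list of frozen discrete markings and parameters for
#'   the span (defaults to parameters only).
#' @param slow_call Internal: jump-equation integrand call.
#' @param g0 Internal: initial accumulator value.
#' @return List with `segment` (matrix: time column plus one column per
#'   state entry), `stop` (`"horizon"` or `"event"`), `event_index`,
#'   `t_stop`, `y_stop`, `g_stop`.
#' @export
ode_integrate <- function(session, t1, times = NULL, events = NULL,
                          frozen = NULL, slow_call = NULL, g0 = 0) {
  stopifnot(inherits(session, "hpn_ode_session"))
  t0 <- session$t
  if (t1 <= t0) stop_hpn("t1 must exceed the current session time", "hpn_ode_error")
  sys <- session$sys
  cfg <- session$config
  frozen <- frozen %||% sys$cm$params
  nS <- length(sys$species)
  aug <- !is.null(slow_call)
  y <- c(session$y, if (aug) c(.g = g0))
  rhs <- make_rhs(sys, frozen, slow_call)
  tt <- sort(unique(c(t0, times[times > t0 & times < t1], t1)))
  rootfun <- if (!is.null(events)) {
    function(t, y, parms) vapply(events, function(f) f(t, y), double(1))
  } else NULL
  out <- tryCatch(
    deSolve::lsodar(y = unname(y), times = tt, func = rhs, parms = NULL,
                    rtol = cfg$rtol, atol = cfg$atol,
                    hmax = if (is.finite(cfg$max_step)) cfg$max_step else NULL,
                    rootfunc = rootfun),
    error = function(e) stop_hpn(
      paste0("ODE solver failure near t = ", signif(session$t, 8), ": ",
             conditionMessage(e)),
      "hpn_solver_failure", t = session$t, y = session$y))
  istate <- attr(out, "istate")[1]
  hit_root <- !is.null(rootfun) && !is.na(istate) && istate == 3
  nrow_out <- nrow(out)
  t_stop <- unname(out[nrow_out, 1])
  y_full <- out[nrow_out, -1, drop = TRUE]
  y_stop <- y_full[seq_len(nS)]
  names(y_stop) <- sys$species
  y_stop <- clamp_nonneg(y_stop, cfg$atol)
  event_index <- if (hit_root) which(attr(out, "iroot") != 0)[1] else NA_integer_
  session$t <- t_stop
  session$y <- y_stop
  colnames(out) <- c("time", sys$species, if (aug) ".g")
  list(segment = out, stop = if (hit_root) "event" else "horizon",
       event_index = event_index, t_stop = t_stop, y_stop = y_stop,
       g_stop = if (aug) unname(y_full[nS + 1L]) else NA_real_)
}

clamp_nonneg <- function(y, atol) {
  neg <- y < 0
  if (any(neg)) {
    if (any(y < -10 * atol))
      stop_hpn(paste0("continuous marking went negative beyond tolerance: ",
                      paste0(names(y)[y < -10 * atol], collapse = ", ")),
               "hpn_negative_marking")
    y[neg] <- 0
  }
  y
}

#' Reinitialise a solver session after a discrete jump
#'
#' Discards the multistep history; subsequent integration restarts from
#' `(t, y_new)`. The reinitialisation counter increments exactly once per
#' call and is reported in trace metadata.
#'
#' @inheritParams ode_integrate
#' @param y_new Named numeric state (finite, non-negative after clamping).
#' @param t Restart time (defaults to the session's current time).
#' @return The session, invisibly.
#' @export
ode_reinitialise <- function(session, y_new = NULL, t = NULL) {
  stopifnot(inherits(session, "hpn_ode_session"))
  y_new <- y_new %||% session$y
  if (any(!is.finite(y_new)))
    stop_hpn("reinitialisation state must be finite", "hpn_ode_error")
  session$y <- clamp_nonneg(setNames(as.double(y_new), names(y_new) %||% session$sys$species),
                            session$config$atol)
  session$t <- t %||% session$t
  session$reinits <- session$reinits + 1L
  invisible(session)
}

#' One-shot integration of an ODE system
#'
#' Convenience wrapper creating a throwaway session: integrate `system`
#' from `(t0, y0)` to `t1` with optional events.
#'
#' @inheritParams ode_integrate
#' @inheritParams ode_session
#' @export
integrate_ode_system <- function(system, y0, t0, t1, events = NULL, times = NULL,
                                 config = integrator_config(), frozen = NULL) {
  s <- ode_session(system, y0 = y0, t0 = t0, config = config)
  ode_integrate(s, t1, times = times, events = events, frozen = frozen)
}
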