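#' Seeded random streams with deterministic substreams
#'
#' Streams wrap R's L'Ecuyer-CMRG generator, a splittable generator with a
#' documented substream derivation (`parallel::nextRNGStream`). The `i`-th
#' substream of a seed is obtained by advancing the stream seed `i` times,
#' so ensemble run `i` sees the same numbers no matter how many workers the
#' ensemble is spread over, and an identical seed reproduces the draw
#' sequence bit-for-bit across platforms.
#'
#' @param seed Integer seed.
#' @return An object of class `hpn_rng` from which uniforms are drawn with
#'   [draw_uniform()].
#' @export
random_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- local({
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
    get(".Random.seed", globalenv())
  })
  class(e) <- "hpn_rng"
  e
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
}

#' @rdname random_stream
#' @param rng An `hpn_rng` stream.
#' @param n Number of draws.
#' @return `draw_uniform()`: `n` doubles strictly inside (0, 1).
#' @export
draw_uniform <- function(rng, n = 1L) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, globalenv())
  r <- runif(n)
  while (any(r <= 0 | r >= 1)) r[r <= 0 | r >= 1] <- runif(sum(r <= 0 | r >= 1))
  rng$state <- get(".Random.seed", globalenv())
  restore_rng_state(old)
  r
}

#' @rdname random_stream
#' @param i Substream index (>= 0); 0 is the stream itself.
#' @return `substream()`: a fresh `hpn_rng` for substream `i`.
#' @export
substream <- function(rng, i) {
  stopifnot(inherits(rng, "hpn_rng"), i >= 0)
  s <- rng$state
  for (k in seq_len(i)) s <- parallel::nextRNGStream(s)
  e <- new.env(parent = emptyenv())
  e$state <- s
  class(e) <- "hpn_rng"
  e
}

#' @rdname random_stream
#' @return `clone_stream()`: an independent copy at the current position.
#' @export
clone_stream <- function(rng) {
  e <- new.env(parent = emptyenv())
  e$state <- rng$state
  class(e) <- "hpn_rng"
  e
}

#' Propensities of the stochastic regime at a marking
#'
#' The propensity of stochastic reaction j is its rate-law value when the
#' transition is enabled at the marking and 0 otherwise.
#'
#' @inheritParams add_place
#' @param marking Named numeric state vector.
#' @param stochastic_set Transition ids of the stochastic regime; defaults
#'   to all transitions of kind `stochastic`.
#' @return An `hpn_propensities` object: list with `a` (named vector),
#'   `a0 = sum(a)` and `transitions`.
#' @export
compute_propensities <- function(net, marking = NULL, stochastic_set = NULL) {
  cm <- compile_hpn(net, check = FALSE)
  marking <- marking %||% cm$init
  stochastic_set <- stochastic_set %||% cm$tid[cm$tkind == "stochastic"]
  propensity_state(cm, marking, stochastic_set)
}

propensity_state <- function(cm, marking, stochastic_set) {
  data <- c(as.list(marking), cm$params)
  a <- vapply(stochastic_set, function(tid) prop_cm(cm, cm$tr[[tid]], marking, data),
              double(1))
  structure(list(a = a, a0 = sum(a), transitions = stochastic_set),
            class = "hpn_propensities")
}

#' One step of the Gillespie direct method
#'
#' Draws the waiting time `tau = -log(r1)/a0` and selects the firing
#' reaction as the smallest index whose cumulative propensity reaches
#' `r2 * a0`.
#'
#' @param ps An `hpn_propensities` object.
#' @param rng An `hpn_rng` stream.
#' @return List with `j` (transition id), `index`, and `tau`; or a list
#'   with `no_event = TRUE` when `a0 == 0` (the caller treats the horizon
#'   as the next event).
#' @export
direct_method_step <- function(ps, rng) {
  if (ps$a0 <= 0) return(list(no_event = TRUE))
  r <- draw_uniform(rng, 2L)
  tau <- -log(r[1]) / ps$a0
  j <- select_index(ps$a, r[2] * ps$a0)
  list(j = ps$transitions[j], index = j, tau = tau, no_event = FALSE)
}

# smallest index with cumulative sum >= target (linear scan; N is small)
select_index <- function(a, target) {
  acc <- 0
  for (k in seq_along(a)) {
    acc <- acc + a[k]
    if (acc >= target) return(k)
  }
  length(a)
}

#' Reaction dependency graph and dependent/independent classification
#'
#' `graph[[j]]` lists the stochastic reactions whose propensity may change
#' when `j` fires, i.e. those whose rate reads -- or whose enabling arcs
#' test -- a place that `j` changes. A stochastic reaction is classed
#' *dependent* iff firing it changes a continuous species or a place read
#' by any deterministic rate (so the ODE solver must be reinitialised);
#' otherwise it is *independent* and its firings leave the deterministic
#' regime untouched.
#'
#' @inheritParams add_place
#' @param partition An [make_partition()] result.
#' @return List with `graph` (named list of character vectors) and
#'   `dependent` (named logical over the stochastic set).
#' @export
build_dependency_graph <- function(net, partition = NULL) {
  partition <- partition %||% make_partition(net)
  cm <- compile_hpn(net, check = FALSE)
  build_dependency_graph_cm(cm, partition)
}

build_dependency_graph_cm <- function(cm, partition) {
  stoch <- partition$stochastic
  det <- partition$deterministic
  det_reads <- unique(unlist(lapply(det, function(tid) cm$tr[[tid]]$deps)))
  changed <- lapply(stoch, function(tid) {
    ct <- cm$tr[[tid]]
    ch <- if (!ct$stoich_dyn) names(ct$stoich) else
      unique(c(ct$pre_place[ct$pre_kind == "standard"],
               {
                 oa <- output_arcs(cm$net, tid); oa$target[oa$kind == "standard"]
               }))
    unique(c(ch, ct$resets))
  })
  names(changed) <- stoch
  graph <- lapply(stoch, function(j) {
    ch <- changed[[j]]
    stoch[vapply(stoch, function(k)
      length(intersect(cm$tr[[k]]$dep_places, ch)) > 0, logical(1))]
  })
  names(graph) <- stoch
  dependent <- vapply(stoch, function(j) {
    length(intersect(changed[[j]],
                     union(partition$continuous_species, det_reads))) > 0
  }, logical(1))
  list(graph = graph, dependent = dependent)
}

#' Fluctuation interval and propensity bounds
#'
#' Builds the rejection-based (RSSA) machinery: a per-species bracket
#' `[x(1-delta), x(1+delta)]` around the current state -- widened to at
#' least `+/- floor` for discrete species and to a small absolute width
#' `cont_floor` for continuous species so that zero-valued species get a
#' usable interval -- together with lower/upper propensity bounds per
#' stochastic reaction obtained by interval arithmetic over the bracket.
#' Propensities need recomputation only when the state leaves the bracket.
#'
#' @inheritParams compute_propensities
#' @param delta Relative half-width in (0, 1).
#' @param floor Minimum absolute half-width for discrete species.
#' @param cont_floor Minimum absolute half-width for continuous species.
#' @return An `hpn_fi` object: named vectors `lo`, `hi` over all places,
#'   `a_lo`, `a_hi` over the stochastic set, and `abar0 = sum(a_hi)`.
#' @export
make_fluctuation_interval <- function(net, marking = NULL, delta = 0.1, floor = 2,
                                      stochastic_set = NULL, cont_floor = 1e-4) {
  if (!is_scalar_number(delta) || delta <= 0 || delta >= 1)
    stop_hpn("delta must lie in (0, 1)", "hpn_fi_error")
  cm <- compile_hpn(net, check = FALSE)
  marking <- marking %||% cm$init
  stochastic_set <- stochastic_set %||% cm$tid[cm$tkind == "stochastic"]
  make_fi_cm(cm, marking, delta, floor, stochastic_set, cont_floor)
}

make_fi_cm <- function(cm, marking, delta, floor, stochastic_set, cont_floor = 1e-4) {
  kind <- cm$place_kind[names(marking)]
  half <- abs(marking) * delta
  half <- pmax(half, ifelse(kind == "discrete", floor, cont_floor))
  lo <- pmax(marking - half, 0)
  hi <- marking + half
  # discrete species keep integer-valued brackets
  lo[kind == "discrete"] <- base::floor(lo[kind == "discrete"])
  hi[kind == "discrete"] <- base::ceiling(hi[kind == "discrete"])
  iv <- lapply(names(marking), function(p) c(lo[[p]], hi[[p]]))
  names(iv) <- names(marking)
  nb <- length(stochastic_set)
  a_lo <- a_hi <- setNames(numeric(nb), stochastic_set)
  for (tid in stochastic_set) {
    b <- propensity_bounds_cm(cm, cm$tr[[tid]], iv)
    a_lo[tid] <- b[1]; a_hi[tid] <- b[2]
  }
  structure(list(lo = lo, hi = hi, a_lo = a_lo, a_hi = a_hi,
                 abar0 = sum(a_hi), transitions = stochastic_set,
                 delta = delta, floor = floor, cont_floor = cont_floor),
            class = "hpn_fi")
}

# conservative propensity bounds over an interval marking, accounting for
# enabledness: if the transition is disabled everywhere in the interval the
# bounds are (0, 0); if it may be disabled somewhere, the lower bound is 0.
propensity_bounds_cm <- function(cm, ct, iv) {
  maybe_disabled <- FALSE
  for (k in seq_along(ct$pre_place)) {
    w <- if (ct$pre_const) ct$pre_wnum[[k]] else
      stop_hpn("fluctuation intervals need constant enabling arc weights", "hpn_fi_error")
    b <- iv[[ct$pre_place[k]]]
    res <- switch(ct$pre_kind[k],
      standard = , read = if (b[2] < w) "never" else if (b[1] < w) "maybe" else "always",
      inhibitor = if (b[1] >= w) "never" else if (b[2] >= w) "maybe" else "always",
      equal = if (b[1] > w || b[2] < w) "never" else
        if (b[1] == w && b[2] == w) "always" else "maybe")
    if (res == "never") return(c(0, 0))
    if (res == "maybe") maybe_disabled <- TRUE
  }
  b <- expr_bounds(ct$rate, iv, cm$params)
  lo <- max(b[[1]], 0)
  hi <- max(b[[2]], 0)
  if (maybe_disabled) lo <- 0
  c(lo, hi)
}

fi_contains <- function(fi, marking) {
  all(marking >= fi$lo[names(marking)] & marking <= fi$hi[names(marking)])
}

#' Rejection-based selection of the next stochastic firing
#'
#' Implements RSSA candidate selection against a fluctuation interval:
#' candidate times are exponential with the total upper-bound rate, the
#' candidate reaction is chosen proportional to the upper bounds, and a
#' candidate is accepted with probability `a_j(x)/a_hi_j` at the exact
#' state (with the squeeze shortcut: auto-accept when
#' `u * a_hi_j <= a_lo_j`, which avoids evaluating the exact propensity).
#' Rejected candidates redraw a fresh exponential time and the loop
#' continues.
#'
#' @param fi An [make_fluctuation_interval()] result.
#' @param marking_provider Function of time returning the exact named state
#'   vector at that time (in hybrid mode, the ODE-coupled state).
#' @param rng An `hpn_rng` stream.
#' @inheritParams add_place
#' @param t0 Current time.
#' @param t_max Horizon; candidates beyond it report no event.
#' @return List with `status` one of `"fire"` (plus `j`, `t`),
#'   `"bounds_exit"` (plus `t`), or `"no_event"`.
#' @export
rssa_select <- function(fi, marking_provider, rng, net, t0 = 0, t_max = Inf) {
  cm <- compile_hpn(net, check = FALSE)
  rssa_select_cm(fi, marking_provider, rng, cm, t0, t_max)
}

rssa_select_cm <- function(fi, marking_provider, rng, cm, t0 = 0, t_max = Inf) {
  if (fi$abar0 <= 0) return(list(status = "no_event"))
  t <- t0
  repeat {
    u <- draw_uniform(rng, 3L)
    t <- t - log(u[1]) / fi$abar0
    if (t > t_max) return(list(status = "no_event"))
    m <- marking_provider(t)
    if (!fi_contains(fi, m)) return(list(status = "bounds_exit", t = t))
    j <- select_index(fi$a_hi, u[2] * fi$abar0)
    tid <- fi$transitions[j]
    accept <- u[3] * fi$a_hi[[tid]] <= fi$a_lo[[tid]]
    if (!accept) {
      a_exact <- prop_cm(cm, cm$tr[[tid]], m)
      accept <- u[3] * fi$a_hi[[tid]] <= a_exact
    }
    if (accept) return(list(status = "fire", j = tid, t = t))
  }
}
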