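#' Create an empty hybrid Petri net
#'
#' A hybrid Petri net is a bipartite graph of places (species) and
#' transitions (reactions) connected by arcs. Places are `discrete`
#' (non-negative integer marking, e.g. molecule counts or channel states) or
#' `continuous` (non-negative real marking, e.g. a concentration).
#' Transitions come in five kinds: `stochastic` (exponential waiting time at
#' the current propensity), `continuous` (deterministic flow at the rate-law
#' value), `immediate` (fire as soon as enabled, conflicts resolved by
#' weight), `deterministic_delay` (fire a fixed delay after enabling) and
#' `scheduled` (fire at fixed wall-clock times). Nets are built with the
#' pipeable verbs [add_place()], [add_transition()] and [add_arc()].
#'
#' @param name Model name (used in file headers and trace metadata).
#' @param parameters Named numeric vector of kinetic constants.
#' @return An object of class `hpn`: a list of tibbles `places`,
#'   `transitions`, `arcs` plus the parameter table.
#' @examples
#' net <- hpn("toy", parameters = c(k = 0.5)) |>
#'   add_place("X", "discrete", initial = 10) |>
#'   add_transition("decay", "stochastic", rate = "k * X") |>
#'   add_arc("X", "decay")
#' validate_hpn(net)
#' @export
hpn <- function(name = "net", parameters = numeric()) {
  if (length(parameters) && is.null(names(parameters)))
    stop_hpn("parameters must be named", "hpn_model_error")
  structure(list(
    name = name,
    places = tibble(id = character(), kind = character(), initial = double(),
                    is_logical = logical()),
    transitions = tibble(id = character(), kind = character(), rate = list(),
                         delay = double(), weight = double(),
                         sched_start = double(), sched_interval = double(),
                         sched_end = double(), partition_hint = character(),
                         combinatorial = logical()),
    arcs = tibble(source = character(), target = character(), kind = character(),
                  weight = list()),
    parameters = parameters
  ), class = "hpn")
}

place_kinds <- c("discrete", "continuous")
transition_kinds <- c("stochastic", "continuous", "immediate",
                      "deterministic_delay", "scheduled")
arc_kinds <- c("standard", "read", "inhibitor", "equal", "reset", "modifier")

node_ids <- function(net) c(net$places$id, net$transitions$id)

check_fresh_id <- function(net, id) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_hpn("element id must be a non-empty string", "hpn_model_error")
  if (id %in% node_ids(net))
    stop_hpn(paste0("duplicate id `", id, "`"), "hpn_duplicate_id", id = id)
}

#' Add a place (species) to a net
#'
#' @param net An [hpn()] object.
#' @param id Unique node id.
#' @param kind `"discrete"` or `"continuous"`.
#' @param initial Initial marking: non-negative integer (discrete) or
#'   non-negative real (continuous).
#' @param is_logical Logical-place flag (a display alias; no effect on the
#'   semantics).
#' @return The updated net.
#' @export
add_place <- function(net, id, kind = c("discrete", "continuous"), initial = 0,
                      is_logical = FALSE) {
  stopifnot(inherits(net, "hpn"))
  kind <- match.arg(kind)
  check_fresh_id(net, id)
  if (!is_scalar_number(initial) || initial < 0)
    stop_hpn(paste0("initial marking of `", id, "` must be a non-negative number"),
             "hpn_model_error")
  if (kind == "discrete" && !is_whole(initial))
    stop_hpn(paste0("discrete place `", id, "` needs an integer initial marking"),
             "hpn_model_error")
  net$places <- bind_rows(net$places, tibble(
    id = id, kind = kind, initial = as.double(initial), is_logical = is_logical))
  net
}

#' Add a transition (reaction) to a net
#'
#' Exactly the fields relevant to `kind` may be set: `rate` for
#' `stochastic`/`continuous`, `delay` for `deterministic_delay`, `schedule`
#' for `scheduled`, `weight` for `immediate`.
#'
#' @inheritParams add_place
#' @param kind One of `stochastic`, `continuous`, `immediate`,
#'   `deterministic_delay`, `scheduled`.
#' @param rate Rate expression (character or language), e.g. `"k * X"` or
#'   `"MassAction(k)"`.
#' @param delay Non-negative firing delay (deterministic_delay).
#' @param weight Positive conflict-resolution weight (immediate).
#' @param schedule Numeric `c(start, interval, end)` (scheduled); an
#'   interval of 0 means a single firing at `start`.
#' @param partition_hint Optional `"stochastic"` or `"deterministic"` pin
#'   honoured by static and dynamic partitioning.
#' @param combinatorial Use falling-factorial (exact CME) expansion for
#'   `MassAction()` on this transition instead of the plain product.
#' @return The updated net.
#' @export
add_transition <- function(net, id, kind = transition_kinds, rate = NULL,
                           delay = NULL, weight = NULL, schedule = NULL,
                           partition_hint = NULL, combinatorial = FALSE) {
  stopifnot(inherits(net, "hpn"))
  kind <- match.arg(kind)
  check_fresh_id(net, id)
  rate_needed <- kind %in% c("stochastic", "continuous")
  if (rate_needed && is.null(rate))
    stop_hpn(paste0("transition `", id, "` of kind ", kind, " needs a rate"), "hpn_model_error")
  if (!rate_needed && !is.null(rate))
    stop_hpn(paste0("transition `", id, "` of kind ", kind, " must not carry a rate"),
             "hpn_model_error")
  if (kind == "deterministic_delay") {
    if (!is_scalar_number(delay) || delay < 0)
      stop_hpn(paste0("transition `", id, "` needs a non-negative delay"), "hpn_model_error")
  } else if (!is.null(delay)) {
    stop_hpn(paste0("delay is only valid for deterministic_delay transitions (`", id, "`)"),
             "hpn_model_error")
  }
  if (kind == "scheduled") {
    if (!is.numeric(schedule) || length(schedule) != 3L || schedule[2] < 0 ||
        schedule[3] < schedule[1])
      stop_hpn(paste0("transition `", id, "` needs schedule = c(start, interval, end)"),
               "hpn_model_error")
  } else if (!is.null(schedule)) {
    stop_hpn(paste0("schedule is only valid for scheduled transitions (`", id, "`)"),
             "hpn_model_error")
  }
  if (kind == "immediate") {
    weight <- weight %||% 1
    if (!is_scalar_number(weight) || weight <= 0)
      stop_hpn(paste0("immediate transition `", id, "` needs a positive weight"),
               "hpn_model_error")
  } else if (!is.null(weight)) {
    stop_hpn(paste0("weight is only valid for immediate transitions (`", id, "`)"),
             "hpn_model_error")
  }
  rate_expr <- if (!is.null(rate)) parse_expression(rate) else NULL
  net$transitions <- bind_rows(net$transitions, tibble(
    id = id, kind = kind, rate = list(rate_expr),
    delay = if (kind == "deterministic_delay") delay else NA_real_,
    weight = if (kind == "immediate") weight else NA_real_,
    sched_start = if (kind == "scheduled") schedule[1] else NA_real_,
    sched_interval = if (kind == "scheduled") schedule[2] else NA_real_,
    sched_end = if (kind == "scheduled") schedule[3] else NA_real_,
    partition_hint = partition_hint %||% NA_character_,
    combinatorial = combinatorial))
  net
}

#' Add an arc between a place and a transition
#'
#' Arc kinds: `standard` arcs move tokens/mass on firing; `read`,
#' `inhibitor`, `equal` and `modifier` arcs never change the marking
#' (`read`: place >= weight to enable; `inhibitor`: place < weight, strict;
#' `equal`: place == weight; `modifier`: merely exposes the place to the
#' rate expression); `reset` arcs set the place to 0 on firing.
#'
#' @inheritParams add_place
#' @param source,target Node ids; one must be a place and the other a
#'   transition.
#' @param kind Arc kind, see Details.
#' @param weight Arc weight: a non-negative number or an expression
#'   (character/language) evaluating to one.
#' @return The updated net.
#' @export
add_arc <- function(net, source, target, kind = arc_kinds, weight = 1) {
  stopifnot(inherits(net, "hpn"))
  kind <- match.arg(kind)
  for (ep in c(source, target)) {
    if (!ep %in% node_ids(net))
      stop_hpn(paste0("dangling arc endpoint `", ep, "`"), "hpn_dangling_endpoint", id = ep)
  }
  s_place <- source %in% net$places$id
  t_place <- target %in% net$places$id
  if (s_place == t_place)
    stop_hpn(paste0("bipartite violation: arc ", source, " -> ", target,
                    " joins two ", if (s_place) "places" else "transitions"),
             "hpn_bipartite_violation")
  w <- if (is.character(weight)) parse_expression(weight) else weight
  if (is_scalar_number(w) && w < 0)
    stop_hpn("arc weight must be non-negative", "hpn_model_error")
  net$arcs <- bind_rows(net$arcs, tibble(
    source = source, target = target, kind = kind, weight = list(w)))
  net
}

#' Set or update model parameters
#' @inheritParams add_place
#' @param ... Named numeric values.
#' @return The updated net.
#' @export
set_parameters <- function(net, ...) {
  stopifnot(inherits(net, "hpn"))
  vals <- c(...)
  if (length(vals) == 0) return(net)
  if (is.null(names(vals)) || any(!nzchar(names(vals))))
    stop_hpn("parameters must be named", "hpn_model_error")
  net$parameters[names(vals)] <- vals
  net
}

#' Initial marking of a net
#' @inheritParams add_place
#' @return Named numeric vector over all places.
#' @export
initial_marking <- function(net) {
  setNames(net$places$initial, net$places$id)
}

# Arc helpers ----------------------------------------------------------------

arcs_for_transition <- function(net, transition) {
  a <- net$arcs
  a[a$source == transition | a$target == transition, , drop = FALSE]
}

# Input arcs (place -> transition) of enabling kinds plus modifier outputs.
input_arcs <- function(net, transition) {
  a <- net$arcs
  a[a$target == transition & a$source %in% net$places$id, , drop = FALSE]
}

output_arcs <- function(net, transition) {
  a <- net$arcs
  a[a$source == transition & a$target %in% net$places$id, , drop = FALSE]
}

# The fully-expanded rate expression of a transition (MassAction resolved
# against its standard/read input arcs).
expanded_rate <- function(net, trow) {
  r <- trow$rate[[1]]
  if (is.null(r)) return(NULL)
  if (!uses_mass_action(r)) return(r)
  ia <- input_arcs(net, trow$id)
  ia <- ia[ia$kind %in% c("standard", "read"), , drop = FALSE]
  expand_mass_action(r, data.frame(place = ia$source,
                                   weight = I(ia$weight)),
                     combinatorial = isTRUE(trow$combinatorial))
}

#' Structural validation of a hybrid Petri net
#'
#' Checks every structural rule of the net class and returns the violations
#' as data, not errors. The result is empty exactly when the net is legal.
#' Rules include: bipartite arcs with existing endpoints; integer initial
#' markings on discrete places; continuous transitions may touch discrete
#' places only through read/inhibitor/equal/modifier arcs (continuous flow
#' must not corrupt integer markings); a discrete place must not be written
#' by both the stochastic and the continuous regime; reset/equal arcs only
#' on discrete places; every place referenced by a rate expression must be
#' connected to that transition by some arc; rate identifiers must be
#' declared places or parameters.
#'
#' @inheritParams add_place
#' @return A tibble with columns `rule`, `nodes`, `message`; zero rows iff
#'   the net is valid. Output order is independent of insertion order.
#' @export
validate_hpn <- function(net) {
  stopifnot(inherits(net, "hpn"))
  v <- list()
  addv <- function(rule, nodes, message) {
    v[[length(v) + 1L]] <<- tibble(rule = rule,
                                   nodes = paste(sort(nodes), collapse = ","),
                                   message = message)
  }
  pl <- net$places
  tr <- net$transitions
  symbols <- c(pl$id, names(net$parameters))

  bad_init <- pl$id[pl$kind == "discrete" & !is_whole(pl$initial)]
  for (p in bad_init)
    addv("discrete_integer_marking", p,
         paste0("discrete place `", p, "` has a non-integer initial marking"))

  A_src <- net$arcs$source; A_tgt <- net$arcs$target
  A_kind <- net$arcs$kind; A_w <- net$arcs$weight
  bytgt <- split(seq_along(A_src), A_tgt)
  bysrc <- split(seq_along(A_src), A_src)
  discrete_places <- pl$id[pl$kind == "discrete"]
  for (i in seq_len(nrow(tr))) {
    tid <- tr$id[i]
    ii <- bytgt[[tid]] %||% integer(0)
    oi <- bysrc[[tid]] %||% integer(0)
    std_places <- unique(c(A_src[ii][A_kind[ii] %in% c("standard", "reset")],
                           A_tgt[oi][A_kind[oi] %in% c("standard", "reset")]))
    if (tr$kind[i] == "continuous") {
      bad <- std_places[std_places %in% discrete_places]
      for (p in bad)
        addv("continuous_transition_discrete_place", c(tid, p),
             paste0("continuous transition `", tid, "` writes discrete place `", p,
                    "` through a standard/reset arc; only read/inhibitor/equal/",
                    "modifier arcs are allowed"))
    }
    r <- tr$rate[[i]]
    if (!is.null(r) && uses_mass_action(r)) {
      ma <- A_kind[ii] %in% c("standard", "read")
      r <- tryCatch(expand_mass_action(r,
                      data.frame(place = A_src[ii][ma], weight = I(A_w[ii][ma])),
                      combinatorial = isTRUE(tr$combinatorial[i])),
                    error = function(e) e)
    }
    if (inherits(r, "error")) {
      addv("rate_expression", tid, conditionMessage(r))
    } else if (!is.null(r)) {
      ids <- expr_dependencies(r)
      unknown <- setdiff(ids, symbols)
      for (u in unknown)
        addv("undeclared_identifier", c(tid, u),
             paste0("rate of `", tid, "` references undeclared identifier `", u, "`"))
      refs <- intersect(ids, pl$id)
      connected <- unique(c(A_src[ii], A_tgt[oi]))
      missing <- setdiff(refs, connected)
      for (p in missing)
        addv("rate_place_unconnected", c(tid, p),
             paste0("rate of `", tid, "` reads place `", p,
                    "` but no arc connects them (add e.g. a modifier arc)"))
    }
  }

  for (k in c("reset", "equal")) {
    a <- net$arcs[net$arcs$kind == k, , drop = FALSE]
    pls <- ifelse(a$source %in% pl$id, a$source, a$target)
    bad <- pls[pls %in% pl$id[pl$kind == "continuous"]]
    for (p in unique(bad))
      addv("reset_equal_discrete_only", p,
           paste0(k, " arcs are only supported on discrete places (`", p, "`)"))
  }

  # both-regimes rule: a discrete place written via standard/reset arcs by
  # both a stochastic and a continuous transition must be continuous.
  wr <- net$arcs[net$arcs$kind %in% c("standard", "reset"), , drop = FALSE]
  for (p in pl$id[pl$kind == "discrete"]) {
    wtr <- unique(c(wr$target[wr$source == p], wr$source[wr$target == p]))
    wtr <- wtr[wtr %in% tr$id]
    kinds <- tr$kind[match(wtr, tr$id)]
    if ("stochastic" %in% kinds && "continuous" %in% kinds)
      addv("both_regimes_continuous", p,
           paste0("place `", p, "` is manipulated by both a stochastic and a ",
                  "continuous transition and must therefore be continuous"))
  }

  out <- if (length(v)) bind_rows(v) else
    tibble(rule = character(), nodes = character(), message = character())
  arrange(out, .data$rule, .data$nodes)
}

#' Stoichiometry of a transition
#'
#' The signed marking change per place caused by one firing: outgoing
#' standard-arc weights minus incoming standard-arc weights, evaluated at
#' `marking` when weights are expressions. Read/inhibitor/equal/modifier
#' arcs contribute nothing; places cleared by reset arcs are reported in the
#' `"resets"` attribute.
#'
#' @inheritParams add_place
#' @param transition Transition id.
#' @param marking Named numeric marking (defaults to the initial marking)
#'   used to evaluate expression-valued weights.
#' @return Named numeric vector of non-zero changes, with attribute
#'   `resets` (character vector of reset places).
#' @export
stoichiometry <- function(net, transition, marking = NULL) {
  stopifnot(inherits(net, "hpn"))
  if (!transition %in% net$transitions$id)
    stop_hpn(paste0("unknown transition `", transition, "`"), "hpn_model_error")
  marking <- marking %||% initial_marking(net)
  data <- c(as.list(marking), as.list(net$parameters))
  delta <- numeric(0)
  bump <- function(p, d) {
    delta[p] <<- (if (p %in% names(delta)) delta[[p]] else 0) + d
  }
  ia <- input_arcs(net, transition)
  oa <- output_arcs(net, transition)
  for (i in seq_len(nrow(ia))) {
    if (ia$kind[i] != "standard") next
    bump(ia$source[i], -eval_expression(ia$weight[[i]], data, where = transition))
  }
  for (i in seq_len(nrow(oa))) {
    if (oa$kind[i] != "standard") next
    bump(oa$target[i], +eval_expression(oa$weight[[i]], data, where = transition))
  }
  resets <- unique(c(ia$source[ia$kind == "reset"], oa$target[oa$kind == "reset"]))
  delta <- delta[delta != 0]
  disc <- net$places$id[net$places$kind == "discrete"]
  bad <- names(delta)[names(delta) %in% disc & !is_whole(delta)]
  if (length(bad))
    stop_hpn(paste0("non-integer net change on discrete place(s) ",
                    paste0("`", bad, "`", collapse = ", "),
                    " at transition `", transition, "`"),
             "hpn_noninteger_change")
  structure(delta, resets = resets)
}

#' Is a transition enabled at a marking?
#'
#' A transition is enabled iff every standard/read input place holds at
#' least the arc weight, every equal input place holds exactly the weight,
#' and every inhibitor input place holds strictly less than the weight.
#' Continuous transitions additionally require a strictly positive rate at
#' the marking.
#'
#' @inheritParams stoichiometry
#' @param marking Named numeric vector covering all places.
#' @return Logical scalar.
#' @export
is_enabled <- function(net, transition, marking = NULL) {
  stopifnot(inherits(net, "hpn"))
  marking <- marking %||% initial_marking(net)
  trow <- net$transitions[net$transitions$id == transition, ]
  if (nrow(trow) != 1L)
    stop_hpn(paste0("unknown transition `", transition, "`"), "hpn_model_error")
  data <- c(as.list(marking), as.list(net$parameters))
  ia <- input_arcs(net, transition)
  for (i in seq_len(nrow(ia))) {
    w <- eval_expression(ia$weight[[i]], data, where = transition)
    m <- marking[[ia$source[i]]]
    ok <- switch(ia$kind[i],
                 standard = , read = m >= w,
                 equal = m == w,
                 inhibitor = m < w,
                 reset = , modifier = TRUE)
    if (!ok) return(FALSE)
  }
  if (trow$kind == "continuous") {
    r <- eval_expression(expanded_rate(net, trow), data, where = transition)
    return(r > 0)
  }
  TRUE
}

#' @export
print.hpn <- function(x, ...) {
  cat("<hpn> ", x$name, ": ", nrow(x$places), " places (",
      sum(x$places$kind == "discrete"), " discrete), ",
      nrow(x$transitions), " transitions (",
      sum(x$transitions$kind == "stochastic"), " stochastic), ",
      nrow(x$arcs), " arcs, ", length(x$parameters), " parameters\n", sep = "")
  invisible(x)
}
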