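#' Coloured hybrid Petri nets
#'
#' A coloured net abstracts repeated network components into parameterised
#' nodes: every place carries a finite colour set (an integer range
#' `[lo..hi]` or a product of ranges, e.g. a 100 x 100 grid), transitions
#' bind colour variables under a boolean guard, and arcs carry one colour
#' expression per component of the place's colour set (a variable, a
#' constant tuple such as `(50, 50)`, or arithmetic like `x + dx` for grid
#' neighbours). A coloured net is simulated by unfolding it to a flat
#' [hpn()]: one flat place per (place, colour), one flat transition per
#' guard-satisfying binding.
#'
#' @param name Model name.
#' @param parameters Named numeric vector of kinetic constants.
#' @return An object of class `chpn`.
#' @export
coloured_hpn <- function(name = "cnet", parameters = numeric()) {
  structure(list(
    name = name,
    colsets = list(),
    places = tibble(id = character(), kind = character(), initial = double(),
                    colset = character(), initial_at = list()),
    transitions = tibble(id = character(), kind = character(), rate = list(),
                         variables = list(), guard = list(),
                         delay = double(), weight = double(),
                         sched_start = double(), sched_interval = double(),
                         sched_end = double(), partition_hint = character(),
                         combinatorial = logical()),
    arcs = tibble(source = character(), target = character(), kind = character(),
                  weight = list(), colour = list()),
    parameters = parameters
  ), class = "chpn")
}

#' Declare colour sets
#'
#' `add_colourset()` declares an integer range set `[lo..hi]`;
#' `add_colourset_product()` declares a product of previously declared
#' range sets (enumerated lexicographically, first component most
#' significant).
#'
#' @param net A [coloured_hpn()].
#' @param name Colour set name.
#' @param lo,hi Integer range bounds (`lo <= hi`).
#' @return The updated net.
#' @export
add_colourset <- function(net, name, lo, hi) {
  stopifnot(inherits(net, "chpn"))
  if (!is_whole(lo) || !is_whole(hi) || hi < lo)
    stop_hpn("colour set range needs integer lo <= hi", "hpn_colour_error")
  if (name %in% names(net$colsets))
    stop_hpn(paste0("duplicate colour set `", name, "`"), "hpn_colour_error")
  net$colsets[[name]] <- list(kind = "range", lo = as.integer(lo), hi = as.integer(hi))
  net
}

#' @rdname add_colourset
#' @param components Character vector of range colour set names.
#' @export
add_colourset_product <- function(net, name, components) {
  stopifnot(inherits(net, "chpn"))
  if (name %in% names(net$colsets))
    stop_hpn(paste0("duplicate colour set `", name, "`"), "hpn_colour_error")
  for (cname in components) {
    cs <- net$colsets[[cname]]
    if (is.null(cs) || cs$kind != "range")
      stop_hpn(paste0("product component `", cname, "` must be a declared range set"),
               "hpn_colour_error")
  }
  net$colsets[[name]] <- list(kind = "product", components = components)
  net
}

colset_components <- function(net, name) {
  cs <- net$colsets[[name]]
  if (is.null(cs)) stop_hpn(paste0("unknown colour set `", name, "`"), "hpn_colour_error")
  if (cs$kind == "range") list(cs) else lapply(cs$components, function(cn) net$colsets[[cn]])
}

colset_size <- function(net, name) {
  prod(vapply(colset_components(net, name), function(c) c$hi - c$lo + 1L, double(1)))
}

# lexicographic enumeration of a colour set as a data.frame of components
colset_enumerate <- function(net, name) {
  comps <- colset_components(net, name)
  doms <- lapply(comps, function(c) c$lo:c$hi)
  g <- expand.grid(rev(doms), KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(seq_along(doms)), drop = FALSE]
  names(g) <- paste0("c", seq_along(doms))
  g
}

colour_labels <- function(df) {
  do.call(paste, c(as.list(df), sep = "_"))
}

flat_name <- function(base, labels) {
  if (length(labels) == 0 || all(labels == "")) base else paste0(base, "__", labels)
}

#' Add a coloured place
#'
#' @inheritParams add_colourset
#' @param id Place id.
#' @param kind `"discrete"` or `"continuous"`.
#' @param colset Colour set name.
#' @param initial Initial marking applied to every colour.
#' @param initial_at Optional named numeric vector of per-colour overrides;
#'   names are colour labels with components joined by `_` (e.g. `"50_50"`).
#' @return The updated net.
#' @export
add_coloured_place <- function(net, id, kind = c("discrete", "continuous"),
                               colset, initial = 0, initial_at = NULL) {
  stopifnot(inherits(net, "chpn"))
  kind <- match.arg(kind)
  if (id %in% c(net$places$id, net$transitions$id))
    stop_hpn(paste0("duplicate id `", id, "`"), "hpn_duplicate_id")
  colset_components(net, colset)  # existence check
  net$places <- bind_rows(net$places, tibble(
    id = id, kind = kind, initial = as.double(initial), colset = colset,
    initial_at = list(initial_at)))
  net
}

#' Add a coloured transition
#'
#' @inheritParams add_coloured_place
#' @param kind Transition kind (see [add_transition()]).
#' @param rate Rate expression; may reference coloured places as calls with
#'   colour arguments (e.g. `Ca(x, y)`) and use `colsum(place)` for the sum
#'   over all colours of a place.
#' @param variables Named character vector mapping colour variables to
#'   range colour set names, e.g. `c(m = "chCS")`.
#' @param guard Boolean guard over the variables (character or language);
#'   only bindings satisfying it are instantiated.
#' @param delay,weight,schedule,partition_hint,combinatorial See
#'   [add_transition()].
#' @return The updated net.
#' @export
add_coloured_transition <- function(net, id, kind = transition_kinds, rate = NULL,
                                    variables = character(), guard = NULL,
                                    delay = NULL, weight = NULL, schedule = NULL,
                                    partition_hint = NULL, combinatorial = FALSE) {
  stopifnot(inherits(net, "chpn"))
  kind <- match.arg(kind)
  if (id %in% c(net$places$id, net$transitions$id))
    stop_hpn(paste0("duplicate id `", id, "`"), "hpn_duplicate_id")
  for (vn in names(variables)) {
    cs <- net$colsets[[variables[[vn]]]]
    if (is.null(cs) || cs$kind != "range")
      stop_hpn(paste0("variable `", vn, "` must range over a declared range colour set"),
               "hpn_colour_error")
  }
  guard_expr <- if (!is.null(guard)) parse_expression(guard, guard = TRUE) else TRUE
  rate_expr <- if (!is.null(rate)) parse_coloured_rate(rate) else NULL
  net$transitions <- bind_rows(net$transitions, tibble(
    id = id, kind = kind, rate = list(rate_expr), variables = list(variables),
    guard = list(guard_expr),
    delay = delay %||% NA_real_, weight = weight %||% NA_real_,
    sched_start = if (!is.null(schedule)) schedule[1] else NA_real_,
    sched_interval = if (!is.null(schedule)) schedule[2] else NA_real_,
    sched_end = if (!is.null(schedule)) schedule[3] else NA_real_,
    partition_hint = partition_hint %||% NA_character_,
    combinatorial = combinatorial))
  net
}

# coloured rates additionally allow place-call forms and colsum(); validated
# lazily at unfolding against the declared places.
parse_coloured_rate <- function(text) {
  if (is.character(text)) {
    tryCatch(str2lang(text), error = function(e)
      stop_hpn(paste0("syntax error in rate `", text, "`: ", conditionMessage(e)),
               "hpn_parse_error"))
  } else text
}

#' Add a coloured arc
#'
#' @inheritParams add_coloured_place
#' @param source,target Node ids (one coloured place, one coloured
#'   transition).
#' @param kind Arc kind (see [add_arc()]).
#' @param weight Arc weight (number or expression over colour variables).
#' @param colour List with one colour expression per component of the
#'   place's colour set: a constant, a variable name, arithmetic such as
#'   `"x + dx"`, or the reserved word `"all"` (read/modifier arcs only) to
#'   fan out to every colour.
#' @return The updated net.
#' @export
add_coloured_arc <- function(net, source, target, kind = arc_kinds, weight = 1,
                             colour = list()) {
  stopifnot(inherits(net, "chpn"))
  kind <- match.arg(kind)
  s_place <- source %in% net$places$id
  t_place <- target %in% net$places$id
  if (!s_place && !source %in% net$transitions$id)
    stop_hpn(paste0("dangling arc endpoint `", source, "`"), "hpn_dangling_endpoint")
  if (!t_place && !target %in% net$transitions$id)
    stop_hpn(paste0("dangling arc endpoint `", target, "`"), "hpn_dangling_endpoint")
  if (s_place == t_place)
    stop_hpn("bipartite violation in coloured arc", "hpn_bipartite_violation")
  place <- if (s_place) source else target
  ncomp <- length(colset_components(net, net$places$colset[net$places$id == place]))
  colour <- lapply(colour, function(ce) {
    if (is.character(ce) && identical(ce, "all")) as.name("all")
    else if (is.character(ce)) str2lang(ce)
    else ce
  })
  if (length(colour) != ncomp)
    stop_hpn(paste0("arc to `", place, "` needs ", ncomp, " colour expression(s)"),
             "hpn_colour_error")
  if (any(vapply(colour, function(ce) identical(ce, as.name("all")), logical(1))) &&
      !kind %in% c("read", "modifier"))
    stop_hpn("`all` colour fan-out is only allowed on read/modifier arcs",
             "hpn_colour_error")
  w <- if (is.character(weight)) str2lang(weight) else weight
  net$arcs <- bind_rows(net$arcs, tibble(
    source = source, target = target, kind = kind,
    weight = list(w), colour = list(colour)))
  net
}

#' Enumerate guard-satisfying bindings of a coloured transition
#'
#' All and only total assignments of the transition's colour variables that
#' satisfy its guard, in canonical (lexicographic, first variable most
#' significant) order. The domains are enumerated with vectorised guard
#' filtering -- a pruned search over the finite colour sets.
#'
#' @inheritParams add_coloured_place
#' @param transition Transition id.
#' @return A tibble with one column per variable and one row per binding.
#' @export
enumerate_bindings <- function(net, transition) {
  stopifnot(inherits(net, "chpn"))
  i <- match(transition, net$transitions$id)
  if (is.na(i)) stop_hpn(paste0("unknown transition `", transition, "`"),
                         "hpn_colour_error")
  vars <- net$transitions$variables[[i]]
  guard <- net$transitions$guard[[i]]
  if (length(vars) == 0) {
    ok <- isTRUE(guard) || isTRUE(eval(guard, net$parameters, baseenv()))
    return(if (ok) tibble(.rows = 1) else tibble(.rows = 0))
  }
  doms <- lapply(names(vars), function(vn) {
    cs <- net$colsets[[vars[[vn]]]]
    cs$lo:cs$hi
  })
  names(doms) <- names(vars)
  total <- prod(vapply(doms, length, double(1)))
  if (total > 5e6)
    stop_hpn("binding space too large to enumerate", "hpn_colour_error")
  g <- expand.grid(rev(doms), KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(seq_along(doms)), drop = FALSE]
  if (!isTRUE(guard)) {
    keep <- eval(guard, c(as.list(g), as.list(net$parameters)), baseenv())
    if (length(keep) == 1L) keep <- rep(keep, nrow(g))
    g <- g[keep, , drop = FALSE]
  }
  rownames(g) <- NULL
  tibble::as_tibble(g)
}

#' Instance counts of the unfolded net, without materialising it
#'
#' @inheritParams add_coloured_place
#' @return A tibble with columns `node`, `class` (`place`/`transition`) and
#'   `instances`.
#' @export
size_report <- function(net) {
  stopifnot(inherits(net, "chpn"))
  pr <- tibble(node = net$places$id, class = "place",
               instances = vapply(net$places$colset, function(cs) colset_size(net, cs),
                                  double(1)))
  tr <- tibble(node = net$transitions$id, class = "transition",
               instances = vapply(net$transitions$id,
                                  function(tid) as.double(nrow(enumerate_bindings(net, tid))),
                                  double(1)))
  bind_rows(pr, tr)
}

# resolve a coloured rate AST under a binding: variables become values,
# place calls become flat place names, colsum(place) becomes the explicit
# sum over all colours.
resolve_rate <- function(expr, binding, pinfo, params, transition) {
  walk <- function(e) {
    if (is.numeric(e)) return(e)
    if (is.name(e)) {
      nm <- as.character(e)
      if (nm %in% names(binding)) return(binding[[nm]])
      return(e)
    }
    if (!is.call(e)) return(e)
    head <- e[[1]]
    if (is.name(head)) {
      hn <- as.character(head)
      if (hn == "colsum") {
        pn <- as.character(e[[2]])
        labs <- pinfo[[pn]]$labels
        if (is.null(labs))
          stop_hpn(paste0("colsum of unknown place `", pn, "`"), "hpn_colour_error")
        flat <- lapply(flat_name(pn, labs), as.name)
        return(Reduce(function(a, b) call("+", a, b), flat))
      }
      if (hn %in% names(pinfo)) {
        args <- as.list(e)[-1]
        comps <- pinfo[[hn]]$comps
        if (length(args) != length(comps))
          stop_hpn(paste0("place `", hn, "` takes ", length(comps),
                          " colour argument(s)"), "hpn_colour_error")
        vals <- vapply(args, function(a)
          eval(do.call(substitute, list(a, binding)), params, baseenv()), double(1))
        check_colour_range(vals, comps, transition, binding, hn)
        return(as.name(flat_name(hn, paste(vals, collapse = "_"))))
      }
    }
    out <- e
    for (k in seq_along(out)[-1]) out[[k]] <- walk(out[[k]])
    out
  }
  walk(expr)
}

check_colour_range <- function(vals, comps, transition, binding, place) {
  for (k in seq_along(vals)) {
    if (!is_whole(vals[k]) || vals[k] < comps[[k]]$lo || vals[k] > comps[[k]]$hi)
      stop_hpn(paste0("colour expression out of range for place `", place,
                      "` at transition `", transition, "` under binding (",
                      paste(names(binding), unlist(binding), sep = "=",
                            collapse = ", "),
                      "): component ", k, " = ", vals[k],
                      " outside [", comps[[k]]$lo, "..", comps[[k]]$hi,
                      "]; the guard must exclude this binding"),
               "hpn_colour_range_error")
  }
}

#' Unfold a coloured net to a flat hybrid Petri net
#'
#' Creates one flat place per (coloured place, colour) named
#' `place__c1_c2...`, and one flat transition per (coloured transition,
#' guard-satisfying binding) named `transition__v1_v2...`; arcs are
#' instantiated by evaluating their colour expressions under each binding.
#' Transitions without colour variables (all arc colour expressions
#' constant) yield exactly one instance under the base name. Duplicate
#' instances are not merged. Colour expressions that evaluate outside the
#' place's colour set raise an error naming the transition and binding
#' (the guard must exclude them); unfolding is deterministic and its
#' naming/counts are independent of declaration order.
#'
#' @inheritParams add_coloured_place
#' @return An [hpn()] object.
#' @export
unfold <- function(net) {
  stopifnot(inherits(net, "chpn"))
  params <- as.list(net$parameters)

  # flat places, vectorised over colours
  pinfo <- list()
  pl_id <- character(); pl_kind <- character(); pl_init <- double()
  for (i in seq_len(nrow(net$places))) {
    prow <- net$places[i, ]
    en <- colset_enumerate(net, prow$colset)
    labs <- colour_labels(en)
    ids <- flat_name(prow$id, labs)
    init <- rep(prow$initial, length(ids))
    ia <- prow$initial_at[[1]]
    if (!is.null(ia)) {
      hit <- match(names(ia), labs)
      if (any(is.na(hit)))
        stop_hpn(paste0("initial_at labels not in colour set of `", prow$id, "`: ",
                        paste(names(ia)[is.na(hit)], collapse = ", ")),
                 "hpn_colour_error")
      init[hit] <- as.double(ia)
    }
    pinfo[[prow$id]] <- list(labels = labs, comps = colset_components(net, prow$colset),
                             kind = prow$kind)
    pl_id <- c(pl_id, ids)
    pl_kind <- c(pl_kind, rep(prow$kind, length(ids)))
    pl_init <- c(pl_init, init)
  }

  tr_rows <- list()
  arc_rows <- list()
  for (i in seq_len(nrow(net$transitions))) {
    trow <- net$transitions[i, ]
    tid <- trow$id
    B <- enumerate_bindings(net, tid)
    nb <- nrow(B)
    if (nb == 0) next
    labs <- if (ncol(B) > 0) colour_labels(B) else rep("", nb)
    flat_ids <- flat_name(tid, labs)
    Bl <- lapply(as.list(B), as.numeric)
    bind_at <- function(r) lapply(Bl, function(col) col[r])
    rates <- if (!is.null(trow$rate[[1]])) {
      if (ncol(B) > 0) {
        lapply(seq_len(nb), function(r)
          resolve_rate(trow$rate[[1]], bind_at(r), pinfo, params, tid))
      } else {
        list(resolve_rate(trow$rate[[1]], list(), pinfo, params, tid))
      }
    } else rep(list(NULL), nb)
    tr_rows[[length(tr_rows) + 1L]] <- tibble(
      id = flat_ids, kind = trow$kind, rate = rates,
      delay = trow$delay, weight = trow$weight,
      sched_start = trow$sched_start, sched_interval = trow$sched_interval,
      sched_end = trow$sched_end, partition_hint = trow$partition_hint,
      combinatorial = trow$combinatorial)

    a <- net$arcs[net$arcs$source == tid | net$arcs$target == tid, , drop = FALSE]
    for (k in seq_len(nrow(a))) {
      arow <- a[k, ]
      place <- if (arow$source == tid) arow$target else arow$source
      out_arc <- arow$source == tid
      comps <- pinfo[[place]]$comps
      cexprs <- arow$colour[[1]]
      is_all <- vapply(cexprs, function(ce) identical(ce, as.name("all")), logical(1))
      if (any(is_all)) {
        if (!all(is_all))
          stop_hpn("`all` must be used for every component of an arc", "hpn_colour_error")
        targets <- flat_name(place, pinfo[[place]]$labels)
        for (fid in flat_ids) {
          arc_rows[[length(arc_rows) + 1L]] <- tibble(
            source = if (out_arc) fid else targets,
            target = if (out_arc) targets else fid,
            kind = arow$kind,
            weight = rep(list(arow$weight[[1]]), length(targets)))
        }
        next
      }
      # vectorised evaluation of each colour component over the bindings
      vals <- matrix(0, nb, length(cexprs))
      for (cc in seq_along(cexprs)) {
        v <- eval(cexprs[[cc]], c(as.list(B), params), baseenv())
        if (length(v) == 1L) v <- rep(v, nb)
        vals[, cc] <- v
      }
      for (cc in seq_along(comps)) {
        bad <- which(!is_whole(vals[, cc]) | vals[, cc] < comps[[cc]]$lo |
                       vals[, cc] > comps[[cc]]$hi)
        if (length(bad)) {
          r <- bad[1]
          check_colour_range(vals[r, ], comps, tid,
                             if (ncol(B) > 0) bind_at(r) else list(), place)
        }
      }
      plabs <- do.call(paste, c(lapply(seq_len(ncol(vals)), function(cc) vals[, cc]),
                                sep = "_"))
      ptargets <- flat_name(place, plabs)
      w <- arow$weight[[1]]
      weights <- if (is_scalar_number(w) || ncol(B) == 0) rep(list(w), nb) else
        lapply(seq_len(nb), function(r) substitute_vars(w, bind_at(r)))
      arc_rows[[length(arc_rows) + 1L]] <- tibble(
        source = if (out_arc) flat_ids else ptargets,
        target = if (out_arc) ptargets else flat_ids,
        kind = arow$kind, weight = weights)
    }
  }

  flat <- hpn(net$name, parameters = net$parameters)
  flat$places <- tibble(id = pl_id, kind = pl_kind, initial = pl_init,
                        is_logical = FALSE)
  flat$transitions <- if (length(tr_rows)) bind_rows(tr_rows) else flat$transitions
  flat$arcs <- if (length(arc_rows)) bind_rows(arc_rows) else flat$arcs
  if (anyDuplicated(flat$places$id) || anyDuplicated(flat$transitions$id))
    stop_hpn("unfolding produced duplicate flat ids", "hpn_colour_error")
  flat
}

#' @export
print.chpn <- function(x, ...) {
  cat("<chpn> ", x$name, ": ", nrow(x$places), " coloured places, ",
      nrow(x$transitions), " coloured transitions, ",
      length(x$colsets), " colour sets\n", sep = "")
  invisible(x)
}
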