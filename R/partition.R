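#' Partition a net into stochastic and deterministic regimes
#'
#' Every rate-bearing transition (kind `stochastic` or `continuous`) is
#' assigned to exactly one regime. By default the transition kind decides
#' (`stochastic` kind -> stochastic regime, `continuous` kind ->
#' deterministic regime); a `partition_hint` on a transition overrides the
#' default, and the `stochastic`/`deterministic` arguments override both.
#' Species classes are then derived: a place is classed continuous iff it is
#' declared continuous or is written (standard/reset arc) by any
#' deterministic-regime transition; consequently any species manipulated by
#' both regimes is continuous and discrete species are written only by the
#' stochastic regime.
#'
#' @inheritParams add_place
#' @param stochastic,deterministic Optional character vectors of transition
#'   ids forcing the respective regime.
#' @return An `hpn_partition`: list with `stochastic`, `deterministic`
#'   (transition ids), `continuous_species`, `discrete_species` (place ids).
#' @export
make_partition <- function(net, stochastic = NULL, deterministic = NULL) {
  stopifnot(inherits(net, "hpn"))
  tr <- net$transitions
  rb <- tr$id[tr$kind %in% c("stochastic", "continuous")]
  regime <- setNames(ifelse(tr$kind[match(rb, tr$id)] == "stochastic",
                            "stochastic", "deterministic"), rb)
  hint <- setNames(tr$partition_hint[match(rb, tr$id)], rb)
  regime[!is.na(hint)] <- hint[!is.na(hint)]
  overlap <- intersect(stochastic, deterministic)
  if (length(overlap))
    stop_hpn(paste0("transitions assigned to both regimes: ",
                    paste(overlap, collapse = ", ")), "hpn_partition_error")
  for (s in stochastic) {
    if (!s %in% rb) stop_hpn(paste0("`", s, "` is not a rate-bearing transition"),
                             "hpn_partition_error")
    regime[s] <- "stochastic"
  }
  for (s in deterministic) {
    if (!s %in% rb) stop_hpn(paste0("`", s, "` is not a rate-bearing transition"),
                             "hpn_partition_error")
    regime[s] <- "deterministic"
  }
  derive_partition(net, names(regime)[regime == "stochastic"],
                   names(regime)[regime == "deterministic"])
}

derive_partition <- function(net, stoch, det) {
  written_by <- function(tids) {
    a <- net$arcs[net$arcs$kind %in% c("standard", "reset"), , drop = FALSE]
    a <- a[a$source %in% tids | a$target %in% tids, , drop = FALSE]
    pls <- c(a$source[a$source %in% net$places$id], a$target[a$target %in% net$places$id])
    unique(pls)
  }
  cont <- union(net$places$id[net$places$kind == "continuous"], written_by(det))
  cont <- intersect(net$places$id, cont)
  structure(list(
    stochastic = stoch, deterministic = det,
    continuous_species = cont,
    discrete_species = setdiff(net$places$id, cont)
  ), class = "hpn_partition")
}

#' @export
print.hpn_partition <- function(x, ...) {
  cat("<hpn_partition> ", length(x$stochastic), " stochastic / ",
      length(x$deterministic), " deterministic transitions; ",
      length(x$discrete_species), " discrete / ",
      length(x$continuous_species), " continuous species\n", sep = "")
  invisible(x)
}

#' State-driven (dynamic) partitioning
#'
#' Classifies each rate-bearing transition from the current state: a
#' transition goes to the deterministic regime iff its current propensity is
#' at least `lambda_prop` and every substrate (standard/read input place)
#' holds at least `n_substrate`; otherwise it is simulated stochastically.
#' Transitions carrying a `partition_hint` are pinned to the hinted regime
#' regardless of the state. Species classes are re-derived as in
#' [make_partition()].
#'
#' @inheritParams add_place
#' @param marking Named numeric state vector.
#' @param lambda_prop Propensity threshold (> 0).
#' @param n_substrate Minimum substrate molecule count (>= 0).
#' @return An `hpn_partition`.
#' @export
dynamic_partition <- function(net, marking = NULL, lambda_prop = 10, n_substrate = 100) {
  stopifnot(inherits(net, "hpn"))
  if (!is_scalar_number(lambda_prop) || lambda_prop <= 0)
    stop_hpn("lambda_prop must be > 0", "hpn_partition_error")
  if (!is_scalar_number(n_substrate) || n_substrate < 0)
    stop_hpn("n_substrate must be >= 0", "hpn_partition_error")
  marking <- marking %||% initial_marking(net)
  cm <- compile_hpn(net, check = FALSE)
  dynamic_partition_cm(cm, marking, lambda_prop, n_substrate)
}

dynamic_partition_cm <- function(cm, marking, lambda_prop, n_substrate) {
  net <- cm$net
  rb <- net$transitions$id[net$transitions$kind %in% c("stochastic", "continuous")]
  data <- c(as.list(marking), cm$params)
  regime <- character(0)
  for (tid in rb) {
    ct <- cm$tr[[tid]]
    if (!is.na(ct$hint)) {
      regime[tid] <- ct$hint
      next
    }
    a <- prop_cm(cm, ct, marking, data)
    subs <- ct$pre_place[ct$pre_kind %in% c("standard", "read")]
    ok <- a >= lambda_prop && all(marking[subs] >= n_substrate)
    regime[tid] <- if (ok) "deterministic" else "stochastic"
  }
  derive_partition(net, names(regime)[regime == "stochastic"],
                   names(regime)[regime == "deterministic"])
}
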