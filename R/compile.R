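# Internal compiled representation of a net: per-transition pre-extracted
# input arcs, constant stoichiometry fast paths and expanded rate ASTs, so
# the simulation loops avoid repeated tibble scans.

compile_hpn <- function(net, check = TRUE) {
  if (check) {
    viol <- validate_hpn(net)
    if (nrow(viol) > 0)
      stop_hpn(paste0("net is not valid: ", paste(viol$message, collapse = "; ")),
               "hpn_invalid_net", violations = viol)
  }
  pl <- net$places
  tr <- net$transitions
  params <- as.list(net$parameters)
  # arc index by endpoint (bipartiteness holds by construction)
  A_src <- net$arcs$source; A_tgt <- net$arcs$target
  A_kind <- net$arcs$kind; A_w <- net$arcs$weight
  bytgt <- split(seq_along(A_src), A_tgt)
  bysrc <- split(seq_along(A_src), A_src)
  place_set <- pl$id
  trs <- vector("list", nrow(tr))
  names(trs) <- tr$id
  tr_kind <- tr$kind; tr_rate <- tr$rate; tr_comb <- tr$combinatorial
  for (i in seq_len(nrow(tr))) {
    tid <- tr$id[i]
    ii <- bytgt[[tid]] %||% integer(0)   # place -> transition arcs
    oi <- bysrc[[tid]] %||% integer(0)   # transition -> place arcs
    in_place <- A_src[ii]; in_kind <- A_kind[ii]; in_w <- A_w[ii]
    out_place <- A_tgt[oi]; out_kind <- A_kind[oi]; out_w <- A_w[oi]
    pre_sel <- in_kind %in% c("standard", "read", "inhibitor", "equal")
    pre_place <- in_place[pre_sel]; pre_kind <- in_kind[pre_sel]
    pre_w <- in_w[pre_sel]
    pre_const <- all(vapply(pre_w, is_scalar_number, logical(1)))
    rate <- tr_rate[[i]]
    if (!is.null(rate) && uses_mass_action(rate)) {
      ma_sel <- in_kind %in% c("standard", "read")
      rate <- expand_mass_action(rate,
                                 data.frame(place = in_place[ma_sel],
                                            weight = I(in_w[ma_sel])),
                                 combinatorial = isTRUE(tr_comb[i]))
    }
    std_w <- c(in_w[in_kind == "standard"], out_w[out_kind == "standard"])
    stoich_const <- all(vapply(std_w, is_scalar_number, logical(1)))
    st <- if (stoich_const) {
      d <- numeric(0)
      for (k in which(in_kind == "standard")) {
        p <- in_place[k]
        d[p] <- (if (p %in% names(d)) d[[p]] else 0) - in_w[[k]]
      }
      for (k in which(out_kind == "standard")) {
        p <- out_place[k]
        d[p] <- (if (p %in% names(d)) d[[p]] else 0) + out_w[[k]]
      }
      d[d != 0]
    } else NULL
    resets <- unique(c(in_place[in_kind == "reset"], out_place[out_kind == "reset"]))
    deps <- if (!is.null(rate)) expr_dependencies(rate, place_set) else character()
    # places whose value can change the propensity: rate reads + enabling arcs
    dep_places <- sort(unique(c(deps, pre_place)))
    trs[[i]] <- list(
      id = tid, kind = tr_kind[i], rate = rate,
      pre_place = pre_place, pre_kind = pre_kind,
      pre_w = pre_w, pre_const = pre_const,
      pre_wnum = if (pre_const) vapply(pre_w, as.double, double(1)) else NULL,
      stoich = st, stoich_dyn = !stoich_const, resets = resets,
      deps = deps, dep_places = dep_places,
      delay = tr$delay[i], imm_weight = tr$weight[i],
      sched = c(tr$sched_start[i], tr$sched_interval[i], tr$sched_end[i]),
      hint = tr$partition_hint[i])
  }
  list(net = net, place_ids = pl$id, place_kind = setNames(pl$kind, pl$id),
       init = initial_marking(net), params = params, tr = trs,
       tid = tr$id, tkind = setNames(tr$kind, tr$id))
}

# enabledness on the compiled form
enabled_cm <- function(cm, ct, marking, data = NULL) {
  np <- length(ct$pre_place)
  if (np > 0) {
    m <- marking[ct$pre_place]
    w <- if (ct$pre_const) ct$pre_wnum else {
      data <- data %||% c(as.list(marking), cm$params)
      vapply(ct$pre_w, eval_expression, double(1), data = data, where = ct$id)
    }
    for (k in seq_len(np)) {
      ok <- switch(ct$pre_kind[k],
                   standard = , read = m[[k]] >= w[[k]],
                   equal = m[[k]] == w[[k]],
                   inhibitor = m[[k]] < w[[k]])
      if (!ok) return(FALSE)
    }
  }
  TRUE
}

# propensity of one transition (0 when disabled; tiny negatives clamped)
prop_cm <- function(cm, ct, marking, data = NULL) {
  if (!enabled_cm(cm, ct, marking, data)) return(0)
  data <- data %||% c(as.list(marking), cm$params)
  v <- eval_expression(ct$rate, data, where = ct$id)
  if (v < 0) {
    if (v > -1e-9) return(0)
    stop_hpn(paste0("negative propensity ", v, " at transition `", ct$id, "`"),
             "hpn_negative_propensity")
  }
  v
}

# apply one firing; returns the new marking
fire_cm <- function(cm, ct, marking) {
  if (!ct$stoich_dyn) {
    st <- ct$stoich
    if (length(st)) marking[names(st)] <- marking[names(st)] + st
  } else {
    st <- stoichiometry(cm$net, ct$id, marking)
    if (length(st)) marking[names(st)] <- marking[names(st)] + st
    if (any(marking < 0))
      stop_hpn(paste0("negative marking after firing `", ct$id, "`"), "hpn_model_error")
  }
  if (length(ct$resets)) marking[ct$resets] <- 0
  marking
}
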