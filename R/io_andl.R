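#' Plain-text net description format
#'
#' `parse_andl()` and `write_andl()` read and write hybrid Petri nets (and
#' their coloured extension) in a line-oriented, human-readable dialect.
#' The grammar (documented in the package vignette) has four sections:
#'
#' ```
#' hpn "name"                      # or: chpn "name" for coloured nets
#' constants:
#'   k_open = 1
#' colorsets:                      # coloured dialect only
#'   chCS = 1 .. 3
#'   Grid2D = GX x GY
#' places:
#'   discrete:
#'     close = 1                   # flat:      name = initial [logical]
#'     closed : chCS = 1           # coloured:  name : set = initial [lab=v,...]
#'   continuous:
#'     Ca = 0
#' transitions:
#'   stochastic:
#'     ch_open:
#'       var m : chCS              # coloured variables
#'       guard: m <= 2             # coloured guard
#'       in close 1                # arcs: in/out/read/inhibitor/equal/
#'       out open 1                #       reset/modifier place[(cexpr,..)] [w]
#'       rate: MassAction(k_open)
#'   immediate:
#'     t1:
#'       weight: 3
#'       in A 1
#'   deterministic_delay:
#'     t2:
#'       delay: 2.5
#'       in A 1
#'   scheduled:
#'     t3:
#'       schedule: 5 0 5
#'       out A 1
#' ```
#'
#' `#` starts a comment; indentation is not significant. The round trip
#' `parse_andl(write_andl(net))` reproduces the net structurally.
#'
#' @param text Character vector of lines, a single string with newlines,
#'   or a file path.
#' @return `parse_andl()`: an [hpn()] or [coloured_hpn()];
#'   `write_andl()`: a single string.
#' @export
parse_andl <- function(text) {
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    readLines(text, warn = FALSE)
  else unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines_raw <- lines
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)

  perr <- function(i, msg) {
    stop_hpn(paste0("parse error at line ", i, " (`", trimws(lines_raw[i]), "`): ", msg),
             "hpn_parse_error", line = i)
  }

  coloured <- FALSE
  name <- "net"
  constants <- list()       # ordered name -> value
  colsets <- list()         # name -> spec
  places <- list()          # list of row specs
  transitions <- list()     # list of specs
  section <- ""
  place_kind <- ""
  tr_kind <- ""
  cur <- NULL               # current transition spec

  flush_tr <- function() {
    if (!is.null(cur)) transitions[[length(transitions) + 1L]] <<- cur
    cur <<- NULL
  }

  kinds_map <- c(stochastic = "stochastic", continuous = "continuous",
                 immediate = "immediate",
                 deterministic_delay = "deterministic_delay",
                 scheduled = "scheduled")

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "") next
    if (grepl("^(hpn|chpn)\\b", ln)) {
      coloured <- grepl("^chpn", ln)
      m <- sub("^(hpn|chpn)\\s*", "", ln)
      name <- gsub('^"|"$', "", trimws(m))
      if (name == "") name <- "net"
      next
    }
    if (ln == "constants:") { flush_tr(); section <- "constants"; next }
    if (ln == "colorsets:") { flush_tr(); section <- "colorsets"; next }
    if (ln == "places:") { flush_tr(); section <- "places"; place_kind <- ""; next }
    if (ln == "transitions:") { flush_tr(); section <- "transitions"; tr_kind <- ""; next }

    if (section == "places" && ln %in% c("discrete:", "continuous:")) {
      place_kind <- sub(":$", "", ln); next
    }
    if (section == "transitions" && sub(":$", "", ln) %in% names(kinds_map)) {
      flush_tr(); tr_kind <- sub(":$", "", ln); next
    }

    if (section == "constants") {
      m <- regmatches(ln, regexec("^([A-Za-z._][A-Za-z0-9._]*)\\s*=\\s*(\\S+)$", ln))[[1]]
      if (length(m) == 0) perr(i, "expected `name = value`")
      v <- suppressWarnings(as.numeric(m[3]))
      if (is.na(v)) perr(i, "constant value must be numeric")
      constants[[m[2]]] <- v
      next
    }
    if (section == "colorsets") {
      if (!coloured) perr(i, "colorsets are only valid in a chpn document")
      m <- regmatches(ln, regexec(
        "^([A-Za-z._][A-Za-z0-9._]*)\\s*=\\s*(-?[0-9]+)\\s*\\.\\.\\s*(-?[0-9]+)$", ln))[[1]]
      if (length(m) > 0) {
        colsets[[m[2]]] <- list(kind = "range", lo = as.integer(m[3]), hi = as.integer(m[4]))
        next
      }
      m <- regmatches(ln, regexec(
        "^([A-Za-z._][A-Za-z0-9._]*)\\s*=\\s*(.+)$", ln))[[1]]
      if (length(m) == 0) perr(i, "expected `name = lo .. hi` or `name = A x B`")
      comps <- trimws(strsplit(m[3], "\\s+x\\s+")[[1]])
      if (length(comps) < 2) perr(i, "product colour set needs at least two components")
      colsets[[m[2]]] <- list(kind = "product", components = comps)
      next
    }
    if (section == "places") {
      if (place_kind == "") perr(i, "place entries must follow `discrete:` or `continuous:`")
      if (coloured) {
        m <- regmatches(ln, regexec(
          "^([A-Za-z._][A-Za-z0-9._]*)\\s*:\\s*([A-Za-z._][A-Za-z0-9._]*)\\s*=\\s*([-0-9.eE+]+)\\s*(\\[.*\\])?$",
          ln))[[1]]
        if (length(m) == 0) perr(i, "expected `name : colourset = initial [lab=v, ...]`")
        ia <- NULL
        if (!is.na(m[5]) && nzchar(m[5])) {
          body <- gsub("^\\[|\\]$", "", m[5])
          if (nzchar(trimws(body))) {
            prs <- strsplit(body, ",")[[1]]
            ia <- numeric(0)
            for (pr in prs) {
              kv <- strsplit(trimws(pr), "=")[[1]]
              if (length(kv) != 2) perr(i, "bad per-colour initial override")
              ia[trimws(kv[1])] <- as.numeric(kv[2])
            }
          }
        }
        places[[length(places) + 1L]] <- list(
          id = m[2], kind = place_kind, colset = m[3],
          initial = as.numeric(m[4]), initial_at = ia)
      } else {
        m <- regmatches(ln, regexec(
          "^([A-Za-z._][A-Za-z0-9._]*)\\s*=\\s*([-0-9.eE+]+)(\\s+logical)?$", ln))[[1]]
        if (length(m) == 0) perr(i, "expected `name = initial [logical]`")
        places[[length(places) + 1L]] <- list(
          id = m[2], kind = place_kind, initial = as.numeric(m[3]),
          is_logical = !is.na(m[4]) && nzchar(m[4]))
      }
      next
    }
    if (section == "transitions") {
      if (tr_kind == "") perr(i, "transition entries must follow a kind header")
      if (grepl("^[A-Za-z._][A-Za-z0-9._]*:$", ln)) {
        flush_tr()
        cur <- list(id = sub(":$", "", ln), kind = kinds_map[[tr_kind]],
                    arcs = list(), variables = character(), line = i)
        next
      }
      if (is.null(cur)) perr(i, "expected a transition name line `id:`")
      if (grepl("^rate:", ln)) { cur$rate <- trimws(sub("^rate:", "", ln)); next }
      if (grepl("^guard:", ln)) { cur$guard <- trimws(sub("^guard:", "", ln)); next }
      if (grepl("^delay:", ln)) { cur$delay <- as.numeric(sub("^delay:", "", ln)); next }
      if (grepl("^weight:", ln)) { cur$weight <- as.numeric(sub("^weight:", "", ln)); next }
      if (grepl("^hint:", ln)) { cur$hint <- trimws(sub("^hint:", "", ln)); next }
      if (grepl("^combinatorial:", ln)) {
        cur$combinatorial <- trimws(sub("^combinatorial:", "", ln)) %in% c("true", "TRUE", "yes")
        next
      }
      if (grepl("^schedule:", ln)) {
        v <- as.numeric(strsplit(trimws(sub("^schedule:", "", ln)), "\\s+")[[1]])
        if (length(v) != 3 || any(is.na(v))) perr(i, "schedule needs three numbers")
        cur$schedule <- v
        next
      }
      if (grepl("^var\\s", ln)) {
        m <- regmatches(ln, regexec(
          "^var\\s+([A-Za-z._][A-Za-z0-9._]*)\\s*:\\s*([A-Za-z._][A-Za-z0-9._]*)$", ln))[[1]]
        if (length(m) == 0) perr(i, "expected `var name : colourset`")
        cur$variables[m[2]] <- m[3]
        next
      }
      m <- regmatches(ln, regexec(
        "^(in|out|read|inhibitor|equal|reset|modifier)\\s+([A-Za-z._][A-Za-z0-9._]*)\\s*(\\([^)]*\\))?\\s*(.*)$",
        ln))[[1]]
      if (length(m) == 0) perr(i, "unrecognised transition clause")
      wtxt <- trimws(m[5])
      colour <- NULL
      if (!is.na(m[4]) && nzchar(m[4])) {
        body <- gsub("^\\(|\\)$", "", m[4])
        colour <- lapply(trimws(strsplit(body, ",")[[1]]), function(ce) {
          if (ce == "all") "all" else ce
        })
      }
      cur$arcs[[length(cur$arcs) + 1L]] <- list(
        dir = m[2], place = m[3], colour = colour,
        weight = if (nzchar(wtxt)) wtxt else "1", line = i)
      next
    }
    perr(i, "statement outside any section")
  }
  flush_tr()

  params <- unlist(constants) %||% numeric()
  if (coloured) {
    net <- coloured_hpn(name, parameters = params)
    for (csn in names(colsets)) {
      cs <- colsets[[csn]]
      net <- if (cs$kind == "range") add_colourset(net, csn, cs$lo, cs$hi)
      else add_colourset_product(net, csn, cs$components)
    }
    for (p in places)
      net <- add_coloured_place(net, p$id, p$kind, colset = p$colset,
                                initial = p$initial, initial_at = p$initial_at)
    for (tr in transitions) {
      net <- add_coloured_transition(
        net, tr$id, tr$kind, rate = tr$rate, variables = tr$variables,
        guard = tr$guard, delay = tr$delay, weight = tr$weight,
        schedule = tr$schedule, partition_hint = tr$hint,
        combinatorial = isTRUE(tr$combinatorial))
      for (a in tr$arcs) {
        src <- if (a$dir %in% c("out")) tr$id else a$place
        tgt <- if (a$dir %in% c("out")) a$place else tr$id
        kind <- switch(a$dir, "in" = , "out" = "standard", a$dir)
        net <- add_coloured_arc(net, src, tgt, kind = kind, weight = a$weight,
                                colour = a$colour %||% list())
      }
    }
  } else {
    net <- hpn(name, parameters = params)
    for (p in places)
      net <- add_place(net, p$id, p$kind, initial = p$initial,
                       is_logical = isTRUE(p$is_logical))
    for (tr in transitions) {
      net <- add_transition(net, tr$id, tr$kind, rate = tr$rate,
                            delay = tr$delay, weight = tr$weight,
                            schedule = tr$schedule, partition_hint = tr$hint,
                            combinatorial = isTRUE(tr$combinatorial))
      for (a in tr$arcs) {
        if (!is.null(a$colour))
          stop_hpn(paste0("colour expressions at line ", a$line,
                          " are only valid in a chpn document"), "hpn_parse_error")
        src <- if (a$dir == "out") tr$id else a$place
        tgt <- if (a$dir == "out") a$place else tr$id
        kind <- switch(a$dir, "in" = , "out" = "standard", a$dir)
        net <- add_arc(net, src, tgt, kind = kind, weight = a$weight)
      }
    }
  }
  net
}

fmt_num <- function(x) {
  if (is_whole(x) && abs(x) < 1e15) format(as.integer(round(x))) else
    format(x, digits = 17, scientific = FALSE)
}

deparse_w <- function(w) {
  if (is_scalar_number(w)) fmt_num(w) else deparse1(w)
}

#' @rdname parse_andl
#' @param net An [hpn()] or [coloured_hpn()] object.
#' @export
write_andl <- function(net) {
  UseMethod("write_andl")
}

write_andl_common <- function(net, header, body) {
  out <- c(paste0(header, ' "', net$name, '"'), "")
  if (length(net$parameters)) {
    out <- c(out, "constants:",
             paste0("  ", names(net$parameters), " = ",
                    vapply(net$parameters, fmt_num, character(1))), "")
  }
  c(out, body)
}

arc_lines <- function(arcs, tid, coloured = FALSE) {
  sel <- arcs$source == tid | arcs$target == tid
  a <- arcs[sel, , drop = FALSE]
  lines <- character(0)
  for (k in seq_len(nrow(a))) {
    out_arc <- a$source[k] == tid
    place <- if (out_arc) a$target[k] else a$source[k]
    dir <- if (a$kind[k] == "standard") (if (out_arc) "out" else "in") else a$kind[k]
    ce <- ""
    if (coloured) {
      cex <- a$colour[[k]]
      if (length(cex))
        ce <- paste0("(", paste(vapply(cex, function(e)
          if (identical(e, as.name("all"))) "all" else deparse_w(e), character(1)),
          collapse = ", "), ")")
    }
    lines <- c(lines, paste0("      ", dir, " ", place, ce, " ",
                             deparse_w(a$weight[[k]])))
  }
  lines
}

transition_block <- function(tr, arcs, coloured = FALSE) {
  body <- character(0)
  for (kind in transition_kinds) {
    rows <- which(tr$kind == kind)
    if (!length(rows)) next
    body <- c(body, paste0("  ", kind, ":"))
    for (i in rows) {
      body <- c(body, paste0("    ", tr$id[i], ":"))
      if (coloured) {
        vars <- tr$variables[[i]]
        for (vn in names(vars))
          body <- c(body, paste0("      var ", vn, " : ", vars[[vn]]))
        g <- tr$guard[[i]]
        if (!isTRUE(g)) body <- c(body, paste0("      guard: ", deparse1(g)))
      }
      if (kind == "deterministic_delay")
        body <- c(body, paste0("      delay: ", fmt_num(tr$delay[i])))
      if (kind == "immediate")
        body <- c(body, paste0("      weight: ", fmt_num(tr$weight[i])))
      if (kind == "scheduled")
        body <- c(body, paste0("      schedule: ", fmt_num(tr$sched_start[i]), " ",
                               fmt_num(tr$sched_interval[i]), " ",
                               fmt_num(tr$sched_end[i])))
      if (!is.na(tr$partition_hint[i]))
        body <- c(body, paste0("      hint: ", tr$partition_hint[i]))
      if (isTRUE(tr$combinatorial[i]))
        body <- c(body, "      combinatorial: true")
      body <- c(body, arc_lines(arcs, tr$id[i], coloured))
      if (!is.null(tr$rate[[i]]))
        body <- c(body, paste0("      rate: ", deparse1(tr$rate[[i]])))
    }
  }
  body
}

#' @export
write_andl.hpn <- function(net) {
  body <- c("places:")
  for (kind in c("discrete", "continuous")) {
    rows <- which(net$places$kind == kind)
    if (!length(rows)) next
    body <- c(body, paste0("  ", kind, ":"),
              paste0("    ", net$places$id[rows], " = ",
                     vapply(net$places$initial[rows], fmt_num, character(1)),
                     ifelse(net$places$is_logical[rows], " logical", "")))
  }
  body <- c(body, "", "transitions:",
            transition_block(net$transitions, net$arcs, coloured = FALSE))
  paste(c(write_andl_common(net, "hpn", body), ""), collapse = "\n")
}

#' @export
write_andl.chpn <- function(net) {
  cs_lines <- character(0)
  for (csn in names(net$colsets)) {
    cs <- net$colsets[[csn]]
    cs_lines <- c(cs_lines, if (cs$kind == "range")
      paste0("  ", csn, " = ", cs$lo, " .. ", cs$hi)
      else paste0("  ", csn, " = ", paste(cs$components, collapse = " x ")))
  }
  body <- c("colorsets:", cs_lines, "", "places:")
  for (kind in c("discrete", "continuous")) {
    rows <- which(net$places$kind == kind)
    if (!length(rows)) next
    body <- c(body, paste0("  ", kind, ":"))
    for (i in rows) {
      ia <- net$places$initial_at[[i]]
      suffix <- if (!is.null(ia) && length(ia))
        paste0(" [", paste(names(ia), vapply(ia, fmt_num, character(1)),
                           sep = "=", collapse = ", "), "]")
      else ""
      body <- c(body, paste0("    ", net$places$id[i], " : ", net$places$colset[i],
                             " = ", fmt_num(net$places$initial[i]), suffix))
    }
  }
  body <- c(body, "", "transitions:",
            transition_block(net$transitions, net$arcs, coloured = TRUE))
  paste(c(write_andl_common(net, "chpn", body), ""), collapse = "\n")
}
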