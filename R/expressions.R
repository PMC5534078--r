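#' Rate, guard and arc-weight expressions
#'
#' Expressions attached to transitions (rates), coloured transitions (guards)
#' and arcs (weights) are ordinary arithmetic formulas over declared place
#' names, parameter names and (in coloured nets) colour variables. They are
#' stored as R language objects and support evaluation against a marking,
#' syntactic dependency extraction, and interval bounds used by the
#' rejection-based simulation machinery.
#'
#' The grammar covers real literals, identifiers, `+ - * / ^`, unary minus,
#' a small set of mathematical functions (`exp`, `log`, `sqrt`, `abs`,
#' `min`, `max`, `floor`, `ceiling`), and -- in guards only -- comparisons
#' (`< <= > >= == !=`) and boolean operators (`& | !`). The call form
#' `MassAction(k)` expands at a transition into `k` times the product of the
#' transition's standard/read input places raised to their arc weights.
#'
#' @param text A character scalar containing the formula, or an object
#'   already parsed (language/numeric), which is returned after validation.
#' @param symbols Optional character vector of declared identifiers (places,
#'   parameters, colour variables). When supplied, any other identifier is an
#'   error.
#' @param guard Logical; allow comparison and boolean operators.
#' @return A language object (or numeric literal) representing the AST.
#' @examples
#' e <- parse_expression("2 * Ca / (1 + Ca)", symbols = "Ca")
#' eval_expression(e, list(Ca = 1))
#' expr_dependencies(e)
#' expr_bounds(parse_expression("k * x * y"), list(x = c(1, 2), y = c(0, 3)),
#'             params = list(k = 1))
#' @export
parse_expression <- function(text, symbols = NULL, guard = FALSE) {
  expr <- if (is.character(text)) {
    if (length(text) != 1L) stop_hpn("expression text must be a single string", "hpn_parse_error")
    tryCatch(
      str2lang(text),
      error = function(e) stop_hpn(
        paste0("syntax error in expression `", text, "`: ", conditionMessage(e)),
        "hpn_parse_error")
    )
  } else if (is.numeric(text) || is.language(text)) {
    text
  } else {
    stop_hpn("expression must be character, numeric or a language object", "hpn_parse_error")
  }
  check_expr_ast(expr, symbols = symbols, guard = guard, src = if (is.character(text)) text else deparse(expr))
  expr
}

arith_ops <- c("+", "-", "*", "/", "^", "(")
guard_ops <- c("<", "<=", ">", ">=", "==", "!=", "&", "|", "!", "&&", "||")
builtin_funs <- c("exp", "log", "sqrt", "abs", "min", "max", "floor", "ceiling")

check_expr_ast <- function(e, symbols, guard, src) {
  if (is.numeric(e) && length(e) == 1L) return(invisible(TRUE))
  if (is.logical(e) && length(e) == 1L) {
    if (!guard) stop_hpn(paste0("logical literal not allowed outside guards in `", src, "`"), "hpn_parse_error")
    return(invisible(TRUE))
  }
  if (is.name(e)) {
    nm <- as.character(e)
    if (!is.null(symbols) && !nm %in% symbols)
      stop_hpn(paste0("unknown identifier `", nm, "` in `", src, "`"), "hpn_parse_error",
               identifier = nm)
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    head <- e[[1]]
    if (!is.name(head))
      stop_hpn(paste0("unsupported call form in `", src, "`"), "hpn_parse_error")
    op <- as.character(head)
    args <- as.list(e)[-1]
    ok <- op %in% arith_ops ||
      (guard && op %in% guard_ops) ||
      op %in% builtin_funs ||
      op == "MassAction"
    if (!ok)
      stop_hpn(paste0("operator or function `", op, "` not allowed in `", src, "`"),
               "hpn_parse_error", identifier = op)
    for (a in args) check_expr_ast(a, symbols, guard, src)
    return(invisible(TRUE))
  }
  stop_hpn(paste0("unsupported expression element in `", src, "`"), "hpn_parse_error")
}

#' Evaluate an expression against a marking and parameter values
#'
#' @param expr A parsed expression (see [parse_expression()]).
#' @param data Named list or vector binding every identifier in `expr`
#'   (place markings, parameters, colour variables).
#' @param where Optional label (e.g. a transition id) used in error messages.
#' @return A double (or logical for guards).
#' @export
eval_expression <- function(expr, data, where = NULL) {
  if (is.numeric(expr)) return(as.double(expr))
  data <- as.list(data)
  v <- tryCatch(eval(expr, data, baseenv()),
                error = function(e) stop_hpn(
                  paste0("failed to evaluate ", deparse1(expr),
                         if (!is.null(where)) paste0(" at `", where, "`"),
                         ": ", conditionMessage(e)),
                  "hpn_eval_error"))
  if (is.logical(v)) return(v)
  if (!is.finite(v)) {
    if (has_zero_division(expr, data))
      stop_hpn(paste0("division by zero while evaluating ", deparse1(expr),
                      if (!is.null(where)) paste0(" at `", where, "`")),
               "hpn_division_by_zero", where = where)
    stop_hpn(paste0("non-finite value from ", deparse1(expr),
                    if (!is.null(where)) paste0(" at `", where, "`")),
             "hpn_eval_error", where = where)
  }
  as.double(v)
}

has_zero_division <- function(e, data) {
  if (!is.call(e)) return(FALSE)
  if (identical(e[[1]], as.name("/"))) {
    den <- tryCatch(eval(e[[3]], data, baseenv()), error = function(err) NA_real_)
    if (isTRUE(!is.na(den) && den == 0)) return(TRUE)
  }
  any(vapply(as.list(e)[-1], has_zero_division, logical(1), data = data))
}

#' Place identifiers referenced by an expression
#'
#' Returns the identifiers syntactically present in the AST. When `places`
#' is given the result is restricted to that set, yielding exactly the place
#' dependencies of a rate expression.
#'
#' @inheritParams eval_expression
#' @param places Optional character vector of place ids to intersect with.
#' @return Character vector (possibly empty), sorted.
#' @export
expr_dependencies <- function(expr, places = NULL) {
  if (is.numeric(expr)) return(character())
  vars <- all.vars(expr)
  if (!is.null(places)) vars <- intersect(vars, places)
  sort(unique(vars))
}

#' Interval bounds of an expression over an interval marking
#'
#' Computes `(lo, hi)` by interval arithmetic such that every pointwise
#' evaluation inside the interval marking lies within the bounds. Bounds are
#' exact for products of non-negative monomials (the mass-action case) and
#' valid, though possibly loose, for general expressions.
#'
#' @inheritParams eval_expression
#' @param intervals Named list mapping place ids to `c(lo, hi)` with
#'   `0 <= lo <= hi`.
#' @param params Named list/vector of scalar values for remaining
#'   identifiers.
#' @return Numeric `c(lo, hi)`.
#' @export
expr_bounds <- function(expr, intervals, params = list()) {
  iv <- lapply(intervals, function(x) {
    if (length(x) != 2L || any(!is.finite(x)) || x[1] > x[2])
      stop_hpn("intervals must be finite c(lo, hi) with lo <= hi", "hpn_bounds_error")
    as.double(x)
  })
  pv <- as.list(params)
  b <- interval_eval(expr, iv, pv)
  c(lo = b[1], hi = b[2])
}

interval_eval <- function(e, iv, pv) {
  if (is.numeric(e) && length(e) == 1L) return(c(e, e))
  if (is.name(e)) {
    nm <- as.character(e)
    if (!is.null(iv[[nm]])) return(iv[[nm]])
    if (!is.null(pv[[nm]])) return(rep(as.double(pv[[nm]]), 2L))
    stop_hpn(paste0("no interval or value for identifier `", nm, "`"), "hpn_bounds_error")
  }
  if (!is.call(e)) stop_hpn("unsupported expression element in bounds()", "hpn_bounds_error")
  op <- as.character(e[[1]])
  args <- as.list(e)[-1]
  if (op == "(") return(interval_eval(args[[1]], iv, pv))
  if (op == "-" && length(args) == 1L) {
    b <- interval_eval(args[[1]], iv, pv); return(c(-b[2], -b[1]))
  }
  if (op %in% c("+", "-", "*", "/")) {
    a <- interval_eval(args[[1]], iv, pv)
    b <- interval_eval(args[[2]], iv, pv)
    return(switch(op,
      "+" = c(a[1] + b[1], a[2] + b[2]),
      "-" = c(a[1] - b[2], a[2] - b[1]),
      "*" = {
        p <- c(a[1] * b[1], a[1] * b[2], a[2] * b[1], a[2] * b[2])
        c(min(p), max(p))
      },
      "/" = {
        if (b[1] <= 0 && b[2] >= 0)
          stop_hpn("interval contains a division-by-zero point", "hpn_division_by_zero")
        p <- c(a[1] / b[1], a[1] / b[2], a[2] / b[1], a[2] / b[2])
        c(min(p), max(p))
      }))
  }
  if (op == "^") {
    a <- interval_eval(args[[1]], iv, pv)
    b <- interval_eval(args[[2]], iv, pv)
    if (b[1] != b[2])
      stop_hpn("interval-valued exponents are not supported in bounds()", "hpn_bounds_error")
    w <- b[1]
    if (a[1] >= 0) {
      if (w >= 0) return(c(a[1]^w, a[2]^w))
      if (a[1] == 0) stop_hpn("negative power of an interval touching zero", "hpn_bounds_error")
      return(c(a[2]^w, a[1]^w))
    }
    if (is_whole(w) && w >= 0) {
      cand <- c(a[1]^w, a[2]^w, if (a[1] < 0 && a[2] > 0) 0)
      return(c(min(cand), max(cand)))
    }
    stop_hpn("unsupported power of a possibly-negative interval", "hpn_bounds_error")
  }
  if (op %in% c("exp", "sqrt", "log")) {
    a <- interval_eval(args[[1]], iv, pv)
    f <- get(op, baseenv())
    if (op == "log" && a[1] <= 0) stop_hpn("log of an interval touching zero", "hpn_bounds_error")
    if (op == "sqrt" && a[1] < 0) stop_hpn("sqrt of a negative interval", "hpn_bounds_error")
    return(c(f(a[1]), f(a[2])))
  }
  if (op == "abs") {
    a <- interval_eval(args[[1]], iv, pv)
    if (a[1] >= 0) return(a)
    if (a[2] <= 0) return(c(-a[2], -a[1]))
    return(c(0, max(-a[1], a[2])))
  }
  if (op %in% c("min", "max")) {
    bs <- lapply(args, interval_eval, iv = iv, pv = pv)
    lo <- vapply(bs, `[`, numeric(1), 1L)
    hi <- vapply(bs, `[`, numeric(1), 2L)
    if (op == "min") return(c(min(lo), min(hi)))
    return(c(max(lo), max(hi)))
  }
  if (op %in% c("floor", "ceiling")) {
    a <- interval_eval(args[[1]], iv, pv)
    f <- get(op, baseenv())
    return(c(f(a[1]), f(a[2])))
  }
  stop_hpn(paste0("operator `", op, "` not supported in bounds()"), "hpn_bounds_error")
}

# Expand MassAction(k) at a transition: k * prod(input place ^ arc weight)
# over the transition's standard/read input arcs. `inputs` is a data frame
# with columns place (chr) and weight (list of numeric/language). With
# combinatorial = TRUE integer constant weights expand to falling factorials
# x * (x-1) * ... * (x-w+1) for exact chemical-master-equation propensities.
expand_mass_action <- function(expr, inputs, combinatorial = FALSE) {
  if (is.numeric(expr) || is.name(expr)) return(expr)
  if (!is.call(expr)) return(expr)
  if (identical(expr[[1]], as.name("MassAction"))) {
    if (length(expr) != 2L)
      stop_hpn("MassAction() takes exactly one argument (the rate constant)", "hpn_parse_error")
    k <- expr[[2]]
    terms <- list(k)
    if (nrow(inputs) > 0) {
      ord <- order(inputs$place)  # arc declaration order must not matter
      for (i in ord) {
        p <- as.name(inputs$place[i])
        w <- inputs$weight[[i]]
        if (combinatorial) {
          if (!is_scalar_number(w) || !is_whole(w))
            stop_hpn("combinatorial mass action needs constant integer arc weights",
                     "hpn_parse_error")
          for (d in seq_len(w) - 1) {
            terms <- c(terms, list(if (d == 0) p else call("-", p, d)))
          }
        } else {
          terms <- c(terms, list(if (is_scalar_number(w) && w == 1) p else call("^", p, w)))
        }
      }
    }
    return(Reduce(function(a, b) call("*", a, b), terms))
  }
  out <- expr
  for (i in seq_along(out)[-1]) out[[i]] <- expand_mass_action(out[[i]], inputs, combinatorial)
  out
}

uses_mass_action <- function(e) {
  if (!is.call(e)) return(FALSE)
  if (identical(e[[1]], as.name("MassAction"))) return(TRUE)
  any(vapply(as.list(e)[-1], uses_mass_action, logical(1)))
}

# Substitute colour-variable values (named list of integers) into an
# expression; fully-constant results fold to numerics.
substitute_vars <- function(expr, values) {
  e <- do.call(substitute, list(expr, as.list(values)))
  if (!is.numeric(e) && length(all.vars(e)) == 0L) {
    folded <- tryCatch(eval(e, baseenv()), error = function(err) NULL)
    if (is.numeric(folded) && length(folded) == 1L && is.finite(folded)) return(folded)
  }
  e
}
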