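#' SBML Level 2 Version 4 import (subset)
#'
#' Reads the subset of SBML L2V4 that maps onto the net class:
#' compartments, species, global and reaction-local parameters, and
#' reactions with MathML kinetic laws. Species become places (all
#' continuous by default, overridable), reactions become transitions
#' (reversible reactions are split into forward/backward halves of a
#' top-level MathML difference), modifiers become modifier arcs, local
#' parameters are namespaced `reaction.parameter`, and species with
#' `boundaryCondition="true"` receive no stoichiometric change. Rules,
#' events, constraints and function definitions are not supported and
#' raise an error naming the element.
#'
#' @param path File path or XML string of an SBML L2 document.
#' @param regime `"continuous"` (default) or `"stochastic"`: the regime
#'   the imported reactions are treated with (SBML carries no hybrid
#'   partition).
#' @param discrete Character vector of species ids to import as discrete
#'   places.
#' @return An [hpn()].
#' @export
import_sbml <- function(path, regime = c("continuous", "stochastic"),
                        discrete = character()) {
  regime <- match.arg(regime)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing"))
    stop_hpn("no <model> element found", "hpn_sbml_error")
  for (bad in c("listOfRules", "listOfEvents", "listOfConstraints",
                "listOfFunctionDefinitions", "listOfInitialAssignments")) {
    node <- xml2::xml_find_first(model, paste0("./s:", bad), ns)
    if (!inherits(node, "xml_missing"))
      stop_hpn(paste0("unsupported SBML element <", bad,
                      ">: rules, events and related constructs are not part ",
                      "of the supported subset"),
               "hpn_sbml_unsupported", element = bad)
  }

  num_attr <- function(node, attr, default = NA_real_) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) default else as.numeric(v)
  }

  params <- numeric()
  compartments <- numeric()
  for (cp in xml2::xml_find_all(model, "./s:listOfCompartments/s:compartment", ns)) {
    id <- xml2::xml_attr(cp, "id")
    compartments[id] <- num_attr(cp, "size", 1)
  }
  for (pp in xml2::xml_find_all(model, "./s:listOfParameters/s:parameter", ns)) {
    params[xml2::xml_attr(pp, "id")] <- num_attr(pp, "value", NA_real_)
  }

  species <- xml2::xml_find_all(model, "./s:listOfSpecies/s:species", ns)
  sp_id <- xml2::xml_attr(species, "id")
  sp_boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  sp_init <- vapply(species, function(s) {
    v <- num_attr(s, "initialAmount")
    if (is.na(v)) v <- num_attr(s, "initialConcentration")
    if (is.na(v)) 0 else v
  }, double(1))

  reactions <- xml2::xml_find_all(model, "./s:listOfReactions/s:reaction", ns)
  tkind <- if (regime == "continuous") "continuous" else "stochastic"
  pkind_default <- if (regime == "continuous") "continuous" else "discrete"

  net <- hpn(xml2::xml_attr(model, "id") %|na|% "sbml_model")
  for (k in seq_along(sp_id)) {
    kind <- if (sp_id[k] %in% discrete || regime == "stochastic") "discrete"
    else pkind_default
    net <- add_place(net, sp_id[k], kind, initial = sp_init[k])
  }

  add_reaction_half <- function(net, rid, rate_expr, reactants, products, modifiers) {
    net <- add_transition(net, rid, tkind, rate = rate_expr)
    rate_refs <- expr_dependencies(rate_expr, sp_id)
    connected <- character()
    for (r in seq_len(nrow(reactants))) {
      sp <- reactants$species[r]
      if (sp_boundary[match(sp, sp_id)]) {
        net <- add_arc(net, sp, rid, kind = "modifier")
      } else {
        net <- add_arc(net, sp, rid, weight = reactants$stoich[r])
      }
      connected <- c(connected, sp)
    }
    for (r in seq_len(nrow(products))) {
      sp <- products$species[r]
      if (!sp_boundary[match(sp, sp_id)])
        net <- add_arc(net, rid, sp, weight = products$stoich[r])
      else
        net <- add_arc(net, sp, rid, kind = "modifier")
      connected <- c(connected, sp)
    }
    for (sp in modifiers) {
      net <- add_arc(net, sp, rid, kind = "modifier")
      connected <- c(connected, sp)
    }
    for (sp in setdiff(rate_refs, connected))
      net <- add_arc(net, sp, rid, kind = "modifier")
    net
  }

  for (rx in reactions) {
    rid <- xml2::xml_attr(rx, "id")
    reversible <- identical(xml2::xml_attr(rx, "reversible"), "true")
    refs <- function(xp) {
      nodes <- xml2::xml_find_all(rx, xp, ns)
      data.frame(species = xml2::xml_attr(nodes, "species"),
                 stoich = vapply(nodes, function(n) num_attr(n, "stoichiometry", 1),
                                 double(1)),
                 stringsAsFactors = FALSE)
    }
    reactants <- refs("./s:listOfReactants/s:speciesReference")
    products <- refs("./s:listOfProducts/s:speciesReference")
    modifiers <- xml2::xml_attr(
      xml2::xml_find_all(rx, "./s:listOfModifiers/s:modifierSpeciesReference", ns),
      "species")
    kl <- xml2::xml_find_first(rx, "./s:kineticLaw", ns)
    if (inherits(kl, "xml_missing"))
      stop_hpn(paste0("reaction `", rid, "` has no kineticLaw"), "hpn_sbml_error")
    for (lp in xml2::xml_find_all(kl, "./s:listOfParameters/s:parameter", ns)) {
      params[paste0(rid, ".", xml2::xml_attr(lp, "id"))] <- num_attr(lp, "value")
    }
    math <- xml2::xml_find_first(kl, "./*[local-name() = 'math']")
    if (inherits(math, "xml_missing"))
      stop_hpn(paste0("reaction `", rid, "` has no MathML math"), "hpn_sbml_error")
    expr <- mathml_to_expr(xml2::xml_child(math), rid)
    expr <- namespace_locals(expr, rid,
                             sub(paste0("^", rid, "\\."), "",
                                 grep(paste0("^", rid, "\\."), names(params),
                                      value = TRUE)))
    if (reversible) {
      if (!(is.call(expr) && identical(expr[[1]], as.name("-")) && length(expr) == 3))
        stop_hpn(paste0("reversible reaction `", rid, "` needs a kinetic law of ",
                        "the form (forward) - (backward) to be split"),
                 "hpn_sbml_error")
      net <- add_reaction_half(net, paste0(rid, "_f"), expr[[2]],
                               reactants, products, modifiers)
      net <- add_reaction_half(net, paste0(rid, "_b"), expr[[3]],
                               products, reactants, modifiers)
    } else {
      net <- add_reaction_half(net, rid, expr, reactants, products, modifiers)
    }
  }
  # compartment sizes enter the symbol table only when a rate references them
  used <- unique(unlist(lapply(net$transitions$rate, expr_dependencies)))
  params <- c(params, compartments[names(compartments) %in% used])
  net$parameters <- params[!is.na(params)]
  net
}

`%|na|%` <- function(x, y) if (is.na(x) || is.null(x)) y else x

# prefix reaction-local parameter names inside the kinetic law
namespace_locals <- function(e, rid, locals) {
  if (!length(locals)) return(e)
  sub_map <- lapply(paste0(rid, ".", locals), as.name)
  names(sub_map) <- locals
  do.call(substitute, list(e, sub_map))
}

mathml_ops <- c(plus = "+", minus = "-", times = "*", divide = "/", power = "^")

mathml_to_expr <- function(node, where) {
  nm <- xml2::xml_name(node)
  if (nm == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type == "e-notation") {
      parts <- xml2::xml_contents(node)
      txt <- trimws(xml2::xml_text(parts))
      txt <- txt[nzchar(txt)]
      return(as.numeric(txt[1]) * 10^as.numeric(txt[2]))
    }
    return(as.numeric(xml2::xml_text(node)))
  }
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "csymbol")
    stop_hpn(paste0("unsupported csymbol in kinetic law of `", where, "`"),
             "hpn_sbml_unsupported")
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], mathml_to_expr, where = where)
    if (op %in% names(mathml_ops)) {
      sym <- mathml_ops[[op]]
      if (length(args) == 1L) {
        if (op == "minus") return(call("-", args[[1]]))
        return(args[[1]])
      }
      return(Reduce(function(a, b) call(sym, a, b), args))
    }
    if (op %in% c("exp", "ln", "log", "root", "abs", "floor", "ceiling")) {
      fn <- switch(op, ln = "log", root = "sqrt", op)
      return(as.call(c(as.name(fn), args)))
    }
    stop_hpn(paste0("unsupported MathML operator <", op, "> in `", where, "`"),
             "hpn_sbml_unsupported")
  }
  stop_hpn(paste0("unsupported MathML element <", nm, "> in `", where, "`"),
           "hpn_sbml_unsupported")
}

expr_to_mathml <- function(e) {
  if (is.numeric(e)) return(paste0("<cn> ", format(e, digits = 17), " </cn>"))
  if (is.name(e)) return(paste0("<ci> ", as.character(e), " </ci>"))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    args <- as.list(e)[-1]
    if (op == "(") return(expr_to_mathml(args[[1]]))
    inner <- paste(vapply(args, expr_to_mathml, character(1)), collapse = " ")
    tag <- names(mathml_ops)[match(op, mathml_ops)]
    if (!is.na(tag)) return(paste0("<apply> <", tag, "/> ", inner, " </apply>"))
    fn <- switch(op, log = "ln", sqrt = "root", op)
    if (fn %in% c("exp", "ln", "root", "abs", "floor", "ceiling"))
      return(paste0("<apply> <", fn, "/> ", inner, " </apply>"))
  }
  stop_hpn(paste0("cannot express ", deparse1(e), " in the SBML subset"),
           "hpn_sbml_error")
}

#' SBML Level 2 Version 4 export
#'
#' Writes the flat structure of a net as SBML: places become species,
#' rate-bearing transitions become irreversible reactions with MathML
#' kinetic laws (`MassAction()` is flattened into an explicit product),
#' read/modifier arcs become modifiers. The hybrid partition cannot be
#' represented in SBML; `regime` records the caller's choice of how the
#' exported model is to be treated. Coloured nets are unfolded first.
#' Inhibitor, equal and reset arcs and timed transition kinds have no SBML
#' counterpart and raise an error.
#'
#' @inheritParams add_place
#' @param path Output file path (NULL returns the XML string).
#' @param regime `"continuous"` or `"stochastic"`.
#' @return The XML string, invisibly when written to a file.
#' @export
export_sbml <- function(net, path = NULL, regime = c("continuous", "stochastic")) {
  regime <- match.arg(regime)
  if (inherits(net, "chpn")) net <- unfold(net)
  stopifnot(inherits(net, "hpn"))
  bad_arcs <- net$arcs$kind %in% c("inhibitor", "equal", "reset")
  if (any(bad_arcs))
    stop_hpn(paste0("arcs of kind ", paste(unique(net$arcs$kind[bad_arcs]),
                                           collapse = "/"),
                    " cannot be represented in SBML"), "hpn_sbml_error")
  bad_tr <- !net$transitions$kind %in% c("stochastic", "continuous")
  if (any(bad_tr))
    stop_hpn("timed/immediate transitions cannot be represented in SBML",
             "hpn_sbml_error")
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  L <- c('<?xml version="1.0" encoding="UTF-8"?>',
         '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
         paste0('  <model id="', esc(net$name), '">'),
         '    <listOfCompartments>',
         '      <compartment id="cell" size="1"/>',
         '    </listOfCompartments>',
         '    <listOfSpecies>')
  for (i in seq_len(nrow(net$places))) {
    L <- c(L, paste0('      <species id="', net$places$id[i],
                     '" compartment="cell" initialAmount="',
                     format(net$places$initial[i], digits = 17), '"/>'))
  }
  L <- c(L, '    </listOfSpecies>')
  if (length(net$parameters)) {
    L <- c(L, '    <listOfParameters>')
    for (pn in names(net$parameters))
      L <- c(L, paste0('      <parameter id="', pn, '" value="',
                       format(net$parameters[[pn]], digits = 17), '"/>'))
    L <- c(L, '    </listOfParameters>')
  }
  L <- c(L, '    <listOfReactions>')
  cmi <- compile_hpn(net, check = FALSE)
  for (i in seq_len(nrow(net$transitions))) {
    trow <- net$transitions[i, ]
    tid <- trow$id
    ia <- input_arcs(net, tid)
    oa <- output_arcs(net, tid)
    L <- c(L, paste0('      <reaction id="', tid, '" reversible="false">'))
    std_in <- ia[ia$kind == "standard", , drop = FALSE]
    std_out <- oa[oa$kind == "standard", , drop = FALSE]
    mods <- unique(c(ia$source[ia$kind %in% c("read", "modifier")],
                     oa$target[oa$kind %in% c("read", "modifier")]))
    if (nrow(std_in)) {
      L <- c(L, '        <listOfReactants>')
      for (k in seq_len(nrow(std_in))) {
        w <- std_in$weight[[k]]
        if (!is_scalar_number(w))
          stop_hpn("SBML export needs constant arc weights", "hpn_sbml_error")
        L <- c(L, paste0('          <speciesReference species="', std_in$source[k],
                         '" stoichiometry="', format(w), '"/>'))
      }
      L <- c(L, '        </listOfReactants>')
    }
    if (nrow(std_out)) {
      L <- c(L, '        <listOfProducts>')
      for (k in seq_len(nrow(std_out))) {
        w <- std_out$weight[[k]]
        if (!is_scalar_number(w))
          stop_hpn("SBML export needs constant arc weights", "hpn_sbml_error")
        L <- c(L, paste0('          <speciesReference species="', std_out$target[k],
                         '" stoichiometry="', format(w), '"/>'))
      }
      L <- c(L, '        </listOfProducts>')
    }
    if (length(mods)) {
      L <- c(L, '        <listOfModifiers>')
      for (m in mods)
        L <- c(L, paste0('          <modifierSpeciesReference species="', m, '"/>'))
      L <- c(L, '        </listOfModifiers>')
    }
    rate <- cmi$tr[[tid]]$rate
    L <- c(L, '        <kineticLaw>',
           '          <math xmlns="http://www.w3.org/1998/Math/MathML">',
           paste0('            ', expr_to_mathml(rate)),
           '          </math>',
           '        </kineticLaw>',
           '      </reaction>')
  }
  L <- c(L, '    </listOfReactions>',
         paste0('    <!-- regime: ', regime, ' -->'),
         '  </model>', '</sbml>')
  xml <- paste(L, collapse = "\n")
  if (!is.null(path)) {
    writeLines(xml, path)
    return(invisible(xml))
  }
  xml
}
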