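# Minimal SBML subset reader/writer (xml2). Supports the ODE-compatible
# core: compartments, species, global/local parameters, reactions with
# stoichiometry and MathML kinetic laws (+, -, *, /, power, symbols,
# numbers). Events, rules and function definitions are rejected rather
# than silently approximated.

mathml_to_expr <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1) stop("unsupported MathML structure",
                                call. = FALSE)
    return(mathml_to_expr(kids[[1]]))
  }
  if (name == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (name == "cn") return(as.numeric(trimws(xml2::xml_text(node))))
  if (name == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], mathml_to_expr)
    fun <- switch(op, plus = "+", minus = "-", times = "*",
                  divide = "/", power = "^", root = "sqrt",
                  exp = "exp", ln = "log",
                  stop("unsupported MathML operator <", op, ">",
                       call. = FALSE))
    if (fun == "+" && length(args) > 2)
      return(Reduce(function(a, b) call("+", a, b), args))
    if (fun == "*" && length(args) > 2)
      return(Reduce(function(a, b) call("*", a, b), args))
    if (fun == "-" && length(args) == 1)
      return(as.call(list(as.name("-"), args[[1]])))
    return(as.call(c(list(as.name(fun)), args)))
  }
  stop("unsupported MathML node <", name, ">", call. = FALSE)
}

expr_to_mathml <- function(e) {
  if (is.numeric(e)) return(paste0("<cn>", format(e, digits = 15),
                                   "</cn>"))
  if (is.name(e)) return(paste0("<ci>", as.character(e), "</ci>"))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power",
                  "(" = return(expr_to_mathml(e[[2]])),
                  stop("cannot serialize operator '", op, "'",
                       call. = FALSE))
    args <- vapply(as.list(e)[-1], expr_to_mathml, "")
    return(paste0("<apply><", tag, "/>", paste(args, collapse = ""),
                  "</apply>"))
  }
  stop("cannot serialize expression", call. = FALSE)
}

#' Load a kinetic model from an SBML file
#'
#' Assembles the ODE system (stoichiometry times rate laws) from an
#' SBML Level 2/3 file. Boundary-condition and constant species become
#' fixed inputs available to the rate laws; local reaction parameters
#' are namespaced as `reactionId.paramId`. Unsupported constructs
#' (events, rules, function definitions, missing kinetic laws) raise
#' explicit errors.
#'
#' @param path SBML file path.
#' @param observed species ids to observe (default: all dynamic
#'   species).
#' @return a [kinetic_model()] with `theta_true` filled from the file's
#'   parameter values.
#' @export
load_sbml <- function(path, observed = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mod <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mod, "xml_missing")) stop("no <model> in SBML file",
                                         call. = FALSE)
  for (bad in c("listOfEvents", "listOfRules", "listOfFunctionDefinitions",
                "listOfConstraints")) {
    if (!inherits(xml2::xml_find_first(mod, paste0(".//", bad)),
                  "xml_missing"))
      stop("unsupported SBML construct: ", bad, call. = FALSE)
  }
  comp_nodes <- xml2::xml_find_all(mod, ".//listOfCompartments/compartment")
  comp_size <- stats::setNames(
    as.numeric(ifelse(is.na(xml2::xml_attr(comp_nodes, "size")), 1,
                      xml2::xml_attr(comp_nodes, "size"))),
    xml2::xml_attr(comp_nodes, "id"))
  sp_nodes <- xml2::xml_find_all(mod, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_init <- as.numeric(ifelse(
    is.na(xml2::xml_attr(sp_nodes, "initialConcentration")),
    xml2::xml_attr(sp_nodes, "initialAmount"),
    xml2::xml_attr(sp_nodes, "initialConcentration")))
  sp_init[is.na(sp_init)] <- 0
  sp_fixed <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true" |
    xml2::xml_attr(sp_nodes, "constant") %in% "true"
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  dyn <- sp_id[!sp_fixed]
  if (!length(dyn)) stop("no dynamic species in model", call. = FALSE)
  par_nodes <- xml2::xml_find_all(mod, ".//listOfParameters/parameter")
  # top-level parameters only (local ones handled per reaction)
  par_nodes <- par_nodes[xml2::xml_name(
    xml2::xml_parent(xml2::xml_parent(par_nodes))) == "model"]
  par_id <- xml2::xml_attr(par_nodes, "id")
  par_val <- as.numeric(xml2::xml_attr(par_nodes, "value"))
  rx_nodes <- xml2::xml_find_all(mod, ".//listOfReactions/reaction")
  if (!length(rx_nodes)) stop("model has no reactions", call. = FALSE)
  reactions <- lapply(rx_nodes, function(rx) {
    rid <- xml2::xml_attr(rx, "id")
    kl <- xml2::xml_find_first(rx, ".//kineticLaw")
    if (inherits(kl, "xml_missing"))
      stop("reaction '", rid, "' has no kinetic law", call. = FALSE)
    math <- xml2::xml_find_first(kl, ".//math")
    if (inherits(math, "xml_missing"))
      stop("reaction '", rid, "' kinetic law has no <math>",
           call. = FALSE)
    loc <- xml2::xml_find_all(kl, ".//parameter")
    loc_id <- xml2::xml_attr(loc, "id")
    loc_val <- as.numeric(xml2::xml_attr(loc, "value"))
    stoich <- function(tag) {
      refs <- xml2::xml_find_all(rx, paste0(".//", tag, "/speciesReference"))
      s <- as.numeric(ifelse(is.na(xml2::xml_attr(refs, "stoichiometry")),
                             1, xml2::xml_attr(refs, "stoichiometry")))
      stats::setNames(s, xml2::xml_attr(refs, "species"))
    }
    list(id = rid, expr = mathml_to_expr(math),
         local = stats::setNames(loc_val, loc_id),
         reactants = stoich("listOfReactants"),
         products = stoich("listOfProducts"))
  })
  # assemble the parameter vector: globals + namespaced locals
  theta <- stats::setNames(par_val, par_id)
  for (r in reactions)
    if (length(r$local))
      theta <- c(theta, stats::setNames(r$local,
                                        paste0(r$id, ".", names(r$local))))
  fixed_inputs <- stats::setNames(sp_init[sp_fixed], sp_id[sp_fixed])
  comp_of <- stats::setNames(comp_size[sp_comp], sp_id)
  if (is.null(observed)) observed <- dyn
  if (!all(observed %in% dyn))
    stop("observed species not in the model's dynamic species: ",
         paste(setdiff(observed, dyn), collapse = ", "), call. = FALSE)
  rhs <- function(x, theta, t) {
    env <- as.list(c(x, theta, fixed_inputs, comp_size))
    env$t <- t
    rates <- numeric(length(dyn))
    names(rates) <- dyn
    for (r in reactions) {
      loc <- theta[paste0(r$id, ".", names(r$local))]
      if (length(loc)) {
        names(loc) <- names(r$local)
        env[names(loc)] <- loc
      }
      v <- eval(r$expr, env)
      for (s in names(r$reactants))
        if (s %in% dyn) rates[[s]] <- rates[[s]] -
            r$reactants[[s]] * v / comp_of[[s]]
      for (s in names(r$products))
        if (s %in% dyn) rates[[s]] <- rates[[s]] +
            r$products[[s]] * v / comp_of[[s]]
    }
    rates
  }
  kinetic_model(name = xml2::xml_attr(mod, "id") %||% "sbml_model",
                rhs = rhs, state_names = dyn,
                param_names = names(theta),
                x0 = sp_init[!sp_fixed],
                observe = NULL, obs_names = observed,
                theta_true = theta)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Write a minimal SBML file
#'
#' Serializes a declarative reaction-network description (used by the
#' fixtures) to SBML Level 2 Version 4. Rate laws are given as R
#' expression strings over species and parameter ids.
#'
#' @param network list with `id`, `species` (named initial
#'   concentrations), `parameters` (named values), `reactions` (list of
#'   lists: `id`, `reactants` / `products` named stoichiometries,
#'   `math` R-syntax rate-law string).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_sbml <- function(network, path) {
  sp <- vapply(names(network$species), function(s) sprintf(
    '      <species id="%s" compartment="cell" initialConcentration="%s"/>',
    s, format(network$species[[s]], digits = 15)), "")
  par <- vapply(names(network$parameters), function(p) sprintf(
    '      <parameter id="%s" value="%s"/>',
    p, format(network$parameters[[p]], digits = 15)), "")
  rx <- vapply(network$reactions, function(r) {
    refs <- function(tag, st) {
      if (!length(st)) return("")
      inner <- paste(vapply(names(st), function(s) sprintf(
        '          <speciesReference species="%s" stoichiometry="%s"/>',
        s, format(st[[s]], digits = 15)), ""), collapse = "\n")
      sprintf("        <%s>\n%s\n        </%s>", tag, inner, tag)
    }
    math <- expr_to_mathml(str2lang(r$math))
    paste0('      <reaction id="', r$id, '" reversible="false">\n',
           refs("listOfReactants", r$reactants), "\n",
           refs("listOfProducts", r$products), "\n",
           '        <kineticLaw>\n',
           '          <math xmlns="http://www.w3.org/1998/Math/MathML">',
           math, '</math>\n',
           '        </kineticLaw>\n      </reaction>')
  }, "")
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">\n',
    '  <model id="', network$id, '">\n',
    '    <listOfCompartments>\n',
    '      <compartment id="cell" size="1"/>\n',
    '    </listOfCompartments>\n',
    '    <listOfSpecies>\n', paste(sp, collapse = "\n"), '\n',
    '    </listOfSpecies>\n',
    '    <listOfParameters>\n', paste(par, collapse = "\n"), '\n',
    '    </listOfParameters>\n',
    '    <listOfReactions>\n', paste(rx, collapse = "\n"), '\n',
    '    </listOfReactions>\n',
    '  </model>\n</sbml>\n')
  writeLines(doc, path)
  invisible(path)
}

#' SBML network description of a fixture model
#'
#' Declarative reaction-network form of the fixtures that map onto mass
#' action / Michaelis-Menten reactions, suitable for [write_sbml()] and
#' round-tripping through [load_sbml()].
#'
#' @param model_id `"mm_chain"` or `"product_ni"`.
#' @return a network list (see [write_sbml()]).
#' @export
fixture_sbml_network <- function(model_id = c("mm_chain", "product_ni")) {
  model_id <- match.arg(model_id)
  m <- build_fixture_model(model_id)
  switch(model_id,
    mm_chain = list(
      id = "mm_chain",
      species = as.list(m$x0),
      parameters = as.list(m$theta_true),
      reactions = list(list(
        id = "v1", reactants = c(S = 1), products = c(P = 1),
        math = "Vmax * S / (Km + S)"))),
    product_ni = list(
      id = "product_ni",
      species = as.list(m$x0),
      parameters = as.list(m$theta_true),
      reactions = list(list(
        id = "decay", reactants = c(x = 1), products = NULL,
        math = "th1 * th2 * x"))))
}
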