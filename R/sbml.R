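# SBML Level 2 Version 4 subset: single compartment, species, parameters,
# irreversible reactions with kinetic laws.  Kinetic laws are interpreted,
# after substitution of molecule-count variables, as mesoscopic
# propensities in events per model time unit; references to the
# compartment id (or a parameter named "Omega") denote the system size.
# Events, rules, reversible reactions and constant species are rejected by
# validation, matching the restrictions required for a consistent
# stochastic interpretation.

SBML_NS <- "http://www.sbml.org/sbml/level2/version4"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

#' Parse an SBML file into a reaction network
#'
#' Supports the Level 2 Version 4 subset described in the package
#' vignette: unit definitions (substance and time), one compartment,
#' species (amounts or concentrations), global and reaction-local
#' parameters, and irreversible reactions with kinetic laws.  Kinetic laws
#' whose expression matches the falling-factorial mass-action form for the
#' declared reactant stoichiometry are recognized as mass-action reactions
#' and their macroscopic rate constant is recovered; all other kinetic
#' laws are kept as symbolic propensities.  Local parameters are inlined
#' at parse time.
#'
#' @param path Path to an SBML file.
#' @param validate If `TRUE` (default), stop with the validation messages
#'   when the document violates the supported subset; set `FALSE` to
#'   obtain the network regardless (for inspection).
#' @return A [reaction_network()].  The validation report is attached as
#'   attribute `validation`.
#' @export
parse_sbml <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("ill-formed SBML ('", conditionMessage(e), "')"))
  ns <- c(s = SBML_NS, m = MATHML_NS)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing")) stop("no <model> element found")

  report <- validate_sbml_doc(doc, ns)
  if (validate && !report$ok) {
    msgs <- vapply(report$errors, function(e) sprintf("[%s] %s", e[["code"]],
                                                      e[["message"]]), "")
    stop("unsupported SBML constructs:\n  ", paste(msgs, collapse = "\n  "))
  }

  comps <- xml2::xml_find_all(model, ".//s:listOfCompartments/s:compartment", ns)
  if (length(comps) < 1L) stop("no compartment defined")
  comp <- comps[[1L]]
  volume <- as.numeric(xml2::xml_attr(comp, "size"))
  if (!is.finite(volume) || volume <= 0) stop("compartment size missing or non-positive")
  comp_id <- xml2::xml_attr(comp, "id")

  unit <- sbml_substance_unit(model, ns)
  time_unit <- sbml_time_unit(model, ns)

  net <- reaction_network(volume, unit = unit, time_unit = time_unit,
                          id = xml2::xml_attr(model, "id"))
  w <- system_size(net)

  for (sp in xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)) {
    id <- xml2::xml_attr(sp, "id")
    amt <- xml2::xml_attr(sp, "initialAmount")
    conc <- xml2::xml_attr(sp, "initialConcentration")
    if (!is.na(amt)) {
      net <- add_species(net, id, as.numeric(amt), kind = "amount",
                         name = xml2::xml_attr(sp, "name") %|na|% id)
    } else {
      net <- add_species(net, id, as.numeric(conc), kind = "concentration",
                         name = xml2::xml_attr(sp, "name") %|na|% id)
    }
  }

  params <- list()
  for (p in xml2::xml_find_all(model, ".//s:listOfParameters/s:parameter", ns))
    params[[xml2::xml_attr(p, "id")]] <- as.numeric(xml2::xml_attr(p, "value"))

  for (rxn in xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)) {
    rid <- xml2::xml_attr(rxn, "id")
    side <- function(xp) {
      refs <- xml2::xml_find_all(rxn, xp, ns)
      out <- integer()
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry") %|na|% "1"
        out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0L) + as.integer(as.numeric(st))
      }
      out
    }
    reactants <- side(".//s:listOfReactants/s:speciesReference")
    products <- side(".//s:listOfProducts/s:speciesReference")
    math <- xml2::xml_find_first(rxn, ".//s:kineticLaw/m:math", ns)
    if (inherits(math, "xml_missing")) stop("reaction ", rid, " has no kinetic law")
    local <- params
    for (p in xml2::xml_find_all(rxn, ".//s:kineticLaw/s:listOfParameters/s:parameter", ns))
      local[[xml2::xml_attr(p, "id")]] <- as.numeric(xml2::xml_attr(p, "value"))
    expr <- mathml_to_expr(xml2::xml_find_first(math, "./*", ns))
    # compartment id and the conventional parameter name denote system size
    subs <- stats::setNames(list(quote(Omega), quote(Omega)),
                            c(comp_id, "Omega"))
    scheme <- paste(side_string(reactants), "->", side_string(products))
    raw <- substitute_values(expr, subs)
    loc2 <- local[setdiff(names(local), "Omega")]
    expr <- substitute_values(raw, loc2)
    # structural fast path: the canonical falling-factorial form with a
    # local rate parameter k round-trips its value exactly
    k <- NULL
    if ("k" %in% names(loc2) &&
        identical(raw, mass_action_expr(list(reactants = reactants))))
      k <- loc2[["k"]]
    if (is.null(k))
      k <- match_mass_action(expr, reactants, net$species$id, w)
    if (!is.null(k)) {
      net <- add_reaction(net, scheme, rate = k, id = rid)
    } else {
      net <- add_reaction(net, scheme, propensity = expr, id = rid)
    }
  }
  attr(net, "validation") <- report
  net
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

side_string <- function(v) {
  if (!length(v)) return("0")
  paste(ifelse(v > 1L, paste(v, names(v)), names(v)), collapse = " + ")
}

sbml_substance_unit <- function(model, ns) {
  ud <- xml2::xml_find_first(
    model, ".//s:listOfUnitDefinitions/s:unitDefinition[@id='substance']/s:listOfUnits/s:unit", ns)
  if (inherits(ud, "xml_missing")) return("molar")
  if (identical(xml2::xml_attr(ud, "kind"), "item")) "item" else "molar"
}

sbml_time_unit <- function(model, ns) {
  ud <- xml2::xml_find_first(
    model, ".//s:listOfUnitDefinitions/s:unitDefinition[@id='time']/s:listOfUnits/s:unit", ns)
  if (inherits(ud, "xml_missing")) return("second")
  mult <- as.numeric(xml2::xml_attr(ud, "multiplier") %|na|% "1")
  if (isTRUE(all.equal(mult, 86400))) "day" else "second"
}

# Convert a MathML element to an R expression.
mathml_to_expr <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (name == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (identical(type, "e-notation")) {
      parts <- trimws(strsplit(xml2::xml_text(node), "\n")[[1]])
      parts <- parts[parts != ""]
      return(as.numeric(parts[1]) * 10^as.numeric(parts[2]))
    }
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  if (name == "csymbol") stop("time-dependent kinetic law (csymbol)")
  if (name != "apply") stop("unsupported MathML element: ", name)
  kids <- xml2::xml_find_all(node, "./*")
  op <- xml2::xml_name(kids[[1]])
  args <- lapply(kids[-1], mathml_to_expr)
  fold <- function(f) Reduce(function(a, b) call(f, a, b), args)
  switch(op,
    times = fold("*"),
    plus = if (length(args) == 0L) 0 else fold("+"),
    minus = if (length(args) == 1L) call("-", args[[1]]) else fold("-"),
    divide = fold("/"),
    power = fold("^"),
    stop("unsupported MathML operator: ", op))
}

# Structural mass-action detection: does expr equal
# k * Omega * prod ff(n_i, s_i) / Omega^(sum s) for some constant k >= 0?
# Tested exactly (to relative 1e-9) at several integer states.
match_mass_action <- function(expr, reactants, ids, w) {
  states <- list()
  base <- c(5, 7, 11, 13, 3)
  for (r in 1:5)
    states[[r]] <- stats::setNames(as.list((seq_along(ids) * 2 + r * base[r]) %% 19 + 2), ids)
  ff_val <- function(n, s) prod(n - seq_len(s) + 1)
  k_est <- NULL
  for (st in states) {
    env <- list2env(st); assign("Omega", w, envir = env)
    v <- tryCatch(eval(expr, env), error = function(e) NA_real_)
    if (!is.finite(v)) return(NULL)
    ref <- w^(1 - sum(reactants)) *
      prod(vapply(names(reactants), function(i) ff_val(st[[i]], reactants[[i]]), 0))
    if (ref == 0) next
    k <- v / ref
    if (is.null(k_est)) k_est <- k
    else if (abs(k - k_est) > 1e-9 * max(abs(k_est), 1e-300)) return(NULL)
  }
  if (is.null(k_est) || !is.finite(k_est) || k_est < 0) return(NULL)
  # snap to a shorter decimal representation when it is equally consistent
  # (removes last-ulp noise from the division above)
  k_snap <- signif(k_est, 12)
  if (abs(k_snap - k_est) <= 1e-11 * abs(k_est)) k_snap else k_est
}

#' Validate an SBML document for stochastic analysis
#'
#' Applies the subset rules: no events, no assignment/rate/algebraic
#' rules, no reversible reactions, no constant or boundary-condition
#' species, a single compartment, and no explicitly time-dependent kinetic
#' laws.  Violations are report entries, not exceptions.
#'
#' @param path Path to an SBML file.
#' @return A `validation_report`.
#' @export
validate_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("ill-formed SBML ('", conditionMessage(e), "')"))
  validate_sbml_doc(doc, c(s = SBML_NS, m = MATHML_NS))
}

validate_sbml_doc <- function(doc, ns) {
  errors <- list()
  add <- function(code, msg) errors[[length(errors) + 1L]] <<- c(code = code, message = msg)
  if (length(xml2::xml_find_all(doc, ".//s:listOfEvents/s:event", ns)))
    add("UNSUPPORTED_EVENT", "SBML events are not supported for stochastic models")
  for (r in xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)) {
    rev <- xml2::xml_attr(r, "reversible")
    if (is.na(rev) || identical(rev, "true"))
      add("REVERSIBLE_REACTION",
          sprintf("reaction '%s' is marked reversible; the reversible attribute cannot be validated for stochastic models",
                  xml2::xml_attr(r, "id")))
  }
  rules <- xml2::xml_find_all(doc, ".//s:listOfRules/*", ns)
  if (length(rules))
    add("UNSUPPORTED_RULE",
        "parameters or species defined by assignment/rate/algebraic rules are not supported")
  for (sp in xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)) {
    if (identical(xml2::xml_attr(sp, "constant"), "true") ||
        identical(xml2::xml_attr(sp, "boundaryCondition"), "true"))
      add("CONSTANT_SPECIES",
          sprintf("species '%s' is constant or boundary-conditioned",
                  xml2::xml_attr(sp, "id")))
  }
  comps <- xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment", ns)
  if (length(comps) > 1L)
    add("MULTI_COMPARTMENT", "only single-compartment models are supported")
  if (length(xml2::xml_find_all(doc, ".//m:csymbol", ns)))
    add("TIME_DEPENDENT_RATE",
        "explicitly time-dependent rates are not supported")
  validation_report(errors)
}

#' Write a reaction network as SBML Level 2 Version 4
#'
#' Emits the subset read by [parse_sbml()]: one compartment, species with
#' initial amounts or concentrations, and irreversible reactions whose
#' kinetic laws are the falling-factorial mass-action propensities (with
#' the macroscopic rate constant as a local parameter `k` and the system
#' size as a global parameter `Omega`), or the verbatim symbolic
#' propensity for custom reactions.  Round trip through [parse_sbml()]
#' recovers an identical network.
#'
#' @param net A [reaction_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
emit_sbml <- function(net, path) {
  w <- system_size(net)
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="2" version="4">', SBML_NS),
    sprintf('  <model id="%s">', esc(net$id)),
    '    <listOfUnitDefinitions>',
    '      <unitDefinition id="substance">',
    sprintf('        <listOfUnits><unit kind="%s"/></listOfUnits>',
            if (net$unit == "molar") "mole" else "item"),
    '      </unitDefinition>',
    '      <unitDefinition id="time">',
    sprintf('        <listOfUnits><unit kind="second" multiplier="%s"/></listOfUnits>',
            if (net$time_unit == "day") "86400" else "1"),
    '      </unitDefinition>',
    '    </listOfUnitDefinitions>',
    '    <listOfCompartments>',
    sprintf('      <compartment id="compartment" size="%.17g"/>', net$volume),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(n_species(net))) {
    s <- net$species[i, ]
    attr <- if (s$kind == "amount")
      sprintf('initialAmount="%.17g" hasOnlySubstanceUnits="true"', s$initial)
    else sprintf('initialConcentration="%.17g"', s$initial)
    lines <- c(lines, sprintf('      <species id="%s" name="%s" compartment="compartment" %s/>',
                              s$id, esc(s$name), attr))
  }
  lines <- c(lines, '    </listOfSpecies>',
             '    <listOfParameters>',
             sprintf('      <parameter id="Omega" value="%.17g"/>', w),
             '    </listOfParameters>',
             '    <listOfReactions>')
  for (rx in net$reactions) {
    lines <- c(lines, sprintf('      <reaction id="%s" reversible="false">', rx$id))
    refs <- function(v, tag) {
      if (!length(v)) return(character(0))
      c(sprintf('        <listOf%ss>', tag),
        sprintf('          <speciesReference species="%s" stoichiometry="%d"/>',
                names(v), as.integer(v)),
        sprintf('        </listOf%ss>', tag))
    }
    lines <- c(lines, refs(rx$reactants, "Reactant"), refs(rx$products, "Product"))
    if (rx$type == "mass_action") {
      expr <- mass_action_expr(rx)
      body <- expr_to_mathml(expr, indent = "          ")
      lines <- c(lines, '        <kineticLaw>',
                 sprintf('          <math xmlns="%s">', MATHML_NS),
                 body, '          </math>',
                 '          <listOfParameters>',
                 sprintf('            <parameter id="k" value="%.17g"/>', rx$rate),
                 '          </listOfParameters>',
                 '        </kineticLaw>')
    } else {
      body <- expr_to_mathml(rx$propensity, indent = "          ")
      lines <- c(lines, '        <kineticLaw>',
                 sprintf('          <math xmlns="%s">', MATHML_NS),
                 body, '          </math>', '        </kineticLaw>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

# count-space falling-factorial propensity of a mass-action reaction,
# as an expression over species counts, k and Omega
mass_action_expr <- function(rx) {
  s <- rx$reactants
  order <- sum(s)
  factors <- list(quote(k))
  for (i in names(s)) for (m in seq_len(s[[i]]) - 1L)
    factors <- c(factors, list(if (m == 0L) as.name(i)
                               else call("-", as.name(i), m)))
  num <- prod_expr(factors)
  if (order == 0L) call("*", num, quote(Omega))
  else if (order == 1L) num
  else call("/", num, if (order == 2L) quote(Omega)
            else call("^", quote(Omega), order - 1L))
}

expr_to_mathml <- function(e, indent = "") {
  rec <- function(e, ind) {
    if (is.numeric(e)) return(sprintf("%s<cn>%.17g</cn>", ind, e))
    if (is.name(e)) return(sprintf("%s<ci>%s</ci>", ind, as.character(e)))
    if (is.call(e)) {
      op <- as.character(e[[1]])
      tag <- switch(op, `*` = "times", `+` = "plus", `-` = "minus",
                    `/` = "divide", `^` = "power", `(` = NULL,
                    stop("cannot emit operator in MathML: ", op))
      if (is.null(tag)) return(rec(e[[2]], ind))
      args <- as.list(e)[-1]
      c(sprintf("%s<apply>", ind), sprintf("%s  <%s/>", ind, tag),
        unlist(lapply(args, rec, ind = paste0(ind, "  "))),
        sprintf("%s</apply>", ind))
    } else stop("cannot emit expression of class ", class(e)[1])
  }
  rec(e, indent)
}
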