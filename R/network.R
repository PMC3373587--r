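#' @useDynLib ssenoise, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Avogadro constant
#'
#' Number of entities per mole, used to convert between molar concentrations
#' and molecule counts.
#'
#' @format A single numeric value, 6.02214076e23 / mol.
#' @export
AVOGADRO <- 6.02214076e23

#' Create an empty reaction network
#'
#' A reaction network describes `N` chemical species confined to a single
#' well-mixed compartment of volume `volume` litres, interacting through `R`
#' irreversible reactions.  Species and reactions are added with
#' [add_species()] and [add_reaction()].
#'
#' Species states are interpreted in one of two frames: the concentration
#' frame (molar for `unit = "molar"`, molecules per litre for
#' `unit = "item"`), and the molecule-count frame used internally by the
#' stochastic simulator and the system size expansion.  The two are linked by
#' the system size `omega`: `n = omega * phi`, where `omega = volume * N_A`
#' for molar models and `omega = volume` for item-based models.
#'
#' @param volume Compartment volume in litres.
#' @param unit Concentration unit descriptor: `"molar"` or `"item"`.
#' @param time_unit Time unit carried as metadata (e.g. `"second"`,
#'   `"day"`).  No internal rescaling is performed.
#' @param id Optional model identifier.
#' @return An object of class `reaction_network`.
#' @seealso [add_species()], [add_reaction()], [stoich_matrix()]
#' @examples
#' net <- reaction_network(volume = 1e-15)
#' net <- add_species(net, "X", initial = 1e-6)
#' net <- add_reaction(net, "0 -> X", rate = 1e-6)
#' net <- add_reaction(net, "X -> 0", rate = 1)
#' net
#' @export
reaction_network <- function(volume, unit = c("molar", "item"),
                             time_unit = "second", id = "model") {
  unit <- match.arg(unit)
  stopifnot(is.numeric(volume), length(volume) == 1L, volume > 0)
  structure(list(
    id = id,
    volume = volume,
    unit = unit,
    time_unit = time_unit,
    species = data.frame(id = character(), name = character(),
                         compartment = character(), initial = numeric(),
                         kind = character(), stringsAsFactors = FALSE),
    reactions = list()
  ), class = "reaction_network")
}

#' System size of a network
#'
#' The factor `omega` converting concentrations to molecule counts:
#' `volume * N_A` for molar models, `volume` for item-based models.
#'
#' @param net A [reaction_network()].
#' @return A positive scalar.
#' @export
system_size <- function(net) {
  if (net$unit == "molar") net$volume * AVOGADRO else net$volume
}

#' Add a species to a network
#'
#' @param net A [reaction_network()].
#' @param id Species identifier (must be unique and a valid symbol).
#' @param initial Initial value, non-negative.  Interpreted according to
#'   `kind`: a concentration (in the network's unit frame) or an absolute
#'   molecule count.
#' @param kind `"concentration"` or `"amount"`.
#' @param name Display name; defaults to the id.
#' @return The updated network.
#' @export
add_species <- function(net, id, initial = 0,
                        kind = c("concentration", "amount"), name = id) {
  stopifnot(inherits(net, "reaction_network"))
  kind <- match.arg(kind)
  if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", id))
    stop("species id must be a valid symbol name: ", id)
  if (id %in% net$species$id) stop("duplicate species id: ", id)
  if (!is.finite(initial) || initial < 0)
    stop("initial value of species ", id, " must be non-negative")
  net$species <- rbind(net$species, data.frame(
    id = id, name = name, compartment = "compartment", initial = initial,
    kind = kind, stringsAsFactors = FALSE))
  net
}

# Parse one side of a reaction string like "2 X + Y" into a named integer
# vector of stoichiometries.  "0" or "" denotes the empty set.
parse_side <- function(txt) {
  txt <- trimws(txt)
  if (txt == "" || txt == "0") return(integer())
  parts <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  out <- integer()
  for (p in parts) {
    m <- regmatches(p, regexec("^([0-9]*)\\s*([A-Za-z][A-Za-z0-9_]*)$", p))[[1]]
    if (length(m) == 0L) stop("cannot parse reaction term: '", p, "'")
    coef <- if (m[2] == "") 1L else as.integer(m[2])
    sp <- m[3]
    out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0L) + coef
  }
  out
}

#' Add a reaction to a network
#'
#' Reactions are written as irreversible schemes such as `"S + E -> ES"`,
#' `"2 X -> 0"` or `"0 -> S"`.  A reaction is either *mass-action*, defined
#' by a macroscopic rate constant `rate` (in concentration/time units
#' matching the reaction order), or *custom*, defined by a symbolic
#' `propensity` expression over species molecule counts and the symbol
#' `Omega` (the system size), evaluating to events per time unit.
#'
#' For a mass-action reaction with reactant stoichiometries `s_i` the
#' microscopic propensity is the falling-factorial form
#' `k * omega * prod_i ff(n_i, s_i) / omega^(sum_i s_i)`, whose macroscopic
#' limit is `k * prod_i phi_i^(s_i)`.
#'
#' @param net A [reaction_network()].
#' @param scheme Reaction string, e.g. `"S + E -> ES"`.
#' @param rate Macroscopic rate constant (mass-action reactions).
#' @param propensity Quoted R expression for the microscopic propensity
#'   (custom reactions); mutually exclusive with `rate`.
#' @param params Named numeric vector of local parameters referenced by
#'   `propensity`; inlined at construction time.
#' @param id Optional reaction identifier.
#' @return The updated network.
#' @export
add_reaction <- function(net, scheme, rate = NULL, propensity = NULL,
                         params = NULL, id = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  sides <- strsplit(scheme, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("reaction scheme must contain '->': ", scheme)
  s <- parse_side(sides[1])
  r <- parse_side(sides[2])
  for (sp in unique(c(names(s), names(r))))
    if (!sp %in% net$species$id)
      stop("reaction references undeclared species: ", sp)
  if (is.null(rate) == is.null(propensity))
    stop("exactly one of 'rate' and 'propensity' must be given")
  if (is.null(id)) id <- paste0("r", length(net$reactions) + 1L)
  rx <- list(id = id, reactants = s, products = r)
  if (!is.null(rate)) {
    stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0)
    rx$type <- "mass_action"
    rx$rate <- rate
  } else {
    if (!is.null(params)) propensity <- substitute_values(propensity, as.list(params))
    syms <- all.vars(propensity)
    unknown <- setdiff(syms, c(net$species$id, "Omega"))
    if (length(unknown))
      stop("propensity references unresolved symbols: ",
           paste(unknown, collapse = ", "))
    rx$type <- "custom"
    rx$propensity <- propensity
  }
  net$reactions <- c(net$reactions, list(rx))
  net
}

# Substitute a named list of values/expressions into an expression.
substitute_values <- function(expr, env_list) {
  eval(call("substitute", expr, env_list))
}

#' Stoichiometric matrix of a network
#'
#' Returns the `N x R` net stoichiometry `S = r - s`, with rows named by
#' species id and columns by reaction id.
#'
#' @param net A [reaction_network()].
#' @param which One of `"net"`, `"reactant"` or `"product"`.
#' @return An integer matrix.
#' @export
stoich_matrix <- function(net, which = c("net", "reactant", "product")) {
  which <- match.arg(which)
  N <- nrow(net$species); R <- length(net$reactions)
  S <- matrix(0L, N, R, dimnames = list(net$species$id,
                                        vapply(net$reactions, `[[`, "", "id")))
  for (j in seq_len(R)) {
    rx <- net$reactions[[j]]
    if (which != "product")
      for (sp in names(rx$reactants)) S[sp, j] <- S[sp, j] - rx$reactants[[sp]]
    if (which == "reactant") next
    for (sp in names(rx$products)) S[sp, j] <- S[sp, j] + rx$products[[sp]]
  }
  if (which == "reactant") -S else S
}

#' Initial state of a network
#'
#' @param net A [reaction_network()].
#' @param frame `"concentration"` for the concentration frame or `"count"`
#'   for molecule counts.  Counts of amount-typed species are returned
#'   verbatim; concentration-typed species are converted with the system
#'   size.  Counts are rounded to the nearest integer only when
#'   `integer = TRUE` (the convention used to initialize stochastic
#'   simulations).
#' @param integer Round counts to nearest integers.
#' @return Named numeric vector of length `N`.
#' @export
initial_state <- function(net, frame = c("concentration", "count"),
                          integer = FALSE) {
  frame <- match.arg(frame)
  w <- system_size(net)
  x <- net$species$initial
  amount <- net$species$kind == "amount"
  out <- if (frame == "count") ifelse(amount, x, x * w) else ifelse(amount, x / w, x)
  if (frame == "count" && integer) out <- round(out)
  names(out) <- net$species$id
  out
}

#' Convert a network to canonical molecule-count units
#'
#' Returns an equivalent network whose species are all amount-typed
#' (molecule counts), with concentrations recoverable as `n / omega` where
#' `omega` is the [system_size()].  The conversion is exactly invertible up
#' to floating point rounding; counts are not rounded to integers here.
#'
#' @param net A [reaction_network()].
#' @return A `reaction_network` in the canonical frame.
#' @export
to_number_units <- function(net) {
  w <- system_size(net)
  conc <- net$species$kind == "concentration"
  net$species$initial[conc] <- net$species$initial[conc] * w
  net$species$kind[] <- "amount"
  net
}

n_species <- function(net) nrow(net$species)
n_reactions <- function(net) length(net$reactions)

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network '%s': %d species, %d reactions\n",
              x$id, n_species(x), n_reactions(x)))
  cat(sprintf("  volume %.4g l (%s frame, time in %ss), system size %.4g\n",
              x$volume, x$unit, x$time_unit, system_size(x)))
  if (n_species(x)) {
    ini <- initial_state(x)
    cat("  species:", paste(sprintf("%s=%.3g", names(ini), ini),
                            collapse = ", "), "\n")
  }
  for (rx in x$reactions) {
    side <- function(v) if (!length(v)) "0" else
      paste(ifelse(v > 1L, paste(v, names(v)), names(v)), collapse = " + ")
    desc <- if (rx$type == "mass_action") sprintf("k = %.4g", rx$rate)
            else paste(deparse(rx$propensity), collapse = "")
    cat(sprintf("  %-4s %s -> %s   [%s]\n", paste0(rx$id, ":"),
                side(rx$reactants), side(rx$products), desc))
  }
  invisible(x)
}

#' Validate a network for stochastic analysis
#'
#' Checks the restrictions required for a consistent mesoscopic
#' interpretation: no reversible reactions (irreversibility is implied by
#' the one-way schemes), non-negative integer stoichiometries, propensities
#' referencing only declared symbols, and positive volume.  SBML documents
#' carry additional constructs (events, rules, constant species); those
#' rules are checked by [validate_sbml()] when parsing.
#'
#' @param net A [reaction_network()].
#' @return A `validation_report` with fields `ok`, `errors`, `warnings`.
#' @export
validate_network <- function(net) {
  errors <- list(); warnings <- list()
  add_err <- function(code, msg) errors[[length(errors) + 1L]] <<- c(code = code, message = msg)
  if (n_species(net) < 1L) add_err("NO_SPECIES", "network has no species")
  if (n_reactions(net) < 1L) add_err("NO_REACTIONS", "network has no reactions")
  if (any(duplicated(net$species$id)))
    add_err("DUPLICATE_SPECIES", "duplicate species ids")
  if (any(net$species$initial < 0))
    add_err("NEGATIVE_INITIAL", "negative initial values")
  for (rx in net$reactions) {
    if (rx$type == "custom") {
      unknown <- setdiff(all.vars(rx$propensity), c(net$species$id, "Omega"))
      if (length(unknown))
        add_err("UNRESOLVED_SYMBOL",
                paste0("reaction ", rx$id, " references: ",
                       paste(unknown, collapse = ", ")))
    }
  }
  validation_report(errors, warnings)
}

validation_report <- function(errors = list(), warnings = list()) {
  structure(list(ok = length(errors) == 0L, errors = errors,
                 warnings = warnings), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(if (x$ok) "Model valid.\n" else "Model INVALID.\n")
  for (e in x$errors) cat(sprintf("  error [%s]: %s\n", e[["code"]], e[["message"]]))
  for (w in x$warnings) cat(sprintf("  warning [%s]: %s\n", w[["code"]], w[["message"]]))
  invisible(x)
}
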