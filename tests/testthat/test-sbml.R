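test_that("fixture models round-trip through SBML unchanged", {
  for (name in c("F1", "birth_death", "F7")) {
    net <- make_paper_model(name)
    f <- tempfile(fileext = ".xml")
    emit_sbml(net, f)
    net2 <- parse_sbml(f)
    expect_identical(net2$species$id, net$species$id, info = name)
    expect_identical(stoich_matrix(net2), stoich_matrix(net), info = name)
    expect_equal(vapply(net2$reactions, `[[`, 0, "rate"),
                 vapply(net$reactions, `[[`, 0, "rate"),
                 tolerance = 1e-12, info = name)
    expect_equal(initial_state(net2), initial_state(net),
                 tolerance = 1e-12, info = name)
    expect_identical(net2$time_unit, net$time_unit, info = name)
    # re-emission is byte-identical (fixed point of parse/emit)
    f2 <- tempfile(fileext = ".xml")
    emit_sbml(net2, f2)
    expect_identical(readLines(f2), readLines(f), info = name)
    # emitted files pass validation and never mark reactions reversible
    expect_true(validate_sbml(f)$ok, info = name)
    expect_false(any(grepl('reversible="true"', readLines(f))), info = name)
  }
})

test_that("truncated or garbled XML fails cleanly with no partial network", {
  net <- make_paper_model("F1")
  f <- tempfile(fileext = ".xml")
  emit_sbml(net, f)
  txt <- paste(readLines(f), collapse = "\n")
  fg <- tempfile(fileext = ".xml")
  writeLines(substr(txt, 1, nchar(txt) %/% 2), fg)
  expect_error(parse_sbml(fg), "ill-formed|no <model>")
  expect_error(parse_sbml(tempfile()), "not found")
})

test_that("each unsupported construct triggers exactly its own error code", {
  codes_of <- function(txt) {
    rep <- validate_sbml(write_sbml_string(txt))
    sort(unique(vapply(rep$errors, `[[`, "", "code")))
  }
  # events
  expect_identical(codes_of(sbml_skeleton(
    extra_model = "<listOfEvents><event id='e'/></listOfEvents>")),
    "UNSUPPORTED_EVENT")
  # reversible reaction
  expect_identical(codes_of(sbml_skeleton(reaction_attr = 'reversible="true"')),
                   "REVERSIBLE_REACTION")
  # missing reversible attribute defaults to reversible in SBML L2
  expect_identical(codes_of(sbml_skeleton(reaction_attr = "")),
                   "REVERSIBLE_REACTION")
  # rules
  expect_identical(codes_of(sbml_skeleton(
    extra_model = '<listOfRules><assignmentRule variable="X"/></listOfRules>')),
    "UNSUPPORTED_RULE")
  # constant species
  expect_identical(codes_of(sbml_skeleton(species_attr = 'constant="true"')),
                   "CONSTANT_SPECIES")
  expect_identical(codes_of(sbml_skeleton(species_attr = 'boundaryCondition="true"')),
                   "CONSTANT_SPECIES")
  # multiple compartments
  expect_identical(codes_of(sbml_skeleton(
    compartments = '<compartment id="c" size="1e-15"/><compartment id="c2" size="1e-15"/>')),
    "MULTI_COMPARTMENT")
  # a fully valid document has no errors
  expect_length(validate_sbml(write_sbml_string(sbml_skeleton()))$errors, 0)
})

test_that("kinetic laws are classified as mass action or custom correctly", {
  # Table-style constants are recovered exactly from the emitted MathML
  net <- make_paper_model("F1")
  f <- tempfile(fileext = ".xml")
  emit_sbml(net, f)
  net2 <- parse_sbml(f)
  rates <- stats::setNames(vapply(net2$reactions, `[[`, 0, "rate"),
                           vapply(net2$reactions, `[[`, "", "id"))
  expect_identical(unname(rates[c("input", "bind", "unbind", "cat", "output")]),
                   c(1.8e-5, 5e7, 5, 5, 7))
  expect_true(all(vapply(net2$reactions, `[[`, "", "type") == "mass_action"))
  # a Hill-type law survives as a custom propensity with equal numerics
  netc <- reaction_network(1e-15)
  netc <- add_species(netc, "S", 1e-6)
  netc <- add_reaction(netc, "0 -> S", rate = 1e-6)
  netc <- add_reaction(netc, "S -> 0",
    propensity = quote(3 * S * S / (Omega + S)))
  fc <- tempfile(fileext = ".xml")
  emit_sbml(netc, fc)
  netc2 <- parse_sbml(fc)
  expect_identical(netc2$reactions[[2]]$type, "custom")
  w <- system_size(netc)
  n <- 500
  env <- list(S = n, Omega = w)
  expect_equal(eval(netc2$reactions[[2]]$propensity, env),
               3 * n * n / (w + n))
})
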