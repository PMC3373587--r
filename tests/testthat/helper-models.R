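# Shared fixtures built in code.

uM <- 1e-6

# flux-balance steady state of the substrate-input Michaelis-Menten scheme,
# derived independently of the ODE/Newton machinery
mm_flux_balance <- function(k_in = 1.8e-5, k_out = 7, k1 = 5e7,
                            k_minus1 = 5, k2 = 5, E_T = 4e-6) {
  KM <- (k_minus1 + k2) / k1
  phi_ES <- k_in / k2
  phi_E <- E_T - phi_ES
  c(S = KM * phi_ES / phi_E, E = phi_E, ES = phi_ES, P = k_in / k_out)
}

# minimal SBML documents exercising individual validation rules
sbml_skeleton <- function(extra_model = "", species_attr = "",
                          reaction_attr = 'reversible="false"',
                          compartments = '<compartment id="c" size="1e-15"/>',
                          kinetic_ci = "X") {
  sprintf('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="m">
    <listOfCompartments>%s</listOfCompartments>
    <listOfSpecies>
      <species id="X" compartment="c" initialAmount="10" %s/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="r1" %s>
        <listOfReactants>
          <speciesReference species="X" stoichiometry="1"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><cn>2</cn><ci>%s</ci></apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
    %s
  </model>
</sbml>', compartments, species_attr, reaction_attr, kinetic_ci, extra_model)
}

write_sbml_string <- function(txt) {
  f <- tempfile(fileext = ".xml")
  writeLines(txt, f)
  f
}

expect_close <- function(actual, expected, rel) {
  expect_lt(abs(actual - expected), rel * abs(expected))
}
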