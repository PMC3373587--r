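# Programmatic reconstructions of the classic demonstration models:
# substrate-input Michaelis-Menten kinetics (F1 large volume, F2 small
# volume), a four-subunit cooperative enzyme (F3, F4) and a single-copy
# circadian gene circuit with negative feedback (F5, F6 weak repression,
# F7 strong repression), plus closed-form oracle models.

make_mm_network <- function(volume, E_T = 4e-6, k_in = 1.8e-5, k_out = 7,
                            k1 = 5e7, k_minus1 = 5, k2 = 5) {
  net <- reaction_network(volume, unit = "molar", time_unit = "second",
                          id = "michaelis_menten_input")
  net <- add_species(net, "S", 0)
  net <- add_species(net, "E", E_T)
  net <- add_species(net, "ES", 0)
  net <- add_species(net, "P", 0)
  net <- add_reaction(net, "0 -> S", rate = k_in, id = "input")
  net <- add_reaction(net, "S + E -> ES", rate = k1, id = "bind")
  net <- add_reaction(net, "ES -> S + E", rate = k_minus1, id = "unbind")
  net <- add_reaction(net, "ES -> E + P", rate = k2, id = "cat")
  net <- add_reaction(net, "P -> 0", rate = k_out, id = "output")
  net
}

make_coop_network <- function(volume, E_T = 1e-6) {
  uM <- 1e-6
  k_in <- 9 * uM; k_out <- 10
  kb <- c(1, 10, 100, 1000) / uM      # binding constants, (M s)^-1
  ku <- rep(10, 4)                     # unbinding, s^-1
  kcat <- 10
  net <- reaction_network(volume, unit = "molar", time_unit = "second",
                          id = "cooperative_enzyme")
  net <- add_species(net, "S", 0)
  net <- add_species(net, "E", E_T)
  for (i in 1:4) net <- add_species(net, paste0("ES", i), 0)
  net <- add_species(net, "P", 0)
  net <- add_reaction(net, "0 -> S", rate = k_in, id = "input")
  for (i in 1:4) {
    from <- if (i == 1) "E" else paste0("ES", i - 1)
    to <- paste0("ES", i)
    net <- add_reaction(net, paste("S +", from, "->", to), rate = kb[i],
                        id = paste0("bind", i))
    net <- add_reaction(net, paste(to, "->", "S +", from), rate = ku[i],
                        id = paste0("unbind", i))
    net <- add_reaction(net, paste(to, "->", from, "+ P"), rate = kcat,
                        id = paste0("cat", i))
  }
  net <- add_reaction(net, "P -> 0", rate = k_out, id = "output")
  net
}

# Circadian clock circuit: single gene copy G with two-step cooperative
# repressor binding (G1, G2 repressed states), mRNA M, cytosolic protein Pc,
# nuclear protein Pn, and two Michaelis-Menten degradation enzymes (EM for
# the mRNA, EP for the cytosolic protein).  Rates on the gene (transcription
# and repressor binding/unbinding) are scaled proportionally to the system
# size so that the macroscopic rate equations are volume independent; the
# primed constants are the volume-independent values, in 1/day and
# 1/(uM day).  Time unit: days.
make_clock_network <- function(volume, k1_factor = 1,
                               E_M = 1e-6, E_P = 8e-6) {
  uM <- 1e-6
  w_uM <- volume * AVOGADRO * uM     # molecules per uM
  k_in <- 5; k_out <- 5
  k0p <- 500                          # transcription, 1/day per free gene
  k1p <- 0.5 * k1_factor              # repressor binding, 1/(uM day)
  km1p <- 0.5                         # unbinding, 1/day
  k0 <- w_uM * k0p                    # gene-scaled constants
  k1 <- w_uM * k1p / uM               # (M day)^-1 after unit conversion
  km1 <- w_uM * km1p
  k2 <- 10 * k1; km2 <- km1
  k3 <- 0.5 / uM; km3 <- 0.5; kcat3 <- 0.5
  k4 <- 10 / uM; km4 <- 5; kcat4 <- 10
  ks <- 5; kdm <- 5; kdp <- 5
  net <- reaction_network(volume, unit = "molar", time_unit = "day",
                          id = "circadian_clock")
  net <- add_species(net, "G", 1, kind = "amount")
  net <- add_species(net, "G1", 0, kind = "amount")
  net <- add_species(net, "G2", 0, kind = "amount")
  net <- add_species(net, "M", 0)
  net <- add_species(net, "Pc", 0)
  net <- add_species(net, "Pn", 0)
  net <- add_species(net, "EM", E_M)
  net <- add_species(net, "CM", 0)
  net <- add_species(net, "EP", E_P)
  net <- add_species(net, "CP", 0)
  net <- add_reaction(net, "G -> G + M", rate = k0, id = "transcribe")
  net <- add_reaction(net, "M -> M + Pc", rate = ks, id = "translate")
  net <- add_reaction(net, "M -> 0", rate = kdm, id = "mrna_decay")
  net <- add_reaction(net, "Pc -> 0", rate = kdp, id = "protein_use")
  net <- add_reaction(net, "Pc -> Pn", rate = k_in, id = "import")
  net <- add_reaction(net, "Pn -> Pc", rate = k_out, id = "export")
  net <- add_reaction(net, "G + Pn -> G1", rate = k1, id = "repress1")
  net <- add_reaction(net, "G1 -> G + Pn", rate = km1, id = "derepress1")
  net <- add_reaction(net, "G1 + Pn -> G2", rate = k2, id = "repress2")
  net <- add_reaction(net, "G2 -> G1 + Pn", rate = km2, id = "derepress2")
  net <- add_reaction(net, "EM + M -> CM", rate = k3, id = "mdeg_bind")
  net <- add_reaction(net, "CM -> EM + M", rate = km3, id = "mdeg_unbind")
  net <- add_reaction(net, "CM -> EM", rate = kcat3, id = "mdeg_cat")
  net <- add_reaction(net, "EP + Pc -> CP", rate = k4, id = "pdeg_bind")
  net <- add_reaction(net, "CP -> EP + Pc", rate = km4, id = "pdeg_unbind")
  net <- add_reaction(net, "CP -> EP", rate = kcat4, id = "pdeg_cat")
  net
}

#' Built-in example models
#'
#' Reconstructs the seven demonstration models from their printed rate
#' constant tables, plus small closed-form oracle models:
#'
#' * `F1`/`F2`: substrate-input Michaelis-Menten kinetics (substrate input,
#'   enzyme binding/unbinding, catalysis, product removal), total enzyme
#'   4 uM, in 5e-16 l (about 1200 enzyme copies) and 1e-17 l (24 copies).
#' * `F3`/`F4`: four-subunit cooperative enzyme with substrate input and
#'   product removal, total enzyme 1 uM, in 1e-15 l (about 600 copies)
#'   and 1e-16 l (60 copies).
#' * `F5`/`F6`/`F7`: single-copy circadian clock gene with two-step
#'   cooperative repression by its nuclear protein, linear and enzymatic
#'   mRNA/protein turnover, in 2 fl (`F5`) and 0.2 fl (`F6`, `F7`); `F7`
#'   has the repressor binding constant multiplied by 100.  Time unit is
#'   days.
#' * `birth_death`: `0 -> X -> 0`, the exactly solvable Poisson oracle
#'   (see [make_birth_death()]).
#' * `dimerization`: input plus dimerization decay `2X -> 0`, the minimal
#'   model with a non-vanishing EMRE correction.
#' * `linear_chain`: a three-species unimolecular cascade (EMRE equals RE
#'   exactly).
#'
#' @param name Model name (see above).
#' @param volume Optional volume override in litres.
#' @param overrides Named list of parameter overrides passed to the
#'   underlying constructor (e.g. `E_T`, `k_in`).
#' @return A [reaction_network()].
#' @examples
#' make_paper_model("F2")
#' @export
make_paper_model <- function(name, volume = NULL, overrides = list()) {
  build <- function(fn, vol, ...) {
    args <- c(list(volume = if (is.null(volume)) vol else volume),
              overrides, list(...))
    args <- args[!duplicated(names(args))]
    do.call(fn, args)
  }
  net <- switch(name,
    F1 = build(make_mm_network, 5e-16),
    F2 = build(make_mm_network, 1e-17),
    F3 = build(make_coop_network, 1e-15),
    F4 = build(make_coop_network, 1e-16),
    F5 = build(make_clock_network, 2e-15, k1_factor = 1),
    F6 = build(make_clock_network, 2e-16, k1_factor = 1),
    F7 = build(make_clock_network, 2e-16, k1_factor = 100),
    birth_death = build(make_birth_death_vol, 1e-15),
    dimerization = build(make_dimerization, 1e-15),
    linear_chain = build(make_linear_chain, 1e-15),
    stop("unknown model name: ", name)
  )
  net$id <- name
  net
}

#' Birth-death oracle model
#'
#' `0 -> X` at concentration rate `k_in` and `X -> 0` at rate `k_out`.
#' The stationary copy-number law is exactly Poisson with mean
#' `k_in * omega / k_out`, giving closed-form oracles for the rate
#' equations (`phi_ss = k_in / k_out`), the LNA (variance equals mean) and
#' the EMRE (no correction).
#'
#' @param k_in Input rate (concentration per time).
#' @param k_out Decay rate constant (1/time).
#' @param volume Compartment volume in litres.
#' @return A [reaction_network()].
#' @export
make_birth_death <- function(k_in = 1e-6, k_out = 1, volume = 1e-15) {
  stopifnot(k_in > 0, k_out > 0)
  net <- reaction_network(volume, unit = "molar", time_unit = "second",
                          id = "birth_death")
  net <- add_species(net, "X", 0)
  net <- add_reaction(net, "0 -> X", rate = k_in, id = "birth")
  net <- add_reaction(net, "X -> 0", rate = k_out, id = "death")
  net
}

make_birth_death_vol <- function(volume, k_in = 1e-6, k_out = 1)
  make_birth_death(k_in, k_out, volume)

make_dimerization <- function(volume, k_in = 1e-6, k_dim = 1e6) {
  net <- reaction_network(volume, unit = "molar", time_unit = "second",
                          id = "dimerization")
  net <- add_species(net, "X", 0)
  net <- add_reaction(net, "0 -> X", rate = k_in, id = "input")
  net <- add_reaction(net, "2 X -> 0", rate = k_dim, id = "dimerize")
  net
}

make_linear_chain <- function(volume, k_in = 1e-6, k = 1) {
  net <- reaction_network(volume, unit = "molar", time_unit = "second",
                          id = "linear_chain")
  net <- add_species(net, "X1", 0)
  net <- add_species(net, "X2", 0)
  net <- add_species(net, "X3", 0)
  net <- add_reaction(net, "0 -> X1", rate = k_in)
  net <- add_reaction(net, "X1 -> X2", rate = k)
  net <- add_reaction(net, "X2 -> X3", rate = 2 * k)
  net <- add_reaction(net, "X3 -> 0", rate = 0.5 * k)
  net
}
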