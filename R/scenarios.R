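## Programmatic builders for the four reference scenarios.  All parameters
## follow the published synthesis table: initial amounts per 100 g_C of
## system carbon for the batch scenarios (reference_mass = 100), absolute
## areal densities (g_C/cm2, reference_mass = 1) for the steady-state
## scenario, whose enzymatic rates are the laboratory values divided by 5.

lab_tau0 <- c(cellulolysis = 1.8, lignolysis = 1, lipidolysis = 0.8,
              proteolysis = 1.8, mic_sugar_lysis = 1.8)
enz_alpha <- c(cellulolysis = 5, lignolysis = 7, lipidolysis = 1.5,
               proteolysis = 5.5, mic_sugar_lysis = 5)
enz_target_class <- c(cellulolysis = "plant_sugar", lignolysis = "lignin",
                      lipidolysis = "lipid", proteolysis = "protein",
                      mic_sugar_lysis = "mic_sugar")
mic_signature <- c(mic_sugar = 0.5, lipid = 0.3, protein = 0.2)

#' Scenario 1: cellulose decomposition
#'
#' A single fully accessible cellulose (plant sugar) pool of 95 g_C is
#' degraded by one plant-decomposer community (5 g_C) producing cellulolytic
#' enzymes (exo-cleaving, `alpha = 5`).  No recycling: necromass leaves the
#' tracked substrate as residues.  Horizon one year.
#'
#' @return a [cstability_config()].
#' @export
scenario_cellulose <- function() {
  cstability_config(
    name = "cellulose",
    classes = list(substrate_class("plant_sugar", accessible = 95)),
    communities = list(
      microbial_community("plant_decomposer", biomass = 5, e0 = 0.4,
                          m0 = 0.02, u0 = c(plant_sugar = 5))),
    enzymes = list(
      enzyme_family("cellulolysis", "plant_sugar", tau0 = 1.8, alpha = 5,
                    producers = c(plant_decomposer = 1))),
    reference_mass = 100,
    solver = list(dt = 0.1, t_end = 365, output_every = 1)
  )
}

#' Scenario 2: lignocellulose with enzyme-gated accessibility
#'
#' 125 g_C of lignocellulose (76% cellulose, 24% lignin).  All cellulose
#' starts in the enzyme-inaccessible pool, embedded in lignin; lignolytic
#' activity (endo/exo mixture, `alpha = 7`, slow rate) progressively
#' transfers it to the accessible pool through a [gated_transfer()] with
#' coefficient 13 /g_C.  One community degrades and takes up both plant
#' classes.
#'
#' @return a [cstability_config()].
#' @export
scenario_lignocellulose <- function() {
  cstability_config(
    name = "lignocellulose",
    classes = list(
      substrate_class("plant_sugar", inaccessible = 0.76 * 125,
                      to_accessible = gated_transfer(13, "lignolysis")),
      substrate_class("lignin", accessible = 0.24 * 125)),
    communities = list(
      microbial_community("plant_decomposer", biomass = 5, e0 = 0.4,
                          m0 = 0.02, u0 = c(plant_sugar = 5, lignin = 5))),
    enzymes = list(
      enzyme_family("cellulolysis", "plant_sugar", tau0 = 1.8, alpha = 5,
                    producers = c(plant_decomposer = 1)),
      enzyme_family("lignolysis", "lignin", tau0 = 1, alpha = 7,
                    producers = c(plant_decomposer = 1))),
    reference_mass = 100,
    solver = list(dt = 0.1, t_end = 365, output_every = 1)
  )
}

#' Scenario 3: succession of two communities on lignocellulose
#'
#' The 76/24 lignocellulose substrate decomposed by two communities of
#' 5 g_C each with microbial recycling; both plant classes start fully
#' enzyme-accessible.  Plant decomposers
#' (e0 = 0.4, m0 = 0.02) produce the cellulolytic and lignolytic enzymes
#' and take up plant-derived oligomers; microbial-residue decomposers
#' (e0 = 0.5, m0 = 0.01) produce lipid-, protein- and microbial-sugar-
#' degrading enzymes and feed on necromass.  Both share the necromass
#' signature 50% microbial sugar, 30% lipid, 20% protein.  With
#' `cheating = FALSE` cross-feeding uptake rates are zero; with
#' `cheating = TRUE` the community not producing the enzymes still takes
#' up the released fragments at rate `u0 = 3`.
#'
#' @param cheating logical; cross-feeding uptake allowed?
#' @param t_end horizon (d), default 1500.
#' @return a [cstability_config()].
#' @export
scenario_succession <- function(cheating = FALSE, t_end = 1500) {
  u_cheat <- if (cheating) 3 else 0
  cstability_config(
    name = if (cheating) "succession_cheating" else "succession",
    classes = list(
      substrate_class("plant_sugar", accessible = 0.76 * 125),
      substrate_class("lignin", accessible = 0.24 * 125),
      substrate_class("mic_sugar"),
      substrate_class("lipid"),
      substrate_class("protein")),
    communities = list(
      microbial_community(
        "plant_decomposer", biomass = 5, e0 = 0.4, m0 = 0.02,
        u0 = c(plant_sugar = 5, lignin = 5, mic_sugar = u_cheat,
               lipid = u_cheat, protein = u_cheat),
        signature = mic_signature),
      microbial_community(
        "mic_decomposer", biomass = 5, e0 = 0.5, m0 = 0.01,
        u0 = c(plant_sugar = u_cheat, lignin = u_cheat, mic_sugar = 5,
               lipid = 5, protein = 5),
        signature = mic_signature)),
    enzymes = list(
      enzyme_family("cellulolysis", "plant_sugar", tau0 = 1.8, alpha = 5,
                    producers = c(plant_decomposer = 1)),
      enzyme_family("lignolysis", "lignin", tau0 = 1, alpha = 7,
                    producers = c(plant_decomposer = 1)),
      enzyme_family("lipidolysis", "lipid", tau0 = 0.8, alpha = 1.5,
                    producers = c(mic_decomposer = 1)),
      enzyme_family("proteolysis", "protein", tau0 = 1.8, alpha = 5.5,
                    producers = c(mic_decomposer = 1)),
      enzyme_family("mic_sugar_lysis", "mic_sugar", tau0 = 1.8, alpha = 5,
                    producers = c(mic_decomposer = 1))),
    reference_mass = 100,
    solver = list(dt = 0.1, t_end = t_end, output_every = 1)
  )
}

#' Scenario 4: soil organic matter under constant input
#'
#' One general decomposer community, constant plant input
#' `I = 2.74e-4` g_C/cm2/d split 76% plant sugar / 24% lignin with the
#' standard profile, full recycling through the 50/30/20 necromass
#' signature, all pools accessible.  Enzymatic rates are the laboratory
#' values divided by 5 to represent in-situ conditions.  Masses are areal
#' densities (g_C/cm2, `reference_mass = 1`).  This configuration has a
#' closed-form steady state, see [steady_state()].
#'
#' The builder's initial biomass is the steady-state value
#' `e0 I / ((1 - e0) m0)`; initial substrate pools are empty, so dynamic
#' runs spin up toward the steady distributions.
#'
#' @param t_end horizon (d) for dynamic runs, default 2000.
#' @return a [cstability_config()].
#' @export
scenario_steady_state <- function(t_end = 2000) {
  I <- 2.74e-4
  cstability_config(
    name = "steady_state",
    classes = list(
      substrate_class("plant_sugar", input_accessible = 0.76 * I),
      substrate_class("lignin", input_accessible = 0.24 * I),
      substrate_class("mic_sugar"),
      substrate_class("lipid"),
      substrate_class("protein")),
    communities = list(
      microbial_community(
        "general_decomposer", biomass = 0.4 * I / (0.6 * 0.02),
        e0 = 0.4, m0 = 0.02,
        u0 = c(plant_sugar = 5, lignin = 5, mic_sugar = 5, lipid = 5,
               protein = 5),
        signature = mic_signature)),
    enzymes = lapply(names(lab_tau0), function(e) {
      enzyme_family(e, enz_target_class[[e]], tau0 = lab_tau0[[e]] / 5,
                    alpha = enz_alpha[[e]],
                    producers = c(general_decomposer = 1))
    }),
    reference_mass = 1,
    solver = list(dt = 0.5, t_end = t_end, output_every = 50)
  )
}
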