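#' Named experimental scenario configs
#'
#' The photoheterotrophic condition ladder used throughout the package's
#' analyses of growth on acetate, expressed as declarative configs: fixed
#' acetate uptake at the measured 1.96 mmol/gDW/h, CO2 export pinned at the
#' measured 0.23 mmol/gDW/h, a CBB (RuBisCO) knockout, the fitted light cap
#' of 36.6 mmol/gDW/h, maximum H2 production, a blocked succinate
#' (reduced-byproduct) export, closed proton uptake, and nitrogen-starved PHB
#' production. Scenarios name reactions by *role*; a name map resolves roles
#' to the ids of whatever model is in use, so the same configs apply to the
#' bundled toy phototroph or to a genome-scale SBML model.
#'
#' @return A named list of scenario configs (lists with `label`,
#'   `description`, `uptake_fixed`, `uptake_cap`, `export_fixed`, `blocks`,
#'   `knockouts`, `objective_role`).
#' @export
paper_scenarios <- function() {
  sc <- list(
    growth_archetype = list(
      label = "A",
      description = "Growth archetype: acetate uptake fixed at 1.96, unlimited photons",
      uptake_fixed = c(acetate_exchange = 1.96),
      uptake_cap = c(photon_exchange = Inf),
      export_fixed = NULL, blocks = NULL, knockouts = NULL,
      objective_role = "biomass"
    ),
    co2_pinned = list(
      label = "B",
      description = "CO2 export pinned at the measured 0.23, unlimited light",
      uptake_fixed = c(acetate_exchange = 1.96),
      uptake_cap = c(photon_exchange = Inf),
      export_fixed = c(co2_exchange = 0.23),
      blocks = NULL, knockouts = NULL,
      objective_role = "biomass"
    ),
    cbb_off = list(
      label = "C",
      description = "CBB inactivated (RuBisCO flux fixed to zero), unlimited light",
      uptake_fixed = c(acetate_exchange = 1.96),
      uptake_cap = c(photon_exchange = Inf),
      export_fixed = NULL, blocks = NULL,
      knockouts = "rubisco",
      objective_role = "biomass"
    ),
    light_limited = list(
      label = "D",
      description = "Fitted light cap 36.6 with acetate fixed and CO2 export pinned",
      uptake_fixed = c(acetate_exchange = 1.96),
      uptake_cap = c(photon_exchange = 36.6),
      export_fixed = c(co2_exchange = 0.23),
      blocks = NULL, knockouts = NULL,
      objective_role = "biomass"
    ),
    succinate_blocked = list(
      label = "F",
      description = "Reduced-byproduct (succinate) export blocked under the light-limited condition",
      uptake_fixed = c(acetate_exchange = 1.96),
      uptake_cap = c(photon_exchange = 36.6),
      export_fixed = c(co2_exchange = 0.23),
      blocks = "byproduct_exchange",
      knockouts = NULL,
      objective_role = "biomass"
    ),
    h2_max = list(
      label = "G",
      description = "Maximum theoretical H2 production (growth left free, expected to cease)",
      uptake_fixed = c(acetate_exchange = 1.96),
      uptake_cap = c(photon_exchange = Inf),
      export_fixed = NULL, blocks = NULL, knockouts = NULL,
      objective_role = "h2_exchange"
    ),
    no_proton_uptake = list(
      label = "H+",
      description = "Proton uptake closed: electron acceptors must be organic exports",
      uptake_fixed = c(acetate_exchange = 1.96),
      uptake_cap = c(photon_exchange = 36.6, proton_exchange = 0),
      export_fixed = NULL, blocks = NULL, knockouts = NULL,
      objective_role = "biomass"
    ),
    n_starved_phb = list(
      label = "PHB",
      description = "Nitrogen starvation with PHB-subunit (C4H6O2) export as the objective",
      uptake_fixed = c(acetate_exchange = 1.96),
      uptake_cap = c(photon_exchange = 36.6, ammonium_exchange = 0),
      export_fixed = NULL, blocks = NULL, knockouts = NULL,
      objective_role = "phb_exchange"
    )
  )
  sc
}

#' Role-to-id name map for the toy phototroph
#'
#' @return Named character vector mapping scenario roles to toy reaction ids.
#' @export
toy_name_map <- function() {
  c(acetate_exchange = "EX_ac",
    photon_exchange = "EX_photon",
    co2_exchange = "EX_co2",
    h2_exchange = "EX_h2",
    byproduct_exchange = "EX_byp",
    rubisco = "FIX_A",
    biomass = "BIOSYN")
}

#' Apply a scenario config to a model
#'
#' Resolves the scenario's roles through `name_map` and returns the
#' constrained model plus the scenario objective. Roles missing from the map
#' (or ids missing from the model) cause the affected setting to be skipped
#' with a warning, so a scenario written for a genome-scale model degrades
#' gracefully on the toy and vice versa.
#'
#' @param model A `stoich_model`.
#' @param scenario One element of [paper_scenarios()].
#' @param name_map Named character vector role -> reaction id (e.g.
#'   [toy_name_map()]).
#' @return List: `model` (constrained), `objective` (a `flux_objective`),
#'   `skipped` (character vector of unresolved roles).
#' @export
apply_scenario <- function(model, scenario, name_map = toy_name_map()) {
  skipped <- character(0)
  resolve <- function(role) {
    id <- unname(name_map[role])
    if (is.na(id) || !id %in% model$reactions$id) {
      skipped <<- c(skipped, role)
      return(NA_character_)
    }
    id
  }
  for (role in names(scenario$uptake_fixed)) {
    id <- resolve(role)
    if (is.na(id)) next
    u <- scenario$uptake_fixed[[role]]
    model <- set_reaction_bounds(model, id, lower = -u, upper = -u)
  }
  for (role in names(scenario$uptake_cap)) {
    id <- resolve(role)
    if (is.na(id)) next
    u <- min(scenario$uptake_cap[[role]], pf_big())
    model <- set_reaction_bounds(model, id, lower = -u)
  }
  for (role in names(scenario$export_fixed)) {
    id <- resolve(role)
    if (is.na(id)) next
    v <- scenario$export_fixed[[role]]
    model <- set_reaction_bounds(model, id, lower = v, upper = v)
  }
  for (role in scenario$blocks) {
    id <- resolve(role)
    if (is.na(id)) next
    model <- set_reaction_bounds(model, id, lower = 0, upper = 0)
  }
  for (role in scenario$knockouts) {
    id <- resolve(role)
    if (is.na(id)) next
    model <- set_reaction_bounds(model, id, lower = 0, upper = 0)
  }
  obj_id <- resolve(scenario$objective_role)
  objective <- if (!is.na(obj_id)) {
    if (identical(scenario$objective_role, "biomass") &&
        !is.null(model$biomass_reaction_id)) {
      biomass_objective(model)
    } else {
      reaction_objective(obj_id, "max", scenario$objective_role)
    }
  } else NULL
  if (length(skipped)) {
    warning("scenario '", scenario$label, "': unresolved role(s) skipped: ",
            paste(unique(skipped), collapse = ", "))
  }
  list(model = model, objective = objective, skipped = unique(skipped))
}
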