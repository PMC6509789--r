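#' Model reaction balance checking
#'
#' Checks element and charge conservation of each internal reaction using the
#' metabolite formulas. Exchange reactions are boundary conversions and are
#' skipped by design; metabolites without formulas are skipped inside a
#' reaction (a pseudo-species like a photon has no elemental content), and a
#' reaction where *no* participant carries a formula is reported as
#' `unchecked` rather than failed.
#'
#' @param model A `stoich_model` with formulas on (some) metabolites.
#' @param reactions Reaction ids to check (default: all).
#' @param tol Absolute residual tolerance (default 1e-6, suited to exact model
#'   stoichiometries; use 0.02 for rounded lumped equations).
#' @param include_charge Should charge enter the verdict (where charges are
#'   known)?
#' @return Tibble: `reaction`, `status` (`balanced`, `unbalanced`, `boundary`,
#'   `unchecked`), `max_residual`, `worst_element`, `skipped_species`
#'   (comma-separated ids without formulas).
#' @export
check_reaction_balance <- function(model, reactions = NULL, tol = 1e-6,
                                   include_charge = FALSE) {
  reactions <- reactions %||% model$reactions$id
  bad <- setdiff(reactions, model$reactions$id)
  if (length(bad)) stop("unknown reaction id(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  met_formula <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  met_charge <- stats::setNames(model$metabolites$charge, model$metabolites$id)
  rows <- purrr::map(reactions, function(rid) {
    if (model$reactions$is_exchange[match(rid, model$reactions$id)]) {
      return(tibble::tibble(reaction = rid, status = "boundary",
                            max_residual = NA_real_, worst_element = NA_character_,
                            skipped_species = NA_character_))
    }
    col <- model$S[, rid]
    mets <- names(col)[col != 0]
    have <- mets[!is.na(met_formula[mets])]
    skipped <- setdiff(mets, have)
    if (length(have) == 0) {
      return(tibble::tibble(reaction = rid, status = "unchecked",
                            max_residual = NA_real_, worst_element = NA_character_,
                            skipped_species = paste(skipped, collapse = ",")))
    }
    resid <- numeric(0)
    charge_resid <- 0
    charge_known <- TRUE
    for (m in have) {
      f <- parse_formula(met_formula[[m]])
      k <- col[[m]]
      for (el in names(f$counts)) {
        resid[el] <- (if (el %in% names(resid)) resid[el] else 0) + k * f$counts[[el]]
      }
      chg <- if (!is.na(met_charge[[m]])) met_charge[[m]] else f$charge
      if (is.na(chg)) charge_known <- FALSE else charge_resid <- charge_resid + k * chg
    }
    vals <- resid
    if (include_charge && charge_known) vals <- c(vals, charge = charge_resid)
    worst <- names(vals)[which.max(abs(vals))]
    tibble::tibble(
      reaction = rid,
      status = if (max(abs(vals)) <= tol) "balanced" else "unbalanced",
      max_residual = max(abs(vals)),
      worst_element = worst,
      skipped_species = if (length(skipped)) paste(skipped, collapse = ",") else NA_character_
    )
  })
  dplyr::bind_rows(rows)
}

metabolite_electrons <- function(model, met_id) {
  i <- match(met_id, model$metabolites$id)
  e_over <- model$metabolites$electrons[i]
  if (!is.na(e_over)) return(e_over)
  f <- model$metabolites$formula[i]
  if (is.na(f)) return(NA_real_)
  fo <- parse_formula(f)
  chg <- model$metabolites$charge[i]
  if (!is.na(chg)) fo$charge <- chg
  electron_content(fo)
}

#' Boundary electron balance of a flux solution
#'
#' Sums the electron flow across all exchange reactions: for each active
#' exchange, the electron content of its metabolite (Roels convention —
#' kappa times C-moles for organics, 2 per H2, 0 for CO2 and H2O) times the
#' exchange flux. For any steady-state solution of a fully balanced model the
#' sum is zero: electrons in (e.g. acetate, kappa = 4) exactly cover electrons
#' out (biomass, H2, reduced byproducts).
#'
#' @param model A `stoich_model`.
#' @param solution A `flux_solution` (or named flux vector).
#' @param zero_tol Fluxes below this are treated as inactive.
#' @return The net boundary electron flow (electron-equivalents mmol/gDW/h);
#'   near zero for balanced models.
#' @export
boundary_electron_balance <- function(model, solution, zero_tol = 1e-9) {
  v <- if (inherits(solution, "flux_solution")) fluxes(solution) else solution
  ex <- exchange_reactions(model)
  total <- 0
  missing_f <- character(0)
  for (rid in ex) {
    flux <- v[[rid]]
    if (is.na(flux) || abs(flux) <= zero_tol) next
    met <- exchange_metabolite(model, rid)
    e <- metabolite_electrons(model, met)
    if (is.na(e)) {
      missing_f <- c(missing_f, met)
      next
    }
    # S[met, rid] is -1 by convention (positive flux = export)
    coef <- model$S[met, rid]
    total <- total + e * (-coef) * flux
  }
  if (length(missing_f)) {
    stop("no formula or electron content for active exchange metabolite(s): ",
         paste(unique(missing_f), collapse = ", "), call. = FALSE)
  }
  total
}
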