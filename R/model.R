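#' Stoichiometric model container
#'
#' A `stoich_model` holds the metabolite and reaction tables of a
#' constraint-based metabolic model together with its stoichiometric matrix
#' `S` (m metabolites by n reactions). Metabolites and reactions are tibbles,
#' so the usual dplyr verbs apply to them directly; the model object itself is
#' a classed list, like `phylo` in ape.
#'
#' @name stoich_model-class
NULL

# Finite stand-in for "unlimited" bounds; keeps every LP bounded.
PF_BIG <- 1e6

pf_big <- function() PF_BIG

#' Construct a stoichiometric model
#'
#' @param metabolites Tibble with columns `id` (unique), and optionally `name`,
#'   `compartment`, `formula` (Hill string or `NA`), `charge`, `is_external`,
#'   `electrons` (override of formula-derived electron content, e.g. 0 for a
#'   photon pseudo-metabolite).
#' @param reactions Tibble with columns `id` (unique), `lower`, `upper`
#'   (mmol/gDW/h), and optionally `name`, `gpr`, `is_exchange`.
#' @param stoichiometry Long tibble with columns `reaction`, `metabolite`,
#'   `coefficient` (negative = consumed).
#' @param biomass Reaction id of the biomass (growth) reaction, or `NULL`.
#' @param maintenance Reaction id of the non-growth-associated maintenance ATP
#'   reaction, or `NULL`.
#' @return A `stoich_model`.
#' @export
stoich_model <- function(metabolites, reactions, stoichiometry,
                         biomass = NULL, maintenance = NULL) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  stoichiometry <- tibble::as_tibble(stoichiometry)

  defaults_m <- list(name = NA_character_, compartment = "c",
                     formula = NA_character_, charge = NA_real_,
                     is_external = FALSE, electrons = NA_real_)
  for (col in names(defaults_m)) {
    if (!col %in% names(metabolites)) metabolites[[col]] <- defaults_m[[col]]
  }
  defaults_r <- list(name = NA_character_, gpr = NA_character_,
                     is_exchange = NA)
  for (col in names(defaults_r)) {
    if (!col %in% names(reactions)) reactions[[col]] <- defaults_r[[col]]
  }

  S <- matrix(0, nrow(metabolites), nrow(reactions),
              dimnames = list(metabolites$id, reactions$id))
  bad_m <- setdiff(stoichiometry$metabolite, metabolites$id)
  bad_r <- setdiff(stoichiometry$reaction, reactions$id)
  if (length(bad_m)) stop("stoichiometry references unknown metabolites: ",
                          paste(bad_m, collapse = ", "), call. = FALSE)
  if (length(bad_r)) stop("stoichiometry references unknown reactions: ",
                          paste(bad_r, collapse = ", "), call. = FALSE)
  S[cbind(stoichiometry$metabolite, stoichiometry$reaction)] <- stoichiometry$coefficient

  # auto-flag exchanges: reactions touching exactly one metabolite
  n_touch <- colSums(S != 0)
  reactions$is_exchange <- ifelse(is.na(reactions$is_exchange),
                                  n_touch[reactions$id] == 1L,
                                  reactions$is_exchange)

  genes <- unique(unlist(lapply(reactions$gpr, gpr_genes)))

  model <- structure(
    list(metabolites = metabolites, reactions = reactions, S = S,
         genes = genes, biomass_reaction_id = biomass,
         maintenance_atp_reaction_id = maintenance),
    class = "stoich_model"
  )
  validate_model(model)
  model
}

#' Validate a stoichiometric model
#'
#' Checks id uniqueness, ordered bounds, non-empty reaction stoichiometries,
#' and that exchange reactions touch exactly one metabolite.
#'
#' @param model A `stoich_model`.
#' @return The model, invisibly; errors describe every violation found.
#' @export
validate_model <- function(model) {
  errs <- character(0)
  if (anyDuplicated(model$metabolites$id)) {
    errs <- c(errs, paste("duplicate metabolite ids:",
      paste(unique(model$metabolites$id[duplicated(model$metabolites$id)]), collapse = ", ")))
  }
  if (anyDuplicated(model$reactions$id)) {
    errs <- c(errs, paste("duplicate reaction ids:",
      paste(unique(model$reactions$id[duplicated(model$reactions$id)]), collapse = ", ")))
  }
  bad_bounds <- model$reactions$id[model$reactions$lower > model$reactions$upper]
  if (length(bad_bounds)) {
    errs <- c(errs, paste("lower > upper for:", paste(bad_bounds, collapse = ", ")))
  }
  n_touch <- colSums(model$S != 0)
  empty <- names(n_touch)[n_touch == 0]
  if (length(empty)) {
    errs <- c(errs, paste("reactions with empty stoichiometry:",
                          paste(empty, collapse = ", ")))
  }
  exch <- model$reactions$id[model$reactions$is_exchange]
  bad_exch <- exch[n_touch[exch] != 1L]
  if (length(bad_exch)) {
    errs <- c(errs, paste("exchange reactions touching != 1 metabolite:",
                          paste(bad_exch, collapse = ", ")))
  }
  if (!is.null(model$biomass_reaction_id) &&
      !model$biomass_reaction_id %in% model$reactions$id) {
    errs <- c(errs, paste("biomass reaction not in model:", model$biomass_reaction_id))
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)
  invisible(model)
}

#' @export
print.stoich_model <- function(x, ...) {
  cat(sprintf("<stoich_model> %d metabolites x %d reactions (%d exchanges, %d genes)\n",
              nrow(x$metabolites), nrow(x$reactions),
              sum(x$reactions$is_exchange), length(x$genes)))
  if (!is.null(x$biomass_reaction_id)) {
    cat("  biomass reaction:", x$biomass_reaction_id, "\n")
  }
  invisible(x)
}

#' Exchange reaction ids of a model
#' @param model A `stoich_model`.
#' @return Character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  model$reactions$id[model$reactions$is_exchange]
}

#' The single metabolite touched by an exchange reaction
#' @keywords internal
exchange_metabolite <- function(model, reaction_id) {
  col <- model$S[, reaction_id]
  names(col)[col != 0]
}

reaction_bounds <- function(model) {
  list(lower = stats::setNames(model$reactions$lower, model$reactions$id),
       upper = stats::setNames(model$reactions$upper, model$reactions$id))
}

set_reaction_bounds <- function(model, id, lower = NULL, upper = NULL) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction id(s): ",
                     paste(id[is.na(i)], collapse = ", "), call. = FALSE)
  if (!is.null(lower)) model$reactions$lower[i] <- lower
  if (!is.null(upper)) model$reactions$upper[i] <- upper
  model
}

#' Stoichiometry in long (tidy) form
#'
#' @param model A `stoich_model`.
#' @return Tibble with `reaction`, `metabolite`, `coefficient`.
#' @export
stoichiometry_tbl <- function(model) {
  idx <- which(model$S != 0, arr.ind = TRUE)
  tibble::tibble(
    reaction = colnames(model$S)[idx[, 2]],
    metabolite = rownames(model$S)[idx[, 1]],
    coefficient = model$S[idx]
  ) |> dplyr::arrange(.data$reaction, .data$metabolite)
}
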