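#' Growth-medium configuration
#'
#' A medium config maps exchange reactions to flux bounds. Internally, uptake
#' is a negative exchange flux, so a config entry `uptake_max: 1.96` becomes a
#' lower bound of -1.96 on the exchange; this lets measured uptake rates be
#' entered with their published (positive) sign.
#'
#' Recognised keys per exchange: `uptake_max`, `uptake_fixed`, `export_max`,
#' `export_fixed`, `lower`, `upper`. The string `"unlimited"` maps to the
#' internal finite cap (1e6 mmol/gDW/h).
#'
#' @name medium
NULL

medium_value <- function(x) {
  if (is.character(x) && identical(tolower(x), "unlimited")) return(pf_big())
  as.numeric(x)
}

#' Read a medium config from YAML
#'
#' Expected layout:
#' ```yaml
#' exchanges:
#'   EX_ac:     {uptake_max: 1.96}
#'   EX_photon: {uptake_max: unlimited}
#'   EX_co2:    {export_fixed: 0.23}
#' ```
#'
#' @param path YAML file path.
#' @return A tibble with columns `reaction`, `lower`, `upper` of class
#'   `medium_config`.
#' @export
read_medium <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$exchanges)) stop("medium YAML must have an 'exchanges' map",
                                   call. = FALSE)
  medium_config(cfg$exchanges)
}

#' Build a medium config from a named list
#'
#' @param entries Named list: exchange reaction id -> list of bound keys (see
#'   [medium]).
#' @return Tibble (`reaction`, `lower`, `upper`) of class `medium_config`.
#' @export
medium_config <- function(entries) {
  rows <- purrr::imap(entries, function(e, id) {
    lower <- NA_real_
    upper <- NA_real_
    if (!is.null(e$lower)) lower <- medium_value(e$lower)
    if (!is.null(e$upper)) upper <- medium_value(e$upper)
    if (!is.null(e$uptake_max)) lower <- -medium_value(e$uptake_max)
    if (!is.null(e$export_max)) upper <- medium_value(e$export_max)
    if (!is.null(e$uptake_fixed)) lower <- upper <- -medium_value(e$uptake_fixed)
    if (!is.null(e$export_fixed)) lower <- upper <- medium_value(e$export_fixed)
    tibble::tibble(reaction = id, lower = lower, upper = upper)
  })
  empty <- tibble::tibble(reaction = character(0), lower = numeric(0),
                          upper = numeric(0))
  out <- dplyr::bind_rows(c(list(empty), rows))
  bad <- out$reaction[!is.na(out$lower) & !is.na(out$upper) & out$lower > out$upper]
  if (length(bad)) stop("medium bounds out of order for: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  class(out) <- c("medium_config", class(out))
  out
}

#' Apply a medium to a model
#'
#' Exchange bounds listed in the medium replace the model's; every exchange
#' *not* listed is closed to uptake (lower bound 0) but left open to export.
#' An `NA` bound in the medium keeps the model's existing value for that side.
#'
#' @param model A `stoich_model`.
#' @param medium A `medium_config` (or tibble with `reaction`, `lower`,
#'   `upper`). An empty tibble closes all uptakes.
#' @return The model with updated exchange bounds.
#' @export
apply_medium <- function(model, medium) {
  medium <- tibble::as_tibble(medium)
  exch <- exchange_reactions(model)
  bad <- setdiff(medium$reaction, exch)
  if (length(bad)) stop("medium entries are not exchange reactions: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  # close uptake on unlisted exchanges
  unlisted <- setdiff(exch, medium$reaction)
  model <- set_reaction_bounds(model, unlisted,
                               lower = pmax(0, model$reactions$lower[match(unlisted, model$reactions$id)]))
  for (i in seq_len(nrow(medium))) {
    id <- medium$reaction[i]
    j <- match(id, model$reactions$id)
    lo <- if (is.na(medium$lower[i])) model$reactions$lower[j] else medium$lower[i]
    hi <- if (is.na(medium$upper[i])) model$reactions$upper[j] else medium$upper[i]
    model <- set_reaction_bounds(model, id, lower = lo, upper = hi)
  }
  validate_model(model)
  model
}
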