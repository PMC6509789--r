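#' Tabular model dialect
#'
#' A plain-TSV representation of a stoichiometric model, convenient for
#' fixtures and hand-built networks. The reaction table has columns
#' `reaction_id`, `equation`, `lower`, `upper`, `gpr`; equations use metabolite
#' ids with optional numeric coefficients, e.g. `"ac + atp -> c + 2 red"`.
#' `->` (or the arrow character) marks an irreversible reaction, `<->` a
#' reversible one; empty bound cells default to `[0, 1e6]` and `[-1e6, 1e6]`
#' respectively. A one-sided equation (`"ac ->"`) is an exchange.
#'
#' An optional metabolite table (`id`, `name`, `compartment`, `formula`,
#' `charge`, `electrons`) attaches chemistry for balance checking.
#'
#' @name tabular-model
NULL

parse_species_list <- function(text, line_no) {
  text <- trimws(text)
  if (!nzchar(text)) return(tibble::tibble(metabolite = character(0), coefficient = numeric(0)))
  terms <- trimws(strsplit(text, "\\s\\+\\s|^\\+\\s|\\s\\+$")[[1]])
  terms <- terms[nzchar(terms)]
  rows <- lapply(terms, function(tm) {
    m <- regexpr("^[0-9]*\\.?[0-9]+\\s+", tm)
    if (m > 0) {
      coef <- as.numeric(trimws(regmatches(tm, m)))
      met <- trimws(substr(tm, attr(m, "match.length") + 1L, nchar(tm)))
    } else {
      coef <- 1
      met <- tm
    }
    if (!nzchar(met) || grepl("\\s", met)) {
      stop("unparseable equation term '", tm, "' on line ", line_no, call. = FALSE)
    }
    tibble::tibble(metabolite = met, coefficient = coef)
  })
  dplyr::bind_rows(rows)
}

parse_reaction_equation <- function(equation, line_no = NA) {
  reversible <- grepl("<->|<=>", equation)
  sides <- strsplit(equation, "<->|<=>|->|→|=>", perl = FALSE)[[1]]
  if (length(sides) > 2 || !grepl("<->|<=>|->|→|=>", equation)) {
    stop("unparseable equation on line ", line_no, ": ", equation, call. = FALSE)
  }
  lhs <- parse_species_list(sides[1], line_no)
  rhs <- if (length(sides) == 2) parse_species_list(sides[2], line_no) else
    tibble::tibble(metabolite = character(0), coefficient = numeric(0))
  stoich <- dplyr::bind_rows(
    dplyr::mutate(lhs, coefficient = -.data$coefficient),
    rhs
  ) |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(coefficient = sum(.data$coefficient), .groups = "drop") |>
    dplyr::filter(.data$coefficient != 0)
  list(stoich = stoich, reversible = reversible)
}

#' Read a model from the tabular dialect
#'
#' @param path Reaction TSV (see [tabular-model]).
#' @param metabolites Optional metabolite TSV path or tibble.
#' @param biomass,maintenance Optional reaction ids.
#' @return A `stoich_model`.
#' @export
read_tabular_model <- function(path, metabolites = NULL,
                               biomass = NULL, maintenance = NULL) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), check.names = FALSE)
  required <- c("reaction_id", "equation")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) stop("tabular model lacks columns: ",
                                 paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$reaction_id)) {
    stop("duplicate reaction id(s): ",
         paste(unique(tab$reaction_id[duplicated(tab$reaction_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!"lower" %in% names(tab)) tab$lower <- NA_real_
  if (!"upper" %in% names(tab)) tab$upper <- NA_real_
  if (!"gpr" %in% names(tab)) tab$gpr <- NA_character_

  parsed <- purrr::imap(tab$equation, function(eq, i) parse_reaction_equation(eq, i + 1L))
  stoich <- dplyr::bind_rows(purrr::map2(parsed, tab$reaction_id, function(p, id) {
    dplyr::mutate(p$stoich, reaction = id)
  }))
  reversible <- vapply(parsed, `[[`, logical(1), "reversible")
  lower <- ifelse(is.na(tab$lower), ifelse(reversible, -pf_big(), 0), as.numeric(tab$lower))
  upper <- ifelse(is.na(tab$upper), pf_big(), as.numeric(tab$upper))

  met_ids <- unique(stoich$metabolite)
  mets <- tibble::tibble(id = met_ids)
  if (!is.null(metabolites)) {
    minfo <- if (is.character(metabolites)) {
      utils::read.delim(metabolites, sep = "\t", stringsAsFactors = FALSE,
                        na.strings = c("NA", ""), check.names = FALSE)
    } else tibble::as_tibble(metabolites)
    mets <- dplyr::left_join(mets, tibble::as_tibble(minfo), by = "id")
  }

  stoich_model(
    metabolites = mets,
    reactions = tibble::tibble(id = tab$reaction_id, lower = lower, upper = upper,
                               gpr = as.character(tab$gpr)),
    stoichiometry = stoich[, c("reaction", "metabolite", "coefficient")],
    biomass = biomass, maintenance = maintenance
  )
}

format_species_side <- function(stoich, sign) {
  rows <- stoich[sign * stoich$coefficient > 0, , drop = FALSE]
  if (nrow(rows) == 0) return("")
  coefs <- abs(rows$coefficient)
  paste(ifelse(coefs == 1, rows$metabolite,
               paste(format(coefs, trim = TRUE, scientific = FALSE), rows$metabolite)),
        collapse = " + ")
}

#' Write a model in the tabular dialect
#'
#' @param model A `stoich_model`.
#' @param path Reaction TSV output path.
#' @param metabolites_path Optional metabolite TSV output path.
#' @return `path`, invisibly.
#' @export
write_tabular_model <- function(model, path, metabolites_path = NULL) {
  st <- stoichiometry_tbl(model)
  eqs <- vapply(model$reactions$id, function(rid) {
    rows <- st[st$reaction == rid, ]
    rev <- model$reactions$lower[match(rid, model$reactions$id)] < 0
    paste(format_species_side(rows, -1), if (rev) "<->" else "->",
          format_species_side(rows, +1))
  }, character(1))
  out <- data.frame(
    reaction_id = model$reactions$id,
    equation = trimws(eqs),
    lower = model$reactions$lower,
    upper = model$reactions$upper,
    gpr = model$reactions$gpr,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(metabolites_path)) {
    utils::write.table(as.data.frame(model$metabolites), metabolites_path,
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  invisible(path)
}
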