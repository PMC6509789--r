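#' SBML input/output
#'
#' A lightweight SBML layer for constraint-based models, built on xml2. The
#' reader handles Level 3 with the fbc extension (flux-bound parameters,
#' gene-product associations, chemical formulas and charges) and Level 2
#' conventions (kinetic-law `LOWER_BOUND`/`UPPER_BOUND` parameters,
#' `GENE_ASSOCIATION`/`FORMULA`/`CHARGE` notes). The writer emits Level 3
#' Version 1 with fbc version 2. Species flagged `boundaryCondition` are kept
#' in the metabolite table as external but excluded from the stoichiometric
#' matrix, following the usual convention.
#'
#' @name sbml-io
NULL

xf <- function(node, xpath) xml2::xml_find_all(node, xpath)
x1 <- function(node, xpath) xml2::xml_find_first(node, xpath)

attr_any <- function(node, names) {
  for (nm in names) {
    v <- xml2::xml_attr(node, nm)
    if (!is.na(v)) return(v)
  }
  NA_character_
}

note_field <- function(node, key) {
  notes <- xf(node, ".//*[local-name()='notes']//*")
  for (p in notes) {
    txt <- trimws(xml2::xml_text(p))
    m <- regexpr(paste0("^", key, ":\\s*"), txt)
    if (m > 0) return(trimws(sub(paste0("^", key, ":\\s*"), "", txt)))
  }
  NA_character_
}

parse_fbc_association <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm %in% c("geneProductRef")) {
    return(attr_any(node, c("fbc:geneProduct", "geneProduct")))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, parse_fbc_association, character(1))
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

#' Read a stoichiometric model from SBML
#'
#' @param path SBML file (Level 2, or Level 3 with fbc).
#' @param default_bounds What to do for reactions without resolvable bounds:
#'   `"error"` (default; lists the offending ids) or `"reversibility"` (derive
#'   `[-1e6, 1e6]` / `[0, 1e6]` from the `reversible` attribute).
#' @param biomass Biomass reaction id; when `NULL`, the reaction named in an
#'   fbc objective is used if one exists, else a reaction whose id contains
#'   "biomass" (case-insensitive), else none. Models carrying several biomass
#'   variants (e.g. light and dark compositions) keep them all; pass the one a
#'   given run should use.
#' @return A `stoich_model`.
#' @export
read_sbml <- function(path, default_bounds = c("error", "reversibility"),
                      biomass = NULL) {
  default_bounds <- match.arg(default_bounds)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed SBML XML in ", path, ": ", conditionMessage(e), call. = FALSE)
  })

  params <- xf(doc, "/*/*[local-name()='model']/*[local-name()='listOfParameters']/*[local-name()='parameter']")
  param_val <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id")
  )

  sp_nodes <- xf(doc, "//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(sp_nodes) == 0) stop("no species found in ", path, call. = FALSE)
  mets <- dplyr::bind_rows(lapply(sp_nodes, function(sp) {
    frm <- attr_any(sp, c("fbc:chemicalFormula", "chemicalFormula"))
    if (is.na(frm)) frm <- note_field(sp, "FORMULA")
    chg <- attr_any(sp, c("fbc:charge", "charge"))
    if (is.na(chg)) chg <- note_field(sp, "CHARGE")
    tibble::tibble(
      id = xml2::xml_attr(sp, "id"),
      name = xml2::xml_attr(sp, "name"),
      compartment = xml2::xml_attr(sp, "compartment"),
      formula = if (is.na(frm) || !nzchar(frm)) NA_character_ else frm,
      charge = suppressWarnings(as.numeric(chg)),
      is_external = identical(xml2::xml_attr(sp, "boundaryCondition"), "true"),
      electrons = NA_real_
    )
  }))
  external <- mets$id[mets$is_external]

  rx_nodes <- xf(doc, "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx_nodes) == 0) stop("no reactions found in ", path, call. = FALSE)

  unresolved <- character(0)
  parts <- lapply(rx_nodes, function(rx) {
    rid <- xml2::xml_attr(rx, "id")
    stoich_one <- function(list_name, sgn) {
      refs <- xf(rx, paste0(".//*[local-name()='", list_name,
                            "']/*[local-name()='speciesReference']"))
      if (length(refs) == 0) return(NULL)
      coefs <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coefs[is.na(coefs)] <- 1
      tibble::tibble(reaction = rid,
                     metabolite = xml2::xml_attr(refs, "species"),
                     coefficient = sgn * coefs)
    }
    st <- dplyr::bind_rows(stoich_one("listOfReactants", -1),
                           stoich_one("listOfProducts", +1))
    st <- st[!st$metabolite %in% external, , drop = FALSE]

    lo <- hi <- NA_real_
    lo_ref <- attr_any(rx, c("fbc:lowerFluxBound", "lowerFluxBound"))
    hi_ref <- attr_any(rx, c("fbc:upperFluxBound", "upperFluxBound"))
    if (!is.na(lo_ref) && lo_ref %in% names(param_val)) lo <- param_val[[lo_ref]]
    if (!is.na(hi_ref) && hi_ref %in% names(param_val)) hi <- param_val[[hi_ref]]
    if (is.na(lo) || is.na(hi)) {
      kl <- xf(rx, ".//*[local-name()='kineticLaw']//*[local-name()='parameter' or local-name()='localParameter']")
      for (p in kl) {
        pid <- xml2::xml_attr(p, "id")
        val <- as.numeric(xml2::xml_attr(p, "value"))
        if (identical(pid, "LOWER_BOUND") && is.na(lo)) lo <- val
        if (identical(pid, "UPPER_BOUND") && is.na(hi)) hi <- val
      }
    }
    if (is.na(lo) || is.na(hi)) {
      if (default_bounds == "reversibility") {
        rev <- !identical(xml2::xml_attr(rx, "reversible"), "false")
        if (is.na(lo)) lo <- if (rev) -pf_big() else 0
        if (is.na(hi)) hi <- pf_big()
      } else {
        unresolved <<- c(unresolved, rid)
      }
    }
    lo <- max(lo, -pf_big()); hi <- min(hi, pf_big())

    gpr <- NA_character_
    assoc <- x1(rx, ".//*[local-name()='geneProductAssociation']")
    if (!inherits(assoc, "xml_missing")) {
      kids <- xml2::xml_children(assoc)
      if (length(kids)) gpr <- parse_fbc_association(kids[[1]])
    }
    if (is.na(gpr)) {
      ga <- note_field(rx, "GENE_ASSOCIATION")
      if (!is.na(ga) && nzchar(ga)) gpr <- ga
    }
    list(reaction = tibble::tibble(id = rid, lower = lo, upper = hi, gpr = gpr),
         stoich = st)
  })
  if (length(unresolved)) {
    stop("reactions without resolvable flux bounds: ",
         paste(unresolved, collapse = ", "),
         " (pass default_bounds = \"reversibility\" or supply a sidecar medium)",
         call. = FALSE)
  }
  reactions <- dplyr::bind_rows(purrr::map(parts, "reaction"))
  stoich <- dplyr::bind_rows(purrr::map(parts, "stoich"))

  if (is.null(biomass)) {
    obj_ref <- x1(doc, "//*[local-name()='listOfObjectives']//*[local-name()='fluxObjective']")
    if (!inherits(obj_ref, "xml_missing")) {
      biomass <- attr_any(obj_ref, c("fbc:reaction", "reaction"))
    } else {
      hits <- grep("biomass", reactions$id, ignore.case = TRUE, value = TRUE)
      if (length(hits) >= 1) biomass <- hits[[1]]
    }
  }

  # gene ids declared as fbc geneProducts map label -> id transparently; GPRs
  # reference the ids, which is all evaluate_gpr needs.
  used <- unique(stoich$metabolite)
  mets_used <- mets[mets$id %in% used | mets$is_external, , drop = FALSE]
  stoich_model(mets_used, reactions, stoich, biomass = biomass)
}

sbml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

gpr_to_fbc <- function(gpr, indent) {
  node_xml <- function(node, pad) {
    sp <- strrep(" ", pad)
    if (node$op == "gene") {
      return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>', sp, node$id))
    }
    tag <- paste0("fbc:", node$op)
    inner <- vapply(node$args, node_xml, character(1), pad = pad + 2)
    paste0(sp, "<", tag, ">\n", paste(inner, collapse = "\n"), "\n", sp, "</", tag, ">")
  }
  ast <- parse_gpr(gpr)
  if (is.null(ast)) return(character(0))
  sp <- strrep(" ", indent)
  paste0(sp, "<fbc:geneProductAssociation>\n",
         node_xml(ast, indent + 2), "\n",
         sp, "</fbc:geneProductAssociation>")
}

#' Write a model as SBML Level 3 (fbc version 2)
#'
#' Bounds become shared parameters referenced through fbc flux-bound
#' attributes; GPRs become fbc gene-product associations; formulas, charges
#' and the biomass objective are preserved so that a write/read round trip
#' reproduces the model (same S, bounds and GPR semantics).
#'
#' @param model A `stoich_model` (must pass [validate_model()] and contain at
#'   least one metabolite and reaction).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  if (nrow(model$metabolites) == 0 || nrow(model$reactions) == 0) {
    stop("refusing to write an empty model", call. = FALSE)
  }
  validate_model(model)
  bounds <- sort(unique(c(model$reactions$lower, model$reactions$upper)))
  bound_id <- stats::setNames(sprintf("bnd_%d", seq_along(bounds)),
                              sprintf("%.17g", bounds))
  bid <- function(v) bound_id[[sprintf("%.17g", v)]]

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="model" fbc:strict="false">',
    '    <listOfCompartments>'
  )
  for (cp in unique(model$metabolites$compartment)) {
    out <- c(out, sprintf('      <compartment id="%s" constant="true"/>', cp))
  }
  out <- c(out, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    attrs <- sprintf(
      'id="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="%s" constant="false"',
      m$id, m$compartment, if (isTRUE(m$is_external)) "true" else "false")
    if (!is.na(m$name)) attrs <- paste0(attrs, sprintf(' name="%s"', sbml_escape(m$name)))
    if (!is.na(m$formula)) attrs <- paste0(attrs, sprintf(' fbc:chemicalFormula="%s"', m$formula))
    if (!is.na(m$charge)) attrs <- paste0(attrs, sprintf(' fbc:charge="%d"', as.integer(m$charge)))
    out <- c(out, sprintf("      <species %s/>", attrs))
  }
  out <- c(out, "    </listOfSpecies>", "    <listOfParameters>")
  for (v in bounds) {
    out <- c(out, sprintf(
      '      <parameter id="%s" value="%s" constant="true"/>',
      bid(v), format(v, digits = 17)))
  }
  out <- c(out, "    </listOfParameters>", "    <listOfReactions>")
  st <- stoichiometry_tbl(model)
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rows <- st[st$reaction == r$id, ]
    out <- c(out, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      r$id, if (r$lower < 0) "true" else "false", bid(r$lower), bid(r$upper)))
    if (!is.na(r$gpr) && nzchar(r$gpr)) {
      out <- c(out, gpr_to_fbc(r$gpr, 8))
    }
    subs <- rows[rows$coefficient < 0, ]
    prods <- rows[rows$coefficient > 0, ]
    if (nrow(subs)) {
      out <- c(out, "        <listOfReactants>",
               sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       subs$metabolite, format(-subs$coefficient, digits = 17)),
               "        </listOfReactants>")
    }
    if (nrow(prods)) {
      out <- c(out, "        <listOfProducts>",
               sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       prods$metabolite, format(prods$coefficient, digits = 17)),
               "        </listOfProducts>")
    }
    out <- c(out, "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>")
  if (length(model$genes)) {
    out <- c(out, "    <fbc:listOfGeneProducts>",
             sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                     model$genes, model$genes),
             "    </fbc:listOfGeneProducts>")
  }
  if (!is.null(model$biomass_reaction_id)) {
    out <- c(out,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
              model$biomass_reaction_id),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  out <- c(out, "  </model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}
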