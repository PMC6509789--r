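#' Elemental formulas and degree-of-reduction accounting
#'
#' Tools for Hill-style elemental formulas with real-valued subscripts (as used
#' for per-carbon-mole biomass compositions such as `CH1.93O0.54N0.22`), the
#' Roels degree of reduction, and element/charge balance checking of reactions
#' and lumped overall conversion equations.
#'
#' @name formula-tools
NULL

# Roels electron-equivalent weights per atom; charge subtracts directly.
.roels_weights <- c(C = 4, H = 1, O = -2, N = -3, S = 6, P = 5)

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "W", "Pt", "Au", "Hg", "Pb", "U"
)

#' Parse an elemental formula
#'
#' Accepts Hill-like notation with real subscripts and an optional trailing
#' charge written sign-first (`"NH4+"`, `"Fe+3"`, `"SO4-2"`, `"H+"`).
#'
#' @param text Formula string, e.g. `"CO2"`, `"CH1.93O0.54N0.22"`, `"NH4+"`.
#' @param charge Optional explicit charge; overrides any charge in `text`.
#' @return An object of class `elemental_formula`: a list with `counts`
#'   (named numeric, elements) and `charge` (numeric).
#' @examples
#' parse_formula("CH1.93O0.54N0.22")
#' parse_formula("NH4+")
#' @export
parse_formula <- function(text, charge = NULL) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  body <- trimws(text)
  if (!nzchar(body)) stop("empty formula", call. = FALSE)

  chg <- 0
  m <- regexpr("([+-]+[0-9]*)$", body)
  if (m > 0) {
    tail <- regmatches(body, m)
    body <- substr(body, 1L, m - 1L)
    sign_chr <- substr(tail, 1L, 1L)
    mag_chr <- sub("^[+-]+", "", tail)
    n_signs <- nchar(gsub("[0-9]", "", tail))
    mag <- if (nzchar(mag_chr)) as.numeric(mag_chr) else n_signs
    chg <- if (sign_chr == "+") mag else -mag
  }
  if (!is.null(charge)) chg <- charge

  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", body)[[1]]
  pieces <- regmatches(body, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", body))[[1]]
  if (length(pieces) == 0 || sum(nchar(pieces)) != nchar(body)) {
    stop("cannot parse formula: ", text, call. = FALSE)
  }
  sym <- sub("([A-Z][a-z]?).*", "\\1", pieces)
  bad <- setdiff(sym, .element_symbols)
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
                        " in formula ", text, call. = FALSE)
  num <- sub("^[A-Z][a-z]?", "", pieces)
  cnt <- ifelse(nzchar(num), as.numeric(num), 1)
  counts <- tapply(cnt, sym, sum)
  counts <- stats::setNames(as.numeric(counts), names(counts))
  if (any(counts < 0)) stop("negative subscript in formula: ", text, call. = FALSE)
  structure(list(counts = counts, charge = chg), class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  subs <- ifelse(x$counts == 1, "", format(x$counts, trim = TRUE))
  cat("<elemental_formula> ", paste0(names(x$counts), subs, collapse = ""),
      if (x$charge != 0) sprintf(" (charge %+g)", x$charge), "\n", sep = "")
  invisible(x)
}

as_formula_obj <- function(x) {
  if (inherits(x, "elemental_formula")) x else parse_formula(x)
}

#' Electron content of a compound
#'
#' Available electron equivalents per formula unit under Roels' convention:
#' 4 per C, 1 per H, -2 per O, -3 per N, 6 per S, 5 per P, minus the charge.
#' This is the numerator of the degree of reduction and is defined for
#' carbon-free species too (H2 carries 2 electrons, H2O and CO2 carry 0).
#'
#' @param f An `elemental_formula` or a formula string.
#' @return Electron equivalents per formula unit (numeric scalar).
#' @export
electron_content <- function(f) {
  f <- as_formula_obj(f)
  unknown <- setdiff(names(f$counts), names(.roels_weights))
  # Elements outside Roels' convention (metals etc.) carry no catabolic
  # electrons here; consistent with per-C-mole bookkeeping of organics.
  w <- .roels_weights[intersect(names(f$counts), names(.roels_weights))]
  sum(w * f$counts[names(w)]) - f$charge
}

#' Roels degree of reduction per carbon mole
#'
#' @param f An `elemental_formula` or a formula string.
#' @return kappa, electron equivalents per C-mole.
#' @examples
#' degree_of_reduction("CH1.93O0.54N0.22") # biomass, 4.19
#' degree_of_reduction("C2H4O2")           # acetate, 4
#' degree_of_reduction("CO2")              # 0
#' @export
degree_of_reduction <- function(f) {
  f <- as_formula_obj(f)
  n_c <- if ("C" %in% names(f$counts)) f$counts[["C"]] else 0
  if (n_c <= 0) {
    stop("degree of reduction per C-mole is undefined for carbon-free formulas",
         call. = FALSE)
  }
  electron_content(f) / n_c
}

# ---- overall conversion equations ------------------------------------------

parse_equation_side <- function(text) {
  terms <- strsplit(text, "\\s\\+\\s")[[1]]
  terms <- trimws(terms)
  terms <- terms[nzchar(terms)]
  out <- lapply(terms, function(tm) {
    m <- regexpr("^[0-9]*\\.?[0-9]+\\s+", tm)
    if (m > 0) {
      coef <- as.numeric(trimws(regmatches(tm, m)))
      frm <- trimws(substr(tm, attr(m, "match.length") + 1L, nchar(tm)))
    } else {
      coef <- 1
      frm <- tm
    }
    list(coef = coef, formula = frm)
  })
  tibble::tibble(
    coef = vapply(out, `[[`, numeric(1), "coef"),
    formula = vapply(out, `[[`, character(1), "formula")
  )
}

#' Parse a lumped conversion equation
#'
#' @param text Equation such as
#'   `"CH0.71O0.43 + 0.2 NH4+ + 0.26 H2O -> 0.9 CH1.93O0.54N0.22 + 0.1 CO2 + 0.29 H+"`.
#'   Both `->` and the arrow character are accepted.
#' @return List with `lhs` and `rhs` tibbles (`coef`, `formula`).
#' @export
parse_equation <- function(text) {
  sides <- strsplit(text, "->|→|<->", perl = FALSE)[[1]]
  if (length(sides) != 2) stop("equation must have exactly one arrow: ", text,
                               call. = FALSE)
  list(lhs = parse_equation_side(sides[[1]]), rhs = parse_equation_side(sides[[2]]))
}

side_totals <- function(side) {
  counts <- numeric(0)
  charge <- 0
  for (i in seq_len(nrow(side))) {
    f <- as_formula_obj(side$formula[[i]])
    k <- side$coef[[i]]
    for (el in names(f$counts)) {
      counts[el] <- (if (el %in% names(counts)) counts[el] else 0) + k * f$counts[[el]]
    }
    charge <- charge + k * f$charge
  }
  list(counts = counts, charge = charge)
}

#' Check the balance of a lumped overall conversion equation
#'
#' Computes per-element residuals (left minus right) and the charge residual.
#' The `balanced` verdict covers the element residuals; published lumped
#' equations routinely write free protons without their counter-ions, so the
#' charge residual is reported alongside but only enters the verdict when
#' `include_charge = TRUE`.
#'
#' @param equation Equation string (see [parse_equation()]), or `NULL` when
#'   `lhs`/`rhs` are given directly.
#' @param lhs,rhs Tibbles or data frames with columns `coef` and `formula`
#'   (string or `elemental_formula`); alternative to `equation`.
#' @param tol Absolute residual tolerance per element (default 0.02, suited to
#'   equations printed with two-decimal coefficients).
#' @param include_charge Should the charge residual count toward `balanced`?
#' @return A `balance_report`: list with `per_element_residual` (named numeric),
#'   `charge_residual`, `balanced`, `tol`. Has a [generics::tidy()] method.
#' @examples
#' check_overall_equation(
#'   "CH0.71O0.43 + 0.2 NH4+ + 0.26 H2O -> 0.9 CH1.93O0.54N0.22 + 0.1 CO2 + 0.29 H+"
#' )
#' @export
check_overall_equation <- function(equation = NULL, lhs = NULL, rhs = NULL,
                                   tol = 0.02, include_charge = FALSE) {
  if (!is.null(equation)) {
    eq <- parse_equation(equation)
    lhs <- eq$lhs
    rhs <- eq$rhs
  }
  stopifnot(!is.null(lhs), !is.null(rhs))
  lhs <- tibble::as_tibble(lhs)
  rhs <- tibble::as_tibble(rhs)
  if (any(lhs$coef < 0) || any(rhs$coef < 0)) {
    stop("coefficients must be non-negative", call. = FALSE)
  }
  lt <- side_totals(lhs)
  rt <- side_totals(rhs)
  els <- union(names(lt$counts), names(rt$counts))
  resid <- vapply(els, function(el) {
    l <- if (el %in% names(lt$counts)) lt$counts[[el]] else 0
    r <- if (el %in% names(rt$counts)) rt$counts[[el]] else 0
    l - r
  }, numeric(1))
  charge_resid <- lt$charge - rt$charge
  ok <- all(abs(resid) <= tol)
  if (include_charge) ok <- ok && abs(charge_resid) <= tol
  structure(
    list(per_element_residual = resid, charge_residual = charge_resid,
         balanced = ok, tol = tol),
    class = "balance_report"
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report> ", if (x$balanced) "balanced" else "UNBALANCED",
      " (tol ", format(x$tol), ")\n", sep = "")
  for (el in names(x$per_element_residual)) {
    cat(sprintf("  %-2s residual: %+.4g\n", el, x$per_element_residual[[el]]))
  }
  cat(sprintf("  charge residual: %+.4g\n", x$charge_residual))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.balance_report <- function(x, ...) {
  tibble::tibble(
    component = c(names(x$per_element_residual), "charge"),
    residual = c(unname(x$per_element_residual), x$charge_residual),
    within_tol = abs(c(unname(x$per_element_residual), x$charge_residual)) <= x$tol
  )
}
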