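#' Synthetic toy phototroph
#'
#' A fixed 12-internal-reaction network that emulates the structure of
#' photoheterotrophic metabolism: light-driven ATP supply decoupled from
#' carbon, two CO2-fixation routes with different ATP costs (a CBB-like and a
#' cheaper rTCA-like route), an ATP-consuming H2-evolving electron sink
#' (nitrogenase-like), and export of a reduced organic byproduct. Every
#' internal reaction is element- and electron-balanced under the fixture
#' formulas (`red` is a 2-electron carrier written as H2; carbon species are
#' per-C-mole tokens), so electron bookkeeping across the boundary closes
#' exactly on any steady-state solution.
#'
#' Reactions (ATP and photon carry no elements; their electron content is 0):
#' \describe{
#'   \item{LHC}{photon -> 2 atp (light harvesting)}
#'   \item{ACT}{ac -> c + red (acetate activation; acetate kappa = 4)}
#'   \item{OX}{c -> co2 + red (oxidation of fixed carbon)}
#'   \item{FIX_A}{co2 + red + 3 atp -> c (CBB-like, expensive)}
#'   \item{FIX_B}{co2 + red + 2 atp -> c (rTCA-like, cheaper)}
#'   \item{BIOSYN}{10 c + red + 15 atp -> biomass}
#'   \item{NIT}{red + 2 atp -> h2 (nitrogenase-like H2 evolution)}
#'   \item{BYP}{c + red -> byp (reduced byproduct, kappa = 4)}
#' }
#' plus exchanges for photon (uptake <= P), acetate (uptake <= A), CO2 (export
#' only), H2, byproduct and biomass (export only).
#'
#' @param P Photon uptake cap, mmol/gDW/h.
#' @param A Acetate uptake cap, mmol/gDW/h.
#' @return A `stoich_model` with GPRs (ACT has an isozyme pair, FIX_A and NIT
#'   are two-subunit complexes) and fixture formulas attached.
#' @examples
#' toy <- make_toy(P = 50, A = 10)
#' fba(toy)$objective_value
#' @export
make_toy <- function(P = 50, A = 10) {
  stopifnot(P >= 0, A >= 0)
  mets <- tibble::tibble(
    id = c("photon", "atp", "ac", "c", "red", "co2", "h2", "byp", "biomass"),
    name = c("photon", "ATP (energy token)", "acetate unit (per C)",
             "fixed carbon unit", "2-electron reduction carrier", "CO2",
             "hydrogen gas", "reduced byproduct unit", "biomass unit"),
    compartment = "c",
    formula = c(NA, NA, "CH4O2", "CH2O2", "H2", "CO2", "H2", "CH4O2",
                "C10H22O20"),
    charge = c(NA, NA, 0, 0, 0, 0, 0, 0, 0),
    is_external = FALSE,
    electrons = c(0, 0, NA, NA, NA, NA, NA, NA, NA)
  )
  rx <- tibble::tribble(
    ~id, ~equation, ~lower, ~upper, ~gpr,
    "LHC",    "photon -> 2 atp",               0, pf_big(), "gLHC",
    "ACT",    "ac -> c + red",                 0, pf_big(), "(gACT1 or gACT2)",
    "OX",     "c -> co2 + red",                0, pf_big(), "gOX",
    "FIX_A",  "co2 + red + 3 atp -> c",        0, pf_big(), "(gFA1 and gFA2)",
    "FIX_B",  "co2 + red + 2 atp -> c",        0, pf_big(), "gFB",
    "BIOSYN", "10 c + red + 15 atp -> biomass",0, pf_big(), "gBIO",
    "NIT",    "red + 2 atp -> h2",             0, pf_big(), "(gNIT1 and gNIT2)",
    "BYP",    "c + red -> byp",                0, pf_big(), "gBYP",
    "EX_photon",  "photon ->",  -P, 0,        NA,
    "EX_ac",      "ac ->",      -A, 0,        NA,
    "EX_co2",     "co2 ->",      0, pf_big(), NA,
    "EX_h2",      "h2 ->",       0, pf_big(), NA,
    "EX_byp",     "byp ->",      0, pf_big(), NA,
    "EX_biomass", "biomass ->",  0, pf_big(), NA
  )
  # exchanges are written products-side ("met ->"): S[met, EX] = -1, so
  # positive flux = export, negative = uptake
  parsed <- purrr::map2(rx$equation, seq_len(nrow(rx)),
                        function(eq, i) parse_reaction_equation(eq, i))
  stoich <- dplyr::bind_rows(purrr::map2(parsed, rx$id, function(p, id) {
    dplyr::mutate(p$stoich, reaction = id)
  }))
  stoich_model(
    metabolites = mets,
    reactions = tibble::tibble(id = rx$id, lower = rx$lower, upper = rx$upper,
                               gpr = rx$gpr),
    stoichiometry = stoich[, c("reaction", "metabolite", "coefficient")],
    biomass = "BIOSYN"
  )
}
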