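#' Flux objectives
#'
#' A linear objective over reaction fluxes: coefficients, a direction, and a
#' label used in Pareto-front output.
#'
#' @param coefficients Named numeric vector (reaction id -> coefficient), or a
#'   tibble with columns `reaction`, `coefficient`.
#' @param direction `"max"` or `"min"`.
#' @param label Short display label.
#' @return A `flux_objective`.
#' @export
flux_objective <- function(coefficients, direction = c("max", "min"),
                           label = NULL) {
  direction <- match.arg(direction)
  if (is.data.frame(coefficients)) {
    coefficients <- stats::setNames(coefficients$coefficient, coefficients$reaction)
  }
  if (is.null(names(coefficients)) || !all(nzchar(names(coefficients)))) {
    stop("objective coefficients must be named by reaction id", call. = FALSE)
  }
  coefficients <- coefficients[coefficients != 0]
  if (length(coefficients) == 0) stop("objective has no non-zero coefficient",
                                      call. = FALSE)
  structure(list(coefficients = coefficients, direction = direction,
                 label = label %||% paste(names(coefficients)[1],
                                          if (length(coefficients) > 1) "...")),
            class = "flux_objective")
}

#' @export
print.flux_objective <- function(x, ...) {
  cat(sprintf("<flux_objective> %s %s (%d term%s)\n", x$direction, x$label,
              length(x$coefficients), if (length(x$coefficients) > 1) "s" else ""))
  invisible(x)
}

#' Single-reaction objective
#' @param reaction Reaction id.
#' @inheritParams flux_objective
#' @export
reaction_objective <- function(reaction, direction = "max", label = reaction) {
  flux_objective(stats::setNames(1, reaction), direction, label)
}

#' Biomass (growth) objective of a model
#' @param model A `stoich_model` with `biomass_reaction_id` set.
#' @export
biomass_objective <- function(model) {
  if (is.null(model$biomass_reaction_id)) {
    stop("model has no biomass reaction set", call. = FALSE)
  }
  reaction_objective(model$biomass_reaction_id, "max", "growth")
}

#' Signed linear transport-minimisation objective
#'
#' On a minimal medium every exchange is sign-constrained (uptake-only or
#' export-only), so the sum of absolute transport rates is linear in the
#' fluxes: |v_e| = -v_e for uptake-only exchanges and +v_e for export-only
#' ones. This builds that signed objective for use inside multi-objective
#' runs; it errors on exchanges that can run in both directions (use
#' [minimize_total_transport()] for the general split-variable treatment).
#'
#' @param model A `stoich_model`.
#' @return A minimisation `flux_objective` labelled `"transport"`.
#' @export
transport_objective <- function(model) {
  ex <- model$reactions[model$reactions$is_exchange, ]
  free <- ex$id[ex$lower < 0 & ex$upper > 0]
  if (length(free)) {
    stop("exchanges can carry flux in both directions (|v| is not linear): ",
         paste(free, collapse = ", "), call. = FALSE)
  }
  sign_vec <- ifelse(ex$lower < 0, -1, 1)
  flux_objective(stats::setNames(sign_vec, ex$id), "min", "transport")
}

objective_vector <- function(model, objective) {
  bad <- setdiff(names(objective$coefficients), model$reactions$id)
  if (length(bad)) stop("objective references unknown reactions: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  v <- stats::setNames(numeric(nrow(model$reactions)), model$reactions$id)
  v[names(objective$coefficients)] <- objective$coefficients
  v
}

new_flux_solution <- function(model, x, objective_value, status, label,
                              direction = "max") {
  fluxes <- if (all(is.na(x))) {
    tibble::tibble(reaction = model$reactions$id, flux = NA_real_)
  } else {
    tibble::tibble(reaction = model$reactions$id, flux = as.numeric(x))
  }
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status, label = label, direction = direction),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> %s: %s, objective = %s\n",
              x$label %||% "objective", x$status,
              format(x$objective_value)))
  invisible(x)
}

#' Fluxes of a solution as a named vector
#' @param solution A `flux_solution`.
#' @export
fluxes <- function(solution) {
  stats::setNames(solution$fluxes$flux, solution$fluxes$reaction)
}

#' @export
tidy.flux_solution <- function(x, ...) x$fluxes

#' @export
glance.flux_solution <- function(x, ...) {
  tibble::tibble(label = x$label %||% NA_character_, status = x$status,
                 objective_value = x$objective_value)
}

# Solve the core FBA LP, optionally with extra >= rows in flux space.
# External (boundary) species leave all-zero rows in S; drop them.
fba_lp <- function(model, obj, maximize, A_ge = NULL, b_ge = NULL) {
  S <- model$S[rowSums(model$S != 0) > 0, , drop = FALSE]
  lp_solve(
    objective = obj,
    lb = model$reactions$lower, ub = model$reactions$upper,
    A_eq = S, b_eq = rep(0, nrow(S)),
    A_ge = A_ge, b_ge = b_ge,
    maximize = maximize
  )
}

# Among alternate optima with c'v (approximately) fixed at z_star, return the
# flux vector minimising total |v|; auxiliary variables t_i >= |v_i|.
parsimonious_lp <- function(model, obj, z_star, A_ge = NULL, b_ge = NULL,
                            band = 1e-9) {
  n <- nrow(model$reactions)
  lb <- model$reactions$lower
  ub <- model$reactions$upper
  tol <- band * (1 + abs(z_star))
  lb2 <- c(lb, rep(0, n))
  ub2 <- c(ub, pmax(abs(lb), abs(ub)))
  pad <- function(A) if (is.null(A)) NULL else cbind(matrix(A, ncol = n), matrix(0, nrow(matrix(A, ncol = n)), n))
  # t_i - v_i >= 0 ; t_i + v_i >= 0
  I <- diag(n)
  A_abs <- rbind(cbind(-I, I), cbind(I, I))
  b_abs <- rep(0, 2 * n)
  # pin the objective within a tiny band
  A_pin <- rbind(c(obj, rep(0, n)), c(-obj, rep(0, n)))
  b_pin <- c(z_star - tol, -(z_star + tol))
  S <- model$S[rowSums(model$S != 0) > 0, , drop = FALSE]
  res <- lp_solve(
    objective = c(rep(0, n), rep(1, n)),
    lb = lb2, ub = ub2,
    A_eq = cbind(S, matrix(0, nrow(S), n)),
    b_eq = rep(0, nrow(S)),
    A_ge = rbind(pad(A_ge), A_abs, A_pin),
    b_ge = c(b_ge, b_abs, b_pin),
    maximize = FALSE
  )
  if (res$status != "optimal") return(NULL)
  res$x[seq_len(n)]
}

#' Flux balance analysis
#'
#' Maximises (or minimises) a linear flux objective subject to steady state
#' (`S v = 0`) and the model's flux bounds. With `refine = "parsimonious"`
#' (the default) the returned flux vector is, among the alternate optima, the
#' one minimising total flux `sum(|v|)` — a deterministic representative, since
#' individual flux routes are otherwise degenerate.
#'
#' @param model A `stoich_model`.
#' @param objective A `flux_objective`; defaults to the biomass objective.
#' @param refine `"parsimonious"` or `"none"`.
#' @return A `flux_solution`; `status` is `"optimal"`, `"infeasible"` or
#'   `"maxiter"` — never a silent failure.
#' @examples
#' toy <- make_toy(P = 50, A = 10)
#' sol <- fba(toy)
#' sol$objective_value
#' @export
fba <- function(model, objective = NULL, refine = c("parsimonious", "none")) {
  refine <- match.arg(refine)
  objective <- objective %||% biomass_objective(model)
  obj <- objective_vector(model, objective)
  maximize <- objective$direction == "max"
  res <- fba_lp(model, obj, maximize)
  if (res$status != "optimal") {
    return(new_flux_solution(model, NA_real_, NA_real_, res$status,
                             objective$label, objective$direction))
  }
  x <- res$x
  if (refine == "parsimonious") {
    x2 <- parsimonious_lp(model, obj, res$objective_value)
    if (!is.null(x2)) x <- x2
  }
  new_flux_solution(model, x, sum(obj * x), "optimal", objective$label,
                    objective$direction)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to steady state, the bounds,
#' and (optionally) a floor on the biomass objective.
#'
#' @param model A `stoich_model`.
#' @param biomass_fraction Fraction of the optimal growth rate that must be
#'   sustained (0 = no floor, the convention used when preparing flux
#'   envelopes for expression-constrained runs).
#' @param reactions Reaction ids to scan (default: all).
#' @return Tibble: `reaction`, `min`, `max`.
#' @export
fva <- function(model, biomass_fraction = 0, reactions = NULL) {
  stopifnot(biomass_fraction >= 0, biomass_fraction <= 1)
  reactions <- reactions %||% model$reactions$id
  A_ge <- NULL; b_ge <- NULL
  if (biomass_fraction > 0) {
    growth <- fba(model, refine = "none")
    if (growth$status != "optimal") stop("base model infeasible", call. = FALSE)
    obj <- objective_vector(model, biomass_objective(model))
    A_ge <- matrix(obj, nrow = 1)
    b_ge <- biomass_fraction * growth$objective_value
  }
  n <- nrow(model$reactions)
  rows <- purrr::map(reactions, function(rid) {
    e <- stats::setNames(numeric(n), model$reactions$id)
    e[rid] <- 1
    lo <- fba_lp(model, e, maximize = FALSE, A_ge = A_ge, b_ge = b_ge)
    hi <- fba_lp(model, e, maximize = TRUE, A_ge = A_ge, b_ge = b_ge)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem not optimal for ", rid, call. = FALSE)
    }
    tibble::tibble(reaction = rid, min = lo$objective_value, max = hi$objective_value)
  })
  dplyr::bind_rows(rows)
}

#' Minimise total transport (sum of absolute exchange fluxes)
#'
#' The nutrient-allocation objective: minimise `sum(|v_e|)` over all exchange
#' reactions, optionally with selected fluxes pinned (e.g. growth at its
#' optimum). Absolute values are linearised with auxiliary variables
#' `t_e >= |v_e|`.
#'
#' @param model A `stoich_model`.
#' @param fixed Named numeric vector of pinned fluxes (reaction id -> value).
#' @return A `flux_solution` whose `objective_value` is the achieved transport
#'   sum.
#' @export
minimize_total_transport <- function(model, fixed = NULL) {
  if (!is.null(fixed)) {
    model <- set_reaction_bounds(model, names(fixed),
                                 lower = unname(fixed), upper = unname(fixed))
  }
  n <- nrow(model$reactions)
  ex_idx <- which(model$reactions$is_exchange)
  ne <- length(ex_idx)
  lb <- c(model$reactions$lower, rep(0, ne))
  ub <- c(model$reactions$upper,
          pmax(abs(model$reactions$lower[ex_idx]), abs(model$reactions$upper[ex_idx])))
  # t_e -/+ v_e >= 0
  A_abs <- matrix(0, 2 * ne, n + ne)
  for (k in seq_len(ne)) {
    A_abs[k, ex_idx[k]] <- -1;        A_abs[k, n + k] <- 1
    A_abs[ne + k, ex_idx[k]] <- 1;    A_abs[ne + k, n + k] <- 1
  }
  S <- model$S[rowSums(model$S != 0) > 0, , drop = FALSE]
  res <- lp_solve(
    objective = c(rep(0, n), rep(1, ne)),
    lb = lb, ub = ub,
    A_eq = cbind(S, matrix(0, nrow(S), ne)),
    b_eq = rep(0, nrow(S)),
    A_ge = A_abs, b_ge = rep(0, 2 * ne),
    maximize = FALSE
  )
  if (res$status != "optimal") {
    return(new_flux_solution(model, NA_real_, NA_real_, res$status,
                             "transport", "min"))
  }
  new_flux_solution(model, res$x[seq_len(n)], res$objective_value,
                    "optimal", "transport", "min")
}

#' Single-gene knockout scan
#'
#' For every gene (in any GPR), reactions whose GPR evaluates to `FALSE` with
#' that gene removed are bounded to zero and the objective re-optimised.
#' Genes absent from every GPR return the wild-type optimum unchanged.
#'
#' @param model A `stoich_model` with GPRs.
#' @param objective A `flux_objective`; defaults to biomass.
#' @param genes Genes to scan (default: all genes in the model).
#' @param essential_tol Objective values below this flag the gene as essential.
#' @return Tibble: `gene`, `status`, `objective_value`, `essential`.
#' @export
knockout_scan <- function(model, objective = NULL, genes = NULL,
                          essential_tol = 1e-9) {
  objective <- objective %||% biomass_objective(model)
  genes <- genes %||% model$genes
  if (length(genes) == 0) stop("model has no genes in GPRs", call. = FALSE)
  wt <- fba(model, objective, refine = "none")
  rxn_genes <- lapply(model$reactions$gpr, gpr_genes)
  rows <- purrr::map(genes, function(g) {
    affected <- model$reactions$id[vapply(seq_len(nrow(model$reactions)), function(i) {
      g %in% rxn_genes[[i]] && !evaluate_gpr(model$reactions$gpr[i], g)
    }, logical(1))]
    if (length(affected) == 0) {
      return(tibble::tibble(gene = g, status = wt$status,
                            objective_value = wt$objective_value,
                            essential = FALSE))
    }
    m2 <- set_reaction_bounds(model, affected, lower = 0, upper = 0)
    sol <- fba(m2, objective, refine = "none")
    val <- sol$objective_value
    tibble::tibble(gene = g, status = sol$status, objective_value = val,
                   essential = sol$status != "optimal" ||
                     abs(val) < essential_tol)
  })
  dplyr::bind_rows(rows)
}

#' Doubling time from a growth rate
#'
#' @param mu Growth rate, 1/h (biomass flux).
#' @return `log(2) / mu`, hours.
#' @export
doubling_time <- function(mu) {
  if (any(mu <= 0)) stop("doubling time undefined for mu <= 0", call. = FALSE)
  log(2) / mu
}

#' Growth rate from a doubling time
#' @param td Doubling time, hours.
#' @export
growth_rate <- function(td) {
  if (any(td <= 0)) stop("growth rate undefined for td <= 0", call. = FALSE)
  log(2) / td
}

#' Fit an uptake bound so that the FBA optimum meets a target
#'
#' Dials the uptake capacity of one exchange (its lower bound is set to minus
#' the dial value) and bisects until the optimal objective value matches
#' `target`. Assumes the optimum is monotone non-decreasing in the dial over
#' the bracket, which holds for relaxations of a single bound.
#'
#' @param model A `stoich_model`.
#' @param exchange Exchange reaction id to dial.
#' @param target Target objective value.
#' @param objective A `flux_objective`; defaults to biomass.
#' @param tol Absolute tolerance on the achieved objective.
#' @param lower,upper Bracket for the uptake magnitude.
#' @param max_iter Bisection iteration cap.
#' @return The fitted uptake magnitude (positive), with attributes `achieved`
#'   (objective at the fit) and `bracket`.
#' @export
fit_uptake_to_target <- function(model, exchange, target, objective = NULL,
                                 tol = 1e-6, lower = 0, upper = pf_big(),
                                 max_iter = 200) {
  objective <- objective %||% biomass_objective(model)
  if (!exchange %in% exchange_reactions(model)) {
    stop(exchange, " is not an exchange reaction", call. = FALSE)
  }
  f <- function(u) {
    m <- set_reaction_bounds(model, exchange, lower = -u)
    sol <- fba(m, objective, refine = "none")
    if (sol$status != "optimal") -Inf else sol$objective_value
  }
  f_lo <- f(lower)
  f_hi <- f(upper)
  if (target < f_lo - tol || target > f_hi + tol) {
    stop(sprintf(
      "target %.6g outside achievable range [%.6g, %.6g] for dial %s",
      target, f_lo, f_hi, exchange), call. = FALSE)
  }
  lo <- lower; hi <- upper
  mid <- (lo + hi) / 2; f_mid <- f(mid)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (abs(f_mid - target) <= tol) break
    if (f_mid < target) lo <- mid else hi <- mid
  }
  structure(mid, achieved = f_mid, bracket = c(lower = lower, upper = upper))
}
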