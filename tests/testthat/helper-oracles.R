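# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: dominance by double loop, fronts by epsilon-constraint
# sweeps, optima by closed-form arithmetic on the toy network.

# Analytic facts about the toy phototroph (P photons, A acetate):
# growth needs 10 c + 1 red + 15 atp per unit; ACT yields c and red 1:1, so
# 9 red per growth unit must leave via nitrogenase (2 atp each) = 33 atp/unit;
# max growth = min(A/10, 2P/33). Max H2 fully oxidises: 2 red per acetate,
# 2 atp per H2 -> H2 = 2A when 2P >= 4A.
toy_max_growth <- function(P, A) min(A / 10, 2 * P / 33)
toy_max_h2 <- function(P, A) min(2 * A, 2 * P / 2)

# O(N^2) brute-force Pareto filter (maximisation sense), duplicate-aware.
oracle_pareto_filter <- function(M, tol = 1e-6) {
  n <- nrow(M)
  keep <- rep(TRUE, n)
  digits <- max(0L, ceiling(-log10(tol)))
  seen <- character(0)
  for (i in seq_len(n)) {
    key <- paste(round(M[i, ], digits), collapse = "|")
    if (key %in% seen) { keep[i] <- FALSE; next }
    seen <- c(seen, key)
  }
  for (i in which(keep)) {
    for (j in which(keep)) {
      if (i == j) next
      d <- M[j, ] - M[i, ]
      if (all(d >= -tol) && any(d > tol)) { keep[i] <- FALSE; break }
    }
  }
  which(keep)
}

# Epsilon-constraint sweep: maximise objective 2 subject to objective 1 >= t.
# Independent of the NNC path (no anchors, no normalisation, no lattice).
epsilon_constraint_point <- function(model, obj1, obj2, t) {
  c1 <- paretoflux:::objective_vector(model, obj1)
  c2 <- paretoflux:::objective_vector(model, obj2)
  res <- paretoflux:::fba_lp(model, c2, maximize = TRUE,
                             A_ge = matrix(c1, nrow = 1), b_ge = t)
  if (res$status != "optimal") return(NULL)
  c(obj1 = sum(c1 * res$x), obj2 = res$objective_value)
}

# Explicit dual of max c'v s.t. S v = 0, l <= v <= u:
#   min u' mu_u - l' mu_l  s.t.  S' y + mu_u - mu_l = c, mu >= 0, y free.
# Solved through the same LP interface but as a different problem entirely.
dual_bound <- function(model, obj_coefs, y_cap = 1e5) {
  S <- model$S[rowSums(model$S != 0) > 0, , drop = FALSE]
  m <- nrow(S); n <- ncol(S)
  lb <- c(rep(-y_cap, m), rep(0, 2 * n))
  ub <- c(rep(y_cap, m), rep(y_cap, 2 * n))
  A_eq <- cbind(t(S), diag(n), -diag(n))
  cc <- c(rep(0, m), model$reactions$upper, -model$reactions$lower)
  res <- paretoflux:::lp_solve(cc, lb, ub, A_eq = A_eq, b_eq = obj_coefs,
                               maximize = FALSE)
  stopifnot(res$status == "optimal")
  res$objective_value
}

# Two-branch network for expression-constrained runs: substrate -> hub ->
# one of two exports; branch choice is free at reference.
make_branch_model <- function(cap = 10) {
  rx <- tibble::tribble(
    ~id, ~equation, ~lower, ~upper, ~gpr,
    "T",     "s -> m",  0, 1e6, "gT",
    "B1",    "m -> p1", 0, 1e6, "gB1",
    "B2",    "m -> p2", 0, 1e6, "gB2",
    "EX_s",  "s ->",  -cap, 0,  NA,
    "EX_p1", "p1 ->",   0, 1e6, NA,
    "EX_p2", "p2 ->",   0, 1e6, NA
  )
  parsed <- purrr::map2(rx$equation, seq_len(nrow(rx)),
                        paretoflux:::parse_reaction_equation)
  stoich <- dplyr::bind_rows(purrr::map2(parsed, rx$id, function(p, id) {
    dplyr::mutate(p$stoich, reaction = id)
  }))
  stoich_model(
    metabolites = tibble::tibble(id = c("s", "m", "p1", "p2")),
    reactions = tibble::tibble(id = rx$id, lower = rx$lower, upper = rx$upper,
                               gpr = rx$gpr),
    stoichiometry = stoich[, c("reaction", "metabolite", "coefficient")]
  )
}

branch_medium <- function(cap = 10) {
  medium_config(list(EX_s = list(uptake_max = cap)))
}

export_objective <- function() {
  flux_objective(c(EX_p1 = 1, EX_p2 = 1), "max", "export")
}
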