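toy <- make_toy(P = 50, A = 10)

test_that("FBA optimum matches the closed-form toy value and its dual bound", {
  sol <- fba(toy)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, toy_max_growth(50, 10), tolerance = 1e-6)

  # steady state and bounds hold
  v <- fluxes(sol)
  expect_lt(max(abs(toy$S %*% v)), 1e-8)
  expect_true(all(v >= toy$reactions$lower - 1e-8))
  expect_true(all(v <= toy$reactions$upper + 1e-8))

  # strong duality: primal optimum equals the explicit dual optimum
  obj <- paretoflux:::objective_vector(toy, biomass_objective(toy))
  expect_equal(sol$objective_value, dual_bound(toy, obj), tolerance = 1e-6)

  # light-limited regime: optimum = 2P/33
  for (P in c(8, 12, 16)) {
    m <- make_toy(P = P, A = 10)
    expect_equal(fba(m)$objective_value, toy_max_growth(P, 10), tolerance = 1e-8)
  }

  # all uptakes closed -> zero growth
  closed <- apply_medium(toy, medium_config(list()))
  expect_equal(fba(closed)$objective_value, 0, tolerance = 1e-9)
})

test_that("FBA optimum is monotone in relaxed exchange bounds", {
  vals <- vapply(c(5, 10, 16.5, 25, 50), function(P) {
    fba(make_toy(P = P, A = 10))$objective_value
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
  vals_a <- vapply(c(2, 5, 10, 20), function(A) {
    fba(make_toy(P = 50, A = A))$objective_value
  }, numeric(1))
  expect_true(all(diff(vals_a) >= -1e-9))
})

test_that("FVA envelopes match per-reaction LP pairs and contain the FBA fluxes", {
  env <- fva(toy, biomass_fraction = 0)
  # oracle: each envelope bound re-derived with a direct single-flux LP
  for (rid in c("ACT", "FIX_A", "FIX_B", "NIT", "EX_h2", "BIOSYN")) {
    e <- stats::setNames(numeric(nrow(toy$reactions)), toy$reactions$id)
    e[rid] <- 1
    lo <- paretoflux:::fba_lp(toy, e, maximize = FALSE)$objective_value
    hi <- paretoflux:::fba_lp(toy, e, maximize = TRUE)$objective_value
    row <- env[env$reaction == rid, ]
    expect_equal(row$min, lo, tolerance = 1e-8)
    expect_equal(row$max, hi, tolerance = 1e-8)
  }
  expect_true(all(env$min <= env$max + 1e-9))
  v <- fluxes(fba(toy))
  expect_true(all(v >= env$min[match(names(v), env$reaction)] - 1e-6))
  expect_true(all(v <= env$max[match(names(v), env$reaction)] + 1e-6))

  # a blocked reaction has a degenerate envelope
  blocked <- paretoflux:::set_reaction_bounds(toy, "BYP", lower = 0, upper = 0)
  be <- fva(blocked, reactions = "BYP")
  expect_equal(c(be$min, be$max), c(0, 0))

  # linear chain: every envelope equals the uptake cap
  chain <- make_branch_model(cap = 2)
  chain <- paretoflux:::set_reaction_bounds(chain, "B2", lower = 0, upper = 0)
  ce <- fva(chain, reactions = c("T", "B1", "EX_p1"))
  expect_equal(ce$min, rep(0, 3), tolerance = 1e-9)
  expect_equal(ce$max, rep(2, 3), tolerance = 1e-9)
})

test_that("FVA with a biomass floor respects the floor", {
  env <- fva(toy, biomass_fraction = 0.9, reactions = c("BIOSYN", "EX_h2"))
  expect_gte(env$min[env$reaction == "BIOSYN"], 0.9 - 1e-8)
})

test_that("transport minimisation achieves the analytic optimum", {
  # at the growth optimum (mu = 1): photon 16.5 + acetate 10 + H2 9 + biomass 1
  sol <- minimize_total_transport(toy, fixed = c(BIOSYN = 1))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 36.5, tolerance = 1e-6)

  # no demand, no maintenance -> all exchanges silent
  rest <- minimize_total_transport(toy, fixed = c(BIOSYN = 0))
  expect_equal(rest$objective_value, 0, tolerance = 1e-9)
  expect_lt(max(abs(fluxes(rest)[exchange_reactions(toy)])), 1e-8)

  # minimal medium: the optimal transport profile is unique -- FVA restricted
  # to the transport optimum collapses every exchange envelope to a point
  m <- paretoflux:::set_reaction_bounds(toy, "BIOSYN", lower = 1, upper = 1)
  v <- fluxes(sol)
  for (rid in exchange_reactions(toy)) {
    e <- stats::setNames(numeric(nrow(m$reactions)), m$reactions$id)
    e[rid] <- 1
    # pin the transport sum at its optimum via the signed linear form
    tr <- paretoflux:::objective_vector(m, transport_objective(m))
    lo <- paretoflux:::fba_lp(m, e, maximize = FALSE,
                              A_ge = rbind(-tr), b_ge = -36.5 - 1e-7)
    hi <- paretoflux:::fba_lp(m, e, maximize = TRUE,
                              A_ge = rbind(-tr), b_ge = -36.5 - 1e-7)
    expect_equal(lo$objective_value, hi$objective_value, tolerance = 1e-5)
    expect_equal(lo$objective_value, v[[rid]], tolerance = 1e-5)
  }

  infeasible <- minimize_total_transport(toy, fixed = c(BIOSYN = 5))
  expect_equal(infeasible$status, "infeasible")
})

test_that("knockout scan flags the right essential genes", {
  ks <- knockout_scan(toy)
  ess <- ks$gene[ks$essential]
  # the only ATP source, biomass synthesis, and the obligatory electron sink
  expect_setequal(ess, c("gLHC", "gBIO", "gNIT1", "gNIT2"))
  # oracle: removing LHC by hand reproduces the knockout value
  no_lhc <- paretoflux:::set_reaction_bounds(toy, "LHC", lower = 0, upper = 0)
  expect_equal(ks$objective_value[ks$gene == "gLHC"],
               fba(no_lhc, refine = "none")$objective_value, tolerance = 1e-9)
  # isozymes: each single knockout retains the wild-type optimum
  wt <- fba(toy, refine = "none")$objective_value
  expect_equal(ks$objective_value[ks$gene == "gACT1"], wt, tolerance = 1e-9)
  expect_equal(ks$objective_value[ks$gene == "gACT2"], wt, tolerance = 1e-9)
  # but the double knockout is lethal (GPR semantics)
  expect_false(evaluate_gpr("(gACT1 or gACT2)", c("gACT1", "gACT2")))
  both <- paretoflux:::set_reaction_bounds(toy, "ACT", lower = 0, upper = 0)
  expect_equal(fba(both)$objective_value, 0, tolerance = 1e-9)
  # a gene in no GPR leaves the optimum untouched
  ks2 <- knockout_scan(toy, genes = "gGHOST")
  expect_equal(ks2$objective_value, wt, tolerance = 1e-12)
  expect_false(ks2$essential)
})

test_that("doubling-time conversions are exact inverses", {
  expect_equal(doubling_time(log(2) / 6.4), 6.4)
  expect_equal(doubling_time(0.0825), 8.4, tolerance = 0.01)
  expect_equal(growth_rate(doubling_time(0.31)), 0.31)
  expect_error(doubling_time(0), "undefined")
  expect_error(doubling_time(-1), "undefined")
})

test_that("uptake fitting recovers the dialled bound by bisection", {
  # dial acetate so growth is half the unconstrained value: closed form A = 5
  target <- toy_max_growth(50, 10) / 2
  fit <- fit_uptake_to_target(toy, "EX_ac", target, tol = 1e-8, upper = 10)
  expect_equal(as.numeric(fit), 5, tolerance = 1e-4)
  expect_equal(attr(fit, "achieved"), target, tolerance = 1e-8)
  # oracle: brute scan at 1e-4 steps around the fit
  grid <- seq(4.99, 5.01, by = 1e-4)
  ix <- which.min(abs(vapply(grid, function(a) {
    fba(paretoflux:::set_reaction_bounds(toy, "EX_ac", lower = -a),
        refine = "none")$objective_value
  }, numeric(1)) - target))
  expect_equal(as.numeric(fit), grid[ix], tolerance = 2e-4)
  # photon dial in the light-limited regime: mu = 2P/33
  fitP <- fit_uptake_to_target(make_toy(P = 50, A = 10), "EX_photon",
                               target = 0.4, tol = 1e-8, upper = 50)
  expect_equal(as.numeric(fitP), 0.4 * 33 / 2, tolerance = 1e-4)
  expect_error(fit_uptake_to_target(toy, "EX_ac", 99, upper = 10),
               "outside achievable range")
})
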