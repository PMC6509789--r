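toy <- make_toy(P = 50, A = 10)
two_obj <- list(biomass_objective(toy), reaction_objective("EX_h2", label = "H2"))

test_that("utopia lattice counts follow the simplex closed form", {
  expect_equal(nrow(generate_utopia_lattice(2, 10)), 11)
  expect_equal(nrow(generate_utopia_lattice(3, 5)), choose(7, 2))
  expect_equal(nrow(generate_utopia_lattice(8, 10)), 19448)
  expect_equal(nrow(generate_utopia_lattice(8, 10)), choose(17, 7))
  W <- generate_utopia_lattice(4, 6)
  expect_equal(nrow(W), choose(9, 3))
  expect_true(all(abs(rowSums(W) - 1) < 1e-12))
  expect_true(all(W >= 0))
  expect_true(all(abs(W * 6 - round(W * 6)) < 1e-9))
  # deterministic lexicographic order, no duplicates
  keys <- apply(W, 1, paste, collapse = ",")
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(keys, apply(generate_utopia_lattice(4, 6), 1,
                               paste, collapse = ","))
})

test_that("anchors attain 1 in their own normalised coordinate; H2 anchor stops growth", {
  prob <- mofa_problem(toy, two_obj, spacing = 10)
  geo <- compute_anchor_points(prob)
  expect_equal(diag(geo$anchors_norm), c(1, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(geo$anchors_norm >= -1e-9 & geo$anchors_norm <= 1 + 1e-9))
  # anchor raw values match direct single-objective FBA
  expect_equal(geo$anchors_raw[1, 1], fba(toy)$objective_value, tolerance = 1e-9)
  expect_equal(geo$anchors_raw[2, 2],
               fba(toy, two_obj[[2]])$objective_value, tolerance = 1e-9)
  # maximum theoretical H2 production ceases growth
  expect_equal(geo$anchors_raw[2, 1], 0, tolerance = 1e-9)
})

test_that("lattice corner weights recover the anchors", {
  prob <- mofa_problem(toy, two_obj, spacing = 10)
  geo <- compute_anchor_points(prob)
  for (k in 1:2) {
    w <- c(0, 0); w[k] <- 1
    res <- solve_lattice_point(prob, geo, w)
    expect_true(res$feasible)
    expect_equal(res$norm, unname(geo$anchors_norm[k, ]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("the NNC front agrees pointwise with an epsilon-constraint sweep", {
  prob <- mofa_problem(toy, two_obj, spacing = 10)
  front <- run_mofa(prob)
  tt <- tidy(front)
  for (i in seq_len(nrow(tt))) {
    oracle <- epsilon_constraint_point(toy, two_obj[[1]], two_obj[[2]],
                                       t = tt$raw_growth[i])
    expect_equal(tt$raw_H2[i], oracle[["obj2"]], tolerance = 1e-6)
  }
  # trade-off monotone: sorted by growth, H2 non-increasing
  ord <- order(tt$raw_growth)
  expect_true(all(diff(tt$raw_H2[ord]) <= 1e-9))
  # toy closed form: H2 = 20 - 11 mu along the front
  expect_equal(tt$raw_H2, 20 - 11 * tt$raw_growth, tolerance = 1e-6)
  # any solution with H2 above the growth anchor's level grows strictly slower
  anchor_growth <- max(tt$raw_growth)
  anchor_h2 <- tt$raw_H2[which.max(tt$raw_growth)]
  above <- tt$raw_H2 > anchor_h2 + 1e-9
  expect_true(all(tt$raw_growth[above] < anchor_growth - 1e-9))
})

test_that("pareto_filter matches a quadratic dominance oracle on 500 random vectors", {
  set.seed(7)
  M <- matrix(stats::runif(500 * 3), 500, 3)
  # seed some duplicates and dominated copies
  M[51:60, ] <- M[1:10, ]
  M[61:70, ] <- pmax(M[11:20, ] - 0.2, 0)
  expect_identical(pareto_filter(M, tol = 1e-6), oracle_pareto_filter(M, 1e-6))

  simple <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5), c(0.4, 0.4))
  expect_identical(pareto_filter(simple), c(1L, 2L, 3L))
  expect_identical(pareto_filter(matrix(c(0.3, 0.3), 1)), 1L)
})

test_that("the filtered front is internally non-dominated and normalised to [0,1]", {
  prob3 <- mofa_problem(toy, list(
    biomass_objective(toy),
    reaction_objective("EX_h2", label = "H2"),
    reaction_objective("EX_co2", label = "CO2")
  ), spacing = 5)
  front <- run_mofa(prob3)
  N <- do.call(rbind, front$solutions$norm)
  expect_true(all(N >= -1e-6 & N <= 1 + 1e-6))
  expect_identical(pareto_filter(N, 1e-6), seq_len(nrow(N)))
  # every front point survives a dense epsilon-constraint oracle:
  # no feasible point dominates it
  geo <- front$geometry
  c1 <- paretoflux:::objective_vector(toy, prob3$objectives[[1]])
  c2 <- paretoflux:::objective_vector(toy, prob3$objectives[[2]])
  c3 <- paretoflux:::objective_vector(toy, prob3$objectives[[3]])
  for (i in seq_len(nrow(front$solutions))) {
    raw <- front$solutions$raw[[i]]
    best3 <- paretoflux:::fba_lp(
      toy, c3, maximize = TRUE,
      A_ge = rbind(c1, c2), b_ge = c(raw[[1]], raw[[2]]))
    expect_equal(best3$objective_value, raw[[3]], tolerance = 1e-6)
  }
})

test_that("the normalised front is invariant to objective rescaling", {
  prob <- mofa_problem(toy, two_obj, spacing = 10)
  f1 <- run_mofa(prob)
  scaled <- list(
    two_obj[[1]],
    flux_objective(c(EX_h2 = 1000), "max", "H2")
  )
  f2 <- run_mofa(mofa_problem(toy, scaled, spacing = 10))
  n1 <- do.call(rbind, f1$solutions$norm)
  n2 <- do.call(rbind, f2$solutions$norm)
  expect_equal(n1, n2, tolerance = 1e-6)
})

test_that("repeated runs are deterministic", {
  prob3 <- mofa_problem(toy, list(
    biomass_objective(toy),
    reaction_objective("EX_h2", label = "H2"),
    reaction_objective("EX_byp", label = "byproduct")
  ), spacing = 5)
  f1 <- run_mofa(prob3)
  f2 <- run_mofa(prob3)
  expect_equal(do.call(rbind, f1$all$norm), do.call(rbind, f2$all$norm),
               tolerance = 1e-12)
  expect_equal(nrow(f1$solutions), nrow(f2$solutions))
})

test_that("front export round-trips and autoplot builds", {
  front <- run_mofa(mofa_problem(toy, two_obj, spacing = 10))
  path <- withr::local_tempfile(fileext = ".tsv")
  export_front(front, path)
  back <- read_front(path)
  expect_equal(nrow(back), nrow(front$solutions))
  expect_true(all(c("norm_growth", "norm_H2", "raw_growth", "raw_H2") %in%
                    names(back)))
  norms <- as.matrix(back[, c("norm_growth", "norm_H2")])
  expect_true(all(norms >= -1e-6 & norms <= 1 + 1e-6))
  p <- autoplot(front)
  expect_s3_class(p, "ggplot")
})

test_that("infeasible lattice points are skipped, not fatal", {
  # pin growth so high that most lattice points cannot reach their plane
  pinned <- paretoflux:::set_reaction_bounds(toy, "BIOSYN", lower = 1, upper = 1)
  prob <- mofa_problem(pinned, list(
    reaction_objective("EX_h2", label = "H2"),
    reaction_objective("EX_co2", label = "CO2")
  ), spacing = 4)
  front <- run_mofa(prob)
  expect_s3_class(front, "pareto_front")
  expect_gte(front$n_skipped, 0)
})
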