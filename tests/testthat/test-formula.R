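test_that("formula parsing handles real subscripts and trailing charges", {
  f <- parse_formula("CH1.93O0.54N0.22")
  expect_equal(f$counts[["C"]], 1)
  expect_equal(f$counts[["H"]], 1.93)
  expect_equal(f$counts[["O"]], 0.54)
  expect_equal(f$counts[["N"]], 0.22)
  expect_equal(f$charge, 0)

  co2 <- parse_formula("CO2")
  expect_equal(co2$counts, c(C = 1, O = 2))

  nh4 <- parse_formula("NH4+")
  expect_equal(nh4$counts[["H"]], 4)
  expect_equal(nh4$charge, 1)
  expect_equal(parse_formula("SO4-2")$charge, -2)
  expect_equal(parse_formula("Fe+3")$charge, 3)

  expect_error(parse_formula("Xx2"), "unknown element")
  expect_error(parse_formula(""), "empty")
})

test_that("degree of reduction reproduces the published per-C-mole values", {
  expect_equal(degree_of_reduction("CH1.93O0.54N0.22"), 4.19, tolerance = 1e-12)
  expect_equal(degree_of_reduction("CH1.8O0.5N0.2"), 4.2, tolerance = 1e-12)
  expect_equal(degree_of_reduction("C2H4O2"), 4)    # acetic acid
  expect_equal(degree_of_reduction("C4H6O4"), 3.5)  # succinic acid
  expect_equal(degree_of_reduction("C5H6O5"), 3.2)  # alpha-ketoglutaric acid
  expect_equal(degree_of_reduction("CO2"), 0)
  expect_error(degree_of_reduction("H2O"), "carbon-free")
})

test_that("kappa is linear under carbon-weighted formula mixing", {
  formulas <- c("C2H4O2", "C4H6O4", "CH1.93O0.54N0.22", "C9H8O3")
  set.seed(11)
  for (rep in 1:20) {
    pick <- sample(formulas, 2)
    w <- runif(1)
    f1 <- parse_formula(pick[1]); f2 <- parse_formula(pick[2])
    c1 <- f1$counts[["C"]]; c2 <- f2$counts[["C"]]
    blend_counts <- numeric(0)
    for (el in union(names(f1$counts), names(f2$counts))) {
      blend_counts[el] <- w * (if (el %in% names(f1$counts)) f1$counts[[el]] else 0) +
        (1 - w) * (if (el %in% names(f2$counts)) f2$counts[[el]] else 0)
    }
    blend <- structure(list(counts = blend_counts, charge = 0),
                       class = "elemental_formula")
    carbon_weight <- w * c1 / (w * c1 + (1 - w) * c2)
    expected <- carbon_weight * degree_of_reduction(f1) +
      (1 - carbon_weight) * degree_of_reduction(f2)
    expect_equal(degree_of_reduction(blend), expected, tolerance = 1e-10)
  }
})

test_that("the three neutral aromatic acids average kappa = 4.17", {
  aromatics <- c(coumarate = "C9H8O3", benzoate = "C7H6O2", hydroxybenzoate = "C7H6O3")
  avg <- mean(vapply(aromatics, degree_of_reduction, numeric(1)))
  expect_equal(round(avg, 2), 4.17)
})

test_that("lumped conversion equations balance per element within 0.02", {
  eqs <- c(
    coumarate_to_biomass =
      "CH0.78O0.33 + 0.22 NH4+ + 0.21 H2O -> CH1.93O0.54N0.22 + 0.15 H+",
    benzoate_to_biomass =
      "CH0.71O0.29 + 0.22 NH4+ + 0.25 H2O -> CH1.93O0.54N0.22 + 0.16 H+",
    hydroxybenzoate_to_biomass =
      "CH0.71O0.43 + 0.22 NH4+ + 0.11 H2O + 0.12 H+ -> CH1.93O0.54N0.22",
    hydroxybenzoate_with_co2 =
      "CH0.71O0.43 + 0.2 NH4+ + 0.26 H2O -> 0.9 CH1.93O0.54N0.22 + 0.1 CO2 + 0.29 H+",
    acetate_to_biomass =
      "CH1.5O + 0.05 H+ + 0.17 NH4+ -> 0.76 CH1.93O0.54N0.22 + 0.29 H2O + 0.06 CO2 + 0.18 CHO"
  )
  for (nm in names(eqs)) {
    rep <- check_overall_equation(eqs[[nm]], tol = 0.02)
    expect_true(rep$balanced, label = paste(nm, "balanced"))
    expect_lt(max(abs(rep$per_element_residual)), 0.02)
  }
})

test_that("balance reports catch imbalance and identity cases", {
  ident <- check_overall_equation("H2O -> H2O")
  expect_true(ident$balanced)
  expect_equal(unname(ident$per_element_residual), c(0, 0))

  bad <- check_overall_equation("CH4 -> CO2", tol = 0.02)
  expect_false(bad$balanced)
  expect_equal(bad$per_element_residual[["H"]], 4)
  expect_equal(bad$per_element_residual[["O"]], -2)

  expect_error(
    check_overall_equation(lhs = data.frame(coef = -1, formula = "CO2"),
                           rhs = data.frame(coef = 1, formula = "CO2")),
    "non-negative")

  td <- tidy(check_overall_equation("CO2 -> CO2"))
  expect_true(all(td$within_tol))
  expect_true("charge" %in% td$component)
})
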