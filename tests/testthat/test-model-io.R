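test_that("GPR evaluation matches brute-force truth tables up to 6 genes", {
  exprs <- c(
    "(g1 and g2)",
    "(g1 or g2)",
    "((g1 and g2) or g3)",
    "(g1 and (g2 or g3) and g4)",
    "((g1 or g2) and (g3 or (g4 and g5)))",
    "(((g1 and g2) or (g3 and g4)) or (g5 and g6))"
  )
  brute <- function(gpr, alive) {
    txt <- gpr
    for (g in paste0("g", 1:6)) {
      txt <- gsub(paste0("\\b", g, "\\b"),
                  if (g %in% alive) "TRUE" else "FALSE", txt)
    }
    txt <- gsub("and", "&&", txt); txt <- gsub("or", "||", txt)
    eval(parse(text = txt))
  }
  for (e in exprs) {
    genes <- gpr_genes(e)
    n <- length(genes)
    for (mask in 0:(2^n - 1)) {
      alive <- genes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      ko <- setdiff(genes, alive)
      expect_identical(evaluate_gpr(e, ko), brute(e, alive),
                       label = paste(e, "ko:", paste(ko, collapse = ",")))
    }
  }
  expect_false(evaluate_gpr("(g1 and g2)", "g1"))
  expect_true(evaluate_gpr("(g1 or g2)", "g1"))
  expect_false(evaluate_gpr("((g1 and g2) or g3)", c("g1", "g3")))
  expect_true(evaluate_gpr(NA, "g1"))
  expect_error(evaluate_gpr("g1 and (g2", "g1"), "parse")
  expect_error(evaluate_gpr("g1 and or g2"), "parse")
})

test_that("tabular equations parse to the expected stoichiometry", {
  p <- paretoflux:::parse_reaction_equation("photon -> 2 atp")
  expect_equal(p$stoich$coefficient[p$stoich$metabolite == "photon"], -1)
  expect_equal(p$stoich$coefficient[p$stoich$metabolite == "atp"], 2)
  expect_false(p$reversible)
  expect_true(paretoflux:::parse_reaction_equation("a <-> b")$reversible)
  expect_error(paretoflux:::parse_reaction_equation("a b c", 7), "line 7")
})

test_that("tabular round trip preserves the model; duplicates are rejected", {
  toy <- make_toy(P = 50, A = 10)
  dir <- withr::local_tempdir()
  rx_path <- file.path(dir, "toy.tsv")
  met_path <- file.path(dir, "toy_mets.tsv")
  write_tabular_model(toy, rx_path, met_path)
  back <- read_tabular_model(rx_path, metabolites = met_path, biomass = "BIOSYN")
  expect_setequal(back$reactions$id, toy$reactions$id)
  expect_equal(back$S[rownames(toy$S), colnames(toy$S)], toy$S)
  expect_equal(
    back$reactions$lower[match(toy$reactions$id, back$reactions$id)],
    toy$reactions$lower)
  expect_equal(
    back$reactions$gpr[match(toy$reactions$id, back$reactions$id)],
    toy$reactions$gpr)

  dup <- "reaction_id\tequation\tlower\tupper\tgpr\nR1\ta -> b\t0\t10\t\nR1\tb -> c\t0\t10\t\n"
  dup_path <- file.path(dir, "dup.tsv")
  writeLines(dup, dup_path)
  expect_error(read_tabular_model(dup_path), "duplicate")

  full <- read_tabular_model(rx_path, metabolites = met_path, biomass = "BIOSYN")
  sol <- fba(full)
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective_value, 0)
})

test_that("SBML round trip preserves S, bounds and GPR semantics", {
  toy <- make_toy(P = 50, A = 10)
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(toy, path)
  back <- read_sbml(path)
  expect_equal(nrow(back$metabolites), nrow(toy$metabolites))
  expect_equal(nrow(back$reactions), nrow(toy$reactions))
  expect_equal(back$S[rownames(toy$S), colnames(toy$S)], toy$S)
  ord <- match(toy$reactions$id, back$reactions$id)
  expect_equal(back$reactions$lower[ord], toy$reactions$lower)
  expect_equal(back$reactions$upper[ord], toy$reactions$upper)
  expect_equal(back$biomass_reaction_id, "BIOSYN")
  # GPR semantic equivalence under every single-gene knockout
  for (i in seq_along(toy$reactions$id)) {
    g_orig <- toy$reactions$gpr[i]
    g_back <- back$reactions$gpr[ord][i]
    for (g in gpr_genes(g_orig)) {
      expect_identical(evaluate_gpr(g_back, g), evaluate_gpr(g_orig, g),
                       label = paste(toy$reactions$id[i], "ko", g))
    }
  }
  # formulas/charges survive
  expect_equal(
    back$metabolites$formula[match("ac", back$metabolites$id)], "CH4O2")

  # one-reaction round trip identity
  tiny <- stoich_model(
    metabolites = tibble::tibble(id = c("a", "b")),
    reactions = tibble::tibble(id = "R1", lower = -3, upper = 7,
                               gpr = "((g1 and g2) or g3)"),
    stoichiometry = tibble::tibble(reaction = "R1", metabolite = c("a", "b"),
                                   coefficient = c(-1, 2)))
  p2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(tiny, p2)
  tiny2 <- read_sbml(p2)
  expect_equal(tiny2$S[rownames(tiny$S), colnames(tiny$S), drop = FALSE], tiny$S)
  expect_equal(tiny2$reactions$lower, -3)
  expect_false(evaluate_gpr(tiny2$reactions$gpr[1], c("g1", "g3")))
  expect_true(evaluate_gpr(tiny2$reactions$gpr[1], "g1"))

  empty <- tiny
  empty$metabolites <- tiny$metabolites[0, ]
  expect_error(write_sbml(empty, path), "empty model")
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model>", bad)
  expect_error(read_sbml(bad), "malformed")
})

test_that("applying a medium closes unlisted uptakes and sets listed bounds", {
  toy <- make_toy(P = 50, A = 10)
  med <- medium_config(list(EX_photon = list(uptake_max = 20),
                            EX_ac = list(uptake_max = 4)))
  m <- apply_medium(toy, med)
  expect_equal(m$reactions$lower[m$reactions$id == "EX_photon"], -20)
  expect_equal(m$reactions$lower[m$reactions$id == "EX_ac"], -4)
  expect_equal(m$reactions$lower[m$reactions$id == "EX_co2"], 0)

  # empty medium: nothing to eat, growth 0
  starved <- apply_medium(toy, medium_config(list()))
  expect_equal(fba(starved)$objective_value, 0, tolerance = 1e-9)

  expect_error(apply_medium(toy, medium_config(list(BIOSYN = list(uptake_max = 1)))),
               "not exchange")

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("exchanges:",
               "  EX_ac: {uptake_max: 1.96}",
               "  EX_photon: {uptake_max: unlimited}"), path)
  y <- read_medium(path)
  expect_equal(y$lower[y$reaction == "EX_ac"], -1.96)
  expect_equal(y$lower[y$reaction == "EX_photon"], -1e6)
})

test_that("model invariants are enforced", {
  expect_error(
    stoich_model(
      metabolites = tibble::tibble(id = c("a", "a")),
      reactions = tibble::tibble(id = "R", lower = 0, upper = 1),
      stoichiometry = tibble::tibble(reaction = "R", metabolite = "a",
                                     coefficient = 1)),
    "duplicate metabolite")
  expect_error(
    stoich_model(
      metabolites = tibble::tibble(id = "a"),
      reactions = tibble::tibble(id = "R", lower = 2, upper = 1),
      stoichiometry = tibble::tibble(reaction = "R", metabolite = "a",
                                     coefficient = 1)),
    "lower > upper")
})
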