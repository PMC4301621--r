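test_that("equation parsing covers arrows, coefficients and exchanges", {
  eq <- parse_reaction_equation("2 A[c] + 3 B[c] -> C[m]")
  expect_equal(eq$stoich, c("A[c]" = -2, "B[c]" = -3, "C[m]" = 1))
  expect_false(eq$reversible)
  expect_true(parse_reaction_equation("A[c] <=> B[c]")$reversible)
  expect_true(parse_reaction_equation("A[c] <-> B[c]")$reversible)
  ex <- parse_reaction_equation("1 glc[e] <=> ")
  expect_equal(ex$stoich, c("glc[e]" = -1))
  expect_equal(parse_reaction_equation("0.5 A[c]+B[c]=>C[c]")$stoich,
               c("A[c]" = -0.5, "B[c]" = -1, "C[c]" = 1))
  expect_error(parse_reaction_equation("A[c] B[c]"), "arrow")
})

test_that("equation formatting round-trips exact decimals", {
  st <- c("atp[c]" = -30, "x[c]" = -0.173076923076923, "bio[c]" = 1)
  eq <- format_reaction_equation(st, reversible = FALSE)
  back <- parse_reaction_equation(eq)
  expect_equal(back$stoich[names(st)], st)
})

test_that("tabular bundle round-trips the synthetic model losslessly", {
  mod <- get_mini()$model
  dir <- withr::local_tempdir()
  write_tabular_model(mod, dir)
  m2 <- read_tabular_model(dir)
  expect_identical(rxn_ids(mod), rxn_ids(m2))
  expect_identical(mod$metabolites$id, m2$metabolites$id)
  expect_identical(mod$metabolites$formula, m2$metabolites$formula)
  expect_identical(mod$objective, m2$objective)
  expect_identical(mod$genes, m2$genes)
  for (id in rxn_ids(mod)) {
    a <- mod$reactions[[id]]; b <- m2$reactions[[id]]
    expect_equal(a$stoich[sort(names(a$stoich))],
                 b$stoich[sort(names(b$stoich))], info = id)
    expect_identical(c(a$lb, a$ub), c(b$lb, b$ub), info = id)
    expect_identical(a$gpr, b$gpr, info = id)
    expect_identical(a$subsystem, b$subsystem, info = id)
    expect_identical(a$rtype, b$rtype, info = id)
  }
})

test_that("duplicate ids in a bundle are rejected", {
  mod <- toy_chain()
  dir <- withr::local_tempdir()
  write_tabular_model(mod, dir)
  rx <- readLines(file.path(dir, "reactions.tsv"))
  writeLines(c(rx, rx[2]), file.path(dir, "reactions.tsv"))
  expect_error(read_tabular_model(dir), "duplicate")
})

test_that("SBML round-trip preserves structure, bounds, GPR semantics", {
  mod <- get_mini()$model
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(mod, path)
  m2 <- read_sbml(path)
  expect_identical(rxn_ids(mod), rxn_ids(m2))
  expect_identical(mod$objective, m2$objective)
  expect_identical(mod$metabolites$compartment, m2$metabolites$compartment)
  expect_identical(mod$metabolites$formula, m2$metabolites$formula)
  expect_setequal(mod$genes, m2$genes)
  for (id in rxn_ids(mod)) {
    a <- mod$reactions[[id]]; b <- m2$reactions[[id]]
    expect_equal(a$stoich[sort(names(a$stoich))],
                 b$stoich[sort(names(b$stoich))], info = id)
    expect_identical(c(a$lb, a$ub), c(b$lb, b$ub), info = id)
  }
  # GPR semantic equivalence under representative deletions
  for (del in list(character(0), "gDS9a", c("gDS9a", "gDS9b", "gDS9c"),
                   c("gHYD1", "gHYD2"), "gME")) {
    for (id in c("DS9", "DS6", "TE_ARA", "ME", "ATPM"))
      expect_identical(evaluate_gpr(mod$reactions[[id]]$gpr, del),
                       evaluate_gpr(m2$reactions[[id]]$gpr, del),
                       info = paste(id, paste(del, collapse = ",")))
  }
})

test_that("SBML without objective loads; FBA refuses until one is set", {
  mod <- toy_chain()
  mod$objective <- NA_character_
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(mod, path)
  m2 <- read_sbml(path)
  expect_true(is.na(m2$objective))
  expect_error(solve_fba(m2), "objective")
  m2 <- set_objective(m2, "SINK_b")
  expect_equal(solve_fba(m2)$objective_value, 1)
})

test_that("SBML reaction pinned to [0,0] loads blocked; FVA reports [0,0]", {
  mod <- toy_parallel()
  mod <- set_bounds(mod, "Q", 0, 0)
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(mod, path)
  m2 <- read_sbml(path)
  expect_equal(c(m2$reactions[["Q"]]$lb, m2$reactions[["Q"]]$ub), c(0, 0))
  fv <- fva(m2, "Q")
  expect_equal(c(fv$min_flux, fv$max_flux), c(0, 0), tolerance = 1e-9)
})

test_that("hand-written minimal SBML without bounds gets defaults + warning", {
  doc <- paste0(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfCompartments>',
    '<compartment id="c" name="cytosol"/><compartment id="e" name="extracellular"/>',
    '</listOfCompartments><listOfSpecies>',
    '<species id="M_a" name="a[e]" compartment="e"/>',
    '<species id="M_b" name="b[c]" compartment="c"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="R_up" reversible="true"><listOfReactants>',
    '<speciesReference species="M_a" stoichiometry="1"/></listOfReactants></reaction>',
    '<reaction id="R_t" reversible="false">',
    '<listOfReactants><speciesReference species="M_a" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M_b" stoichiometry="1"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(doc, path)
  expect_warning(m <- read_sbml(path), "defaults")
  expect_equal(m$reactions[["up"]]$lb, -1000)
  expect_equal(m$reactions[["t"]]$lb, 0)
})

test_that("write_flux_table emits one row per reaction at 6 significant digits", {
  mod <- toy_branched()
  sol <- solve_fba(mod)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_flux_table(sol, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), length(rxn_ids(mod)))
  expect_named(tab, c("reaction", "flux"))
  fv <- fva(mod, rxn_ids(mod))
  write_flux_table(fv, path)
  expect_named(read.delim(path), c("reaction", "min_flux", "max_flux"))
})

test_that("medium files round-trip", {
  med <- medium_ye()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_medium(med, path)
  m2 <- read_medium(path)
  expect_equal(m2$name, "YE")
  expect_setequal(names(m2$overrides), names(med$overrides))
  expect_equal(m2$overrides[["EX_glc"]], med$overrides[["EX_glc"]])
  expect_setequal(m2$always_open, med$always_open)
  # and the shipped presets parse
  shipped <- read_medium(system.file("extdata", "media", "MG.tsv",
                                     package = "oleoflux"))
  expect_equal(shipped$overrides[["EX_glc"]][1], -0.8)
})
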