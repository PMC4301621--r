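test_that("knockout_gene blocks exactly the reactions its GPR disables", {
  mod <- toy_parallel()
  ko <- knockout_gene(mod, "gP")
  expect_equal(c(ko$reactions[["P"]]$lb, ko$reactions[["P"]]$ub), c(0, 0))
  expect_equal(ko$reactions[["Q"]]$ub, 1000)       # isozyme branch untouched
  expect_error(knockout_gene(mod, "nosuchgene"), "unknown gene")
  # OR-ed isozymes: deleting one leaves the reaction active
  ma <- get_mini()$model
  ko2 <- knockout_gene(ma, "gDS9a")
  expect_equal(ko2$reactions[["DS9"]]$ub, 1000)
  ko3 <- knockout_gene(ma, c("gDS9a", "gDS9b", "gDS9c"))
  expect_equal(ko3$reactions[["DS9"]]$ub, 0)
})

test_that("empty knockout returns the reference with distance zero", {
  mod <- toy_chain()
  ref <- solve_fba(mod)
  sol <- solve_moma(mod, ref)
  expect_equal(sol$status, "optimal")
  expect_lt(sol$distance, 1e-7)
  expect_equal(sol$flux, ref$flux, tolerance = 1e-6)
})

test_that("parallel-branch knockout: flux moves to the isozyme branch", {
  mod <- toy_parallel()
  ref <- setNames(c(-1, 1, 1, 0, 1), rxn_ids(mod))  # all flux through P
  # spec scenario: auxiliary fluxes pinned at the reference, only P/Q free
  pinned <- mod
  for (id in c("EX_a", "T_a", "SINK_b"))
    pinned <- set_bounds(pinned, id, ref[[id]], ref[[id]])
  sol <- solve_moma(knockout_gene(pinned, "gP"), ref)
  expect_equal(sol$distance, sqrt(2), tolerance = 1e-6)
  expect_equal(unname(sol$flux[["Q"]]), 1, tolerance = 1e-6)
  # free projection: throughput relaxes to 3/4, distance sqrt(7)/2
  free <- solve_moma(knockout_gene(mod, "gP"), ref)
  expect_equal(free$distance, sqrt(1.75), tolerance = 1e-6)
  expect_equal(unname(free$flux[["Q"]]), 0.75, tolerance = 1e-6)
})

test_that("MOMA equals the Dykstra projection oracle on small problems", {
  set.seed(21)
  for (make in list(toy_chain, toy_parallel, toy_branched)) {
    mod <- make()
    ref <- solve_fba(mod)
    # perturb the reference so the projection is non-trivial
    vref <- ref$flux + round(runif(length(ref$flux), -0.3, 0.3), 2)
    p <- moma_problem(mod)
    want <- oracle_moma(p$S, p$lb, p$ub, as.numeric(vref))
    got <- solve_moma(mod, setNames(vref, names(ref$flux)))
    expect_equal(as.numeric(got$flux), want, tolerance = 1e-6,
                 info = mod$id)
  }
})

test_that("MOMA is invariant under reaction reordering", {
  mod <- toy_branched()
  ref <- solve_fba(mod)
  vref <- ref$flux + 0.1
  d1 <- solve_moma(mod, vref)$distance
  perm <- mod
  set.seed(5)
  perm$reactions <- perm$reactions[sample(length(perm$reactions))]
  d2 <- solve_moma(perm, vref[rxn_ids(perm)])$distance
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("ME knockout under MOMA: feasible, suboptimal, ARA drops strictly", {
  ma <- get_mini()
  ye <- apply_medium(ma$model, medium_ye())
  ref <- solve_fba_fixed_growth(ye, 0.03, "EX_ara")
  expect_gt(unname(ref$flux[[ma$ground_truth$me_reaction]]), 0)  # ME active in WT
  ko <- set_bounds(knockout_gene(ye, ma$ground_truth$me_gene),
                   "BIOMASS", 0.03, 0.03)
  sol <- solve_moma(ko, ref)
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$flux[[ma$ground_truth$me_reaction]]), 0)
  # strict ARA decrease (the qualitative mirror of the published -38.28%)
  expect_lt(sol$flux[["EX_ara"]], ref$flux[["EX_ara"]] - 1e-3)
  # MOMA solution is feasible in the knockout model
  S <- stoichiometric_matrix(ko)
  expect_lt(max(abs(S %*% sol$flux)), 1e-6)
  # MOMA objective flux cannot exceed the knockout FBA optimum
  fba_ko <- solve_fba(ko, objective = "EX_ara")
  expect_lte(sol$flux[["EX_ara"]], fba_ko$objective_value + 1e-6)
})

test_that("infeasible knockout is reported as such", {
  mod <- toy_chain()
  ko <- knockout_gene(mod, "g1")          # sole path blocked
  ko <- set_bounds(ko, "SINK_b", 0.5, 1000)  # but demand forced
  sol <- solve_moma(ko, solve_fba(mod))
  expect_equal(sol$status, "infeasible")
  expect_true(is.na(sol$distance))
})

test_that("L1 MOMA variant minimizes the absolute adjustment", {
  mod <- toy_parallel()
  ref <- setNames(c(-1, 1, 1, 0, 1), rxn_ids(mod))
  sol <- solve_moma_l1(knockout_gene(mod, "gP"), ref)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$norm, "L1")
  # minimal L1 adjustment is 2 (P: 1->0 and Q: 0->1); L2 distance of any
  # L1 optimum is >= the unique L2 optimum distance
  expect_equal(sol$distance, 2, tolerance = 1e-6)
})

test_that("count_changed_reactions applies a strict threshold", {
  a <- c(r1 = 1, r2 = 2, r3 = 3)
  expect_equal(count_changed_reactions(a, a)$count, 0)
  b <- c(r1 = 1, r2 = 2.5, r3 = 3 + 1e-7)
  res <- count_changed_reactions(a, b, threshold = 1e-6)
  expect_equal(res$ids, "r2")
  expect_equal(count_changed_reactions(a, b, threshold = 0)$count, 2)
  expect_error(count_changed_reactions(a, c(r1 = 1, rX = 2, r3 = 3)),
               "universes")
})
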