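test_that("chain toy: objective equals the uptake bottleneck", {
  sol <- solve_fba(toy_chain())
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 1, tolerance = 1e-9)
  expect_equal(unname(sol$flux[["EX_a"]]), -1, tolerance = 1e-9)
})

test_that("FBA and FVA agree with vertex enumeration on all toy networks", {
  for (make in list(toy_chain, toy_parallel, toy_branched)) {
    mod <- make()
    mine <- solve_fba(mod)
    orc <- oracle_fba(mod)
    expect_lt(abs(mine$objective_value - orc$obj), 1e-9)
    # FVA bounds per reaction against enumeration with objective pinned
    fv <- fva(mod, rxn_ids(mod))
    pinned <- set_bounds(mod, mod$objective,
                         lb = mine$objective_value, ub = mine$objective_value)
    for (k in seq_len(nrow(fv))) {
      lo <- oracle_fba(pinned, objective = fv$reaction[k], maximize = FALSE)
      hi <- oracle_fba(pinned, objective = fv$reaction[k], maximize = TRUE)
      expect_lt(abs(fv$min_flux[k] - lo$obj), 1e-8)
      expect_lt(abs(fv$max_flux[k] - hi$obj), 1e-8)
    }
  }
})

test_that("steady state and bounds hold at every optimum", {
  mod <- apply_medium(get_mini()$model, medium_ye())
  sol <- solve_fba(mod)
  S <- stoichiometric_matrix(mod)
  expect_lt(max(abs(S %*% sol$flux)), 1e-6)
  lb <- vapply(mod$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(mod$reactions, `[[`, numeric(1), "ub")
  expect_lt(max(pmax(lb - sol$flux, sol$flux - ub, 0)), 1e-9)
})

test_that("objective value is invariant under model permutation", {
  mod <- apply_medium(get_mini()$model, medium_mg())
  base <- solve_fba(mod)$objective_value
  set.seed(3)
  perm <- mod
  perm$reactions <- perm$reactions[sample(length(perm$reactions))]
  perm$metabolites <- perm$metabolites[sample(nrow(perm$metabolites)), ]
  expect_lt(abs(solve_fba(perm)$objective_value - base), 1e-9)
})

test_that("apply_medium closes unlisted uptakes and applies overrides", {
  mod <- get_mini()$model
  mg <- apply_medium(mod, medium_mg())
  expect_equal(mg$reactions[["EX_glc"]]$lb, -0.8)
  expect_equal(mg$reactions[["EX_glyc"]]$lb, 0)    # closed
  expect_equal(mg$reactions[["EX_o2"]]$lb, -1000)  # always open
  expect_gt(solve_fba(mg)$objective_value, 0)
  # empty medium: nothing to eat and maintenance unmet -> infeasible/zero
  starved <- solve_fba(apply_medium(mod, medium("empty")))
  expect_true(starved$status == "infeasible" ||
                starved$objective_value < 1e-9)
  # override on a non-exchange reaction is rejected
  expect_error(apply_medium(mod, medium("bad", list(FAS = c(0, 1)))),
               "non-exchange")
})

test_that("YE medium = MG + 20 amino acids at uptake 0.01", {
  ye <- medium_ye()
  aa_ids <- grep("^EX_(ala|arg|asn|asp|cys|gln|glu|gly|his|ile|leu|lys|met|phe|pro|ser|thr|trp|tyr|val)$",
                 names(ye$overrides), value = TRUE)
  expect_length(aa_ids, 20)
  for (id in aa_ids) expect_equal(ye$overrides[[id]][1], -0.01)
  expect_equal(ye$overrides[["EX_glc"]], medium_mg()$overrides[["EX_glc"]])
})

test_that("fixed-growth FBA pins biomass and optimizes the product", {
  ye <- apply_medium(get_mini()$model, medium_ye())
  prod <- solve_fba_fixed_growth(ye, 0.03, "EX_ara")
  expect_equal(prod$status, "optimal")
  expect_equal(unname(prod$flux[["BIOMASS"]]), 0.03, tolerance = 1e-9)
  expect_gt(prod$objective_value, 0)
  # zero-growth pin gives at least as much ARA as any positive pin
  prod0 <- solve_fba_fixed_growth(ye, 0, "EX_ara")
  expect_gte(prod0$objective_value + 1e-9, prod$objective_value)
  # pin above the achievable maximum is infeasible
  gmax <- solve_fba(ye)$objective_value
  expect_equal(solve_fba_fixed_growth(ye, gmax * 2, "EX_ara")$status,
               "infeasible")
  # pinning at the optimum then re-maximizing biomass returns the optimum
  again <- solve_fba_fixed_growth(ye, gmax, "BIOMASS")
  expect_equal(again$objective_value, gmax, tolerance = 1e-9)
})

test_that("FVA: objective at fraction 1 is [opt, opt]; parallel branches [0, 1]", {
  mod <- toy_parallel()
  opt <- solve_fba(mod)$objective_value
  fv <- fva(mod, c("SINK_b", "P", "Q"))
  expect_equal(unlist(fv[fv$reaction == "SINK_b", c("min_flux", "max_flux")]),
               c(opt, opt), tolerance = 1e-6, ignore_attr = TRUE)
  for (br in c("P", "Q"))
    expect_equal(unlist(fv[fv$reaction == br, c("min_flux", "max_flux")]),
                 c(0, 1), tolerance = 1e-9, ignore_attr = TRUE)
  # FVA envelope contains the FBA vertex componentwise
  sol <- solve_fba(mod)
  full <- fva(mod, rxn_ids(mod))
  expect_true(all(sol$flux >= full$min_flux - 1e-6 &
                    sol$flux <= full$max_flux + 1e-6))
})

test_that("FVA on an infeasible base problem errors before per-reaction solves", {
  mod <- set_bounds(toy_chain(), "EX_a", 0, 0)
  mod <- set_bounds(mod, "SINK_b", 1, 1000)   # demand with nothing to eat
  expect_error(fva(mod, "SINK_b"), "infeasible")
})

test_that("robustness scan: interior single peak for ARA vs oxygen", {
  ye <- apply_medium(get_mini()$model, medium_ye())
  rc <- robustness_scan(ye, "EX_o2", seq(0.25, 6, by = 0.25),
                        objective = "EX_ara", min_growth = 0.03)
  ok <- which(!is.na(rc$objective_value))
  expect_gt(length(ok), 10)
  y <- rc$objective_value[ok]
  i <- which.max(y)
  expect_gt(i, 1); expect_lt(i, length(y))          # interior
  expect_true(all(diff(y[seq_len(i)]) >= -1e-7))     # rises
  expect_true(all(diff(y[i:length(y)]) <= 1e-7))     # then falls
  # infeasible points at very high forced uptake are absent, not zero
  expect_true(anyNA(rc$objective_value))
})

test_that("robustness scan of a relaxed resource with growth objective", {
  mod <- toy_chain()
  # pinning uptake of the sole substrate: objective tracks the pin linearly,
  # so the curve is non-decreasing over the scan
  rc <- robustness_scan(set_bounds(mod, "EX_a", -10, 1000), "EX_a",
                        c(0.2, 0.5, 1, 2), objective = "SINK_b")
  expect_equal(rc$objective_value, c(0.2, 0.5, 1, 2), tolerance = 1e-9)
  expect_error(robustness_scan(mod, "EX_a", numeric(0), objective = "SINK_b"),
               "empty")
  expect_error(robustness_scan(mod, "EX_a", c(1, 1), objective = "SINK_b"),
               "increasing")
  expect_error(robustness_scan(mod, "R_ab", 1, objective = "SINK_b"),
               "not an exchange")
})

test_that("substrate screen: pathway presence decides growth calls", {
  ma <- get_mini()
  scr <- substrate_utilization_screen(
    ma$model, medium_mg(),
    c("EX_glc", "EX_glyc", "EX_etoh", "EX_ac", "EX_lac", "EX_rha"),
    remove = "EX_glc")
  expect_true(all(scr$grows))
  # orphaned sugar: removing the rhamnose lyase kills rhamnose growth only
  crippled <- remove_reactions(ma$model, ma$ground_truth$rhamnose_lyase)
  scr2 <- substrate_utilization_screen(crippled, medium_mg(),
                                       c("EX_glc", "EX_rha"),
                                       remove = "EX_glc")
  expect_equal(scr2$grows, c(TRUE, FALSE))
  # candidate identical to the base source grows iff the base grows
  expect_true(substrate_utilization_screen(ma$model, medium_mg(), "EX_glc",
                                           remove = "EX_glc", uptake = 0.8)$grows)
})

test_that("nitrogen screen: glutamate and glycine serve as sole N sources", {
  mod <- get_mini()$model
  mgN <- medium_mg()
  mgN$overrides[["EX_no3"]] <- NULL
  for (aa in c("EX_glu", "EX_gly")) {
    med <- mgN
    med$overrides[[aa]] <- c(-1, 1000)
    expect_gt(solve_fba(apply_medium(mod, med))$objective_value, 1e-6)
  }
  # no nitrogen at all: no growth
  ng <- solve_fba(apply_medium(mod, mgN))
  expect_true(ng$status == "infeasible" || ng$objective_value < 1e-9)
})
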