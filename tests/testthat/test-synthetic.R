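test_that("default synthetic model validates, grows on MG, makes ARA", {
  ma <- get_mini()
  expect_s3_class(ma$model, "metabolic_model")
  expect_identical(validate_model(ma$model), ma$model)
  expect_setequal(names(ma$model$compartments), c("e", "c", "m", "x"))
  expect_gt(solve_fba(apply_medium(ma$model, medium_mg()))$objective_value, 0)
  prod <- solve_fba_fixed_growth(apply_medium(ma$model, medium_ye()),
                                 0.03, "EX_ara")
  expect_gt(prod$objective_value, 0)
})

test_that("generation is deterministic", {
  a <- mini_alpina()
  b <- mini_alpina()
  expect_identical(a$model, b$model)
  expect_identical(a$ground_truth$nadph_reactions, b$ground_truth$nadph_reactions)
})

test_that("disabling PPP and malic enzyme removes every NADPH source", {
  crippled <- mini_alpina(mini_alpina_spec(ppp = FALSE, malic_enzyme = FALSE))
  expect_false("ME" %in% rxn_ids(crippled$model))
  expect_false("G6PDH" %in% rxn_ids(crippled$model))
  g <- solve_fba(apply_medium(crippled$model, medium_mg()))
  expect_true(g$status == "infeasible" || g$objective_value < 1e-9)
})

test_that("omega-3 toggle isolates the EPA branch", {
  no3 <- mini_alpina(mini_alpina_spec(include_omega3 = FALSE))
  expect_false("DS17" %in% rxn_ids(no3$model))
  expect_equal(no3$model$reactions[["EX_epa"]]$ub, 0)   # blocked, not absent
  ye <- apply_medium(no3$model, medium_ye())
  ara <- solve_fba_fixed_growth(ye, 0.03, "EX_ara")$objective_value
  with3 <- mini_alpina()
  ara3 <- solve_fba_fixed_growth(apply_medium(with3$model, medium_ye()),
                                 0.03, "EX_ara")$objective_value
  expect_equal(ara, ara3, tolerance = 1e-6)   # ARA unaffected by the branch
})

test_that("desaturation stoichiometry follows the per-step O2/NADPH costs", {
  sp <- mini_alpina_spec(o2_per_desaturation = 2, nadph_per_desaturation = 1)
  mod <- mini_alpina(sp)$model
  expect_equal(unname(mod$reactions[["DS9"]]$stoich[["o2[c]"]]), -2)
  expect_equal(unname(mod$reactions[["DS9"]]$stoich[["nadph[c]"]]), -1)
  # EPA needs strictly more oxygen per mole than ARA (one more double bond)
  ye <- apply_medium(get_mini()$model, medium_ye())
  o2_for <- function(product) {
    m <- set_bounds(ye, "BIOMASS", 0.03, 0.03)
    best <- solve_fba(m, objective = product)
    m <- set_bounds(m, product, best$objective_value, best$objective_value)
    fv <- fva(m, "EX_o2", objective = product)
    -fv$max_flux / best$objective_value     # min O2 uptake per unit product
  }
  expect_gt(o2_for("EX_epa"), o2_for("EX_ara"))
})

test_that("random viable models: determinism, backbone viability, gaps", {
  a <- random_viable_model(seed = 42)
  b <- random_viable_model(seed = 42)
  expect_identical(a, b)
  expect_gt(solve_fba(a)$objective_value, 0)
  # backbone-only model has no blocked metabolites
  bare <- random_viable_model(n_metabolites = 4, n_reactions = 6,
                              backbone_len = 3, seed = 1)
  expect_length(find_blocked_metabolites(bare)$no_production, 0)
  expect_error(random_viable_model(n_metabolites = 2, n_reactions = 2),
               "backbone")
})

test_that("remove_reactions revalidates and protects the biomass reaction", {
  ma <- get_mini()
  slim <- remove_reactions(ma$model, "ME")
  expect_false("ME" %in% rxn_ids(slim))
  expect_false("gME" %in% slim$genes)
  expect_error(remove_reactions(ma$model, "BIOMASS"), "refusing")
  expect_error(remove_reactions(ma$model, "NOPE"), "unknown")
  # removing the sole glucose transporter kills growth on glucose
  noglc <- remove_reactions(ma$model, "T_glc")
  g <- solve_fba(apply_medium(noglc, medium_mg()))
  expect_true(g$status == "infeasible" || g$objective_value < 1e-9)
})

test_that("ground truth matches the built model", {
  ma <- get_mini()
  gt <- ma$ground_truth
  expect_true(all(c(gt$me_reaction, gt$ara_exchange, gt$biomass_reaction,
                    gt$rhamnose_lyase) %in% rxn_ids(ma$model)))
  expect_true(gt$me_gene %in% ma$model$genes)
  expect_setequal(gt$nadph_reactions,
                  reactions_involving(ma$model, "nadph[c]"))
})
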