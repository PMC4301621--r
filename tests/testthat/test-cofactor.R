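test_that("differential report: identical solutions give an empty changed set", {
  mod <- toy_branched()
  sol <- solve_fba(mod)
  rep <- differential_flux_report(mod, "a[c]", sol, sol)
  expect_equal(sum(rep$changed), 0)
})

test_that("hand-built report flags exactly the reactions over threshold", {
  mod <- toy_branched()
  a <- setNames(c(-2, 2, 1, 0.5, 0.5, 1), rxn_ids(mod))
  b <- a + c(0, 0, 1e-3, -1e-3, 0, 0)
  rep <- differential_flux_report(mod, "a[c]", a, b, threshold = 1e-6)
  expect_setequal(rep$reaction[rep$changed], c("R1", "R2"))
  expect_equal(rep$abs_change[rep$reaction == "R1"], 1e-3)
  # strictly greater-than: a change of exactly the threshold does not count
  b2 <- a; b2[["R1"]] <- a[["R1"]] + 1e-6
  expect_equal(sum(differential_flux_report(mod, "a[c]", a, b2)$changed), 0)
  expect_error(differential_flux_report(mod, "a[c]", a, a[-1]), "universes")
})

test_that("swapping conditions permutes columns but preserves the changed set", {
  mod <- toy_branched()
  a <- setNames(c(-2, 2, 1, 0.5, 0.5, 1), rxn_ids(mod))
  b <- a + c(0, 0, 2e-3, 0, -1e-3, 0)
  ab <- differential_flux_report(mod, "a[c]", a, b)
  ba <- differential_flux_report(mod, "a[c]", b, a)
  expect_equal(ab$flux_A, ba$flux_B)
  expect_setequal(ab$reaction[ab$changed], ba$reaction[ba$changed])
})

test_that("growth-mode vs production-mode NADPH shift includes PPP and ME", {
  ma <- get_mini()
  ye <- apply_medium(ma$model, medium_ye())
  grow <- solve_fba_fixed_growth(ye, 0.06, "EX_ara")
  prod <- solve_fba_fixed_growth(ye, 0.03, "EX_ara")
  rep <- differential_flux_report(ma$model, "nadph[c]", grow, prod,
                                  labels = c("growth", "production"))
  expect_setequal(rep$reaction, ma$ground_truth$nadph_reactions)
  changed <- rep$reaction[rep$changed]
  expect_gt(length(changed), 0)
  expect_true(ma$ground_truth$me_reaction %in% changed)
  expect_true(any(ma$ground_truth$ppp_reactions %in% changed))
})

test_that("producer/consumer split: shares and conservation", {
  mets <- rbind(metabolite("x[e]", "x", "e"), metabolite("n[c]", "n", "c"))
  mod <- metabolic_model(mets, list(
    reaction("SRC", c("x[e]" = -1, "n[c]" = 1), lb = -1000),
    reaction("EX_x", c("x[e]" = -1), lb = -1000),
    reaction("C1", c("n[c]" = -1)),
    reaction("C2", c("n[c]" = -1))),
    objective = NA_character_)
  v <- c(SRC = 10, EX_x = -10, C1 = 6, C2 = 4)
  sp <- producer_consumer_split(mod, "n[c]", v)
  expect_equal(sp$production_total, 10)
  expect_equal(sp$consumption_total, 10)
  shares <- setNames(sp$turnover$share_percent, sp$turnover$reaction)
  expect_equal(unname(shares[c("C1", "C2")]), c(60, 40))
  expect_equal(sum(sp$turnover$share_percent[sp$turnover$side == "consumption"]),
               100, tolerance = 1e-4)
  # all-zero turnover: defined empty split, no division error
  sp0 <- producer_consumer_split(mod, "n[c]", v * 0)
  expect_equal(nrow(sp0$turnover), 0)
  expect_equal(sp0$production_total, 0)
})

test_that("steady-state turnover balances for every internal metabolite", {
  ma <- get_mini()
  ye <- apply_medium(ma$model, medium_ye())
  sol <- solve_fba(ye)
  internal <- met_ids(ma$model)[ma$model$metabolites$compartment != "e"]
  for (met in internal) {
    sp <- producer_consumer_split(ma$model, met, sol)
    expect_lt(abs(sp$production_total - sp$consumption_total), 1e-6)
    if (sp$production_total > 1e-6) {
      prod_side <- sp$turnover$share_percent[sp$turnover$side == "production"]
      expect_lt(abs(sum(prod_side) - 100), 1e-4)
    }
  }
})

test_that("acetyl-CoA routing shifts toward fatty acids in production mode", {
  ma <- get_mini()
  ye <- apply_medium(ma$model, medium_ye())
  grow <- solve_fba(ye)                                  # growth mode
  prod <- solve_fba_fixed_growth(ye, 0.03, "EX_ara")     # production mode
  fa_share <- function(sol) {
    sp <- producer_consumer_split(ma$model, "accoa[c]", sol)
    tp <- sp$turnover
    sum(tp$share_percent[tp$side == "consumption" & tp$reaction %in%
                           c("ACC", "FAS")])
  }
  expect_gt(fa_share(prod), fa_share(grow))
})

test_that("flux_ratio_change reproduces printed worked examples", {
  # acetyl-CoA from pyruvate, growth 1.22 -> production 1.56: +27.87%
  expect_equal(round(flux_ratio_change(1.22, 1.56), 2), 27.87)
  # ACC flux 0.79 -> 1.43: +81.0%
  expect_equal(round(flux_ratio_change(0.79, 1.43), 1), 81.0)
  # ARA drop 0.128 -> 0.079 under the ME knockout: -38.28%
  expect_equal(round(flux_ratio_change(0.128, 0.079), 2), -38.28)
  expect_equal(flux_ratio_change(2, 2), 0)
  expect_warning(res <- flux_ratio_change(0, 1), "undefined")
  expect_true(is.na(res))
})
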