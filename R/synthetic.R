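# Deterministic synthetic test models.
#
# mini_alpina() builds a compact (~200 reaction) oleaginous-fungus network
# spanning four compartments with the canonical PUFA chain: lumped
# glycolysis and oxidative PPP, the pyruvate-carboxylase / malate /
# malic-enzyme transhydrogenation cycle, a citrate shuttle exporting
# acetyl-CoA, lumped fatty-acid synthase to palmitate, explicit
# elongase/desaturase steps to arachidonic (ARA) and eicosapentaenoic
# (EPA) acid, nitrate assimilation, 20 amino acids with lumped synthesis
# (plus degradation routes for Asp/Ile/Leu/Lys/Glu/Gly), rhamnose /
# glycerol / ethanol / acetate / lactate catabolism and peroxisomal
# beta-oxidation.  Stoichiometries of the carbon/energy core are exact
# rationals and elementally balanced (see elemental_audit()); lumped
# amino-acid and polymer reactions carry no formulas and are excluded
# from the audit by construction.

#' Parameters for the synthetic oleaginous-fungus model
#'
#' @param include_omega3 include the omega-3 desaturation branch to EPA.
#' @param o2_per_desaturation mol O2 per desaturation step (canonical 1).
#' @param nadph_per_desaturation mol NADPH per desaturation step
#'   (canonical 1).
#' @param nadph_per_elongation mol NADPH per 2-carbon elongation cycle
#'   (canonical 2).
#' @param malic_enzyme include cytosolic malic enzyme.
#' @param ppp include the oxidative pentose phosphate branch.
#' @param gam,ngam growth / non-growth ATP maintenance (mmol gDW-1 (h-1)).
#' @param glucose_uptake default MG glucose uptake bound (mmol gDW-1 h-1).
#' @param aa_uptake YE per-amino-acid uptake bound (mmol gDW-1 h-1).
#' @param seed unused placeholder (generation is fully deterministic).
#' @export
mini_alpina_spec <- function(include_omega3 = TRUE,
                             o2_per_desaturation = 1,
                             nadph_per_desaturation = 1,
                             nadph_per_elongation = 2,
                             malic_enzyme = TRUE,
                             ppp = TRUE,
                             gam = 30, ngam = 1,
                             glucose_uptake = 0.8,
                             aa_uptake = 0.01,
                             seed = 1L) {
  list(include_omega3 = include_omega3,
       o2_per_desaturation = o2_per_desaturation,
       nadph_per_desaturation = nadph_per_desaturation,
       nadph_per_elongation = nadph_per_elongation,
       malic_enzyme = malic_enzyme, ppp = ppp,
       gam = gam, ngam = ngam,
       glucose_uptake = glucose_uptake, aa_uptake = aa_uptake,
       seed = seed)
}

AA3 <- c("ala", "arg", "asn", "asp", "cys", "gln", "glu", "gly", "his",
         "ile", "leu", "lys", "met", "phe", "pro", "ser", "thr", "trp",
         "tyr", "val")

AA_MASS <- c(ala = 89.09, arg = 174.20, asn = 132.12, asp = 133.10,
             cys = 121.16, gln = 146.15, glu = 147.13, gly = 75.07,
             his = 155.15, ile = 131.17, leu = 131.17, lys = 146.19,
             met = 149.21, phe = 165.19, pro = 115.13, ser = 105.09,
             thr = 119.12, trp = 204.23, tyr = 181.19, val = 117.15)

# lumped amino-acid synthesis recipe: precursor demands per mol amino acid
AA_RECIPE <- data.frame(
  aa    = AA3,
  pyr   = c(1, 2, 2, 2, 1, 2, 2, 1, 2, 2, 2, 2, 2, 3, 2, 1, 2, 4, 3, 2),
  accoa = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 1, 1, 1, 0, 1, 0, 1, 0, 0, 0),
  nh3   = c(1, 4, 2, 1, 1, 2, 1, 1, 3, 1, 1, 2, 1, 1, 1, 1, 1, 2, 1, 1),
  atp   = c(1, 4, 3, 1, 4, 2, 1, 1, 5, 2, 2, 3, 6, 3, 2, 1, 2, 5, 3, 2),
  nadph = c(1, 2, 1, 1, 5, 1, 2, 1, 1, 3, 2, 3, 6, 2, 3, 1, 2, 2, 2, 2),
  so4   = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0),
  carbons = c(3, 6, 4, 4, 3, 5, 5, 2, 6, 6, 6, 6, 5, 9, 5, 3, 4, 11, 9, 5),
  stringsAsFactors = FALSE)

#' Default biomass composition of the synthetic model
#'
#' A literature-typical oleaginous-fungus macromolecular composition
#' (g/gDW): protein 0.42, cell wall 0.25, lipid 0.18, RNA 0.06, DNA 0.015,
#' small-molecule pool 0.075.  These are NOT the values of any published
#' reconstruction; they are the synthetic model's stated world.
#'
#' @param gam,ngam ATP maintenance parameters.
#' @export
mini_alpina_composition <- function(gam = 30, ngam = 1) {
  prot <- setNames(rep(0.05, 20), paste0(AA3, "[c]"))
  biomass_composition(
    fractions = c(protein = 0.42, dna = 0.015, rna = 0.06, lipid = 0.18,
                  cell_wall = 0.25, small_pool = 0.075),
    monomers = list(protein = prot,
                    dna = c("dntp[c]" = 1),
                    rna = c("ntp[c]" = 1),
                    lipid = c("c160[c]" = 1),
                    cell_wall = c("glucan[c]" = 1),
                    small_pool = c("pool[c]" = 1)),
    gam = gam, ngam = ngam)
}

#' Monomer molar masses used by the synthetic biomass equation (g/mol)
#' @export
mini_alpina_monomer_masses <- function() {
  c(setNames(AA_MASS, paste0(AA3, "[c]")),
    "dntp[c]" = 471.0, "ntp[c]" = 487.0, "c160[c]" = 256.42,
    "glucan[c]" = 162.14, "pool[c]" = 300.0)
}

#' Generate the synthetic oleaginous-fungus model
#'
#' @param spec a \code{\link{mini_alpina_spec}}.
#' @return list with \code{model} (a validated \code{metabolic_model},
#'   objective = biomass) and \code{ground_truth}, a record of generator
#'   facts used by tests: NADPH reaction ids, malic-enzyme reaction/gene,
#'   exchange ids, expected essential/non-essential gene sets per medium,
#'   and the rhamnose-lyase id for gap fixtures.
#' @export
mini_alpina <- function(spec = mini_alpina_spec()) {
  mets <- list(); rxns <- list()
  addm <- function(id, name, comp, formula = NA_character_) {
    mets[[length(mets) + 1L]] <<- metabolite(id, name, comp, formula)
  }
  addr <- function(id, stoich, lb = 0, ub = 1000, name = id, subsystem = "",
                   gpr = "", rtype = NA_character_) {
    rxns[[length(rxns) + 1L]] <<- reaction(id, stoich, lb = lb, ub = ub,
                                           name = name, rtype = rtype,
                                           subsystem = subsystem, gpr = gpr)
  }

  # ---- metabolites ---------------------------------------------------------
  core <- list(
    glc = "C6H12O6", glyc = "C3H8O3", etoh = "C2H6O", ac = "C2H4O2",
    lac = "C3H6O3", rha = "C6H12O5", o2 = "O2", co2 = "CO2", h2o = "H2O",
    h = "H", pi = "H3O4P", so4 = "H2O4S", no3 = "HNO3", nh3 = "H3N",
    ara = "C20H32O2", epa = "C20H30O2", biomass = NA_character_)
  for (id in names(core)) addm(paste0(id, "[e]"), id, "e", core[[id]])
  for (aa in AA3) addm(paste0(aa, "[e]"), aa, "e")

  cyt <- list(
    glc = "C6H12O6", g6p = "C6H13O9P", pg6 = "C6H13O10P", ru5p = "C5H11O8P",
    pep = "C3H5O6P", pyr = "C3H4O3", oaa = "C4H4O5", mal = "C4H6O5",
    cit = "C6H8O7", glyc = "C3H8O3", glyc3p = "C3H9O6P", dhap = "C3H7O6P",
    etoh = "C2H6O", acald = "C2H4O", ac = "C2H4O2", lac = "C3H6O3",
    rha = "C6H12O5", rhau = "C6H12O5", rha1p = "C6H13O8P",
    lactald = "C3H6O2",
    atp = "C10H16N5O13P3", adp = "C10H15N5O10P2", pi = "H3O4P",
    nad = "C21H27N7O14P2", nadh = "C21H28N7O14P2",
    nadp = "C21H28N7O17P3", nadph = "C21H29N7O17P3",
    coa = "C21H36N7O16P3S", accoa = "C23H38N7O17P3S",
    malcoa = "C24H38N7O19P3S",
    c160 = "C16H32O2", c160coa = "C37H66N7O17P3S",
    c180coa = "C39H70N7O17P3S", c181coa = "C39H68N7O17P3S",
    c182coa = "C39H66N7O17P3S", c183coa = "C39H64N7O17P3S",
    c203coa = "C41H68N7O17P3S", c204coa = "C41H66N7O17P3S",
    c205coa = "C41H64N7O17P3S",
    ara = "C20H32O2", epa = "C20H30O2",
    o2 = "O2", co2 = "CO2", h2o = "H2O", h = "H", so4 = "H2O4S",
    no3 = "HNO3", no2 = "HNO2", nh3 = "H3N",
    ntp = NA_character_, dntp = NA_character_, pool = NA_character_,
    glucan = "C6H10O5", biomass = NA_character_)
  for (id in names(cyt)) addm(paste0(id, "[c]"), id, "c", cyt[[id]])
  for (aa in AA3) addm(paste0(aa, "[c]"), aa, "c")

  mito <- list(pyr = "C3H4O3", accoa = "C23H38N7O17P3S",
               coa = "C21H36N7O16P3S", oaa = "C4H4O5", mal = "C4H6O5",
               cit = "C6H8O7", nad = "C21H27N7O14P2", nadh = "C21H28N7O14P2",
               atp = "C10H16N5O13P3", adp = "C10H15N5O10P2", pi = "H3O4P",
               o2 = "O2", co2 = "CO2", h2o = "H2O", h = "H")
  for (id in names(mito)) addm(paste0(id, "[m]"), id, "m", mito[[id]])

  perox <- list(c160coa = "C37H66N7O17P3S", coa = "C21H36N7O16P3S",
                accoa = "C23H38N7O17P3S", ac = "C2H4O2", o2 = "O2",
                h2o = "H2O")
  for (id in names(perox)) addm(paste0(id, "[x]"), id, "x", perox[[id]])

  metdf <- do.call(rbind, mets)

  # ---- exchanges -----------------------------------------------------------
  EXCH <- "Exchange"
  for (id in c("glc", "glyc", "etoh", "ac", "lac", "rha", "o2", "co2",
               "h2o", "h", "pi", "so4", "no3", "nh3")) {
    addr(paste0("EX_", id), setNames(-1, paste0(id, "[e]")),
         lb = -1000, ub = 1000, subsystem = EXCH, rtype = "exchange")
  }
  for (id in c("ara", "epa", "biomass")) {
    # without the omega-3 branch the EPA exchange ships blocked, not absent
    ub_id <- if (id == "epa" && !spec$include_omega3) 0 else 1000
    addr(paste0("EX_", id), setNames(-1, paste0(id, "[e]")),
         lb = 0, ub = ub_id, subsystem = EXCH, rtype = "exchange")
  }
  for (aa in AA3)
    addr(paste0("EX_", aa), setNames(-1, paste0(aa, "[e]")),
         lb = -1000, ub = 1000, subsystem = EXCH, rtype = "exchange")

  # ---- transport -----------------------------------------------------------
  TRN <- "Transport"
  tr <- function(id, from, to, gpr = "", rev = FALSE, met = NULL) {
    if (is.null(met)) met <- sub("^T_", "", id)
    addr(id, setNames(c(-1, 1), c(paste0(met, "[", from, "]"),
                                  paste0(met, "[", to, "]"))),
         lb = if (rev) -1000 else 0, ub = 1000, subsystem = TRN, gpr = gpr,
         rtype = "transport")
  }
  tr("T_glc", "e", "c", gpr = "gGLCT")
  tr("T_glyc", "e", "c", gpr = "gGLPT")
  tr("T_etoh", "e", "c", rev = TRUE)
  tr("T_ac", "e", "c", gpr = "gACT", rev = TRUE)
  tr("T_lac", "e", "c", gpr = "gLACT", rev = TRUE)
  tr("T_rha", "e", "c", gpr = "gRHAT")
  tr("T_o2", "e", "c", rev = TRUE, met = "o2")
  addr("T_o2m", c("o2[c]" = -1, "o2[m]" = 1), lb = -1000, subsystem = TRN,
       rtype = "transport")
  addr("T_o2x", c("o2[c]" = -1, "o2[x]" = 1), lb = -1000, subsystem = TRN,
       rtype = "transport")
  tr("T_co2", "c", "e", rev = TRUE, met = "co2")
  addr("T_co2m", c("co2[m]" = -1, "co2[c]" = 1), lb = -1000, subsystem = TRN,
       rtype = "transport")
  tr("T_h2o", "e", "c", rev = TRUE, met = "h2o")
  addr("T_h2om", c("h2o[c]" = -1, "h2o[m]" = 1), lb = -1000, subsystem = TRN,
       rtype = "transport")
  addr("T_h2ox", c("h2o[c]" = -1, "h2o[x]" = 1), lb = -1000, subsystem = TRN,
       rtype = "transport")
  tr("T_h", "e", "c", rev = TRUE, met = "h")
  addr("T_hm", c("h[c]" = -1, "h[m]" = 1), lb = -1000, subsystem = TRN,
       rtype = "transport")
  tr("T_pi", "e", "c", gpr = "gPIT", rev = TRUE, met = "pi")
  addr("T_pim", c("pi[c]" = -1, "pi[m]" = 1), lb = -1000, subsystem = TRN,
       rtype = "transport")
  tr("T_so4", "e", "c", gpr = "gSUT", met = "so4")
  tr("T_no3", "e", "c", gpr = "gNRT", met = "no3")
  tr("T_nh3", "e", "c", rev = TRUE, met = "nh3")
  addr("T_pyrm", c("pyr[c]" = -1, "pyr[m]" = 1), subsystem = TRN,
       rtype = "transport")
  addr("T_citm", c("cit[m]" = -1, "cit[c]" = 1), lb = -1000, subsystem = TRN,
       gpr = "gCTP", rtype = "transport")
  addr("T_malm", c("mal[c]" = -1, "mal[m]" = 1), lb = -1000, subsystem = TRN,
       gpr = "gDIC", rtype = "transport")
  addr("T_atpadp", c("atp[m]" = -1, "adp[c]" = -1, "atp[c]" = 1,
                     "adp[m]" = 1), lb = -1000, subsystem = TRN,
       gpr = "gANT", rtype = "transport")
  # external NADH dehydrogenase / glycerol-3-phosphate shuttle lump:
  # cytosolic NADH reduces the mitochondrial pool without carbon cost
  addr("T_redox", c("nadh[c]" = -1, "nad[m]" = -1, "nad[c]" = 1,
                    "nadh[m]" = 1), subsystem = TRN, gpr = "gNDE",
       rtype = "transport", name = "cytosolic NADH shuttle lump")
  addr("T_c160coax", c("c160coa[c]" = -1, "c160coa[x]" = 1),
       subsystem = TRN, rtype = "transport")
  addr("T_coax", c("coa[x]" = -1, "coa[c]" = 1), lb = -1000,
       subsystem = TRN, rtype = "transport")
  addr("T_acx", c("ac[x]" = -1, "ac[c]" = 1), subsystem = TRN,
       rtype = "transport")
  addr("T_ara", c("ara[c]" = -1, "ara[e]" = 1), subsystem = TRN,
       rtype = "transport")
  addr("T_epa", c("epa[c]" = -1, "epa[e]" = 1), subsystem = TRN,
       rtype = "transport")
  addr("T_biomass", c("biomass[c]" = -1, "biomass[e]" = 1),
       subsystem = TRN, rtype = "transport")
  for (aa in AA3)
    addr(paste0("T_", aa), setNames(c(-1, 1), paste0(aa, c("[e]", "[c]"))),
         lb = -1000, ub = 1000, subsystem = TRN, gpr = "gAAP",
         rtype = "transport")

  # ---- central carbon (cytosol) -------------------------------------------
  GLYCO <- "Glycolysis"
  addr("HXK", c("glc[c]" = -1, "atp[c]" = -1, "g6p[c]" = 1, "adp[c]" = 1),
       subsystem = GLYCO, gpr = "gHXK")
  addr("GLY", c("g6p[c]" = -1, "pi[c]" = -2, "nad[c]" = -2, "adp[c]" = -1,
                "pep[c]" = 2, "nadh[c]" = 2, "atp[c]" = 1, "h2o[c]" = 2,
                "h[c]" = 2),
       subsystem = GLYCO, gpr = "gGLY", name = "glycolysis lump g6p->2 pep")
  addr("PYK", c("pep[c]" = -1, "adp[c]" = -1, "pyr[c]" = 1, "atp[c]" = 1),
       subsystem = GLYCO, gpr = "gPYK")
  addr("GNG", c("pep[c]" = -2, "nadh[c]" = -2, "atp[c]" = -2, "h2o[c]" = -3,
                "h[c]" = -2, "g6p[c]" = 1, "nad[c]" = 2, "adp[c]" = 2,
                "pi[c]" = 3),
       subsystem = GLYCO, gpr = "gFBP",
       name = "gluconeogenesis lump 2 pep->g6p")
  addr("PC", c("pyr[c]" = -1, "co2[c]" = -1, "atp[c]" = -1, "h2o[c]" = -1,
               "oaa[c]" = 1, "adp[c]" = 1, "pi[c]" = 1),
       subsystem = "Pyruvate metabolism", gpr = "gPC",
       name = "pyruvate carboxylase")
  addr("MDHc", c("oaa[c]" = -1, "nadh[c]" = -1, "h[c]" = -1, "mal[c]" = 1,
                 "nad[c]" = 1), lb = -1000,
       subsystem = "Pyruvate metabolism", gpr = "gMDHc")
  if (spec$malic_enzyme)
    addr("ME", c("mal[c]" = -1, "nadp[c]" = -1, "pyr[c]" = 1, "co2[c]" = 1,
                 "nadph[c]" = 1, "h[c]" = 1),
         subsystem = "Pyruvate metabolism", gpr = "gME",
         name = "malic enzyme (NADP+)")
  addr("ACL", c("cit[c]" = -1, "atp[c]" = -1, "coa[c]" = -1, "accoa[c]" = 1,
                "oaa[c]" = 1, "adp[c]" = 1, "pi[c]" = 1),
       subsystem = "Pyruvate metabolism", gpr = "gACL",
       name = "ATP-citrate lyase")
  addr("ACS", c("ac[c]" = -1, "coa[c]" = -1, "atp[c]" = -1, "accoa[c]" = 1,
                "adp[c]" = 1, "pi[c]" = 1),
       subsystem = "Pyruvate metabolism", gpr = "gACS")
  addr("LDH", c("lac[c]" = -1, "nad[c]" = -1, "pyr[c]" = 1, "nadh[c]" = 1,
                "h[c]" = 1), lb = -1000,
       subsystem = "Pyruvate metabolism", gpr = "gLDH")
  addr("PEPCK", c("oaa[c]" = -1, "atp[c]" = -1, "pep[c]" = 1, "co2[c]" = 1,
                  "adp[c]" = 1),
       subsystem = "Pyruvate metabolism", gpr = "gPCK",
       name = "PEP carboxykinase")
  addr("GLX", c("accoa[c]" = -2, "nad[c]" = -3, "h2o[c]" = -3, "oaa[c]" = 1,
                "coa[c]" = 2, "nadh[c]" = 3, "h[c]" = 3),
       subsystem = "Pyruvate metabolism", gpr = "gICL",
       name = "glyoxylate shunt lump 2 acetyl-CoA -> oxaloacetate")

  if (spec$ppp) {
    PPPs <- "Pentose phosphate pathway"
    addr("G6PDH", c("g6p[c]" = -1, "nadp[c]" = -1, "h2o[c]" = -1,
                    "pg6[c]" = 1, "nadph[c]" = 1, "h[c]" = 1),
         subsystem = PPPs, gpr = "gZWF",
         name = "glucose-6-phosphate dehydrogenase + lactonase lump")
    addr("GND", c("pg6[c]" = -1, "nadp[c]" = -1, "ru5p[c]" = 1,
                  "co2[c]" = 1, "nadph[c]" = 1, "h[c]" = 1),
         subsystem = PPPs, gpr = "gGND",
         name = "6-phosphogluconate dehydrogenase")
  }
  addr("PPPNOX", c("ru5p[c]" = -6, "h2o[c]" = -1, "g6p[c]" = 5,
                   "pi[c]" = 1), lb = -1000,
       subsystem = "Pentose phosphate pathway", gpr = "gTKT",
       name = "non-oxidative PPP lump")

  # glycerol / ethanol / rhamnose catabolism
  ALT <- "Alternative carbon sources"
  addr("GLYK", c("glyc[c]" = -1, "atp[c]" = -1, "glyc3p[c]" = 1,
                 "adp[c]" = 1), subsystem = ALT, gpr = "gGLYK")
  addr("G3PDH", c("glyc3p[c]" = -1, "nad[c]" = -1, "dhap[c]" = 1,
                  "nadh[c]" = 1, "h[c]" = 1), subsystem = ALT, gpr = "gG3PD")
  addr("DHAPPEP", c("dhap[c]" = -1, "pi[c]" = -1, "nad[c]" = -1,
                    "adp[c]" = -1, "pep[c]" = 1, "nadh[c]" = 1,
                    "atp[c]" = 1, "h2o[c]" = 1, "h[c]" = 1),
       subsystem = ALT, gpr = "gGAPD",
       name = "triose phosphate to PEP lump")
  addr("ADH", c("etoh[c]" = -1, "nad[c]" = -1, "acald[c]" = 1,
                "nadh[c]" = 1, "h[c]" = 1), lb = -1000,
       subsystem = ALT, gpr = "gADH")
  addr("ALDH", c("acald[c]" = -1, "nad[c]" = -1, "h2o[c]" = -1,
                 "ac[c]" = 1, "nadh[c]" = 1, "h[c]" = 1),
       subsystem = ALT, gpr = "gALDH")
  addr("RHAI", c("rha[c]" = -1, "rhau[c]" = 1), lb = -1000,
       subsystem = ALT, gpr = "gRHAI", name = "rhamnose isomerase")
  addr("RHAK", c("rhau[c]" = -1, "atp[c]" = -1, "rha1p[c]" = 1,
                 "adp[c]" = 1), subsystem = ALT, gpr = "gRHAK",
       name = "rhamnulose kinase")
  addr("RHALYA", c("rha1p[c]" = -1, "dhap[c]" = 1, "lactald[c]" = 1),
       subsystem = ALT, gpr = "gLYA",
       name = "rhamnulose-1-phosphate aldolase (lactaldehyde lyase)")
  addr("LALDH", c("lactald[c]" = -1, "nad[c]" = -1, "h2o[c]" = -1,
                  "lac[c]" = 1, "nadh[c]" = 1, "h[c]" = 1),
       subsystem = ALT, gpr = "gLALD")

  # ---- mitochondrion -------------------------------------------------------
  TCAs <- "TCA cycle"
  addr("PDH", c("pyr[m]" = -1, "coa[m]" = -1, "nad[m]" = -1,
                "accoa[m]" = 1, "co2[m]" = 1, "nadh[m]" = 1, "h[m]" = 1),
       subsystem = TCAs, gpr = "gPDH", name = "pyruvate dehydrogenase")
  addr("CS", c("accoa[m]" = -1, "oaa[m]" = -1, "h2o[m]" = -1, "cit[m]" = 1,
               "coa[m]" = 1),
       subsystem = TCAs, gpr = "gCS", name = "citrate synthase")
  addr("MDHm", c("mal[m]" = -1, "nad[m]" = -1, "oaa[m]" = 1, "nadh[m]" = 1,
                 "h[m]" = 1), lb = -1000, subsystem = TCAs, gpr = "gMDHm")
  addr("TCA", c("accoa[m]" = -1, "nad[m]" = -4, "adp[m]" = -1, "pi[m]" = -1,
                "h2o[m]" = -2, "co2[m]" = 2, "nadh[m]" = 4, "coa[m]" = 1,
                "atp[m]" = 1, "h[m]" = 4),
       subsystem = TCAs, gpr = "gTCA", name = "TCA oxidation lump")
  addr("RESP", c("nadh[m]" = -1, "o2[m]" = -0.5, "adp[m]" = -2.5,
                 "pi[m]" = -2.5, "h[m]" = -1, "nad[m]" = 1, "atp[m]" = 2.5,
                 "h2o[m]" = 3.5),
       subsystem = "Oxidative phosphorylation", gpr = "gRESP",
       name = "respiratory chain lump, P/O 2.5")
  addr("AOX", c("nadh[m]" = -1, "o2[m]" = -0.5, "h[m]" = -1, "nad[m]" = 1,
                "h2o[m]" = 1),
       subsystem = "Oxidative phosphorylation", gpr = "gAOX",
       name = "alternative oxidase (non-phosphorylating)")

  # ---- peroxisomal beta-oxidation -----------------------------------------
  addr("BOX", c("c160coa[x]" = -1, "coa[x]" = -7, "o2[x]" = -7,
                "accoa[x]" = 8, "h2o[x]" = 7),
       subsystem = "Fatty acid degradation", gpr = "gBOX",
       name = "peroxisomal beta-oxidation lump")
  addr("ACH", c("accoa[x]" = -1, "h2o[x]" = -1, "ac[x]" = 1, "coa[x]" = 1),
       subsystem = "Fatty acid degradation", gpr = "gACH",
       name = "acetyl-CoA hydrolase")

  # ---- fatty acid and PUFA biosynthesis -----------------------------------
  FASs <- "Fatty acid biosynthesis"
  addr("ACC", c("accoa[c]" = -1, "co2[c]" = -1, "atp[c]" = -1,
                "h2o[c]" = -1, "malcoa[c]" = 1, "adp[c]" = 1, "pi[c]" = 1),
       subsystem = FASs, gpr = "gACC", name = "acetyl-CoA carboxylase")
  addr("FAS", c("accoa[c]" = -1, "malcoa[c]" = -7, "nadph[c]" = -14,
                "h[c]" = -14, "c160[c]" = 1, "co2[c]" = 7, "coa[c]" = 8,
                "nadp[c]" = 14, "h2o[c]" = 6),
       subsystem = FASs, gpr = "gFAS",
       name = "fatty acid synthase lump to palmitate")
  addr("FAA1", c("c160[c]" = -1, "coa[c]" = -1, "atp[c]" = -1,
                 "c160coa[c]" = 1, "adp[c]" = 1, "pi[c]" = 1),
       subsystem = FASs, gpr = "gFAA", name = "acyl-CoA synthetase")

  PUFA <- "PUFA biosynthesis"
  nelo <- spec$nadph_per_elongation
  elong <- function(id, sub, prod, gpr) {
    addr(id, setNames(c(-1, -1, -nelo, -nelo, 1, 1, 1, nelo, 1),
                      c(sub, "malcoa[c]", "nadph[c]", "h[c]", prod,
                        "co2[c]", "coa[c]", "nadp[c]", "h2o[c]")),
         subsystem = PUFA, gpr = gpr)
  }
  no2d <- spec$o2_per_desaturation
  ndes <- spec$nadph_per_desaturation
  desat <- function(id, sub, prod, gpr, name = id) {
    addr(id, setNames(c(-1, -no2d, -ndes, -ndes, 1, ndes, 2 * no2d),
                      c(sub, "o2[c]", "nadph[c]", "h[c]", prod, "nadp[c]",
                        "h2o[c]")),
         subsystem = PUFA, gpr = gpr, name = name)
  }
  elong("ELO1", "c160coa[c]", "c180coa[c]", "gELO1")
  desat("DS9", "c180coa[c]", "c181coa[c]", "gDS9a or gDS9b or gDS9c",
        name = "delta-9 desaturase")
  desat("DS12", "c181coa[c]", "c182coa[c]", "gDS12",
        name = "delta-12 desaturase")
  desat("DS6", "c182coa[c]", "c183coa[c]", "gDS6a or gDS6b",
        name = "delta-6 desaturase")
  elong("ELO2", "c183coa[c]", "c203coa[c]", "gGLELO or gMAELO")
  desat("DS5", "c203coa[c]", "c204coa[c]", "gDS5",
        name = "delta-5 desaturase")
  addr("TE_ARA", c("c204coa[c]" = -1, "h2o[c]" = -1, "ara[c]" = 1,
                   "coa[c]" = 1),
       subsystem = PUFA, gpr = "gHYD1 or gHYD2",
       name = "arachidonyl-CoA hydrolase")
  if (spec$include_omega3) {
    desat("DS17", "c204coa[c]", "c205coa[c]", "gDS17",
          name = "omega-3 desaturase lump to EPA-CoA")
    addr("TE_EPA", c("c205coa[c]" = -1, "h2o[c]" = -1, "epa[c]" = 1,
                     "coa[c]" = 1), subsystem = PUFA, gpr = "gHYD1 or gHYD2")
  }

  # ---- nitrogen and sulfur assimilation -----------------------------------
  NIT <- "Nitrogen metabolism"
  addr("NR", c("no3[c]" = -1, "nadph[c]" = -1, "h[c]" = -1, "no2[c]" = 1,
               "nadp[c]" = 1, "h2o[c]" = 1),
       subsystem = NIT, gpr = "gNR", name = "nitrate reductase")
  addr("NIR", c("no2[c]" = -1, "nadph[c]" = -3, "h[c]" = -3, "nh3[c]" = 1,
                "nadp[c]" = 3, "h2o[c]" = 2),
       subsystem = NIT, gpr = "gNIR", name = "nitrite reductase")

  # ---- amino acid metabolism ----------------------------------------------
  AAM <- "Amino acid metabolism"
  for (i in seq_len(nrow(AA_RECIPE))) {
    r <- AA_RECIPE[i, ]
    co2out <- 3 * r$pyr + 2 * r$accoa - r$carbons
    st <- c(-r$pyr, -r$nh3, -r$atp, -r$atp, -r$nadph, 1, r$atp, r$atp,
            r$nadph)
    names(st) <- c("pyr[c]", "nh3[c]", "atp[c]", "h2o[c]", "nadph[c]",
                   paste0(r$aa, "[c]"), "adp[c]", "pi[c]", "nadp[c]")
    if (r$accoa > 0) st <- c(st, "accoa[c]" = -r$accoa, "coa[c]" = r$accoa)
    if (r$so4 > 0) st <- c(st, "so4[c]" = -r$so4)
    if (co2out > 0) st <- c(st, "co2[c]" = co2out)
    addr(paste0("SYN_", r$aa), st, subsystem = AAM,
         gpr = paste0("gSYN", toupper(r$aa)),
         name = paste0(r$aa, " synthesis lump"))
  }
  deg <- list(
    asp = c("asp[c]" = -1, "coa[c]" = -1, "nad[c]" = -2, "h2o[c]" = -2,
            "accoa[c]" = 1, "nh3[c]" = 1, "co2[c]" = 2, "nadh[c]" = 2),
    ile = c("ile[c]" = -1, "coa[c]" = -2, "nad[c]" = -4, "h2o[c]" = -3,
            "accoa[c]" = 2, "nh3[c]" = 1, "co2[c]" = 2, "nadh[c]" = 4),
    leu = c("leu[c]" = -1, "coa[c]" = -3, "nad[c]" = -2, "h2o[c]" = -2,
            "accoa[c]" = 3, "nh3[c]" = 1, "nadh[c]" = 2),
    lys = c("lys[c]" = -1, "coa[c]" = -2, "nad[c]" = -4, "h2o[c]" = -4,
            "accoa[c]" = 2, "nh3[c]" = 2, "co2[c]" = 2, "nadh[c]" = 4),
    glu = c("glu[c]" = -1, "nad[c]" = -2, "h2o[c]" = -2, "pyr[c]" = 1,
            "nh3[c]" = 1, "co2[c]" = 2, "nadh[c]" = 2),
    gly = c("gly[c]" = -1, "nad[c]" = -2, "h2o[c]" = -1, "co2[c]" = 2,
            "nh3[c]" = 1, "nadh[c]" = 2))
  for (aa in names(deg))
    addr(paste0("DEG_", aa), deg[[aa]], subsystem = AAM,
         gpr = paste0("gDEG", toupper(aa)),
         name = paste0(aa, " degradation lump"))

  # ---- polymers, nucleotides, pool, maintenance, biomass ------------------
  NUC <- "Nucleotide metabolism"
  addr("SYN_ntp", c("ru5p[c]" = -1, "pyr[c]" = -2, "atp[c]" = -4,
                    "h2o[c]" = -4, "nh3[c]" = -2, "co2[c]" = -1,
                    "ntp[c]" = 1, "adp[c]" = 4, "pi[c]" = 4),
       subsystem = NUC, gpr = "gNTP", name = "nucleotide synthesis lump")
  addr("SYN_dntp", c("ntp[c]" = -1, "nadph[c]" = -1, "dntp[c]" = 1,
                     "nadp[c]" = 1, "h2o[c]" = 1),
       subsystem = NUC, gpr = "gRNR", name = "ribonucleotide reductase lump")
  addr("SYN_pool", c("g6p[c]" = -1, "atp[c]" = -2, "h2o[c]" = -2,
                     "nh3[c]" = -1, "nadph[c]" = -1, "pool[c]" = 1,
                     "adp[c]" = 2, "pi[c]" = 2, "nadp[c]" = 1),
       subsystem = "Small molecule pool", gpr = "gPOOL",
       name = "small-molecule pool lump")
  addr("WALL", c("g6p[c]" = -1, "atp[c]" = -1, "h2o[c]" = -1,
                 "glucan[c]" = 1, "adp[c]" = 1, "pi[c]" = 2),
       subsystem = "Cell wall", gpr = "gWALL",
       name = "beta-glucan synthesis lump")
  addr("ATPM", c("atp[c]" = -1, "h2o[c]" = -1, "adp[c]" = 1, "pi[c]" = 1),
       lb = spec$ngam, ub = spec$ngam, subsystem = "Maintenance",
       name = "non-growth ATP maintenance")

  comp <- mini_alpina_composition(gam = spec$gam, ngam = spec$ngam)
  rxns[[length(rxns) + 1L]] <-
    build_biomass_reaction(comp, mini_alpina_monomer_masses())

  model <- metabolic_model(metdf, rxns, objective = "BIOMASS",
                           id = "mini_alpina")

  nadph_rxns <- reactions_involving(model, "nadph[c]")
  gt <- list(
    biomass_reaction = "BIOMASS",
    atpm = "ATPM",
    ara_exchange = "EX_ara",
    epa_exchange = if (spec$include_omega3) "EX_epa" else NA_character_,
    glucose_exchange = "EX_glc",
    oxygen_exchange = "EX_o2",
    nitrate_exchange = "EX_no3",
    me_reaction = if (spec$malic_enzyme) "ME" else NA_character_,
    me_gene = if (spec$malic_enzyme) "gME" else NA_character_,
    ppp_reactions = if (spec$ppp) c("G6PDH", "GND") else character(0),
    nadph_reactions = nadph_rxns,
    rhamnose_lyase = "RHALYA",
    rhamnose_exchange = "EX_rha",
    nitrate_assimilation_genes = c("gNR", "gNIR"),
    aa_synthesis_genes = paste0("gSYN", toupper(AA3)),
    delta5_gene = "gDS5", delta12_gene = "gDS12",
    delta5_reaction = "DS5",
    production_growth_rate = 0.03,
    carbon_sources_growing = c("EX_glc", "EX_glyc", "EX_etoh", "EX_ac",
                               "EX_lac", "EX_rha"),
    oxygen_scan = list(range = c(0, 20),
                       expectation = "interior single-peaked optimum"),
    composition = comp,
    spec = spec)
  list(model = model, ground_truth = gt)
}

#' Built-in MG (minimal) medium for the synthetic model
#'
#' Glucose + nitrate + mineral salts; O2/CO2/water/protons/phosphate/
#' sulfate are always open (without free water and protons no genome-scale
#' model is feasible).
#'
#' @param glucose_uptake maximum glucose uptake (default 0.8).
#' @export
medium_mg <- function(glucose_uptake = 0.8) {
  medium("MG",
         overrides = list(EX_glc = c(-glucose_uptake, 1000),
                          EX_no3 = c(-1000, 1000)),
         always_open = c("EX_o2", "EX_co2", "EX_h2o", "EX_h", "EX_pi",
                         "EX_so4"))
}

#' Built-in YE (yeast-extract analogue) medium
#'
#' MG plus all 20 regular amino acids at a maximum uptake of
#' \code{aa_uptake} each (default 0.01 mmol gDW-1 h-1).
#'
#' @param glucose_uptake maximum glucose uptake (default 0.8).
#' @param aa_uptake per-amino-acid maximum uptake (default 0.01).
#' @export
medium_ye <- function(glucose_uptake = 0.8, aa_uptake = 0.01) {
  med <- medium_mg(glucose_uptake)
  med$name <- "YE"
  for (aa in AA3) med$overrides[[paste0("EX_", aa)]] <- c(-aa_uptake, 1000)
  med
}

#' Generate a random viable model
#'
#' Embeds a deterministic linear uptake -> biomass backbone (so FBA growth
#' is positive by construction) and decorates it with random reactions that
#' may create gaps.  With \code{mode = "acyclic"} all decorations are
#' irreversible unimolecular conversions along a topological order, so
#' blocked metabolites are exactly the graph-unreachable ones.
#'
#' @param n_metabolites,n_reactions,n_genes sizes; \code{n_reactions} must
#'   cover the backbone (\code{backbone_len + 2}).
#' @param rev_fraction fraction of decorating reactions made reversible
#'   (ignored for \code{mode = "acyclic"}).
#' @param seed integer; same seed, same model.
#' @param mode \code{"decorated"} (random bimolecular decorations) or
#'   \code{"acyclic"} (unimolecular DAG, for reachability oracles).
#' @param backbone_len number of internal backbone conversions.
#' @export
random_viable_model <- function(n_metabolites = 12, n_reactions = 18,
                                n_genes = 6, rev_fraction = 0.2, seed = 1L,
                                mode = c("decorated", "acyclic"),
                                backbone_len = 3L) {
  mode <- match.arg(mode)
  if (n_metabolites < backbone_len + 1L)
    stop("n_metabolites too small for the backbone")
  if (n_reactions < backbone_len + 2L)
    stop("n_reactions too small for the backbone")
  set.seed(seed)
  mets <- list(metabolite("s[e]", "substrate", "e"))
  for (i in seq_len(n_metabolites))
    mets[[i + 1L]] <- metabolite(sprintf("m%02d[c]", i), sprintf("m%02d", i), "c")
  metdf <- do.call(rbind, mets)
  genes <- sprintf("g%02d", seq_len(n_genes))
  rxns <- list()
  rxns[[1]] <- reaction("EX_s", c("s[e]" = -1), lb = -10, ub = 1000,
                        rtype = "exchange", subsystem = "Exchange")
  rxns[[2]] <- reaction("T_s", c("s[e]" = -1, "m01[c]" = 1),
                        rtype = "transport", subsystem = "Transport")
  for (i in seq_len(backbone_len)) {
    rxns[[2L + i]] <- reaction(sprintf("B%02d", i),
                               setNames(c(-1, 1), sprintf("m%02d[c]", c(i, i + 1L))),
                               subsystem = "Backbone",
                               gpr = genes[(i - 1L) %% n_genes + 1L])
  }
  rxns[[backbone_len + 3L]] <-
    reaction("BIOMASS", setNames(-1, sprintf("m%02d[c]", backbone_len + 1L)),
             subsystem = "Biomass", rtype = "biochemical")
  n_extra <- n_reactions - backbone_len - 3L
  k <- length(rxns)
  for (j in seq_len(max(n_extra, 0L))) {
    if (mode == "acyclic") {
      from <- sample(n_metabolites - 1L, 1L)
      higher <- (from + 1L):n_metabolites
      to <- higher[sample.int(length(higher), 1L)]   # sample(x, 1) trap
      st <- setNames(c(-1, 1), sprintf("m%02d[c]", c(from, to)))
      rev <- FALSE
    } else {
      pair <- sample(n_metabolites, 2L)
      st <- setNames(c(-1, 1), sprintf("m%02d[c]", pair))
      rev <- runif(1) < rev_fraction
    }
    k <- k + 1L
    rxns[[k]] <- reaction(sprintf("R%02d", j), st, reversible = rev,
                          subsystem = "Decoration",
                          gpr = genes[sample(n_genes, 1L)])
  }
  metabolic_model(metdf, rxns, objective = "BIOMASS",
                  id = sprintf("random_%d", seed))
}

#' Remove reactions from a model
#'
#' @param model a \code{metabolic_model}.
#' @param ids reaction ids to delete; removing the objective (biomass)
#'   reaction is refused.
#' @return the revalidated model.
#' @export
remove_reactions <- function(model, ids) {
  missing <- setdiff(ids, rxn_ids(model))
  if (length(missing)) stop("unknown reaction(s): ", paste(missing, collapse = ", "))
  if (!is.na(model$objective) && model$objective %in% ids)
    stop("refusing to remove the objective (biomass) reaction")
  model$reactions[ids] <- NULL
  model$genes <- sort(unique(unlist(lapply(model$reactions,
                                           function(r) gpr_genes(r$gpr)))))
  validate_model(model)
  model
}
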