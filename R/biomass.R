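# Biomass equation assembly.
#
# Biomass is modelled as six macromolecular components (protein, DNA, RNA,
# lipid, cell wall, small-molecule pool) with per-component monomer weight
# fractions.  Coefficients are mmol of monomer drained per gram dry weight:
#   coef = component fraction x monomer fraction / monomer molar mass x 1000.
# Growth-associated maintenance (GAM) adds a mass-neutral ATP hydrolysis
# cycle; non-growth maintenance (NGAM) is a fixed standalone ATP drain.

BIOMASS_COMPONENTS <- c("protein", "dna", "rna", "lipid", "cell_wall",
                        "small_pool")

#' Define a biomass composition
#'
#' @param fractions named numeric, g per gDW for the six components
#'   (names must be \code{protein, dna, rna, lipid, cell_wall, small_pool});
#'   must sum to 1 within \code{tol} unless \code{normalize = TRUE}.
#' @param monomers named list; for each component a named numeric vector of
#'   monomer weight fractions (metabolite id -> fraction, summing to 1).
#' @param gam growth-associated maintenance, mmol ATP per gDW.
#' @param ngam non-growth-associated maintenance, mmol ATP gDW-1 h-1.
#' @param normalize rescale component fractions to sum to 1.
#' @param tol tolerance on the fraction sums (default 1e-6).
#' @export
biomass_composition <- function(fractions, monomers, gam = 30, ngam = 1,
                                normalize = FALSE, tol = 1e-6) {
  if (!setequal(names(fractions), BIOMASS_COMPONENTS))
    stop("fractions must be named exactly: ",
         paste(BIOMASS_COMPONENTS, collapse = ", "))
  if (any(fractions < 0)) stop("component fractions must be >= 0")
  s <- sum(fractions)
  if (abs(s - 1) > tol) {
    if (normalize) fractions <- fractions / s
    else stop(sprintf("component fractions sum to %.8f, not 1 (use normalize = TRUE)", s))
  }
  if (!setequal(names(monomers), BIOMASS_COMPONENTS))
    stop("monomers must have one entry per component")
  for (cmp in BIOMASS_COMPONENTS) {
    mf <- monomers[[cmp]]
    if (fractions[[cmp]] > 0 && abs(sum(mf) - 1) > tol)
      stop(sprintf("monomer fractions for '%s' sum to %.8f, not 1", cmp, sum(mf)))
  }
  if (gam < 0 || ngam < 0) stop("GAM and NGAM must be >= 0")
  structure(list(fractions = fractions[BIOMASS_COMPONENTS],
                 monomers = monomers[BIOMASS_COMPONENTS],
                 gam = gam, ngam = ngam),
            class = "biomass_composition")
}

#' Build the biomass reaction from a composition
#'
#' @param composition a \code{\link{biomass_composition}}.
#' @param monomer_molar_masses named numeric, g/mol for every monomer id
#'   used by the composition.
#' @param energy named character vector with entries \code{atp, adp, pi,
#'   h2o, h} giving the metabolite ids of the GAM hydrolysis cycle.
#' @param biomass_met id of the produced biomass metabolite.
#' @param id reaction id (default \code{"BIOMASS"}).
#' @return a \code{\link{reaction}} (bounds [0, 1000], rtype biochemical,
#'   flux in h-1).
#' @export
build_biomass_reaction <- function(composition, monomer_molar_masses,
                                   energy = c(atp = "atp[c]", adp = "adp[c]",
                                              pi = "pi[c]", h2o = "h2o[c]",
                                              h = "h[c]"),
                                   biomass_met = "biomass[c]",
                                   id = "BIOMASS") {
  stopifnot(inherits(composition, "biomass_composition"))
  if (any(monomer_molar_masses <= 0)) stop("molar masses must be > 0")
  stoich <- numeric(0)
  for (cmp in BIOMASS_COMPONENTS) {
    f <- composition$fractions[[cmp]]
    if (f <= 0) next
    for (mono in names(composition$monomers[[cmp]])) {
      w <- composition$monomers[[cmp]][[mono]]
      if (w <= 0) next
      if (!(mono %in% names(monomer_molar_masses)))
        stop(sprintf("no molar mass given for monomer '%s'", mono))
      coef <- f * w / monomer_molar_masses[[mono]] * 1000  # mmol per gDW
      stoich[mono] <- (if (mono %in% names(stoich)) stoich[[mono]] else 0) - coef
    }
  }
  gam <- composition$gam
  add <- c(-gam, gam, gam, -gam, gam)
  names(add) <- energy[c("atp", "adp", "pi", "h2o", "h")]
  for (k in names(add)) {
    stoich[k] <- (if (k %in% names(stoich)) stoich[[k]] else 0) + add[[k]]
  }
  stoich[biomass_met] <- 1
  reaction(id, stoich, lb = 0, ub = 1000, name = "biomass assembly",
           rtype = "biochemical", subsystem = "Biomass")
}

#' Total monomer mass drained per unit biomass flux
#'
#' Mass-conservation audit of a biomass reaction: should be 1 g per gDW
#' (the GAM ATP cycle is mass-neutral and excluded).
#'
#' @param biomass_reaction the reaction from
#'   \code{\link{build_biomass_reaction}}.
#' @param monomer_molar_masses named numeric g/mol; ids absent from this
#'   vector (the energy cycle and the biomass product) are skipped.
#' @export
biomass_drain_mass <- function(biomass_reaction, monomer_molar_masses) {
  st <- biomass_reaction$stoich
  ids <- intersect(names(st), names(monomer_molar_masses))
  sum(-st[ids] * monomer_molar_masses[ids]) / 1000
}

#' Impose non-growth-associated maintenance
#'
#' Pins the ATP maintenance reaction to exactly \code{ngam_value}
#' (lb = ub = value).
#'
#' @param model a \code{metabolic_model}.
#' @param ngam_value mmol ATP gDW-1 h-1, >= 0.
#' @param reaction_id maintenance reaction id (default \code{"ATPM"}).
#' @export
add_ngam <- function(model, ngam_value, reaction_id = "ATPM") {
  if (ngam_value < 0) stop("NGAM must be >= 0")
  if (!(reaction_id %in% rxn_ids(model)))
    stop(sprintf("no maintenance reaction '%s' in model", reaction_id))
  set_bounds(model, reaction_id, lb = ngam_value, ub = ngam_value)
}
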