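# In-memory representation of a compartmentalized genome-scale model.
#
# A metabolic_model is a plain S3 list: a metabolites data.frame, a named
# list of reactions (each with a named stoichiometry vector, bounds, type,
# subsystem and GPR string), a gene vector derived from the GPRs, and an
# objective reaction id.  Metabolite ids carry their compartment as a
# bracketed suffix ("glc[c]") in the tabular convention; the compartment is
# also stored explicitly so SBML IO does not depend on the suffix.

DEFAULT_COMPARTMENTS <- c(e = "extracellular", c = "cytosol",
                          m = "mitochondrion", x = "peroxisome")

#' Create a metabolite record
#'
#' @param id unique metabolite id (conventionally \code{"name[comp]"}).
#' @param name free-text name.
#' @param compartment compartment key (e.g. \code{"c"}); must be registered
#'   in the model's compartment table.
#' @param formula optional elemental formula string (e.g. \code{"C6H12O6"}).
#' @param charge optional integer charge.
#' @export
metabolite <- function(id, name = id, compartment, formula = NA_character_,
                       charge = NA_real_) {
  data.frame(id = id, name = name, compartment = compartment,
             formula = formula, charge = charge, stringsAsFactors = FALSE)
}

#' Create a reaction record
#'
#' @param id unique reaction id.
#' @param stoich named numeric vector: metabolite id -> signed coefficient
#'   (negative = consumed).
#' @param lb,ub flux bounds in mmol gDW-1 h-1 (the biomass reaction is in
#'   h-1). Defaults follow the COBRA convention: irreversible [0, 1000],
#'   reversible [-1000, 1000].
#' @param name free-text name.
#' @param rtype \code{"biochemical"}, \code{"transport"} or
#'   \code{"exchange"}; if \code{NA} it is inferred from the compartments
#'   spanned when the reaction is validated in a model.
#' @param subsystem free subsystem label.
#' @param gpr GPR rule string (\code{""} = no gene association).
#' @param reversible logical; sets default bounds when lb/ub not given.
#' @export
reaction <- function(id, stoich, lb = NULL, ub = NULL, name = id,
                     rtype = NA_character_, subsystem = "", gpr = "",
                     reversible = FALSE) {
  if (is.null(lb)) lb <- if (reversible) -1000 else 0
  if (is.null(ub)) ub <- 1000
  stopifnot(is.numeric(stoich), !is.null(names(stoich)), all(nzchar(names(stoich))))
  if (lb > ub) stop(sprintf("reaction '%s': lower bound %g exceeds upper bound %g",
                            id, lb, ub))
  structure(list(id = id, name = name, stoich = stoich, lb = lb, ub = ub,
                 rtype = rtype, subsystem = subsystem, gpr = gpr),
            class = "model_reaction")
}

#' Assemble a metabolic model
#'
#' @param metabolites data.frame as produced by rbind-ing
#'   \code{\link{metabolite}} rows.
#' @param reactions list of \code{\link{reaction}} objects.
#' @param objective id of the objective (usually biomass) reaction, or
#'   \code{NA} if not yet chosen.
#' @param compartments named character vector, key -> long name.
#' @param id model identifier.
#' @param validate run \code{\link{validate_model}} (default TRUE).
#' @return object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(metabolites, reactions, objective = NA_character_,
                            compartments = DEFAULT_COMPARTMENTS,
                            id = "model", validate = TRUE) {
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  mod <- structure(list(id = id,
                        compartments = compartments,
                        metabolites = metabolites,
                        reactions = reactions,
                        genes = character(0),
                        objective = objective),
                   class = "metabolic_model")
  mod$genes <- sort(unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr)))))
  # infer reaction types where unset
  mod$reactions <- lapply(mod$reactions, function(r) {
    if (is.na(r$rtype)) r$rtype <- infer_rtype(mod, r)
    r
  })
  if (validate) validate_model(mod)
  mod
}

#' Metabolite / reaction id accessors
#' @param model a \code{metabolic_model}.
#' @export
met_ids <- function(model) model$metabolites$id

#' @rdname met_ids
#' @export
rxn_ids <- function(model) names(model$reactions)

met_compartment <- function(model, ids) {
  model$metabolites$compartment[match(ids, model$metabolites$id)]
}

infer_rtype <- function(model, r) {
  comps <- unique(met_compartment(model, names(r$stoich)))
  if (length(r$stoich) == 1L && identical(comps, "e")) return("exchange")
  if (length(comps) >= 2L) return("transport")
  "biochemical"
}

#' Validate model structural invariants
#'
#' Checks id uniqueness, compartment registration, stoichiometry resolution,
#' bound ordering, reaction-type compartment rules, GPR parseability and
#' gene-list consistency. Stops with an informative error on the first
#' violation.
#'
#' @param model a \code{metabolic_model}.
#' @return the model, invisibly.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  bad_comp <- setdiff(unique(mets$compartment), names(model$compartments))
  if (length(bad_comp))
    stop("unregistered compartments: ", paste(bad_comp, collapse = ", "))
  if (anyDuplicated(names(model$reactions)))
    stop("duplicate reaction ids: ",
         paste(unique(names(model$reactions)[duplicated(names(model$reactions))]),
               collapse = ", "))
  gpr_union <- character(0)
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoich), mets$id)
    if (length(missing))
      stop(sprintf("structural integrity: reaction '%s' references unknown metabolite(s): %s",
                   r$id, paste(missing, collapse = ", ")))
    if (r$lb > r$ub)
      stop(sprintf("reaction '%s': lb > ub", r$id))
    comps <- unique(met_compartment(model, names(r$stoich)))
    if (r$rtype == "exchange") {
      if (length(r$stoich) != 1L || !identical(comps, "e"))
        stop(sprintf("exchange reaction '%s' must have exactly one extracellular metabolite", r$id))
    } else if (r$rtype == "transport") {
      if (length(comps) < 2L)
        stop(sprintf("transport reaction '%s' must span >= 2 compartments", r$id))
    } else if (r$rtype == "biochemical") {
      if (length(comps) != 1L)
        stop(sprintf("biochemical reaction '%s' must live in a single compartment (spans: %s)",
                     r$id, paste(comps, collapse = ", ")))
    } else stop(sprintf("reaction '%s': unknown rtype '%s'", r$id, r$rtype))
    gpr_union <- c(gpr_union, gpr_genes(r$gpr))  # errors if unparseable
  }
  if (!setequal(model$genes, unique(gpr_union)))
    stop("model gene list does not equal the union of GPR leaves")
  if (!is.na(model$objective) && !(model$objective %in% rxn_ids(model)))
    stop(sprintf("objective reaction '%s' not in model", model$objective))
  invisible(model)
}

#' Build the stoichiometric matrix S (metabolites x reactions)
#'
#' Entry (i, j) is the signed coefficient of metabolite i in reaction j.
#' Row and column order follow model ordering and are stable.
#'
#' @param model a validated \code{metabolic_model}.
#' @return dense numeric matrix with dimnames (metabolite ids, reaction ids).
#' @export
stoichiometric_matrix <- function(model) {
  m <- nrow(model$metabolites); n <- length(model$reactions)
  S <- matrix(0, m, n, dimnames = list(model$metabolites$id, rxn_ids(model)))
  for (j in seq_len(n)) {
    st <- model$reactions[[j]]$stoich
    idx <- match(names(st), model$metabolites$id)
    if (anyNA(idx))
      stop(sprintf("structural integrity: reaction '%s' references unknown metabolite(s): %s",
                   model$reactions[[j]]$id,
                   paste(names(st)[is.na(idx)], collapse = ", ")))
    S[idx, j] <- S[idx, j] + st
  }
  S
}

#' Reactions whose stoichiometry involves a metabolite
#'
#' @param model a \code{metabolic_model}.
#' @param metabolite_id full metabolite id, or a compartment-free base name
#'   when \code{pooled = TRUE} (then any \code{"base[x]"} variant matches).
#' @param compartment optional compartment key filter.
#' @param pooled treat \code{metabolite_id} as a base name across all
#'   compartments.
#' @return character vector of reaction ids.
#' @export
reactions_involving <- function(model, metabolite_id, compartment = NULL,
                                pooled = FALSE) {
  if (pooled) {
    targets <- met_ids(model)[sub("\\[[^]]*\\]$", "", met_ids(model)) == metabolite_id]
  } else {
    if (!(metabolite_id %in% met_ids(model)))
      stop(sprintf("unknown metabolite '%s'", metabolite_id))
    targets <- metabolite_id
  }
  if (!is.null(compartment))
    targets <- targets[met_compartment(model, targets) %in% compartment]
  hit <- vapply(model$reactions, function(r) any(names(r$stoich) %in% targets),
                logical(1))
  names(model$reactions)[hit]
}

#' Exchange reaction ids of a model
#' @param model a \code{metabolic_model}.
#' @export
exchange_ids <- function(model) {
  names(model$reactions)[vapply(model$reactions, function(r)
    identical(r$rtype, "exchange"), logical(1))]
}

#' Set bounds on one reaction
#' @param model a \code{metabolic_model}.
#' @param id reaction id.
#' @param lb,ub new bounds (either may be NULL to keep current).
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  if (!(id %in% rxn_ids(model))) stop(sprintf("unknown reaction '%s'", id))
  if (!is.null(lb)) model$reactions[[id]]$lb <- lb
  if (!is.null(ub)) model$reactions[[id]]$ub <- ub
  if (model$reactions[[id]]$lb > model$reactions[[id]]$ub)
    stop(sprintf("reaction '%s': lb > ub", id))
  model
}

reaction_bounds <- function(model) {
  list(lb = vapply(model$reactions, `[[`, numeric(1), "lb"),
       ub = vapply(model$reactions, `[[`, numeric(1), "ub"))
}

#' Set the objective reaction
#' @param model a \code{metabolic_model}.
#' @param id reaction id to optimize.
#' @export
set_objective <- function(model, id) {
  if (!(id %in% rxn_ids(model))) stop(sprintf("unknown reaction '%s'", id))
  model$objective <- id
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  tab <- table(vapply(x$reactions, `[[`, character(1), "rtype"))
  cat(sprintf("<metabolic_model> %s: %d metabolites x %d reactions, %d genes\n",
              x$id, nrow(x$metabolites), length(x$reactions), length(x$genes)))
  cat("  compartments:", paste(sprintf("%s (%s)", names(x$compartments),
                                       x$compartments), collapse = ", "), "\n")
  cat("  reactions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  objective:", if (is.na(x$objective)) "(unset)" else x$objective, "\n")
  invisible(x)
}

# ---- elemental audit -------------------------------------------------------

#' Parse an elemental formula string
#' @param formula e.g. \code{"C6H12O6"}; returns a named numeric vector of
#'   element counts, or NULL for NA/empty formulas.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula, perl = TRUE)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula, perl = TRUE))[[1]]
  if (sum(nchar(parts)) != nchar(formula))
    stop(sprintf("cannot parse formula '%s'", formula))
  out <- numeric(0)
  for (p in parts) {
    el <- regmatches(p, regexpr("^[A-Z][a-z]?", p))
    ct <- sub("^[A-Z][a-z]?", "", p)
    n <- if (nzchar(ct)) as.numeric(ct) else 1
    out[el] <- (if (el %in% names(out)) out[[el]] else 0) + n
  }
  out
}

#' Audit elemental balance of model reactions
#'
#' For every non-exchange reaction whose participants all carry formulas,
#' sums element counts weighted by stoichiometric coefficients. Balanced
#' reactions sum to zero for every element.
#'
#' @param model a \code{metabolic_model}.
#' @param tol imbalance tolerance per element (default 1e-6).
#' @return data.frame with columns reaction, audited (logical: all formulas
#'   present), balanced (logical, NA when not audited), imbalance
#'   (worst absolute element excess).
#' @export
elemental_audit <- function(model, tol = 1e-6) {
  forms <- lapply(model$metabolites$formula, parse_formula)
  names(forms) <- model$metabolites$id
  out <- lapply(model$reactions, function(r) {
    if (r$rtype == "exchange")
      return(data.frame(reaction = r$id, audited = FALSE, balanced = NA,
                        imbalance = NA_real_))
    fs <- forms[names(r$stoich)]
    if (any(vapply(fs, is.null, logical(1))))
      return(data.frame(reaction = r$id, audited = FALSE, balanced = NA,
                        imbalance = NA_real_))
    els <- unique(unlist(lapply(fs, names)))
    tot <- setNames(numeric(length(els)), els)
    for (k in seq_along(fs)) {
      f <- fs[[k]]
      tot[names(f)] <- tot[names(f)] + r$stoich[[k]] * f
    }
    data.frame(reaction = r$id, audited = TRUE,
               balanced = max(abs(tot)) <= tol, imbalance = max(abs(tot)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
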