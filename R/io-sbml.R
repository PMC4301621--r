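# SBML Level 3 Version 1 + fbc version 2 reader/writer on xml2.
#
# No libsbml binding exists in this R stack, so a constrained but
# standards-following subset is implemented directly: compartments,
# species (with fbc chemical formula/charge), reactions with
# reactant/product stoichiometries, flux bounds as shared fbc parameters,
# nested fbc gene-product associations, the active objective, and
# subsystem labels in COBRA-style notes.  Identifiers are encoded with the
# COBRA "__<ascii>__" convention so arbitrary metabolite/reaction ids
# round-trip bit-exactly.  A minimal COBRA Level-2 fallback (bounds in
# kineticLaw parameters, GPR in GENE_ASSOCIATION notes) is also read.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_encode_id <- function(x, prefix) {
  enc <- vapply(strsplit(x, "")[[1]], function(ch) {
    if (grepl("^[A-Za-z0-9_]$", ch)) ch
    else sprintf("__%d__", utf8ToInt(ch))
  }, character(1))
  paste0(prefix, paste(enc, collapse = ""))
}

sbml_decode_id <- function(x, prefix) {
  x <- sub(paste0("^", prefix), "", x)
  m <- gregexpr("__([0-9]+)__", x)
  regmatches(x, m) <- lapply(regmatches(x, m), function(codes)
    vapply(codes, function(cd)
      intToUtf8(as.integer(sub("^__([0-9]+)__$", "\\1", cd))), character(1)))
  x
}

#' Write a model as SBML Level 3 + fbc
#'
#' @param model a \code{metabolic_model}.
#' @param path output file.
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mnode <- xml2::xml_add_child(doc, "model", id = sbml_encode_id(model$id, ""),
                               "fbc:strict" = "true")
  lc <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (k in names(model$compartments))
    xml2::xml_add_child(lc, "compartment", id = k,
                        name = model$compartments[[k]], constant = "true")
  ls <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species",
                              id = sbml_encode_id(mt$id, "M_"),
                              name = mt$name, compartment = mt$compartment,
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    if (!is.na(mt$formula)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", mt$formula)
    if (!is.na(mt$charge)) xml2::xml_set_attr(sp, "fbc:charge",
                                              format(mt$charge))
  }
  # shared flux-bound parameters
  bounds <- unique(c(vapply(model$reactions, `[[`, numeric(1), "lb"),
                     vapply(model$reactions, `[[`, numeric(1), "ub")))
  pid <- setNames(sprintf("fb_%d", seq_along(bounds)),
                  vapply(bounds, format, character(1), digits = 17))
  lp <- xml2::xml_add_child(mnode, "listOfParameters")
  for (b in bounds)
    xml2::xml_add_child(lp, "parameter", id = pid[[format(b, digits = 17)]],
                        value = format(b, digits = 17), constant = "true",
                        sboTerm = "SBO:0000626")
  lg <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
  for (g in model$genes)
    xml2::xml_add_child(lg, "fbc:geneProduct",
                        "fbc:id" = sbml_encode_id(g, "G_"), "fbc:label" = g)
  lr <- xml2::xml_add_child(mnode, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(lr, "reaction",
                              id = sbml_encode_id(r$id, "R_"), name = r$name,
                              reversible = if (r$lb < 0) "true" else "false",
                              fast = "false",
                              "fbc:lowerFluxBound" = pid[[format(r$lb, digits = 17)]],
                              "fbc:upperFluxBound" = pid[[format(r$ub, digits = 17)]])
    if (nzchar(r$subsystem)) {
      nt <- xml2::xml_add_child(rn, "notes")
      bd <- xml2::xml_add_child(nt, "body", xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(bd, "p", paste0("SUBSYSTEM: ", r$subsystem))
    }
    react <- r$stoich[r$stoich < 0]; prods <- r$stoich[r$stoich > 0]
    if (length(react)) {
      lrx <- xml2::xml_add_child(rn, "listOfReactants")
      for (k in names(react))
        xml2::xml_add_child(lrx, "speciesReference",
                            species = sbml_encode_id(k, "M_"),
                            stoichiometry = format(-react[[k]], digits = 17),
                            constant = "true")
    }
    if (length(prods)) {
      lpx <- xml2::xml_add_child(rn, "listOfProducts")
      for (k in names(prods))
        xml2::xml_add_child(lpx, "speciesReference",
                            species = sbml_encode_id(k, "M_"),
                            stoichiometry = format(prods[[k]], digits = 17),
                            constant = "true")
    }
    rule <- parse_gpr(r$gpr)
    if (!is.null(rule$tree)) {
      ga <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      sbml_write_gpr(ga, rule$tree)
    }
  }
  if (!is.na(model$objective)) {
    lo <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = sbml_encode_id(model$objective, "R_"),
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

sbml_write_gpr <- function(parent, node) {
  if (is.character(node)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = sbml_encode_id(node, "G_"))
  } else {
    grp <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
    for (a in node$args) sbml_write_gpr(grp, a)
  }
}

xfind <- function(node, tag) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", tag))
}
xattr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  v
}

#' Read a model from SBML
#'
#' Supports Level 3 + fbc v2 (flux-bound parameters, gene-product
#' associations, active objective) and, as a fallback, COBRA-style Level 2
#' (kineticLaw LOWER_BOUND/UPPER_BOUND parameters, GENE_ASSOCIATION
#' notes). Reactions without bounds get the reversibility-based defaults
#' with a warning.
#'
#' @param path SBML file.
#' @return a validated \code{metabolic_model}.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("cannot read SBML file '", path, "': ", conditionMessage(e)))
  mnode <- xfind(doc, "model")[[1]]
  comps <- xfind(mnode, "compartment")
  compartments <- setNames(
    ifelse(is.na(xml2::xml_attr(comps, "name")), xml2::xml_attr(comps, "id"),
           xml2::xml_attr(comps, "name")),
    xml2::xml_attr(comps, "id"))
  if (!length(compartments)) compartments <- DEFAULT_COMPARTMENTS

  sp <- xfind(mnode, "species")
  sids <- xml2::xml_attr(sp, "id")
  mets <- data.frame(
    id = sbml_decode_id(sids, "M_"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  sbml_decode_id(sids, "M_"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    charge = suppressWarnings(as.numeric(xml2::xml_attr(sp, "charge"))),
    stringsAsFactors = FALSE)
  sid2id <- setNames(mets$id, sids)

  params <- xfind(mnode, "parameter")
  pvals <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                    xml2::xml_attr(params, "id"))
  gps <- xfind(mnode, "geneProduct")
  gid2label <- setNames(
    ifelse(is.na(xml2::xml_attr(gps, "label")),
           sbml_decode_id(xml2::xml_attr(gps, "id"), "G_"),
           xml2::xml_attr(gps, "label")),
    xml2::xml_attr(gps, "id"))

  missing_bounds <- character(0)
  rxns <- list()
  for (rn in xml2::xml_find_all(mnode, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")) {
    rid <- sbml_decode_id(xml2::xml_attr(rn, "id"), "R_")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rn, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")) {
      k <- sid2id[[xml2::xml_attr(sr, "species")]]
      st[k] <- (if (k %in% names(st)) st[[k]] else 0) -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rn, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")) {
      k <- sid2id[[xml2::xml_attr(sr, "species")]]
      st[k] <- (if (k %in% names(st)) st[[k]] else 0) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    lbref <- xml2::xml_attr(rn, "lowerFluxBound")
    ubref <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- ub <- NA_real_
    if (!is.na(lbref) && lbref %in% names(pvals)) lb <- pvals[[lbref]]
    if (!is.na(ubref) && ubref %in% names(pvals)) ub <- pvals[[ubref]]
    if (is.na(lb) || is.na(ub)) {       # COBRA L2 kineticLaw fallback
      for (kp in xml2::xml_find_all(rn, ".//*[local-name()='kineticLaw']//*[local-name()='parameter']")) {
        pn <- xml2::xml_attr(kp, "id")
        if (identical(pn, "LOWER_BOUND")) lb <- as.numeric(xml2::xml_attr(kp, "value"))
        if (identical(pn, "UPPER_BOUND")) ub <- as.numeric(xml2::xml_attr(kp, "value"))
      }
    }
    if (is.na(lb)) { lb <- if (rev) -1000 else 0; missing_bounds <- c(missing_bounds, rid) }
    if (is.na(ub)) { ub <- 1000; missing_bounds <- unique(c(missing_bounds, rid)) }

    gpr <- ""
    ga <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']")
    if (!inherits(ga, "xml_missing")) {
      kids <- xml2::xml_children(ga)
      if (length(kids)) gpr <- sbml_read_gpr(kids[[1]], gid2label)
    } else {
      notes <- xml2::xml_text(xml2::xml_find_all(rn, ".//*[local-name()='notes']//text()"))
      gm <- grep("GENE_ASSOCIATION:", notes, value = TRUE)
      if (length(gm)) gpr <- trimws(sub(".*GENE_ASSOCIATION:", "", gm[1]))
    }
    sub <- ""
    notes <- xml2::xml_text(xml2::xml_find_all(rn, ".//*[local-name()='notes']//text()"))
    sm <- grep("SUBSYSTEM:", notes, value = TRUE)
    if (length(sm)) sub <- trimws(sub(".*SUBSYSTEM:", "", sm[1]))
    nm <- xml2::xml_attr(rn, "name")
    rxns[[length(rxns) + 1L]] <-
      reaction(rid, st, lb = lb, ub = ub, name = if (is.na(nm)) rid else nm,
               subsystem = sub, gpr = gpr)
  }
  if (length(missing_bounds))
    warning("no flux bounds for reaction(s) ",
            paste(missing_bounds, collapse = ", "),
            "; reversibility-based defaults applied")

  objective <- NA_character_
  fo <- xml2::xml_find_first(mnode, ".//*[local-name()='fluxObjective']")
  if (!inherits(fo, "xml_missing"))
    objective <- sbml_decode_id(xml2::xml_attr(fo, "reaction"), "R_")

  mid <- xml2::xml_attr(mnode, "id")
  metabolic_model(mets, rxns, objective = objective,
                  compartments = compartments,
                  id = if (is.na(mid)) "model" else sbml_decode_id(mid, ""))
}

sbml_read_gpr <- function(node, gid2label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    lab <- if (gid %in% names(gid2label)) gid2label[[gid]]
           else sbml_decode_id(gid, "G_")
    return(lab)
  }
  parts <- vapply(xml2::xml_children(node), sbml_read_gpr, character(1),
                  gid2label = gid2label)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}
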