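# Tabular model IO: reaction equation strings, the TSV bundle
# (reactions.tsv / metabolites.tsv / genes.tsv / model.tsv), flux-result
# tables and medium config files.

#' Parse a reaction equation string
#'
#' Accepted arrows: \code{->}, \code{=>} (irreversible), \code{<=>},
#' \code{<->} (reversible); whitespace-insensitive. An empty side denotes
#' the boundary, e.g. \code{"1 glc[e] <=> "} for an exchange.
#'
#' @param equation character scalar, e.g.
#'   \code{"2 A[c] + 3 B[c] -> C[m]"}.
#' @return list with \code{stoich} (named numeric) and \code{reversible}.
#' @export
parse_reaction_equation <- function(equation) {
  arrows <- c("<=>", "<->", "=>", "->")
  arrow <- NULL
  for (a in arrows) if (grepl(a, equation, fixed = TRUE)) { arrow <- a; break }
  if (is.null(arrow))
    stop(sprintf("no reaction arrow found in '%s'", equation))
  sides <- strsplit(equation, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L)
    stop(sprintf("more than one arrow in '%s'", equation))
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (term in terms) {
      if (!nzchar(term)) stop(sprintf("empty term in '%s'", equation))
      m <- regmatches(term, regexec("^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)?\\s*(\\S.*)$", term))[[1]]
      if (length(m) != 3L || !nzchar(m[3]))
        stop(sprintf("cannot parse term '%s' in '%s'", term, equation))
      coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
      met <- trimws(m[3])
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (k in names(rhs)) st[k] <- (if (k %in% names(st)) st[[k]] else 0) + rhs[k]
  st <- st[st != 0]
  list(stoich = st, reversible = arrow %in% c("<=>", "<->"))
}

#' Format a stoichiometry as an equation string
#'
#' Coefficients are serialized as shortest exact decimals (up to 15
#' significant digits) and never rounded.
#'
#' @param stoich named numeric vector.
#' @param reversible reversible arrow?
#' @export
format_reaction_equation <- function(stoich, reversible = FALSE) {
  fmt <- function(ids) {
    if (!length(ids)) return("")
    paste(vapply(ids, function(k) {
      cf <- abs(stoich[[k]])
      if (cf == 1) k else paste(format(cf, digits = 15, trim = TRUE,
                                       scientific = FALSE), k)
    }, character(1)), collapse = " + ")
  }
  lhs <- fmt(names(stoich)[stoich < 0])
  rhs <- fmt(names(stoich)[stoich > 0])
  paste(lhs, if (reversible) "<=>" else "->", rhs)
}

#' Write a model as a TSV bundle
#'
#' Creates \code{reactions.tsv}, \code{metabolites.tsv}, \code{genes.tsv}
#' and \code{model.tsv} (objective, model id) in \code{dir}.
#'
#' @param model a \code{metabolic_model}.
#' @param dir output directory (created if missing).
#' @export
write_tabular_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rx <- do.call(rbind, lapply(model$reactions, function(r) {
    data.frame(id = r$id, name = r$name,
               equation = format_reaction_equation(r$stoich, r$lb < 0),
               lower_bound = format(r$lb, digits = 15, scientific = FALSE),
               upper_bound = format(r$ub, digits = 15, scientific = FALSE),
               subsystem = r$subsystem, rtype = r$rtype, gpr = r$gpr,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rx, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(model$metabolites, file.path(dir, "metabolites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id = model$genes, name = model$genes),
                     file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(key = c("model_id", "objective"),
                                value = c(model$id,
                                          ifelse(is.na(model$objective), "",
                                                 model$objective))),
                     file.path(dir, "model.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

#' Read a model from a TSV bundle
#'
#' @param dir directory containing the bundle written by
#'   \code{\link{write_tabular_model}} (or assembled by hand).
#' @return a validated \code{metabolic_model}.
#' @export
read_tabular_model <- function(dir) {
  rf <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
                                      header = TRUE, quote = "",
                                      stringsAsFactors = FALSE,
                                      comment.char = "", check.names = FALSE,
                                      colClasses = "character")
  rx <- rf("reactions.tsv")
  mets <- rf("metabolites.tsv")
  if (anyDuplicated(rx$id))
    stop("duplicate reaction ids in reactions.tsv: ",
         paste(unique(rx$id[duplicated(rx$id)]), collapse = ", "))
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite ids in metabolites.tsv")
  mets$charge <- suppressWarnings(as.numeric(mets$charge))
  mets$formula[!nzchar(mets$formula) | mets$formula == "NA" |
                 is.na(mets$formula)] <- NA_character_
  comps <- DEFAULT_COMPARTMENTS
  extra <- setdiff(unique(mets$compartment), names(comps))
  if (length(extra)) comps <- c(comps, setNames(extra, extra))
  rxns <- vector("list", nrow(rx))
  for (i in seq_len(nrow(rx))) {
    eq <- tryCatch(parse_reaction_equation(rx$equation[i]), error = function(e)
      stop(sprintf("reactions.tsv line %d (%s): %s", i + 1L, rx$id[i],
                   conditionMessage(e))))
    rxns[[i]] <- reaction(rx$id[i], eq$stoich,
                          lb = as.numeric(rx$lower_bound[i]),
                          ub = as.numeric(rx$upper_bound[i]),
                          name = rx$name[i],
                          rtype = if ("rtype" %in% names(rx) && nzchar(rx$rtype[i]))
                            rx$rtype[i] else NA_character_,
                          subsystem = if ("subsystem" %in% names(rx))
                            rx$subsystem[i] else "",
                          gpr = if ("gpr" %in% names(rx)) rx$gpr[i] else "")
  }
  objective <- NA_character_
  id <- "model"
  mpath <- file.path(dir, "model.tsv")
  if (file.exists(mpath)) {
    kv <- rf("model.tsv")
    o <- kv$value[kv$key == "objective"]
    if (length(o) && nzchar(o)) objective <- o
    mid <- kv$value[kv$key == "model_id"]
    if (length(mid)) id <- mid
  }
  metabolic_model(mets, rxns, objective = objective, compartments = comps,
                  id = id)
}

#' Write a flux-analysis result as TSV
#'
#' Accepts a \code{flux_distribution}, \code{moma_solution},
#' \code{fva_result}, \code{essentiality_report} or
#' \code{differential_flux_report}; one row per reaction (or gene), floats
#' at 6 significant digits.
#'
#' @param result the result object.
#' @param path output file.
#' @export
write_flux_table <- function(result, path) {
  df <- if (inherits(result, "flux_distribution") ||
            inherits(result, "moma_solution")) {
    data.frame(reaction = names(result$flux),
               flux = as.numeric(result$flux))
  } else if (is.data.frame(result)) {
    as.data.frame(result)
  } else stop("unsupported result type: ", paste(class(result), collapse = "/"))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a medium config file
#'
#' Flat TSV with columns \code{id}, \code{lower_bound}, \code{upper_bound},
#' \code{role} (\code{override} or \code{always_open}); the medium name is
#' carried in a \code{# name=} header comment.
#'
#' @param medium a \code{\link{medium}}.
#' @param path file path.
#' @export
write_medium <- function(medium, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# name=%s", medium$name), con)
  writeLines("id\tlower_bound\tupper_bound\trole", con)
  for (id in names(medium$overrides)) {
    b <- medium$overrides[[id]]
    writeLines(sprintf("%s\t%.10g\t%.10g\toverride", id, b[1], b[2]), con)
  }
  for (id in medium$always_open)
    writeLines(sprintf("%s\tNA\tNA\talways_open", id), con)
  invisible(path)
}

#' @rdname write_medium
#' @param path file path.
#' @export
read_medium <- function(path) {
  first <- readLines(path, n = 1L)
  name <- if (grepl("^#\\s*name=", first)) sub("^#\\s*name=", "", first) else
    tools::file_path_sans_ext(basename(path))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  ov <- df[df$role == "override", , drop = FALSE]
  overrides <- setNames(lapply(seq_len(nrow(ov)), function(i)
    c(ov$lower_bound[i], ov$upper_bound[i])), ov$id)
  medium(name, overrides = overrides,
         always_open = df$id[df$role == "always_open"])
}
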