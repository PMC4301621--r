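# Single-gene and single-reaction essentiality screening.

#' Single-gene deletion screen
#'
#' Deletes each gene in turn, re-solves FBA for biomass on the given
#' medium, and calls a gene essential when the knockout growth ratio drops
#' below \code{threshold} (deletions that make the LP infeasible are also
#' called essential). Only genes whose deletion actually disables at least
#' one reaction are re-solved; the rest trivially retain wild-type growth.
#'
#' @param model a \code{metabolic_model}.
#' @param medium optional \code{\link{medium}} applied first.
#' @param threshold essentiality ratio (default 0.01: 1 percent of
#'   wild-type growth; the field's conservative standard).
#' @param objective biomass reaction id (default: model objective).
#' @return data.frame of class \code{essentiality_report}: columns
#'   \code{gene}, \code{growth}, \code{ratio}, \code{call},
#'   \code{subsystem}; attributes \code{wild_type_growth}, \code{medium},
#'   \code{threshold}.
#' @export
single_gene_deletion <- function(model, medium = NULL, threshold = 0.01,
                                 objective = model$objective) {
  model <- apply_medium(model, medium)
  wt <- solve_fba(model, objective = objective)
  if (wt$status != "optimal" || wt$objective_value <= 0)
    stop("medium does not support growth (wild-type FBA ",
         if (wt$status != "optimal") wt$status else "growth 0", ")")
  wtg <- wt$objective_value

  rules <- lapply(model$reactions, function(r) parse_gpr(r$gpr))
  rule_genes <- lapply(rules, function(p) gpr_genes(p))
  gene_sub <- gene_subsystems(model)

  rows <- lapply(model$genes, function(g) {
    touches <- which(vapply(rule_genes, function(gs) g %in% gs, logical(1)))
    disabled <- touches[!vapply(rules[touches], gpr_eval_rule_deleted,
                                logical(1), gene = g)]
    if (length(disabled) == 0L ||
        all(abs(wt$flux[disabled]) < 1e-9)) {
      # deletions leaving the wild-type optimum feasible keep its growth
      growth <- wtg
    } else {
      m2 <- model
      for (j in disabled) {
        m2$reactions[[j]]$lb <- 0
        m2$reactions[[j]]$ub <- 0
      }
      sol <- solve_fba(m2, objective = objective)
      growth <- if (sol$status == "optimal") sol$objective_value else 0
    }
    data.frame(gene = g, growth = growth, ratio = growth / wtg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$call <- ifelse(out$ratio < threshold, "essential", "non-essential")
  out$subsystem <- gene_sub[out$gene]
  rownames(out) <- NULL
  structure(out, wild_type_growth = wtg,
            medium = if (is.null(medium)) "(as-is)" else medium$name,
            threshold = threshold,
            class = c("essentiality_report", "data.frame"))
}

gpr_eval_rule_deleted <- function(rule, gene) gpr_eval_node(rule$tree, gene)

# each gene is labelled with the subsystem of the first reaction whose GPR
# references it (a gene touching several subsystems keeps the first)
gene_subsystems <- function(model) {
  out <- setNames(rep(NA_character_, length(model$genes)), model$genes)
  for (r in model$reactions) {
    for (g in gpr_genes(r$gpr)) {
      if (is.na(out[[g]])) out[[g]] <- r$subsystem
    }
  }
  out
}

#' Single-reaction deletion screen
#'
#' As \code{\link{single_gene_deletion}} but constraining each reaction in
#' turn to bounds (0, 0).
#'
#' @inheritParams single_gene_deletion
#' @param reaction_ids reactions to screen (default: all except the
#'   objective).
#' @export
single_reaction_deletion <- function(model, medium = NULL, threshold = 0.01,
                                     objective = model$objective,
                                     reaction_ids = setdiff(rxn_ids(model),
                                                            objective)) {
  model <- apply_medium(model, medium)
  wt <- solve_fba(model, objective = objective)
  if (wt$status != "optimal" || wt$objective_value <= 0)
    stop("medium does not support growth")
  wtg <- wt$objective_value
  rows <- lapply(reaction_ids, function(id) {
    m2 <- model
    m2$reactions[[id]]$lb <- 0
    m2$reactions[[id]]$ub <- 0
    # zero flux in the wild-type optimum means the knockout is free
    growth <- if (abs(wt$flux[[id]]) < 1e-9) {
      wtg
    } else {
      sol <- solve_fba(m2, objective = objective)
      if (sol$status == "optimal") sol$objective_value else 0
    }
    data.frame(reaction = id, growth = growth, ratio = growth / wtg,
               subsystem = model$reactions[[id]]$subsystem,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$call <- ifelse(out$ratio < threshold, "essential", "non-essential")
  rownames(out) <- NULL
  structure(out, wild_type_growth = wtg,
            medium = if (is.null(medium)) "(as-is)" else medium$name,
            threshold = threshold,
            class = c("essentiality_report", "data.frame"))
}

#' @export
print.essentiality_report <- function(x, ...) {
  unit <- if ("gene" %in% names(x)) "genes" else "reactions"
  ess <- sum(x$call == "essential")
  cat(sprintf("<essentiality_report> medium %s: %d/%d %s essential (threshold %g, wild-type growth %.6g)\n",
              attr(x, "medium"), ess, nrow(x), unit, attr(x, "threshold"),
              attr(x, "wild_type_growth")))
  invisible(x)
}

#' Compare two essentiality reports
#'
#' @param report_A,report_B \code{essentiality_report}s over the same gene
#'   (or reaction) universe.
#' @return list with \code{A_only}, \code{B_only}, \code{both} (id sets)
#'   and \code{per_subsystem}, a tally of essential ids per subsystem and
#'   report.
#' @export
compare_essentiality <- function(report_A, report_B) {
  key <- if ("gene" %in% names(report_A)) "gene" else "reaction"
  if (!identical(sort(report_A[[key]]), sort(report_B[[key]])))
    stop("reports cover different ", key, " universes")
  essA <- report_A[[key]][report_A$call == "essential"]
  essB <- report_B[[key]][report_B$call == "essential"]
  subs <- setNames(report_A$subsystem, report_A[[key]])
  tallies <- function(ids) {
    if (!length(ids)) return(table(factor(character(0))))
    table(subs[ids], useNA = "ifany")
  }
  list(A_only = setdiff(essA, essB),
       B_only = setdiff(essB, essA),
       both = intersect(essA, essB),
       per_subsystem = list(A = tallies(essA), B = tallies(essB)))
}
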