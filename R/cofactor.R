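# Metabolite-centric flux bookkeeping: differential flux across two
# conditions for all reactions touching a cofactor, and producer/consumer
# turnover decomposition of one solution.

#' Differential flux report around a metabolite
#'
#' Compares the fluxes of all reactions involving a metabolite between two
#' steady-state solutions of the same model, flagging those whose absolute
#' flux change exceeds the (strict) threshold — 1e-6 mmol gDW-1 h-1 by
#' convention.
#'
#' @param model a \code{metabolic_model}.
#' @param metabolite_id metabolite id; with \code{pooled = TRUE} a
#'   compartment-free base name matched across compartments.
#' @param solution_A,solution_B \code{flux_distribution}s (or named flux
#'   vectors) over the model's reactions.
#' @param threshold strict change threshold (default 1e-6).
#' @param labels length-2 character condition labels.
#' @param pooled pool the metabolite across compartments.
#' @return data.frame of class \code{differential_flux_report} with columns
#'   \code{reaction}, \code{flux_A}, \code{flux_B}, \code{abs_change},
#'   \code{changed}; attributes \code{metabolite}, \code{threshold},
#'   \code{labels}.
#' @export
differential_flux_report <- function(model, metabolite_id, solution_A,
                                     solution_B, threshold = 1e-6,
                                     labels = c("A", "B"), pooled = FALSE) {
  a <- if (inherits(solution_A, "flux_distribution")) solution_A$flux else solution_A
  b <- if (inherits(solution_B, "flux_distribution")) solution_B$flux else solution_B
  if (!identical(sort(names(a)), sort(names(b))))
    stop("solutions cover different reaction universes")
  if (!all(rxn_ids(model) %in% names(a)))
    stop("solutions do not cover the model's reactions")
  ids <- reactions_involving(model, metabolite_id, pooled = pooled)
  out <- data.frame(reaction = ids,
                    flux_A = as.numeric(a[ids]),
                    flux_B = as.numeric(b[ids]))
  out$abs_change <- abs(out$flux_A - out$flux_B)
  out$changed <- out$abs_change > threshold
  structure(out, metabolite = metabolite_id, threshold = threshold,
            labels = labels,
            class = c("differential_flux_report", "data.frame"))
}

#' @export
print.differential_flux_report <- function(x, ...) {
  cat(sprintf("<differential_flux_report> %s: %d reactions, %d changed (> %g) between %s and %s\n",
              attr(x, "metabolite"), nrow(x), sum(x$changed),
              attr(x, "threshold"), attr(x, "labels")[1], attr(x, "labels")[2]))
  invisible(x)
}

#' Producer/consumer split of a metabolite's turnover
#'
#' For one steady-state solution, decomposes the turnover of a metabolite:
#' each reaction contributes coefficient x flux (positive = production).
#' At steady state the production and consumption totals balance; shares
#' are percentages of each side's total. Reversible reactions are
#' classified by their realized flux sign.
#'
#' @param model a \code{metabolic_model}.
#' @param metabolite_id metabolite id (or base name with
#'   \code{pooled = TRUE}).
#' @param solution a \code{flux_distribution} or named flux vector.
#' @param pooled pool across compartments.
#' @param zero_tol turnovers below this magnitude are dropped (default
#'   1e-9).
#' @return object of class \code{producer_consumer_split}: data.frame
#'   \code{turnover} (reaction, turnover, side, share_percent), totals
#'   \code{production_total}, \code{consumption_total}.
#' @export
producer_consumer_split <- function(model, metabolite_id, solution,
                                    pooled = FALSE, zero_tol = 1e-9) {
  v <- if (inherits(solution, "flux_distribution")) solution$flux else solution
  ids <- reactions_involving(model, metabolite_id, pooled = pooled)
  targets <- if (pooled) {
    met_ids(model)[sub("\\[[^]]*\\]$", "", met_ids(model)) == metabolite_id]
  } else metabolite_id
  turn <- vapply(ids, function(id) {
    st <- model$reactions[[id]]$stoich
    sum(st[intersect(names(st), targets)]) * v[[id]]
  }, numeric(1))
  turn <- turn[abs(turn) > zero_tol]
  prod_tot <- sum(turn[turn > 0])
  cons_tot <- -sum(turn[turn < 0])
  df <- data.frame(reaction = names(turn), turnover = as.numeric(turn),
                   side = ifelse(turn > 0, "production", "consumption"))
  df$share_percent <- ifelse(df$side == "production",
                             100 * df$turnover / prod_tot,
                             100 * -df$turnover / cons_tot)
  if (nrow(df)) df <- df[order(df$side, -abs(df$turnover)), ]
  rownames(df) <- NULL
  structure(list(metabolite = metabolite_id, turnover = df,
                 production_total = prod_tot, consumption_total = cons_tot),
            class = "producer_consumer_split")
}

#' @export
print.producer_consumer_split <- function(x, ...) {
  cat(sprintf("<producer_consumer_split> %s: production total %.6g, consumption total %.6g\n",
              x$metabolite, x$production_total, x$consumption_total))
  if (nrow(x$turnover)) print(utils::head(x$turnover, 10))
  invisible(x)
}

#' Percentage change between two fluxes
#'
#' \code{100 * (after - before) / before}; undefined (NA with a warning)
#' when \code{before} is zero. Rounding is left to presentation.
#'
#' @param flux_before,flux_after numeric scalars or vectors.
#' @export
flux_ratio_change <- function(flux_before, flux_after) {
  out <- 100 * (flux_after - flux_before) / flux_before
  if (any(flux_before == 0)) {
    warning("percent change undefined for zero reference flux; returning NA")
    out[flux_before == 0] <- NA_real_
  }
  out
}
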