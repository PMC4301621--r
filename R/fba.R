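# Flux balance analysis and derived screens.
#
# Sign convention: exchange reactions are written "met[e] <=> (nothing)";
# negative flux is uptake, positive is secretion.  An uptake allowance of
# magnitude u is encoded as lower bound -u on the exchange.

#' Define a growth medium
#'
#' A medium is a named set of exchange-bound overrides. Applying it closes
#' every exchange lower bound to 0 except the overridden ids and the
#' "always open" set (typically O2, CO2, water, protons and mineral salts,
#' without which no genome-scale model is feasible).
#'
#' @param name medium label.
#' @param overrides named list: exchange id -> c(lb, ub).
#' @param always_open exchange ids whose bounds are left untouched.
#' @export
medium <- function(name, overrides = list(), always_open = character(0)) {
  stopifnot(is.list(overrides))
  for (v in overrides) stopifnot(is.numeric(v), length(v) == 2L)
  structure(list(name = name, overrides = overrides, always_open = always_open),
            class = "growth_medium")
}

#' @export
print.growth_medium <- function(x, ...) {
  cat(sprintf("<growth_medium> %s: %d overrides, %d always-open\n",
              x$name, length(x$overrides), length(x$always_open)))
  invisible(x)
}

#' Apply a medium to a model
#'
#' @param model a \code{metabolic_model}.
#' @param medium a \code{\link{medium}} object, or NULL for no change.
#' @return a modified copy of the model.
#' @export
apply_medium <- function(model, medium) {
  if (is.null(medium)) return(model)
  stopifnot(inherits(medium, "growth_medium"))
  ex <- exchange_ids(model)
  bad <- setdiff(c(names(medium$overrides), medium$always_open), ex)
  if (length(bad))
    stop("medium refers to non-exchange or unknown reaction(s): ",
         paste(bad, collapse = ", "))
  for (id in setdiff(ex, c(names(medium$overrides), medium$always_open))) {
    model$reactions[[id]]$lb <- max(model$reactions[[id]]$lb, 0)
  }
  for (id in names(medium$overrides)) {
    b <- medium$overrides[[id]]
    model <- set_bounds(model, id, lb = b[1], ub = b[2])
  }
  model
}

fba_problem <- function(model) {
  S <- stoichiometric_matrix(model)
  b <- reaction_bounds(model)
  list(S = S, lb = b$lb, ub = b$ub)
}

new_flux_distribution <- function(model, res) {
  flux <- if (res$status == "optimal")
    setNames(res$x, rxn_ids(model)) else setNames(rep(NA_real_, length(model$reactions)), rxn_ids(model))
  structure(list(flux = flux,
                 objective_value = res$objective,
                 status = res$status),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> status: %s, objective: %s, %d reactions\n",
              x$status,
              if (is.na(x$objective_value)) "NA" else format(x$objective_value, digits = 8),
              length(x$flux)))
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of the objective reaction subject to
#' steady-state mass balance S v = 0 and flux bounds. Only the objective
#' value is guaranteed reproducible; with degenerate alternate optima the
#' flux vector is "an optimal vertex".
#'
#' @param model a \code{metabolic_model}.
#' @param objective objective reaction id (default: the model's).
#' @param direction \code{"max"} or \code{"min"}.
#' @param extra_constraints list of \code{list(id, lo, hi)} temporary bound
#'   overrides applied before solving.
#' @return a \code{flux_distribution} with status \code{optimal},
#'   \code{infeasible} or \code{unbounded}.
#' @export
solve_fba <- function(model, objective = model$objective, direction = "max",
                      extra_constraints = NULL) {
  if (is.na(objective))
    stop("no objective reaction set; use set_objective() first")
  if (!(objective %in% rxn_ids(model)))
    stop(sprintf("unknown objective reaction '%s'", objective))
  for (con in extra_constraints)
    model <- set_bounds(model, con[[1]], lb = con[[2]], ub = con[[3]])
  p <- fba_problem(model)
  cvec <- as.numeric(rxn_ids(model) == objective)
  res <- lp_solve(p$S, rep(0, nrow(p$S)), cvec, p$lb, p$ub,
                  maximize = identical(direction, "max"))
  if (res$status == "numeric_failure")
    stop("LP solver failed numerically on this model")
  new_flux_distribution(model, res)
}

#' FBA with the growth rate pinned
#'
#' Fixes the biomass flux (lb = ub = growth rate) and then optimizes a
#' secondary objective, typically a product exchange.
#'
#' @param model a \code{metabolic_model}; its objective must be the biomass
#'   reaction unless \code{growth_id} says otherwise.
#' @param growth_rate pinned specific growth rate (h-1).
#' @param objective secondary objective reaction id.
#' @param growth_id biomass reaction id (default: model objective).
#' @param direction \code{"max"} or \code{"min"}.
#' @export
solve_fba_fixed_growth <- function(model, growth_rate, objective,
                                   growth_id = model$objective,
                                   direction = "max") {
  if (is.na(growth_id)) stop("no biomass reaction identified")
  model <- set_bounds(model, growth_id, lb = growth_rate, ub = growth_rate)
  solve_fba(model, objective = objective, direction = direction)
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux compatible with the
#' objective staying at (at least) \code{fraction_of_optimum} times its FBA
#' optimum; two LPs per reaction.
#'
#' @param model a \code{metabolic_model}.
#' @param reaction_ids reactions to scan (default: all).
#' @param fraction_of_optimum fraction in (0, 1] (default 1.0).
#' @param objective objective reaction id (default: the model's).
#' @return data.frame (class \code{fva_result}) with columns
#'   \code{reaction}, \code{min_flux}, \code{max_flux}; attributes
#'   \code{optimum} and \code{fraction}.
#' @export
fva <- function(model, reaction_ids = rxn_ids(model),
                fraction_of_optimum = 1.0, objective = model$objective) {
  base <- solve_fba(model, objective = objective)
  if (base$status != "optimal")
    stop("base FBA problem is ", base$status, "; FVA aborted")
  opt <- base$objective_value
  floor_val <- if (opt >= 0) fraction_of_optimum * opt
               else opt / fraction_of_optimum
  model <- set_bounds(model, objective,
                      lb = max(model$reactions[[objective]]$lb, floor_val),
                      ub = model$reactions[[objective]]$ub)
  p <- fba_problem(model)
  ids <- rxn_ids(model)
  out <- data.frame(reaction = reaction_ids,
                    min_flux = NA_real_, max_flux = NA_real_)
  for (k in seq_along(reaction_ids)) {
    j <- match(reaction_ids[k], ids)
    if (is.na(j)) stop(sprintf("unknown reaction '%s'", reaction_ids[k]))
    cvec <- numeric(length(ids)); cvec[j] <- 1
    lo <- lp_solve(p$S, rep(0, nrow(p$S)), cvec, p$lb, p$ub, maximize = FALSE)
    hi <- lp_solve(p$S, rep(0, nrow(p$S)), cvec, p$lb, p$ub, maximize = TRUE)
    out$min_flux[k] <- lo$objective
    out$max_flux[k] <- hi$objective
  }
  structure(out, optimum = opt, fraction = fraction_of_optimum,
            class = c("fva_result", "data.frame"))
}

#' Robustness scan over an exchange flux
#'
#' For each scanned value, the exchange uptake is pinned to that magnitude
#' (lb = ub = -value), optionally a minimum growth rate is required, and the
#' objective is maximized. Infeasible points are recorded as \code{NA}, not
#' zero.
#'
#' @param model a \code{metabolic_model}.
#' @param scanned_exchange exchange reaction id.
#' @param values strictly increasing uptake magnitudes.
#' @param objective objective reaction id.
#' @param min_growth optional minimum biomass flux.
#' @param growth_id biomass reaction id (default: model objective).
#' @return list (class \code{robustness_curve}) with \code{parameter},
#'   \code{objective_value} and a \code{fixed} record.
#' @export
robustness_scan <- function(model, scanned_exchange, values, objective,
                            min_growth = NULL, growth_id = model$objective) {
  if (length(values) == 0L) stop("empty scan value list")
  if (any(diff(values) <= 0)) stop("scan values must be strictly increasing")
  if (!(scanned_exchange %in% exchange_ids(model)))
    stop(sprintf("'%s' is not an exchange reaction", scanned_exchange))
  if (!is.null(min_growth))
    model <- set_bounds(model, growth_id, lb = min_growth,
                        ub = model$reactions[[growth_id]]$ub)
  obj <- vapply(values, function(v) {
    m2 <- set_bounds(model, scanned_exchange, lb = -v, ub = -v)
    sol <- solve_fba(m2, objective = objective)
    if (sol$status == "optimal") sol$objective_value else NA_real_
  }, numeric(1))
  structure(list(parameter = values, objective_value = obj,
                 fixed = list(exchange = scanned_exchange, objective = objective,
                              min_growth = min_growth)),
            class = "robustness_curve")
}

#' @export
print.robustness_curve <- function(x, ...) {
  ok <- !is.na(x$objective_value)
  cat(sprintf("<robustness_curve> %s scanned over [%g, %g] (%d points, %d feasible)\n",
              x$fixed$exchange, min(x$parameter), max(x$parameter),
              length(x$parameter), sum(ok)))
  if (any(ok)) {
    i <- which.max(x$objective_value)
    cat(sprintf("  max %s = %g at %s = %g\n", x$fixed$objective,
                x$objective_value[i], x$fixed$exchange, x$parameter[i]))
  }
  invisible(x)
}

#' Single-source substrate utilization screen
#'
#' Each candidate exchange in turn replaces the base source at the
#' stated uptake; growth is called if FBA growth exceeds the threshold.
#'
#' @param model a \code{metabolic_model}.
#' @param base_medium a \code{\link{medium}}.
#' @param candidate_exchanges exchange ids to test as sole source.
#' @param remove exchange id(s) of the base source(s) being replaced
#'   (e.g. the glucose exchange for a carbon screen).
#' @param uptake uptake magnitude for each candidate (default 1.0).
#' @param growth_threshold minimal growth rate called "grows"
#'   (default 1e-6).
#' @param objective biomass reaction id (default: model objective).
#' @return data.frame with columns \code{source}, \code{growth},
#'   \code{grows}.
#' @export
substrate_utilization_screen <- function(model, base_medium,
                                         candidate_exchanges,
                                         remove = character(0),
                                         uptake = 1.0,
                                         growth_threshold = 1e-6,
                                         objective = model$objective) {
  stopifnot(inherits(base_medium, "growth_medium"))
  bad <- setdiff(candidate_exchanges, exchange_ids(model))
  if (length(bad)) stop("not exchange reactions: ", paste(bad, collapse = ", "))
  res <- lapply(candidate_exchanges, function(cand) {
    med <- base_medium
    med$overrides[remove] <- NULL
    med$overrides[[cand]] <- c(-uptake, 1000)
    sol <- solve_fba(apply_medium(model, med), objective = objective)
    g <- if (sol$status == "optimal") sol$objective_value else 0
    data.frame(source = cand, growth = g, grows = g > growth_threshold)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
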