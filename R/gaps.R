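# Blocked-metabolite (gap) and dead-end reaction detection.
#
# Production semantics follow the gapFind MILP: a metabolite is producible
# when SOME reaction direction producing it can carry flux (>= eps) while
# every other metabolite is allowed to accumulate (S v >= 0) — not when
# strictly positive NET production is achievable at steady state, which
# would misclassify every conserved-moiety cofactor (ATP/ADP, NAD(P)(H),
# CoA) as a gap.  Consumability is the mirror image under S v <= 0.
# Instead of one MILP, a certificate-sharing LP search is used: each
# feasibility LP that activates a direction also certifies every other
# direction carrying flux in its solution, so well-connected models need
# only a handful of LPs.

gap_side <- function(model, side = c("production", "consumption"),
                     eps = 1e-4, tol = 1e-7) {
  side <- match.arg(side)
  S <- stoichiometric_matrix(model)
  bnd <- reaction_bounds(model)
  m <- nrow(S); n <- ncol(S)
  slack_sign <- if (side == "production") -1 else 1
  A <- cbind(S, diag(slack_sign, m))
  lbA <- c(bnd$lb, rep(0, m))
  ubA <- c(bnd$ub, rep(1e5, m))

  # which metabolites does direction (j, +1/-1) generate on this side?
  gen <- function(j, dir) {
    col <- S[, j]
    if (side == "production") {
      if (dir > 0) which(col > 0) else which(col < 0)
    } else {
      if (dir > 0) which(col < 0) else which(col > 0)
    }
  }
  active <- matrix(FALSE, 2, n)    # row 1: forward, row 2: backward
  tested <- matrix(FALSE, 2, n)
  covered <- logical(m)
  mark <- function(v) {
    fwd <- which(v[seq_len(n)] > tol & !active[1, ])
    bwd <- which(v[seq_len(n)] < -tol & !active[2, ])
    for (j in fwd) { active[1, j] <<- TRUE; covered[gen(j, +1)] <<- TRUE }
    for (j in bwd) { active[2, j] <<- TRUE; covered[gen(j, -1)] <<- TRUE }
  }
  for (j in seq_len(n)) {
    for (dir in 1:2) {
      if (tested[dir, j] || active[dir, j]) next
      sgn <- if (dir == 1L) 1 else -1
      if (dir == 1L && bnd$ub[j] < eps) next
      if (dir == 2L && bnd$lb[j] > -eps) next
      if (!any(!covered[gen(j, sgn)])) next      # nothing new to learn
      tested[dir, j] <- TRUE
      lb2 <- lbA; ub2 <- ubA
      if (dir == 1L) lb2[j] <- max(lb2[j], eps) else ub2[j] <- min(ub2[j], -eps)
      res <- lp_solve(A, rep(0, m), rep(0, n + m), lb2, ub2)
      if (res$status == "optimal") mark(res$x)
    }
  }
  covered
}

#' Detect blocked metabolites
#'
#' @param model a \code{metabolic_model}.
#' @param medium optional \code{\link{medium}}; \code{NULL} opens all
#'   exchanges to \code{[-1000, 1000]} (structural gap detection).
#' @param eps minimal certified flux through a producing/consuming
#'   direction (default 1e-4).
#' @return object of class \code{gap_report}: character vectors
#'   \code{no_production}, \code{no_consumption}, \code{root_no_production},
#'   \code{root_no_consumption} ("root" = no producing/consuming reaction
#'   at all, regardless of flux feasibility).
#' @export
find_blocked_metabolites <- function(model, medium = NULL, eps = 1e-4) {
  model <- prep_gap_model(model, medium)
  S <- stoichiometric_matrix(model)
  bnd <- reaction_bounds(model)
  tol <- 1e-9
  can_produce <- gap_side(model, "production", eps)
  can_consume <- gap_side(model, "consumption", eps)
  m <- nrow(S)
  root_prod <- root_cons <- logical(m)
  for (i in seq_len(m)) {
    row <- S[i, ]
    root_prod[i] <- !any((row > 0 & bnd$ub > tol) | (row < 0 & bnd$lb < -tol))
    root_cons[i] <- !any((row < 0 & bnd$ub > tol) | (row > 0 & bnd$lb < -tol))
  }
  ids <- rownames(S)
  structure(list(no_production = ids[!can_produce],
                 no_consumption = ids[!can_consume],
                 root_no_production = ids[root_prod],
                 root_no_consumption = ids[root_cons]),
            class = "gap_report")
}

prep_gap_model <- function(model, medium) {
  if (is.null(medium)) {
    for (id in exchange_ids(model)) {
      model$reactions[[id]]$lb <- -1000
      model$reactions[[id]]$ub <- 1000
    }
  } else {
    model <- apply_medium(model, medium)
  }
  # gap detection asks what the network can route, not what maintenance
  # demands; forced drains (lb > 0 internal reactions) are relaxed to 0
  for (id in rxn_ids(model)) {
    if (model$reactions[[id]]$rtype != "exchange" &&
        model$reactions[[id]]$lb > 0)
      model$reactions[[id]]$lb <- 0
  }
  model
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("<gap_report> %d no-production (%d root), %d no-consumption (%d root)\n",
              length(x$no_production), length(x$root_no_production),
              length(x$no_consumption), length(x$root_no_consumption)))
  invisible(x)
}

#' Detect blocked (dead-end) reactions
#'
#' Reactions that cannot carry any flux over the steady-state feasible set
#' (FVA range exactly [0, 0]); at most two LPs per reaction, with
#' certificate sharing.
#'
#' @inheritParams find_blocked_metabolites
#' @param tol flux magnitude below which a reaction counts as blocked.
#' @return character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(model, medium = NULL, tol = 1e-9) {
  model <- prep_gap_model(model, medium)
  S <- stoichiometric_matrix(model)
  bnd <- reaction_bounds(model)
  ids <- rxn_ids(model)
  n <- length(ids)
  active <- logical(n)
  mark <- function(v) active[abs(v) > 1e-7] <<- TRUE
  for (j in seq_len(n)) {
    if (active[j]) next
    cvec <- numeric(n); cvec[j] <- 1
    hi <- lp_solve(S, rep(0, nrow(S)), cvec, bnd$lb, bnd$ub, maximize = TRUE)
    if (hi$status == "optimal") {
      if (hi$objective > tol) { mark(hi$x); next }
    }
    lo <- lp_solve(S, rep(0, nrow(S)), cvec, bnd$lb, bnd$ub, maximize = FALSE)
    if (lo$status == "optimal" && lo$objective < -tol) mark(lo$x)
  }
  ids[!active]
}
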