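# Minimization of metabolic adjustment (MOMA).
#
# Given a wild-type reference flux vector v_wt and a knockout model, MOMA
# finds the feasible flux vector of the knockout that minimizes the
# Euclidean distance ||v - v_wt||; the projection onto the knockout
# polytope is unique by strict convexity.  The QP is solved with
# quadprog::solve.QP after reducing the mass-balance rows to a linearly
# independent set (conserved moieties make S row-deficient, which
# solve.QP's equality handling cannot tolerate).

#' Delete genes from a model
#'
#' Every reaction whose GPR rule evaluates inactive under the deletion gets
#' bounds (0, 0); all other reactions are untouched.
#'
#' @param model a \code{metabolic_model}.
#' @param gene_ids genes to delete (must exist in the model).
#' @return the constrained model copy.
#' @export
knockout_gene <- function(model, gene_ids) {
  unknown <- setdiff(gene_ids, model$genes)
  if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  for (id in rxn_ids(model)) {
    g <- model$reactions[[id]]$gpr
    if (!nzchar(g)) next
    if (!evaluate_gpr(g, gene_ids)) {
      model$reactions[[id]]$lb <- 0
      model$reactions[[id]]$ub <- 0
    }
  }
  model
}

#' Solve the MOMA quadratic program
#'
#' Minimizes \code{sum_j (v_j - v_wt_j)^2} subject to S v = 0 and the
#' knockout model's bounds.
#'
#' @param model the (knockout) \code{metabolic_model}. Alternatively pass
#'   the wild-type model plus \code{knockout_genes}.
#' @param reference a \code{flux_distribution} (or named flux vector) over
#'   the same reaction universe — typically the wild-type FBA solution.
#' @param knockout_genes optional genes to delete from \code{model} first.
#' @return object of class \code{moma_solution}: \code{flux},
#'   \code{distance} (Euclidean), \code{status}.
#' @export
solve_moma <- function(model, reference, knockout_genes = NULL) {
  vref <- if (inherits(reference, "flux_distribution")) reference$flux else reference
  if (!identical(sort(names(vref)), sort(rxn_ids(model))))
    stop("reference and model reaction universes differ")
  vref <- vref[rxn_ids(model)]
  if (!is.null(knockout_genes)) model <- knockout_gene(model, knockout_genes)
  S <- stoichiometric_matrix(model)
  bnd <- reaction_bounds(model)
  n <- ncol(S)
  w <- as.numeric(vref)
  infeasible <- function() structure(
    list(flux = setNames(rep(NA_real_, n), rxn_ids(model)),
         distance = NA_real_, status = "infeasible"),
    class = "moma_solution")

  # certify feasibility and obtain a relative-interior anchor (midpoint of
  # two opposite LP vertices); quadprog is then run in null-space
  # coordinates around that anchor, where the Hessian is the identity.
  # Anchoring at a single vertex leaves too many constraints exactly
  # active and makes solve.QP's active-set method fail spuriously.
  f1 <- lp_solve(S, rep(0, nrow(S)), rep(1, n), bnd$lb, bnd$ub, maximize = TRUE)
  if (f1$status != "optimal") return(infeasible())
  f2 <- lp_solve(S, rep(0, nrow(S)), rep(1, n), bnd$lb, bnd$ub, maximize = FALSE)
  if (f2$status != "optimal") return(infeasible())
  feas <- list(x = (f1$x + f2$x) / 2)

  pinned <- which(bnd$lb == bnd$ub)
  free <- setdiff(seq_len(n), pinned)
  vpin <- bnd$lb[pinned]
  SF <- S[, free, drop = FALSE]
  qrR <- qr(t(SF))
  r <- qrR$rank
  keep <- qrR$pivot[seq_len(r)]
  A <- SF[keep, , drop = FALSE]
  v0 <- feas$x[free]
  Q <- qr.Q(qr(t(A)), complete = TRUE)
  Z <- Q[, setdiff(seq_len(ncol(Q)), seq_len(r)), drop = FALSE]
  if (ncol(Z) == 0L) {
    vF <- v0
    if (any(vF < bnd$lb[free] - 1e-7) || any(vF > bnd$ub[free] + 1e-7))
      return(infeasible())
  } else {
    dvec <- as.numeric(crossprod(Z, w[free] - v0))
    CZ <- rbind(Z, -Z)
    bb <- c(bnd$lb[free] - v0, v0 - bnd$ub[free])
    nrm <- sqrt(rowSums(CZ^2))
    # variables fully determined by the equalities have ~zero normals in
    # null-space coordinates: their bound constraints are either satisfied
    # identically or witness infeasibility
    degen <- nrm < 1e-8
    if (any(bb[degen] > 1e-6)) return(infeasible())
    CZ <- CZ[!degen, , drop = FALSE] / nrm[!degen]
    bb <- bb[!degen] / nrm[!degen]
    # solve.QP occasionally reports spurious inconsistency on exactly
    # degenerate vertices; a ladder of tiny feasibility relaxations
    # (solution shift is O(eps), far below the 1e-6 contract tolerance)
    sol <- NULL
    for (eps in c(0, 1e-10, 1e-9, 1e-8)) {
      sol <- tryCatch(
        quadprog::solve.QP(Dmat = diag(ncol(Z)), dvec = dvec,
                           Amat = t(CZ), bvec = bb - eps),
        error = function(e) NULL)
      if (!is.null(sol)) break
    }
    if (is.null(sol)) return(infeasible())
    vF <- v0 + as.numeric(Z %*% sol$solution)
  }
  v <- numeric(n)
  v[pinned] <- vpin
  v[free] <- vF
  v <- pmin(pmax(v, bnd$lb), bnd$ub)
  structure(list(flux = setNames(v, rxn_ids(model)),
                 distance = sqrt(sum((v - vref)^2)),
                 status = "optimal"),
            class = "moma_solution")
}

#' @export
print.moma_solution <- function(x, ...) {
  cat(sprintf("<moma_solution> status: %s, distance to reference: %s\n",
              x$status,
              if (is.na(x$distance)) "NA" else format(x$distance, digits = 6)))
  invisible(x)
}

#' Linear (L1) MOMA variant
#'
#' Minimizes \code{sum_j |v_j - v_wt_j|} by LP. This is a labelled
#' alternative to quadratic MOMA, never a silent substitute: the L1
#' solution need not be unique.
#'
#' @inheritParams solve_moma
#' @export
solve_moma_l1 <- function(model, reference, knockout_genes = NULL) {
  vref <- if (inherits(reference, "flux_distribution")) reference$flux else reference
  if (!identical(sort(names(vref)), sort(rxn_ids(model))))
    stop("reference and model reaction universes differ")
  vref <- vref[rxn_ids(model)]
  if (!is.null(knockout_genes)) model <- knockout_gene(model, knockout_genes)
  S <- stoichiometric_matrix(model)
  bnd <- reaction_bounds(model)
  m <- nrow(S); n <- ncol(S)
  # variables [v; d]; S v = 0; v - d + s1 = vref; -v - d + s2 = -vref
  A <- rbind(cbind(S, matrix(0, m, n)),
             cbind(diag(n), -diag(n)),
             cbind(-diag(n), -diag(n)))
  A <- cbind(A, rbind(matrix(0, m, 2 * n), diag(2 * n)))
  b <- c(rep(0, m), vref, -vref)
  big <- 4000 + 2 * max(abs(vref))
  lb <- c(bnd$lb, rep(0, n), rep(0, 2 * n))
  ub <- c(bnd$ub, rep(big, n), rep(2 * big, 2 * n))
  cvec <- c(rep(0, n), rep(1, n), rep(0, 2 * n))
  res <- lp_solve(A, b, cvec, lb, ub, maximize = FALSE)
  if (res$status != "optimal")
    return(structure(list(flux = setNames(rep(NA_real_, n), rxn_ids(model)),
                          distance = NA_real_, status = res$status),
                     class = "moma_solution"))
  v <- res$x[seq_len(n)]
  structure(list(flux = setNames(v, rxn_ids(model)),
                 distance = sum(abs(v - vref)), status = "optimal",
                 norm = "L1"),
            class = "moma_solution")
}

#' Count reactions whose flux changed between two states
#'
#' @param reference,solution \code{flux_distribution}/\code{moma_solution}
#'   objects or named flux vectors over the same reaction universe.
#' @param threshold strict change threshold (default 1e-6, the reporting
#'   convention for NADPH flux changes).
#' @return list with \code{count} and \code{ids}.
#' @export
count_changed_reactions <- function(reference, solution, threshold = 1e-6) {
  a <- if (is.list(reference)) reference$flux else reference
  b <- if (is.list(solution)) solution$flux else solution
  if (!identical(sort(names(a)), sort(names(b))))
    stop("flux vectors cover different reaction universes")
  b <- b[names(a)]
  changed <- names(a)[abs(a - b) > threshold]
  list(count = length(changed), ids = changed)
}
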