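# Bounded-variable primal simplex.
#
# Solves   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
# with all bounds finite (metabolic models use +/-1000 as the "unbounded"
# sentinel, so finiteness is not a practical restriction; infinite bounds on
# the entering variable are still handled for artificials).
#
# Phase I introduces signed artificial columns and minimizes their sum;
# Phase II prices with Dantzig's rule, falling back to Bland's rule after
# 2*(m+n) iterations to guarantee termination under degeneracy.  The basis
# inverse is maintained by product-form row updates and refactorized every
# 60 pivots for numerical hygiene.

#' Solve a bounded linear program
#'
#' Low-level solver used by all flux-analysis routines. Maximizes (or
#' minimizes) \code{c'x} subject to \code{A x = b} and \code{lb <= x <= ub}.
#'
#' @param A constraint matrix (m x n), dense numeric.
#' @param b right-hand side, length m.
#' @param cvec objective coefficients, length n.
#' @param lb,ub variable bounds, length n; \code{lb <= ub} elementwise.
#' @param maximize logical; maximize if \code{TRUE} (default).
#' @param tol feasibility/optimality tolerance (default \code{1e-9}).
#' @return list with \code{status} ("optimal", "infeasible" or "unbounded"),
#'   \code{x} (primal solution, length n) and \code{objective}.
#' @keywords internal
#' @export
lp_solve <- function(A, b, cvec, lb, ub, maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(cvec) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol))
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  lb <- pmin(lb, ub)  # collapse tiny inversions within tol
  if (!maximize) cvec <- -cvec

  if (n == 0L) {
    status <- if (m == 0L || max(abs(b)) <= 1e-7) "optimal" else "infeasible"
    return(list(status = status, x = numeric(0),
                objective = if (status == "optimal") 0 else NA_real_))
  }
  if (m == 0L) {
    x <- ifelse(cvec > 0, ub, lb)
    if (any(!is.finite(x)))
      return(list(status = "unbounded", x = rep(NA_real_, n), objective = NA_real_))
    return(list(status = "optimal", x = x, objective = sum(cvec * x)))
  }

  # nonbasic start: each structural variable at its bound of least magnitude
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  x[!is.finite(x)] <- 0
  at_upper <- x == ub & lb != ub

  r <- b - as.vector(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)

  # augmented problem: structural cols then artificial +/- identity
  Aa <- cbind(A, diag(sgn, nrow = m))
  lba <- c(lb, rep(0, m))
  uba <- c(ub, rep(Inf, m))
  xa <- c(x, abs(r))
  at_upper <- c(at_upper, rep(FALSE, m))
  basis <- n + seq_len(m)
  Binv <- diag(1 / sgn, nrow = m)

  art <- n + seq_len(m)

  run_simplex <- function(cost, xa, at_upper, basis, Binv) {
    nt <- n + m
    iter <- 0L
    max_iter <- 80L * (m + nt) + 2000L
    refact <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        return(list(status = "maxiter", xa = xa, at_upper = at_upper,
                    basis = basis, Binv = Binv))
      refact <- refact + 1L
      if (refact >= 60L) {
        Binv <- tryCatch(solve(Aa[, basis, drop = FALSE]),
                         error = function(e) NULL)
        if (is.null(Binv))
          return(list(status = "numeric", xa = xa, at_upper = at_upper,
                      basis = basis, Binv = diag(m)))
        refact <- 0L
      }
      cb <- cost[basis]
      y <- as.vector(crossprod(Binv, cb))        # y = Binv' cb
      nonbasic <- setdiff(seq_len(nt), basis)
      d <- cost[nonbasic] - as.vector(y %*% Aa[, nonbasic, drop = FALSE])
      fixed <- lba[nonbasic] == uba[nonbasic]
      elig_lo <- !at_upper[nonbasic] & d > tol & !fixed
      elig_up <- at_upper[nonbasic] & d < -tol & !fixed
      elig <- elig_lo | elig_up
      if (!any(elig))
        return(list(status = "optimal", xa = xa, at_upper = at_upper,
                    basis = basis, Binv = Binv))
      cand <- nonbasic[elig]
      if (iter > 2L * (m + nt)) {
        e <- min(cand)                            # Bland
      } else {
        e <- cand[which.max(abs(d[elig]))]        # Dantzig
      }
      bland <- iter > 2L * (m + nt)
      s <- if (at_upper[e]) -1 else 1
      w <- as.vector(Binv %*% Aa[, e])

      # ratio test: x_B moves by -t*s*w while the entering var moves by s*t
      sw <- s * w
      xb <- xa[basis]
      ratios <- rep(Inf, m)
      up_hit <- sw > 1e-10
      dn_hit <- sw < -1e-10
      ratios[up_hit] <- (xb[up_hit] - lba[basis[up_hit]]) / sw[up_hit]
      fin_dn <- dn_hit & is.finite(uba[basis])
      ratios[fin_dn] <- (uba[basis[fin_dn]] - xb[fin_dn]) / (-sw[fin_dn])
      ratios[ratios < 0] <- 0
      t_basic <- min(ratios)
      range_e <- uba[e] - lba[e]
      if (!is.finite(min(t_basic, range_e)))
        return(list(status = "unbounded", xa = xa, at_upper = at_upper,
                    basis = basis, Binv = Binv))

      if (is.finite(range_e) && range_e <= t_basic + 1e-12) {
        # bound-to-bound flip of the entering variable
        xa[basis] <- xb - range_e * sw
        xa[e] <- if (at_upper[e]) lba[e] else uba[e]
        at_upper[e] <- !at_upper[e]
      } else {
        ties <- which(ratios <= t_basic + 1e-12)
        leave <- if (bland) ties[which.min(basis[ties])]
                 else ties[which.max(abs(sw[ties]))]
        xa[basis] <- xb - t_basic * sw
        xa[e] <- xa[e] + s * t_basic
        lv <- basis[leave]
        # leaving variable parks at whichever bound it hit
        at_upper[lv] <- sw[leave] < 0
        xa[lv] <- if (at_upper[lv]) uba[lv] else lba[lv]
        basis[leave] <- e
        piv <- w[leave]
        if (abs(piv) < 1e-11) {
          Binv <- tryCatch(solve(Aa[, basis, drop = FALSE]),
                           error = function(e) NULL)
          if (is.null(Binv))
            return(list(status = "numeric", xa = xa, at_upper = at_upper,
                        basis = basis, Binv = diag(m)))
          refact <- 0L
        } else {
          er <- Binv[leave, ] / piv
          Binv <- Binv - outer(w, er)
          Binv[leave, ] <- er
        }
      }
    }
  }

  # ---- Phase I ----
  cost1 <- c(rep(0, n), rep(-1, m))
  res1 <- run_simplex(cost1, xa, at_upper, basis, Binv)
  if (res1$status %in% c("maxiter", "numeric"))
    return(list(status = "numeric_failure", x = rep(NA_real_, n),
                objective = NA_real_))
  art_sum <- sum(res1$xa[art])
  if (art_sum > 1e-7)
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))

  # pin artificials at zero for Phase II
  lba[art] <- 0; uba[art] <- 0
  xa <- res1$xa; xa[art] <- 0

  cost2 <- c(cvec, rep(0, m))
  res2 <- run_simplex(cost2, xa, res1$at_upper, res1$basis, res1$Binv)
  if (res2$status %in% c("maxiter", "numeric"))
    return(list(status = "numeric_failure", x = rep(NA_real_, n),
                objective = NA_real_))
  if (res2$status == "unbounded")
    return(list(status = "unbounded", x = rep(NA_real_, n), objective = NA_real_))

  x <- res2$xa[seq_len(n)]
  x <- pmin(pmax(x, lb), ub)  # clamp round-off
  obj <- sum(cvec * x)
  list(status = "optimal", x = x, objective = if (maximize) obj else -obj)
}

# Feasibility check only: is {x : A x = b, lb <= x <= ub} non-empty?
lp_feasible <- function(A, b, lb, ub, tol = 1e-9) {
  res <- lp_solve(A, b, rep(0, ncol(A)), lb, ub, maximize = TRUE, tol = tol)
  res$status == "optimal"
}
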