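# Independent oracles and shared toy fixtures.  Every oracle here is kept
# deliberately naive (enumeration, fixed-point iteration, closure) and
# never calls the solver paths it is used to check.

# ---- exhaustive vertex enumeration for bounded LPs -------------------------
# max c'x s.t. A x = b, lb <= x <= ub, by enumerating all basic solutions:
# every choice of basis columns with the remaining variables at one of
# their bounds.  Exponential; only for n <= ~8.
oracle_lp <- function(A, b, cvec, lb, ub, maximize = TRUE) {
  n <- ncol(A); m <- nrow(A)
  best <- NULL
  rankA <- if (m > 0) qr(A)$rank else 0L
  basis_sets <- if (rankA == 0L) list(integer(0)) else
    utils::combn(n, rankA, simplify = FALSE)
  for (B in basis_sets) {
    if (rankA > 0 && qr(A[, B, drop = FALSE])$rank < rankA) next
    N <- setdiff(seq_len(n), B)
    grid <- expand.grid(rep(list(c(1L, 2L)), length(N)))
    if (nrow(grid) == 0L) grid <- data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      if (length(N)) {
        pick <- as.integer(grid[g, ])
        x[N] <- ifelse(pick == 1L, lb[N], ub[N])
      }
      rhs <- b - if (length(N)) A[, N, drop = FALSE] %*% x[N] else rep(0, m)
      xb <- tryCatch(qr.solve(A[, B, drop = FALSE], rhs), error = function(e) NULL)
      if (is.null(xb)) next
      x[B] <- xb
      if (any(x < lb - 1e-8) || any(x > ub + 1e-8)) next
      val <- sum(cvec * x)
      if (is.null(best) || (maximize && val > best$obj) ||
          (!maximize && val < best$obj))
        best <- list(obj = val, x = x)
    }
  }
  best   # NULL = infeasible (no feasible basic solution; bounded LPs attain
         # their optimum at one)
}

oracle_fba <- function(model, objective = model$objective, maximize = TRUE) {
  S <- stoichiometric_matrix(model)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(model$reactions, `[[`, numeric(1), "ub")
  cvec <- as.numeric(rxn_ids(model) == objective)
  oracle_lp(S, rep(0, nrow(S)), cvec, lb, ub, maximize)
}

# ---- Dykstra alternating projection as a MOMA oracle -----------------------
# Projection of w onto {v : S v = 0, lb <= v <= ub}; converges to the
# exact Euclidean projection (the MOMA optimum) for small problems.
oracle_moma <- function(S, lb, ub, w, iters = 20000L) {
  n <- ncol(S)
  P <- diag(n) - t(S) %*% MASS::ginv(S %*% t(S)) %*% S  # onto null(S)
  x <- w; p <- numeric(n); q <- numeric(n)
  for (k in seq_len(iters)) {
    y <- as.numeric(P %*% (x + p))
    p <- x + p - y
    x <- pmin(pmax(y + q, lb), ub)
    q <- y + q - x
  }
  x
}

# ---- GPR truth-table oracle ------------------------------------------------
# Evaluates a rule string by translating it to an R logical expression.
oracle_gpr <- function(rule_string, deleted, genes) {
  s <- gsub(",", " | ", rule_string)
  s <- gsub("\\band\\b", "&", s, ignore.case = TRUE)
  s <- gsub("\\bor\\b", "|", s, ignore.case = TRUE)
  env <- new.env()
  for (g in genes) assign(g, !(g %in% deleted), envir = env)
  isTRUE(eval(parse(text = s), envir = env))
}

# ---- reachability closure oracle for acyclic unimolecular networks ---------
oracle_unreachable <- function(model, sources = "s[e]") {
  ok <- sources
  repeat {
    added <- FALSE
    for (r in model$reactions) {
      subs <- names(r$stoich)[r$stoich < 0]
      prods <- names(r$stoich)[r$stoich > 0]
      if (r$ub > 1e-9 && all(subs %in% ok) && length(prods) &&
          !all(prods %in% ok)) {
        ok <- union(ok, prods)
        added <- TRUE
      }
    }
    if (!added) break
  }
  setdiff(met_ids(model), ok)
}

# ---- shared toy fixtures ---------------------------------------------------

# linear chain: substrate uptake (<= 1) -> internal -> sink
toy_chain <- function() {
  mets <- rbind(metabolite("a[e]", "a", "e"), metabolite("a[c]", "a", "c"),
                metabolite("b[c]", "b", "c"))
  metabolic_model(mets, list(
    reaction("EX_a", c("a[e]" = -1), lb = -1, ub = 1000),
    reaction("T_a", c("a[e]" = -1, "a[c]" = 1)),
    reaction("R_ab", c("a[c]" = -1, "b[c]" = 1), gpr = "g1"),
    reaction("SINK_b", c("b[c]" = -1))),
    objective = "SINK_b", id = "toy_chain")
}

# two parallel equivalent branches (P, Q) between a and b
toy_parallel <- function() {
  mets <- rbind(metabolite("a[e]", "a", "e"), metabolite("a[c]", "a", "c"),
                metabolite("b[c]", "b", "c"))
  metabolic_model(mets, list(
    reaction("EX_a", c("a[e]" = -1), lb = -1, ub = 1000),
    reaction("T_a", c("a[e]" = -1, "a[c]" = 1)),
    reaction("P", c("a[c]" = -1, "b[c]" = 1), gpr = "gP"),
    reaction("Q", c("a[c]" = -1, "b[c]" = 1), gpr = "gQ"),
    reaction("SINK_b", c("b[c]" = -1))),
    objective = "SINK_b", id = "toy_parallel")
}

# branched network with competing yields: a -> b (yield 1) vs a -> 2 c via
# lossy route; objective consumes b and c with different worth
toy_branched <- function() {
  mets <- rbind(metabolite("a[e]", "a", "e"), metabolite("a[c]", "a", "c"),
                metabolite("b[c]", "b", "c"), metabolite("c[c]", "c", "c"))
  metabolic_model(mets, list(
    reaction("EX_a", c("a[e]" = -1), lb = -2, ub = 1000),
    reaction("T_a", c("a[e]" = -1, "a[c]" = 1)),
    reaction("R1", c("a[c]" = -1, "b[c]" = 1)),
    reaction("R2", c("a[c]" = -2, "c[c]" = 3)),
    reaction("OBJ", c("b[c]" = -2, "c[c]" = -1)),
    reaction("SINK_c", c("c[c]" = -1))),
    objective = "OBJ", id = "toy_branched")
}

moma_problem <- function(model) {
  list(S = stoichiometric_matrix(model),
       lb = vapply(model$reactions, `[[`, numeric(1), "lb"),
       ub = vapply(model$reactions, `[[`, numeric(1), "ub"))
}

# mini-alpina is expensive enough to build once per test run
mini_cache <- new.env(parent = emptyenv())
get_mini <- function() {
  if (is.null(mini_cache$ma)) mini_cache$ma <- mini_alpina()
  mini_cache$ma
}
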