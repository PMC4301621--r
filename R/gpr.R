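# Gene-protein-reaction (GPR) boolean rules.
#
# Grammar: infix boolean over gene identifiers with AND binding tighter than
# OR, parentheses, case-insensitive keywords.  Commas are accepted as OR so
# that tabular isozyme lists ("gene1, gene2, gene3") parse directly.

#' Parse a GPR rule string
#'
#' @param expression character scalar; empty string or \code{NA} means "no
#'   gene association" (the reaction is always active).
#' @return an object of class \code{gpr_rule}: either \code{NULL} (empty), a
#'   character gene leaf, or a list \code{list(op = "and"|"or", args = ...)}.
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' parse_gpr("MA-055-51, MA-101-533")   # comma = isozyme OR
#' @export
parse_gpr <- function(expression) {
  if (is.null(expression) || length(expression) == 0L ||
      is.na(expression) || !nzchar(trimws(expression))) {
    return(structure(list(tree = NULL, string = ""), class = "gpr_rule"))
  }
  toks <- gpr_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$src <- expression
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks$type)) {
    stop(sprintf("GPR parse error at position %d of '%s': unexpected '%s'",
                 st$toks$at[st$pos], expression, st$toks$val[st$pos]))
  }
  structure(list(tree = tree, string = expression), class = "gpr_rule")
}

gpr_tokenize <- function(s) {
  type <- character(0); val <- character(0); at <- integer(0)
  i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { type <- c(type, "lpar"); val <- c(val, "("); at <- c(at, i); i <- i + 1L; next }
    if (ch == ")") { type <- c(type, "rpar"); val <- c(val, ")"); at <- c(at, i); i <- i + 1L; next }
    if (ch == ",") { type <- c(type, "or"); val <- c(val, ","); at <- c(at, i); i <- i + 1L; next }
    if (ch == "&") { type <- c(type, "and"); val <- c(val, "&"); at <- c(at, i); i <- i + 1L; next }
    if (ch == "|") { type <- c(type, "or"); val <- c(val, "|"); at <- c(at, i); i <- i + 1L; next }
    m <- regmatches(substr(s, i, n), regexpr("^[^\\s(),&|]+", substr(s, i, n), perl = TRUE))
    if (length(m) == 0L) stop(sprintf("GPR parse error at position %d of '%s'", i, s))
    w <- m[[1]]
    lw <- tolower(w)
    if (lw == "and") { type <- c(type, "and") }
    else if (lw == "or") { type <- c(type, "or") }
    else { type <- c(type, "gene") }
    val <- c(val, w); at <- c(at, i)
    i <- i + nchar(w)
  }
  list(type = type, val = val, at = at)
}

gpr_peek <- function(st) if (st$pos <= length(st$toks$type)) st$toks$type[st$pos] else "eof"
gpr_take <- function(st) { st$pos <- st$pos + 1L; st$toks$val[st$pos - 1L] }

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (gpr_peek(st) == "or") { gpr_take(st); args <- c(args, list(gpr_parse_and(st))) }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (gpr_peek(st) == "and") { gpr_take(st); args <- c(args, list(gpr_parse_atom(st))) }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (tk == "lpar") {
    gpr_take(st)
    inner <- gpr_parse_or(st)
    if (gpr_peek(st) != "rpar")
      stop(sprintf("GPR parse error in '%s': unbalanced parenthesis", st$src))
    gpr_take(st)
    return(inner)
  }
  if (tk == "gene") return(gpr_take(st))
  stop(sprintf("GPR parse error at position %d of '%s': expected gene or '('",
               if (st$pos <= length(st$toks$at)) st$toks$at[st$pos] else nchar(st$src) + 1L,
               st$src))
}

#' Evaluate a GPR rule under a gene deletion set
#'
#' Deleted genes are FALSE, all others TRUE; a reaction with an empty rule is
#' always active.
#'
#' @param rule a \code{gpr_rule} from \code{\link{parse_gpr}} (a character
#'   string is parsed on the fly).
#' @param deleted_genes character vector of deleted gene ids.
#' @return logical: is the reaction still catalyzable?
#' @examples
#' evaluate_gpr(parse_gpr("g1 or g2"), "g1")              # TRUE (isozyme)
#' evaluate_gpr(parse_gpr("(g1 and g2) or g3"), c("g2", "g3"))  # FALSE
#' @export
evaluate_gpr <- function(rule, deleted_genes = character(0)) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  stopifnot(inherits(rule, "gpr_rule"))
  gpr_eval_node(rule$tree, deleted_genes)
}

gpr_eval_node <- function(node, deleted) {
  if (is.null(node)) return(TRUE)
  if (is.character(node)) return(!(node %in% deleted))
  vals <- vapply(node$args, gpr_eval_node, logical(1), deleted = deleted)
  if (node$op == "and") all(vals) else any(vals)
}

#' Genes referenced by a GPR rule
#' @param rule a \code{gpr_rule} or rule string.
#' @return character vector of unique gene ids (possibly empty).
#' @export
gpr_genes <- function(rule) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  unique(gpr_collect(rule$tree))
}

gpr_collect <- function(node) {
  if (is.null(node)) return(character(0))
  if (is.character(node)) return(node)
  unlist(lapply(node$args, gpr_collect))
}

#' @export
print.gpr_rule <- function(x, ...) {
  cat("<gpr_rule> ", if (nzchar(x$string)) x$string else "(none)", "\n", sep = "")
  invisible(x)
}
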