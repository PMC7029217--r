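# Gene-protein-reaction (GPR) rules ------------------------------------------
#
# A GPR is a Boolean expression over gene ids with "and"/"or" (case
# insensitive) and parentheses. The AST is a plain list: leaves are
# list(gene = "id"); inner nodes list(op = "and"|"or", args = list(...)).
# An empty rule parses to NULL: the reaction has no gene requirement.

gpr_tokenize <- function(rule) {
  pat <- "\\(|\\)|[^\\s()]+"
  m <- gregexpr(pat, rule, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(character(0))
  regmatches(rule, list(m))[[1L]]
}

#' Parse a gene-protein-reaction rule
#'
#' Grammar: `expr := term ("or" term)*`, `term := factor ("and" factor)*`,
#' `factor := gene | "(" expr ")"` — so `and` binds tighter than `or`, the
#' usual COBRA convention. Operators are case-insensitive; anything else is
#' a gene id.
#'
#' @param rule GPR string; `""`/`NA` gives `NULL` (no gene requirement).
#' @return a GPR abstract syntax tree, or `NULL` for the empty rule.
#' @examples
#' parse_gpr("g1 and g2")
#' parse_gpr("g1 or g2 and g3")   # OR(g1, AND(g2, g3))
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L || is.na(rule) || !nzchar(trimws(rule))) {
    return(NULL)
  }
  toks <- gpr_tokenize(rule)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  is_op <- function(t, op) !is.na(t) && tolower(t) == op

  parse_expr <- function() {
    args <- list(parse_term())
    while (is_op(peek(), "or")) {
      take()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_op(peek(), "and")) {
      take()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("GPR parse error: unexpected end of rule in '", rule, "'")
    if (t == "(") {
      e <- parse_expr()
      cl <- take()
      if (is.na(cl) || cl != ")") {
        stop("GPR parse error: unbalanced parentheses in '", rule, "'")
      }
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      stop("GPR parse error: unexpected token '", t, "' in '", rule, "'")
    }
    list(gene = t)
  }

  ast <- parse_expr()
  if (pos <= length(toks)) {
    stop("GPR parse error: trailing token '", toks[pos], "' in '", rule, "'")
  }
  ast
}

#' Re-serialise a GPR tree to a normalized rule string
#'
#' @param ast tree from [parse_gpr()] (or `NULL`).
#' @return normalized rule string; `""` for `NULL`.
#' @export
deparse_gpr <- function(ast) {
  if (is.null(ast)) return("")
  rec <- function(node, parent_op) {
    if (!is.null(node$gene)) return(node$gene)
    parts <- vapply(node$args, rec, "", parent_op = node$op)
    s <- paste(parts, collapse = paste0(" ", node$op, " "))
    # parenthesize an OR nested under an AND
    if (!is.null(parent_op) && node$op == "or" && parent_op == "and") {
      s <- paste0("(", s, ")")
    }
    s
  }
  rec(ast, NULL)
}

#' Genes referenced by a GPR tree
#' @param ast tree from [parse_gpr()].
#' @return character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(ast) {
  if (is.null(ast)) return(character(0))
  if (!is.null(ast$gene)) return(ast$gene)
  unique(unlist(lapply(ast$args, gpr_genes)))
}

#' Evaluate a GPR under a gene deletion set
#'
#' Deleted genes evaluate to `FALSE`, all others to `TRUE`; `and`/`or` are
#' Boolean conjunction/disjunction. A reaction catalysed by isozymes (an
#' `or` of genes) therefore survives any single deletion, while deleting one
#' subunit of a complex (`and`) disables it. The empty rule is always active.
#'
#' @param ast tree from [parse_gpr()] (or `NULL`).
#' @param deleted_genes character vector of deleted gene ids.
#' @return logical: is the reaction still catalysable?
#' @export
evaluate_gpr <- function(ast, deleted_genes = character(0)) {
  if (is.null(ast)) return(TRUE)
  if (!is.null(ast$gene)) return(!(ast$gene %in% deleted_genes))
  vals <- vapply(ast$args, evaluate_gpr, NA, deleted_genes = deleted_genes)
  if (ast$op == "and") all(vals) else any(vals)
}

#' Expression score of a GPR tree
#'
#' Maps per-gene expression values to a reaction activity score:
#' `and` nodes take the minimum of their scored children (a complex is
#' limited by its scarcest subunit), `or` nodes the sum (isozymes add
#' capacity). The sentinel `-1` marks a gene without data; a `-1` child is
#' ignored whenever a sibling is scored, and a node whose children are all
#' `-1` is itself `-1`. The empty rule scores `-1` (orphan reaction).
#'
#' @param ast tree from [parse_gpr()] (or `NULL`).
#' @param expr named numeric vector, gene id -> expression (>= 0 or -1);
#'   genes absent from `expr` count as missing (-1).
#' @return a single numeric score (>= 0) or -1.
#' @export
gpr_expression_score <- function(ast, expr) {
  if (is.null(ast)) return(-1)
  if (!is.null(ast$gene)) {
    v <- if (ast$gene %in% names(expr)) unname(expr[[ast$gene]]) else -1
    if (is.na(v)) stop("NA expression value for gene ", ast$gene)
    return(v)
  }
  vals <- vapply(ast$args, gpr_expression_score, 0, expr = expr)
  scored <- vals[vals >= 0]
  if (!length(scored)) return(-1)
  if (ast$op == "and") min(scored) else sum(scored)
}
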