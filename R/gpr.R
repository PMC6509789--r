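#' Gene-protein-reaction (GPR) rules
#'
#' GPRs are boolean expressions over gene identifiers: `and` joins subunits of
#' an enzyme complex (all required), `or` joins isozymes (any suffices).
#' Parsing is a small recursive-descent pass so that gene identifiers may
#' contain dots, dashes and digits without escaping.
#'
#' @name gpr
NULL

gpr_tokenize <- function(gpr) {
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", gpr)[[1]]
  if (m[1] == -1) character(0) else regmatches(gpr, gregexpr("\\(|\\)|[^()[:space:]]+", gpr))[[1]]
}

# Grammar: expr := term ("or" term)* ; term := factor ("and" factor)* ;
# factor := gene | "(" expr ")". Returns nested list AST.
parse_gpr <- function(gpr) {
  tokens <- gpr_tokenize(gpr)
  if (length(tokens) == 0) return(NULL)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NA_character_
  advance <- function() { pos <<- pos + 1L }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      node <- list(op = "or", args = list(node, parse_term()))
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      node <- list(op = "and", args = list(node, parse_factor()))
    }
    node
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.na(tok)) stop("GPR parse error: unexpected end of expression in: ", gpr,
                         call. = FALSE)
    if (tok == "(") {
      advance()
      node <- parse_expr()
      if (is.na(peek()) || peek() != ")") {
        stop("GPR parse error: missing ')' in: ", gpr, call. = FALSE)
      }
      advance()
      return(node)
    }
    if (tok == ")" || tolower(tok) %in% c("and", "or")) {
      stop("GPR parse error: unexpected token '", tok, "' in: ", gpr, call. = FALSE)
    }
    advance()
    list(op = "gene", id = tok)
  }
  ast <- parse_expr()
  if (pos <= length(tokens)) {
    stop("GPR parse error: trailing tokens in: ", gpr, call. = FALSE)
  }
  ast
}

eval_gpr_ast <- function(node, knocked_out) {
  switch(node$op,
    gene = !(node$id %in% knocked_out),
    and = eval_gpr_ast(node$args[[1]], knocked_out) &&
          eval_gpr_ast(node$args[[2]], knocked_out),
    or = eval_gpr_ast(node$args[[1]], knocked_out) ||
         eval_gpr_ast(node$args[[2]], knocked_out)
  )
}

gpr_ast_genes <- function(node) {
  if (is.null(node)) return(character(0))
  if (node$op == "gene") return(node$id)
  unique(unlist(lapply(node$args, gpr_ast_genes)))
}

#' Evaluate a GPR rule under a gene knockout
#'
#' @param gpr GPR string, e.g. `"(g1 and g2) or g3"`. Empty/`NA` rules return
#'   `TRUE` (no genetic requirement).
#' @param knocked_out Character vector of knocked-out gene ids.
#' @return `TRUE` if the reaction remains catalysable.
#' @examples
#' evaluate_gpr("(g1 and g2) or g3", knocked_out = c("g1", "g3"))
#' @export
evaluate_gpr <- function(gpr, knocked_out = character(0)) {
  if (is.null(gpr) || length(gpr) == 0 || is.na(gpr) || !nzchar(trimws(gpr))) {
    return(TRUE)
  }
  eval_gpr_ast(parse_gpr(gpr), knocked_out)
}

#' Genes referenced by a GPR rule
#'
#' @inheritParams evaluate_gpr
#' @return Character vector of gene ids (empty for empty rules).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr) || length(gpr) == 0 || is.na(gpr) || !nzchar(trimws(gpr))) {
    return(character(0))
  }
  gpr_ast_genes(parse_gpr(gpr))
}
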