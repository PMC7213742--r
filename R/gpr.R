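#' Evaluate a gene-protein-reaction (GPR) rule under gene deletions
#'
#' A GPR rule is a boolean expression over gene identifiers using `and`, `or`
#' and parentheses (keywords are case-insensitive). It states which gene
#' products must be present for a reaction to be catalysed: `and` joins
#' subunits of a complex, `or` joins isozymes. Deleted genes evaluate to
#' `FALSE`, all other genes to `TRUE`.
#'
#' The empty rule evaluates to `TRUE`: a reaction with no gene association
#' (biomass, exchanges, spontaneous reactions) survives every gene deletion.
#' `not` is not part of the grammar, matching field convention.
#'
#' @param rule Character scalar, the rule (may be `""`).
#' @param deleted Character vector of deleted gene ids.
#' @return Logical scalar.
#' @examples
#' evaluate_gene_rule("g1 and g2", deleted = "g1")        # FALSE
#' evaluate_gene_rule("(g1 and g2) or g3", deleted = "g1") # TRUE
#' evaluate_gene_rule("", deleted = c("g1", "g2"))         # TRUE
#' @export
evaluate_gene_rule <- function(rule, deleted = character()) {
  stopifnot(is.character(rule), length(rule) == 1L)
  if (is.na(rule) || !nzchar(trimws(rule))) return(TRUE)
  ast <- parse_gene_rule(rule)
  eval_gpr_node(ast, deleted)
}

#' List the gene ids appearing in a GPR rule
#' @param rule Character scalar GPR rule.
#' @return Character vector of unique gene ids (empty for the empty rule).
#' @export
gene_rule_genes <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(character())
  toks <- tokenize_gpr(rule)
  unique(vapply(Filter(function(t) t$type == "gene", toks),
                function(t) t$value, character(1)))
}

# --- recursive-descent parser -------------------------------------------

tokenize_gpr <- function(rule) {
  tokens <- list()
  i <- 1L
  n <- nchar(rule)
  while (i <= n) {
    ch <- substr(rule, i, i)
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch == "(") {
      tokens[[length(tokens) + 1L]] <- list(type = "lparen", pos = i)
      i <- i + 1L
    } else if (ch == ")") {
      tokens[[length(tokens) + 1L]] <- list(type = "rparen", pos = i)
      i <- i + 1L
    } else {
      m <- regmatches(substr(rule, i, n),
                      regexpr("^[^()[:space:]]+", substr(rule, i, n)))
      word <- m[1]
      lw <- tolower(word)
      type <- if (lw == "and") "and" else if (lw == "or") "or" else "gene"
      tokens[[length(tokens) + 1L]] <- list(type = type, value = word, pos = i)
      i <- i + nchar(word)
    }
  }
  tokens
}

parse_gene_rule <- function(rule) {
  toks <- tokenize_gpr(rule)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$i <- 1L
  state$rule <- rule
  node <- parse_or(state)
  if (state$i <= length(state$toks)) {
    gpr_error(state, "unexpected token")
  }
  node
}

gpr_error <- function(state, msg) {
  pos <- if (state$i <= length(state$toks)) state$toks[[state$i]]$pos
         else nchar(state$rule) + 1L
  stop(sprintf("gene rule syntax error at position %d in %s: %s",
               pos, dQuote(state$rule), msg), call. = FALSE)
}

peek <- function(state) {
  if (state$i > length(state$toks)) NULL else state$toks[[state$i]]
}

parse_or <- function(state) {
  left <- parse_and(state)
  while (!is.null(tk <- peek(state)) && tk$type == "or") {
    state$i <- state$i + 1L
    right <- parse_and(state)
    left <- list(op = "or", args = list(left, right))
  }
  left
}

parse_and <- function(state) {
  left <- parse_atom(state)
  while (!is.null(tk <- peek(state)) && tk$type == "and") {
    state$i <- state$i + 1L
    right <- parse_atom(state)
    left <- list(op = "and", args = list(left, right))
  }
  left
}

parse_atom <- function(state) {
  tk <- peek(state)
  if (is.null(tk)) gpr_error(state, "expected gene id or '('")
  if (tk$type == "gene") {
    state$i <- state$i + 1L
    return(list(op = "gene", id = tk$value))
  }
  if (tk$type == "lparen") {
    state$i <- state$i + 1L
    node <- parse_or(state)
    tk2 <- peek(state)
    if (is.null(tk2) || tk2$type != "rparen") gpr_error(state, "expected ')'")
    state$i <- state$i + 1L
    return(node)
  }
  gpr_error(state, "expected gene id or '('")
}

eval_gpr_node <- function(node, deleted) {
  switch(node$op,
    gene = !(node$id %in% deleted),
    and  = eval_gpr_node(node$args[[1]], deleted) &&
           eval_gpr_node(node$args[[2]], deleted),
    or   = eval_gpr_node(node$args[[1]], deleted) ||
           eval_gpr_node(node$args[[2]], deleted)
  )
}
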