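# Gene-protein-reaction boolean rules.
#
# Rules are boolean expressions over gene symbols with `and` (enzyme
# complexes: availability limited by the scarcest subunit) and `or`
# (isozymes: capacities add). For quantitative mapping of expression onto a
# reaction, `and` therefore evaluates to the minimum and `or` to the sum of
# its operands; genes missing from the expression vector count as 0.

#' Parse a GPR rule into an expression tree
#'
#' Grammar: `expr := term ("or" term)*`, `term := factor ("and" factor)*`,
#' `factor := gene | "(" expr ")"`. Operators are case-insensitive; gene
#' symbols may contain letters, digits, `_`, `.` and `-`.
#'
#' @param rule GPR string; `""` or `NA` yield `NULL` (no rule).
#' @return nested list tree: leaves are `list(gene = <symbol>)`, internal
#'   nodes `list(op = "and"|"or", args = list(...))`; `NULL` for no rule.
#' @export
parseGPR <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  tokens <- regmatches(rule, gregexpr("\\(|\\)|[A-Za-z0-9_.\\-]+", rule))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { tok <- tokens[pos]; pos <<- pos + 1L; tok }
  parseExpr <- function() {
    args <- list(parseTerm())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance(); args <- c(args, list(parseTerm()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parseTerm <- function() {
    args <- list(parseFactor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance(); args <- c(args, list(parseFactor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parseFactor <- function() {
    tok <- peek()
    if (is.na(tok)) stop("malformed GPR rule: ", rule)
    if (tok == "(") {
      advance()
      node <- parseExpr()
      if (is.na(peek()) || advance() != ")") stop("unbalanced parentheses in GPR: ", rule)
      return(node)
    }
    if (tok == ")" || tolower(tok) %in% c("and", "or"))
      stop("malformed GPR rule: ", rule)
    list(gene = advance())
  }
  tree <- parseExpr()
  if (pos <= length(tokens)) stop("trailing tokens in GPR: ", rule)
  tree
}

#' Evaluate a GPR tree against gene-level values
#'
#' @param tree result of [parseGPR()] (or a rule string).
#' @param values named numeric vector of gene-level abundances.
#' @param orFun,andFun aggregation for isozymes / complex subunits
#'   (defaults: sum and min).
#' @param missing value used for genes absent from `values`.
#' @return numeric scalar; `NA` for a `NULL` tree.
#' @export
evalGPR <- function(tree, values, orFun = sum, andFun = min, missing = 0) {
  if (is.character(tree)) tree <- parseGPR(tree)
  if (is.null(tree)) return(NA_real_)
  rec <- function(node) {
    if (!is.null(node$gene)) {
      v <- values[node$gene]
      return(if (is.na(v)) missing else unname(v))
    }
    vals <- vapply(node$args, rec, numeric(1))
    if (node$op == "or") orFun(vals) else andFun(vals)
  }
  rec(tree)
}

#' Genes referenced by a GPR rule
#'
#' @param rule GPR string or parsed tree.
#' @return character vector of unique gene symbols (empty for no rule).
#' @export
gprGenes <- function(rule) {
  if (is.character(rule)) rule <- parseGPR(rule)
  if (is.null(rule)) return(character())
  rec <- function(node) {
    if (!is.null(node$gene)) return(node$gene)
    unlist(lapply(node$args, rec))
  }
  unique(rec(rule))
}

#' All genes of a network's GPR rules
#'
#' @param network a [MetabolicNetwork-class].
#' @return character vector of unique gene symbols.
#' @export
networkGenes <- function(network) {
  unique(unlist(lapply(reactions(network)$gpr, gprGenes)))
}
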