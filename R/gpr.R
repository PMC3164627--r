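#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers in which `and`
#' denotes a protein complex (every subunit required) and `or` denotes
#' isozymes (any one suffices).  `and` binds tighter than `or`;
#' parentheses override.  Operators are matched case-insensitively.  An
#' empty rule (`""` or `NA`) stands for a spontaneous or orphan reaction
#' and is represented by `NULL`, which always evaluates to `TRUE`.
#'
#' @param rule a single character string, e.g. `"(g1 and g2) or g3"`.
#' @return an object of class `"gpr"` (a boolean expression tree), or
#'   `NULL` for an empty rule.
#' @examples
#' g <- parse_gpr("(nifH and nifD) or nifK")
#' eval_gpr(g, present = "nifK")
#' gpr_genes(g)
#' @seealso [eval_gpr()], [gpr_genes()], [render_gpr()]
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0) return(NULL)
  if (length(rule) != 1) abort("`rule` must be a single string")
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)

  tokens <- gpr_tokenize(rule)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  state$rule <- rule
  expr <- gpr_parse_or(state)
  if (state$pos <= length(state$tokens)) {
    abort(paste0("GPR parse error in rule '", rule, "': unexpected token '",
                 state$tokens[state$pos], "'"))
  }
  expr
}

gpr_tokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  tokens <- strsplit(trimws(rule), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

gpr_peek <- function(state) {
  if (state$pos > length(state$tokens)) NA_character_ else state$tokens[state$pos]
}

gpr_take <- function(state) {
  tok <- gpr_peek(state)
  state$pos <- state$pos + 1L
  tok
}

gpr_parse_or <- function(state) {
  args <- list(gpr_parse_and(state))
  while (!is.na(tok <- gpr_peek(state)) && tolower(tok) == "or") {
    gpr_take(state)
    args <- c(args, list(gpr_parse_and(state)))
  }
  if (length(args) == 1) args[[1]] else gpr_node("or", args)
}

gpr_parse_and <- function(state) {
  args <- list(gpr_parse_atom(state))
  while (!is.na(tok <- gpr_peek(state)) && tolower(tok) == "and") {
    gpr_take(state)
    args <- c(args, list(gpr_parse_atom(state)))
  }
  if (length(args) == 1) args[[1]] else gpr_node("and", args)
}

gpr_parse_atom <- function(state) {
  tok <- gpr_take(state)
  if (is.na(tok)) {
    abort(paste0("GPR parse error in rule '", state$rule, "': empty operand"))
  }
  if (tok == "(") {
    expr <- gpr_parse_or(state)
    close <- gpr_take(state)
    if (is.na(close) || close != ")") {
      abort(paste0("GPR parse error in rule '", state$rule,
                   "': unbalanced parentheses"))
    }
    return(expr)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    abort(paste0("GPR parse error in rule '", state$rule,
                 "': empty operand before '", tok, "'"))
  }
  gpr_leaf(tok)
}

gpr_leaf <- function(gene) {
  structure(list(type = "gene", gene = gene), class = "gpr")
}

gpr_node <- function(op, args) {
  structure(list(type = op, args = args), class = "gpr")
}

#' Evaluate a GPR rule under a gene-presence assignment
#'
#' @param gpr a `"gpr"` tree from [parse_gpr()], or `NULL` (spontaneous,
#'   always `TRUE`).
#' @param present character vector of genes assumed present; every other
#'   gene is absent.
#' @return `TRUE` if the reaction retains enzymatic support, else `FALSE`.
#' @export
eval_gpr <- function(gpr, present) {
  if (is.null(gpr)) return(TRUE)
  switch(gpr$type,
    gene = gpr$gene %in% present,
    and = all(vapply(gpr$args, eval_gpr, logical(1), present = present)),
    or = any(vapply(gpr$args, eval_gpr, logical(1), present = present)),
    abort("corrupt GPR tree")
  )
}

#' Genes referenced by a GPR rule
#'
#' @inheritParams eval_gpr
#' @return character vector of distinct gene identifiers (empty for `NULL`).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (gpr$type == "gene") return(gpr$gene)
  unique(unlist(lapply(gpr$args, gpr_genes)))
}

#' Render a GPR tree back to its canonical rule string
#'
#' Canonical form uses lower-case operators and parenthesizes `or` groups
#' nested inside `and` (the only place precedence requires it), so that
#' `parse_gpr(render_gpr(x))` reproduces `x`.
#'
#' @inheritParams eval_gpr
#' @return a character string (`""` for `NULL`).
#' @export
render_gpr <- function(gpr) {
  if (is.null(gpr)) return("")
  if (gpr$type == "gene") return(gpr$gene)
  parts <- vapply(gpr$args, function(a) {
    s <- render_gpr(a)
    if (gpr$type == "and" && !is.null(a$type) && a$type == "or") {
      s <- paste0("(", s, ")")
    }
    s
  }, character(1))
  paste(parts, collapse = paste0(" ", gpr$type, " "))
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", render_gpr(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.gpr <- function(x, ...) render_gpr(x)
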