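#' Infix formula grammar
#'
#' Formulae serialize to a small infix grammar and parse back to identical
#' semantics:
#'
#' ```
#' expr   := term (("+" | "-") term)*
#' term   := unary (("*" | "/") unary)*
#' unary  := "-" unary | primary
#' primary:= number | identifier | func "(" expr ")" | "(" expr ")"
#' func   := "log" | "exp" | "sqrt" | "neg"
#' ```
#'
#' `+ -` bind loosest, `* /` tighter, unary minus and the named functions
#' tightest. Identifiers match `[A-Za-z_][A-Za-z0-9_.]*`; the function names
#' are reserved. Division, `log` and `sqrt` carry the protected semantics of
#' [tree_evaluate()].
#'
#' @name formula_grammar
NULL

#' Render an expression tree as a formula string
#'
#' Produces fully parenthesised infix text (function syntax for the unary
#' operators), so that [parse_formula()] reconstructs a tree with identical
#' evaluation semantics.
#'
#' @param tree an `expr_tree`.
#' @return Character scalar.
#' @export
to_formula_text <- function(tree) {
  switch(tree$kind,
    const = format(tree$value, digits = 17),
    feat = tree$name,
    op = {
      if (.mosr_ops[[tree$op]] == 1L) {
        inner <- to_formula_text(tree$args[[1L]])
        if (tree$op == "neg") paste0("neg(", inner, ")")
        else paste0(tree$op, "(", inner, ")")
      } else {
        paste0("(", to_formula_text(tree$args[[1L]]), " ", tree$op, " ",
               to_formula_text(tree$args[[2L]]), ")")
      }
    })
}

.FUNC_NAMES <- c("log", "exp", "sqrt", "neg")

.tokenize_formula <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, pos)
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, pos = pos)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("+", "-", "*", "/", "(", ")")) {
      push(ch, ch, i); i <- i + 1L; next
    }
    rest <- substr(text, i, n)
    m <- regmatches(rest, regexpr("^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?", rest))
    if (length(m) == 1 && nzchar(m)) {
      push("number", as.numeric(m), i); i <- i + nchar(m); next
    }
    m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_.]*", rest))
    if (length(m) == 1 && nzchar(m)) {
      push(if (m %in% .FUNC_NAMES) "func" else "ident", m, i)
      i <- i + nchar(m); next
    }
    stop("formula syntax error at offset ", i, ": unexpected character '", ch, "'")
  }
  push("eof", "", n + 1L)
  tokens
}

#' Parse a formula string into an expression tree
#'
#' Recursive-descent parser for the grammar documented in
#' [formula_grammar]. Syntax errors report the 1-based character offset.
#'
#' @param text character scalar in the infix grammar.
#' @return An `expr_tree`.
#' @examples
#' t <- parse_formula("(x1 + 2.5) * x3")
#' tree_evaluate(t, data.frame(x1 = 1, x3 = 2))  # 7
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- .tokenize_formula(text)
  pos <- 1L
  peek <- function() tokens[[pos]]
  advance <- function() { tok <- tokens[[pos]]; pos <<- pos + 1L; tok }
  expect <- function(type) {
    tok <- peek()
    if (tok$type != type)
      stop("formula syntax error at offset ", tok$pos,
           ": expected '", type, "', found '",
           if (tok$type == "eof") "end of input" else tok$value, "'")
    advance()
  }

  parse_expr <- function() {
    node <- parse_term()
    while (peek()$type %in% c("+", "-")) {
      op <- advance()$type
      node <- tree_op(op, node, parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_unary()
    while (peek()$type %in% c("*", "/")) {
      op <- advance()$type
      node <- tree_op(op, node, parse_unary())
    }
    node
  }
  parse_unary <- function() {
    if (peek()$type == "-") {
      advance()
      return(tree_op("neg", parse_unary()))
    }
    parse_primary()
  }
  parse_primary <- function() {
    tok <- peek()
    if (tok$type == "number") { advance(); return(tree_const(tok$value)) }
    if (tok$type == "ident") { advance(); return(tree_feat(tok$value)) }
    if (tok$type == "func") {
      advance()
      expect("(")
      inner <- parse_expr()
      expect(")")
      return(tree_op(tok$value, inner))
    }
    if (tok$type == "(") {
      advance()
      inner <- parse_expr()
      expect(")")
      return(inner)
    }
    stop("formula syntax error at offset ", tok$pos, ": expected an operand, found '",
         if (tok$type == "eof") "end of input" else tok$value, "'")
  }

  out <- parse_expr()
  tok <- peek()
  if (tok$type != "eof")
    stop("formula syntax error at offset ", tok$pos, ": unexpected '", tok$value, "'")
  out
}
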