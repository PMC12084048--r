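#' Expression trees over named features
#'
#' An `expr_tree` is a recursive list structure representing a mathematical
#' formula over named features: the genotype of a symbolic-regression model.
#' Nodes are one of
#'
#' * constants: `list(kind = "const", value = <numeric scalar>)`
#' * feature references: `list(kind = "feat", name = <character scalar>)`
#' * operator applications: `list(kind = "op", op = <name>, args = <list>)`
#'
#' The closed function set is `+`, `-`, `*`, protected `/`, `neg`, protected
#' `log`, clamped `exp` and protected `sqrt`. Protection conventions keep
#' evaluation total on finite inputs: division by zero yields 1, `log` of a
#' non-positive argument yields 0, `sqrt` acts on the absolute value, and the
#' argument of `exp` is clamped to \[-50, 50\].
#'
#' @name expr_tree
NULL

# operator table: arity of each supported operator
.mosr_ops <- c("+" = 2L, "-" = 2L, "*" = 2L, "/" = 2L,
               "neg" = 1L, "log" = 1L, "exp" = 1L, "sqrt" = 1L)

#' Construct expression tree nodes
#'
#' Low-level constructors used by the random tree generator, the parser and
#' tests. `tree_op()` checks the operator name and its arity.
#'
#' @param value numeric scalar.
#' @param name feature name (character scalar).
#' @param op operator name, one of `+ - * / neg log exp sqrt`.
#' @param ... child nodes.
#' @return An `expr_tree` node.
#' @export
tree_const <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(kind = "const", value = as.numeric(value)), class = "expr_tree")
}

#' @rdname tree_const
#' @export
tree_feat <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(kind = "feat", name = name), class = "expr_tree")
}

#' @rdname tree_const
#' @export
tree_op <- function(op, ...) {
  args <- list(...)
  if (!op %in% names(.mosr_ops))
    stop("unknown operator: ", op)
  if (length(args) != .mosr_ops[[op]])
    stop("operator '", op, "' expects ", .mosr_ops[[op]], " argument(s)")
  structure(list(kind = "op", op = op, args = args), class = "expr_tree")
}

.protected_div <- function(a, b) {
  out <- a / b
  out[b == 0] <- 1
  out
}

.protected_log <- function(a) {
  out <- numeric(length(a))
  pos <- a > 0
  out[pos] <- log(a[pos])
  out
}

.clamped_exp <- function(a) exp(pmin(pmax(a, -50), 50))

#' Evaluate an expression tree on tabular data
#'
#' Computes the raw (real-valued) score of a formula for every row of a data
#' frame or named list of feature vectors. Evaluation is vectorised over rows
#' and total on finite inputs: the protected operator set never produces
#' `NaN`/`Inf` from finite arguments.
#'
#' @param tree an `expr_tree`.
#' @param data a data frame (or named list) whose columns are the feature
#'   catalogue; every feature referenced by `tree` must be present.
#' @return Numeric vector of raw scores, one per row.
#' @seealso [tree_probability()] for the sigmoid-linked probability.
#' @export
tree_evaluate <- function(tree, data) {
  n <- if (is.data.frame(data)) nrow(data) else length(data[[1]])
  .eval_node(tree, data, n)
}

.eval_node <- function(node, data, n) {
  switch(node$kind,
    const = rep.int(node$value, n),
    feat = {
      v <- data[[node$name]]
      if (is.null(v)) stop("unresolved feature reference: ", node$name)
      as.numeric(v)
    },
    op = {
      a <- .eval_node(node$args[[1L]], data, n)
      switch(node$op,
        "+"  = a + .eval_node(node$args[[2L]], data, n),
        "-"  = a - .eval_node(node$args[[2L]], data, n),
        "*"  = a * .eval_node(node$args[[2L]], data, n),
        "/"  = .protected_div(a, .eval_node(node$args[[2L]], data, n)),
        neg  = -a,
        log  = .protected_log(a),
        exp  = .clamped_exp(a),
        sqrt = sqrt(abs(a)),
        stop("unknown operator: ", node$op))
    },
    stop("malformed node kind: ", node$kind))
}

#' Classification probability of an expression tree
#'
#' Applies the logistic link to the raw score and clips the result into
#' `[1e-12, 1 - 1e-12]` so the cross-entropy loss stays finite.
#'
#' @inheritParams tree_evaluate
#' @return Probabilities strictly inside (0, 1).
#' @export
tree_probability <- function(tree, data) {
  clip_probability(stats::plogis(tree_evaluate(tree, data)))
}

#' Clip probabilities away from 0 and 1
#'
#' @param p numeric vector of probabilities.
#' @param eps clipping margin (default `1e-12`).
#' @return `p` clipped into `[eps, 1 - eps]`.
#' @export
clip_probability <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Complexity of an expression tree
#'
#' Total node count, operators and leaves alike: the complexity measure used
#' by the evolutionary engine's parsimony objective.
#'
#' @param tree an `expr_tree`.
#' @return Integer node count (>= 1).
#' @export
tree_complexity <- function(tree) {
  if (tree$kind != "op") return(1L)
  1L + sum(vapply(tree$args, tree_complexity, integer(1)))
}

#' Depth of an expression tree
#'
#' A single leaf has depth 1.
#'
#' @param tree an `expr_tree`.
#' @return Integer depth.
#' @export
tree_depth <- function(tree) {
  if (tree$kind != "op") return(1L)
  1L + max(vapply(tree$args, tree_depth, integer(1)))
}

#' Features referenced by a formula
#'
#' @param tree an `expr_tree`.
#' @return Sorted character vector of the distinct feature names appearing at
#'   the leaves (empty for constant-only trees).
#' @export
used_features <- function(tree) {
  acc <- character(0)
  walk <- function(node) {
    if (node$kind == "feat") acc[[length(acc) + 1L]] <<- node$name
    else if (node$kind == "op") for (a in node$args) walk(a)
  }
  walk(tree)
  sort(unique(acc))
}

#' @export
print.expr_tree <- function(x, ...) {
  cat("<expr_tree> ", to_formula_text(x), "\n",
      "  nodes: ", tree_complexity(x),
      "  depth: ", tree_depth(x),
      "  features: ", paste(used_features(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize an expression tree to/from JSON
#'
#' Trees round-trip losslessly through nested JSON objects (`kind`, `value`,
#' `name`, `op`, `args` fields mirroring the node structure).
#'
#' @param tree an `expr_tree`.
#' @param json JSON string as produced by `tree_to_json()`.
#' @return `tree_to_json()`: a JSON string. `tree_from_json()`: an
#'   `expr_tree`.
#' @export
tree_to_json <- function(tree) {
  jsonlite::toJSON(unclass_tree(tree), auto_unbox = TRUE, digits = NA)
}

unclass_tree <- function(node) {
  node <- unclass(node)
  if (identical(node$kind, "op"))
    node$args <- lapply(node$args, unclass_tree)
  node
}

#' @rdname tree_to_json
#' @export
tree_from_json <- function(json) {
  reclass <- function(node) {
    if (identical(node$kind, "op"))
      node$args <- lapply(node$args, reclass)
    structure(node, class = "expr_tree")
  }
  reclass(jsonlite::fromJSON(json, simplifyVector = FALSE))
}
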