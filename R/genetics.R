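#' Genetic operators for expression trees
#'
#' Random tree generation (ramped half-and-half), subtree crossover, and
#' the three mutation kinds (subtree replacement, point operator change,
#' constant perturbation). All randomness goes through R's RNG stream; callers
#' seed it once per run. New constants are ephemeral random constants drawn
#' uniformly on \[-2, 2\].
#'
#' @name genetics
NULL

.ERC_RANGE <- c(-2, 2)

random_constant <- function() tree_const(stats::runif(1, .ERC_RANGE[1], .ERC_RANGE[2]))

random_leaf <- function(features, p_const = 0.2) {
  if (stats::runif(1) < p_const) random_constant() else tree_feat(sample(features, 1L))
}

#' Generate a random expression tree
#'
#' `method = "grow"` lets branches terminate early; `"full"` expands every
#' branch to `max_depth`. [random_population()] applies ramped half-and-half
#' over the depth range to seed an evolutionary run.
#'
#' @param features character vector of feature names to draw leaves from.
#' @param max_depth maximum depth of the generated tree.
#' @param method `"grow"` or `"full"`.
#' @param function_set operator names to draw from.
#' @return An `expr_tree`.
#' @export
random_tree <- function(features, max_depth = 4L, method = c("grow", "full"),
                        function_set = names(.mosr_ops)) {
  method <- match.arg(method)
  stopifnot(length(features) >= 1L, max_depth >= 1L)
  build <- function(depth) {
    terminate <- depth >= max_depth ||
      (method == "grow" && depth > 1L && stats::runif(1) < 0.3)
    if (terminate) return(random_leaf(features))
    op <- sample(function_set, 1L)
    if (.mosr_ops[[op]] == 1L) tree_op(op, build(depth + 1L))
    else tree_op(op, build(depth + 1L), build(depth + 1L))
  }
  build(1L)
}

#' @param n population size.
#' @param depths depth ramp for half-and-half initialization.
#' @rdname random_tree
#' @export
random_population <- function(n, features, depths = 2:5,
                              function_set = names(.mosr_ops)) {
  lapply(seq_len(n), function(i) {
    d <- depths[1L + (i - 1L) %% length(depths)]
    m <- if (i %% 2L == 0L) "full" else "grow"
    random_tree(features, max_depth = d, method = m, function_set = function_set)
  })
}

# enumerate node paths (each path = integer vector of child indices from root)
tree_paths <- function(tree) {
  out <- list()
  walk <- function(node, path) {
    out[[length(out) + 1L]] <<- path
    if (node$kind == "op")
      for (i in seq_along(node$args)) walk(node$args[[i]], c(path, i))
  }
  walk(tree, integer(0))
  out
}

subtree_at <- function(tree, path) {
  for (i in path) tree <- tree$args[[i]]
  tree
}

replace_at <- function(tree, path, replacement) {
  if (length(path) == 0L) return(replacement)
  tree$args[[path[1L]]] <- replace_at(tree$args[[path[1L]]], path[-1L], replacement)
  tree
}

#' Subtree crossover
#'
#' Swaps a uniformly chosen subtree of `a` for a uniformly chosen subtree of
#' `b`. Offspring violating the depth/size caps are rejected and the parent
#' returned unchanged (cap enforcement, not repair).
#'
#' @param a,b parent `expr_tree`s.
#' @param max_depth,max_nodes structural caps applied to the offspring.
#' @return An `expr_tree`.
#' @export
crossover <- function(a, b, max_depth = 8L, max_nodes = 40L) {
  pa <- tree_paths(a)
  pb <- tree_paths(b)
  child <- replace_at(a, pa[[sample.int(length(pa), 1L)]],
                      subtree_at(b, pb[[sample.int(length(pb), 1L)]]))
  if (tree_depth(child) > max_depth || tree_complexity(child) > max_nodes) a else child
}

#' Mutation operators
#'
#' `mutate_tree()` picks one of three kinds: subtree replacement (a random
#' grown subtree replaces a random node), point mutation (one operator is
#' swapped for another of the same arity), or constant perturbation (one
#' constant is jittered by Gaussian noise, sd 0.1; if the tree has no
#' constants, falls back to point mutation).
#'
#' @param tree an `expr_tree`.
#' @param features feature catalogue for new leaves.
#' @inheritParams crossover
#' @param function_set operator names available to point mutation.
#' @return A mutated `expr_tree` respecting the caps.
#' @export
mutate_tree <- function(tree, features, max_depth = 8L, max_nodes = 40L,
                        function_set = names(.mosr_ops)) {
  kind <- sample(c("subtree", "point", "const"), 1L, prob = c(0.5, 0.3, 0.2))
  out <- switch(kind,
    subtree = {
      paths <- tree_paths(tree)
      replace_at(tree, paths[[sample.int(length(paths), 1L)]],
                 random_tree(features, max_depth = 3L, method = "grow",
                             function_set = function_set))
    },
    point = .point_mutate(tree, function_set),
    const = .perturb_constant(tree, function_set))
  if (tree_depth(out) > max_depth || tree_complexity(out) > max_nodes) tree else out
}

.point_mutate <- function(tree, function_set) {
  paths <- tree_paths(tree)
  op_paths <- Filter(function(p) subtree_at(tree, p)$kind == "op", paths)
  if (length(op_paths) == 0L) return(tree)
  path <- op_paths[[sample.int(length(op_paths), 1L)]]
  node <- subtree_at(tree, path)
  arity <- .mosr_ops[[node$op]]
  candidates <- setdiff(function_set[.mosr_ops[function_set] == arity], node$op)
  if (length(candidates) == 0L) return(tree)
  node$op <- sample(candidates, 1L)
  replace_at(tree, path, node)
}

.perturb_constant <- function(tree, function_set) {
  paths <- tree_paths(tree)
  const_paths <- Filter(function(p) subtree_at(tree, p)$kind == "const", paths)
  if (length(const_paths) == 0L) return(.point_mutate(tree, function_set))
  path <- const_paths[[sample.int(length(const_paths), 1L)]]
  node <- subtree_at(tree, path)
  node$value <- node$value + stats::rnorm(1, sd = 0.1)
  replace_at(tree, path, node)
}
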