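#' Non-dominated sorting and crowding distance
#'
#' The two-objective machinery of NSGA-II selection: fast non-dominated
#' sorting into Pareto fronts and per-front crowding distances. Both
#' objectives are minimised. Point `i` dominates point `j` when it is no
#' worse in both objectives and strictly better in at least one.
#'
#' @param objectives numeric matrix, one row per individual, one column per
#'   objective (both minimised).
#' @return `non_dominated_sort()`: a list of integer vectors, `fronts[[1]]`
#'   being the maximal non-dominated set, each later front non-dominated
#'   after removing earlier ones. `crowding_distance()`: numeric vector of
#'   crowding distances (boundary points get `Inf`).
#' @export
non_dominated_sort <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0L) return(list())
  if (any(!is.finite(objectives))) stop("objective values must be finite")
  # dominates[i, j]: i dominates j
  leq <- gt <- matrix(FALSE, n, n)
  for (m in seq_len(ncol(objectives))) {
    o <- objectives[, m]
    cmp <- outer(o, o, "<=")
    leq <- if (m == 1L) cmp else leq & cmp
    gt <- gt | outer(o, o, "<")
  }
  dominates <- leq & gt
  dominated_count <- colSums(dominates)
  fronts <- list()
  assigned <- rep(FALSE, n)
  current <- which(dominated_count == 0L)
  while (length(current) > 0L) {
    fronts[[length(fronts) + 1L]] <- current
    assigned[current] <- TRUE
    dominated_count <- dominated_count - colSums(dominates[current, , drop = FALSE])
    current <- which(dominated_count == 0L & !assigned)
  }
  fronts
}

#' @rdname non_dominated_sort
#' @export
crowding_distance <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  dist <- rep(0, n)
  if (n <= 2L) return(rep(Inf, n))
  for (m in seq_len(ncol(objectives))) {
    o <- objectives[, m]
    ord <- order(o)
    rng <- o[ord[n]] - o[ord[1L]]
    dist[ord[c(1L, n)]] <- Inf
    if (rng > 0)
      dist[ord[2:(n - 1L)]] <- dist[ord[2:(n - 1L)]] +
        (o[ord[3:n]] - o[ord[1:(n - 2L)]]) / rng
  }
  dist
}

#' Update a Pareto archive with new individuals
#'
#' Maintains the running non-dominated set over (bce, paic): the archive plus
#' candidates is reduced to its first non-dominated front, with exact
#' duplicates (same objectives and same formula text) dropped.
#'
#' @param archive list of individuals (each with `bce` and `paic` fields).
#' @param candidates list of new individuals.
#' @return Updated archive list; no member dominates another.
#' @export
archive_update <- function(archive, candidates) {
  pool <- c(archive, candidates)
  if (length(pool) == 0L) return(pool)
  obj <- cbind(vapply(pool, `[[`, numeric(1), "bce"),
               vapply(pool, `[[`, numeric(1), "paic"))
  front <- non_dominated_sort(obj)[[1L]]
  pool <- pool[front]
  key <- vapply(pool, function(ind)
    paste(format(ind$bce, digits = 17), format(ind$paic, digits = 17),
          to_formula_text(ind$tree)), character(1))
  pool[!duplicated(key)]
}
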