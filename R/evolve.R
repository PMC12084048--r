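#' Evolution settings
#'
#' Configuration for [mosr_evolve()]. Defaults mirror a full study run (300
#' individuals, 500 generations); tests and examples use far smaller values.
#'
#' @param population_size number of individuals per generation (>= 2).
#' @param generations number of generations to evolve (0 = score the initial
#'   population only).
#' @param crossover_rate probability an offspring is produced by subtree
#'   crossover rather than copied.
#' @param mutation_rate probability an offspring is mutated.
#' @param tournament_size competitors per selection tournament.
#' @param max_depth,max_nodes structural caps enforced after every genetic
#'   operation.
#' @param function_set operator names available to the engine.
#' @param init_depths depth ramp for half-and-half initialization.
#' @param immigration_rate fraction of each offspring generation replaced by
#'   fresh random trees (guards against premature convergence; default 0.05).
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#' @return A list of class `evolution_config`.
#' @export
evolution_config <- function(population_size = 300L, generations = 500L,
                             crossover_rate = 0.8, mutation_rate = 0.2,
                             tournament_size = 2L, max_depth = 8L,
                             max_nodes = 40L,
                             function_set = names(.mosr_ops),
                             init_depths = 2:5, immigration_rate = 0.05,
                             seed = NULL) {
  stopifnot(population_size >= 2L, generations >= 0L,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            tournament_size >= 1L, max_depth >= 2L, max_nodes >= 3L,
            immigration_rate >= 0, immigration_rate <= 1,
            all(function_set %in% names(.mosr_ops)))
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 max_depth = as.integer(max_depth),
                 max_nodes = as.integer(max_nodes),
                 function_set = function_set,
                 init_depths = init_depths,
                 immigration_rate = immigration_rate,
                 seed = seed),
            class = "evolution_config")
}

.score_individual <- function(tree, x, y, n, age) {
  bce <- binary_cross_entropy(tree_probability(tree, x), y)
  k <- tree_complexity(tree)
  list(tree = tree, bce = bce, paic = partial_aic(bce, n, k),
       nodes = k, age = age)
}

.objective_matrix <- function(pop)
  cbind(vapply(pop, `[[`, numeric(1), "bce"),
        vapply(pop, `[[`, numeric(1), "paic"))

# NSGA-II environmental selection: fill by front, truncate last by crowding
.select_next <- function(pop, size) {
  obj <- .objective_matrix(pop)
  fronts <- non_dominated_sort(obj)
  chosen <- integer(0)
  rank_of <- integer(length(pop))
  crowd_of <- numeric(length(pop))
  for (fi in seq_along(fronts)) {
    f <- fronts[[fi]]
    rank_of[f] <- fi
    crowd_of[f] <- crowding_distance(obj[f, , drop = FALSE])
    if (length(chosen) + length(f) <= size) {
      chosen <- c(chosen, f)
    } else {
      need <- size - length(chosen)
      keep <- f[order(-crowd_of[f])][seq_len(need)]
      chosen <- c(chosen, keep)
      break
    }
  }
  list(index = chosen, rank = rank_of, crowding = crowd_of)
}

.tournament_pick <- function(rank, crowding, k) {
  cand <- sample.int(length(rank), k, replace = TRUE)
  best <- cand[1L]
  for (c in cand[-1L]) {
    if (rank[c] < rank[best] ||
        (rank[c] == rank[best] && crowding[c] > crowding[best])) best <- c
  }
  best
}

#' Evolve symbolic-regression classifiers
#'
#' Runs NSGA-II-style multi-objective genetic programming over expression
#' trees, minimising training binary cross-entropy and the
#' complexity-penalised AIC ([partial_aic()]) jointly. Returns the running
#' Pareto archive of every non-dominated formula encountered, a champion
#' picked by validation loss, and a per-generation history log.
#'
#' The champion is the archive member with the lowest binary cross-entropy on
#' the validation rows (training rows when no validation set is supplied);
#' ties break towards lower `paic`, then fewer nodes, then the earliest
#' generation of creation.
#'
#' @param data data frame holding the training features and the outcome.
#' @param outcome name of the binary 0/1 outcome column.
#' @param config an [evolution_config()].
#' @param validation optional data frame with the same columns, used only for
#'   champion selection — never for fitness.
#' @return An object of class `mosr_fit` with elements `champion`
#'   (individual: `tree`, `bce`, `paic`, `nodes`, `age`), `archive` (list of
#'   individuals), `history` (data frame: generation, best/median of each
#'   objective, archive size), `config`, and `feature_names`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(100), x2 = rnorm(100))
#' d$y <- as.integer(runif(100) < plogis(2 * d$x1 - 2 * d$x2))
#' fit <- mosr_evolve(d, "y", evolution_config(30, 10, seed = 1))
#' to_formula_text(fit$champion$tree)
#' @export
mosr_evolve <- function(data, outcome, config = evolution_config(),
                        validation = NULL) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: only one class present in training data")
  x <- data[setdiff(names(data), outcome)]
  if (ncol(x) < 1L) stop("no feature columns")
  if (any(!vapply(x, is.numeric, logical(1))))
    stop("all features must be numeric (preprocess categorical columns first)")
  if (any(!is.finite(as.matrix(x)))) stop("missing or non-finite feature values")
  if (!is.null(config$seed)) set.seed(config$seed)

  features <- names(x)
  n <- nrow(x)
  pop <- lapply(random_population(config$population_size, features,
                                  depths = config$init_depths,
                                  function_set = config$function_set),
                .score_individual, x = x, y = y, n = n, age = 0L)
  archive <- archive_update(list(), pop)
  history <- vector("list", config$generations + 1L)
  log_gen <- function(gen) {
    bces <- vapply(pop, `[[`, numeric(1), "bce")
    paics <- vapply(pop, `[[`, numeric(1), "paic")
    data.frame(generation = gen,
               best_bce = min(bces), median_bce = stats::median(bces),
               best_paic = min(paics), median_paic = stats::median(paics),
               archive_best_bce = min(vapply(archive, `[[`, numeric(1), "bce")),
               archive_size = length(archive))
  }
  history[[1L]] <- log_gen(0L)

  gen <- 0L
  while (gen < config$generations) {
    gen <- gen + 1L
    sel <- .select_next(pop, config$population_size)
    offspring <- vector("list", config$population_size)
    n_immigrants <- floor(config$immigration_rate * config$population_size)
    for (i in seq_len(config$population_size)) {
      child <- if (i <= n_immigrants) {
        random_tree(features, max_depth = 4L, method = "grow",
                    function_set = config$function_set)
      } else {
        p1 <- pop[[.tournament_pick(sel$rank, sel$crowding, config$tournament_size)]]$tree
        c1 <- if (stats::runif(1) < config$crossover_rate) {
          p2 <- pop[[.tournament_pick(sel$rank, sel$crowding, config$tournament_size)]]$tree
          crossover(p1, p2, config$max_depth, config$max_nodes)
        } else p1
        if (stats::runif(1) < config$mutation_rate)
          c1 <- mutate_tree(c1, features, config$max_depth,
                            config$max_nodes, config$function_set)
        c1
      }
      offspring[[i]] <- .score_individual(child, x, y, n, gen)
    }
    combined <- c(pop, offspring)
    pop <- combined[.select_next(combined, config$population_size)$index]
    archive <- archive_update(archive, offspring)
    history[[gen + 1L]] <- log_gen(gen)
  }

  champion <- .pick_champion(archive, validation, outcome)
  structure(list(champion = champion, archive = archive,
                 history = do.call(rbind, history),
                 config = config, feature_names = features,
                 n_train = n),
            class = "mosr_fit")
}

.pick_champion <- function(archive, validation, outcome) {
  sel_bce <- if (is.null(validation)) {
    vapply(archive, `[[`, numeric(1), "bce")
  } else {
    vy <- validation[[outcome]]
    vx <- validation[setdiff(names(validation), outcome)]
    vapply(archive, function(ind)
      binary_cross_entropy(tree_probability(ind$tree, vx), vy), numeric(1))
  }
  ord <- order(sel_bce,
               vapply(archive, `[[`, numeric(1), "paic"),
               vapply(archive, `[[`, numeric(1), "nodes"),
               vapply(archive, `[[`, numeric(1), "age"))
  champ <- archive[[ord[1L]]]
  champ$selection_bce <- sel_bce[ord[1L]]
  champ
}

#' @export
print.mosr_fit <- function(x, ...) {
  cat("Multi-objective symbolic regression fit\n")
  cat("  champion: ", to_formula_text(x$champion$tree), "\n", sep = "")
  cat(sprintf("  train BCE %.4f | paic %.2f | nodes %d | archive size %d\n",
              x$champion$bce, x$champion$paic, x$champion$nodes,
              length(x$archive)))
  invisible(x)
}

#' Predict from an evolved formula
#'
#' @param object an `mosr_fit`.
#' @param newdata data frame containing the model's features.
#' @param type `"prob"` for sigmoid-linked probabilities, `"score"` for raw
#'   formula values, `"class"` for the 0/1 decision at threshold 0.5.
#' @param ... unused.
#' @return Numeric (or integer for `"class"`) vector, one value per row.
#' @export
predict.mosr_fit <- function(object, newdata, type = c("prob", "score", "class"),
                             ...) {
  type <- match.arg(type)
  tree <- object$champion$tree
  switch(type,
    prob = tree_probability(tree, newdata),
    score = tree_evaluate(tree, newdata),
    class = as.integer(tree_probability(tree, newdata) >= 0.5))
}
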