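## Steady-state genetic algorithm over binary descriptor-inclusion vectors.
## Fitness of a chromosome is MCC_TR * MCC_TE of a CP-ANN trained on the
## selected descriptors (each MCC the mean of the per-class one-vs-rest
## MCCs), so a subset must generalize to the test set to score well.
## Each generation produces one offspring by rank-proportional parent
## selection, uniform crossover and per-bit mutation; the offspring
## replaces the weakest non-elite member. Fitness values are memoized by
## bit pattern, and every CP-ANN fit uses the same derived seed, so a
## chromosome always scores identically within a run.

#' Genetic-algorithm configuration for descriptor selection
#'
#' Defaults follow the published search settings: 95 chromosomes, 150
#' generations, 20 survivors (elite), mutation rate 0.02, CP-ANN learning
#' rates 0.6 / 0.001. The fitness networks default to a reduced 20 x 20
#' grid and 150 epochs; the full-size network is refit once after the
#' search.
#'
#' @param population_size number of chromosomes (default 95).
#' @param generations offspring produced (default 150).
#' @param survivors elite size never eligible for replacement (default 20).
#' @param mutation_rate per-bit flip probability (default 0.02).
#' @param initial_genes bits set per initial chromosome (default: a third
#'   of the candidates, computed at run time).
#' @param grid_rows,grid_cols,epochs CP-ANN size used inside the fitness
#'   evaluation.
#' @param a_max,a_min CP-ANN learning-rate bounds (fixed 0.6 / 0.001).
#' @param seed integer seed for the whole search.
#' @return an object of class `"ga_config"`.
#' @export
ga_config <- function(population_size = 95L, generations = 150L,
                      survivors = 20L, mutation_rate = 0.02,
                      initial_genes = NULL,
                      grid_rows = 20L, grid_cols = 20L, epochs = 150L,
                      a_max = 0.6, a_min = 0.001, seed = 1L) {
  population_size <- as.integer(population_size)
  survivors <- as.integer(survivors)
  if (population_size < 2L) stop_("population_size must be >= 2")
  if (survivors >= population_size)
    stop_("survivors must be smaller than the population")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop_("mutation_rate must be in [0, 1]")
  structure(list(population_size = population_size,
                 generations = as.integer(generations),
                 survivors = survivors,
                 mutation_rate = mutation_rate,
                 initial_genes = if (is.null(initial_genes)) NULL
                                 else as.integer(initial_genes),
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 epochs = as.integer(epochs),
                 a_max = a_max, a_min = a_min,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Uniform crossover of two chromosomes
#'
#' Each bit of the offspring is copied from one of the two parents with
#' equal probability, so the offspring's gene set always contains the
#' parents' intersection and is contained in their union.
#'
#' @param parent_a,parent_b logical vectors of equal length.
#' @return logical offspring vector.
#' @export
crossover <- function(parent_a, parent_b) {
  if (length(parent_a) != length(parent_b))
    stop_("parents must have equal length")
  from_a <- runif(length(parent_a)) < 0.5
  ifelse(from_a, parent_a, parent_b)
}

#' Per-bit mutation of a chromosome
#'
#' Flips every bit independently with probability `rate`.
#'
#' @param chromosome logical vector.
#' @param rate flip probability in \[0, 1\].
#' @return mutated logical vector.
#' @export
mutate <- function(chromosome, rate) {
  if (rate < 0 || rate > 1) stop_("rate must be in [0, 1]")
  xor(chromosome, runif(length(chromosome)) < rate)
}

#' CP-ANN wrapper fitness of a descriptor subset
#'
#' Trains a CP-ANN on the training set restricted to the chromosome's
#' descriptors and returns `MCC_TR * MCC_TE`, each factor the mean per-class
#' one-vs-rest MCC on the respective set. An empty chromosome scores
#' `-Inf` (sentinel, not an error), so it can never win the search.
#'
#' @param chromosome logical inclusion vector over `colnames(x_tr)`.
#' @param x_tr,y_tr training descriptors (already autoscaled) and labels.
#' @param x_te,y_te test descriptors (same scaling) and labels.
#' @param config a [ga_config()]; its grid, epochs, learning rates and
#'   derived seed parameterize the fitness network.
#' @return scalar fitness.
#' @export
evaluate_fitness <- function(chromosome, x_tr, y_tr, x_te, y_te, config) {
  if (!any(chromosome)) return(-Inf)
  sel <- colnames(x_tr)[chromosome]
  cfg <- som_config(config$grid_rows, config$grid_cols, config$epochs,
                    config$a_max, config$a_min,
                    seed = derive_seed(config$seed, 7L))
  fit <- cpann(x_tr[, sel, drop = FALSE], y_tr, config = cfg,
               scaling = FALSE)
  p_tr <- predict(fit, x_tr[, sel, drop = FALSE], scaled = TRUE)
  p_te <- predict(fit, x_te[, sel, drop = FALSE], scaled = TRUE)
  mcc_tr <- mean_mcc(y_tr, p_tr$class, classes = fit$classes)
  mcc_te <- mean_mcc(y_te, p_te$class, classes = fit$classes)
  mcc_tr * mcc_te
}

#' Genetic-algorithm descriptor selection
#'
#' Runs the steady-state search: an initial population of
#' `population_size` chromosomes with `initial_genes` random bits each is
#' evaluated; every generation two parents are drawn by rank-proportional
#' roulette, recombined by uniform crossover, mutated, evaluated, and the
#' offspring replaces the weakest chromosome outside the `survivors` elite.
#' Elitism makes the best-so-far fitness non-decreasing. The whole run is
#' deterministic for a fixed `config$seed`.
#'
#' @param x_tr,y_tr,x_te,y_te autoscaled training/test descriptor matrices
#'   (sharing columns) and their labels.
#' @param config a [ga_config()].
#' @return an object of class `"ga_selection"`: `best` (logical
#'   chromosome), `best_fitness`, `descriptors` (selected names), `history`
#'   (per-generation best/mean fitness, generation 0 = initial population),
#'   `n_evaluated` (distinct chromosomes scored).
#' @examples
#' \donttest{
#' d <- generate_dataset(synthetic_spec(n_per_class = c(25, 25, 25),
#'                                      n_noise = 10, seed = 2))
#' x <- autoscale(descriptor_matrix(d))$x
#' i <- seq_len(45)
#' sel <- run_ga(x[i, ], class_labels(d)[i], x[-i, ], class_labels(d)[-i],
#'               ga_config(population_size = 8, generations = 5,
#'                         survivors = 3, grid_rows = 6, grid_cols = 6,
#'                         epochs = 30, seed = 2))
#' sel$descriptors
#' }
#' @export
run_ga <- function(x_tr, y_tr, x_te, y_te, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  x_tr <- as_matrix(x_tr); x_te <- as_matrix(x_te)
  if (!identical(colnames(x_tr), colnames(x_te)))
    stop_("training and test sets must share the descriptor space")
  p <- ncol(x_tr)
  n_init <- config$initial_genes %||% max(1L, p %/% 3L)
  if (n_init < 1L || n_init > p) stop_("initial_genes must be in [1, %d]", p)

  cache <- new.env(parent = emptyenv())
  n_evaluated <- 0L
  fitness_of <- function(ch) {
    key <- paste(which(ch), collapse = ",")
    if (is.null(cache[[key]])) {
      cache[[key]] <- evaluate_fitness(ch, x_tr, y_tr, x_te, y_te, config)
      n_evaluated <<- n_evaluated + 1L
    }
    cache[[key]]
  }

  with_seed(config$seed, {
    pop <- lapply(seq_len(config$population_size), function(i) {
      ch <- rep(FALSE, p)
      ch[sample.int(p, n_init)] <- TRUE
      ch
    })
    fit <- vapply(pop, fitness_of, numeric(1))
    history <- data.frame(generation = 0L, best_fitness = max(fit),
                          mean_fitness = mean(fit[is.finite(fit)]))
    best <- pop[[which.max(fit)]]
    best_fitness <- max(fit)

    for (gen in seq_len(config$generations)) {
      rk <- rank(fit, ties.method = "first")
      parents <- sample.int(length(pop), 2L, replace = TRUE, prob = rk)
      child <- mutate(crossover(pop[[parents[1L]]], pop[[parents[2L]]]),
                      config$mutation_rate)
      child_fit <- fitness_of(child)
      elite <- order(fit, decreasing = TRUE)[seq_len(config$survivors)]
      replaceable <- setdiff(seq_along(pop), elite)
      weakest <- replaceable[which.min(fit[replaceable])]
      pop[[weakest]] <- child
      fit[weakest] <- child_fit
      if (child_fit > best_fitness) {
        best <- child; best_fitness <- child_fit
      }
      history <- rbind(history,
                       data.frame(generation = gen, best_fitness = best_fitness,
                                  mean_fitness = mean(fit[is.finite(fit)])))
    }
    structure(list(best = best, best_fitness = best_fitness,
                   descriptors = colnames(x_tr)[best],
                   history = history, n_evaluated = n_evaluated,
                   config = config),
              class = "ga_selection")
  })
}

#' @export
print.ga_selection <- function(x, ...) {
  cat(sprintf("GA descriptor selection: %d of %d descriptors, fitness %.4f\n",
              sum(x$best), length(x$best), x$best_fitness))
  cat(sprintf("%d generations, %d distinct chromosomes evaluated\n",
              max(x$history$generation), x$n_evaluated))
  invisible(x)
}

#' Write a GA fitness history as TSV
#'
#' @param selection a `"ga_selection"`.
#' @param file output path (columns generation, best_fitness,
#'   mean_fitness).
#' @return `file`, invisibly.
#' @export
write_ga_history <- function(selection, file) {
  utils::write.table(selection$history, file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
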