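## Kohonen self-organizing map on a square, non-toroidal grid with a
## triangular neighbourhood. Winner search minimizes Euclidean distance;
## the learning rate decays linearly from a_max to a_min over the epochs and
## the neighbourhood radius shrinks linearly from max(rows, cols) - 1 to 0.
## The epoch loop runs in compiled code (cpann_train_core); the R-level
## primitives below expose single steps for inspection and testing.

#' Kohonen map training parameters
#'
#' @param rows,cols grid dimensions (square topology, non-toroidal
#'   boundaries).
#' @param epochs number of learning epochs; each epoch presents every
#'   object once in a seeded random order.
#' @param a_max,a_min maximal and minimal learning rate of the linear
#'   schedule (defaults 0.5 / 0.01, the splitting-map convention).
#' @param seed integer seed driving weight initialization and the per-epoch
#'   presentation shuffles.
#' @return an object of class `"som_config"`.
#' @export
som_config <- function(rows = 20L, cols = 20L, epochs = 100L,
                       a_max = 0.5, a_min = 0.01, seed = 1L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  epochs <- as.integer(epochs)
  if (rows < 1L || cols < 1L) stop_("grid dimensions must be >= 1")
  if (epochs < 1L) stop_("epochs must be >= 1")
  if (!(a_min > 0 && a_min <= a_max && a_max <= 1))
    stop_("learning rates must satisfy 0 < a_min <= a_max <= 1")
  structure(list(rows = rows, cols = cols, epochs = epochs,
                 a_max = a_max, a_min = a_min,
                 topology = "square", boundary = "non-toroidal",
                 neighbourhood = "triangular",
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "som_config")
}

#' @export
print.som_config <- function(x, ...) {
  cat(sprintf("SOM config: %d x %d grid, %d epochs, learning rate %g -> %g\n",
              x$rows, x$cols, x$epochs, x$a_max, x$a_min))
  invisible(x)
}

#' Linear learning-rate schedule
#'
#' `eta(t) = (a_max - a_min) * (t_max - t) / (t_max - 1) + a_min`: the rate
#' is `a_max` at the first epoch and decays linearly to `a_min` at the last.
#'
#' @param t epoch index, `1 <= t <= epochs`.
#' @param config a [som_config()] with `epochs >= 2`.
#' @return the learning rate at epoch `t`.
#' @examples
#' learning_rate(50, som_config(epochs = 100, a_max = 0.5, a_min = 0.01))
#' @export
learning_rate <- function(t, config) {
  stopifnot(inherits(config, "som_config"))
  t_max <- config$epochs
  if (t_max < 2L) stop_("the schedule needs at least two epochs")
  if (t < 1 || t > t_max) stop_("epoch t out of range [1, %d]", t_max)
  (config$a_max - config$a_min) * (t_max - t) / (t_max - 1) + config$a_min
}

## grid coordinates of row-major neuron index (1-based); coords are
## (row, col), both 1-based
neuron_coords <- function(index, cols) {
  cbind(row = (index - 1L) %/% cols + 1L, col = (index - 1L) %% cols + 1L)
}
neuron_index <- function(row, col, cols) (row - 1L) * cols + col

#' Topological distance between grid positions
#'
#' Ring distance on the square layout without wraparound: the eight
#' surrounding neurons form ring 1, their surrounders ring 2, and so on
#' (Chebyshev distance).
#'
#' @param a,b length-2 integer vectors `(row, col)`.
#' @return non-negative integer ring distance.
#' @export
topological_distance <- function(a, b) {
  max(abs(as.integer(a) - as.integer(b)))
}

#' Winner (central) neuron for an input vector
#'
#' Scans all neurons and returns the one whose weight vector has the
#' smallest Euclidean distance to `x`; ties resolve to the first neuron in
#' row-major order.
#'
#' @param grid a `"som_grid"`.
#' @param x numeric vector of length equal to the grid's input
#'   dimensionality.
#' @return list with `index` (row-major, 1-based), `coords` `(row, col)` and
#'   `distance` (Euclidean, with the square root taken).
#' @export
find_winner <- function(grid, x) {
  stopifnot(inherits(grid, "som_grid"))
  if (length(x) != ncol(grid$weights))
    stop_("input has %d components, grid expects %d",
          length(x), ncol(grid$weights))
  mp <- map_winners_core(matrix(as.numeric(x), nrow = 1L), grid$weights)
  list(index = mp$winner[1L],
       coords = drop(neuron_coords(mp$winner[1L], grid$cols)),
       distance = mp$distance[1L])
}

#' One neighbourhood update step
#'
#' Moves every neuron within topological distance `radius` of the winner
#' toward `x` by `eta * a(d)` with the triangular neighbourhood
#' `a(d) = 1 - d / (radius + 1)`; neurons outside the radius are unchanged.
#' Each new weight is a convex combination of the old weight and `x`, so a
#' factor of exactly 1 maps the winner onto the input.
#'
#' @param grid a `"som_grid"`.
#' @param x input vector.
#' @param winner winner as returned by [find_winner()] (or its `index`).
#' @param eta learning rate in (0, 1].
#' @param radius neighbourhood radius (>= 0).
#' @return the updated `"som_grid"`.
#' @export
update_weights <- function(grid, x, winner, eta, radius) {
  stopifnot(inherits(grid, "som_grid"), radius >= 0, eta > 0, eta <= 1)
  idx <- if (is.list(winner)) winner$index else as.integer(winner)
  wc <- neuron_coords(idx, grid$cols)
  all_coords <- neuron_coords(seq_len(nrow(grid$weights)), grid$cols)
  d <- pmax(abs(all_coords[, "row"] - wc[, "row"]),
            abs(all_coords[, "col"] - wc[, "col"]))
  f <- ifelse(d <= radius, eta * (1 - d / (radius + 1)), 0)
  grid$weights <- grid$weights +
    f * sweep(-grid$weights, 2L, as.numeric(x), "+")
  grid
}

new_som_grid <- function(weights, rows, cols, config, qe = NULL,
                         descriptors = NULL) {
  structure(list(weights = weights, rows = rows, cols = cols,
                 config = config, qe = qe,
                 descriptors = descriptors %||% colnames(weights)),
            class = "som_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

init_weights <- function(k, m, names = NULL) {
  w <- matrix(runif(k * m), k, m)
  colnames(w) <- names
  w
}

presentation_orders <- function(n, epochs) {
  ord <- matrix(0L, epochs, n)
  for (t in seq_len(epochs)) ord[t, ] <- sample.int(n)
  ord
}

#' Train a Kohonen self-organizing map
#'
#' Competitive learning over `config$epochs` epochs: each epoch presents
#' every object once in a seeded random order; for each object the winner is
#' found by Euclidean distance and its neighbourhood moves toward the input
#' with the triangular kernel and the linear learning-rate and radius
#' schedules. Weights initialize uniformly in \[0, 1\]. Autoscaled input is
#' recommended so all descriptors carry comparable weight.
#'
#' @param x numeric matrix (objects x variables) or labelled descriptor
#'   data frame.
#' @param config a [som_config()].
#' @param init optional initial weight matrix (neurons x variables, row-major
#'   neuron order) overriding the seeded uniform initialization; mainly for
#'   reproducing runs and for equivariance checks.
#' @return an object of class `"som_grid"`: `weights` (neurons x variables,
#'   row-major neuron order), grid dimensions, the config, and `qe`, the
#'   per-epoch mean quantization error (mean Euclidean distance of each
#'   object to its winner at presentation time).
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' m <- train_som(x, som_config(rows = 4, cols = 4, epochs = 10, seed = 2))
#' tail(m$qe, 1) <= m$qe[1]
#' @export
train_som <- function(x, config = som_config(), init = NULL) {
  stopifnot(inherits(config, "som_config"))
  x <- as_matrix(x)
  if (nrow(x) < 1L) stop_("at least one object is required")
  k <- config$rows * config$cols
  with_seed(config$seed, {
    w0 <- if (is.null(init)) init_weights(k, ncol(x), colnames(x)) else {
      stopifnot(is.matrix(init), nrow(init) == k, ncol(init) == ncol(x))
      init
    }
    ord <- presentation_orders(nrow(x), config$epochs)
    fit <- cpann_train_core(x, NULL, w0, NULL, ord,
                            config$rows, config$cols,
                            config$a_max, config$a_min)
    new_som_grid(fit$weights, config$rows, config$cols, config,
                 qe = fit$qe, descriptors = colnames(x))
  })
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("Kohonen map: %d x %d neurons, %d inputs, %d epochs trained\n",
              x$rows, x$cols, ncol(x$weights),
              length(x$qe) %||% x$config$epochs))
  if (!is.null(x$qe))
    cat(sprintf("quantization error: %.4f (first epoch) -> %.4f (last)\n",
                x$qe[1L], x$qe[length(x$qe)]))
  invisible(x)
}

#' Assign objects to their winning neurons (top-map)
#'
#' @param grid a trained `"som_grid"`.
#' @param x objects to map (matrix or labelled descriptor data frame).
#' @param labels optional class labels, used to annotate each occupied
#'   neuron with its majority class (ties resolve to the earlier factor
#'   level).
#' @return an object of class `"top_map"`: `assignments` data frame
#'   (`id`, `row`, `col`, `neuron`, `distance`), `occupancy` (rows x cols
#'   integer matrix summing to `nrow(x)`), and `majority` (character matrix
#'   of per-neuron majority classes, when labels are given).
#' @export
build_top_map <- function(grid, x, labels = NULL) {
  stopifnot(inherits(grid, "som_grid"))
  x <- as_matrix(x)
  mp <- map_winners_core(x, grid$weights)
  coords <- neuron_coords(mp$winner, grid$cols)
  tab <- tabulate(mp$winner, nbins = grid$rows * grid$cols)
  occupancy <- matrix(tab, grid$rows, grid$cols, byrow = TRUE)
  majority <- NULL
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    stopifnot(length(labels) == nrow(x))
    majority <- matrix(NA_character_, grid$rows, grid$cols)
    for (j in unique(mp$winner)) {
      cnt <- table(labels[mp$winner == j])
      rc <- neuron_coords(j, grid$cols)
      majority[rc[, "row"], rc[, "col"]] <- names(cnt)[which.max(cnt)]
    }
  }
  structure(list(
    assignments = data.frame(id = rownames(x) %||% as.character(seq_len(nrow(x))),
                             row = coords[, "row"], col = coords[, "col"],
                             neuron = mp$winner, distance = mp$distance,
                             stringsAsFactors = FALSE),
    occupancy = occupancy, majority = majority,
    rows = grid$rows, cols = grid$cols),
    class = "top_map")
}

#' @export
print.top_map <- function(x, ...) {
  cat(sprintf("top-map: %d objects on %d x %d grid, %d occupied neurons\n",
              nrow(x$assignments), x$rows, x$cols, sum(x$occupancy > 0)))
  invisible(x)
}

#' Serialize / restore a Kohonen map
#'
#' Writes the grid as JSON (config, shape, row-major flat weight vector and
#' descriptor names), and reads it back.
#'
#' @param grid a `"som_grid"`.
#' @param file path to a JSON file.
#' @return `write_som_json()` returns `file` invisibly; `read_som_json()`
#'   returns the restored `"som_grid"`.
#' @export
write_som_json <- function(grid, file) {
  stopifnot(inherits(grid, "som_grid"))
  jsonlite::write_json(list(
    config = unclass(grid$config), rows = grid$rows, cols = grid$cols,
    descriptors = grid$descriptors,
    weights = as.numeric(t(grid$weights)), qe = grid$qe),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_som_json
#' @export
read_som_json <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  cfg <- do.call(som_config, j$config[c("rows", "cols", "epochs",
                                        "a_max", "a_min", "seed")])
  w <- matrix(j$weights, nrow = j$rows * j$cols, byrow = TRUE)
  colnames(w) <- j$descriptors
  new_som_grid(w, j$rows, j$cols, cfg, qe = j$qe, descriptors = j$descriptors)
}
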