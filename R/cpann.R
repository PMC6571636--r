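## Counter-propagation ANN: a Kohonen layer mapping descriptor vectors onto
## a 2-D grid, plus an output layer of the same shape holding one weight per
## class and neuron. Per presented object the winner is found from the
## descriptors only; the Kohonen weights of its neighbourhood move toward
## the input and the output weights of the same neighbourhood move toward
## the one-hot class target, both by eta(t) * (1 - d / (radius + 1)).
## Output weights therefore stay in [0, 1] and read as bounded class
## indicators.

#' Fit a counter-propagation neural network classifier
#'
#' Trains the two-layer network on a descriptor matrix and a class factor.
#' Targets are one-hot encoded; Kohonen and output layers are updated within
#' the same pass (after each winner search the output weights of the same
#' neighbourhood are corrected toward the target with the same
#' learning-rate factor). Both weight layers initialize uniformly in
#' \[0, 1\].
#'
#' Descriptors are autoscaled before mapping and the transform is stored in
#' the model, so `predict()` accepts raw descriptor values. Pass a
#' previously fitted `"scaling_params"` to reuse an external transform, or
#' `scaling = FALSE` when the matrix is already scaled.
#'
#' @param x descriptor matrix (compounds x descriptors) or labelled
#'   descriptor data frame (its `class` column is then the default `y`).
#' @param y factor (or vector) of class labels, one per compound.
#' @param config a [som_config()]; `som_config(43, 43, 600, 0.6, 0.001)`
#'   is the published P-gp model configuration, while the default here is a
#'   small net suitable for datasets of a few hundred compounds.
#' @param scaling `NULL` to fit autoscaling on `x`, a `"scaling_params"`
#'   object to apply an external transform, or `FALSE` if `x` is already
#'   autoscaled.
#' @param descriptors optional character vector restricting the model to a
#'   descriptor subset (e.g. a GA selection).
#' @return an object of class `"cpann"`: `kohonen` (`"som_grid"`),
#'   `output_weights` (neurons x classes, in \[0, 1\]), `classes`,
#'   `scaling`, `descriptors`, `config`, plus the training top-map and
#'   fitted scores.
#' @examples
#' d <- generate_dataset(synthetic_spec(n_per_class = c(30, 30, 30), seed = 5))
#' fit <- cpann(d, config = som_config(rows = 8, cols = 8, epochs = 40,
#'                                     a_max = 0.6, a_min = 0.001, seed = 5))
#' fit
#' @export
cpann <- function(x, y = NULL,
                  config = som_config(rows = 12L, cols = 12L, epochs = 200L,
                                      a_max = 0.6, a_min = 0.001),
                  scaling = NULL, descriptors = NULL) {
  if (is.data.frame(x) && "class" %in% names(x)) {
    if (is.null(y)) y <- class_labels(x)
    x <- descriptor_matrix(x)
  }
  x <- as_matrix(x)
  if (is.null(y)) stop_("class labels y are required")
  y <- as.factor(y)
  if (length(y) != nrow(x)) stop_("x and y are misaligned: %d rows vs %d labels",
                                  nrow(x), length(y))
  if (nlevels(y) < 2L) stop_("at least two classes are required")
  if (!is.null(descriptors)) {
    miss <- setdiff(descriptors, colnames(x))
    if (length(miss)) stop_("missing descriptor: %s", paste(miss, collapse = ", "))
    x <- x[, descriptors, drop = FALSE]
  }

  if (isFALSE(scaling)) {
    params <- NULL
    xs <- x
  } else {
    sc <- autoscale(x, params = if (inherits(scaling, "scaling_params")) scaling else NULL)
    params <- sc$params
    xs <- sc$x
  }

  Y <- one_hot(y)
  k <- config$rows * config$cols
  fit <- with_seed(config$seed, {
    w0 <- init_weights(k, ncol(xs), colnames(xs))
    u0 <- init_weights(k, ncol(Y), colnames(Y))
    ord <- presentation_orders(nrow(xs), config$epochs)
    cpann_train_core(xs, Y, w0, u0, ord, config$rows, config$cols,
                     config$a_max, config$a_min)
  })
  grid <- new_som_grid(fit$weights, config$rows, config$cols, config,
                       qe = fit$qe, descriptors = colnames(xs))
  model <- structure(list(kohonen = grid,
                          output_weights = fit$output_weights,
                          classes = levels(y),
                          scaling = params,
                          descriptors = colnames(xs),
                          config = config),
                     class = "cpann")
  model$top_map <- build_top_map(grid, xs, labels = y)
  tr_pred <- predict(model, x, scaled = isFALSE(scaling))
  model$fitted_scores <- as.matrix(tr_pred[paste0("score_", model$classes)])
  colnames(model$fitted_scores) <- model$classes
  rownames(model$fitted_scores) <- rownames(xs)
  model$y <- y
  model
}

one_hot <- function(y) {
  Y <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

scale_newdata <- function(object, x) {
  x <- as_matrix(x)
  miss <- setdiff(object$descriptors, colnames(x))
  if (length(miss))
    stop_("missing descriptor: %s", paste(miss, collapse = ", "))
  x <- x[, object$descriptors, drop = FALSE]
  if (!is.null(object$scaling)) autoscale(x, params = object$scaling)$x else x
}

#' Predict classes for new compounds
#'
#' Applies the stored autoscaling, finds each compound's winning neuron in
#' the Kohonen layer, and reads that neuron's output-weight vector as the
#' class scores. A class with score above `threshold` (default 0.5) counts
#' as predicted membership; the single assigned class is the score argmax.
#' When no class — or more than one — clears the threshold, the row is
#' flagged (`"below-threshold"` / `"multiple-above"`) as an uncertain,
#' lower-reliability prediction.
#'
#' @param object a fitted [cpann()] model.
#' @param newdata descriptor matrix or labelled descriptor data frame with
#'   all model descriptors (raw values unless `scaled = TRUE`).
#' @param threshold class-membership score threshold, default 0.5.
#' @param scaled set TRUE when `newdata` is already autoscaled with the
#'   model's parameters.
#' @param ... unused.
#' @return a data frame, one row per compound: `score_<class>` columns, the
#'   assigned `class`, `n_above` (classes above threshold), `flag`
#'   (`"ok"`, `"below-threshold"` or `"multiple-above"`), the winner
#'   coordinates (`row`, `col`) and `ed`, the Euclidean distance to the
#'   winning neuron in autoscaled descriptor space.
#' @export
predict.cpann <- function(object, newdata, threshold = 0.5, scaled = FALSE,
                          ...) {
  xs <- if (scaled) {
    x <- as_matrix(newdata)
    miss <- setdiff(object$descriptors, colnames(x))
    if (length(miss)) stop_("missing descriptor: %s", paste(miss, collapse = ", "))
    x[, object$descriptors, drop = FALSE]
  } else scale_newdata(object, newdata)
  if (nrow(xs) == 0L) {
    out <- data.frame(matrix(numeric(0), 0, length(object$classes)))
    names(out) <- paste0("score_", object$classes)
    out$class <- factor(character(0), levels = object$classes)
    out$n_above <- integer(0); out$flag <- character(0)
    out$row <- integer(0); out$col <- integer(0); out$ed <- numeric(0)
    return(out)
  }
  mp <- map_winners_core(xs, object$kohonen$weights)
  scores <- object$output_weights[mp$winner, , drop = FALSE]
  colnames(scores) <- object$classes
  assigned <- object$classes[max.col(scores, ties.method = "first")]
  n_above <- rowSums(scores > threshold)
  flag <- ifelse(n_above == 1L, "ok",
                 ifelse(n_above == 0L, "below-threshold", "multiple-above"))
  coords <- neuron_coords(mp$winner, object$kohonen$cols)
  out <- as.data.frame(scores)
  names(out) <- paste0("score_", object$classes)
  out$class <- factor(assigned, levels = object$classes)
  out$n_above <- as.integer(n_above)
  out$flag <- flag
  out$row <- coords[, "row"]; out$col <- coords[, "col"]
  out$ed <- mp$distance
  rownames(out) <- rownames(xs)
  out
}

#' Batch prediction with optional truth table
#'
#' Convenience wrapper around [predict.cpann()] that, when `labels` are
#' supplied (or present as a `class` column), appends the true class and
#' returns the evaluation-ready predicted-vs-true table.
#'
#' @inheritParams predict.cpann
#' @param labels optional true class labels aligned with `newdata`.
#' @return the [predict.cpann()] data frame, plus a `true` column when
#'   labels are available.
#' @export
predict_batch <- function(object, newdata, labels = NULL, threshold = 0.5,
                          scaled = FALSE) {
  if (is.null(labels) && is.data.frame(newdata) && "class" %in% names(newdata))
    labels <- class_labels(newdata)
  out <- predict(object, newdata, threshold = threshold, scaled = scaled)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(out))
    out$true <- factor(as.character(labels), levels = object$classes)
  }
  out
}

#' @export
print.cpann <- function(x, ...) {
  cat(sprintf("counter-propagation ANN: %d x %d neurons, %d descriptors, %d classes\n",
              x$config$rows, x$config$cols, length(x$descriptors),
              length(x$classes)))
  cat(sprintf("classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("trained %d epochs, learning rate %g -> %g\n",
              x$config$epochs, x$config$a_max, x$config$a_min))
  invisible(x)
}

#' @export
summary.cpann <- function(object, ...) {
  pred <- factor(object$classes[max.col(object$fitted_scores,
                                        ties.method = "first")],
                 levels = object$classes)
  rep <- global_report(object$y, pred, classes = object$classes)
  out <- list(model = object, train_report = rep,
              occupied = sum(object$top_map$occupancy > 0),
              qe = object$kohonen$qe)
  class(out) <- "summary.cpann"
  out
}

#' @export
print.summary.cpann <- function(x, ...) {
  print(x$model)
  cat(sprintf("occupied neurons: %d; final quantization error %.4f\n",
              x$occupied, tail(x$qe, 1L)))
  cat("training-set performance:\n")
  print(x$train_report)
  invisible(x)
}

#' @export
coef.cpann <- function(object, layer = c("output", "kohonen"), ...) {
  layer <- match.arg(layer)
  if (layer == "output") object$output_weights else object$kohonen$weights
}

#' @export
fitted.cpann <- function(object, ...) object$fitted_scores

#' Training-set residuals of a CP-ANN
#'
#' Per class, target minus fitted score (`y - u`), the quantity plotted
#' against the Euclidean distance to the winning neuron in
#' applicability-domain diagnostics.
#'
#' @param object a fitted [cpann()] model.
#' @param ... unused.
#' @return numeric matrix (compounds x classes) of residuals in \[-1, 1\].
#' @export
residuals.cpann <- function(object, ...) {
  one_hot(object$y) - object$fitted_scores
}

#' Plot a CP-ANN top-map
#'
#' Displays neuron occupancy of the training top-map as an image, with the
#' per-neuron majority class overprinted.
#'
#' @param x a fitted [cpann()] model.
#' @param ... passed to [graphics::image()].
#' @export
plot.cpann <- function(x, ...) {
  occ <- x$top_map$occupancy
  graphics::image(seq_len(ncol(occ)), seq_len(nrow(occ)),
                  t(occ[rev(seq_len(nrow(occ))), , drop = FALSE]),
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  xlab = "column", ylab = "row",
                  main = "CP-ANN top-map occupancy", ...)
  maj <- x$top_map$majority
  if (!is.null(maj)) {
    for (r in seq_len(nrow(maj))) for (cc in seq_len(ncol(maj))) {
      if (!is.na(maj[r, cc]))
        graphics::text(cc, nrow(maj) - r + 1L,
                       substr(maj[r, cc], 1L, 1L), cex = 0.6)
    }
  }
  invisible(x)
}

#' Serialize / restore a CP-ANN model
#'
#' Writes the whole model (config, both weight layers, scaling parameters,
#' descriptor and class names) as a single JSON document.
#'
#' @param model a `"cpann"` model.
#' @param file path to a JSON file.
#' @return `write_cpann_json()` returns `file` invisibly;
#'   `read_cpann_json()` the restored model (without training top-map and
#'   fitted scores, which belong to the training data rather than the
#'   model).
#' @export
write_cpann_json <- function(model, file) {
  stopifnot(inherits(model, "cpann"))
  jsonlite::write_json(list(
    config = unclass(model$config),
    rows = model$config$rows, cols = model$config$cols,
    classes = model$classes, descriptors = model$descriptors,
    kohonen_weights = as.numeric(t(model$kohonen$weights)),
    output_weights = as.numeric(t(model$output_weights)),
    scaling = if (is.null(model$scaling)) NULL else
      list(mean = unname(model$scaling$mean), sd = unname(model$scaling$sd),
           descriptors = model$scaling$descriptors)),
    file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' @rdname write_cpann_json
#' @export
read_cpann_json <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  cfg <- do.call(som_config, j$config[c("rows", "cols", "epochs",
                                        "a_max", "a_min", "seed")])
  m <- length(j$descriptors); g <- length(j$classes)
  w <- matrix(j$kohonen_weights, ncol = m, byrow = TRUE,
              dimnames = list(NULL, j$descriptors))
  u <- matrix(j$output_weights, ncol = g, byrow = TRUE,
              dimnames = list(NULL, j$classes))
  scaling <- NULL
  if (!is.null(j$scaling)) {
    scaling <- structure(list(
      mean = stats::setNames(j$scaling$mean, j$scaling$descriptors),
      sd = stats::setNames(j$scaling$sd, j$scaling$descriptors),
      descriptors = j$scaling$descriptors), class = "scaling_params")
  }
  structure(list(kohonen = new_som_grid(w, j$rows, j$cols, cfg,
                                        descriptors = j$descriptors),
                 output_weights = u, classes = j$classes, scaling = scaling,
                 descriptors = j$descriptors, config = cfg),
            class = "cpann")
}
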