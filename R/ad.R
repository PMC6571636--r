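## Distance-to-model applicability domain: each compound's Euclidean
## distance (in autoscaled descriptor space) to its winning Kohonen neuron,
## compared against the maximum distance observed on a reference partition
## (conventionally the test set). Predictions additionally carry an
## uncertainty flag when any class score falls close to the 0.5 membership
## threshold. Flags are advisory: out-of-domain compounds may still show
## the modelled response, so no prediction is rejected outright.

#' Euclidean distance to the winning neuron
#'
#' Applies the model's stored autoscaling and returns, per compound, the
#' Euclidean distance between the scaled descriptor vector and the weight
#' vector of its winning (central) neuron. Distances are unitless because
#' the descriptors are autoscaled.
#'
#' @param model a fitted [cpann()] model.
#' @param x descriptor matrix, labelled descriptor data frame, or a single
#'   descriptor vector named by descriptor.
#' @param scaled TRUE when `x` is already autoscaled with the model's
#'   parameters.
#' @return numeric vector of distances (one per compound).
#' @export
ed_to_winner <- function(model, x, scaled = FALSE) {
  stopifnot(inherits(model, "cpann"))
  if (is.null(dim(x)) && !is.data.frame(x))
    x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  predict(model, x, scaled = scaled)$ed
}

#' Applicability-domain reference distance
#'
#' The domain boundary: the largest compound-to-winner Euclidean distance
#' observed on a reference partition. The published convention takes the
#' test set as reference; compounds at or below this distance count as
#' in-domain (boundary inclusive).
#'
#' @param model a fitted [cpann()] model.
#' @param x reference partition (non-empty).
#' @param partition label recorded for provenance (default `"TE"`).
#' @param scaled TRUE when `x` is already autoscaled.
#' @return an object of class `"ad_reference"` with fields `reference_ed`,
#'   `partition` and `n`.
#' @export
build_reference <- function(model, x, partition = "TE", scaled = FALSE) {
  ed <- ed_to_winner(model, x, scaled = scaled)
  if (length(ed) == 0L) stop_("reference partition is empty")
  structure(list(reference_ed = max(ed), partition = partition,
                 n = length(ed)),
            class = "ad_reference")
}

#' @export
print.ad_reference <- function(x, ...) {
  cat(sprintf("AD reference: max ED %.4f over %d compounds (%s set)\n",
              x$reference_ed, x$n, x$partition))
  invisible(x)
}

#' Assess compounds against the applicability domain
#'
#' For every compound: the Euclidean distance to its winning neuron, the
#' predicted class scores, an `in_domain` flag (`ed <= reference_ed`,
#' boundary inclusive), and an `uncertain` flag set when any class score
#' lies within `uncertainty_band` of the 0.5 membership threshold. With
#' labels supplied, per-class residuals `y_target - y_predicted` are added
#' — the coordinates of the classic ED-versus-residual domain plots.
#'
#' @param model a fitted [cpann()] model.
#' @param reference an [build_reference()] result.
#' @param x compounds to assess.
#' @param labels optional true class labels (or taken from a `class`
#'   column).
#' @param uncertainty_band half-width of the uncertainty zone around 0.5,
#'   in (0, 0.5); default 0.1.
#' @param scaled TRUE when `x` is already autoscaled.
#' @return a data frame of class `"ad_assessment"`: `id`, `ed`,
#'   `score_<class>` columns, predicted `class`, `in_domain`, `uncertain`,
#'   and `residual_<class>` columns when labels are available.
#' @export
assess_domain <- function(model, reference, x, labels = NULL,
                          uncertainty_band = 0.1, scaled = FALSE) {
  stopifnot(inherits(reference, "ad_reference"))
  if (uncertainty_band <= 0 || uncertainty_band >= 0.5)
    stop_("uncertainty_band must be in (0, 0.5)")
  if (is.null(labels) && is.data.frame(x) && "class" %in% names(x))
    labels <- class_labels(x)
  pred <- predict(model, x, scaled = scaled)
  score_cols <- paste0("score_", model$classes)
  scores <- as.matrix(pred[score_cols])
  out <- data.frame(id = rownames(pred) %||% as.character(seq_len(nrow(pred))),
                    ed = pred$ed, stringsAsFactors = FALSE)
  out[score_cols] <- pred[score_cols]
  out$class <- pred$class
  out$in_domain <- pred$ed <= reference$reference_ed
  out$uncertain <- apply(abs(scores - 0.5) <= uncertainty_band, 1L, any)
  if (!is.null(labels)) {
    y <- factor(as.character(labels), levels = model$classes)
    resid <- one_hot(y) - scores
    colnames(resid) <- paste0("residual_", model$classes)
    out <- cbind(out, resid)
  }
  attr(out, "reference") <- reference
  class(out) <- c("ad_assessment", class(out))
  out
}

#' Write an AD assessment as TSV
#'
#' One row per compound with distance, scores, flags and residuals — the
#' columns needed to regenerate ED-versus-residual domain plots.
#'
#' @param assessment an [assess_domain()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_ad_tsv <- function(assessment, file) {
  utils::write.table(as.data.frame(assessment), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Plot an applicability-domain assessment
#'
#' Euclidean distance to the winning neuron against the residual
#' `y_target - y_predicted` for one class, with the reference boundary as a
#' vertical line and the zero-residual axis marked — the standard domain
#' diagnostic.
#'
#' @param x an [assess_domain()] result containing residual columns.
#' @param class class whose residuals to plot (default: first model class
#'   present).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ad_assessment <- function(x, class = NULL, ...) {
  resid_cols <- grep("^residual_", names(x), value = TRUE)
  if (length(resid_cols) == 0L)
    stop_("assessment has no residuals; supply labels to assess_domain()")
  cls <- class %||% sub("^residual_", "", resid_cols[1L])
  col <- paste0("residual_", cls)
  if (!col %in% names(x)) stop_("no residuals for class '%s'", cls)
  graphics::plot(x$ed, x[[col]], xlab = "ED to central neuron",
                 ylab = sprintf("residual (%s)", cls),
                 pch = ifelse(x$in_domain, 1L, 4L), ...)
  graphics::abline(h = 0, lty = 3L)
  ref <- attr(x, "reference")
  if (!is.null(ref)) graphics::abline(v = ref$reference_ed, lty = 2L)
  invisible(x)
}
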