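## Descriptor-matrix preprocessing: autoscaling, low-variance filter,
## pairwise-correlation filter and SOM-based descriptor reduction. The
## canonical order in the modelling pipeline is
##   variance filter -> correlation filter -> autoscale -> SOM reduction,
## and every removed descriptor is accounted for in a reduction report.

new_reduction_report <- function(descriptor = character(),
                                 stage = character(),
                                 reason = character(),
                                 partner = character()) {
  data.frame(descriptor = descriptor, stage = stage, reason = reason,
             partner = partner, stringsAsFactors = FALSE)
}

#' Autoscale a descriptor matrix
#'
#' Standardizes every descriptor to zero mean and unit standard deviation,
#' `(x - mean(x)) / sd(x)`, with the sample SD (n - 1 denominator). The
#' centring/scaling parameters are returned so the same transform can be
#' re-applied to test, validation or new compounds; passing a previous
#' `params` applies that stored transform instead of refitting.
#'
#' @param x numeric matrix (compounds x descriptors) or a labelled
#'   descriptor data frame.
#' @param params optional `"scaling_params"` from an earlier call; when
#'   supplied, its means and SDs are used unchanged.
#' @return list with `x`, the scaled matrix, and `params`, an object of
#'   class `"scaling_params"` (fields `mean` and `sd`, named by descriptor).
#' @examples
#' sc <- autoscale(cbind(a = c(1, 2, 3), b = c(10, 20, 60)))
#' colMeans(sc$x); apply(sc$x, 2, sd)
#' @export
autoscale <- function(x, params = NULL) {
  x <- as_matrix(x)
  if (is.null(params)) {
    mu <- colMeans(x)
    s <- apply(x, 2L, sd)
    bad <- which(s == 0 | !is.finite(s))
    if (length(bad))
      stop_("constant descriptor: %s", paste(colnames(x)[bad], collapse = ", "))
    params <- structure(list(mean = mu, sd = s, descriptors = colnames(x)),
                        class = "scaling_params")
  } else {
    stopifnot(inherits(params, "scaling_params"))
    miss <- setdiff(params$descriptors, colnames(x))
    if (length(miss))
      stop_("missing descriptor: %s", paste(miss, collapse = ", "))
    x <- x[, params$descriptors, drop = FALSE]
  }
  scaled <- sweep(sweep(x, 2L, params$mean, "-"), 2L, params$sd, "/")
  list(x = scaled, params = params)
}

#' @export
print.scaling_params <- function(x, ...) {
  cat(sprintf("autoscaling parameters for %d descriptors\n",
              length(x$mean)))
  invisible(x)
}

as_matrix <- function(x) {
  if (is.data.frame(x)) {
    if ("class" %in% names(x) || !is.numeric(x[[1L]])) return(descriptor_matrix(x))
    x <- as.matrix(x)
  }
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(colnames(x))) colnames(x) <- sprintf("d%03d", seq_len(ncol(x)))
  x
}

#' Remove near-constant descriptors
#'
#' Drops every descriptor whose sample standard deviation falls below
#' `sd_threshold` (default 1e-4), the conventional cut for constant or
#' numerically constant Dragon descriptors.
#'
#' @param x descriptor matrix or labelled descriptor data frame.
#' @param sd_threshold positive SD cutoff; columns with `sd < sd_threshold`
#'   are removed.
#' @return list with `x` (retained columns) and `report`, a data frame of
#'   removals (descriptor, stage, reason, partner).
#' @export
filter_low_variance <- function(x, sd_threshold = 1e-4) {
  if (sd_threshold <= 0) stop_("sd_threshold must be positive")
  x <- as_matrix(x)
  s <- apply(x, 2L, sd)
  drop <- which(s < sd_threshold)
  if (length(drop) == ncol(x)) stop_("all descriptors fall below the SD threshold")
  report <- new_reduction_report(
    descriptor = colnames(x)[drop],
    stage = rep("variance", length(drop)),
    reason = ifelse(s[drop] == 0, "constant", "low-SD"),
    partner = rep(NA_character_, length(drop)))
  list(x = x[, setdiff(seq_len(ncol(x)), drop), drop = FALSE], report = report)
}

#' Remove pairwise-correlated descriptors
#'
#' Scans descriptors in column order; whenever a descriptor has absolute
#' Pearson correlation at or above `r_threshold` with an already retained
#' one, the later descriptor is removed and the retained partner recorded.
#' The retained set therefore contains no pair with `|r| >= r_threshold`,
#' and re-applying the filter removes nothing.
#'
#' @param x descriptor matrix or labelled descriptor data frame.
#' @param r_threshold absolute-correlation cutoff in (0, 1]; default 0.95.
#' @return list with `x` (retained columns) and `report` (removals, with the
#'   surviving partner each removal correlated with).
#' @export
filter_correlated <- function(x, r_threshold = 0.95) {
  if (r_threshold <= 0 || r_threshold > 1) stop_("r_threshold must be in (0, 1]")
  x <- as_matrix(x)
  p <- ncol(x)
  r <- abs(suppressWarnings(cor(x)))
  r[is.na(r)] <- 0
  keep <- logical(p)
  partner <- rep(NA_character_, p)
  for (j in seq_len(p)) {
    hits <- which(keep & r[j, ] >= r_threshold)
    if (length(hits) == 0L) keep[j] <- TRUE
    else partner[j] <- colnames(x)[hits[1L]]
  }
  drop <- which(!keep)
  report <- new_reduction_report(
    descriptor = colnames(x)[drop],
    stage = rep("correlation", length(drop)),
    reason = rep("correlated-with", length(drop)),
    partner = partner[drop])
  list(x = x[, keep, drop = FALSE], report = report)
}

#' SOM-based descriptor reduction
#'
#' Maps the descriptors themselves (rows of the transposed, autoscaled
#' matrix) onto a small Kohonen grid, then keeps from each occupied neuron
#' the descriptor closest to and the descriptor farthest from that neuron's
#' weight vector. Descriptors sharing a neuron are near-duplicates in
#' compound space, so this caps the retained count at twice the number of
#' occupied neurons (a 7 x 7 grid keeps at most 98 descriptors).
#'
#' @param x autoscaled descriptor matrix.
#' @param grid_rows,grid_cols grid dimensions, default 7 x 7.
#' @param config a [som_config()] for the reduction map; its `rows`/`cols`
#'   are overridden by `grid_rows`/`grid_cols`.
#' @return list with `x` (retained columns), `report` (removals with stage
#'   `"som"`), and `som`, the trained `"som_grid"` over descriptors.
#' @export
som_reduce_descriptors <- function(x, grid_rows = 7L, grid_cols = 7L,
                                   config = som_config(rows = grid_rows,
                                                       cols = grid_cols)) {
  x <- as_matrix(x)
  if (ncol(x) < 1L) stop_("at least one descriptor is required")
  config$rows <- as.integer(grid_rows)
  config$cols <- as.integer(grid_cols)
  xt <- t(x)                                  # descriptors become objects
  som <- train_som(xt, config)
  mp <- map_winners_core(xt, som$weights)
  win <- mp$winner
  keep <- logical(ncol(x))
  partner <- rep(NA_character_, ncol(x))
  for (j in unique(win)) {
    members <- which(win == j)
    d <- mp$distance[members]
    sel <- unique(c(members[which.min(d)], members[which.max(d)]))
    keep[sel] <- TRUE
    partner[members] <- colnames(x)[members[which.min(d)]]
  }
  drop <- which(!keep)
  report <- new_reduction_report(
    descriptor = colnames(x)[drop],
    stage = rep("som", length(drop)),
    reason = rep("not-selected-by-SOM", length(drop)),
    partner = partner[drop])
  list(x = x[, keep, drop = FALSE], report = report, som = som)
}

#' Full descriptor preprocessing
#'
#' Applies the canonical reduction chain: low-variance filter, pairwise
#' correlation filter, autoscaling, and (optionally) SOM-based descriptor
#' reduction. The scaling statistics can be fitted on all supplied compounds
#' (`scale_on = "all"`, the historical convention of normalizing the entire
#' dataset before splitting) or on a training subset only
#' (`scale_on = "train"`, leak-free for new-compound prediction).
#'
#' @param x descriptor matrix or labelled descriptor data frame.
#' @param sd_threshold,r_threshold filter cutoffs, see
#'   [filter_low_variance()] and [filter_correlated()].
#' @param som_grid `NULL` to skip SOM reduction, or `c(rows, cols)`
#'   (default `c(7, 7)`).
#' @param som_config SOM parameters for the reduction map.
#' @param scale_on `"all"` or `"train"`; with `"train"`, `train_ids` gives
#'   the compounds whose statistics define the transform.
#' @param train_ids compound IDs (rownames) used when `scale_on = "train"`.
#' @return list with `x` (reduced, autoscaled matrix), `params`
#'   (`"scaling_params"` restricted to the retained descriptors), `report`
#'   (all removals across stages), and `retained` (descriptor names).
#' @export
preprocess_descriptors <- function(x, sd_threshold = 1e-4, r_threshold = 0.95,
                                   som_grid = c(7L, 7L),
                                   som_config = NULL,
                                   scale_on = c("all", "train"),
                                   train_ids = NULL) {
  scale_on <- match.arg(scale_on)
  x <- as_matrix(x)
  v <- filter_low_variance(x, sd_threshold)
  cf <- filter_correlated(v$x, r_threshold)
  fit_rows <- if (scale_on == "train") {
    if (is.null(train_ids)) stop_("train_ids required when scale_on = 'train'")
    rownames(cf$x) %in% train_ids
  } else rep(TRUE, nrow(cf$x))
  sc <- autoscale(cf$x[fit_rows, , drop = FALSE])
  scaled <- autoscale(cf$x, params = sc$params)$x
  report <- rbind(v$report, cf$report)
  som <- NULL
  if (!is.null(som_grid)) {
    cfg <- if (is.null(som_config))
      som_config(rows = som_grid[1L], cols = som_grid[2L]) else som_config
    red <- som_reduce_descriptors(scaled, som_grid[1L], som_grid[2L], cfg)
    scaled <- red$x
    report <- rbind(report, red$report)
    som <- red$som
  }
  retained <- colnames(scaled)
  params <- structure(list(mean = sc$params$mean[retained],
                           sd = sc$params$sd[retained],
                           descriptors = retained),
                      class = "scaling_params")
  list(x = scaled, params = params, report = report, retained = retained,
       som = som)
}

#' Write a reduction report as TSV
#'
#' @param report a reduction-report data frame (`descriptor`, `stage`,
#'   `reason`, `partner`).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_reduction_report <- function(report, file) {
  utils::write.table(report, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
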