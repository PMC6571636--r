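## End-to-end modelling workflow: SOM-based split -> descriptor
## preprocessing -> GA descriptor selection -> final CP-ANN fit ->
## evaluation on TR/TE/V -> applicability-domain assessment. The
## validation partition is fixed before any model construction and enters
## no training, selection or tuning stage. Every stage's seed derives
## deterministically from the master seed, so a configuration reruns to
## identical artifacts.

#' Pipeline configuration
#'
#' Bundles every stage's parameters with the published defaults: the
#' 20 x 20 / 100-epoch / 0.5-0.01 splitting map with fractions
#' 0.711/0.136/0.153; SD cutoff 1e-4 and |r| cutoff 0.95 with a 7 x 7
#' reduction map; the 95/150/20/0.02 GA with 0.6/0.001 learning rates; and
#' the 43 x 43 / 600-epoch final network. Every stage's seed is derived
#' from `seed`.
#'
#' @param split_som [som_config()] for the splitting map (its `seed` is
#'   overridden by the derived stage seed).
#' @param fractions TR/TE/V fractions summing to 1.
#' @param sd_threshold,r_threshold,som_grid preprocessing parameters, see
#'   [preprocess_descriptors()].
#' @param scale_on `"all"` (normalize the entire dataset before splitting,
#'   the historical convention and default) or `"train"` (fit scaling on TR
#'   only).
#' @param ga [ga_config()] for descriptor selection, or `NULL` to skip
#'   selection and keep all preprocessed descriptors.
#' @param final_som [som_config()] for the final CP-ANN.
#' @param uncertainty_band AD uncertainty half-width, see
#'   [assess_domain()].
#' @param seed master seed.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(split_som = som_config(20L, 20L, 100L, 0.5, 0.01),
                            fractions = c(0.711, 0.136, 0.153),
                            sd_threshold = 1e-4, r_threshold = 0.95,
                            som_grid = c(7L, 7L),
                            scale_on = c("all", "train"),
                            ga = ga_config(),
                            final_som = som_config(43L, 43L, 600L, 0.6, 0.001),
                            uncertainty_band = 0.1,
                            seed = 1L) {
  scale_on <- match.arg(scale_on)
  structure(list(split_som = split_som, fractions = fractions,
                 sd_threshold = sd_threshold, r_threshold = r_threshold,
                 som_grid = som_grid, scale_on = scale_on, ga = ga,
                 final_som = final_som, uncertainty_band = uncertainty_band,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full classification workflow
#'
#' Executes, in order: SOM-based TR/TE/V split on the full descriptor
#' matrix; variance, correlation and SOM descriptor reduction with
#' autoscaling; GA descriptor selection driven by `MCC_TR * MCC_TE`
#' fitness; a final CP-ANN fit on TR with the selected descriptors;
#' evaluation reports on TR, TE and the held-out V set; and an
#' applicability-domain assessment with the TE set as reference. The V
#' partition takes no part in preprocessing decisions, GA fitness or
#' training — it is scored exactly once at the end.
#'
#' @param data labelled descriptor data frame (or path to such a CSV).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every artifact (split,
#'   reduction report, GA history, model, reports, AD table, manifest) is
#'   written there.
#' @return an object of class `"cpann_pipeline"`: `split`, `reduction`,
#'   `selection`, `model`, `reports` (TR/TE/V `"class_report"`s),
#'   `predictions` (per-partition predicted-vs-true tables), `ad`
#'   (assessment of all compounds), `reference`, `config`.
#' @examples
#' \donttest{
#' d <- generate_dataset(synthetic_spec(n_per_class = c(40, 30, 35),
#'                                      n_noise = 10, seed = 11))
#' cfg <- pipeline_config(
#'   split_som = som_config(6, 6, 30, 0.5, 0.01),
#'   ga = NULL,
#'   final_som = som_config(10, 10, 100, 0.6, 0.001),
#'   seed = 11)
#' run <- run_pipeline(d, cfg)
#' run$reports$V$NER
#' }
#' @export
run_pipeline <- function(data, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(data)) data <- read_descriptor_csv(data)
  y <- class_labels(data)
  if (nlevels(droplevels(y)) < 2L) stop_("at least two classes are required")
  x <- descriptor_matrix(data)

  stage <- "split"
  result <- tryCatch({
    split_cfg <- config$split_som
    split_cfg$seed <- derive_seed(config$seed, 1L)
    split <- som_split(x, config = split_cfg, fractions = config$fractions)
    tr_ids <- names(split$partition)[split$partition == "TR"]
    te_ids <- names(split$partition)[split$partition == "TE"]
    v_ids <- names(split$partition)[split$partition == "V"]

    stage <- "preprocess"
    pre_cfg <- som_config(config$som_grid[1L], config$som_grid[2L],
                          100L, 0.5, 0.01,
                          seed = derive_seed(config$seed, 2L))
    pre <- preprocess_descriptors(
      x, sd_threshold = config$sd_threshold,
      r_threshold = config$r_threshold, som_grid = config$som_grid,
      som_config = pre_cfg, scale_on = config$scale_on,
      train_ids = tr_ids)
    xs <- pre$x

    stage <- "ga_selection"
    selection <- NULL
    selected <- colnames(xs)
    if (!is.null(config$ga)) {
      ga_cfg <- config$ga
      ga_cfg$seed <- derive_seed(config$seed, 3L)
      selection <- run_ga(xs[tr_ids, , drop = FALSE], y[tr_ids],
                          xs[te_ids, , drop = FALSE], y[te_ids],
                          config = ga_cfg)
      selected <- selection$descriptors
    }

    stage <- "train"
    fin_cfg <- config$final_som
    fin_cfg$seed <- derive_seed(config$seed, 4L)
    model <- cpann(xs[tr_ids, selected, drop = FALSE], y[tr_ids],
                   config = fin_cfg, scaling = FALSE)
    ## store the global autoscaling so the model predicts from raw values
    model$scaling <- structure(list(mean = pre$params$mean[selected],
                                    sd = pre$params$sd[selected],
                                    descriptors = selected),
                               class = "scaling_params")

    stage <- "evaluate"
    sets <- list(TR = tr_ids, TE = te_ids, V = v_ids)
    predictions <- lapply(sets, function(ids)
      predict_batch(model, xs[ids, selected, drop = FALSE],
                    labels = y[ids], scaled = TRUE))
    reports <- lapply(predictions, function(p)
      global_report(p$true, p$class, classes = model$classes))

    stage <- "applicability_domain"
    reference <- build_reference(model, xs[te_ids, selected, drop = FALSE],
                                 partition = "TE", scaled = TRUE)
    ad <- assess_domain(model, reference, xs[, selected, drop = FALSE],
                        labels = y, uncertainty_band = config$uncertainty_band,
                        scaled = TRUE)

    structure(list(split = split, reduction = pre$report,
                   scaling = pre$params, selection = selection,
                   selected = selected, model = model,
                   predictions = predictions, reports = reports,
                   reference = reference, ad = ad, config = config),
              class = "cpann_pipeline")
  }, error = function(e) {
    stop_("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })

  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

#' @export
print.cpann_pipeline <- function(x, ...) {
  cat("CP-ANN classification pipeline\n")
  print(x$split)
  cat(sprintf("descriptors: %d retained after preprocessing%s\n",
              length(x$selected),
              if (is.null(x$selection)) "" else
                sprintf(", %d GA-selected", sum(x$selection$best))))
  for (s in names(x$reports))
    cat(sprintf("%s: NER %.2f%%  AvPr %.2f%%\n",
                s, x$reports[[s]]$NER, x$reports[[s]]$AvPr))
  cat(sprintf("AD reference (max TE ED): %.4f\n", x$reference$reference_ed))
  invisible(x)
}

write_pipeline_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_split_tsv(run$split, p("split.tsv"))
  write_reduction_report(run$reduction, p("reduction_report.tsv"))
  if (!is.null(run$selection)) {
    write_ga_history(run$selection, p("ga_history.tsv"))
    writeLines(run$selection$descriptors, p("selected_descriptors.txt"))
  }
  write_cpann_json(run$model, p("model.json"))
  for (s in names(run$reports))
    write_report_json(run$reports[[s]], p(sprintf("report_%s.json", s)))
  for (s in names(run$predictions))
    utils::write.table(run$predictions[[s]],
                       p(sprintf("predictions_%s.tsv", s)),
                       sep = "\t", row.names = TRUE, quote = FALSE)
  write_ad_tsv(run$ad, p("ad_assessment.tsv"))
  manifest <- list(seed = run$config$seed,
                   fractions = run$config$fractions,
                   scale_on = run$config$scale_on,
                   n_selected = length(run$selected),
                   selected = run$selected,
                   reference_ed = run$reference$reference_ed)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
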