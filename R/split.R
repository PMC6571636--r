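## Structure-driven training/test/validation split: compounds are clustered
## on a Kohonen top-map and each occupied neuron contributes to every
## partition via a weighted round-robin, so all partitions cover the whole
## descriptor space. The validation set is selected here, before any model
## construction, and never revisited.

#' Split a dataset from Kohonen top-map clusters
#'
#' Trains a SOM on the full (autoscaled) descriptor matrix and allocates
#' compounds to training (TR), test (TE) and validation (V) partitions
#' neuron by neuron: within each occupied neuron compounds are taken in a
#' seeded random order; the first compound of every neuron goes to TR (so
#' every cluster is represented in training), and each subsequent compound
#' joins the partition currently furthest below its target fraction
#' (weighted round-robin with TR filled first on ties). Global partition
#' sizes track the requested fractions to within a couple of compounds.
#'
#' @param data labelled descriptor data frame, or a numeric matrix with
#'   compound IDs as rownames.
#' @param config a [som_config()]; the defaults (20 x 20 grid, 100 epochs,
#'   learning rate 0.5 -> 0.01) are the splitting-map convention.
#' @param fractions length-3 numeric `(f_tr, f_te, f_v)` summing to 1. The
#'   default `(0.711, 0.136, 0.153)` reproduces a 1786/341/385 split of
#'   2512 compounds.
#' @param autoscale_first autoscale the matrix before mapping (default
#'   TRUE); disable when the input is already scaled.
#' @return an object of class `"som_split"`: `partition`, a factor
#'   (levels TR/TE/V) named by compound ID; `top_map`; `som`; `fractions`;
#'   `config`.
#' @examples
#' d <- generate_dataset(synthetic_spec(n_per_class = c(40, 30, 30), seed = 3))
#' sp <- som_split(d, som_config(rows = 6, cols = 6, epochs = 20, seed = 3))
#' table(sp$partition)
#' @export
som_split <- function(data, config = som_config(),
                      fractions = c(0.711, 0.136, 0.153),
                      autoscale_first = TRUE) {
  if (length(fractions) != 3L || any(fractions <= 0))
    stop_("fractions must be three positive numbers")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop_("fractions must sum to 1 (got %.4f)", sum(fractions))
  x <- as_matrix(data)
  if (nrow(x) < 3L) stop_("at least three compounds are required")
  if (autoscale_first) {
    keep <- apply(x, 2L, sd) > 0
    x <- autoscale(x[, keep, drop = FALSE])$x
  }
  som <- train_som(x, config)
  tm <- build_top_map(som, x)

  parts <- c("TR", "TE", "V")
  assigned <- numeric(3L)                 # running partition sizes
  names(assigned) <- parts
  partition <- character(nrow(x))
  total <- 0L
  with_seed(derive_seed(config$seed, 97L), {
    for (j in sort(unique(tm$assignments$neuron))) {
      members <- which(tm$assignments$neuron == j)
      members <- members[sample.int(length(members))]
      for (i in seq_along(members)) {
        total <- total + 1L
        pick <- if (i == 1L) 1L else {
          deficit <- fractions * total - assigned
          which.max(deficit)              # ties resolve TR, TE, V in order
        }
        partition[members[i]] <- parts[pick]
        assigned[pick] <- assigned[pick] + 1L
      }
    }
  })
  partition <- factor(partition, levels = parts)
  names(partition) <- rownames(x)
  structure(list(partition = partition, top_map = tm, som = som,
                 fractions = fractions, config = config),
            class = "som_split")
}

#' @export
print.som_split <- function(x, ...) {
  n <- length(x$partition)
  cnt <- table(x$partition)
  cat(sprintf("SOM-based split of %d compounds: TR %d / TE %d / V %d\n",
              n, cnt[["TR"]], cnt[["TE"]], cnt[["V"]]))
  invisible(x)
}

#' Read or write a split as TSV
#'
#' Two columns, `compound_id` and `partition` (TR/TE/V); reading returns a
#' named factor usable wherever a [som_split()] partition is, e.g. to
#' reproduce an externally supplied split.
#'
#' @param split a `"som_split"` or a named partition factor.
#' @param file path to a TSV file.
#' @return `write_split_tsv()` returns `file` invisibly; `read_split_tsv()`
#'   the named factor.
#' @export
write_split_tsv <- function(split, file) {
  p <- if (inherits(split, "som_split")) split$partition else split
  utils::write.table(
    data.frame(compound_id = names(p), partition = as.character(p)),
    file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_split_tsv
#' @export
read_split_tsv <- function(file) {
  d <- utils::read.table(file, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  p <- factor(d$partition, levels = c("TR", "TE", "V"))
  names(p) <- d$compound_id
  p
}
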