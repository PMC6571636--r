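#' Specify a synthetic three-class descriptor dataset
#'
#' Describes a compounds-by-descriptors table with the statistical structure
#' typical of curated 2D-descriptor QSAR matrices: a handful of descriptors
#' that separate the classes, a majority of pure-noise descriptors, blocks of
#' near-duplicate (highly correlated) descriptors, and constant columns.
#' Defaults mirror a P-glycoprotein ligand dataset with class sizes
#' 1178 inhibitors / 477 substrates / 857 non-active compounds.
#'
#' @param n_per_class integer vector of length 3: compounds per class, in the
#'   order inhibitor, substrate, non_active.
#' @param n_informative number of class-separating descriptors.
#' @param n_noise number of standard-normal noise descriptors.
#' @param n_redundant number of near-duplicates of informative descriptors
#'   (absolute Pearson correlation with their source >= 0.95).
#' @param n_constant number of constant descriptors (SD below 1e-4).
#' @param separation distance between neighbouring class-conditional means on
#'   each informative descriptor, in within-class standard-deviation units.
#' @param seed integer seed; the whole table is reproducible from it.
#' @return an object of class `"synthetic_spec"`.
#' @seealso [generate_dataset()]
#' @export
synthetic_spec <- function(n_per_class = c(1178L, 477L, 857L),
                           n_informative = 8L, n_noise = 40L,
                           n_redundant = 6L, n_constant = 3L,
                           separation = 3, seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) != 3L || any(n_per_class < 1L))
    stop_("n_per_class must be three positive integers")
  counts <- c(n_informative = n_informative, n_noise = n_noise,
              n_redundant = n_redundant, n_constant = n_constant)
  if (any(counts < 0L)) stop_("descriptor counts must be non-negative")
  if (separation < 0) stop_("separation must be non-negative")
  if (separation > 0 && n_informative < 1L)
    stop_("at least one informative descriptor is required when separation > 0")
  if (n_redundant > 0L && n_informative < 1L)
    stop_("redundant descriptors need an informative source column")
  structure(list(n_per_class = n_per_class,
                 n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise),
                 n_redundant = as.integer(n_redundant),
                 n_constant = as.integer(n_constant),
                 separation = separation, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a labelled synthetic descriptor table
#'
#' Draws a three-class descriptor table according to a [synthetic_spec()].
#' Class-conditional distributions are multivariate normal with identity
#' within-class covariance; on each informative descriptor the three class
#' means are a random permutation of `(-separation, 0, +separation)`, so
#' neighbouring class means differ by `separation` within-class SDs.
#' Redundant descriptors are affine copies of informative ones plus Gaussian
#' noise with SD 0.2 of the source's, giving |Pearson r| about 0.98; half of
#' them are sign-flipped. Constant descriptors hold a single repeated value.
#' Column order is shuffled, but descriptor names record each column's role
#' (`inf*`, `noise*`, `red*_inf*`, `const*`).
#'
#' @param spec a [synthetic_spec()].
#' @return a data frame: `compound_id`, one numeric column per descriptor,
#'   and a `class` factor with levels inhibitor, substrate, non_active.
#' @examples
#' d <- generate_dataset(synthetic_spec(n_per_class = c(30, 20, 25), seed = 7))
#' table(d$class)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- sum(spec$n_per_class)
    classes <- c("inhibitor", "substrate", "non_active")
    y <- factor(rep(classes, times = spec$n_per_class), levels = classes)
    cls <- as.integer(y)

    blocks <- list()
    if (spec$n_informative > 0L) {
      inf <- matrix(rnorm(n * spec$n_informative), n, spec$n_informative)
      for (j in seq_len(spec$n_informative)) {
        offsets <- sample(c(-spec$separation, 0, spec$separation))
        inf[, j] <- inf[, j] + offsets[cls]
      }
      colnames(inf) <- sprintf("inf%02d", seq_len(spec$n_informative))
      blocks$inf <- inf
    }
    if (spec$n_noise > 0L) {
      noi <- matrix(rnorm(n * spec$n_noise), n, spec$n_noise)
      colnames(noi) <- sprintf("noise%02d", seq_len(spec$n_noise))
      blocks$noise <- noi
    }
    if (spec$n_redundant > 0L) {
      src <- rep_len(seq_len(spec$n_informative), spec$n_redundant)
      red <- sapply(seq_len(spec$n_redundant), function(j) {
        s <- blocks$inf[, src[j]]
        sgn <- if (j %% 2L == 0L) -1 else 1
        sgn * (1.5 * s + 0.3) + rnorm(n, sd = 0.2 * sd(s))
      })
      red <- matrix(red, n, spec$n_redundant)
      colnames(red) <- sprintf("red%02d_inf%02d", seq_len(spec$n_redundant), src)
      blocks$red <- red
    }
    if (spec$n_constant > 0L) {
      const <- matrix(rep(round(runif(spec$n_constant), 2), each = n),
                      n, spec$n_constant)
      colnames(const) <- sprintf("const%02d", seq_len(spec$n_constant))
      blocks$const <- const
    }

    x <- do.call(cbind, unname(blocks))
    x <- x[, sample(ncol(x)), drop = FALSE]
    out <- data.frame(compound_id = sprintf("cmpd%05d", seq_len(n)),
                      x, class = y,
                      stringsAsFactors = FALSE, check.names = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Printed validation-set confusion matrices for the P-gp CP-ANN model
#'
#' The published external-validation confusion matrices (385 compounds) of
#' the three-class P-glycoprotein CP-ANN classifier, as one-vs-rest counts:
#' inhibitors TP 136 / FP 35 / FN 43 / TN 171, substrates
#' TP 47 / FP 29 / FN 25 / TN 284, non-active TP 93 / FP 42 / FN 41 / TN 209.
#' Used as fixtures for the evaluation module; each matrix sums to 385.
#'
#' @return named list of three [confusion_matrix()] objects
#'   (`inhibitor`, `substrate`, `non_active`).
#' @seealso [report_from_confusions()]
#' @export
validation_confusion_fixtures <- function() {
  list(
    inhibitor  = new_confusion(136L, 35L, 43L, 171L, positive = "inhibitor"),
    substrate  = new_confusion(47L, 29L, 25L, 284L, positive = "substrate"),
    non_active = new_confusion(93L, 42L, 41L, 209L, positive = "non_active")
  )
}

#' Read or write a labelled descriptor table as CSV
#'
#' The on-disk layout is the package-wide convention: first column
#' `compound_id`, last column `class`, all columns in between numeric
#' descriptors with header names.
#'
#' @param file path to a CSV file.
#' @param data a labelled descriptor data frame.
#' @return `read_descriptor_csv()` returns the data frame with `class` as a
#'   factor; `write_descriptor_csv()` returns `file` invisibly.
#' @export
read_descriptor_csv <- function(file) {
  d <- read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 3L || names(d)[ncol(d)] != "class")
    stop_("descriptor CSV must end with a 'class' column")
  canonical <- c("inhibitor", "substrate", "non_active")
  d$class <- if (all(d$class %in% canonical))
    factor(d$class, levels = canonical) else factor(d$class)
  d
}

#' @rdname read_descriptor_csv
#' @export
write_descriptor_csv <- function(data, file) {
  stopifnot(is.data.frame(data))
  write.csv(data, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
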