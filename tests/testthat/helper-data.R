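# Shared fixtures, all generated in code.

# small three-class table with every descriptor role present
small_dataset <- function(seed = 7L, n = c(60L, 40L, 50L), separation = 3) {
  generate_dataset(synthetic_spec(
    n_per_class = n, n_informative = 8L, n_noise = 10L,
    n_redundant = 4L, n_constant = 3L, separation = separation, seed = seed))
}

# clean autoscaled matrix + labels (no constant/redundant columns)
clean_xy <- function(seed = 7L, n = c(60L, 40L, 50L), separation = 3,
                     n_informative = 8L, n_noise = 10L) {
  d <- generate_dataset(synthetic_spec(
    n_per_class = n, n_informative = n_informative, n_noise = n_noise,
    n_redundant = 0L, n_constant = 0L, separation = separation, seed = seed))
  list(x = autoscale(descriptor_matrix(d))$x, y = class_labels(d))
}

# brute-force one-vs-rest confusion counts, independent of the package path
tally_confusion <- function(y_true, y_pred, positive) {
  counts <- c(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
  for (i in seq_along(y_true)) {
    t_pos <- y_true[i] == positive
    p_pos <- y_pred[i] == positive
    if (t_pos && p_pos) counts["TP"] <- counts["TP"] + 1L
    else if (!t_pos && p_pos) counts["FP"] <- counts["FP"] + 1L
    else if (t_pos && !p_pos) counts["FN"] <- counts["FN"] + 1L
    else counts["TN"] <- counts["TN"] + 1L
  }
  counts
}

# brute-force winner scan over all neurons
scan_winner <- function(weights, x) {
  d <- apply(weights, 1L, function(w) sqrt(sum((x - w)^2)))
  list(index = which.min(d), distance = min(d))
}

# tiny trained model for prediction-surface tests
tiny_model <- function(seed = 3L) {
  xy <- clean_xy(seed = seed, n = c(25L, 20L, 20L), n_noise = 4L)
  cpann(xy$x, xy$y, scaling = FALSE,
        config = som_config(7, 7, 60, a_max = 0.6, a_min = 0.001,
                            seed = seed))
}
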