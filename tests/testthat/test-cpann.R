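test_that("a single compound on a 1x1 grid converges to its one-hot target", {
  x <- matrix(c(0.2, 0.8), 1, 2, dimnames = list("c1", c("a", "b")))
  y <- factor("inhibitor", levels = c("inhibitor", "substrate"))
  fit <- cpann(x, y, scaling = FALSE,
               config = som_config(1, 1, 400, a_max = 0.9, a_min = 0.5,
                                   seed = 1))
  expect_equal(as.vector(fit$output_weights),
               c(1, 0), tolerance = 1e-3)
})

test_that("identical targets pull every neuron's output weights toward them", {
  set.seed(2)
  x <- matrix(runif(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- factor(rep("substrate", 30), levels = c("inhibitor", "substrate"))
  fit <- cpann(x, y, scaling = FALSE,
               config = som_config(3, 3, 300, a_max = 0.8, a_min = 0.1,
                                   seed = 2))
  expect_true(all(fit$output_weights[, "substrate"] > 0.9))
  expect_true(all(fit$output_weights[, "inhibitor"] < 0.1))
})

test_that("output weights stay within [0, 1] throughout training", {
  fit <- tiny_model(seed = 4)
  expect_true(all(fit$output_weights >= 0 & fit$output_weights <= 1))
  # one-to-one layer correspondence: one output vector per Kohonen neuron
  expect_equal(nrow(fit$output_weights), nrow(fit$kohonen$weights))
  expect_equal(ncol(fit$output_weights), length(fit$classes))
})

test_that("separable three-class data trains to NER >= 0.95 on TR", {
  xy <- clean_xy(seed = 5, n = c(60L, 40L, 50L), separation = 3)
  fit <- cpann(xy$x, xy$y, scaling = FALSE,
               config = som_config(12, 12, 200, a_max = 0.6, a_min = 0.001,
                                   seed = 5))
  p <- predict(fit, xy$x, scaled = TRUE)
  expect_gte(global_report(xy$y, p$class)$NER, 95)
})

test_that("prediction applies the 0.5 threshold with argmax fallback", {
  fit <- tiny_model(seed = 6)
  # rebuild predictions by hand from the winner's output weights
  xy <- clean_xy(seed = 6, n = c(10L, 8L, 9L), n_noise = 4L)
  p <- predict(fit, xy$x, scaled = TRUE)
  scores <- as.matrix(p[paste0("score_", fit$classes)])
  expect_equal(as.character(p$class),
               fit$classes[max.col(scores, ties.method = "first")])
  expect_equal(p$n_above, as.integer(rowSums(scores > 0.5)))
  expect_true(all(p$flag[p$n_above == 0] == "below-threshold"))
  expect_true(all(p$flag[p$n_above == 1] == "ok"))
  expect_true(all(p$flag[p$n_above > 1] == "multiple-above"))
})

test_that("compounds in pure-class neurons are assigned their true class", {
  xy <- clean_xy(seed = 7, n = c(40L, 30L, 35L), separation = 4)
  fit <- cpann(xy$x, xy$y, scaling = FALSE,
               config = som_config(10, 10, 150, a_max = 0.6, a_min = 0.001,
                                   seed = 7))
  p <- predict(fit, xy$x, scaled = TRUE)
  tm <- fit$top_map
  neuron_of <- tm$assignments$neuron
  for (j in unique(neuron_of)) {
    members <- which(neuron_of == j)
    if (length(unique(xy$y[members])) == 1L) {
      expect_true(all(p$class[members] == xy$y[members][1]))
    }
  }
})

test_that("batch prediction equals row-wise prediction and preserves order", {
  fit <- tiny_model(seed = 8)
  xy <- clean_xy(seed = 8, n = c(12L, 10L, 11L), n_noise = 4L)
  batch <- predict(fit, xy$x, scaled = TRUE)
  for (i in c(1L, 7L, 33L)) {
    single <- predict(fit, xy$x[i, , drop = FALSE], scaled = TRUE)
    expect_equal(unname(unlist(single[1, ])), unname(unlist(batch[i, ])))
  }
  empty <- predict(fit, xy$x[0, , drop = FALSE], scaled = TRUE)
  expect_equal(nrow(empty), 0L)

  with_truth <- predict_batch(fit, xy$x, labels = xy$y, scaled = TRUE)
  expect_equal(with_truth$true, factor(as.character(xy$y),
                                       levels = fit$classes),
               ignore_attr = TRUE)
})

test_that("training is reproducible: identical refits, identical predictions", {
  xy <- clean_xy(seed = 9, n = c(20L, 15L, 18L), n_noise = 5L)
  cfg <- som_config(6, 6, 80, a_max = 0.6, a_min = 0.001, seed = 9)
  f1 <- cpann(xy$x, xy$y, scaling = FALSE, config = cfg)
  f2 <- cpann(xy$x, xy$y, scaling = FALSE, config = cfg)
  expect_identical(f1$kohonen$weights, f2$kohonen$weights)
  expect_identical(f1$output_weights, f2$output_weights)
  expect_identical(predict(f1, xy$x, scaled = TRUE),
                   predict(f2, xy$x, scaled = TRUE))
})

test_that("raw-descriptor prediction applies the stored autoscaling", {
  d <- generate_dataset(synthetic_spec(n_per_class = c(25L, 20L, 20L),
                                       n_redundant = 0L, n_constant = 0L,
                                       seed = 10))
  x <- descriptor_matrix(d); y <- class_labels(d)
  fit <- cpann(x, y, config = som_config(7, 7, 60, a_max = 0.6,
                                         a_min = 0.001, seed = 10))
  p_raw <- predict(fit, x)
  p_scaled <- predict(fit, autoscale(x)$x, scaled = TRUE)
  expect_equal(p_raw, p_scaled)
  expect_error(predict(fit, x[, -1]), "missing descriptor")
})

test_that("misaligned inputs and degenerate labels are rejected", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(cpann(x, factor(rep("u", 9))), "misaligned")
  expect_error(cpann(x, factor(rep("u", 10))), "two classes")
})

test_that("model accessors expose weights, scores and residuals", {
  fit <- tiny_model(seed = 11)
  expect_equal(coef(fit), fit$output_weights)
  expect_equal(dim(coef(fit, "kohonen")), dim(fit$kohonen$weights))
  expect_equal(dim(fitted(fit)), c(65L, 3L))
  r <- residuals(fit)
  expect_true(all(abs(r) <= 1))
  # residual = one-hot target minus fitted score
  i <- 5L
  g <- as.integer(fit$y[i])
  expect_equal(unname(r[i, g]), unname(1 - fitted(fit)[i, g]))
})

test_that("models round-trip through JSON with identical predictions", {
  d <- generate_dataset(synthetic_spec(n_per_class = c(15L, 12L, 13L),
                                       n_redundant = 0L, n_constant = 0L,
                                       seed = 12))
  x <- descriptor_matrix(d); y <- class_labels(d)
  fit <- cpann(x, y, config = som_config(5, 5, 40, a_max = 0.6,
                                         a_min = 0.001, seed = 12))
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_cpann_json(fit, f)
  fit2 <- read_cpann_json(f)
  expect_equal(predict(fit2, x), predict(fit, x), tolerance = 1e-12)
})
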