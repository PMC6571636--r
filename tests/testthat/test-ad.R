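test_that("distance to the winning neuron matches brute force", {
  fit <- tiny_model(seed = 41)
  xy <- clean_xy(seed = 41, n = c(15L, 12L, 13L), n_noise = 4L)
  ed <- ed_to_winner(fit, xy$x, scaled = TRUE)
  xs <- xy$x[, fit$descriptors]   # model column order for the brute force
  for (i in seq_len(nrow(xs))) {
    ref <- scan_winner(fit$kohonen$weights, xs[i, ])
    expect_equal(ed[i], ref$distance, tolerance = 1e-12)
  }
  expect_true(all(ed >= 0))
})

test_that("a compound equal to a neuron's weights has distance zero", {
  fit <- tiny_model(seed = 42)
  w <- fit$kohonen$weights[5, ]
  expect_equal(ed_to_winner(fit, w, scaled = TRUE), 0)
})

test_that("distance ignores components equal between input and winner", {
  fit <- tiny_model(seed = 43)
  xy <- clean_xy(seed = 43, n = c(10L, 8L, 9L), n_noise = 4L)
  x <- xy$x[3, ]
  winner <- find_winner(fit$kohonen, x)
  w <- fit$kohonen$weights[winner$index, ]
  # 1-d intuition: |x - w| on a single differing component
  diff1 <- sqrt(sum((x - w)^2))
  expect_equal(winner$distance, diff1)
})

test_that("the reference distance is the partition maximum", {
  fit <- tiny_model(seed = 44)
  xy <- clean_xy(seed = 44, n = c(20L, 15L, 18L), n_noise = 4L)
  te <- xy$x[1:20, ]
  ref <- build_reference(fit, te, scaled = TRUE)
  expect_equal(ref$reference_ed, max(ed_to_winner(fit, te, scaled = TRUE)))

  one <- build_reference(fit, te[1, , drop = FALSE], scaled = TRUE)
  expect_equal(one$reference_ed, ed_to_winner(fit, te[1, , drop = FALSE],
                                              scaled = TRUE))
  # max over a superset can only grow
  ref_all <- build_reference(fit, xy$x, scaled = TRUE)
  expect_gte(ref_all$reference_ed, ref$reference_ed)
  expect_error(build_reference(fit, te[0, , drop = FALSE], scaled = TRUE),
               "empty")
})

test_that("domain and uncertainty flags follow the declared conventions", {
  fit <- tiny_model(seed = 45)
  xy <- clean_xy(seed = 45, n = c(20L, 15L, 18L), n_noise = 4L)
  ref <- build_reference(fit, xy$x[1:20, ], scaled = TRUE)
  ad <- assess_domain(fit, ref, xy$x, labels = xy$y, scaled = TRUE)

  # boundary inclusive: ED == reference is in-domain
  expect_identical(ad$in_domain, ad$ed <= ref$reference_ed)
  expect_true(any(abs(ad$ed - ref$reference_ed) < 1e-12 & ad$in_domain))

  scores <- as.matrix(ad[paste0("score_", fit$classes)])
  expect_identical(ad$uncertain,
                   apply(abs(scores - 0.5) <= 0.1, 1, any))

  # out-of-domain census on a held-out chunk matches direct counting
  held <- xy$x[31:53, ]
  ad_h <- assess_domain(fit, ref, held, scaled = TRUE)
  expect_equal(sum(!ad_h$in_domain),
               sum(ed_to_winner(fit, held, scaled = TRUE) > ref$reference_ed))

  expect_error(assess_domain(fit, ref, xy$x, uncertainty_band = 0.7,
                             scaled = TRUE), "uncertainty_band")
})

test_that("residuals are target minus predicted score per class", {
  fit <- tiny_model(seed = 46)
  xy <- clean_xy(seed = 46, n = c(15L, 12L, 13L), n_noise = 4L)
  ref <- build_reference(fit, xy$x, scaled = TRUE)
  ad <- assess_domain(fit, ref, xy$x, labels = xy$y, scaled = TRUE)
  i <- 7L
  g <- fit$classes[1]
  target <- as.numeric(as.character(xy$y[i]) == g)
  expect_equal(ad[[paste0("residual_", g)]][i],
               target - ad[[paste0("score_", g)]][i])
})

test_that("in-domain certain predictions carry smaller residuals", {
  xy <- clean_xy(seed = 47, n = c(60L, 45L, 50L), separation = 3)
  tr <- seq_len(110)
  fit <- cpann(xy$x[tr, ], xy$y[tr], scaling = FALSE,
               config = som_config(10, 10, 150, a_max = 0.6, a_min = 0.001,
                                   seed = 47))
  ref <- build_reference(fit, xy$x[-tr, ], scaled = TRUE)
  ad <- assess_domain(fit, ref, xy$x, labels = xy$y, scaled = TRUE)
  res_cols <- paste0("residual_", fit$classes)
  mean_abs <- rowMeans(abs(as.matrix(ad[res_cols])))
  reliable <- ad$in_domain & !ad$uncertain
  expect_gt(sum(reliable), 0)
  expect_gt(sum(!reliable), 0)
  expect_lte(mean(mean_abs[reliable]), mean(mean_abs[!reliable]))
})

test_that("TR compounds never exceed their own maximum distance", {
  fit <- tiny_model(seed = 48)
  xy <- clean_xy(seed = 48, n = c(25L, 20L, 20L), n_noise = 4L)
  ed <- ed_to_winner(fit, xy$x, scaled = TRUE)
  ref <- build_reference(fit, xy$x, partition = "TR", scaled = TRUE)
  expect_true(all(ed <= ref$reference_ed))
})

test_that("refitting the scaling after a unit change leaves ED unchanged", {
  d <- generate_dataset(synthetic_spec(n_per_class = c(20L, 15L, 18L),
                                       n_redundant = 0L, n_constant = 0L,
                                       seed = 49))
  x <- descriptor_matrix(d); y <- class_labels(d)
  cfg <- som_config(6, 6, 60, a_max = 0.6, a_min = 0.001, seed = 49)
  fit1 <- cpann(x, y, config = cfg)
  x2 <- x
  x2[, 1] <- x2[, 1] * 1000   # e.g. g -> mg units
  fit2 <- cpann(x2, y, config = cfg)
  expect_equal(ed_to_winner(fit1, x), ed_to_winner(fit2, x2),
               tolerance = 1e-8)
})

test_that("assessments serialize to TSV with all plot coordinates", {
  fit <- tiny_model(seed = 50)
  xy <- clean_xy(seed = 50, n = c(10L, 8L, 9L), n_noise = 4L)
  ref <- build_reference(fit, xy$x, scaled = TRUE)
  ad <- assess_domain(fit, ref, xy$x, labels = xy$y, scaled = TRUE)
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write_ad_tsv(ad, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(ad))
  expect_true(all(c("id", "ed", "in_domain", "uncertain",
                    paste0("residual_", fit$classes)) %in% names(back)))
})
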