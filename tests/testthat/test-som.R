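test_that("learning-rate schedule matches the closed form", {
  cfg <- som_config(epochs = 100, a_max = 0.5, a_min = 0.01)
  expect_equal(learning_rate(1, cfg), 0.5)
  expect_equal(learning_rate(100, cfg), 0.01)
  # direct substitution: (0.5 - 0.01) * (100 - 50) / 99 + 0.01
  expect_equal(learning_rate(50, cfg), 0.257474747474747, tolerance = 1e-10)
  expect_error(learning_rate(0, cfg), "out of range")
  expect_error(learning_rate(101, cfg), "out of range")
})

test_that("learning rate is strictly decreasing and affine in t", {
  cfg <- som_config(epochs = 40, a_max = 0.6, a_min = 0.001)
  eta <- sapply(1:40, learning_rate, config = cfg)
  expect_true(all(diff(eta) < 0))
  expect_equal(max(abs(diff(diff(eta)))), 0, tolerance = 1e-12)
})

test_that("topological distance is the Chebyshev ring distance", {
  expect_equal(topological_distance(c(3, 3), c(3, 3)), 0)
  expect_equal(topological_distance(c(1, 1), c(2, 2)), 1)   # diagonal = ring 1
  expect_equal(topological_distance(c(1, 1), c(4, 2)), 3)
  # corner of a 5x5 non-toroidal grid has exactly 3 ring-1 neighbours
  grid <- expand.grid(row = 1:5, col = 1:5)
  d_corner <- apply(grid, 1, topological_distance, a = c(1, 1))
  expect_equal(sum(d_corner == 1), 3)
  # an interior neuron has 8
  d_mid <- apply(grid, 1, topological_distance, a = c(3, 3))
  expect_equal(sum(d_mid == 1), 8)
})

test_that("winner search is exact, deterministic and matches brute force", {
  set.seed(10)
  for (i in 1:100) {
    rows <- sample(2:6, 1); cols <- sample(2:6, 1); m <- sample(2:8, 1)
    w <- matrix(runif(rows * cols * m), rows * cols, m)
    g <- cpann:::new_som_grid(w, rows, cols, som_config(rows, cols, 10))
    x <- runif(m)
    got <- find_winner(g, x)
    ref <- scan_winner(w, x)
    expect_equal(got$index, ref$index)
    expect_equal(got$distance, ref$distance, tolerance = 1e-12)
  }
})

test_that("winner ties break to the first neuron in row-major order", {
  w <- rbind(c(0, 0), c(0, 0), c(1, 1), c(0, 0))
  g <- cpann:::new_som_grid(w, 2, 2, som_config(2, 2, 10))
  expect_equal(find_winner(g, c(0, 0))$index, 1L)
  # exact weight match gives distance zero
  expect_equal(find_winner(g, c(1, 1))$distance, 0)
  expect_equal(find_winner(g, c(1, 1))$index, 3L)
  expect_error(find_winner(g, c(1, 2, 3)), "components")
})

test_that("weight update is a convex pull toward the input", {
  w <- matrix(runif(9 * 3), 9, 3)
  g <- cpann:::new_som_grid(w, 3, 3, som_config(3, 3, 10))
  x <- runif(3)
  winner <- find_winner(g, x)

  # full-rate update maps the winner exactly onto the input
  g1 <- update_weights(g, x, winner, eta = 1, radius = 0)
  expect_equal(as.vector(g1$weights[winner$index, ]), as.vector(x))

  # neurons outside the radius never move
  g2 <- update_weights(g, x, winner, eta = 0.5, radius = 1)
  coords <- cpann:::neuron_coords(1:9, 3)
  far <- which(pmax(abs(coords[, "row"] - winner$coords["row"]),
                    abs(coords[, "col"] - winner$coords["col"])) > 1)
  expect_equal(g2$weights[far, ], w[far, ])

  # partial updates strictly shrink the winner-to-input distance
  g3 <- update_weights(g, x, winner, eta = 0.3, radius = 2)
  expect_lt(sqrt(sum((g3$weights[winner$index, ] - x)^2)),
            sqrt(sum((w[winner$index, ] - x)^2)))
  # and never overshoot: new weight between old weight and x componentwise
  between <- (g3$weights[winner$index, ] - x) * (w[winner$index, ] - x)
  expect_true(all(between >= -1e-12))
})

test_that("training collapses identical compounds onto one converged neuron", {
  x <- matrix(rep(c(0.3, 0.7, 0.1), each = 20), 20, 3)
  colnames(x) <- c("a", "b", "c")
  m <- train_som(x, som_config(4, 4, 50, 0.5, 0.01, seed = 1))
  tm <- build_top_map(m, x)
  expect_equal(sum(tm$occupancy > 0), 1L)
  winner <- which(tm$occupancy > 0, arr.ind = TRUE)
  idx <- cpann:::neuron_index(winner[1, 1], winner[1, 2], 4L)
  expect_equal(as.vector(m$weights[idx, ]), c(0.3, 0.7, 0.1), tolerance = 0.01)
})

test_that("well-separated clusters win disjoint neuron sets", {
  set.seed(2)
  x <- rbind(matrix(rnorm(50 * 4), 50, 4),
             matrix(rnorm(50 * 4, mean = 10), 50, 4))
  colnames(x) <- paste0("d", 1:4)
  xs <- autoscale(x)$x
  m <- train_som(xs, som_config(10, 10, 60, 0.5, 0.01, seed = 2))
  tm <- build_top_map(m, xs)
  n1 <- unique(tm$assignments$neuron[1:50])
  n2 <- unique(tm$assignments$neuron[51:100])
  expect_length(intersect(n1, n2), 0)
})

test_that("quantization error does not grow over training", {
  xy <- clean_xy(seed = 3)
  m <- train_som(xy$x, som_config(8, 8, 50, 0.5, 0.01, seed = 3))
  expect_lte(tail(m$qe, 1), m$qe[1])
})

test_that("training is deterministic and permutation-equivariant in columns", {
  xy <- clean_xy(seed = 4, n = c(20L, 15L, 15L), n_noise = 4L)
  cfg <- som_config(5, 5, 30, 0.5, 0.01, seed = 4)
  m1 <- train_som(xy$x, cfg)
  m2 <- train_som(xy$x, cfg)
  expect_identical(m1$weights, m2$weights)

  # the update equations are equivariant in descriptor order: permuting
  # input columns (and the initial weights identically) permutes the
  # trained weight components
  set.seed(1)
  perm <- sample(ncol(xy$x))
  w0 <- matrix(runif(25 * ncol(xy$x)), 25, ncol(xy$x),
               dimnames = list(NULL, colnames(xy$x)))
  m4 <- train_som(xy$x, cfg, init = w0)
  m5 <- train_som(xy$x[, perm], cfg, init = w0[, perm])
  expect_equal(m5$weights, m4$weights[, perm], tolerance = 1e-12)
})

test_that("top-map occupancy is conserved and majority classes recorded", {
  xy <- clean_xy(seed = 6, n = c(30L, 20L, 25L))
  m <- train_som(xy$x, som_config(6, 6, 40, 0.5, 0.01, seed = 6))
  tm <- build_top_map(m, xy$x, labels = xy$y)
  expect_equal(sum(tm$occupancy), nrow(xy$x))
  expect_equal(sum(!is.na(tm$majority)), sum(tm$occupancy > 0))

  one <- build_top_map(m, xy$x[1, , drop = FALSE])
  expect_equal(sum(one$occupancy), 1L)
  expect_equal(sum(one$occupancy > 0), 1L)
})

test_that("separable data yields contiguous class regions above chance", {
  xy <- clean_xy(seed = 9, n = c(40L, 30L, 35L), separation = 4)
  m <- train_som(xy$x, som_config(8, 8, 60, 0.5, 0.01, seed = 9))
  tm <- build_top_map(m, xy$x, labels = xy$y)
  maj <- tm$majority
  agree <- function(mat) {
    s <- 0L; tot <- 0L
    for (r in seq_len(nrow(mat))) for (cc in seq_len(ncol(mat) - 1L)) {
      if (!is.na(mat[r, cc]) && !is.na(mat[r, cc + 1L])) {
        tot <- tot + 1L
        s <- s + (mat[r, cc] == mat[r, cc + 1L])
      }
    }
    for (cc in seq_len(ncol(mat))) for (r in seq_len(nrow(mat) - 1L)) {
      if (!is.na(mat[r, cc]) && !is.na(mat[r + 1L, cc])) {
        tot <- tot + 1L
        s <- s + (mat[r, cc] == mat[r + 1L, cc])
      }
    }
    s / tot
  }
  obs <- agree(maj)
  set.seed(99)
  perm_base <- replicate(50, {
    shuffled <- maj
    filled <- !is.na(maj)
    shuffled[filled] <- sample(maj[filled])
    agree(shuffled)
  })
  expect_gt(obs, quantile(perm_base, 0.95))
})

test_that("SOM grids round-trip through JSON", {
  xy <- clean_xy(seed = 12, n = c(15L, 10L, 10L), n_noise = 3L)
  m <- train_som(xy$x, som_config(4, 4, 20, 0.5, 0.01, seed = 12))
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_som_json(m, f)
  m2 <- read_som_json(f)
  expect_equal(m2$weights, m$weights, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(m2$rows, m$rows)
  expect_equal(m2$descriptors, m$descriptors)
})
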