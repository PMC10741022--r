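test_that("rank-order weights follow the geometric modulation", {
  fired <- diag(3) > 0
  r <- make_raster(fired)
  w <- encode_state(r, desnn_params(mod = 0.8, alpha = 1,
                                    drift_up = 0, drift_down = 0))
  expect_equal(w, c(1, 0.8, 0.64))
  # strictly decreasing in order for mod < 1
  expect_true(all(diff(w[order(r$first_spike_time)]) < 0))
})

test_that("silent neurons stay at zero and never drift", {
  fired <- matrix(FALSE, 2, 6)
  fired[1, 2] <- TRUE
  w <- encode_state(make_raster(fired), desnn_params())
  expect_equal(w[2], 0)
  expect_gt(w[1], 0)
})

test_that("drift accumulates per step after the first spike", {
  # order 0 neuron fires at 3 of the 5 steps after its first spike:
  # w = 1 + 3 * 0.005 - 2 * 0.005 = 1.005
  fired <- matrix(FALSE, 1, 6)
  fired[1, c(1, 2, 4, 6)] <- TRUE
  w <- encode_state(make_raster(fired),
                    desnn_params(drift_up = 0.005, drift_down = 0.005))
  expect_equal(w, 1 + 3 * 0.005 - 2 * 0.005)
})

test_that("first-spike ties share ascending ranks by neuron index", {
  fired <- matrix(FALSE, 3, 4)
  fired[, 2] <- TRUE   # all three first fire at t = 2
  w <- encode_state(make_raster(fired),
                    desnn_params(drift_up = 0, drift_down = 0))
  expect_equal(w, c(1, 0.8, 0.64))
})

test_that("encode_state is permutation-equivariant", {
  withr::with_seed(15, fired <- matrix(runif(8 * 20) < 0.2, 8, 20))
  p <- desnn_params()
  w <- encode_state(make_raster(fired), p)
  perm <- c(3, 1, 7, 2, 8, 5, 4, 6)
  wp <- encode_state(make_raster(fired[perm, ]), p)
  expect_equal(wp, w[perm])
})

test_that("with zero drift only first-spike order matters", {
  p0 <- desnn_params(drift_up = 0, drift_down = 0)
  withr::with_seed(4, fired <- matrix(runif(5 * 30) < 0.25, 5, 30))
  r <- make_raster(fired)
  # scramble all spiking after each neuron's first spike
  fired2 <- matrix(FALSE, 5, 30)
  for (j in 1:5) {
    fs <- r$first_spike_time[j]
    if (!is.na(fs)) {
      fired2[j, fs] <- TRUE
      if (fs < 30) fired2[j, (fs + 1):30] <- rev(fired[j, (fs + 1):30])
    }
  }
  expect_equal(encode_state(make_raster(fired2), p0), encode_state(r, p0))
})

test_that("training stores one output neuron per labelled sample", {
  withr::with_seed(2, {
    rasters <- lapply(1:9, function(i) make_raster(matrix(runif(4 * 10) < 0.3, 4, 10)))
  })
  labels <- rep(c("up", "straight", "down"), each = 3)
  m <- desnn_train(rasters, labels)
  expect_equal(nrow(m$weights), 9L)
  expect_equal(as.vector(table(m$labels)), c(3L, 3L, 3L))
  expect_error(desnn_train(list(), character(0)), "no training rasters")
  expect_error(desnn_train(rasters, labels[-1]), "lengths differ")
  # duplicated rasters yield identical output neurons
  m2 <- desnn_train(rasters[c(1, 1)], c("a", "a"))
  expect_equal(m2$weights[1, ], m2$weights[2, ])
  expect_equal(tidy(m)$output_neuron, 1:9)
  expect_equal(glance(m)$n_output_neurons, 9L)
})

test_that("classification is nearest-neighbour on encoded states", {
  # two stored states firing in opposite orders
  ra <- make_raster(rbind(c(TRUE, FALSE), c(FALSE, TRUE)))
  rb <- make_raster(rbind(c(FALSE, TRUE), c(TRUE, FALSE)))
  m <- desnn_train(list(ra, rb), c("A", "B"),
                   desnn_params(drift_up = 0, drift_down = 0))
  # self-recall: own class at distance zero
  out <- desnn_classify(m, ra)
  expect_equal(as.character(out$class), "A")
  expect_equal(out$distances[1], 0)
  expect_equal(as.character(desnn_classify(m, rb)$class), "B")
})

test_that("K-nearest voting saturates to the majority class", {
  withr::with_seed(10, {
    rasters <- lapply(1:5, function(i) make_raster(matrix(runif(3 * 8) < 0.4, 3, 8)))
  })
  m <- desnn_train(rasters, c("A", "A", "A", "B", "B"),
                   desnn_params(k_neighbors = 5L))
  for (r in rasters) {
    expect_equal(as.character(desnn_classify(m, r)$class), "A")
  }
})
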