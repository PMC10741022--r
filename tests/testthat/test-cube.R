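test_that("connection probability follows the squared-distance decay", {
  expect_equal(connection_probability(0, C = 1, lambda = 1), 1)
  expect_equal(connection_probability(1, C = 1, lambda = 1), exp(-1))
  expect_lt(connection_probability(1, C = 1, lambda = 1e-6), 1e-12)
  expect_equal(connection_probability(2, C = 0.5, lambda = 2),
               0.5 * exp(-1))
})

test_that("wiring requires a seed and respects the distance cutoff", {
  cube <- new_snn_cube(grid_template(3, 3, 3))
  expect_error(init_small_world(cube, small_world_params()), "seed")
  wired <- init_small_world(cube, small_world_params(
    max_distance = 1, seed = 5, inhibitory_fraction = 0))
  expect_gt(length(wired$weight), 0L)
  d <- sqrt(rowSums((wired$template$coordinates[wired$pre, ] -
                       wired$template$coordinates[wired$post, ])^2))
  expect_true(all(d <= 1 + 1e-12))
  expect_true(all(wired$pre != wired$post))
  expect_true(all(wired$weight > 0 & wired$weight <= 0.1))
  # identical seed -> identical wiring
  wired2 <- init_small_world(cube, small_world_params(
    max_distance = 1, seed = 5, inhibitory_fraction = 0))
  expect_identical(wired$weight, wired2$weight)
})

test_that("inhibitory neurons have all-negative outgoing weights", {
  cube <- init_small_world(
    new_snn_cube(grid_template(3, 3, 3)),
    small_world_params(seed = 11, inhibitory_fraction = 0.5))
  by_pre <- split(cube$weight, cube$pre)
  same_sign <- vapply(by_pre, function(w) all(w > 0) || all(w < 0),
                      logical(1L))
  expect_true(all(same_sign))
  expect_gt(sum(cube$weight < 0), 0L)
})

test_that("pairwise STDP deltas match the exponential rule", {
  p <- stdp_params(a_plus = 0.01, a_minus = 0.01, tau_plus = 10,
                   tau_minus = 10)
  expect_equal(stdp_delta(0, 10, p), 0.01 * exp(-1))
  expect_equal(stdp_delta(10, 0, p), -0.01 * exp(-1))
  expect_equal(stdp_delta(5, 5, p), 0)
  expect_lt(abs(stdp_delta(0, 1e4, p)), 1e-12)
  expect_lt(abs(stdp_delta(1e4, 0, p)), 1e-12)
})

test_that("a single input spike above threshold fires the mapped neuron", {
  cube <- hand_cube(1, integer(0), integer(0), numeric(0),
                    input_gain = 0.6)
  sp <- hand_spikes(array(c(0L, 1L, 0L, 0L), c(1, 1, 4)))
  r <- simulate_cube(cube, sp, 1)
  expect_equal(r$first_spike_time, 2L)
  expect_equal(unname(which(r$fired[1, ])), 2L)
})

test_that("membrane integration matches the hand-computed leak arithmetic", {
  # gain 0.3, threshold 0.5, leak 0.002: u = 0.3, then 0.3*0.998+0.3 = 0.5994
  cube <- hand_cube(1, integer(0), integer(0), numeric(0),
                    lif = lif_params(0.5, 0.002, 6L), input_gain = 0.3)
  sp <- hand_spikes(array(c(1L, 1L, 0L, 0L), c(1, 1, 4)))
  r <- simulate_cube(cube, sp, 1)
  expect_equal(r$first_spike_time, 2L)
  # with one fewer input the potential stays below threshold
  sp1 <- hand_spikes(array(c(1L, 0L, 0L, 0L), c(1, 1, 4)))
  expect_true(is.na(simulate_cube(cube, sp1, 1)$first_spike_time))
})

test_that("no input drive leaves the raster empty", {
  cube <- init_small_world(new_snn_cube(grid_template(2, 2, 2)),
                           small_world_params(seed = 3))
  cube <- set_input_map(cube, c(V1 = 1L))
  r <- simulate_cube(cube, hand_spikes(array(0L, c(1, 1, 10))), 1)
  expect_equal(sum(r$fired), 0L)
  expect_error(simulate_cube(cube, hand_spikes(array(0L, c(1, 1, 0))), 1),
               "length 0")
})

test_that("refractory neurons never fire twice within the refractory window", {
  refr <- 4L
  cube <- init_small_world(
    new_snn_cube(grid_template(3, 3, 3),
                 lif = lif_params(0.5, 0.002, refr)),
    small_world_params(seed = 21, inhibitory_fraction = 0))
  cube <- set_input_map(cube, c(V1 = 1L, V2 = 14L, V3 = 27L))
  withr::with_seed(77, {
    pol <- array(sample(c(-1L, 0L, 1L), 3 * 60, TRUE, c(0.1, 0.3, 0.6)),
                 c(1, 3, 60))
  })
  r <- simulate_cube(cube, hand_spikes(pol), 1, learn = TRUE)
  gaps <- apply(r$fired, 1L, function(f) diff(which(f)))
  expect_true(all(unlist(gaps) > refr))
})

test_that("simulation is reproducible for a fixed cube state", {
  cube <- init_small_world(new_snn_cube(grid_template(3, 3, 3)),
                           small_world_params(seed = 9))
  cube <- set_input_map(cube, c(V1 = 5L, V2 = 20L))
  withr::with_seed(5, {
    pol <- array(sample(c(0L, 1L), 2 * 40, TRUE), c(1, 2, 40))
  })
  sp <- hand_spikes(pol)
  expect_identical(simulate_cube(cube, sp, 1)$fired,
                   simulate_cube(cube, sp, 1)$fired)
})

test_that("zero learning rates leave the weights unchanged", {
  cube <- init_small_world(
    new_snn_cube(grid_template(3, 3, 3),
                 stdp = stdp_params(a_plus = 0, a_minus = 0)),
    small_world_params(seed = 13))
  cube <- set_input_map(cube, c(V1 = 1L, V2 = 27L))
  withr::with_seed(6, pol <- array(sample(c(0L, 1L), 2 * 50, TRUE), c(1, 2, 50)))
  before <- cube$weight
  trained <- train_unsupervised(cube, hand_spikes(pol))
  expect_identical(trained$weight, before)
  expect_true(trained$trained)
})

test_that("repeated causal pre->post pairing potentiates monotonically", {
  # input drives neuron 1 every 8 steps; 1 -> 2 with weight 0.6 makes 2 fire
  # one step later: strictly causal, so the connection only strengthens.
  cube <- hand_cube(2, 1L, 2L, 0.6, lif = lif_params(0.5, 0, 2L))
  pol <- array(0L, c(1, 1, 48))
  pol[1, 1, seq(2, 48, by = 8)] <- 1L
  w <- 0.6
  for (k in 1:3) {
    res <- simulate_cube(cube, hand_spikes(pol), 1, learn = TRUE)
    cube <- attr(res, "cube")
    expect_gt(cube$weight, w)
    w <- cube$weight
  }
})

test_that("accumulated STDP equals a brute-force pairing oracle", {
  cube <- hand_cube(2, 1L, 2L, 0.6,
                    lif = lif_params(0.5, 0.01, 3L),
                    stdp = stdp_params(a_plus = 0.004, a_minus = 0.003,
                                       tau_plus = 7, tau_minus = 9))
  withr::with_seed(31, {
    pol <- array(sample(c(0L, 1L), 80, TRUE, c(0.5, 0.5)), c(1, 1, 80))
  })
  res <- simulate_cube(cube, hand_spikes(pol), 1, learn = TRUE)
  trained <- attr(res, "cube")
  t1 <- which(res$fired[1, ])   # pre spikes
  t2 <- which(res$fired[2, ])   # post spikes
  # oracle: replay the realized spike trains, pairing each event with the
  # nearest preceding spike of the other neuron
  w <- 0.6
  p <- trained$stdp
  for (t in sort(union(t1, t2))) {
    if (t %in% t2) {
      prev_pre <- t1[t1 < t]
      if (length(prev_pre)) w <- w + stdp_delta(max(prev_pre), t, p)
    }
    if (t %in% t1) {
      prev_post <- t2[t2 < t]
      if (length(prev_post)) w <- w + stdp_delta(t, max(prev_post), p)
    }
  }
  expect_equal(trained$weight, w, tolerance = 1e-12)
  expect_gt(length(t2), 0L)
})

test_that("training preserves connection signs and the magnitude clip", {
  cube <- init_small_world(
    new_snn_cube(grid_template(3, 3, 3),
                 lif = lif_params(0.4, 0.002, 2L),
                 stdp = stdp_params(a_plus = 0.05, a_minus = 0.05,
                                    w_max = 0.8)),
    small_world_params(seed = 17, inhibitory_fraction = 0.3))
  cube <- set_input_map(cube, c(V1 = 1L, V2 = 14L, V3 = 27L))
  withr::with_seed(8, {
    pol <- array(sample(c(-1L, 0L, 1L), 3 * 50 * 4, TRUE), c(4, 3, 50))
  })
  trained <- train_unsupervised(cube, hand_spikes(pol))
  expect_true(all(trained$weight[trained$sign > 0] >= 0))
  expect_true(all(trained$weight[trained$sign < 0] <= 0))
  expect_true(all(abs(trained$weight) <= 0.8 + 1e-12))
  expect_false(identical(trained$weight, cube$weight))
})
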