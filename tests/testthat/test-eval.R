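test_that("retained memory accuracy is the plain ratio with guarded domain", {
  expect_equal(rma(95, 100), 0.95)
  expect_equal(rma(86, 100), 0.86)
  expect_equal(rma(0.42, 0.42), 1)
  expect_error(rma(50, 0), "undefined")
  expect_error(rma("a", 1), "numeric")
})

test_that("temporal truncation keeps a floored prefix of at least one step", {
  d <- tiny_eeg(n = 4L, t = 128L)
  expect_equal(n_time(truncate_temporal(d, 1)), 128L)
  expect_equal(truncate_temporal(d, 1)$values, d$values)
  expect_equal(n_time(truncate_temporal(d, 0.8)), 102L)  # floor(0.8 * 128)
  expect_equal(n_time(truncate_temporal(d, 1e-6)), 1L)
  sp <- step_forward_encode(d, encoder_params())
  half <- truncate_temporal(sp, 0.5)   # spike-train method
  expect_equal(dim(half)[3L], 64L)
  expect_equal(half$polarity, sp$polarity[, , 1:64])
  expect_error(truncate_temporal(d, 0), "\\(0, 1\\]")
  expect_error(truncate_temporal(d, 1.2), "\\(0, 1\\]")
})

test_that("variable masking silences exactly the dropped channels", {
  d <- tiny_eeg(n = 3L, t = 40L)
  sp <- step_forward_encode(d, encoder_params())
  all_kept <- mask_variables(sp, d$variable_names)
  expect_equal(all_kept$polarity, sp$polarity)
  masked <- mask_variables(sp, setdiff(d$variable_names, "ch7"))
  expect_true(all(masked$polarity[, "ch7", ] == 0L))
  expect_equal(masked$polarity[, -7, ], sp$polarity[, -7, ])
  expect_error(mask_variables(sp, character(0)), "at least one")
  expect_error(mask_variables(sp, "nope"), "unknown variables")
})

test_that("full recall reproduces the training accuracy with RMA exactly 1", {
  d <- tiny_eeg()
  fit <- stam_fit(d, tiny_config())
  ev <- stam_evaluate(fit, d, recall_spec())
  expect_equal(ev$accuracy, 1)           # self-match of stored states
  expect_equal(ev$rma, 1)
  expect_equal(ev$mode, "temporal_association")
  expect_equal(sum(ev$confusion[[1]]), n_samples(d))
  expect_error(stam_evaluate(fit, d, recall_spec(keep_variables = "zz")),
               "unknown variables")
})

test_that("recall never mutates the fitted model", {
  d <- tiny_eeg(n = 9L, t = 32L)
  fit <- stam_fit(d, tiny_config(dims = 3L))
  h_before <- rlang::hash(fit)
  invisible(stam_evaluate(fit, d, recall_spec(0.6)))
  invisible(stam_evaluate(fit, d,
                          recall_spec(0.8, keep_variables = paste0("ch", 1:7))))
  expect_identical(rlang::hash(fit), h_before)
})

test_that("accuracy is invariant to sample order", {
  d <- tiny_eeg(n = 9L, t = 32L)
  fit <- stam_fit(d, tiny_config(dims = 3L))
  perm <- c(5, 1, 9, 3, 7, 2, 8, 4, 6)
  dperm <- sample_set(d$values[perm, , ], d$labels[perm], d$coordinates,
                      d$variable_names)
  a <- stam_evaluate(fit, d, recall_spec(0.7))$accuracy
  b <- stam_evaluate(fit, dperm, recall_spec(0.7))$accuracy
  expect_equal(a, b)
})

test_that("recall sweeps produce the tabulated report shape", {
  d <- tiny_eeg()
  cfg <- tiny_config()
  keep13 <- paste0("ch", 1:13)
  sw <- run_stam_suite(d, cfg, fractions = c(1, 0.95, 0.9, 0.8),
                       variable_subsets = list(NULL, keep13))
  expect_equal(nrow(sw), 8L)
  expect_equal(sw$mode[1:4], rep("temporal_association", 4))
  expect_equal(sw$mode[5:8], rep("spatial_association", 4))
  expect_equal(sw$n_variables, rep(c(14L, 13L), each = 4L))
  expect_equal(sw$rma, sw$accuracy / sw$full_accuracy)
  expect_equal(sw$rma[1], 1)
  # deterministic given the same config seed
  sw2 <- run_stam_suite(d, cfg, fractions = c(1, 0.95, 0.9, 0.8),
                        variable_subsets = list(NULL, keep13))
  expect_equal(sw$accuracy, sw2$accuracy)
  # empty sweep
  expect_equal(nrow(run_stam_suite(d, cfg, fractions = numeric(0))), 0L)
})

test_that("holdout splits are stratified, seeded and labelled generalization", {
  d <- tiny_eeg(n = 18L)
  cfg <- tiny_config()
  sw <- run_stam_suite(d, cfg, fractions = c(1, 0.8),
                       splits = c("resubstitution", "holdout"),
                       split_seed = 123)
  expect_equal(sw$mode, c("temporal_association", "temporal_association",
                          "temporal_generalization",
                          "temporal_generalization"))
  # generalization accuracy cannot exceed the (perfect) association accuracy
  expect_lte(sw$accuracy[3], sw$accuracy[1])
  ix <- stamcube:::stratified_split(d$labels, 123)
  expect_equal(sort(c(ix$train, ix$test)), 1:18)
  expect_equal(as.vector(table(d$labels[ix$train])), rep(3L, 3))
})

test_that("reports serialize to CSV with a JSON twin", {
  d <- tiny_eeg(n = 6L, t = 32L)
  sw <- run_stam_suite(d, tiny_config(dims = 3L), fractions = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(sw, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$accuracy, sw$accuracy)
  expect_true(file.exists(sub("\\.csv$", ".json", path)))
  js <- jsonlite::read_json(sub("\\.csv$", ".json", path))
  expect_equal(length(js), nrow(sw))
})
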