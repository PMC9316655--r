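test_that("instrument context resolves with the 30 eV boundary and type map", {
  mk <- function(ce, itype, mode = "positive") {
    good_spectrum(collision_energy_raw = ce, instrument_type = itype,
                  ionization_mode = mode)
  }
  ctx <- resolve_context(mk("35 eV", "Orbitrap"))
  expect_equal(ctx$energy, "high")
  expect_equal(ctx$resolution, "high")
  expect_equal(ctx$mode, "positive")
  # threshold is strict: 29.9 eV is low, 30.0 eV is high
  expect_equal(resolve_context(mk("29.9", "QqQ"))$energy, "low")
  expect_equal(resolve_context(mk("30", "QqQ"))$energy, "high")
  expect_equal(resolve_context(mk("40", "Q-TOF"))$resolution, "high")
  expect_equal(resolve_context(mk("40", "Ion Trap"))$resolution, "low")
  expect_equal(resolve_context(mk("40", "QqQ"))$resolution, "low")
  # absent energy takes the configurable default, with provenance
  none <- resolve_context(mk(NA, "Orbitrap"), default_energy = "low")
  expect_equal(none$energy, "low")
  expect_true(none$energy_defaulted)
  s <- mk("35", "Orbitrap"); s$ionization_mode <- NA_character_
  expect_error(resolve_context(s), "ionization_mode")
})

test_that("every record resolves to exactly one of the eight context cells", {
  set.seed(44)
  corp <- tiny_planted_corpus(n_compounds = 30, spectra_per_compound = 2,
                              seed = 44)
  ctx <- resolve_context(corp$spectra)
  expect_true(all(ctx$context_key %in% context_keys()))
  expect_true(all(ctx$context_index %in% 1:8))
  expect_equal(length(context_keys()), 8)
  expect_false(any(duplicated(context_keys())))
  # index and key agree
  expect_equal(ctx$context_key, context_keys()[ctx$context_index])
})

test_that("the built network is the canonical 12-layer stack", {
  m <- build_cnn(tiny_cnn_config())
  expect_equal(nn_layer_types(m),
               c("embedding", "conv1d", "maxpool1d", "conv1d", "maxpool1d",
                 "dropout", "flatten", "dense", "dense", "dense", "dense",
                 "output"))
  expect_length(m$layers, 12)
  # raw-intensity variant has no embedding stage
  m2 <- build_cnn(tiny_cnn_config(use_embedding = FALSE))
  expect_length(m2$layers, 11)
  expect_error(cnn_config(input_length = 4, pool_sizes = c(4L, 4L)),
               class = "specfp_config_error")
  # identical seeds give bit-identical initial weights
  w1 <- build_cnn(tiny_cnn_config())$layers[[2]]$W
  w2 <- build_cnn(tiny_cnn_config())$layers[[2]]$W
  expect_identical(w1, w2)
})

test_that("forward passes produce sigmoid outputs of the right shape", {
  m <- build_cnn(tiny_cnn_config())
  x <- matrix(runif(4 * 40, 0, 100), 4, 40)
  out <- predict_fingerprint(m, x)
  expect_equal(dim(out$probabilities), c(4, 528))
  expect_true(all(out$probabilities > 0 & out$probabilities < 1))
  expect_true(all(out$bits %in% c(0L, 1L)))
})

test_that("intensity quantisation rounds into the vocabulary", {
  expect_equal(quantize_for_embedding(c(0, 2.4, 99.6), 101), c(0L, 2L, 100L))
  expect_equal(quantize_for_embedding(c(0, 0, 0), 101), c(0L, 0L, 0L))
  expect_equal(quantize_for_embedding(100, 101), 100L)
  expect_equal(quantize_for_embedding(250, 101), 100L)  # clamped
  m <- quantize_for_embedding(matrix(c(0.4, 50.5), 1), 101)
  expect_true(is.matrix(m))
})

test_that("training learns a separable planted task and logs reproducibly", {
  set.seed(33)
  n <- 120; L <- 40
  active_bits <- sample(528, 12)
  bit_bin <- sample(L, 12)
  Y <- matrix(0L, n, 528)
  Y[, active_bits] <- matrix(rbinom(n * 12, 1, 0.5), n)
  X <- matrix(0, n, L)
  for (i in seq_len(n)) X[i, bit_bin[Y[i, active_bits] == 1]] <- 100
  cfg <- tiny_cnn_config(dropout_rate = 0)
  m <- train_cnn(build_cnn(cfg), X, Y, epochs = 25)
  log <- tidy(m)
  expect_equal(nrow(log), 25)
  expect_gt(log$binary_accuracy[25], 0.95)
  expect_lt(log$loss[25], log$loss[1])
  # fixed seed: bit-identical logs
  m2 <- train_cnn(build_cnn(cfg), X, Y, epochs = 25)
  expect_identical(m$training_log, m2$training_log)
  # planted-structure recovery beats random fingerprints for most spectra
  pred <- predict_fingerprint(m, X)
  set.seed(1)
  rand_fp <- matrix(rbinom(n * 528, 1, mean(Y)), n)
  wins <- vapply(seq_len(n), function(i) {
    as.numeric(tanimoto(pred$bits[i, ], Y[i, ])) >=
      as.numeric(tanimoto(pred$bits[i, ], rand_fp[i, ]))
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("degenerate all-zero targets drive predictions to zero", {
  X <- matrix(runif(30 * 40, 0, 100), 30, 40)
  Y <- matrix(0L, 30, 528)
  m <- train_cnn(build_cnn(tiny_cnn_config(dropout_rate = 0)), X, Y,
                 epochs = 10)
  pred <- predict_fingerprint(m, X)
  expect_true(all(pred$bits == 0L))
})

test_that("binarisation respects the threshold boundary", {
  probs <- c(0.49, 0.5, 0.51)
  expect_equal(as.integer(probs >= 0.5), c(0L, 1L, 1L))
  m <- build_cnn(tiny_cnn_config())
  x <- matrix(runif(2 * 40, 0, 100), 2, 40)
  all_zero <- predict_fingerprint(m, x, threshold = 1.01)
  expect_true(all(all_zero$bits == 0L))
  expect_error(predict_fingerprint(m, matrix(0, 2, 17)), "width")
})

test_that("baseline models have the documented shapes and learn a toy task", {
  slp <- build_baseline("SLP", input_dim = 10)
  expect_equal(baseline_n_parameters(slp), (10 + 1) * 528)
  mlp <- build_baseline("MLP", input_dim = 10, hidden = 8L)
  expect_equal(baseline_n_parameters(mlp), (10 + 1) * 8 + (8 + 1) * 528)
  expect_error(build_baseline("GBM", input_dim = 10))

  # linearly separable toy task: bit j on iff feature j active
  set.seed(55)
  n <- 80; d <- 10
  X <- matrix(rbinom(n * d, 1, 0.5) * 1.0, n, d)
  Y <- matrix(0L, n, 528)
  Y[, 1:d] <- X
  for (kind in c("LR", "SLP")) {
    b <- train_baseline(build_baseline(kind, input_dim = d, epochs = 120L,
                                       learning_rate = 5e-2, seed = 3), X, Y)
    pred <- predict_fingerprint(b, X)
    f1 <- mean(vapply(seq_len(n), function(i)
      as.numeric(f1_score(pred$bits[i, ], Y[i, ])), numeric(1)))
    expect_gt(f1, 0.95)
  }
  # SVM with a constant label column predicts that constant
  svm <- train_baseline(build_baseline("SVM", input_dim = d), X[1:20, ],
                        Y[1:20, ])
  pred <- predict_fingerprint(svm, X[1:5, ])
  expect_true(all(pred$bits[, 529 - 1] == Y[1, 528]))
  expect_true(all(pred$bits[, 528] == Y[1, 528]))
})

test_that("strategies build the promised members and route predictions", {
  set.seed(66)
  corp <- tiny_planted_corpus(n_compounds = 24, spectra_per_compound = 4,
                              seed = 66)
  spec <- binning_spec(bin_count = 140)
  pp <- preprocess_spectra(corp$spectra, spec = spec, merge = FALSE)
  fps <- attr(corp$compounds, "fingerprints")
  y <- fps[pp$spectra$inchikey, , drop = FALSE]
  ctx <- resolve_context(pp$spectra)
  cfg <- tiny_cnn_config(input_length = 140L)

  single <- fit_strategy(pp$binned, y, ctx, "single", cfg, epochs = 1)
  expect_equal(names(single$members), "all")

  with_ctx <- fit_strategy(pp$binned, y, ctx, "single_with_context", cfg,
                           epochs = 1)
  expect_equal(with_ctx$members$all$cfg$input_length, 143L)

  warnings <- testthat::capture_warnings(
    eight <- fit_strategy(pp$binned, y, ctx, "eight", cfg, min_cell = 14,
                          epochs = 1))
  expect_true(any(grepl("skipped", warnings)))
  expect_true(length(eight$members) >= 1)
  expect_true(all(names(eight$members) %in% context_keys()))

  # prediction routes every spectrum to exactly one member
  pred <- predict_bundle(eight, pp$binned, ctx)
  expect_length(pred$member, nrow(pp$binned$values))
  expect_true(all(pred$member %in% names(eight$members)))
  # spectra whose cell exists route to it
  routed <- ctx$context_key %in% names(eight$members)
  expect_equal(pred$member[routed], ctx$context_key[routed])
})

test_that("all eight members train when every cell is populated", {
  set.seed(77)
  corp <- tiny_planted_corpus(n_compounds = 32, spectra_per_compound = 6,
                              seed = 77)
  spec <- binning_spec(bin_count = 140)
  pp <- preprocess_spectra(corp$spectra, spec = spec, merge = FALSE)
  fps <- attr(corp$compounds, "fingerprints")
  y <- fps[pp$spectra$inchikey, , drop = FALSE]
  ctx <- resolve_context(pp$spectra)
  expect_equal(length(unique(ctx$context_key)), 8)
  bundle <- fit_strategy(pp$binned, y, ctx, "eight",
                         tiny_cnn_config(input_length = 140L),
                         min_cell = 2, epochs = 1)
  expect_equal(length(bundle$members), 8)
  expect_setequal(names(bundle$members), context_keys())
})

test_that("bundles survive a save/load round trip", {
  set.seed(88)
  corp <- tiny_planted_corpus(n_compounds = 8, spectra_per_compound = 1,
                              seed = 88)
  spec <- binning_spec(bin_count = 140)
  pp <- preprocess_spectra(corp$spectra, spec = spec, merge = FALSE)
  fps <- attr(corp$compounds, "fingerprints")
  bundle <- fit_strategy(pp$binned, fps[pp$spectra$inchikey, , drop = FALSE],
                         resolve_context(pp$spectra), "single",
                         tiny_cnn_config(input_length = 140L), epochs = 1)
  dir <- tempfile()
  save_bundle(bundle, dir)
  back <- load_bundle(dir)
  expect_equal(back$strategy, "single")
  p1 <- predict_bundle(bundle, pp$binned, resolve_context(pp$spectra))
  p2 <- predict_bundle(back, pp$binned, resolve_context(pp$spectra))
  expect_equal(p1$probabilities, p2$probabilities)
  unlink(dir, recursive = TRUE)
})
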