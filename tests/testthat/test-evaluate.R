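test_that("structure-disjoint splits never share a skeleton and reproduce", {
  set.seed(2)
  comp <- generate_compound_table(40, seed = 2, n_shared_groups = 3,
                                  shared_group_size = 3)
  s1 <- structure_disjoint_split(comp$inchikey, 0.8, seed = 10)
  s2 <- structure_disjoint_split(comp$inchikey, 0.8, seed = 10)
  expect_identical(s1, s2)
  expect_length(intersect(inchikey_block(s1$train), inchikey_block(s1$test)), 0)
  # skeleton-sharing groups move together
  for (blk in unique(inchikey_block(comp$inchikey))) {
    members <- comp$inchikey[inchikey_block(comp$inchikey) == blk]
    expect_true(all(members %in% s1$train) || all(members %in% s1$test))
  }
  expect_error(structure_disjoint_split(rep(comp$inchikey[1], 5), 0.8, 1),
               "distinct")
})

test_that("the realised train fraction stays near its target across seeds", {
  comp <- generate_compound_table(100, seed = 3)
  fractions <- vapply(1:25, function(s)
    structure_disjoint_split(comp$inchikey, 0.8, seed = s)$train_fraction,
    numeric(1))
  expect_true(all(fractions >= 0.7 & fractions <= 0.9))
})

test_that("k-fold assignment validates every compound exactly once", {
  comp <- generate_compound_table(50, seed = 4, n_shared_groups = 2,
                                  shared_group_size = 4)
  folds <- make_folds(comp$inchikey, k = 5, seed = 6)
  expect_length(folds, 50)
  expect_setequal(unique(folds), 1:5)
  # same-skeleton compounds share a fold
  for (blk in unique(inchikey_block(comp$inchikey))) {
    expect_length(unique(folds[inchikey_block(comp$inchikey) == blk]), 1)
  }
  expect_identical(folds, make_folds(comp$inchikey, k = 5, seed = 6))
  # two blocks / two folds degenerate case
  two <- c("AAAAAAAAAAAAAA-XXXXXXXXXX-N", "BBBBBBBBBBBBBB-XXXXXXXXXX-N")
  expect_setequal(make_folds(two, k = 2, seed = 1), 1:2)
  expect_error(make_folds(two, k = 3, seed = 1), "folds")
})

test_that("corpus bookkeeping adds library strata and the compound split", {
  design <- corpus_design(c(mona_pos = 79404, mona_neg = 32269,
                            nist_pos = 401985, nist_neg = 136895),
                          train_compounds = 29588, test_compounds = 6290)
  expect_equal(design$total_spectra, 650553)
  expect_equal(design$total_compounds, 35878)
  expect_equal(design$train_fraction, 29588 / 35878, tolerance = 1e-12)
})

test_that("an oracle predictor ranks the true compound first", {
  set.seed(8)
  corp <- tiny_planted_corpus(n_compounds = 10, spectra_per_compound = 1,
                              seed = 8)
  fps <- attr(corp$compounds, "fingerprints")
  queries <- corp$spectra
  hits <- logical(nrow(queries))
  for (i in seq_len(nrow(queries))) {
    cands <- retrieve_candidates(queries$precursor_mz[i],
                                 queries$ionization_mode[i], corp$compounds)
    ranked <- rank_candidates(fps[queries$true_inchikey[i], ], cands)
    hits[i] <- topk_hit(ranked, queries$true_inchikey[i], 1)
  }
  # with the true fingerprint, the true compound tops its list whenever its
  # fingerprint is unique among candidates (it is, with random 528-bit fps)
  expect_true(all(hits))
})

test_that("cross-validation trains on disjoint folds and pools the reports", {
  set.seed(19)
  corp <- tiny_planted_corpus(n_compounds = 8, spectra_per_compound = 2,
                              seed = 19)
  spectra <- corp$spectra
  fps <- attr(corp$compounds, "fingerprints")
  cv <- kfold_cv(spectra, corp$compounds, k = 2, strategy = "single",
                 cnn_cfg = tiny_cnn_config(input_length = 300L),
                 seed = 5, spec = binning_spec(bin_count = 300),
                 true_fps = fps, epochs = 1)
  expect_length(cv$folds, 2)
  expect_equal(nrow(cv$pooled), 2)
  # every spectrum is validated exactly once across folds
  validated <- unlist(lapply(cv$folds, function(r) r$per_query$spectrum_id))
  expect_setequal(validated, spectra$spectrum_id)
  expect_false(any(duplicated(validated)))
})

test_that("removing true compounds from the database moves the denominators apart", {
  set.seed(12)
  corp <- tiny_planted_corpus(n_compounds = 10, spectra_per_compound = 1,
                              seed = 12)
  fps <- attr(corp$compounds, "fingerprints")
  spec <- binning_spec(bin_count = 300)
  cfg <- tiny_cnn_config(input_length = 300L)
  pp <- preprocess_spectra(corp$spectra, spec = spec, merge = TRUE)
  y <- fps[pp$spectra$inchikey, , drop = FALSE]
  bundle <- fit_strategy(pp$binned, y, resolve_context(pp$spectra),
                         "single", cfg, epochs = 1)
  drop_keys <- corp$compounds$inchikey[1:2]
  db_missing <- corp$compounds[!corp$compounds$inchikey %in% drop_keys, ]
  queries <- corp$spectra
  report <- evaluate_annotation(queries, bundle, db_missing, true_fps = fps,
                                spec = spec)
  expect_equal(report$n_queries, 10)
  expect_equal(report$n_excluded_true_missing, 2)
  # true-present percentages use the smaller denominator, so they are >=
  expect_true(all(report$topk_true_present >= report$topk_all - 1e-12))
  td <- tidy(report)
  expect_equal(nrow(td), 2 * length(report$ks))
  expect_true(all(diff(td$accuracy[td$denominator == "all_queries"]) >= 0))
  g <- glance(report)
  expect_equal(g$n_excluded_true_missing, 2)

  # with every true compound present the two variants coincide
  report2 <- evaluate_annotation(queries, bundle, corp$compounds,
                                 true_fps = fps, spec = spec)
  expect_equal(report2$n_excluded_true_missing, 0)
  expect_equal(unname(report2$topk_all), unname(report2$topk_true_present))
})
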