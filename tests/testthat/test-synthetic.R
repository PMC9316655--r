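test_that("compound tables reproduce exactly under a fixed seed", {
  a <- generate_compound_table(30, seed = 7)
  b <- generate_compound_table(30, seed = 7)
  expect_identical(a, b)
  expect_identical(attr(a, "fingerprints"), attr(b, "fingerprints"))
  expect_false(identical(a, generate_compound_table(30, seed = 8)))
  expect_true(all(is_valid_inchikey(a$inchikey)))
  expect_true(all(a$monoisotopic_mass > 0))
})

test_that("set-bit prevalence follows the binomial expectation", {
  comp <- generate_compound_table(120, seed = 9, prevalence = 0.1,
                                  min_bits = 1L)
  fps <- attr(comp, "fingerprints")
  mean_bits <- mean(rowSums(fps))
  # binomial mean 52.8, SD sqrt(528 * .1 * .9)/sqrt(120) per the mean
  expect_lt(abs(mean_bits - 52.8), 3 * sqrt(528 * 0.1 * 0.9 / 120))
})

test_that("skeleton-sharing groups land in the table intact", {
  comp <- generate_compound_table(20, seed = 10, n_shared_groups = 1,
                                  shared_group_size = 5)
  blocks <- inchikey_block(comp$inchikey)
  expect_equal(max(table(blocks)), 5)
  split <- structure_disjoint_split(comp$inchikey, 0.6, seed = 1)
  shared <- names(which.max(table(blocks)))
  members <- comp$inchikey[blocks == shared]
  expect_true(all(members %in% split$train) || all(members %in% split$test))
})

test_that("the structure pool provides real chemistry for fingerprints", {
  pool <- bundled_metabolites()
  expect_gte(nrow(pool), 30)
  expect_true(all(is_valid_inchikey(pool$inchikey)))
  comp <- generate_compound_table(5, smiles_pool = pool)
  fps <- attr(comp, "fingerprints")
  expect_equal(dim(fps), c(5L, 528L))
  expect_true(all(rowSums(fps) > 0))
})

test_that("noiseless injective generation decodes back to the fingerprints", {
  comp <- generate_compound_table(8, seed = 21, mass_range = c(700, 1000))
  map <- planted_mapping(bin_range = c(50L, 650L), bins_per_bit = 1L,
                         injective = TRUE, seed = 22)
  sp <- generate_spectra(comp, map, spectra_per_compound = 1,
                         noise_sd = 0, dropout_prob = 0, seed = 23)
  pp <- preprocess_spectra(sp, spec = binning_spec(bin_count = 700),
                           merge = FALSE)
  decoded <- decode_planted(pp$binned, map)
  fps <- attr(comp, "fingerprints")
  expect_identical(unname(decoded),
                   unname(fps[pp$spectra$inchikey, , drop = FALSE]))
})

test_that("bin dropout thins excited peaks at the requested rate", {
  comp <- generate_compound_table(40, seed = 31)
  map <- planted_mapping(seed = 32)
  full <- generate_spectra(comp, map, spectra_per_compound = 1,
                           dropout_prob = 0, noise_sd = 0, seed = 33)
  half <- generate_spectra(comp, map, spectra_per_compound = 1,
                           dropout_prob = 0.5, noise_sd = 0, seed = 33)
  n_full <- sum(vapply(full$peaks, nrow, integer(1)))
  n_half <- sum(vapply(half$peaks, nrow, integer(1)))
  # binomial thinning at 1/2 (the generator keeps a >= 5 peak floor,
  # which biases the count slightly upward)
  expect_lt(abs(n_half - 0.5 * n_full), 3 * sqrt(n_full * 0.25) + 0.05 * n_full)
})

test_that("corrupted spectra fail the peak-count filter by construction", {
  comp <- generate_compound_table(5, seed = 41)
  map <- planted_mapping(seed = 42)
  bad <- generate_spectra(comp, map, spectra_per_compound = 1,
                          corruption = "few-peaks", seed = 43)
  flt <- filter_spectra(bad)
  expect_true(all(!flt$kept))
  expect_true(all(flt$reject_reason == "too_few_peaks"))
})

test_that("generated records round-trip through the MSP writer", {
  corp <- tiny_planted_corpus(n_compounds = 6, spectra_per_compound = 2,
                              seed = 51)
  sp <- corp$spectra[, setdiff(names(corp$spectra), "true_inchikey")]
  back <- parse_msp(write_msp(sp))
  expect_equal(nrow(back), nrow(sp))
  expect_equal(back$inchikey, sp$inchikey)
  expect_equal(back$precursor_mz, sp$precursor_mz, tolerance = 1e-10)
  expect_equal(back$collision_energy_ev, sp$collision_energy_ev)
})

test_that("requested context distribution is realised within tolerance", {
  comp <- generate_compound_table(60, seed = 61)
  map <- planted_mapping(seed = 62)
  probs <- setNames(c(0.5, 0.5, rep(0, 6)), context_keys())
  sp <- generate_spectra(comp, map, contexts = probs,
                         spectra_per_compound = 4, seed = 63)
  ctx <- resolve_context(sp)
  counts <- table(factor(ctx$context_key, levels = context_keys()))
  expect_equal(sum(counts[3:8]), 0)
  n <- sum(counts)
  expect_lt(abs(counts[1] - 0.5 * n), 3 * sqrt(n * 0.25))
})

test_that("the miniature benchmark is disjoint, covered and reproducible", {
  bench <- make_benchmark(seed = 71, n_compounds = 60,
                          spectra_per_compound = 2)
  expect_length(intersect(inchikey_block(bench$split$train),
                          inchikey_block(bench$split$test)), 0)
  expect_true(all(bench$truth$inchikey %in% bench$compounds$inchikey))
  ctx <- resolve_context(dplyr::bind_rows(bench$train_spectra,
                                          bench$test_spectra))
  expect_equal(length(unique(ctx$context_key)), 8)
  bench2 <- make_benchmark(seed = 71, n_compounds = 60,
                           spectra_per_compound = 2)
  expect_identical(bench$compounds, bench2$compounds)
  expect_identical(bench$train_spectra, bench2$train_spectra)
})
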