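test_that("intensity scaling maps the base peak to the ceiling", {
  pk <- data.frame(mz = c(100, 110, 120), intensity = c(10, 20, 40))
  expect_equal(scale_intensities(pk)$intensity, c(25, 50, 100))
  one <- scale_intensities(data.frame(mz = 50, intensity = 0.37))
  expect_equal(one$intensity, 100)
  # idempotent at the ceiling
  scaled <- scale_intensities(pk)
  expect_equal(scale_intensities(scaled)$intensity, scaled$intensity)
  expect_error(scale_intensities(data.frame(mz = 1, intensity = 0)),
               class = "specfp_degenerate_spectrum")
})

test_that("the five-peaks / 2 percent filter reproduces hand decisions", {
  pass <- good_spectrum(mz = 101:106,
                        intensity = c(100, 50, 30, 10, 3, 1))
  out <- filter_spectrum(pass)
  expect_true(out$kept)       # 5 peaks above 2% of base
  fail <- good_spectrum(mz = 101:106,
                        intensity = c(100, 50, 1, 1, 1, 1))
  out2 <- filter_spectrum(fail)
  expect_false(out2$kept)     # only 2 peaks above 2%
  expect_equal(out2$reject_reason, "too_few_peaks")
})

test_that("peaks above the precursor are dropped before anything else", {
  s <- good_spectrum(mz = c(150, 299, 301, 120, 130, 140),
                     intensity = c(100, 90, 1e5, 80, 70, 60),
                     precursor_mz = 300)
  out <- filter_spectrum(s)
  expect_true(out$kept)
  expect_false(301 %in% out$peaks[[1]]$mz)
  # the spurious 1e5 peak at 301 must not act as the base peak
  expect_equal(max(out$peaks[[1]]$intensity), 100)
})

test_that("instrument, precursor and mass-window rules reject with reasons", {
  s <- good_spectrum(instrument_type = "FTICR")
  expect_equal(filter_spectrum(s)$reject_reason, "instrument_type")
  s2 <- good_spectrum(precursor_mz = NA)
  expect_equal(filter_spectrum(s2)$reject_reason, "missing_precursor")
  # neutral mass 181.0707 - 1.00728 = 180.06 is inside [100, 1010];
  # shrinking the window rejects it
  s3 <- good_spectrum()
  cfg <- preprocess_config(mass_min = 200, mass_max = 1010)
  expect_equal(filter_spectrum(s3, cfg)$reject_reason, "mass_range")
  expect_true(filter_spectrum(s3)$kept)
})

test_that("relaxing the filter thresholds never rejects a previously kept spectrum", {
  set.seed(7)
  spectra <- dplyr::bind_rows(lapply(1:40, function(i) {
    good_spectrum(id = paste0("m", i),
                  mz = sort(runif(8, 50, 170)),
                  intensity = runif(8, 0.5, 100))
  }))
  strict <- filter_spectra(spectra, preprocess_config(min_peaks = 6,
                                                      min_rel_intensity = 5))
  loose <- filter_spectra(spectra, preprocess_config(min_peaks = 4,
                                                     min_rel_intensity = 1))
  expect_true(all(loose$kept[strict$kept]))
})

test_that("merging collapses records per InChIKey and accumulates coincident peaks", {
  key <- "AAAAAAAAAAAAAA-BBBBBBBBBB-N"
  a <- good_spectrum(id = "a", mz = c(100.2, 120.3), intensity = c(100, 50),
                     inchikey = key)
  b <- good_spectrum(id = "b", mz = c(100.4, 130.1), intensity = c(40, 100),
                     inchikey = key)
  c <- good_spectrum(id = "c", mz = c(100.2, 120.3), intensity = c(10, 10),
                     inchikey = key)
  merged <- merge_spectra(dplyr::bind_rows(a, b, c))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_merged, 3)
  pk <- merged$peaks[[1]]
  # peaks at 100.2 and 100.4 share integer bin 100: 100 + 40 + 10 = 150,
  # the new base peak, rescaled to 100
  expect_equal(nrow(pk), 3)
  expect_equal(max(pk$intensity), 100)
  expect_equal(pk$intensity[floor(pk$mz) == 100], 100)
  expect_equal(pk$intensity[floor(pk$mz) == 120], (50 + 10) / 150 * 100)

  # disjoint keys stay separate; keyless records pass through flagged
  d <- good_spectrum(id = "d", inchikey = "CCCCCCCCCCCCCC-DDDDDDDDDD-N")
  e <- good_spectrum(id = "e", inchikey = NA)
  out <- merge_spectra(dplyr::bind_rows(a, d, e))
  expect_equal(nrow(out), 3)
  expect_equal(sum(out$unmerged_no_key), 1)
})

test_that("binning accumulates by floored m/z and conserves in-range intensity", {
  v <- bin_spectrum(data.frame(mz = c(150.2, 150.9, 151.1),
                               intensity = c(60, 40, 100)),
                    binning_spec(bin_count = 200))
  expect_equal(v[150], 100)
  expect_equal(v[151], 100)
  expect_equal(sum(v), 200)
  expect_equal(bin_spectrum(data.frame(mz = numeric(), intensity = numeric()),
                            binning_spec(bin_count = 50)),
               numeric(50), ignore_attr = TRUE)
  # one peak per distinct integer bin reproduces the intensities
  pk <- data.frame(mz = c(10.5, 20.5, 30.5), intensity = c(1, 2, 3))
  v2 <- bin_spectrum(pk, binning_spec(bin_count = 40))
  expect_equal(v2[c(10, 20, 30)], c(1, 2, 3))
})

test_that("binning agrees with a naive double-loop accumulator on random spectra", {
  set.seed(11)
  spec <- binning_spec(bin_start = 1, bin_count = 200)
  for (i in 1:200) {
    pk <- random_peaks(sample(1:30, 1), mz_max = 250)
    naive <- numeric(spec$bin_count)
    for (p in seq_len(nrow(pk))) {
      b <- floor(pk$mz[p])
      if (b >= spec$bin_start && b < spec$bin_start + spec$bin_count) {
        naive[b - spec$bin_start + 1] <- naive[b - spec$bin_start + 1] + pk$intensity[p]
      }
    }
    expect_equal(as.numeric(bin_spectrum(pk, spec)), naive, tolerance = 1e-12)
  }
})

test_that("all-zero columns are dropped and reapplied consistently", {
  m <- rbind(c(1, 0, 2, 0), c(3, 0, 0, 0), c(0, 0, 1, 0))
  red <- drop_zero_bins(m)
  expect_equal(red$kept_bins, c(1L, 3L))
  expect_equal(ncol(red$values), 2)
  expect_equal(project_bins(rbind(c(9, 9, 9, 9)), red$kept_bins),
               rbind(c(9, 9)))
  # no zero columns: identity
  full <- drop_zero_bins(rbind(c(1, 2), c(3, 4)))
  expect_equal(full$kept_bins, c(1L, 2L))
  expect_warning(empty <- drop_zero_bins(rbind(c(0, 0))), "zero")
  expect_equal(length(empty$kept_bins), 0)
})

test_that("context bits append in (energy, resolution, mode) order exactly once", {
  v <- numeric(1174)
  ctx_high <- tibble::tibble(energy = "high", resolution = "high", mode = "positive")
  out <- attach_context(v, ctx_high)
  expect_length(out, 1177)
  expect_equal(tail(as.numeric(out), 3), c(1, 1, 1))
  ctx_low <- tibble::tibble(energy = "low", resolution = "low", mode = "negative")
  expect_equal(tail(as.numeric(attach_context(v, ctx_low)), 3), c(0, 0, 0))
  expect_error(attach_context(out, ctx_high), "already")
  expect_error(attach_context(v, tibble::tibble(energy = NA_character_,
                                                resolution = "low",
                                                mode = "negative")),
               "Unresolved")
})

test_that("the pipeline conserves binned intensity for kept spectra", {
  set.seed(21)
  corp <- tiny_planted_corpus(n_compounds = 8)
  pp <- preprocess_spectra(corp$spectra, spec = binning_spec(bin_count = 300),
                           merge = FALSE)
  for (r in seq_len(nrow(pp$spectra))) {
    expect_equal(sum(pp$binned$values[r, ]),
                 sum(pp$spectra$peaks[[r]]$intensity), tolerance = 1e-9)
  }
})
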