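# Shared fixture builders. Everything is generated in code; no files.

msp_two_entries <- function() {
  paste(
    "Name: spec-one",
    "InChIKey: AAAAAAAAAAAAAA-BBBBBBBBBB-N",
    "Ion_mode: P",
    "PrecursorMZ: 181.0707",
    "Num Peaks: 3",
    "100.1 50",
    "99.2 10",
    "120.5 30",
    "",
    "Name: spec-two",
    "Ion_mode: N",
    "PrecursorMZ: 300.2",
    "MyCustomKey: kept-verbatim",
    "Num Peaks: 5",
    "50 1",
    "60 2",
    "70 3",
    "80 4",
    "90 5",
    sep = "\n")
}

# a spectrum tibble that passes the default filters
good_spectrum <- function(id = "ok", mz = c(110, 120, 130, 140, 150),
                          intensity = c(100, 80, 60, 40, 20),
                          precursor_mz = 181.0707,
                          instrument_type = "Orbitrap",
                          ionization_mode = "positive",
                          adduct = "[M+H]+",
                          inchikey = "AAAAAAAAAAAAAA-BBBBBBBBBB-N",
                          collision_energy_raw = "35 eV") {
  spectrum_record(
    data.frame(mz = mz, intensity = intensity),
    spectrum_id = id, inchikey = inchikey,
    ionization_mode = ionization_mode, adduct = adduct,
    precursor_mz = precursor_mz, instrument_type = instrument_type,
    collision_energy_raw = collision_energy_raw)
}

random_inchikey_for_tests <- function() {
  paste0(paste(sample(LETTERS, 14, TRUE), collapse = ""), "-",
         paste(sample(LETTERS, 10, TRUE), collapse = ""), "-N")
}

random_peaks <- function(n, mz_max = 500) {
  data.frame(mz = runif(n, 1, mz_max), intensity = runif(n, 0.1, 100))
}

# tiny CNN configuration for fast structural tests
tiny_cnn_config <- function(...) {
  defaults <- list(input_length = 40L, embedding_vocab = 11L,
                   embedding_dim = 4L, conv_filters = c(3L, 4L),
                   conv_kernels = c(3L, 3L), pool_sizes = c(2L, 2L),
                   dropout_rate = 0.2, dense_sizes = c(16L, 12L, 10L, 8L),
                   epochs = 3L, batch_size = 16L, seed = 7L)
  do.call(cnn_config, utils::modifyList(defaults, list(...)))
}

# small corpus with a planted mapping confined to a narrow bin range
tiny_planted_corpus <- function(n_compounds = 12, spectra_per_compound = 2,
                                seed = 5, bin_hi = 120L, ...) {
  compounds <- generate_compound_table(n_compounds, seed = seed,
                                       mass_range = c(400, 900))
  mapping <- planted_mapping(bin_range = c(20L, bin_hi), seed = seed + 1)
  spectra <- generate_spectra(compounds, mapping,
                              spectra_per_compound = spectra_per_compound,
                              seed = seed + 2, ...)
  list(compounds = compounds, mapping = mapping, spectra = spectra)
}
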