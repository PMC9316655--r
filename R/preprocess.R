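# The preprocessing chain that turns raw spectra into fixed-length model
# inputs: select(instrument) -> scale -> filter -> [merge] -> bin. The
# merge step is skipped at prediction/testing time so that individual
# spectra are evaluated.

#' Preprocessing configuration
#'
#' Collects the tunable constants of the spectral cleaning chain.
#'
#' @param min_peaks Minimum number of peaks above the relative-intensity
#'   floor for a spectrum to be kept (default 5).
#' @param min_rel_intensity Relative-intensity floor as percent of the
#'   base peak (default 2).
#' @param mass_min,mass_max Accepted neutral monoisotopic mass window in
#'   Da (default 100–1010).
#' @param scale_max Intensity ceiling after max-normalisation (default
#'   100, so scaled intensities double as relative percentages).
#' @param allowed_instrument_types Instrument classes retained by the
#'   selection step. Matched after [normalize_instrument_type()].
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(min_peaks = 5L,
                              min_rel_intensity = 2,
                              mass_min = 100,
                              mass_max = 1010,
                              scale_max = 100,
                              allowed_instrument_types = c("Orbitrap", "QqQ", "Q-TOF", "IT")) {
  stopifnot(min_peaks >= 1, min_rel_intensity >= 0, min_rel_intensity < 100,
            mass_min < mass_max, scale_max > 0)
  structure(
    list(min_peaks = as.integer(min_peaks),
         min_rel_intensity = min_rel_intensity,
         mass_min = mass_min, mass_max = mass_max,
         scale_max = scale_max,
         allowed_instrument_types = allowed_instrument_types),
    class = "preprocess_config")
}

#' Integer m/z binning specification
#'
#' Bins are consecutive half-open unit intervals `[b, b+1)` for
#' `b = bin_start, ..., bin_start + bin_count - 1`; a peak falls in the
#' bin of its floored m/z. The default 1174 bins starting at m/z 1 give
#' the canonical model input width.
#'
#' @param bin_start First integer m/z covered (default 1).
#' @param bin_count Number of unit bins (default 1174).
#' @return A `binning_spec` list (bin width is fixed at 1 Th).
#' @export
binning_spec <- function(bin_start = 1L, bin_count = 1174L) {
  stopifnot(bin_count >= 1, bin_start >= 0)
  structure(list(bin_start = as.integer(bin_start),
                 bin_count = as.integer(bin_count),
                 bin_width = 1L),
            class = "binning_spec")
}

#' Normalize instrument-type strings
#'
#' Maps the vendor spellings seen in spectral libraries onto the four
#' canonical classes `Orbitrap`, `QqQ`, `Q-TOF`, `IT`; anything else is
#' returned unchanged.
#'
#' @param x Character vector.
#' @return Character vector of canonical classes.
#' @export
normalize_instrument_type <- function(x) {
  key <- gsub("[^a-z]", "", tolower(x))
  out <- case_when(
    grepl("orbitrap", key) ~ "Orbitrap",
    key %in% c("qqq", "triplequadrupole", "qqqms", "tripleq") ~ "QqQ",
    grepl("qtof|quadrupoletof|qq?tof", key) ~ "Q-TOF",
    key %in% c("it", "iontrap", "ittof", "lineariontrap", "itft", "qit") ~ "IT",
    TRUE ~ as.character(x)
  )
  out[is.na(x)] <- NA_character_
  out
}

#' Max-normalise peak intensities
#'
#' Rescales intensities so the base peak equals `scale_max` and all values
#' lie in `[0, scale_max]`: `x -> x / max(x) * scale_max`. The implicit
#' minimum is 0 (a literal min–max map would zero the smallest observed
#' peak and defeat the relative-intensity filter).
#'
#' @param peaks Peak data frame (`mz`, `intensity`).
#' @param scale_max Ceiling, default 100.
#' @return Peak tibble with scaled intensities, order preserved.
#' @export
scale_intensities <- function(peaks, scale_max = 100) {
  peaks <- as_tibble(peaks)
  m <- max(peaks$intensity)
  if (!nrow(peaks) || m <= 0) {
    abort("Degenerate spectrum: no peak with positive intensity.",
          class = "specfp_degenerate_spectrum")
  }
  peaks$intensity <- peaks$intensity / m * scale_max
  peaks
}

# Default adduct table: name, mass shift (Da) added to the neutral
# molecule, charge (sign carries the polarity). Proton 1.007276 Da.
#' Built-in adduct table
#'
#' @return Tibble with columns `adduct`, `mass_shift` (Da, observed m/z
#'   minus neutral monoisotopic mass for singly charged ions) and
#'   `charge`.
#' @export
default_adducts <- function() {
  tibble(
    adduct = c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M-H]-", "[M+Cl]-"),
    mass_shift = c(1.007276, 22.989218, 18.033823, -1.007276, 34.969402),
    charge = c(1L, 1L, 1L, -1L, -1L)
  )
}

# Neutral monoisotopic mass implied by precursor m/z + adduct; falls back
# to exact_mass when the adduct is unknown, then to a mode-default adduct.
neutral_mass <- function(precursor_mz, adduct, exact_mass, ionization_mode,
                         adducts = default_adducts()) {
  shift <- adducts$mass_shift[match(adduct, adducts$adduct)]
  out <- precursor_mz - shift
  fallback <- is.na(out)
  out[fallback] <- exact_mass[fallback]
  still <- is.na(out) & !is.na(precursor_mz)
  if (any(still)) {
    mode_shift <- ifelse(ionization_mode[still] == "negative", -1.007276, 1.007276)
    out[still] <- precursor_mz[still] - mode_shift
  }
  out
}

#' Filter and scale spectra
#'
#' Applies the cleaning rules to every spectrum and annotates the result
#' rather than silently dropping rows:
#' (1) the spectrum is rejected when its (normalised) instrument type is
#' not in the allowed set; (2) peaks with m/z above the precursor are
#' removed; (3) intensities are max-scaled to `scale_max`; (4) the
#' spectrum is rejected when fewer than `min_peaks` remaining peaks exceed
#' `min_rel_intensity` percent of the base peak (measured after rule 2, so
#' spurious super-precursor peaks cannot mask real ones); (5) the spectrum
#' is rejected when the neutral monoisotopic mass implied by precursor and
#' adduct (falling back to `exact_mass`) lies outside
#' `[mass_min, mass_max]`. A missing precursor m/z is itself a rejection
#' reason because rule 2 cannot be applied.
#'
#' @param spectra Spectrum tibble.
#' @param cfg A [preprocess_config()].
#' @return The tibble with scaled, filtered `peaks` plus logical `kept`
#'   and character `reject_reason` columns.
#' @export
filter_spectra <- function(spectra, cfg = preprocess_config()) {
  n <- nrow(spectra)
  reason <- rep(NA_character_, n)
  peaks_out <- spectra$peaks
  itype <- normalize_instrument_type(spectra$instrument_type)
  nmass <- neutral_mass(spectra$precursor_mz, spectra$adduct,
                        spectra$exact_mass, spectra$ionization_mode)
  for (r in seq_len(n)) {
    if (is.na(itype[r]) || !itype[r] %in% cfg$allowed_instrument_types) {
      reason[r] <- "instrument_type"; next
    }
    if (is.na(spectra$precursor_mz[r])) { reason[r] <- "missing_precursor"; next }
    pk <- spectra$peaks[[r]]
    pk <- pk[pk$mz <= spectra$precursor_mz[r], ]
    if (!nrow(pk) || max(pk$intensity) <= 0) { reason[r] <- "no_signal"; next }
    pk <- scale_intensities(pk, cfg$scale_max)
    n_above <- sum(pk$intensity > cfg$min_rel_intensity / 100 * cfg$scale_max)
    if (n_above < cfg$min_peaks) { reason[r] <- "too_few_peaks"; next }
    if (is.na(nmass[r]) || nmass[r] < cfg$mass_min || nmass[r] > cfg$mass_max) {
      reason[r] <- "mass_range"; next
    }
    peaks_out[[r]] <- pk
  }
  spectra$peaks <- peaks_out
  spectra$kept <- is.na(reason)
  spectra$reject_reason <- reason
  spectra
}

#' Filter a single spectrum
#'
#' Single-record convenience over [filter_spectra()].
#'
#' @param record One-row spectrum tibble.
#' @inheritParams filter_spectra
#' @return The filtered one-row tibble (`kept`/`reject_reason` columns
#'   added).
#' @export
filter_spectrum <- function(record, cfg = preprocess_config()) {
  filter_spectra(record, cfg)
}

#' Merge spectra of the same compound
#'
#' Collapses all (already filtered and scaled) spectra sharing a full
#' InChIKey into one consensus record: member peak lists are pooled,
#' coincident peaks (same integer m/z bin) accumulate their intensities
#' (the representative m/z is the intensity-weighted mean), and the pooled
#' list is re-scaled to `scale_max`. The merged precursor m/z is taken
#' from the most frequent adduct group among members. Records without an
#' InChIKey pass through unmerged and are flagged.
#'
#' @param spectra Spectrum tibble (filtered rows).
#' @param scale_max Re-scaling ceiling (default 100).
#' @return A spectrum tibble with one row per distinct InChIKey plus the
#'   unmergeable rows; extra columns `n_merged` (member count) and
#'   `merged_from` (list of member spectrum ids), and logical `unmerged_no_key`.
#' @export
merge_spectra <- function(spectra, scale_max = 100) {
  has_key <- !is.na(spectra$inchikey)
  loose <- spectra[!has_key, ]
  keyed <- spectra[has_key, ]
  merged <- list()
  for (key in unique(keyed$inchikey)) {
    members <- keyed[keyed$inchikey == key, ]
    pooled <- bind_rows(members$peaks)
    bin <- floor(pooled$mz)
    agg <- pooled |>
      mutate(bin = bin) |>
      group_by(bin) |>
      summarise(mz = sum(.data$mz * .data$intensity) / sum(.data$intensity),
                intensity = sum(.data$intensity), .groups = "drop") |>
      select("mz", "intensity") |>
      arrange(.data$mz)
    agg <- scale_intensities(agg, scale_max)
    # representative metadata: modal adduct group defines the precursor
    adduct_tab <- sort(table(members$adduct[!is.na(members$adduct)]), decreasing = TRUE)
    rep_adduct <- if (length(adduct_tab)) names(adduct_tab)[1] else NA_character_
    in_group <- if (is.na(rep_adduct)) rep(TRUE, nrow(members)) else
      !is.na(members$adduct) & members$adduct == rep_adduct
    rep_row <- members[which(in_group)[1], ]
    rep_row$precursor_mz <- mean(members$precursor_mz[in_group], na.rm = TRUE)
    rep_row$peaks <- list(agg)
    rep_row$n_merged <- nrow(members)
    rep_row$merged_from <- list(members$spectrum_id)
    merged[[length(merged) + 1L]] <- rep_row
  }
  out_m <- if (length(merged)) bind_rows(merged) else NULL
  if (nrow(loose)) {
    loose$n_merged <- 1L
    loose$merged_from <- as.list(loose$spectrum_id)
  }
  out <- bind_rows(out_m, loose)
  out$unmerged_no_key <- is.na(out$inchikey)
  out
}

#' Bin one peak list onto the integer m/z grid
#'
#' Accumulates the intensity of every peak whose floored m/z falls in the
#' covered range into its unit bin. In-range total intensity is conserved;
#' out-of-range peaks are dropped and counted in the `"n_dropped"`
#' attribute.
#'
#' @param peaks Peak data frame (scaled).
#' @param spec A [binning_spec()].
#' @return Numeric vector of length `spec$bin_count`.
#' @examples
#' bin_spectrum(data.frame(mz = c(150.2, 150.9, 151.1),
#'                         intensity = c(60, 40, 100)),
#'              binning_spec(bin_count = 200))[150:151]
#' @export
bin_spectrum <- function(peaks, spec = binning_spec()) {
  v <- numeric(spec$bin_count)
  idx <- floor(peaks$mz) - spec$bin_start + 1L
  keep <- idx >= 1L & idx <= spec$bin_count
  if (any(keep)) {
    s <- rowsum(peaks$intensity[keep], idx[keep])
    v[as.integer(rownames(s))] <- s[, 1]
  }
  attr(v, "n_dropped") <- sum(!keep)
  v
}

#' Bin a spectrum collection into a dense matrix
#'
#' @param spectra Spectrum tibble (rows to use; typically the `kept` rows
#'   after [filter_spectra()]).
#' @param spec A [binning_spec()].
#' @return A `binned_spectra` object: list with `values` (numeric matrix,
#'   one row per spectrum), `meta` (tibble: spectrum_id, inchikey,
#'   compound_key) and `spec`.
#' @export
bin_spectra <- function(spectra, spec = binning_spec()) {
  mat <- matrix(0, nrow(spectra), spec$bin_count)
  for (r in seq_len(nrow(spectra))) {
    mat[r, ] <- bin_spectrum(spectra$peaks[[r]], spec)
  }
  new_binned_spectra(
    values = mat,
    meta = tibble(spectrum_id = spectra$spectrum_id,
                  inchikey = spectra$inchikey,
                  compound_key = inchikey_block(spectra$inchikey)),
    spec = spec)
}

new_binned_spectra <- function(values, meta, spec, context_attached = FALSE) {
  structure(list(values = values, meta = meta, spec = spec,
                 context_attached = context_attached),
            class = "binned_spectra")
}

#' @export
print.binned_spectra <- function(x, ...) {
  cat(sprintf("<binned_spectra: %d spectra x %d bins%s>\n",
              nrow(x$values), x$spec$bin_count,
              if (x$context_attached) " + 3 context bits" else ""))
  invisible(x)
}

#' @export
dim.binned_spectra <- function(x) dim(x$values)

#' Drop bins that are zero in every spectrum
#'
#' Dimension reduction for the flat baseline models (logistic regression,
#' SLP, SVM, MLP): columns identically zero across the whole training
#' matrix carry no information and are removed. The convolutional model
#' keeps all bins, because convolution requires consecutive bins.
#'
#' @param x A `binned_spectra` object or plain numeric matrix.
#' @return List with `values` (reduced matrix) and `kept_bins` (column
#'   indices retained, for projecting new spectra with
#'   [project_bins()]).
#' @export
drop_zero_bins <- function(x) {
  mat <- if (inherits(x, "binned_spectra")) x$values else x
  stopifnot(nrow(mat) >= 1)
  kept <- which(colSums(mat != 0) > 0)
  if (!length(kept)) warn("All bins are zero across all spectra.")
  list(values = mat[, kept, drop = FALSE], kept_bins = kept)
}

#' Project spectra onto a reduced bin space
#'
#' @param x `binned_spectra` or matrix.
#' @param kept_bins Column index vector from [drop_zero_bins()].
#' @return Numeric matrix restricted to `kept_bins`.
#' @export
project_bins <- function(x, kept_bins) {
  mat <- if (inherits(x, "binned_spectra")) x$values else x
  mat[, kept_bins, drop = FALSE]
}

#' Append instrument-context bits to binned spectra
#'
#' Extends each binned vector by three binary entries encoding the
#' instrument context in the fixed order (energy, resolution, mode):
#' high energy = 1, high resolution = 1, positive mode = 1.
#'
#' @param binned A `binned_spectra` object (or bare numeric vector for a
#'   single spectrum).
#' @param ctx A context tibble from [resolve_context()] (columns `energy`,
#'   `resolution`, `mode`), one row per spectrum — or one row to recycle.
#' @return The augmented object; width grows by 3. Applying twice is an
#'   error.
#' @export
attach_context <- function(binned, ctx) {
  enc <- context_bits(ctx)
  if (is.numeric(binned) && is.null(dim(binned))) {
    if (!is.null(attr(binned, "context_attached"))) {
      abort("Context bits already attached.")
    }
    stopifnot(nrow(enc) == 1)
    out <- c(as.numeric(binned), as.numeric(enc[1, ]))
    attr(out, "context_attached") <- TRUE
    return(out)
  }
  stopifnot(inherits(binned, "binned_spectra"))
  if (binned$context_attached) abort("Context bits already attached.")
  if (nrow(enc) == 1 && nrow(binned$values) > 1) {
    enc <- enc[rep(1, nrow(binned$values)), , drop = FALSE]
  }
  stopifnot(nrow(enc) == nrow(binned$values))
  values <- cbind(binned$values, unname(as.matrix(enc)))
  new_binned_spectra(values, binned$meta, binned$spec,
                     context_attached = TRUE)
}

context_bits <- function(ctx) {
  stopifnot(all(c("energy", "resolution", "mode") %in% names(ctx)))
  if (anyNA(ctx$energy) || anyNA(ctx$resolution) || anyNA(ctx$mode)) {
    abort("Unresolved instrument context (NA field).")
  }
  tibble(energy_bit = as.numeric(ctx$energy == "high"),
         resolution_bit = as.numeric(ctx$resolution == "high"),
         mode_bit = as.numeric(ctx$mode == "positive"))
}

#' Run the full preprocessing chain
#'
#' select(instrument) -> scale -> filter -> merge (training only) -> bin.
#' At testing/prediction time merging is skipped so that individual
#' spectra are evaluated.
#'
#' @param spectra Spectrum tibble.
#' @param cfg A [preprocess_config()].
#' @param spec A [binning_spec()].
#' @param merge Merge spectra of the same compound (`TRUE` for training
#'   corpora, `FALSE` for evaluation queries).
#' @return List with `binned` (a `binned_spectra`), `spectra` (the kept,
#'   possibly merged records) and `rejected` (rows with reasons).
#' @export
preprocess_spectra <- function(spectra, cfg = preprocess_config(),
                               spec = binning_spec(), merge = TRUE) {
  flt <- filter_spectra(spectra, cfg)
  rejected <- flt[!flt$kept, c("spectrum_id", "reject_reason")]
  kept <- flt[flt$kept, setdiff(names(flt), c("kept", "reject_reason"))]
  if (merge && nrow(kept)) kept <- merge_spectra(kept, cfg$scale_max)
  list(binned = bin_spectra(kept, spec), spectra = kept, rejected = rejected)
}
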