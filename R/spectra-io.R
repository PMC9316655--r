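# Reading and writing MS/MS spectral libraries (MSP / MGF text dialects).
#
# A spectrum collection is a tibble with one row per spectrum. The 16
# metadata fields carried for every spectrum match what MS/MS libraries
# such as NIST-style MSP exports and MoNA dumps provide; the fragment peak
# list lives in the `peaks` list-column (a tibble of mz / intensity sorted
# ascending by mz), and unrecognised metadata keys are preserved verbatim
# in the `extra` list-column.

SPECTRUM_COLUMNS <- c(
  "spectrum_id", "inchikey", "smiles", "source", "ionization_mode", "adduct",
  "precursor_mz", "exact_mass", "instrument_type", "instrument",
  "collision_energy_raw", "collision_energy_ev", "mass_accuracy",
  "library", "external_ids"
)

#' Construct a single spectrum record
#'
#' Builds a one-row spectrum tibble with the full metadata schema used
#' throughout the package. Unspecified fields are `NA`; `peaks` are sorted
#' ascending by m/z on construction.
#'
#' @param peaks A data frame with numeric columns `mz` (> 0) and
#'   `intensity` (>= 0).
#' @param spectrum_id Identifier string.
#' @param inchikey 27-character InChIKey (format-checked, not checksummed),
#'   or `NA`.
#' @param smiles SMILES string or `NA`.
#' @param ionization_mode `"positive"`, `"negative"` or `NA`.
#' @param adduct Adduct notation such as `"[M+H]+"`, or `NA`.
#' @param precursor_mz Precursor mass-to-charge ratio (Th).
#' @param exact_mass Neutral monoisotopic mass (Da) if known.
#' @param instrument_type,instrument Instrument class and model strings.
#' @param collision_energy_raw Vendor collision-energy string as found in
#'   the source file; the parsed eV value is derived with
#'   [parse_collision_energy()].
#' @param mass_accuracy Stated mass accuracy (ppm) or `NA`.
#' @param source,library,external_ids Provenance strings.
#' @param extra Named character vector of passthrough metadata keys.
#'
#' @return A one-row tibble with the spectrum schema.
#' @examples
#' spectrum_record(data.frame(mz = c(99.2, 100.1), intensity = c(10, 50)),
#'                 spectrum_id = "demo", precursor_mz = 181.07)
#' @export
spectrum_record <- function(peaks,
                            spectrum_id = NA_character_,
                            inchikey = NA_character_,
                            smiles = NA_character_,
                            source = NA_character_,
                            ionization_mode = NA_character_,
                            adduct = NA_character_,
                            precursor_mz = NA_real_,
                            exact_mass = NA_real_,
                            instrument_type = NA_character_,
                            instrument = NA_character_,
                            collision_energy_raw = NA_character_,
                            mass_accuracy = NA_real_,
                            library = NA_character_,
                            external_ids = NA_character_,
                            extra = character()) {
  peaks <- as_peak_tbl(peaks)
  if (!is.na(ionization_mode) &&
      !ionization_mode %in% c("positive", "negative")) {
    abort("`ionization_mode` must be \"positive\", \"negative\" or NA.")
  }
  if (!is.na(inchikey) && !is_valid_inchikey(inchikey)) {
    abort(sprintf("Not a format-valid InChIKey: '%s'", inchikey))
  }
  tibble(
    spectrum_id = as.character(spectrum_id),
    inchikey = as.character(inchikey),
    smiles = as.character(smiles),
    source = as.character(source),
    ionization_mode = as.character(ionization_mode),
    adduct = as.character(adduct),
    precursor_mz = as.numeric(precursor_mz),
    exact_mass = as.numeric(exact_mass),
    instrument_type = as.character(instrument_type),
    instrument = as.character(instrument),
    collision_energy_raw = as.character(collision_energy_raw),
    collision_energy_ev = parse_collision_energy(as.character(collision_energy_raw)),
    mass_accuracy = as.numeric(mass_accuracy),
    library = as.character(library),
    external_ids = as.character(external_ids),
    peaks = list(peaks),
    extra = list(extra)
  )
}

as_peak_tbl <- function(peaks) {
  peaks <- as_tibble(peaks)
  if (!all(c("mz", "intensity") %in% names(peaks))) {
    abort("`peaks` needs `mz` and `intensity` columns.")
  }
  peaks <- peaks[c("mz", "intensity")]
  peaks$mz <- as.numeric(peaks$mz)
  peaks$intensity <- as.numeric(peaks$intensity)
  if (nrow(peaks) && (any(peaks$mz <= 0) || any(peaks$intensity < 0))) {
    abort("Peaks must have mz > 0 and intensity >= 0.")
  }
  peaks[order(peaks$mz), ]
}

#' Check InChIKey format
#'
#' Format-only validation (27 characters in a 14-10-1 hyphenated layout of
#' uppercase letters); the internal checksum is not verified.
#'
#' @param x Character vector.
#' @return Logical vector.
#' @export
is_valid_inchikey <- function(x) {
  !is.na(x) & grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x)
}

#' First block (2D skeleton) of an InChIKey
#'
#' The leading 14 characters hash the bond skeleton and are the unit of
#' structure-disjoint train/test separation.
#'
#' @param x Character vector of InChIKeys.
#' @return Character vector of 14-character blocks (`NA` passed through).
#' @export
inchikey_block <- function(x) {
  ifelse(is.na(x), NA_character_, substr(x, 1L, 14L))
}

# Case-insensitive metadata synonym table: MSP/MGF dialects differ between
# libraries, so keys are normalised before mapping onto the schema.
METADATA_SYNONYMS <- list(
  spectrum_id = c("name", "title", "spectrum id", "spectrumid", "db#"),
  inchikey = c("inchikey", "inchi key"),
  smiles = c("smiles"),
  source = c("source", "data source"),
  ionization_mode = c("ion mode", "ion_mode", "ionmode", "ionization mode",
                      "ionization_mode", "ionization", "polarity", "mode"),
  adduct = c("precursor_type", "precursortype", "precursor type", "adduct"),
  precursor_mz = c("precursormz", "precursor m/z", "precursor_mz", "pepmass",
                   "precursor mz"),
  exact_mass = c("exactmass", "exact mass", "exact_mass", "mw"),
  instrument_type = c("instrument_type", "instrumenttype", "instrument type"),
  instrument = c("instrument"),
  collision_energy_raw = c("collision_energy", "collisionenergy",
                           "collision energy", "ce"),
  mass_accuracy = c("mass_accuracy", "mass accuracy", "ms_mass_analyzer_accuracy"),
  library = c("library", "library_membership"),
  external_ids = c("external_ids", "externalids", "external ids", "casno",
                   "cas#")
)

normalize_meta_key <- function(key) {
  key <- tolower(trimws(key))
  for (field in names(METADATA_SYNONYMS)) {
    if (key %in% METADATA_SYNONYMS[[field]]) return(field)
  }
  NA_character_
}

normalize_ion_mode <- function(x) {
  if (is.na(x)) return(NA_character_)
  x <- tolower(trimws(x))
  if (x %in% c("positive", "pos", "p", "+", "1+", "positive ion mode")) return("positive")
  if (x %in% c("negative", "neg", "n", "-", "1-", "negative ion mode")) return("negative")
  NA_character_
}

# Build a spectrum row from a named list of raw metadata + a peak matrix.
record_from_fields <- function(fields, peaks, extra) {
  num_or_na <- function(v) suppressWarnings(as.numeric(sub(",", ".", v %||% NA_character_)))
  chr <- function(v) if (is.null(v)) NA_character_ else as.character(v)
  ik <- chr(fields$inchikey)
  if (!is.na(ik)) {
    # MoNA-style "InChIKey=XXX" prefixes
    ik <- sub("^InChIKey=", "", ik, ignore.case = TRUE)
    if (!is_valid_inchikey(ik)) ik <- NA_character_
  }
  # PEPMASS may carry "mz intensity"
  pmz <- chr(fields$precursor_mz)
  if (!is.na(pmz)) pmz <- strsplit(trimws(pmz), "[[:space:]]+")[[1]][1]
  spectrum_record(
    peaks = peaks,
    spectrum_id = chr(fields$spectrum_id),
    inchikey = ik,
    smiles = chr(fields$smiles),
    source = chr(fields$source),
    ionization_mode = normalize_ion_mode(chr(fields$ionization_mode)),
    adduct = chr(fields$adduct),
    precursor_mz = num_or_na(pmz),
    exact_mass = num_or_na(chr(fields$exact_mass)),
    instrument_type = chr(fields$instrument_type),
    instrument = chr(fields$instrument),
    collision_energy_raw = chr(fields$collision_energy_raw),
    mass_accuracy = num_or_na(chr(fields$mass_accuracy)),
    library = chr(fields$library),
    external_ids = chr(fields$external_ids),
    extra = extra
  )
}

empty_spectrum_tbl <- function() {
  spectrum_record(data.frame(mz = numeric(), intensity = numeric()))[0, ]
}

#' Parse an MSP-format spectral library
#'
#' Parses the NIST text dialect of MSP: blocks of `Key: value` metadata
#' lines followed by `Num Peaks:` and one peak per line, blocks separated
#' by blank lines. Metadata keys are matched case-insensitively against a
#' synonym table covering the common MSP/MGF dialect differences; keys
#' that do not map onto the schema are preserved in the `extra` column.
#'
#' A block whose listed peak count disagrees with its `Num Peaks` value is
#' skipped; the error (with the line number of the block) is recorded and
#' parsing continues. Accumulated errors are attached as the
#' `"parse_errors"` attribute (see [parse_errors()]) and surfaced as one
#' warning.
#'
#' @param text MSP text (single string or character vector of lines).
#' @return A spectrum tibble, one row per successfully parsed entry.
#' @seealso [read_msp()] for files, [write_msp()] for the inverse.
#' @export
parse_msp <- function(text) {
  lines <- split_lines(text)
  n <- length(lines)
  records <- list()
  errors <- list()
  i <- 1L
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    start <- i
    fields <- list(); extra <- character()
    declared <- NA_integer_
    mz <- numeric(); inten <- numeric()
    bad <- NULL
    in_peaks <- FALSE
    while (i <= n && nzchar(trimws(lines[i]))) {
      line <- lines[i]
      if (!in_peaks && grepl("^[^:]+:", line)) {
        key <- sub(":.*$", "", line)
        val <- trimws(sub("^[^:]+:", "", line))
        if (tolower(trimws(key)) %in% c("num peaks", "numpeaks", "num_peaks")) {
          declared <- suppressWarnings(as.integer(val))
          in_peaks <- TRUE
        } else {
          field <- normalize_meta_key(key)
          if (is.na(field)) {
            extra[trimws(key)] <- val
          } else {
            fields[[field]] <- val
          }
        }
      } else if (in_peaks) {
        pk <- parse_peak_line(line)
        if (is.null(pk)) {
          bad <- sprintf("line %d: malformed peak line '%s'", i, line)
        } else {
          mz <- c(mz, pk[1]); inten <- c(inten, pk[2])
        }
      }
      i <- i + 1L
    }
    if (is.null(bad) && !is.na(declared) && declared != length(mz)) {
      bad <- sprintf(
        "line %d: 'Num Peaks: %d' but %d peak line(s) found", start,
        declared, length(mz))
    }
    if (is.null(bad)) {
      records[[length(records) + 1L]] <- record_from_fields(
        fields, data.frame(mz = mz, intensity = inten), extra)
    } else {
      errors[[length(errors) + 1L]] <- tibble(line = start, message = bad)
    }
  }
  finish_parse(records, errors, "MSP")
}

#' Parse an MGF-format spectral library
#'
#' Parses Mascot generic format: `BEGIN IONS` ... `END IONS` blocks with
#' `KEY=value` metadata and peak lines. `PEPMASS` maps to the precursor
#' m/z; when no ion-mode key is present the sign of `CHARGE` determines
#' the ionization mode. A trailing block without `END IONS` is reported as
#' a parse error.
#'
#' @inheritParams parse_msp
#' @return A spectrum tibble; parse errors attached as for [parse_msp()].
#' @export
parse_mgf <- function(text) {
  lines <- split_lines(text)
  n <- length(lines)
  records <- list(); errors <- list()
  i <- 1L
  while (i <= n) {
    if (!grepl("^\\s*BEGIN IONS\\s*$", lines[i], ignore.case = TRUE)) {
      i <- i + 1L; next
    }
    start <- i
    i <- i + 1L
    fields <- list(); extra <- character(); charge <- NA_character_
    mz <- numeric(); inten <- numeric()
    closed <- FALSE
    while (i <= n) {
      line <- trimws(lines[i])
      if (grepl("^END IONS$", line, ignore.case = TRUE)) {
        closed <- TRUE; i <- i + 1L; break
      }
      if (grepl("=", line, fixed = TRUE)) {
        key <- sub("=.*$", "", line)
        val <- trimws(sub("^[^=]+=", "", line))
        if (toupper(trimws(key)) == "CHARGE") {
          charge <- val
        } else {
          field <- normalize_meta_key(key)
          if (is.na(field)) extra[trimws(key)] <- val else fields[[field]] <- val
        }
      } else if (nzchar(line)) {
        pk <- parse_peak_line(line)
        if (!is.null(pk)) { mz <- c(mz, pk[1]); inten <- c(inten, pk[2]) }
      }
      i <- i + 1L
    }
    if (!closed) {
      errors[[length(errors) + 1L]] <- tibble(
        line = start, message = sprintf("line %d: BEGIN IONS without END IONS", start))
      next
    }
    if (is.null(fields$ionization_mode) && !is.na(charge)) {
      # MGF convention: trailing sign of CHARGE ("1-", "2+")
      fields$ionization_mode <-
        if (grepl("-", charge, fixed = TRUE)) "negative" else "positive"
    }
    records[[length(records) + 1L]] <- record_from_fields(
      fields, data.frame(mz = mz, intensity = inten), extra)
  }
  finish_parse(records, errors, "MGF")
}

finish_parse <- function(records, errors, dialect) {
  out <- if (length(records)) bind_rows(records) else empty_spectrum_tbl()
  errs <- if (length(errors)) bind_rows(errors) else tibble(line = integer(), message = character())
  attr(out, "parse_errors") <- errs
  if (nrow(errs)) {
    warn(sprintf("%d %s record(s) skipped; see parse_errors().", nrow(errs), dialect))
  }
  out
}

parse_peak_line <- function(line) {
  parts <- strsplit(trimws(line), "[\\s;,]+", perl = TRUE)[[1]]
  if (length(parts) < 2) return(NULL)
  vals <- suppressWarnings(as.numeric(parts[1:2]))
  if (anyNA(vals)) return(NULL)
  vals
}

split_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  sub("\r$", "", text)
}

#' Per-record parse errors from the last parse
#'
#' @param x A spectrum tibble returned by [parse_msp()] / [parse_mgf()].
#' @return A tibble with columns `line` and `message`.
#' @export
parse_errors <- function(x) {
  attr(x, "parse_errors") %||% tibble(line = integer(), message = character())
}

#' Read a spectral library file
#'
#' Reads MSP or MGF from disk (gzip-compressed input is handled
#' transparently) and parses it.
#'
#' @param path File path (`.msp`, `.mgf`, optionally `.gz`).
#' @return A spectrum tibble.
#' @export
read_msp <- function(path) parse_msp(read_text_lines(path))

#' @rdname read_msp
#' @export
read_mgf <- function(path) parse_mgf(read_text_lines(path))

read_text_lines <- function(path) {
  con <- gzfile(path, "rt", encoding = "UTF-8")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

MSP_KEY_NAMES <- c(
  spectrum_id = "Name", inchikey = "InChIKey", smiles = "SMILES",
  source = "Source", ionization_mode = "Ion_mode", adduct = "Precursor_type",
  precursor_mz = "PrecursorMZ", exact_mass = "ExactMass",
  instrument_type = "Instrument_type", instrument = "Instrument",
  collision_energy_raw = "Collision_energy", mass_accuracy = "Mass_accuracy",
  library = "Library", external_ids = "External_IDs"
)

#' Write spectra as MSP text
#'
#' Serialises a spectrum tibble to the NIST MSP text dialect such that
#' `parse_msp(write_msp(x))` reproduces every modelled field. Fields that
#' are `NA` are omitted from the output; `extra` passthrough keys are
#' written verbatim.
#'
#' @param records A spectrum tibble.
#' @param path Optional file path; when given the text is also written
#'   there (gzip if the path ends in `.gz`).
#' @return The MSP text, invisibly when `path` is given.
#' @export
write_msp <- function(records, path = NULL) {
  blocks <- character(nrow(records))
  for (r in seq_len(nrow(records))) {
    row <- records[r, ]
    lines <- character()
    for (field in names(MSP_KEY_NAMES)) {
      val <- row[[field]]
      if (length(val) == 1 && !is.na(val)) {
        lines <- c(lines, paste0(MSP_KEY_NAMES[[field]], ": ", format_meta(val)))
      }
    }
    ex <- row$extra[[1]]
    for (k in names(ex)) lines <- c(lines, paste0(k, ": ", ex[[k]]))
    pk <- row$peaks[[1]]
    lines <- c(lines, paste0("Num Peaks: ", nrow(pk)),
               sprintf("%s %s", format_meta(pk$mz), format_meta(pk$intensity)))
    blocks[r] <- paste(lines, collapse = "\n")
  }
  text <- if (length(blocks)) paste0(paste(blocks, collapse = "\n\n"), "\n") else ""
  if (!is.null(path)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    writeLines(text, con, sep = "")
    close(con)
    return(invisible(text))
  }
  text
}

format_meta <- function(x) {
  if (is.numeric(x)) format(x, digits = 15, scientific = FALSE, trim = TRUE) else as.character(x)
}

#' Parse a vendor collision-energy string to eV
#'
#' MS/MS libraries carry collision energies in hundreds of vendor formats
#' (`"35"`, `"35 eV"`, `"CE: 10V"`, `"20-40"`, `"HCD (NCE 30%)"` ...). A
#' single eV value is extracted when the string has eV-compatible
#' semantics: plain numbers and `eV`/`V` suffixes are taken as-is, numeric
#' ranges collapse to their arithmetic mean, and normalised collision
#' energy (a `%` sign or an `NCE` token) returns `NA` because percentages
#' are not convertible to eV without instrument calibration. The function
#' never fails: anything unparseable maps to `NA`.
#'
#' @param raw Character vector of vendor strings.
#' @return Numeric vector of eV values (`NA` where not extractable).
#' @examples
#' parse_collision_energy(c("35 eV", "20-40", "HCD (NCE 30%)"))
#' @export
parse_collision_energy <- function(raw) {
  vapply(as.character(raw), parse_ce_one, numeric(1), USE.NAMES = FALSE)
}

parse_ce_one <- function(raw) {
  if (is.na(raw) || !nzchar(trimws(raw))) return(NA_real_)
  if (grepl("%", raw, fixed = TRUE) || grepl("\\bnce\\b", raw, ignore.case = TRUE)) {
    return(NA_real_)
  }
  # range "a-b" (allow spaces and decimals); require both sides numeric
  range_m <- regmatches(raw, regexec(
    "(\\d+(?:\\.\\d+)?)\\s*-\\s*(\\d+(?:\\.\\d+)?)", raw))[[1]]
  if (length(range_m) == 3) {
    vals <- as.numeric(range_m[2:3])
    return(mean(vals))
  }
  num_m <- regmatches(raw, regexec("(\\d+(?:\\.\\d+)?)", raw))[[1]]
  if (length(num_m) == 2) {
    v <- as.numeric(num_m[2])
    if (v >= 0) return(v)
  }
  NA_real_
}
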