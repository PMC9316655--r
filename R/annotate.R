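# Candidate retrieval and ranking: look up compounds whose monoisotopic
# mass is compatible with an observed precursor m/z under some adduct
# (20 ppm default tolerance), optionally restrict to a known molecular
# formula, and rank by Tanimoto similarity between the predicted
# fingerprint and each candidate's computed fingerprint.

#' Candidate-search configuration
#'
#' @param ppm_tolerance Mass tolerance in parts per million (default 20).
#' @param adducts Adduct table (`adduct`, `mass_shift`, `charge`); see
#'   [default_adducts()]. User-extensible.
#' @param mode_filter Honor the ionization mode when selecting adducts
#'   (default `TRUE`).
#' @return A `search_config` list.
#' @export
search_config <- function(ppm_tolerance = 20,
                          adducts = default_adducts(),
                          mode_filter = TRUE) {
  stopifnot(ppm_tolerance > 0, all(adducts$charge != 0))
  structure(list(ppm_tolerance = ppm_tolerance, adducts = adducts,
                 mode_filter = isTRUE(mode_filter)),
            class = "search_config")
}

#' Read a compound table
#'
#' Loads a local candidate database: delimited text with the header
#' columns `id`, `inchikey`, `smiles`, `formula`, `monoisotopic_mass`
#' (an optional `fingerprint_hex` column supplies precomputed
#' fingerprints). Such a table can be exported from any compound
#' database.
#'
#' @param path TSV/CSV path.
#' @param sep Field separator (default tab).
#' @return A compound tibble.
#' @export
read_compound_table <- function(path, sep = "\t") {
  df <- as_tibble(read.delim(path, sep = sep, stringsAsFactors = FALSE))
  required <- c("id", "inchikey", "smiles", "formula", "monoisotopic_mass")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste("Compound table lacks column(s):", paste(missing, collapse = ", ")))
  }
  df
}

#' Write a compound table
#' @param compounds Compound tibble.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_compound_table <- function(compounds, path, sep = "\t") {
  out <- compounds
  out <- out[, !vapply(out, is.list, logical(1))]
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Retrieve candidate compounds by precursor mass
#'
#' A compound is a candidate when, for at least one adduct compatible
#' with the ionization mode, the neutral mass implied by the precursor
#' m/z lies within `ppm_tolerance` of the compound's monoisotopic mass.
#' Compounds matching through several adducts are reported once with all
#' matching adducts listed.
#'
#' @param precursor_mz Observed precursor m/z (Th).
#' @param mode `"positive"` or `"negative"`.
#' @param compounds Compound tibble (see [read_compound_table()]).
#' @param cfg A [search_config()].
#' @return The matching compound rows plus `matched_adducts` (comma
#'   separated), `ppm_error` (best match) and `mass_error_da`.
#' @examples
#' db <- tibble::tibble(id = "glc", inchikey = NA, smiles = NA,
#'                      formula = "C6H12O6", monoisotopic_mass = 180.0634)
#' retrieve_candidates(181.0707, "positive", db)
#' @export
retrieve_candidates <- function(precursor_mz, mode, compounds,
                                cfg = search_config()) {
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1)
  adducts <- cfg$adducts
  if (cfg$mode_filter) {
    want <- if (mode == "positive") 1L else -1L
    adducts <- adducts[sign(adducts$charge) == want, , drop = FALSE]
  }
  if (!nrow(adducts)) {
    abort(sprintf("No adduct configured for mode '%s'.", mode),
          class = "specfp_config_error")
  }
  if (!nrow(compounds)) return(compounds)
  hits <- vector("list", nrow(adducts))
  for (a in seq_len(nrow(adducts))) {
    implied <- precursor_mz - adducts$mass_shift[a]
    ppm <- abs(implied - compounds$monoisotopic_mass) /
      compounds$monoisotopic_mass * 1e6
    ok <- which(ppm <= cfg$ppm_tolerance)
    if (length(ok)) {
      hits[[a]] <- tibble(row = ok, adduct = adducts$adduct[a],
                          ppm_error = ppm[ok],
                          mass_error_da = abs(implied - compounds$monoisotopic_mass)[ok])
    }
  }
  hits <- bind_rows(hits)
  if (!nrow(hits)) return(compounds[0, ])
  agg <- hits |>
    group_by(.data$row) |>
    summarise(matched_adducts = paste(.data$adduct, collapse = ","),
              ppm_error = min(.data$ppm_error),
              mass_error_da = min(.data$mass_error_da), .groups = "drop")
  out <- compounds[agg$row, ]
  out$matched_adducts <- agg$matched_adducts
  out$ppm_error <- agg$ppm_error
  out$mass_error_da <- agg$mass_error_da
  out
}

#' Parse a molecular formula into an element-count map
#'
#' Supports plain Hill-style formulas (`C6H12O6`, element symbols with
#' optional counts); parentheses and charges are not supported.
#'
#' @param formula Formula string.
#' @return Named integer vector of element counts, sorted by element.
#' @export
parse_formula <- function(formula) {
  f <- trimws(formula)
  if (!nzchar(f) || grepl("[^A-Za-z0-9]", f)) {
    abort(sprintf("Unparseable formula: '%s'", formula),
          class = "specfp_formula_error")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  tokens <- regmatches(f, list(m))[[1]]
  if (!length(tokens) || sum(nchar(tokens)) != nchar(f)) {
    abort(sprintf("Unparseable formula: '%s'", formula),
          class = "specfp_formula_error")
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  out <- tapply(counts, elements, sum)
  out <- setNames(as.integer(out), names(out))
  out[order(names(out))]
}

#' Compare two molecular formulas
#'
#' Element-multiset equality, so `"C6H12O6"` and `"H12C6O6"` are equal.
#'
#' @param a,b Formula strings.
#' @return Logical.
#' @export
formula_equal <- function(a, b) {
  identical(parse_formula(a), parse_formula(b))
}

#' Restrict candidates to a known molecular formula
#'
#' @param candidates Compound tibble.
#' @param formula Query formula string.
#' @return The subset of candidates with the identical element-count
#'   map; input order preserved.
#' @export
filter_by_formula <- function(candidates, formula) {
  target <- parse_formula(formula)
  keep <- vapply(candidates$formula, function(f) {
    if (is.na(f)) return(FALSE)
    tryCatch(identical(parse_formula(f), target), error = function(e) FALSE)
  }, logical(1))
  candidates[keep, ]
}

candidate_fps <- function(candidates) {
  n <- nrow(candidates)
  fps <- matrix(NA_integer_, n, sum(fingerprint_segments()))
  ok <- rep(TRUE, n)
  if ("fingerprint_hex" %in% names(candidates)) {
    has_hex <- !is.na(candidates$fingerprint_hex)
    for (i in which(has_hex)) fps[i, ] <- hex_to_fingerprint(candidates$fingerprint_hex[i])
  } else {
    has_hex <- rep(FALSE, n)
  }
  for (i in which(!has_hex)) {
    fp <- tryCatch(compute_fingerprint(candidates$smiles[i]),
                   error = function(e) NULL)
    if (is.null(fp)) ok[i] <- FALSE else fps[i, ] <- fp
  }
  list(fps = fps, ok = ok)
}

#' Rank candidates by Tanimoto similarity to a predicted fingerprint
#'
#' Scores every candidate's computed (or precomputed) fingerprint against
#' the predicted one and orders them by descending Tanimoto similarity.
#' Ties break deterministically: smaller mass error first, then
#' lexicographic InChIKey. Candidates whose structure cannot be parsed
#' are dropped with a warning and counted in the `"n_dropped"` attribute.
#'
#' @param predicted Predicted binary fingerprint (length 528).
#' @param candidates Compound tibble (from [retrieve_candidates()], or
#'   any table with `inchikey`, `smiles` / `fingerprint_hex`,
#'   `monoisotopic_mass`).
#' @param query_id Identifier of the query spectrum (metadata).
#' @param basis `"mass"` or `"formula"` — how the list was obtained.
#' @return A `ranked_annotation` tibble: `rank`, candidate columns and
#'   `tanimoto`, with attributes `query_id` and `basis`.
#' @export
rank_candidates <- function(predicted, candidates, query_id = NA_character_,
                            basis = c("mass", "formula")) {
  basis <- match.arg(basis)
  cf <- candidate_fps(candidates)
  if (any(!cf$ok)) {
    warn(sprintf("%d candidate(s) dropped (unparseable structure).", sum(!cf$ok)))
  }
  out <- candidates[cf$ok, ]
  fps <- cf$fps[cf$ok, , drop = FALSE]
  scores <- if (nrow(out)) tanimoto_rows(predicted, fps) else numeric()
  out$tanimoto <- scores
  mass_err <- if ("mass_error_da" %in% names(out)) out$mass_error_da else
    rep(0, nrow(out))
  ord <- order(-out$tanimoto, mass_err, out$inchikey)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", setdiff(names(out), "rank"))]
  attr(out, "query_id") <- query_id
  attr(out, "basis") <- basis
  attr(out, "n_dropped") <- sum(!cf$ok)
  class(out) <- c("ranked_annotation", class(out))
  out
}

#' Top-k hit test
#'
#' Whether the true compound appears in the first `k` entries of a
#' ranked candidate list. Matching is at the InChIKey first-block (2D
#' skeleton) level by default, consistent with structure-disjoint
#' evaluation; `match = "full"` compares complete keys.
#'
#' @param ranked A `ranked_annotation` (or tibble with `rank`,
#'   `inchikey`).
#' @param true_inchikey InChIKey of the true compound.
#' @param k Rank depth (>= 1).
#' @param match `"block"` or `"full"`.
#' @return Logical.
#' @export
topk_hit <- function(ranked, true_inchikey, k, match = c("block", "full")) {
  match <- match.arg(match)
  stopifnot(k >= 1)
  top <- ranked$inchikey[ranked$rank <= k]
  if (match == "block") {
    any(!is.na(top) & inchikey_block(top) == inchikey_block(true_inchikey))
  } else {
    any(!is.na(top) & top == true_inchikey)
  }
}

#' Annotate spectra end to end
#'
#' For each query spectrum: preprocess (no merging), predict the
#' fingerprint with the model bundle, retrieve candidates by precursor
#' mass (optionally restricted to a known formula), and rank by Tanimoto
#' similarity.
#'
#' @param spectra Spectrum tibble of queries.
#' @param compounds Compound tibble (candidate database).
#' @param bundle A `model_bundle` from [fit_strategy()].
#' @param cfg A [search_config()].
#' @param prep A [preprocess_config()].
#' @param spec The [binning_spec()] the bundle was trained with.
#' @param formulas Optional character vector of known query formulas
#'   (`NA` where unknown) switching those queries to formula-based
#'   candidate lists.
#' @param threshold Fingerprint binarisation threshold.
#' @return A tibble with one row per kept query (`spectrum_id`, `basis`,
#'   `n_candidates`) and the ranked lists in the `ranking` list-column;
#'   rejected queries are in the `"rejected"` attribute.
#' @export
annotate_spectra <- function(spectra, compounds, bundle,
                             cfg = search_config(),
                             prep = preprocess_config(),
                             spec = binning_spec(),
                             formulas = NULL, threshold = 0.5) {
  pp <- preprocess_spectra(spectra, prep, spec, merge = FALSE)
  kept <- pp$spectra
  if (!is.null(formulas)) {
    formulas <- formulas[match(kept$spectrum_id, spectra$spectrum_id)]
  }
  if (!nrow(kept)) {
    return(structure(tibble(spectrum_id = character(), basis = character(),
                            n_candidates = integer(), ranking = list()),
                     rejected = pp$rejected))
  }
  ctx <- resolve_context(kept)
  pred <- predict_bundle(bundle, pp$binned, ctx, threshold)
  rows <- vector("list", nrow(kept))
  for (i in seq_len(nrow(kept))) {
    cands <- retrieve_candidates(kept$precursor_mz[i], kept$ionization_mode[i],
                                 compounds, cfg)
    basis <- "mass"
    if (!is.null(formulas) && !is.na(formulas[i])) {
      cands <- filter_by_formula(cands, formulas[i])
      basis <- "formula"
    }
    ranked <- rank_candidates(pred$bits[i, ], cands,
                              query_id = kept$spectrum_id[i], basis = basis)
    rows[[i]] <- tibble(spectrum_id = kept$spectrum_id[i], basis = basis,
                        n_candidates = nrow(ranked), ranking = list(ranked))
  }
  structure(bind_rows(rows), rejected = pp$rejected)
}
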