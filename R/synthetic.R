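# Download-free synthetic corpora. A planted mapping assigns each
# fingerprint bit a small set of m/z bins it excites; compounds get
# random (or chemistry-derived) fingerprints, masses arranged in
# near-isobaric clusters (some clusters isomeric, sharing a formula) so
# that candidate retrieval is non-trivial; spectra are the union of the
# excited bins with intensity noise and bin dropout, wrapped in full
# instrument metadata so every pipeline stage can be exercised.

#' Planted fingerprint-to-spectrum mapping
#'
#' @param n_bits Number of fingerprint bits (default 528).
#' @param bin_range Integer m/z range the excited bins are drawn from;
#'   kept low (default 50–280) so fragment peaks stay below any
#'   precursor.
#' @param bins_per_bit Number of bins each bit excites (default 2; bits
#'   may share bins, making the decoding task non-trivial).
#' @param injective Assign each bit its own private bin (requires
#'   `bins_per_bit = 1` and a range of at least `n_bits` bins); makes
#'   the fingerprint exactly recoverable by [decode_planted()].
#' @param seed Integer seed.
#' @return A `planted_mapping`: list with `assignment` (list of bin
#'   vectors per bit) and the parameters.
#' @export
planted_mapping <- function(n_bits = 528L, bin_range = c(50L, 280L),
                            bins_per_bit = 2L, injective = FALSE,
                            seed = 1L) {
  stopifnot(bin_range[1] < bin_range[2], bins_per_bit >= 1)
  bins <- seq(bin_range[1], bin_range[2])
  if (injective) {
    stopifnot(bins_per_bit == 1L, length(bins) >= n_bits)
  }
  with_seed(seed, {
    assignment <- if (injective) {
      as.list(sample(bins, n_bits))
    } else {
      lapply(seq_len(n_bits), function(i) sample(bins, bins_per_bit))
    }
    # characteristic relative intensity of each excited bin: fragment
    # abundances are reproducible properties of a fragmentation channel,
    # so each bit-bin pair gets a fixed lognormal level
    intensity <- lapply(assignment, function(b)
      exp(rnorm(length(b), log(40), 0.6)))
    structure(list(assignment = assignment, intensity = intensity,
                   n_bits = as.integer(n_bits),
                   bin_range = as.integer(bin_range),
                   bins_per_bit = as.integer(bins_per_bit),
                   injective = isTRUE(injective), seed = seed),
              class = "planted_mapping")
  })
}

random_inchikey <- function(n, block1 = NULL) {
  rand_block <- function(k) {
    vapply(seq_len(k), function(i)
      paste(sample(LETTERS, 14, replace = TRUE), collapse = ""), character(1))
  }
  b1 <- block1 %||% rand_block(n)
  b2 <- vapply(seq_len(n), function(i)
    paste(sample(LETTERS, 10, replace = TRUE), collapse = ""), character(1))
  paste0(b1, "-", b2, "-N")
}

synthetic_formula <- function(mass, variant = 0L) {
  c_n <- pmax(4L, round(mass / 19) + variant)
  h_n <- pmax(4L, round(mass / 11))
  o_n <- pmax(1L, round(mass / 55) - variant)
  sprintf("C%dH%dO%d", c_n, h_n, o_n)
}

#' Generate a synthetic compound table
#'
#' Without a SMILES pool, compounds get random 528-bit fingerprints with
#' the given per-bit prevalence (resampled to at least `min_bits` set
#' bits so every compound produces a filter-passing spectrum) and
#' synthetic InChIKeys. Monoisotopic masses are arranged in clusters of
#' `cluster_size` near-isobaric compounds (within the retrieval
#' tolerance of each other) and a fraction of the clusters is isomeric —
#' identical mass and molecular formula — so formula filtering genuinely
#' shortens candidate lists. `n_shared_groups` groups of
#' `shared_group_size` compounds reuse one InChIKey first block, to
#' exercise structure-disjoint splitting.
#'
#' With `smiles_pool` (a tibble with `name`, `smiles`, `inchikey`,
#' `formula`, `monoisotopic_mass`, e.g. [bundled_metabolites()]), real
#' structures are used and fingerprints are computed from chemistry.
#'
#' @param n Number of compounds.
#' @param seed Integer seed; same seed, same table.
#' @param smiles_pool Optional structure pool tibble.
#' @param prevalence Per-bit probability of a set bit (default 0.1).
#' @param min_bits Minimum set bits per compound (default 10).
#' @param cluster_size Compounds per mass cluster (default 8).
#' @param isomer_fraction Fraction of clusters that are isomeric
#'   (default 0.5).
#' @param n_shared_groups,shared_group_size Skeleton-sharing compound
#'   groups (default none).
#' @param mass_range Range the cluster-centre masses are drawn from
#'   (default 300–1000 Da).
#' @return A compound tibble: `id`, `inchikey`, `smiles`, `formula`,
#'   `monoisotopic_mass`, `fingerprint_hex`, plus a `fingerprints`
#'   attribute (binary matrix, rownames = InChIKey).
#' @export
generate_compound_table <- function(n, seed = 1L, smiles_pool = NULL,
                                    prevalence = 0.1, min_bits = 10L,
                                    cluster_size = 8L, isomer_fraction = 0.5,
                                    n_shared_groups = 0L,
                                    shared_group_size = 2L,
                                    mass_range = c(300, 1000)) {
  stopifnot(n >= 1)
  n_fp_bits <- sum(fingerprint_segments())
  if (!is.null(smiles_pool)) {
    stopifnot(n <= nrow(smiles_pool))
    pool <- smiles_pool[seq_len(n), ]
    fps <- compute_fingerprint(pool$smiles)
    if (is.null(dim(fps))) fps <- matrix(fps, 1)
    rownames(fps) <- pool$inchikey
    out <- tibble(id = pool$name, inchikey = pool$inchikey,
                  smiles = pool$smiles, formula = pool$formula,
                  monoisotopic_mass = pool$monoisotopic_mass,
                  fingerprint_hex = apply(fps, 1, fingerprint_to_hex))
    attr(out, "fingerprints") <- fps
    return(out)
  }
  with_seed(seed, {
    n_clusters <- ceiling(n / cluster_size)
    centers <- runif(n_clusters, mass_range[1], mass_range[2])
    isomeric <- runif(n_clusters) < isomer_fraction
    cluster <- rep(seq_len(n_clusters), each = cluster_size)[seq_len(n)]
    mass <- numeric(n); formula <- character(n)
    for (i in seq_len(n)) {
      cl <- cluster[i]
      if (isomeric[cl]) {
        mass[i] <- centers[cl]
        formula[i] <- synthetic_formula(centers[cl])
      } else {
        # near-isobars: inside the default 20 ppm retrieval window but
        # with distinct formulas
        mass[i] <- centers[cl] * (1 + runif(1, -8e-6, 8e-6))
        formula[i] <- synthetic_formula(centers[cl], variant = i %% 5L)
      }
    }
    fps <- matrix(0L, n, n_fp_bits)
    for (i in seq_len(n)) {
      repeat {
        bits <- rbinom(n_fp_bits, 1L, prevalence)
        if (sum(bits) >= min_bits) break
      }
      fps[i, ] <- bits
    }
    block1 <- NULL
    if (n_shared_groups > 0) {
      shared <- rep(vapply(seq_len(n_shared_groups), function(i)
        paste(sample(LETTERS, 14, replace = TRUE), collapse = ""),
        character(1)), each = shared_group_size)
      stopifnot(length(shared) <= n)
      block1 <- c(shared, vapply(seq_len(n - length(shared)), function(i)
        paste(sample(LETTERS, 14, replace = TRUE), collapse = ""), character(1)))
    }
    inchikey <- random_inchikey(n, block1)
    rownames(fps) <- inchikey
    out <- tibble(id = sprintf("SYNC%04d", seq_len(n)),
                  inchikey = inchikey,
                  smiles = NA_character_,
                  formula = formula,
                  monoisotopic_mass = mass,
                  fingerprint_hex = apply(fps, 1, fingerprint_to_hex))
    attr(out, "fingerprints") <- fps
    out
  })
}

CE_STRINGS <- list(low = c("10 eV", "15 eV", "20", "25 eV", "CE: 28V"),
                   high = c("35 eV", "40 eV", "45", "55 eV", "CE: 60V"))
INSTRUMENTS <- list(high = c("Orbitrap", "Q-TOF"), low = c("IT", "QqQ"))

#' Generate synthetic MS/MS spectra from a planted mapping
#'
#' Each spectrum contains one peak per bin excited by the compound's set
#' fingerprint bits (after per-bin dropout). A bin's intensity is the sum
#' of the characteristic levels of all set bits exciting it (co-produced
#' fragments accumulate), times `base_intensity`, plus Gaussian noise.
#' The precursor m/z is consistent
#' with the compound mass and a sampled mode-compatible adduct; the
#' collision-energy string, instrument type and ionization mode are
#' sampled from the requested distribution over the eight instrument
#' contexts. Generated records pass the default preprocessing filters by
#' construction unless a corruption flag is set.
#'
#' @param compounds Compound tibble from [generate_compound_table()].
#' @param mapping A [planted_mapping()].
#' @param contexts Probability vector over the 8 context cells (named by
#'   [context_keys()]; default uniform).
#' @param spectra_per_compound Replicates per compound (default 5).
#' @param base_intensity Global intensity scale multiplier (default 1;
#'   preprocessing max-scales spectra, so only relative levels matter).
#' @param noise_sd Additive intensity noise SD (default 5, on the scale
#'   of the mapping's lognormal levels, median 40).
#' @param dropout_prob Probability an excited bin is silenced (default
#'   0.1).
#' @param precursor_ppm_error SD of the relative measurement error on
#'   the recorded precursor m/z, in ppm (default 3 — high-resolution
#'   instrument territory; keeps candidates retrievable at 20 ppm while
#'   making observed mass errors uninformative about identity).
#' @param corruption `NULL`, or `"few-peaks"` to emit filter-failing
#'   2-peak spectra (negative fixtures).
#' @param seed Integer seed.
#' @return A spectrum tibble with `true_inchikey` set to the source
#'   compound.
#' @export
generate_spectra <- function(compounds, mapping, contexts = NULL,
                             spectra_per_compound = 5L,
                             base_intensity = 1, noise_sd = 5,
                             dropout_prob = 0.1, precursor_ppm_error = 3,
                             corruption = NULL, seed = 1L) {
  stopifnot(inherits(mapping, "planted_mapping"),
            noise_sd >= 0, dropout_prob >= 0, dropout_prob < 1)
  keys <- context_keys()
  probs <- contexts %||% setNames(rep(1 / 8, 8), keys)
  stopifnot(all(names(probs) %in% keys))
  fps <- attr(compounds, "fingerprints")
  if (is.null(fps)) {
    fps <- t(vapply(compounds$fingerprint_hex, hex_to_fingerprint,
                    integer(sum(fingerprint_segments())), USE.NAMES = FALSE))
    rownames(fps) <- compounds$inchikey
  }
  adducts <- default_adducts()
  with_seed(seed, {
    rows <- vector("list", nrow(compounds) * spectra_per_compound)
    r <- 0L
    for (i in seq_len(nrow(compounds))) {
      set_bits <- which(fps[i, ] != 0)
      tab <- rowsum(unlist(mapping$intensity[set_bits]),
                    unlist(mapping$assignment[set_bits]))
      all_bins <- as.integer(rownames(tab))   # rowsum sorts group keys
      levels_all <- tab[, 1] * base_intensity
      for (s in seq_len(spectra_per_compound)) {
        r <- r + 1L
        key <- sample(names(probs), 1, prob = probs)
        parts <- strsplit(key, ".", fixed = TRUE)[[1]]
        energy <- parts[1]; resolution <- parts[2]; mode <- parts[3]
        ce <- sample(CE_STRINGS[[energy]], 1)
        itype <- sample(INSTRUMENTS[[resolution]], 1)
        ad <- adducts[sign(adducts$charge) == (if (mode == "positive") 1 else -1), ]
        ad <- ad[sample.int(nrow(ad), 1), ]
        keep <- runif(length(all_bins)) >= dropout_prob
        if (sum(keep) < 5) keep[seq_len(min(5, length(all_bins)))] <- TRUE
        if (identical(corruption, "few-peaks")) {
          keep <- seq_along(all_bins) <= 2
        }
        bins <- all_bins[keep]
        inten <- pmax(levels_all[keep] + rnorm(length(bins), 0, noise_sd), 1)
        rows[[r]] <- spectrum_record(
          peaks = data.frame(mz = bins + 0.5, intensity = inten),
          spectrum_id = sprintf("SYNS-%s-%02d", compounds$id[i], s),
          inchikey = compounds$inchikey[i],
          smiles = compounds$smiles[i],
          source = "synthetic", library = "synthetic",
          ionization_mode = mode,
          adduct = ad$adduct,
          precursor_mz = (compounds$monoisotopic_mass[i] + ad$mass_shift) *
            (1 + rnorm(1, 0, precursor_ppm_error * 1e-6)),
          exact_mass = compounds$monoisotopic_mass[i],
          instrument_type = itype,
          instrument = paste("synthetic", itype),
          collision_energy_raw = ce,
          mass_accuracy = 5)
      }
    }
    out <- bind_rows(rows)
    out$true_inchikey <- out$inchikey
    out
  })
}

#' Oracle decoder for noiseless planted spectra
#'
#' For dropout-free, noise-free generation with a collision-free
#' mapping, a fingerprint bit is recoverable as set iff every bin it
#' excites carries signal. Used to verify the end-to-end identity of the
#' generator + preprocessing chain.
#'
#' @param binned A `binned_spectra` (or numeric vector/matrix of bin
#'   values).
#' @param mapping The [planted_mapping()] used for generation.
#' @return Binary matrix (n x n_bits) of decoded fingerprints.
#' @export
decode_planted <- function(binned, mapping) {
  mat <- if (inherits(binned, "binned_spectra")) binned$values else
    if (is.null(dim(binned))) matrix(binned, 1) else binned
  out <- matrix(0L, nrow(mat), mapping$n_bits)
  for (j in seq_len(mapping$n_bits)) {
    bins <- mapping$assignment[[j]]
    out[, j] <- as.integer(rowSums(mat[, bins, drop = FALSE] > 0) == length(bins))
  }
  out
}

#' Bundled metabolite structure pool
#'
#' A small table of common metabolites (name, SMILES, InChIKey, formula,
#' monoisotopic mass) shipped as plain text, so fingerprint computation
#' can be exercised on real chemistry without any download.
#'
#' @return A tibble.
#' @export
bundled_metabolites <- function() {
  path <- system.file("extdata", "metabolite_smiles.tsv", package = "specfp")
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Build the miniature benchmark corpus
#'
#' A self-contained desk-scale replica of the annotation experiment:
#' compounds with clustered masses and planted fingerprints, several
#' spectra per compound across all eight instrument contexts, a
#' structure-disjoint 80/20 train/test split, the compound table as
#' candidate database, and a truth table mapping every test spectrum to
#' its compound.
#'
#' @param seed Integer seed (whole corpus reproduces byte-identically).
#' @param n_compounds Number of compounds (default 300).
#' @param spectra_per_compound Spectra per compound (default 5).
#' @param train_fraction Structure-disjoint training share (default
#'   0.8).
#' @param noise_sd,dropout_prob Generator noise parameters (defaults 5
#'   and 0.1).
#' @param bin_range Excited-bin range of the planted mapping.
#' @return List: `train_spectra`, `test_spectra` (spectrum tibbles),
#'   `compounds` (candidate db), `truth` (spectrum_id -> inchikey),
#'   `fingerprints` (binary matrix by InChIKey), `mapping`, `split`.
#' @export
make_benchmark <- function(seed = 1L, n_compounds = 300L,
                           spectra_per_compound = 5L, train_fraction = 0.8,
                           noise_sd = 5, dropout_prob = 0.1,
                           bin_range = c(50L, 280L)) {
  compounds <- generate_compound_table(n_compounds, seed = seed)
  mapping <- planted_mapping(bin_range = bin_range, seed = seed + 1L)
  spectra <- generate_spectra(compounds, mapping,
                              spectra_per_compound = spectra_per_compound,
                              noise_sd = noise_sd,
                              dropout_prob = dropout_prob,
                              seed = seed + 2L)
  split <- structure_disjoint_split(compounds$inchikey, train_fraction,
                                    seed = seed + 3L)
  train_spectra <- spectra[spectra$inchikey %in% split$train, ]
  test_spectra <- spectra[spectra$inchikey %in% split$test, ]
  list(train_spectra = train_spectra,
       test_spectra = test_spectra,
       compounds = compounds,
       truth = tibble(spectrum_id = test_spectra$spectrum_id,
                      inchikey = test_spectra$inchikey),
       fingerprints = attr(compounds, "fingerprints"),
       mapping = mapping,
       split = split)
}
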