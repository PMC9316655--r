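# The 528-bit composite structural fingerprint (MACCS || FP3 || FP4) and
# the similarity / agreement metrics used to score predictions against
# computed candidate fingerprints.
#
# OpenBabel (through ChemmineOB) is the fingerprint backend. Its bit
# vectors come back padded to 32-bit word multiples (MACCS 256, FP3 64,
# FP4 512); position i (1-based) corresponds to native key number i, so
# truncating to the canonical segment lengths 166 / 55 / 307 gives a
# backend-independent 528-bit composite.

FP_SEGMENTS <- c(MACCS = 166L, FP3 = 55L, FP4 = 307L)

#' Composite fingerprint length and segment boundaries
#'
#' @return Named integer vector of segment lengths (MACCS 166, FP3 55,
#'   FP4 307; total 528).
#' @export
fingerprint_segments <- function() FP_SEGMENTS

#' Compute the 528-bit composite fingerprint of a structure
#'
#' Computes OpenBabel MACCS, FP3 and FP4 keys for each structure and
#' concatenates them (in that order) into a 528-element binary vector.
#' Input is SMILES; strings starting with `InChI=` are converted first.
#' Structures the backend cannot parse raise a structure error carrying
#' the offending string.
#'
#' @param structures Character vector of SMILES (or InChI) strings.
#' @return An integer matrix with one 528-column row per structure
#'   (rownames = input strings). For a single structure a plain named
#'   integer vector of length 528.
#' @examples
#' \donttest{
#' length(compute_fingerprint("c1ccccc1"))
#' }
#' @export
compute_fingerprint <- function(structures) {
  stopifnot(is.character(structures), length(structures) >= 1)
  smiles <- vapply(structures, inchi_to_smiles, character(1), USE.NAMES = FALSE)
  mols <- lapply(smiles, parse_smiles_ob)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) {
    abort(sprintf("Unparseable structure(s): %s",
                  paste(structures[bad], collapse = ", ")),
          class = "specfp_structure_error")
  }
  out <- matrix(0L, length(mols), sum(FP_SEGMENTS))
  for (i in seq_along(mols)) {
    segs <- lapply(names(FP_SEGMENTS), function(fp) {
      bits <- ChemmineOB::fingerprint_OB(mols[i], fp)
      # backend pads to word multiples; enforce canonical segment length
      as.integer(bits[seq_len(FP_SEGMENTS[[fp]])])
    })
    out[i, ] <- unlist(segs)
  }
  rownames(out) <- structures
  if (length(structures) == 1L) {
    fp <- out[1, ]
    names(fp) <- NULL
    return(fp)
  }
  out
}

inchi_to_smiles <- function(x) {
  if (grepl("^InChI=", x)) {
    out <- tryCatch(
      ChemmineOB::convertFormat("INCHI", "SMILES", x),
      error = function(e) "")
    out <- trimws(strsplit(out, "[\t\n]")[[1]][1] %||% "")
    if (!nzchar(out)) {
      abort(sprintf("Unparseable structure(s): %s", x),
            class = "specfp_structure_error")
    }
    return(out)
  }
  x
}

parse_smiles_ob <- function(smi) {
  if (is.na(smi) || !nzchar(trimws(smi))) return(NULL)
  mols <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smi, identity)),
    error = function(e) list())
  if (!length(mols)) return(NULL)
  # an unparseable SMILES yields no molecule or an empty canonical SMILES
  cansmi <- tryCatch(ChemmineOB::prop_OB(mols[1])$cansmi,
                     error = function(e) "")
  if (is.null(cansmi) || !nzchar(trimws(cansmi %||% ""))) return(NULL)
  mols[[1]]
}

check_fp_pair <- function(pred, true) {
  if (length(pred) != length(true)) {
    abort(sprintf("Fingerprint length mismatch: %d vs %d",
                  length(pred), length(true)))
  }
}

#' Position-wise confusion counts between two binary fingerprints
#'
#' @param pred,true Binary vectors of equal length (predicted and true
#'   fingerprint).
#' @return Named integer vector `c(TP, FP, FN, TN)`; the four counts sum
#'   to the fingerprint length.
#' @export
fp_confusion <- function(pred, true) {
  check_fp_pair(pred, true)
  p <- pred != 0; t <- true != 0
  c(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t), TN = sum(!p & !t))
}

#' Tanimoto similarity between binary fingerprints
#'
#' `TP / (TP + FP + FN)` — positions where both vectors are zero do not
#' enter the score, which matters because fingerprints are dominated by
#' zeros. Two all-zero vectors score 0 (flagged with the `"degenerate"`
#' attribute) rather than raising, so batch ranking never aborts.
#'
#' @inheritParams fp_confusion
#' @return A similarity in `[0, 1]`.
#' @examples
#' a <- b <- numeric(528); a[c(1, 2)] <- 1; b[c(2, 3)] <- 1
#' tanimoto(a, b)  # 1/3
#' @export
tanimoto <- function(pred, true) {
  check_fp_pair(pred, true)
  p <- pred != 0; t <- true != 0
  tp <- sum(p & t)
  denom <- sum(p | t)  # TP + FP + FN
  if (denom == 0) return(structure(0, degenerate = TRUE))
  tp / denom
}

#' F1 score between binary fingerprints
#'
#' Harmonic mean of precision `TP/(TP+FP)` and recall `TP/(TP+FN)`.
#' Degenerate denominators (no predicted or no true positives) map to 0
#' with the `"degenerate"` attribute set.
#'
#' @inheritParams fp_confusion
#' @return A score in `[0, 1]`.
#' @export
f1_score <- function(pred, true) {
  check_fp_pair(pred, true)
  p <- pred != 0; t <- true != 0
  tp <- sum(p & t)
  if (tp == 0) {
    return(structure(0, degenerate = (sum(p) == 0 || sum(t) == 0)))
  }
  precision <- tp / sum(p)
  recall <- tp / sum(t)
  2 * precision * recall / (precision + recall)
}

#' Row-wise Tanimoto of one fingerprint against a matrix
#'
#' Vectorised scoring of a predicted fingerprint against many candidate
#' fingerprints at once.
#'
#' @param pred Binary vector (length d).
#' @param mat Binary matrix (n x d).
#' @return Numeric vector of n Tanimoto scores.
#' @export
tanimoto_rows <- function(pred, mat) {
  stopifnot(length(pred) == ncol(mat))
  p <- as.numeric(pred != 0)
  m <- (mat != 0) * 1
  tp <- as.numeric(m %*% p)
  denom <- rowSums(m) + sum(p) - tp
  ifelse(denom == 0, 0, tp / denom)
}

# --- hex-packed persistence ------------------------------------------------

#' Pack a binary fingerprint into a hex string
#'
#' 528 bits pack into 132 hex characters (4 bits per character,
#' big-endian within each nibble). Round-trips through
#' [hex_to_fingerprint()].
#'
#' @param fp Binary vector whose length is a multiple of 4.
#' @return Hex string.
#' @export
fingerprint_to_hex <- function(fp) {
  stopifnot(length(fp) %% 4 == 0)
  bits <- as.integer(fp != 0)
  nib <- matrix(bits, nrow = 4)
  vals <- nib[1, ] * 8L + nib[2, ] * 4L + nib[3, ] * 2L + nib[4, ]
  paste(substring("0123456789abcdef", vals + 1L, vals + 1L), collapse = "")
}

#' Unpack a hex string into a binary fingerprint
#'
#' @param hex Hex string from [fingerprint_to_hex()].
#' @return Integer binary vector (4 bits per hex character).
#' @export
hex_to_fingerprint <- function(hex) {
  vals <- match(strsplit(tolower(hex), "")[[1]],
                strsplit("0123456789abcdef", "")[[1]]) - 1L
  if (anyNA(vals)) abort("Invalid hex fingerprint string.")
  as.integer(rbind(vals %/% 8L, vals %/% 4L %% 2L, vals %/% 2L %% 2L, vals %% 2L))
}

#' Write fingerprints alongside InChIKeys as TSV
#'
#' @param inchikeys Character vector.
#' @param fps Binary matrix, one fingerprint per row.
#' @param path Output TSV path (columns `inchikey`, `fingerprint_hex`).
#' @export
write_fingerprints <- function(inchikeys, fps, path) {
  stopifnot(length(inchikeys) == nrow(fps))
  hex <- apply(fps, 1, fingerprint_to_hex)
  write.table(data.frame(inchikey = inchikeys, fingerprint_hex = hex),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read fingerprints written by [write_fingerprints()]
#'
#' @param path TSV path.
#' @return List with `inchikeys` and binary matrix `fps`.
#' @export
read_fingerprints <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  fps <- t(vapply(df$fingerprint_hex, hex_to_fingerprint,
                  integer(4L * nchar(df$fingerprint_hex[1])), USE.NAMES = FALSE))
  list(inchikeys = df$inchikey, fps = fps)
}
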