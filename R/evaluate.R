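# Structure-disjoint evaluation: splits and folds at the InChIKey
# first-block (2D skeleton) level, the annotation protocol with its two
# top-k denominators, and corpus bookkeeping.

#' Structure-disjoint train/test split
#'
#' Partitions compounds so that no InChIKey first block (2D skeleton)
#' appears on both sides: blocks are shuffled with the given seed and
#' assigned greedily to the training side until its share reaches
#' `train_fraction`. Because whole blocks move together the realised
#' fraction deviates from the target by at most the largest block.
#'
#' @param inchikeys Character vector of compound InChIKeys.
#' @param train_fraction Target training share (0 < f < 1; default 0.8).
#' @param seed Integer seed; the same seed reproduces the split.
#' @return List with `train` and `test` (the input keys), and the
#'   realised `train_fraction`.
#' @export
structure_disjoint_split <- function(inchikeys, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  blocks <- inchikey_block(inchikeys)
  ub <- unique(blocks)
  if (length(ub) < 2) {
    abort("Need at least 2 distinct InChIKey first blocks to split.")
  }
  with_seed(seed, {
    ord <- sample(ub)
    sizes <- table(blocks)[ord]
    cum <- cumsum(as.integer(sizes))
    n_train_blocks <- sum(cum <= round(train_fraction * length(inchikeys)))
    n_train_blocks <- max(1L, min(n_train_blocks, length(ub) - 1L))
    train_blocks <- ord[seq_len(n_train_blocks)]
    in_train <- blocks %in% train_blocks
    list(train = inchikeys[in_train], test = inchikeys[!in_train],
         train_fraction = mean(in_train))
  })
}

#' Structure-disjoint fold assignment
#'
#' Assigns InChIKey first blocks to `k` cross-validation folds
#' (shuffled, round-robin), so every compound is validated exactly once
#' and no skeleton spans folds.
#'
#' @param inchikeys Character vector of compound InChIKeys.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @param structure_disjoint Group by first block before assignment
#'   (default `TRUE`); `FALSE` folds individual compounds naively.
#' @return Integer vector of fold ids (1..k) aligned with `inchikeys`.
#' @export
make_folds <- function(inchikeys, k = 5L, seed = 1L, structure_disjoint = TRUE) {
  stopifnot(k >= 2)
  units <- if (structure_disjoint) inchikey_block(inchikeys) else inchikeys
  uu <- unique(units)
  if (length(uu) < k) {
    abort(sprintf("Only %d distinct unit(s) for %d folds.", length(uu), k))
  }
  with_seed(seed, {
    ord <- sample(uu)
    fold_of <- setNames(rep(seq_len(k), length.out = length(ord)), ord)
    as.integer(fold_of[units])
  })
}

#' Corpus-design bookkeeping
#'
#' Tallies a spectral corpus design from its per-library spectrum counts
#' and the compound-level train/test split: total spectra, total
#' compounds and the realised training share.
#'
#' @param spectra Named numeric vector of spectrum counts per
#'   library/mode stratum.
#' @param train_compounds,test_compounds Compound counts on each side of
#'   the structure-disjoint split.
#' @return A one-row tibble: `total_spectra`, `total_compounds`,
#'   `train_compounds`, `test_compounds`, `train_fraction`.
#' @examples
#' corpus_design(c(mona_pos = 79404, mona_neg = 32269,
#'                 nist_pos = 401985, nist_neg = 136895),
#'               train_compounds = 29588, test_compounds = 6290)
#' @export
corpus_design <- function(spectra, train_compounds, test_compounds) {
  stopifnot(all(spectra >= 0), train_compounds >= 0, test_compounds >= 0)
  tibble(
    total_spectra = sum(spectra),
    total_compounds = train_compounds + test_compounds,
    train_compounds = train_compounds,
    test_compounds = test_compounds,
    train_fraction = train_compounds / (train_compounds + test_compounds)
  )
}

#' Evaluate annotation on queries with known truth
#'
#' Runs the full annotation protocol for every query spectrum and
#' reports mean fingerprint-prediction quality (F1 and Tanimoto against
#' the true fingerprints, per spectrum) and top-k ranking accuracy under
#' both denominators: over all queries, and excluding queries whose
#' candidate list does not contain the true compound.
#'
#' @param queries Spectrum tibble with a `true_inchikey` column.
#' @param bundle A `model_bundle`.
#' @param compounds Candidate database tibble.
#' @param true_fps Optional binary matrix of true fingerprints with
#'   rownames = InChIKeys (computed from `compounds` SMILES /
#'   `fingerprint_hex` when omitted).
#' @param cfg,prep,spec,formulas,threshold As in [annotate_spectra()].
#' @param ks Rank depths to report (default 1, 3, 5, 10).
#' @return An `eval_report` object.
#' @export
evaluate_annotation <- function(queries, bundle, compounds, true_fps = NULL,
                                cfg = search_config(),
                                prep = preprocess_config(),
                                spec = binning_spec(),
                                formulas = NULL, threshold = 0.5,
                                ks = c(1L, 3L, 5L, 10L)) {
  stopifnot("true_inchikey" %in% names(queries))
  ann <- annotate_spectra(queries, compounds, bundle, cfg, prep, spec,
                          formulas, threshold)
  truth <- queries$true_inchikey[match(ann$spectrum_id, queries$spectrum_id)]
  if (is.null(true_fps)) {
    cf <- candidate_fps(compounds)
    true_fps <- cf$fps[cf$ok, , drop = FALSE]
    rownames(true_fps) <- compounds$inchikey[cf$ok]
  }
  # fingerprint-prediction quality where the true structure is known
  pp <- preprocess_spectra(queries, prep, spec, merge = FALSE)
  ctx <- resolve_context(pp$spectra)
  pred <- predict_bundle(bundle, pp$binned, ctx, threshold)
  truth_all <- queries$true_inchikey[match(pp$spectra$spectrum_id,
                                           queries$spectrum_id)]
  have_fp <- truth_all %in% rownames(true_fps)
  f1s <- tanis <- numeric(0)
  if (any(have_fp)) {
    idx <- which(have_fp)
    f1s <- vapply(idx, function(i)
      f1_score(pred$bits[i, ], true_fps[truth_all[i], ]), numeric(1))
    tanis <- vapply(idx, function(i)
      tanimoto(pred$bits[i, ], true_fps[truth_all[i], ]), numeric(1))
  }
  hits <- matrix(FALSE, nrow(ann), length(ks),
                 dimnames = list(NULL, paste0("top", ks)))
  true_present <- logical(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    ranked <- ann$ranking[[i]]
    true_present[i] <- any(!is.na(ranked$inchikey) &
                             inchikey_block(ranked$inchikey) ==
                             inchikey_block(truth[i]))
    for (j in seq_along(ks)) {
      hits[i, j] <- topk_hit(ranked, truth[i], ks[j])
    }
  }
  topk_all <- colMeans(hits)
  topk_present <- if (any(true_present))
    colMeans(hits[true_present, , drop = FALSE]) else setNames(rep(NA_real_, length(ks)), colnames(hits))
  structure(list(
    mean_f1 = if (length(f1s)) mean(f1s) else NA_real_,
    mean_tanimoto = if (length(tanis)) mean(tanis) else NA_real_,
    topk_all = topk_all,
    topk_true_present = topk_present,
    basis = unique(ann$basis),
    ks = ks,
    n_queries = nrow(ann),
    n_excluded_true_missing = sum(!true_present),
    n_rejected = nrow(attr(ann, "rejected")),
    per_query = tibble(spectrum_id = ann$spectrum_id,
                       basis = ann$basis,
                       n_candidates = ann$n_candidates,
                       true_present = true_present,
                       as_tibble(hits))
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d queries (%d without true compound in list)>\n",
              x$n_queries, x$n_excluded_true_missing))
  cat(sprintf("  mean F1 %.3f  mean Tanimoto %.3f\n", x$mean_f1, x$mean_tanimoto))
  for (j in seq_along(x$ks)) {
    cat(sprintf("  top-%d: %.1f%% (all) / %.1f%% (true present)\n",
                x$ks[j], 100 * x$topk_all[j], 100 * x$topk_true_present[j]))
  }
  invisible(x)
}

#' @describeIn evaluate_annotation Tidy the per-k accuracies of an
#'   `eval_report` into a long tibble (`k`, `denominator`, `accuracy`).
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) {
  bind_rows(
    tibble(k = x$ks, denominator = "all_queries", accuracy = unname(x$topk_all)),
    tibble(k = x$ks, denominator = "true_present",
           accuracy = unname(x$topk_true_present))
  )
}

#' @describeIn evaluate_annotation One-row summary of an `eval_report`.
#' @export
glance.eval_report <- function(x, ...) {
  tibble(n_queries = x$n_queries,
         n_excluded_true_missing = x$n_excluded_true_missing,
         mean_f1 = x$mean_f1, mean_tanimoto = x$mean_tanimoto,
         top1_all = unname(x$topk_all["top1"]),
         top1_true_present = unname(x$topk_true_present["top1"]))
}

#' Structure-disjoint k-fold cross-validation
#'
#' Folds the corpus at the InChIKey first-block level, trains the
#' strategy on each training split and evaluates annotation on the held
#' out fold.
#'
#' @param spectra Spectrum tibble with `true_inchikey`.
#' @param compounds Candidate database.
#' @param k Number of folds.
#' @param strategy,cnn_cfg Passed to [fit_strategy()].
#' @param seed Fold-assignment seed.
#' @param prep,spec,cfg Preprocessing, binning and search configuration.
#' @param true_fps Optional true-fingerprint matrix (rownames =
#'   InChIKeys).
#' @param ... Passed to [fit_strategy()] (e.g. `epochs`).
#' @return List with `folds` (per-fold `eval_report`s) and `pooled`
#'   (tibble of per-fold summaries plus means).
#' @export
kfold_cv <- function(spectra, compounds, k = 5L, strategy = "single",
                     cnn_cfg = cnn_config(), seed = 1L,
                     prep = preprocess_config(), spec = binning_spec(),
                     cfg = search_config(), true_fps = NULL, ...) {
  stopifnot("true_inchikey" %in% names(spectra))
  fold_id <- make_folds(spectra$true_inchikey, k, seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    train <- spectra[fold_id != f, ]
    test <- spectra[fold_id == f, ]
    pp <- preprocess_spectra(train, prep, spec, merge = TRUE)
    y <- true_fp_matrix(pp$spectra$inchikey, compounds, true_fps)
    ctx <- resolve_context(pp$spectra)
    bundle <- fit_strategy(pp$binned, y, ctx, strategy, cnn_cfg, ...)
    reports[[f]] <- evaluate_annotation(test, bundle, compounds, true_fps,
                                        cfg, prep, spec)
  }
  summaries <- bind_rows(lapply(reports, glance))
  summaries$fold <- seq_len(k)
  list(folds = reports,
       pooled = summaries,
       mean_f1 = mean(summaries$mean_f1, na.rm = TRUE),
       mean_tanimoto = mean(summaries$mean_tanimoto, na.rm = TRUE))
}

true_fp_matrix <- function(inchikeys, compounds, true_fps = NULL) {
  if (is.null(true_fps)) {
    cf <- candidate_fps(compounds)
    true_fps <- cf$fps[cf$ok, , drop = FALSE]
    rownames(true_fps) <- compounds$inchikey[cf$ok]
  }
  missing <- setdiff(inchikeys, rownames(true_fps))
  if (length(missing)) {
    abort(sprintf("No fingerprint available for %d training compound(s).",
                  length(missing)))
  }
  true_fps[inchikeys, , drop = FALSE]
}
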