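# Fingerprint predictors: the 1D convolutional network, the classical
# multi-label baselines (LR / SLP / SVM / MLP), instrument-context
# resolution and the three training strategies (one model, one model with
# context bits, eight context-specific models).

#' Resolve the instrument context of spectra
#'
#' Derives the three binary instrument-context factors used for
#' multi-model routing: collision energy is split at 30 eV (`< 30` low,
#' `>= 30` high); Orbitrap and Q-TOF count as high resolution while ion
#' trap (IT) and QqQ count as low; mode is the ionization mode. Records
#' with no parseable collision energy take `default_energy`, unknown
#' instrument types take `default_resolution`; a missing ionization mode
#' is an error.
#'
#' @param spectra Spectrum tibble.
#' @param default_energy Energy class assumed when no eV value is
#'   available (`"low"` by default).
#' @param default_resolution Resolution class for unknown instrument
#'   types (`"high"` by default).
#' @return A tibble with columns `energy`, `resolution`, `mode`,
#'   `context_key` (e.g. `"high.low.positive"`), integer `context_index`
#'   (1–8) and logical `energy_defaulted` provenance flag.
#' @examples
#' s <- spectrum_record(data.frame(mz = 100, intensity = 1),
#'                      ionization_mode = "positive",
#'                      instrument_type = "Orbitrap",
#'                      collision_energy_raw = "35 eV")
#' resolve_context(s)
#' @export
resolve_context <- function(spectra, default_energy = c("low", "high"),
                            default_resolution = c("high", "low")) {
  default_energy <- match.arg(default_energy)
  default_resolution <- match.arg(default_resolution)
  if (anyNA(spectra$ionization_mode)) {
    abort("Cannot resolve context: missing ionization_mode.")
  }
  ev <- spectra$collision_energy_ev
  energy <- ifelse(is.na(ev), default_energy, ifelse(ev >= 30, "high", "low"))
  itype <- normalize_instrument_type(spectra$instrument_type)
  resolution <- case_when(
    itype %in% c("Orbitrap", "Q-TOF") ~ "high",
    itype %in% c("IT", "QqQ") ~ "low",
    TRUE ~ default_resolution
  )
  mode <- spectra$ionization_mode
  tibble(
    energy = energy, resolution = resolution, mode = mode,
    context_key = paste(energy, resolution, mode, sep = "."),
    context_index = 1L +
      4L * (energy == "high") + 2L * (resolution == "high") + (mode == "positive"),
    energy_defaulted = is.na(ev)
  )
}

#' All eight instrument-context keys
#' @return Character vector of the 8 `energy.resolution.mode` keys in
#'   `context_index` order.
#' @export
context_keys <- function() {
  grid <- expand.grid(mode = c("negative", "positive"),
                      resolution = c("low", "high"),
                      energy = c("low", "high"),
                      stringsAsFactors = FALSE)
  paste(grid$energy, grid$resolution, grid$mode, sep = ".")
}

#' Configuration of the convolutional fingerprint predictor
#'
#' The network is: embedding (quantised intensity tokens) -> conv1d ->
#' maxpool -> conv1d -> maxpool -> dropout -> flatten -> four dense ReLU
#' layers -> 528 sigmoid outputs, trained with binary cross-entropy and
#' Adam. With the embedding counted first and the sigmoid output counted
#' last this is a 12-layer sequence. Defaults are sized for single-CPU
#' training of desk-scale corpora; every field is open.
#'
#' @param input_length Number of input bins (1174, or 1177 with context
#'   bits).
#' @param embedding_vocab Token vocabulary (quantised intensities 0–100
#'   -> 101).
#' @param embedding_dim Embedding width.
#' @param use_embedding `FALSE` switches to a raw-intensity input channel
#'   (no embedding / quantisation); the layer count drops to 11.
#' @param conv_filters,conv_kernels,pool_sizes Two-stage convolution
#'   parameters (kernels must be odd; same padding).
#' @param dropout_rate Dropout fraction after the second pooling stage.
#' @param dense_sizes Widths of the four hidden dense layers.
#' @param output_size Number of fingerprint bits (fixed 528).
#' @param epochs,batch_size,learning_rate Training-loop parameters.
#' @param seed Seed controlling weight init, shuffling and dropout.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(input_length = 1174L,
                       embedding_vocab = 101L,
                       embedding_dim = 16L,
                       use_embedding = TRUE,
                       conv_filters = c(16L, 32L),
                       conv_kernels = c(5L, 5L),
                       pool_sizes = c(2L, 2L),
                       dropout_rate = 0.5,
                       dense_sizes = c(256L, 128L, 64L, 64L),
                       output_size = 528L,
                       epochs = 100L,
                       batch_size = 32L,
                       learning_rate = 3e-3,
                       seed = 1L) {
  stopifnot(length(conv_filters) == 2, length(conv_kernels) == 2,
            length(pool_sizes) == 2, length(dense_sizes) == 4,
            all(conv_kernels %% 2 == 1), dropout_rate >= 0, dropout_rate < 1,
            input_length >= 4, output_size == 528L)
  l_after <- input_length %/% pool_sizes[1] %/% pool_sizes[2]
  if (l_after < 1) {
    abort("Pool sizes exceed the input length.", class = "specfp_config_error")
  }
  structure(list(
    input_length = as.integer(input_length),
    embedding_vocab = as.integer(embedding_vocab),
    embedding_dim = as.integer(embedding_dim),
    use_embedding = isTRUE(use_embedding),
    conv_filters = as.integer(conv_filters),
    conv_kernels = as.integer(conv_kernels),
    pool_sizes = as.integer(pool_sizes),
    dropout_rate = dropout_rate,
    dense_sizes = as.integer(dense_sizes),
    output_size = as.integer(output_size),
    optimizer = "adam", loss = "binary_crossentropy",
    metric = "binary_accuracy",
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, seed = as.integer(seed)
  ), class = "cnn_config")
}

#' Build the (untrained) convolutional fingerprint predictor
#'
#' Realises the layer stack of [cnn_config()] with seeded weight
#' initialisation; two builds from the same config are bit-identical.
#'
#' @param cfg A [cnn_config()].
#' @return A `cnn_model` object (layers + config; untrained).
#' @export
build_cnn <- function(cfg = cnn_config()) {
  stopifnot(inherits(cfg, "cnn_config"))
  with_seed(cfg$seed, {
    layers <- list()
    c_in <- if (cfg$use_embedding) cfg$embedding_dim else 1L
    if (cfg$use_embedding) {
      layers <- c(layers, list(layer_embedding(cfg$embedding_vocab, cfg$embedding_dim)))
    }
    L <- cfg$input_length
    for (s in 1:2) {
      layers <- c(layers, list(layer_conv1d(c_in, cfg$conv_filters[s],
                                            cfg$conv_kernels[s])))
      c_in <- cfg$conv_filters[s]
      layers <- c(layers, list(layer_maxpool1d(cfg$pool_sizes[s])))
      L <- L %/% cfg$pool_sizes[s]
      if (L < 1) abort("Pool size larger than sequence.", class = "specfp_config_error")
    }
    layers <- c(layers, list(layer_dropout(cfg$dropout_rate), layer_flatten()))
    d_in <- L * c_in
    for (w in cfg$dense_sizes) {
      layers <- c(layers, list(layer_dense(d_in, w, "relu")))
      d_in <- w
    }
    layers <- c(layers, list(layer_dense(d_in, cfg$output_size, "sigmoid")))
    structure(list(cfg = cfg, layers = layers, trained = FALSE,
                   training_log = NULL),
              class = "cnn_model")
  })
}

#' Layer types of a built model
#'
#' Introspection helper: the default architecture reports the 12-layer
#' sequence embedding, conv1d, maxpool1d, conv1d, maxpool1d, dropout,
#' flatten, dense x4, output (sigmoid dense).
#'
#' @param model A `cnn_model`.
#' @return Character vector of layer type names.
#' @export
nn_layer_types <- function(model) {
  types <- vapply(model$layers, `[[`, character(1), "type")
  types[length(types)] <- "output"
  types
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model: input %d, %s, %d outputs>\n",
              x$cfg$input_length, paste(nn_layer_types(x), collapse = " -> "),
              x$cfg$output_size))
  invisible(x)
}

#' Quantise scaled intensities into embedding tokens
#'
#' The embedding front-end consumes integer tokens, so scaled bin
#' intensities in `[0, scale_max]` are rounded to the nearest integer in
#' `[0, vocab - 1]`. Zero stays zero, so empty bins share one token.
#'
#' @param x Numeric vector or matrix of scaled intensities.
#' @param vocab Vocabulary size (default 101 for intensities 0–100).
#' @return Integer vector/matrix of tokens.
#' @export
quantize_for_embedding <- function(x, vocab = 101L) {
  q <- round(x)
  q[q < 0] <- 0L
  q[q > vocab - 1L] <- vocab - 1L
  if (is.matrix(x)) matrix(as.integer(q), nrow(x), ncol(x)) else as.integer(q)
}

model_input <- function(model, x) {
  mat <- if (inherits(x, "binned_spectra")) x$values else
    if (is.null(dim(x))) matrix(x, nrow = 1) else x
  if (ncol(mat) != model$cfg$input_length) {
    abort(sprintf("Input width %d does not match model input length %d.",
                  ncol(mat), model$cfg$input_length))
  }
  if (model$cfg$use_embedding) {
    quantize_for_embedding(mat, model$cfg$embedding_vocab)
  } else {
    # raw-intensity channel: bring [0, scale_max] intensities to unit scale
    mat / (model$cfg$embedding_vocab - 1L)
  }
}

#' Train the convolutional fingerprint predictor
#'
#' Minibatch Adam on mean binary cross-entropy over the 528 sigmoid
#' outputs. The per-epoch loss and binary accuracy are recorded in the
#' training log; a fixed config seed makes the whole run reproducible.
#' Training aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param model An untrained (or previously trained) `cnn_model`.
#' @param x Binned spectra: a `binned_spectra` object or numeric matrix
#'   of scaled intensities (quantisation happens internally when the
#'   model uses an embedding).
#' @param y Binary fingerprint matrix, one 528-bit row per spectrum.
#' @param epochs,batch_size,learning_rate Optional overrides of the
#'   config values.
#' @param init_output_bias Initialise the output-layer bias at the
#'   per-bit base-rate logit (default `TRUE`). With 528 heavily
#'   imbalanced outputs this removes the long initial phase in which the
#'   network only learns the bit prevalences.
#' @param verbose Print per-epoch progress.
#' @return The trained `cnn_model` with `training_log` (tibble: epoch,
#'   loss, binary_accuracy).
#' @export
train_cnn <- function(model, x, y, epochs = NULL, batch_size = NULL,
                      learning_rate = NULL, init_output_bias = TRUE,
                      verbose = FALSE) {
  cfg <- model$cfg
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- learning_rate %||% cfg$learning_rate
  X <- model_input(model, x)
  y <- as.matrix(y)
  stopifnot(nrow(X) == nrow(y), ncol(y) == cfg$output_size)
  n <- nrow(X)
  with_seed(cfg$seed + 1L, {
    layers <- model$layers
    if (init_output_bias && !model$trained) {
      base <- pmin(pmax(colMeans(y), 1e-4), 1 - 1e-4)
      layers[[length(layers)]]$b <- log(base / (1 - base))
    }
    state <- adam_state(layers)
    step <- 0L
    log <- vector("list", epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_acc <- 0; seen <- 0
      for (start in seq(1L, n, by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1L, n)]
        B <- length(rows)
        fw <- nn_forward(layers, X[rows, , drop = FALSE], B,
                         training = TRUE, keep_cache = TRUE)
        p <- fw$out
        yb <- y[rows, , drop = FALSE]
        loss <- bce_loss(p, yb)
        if (!is.finite(loss)) {
          abort(sprintf("Non-finite loss at epoch %d (step %d); try a lower learning rate.",
                        ep, step), class = "specfp_training_error")
        }
        dZ <- (p - yb) / length(yb)         # fused sigmoid + BCE gradient
        grads <- nn_backward(layers, fw$caches, dZ, B)
        step <- step + 1L
        upd <- adam_update(layers, grads, state, step, lr = lr)
        layers <- upd$layers; state <- upd$state
        ep_loss <- ep_loss + loss * B
        ep_acc <- ep_acc + binary_accuracy(p, yb) * B
        seen <- seen + B
      }
      log[[ep]] <- tibble(epoch = ep, loss = ep_loss / seen,
                          binary_accuracy = ep_acc / seen)
      if (verbose) {
        message(sprintf("epoch %d/%d  loss %.4f  acc %.4f",
                        ep, epochs, ep_loss / seen, ep_acc / seen))
      }
    }
    model$layers <- layers
    model$trained <- TRUE
    model$training_log <- bind_rows(model$training_log, bind_rows(log))
    model
  })
}

#' Predict fingerprints from binned spectra
#'
#' Forward pass (dropout off) followed by thresholding: bit i is set iff
#' its sigmoid probability is `>= threshold`.
#'
#' @param model A trained `cnn_model` (or baseline model).
#' @param x `binned_spectra`, matrix, or single numeric vector.
#' @param threshold Binarisation threshold (default 0.5).
#' @return List with `probabilities` (n x 528 matrix) and `bits` (binary
#'   integer matrix of the same shape).
#' @export
predict_fingerprint <- function(model, x, threshold = 0.5) {
  UseMethod("predict_fingerprint")
}

#' @export
predict_fingerprint.cnn_model <- function(model, x, threshold = 0.5) {
  X <- model_input(model, x)
  n <- nrow(X)
  probs <- matrix(0, n, model$cfg$output_size)
  chunk <- 256L
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    fw <- nn_forward(model$layers, X[rows, , drop = FALSE], length(rows),
                     training = FALSE, keep_cache = FALSE)
    probs[rows, ] <- fw$out
  }
  list(probabilities = probs,
       bits = matrix(as.integer(probs >= threshold), n))
}

# --- classical baselines ---------------------------------------------------

#' Build a classical multi-label baseline model
#'
#' The four reference models trained on the zero-bin-reduced input:
#' `LR` fits an independent binomial GLM per fingerprint bit; `SLP` is a
#' single dense sigmoid layer (joint binary cross-entropy); `MLP` adds
#' ReLU hidden layers; `SVM` fits an independent linear support vector
#' classifier per bit (via e1071). Bits that are constant in training are
#' predicted constant.
#'
#' @param kind One of `"LR"`, `"SLP"`, `"SVM"`, `"MLP"`.
#' @param input_dim Number of (reduced) input bins.
#' @param output_size Number of fingerprint bits (default 528).
#' @param hidden Hidden widths for `MLP` (default 128).
#' @param epochs,batch_size,learning_rate,seed Training parameters for
#'   the gradient-trained kinds.
#' @return A `baseline_model` object; train with [train_baseline()].
#' @export
build_baseline <- function(kind = c("LR", "SLP", "SVM", "MLP"),
                           input_dim, output_size = 528L, hidden = 128L,
                           epochs = 30L, batch_size = 32L,
                           learning_rate = 1e-2, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, input_dim = as.integer(input_dim),
                 output_size = as.integer(output_size),
                 hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 fit = NULL, trained = FALSE),
            class = "baseline_model")
}

#' Number of trainable parameters of a baseline
#' @param model A `baseline_model`.
#' @return Integer count (weights + biases) for the dense kinds.
#' @export
baseline_n_parameters <- function(model) {
  if (model$kind == "SLP") return((model$input_dim + 1L) * model$output_size)
  if (model$kind == "MLP") {
    dims <- c(model$input_dim, model$hidden, model$output_size)
    return(sum((dims[-length(dims)] + 1L) * dims[-1]))
  }
  NA_integer_
}

#' Train a baseline model
#'
#' @param model A `baseline_model` from [build_baseline()].
#' @param x Numeric matrix (reduced bins; see [drop_zero_bins()]).
#' @param y Binary fingerprint matrix.
#' @return The trained model.
#' @export
train_baseline <- function(model, x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), ncol(y) == model$output_size)
  if (model$kind %in% c("SLP", "MLP")) {
    widths <- if (model$kind == "SLP") integer() else model$hidden
    with_seed(model$seed, {
      layers <- list()
      d_in <- model$input_dim
      for (w in widths) {
        layers <- c(layers, list(layer_dense(d_in, w, "relu"))); d_in <- w
      }
      layers <- c(layers, list(layer_dense(d_in, model$output_size, "sigmoid")))
      state <- adam_state(layers)
      step <- 0L
      n <- nrow(x)
      for (ep in seq_len(model$epochs)) {
        ord <- sample.int(n)
        for (start in seq(1L, n, by = model$batch_size)) {
          rows <- ord[start:min(start + model$batch_size - 1L, n)]
          fw <- nn_forward(layers, x[rows, , drop = FALSE], length(rows),
                           training = TRUE, keep_cache = TRUE)
          dZ <- (fw$out - y[rows, , drop = FALSE]) / length(rows) / model$output_size
          grads <- nn_backward(layers, fw$caches, dZ, length(rows))
          step <- step + 1L
          upd <- adam_update(layers, grads, state, step, lr = model$learning_rate)
          layers <- upd$layers; state <- upd$state
        }
      }
      model$fit <- list(layers = layers)
    })
  } else if (model$kind == "LR") {
    fits <- vector("list", ncol(y))
    xi <- cbind(1, x)
    for (j in seq_len(ncol(y))) {
      yj <- y[, j]
      if (length(unique(yj)) == 1L) {
        fits[[j]] <- list(constant = yj[1])
      } else {
        cf <- suppressWarnings(
          glm.fit(xi, yj, family = binomial())$coefficients)
        cf[is.na(cf)] <- 0
        fits[[j]] <- list(coef = cf)
      }
    }
    model$fit <- list(bits = fits)
  } else if (model$kind == "SVM") {
    fits <- vector("list", ncol(y))
    for (j in seq_len(ncol(y))) {
      yj <- factor(y[, j], levels = c(0, 1))
      if (length(unique(y[, j])) == 1L) {
        fits[[j]] <- list(constant = y[1, j])
      } else {
        fits[[j]] <- list(svm = e1071::svm(x, yj, kernel = "linear",
                                           scale = FALSE, probability = FALSE))
      }
    }
    model$fit <- list(bits = fits)
  }
  model$trained <- TRUE
  model
}

#' @export
predict_fingerprint.baseline_model <- function(model, x, threshold = 0.5) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (model$kind %in% c("SLP", "MLP")) {
    fw <- nn_forward(model$fit$layers, x, n, training = FALSE)
    probs <- fw$out
  } else if (model$kind == "LR") {
    xi <- cbind(1, x)
    probs <- vapply(model$fit$bits, function(f) {
      if (!is.null(f$constant)) rep(as.numeric(f$constant), n)
      else plogis(as.numeric(xi %*% f$coef))
    }, numeric(n))
    probs <- matrix(probs, n)
  } else {
    probs <- vapply(model$fit$bits, function(f) {
      if (!is.null(f$constant)) rep(as.numeric(f$constant), n)
      else as.numeric(as.character(predict(f$svm, x)))
    }, numeric(n))
    probs <- matrix(probs, n)
  }
  list(probabilities = probs,
       bits = matrix(as.integer(probs >= threshold), n))
}

# --- strategies ------------------------------------------------------------

#' Fit a fingerprint-prediction strategy
#'
#' Three ways of handling instrument heterogeneity: `"single"` trains one
#' network on the plain bins; `"single_with_context"` trains one network
#' on bins extended by the three context bits; `"eight"` trains one
#' network per populated instrument-context cell (cells with fewer than
#' `min_cell` spectra are skipped with a warning, and prediction for a
#' missing cell falls back to the nearest populated cell by the priority
#' mode > resolution > energy).
#'
#' @param x A `binned_spectra` of the training corpus (plain bins; the
#'   context variants are derived internally).
#' @param y Binary fingerprint matrix aligned with the rows of `x`.
#' @param context Context tibble from [resolve_context()] aligned with
#'   `x` (required for the context strategies).
#' @param strategy One of `"single"`, `"single_with_context"`, `"eight"`.
#' @param cfg A [cnn_config()] sized for the plain bin width; widths and
#'   member seeds are adjusted per strategy.
#' @param min_cell Minimum spectra for an eight-strategy cell.
#' @param ... Passed to [train_cnn()] (e.g. `epochs`, `verbose`).
#' @return A `model_bundle`.
#' @export
fit_strategy <- function(x, y, context = NULL,
                         strategy = c("single", "single_with_context", "eight"),
                         cfg = cnn_config(), min_cell = 20L, ...) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(x, "binned_spectra"))
  y <- as.matrix(y)
  if (strategy != "single" && is.null(context)) {
    abort("`context` is required for the context-aware strategies.")
  }
  members <- list()
  if (strategy == "single") {
    model <- train_cnn(build_cnn(cfg), x, y, ...)
    members[["all"]] <- model
  } else if (strategy == "single_with_context") {
    xa <- attach_context(x, context)
    cfg2 <- cfg
    cfg2$input_length <- cfg$input_length + 3L
    cfg2 <- do.call(cnn_config, cfg2[intersect(names(cfg2), names(formals(cnn_config)))])
    model <- train_cnn(build_cnn(cfg2), xa, y, ...)
    members[["all"]] <- model
  } else {
    for (key in context_keys()) {
      rows <- which(context$context_key == key)
      if (length(rows) < min_cell) {
        warn(sprintf("Context cell '%s' has %d spectra (< %d); skipped.",
                     key, length(rows), min_cell))
        next
      }
      cfg_k <- cfg
      cfg_k$seed <- cfg$seed + match(key, context_keys())
      cfg_k <- do.call(cnn_config, cfg_k[intersect(names(cfg_k), names(formals(cnn_config)))])
      sub <- new_binned_spectra(x$values[rows, , drop = FALSE],
                                x$meta[rows, ], x$spec)
      members[[key]] <- train_cnn(build_cnn(cfg_k), sub,
                                  y[rows, , drop = FALSE], ...)
    }
    if (!length(members)) abort("No context cell reached `min_cell` spectra.")
  }
  structure(list(strategy = strategy, members = members, cfg = cfg,
                 training_log = lapply(members, `[[`, "training_log")),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle: strategy '%s', %d member(s): %s>\n",
              x$strategy, length(x$members),
              paste(names(x$members), collapse = ", ")))
  invisible(x)
}

# nearest populated cell: agreement weighted mode (4) > resolution (2) >
# energy (1); deterministic tie-break by cell order.
route_cell <- function(key, available) {
  if (key %in% available) return(key)
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  score <- vapply(available, function(a) {
    p <- strsplit(a, ".", fixed = TRUE)[[1]]
    4 * (p[3] == parts[3]) + 2 * (p[2] == parts[2]) + 1 * (p[1] == parts[1])
  }, numeric(1))
  available[which.max(score)]
}

#' Predict fingerprints with a fitted strategy bundle
#'
#' Routes each spectrum to the bundle member implied by its instrument
#' context (for the eight-model strategy) or augments the input with
#' context bits (for the context-input strategy).
#'
#' @param bundle A `model_bundle` from [fit_strategy()].
#' @param x A `binned_spectra` (plain bins).
#' @param context Context tibble from [resolve_context()] (required
#'   unless `strategy == "single"`).
#' @param threshold Binarisation threshold.
#' @return As [predict_fingerprint()]: list of `probabilities` and
#'   `bits`, plus `member` (the member key used per spectrum).
#' @export
predict_bundle <- function(bundle, x, context = NULL, threshold = 0.5) {
  stopifnot(inherits(bundle, "model_bundle"))
  n <- nrow(x$values)
  if (bundle$strategy == "single") {
    out <- predict_fingerprint(bundle$members$all, x, threshold)
    out$member <- rep("all", n)
    return(out)
  }
  if (is.null(context)) abort("`context` is required for this strategy.")
  if (bundle$strategy == "single_with_context") {
    xa <- attach_context(x, context)
    out <- predict_fingerprint(bundle$members$all, xa, threshold)
    out$member <- rep("all", n)
    return(out)
  }
  avail <- names(bundle$members)
  member <- vapply(context$context_key, route_cell, character(1),
                   available = avail, USE.NAMES = FALSE)
  probs <- matrix(0, n, bundle$cfg$output_size)
  for (key in unique(member)) {
    rows <- which(member == key)
    sub <- new_binned_spectra(x$values[rows, , drop = FALSE],
                              x$meta[rows, ], x$spec)
    probs[rows, ] <- predict_fingerprint(bundle$members[[key]], sub,
                                         threshold)$probabilities
  }
  list(probabilities = probs,
       bits = matrix(as.integer(probs >= threshold), n),
       member = member)
}

# --- persistence -----------------------------------------------------------

#' Save / load a model bundle
#'
#' A bundle directory holds a JSON manifest (strategy + config), one
#' weights file per member and the training logs as TSV.
#'
#' @param bundle A `model_bundle`.
#' @param dir Directory to create.
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(strategy = bundle$strategy,
                   members = names(bundle$members),
                   cfg = unclass(bundle$cfg),
                   package_version = as.character(packageVersion("specfp")))
  jsonlite::write_json(manifest, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA)
  for (key in names(bundle$members)) {
    member <- bundle$members[[key]]
    saveRDS(member, file.path(dir, paste0("member-", gsub("[^a-z.]", "_", key), ".rds")))
    if (!is.null(member$training_log)) {
      write.table(member$training_log,
                  file.path(dir, paste0("log-", gsub("[^a-z.]", "_", key), ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname save_bundle
#' @return `load_bundle()` returns the restored `model_bundle`.
#' @export
load_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "bundle.json"),
                                  simplifyVector = TRUE)
  cfg_args <- manifest$cfg[intersect(names(manifest$cfg), names(formals(cnn_config)))]
  cfg <- do.call(cnn_config, cfg_args)
  members <- list()
  for (key in manifest$members) {
    members[[key]] <- readRDS(file.path(dir, paste0("member-", gsub("[^a-z.]", "_", key), ".rds")))
  }
  structure(list(strategy = manifest$strategy, members = members, cfg = cfg,
                 training_log = lapply(members, `[[`, "training_log")),
            class = "model_bundle")
}

# local seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
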