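#' Ensemble configuration
#'
#' Settings for the hybrid-learning ensemble: which feature encoders to use
#' (defaults to the full ten-encoder registry; the registry order fixes the
#' stacking-vector slots), base-learner hyperparameters, the internal
#' stacking split, and the false-positive-rate targets that define the
#' high/medium/low score cutoffs.
#'
#' @param features character vector of encoder names (subset of
#'   [list_encoders()], order preserved).
#' @param dnn list from [dnn_architecture()].
#' @param tnn list from [tnn_config()].
#' @param use_tnn train the two transformer learners (default TRUE).
#' @param l2_strength ridge penalty for the per-feature logistic learners.
#' @param meta_l2 ridge penalty for the meta-learner.
#' @param stack_frac fraction of training rows held out from base-model
#'   training and used to fit the meta-learner on unbiased base scores.
#' @param cutoff_fprs named FPR targets for the high/medium/low cutoffs.
#' @return named list of class settings.
#' @export
ensemble_config <- function(features = list_encoders(),
                            dnn = dnn_architecture(),
                            tnn = tnn_config(),
                            use_tnn = TRUE,
                            l2_strength = 1e-3,
                            meta_l2 = 1e-2,
                            stack_frac = 0.25,
                            cutoff_fprs = c(high = 0.02, medium = 0.06, low = 0.10)) {
  stopifnot(all(features %in% list_encoders()), length(features) >= 1L)
  list(features = features, dnn = dnn, tnn = tnn, use_tnn = use_tnn,
       l2_strength = l2_strength, meta_l2 = meta_l2, stack_frac = stack_frac,
       cutoff_fprs = cutoff_fprs)
}

# Stratified row split used for stacking: returns indices of the stack split.
stack_split_idx <- function(y, frac, seed) {
  withr_seed(seed, {
    idx1 <- which(y == 1); idx0 <- which(y == 0)
    c(sample(idx1, max(1L, round(length(idx1) * frac))),
      sample(idx0, max(1L, round(length(idx0) * frac))))
  })
}

# Encode + scale one feature for an ensemble (fitting or applying scalers).
encode_scaled <- function(windows, feature, gps_reference, scaler = NULL,
                          exclude_self = TRUE) {
  X <- encode_windows(windows, feature, reference = gps_reference,
                      exclude_self = exclude_self)
  if (is.null(scaler)) {
    scaler <- fit_scaler(X, if (feature == "GPS") "zscore" else "minmax")
  }
  list(X = apply_scaler(X, scaler), scaler = scaler)
}

#' Train the stacked hybrid-learning ensemble
#'
#' Fits, per configured feature, one feed-forward network and one ridge
#' logistic model, plus (optionally) a bidirectional-encoder and a
#' causal-decoder transformer on the token stream. Base models are trained on
#' an internal training split; their scores on the remaining stacking split
#' form the stacking vectors on which the logistic meta-learner is fitted.
#' Score cutoffs are then calibrated on the training negatives.
#'
#' @param windows character vector of peptide windows (equal length).
#' @param y binary labels (1 = modified site).
#' @param residue_class `"ST"` or `"Y"` (recorded in the model).
#' @param config list from [ensemble_config()].
#' @param seed integer seed controlling every stochastic step.
#' @return object of class `dephos_ensemble`.
#' @export
train_ensemble <- function(windows, y, residue_class = "ST",
                           config = ensemble_config(), seed = 1L) {
  y <- as.numeric(y)
  if (length(windows) != length(y)) stop("windows and y lengths differ")
  if (sum(y == 1) < 2L) stop("need at least 2 positive windows")
  if (sum(y == 0) < 2L) stop("need at least 2 negative windows")
  si <- stack_split_idx(y, config$stack_frac, seed_offset(seed, 11L))
  w_base <- windows[-si]; y_base <- y[-si]
  w_stack <- windows[si]; y_stack <- y[si]
  gps_reference <- unique(w_base[y_base == 1])

  dnns <- list(); plrs <- list(); scalers <- list()
  for (k in seq_along(config$features)) {
    f <- config$features[[k]]
    enc <- encode_scaled(w_base, f, gps_reference)
    scalers[[f]] <- enc$scaler
    dnns[[f]] <- train_dnn(enc$X, y_base, config$dnn,
                           seed = seed_offset(seed, 20L + k), feature_name = f)
    plrs[[f]] <- train_plr(enc$X, y_base, config$l2_strength, feature_name = f)
  }
  tnns <- NULL
  if (config$use_tnn) {
    tnns <- list(
      encoder = train_transformer(tokenize_windows(w_base, cls = TRUE), y_base,
                                  "encoder-bidirectional", config$tnn,
                                  seed = seed_offset(seed, 41L)),
      decoder = train_transformer(tokenize_windows(w_base, cls = FALSE), y_base,
                                  "decoder-causal", config$tnn,
                                  seed = seed_offset(seed, 42L)))
  }
  obj <- structure(list(residue_class = residue_class, config = config,
                        features = config$features, gps_reference = gps_reference,
                        scalers = scalers, dnns = dnns, plrs = plrs, tnns = tnns,
                        meta = NULL, cutoffs = NULL, seed = seed),
                   class = "dephos_ensemble")
  V <- stack_vector(obj, w_stack)
  obj$meta <- train_stacker(V, y_stack, config$meta_l2)
  neg_scores <- predict(obj, windows[y == 0])
  obj$cutoffs <- calibrate_cutoffs(neg_scores, config$cutoff_fprs)
  obj
}

#' Assemble stacking vectors for peptide windows
#'
#' Produces the 2k+2-dimensional stacking vector for each window (22 for the
#' full ten-feature registry): the feed-forward block in registry order, then
#' the logistic block, then the encoder- and decoder-transformer scores.
#'
#' @param ensemble a `dephos_ensemble`.
#' @param windows character vector of windows.
#' @return numeric matrix, one row per window, named columns.
#' @export
stack_vector <- function(ensemble, windows) {
  feats <- ensemble$features
  for (f in feats) {
    if (is.null(ensemble$dnns[[f]])) stop("missing DNN base model for slot ", f)
    if (is.null(ensemble$plrs[[f]])) stop("missing PLR base model for slot ", f)
  }
  cols <- list()
  for (f in feats) {
    enc <- encode_scaled(windows, f, ensemble$gps_reference, ensemble$scalers[[f]])
    cols[[paste0("D_", f)]] <- predict(ensemble$dnns[[f]], enc$X)
    cols[[paste0("P_", f)]] <- predict(ensemble$plrs[[f]], enc$X)
  }
  V <- matrix(0, length(windows),
              2L * length(feats) + if (is.null(ensemble$tnns)) 0L else 2L)
  nm <- c(paste0("D", seq_along(feats)), paste0("P", seq_along(feats)))
  for (k in seq_along(feats)) {
    V[, k] <- cols[[paste0("D_", feats[k])]]
    V[, length(feats) + k] <- cols[[paste0("P_", feats[k])]]
  }
  if (!is.null(ensemble$tnns)) {
    if (is.null(ensemble$tnns$encoder) || is.null(ensemble$tnns$decoder))
      stop("missing transformer base model slot")
    V[, 2L * length(feats) + 1L] <-
      predict(ensemble$tnns$encoder, tokenize_windows(windows, cls = TRUE))
    V[, 2L * length(feats) + 2L] <-
      predict(ensemble$tnns$decoder, tokenize_windows(windows, cls = FALSE))
    nm <- c(nm, "B", "G")
  }
  colnames(V) <- nm
  V
}

#' Train the logistic meta-learner over stacking vectors
#'
#' @param V_matrix matrix of stacking vectors.
#' @param y binary labels.
#' @param l2_strength ridge penalty.
#' @return `dephos_plr` meta-model.
#' @export
train_stacker <- function(V_matrix, y, l2_strength = 1e-2) {
  train_plr(V_matrix, y, l2_strength, feature_name = "stack", nonneg = TRUE)
}

#' Predict dephosphorylation/phosphorylation scores
#'
#' @param object a `dephos_ensemble`.
#' @param windows character vector of peptide windows.
#' @param type `"response"` for the final meta probability, `"stack"` for the
#'   matrix of base-model scores.
#' @param ... unused.
#' @return numeric vector of probabilities, or the stacking matrix.
#' @export
predict.dephos_ensemble <- function(object, windows, type = c("response", "stack"), ...) {
  type <- match.arg(type)
  V <- stack_vector(object, windows)
  if (type == "stack") return(V)
  predict(object$meta, V)
}

#' @export
print.dephos_ensemble <- function(x, ...) {
  nb <- 2L * length(x$features) + if (is.null(x$tnns)) 0L else 2L
  cat("Stacked hybrid-learning ensemble (", x$residue_class, " sites)\n", sep = "")
  cat("  features: ", paste(x$features, collapse = ", "), "\n", sep = "")
  cat("  base models: ", nb, " (+ logistic meta-learner)\n", sep = "")
  cat("  positive reference peptides: ", length(x$gps_reference), "\n", sep = "")
  if (!is.null(x$cutoffs))
    cat("  cutoffs (high/medium/low): ",
        paste(signif(unlist(x$cutoffs), 4), collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.dephos_ensemble <- function(object, ...) {
  co <- object$meta$coef
  nm <- c(paste0("D", seq_along(object$features)),
          paste0("P", seq_along(object$features)),
          if (!is.null(object$tnns)) c("B", "G"))
  print(object)
  cat("  meta-learner coefficients:\n")
  print(stats::setNames(round(co, 4), nm))
  invisible(object)
}

#' @export
coef.dephos_ensemble <- function(object, ...) {
  stats::setNames(c(object$meta$intercept, object$meta$coef),
                  c("(Intercept)",
                    c(paste0("D", seq_along(object$features)),
                      paste0("P", seq_along(object$features)),
                      if (!is.null(object$tnns)) c("B", "G"))))
}

# ---- model bundle I/O -------------------------------------------------------

#' Save an ensemble as a model bundle directory
#'
#' Writes a JSON manifest (schema version, registry order, configuration,
#' cutoffs, seed) plus per-component weight files. [load_ensemble()] restores
#' a bundle; predictions round-trip exactly.
#'
#' @param ensemble a `dephos_ensemble`.
#' @param path bundle directory (created if missing).
#' @return `path`, invisibly.
#' @export
save_ensemble <- function(ensemble, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(schema_version = 1L,
                   residue_class = ensemble$residue_class,
                   features = ensemble$features,
                   has_tnn = !is.null(ensemble$tnns),
                   seed = ensemble$seed,
                   cutoffs = as.list(ensemble$cutoffs),
                   config = ensemble$config[c("l2_strength", "meta_l2", "stack_frac")])
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(ensemble, file.path(path, "ensemble.rds"))
  invisible(path)
}

#' Load a model bundle written by [save_ensemble()]
#' @param path bundle directory.
#' @return a `dephos_ensemble`.
#' @export
load_ensemble <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", path)
  manifest <- jsonlite::read_json(mf)
  if (is.null(manifest$schema_version) || manifest$schema_version != 1L)
    stop("unsupported bundle schema version")
  obj <- readRDS(file.path(path, "ensemble.rds"))
  if (!identical(unlist(manifest$features), obj$features))
    stop("manifest feature registry does not match stored model")
  obj
}
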