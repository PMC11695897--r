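#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computed as the probability that a random positive outscores a random
#' negative, with ties counted 1/2:
#' `(#\{pos>neg\} + 0.5 #\{pos=neg\}) / (n_pos n_neg)`.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = positive).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)   # midranks handle the tie convention
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Returns (FPR, TPR) points starting at (0,0) and ending at (1,1), with one
#' step per distinct score (ties grouped into a single threshold step). The
#' trapezoidal area under these points equals [auc_score()].
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return data.frame with columns `fpr`, `tpr`, ordered along the curve.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)   # last index within each tie block
  data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
}

trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Confusion counts at a score cutoff
#'
#' Scores `>= cutoff` are called positive.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param cutoff finite threshold.
#' @return named integer vector: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(scores, labels, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  labels <- as.numeric(labels)
  called <- scores >= cutoff
  c(tp = sum(called & labels == 1), fp = sum(called & labels == 0),
    tn = sum(!called & labels == 0), fn = sum(!called & labels == 1))
}

#' Stratified k-fold cross-validation
#'
#' Splits positives and negatives separately into k folds (sizes differing by
#' at most one per class), trains with `train_fn` on each training part and
#' scores the held-out part. Reports per-fold AUCs and the pooled AUC over
#' the concatenated held-out scores (the headline number).
#'
#' @param x predictor object passed to `train_fn` (matrix or vector; subset
#'   by row).
#' @param y binary labels.
#' @param k folds, one of 4, 6, 8, 10.
#' @param train_fn `function(x_train, y_train)` returning a scoring
#'   `function(x_new)`.
#' @param seed integer seed for fold assignment.
#' @return list of class `dephos_eval`: `auc` (pooled), `per_fold_aucs`,
#'   `roc`, `scores`, `labels`, `folds`, `n_pos`, `n_neg`.
#' @export
kfold_cv <- function(x, y, k = 10L, train_fn, seed = 1L) {
  if (!k %in% c(4L, 6L, 8L, 10L)) stop("k must be one of 4, 6, 8, 10")
  y <- as.numeric(y)
  if (sum(y == 1) < k || sum(y == 0) < k)
    stop("need at least k examples of each class")
  folds <- integer(length(y))
  withr_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  take <- function(obj, i) if (is.matrix(obj) || is.data.frame(obj))
    obj[i, , drop = FALSE] else obj[i]
  scores <- numeric(length(y))
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    model_fn <- train_fn(take(x, which(tr)), y[tr])
    scores[!tr] <- model_fn(take(x, which(!tr)))
    per_fold[f] <- auc_score(scores[!tr], y[!tr])
  }
  structure(list(auc = auc_score(scores, y), per_fold_aucs = per_fold,
                 roc = roc_curve(scores, y), scores = scores, labels = y,
                 folds = folds, n_pos = sum(y == 1), n_neg = sum(y == 0)),
            class = "dephos_eval")
}

#' @export
print.dephos_eval <- function(x, ...) {
  cat("Cross-validation: pooled AUC ", round(x$auc, 4), " (",
      length(x$per_fold_aucs), " folds, per-fold mean ",
      round(mean(x$per_fold_aucs), 4), "); ",
      x$n_pos, " positives / ", x$n_neg, " negatives\n", sep = "")
  invisible(x)
}

#' Calibrate high/medium/low score cutoffs from negative scores
#'
#' For each false-positive-rate target f, the cutoff is the smallest observed
#' score s such that the fraction of negatives scoring `>= s` is at most f
#' (one notch above the maximum when even that fails). Cutoffs are monotone:
#' the stricter the FPR target, the higher the cutoff.
#'
#' @param negative_scores scores of negative sites under the model.
#' @param fpr_targets named numeric vector of FPR targets.
#' @return named list of cutoffs.
#' @export
calibrate_cutoffs <- function(negative_scores,
                              fpr_targets = c(high = 0.02, medium = 0.06, low = 0.10)) {
  if (!length(negative_scores)) stop("no negative scores supplied")
  if (length(negative_scores) < 50L)
    warning("fewer than 50 negative scores; cutoff calibration is coarse")
  s <- sort(unique(negative_scores))
  n <- length(negative_scores)
  out <- lapply(fpr_targets, function(f) {
    for (v in s) {
      if (sum(negative_scores >= v) / n <= f) return(v)
    }
    max(negative_scores) + 1e-9
  })
  as.list(out)
}

#' Cross-predictor specificity matrix
#'
#' Entry (i, j) is model i's AUC when scoring model j's positive set against
#' model i's own negatives; the diagonal uses each model's own positives.
#' Diagonal dominance indicates phosphatase-specific recognition.
#'
#' @param models named list of `dephos_ensemble` objects.
#' @param positive_sets named list of window vectors (positives per model).
#' @param negative_sets named list of window vectors (negatives per model).
#' @return numeric matrix with model names on both dimensions; entries are NA
#'   where a positive set is empty.
#' @export
specificity_matrix <- function(models, positive_sets, negative_sets) {
  if (length(models) < 2L) stop("need at least 2 models")
  n <- length(models)
  nm <- names(models)
  M <- matrix(NA_real_, n, n, dimnames = list(predictor = nm, positives = nm))
  neg_scores <- lapply(nm, function(i) predict(models[[i]], negative_sets[[i]]))
  names(neg_scores) <- nm
  for (i in nm) for (j in nm) {
    pos <- positive_sets[[j]]
    if (!length(pos)) next
    ps <- predict(models[[i]], pos)
    M[i, j] <- auc_score(c(ps, neg_scores[[i]]),
                         c(rep(1, length(ps)), rep(0, length(neg_scores[[i]]))))
  }
  M
}

#' Evaluate a model on an untouched independent test set
#'
#' Verifies that the held-out sites are disjoint from the model's training
#' sites by (accession, position) before scoring.
#'
#' @param model a `dephos_ensemble`.
#' @param heldout data.frame with columns `accession`, `position`, `window`,
#'   `label` (site-peptide rows, positives and negatives).
#' @param train_sites data.frame with columns `accession`, `position` used in
#'   training (leakage guard).
#' @return list: `auc`, `roc`, `confusion` at the medium cutoff, `n_pos`,
#'   `n_neg`.
#' @export
independent_test <- function(model, heldout, train_sites) {
  key_h <- paste(heldout$accession, heldout$position)
  key_t <- paste(train_sites$accession, train_sites$position)
  bad <- intersect(key_h, key_t)
  if (length(bad))
    stop("held-out sites overlap training sites: ", paste(bad, collapse = "; "))
  y <- as.numeric(heldout$label == "positive")
  s <- predict(model, heldout$window)
  cutoff <- if (!is.null(model$cutoffs)) model$cutoffs$medium else 0.5
  list(auc = auc_score(s, y), roc = roc_curve(s, y),
       confusion = confusion_counts(s, y, cutoff),
       n_pos = sum(y == 1), n_neg = sum(y == 0))
}
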