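# Shapley-value attribution. A generic sampling/exact estimator over an
# arbitrary value function, plus the position-level attribution used by the
# motif pipeline: each flanking position of a peptide window is a player,
# and an absent position is filled in from background windows.

#' Shapley values for a black-box scoring function
#'
#' Exact enumeration over all coalitions when `2^p` is small (p <= 12),
#' otherwise permutation sampling (mean marginal contribution over sampled
#' orderings). Both satisfy local accuracy: per row, the attributions sum to
#' `f(x) - f(background mean)` (exactly for enumeration and for averaged
#' permutations, up to Monte Carlo noise in the background expectation).
#'
#' @param f function taking a numeric matrix and returning one score per row.
#' @param X numeric matrix of instances to explain.
#' @param background numeric matrix of background rows (absent features are
#'   drawn from these).
#' @param nperm permutations per instance in sampling mode.
#' @param nbg background rows sampled per evaluation (capped at
#'   `nrow(background)`).
#' @param seed integer seed.
#' @return matrix of attributions, same shape as `X`, with the expected base
#'   value in attribute `"base_value"`.
#' @export
shap_values <- function(f, X, background, nperm = 32L, nbg = 8L, seed = 1L) {
  X <- as.matrix(X); background <- as.matrix(background)
  p <- ncol(X)
  nbg <- min(nbg, nrow(background))
  bgi <- withr_seed(seed_offset(seed, 7L), sample.int(nrow(background), nbg))
  bg <- background[bgi, , drop = FALSE]
  # value of a coalition S for all rows: mean over background rows of
  # f(x with features outside S replaced by the background row)
  coalition_value <- function(S) {
    tot <- numeric(nrow(X))
    for (b in seq_len(nbg)) {
      Z <- bg[rep(b, nrow(X)), , drop = FALSE]
      if (length(S)) Z[, S] <- X[, S, drop = FALSE]
      tot <- tot + f(Z)
    }
    tot / nbg
  }
  phi <- matrix(0, nrow(X), p)
  if (p <= 12L) {
    # exact: iterate subsets, accumulate weighted marginal contributions
    vals <- vector("list", 2^p)
    subsets <- lapply(0:(2^p - 1L), function(m) which(bitwAnd(m, 2^(0:(p - 1L))) > 0))
    for (m in seq_along(subsets)) vals[[m]] <- coalition_value(subsets[[m]])
    fact <- factorial(0:p)
    for (j in seq_len(p)) {
      for (m in seq_along(subsets)) {
        S <- subsets[[m]]
        if (j %in% S) next
        s <- length(S)
        wgt <- fact[s + 1L] * fact[p - s] / fact[p + 1L]
        m_with <- m + 2^(j - 1L)
        phi[, j] <- phi[, j] + wgt * (vals[[m_with]] - vals[[m]])
      }
    }
    base <- vals[[1L]]
  } else {
    base <- coalition_value(integer(0))
    withr_seed(seed_offset(seed, 8L), {
      for (r in seq_len(nperm)) {
        ord <- sample.int(p)
        prev <- base
        S <- integer(0)
        for (j in ord) {
          S <- c(S, j)
          cur <- coalition_value(S)
          phi[, j] <- phi[, j] + (cur - prev) / nperm
          prev <- cur
        }
      }
    })
  }
  attr(phi, "base_value") <- base
  phi
}

#' Position-level Shapley attribution for peptide windows
#'
#' Treats each selected window position as a player: an absent position is
#' replaced by the residue at that position in background windows, and the
#' ensemble rescored. Positions default to the central `DSP(3,3)` region
#' (offsets -3..3 around the site), where the per-site attribution budget for
#' motif analysis is spent; enumeration is exact there (128 coalitions).
#'
#' @param ensemble a trained `dephos_ensemble` (or any object with a
#'   `predict` method over window strings).
#' @param windows character vector of windows to attribute.
#' @param background character vector of background windows.
#' @param positions integer offsets relative to the central residue.
#' @param nbg background windows per evaluation.
#' @param seed integer seed.
#' @return numeric matrix `length(windows)` x `length(positions)`, columns
#'   named by offset.
#' @export
shap_attributions <- function(ensemble, windows, background,
                              positions = -3:3, nbg = 4L, seed = 1L) {
  if (inherits(ensemble, "dephos_ensemble") && is.null(ensemble$meta))
    stop("ensemble is not trained")
  L <- unique(nchar(windows))
  if (length(L) != 1L) stop("windows must share one length")
  flank <- (L - 1L) %/% 2L
  cols <- flank + 1L + positions
  if (any(cols < 1L | cols > L)) stop("positions outside the window")
  Wc <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  Bc <- do.call(rbind, strsplit(background, "", fixed = TRUE))
  f <- function(Z) {
    # Z carries the selected position columns as characters
    W2 <- Wc
    W2[, cols] <- Z
    predict(ensemble, apply(W2, 1L, paste, collapse = ""))
  }
  phi <- shap_values(f, Wc[, cols, drop = FALSE], Bc[, cols, drop = FALSE],
                     nbg = nbg, seed = seed)
  colnames(phi) <- as.character(positions)
  phi
}
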