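# Ten-feature encoder registry. The order is load-bearing: it defines the
# D1..D10 / P1..P10 slots of the 22-score stacking vector and is persisted
# with every trained ensemble.
ENCODER_REGISTRY <- c("GPS", "onehot", "CKSAAP", "AAindex", "OPF_10bit",
                      "EAAC", "BLOSUMrow", "ZScale", "CTDC", "EGAAC")

#' List the registered sequence feature encoders
#'
#' Returns the ten encoder names in their canonical, stable order. This order
#' defines the positions of the per-feature scores in the stacking vector.
#'
#' @return character vector of length 10, `"GPS"` first.
#' @export
list_encoders <- function() {
  if (anyDuplicated(ENCODER_REGISTRY)) stop("encoder registry contains duplicates")
  ENCODER_REGISTRY
}

# ---- physicochemical tables -------------------------------------------------

# Overlapping-property membership (10 classes, Taylor-style overlapping sets).
OPF10_CLASSES <- list(
  hydrophobic = c("A","C","F","G","H","I","K","L","M","T","V","W","Y"),
  positive    = c("H","K","R"),
  negative    = c("D","E"),
  polar       = c("C","D","E","H","K","N","Q","R","S","T","W","Y"),
  charged     = c("D","E","H","K","R"),
  small       = c("A","C","D","G","N","P","S","T","V"),
  tiny        = c("A","C","G","S"),
  aromatic    = c("F","H","W","Y"),
  aliphatic   = c("I","L","V"),
  proline     = c("P")
)

# Five-group amino-acid classification (aliphatic / aromatic / positive /
# negative / uncharged) used by the grouped composition encoder.
GAAC5_GROUPS <- list(
  aliphatic = c("G","A","V","L","M","I"),
  aromatic  = c("F","Y","W"),
  positive  = c("K","R","H"),
  negative  = c("D","E"),
  uncharged = c("S","T","C","P","N","Q")
)

# Sandberg z-scales (5 principal property scales per residue).
ZSCALE5 <- matrix(c(
   0.24, -2.32,  0.60, -0.14,  1.30,   # A
   3.52,  2.50, -3.50,  1.99, -0.17,   # R
   3.05,  1.62,  1.04, -1.15,  1.61,   # N
   3.98,  0.93,  1.93, -2.46,  0.75,   # D
   0.84, -1.67,  3.71,  0.18, -2.65,   # C
   1.75,  0.50, -1.44, -1.34,  0.66,   # Q
   3.11,  0.26, -0.11, -3.04, -0.25,   # E
   2.05, -4.06,  0.36, -0.82, -0.38,   # G
   2.47,  1.95,  0.26,  3.90,  0.09,   # H
  -3.89, -1.73, -1.71, -0.84,  0.26,   # I
  -4.28, -1.30, -1.49, -0.72,  0.84,   # L
   2.29,  0.89, -2.49,  1.49,  0.31,   # K
  -2.85, -0.22,  0.47,  1.94, -0.98,   # M
  -4.22,  1.94,  1.06,  0.54, -0.62,   # F
  -1.66,  0.27,  1.84,  0.70,  2.00,   # P
   2.39, -1.07,  1.15, -1.39,  0.67,   # S
   0.75, -2.18, -1.12, -1.46, -0.40,   # T
  -4.36,  3.94,  0.59,  3.44, -1.59,   # W
  -2.54,  2.44,  0.43,  0.04, -1.47,   # Y
  -2.59, -2.64, -1.54, -0.85, -0.02    # V
), nrow = 20, byrow = TRUE, dimnames = list(AA20, paste0("z", 1:5)))

# Three-group splits for seven physicochemical properties (composition part
# of the composition/transition/distribution descriptor family).
CTD_GROUPS <- list(
  hydrophobicity = list(c("R","K","E","D","Q","N"), c("G","A","S","T","P","H","Y"), c("C","L","V","I","M","F","W")),
  vdw_volume     = list(c("G","A","S","T","P","D"), c("N","V","E","Q","I","L"),     c("M","H","K","F","R","Y","W")),
  polarity       = list(c("L","I","F","W","C","M","V","Y"), c("P","A","T","G","S"), c("H","Q","R","K","N","E","D")),
  polarizability = list(c("G","A","S","D","T"), c("C","P","N","V","E","Q","I","L"), c("K","M","H","F","R","Y","W")),
  charge         = list(c("K","R"), c("A","N","C","Q","G","H","I","L","M","F","P","S","T","W","Y","V"), c("D","E")),
  secondary_str  = list(c("E","A","L","M","Q","K","R","H"), c("V","I","Y","C","W","F","T"), c("G","N","P","S","D")),
  solvent_access = list(c("A","L","F","C","G","I","V","W"), c("R","K","Q","E","N","D"), c("M","S","P","T","H","Y"))
)

# Eight AAindex physicochemical indices (by accession) used by the AAindex
# encoder: hydropathy, hydrophilicity, polarity, isoelectric point,
# flexibility, buried fraction, bulkiness, van der Waals volume.
AAINDEX_ACCESSIONS <- c("KYTJ820101", "HOPT810101", "GRAR740102", "ZIMJ680104",
                        "BHAR880101", "JANJ780101", "ZIMJ680102", "FAUJ880103")

aaindex_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    env <- new.env()
    utils::data("aaindex", package = "seqinr", envir = env)
    acc <- vapply(env$aaindex, function(a) a$H, character(1))
    tab <- sapply(AAINDEX_ACCESSIONS, function(h) {
      v <- env$aaindex[[which(acc == h)[1L]]]$I
      # seqinr names values by three-letter code; map onto AA20 order
      names(v) <- seqinr::a(names(v))
      v <- v[AA20]
      (v - min(v)) / (max(v) - min(v))   # min-max over the 20 residues
    })
    cache <<- tab  # 20 x 8, rows in AA20 order
    cache
  }
})

# ---- GPS similarity score ---------------------------------------------------

#' Peptide similarity score against a positive reference set
#'
#' For each query window, the score is the mean over reference peptides of the
#' summed position-wise substitution-matrix similarity. A query that is itself
#' present in the reference (identical window string) has those reference
#' entries excluded from its mean (leakage guard); if exclusion empties the
#' reference the score is 0 with a warning.
#'
#' @param windows character vector of query windows.
#' @param reference character vector of positive reference windows (same length).
#' @param matrix substitution matrix from [substitution_matrix()].
#' @param exclude_self apply the identical-window leakage guard (default TRUE).
#' @return numeric vector of scores, one per query window.
#' @export
gps_score <- function(windows, reference, matrix = substitution_matrix(),
                      exclude_self = TRUE) {
  if (!length(reference)) stop("empty reference set")
  if (length(unique(nchar(c(windows, reference)))) != 1L)
    stop("query and reference windows must all have the same length")
  Q <- window_index_matrix22(windows)
  R <- window_index_matrix22(reference)
  n <- nrow(Q); m <- nrow(R)
  S <- matrix(0, n, m)
  for (i in seq_len(ncol(Q))) S <- S + matrix[Q[, i], R[, i], drop = FALSE]
  if (exclude_self) {
    keep <- matrix(TRUE, n, m)
    for (j in seq_len(m)) keep[windows == reference[j], j] <- FALSE
    denom <- rowSums(keep)
    out <- ifelse(denom > 0, rowSums(S * keep) / pmax(denom, 1L), 0)
    if (any(denom == 0))
      warning(sum(denom == 0), " window(s) scored 0: reference empty after self-exclusion")
    unname(out)
  } else {
    unname(rowSums(S) / m)
  }
}

# ---- encoders ---------------------------------------------------------------

#' Dimension of an encoder's output for a given window length
#' @param encoder encoder name from [list_encoders()].
#' @param window_length window length (default 61).
#' @return integer output dimension.
#' @export
encoder_dim <- function(encoder, window_length = 61L) {
  L <- window_length
  switch(encoder,
    GPS       = 1L,
    onehot    = L * 21L,
    CKSAAP    = 4L * 400L,
    AAindex   = L * 8L,
    OPF_10bit = L * 10L,
    EAAC      = (L - 4L) * 20L,
    BLOSUMrow = L * 20L,
    ZScale    = L * 5L,
    CTDC      = 21L,
    EGAAC     = (L - 4L) * 5L,
    stop("unknown encoder '", encoder, "'; valid: ", paste(list_encoders(), collapse = ", "))
  )
}

encode_onehot <- function(idx) {
  n <- nrow(idx); L <- ncol(idx)
  X <- matrix(0, n, L * 21L)
  off <- (seq_len(L) - 1L) * 21L
  for (i in seq_len(L)) X[cbind(seq_len(n), off[i] + idx[, i])] <- 1
  X
}

encode_cksaap <- function(idx22, k_max = 3L) {
  n <- nrow(idx22); L <- ncol(idx22)
  X <- matrix(0, n, (k_max + 1L) * 400L)
  real <- idx22 <= 20L   # pairs must join two real amino acids
  for (k in 0:k_max) {
    gap <- k + 1L
    block <- k * 400L
    cnt <- matrix(0, n, 400L)
    npair <- numeric(n)
    for (i in seq_len(max(0L, L - gap))) {
      a <- idx22[, i]; b <- idx22[, i + gap]
      ok <- real[, i] & real[, i + gap]
      pair <- (a - 1L) * 20L + b
      rows <- which(ok)
      if (length(rows)) {
        ind <- cbind(rows, pair[rows])
        cnt[ind] <- cnt[ind] + 1
        npair[rows] <- npair[rows] + 1
      }
    }
    X[, block + seq_len(400L)] <- cnt / pmax(npair, 1)
  }
  X
}

encode_per_position <- function(idx, table) {
  # table: 20 x p values per residue; X/pad rows are zero
  p <- ncol(table)
  full <- rbind(table, matrix(0, 1L, p))   # 21st row for OTHER
  n <- nrow(idx); L <- ncol(idx)
  X <- matrix(0, n, L * p)
  for (i in seq_len(L))
    X[, (i - 1L) * p + seq_len(p)] <- full[idx[, i], , drop = FALSE]
  X
}

encode_sliding_composition <- function(idx, groups_idx, width = 5L) {
  # groups_idx: integer vector length 21 mapping symbol -> group (NA = none)
  n <- nrow(idx); L <- ncol(idx)
  G <- max(groups_idx, na.rm = TRUE)
  nwin <- L - width + 1L
  X <- matrix(0, n, nwin * G)
  gmat <- matrix(groups_idx[idx], n, L)
  for (w in seq_len(nwin)) {
    block <- (w - 1L) * G
    sub <- gmat[, w:(w + width - 1L), drop = FALSE]
    denom <- rowSums(!is.na(sub))
    for (g in seq_len(G))
      X[, block + g] <- rowSums(sub == g, na.rm = TRUE) / pmax(denom, 1)
  }
  X
}

membership_table <- function(classes) {
  tab <- sapply(classes, function(s) as.numeric(AA20 %in% s))
  rownames(tab) <- AA20
  tab
}

#' Encode peptide windows with a registered feature encoder
#'
#' @param windows character vector of equal-length windows.
#' @param encoder encoder name from [list_encoders()].
#' @param reference positive reference windows, required for `"GPS"` only.
#' @param matrix substitution matrix for `"GPS"`.
#' @param exclude_self GPS leakage guard (see [gps_score()]).
#' @return numeric matrix, `length(windows)` rows, [encoder_dim()] columns.
#' @export
encode_windows <- function(windows, encoder, reference = NULL,
                           matrix = substitution_matrix(), exclude_self = TRUE) {
  L <- unique(nchar(windows))
  dim_out <- encoder_dim(encoder, L)
  if (encoder == "GPS") {
    if (is.null(reference)) stop("GPS encoder requires a reference set")
    X <- matrix(gps_score(windows, reference, matrix, exclude_self), ncol = 1L)
  } else {
    idx <- window_index_matrix(windows)
    X <- switch(encoder,
      onehot    = encode_onehot(idx),
      CKSAAP    = encode_cksaap(window_index_matrix22(windows)),
      AAindex   = encode_per_position(idx, aaindex_table()),
      OPF_10bit = encode_per_position(idx, membership_table(OPF10_CLASSES)),
      EAAC      = encode_sliding_composition(idx, group_index(GAAC5_GROUPS, per_residue = TRUE)),
      BLOSUMrow = encode_per_position(idx, substitution_matrix()[AA20, AA20]),
      ZScale    = encode_per_position(idx, ZSCALE5),
      CTDC      = encode_ctdc(idx),
      EGAAC     = encode_sliding_composition(idx, group_index(GAAC5_GROUPS)),
      stop("unknown encoder '", encoder, "'; valid: ",
           paste(list_encoders(), collapse = ", "))
    )
  }
  stopifnot(ncol(X) == dim_out)
  if (!all(is.finite(X))) stop("non-finite values in ", encoder, " encoding")
  X
}

group_index <- function(groups, per_residue = FALSE) {
  g <- rep(NA_integer_, 21L)
  if (per_residue) {
    # identity grouping: each of the 20 residues is its own "group"
    g[seq_len(20L)] <- seq_len(20L)
  } else {
    for (k in seq_along(groups)) g[match(groups[[k]], AA20)] <- k
  }
  g
}

encode_ctdc <- function(idx) {
  n <- nrow(idx); L <- ncol(idx)
  X <- matrix(0, n, 21L)
  real <- idx <= 20L
  denom <- rowSums(real)
  col <- 0L
  for (prop in CTD_GROUPS) {
    for (grp in prop) {
      col <- col + 1L
      members <- match(grp, AA20)
      X[, col] <- rowSums(matrix(idx %in% members, n, L) & real) / pmax(denom, 1)
    }
  }
  X
}

# ---- tokenizer --------------------------------------------------------------

TOKEN_VOCAB <- 22L   # 20 AA + OTHER (X/pad) + CLS

#' Tokenize windows for the transformer learners
#'
#' Maps each window to integer tokens over the 21-symbol vocabulary (20 amino
#' acids plus one shared slot for 'X' and pads). With `cls = TRUE` a reserved
#' class token (id 22) is prepended at index 1, as consumed by the
#' bidirectional encoder.
#'
#' @param windows character vector of windows.
#' @param cls prepend the class token.
#' @return integer matrix of token ids.
#' @export
tokenize_windows <- function(windows, cls = FALSE) {
  idx <- window_index_matrix(windows)
  if (cls) idx <- cbind(22L, idx)
  idx
}

#' Invert [tokenize_windows()]
#' @param tokens integer token matrix.
#' @return character vector of windows (class token dropped; OTHER prints as '*').
#' @export
detokenize_windows <- function(tokens) {
  if (all(tokens[, 1L] == 22L)) tokens <- tokens[, -1L, drop = FALSE]
  syms <- c(AA20, PAD_CHAR)
  apply(tokens, 1L, function(r) paste(syms[r], collapse = ""))
}

# ---- per-dimension scaling --------------------------------------------------

fit_scaler <- function(X, type = c("minmax", "zscore")) {
  type <- match.arg(type)
  if (type == "minmax") {
    lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
    rng <- hi - lo; rng[rng == 0] <- 1
    list(type = "minmax", lo = lo, rng = rng)
  } else {
    mu <- colMeans(X); sd <- apply(X, 2L, stats::sd)
    sd[!is.finite(sd) | sd == 0] <- 1
    list(type = "zscore", mu = mu, sd = sd)
  }
}

apply_scaler <- function(X, scaler) {
  if (scaler$type == "minmax") sweep(sweep(X, 2L, scaler$lo), 2L, scaler$rng, "/")
  else sweep(sweep(X, 2L, scaler$mu), 2L, scaler$sd, "/")
}
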