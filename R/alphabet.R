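# 20 standard amino acids, fixed order used by every encoder.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Pad character used where a window overhangs a protein terminus.
PAD_CHAR <- "*"
UNK_CHAR <- "X"

# Encoding symbol set: the 20 amino acids plus one OTHER slot that absorbs
# both the unknown residue 'X' and the terminal pad '*'.
SYMBOLS21 <- c(AA20, "OTHER")

#' Map window strings to integer symbol indices
#'
#' Converts peptide windows (equal-length strings over the amino-acid alphabet
#' plus 'X' and the pad character) to an integer matrix with values 1..21,
#' where 21 is the shared OTHER slot for 'X' and pads.
#'
#' @param windows character vector of equal-length peptide windows.
#' @return integer matrix, one row per window, one column per position.
#' @keywords internal
window_index_matrix <- function(windows) {
  if (!length(windows)) stop("no windows supplied")
  L <- unique(nchar(windows))
  if (length(L) != 1L) stop("windows must all have the same length")
  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(windows), byrow = TRUE)
  idx <- match(chars, AA20)
  idx[is.na(idx)] <- 21L
  matrix(as.integer(idx), nrow = length(windows))
}

# Separate index keeping pad distinct from X (1..20 AA, 21 = X, 22 = pad);
# used where pads must be treated specially (GPS, CKSAAP pair validity).
window_index_matrix22 <- function(windows) {
  L <- unique(nchar(windows))
  if (length(L) != 1L) stop("windows must all have the same length")
  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(windows), byrow = TRUE)
  idx <- match(chars, c(AA20, UNK_CHAR, PAD_CHAR))
  if (anyNA(idx)) stop("window contains characters outside the alphabet")
  matrix(as.integer(idx), nrow = length(windows))
}

#' Substitution matrix for peptide similarity scoring
#'
#' Returns a 22x22 integer similarity matrix over the 20 amino acids, 'X' and
#' the pad character. Scores for the 21 real symbols come from the named NCBI
#' matrix (BLOSUM62 by default, via Biostrings); the pad row and column are
#' fixed at zero so overhanging positions never contribute to similarity.
#'
#' @param name matrix name; currently "BLOSUM62".
#' @return integer matrix with dimnames over `c(AA20, "X", "*")`.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  name <- match.arg(name, "BLOSUM62")
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  B <- env$BLOSUM62
  syms <- c(AA20, UNK_CHAR)
  M <- matrix(0L, 22L, 22L, dimnames = list(c(syms, PAD_CHAR), c(syms, PAD_CHAR)))
  M[syms, syms] <- B[syms, syms]
  storage.mode(M) <- "integer"
  M
}

# UniProt/Swiss-Prot-like background amino-acid frequencies used by the
# synthetic proteome generator (approximate database composition).
AA_BACKGROUND_FREQ <- c(
  A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
  Q = 0.0393, E = 0.0674, G = 0.0708, H = 0.0227, I = 0.0593,
  L = 0.0965, K = 0.0582, M = 0.0241, F = 0.0386, P = 0.0472,
  S = 0.0660, T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0686
)

seed_offset <- function(seed, k) {
  # keep derived seeds inside 32-bit integer range
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483563) + 1L
}
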