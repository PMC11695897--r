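#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and any character outside the 20-letter amino-acid
#' alphabet is replaced by 'X' (with a warning naming the affected records).
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `accession` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("no sequences in FASTA file: ", path)
  acc <- sub("\\s.*$", "", names(set))
  dup <- unique(acc[duplicated(acc)])
  if (length(dup)) stop("duplicate accession(s) in FASTA: ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "]"), seqs)
  if (any(bad)) {
    seqs <- gsub(paste0("[^", paste(AA20, collapse = ""), "]"), UNK_CHAR, seqs)
    warning("non-standard residues replaced by 'X' in: ",
            paste(acc[bad], collapse = ", "))
  }
  if (any(!nchar(seqs))) stop("empty sequence for accession(s): ",
                              paste(acc[!nchar(seqs)], collapse = ", "))
  data.frame(accession = acc, sequence = seqs, stringsAsFactors = FALSE)
}

#' Extract a centred peptide window around a site
#'
#' Returns the window of `2*flank + 1` residues centred on `position`
#' (1-based). Positions beyond either terminus are padded with '*'; pads can
#' only form a prefix and/or suffix run.
#'
#' @param sequence protein sequence string (or a one-row protein data.frame).
#' @param position 1-based position of the central residue.
#' @param flank number of residues on each side (default 30, i.e. a 61-mer).
#' @return window string of length `2*flank + 1`.
#' @export
extract_window <- function(sequence, position, flank = 30L) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[[1L]]
  n <- nchar(sequence)
  if (position < 1L || position > n)
    stop("position ", position, " out of range 1..", n)
  lo <- position - flank
  hi <- position + flank
  core <- substr(sequence, max(1L, lo), min(n, hi))
  paste0(strrep(PAD_CHAR, max(0L, 1L - lo)), core, strrep(PAD_CHAR, max(0L, hi - n)))
}

# Vectorised window extraction for one sequence and many positions.
extract_windows <- function(sequence, positions, flank = 30L) {
  vapply(positions, function(p) extract_window(sequence, p, flank), character(1))
}

residue_class_of <- function(residue) ifelse(residue == "Y", "Y", "ST")

class_residues <- function(residue_class) {
  if (residue_class == "ST") c("S", "T") else "Y"
}

# All positions of the given residue class in a sequence.
site_positions <- function(sequence, residue_class) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  which(chars %in% class_residues(residue_class))
}

# Internal: assemble a site-peptide data.frame for (accession, position) pairs.
make_site_peptides <- function(proteins, acc, pos, flank, label, residue_class) {
  if (!length(acc)) {
    return(data.frame(accession = character(0), position = integer(0),
                      residue = character(0), window = character(0),
                      label = character(0), residue_class = character(0),
                      stringsAsFactors = FALSE))
  }
  seqmap <- stats::setNames(proteins$sequence, proteins$accession)
  win <- character(length(acc))
  res <- character(length(acc))
  for (i in seq_along(acc)) {
    s <- seqmap[[acc[i]]]
    win[i] <- extract_window(s, pos[i], flank)
    res[i] <- substr(s, pos[i], pos[i])
  }
  data.frame(accession = acc, position = as.integer(pos), residue = res,
             window = win, label = label, residue_class = residue_class,
             stringsAsFactors = FALSE)
}

# Exact-window deduplication within one split (redundancy control).
dedup_windows <- function(df) df[!duplicated(df$window), , drop = FALSE]

#' Build phosphorylation training datasets
#'
#' Windows around known phosphorylation sites of the requested residue class
#' are the positives; windows around every other residue of that class in the
#' same protein collection are the negatives. Duplicate window strings are
#' removed within each set.
#'
#' @param proteins data.frame from [read_fasta()].
#' @param known_psites data.frame with columns `accession`, `position`
#'   (1-based) and optionally `residue`.
#' @param residue_class `"ST"` (pooled serine/threonine) or `"Y"`.
#' @param flank window flank (default 30).
#' @return list with data.frames `positives` and `negatives`.
#' @export
build_phospho_datasets <- function(proteins, known_psites, residue_class = c("ST", "Y"),
                                   flank = 30L) {
  residue_class <- match.arg(residue_class)
  seqmap <- stats::setNames(proteins$sequence, proteins$accession)
  ps <- known_psites[known_psites$accession %in% proteins$accession, , drop = FALSE]
  res <- substr(seqmap[ps$accession], ps$position, ps$position)
  keep <- res %in% class_residues(residue_class)
  if ("residue" %in% names(known_psites)) {
    ok <- res == ps$residue | !keep
    nbad <- sum(!ok)
    if (nbad) {
      warning(nbad, " site record(s) skipped: residue mismatch with sequence")
      keep <- keep & ok
    }
  }
  ps <- ps[keep, , drop = FALSE]
  pos_key <- paste(ps$accession, ps$position)
  positives <- make_site_peptides(proteins, ps$accession, ps$position, flank,
                                  "positive", residue_class)
  neg_acc <- character(0); neg_pos <- integer(0)
  for (i in seq_len(nrow(proteins))) {
    p <- site_positions(proteins$sequence[i], residue_class)
    if (!length(p)) next
    k <- paste(proteins$accession[i], p)
    p <- p[!(k %in% pos_key)]
    neg_acc <- c(neg_acc, rep(proteins$accession[i], length(p)))
    neg_pos <- c(neg_pos, p)
  }
  negatives <- make_site_peptides(proteins, neg_acc, neg_pos, flank,
                                  "negative", residue_class)
  list(positives = dedup_windows(positives), negatives = dedup_windows(negatives))
}

#' Build dephosphorylation training datasets
#'
#' Windows around dephosphorylation sites are the positives. Negatives are
#' drawn only from the substrate proteins that carry at least one positive:
#' by default from every other residue of the same class on those substrates;
#' with `negatives_from_psites = TRUE`, only from known phosphorylation sites
#' that are not dephosphorylation sites (dephosphorylation presupposes
#' phosphorylation).
#'
#' @param proteins data.frame from [read_fasta()].
#' @param dephos_sites data.frame with columns `accession`, `position`.
#' @param all_psites optional data.frame of known p-sites (same columns);
#'   required when `negatives_from_psites = TRUE`.
#' @param residue_class `"ST"` or `"Y"`.
#' @param flank window flank.
#' @param negatives_from_psites restrict negatives to known p-sites.
#' @return list with data.frames `positives` and `negatives`.
#' @export
build_dephos_datasets <- function(proteins, dephos_sites, all_psites = NULL,
                                  residue_class = c("ST", "Y"), flank = 30L,
                                  negatives_from_psites = FALSE) {
  residue_class <- match.arg(residue_class)
  seqmap <- stats::setNames(proteins$sequence, proteins$accession)
  ds <- unique(dephos_sites[dephos_sites$accession %in% proteins$accession,
                            c("accession", "position")])
  res <- substr(seqmap[ds$accession], ds$position, ds$position)
  keep <- res %in% class_residues(residue_class)
  ds <- ds[keep, , drop = FALSE]
  if (!nrow(ds)) stop("no positives: no dephosphorylation sites of class ",
                      residue_class, " on the supplied substrates")
  pos_key <- paste(ds$accession, ds$position)
  positives <- make_site_peptides(proteins, ds$accession, ds$position, flank,
                                  "positive", residue_class)
  substrates <- unique(ds$accession)
  neg_acc <- character(0); neg_pos <- integer(0)
  if (negatives_from_psites) {
    if (is.null(all_psites)) stop("all_psites required when negatives_from_psites = TRUE")
    cand <- unique(all_psites[all_psites$accession %in% substrates,
                              c("accession", "position")])
    cres <- substr(seqmap[cand$accession], cand$position, cand$position)
    cand <- cand[cres %in% class_residues(residue_class), , drop = FALSE]
    k <- paste(cand$accession, cand$position)
    cand <- cand[!(k %in% pos_key), , drop = FALSE]
    neg_acc <- cand$accession; neg_pos <- cand$position
  } else {
    for (a in substrates) {
      p <- site_positions(seqmap[[a]], residue_class)
      if (!length(p)) next
      k <- paste(a, p)
      p <- p[!(k %in% pos_key)]
      neg_acc <- c(neg_acc, rep(a, length(p)))
      neg_pos <- c(neg_pos, p)
    }
  }
  negatives <- make_site_peptides(proteins, neg_acc, neg_pos, flank,
                                  "negative", residue_class)
  list(positives = dedup_windows(positives), negatives = dedup_windows(negatives))
}

#' Resample negatives at a fixed positive:negative ratio
#'
#' Samples `ratio * nrow(positives)` negatives without replacement (all of
#' them, with a warning, if fewer are available). Input rows are sorted by
#' (accession, position) before sampling so the draw is invariant to input
#' order for a fixed seed.
#'
#' @param positives,negatives site-peptide data.frames.
#' @param ratio negatives per positive (default 10).
#' @param seed integer seed.
#' @return data.frame subset of `negatives`.
#' @export
resample_negatives <- function(positives, negatives, ratio = 10L, seed = 1L) {
  if (ratio < 1L) stop("ratio must be >= 1")
  n_want <- nrow(positives) * ratio
  ord <- order(negatives$accession, negatives$position)
  negatives <- negatives[ord, , drop = FALSE]
  if (nrow(negatives) <= n_want) {
    if (nrow(negatives) < n_want)
      warning("only ", nrow(negatives), " negatives available for requested ", n_want)
    return(negatives)
  }
  idx <- withr_seed(seed, sample.int(nrow(negatives), n_want))
  negatives[sort(idx), , drop = FALSE]
}

# Evaluate an expression under a local RNG seed, restoring RNG state after.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a site-specific phosphatase-substrate relationship table
#'
#' Reads a tab-delimited table with header columns `phosphatase`, `accession`,
#' `position`, `residue`, `evidence`, `source` and validates each record. When
#' `proteins` is supplied, the residue annotation is checked against the
#' sequence. Summary counts (records, distinct sites, distinct substrates,
#' distinct phosphatases) are attached as the `"counts"` attribute and
#' reported via `message()`.
#'
#' @param path path to the TSV file.
#' @param proteins optional data.frame from [read_fasta()] for validation.
#' @return data.frame of validated records with a `counts` attribute.
#' @export
read_sspsr_table <- function(path, proteins = NULL) {
  if (!file.exists(path)) stop("table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("phosphatase", "accession", "position", "residue", "evidence", "source")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("empty ssPSR table: ", path)
  bad <- which(is.na(df$position) | df$position < 1 | !(df$residue %in% c("S", "T", "Y")))
  if (length(bad)) stop("malformed row(s): ", paste(bad, collapse = ", "))
  key <- paste(df$phosphatase, df$accession, df$position)
  if (anyDuplicated(key)) stop("duplicate (phosphatase, accession, position) record(s): ",
                               paste(unique(key[duplicated(key)]), collapse = "; "))
  if (!is.null(proteins)) {
    seqmap <- stats::setNames(proteins$sequence, proteins$accession)
    known <- df$accession %in% names(seqmap)
    res <- substr(seqmap[df$accession[known]], df$position[known], df$position[known])
    mism <- which(known)[res != df$residue[known]]
    if (length(mism)) stop("residue/position mismatch at row(s): ",
                           paste(mism, collapse = ", "))
  }
  counts <- c(records = nrow(df),
              sites = length(unique(paste(df$accession, df$position))),
              substrates = length(unique(df$accession)),
              phosphatases = length(unique(df$phosphatase)))
  message("ssPSR table: ", counts["records"], " records, ", counts["sites"],
          " distinct sites, ", counts["substrates"], " substrates, ",
          counts["phosphatases"], " phosphatases")
  attr(df, "counts") <- counts
  df
}

# Recover (accession, position) of a window in its source protein; used by
# the round-trip invariant tests.
locate_window <- function(window, proteins) {
  core <- gsub("\\*", "", window)
  flank <- (nchar(window) - 1L) %/% 2L
  lead <- nchar(sub("[^*].*$", "", window))
  for (i in seq_len(nrow(proteins))) {
    at <- regexpr(core, proteins$sequence[i], fixed = TRUE)
    if (at > 0L) {
      return(list(accession = proteins$accession[i],
                  position = as.integer(at) + (flank - lead)))
    }
  }
  NULL
}
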