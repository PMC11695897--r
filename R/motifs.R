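# Motif discovery around dephosphorylation sites: triplet statistics over the
# upstream (-3,-1) and downstream (1,3) blocks of the site, attribution and
# correlation filters, and enrichment against curated motif patterns.

#' Parse a dephosphorylation motif pattern
#'
#' Grammar: uppercase letters are literal residues, `[ABC]` is a residue
#' class, lowercase `x` matches any amino acid (never a pad), and lowercase
#' `p` introduces the site anchor (`p[ST]`, `pY`, ...). Tokens before the
#' anchor constrain the residues immediately upstream of the site
#' (right-aligned), tokens after it the residues immediately downstream.
#' A pattern without an anchor (e.g. a docking motif such as `RVxF`) is
#' unanchored and is matched anywhere in the window.
#'
#' @param pattern pattern string.
#' @return object of class `dephos_motif`: parsed token sets and anchoring.
#' @export
parse_motif_pattern <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  i <- 1L
  tokens <- list()
  anchor_at <- NA_integer_
  site <- NULL
  read_class <- function(i) {
    j <- i
    while (j <= length(chars) && chars[j] != "]") j <- j + 1L
    if (j > length(chars))
      stop("motif parse error at position ", i - 1L, ": unclosed '[' in '", pattern, "'")
    list(set = chars[(i):(j - 1L)], nxt = j + 1L)
  }
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "p") {
      if (!is.na(anchor_at))
        stop("motif parse error at position ", i, ": second site anchor in '", pattern, "'")
      i <- i + 1L
      if (i > length(chars))
        stop("motif parse error at position ", i, ": dangling 'p' in '", pattern, "'")
      if (chars[i] == "[") {
        cl <- read_class(i + 1L); site <- cl$set; i <- cl$nxt
      } else if (chars[i] %in% c("S", "T", "Y")) {
        site <- chars[i]; i <- i + 1L
      } else {
        stop("motif parse error at position ", i,
             ": 'p' must be followed by a site residue or class in '", pattern, "'")
      }
      anchor_at <- length(tokens) + 1L
    } else if (ch == "[") {
      cl <- read_class(i + 1L)
      tokens[[length(tokens) + 1L]] <- cl$set
      i <- cl$nxt
    } else if (ch == "x") {
      tokens[[length(tokens) + 1L]] <- AA20
      i <- i + 1L
    } else if (ch %in% AA20) {
      tokens[[length(tokens) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("motif parse error at position ", i, ": unexpected '", ch,
           "' in '", pattern, "'")
    }
  }
  if (!is.na(anchor_at)) {
    up <- if (anchor_at > 1L) tokens[seq_len(anchor_at - 1L)] else list()
    down <- if (anchor_at <= length(tokens)) tokens[seq(anchor_at, length(tokens))] else list()
    structure(list(pattern = pattern, anchored = TRUE, site = site,
                   up = up, down = down), class = "dephos_motif")
  } else {
    structure(list(pattern = pattern, anchored = FALSE, site = NULL,
                   tokens = tokens), class = "dephos_motif")
  }
}

#' @export
print.dephos_motif <- function(x, ...) {
  cat("Motif '", x$pattern, "' (", if (x$anchored) "site-anchored" else "unanchored",
      ")\n", sep = "")
  invisible(x)
}

#' Match a motif against a full site window
#'
#' Anchored motifs are evaluated at the central residue; unanchored motifs
#' are searched at every offset. Pads never match any token.
#'
#' @param motif a `dephos_motif`.
#' @param window site window string (odd length, site at the centre).
#' @return TRUE or FALSE.
#' @export
motif_matches_window <- function(motif, window) {
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  tok_ok <- function(set, ch) ch %in% set   # pads/X fail: sets only hold AA20
  if (motif$anchored) {
    c0 <- (L + 1L) %/% 2L
    if (!(chars[c0] %in% motif$site)) return(FALSE)
    nu <- length(motif$up)
    for (i in seq_len(nu)) {
      pos <- c0 - nu + i - 1L
      if (pos < 1L || !tok_ok(motif$up[[i]], chars[pos])) return(FALSE)
    }
    for (i in seq_along(motif$down)) {
      pos <- c0 + i
      if (pos > L || !tok_ok(motif$down[[i]], chars[pos])) return(FALSE)
    }
    TRUE
  } else {
    nt <- length(motif$tokens)
    if (nt > L) return(FALSE)
    for (off in 0:(L - nt)) {
      ok <- TRUE
      for (i in seq_len(nt)) {
        if (!tok_ok(motif$tokens[[i]], chars[off + i])) { ok <- FALSE; break }
      }
      if (ok) return(TRUE)
    }
    FALSE
  }
}

# Does a block triplet candidate conform to the motif? Anchored motifs
# require the site class to be compatible and the relevant block to carry at
# least one constrained (non-wildcard) position; unanchored motifs match if
# the triplet fits inside the pattern at some alignment.
motif_matches_kmer <- function(motif, kmer, block, residue_class) {
  chars <- strsplit(kmer, "", fixed = TRUE)[[1L]]
  k <- length(chars)
  if (motif$anchored) {
    if (!length(intersect(motif$site, class_residues(residue_class)))) return(FALSE)
    toks <- if (block == "downstream") motif$down else motif$up
    if (!length(toks)) return(FALSE)
    constrained <- FALSE
    if (block == "downstream") {
      for (i in seq_len(min(k, length(toks)))) {
        if (!(chars[i] %in% toks[[i]])) return(FALSE)
        if (length(toks[[i]]) < 20L) constrained <- TRUE
      }
    } else {
      # upstream tokens are right-aligned at the site: last token is offset -1
      nu <- length(toks)
      for (i in seq_len(min(k, nu))) {
        # kmer position k - i + 1 sits at offset -i
        if (!(chars[k - i + 1L] %in% toks[[nu - i + 1L]])) return(FALSE)
        if (length(toks[[nu - i + 1L]]) < 20L) constrained <- TRUE
      }
    }
    constrained
  } else {
    nt <- length(motif$tokens)
    if (nt < k) return(FALSE)
    for (off in 0:(nt - k)) {
      ok <- TRUE
      for (i in seq_len(k)) {
        if (!(chars[i] %in% motif$tokens[[off + i]])) { ok <- FALSE; break }
      }
      if (ok) return(TRUE)
    }
    FALSE
  }
}

#' Triplet frequency / attribution tables for one position block
#'
#' For every exact triplet observed in the chosen block across the positive
#' sites: its site frequency, the mean summed attribution over the block
#' among sites carrying it, the Pearson correlation between its per-position
#' residue-frequency profile and the per-position mean-attribution profile
#' (plus a pooled site-level variant), and the z-score of its mean
#' attribution within the block.
#'
#' @param windows character vector of positive site windows (flank >= 3).
#' @param attributions matrix from [shap_attributions()] with columns named
#'   by offset (must cover -3..3).
#' @param block `"downstream"` (offsets 1..3) or `"upstream"` (-3..-1).
#' @param residue_class `"ST"` or `"Y"` (recorded in the table).
#' @return data.frame of class `dephos_motif_stats`.
#' @export
block_kmer_tables <- function(windows, attributions, block = c("downstream", "upstream"),
                              residue_class = "ST") {
  block <- match.arg(block)
  if (!length(windows)) stop("no positive windows supplied")
  L <- unique(nchar(windows))
  flank <- (L - 1L) %/% 2L
  if (flank < 3L) stop("windows must have flank >= 3")
  offs <- if (block == "downstream") 1:3 else -3:-1
  cols <- as.character(offs)
  if (!all(cols %in% colnames(attributions)))
    stop("attribution matrix must cover offsets ", paste(cols, collapse = ", "))
  A <- attributions[, cols, drop = FALSE]
  chars <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  blk <- chars[, flank + 1L + offs, drop = FALSE]
  kmers <- apply(blk, 1L, paste, collapse = "")
  site_attr <- rowSums(A)
  tab <- sort(table(kmers), decreasing = TRUE)
  n <- length(windows)
  stats <- lapply(names(tab), function(km) {
    idx <- which(kmers == km)
    kc <- strsplit(km, "", fixed = TRUE)[[1L]]
    fprof <- vapply(1:3, function(j) mean(blk[, j] == kc[j]), numeric(1))
    sprof <- vapply(1:3, function(j) mean(A[idx, j]), numeric(1))
    pcc <- if (isTRUE(stats::sd(fprof) > 0) && isTRUE(stats::sd(sprof) > 0))
      stats::cor(fprof, sprof) else 0
    ind <- as.numeric(kmers == km)
    pcc_pooled <- if (isTRUE(stats::sd(ind) > 0) && isTRUE(stats::sd(site_attr) > 0))
      stats::cor(ind, site_attr) else 0
    data.frame(block = block, residue_class = residue_class, kmer = km,
               n_sites = length(idx), frequency = length(idx) / n,
               mean_shap = mean(site_attr[idx]), pcc = pcc,
               pcc_pooled = pcc_pooled, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, stats)
  ms <- out$mean_shap
  out$z_mean_shap <- if (isTRUE(stats::sd(ms) > 0)) (ms - mean(ms)) / stats::sd(ms) else 0
  class(out) <- c("dephos_motif_stats", class(out))
  out
}

#' Apply the correlation and attribution filters to triplet statistics
#'
#' A triplet passes the correlation filter when `|pcc| > pcc_threshold`
#' (strictly) and the attribution filter when its z-scored mean attribution
#' exceeds `z_threshold` (strictly).
#'
#' @param stats data.frame from [block_kmer_tables()] (blocks may be mixed).
#' @param pcc_threshold absolute-correlation cutoff (default 0.2).
#' @param z_threshold normalized mean-attribution cutoff (default 0.15).
#' @return list with data.frames `pcc_pass`, `z_pass`, `both`, and the
#'   annotated input as `stats` (flag columns `passes_pcc`, `passes_z`).
#' @export
filter_candidates <- function(stats, pcc_threshold = 0.2, z_threshold = 0.15) {
  if (!nrow(stats)) stop("empty statistics table")
  stats$passes_pcc <- abs(stats$pcc) > pcc_threshold
  stats$passes_z <- stats$z_mean_shap > z_threshold
  list(pcc_pass = stats[stats$passes_pcc, , drop = FALSE],
       z_pass = stats[stats$passes_z, , drop = FALSE],
       both = stats[stats$passes_pcc & stats$passes_z, , drop = FALSE],
       stats = stats)
}

#' Enrichment of known motifs among candidate triplets
#'
#' For each known motif: how many candidate triplets conform to it versus the
#' background rate among all observed triplets, with a one-sided
#' hypergeometric p-value and Benjamini-Hochberg adjustment across motifs.
#'
#' @param candidates data.frame with columns `kmer`, `block`, `residue_class`
#'   (e.g. a component of [filter_candidates()]).
#' @param known data.frame with columns `pattern`, `phosphatases` (motif
#'   list; one row per motif).
#' @param background data.frame with the same columns as `candidates`,
#'   a superset of them (all observed triplets).
#' @param q_cutoff significance level on the adjusted p-value.
#' @return data.frame: per motif, match counts, `p_value`, `q_value`,
#'   `significant`; unparseable patterns are reported with `error = TRUE`.
#' @export
motif_enrichment <- function(candidates, known, background, q_cutoff = 0.05) {
  key <- function(df) paste(df$kmer, df$block, df$residue_class)
  if (!all(key(candidates) %in% key(background)))
    stop("background must contain all candidates")
  rows <- lapply(seq_len(nrow(known)), function(i) {
    pat <- known$pattern[i]
    m <- tryCatch(parse_motif_pattern(pat), error = function(e) e)
    if (inherits(m, "error")) {
      return(data.frame(pattern = pat, n_candidates = NA, n_matching = NA,
                        bg_matching = NA, p_value = NA, error = TRUE,
                        stringsAsFactors = FALSE))
    }
    match_df <- function(df) {
      if (!nrow(df)) return(logical(0))
      vapply(seq_len(nrow(df)), function(r)
        motif_matches_kmer(m, df$kmer[r], df$block[r], df$residue_class[r]),
        logical(1))
    }
    k <- sum(match_df(candidates))
    K <- sum(match_df(background))
    N <- nrow(background); n <- nrow(candidates)
    p <- if (n == 0L || K == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(pattern = pat, n_candidates = n, n_matching = k,
               bg_matching = K, p_value = p, error = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !out$error
  out$q_value <- NA_real_
  out$q_value[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  out$significant <- !is.na(out$q_value) & out$q_value < q_cutoff
  out[order(out$q_value), ]
}

#' Observed block triplets of a window collection
#'
#' Enumerates the exact triplet at the chosen block of every window (one row
#' per distinct triplet). Used to assemble the enrichment background from all
#' candidate sites, positives and negatives alike, so that enrichment is
#' measured against the peptide space the filters selected from.
#'
#' @param windows character vector of site windows (flank >= 3).
#' @param block `"downstream"` or `"upstream"`.
#' @param residue_class `"ST"` or `"Y"`.
#' @return data.frame with columns `kmer`, `block`, `residue_class`.
#' @export
observed_block_kmers <- function(windows, block = c("downstream", "upstream"),
                                 residue_class = "ST") {
  block <- match.arg(block)
  L <- unique(nchar(windows))
  flank <- (L - 1L) %/% 2L
  offs <- if (block == "downstream") 1:3 else -3:-1
  chars <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  kmers <- unique(apply(chars[, flank + 1L + offs, drop = FALSE], 1L,
                        paste, collapse = ""))
  data.frame(kmer = kmers, block = block, residue_class = residue_class,
             stringsAsFactors = FALSE)
}

#' Read a known-motif list
#'
#' Tab-delimited file with columns `pattern`, `phosphatases`, `source`.
#'
#' @param path TSV path.
#' @return data.frame of motifs.
#' @export
read_motif_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pattern", "phosphatases", "source")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df
}
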