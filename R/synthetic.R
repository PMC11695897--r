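# Synthetic proteome generator: background proteins with planted
# phosphatase-specific dephosphorylation motifs, background phosphorylation,
# and the taxonomy/site tables the rest of the pipeline consumes. Every
# dataset this package is tested on comes from here, so all knobs (counts,
# lengths, signal strength) are explicit and seeded.

#' Specification for a synthetic proteome
#'
#' @param n_proteins number of substrate proteins.
#' @param length_range min/max protein length.
#' @param background named residue frequencies (defaults to database-like
#'   amino-acid composition).
#' @param phosphatases data.frame with columns `name`, `family`, `group`,
#'   `motif` (pattern string), `residue_class` (`"ST"`/`"Y"`), `n_sites`,
#'   `signal_strength` in [0,1].
#' @param phospho_background probability that a non-dephosphorylation S/T/Y
#'   residue is annotated as a background phosphorylation site.
#' @param seed integer seed.
#' @return list of class `dephos_simspec`.
#' @export
generator_spec <- function(n_proteins = 60L, length_range = c(200L, 400L),
                           background = AA_BACKGROUND_FREQ,
                           phosphatases = example_phosphatase_panel(),
                           phospho_background = 0.05, seed = 1L) {
  stopifnot(length(length_range) == 2L, length_range[1] <= length_range[2],
            all(c("name", "family", "group", "motif", "residue_class",
                  "n_sites", "signal_strength") %in% names(phosphatases)))
  if (any(phosphatases$signal_strength < 0 | phosphatases$signal_strength > 1))
    stop("signal_strength must lie in [0, 1]")
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 background = background / sum(background),
                 phosphatases = phosphatases,
                 phospho_background = phospho_background,
                 seed = as.integer(seed)),
            class = "dephos_simspec")
}

#' Example phosphatase panel with distinct planted motifs
#'
#' Three groups / six families / six phosphatases with well-separated,
#' literature-style recognition motifs (proline-directed, acidic,
#' aromatic-flanked), covering both residue classes.
#'
#' @return data.frame usable as the `phosphatases` field of [generator_spec()].
#' @export
example_phosphatase_panel <- function() {
  data.frame(
    name = c("PP1A", "PP2AC", "PPM1", "PTP1", "PTP2", "DUSP1"),
    family = c("PPP1", "PPP2", "PPM", "PTPN", "PTPN", "DUSP"),
    group = c("SerThr", "SerThr", "SerThr", "Tyr", "Tyr", "DualSpec"),
    motif = c("p[ST]P", "LSPIxE", "RVxF", "[ED]pY[ED]", "pY[LIV][LIV]", "W[ST]xpYG"),
    residue_class = c("ST", "ST", "ST", "Y", "Y", "Y"),
    n_sites = c(40L, 40L, 40L, 40L, 40L, 40L),
    signal_strength = rep(1, 6),
    stringsAsFactors = FALSE
  )
}

# Rewrite seq characters to realise a motif around position pos; returns the
# updated character vector. Only the minimal residues needed are changed.
plant_motif <- function(chars, pos, motif, residue_class) {
  pick <- function(set) if (length(set) >= 20L) NA_character_ else
    set[sample.int(length(set), 1L)]
  if (motif$anchored) {
    site_allowed <- intersect(motif$site, class_residues(residue_class))
    if (!length(site_allowed)) stop("motif site class incompatible with residue class")
    chars[pos] <- site_allowed[sample.int(length(site_allowed), 1L)]
    nu <- length(motif$up)
    for (i in seq_len(nu)) {
      p <- pos - nu + i - 1L
      r <- pick(motif$up[[i]])
      if (p >= 1L && !is.na(r)) chars[p] <- r
    }
    for (i in seq_along(motif$down)) {
      p <- pos + i
      r <- pick(motif$down[[i]])
      if (p <= length(chars) && !is.na(r)) chars[p] <- r
    }
  } else {
    # docking-style motif: site residue from the class, motif planted nearby
    chars[pos] <- sample(class_residues(residue_class), 1L)
    nt <- length(motif$tokens)
    off <- pos + sample(2:6, 1L)            # downstream of the site
    if (off + nt - 1L > length(chars)) off <- max(1L, pos - 6L - nt)
    for (i in seq_len(nt)) {
      r <- pick(motif$tokens[[i]])
      if (!is.na(r)) chars[off + i - 1L] <- r
    }
  }
  chars
}

#' Generate a synthetic proteome with planted dephosphorylation sites
#'
#' Proteins are drawn from the background residue composition; each
#' phosphatase's sites are planted at random positions, realising its motif
#' with probability `signal_strength` (otherwise only the central residue is
#' set). Every planted dephosphorylation site is also a phosphorylation
#' site; additional background p-sites are sprinkled at the configured rate.
#' Byte-identical output for a fixed seed.
#'
#' @param spec a [generator_spec()].
#' @return list: `proteins` (accession/sequence), `psites`
#'   (accession/position/residue), `sspsr` (phosphatase site table),
#'   `taxonomy` (phosphatase/family/group), `truth` (planted-site manifest
#'   with the generating motif and whether it was realised).
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "dephos_simspec"))
  min_len <- spec$length_range[1]
  for (i in seq_len(nrow(spec$phosphatases))) {
    m <- parse_motif_pattern(spec$phosphatases$motif[i])
    span <- if (m$anchored) length(m$up) + length(m$down) + 1L else length(m$tokens) + 8L
    if (span > min_len)
      stop("motif '", spec$phosphatases$motif[i], "' cannot fit in proteins of length ",
           min_len)
  }
  withr_seed(spec$seed, {
    lens <- sample(spec$length_range[1]:spec$length_range[2],
                   spec$n_proteins, replace = TRUE)
    seqs <- lapply(lens, function(L)
      sample(names(spec$background), L, replace = TRUE, prob = spec$background))
    acc <- sprintf("SYN%04d", seq_len(spec$n_proteins))
    used <- character(0)   # "acc pos" keys blocked for further planting
    truth <- list()
    for (i in seq_len(nrow(spec$phosphatases))) {
      pp <- spec$phosphatases[i, ]
      motif <- parse_motif_pattern(pp$motif)
      planted <- 0L
      guard <- 0L
      while (planted < pp$n_sites) {
        guard <- guard + 1L
        if (guard > 200L * pp$n_sites)
          stop("could not place ", pp$n_sites, " sites for ", pp$name)
        pi <- sample.int(spec$n_proteins, 1L)
        pos <- sample(8:(lens[pi] - 8L), 1L)
        keys <- paste(acc[pi], (pos - 7L):(pos + 7L))
        if (any(keys %in% used)) next
        realise <- stats::runif(1) < pp$signal_strength
        if (realise) {
          seqs[[pi]] <- plant_motif(seqs[[pi]], pos, motif, pp$residue_class)
        } else {
          seqs[[pi]][pos] <- sample(class_residues(pp$residue_class), 1L)
        }
        used <- c(used, paste(acc[pi], pos))
        planted <- planted + 1L
        truth[[length(truth) + 1L]] <-
          data.frame(phosphatase = pp$name, accession = acc[pi], position = pos,
                     residue = seqs[[pi]][pos], motif = pp$motif,
                     realised = realise, stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    proteins <- data.frame(accession = acc,
                           sequence = vapply(seqs, paste, character(1), collapse = ""),
                           stringsAsFactors = FALSE)
    # background p-sites on untouched S/T/Y residues
    bg <- list()
    dephos_key <- paste(truth$accession, truth$position)
    for (pi in seq_len(spec$n_proteins)) {
      stv <- which(seqs[[pi]] %in% c("S", "T", "Y"))
      stv <- stv[!(paste(acc[pi], stv) %in% dephos_key)]
      on <- stv[stats::runif(length(stv)) < spec$phospho_background]
      if (length(on))
        bg[[length(bg) + 1L]] <- data.frame(accession = acc[pi], position = on,
                                            residue = seqs[[pi]][on],
                                            stringsAsFactors = FALSE)
    }
    psites <- rbind(truth[, c("accession", "position", "residue")],
                    if (length(bg)) do.call(rbind, bg))
    psites <- psites[order(psites$accession, psites$position), ]
    rownames(psites) <- NULL
    sspsr <- data.frame(phosphatase = truth$phosphatase,
                        accession = truth$accession,
                        position = truth$position,
                        residue = truth$residue,
                        evidence = "experimental",
                        source = "synthetic-proteome-generator",
                        stringsAsFactors = FALSE)
    taxonomy <- unique(spec$phosphatases[, c("name", "family", "group")])
    names(taxonomy)[1] <- "phosphatase"
    rownames(taxonomy) <- NULL
    list(proteins = proteins, psites = psites, sspsr = sspsr,
         taxonomy = taxonomy, truth = truth)
  })
}

#' Write a generated proteome to disk
#'
#' FASTA for sequences, TSV for the site/taxonomy tables, JSON for the truth
#' manifest — the exact formats the I/O layer reads back.
#'
#' @param sim result of [generate_proteome()].
#' @param dir output directory (created if missing).
#' @return named vector of file paths, invisibly.
#' @export
write_proteome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "proteome.fasta"),
             psites = file.path(dir, "psites.tsv"),
             sspsr = file.path(dir, "sspsr.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "truth.json"))
  ss <- Biostrings::BStringSet(stats::setNames(sim$proteins$sequence,
                                               sim$proteins$accession))
  Biostrings::writeXStringSet(ss, paths["fasta"])
  utils::write.table(sim$psites, paths["psites"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$sspsr, paths["sspsr"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$taxonomy, paths["taxonomy"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Split site tables into training and independent test sets
#'
#' Site-level split (each distinct (accession, position) lands on exactly one
#' side), stratified by phosphatase; strata with fewer than 2 sites stay
#' whole in the training set with a warning.
#'
#' @param sspsr phosphatase site table.
#' @param fraction test fraction in (0, 1).
#' @param seed integer seed.
#' @return list with data.frames `train` and `test`.
#' @export
split_holdout <- function(sspsr, fraction = 0.2, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  key <- paste(sspsr$accession, sspsr$position)
  site_pp <- tapply(sspsr$phosphatase, key, function(x) x[1])
  sites <- names(site_pp)
  test_sites <- character(0)
  withr_seed(seed, {
    for (pp in unique(site_pp)) {
      mine <- sites[site_pp == pp]
      n_test <- round(length(mine) * fraction)
      if (length(mine) < 2L || n_test < 1L) {
        if (length(mine) < 2L)
          warning("stratum '", pp, "' too small to split; kept in training")
        next
      }
      test_sites <- c(test_sites, sample(mine, n_test))
    }
  })
  in_test <- key %in% test_sites
  list(train = sspsr[!in_test, , drop = FALSE],
       test = sspsr[in_test, , drop = FALSE])
}
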