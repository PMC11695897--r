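test_that("FASTA reading normalizes case, alphabet and rejects bad input", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MSTY"), fa)
  p <- read_fasta(fa)
  expect_equal(p$accession, "P1")
  expect_equal(p$sequence, "MSTY")

  writeLines(c(">P1", "msty"), fa)
  expect_equal(read_fasta(fa)$sequence, "MSTY")

  writeLines(c(">P1", "MSBTY"), fa)
  expect_warning(p <- read_fasta(fa), "replaced by 'X'")
  expect_equal(p$sequence, "MSXTY")

  writeLines(c(">P1", "MST", ">P1", "AAA"), fa)
  expect_error(read_fasta(fa), "duplicate accession.*P1")

  writeLines(character(0), fa)
  expect_error(read_fasta(fa), "no sequences")
})

test_that("window extraction pads exactly at the termini", {
  expect_equal(nchar(extract_window("MSTYASPA", 4, 30)), 61)
  expect_equal(extract_window("MST", 2, 30),
               paste0(strrep("*", 29), "MST", strrep("*", 29)))
  seqc <- strrep("A", 100)
  w <- extract_window(paste0(substr(seqc, 1, 46), "KRS", substr(seqc, 50, 100)), 50, 3)
  expect_equal(nchar(w), 7)
  expect_false(grepl("\\*", w))
  expect_error(extract_window("MST", 4, 3), "out of range")
  # pads only ever form a prefix/suffix run
  w2 <- extract_window("MSTYASPA", 2, 5)
  expect_match(w2, "^\\*+[A-Z]+\\*?$")
})

test_that("phosphorylation dataset builder enumerates positives and negatives", {
  prot <- data.frame(accession = "P1", sequence = "ASASA")
  d <- build_phospho_datasets(prot, data.frame(accession = "P1", position = 2),
                              "ST", flank = 2)
  expect_equal(nrow(d$positives), 1L)
  expect_equal(d$positives$position, 2L)
  expect_equal(d$negatives$position, 4L)

  prot_noy <- data.frame(accession = "P1", sequence = "ASASA")
  dy <- build_phospho_datasets(prot_noy, data.frame(accession = "P1", position = 2)[0, ],
                               "Y")
  expect_equal(nrow(dy$positives), 0L)
  expect_equal(nrow(dy$negatives), 0L)
})

test_that("positives from the generator are recovered exactly", {
  sim <- fixture("sim_tiny", function() st_cohort(n_sites = 25L, seed = 9L))
  truth_sites <- unique(sim$truth[, c("accession", "position")])
  d <- build_phospho_datasets(sim$proteins, sim$psites, "ST")
  # planted ST sites are a subset of all p-sites and must all be positives
  key_pos <- paste(d$positives$accession, d$positives$position)
  key_truth <- paste(truth_sites$accession, truth_sites$position)
  expect_true(all(key_truth %in% key_pos))
})

test_that("dephosphorylation negatives stay on the positive substrates", {
  sim <- fixture("sim_tiny", function() st_cohort(n_sites = 25L, seed = 9L))
  d <- build_dephos_datasets(sim$proteins,
                             unique(sim$sspsr[, c("accession", "position")]),
                             residue_class = "ST")
  expect_true(all(d$negatives$accession %in% unique(d$positives$accession)))
  # no overlap by (accession, position)
  expect_length(intersect(paste(d$positives$accession, d$positives$position),
                          paste(d$negatives$accession, d$negatives$position)), 0)
  expect_error(
    build_dephos_datasets(sim$proteins,
                          data.frame(accession = "NOPE", position = 1L),
                          residue_class = "ST"),
    "no positives")
})

test_that("negative resampling honors ratio, shortfall and determinism", {
  pos <- data.frame(accession = rep("P", 5), position = 1:5,
                    window = strrep("A", 5), stringsAsFactors = FALSE)
  mkneg <- function(n) data.frame(accession = sample(sprintf("Q%03d", 1:n)),
                                  position = sample.int(1000, n),
                                  window = replicate(n, paste(sample(AA20, 5, TRUE), collapse = "")),
                                  stringsAsFactors = FALSE)
  neg <- withr_seed(1, mkneg(200))
  out <- resample_negatives(pos, neg, 10, seed = 42)
  expect_equal(nrow(out), 50L)
  expect_true(all(paste(out$accession, out$position) %in% paste(neg$accession, neg$position)))

  small <- withr_seed(2, mkneg(30))
  expect_warning(out2 <- resample_negatives(pos, small, 10, seed = 1), "only 30")
  expect_equal(nrow(out2), 30L)

  out3 <- resample_negatives(pos, neg, 10, seed = 42)
  expect_identical(out, out3)
  # invariant under input row permutation (sort-before-sample contract)
  perm <- withr_seed(3, neg[sample.int(nrow(neg)), ])
  out4 <- resample_negatives(pos, perm, 10, seed = 42)
  expect_equal(sort(paste(out$accession, out$position)),
               sort(paste(out4$accession, out4$position)))
})

test_that("ssPSR table reading validates and counts correctly", {
  tf <- tempfile(fileext = ".tsv")
  df <- data.frame(phosphatase = c("PP1", "PP2A", "PP1"),
                   accession = c("P1", "P1", "P2"),
                   position = c(10L, 10L, 5L),
                   residue = c("S", "S", "Y"),
                   evidence = "experimental", source = "x")
  write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(out <- read_sspsr_table(tf), "3 records, 2 distinct sites")
  cnt <- attr(out, "counts")
  expect_equal(unname(cnt[c("records", "sites", "substrates", "phosphatases")]),
               c(3L, 2L, 2L, 2L))

  write.table(df[0, ], tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sspsr_table(tf), "empty")

  df_bad <- df; df_bad$residue[1] <- "Q"
  write.table(df_bad, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sspsr_table(tf), "malformed row")

  # residue/sequence cross-check
  write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  prot <- data.frame(accession = c("P1", "P2"),
                     sequence = c(paste0(strrep("A", 9), "S", strrep("A", 5)),
                                  paste0("AAAA", "S", "AA")))
  expect_error(read_sspsr_table(tf, prot), "mismatch")
})

test_that("windows round-trip to their source coordinates", {
  sim <- fixture("sim_tiny", function() st_cohort(n_sites = 25L, seed = 9L))
  d <- build_phospho_datasets(sim$proteins, sim$psites, "ST")
  take <- d$positives[seq_len(min(10, nrow(d$positives))), ]
  for (i in seq_len(nrow(take))) {
    loc <- dephos:::locate_window(take$window[i], sim$proteins)
    expect_equal(loc$position, take$position[i])
  }
})
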