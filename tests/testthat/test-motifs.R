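test_that("motif patterns parse into site-anchored and unanchored matchers", {
  m <- parse_motif_pattern("p[ST]P")
  expect_true(m$anchored)
  expect_setequal(m$site, c("S", "T"))
  expect_length(m$up, 0)
  expect_length(m$down, 1)

  r <- parse_motif_pattern("RVxF")
  expect_false(r$anchored)
  expect_length(r$tokens, 4)
  expect_length(r$tokens[[3]], 20)   # x matches every residue

  u <- parse_motif_pattern("[EDY]pY")
  expect_true(u$anchored)
  expect_setequal(u$up[[1]], c("E", "D", "Y"))

  expect_error(parse_motif_pattern("p[ST"), "parse error at position")
  expect_error(parse_motif_pattern("pZ"), "parse error")
  expect_error(parse_motif_pattern("A?B"), "unexpected")
})

test_that("window matching anchors at the site and never matches pads", {
  m <- parse_motif_pattern("p[ST]P")
  expect_true(motif_matches_window(m, "AAASPAA"))
  expect_false(motif_matches_window(m, "AAAYPAA"))   # wrong site residue
  expect_false(motif_matches_window(m, "AAASAAA"))   # no proline at +1
  expect_false(motif_matches_window(m, "AAAS*AA"))   # pad cannot satisfy P

  r <- parse_motif_pattern("RVxF")
  expect_true(motif_matches_window(r, "AARVAFS"))
  expect_true(motif_matches_window(r, "RVQFAAA"))
  expect_false(motif_matches_window(r, "AARV*FS"))   # x never matches pad

  x <- parse_motif_pattern("pSx")
  expect_true(motif_matches_window(x, "AAASQAA"))
  expect_false(motif_matches_window(x, "AAAS*AA"))
})

test_that("triplet matching respects block anchoring semantics", {
  m <- parse_motif_pattern("p[ST]P")
  expect_true(dephos:::motif_matches_kmer(m, "PIA", "downstream", "ST"))
  expect_false(dephos:::motif_matches_kmer(m, "PIA", "upstream", "ST"))
  expect_false(dephos:::motif_matches_kmer(m, "PIA", "downstream", "Y"))
  expect_false(dephos:::motif_matches_kmer(m, "IPA", "downstream", "ST"))

  up <- parse_motif_pattern("[EDY]pY")
  expect_true(dephos:::motif_matches_kmer(up, "AAE", "upstream", "Y"))
  expect_false(dephos:::motif_matches_kmer(up, "EAA", "upstream", "Y"))
})

test_that("triplet tables report frequencies that sum to one per block", {
  wins <- c("LKASPIA", "MQTSPDA", "AAASPIA", "RRRSQEA")
  phi <- matrix(0.1, 4, 7, dimnames = list(NULL, as.character(-3:3)))
  phi[, "1"] <- c(0.9, 0.8, 0.7, 0.0)
  st <- block_kmer_tables(wins, phi, "downstream", "ST")
  expect_equal(sum(st$frequency), 1.0)
  expect_equal(st$frequency[st$kmer == "PIA"], 0.5)
  expect_true(all(st$pcc >= -1 & st$pcc <= 1))
  # single positive site: its triplet has frequency 1
  st1 <- block_kmer_tables(wins[1], phi[1, , drop = FALSE], "downstream", "ST")
  expect_equal(st1$frequency, 1.0)
  expect_equal(st1$kmer, "PIA")
  expect_error(block_kmer_tables(character(0), phi, "downstream"), "no positive")
})

test_that("degenerate attribution variance gives zero z-scores that never pass", {
  wins <- c("AAASPIA", "CCCSPIC", "DDDSQED")
  phi <- matrix(0.5, 3, 7, dimnames = list(NULL, as.character(-3:3)))
  st <- block_kmer_tables(wins, phi, "downstream", "ST")
  expect_true(all(st$z_mean_shap == 0))
  fl <- filter_candidates(st)
  expect_equal(nrow(fl$z_pass), 0L)
})

test_that("filters are strict at their thresholds", {
  st <- data.frame(block = "downstream", residue_class = "ST",
                   kmer = c("AAA", "BBB", "CCC", "DDD"),
                   n_sites = 1, frequency = 0.25,
                   mean_shap = c(1, 2, 3, 4),
                   pcc = c(0.2, 0.21, -0.25, 0.1),
                   pcc_pooled = 0,
                   z_mean_shap = c(0.15, 0.151, 0.2, -1))
  fl <- filter_candidates(st)
  expect_setequal(fl$pcc_pass$kmer, c("BBB", "CCC"))   # 0.2 exactly fails
  expect_setequal(fl$z_pass$kmer, c("BBB", "CCC"))     # 0.15 exactly fails
  expect_setequal(fl$both$kmer, c("BBB", "CCC"))
  # an empty pass set is a valid outcome
  st0 <- st; st0$pcc <- 0; st0$z_mean_shap <- 0
  expect_equal(nrow(filter_candidates(st0)$pcc_pass), 0L)
})

test_that("enrichment reproduces the exact hypergeometric tail", {
  bg <- data.frame(kmer = c("PAA", "PBB", "PCC", sprintf("Q%02d", 1:7)),
                   block = "downstream", residue_class = "ST",
                   stringsAsFactors = FALSE)
  cand <- bg[1:3, ]   # all three candidates match p[ST]P; K = 3, N = 10, n = 3
  known <- data.frame(pattern = "p[ST]P", phosphatases = "PP1", source = "t")
  enr <- motif_enrichment(cand, known, bg)
  expect_equal(enr$p_value, choose(3, 3) * choose(7, 0) / choose(10, 3),
               tolerance = 1e-12)
  expect_equal(enr$p_value, 1 / 120, tolerance = 1e-12)

  # empty candidate set: p = 1 for every motif
  enr0 <- motif_enrichment(cand[0, ], known, bg)
  expect_equal(enr0$p_value, 1)

  # unparseable pattern is reported but does not abort the report
  known2 <- rbind(known, data.frame(pattern = "p[", phosphatases = "x", source = "t"))
  enr2 <- motif_enrichment(cand, known2, bg)
  expect_true(any(enr2$error))
  expect_equal(sum(!enr2$error), 1L)
  expect_error(motif_enrichment(bg, known, cand), "background must contain")
})

test_that("Benjamini-Hochberg adjustment preserves the p-value ordering", {
  withr_seed(41, {
    bg <- data.frame(kmer = replicate(60, paste(sample(AA20, 3, TRUE), collapse = "")),
                     block = "downstream", residue_class = "ST",
                     stringsAsFactors = FALSE)
    cand <- bg[sample.int(60, 12), ]
    known <- data.frame(pattern = c("p[ST]P", "p[ST]xE", "pS[DE]", "p[ST]G", "pSxxS"),
                        phosphatases = "x", source = "t")
  })
  enr <- motif_enrichment(cand, known, bg)
  ord <- order(enr$p_value)
  expect_true(all(diff(enr$q_value[ord]) >= -1e-12))
  expect_true(all(enr$q_value >= enr$p_value - 1e-12))
})
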