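# Shared fixtures. Expensive objects (simulated cohorts, trained ensembles)
# are built once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A small, fast ensemble configuration used wherever the scientific property
# under test does not depend on the full ten-feature registry.
small_config <- function(features = c("GPS", "onehot", "BLOSUMrow"),
                         epochs = 6L, use_tnn = FALSE) {
  ensemble_config(features = features, use_tnn = use_tnn,
                  dnn = dnn_architecture(epochs = epochs))
}

# Proline-directed ST cohort: one phosphatase, anchored p[ST]P motif.
st_cohort <- function(n_sites = 60L, strength = 1, seed = 1L, n_proteins = 30L) {
  panel <- example_phosphatase_panel()[1L, ]
  panel$n_sites <- as.integer(n_sites)
  panel$signal_strength <- strength
  generate_proteome(generator_spec(n_proteins = n_proteins,
                                   phosphatases = panel, seed = seed))
}

# Windows + labels for the dephosphorylation task of a simulated cohort.
cohort_task <- function(sim, residue_class = "ST", ratio = 10L, seed = 1L) {
  ds <- build_dephos_datasets(sim$proteins,
                              unique(sim$sspsr[, c("accession", "position")]),
                              residue_class = residue_class)
  neg <- resample_negatives(ds$positives, ds$negatives, ratio, seed)
  list(windows = c(ds$positives$window, neg$window),
       y = c(rep(1, nrow(ds$positives)), rep(0, nrow(neg))),
       datasets = ds)
}

# Planted-motif feature matrix for learner unit tests: 200 random windows,
# positives carry a proline immediately downstream of the centre.
planted_matrix_task <- function(n = 200L, seed = 4L) {
  withr_seed(seed, {
    chars <- matrix(sample(AA20, n * 61L, replace = TRUE), n, 61L)
    y <- rbinom(n, 1, 0.5)
    chars[, 31L] <- sample(c("S", "T"), n, replace = TRUE)
    chars[y == 1, 32L] <- "P"
    windows <- apply(chars, 1L, paste, collapse = "")
    list(windows = windows, y = y)
  })
}

withr_seed <- dephos:::withr_seed

expect_auc <- function(scores, labels, at_least) {
  expect_gte(auc_score(scores, labels), at_least)
}
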