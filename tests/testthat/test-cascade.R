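test_that("route assignment switches exactly at 3 and 30 distinct sites", {
  mk_sspsr <- function(n) data.frame(phosphatase = "PPX",
                                     accession = sprintf("P%03d", seq_len(n)),
                                     position = rep(10L, n), residue = "S",
                                     evidence = "experimental", source = "t",
                                     stringsAsFactors = FALSE)
  tax <- data.frame(phosphatase = "PPX", family = "F", group = "G")
  for (n in c(2L, 3L, 29L, 30L)) {
    cl <- cluster_pps(mk_sspsr(n), tax)
    single <- Filter(function(x) x$level == "single", cl)[[1]]
    expected <- if (n < 3) "excluded" else if (n < 30) "maml" else "transfer"
    expect_equal(single$route, expected, info = paste("n =", n))
    expect_equal(single$n_sites, n)
  }
})

test_that("clusters are emitted at all three levels and split by residue class", {
  sspsr <- data.frame(
    phosphatase = c("A1", "A2", "B1", "B1"),
    accession = c("P1", "P2", "P3", "P4"),
    position = c(5L, 6L, 7L, 8L),
    residue = c("S", "T", "Y", "S"),
    evidence = "experimental", source = "t", stringsAsFactors = FALSE)
  tax <- data.frame(phosphatase = c("A1", "A2", "B1"),
                    family = c("FA", "FA", "FB"),
                    group = c("G1", "G1", "G2"))
  cl <- cluster_pps(sspsr, tax)
  levels <- vapply(cl, function(x) x$level, character(1))
  expect_setequal(unique(levels), c("group", "family", "single"))
  # B1 has one Y site and one S site -> two class-specific clusters
  b1 <- Filter(function(x) x$name == "B1" && x$level == "single", cl)
  expect_setequal(vapply(b1, function(x) x$residue_class, character(1)),
                  c("ST", "Y"))
  # distinct-site counting by (accession, position), shared sites counted once
  sspsr2 <- sspsr; sspsr2$accession <- "P1"; sspsr2$position <- 5L
  sspsr2$residue <- "S"
  cl2 <- cluster_pps(sspsr2, tax)
  grp <- Filter(function(x) x$level == "group" && x$name == "G1", cl2)[[1]]
  expect_equal(grp$n_sites, 1L)
  expect_error(cluster_pps(sspsr[0, ], tax), "empty")
  expect_warning(cluster_pps(sspsr, tax[1:2, ]), "singleton")
})

test_that("freeze-backbone fine-tuning leaves base-model weights untouched", {
  sim <- fixture("sim_tiny", function() st_cohort(n_sites = 25L, seed = 9L))
  task <- cohort_task(sim, seed = 2)
  ens <- fixture("ens_tiny", function()
    train_ensemble(task$windows, task$y, "ST",
                   small_config(epochs = 2L, use_tnn = TRUE), seed = 3))
  ft <- dephos:::finetune_freeze(ens, task$windows, task$y)
  expect_identical(serialize(ft$dnns, NULL), serialize(ens$dnns, NULL))
  expect_identical(serialize(ft$plrs, NULL), serialize(ens$plrs, NULL))
  expect_identical(serialize(ft$tnns, NULL), serialize(ens$tnns, NULL))
  # the reference set and meta-learner do change
  expect_false(identical(ft$meta, ens$meta))
  expect_setequal(ft$gps_reference, unique(task$windows[task$y == 1]))
})

test_that("transfer-route fine-tuning reports fold AUCs and stops early", {
  sim <- fixture("sim_transfer", function() st_cohort(n_sites = 35L, seed = 5L))
  ens <- fixture("ens_transfer_general", function() {
    task <- cohort_task(sim, seed = 1)
    train_ensemble(task$windows, task$y, "ST", small_config(), seed = 2)
  })
  cl <- Filter(function(x) x$level == "single" && x$route == "transfer",
               cluster_pps(sim$sspsr, sim$taxonomy))[[1]]
  plan <- train_plan(iterations = 6, folds = 4, seed = 3, early_stop = 2)
  res <- finetune_specific_transfer(ens, cl, sim$proteins, plan)
  expect_length(res$cv$per_fold_aucs, 4L)
  expect_s3_class(res$model, "dephos_ensemble")
  # early stop: at most early_stop non-improving iterations after the best
  expect_lte(length(res$iteration_aucs), plan$iterations)
  best_at <- which.max(res$iteration_aucs)
  expect_lte(length(res$iteration_aucs) - best_at, plan$early_stop)
  # route mismatch errors
  cl_bad <- cl; cl_bad$route <- "maml"
  expect_error(finetune_specific_transfer(ens, cl_bad, sim$proteins, plan),
               "routes to maml")
})

test_that("the inner meta-learning update matches the closed-form gradient step", {
  # quadratic toy: L(w) = (w - a)^2, gradient 2(w - a); one step from 0 with
  # lr = 0.1 lands on 0.2 a
  a <- 1.7
  w1 <- inner_update(0, function(w) 2 * (w - a), lr = 0.1, steps = 1)
  expect_equal(w1, 0.2 * a, tolerance = 1e-9)
  w0 <- inner_update(0.42, function(w) 2 * (w - a), lr = 0.1, steps = 0)
  expect_identical(w0, 0.42)
  # two steps compose: w2 = w1 + 0.2 (a - w1)
  w2 <- inner_update(0, function(w) 2 * (w - a), lr = 0.1, steps = 2)
  expect_equal(w2, 0.2 * a + 0.2 * (a - 0.2 * a), tolerance = 1e-9)
})

test_that("meta-learning adaptation with zero inner steps is the identity", {
  sim <- fixture("sim_maml", function() {
    panel <- example_phosphatase_panel()[1:3, ]
    panel$n_sites <- c(8L, 8L, 8L)
    generate_proteome(generator_spec(n_proteins = 25, phosphatases = panel,
                                     seed = 21))
  })
  ens <- fixture("ens_maml_general", function() {
    task <- cohort_task(sim, seed = 1)
    train_ensemble(task$windows, task$y, "ST", small_config(epochs = 3L), seed = 2)
  })
  clusters <- cluster_pps(sim$sspsr, sim$taxonomy)
  singles <- Filter(function(x) x$level == "single" && x$route == "maml" &&
                      x$residue_class == "ST", clusters)
  target <- singles[[1]]
  cfg0 <- maml_config(inner_steps = 0, outer_steps = 0)
  plan <- train_plan(iterations = 1, folds = 4, seed = 5)
  expect_warning(
    res0 <- maml_adapt(ens, singles[-1], target, sim$proteins, cfg0, plan),
    "inner_steps = 0")
  # neural weights of the adapted model equal the general model's
  expect_identical(serialize(res0$model$dnns, NULL), serialize(ens$dnns, NULL))
  expect_equal(res0$meta_theta$dnn_GPS, dephos:::mlp_flatten(ens$dnns$GPS$par))
  cl_bad <- target; cl_bad$route <- "transfer"
  expect_error(maml_adapt(ens, singles[-1], cl_bad, sim$proteins, cfg0, plan),
               "routes to transfer")
})

test_that("the registry builds one model per non-excluded cluster", {
  sim <- fixture("sim_maml", function() {
    panel <- example_phosphatase_panel()[1:3, ]
    panel$n_sites <- c(8L, 8L, 8L)
    generate_proteome(generator_spec(n_proteins = 25, phosphatases = panel,
                                     seed = 21))
  })
  ens <- fixture("ens_maml_general", function() {
    task <- cohort_task(sim, seed = 1)
    train_ensemble(task$windows, task$y, "ST", small_config(epochs = 3L), seed = 2)
  })
  clusters <- cluster_pps(sim$sspsr, sim$taxonomy)
  n_expected <- sum(vapply(clusters, function(x) x$route != "excluded", logical(1)))
  reg <- fixture("registry_small", function()
    build_all_specific(list(ST = ens), sim$sspsr, sim$taxonomy, sim$proteins,
                       train_plan(iterations = 1, folds = 4, seed = 7),
                       maml_config(outer_steps = 1, meta_batch = 2)))
  expect_equal(length(reg$models) + length(reg$failures), n_expected)
  expect_length(reg$failures, 0)
  expect_true(all(reg$manifest$route %in% c("transfer", "maml")))
  # registry round-trips through save/load
  dir <- tempfile("registry")
  save_registry(reg, dir)
  back <- load_registry(dir)
  expect_equal(back$manifest, reg$manifest)
  expect_identical(names(back$models), names(reg$models))

  # an all-excluded table yields an empty registry with a warning, not an error
  tiny <- sim$sspsr[1:2, ]
  expect_warning(
    reg0 <- build_all_specific(list(ST = ens), tiny, sim$taxonomy, sim$proteins),
    "excluded")
  expect_length(reg0$models, 0)
})

test_that("meta-learned adaptation is directionally better than direct fine-tuning", {
  # the few-shot scenario: the target family (proline-directed) is absent
  # from the general model's pool (docking motifs only) and carries imperfect
  # signal, so a handful of support exemplars is unreliable on its own;
  # 8 data-rich sibling tasks carry the family signal; 12 replicates
  # (4 targets x 3 seeds)
  panel <- rbind(
    data.frame(name = c("BG1", "BG2"), family = c("FB1", "FB2"),
               group = "SerThrBG", motif = c("LSPIxE", "RVxF"),
               residue_class = "ST", n_sites = 60L, signal_strength = 1,
               stringsAsFactors = FALSE),
    data.frame(name = sprintf("PP%02d", 1:12), family = sprintf("F%02d", 1:12),
               group = "SerThr", motif = "p[ST]P", residue_class = "ST",
               n_sites = c(rep(35L, 8), rep(5L, 4)), signal_strength = 0.7,
               stringsAsFactors = FALSE))
  sim <- generate_proteome(generator_spec(n_proteins = 70, phosphatases = panel,
                                          seed = 61))
  bg_sites <- sim$sspsr[sim$sspsr$phosphatase %in% c("BG1", "BG2"), ]
  ds <- build_dephos_datasets(sim$proteins,
                              unique(bg_sites[, c("accession", "position")]),
                              residue_class = "ST")
  neg <- suppressWarnings(resample_negatives(ds$positives, ds$negatives, 10, 1))
  gen <- suppressWarnings(train_ensemble(
    c(ds$positives$window, neg$window),
    c(rep(1, nrow(ds$positives)), rep(0, nrow(neg))),
    "ST", small_config(), seed = 2))
  singles <- Filter(function(x) x$level == "single",
                    cluster_pps(sim$sspsr, sim$taxonomy))
  targets <- Filter(function(x) x$route == "maml", singles)
  sibs <- Filter(function(x) x$route == "transfer" && grepl("^PP", x$name), singles)
  maml_aucs <- numeric(0); direct_aucs <- numeric(0)
  for (tg in targets) {
    for (sd in 1:3) {
      res <- suppressWarnings(maml_adapt(
        gen, sibs, tg, sim$proteins,
        maml_config(outer_steps = 10, meta_batch = 3, inner_steps = 3),
        train_plan(iterations = 1, folds = 4, seed = 100 * sd)))
      maml_aucs <- c(maml_aucs, res$loo$auc)
      # direct route: freeze-backbone fine-tune on each leave-one-out split
      ds_t <- dephos:::cluster_datasets(tg, sim$proteins)
      sc <- c(); lb <- c()
      for (i in seq_len(nrow(ds_t$positives))) {
        sup <- ds_t$positives[-i, , drop = FALSE]
        nn <- suppressWarnings(resample_negatives(sup, ds_t$negatives, 10,
                                                  500 * sd + i))
        m <- suppressWarnings(dephos:::finetune_freeze(
          gen, c(sup$window, nn$window),
          c(rep(1, nrow(sup)), rep(0, nrow(nn)))))
        tn <- suppressWarnings(resample_negatives(
          ds_t$positives[i, , drop = FALSE], ds_t$negatives, 10, 600 * sd + i))
        sc <- c(sc, predict(m, c(ds_t$positives$window[i], tn$window)))
        lb <- c(lb, c(1, rep(0, nrow(tn))))
      }
      direct_aucs <- c(direct_aucs, auc_score(sc, lb))
    }
  }
  message("median LOO AUC meta-learned ", signif(median(maml_aucs), 3),
          " vs direct fine-tune ", signif(median(direct_aucs), 3),
          " (meta wins ", sum(maml_aucs > direct_aucs), "/", length(maml_aucs), ")")
  expect_gte(median(maml_aucs), median(direct_aucs))
})
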