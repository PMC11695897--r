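test_that("ridge logistic regression behaves at both penalty extremes", {
  withr_seed(1, {
    x <- c(runif(20, -2, -0.1), runif(20, 0.1, 2))
    y <- as.numeric(x > 0)
    X <- cbind(x)
  })
  m <- train_plr(X, y, l2_strength = 1e-6)
  expect_equal(mean((predict(m, X) > 0.5) == y), 1.0)

  m_inf <- train_plr(X, y, l2_strength = 1e6)
  expect_lt(abs(m_inf$coef), 1e-3)
  expect_equal(m_inf$intercept, qlogis(mean(y)), tolerance = 1e-2)

  expect_error(train_plr(X, rep(1, 40)), "both classes")
  X_bad <- X; X_bad[1] <- NA
  expect_error(train_plr(X_bad, y), "non-finite")
})

test_that("ridge logistic coefficients match a gradient-descent oracle", {
  withr_seed(2, {
    X <- matrix(rnorm(60), 20, 3)
    y <- rbinom(20, 1, plogis(X %*% c(1, -1, 0.5)))
  })
  m <- train_plr(X, y, l2_strength = 0.1, tol = 1e-14)
  # full-batch gradient descent on the same objective
  w <- rep(0, 4)
  for (i in 1:200000) {
    p <- plogis(cbind(1, X) %*% w)
    g <- crossprod(cbind(1, X), p - y) / 20 + 0.1 * c(0, w[-1])
    w <- w - 0.5 * g
    if (max(abs(g)) < 1e-12) break
  }
  expect_equal(c(m$intercept, m$coef), as.numeric(w), tolerance = 1e-4)
  # closed-form score check
  xnew <- matrix(c(0.3, -1, 2), 1)
  expect_equal(predict(m, xnew),
               plogis(as.numeric(xnew %*% m$coef + m$intercept)))
})

test_that("the feed-forward learner overfits a strongly planted motif", {
  task <- planted_matrix_task()
  X <- encode_windows(task$windows, "onehot")
  m <- train_dnn(X, task$y, dnn_architecture(epochs = 15), seed = 3)
  expect_auc(predict(m, X), task$y, 0.95)
  expect_lt(tail(m$losses, 1), m$losses[1])
})

test_that("untrained and reseeded feed-forward models are well-defined", {
  withr_seed(4, { X <- matrix(rnorm(50 * 8), 50, 8); y <- rbinom(50, 1, 0.5) })
  m0 <- train_dnn(X, y, dnn_architecture(epochs = 0), seed = 1)
  p0 <- predict(m0, X)
  expect_true(all(is.finite(p0) & p0 >= 0 & p0 <= 1))

  m1 <- train_dnn(X, y, dnn_architecture(epochs = 3), seed = 7)
  m2 <- train_dnn(X, y, dnn_architecture(epochs = 3), seed = 7)
  expect_identical(predict(m1, X), predict(m2, X))
  # duplicated rows score identically
  expect_equal(predict(m1, X[c(1, 1), ]), rep(predict(m1, X[1, , drop = FALSE]), 2))
})

test_that("the causal decoder never looks ahead and the encoder masks pads", {
  cfg <- tnn_config(layers = 1, heads = 2, embed_dim = 8, ff_dim = 16, epochs = 0)
  withr_seed(5, tok <- matrix(sample(1:20, 3 * 9, TRUE), 3, 9))
  par <- dephos:::tnn_init(9, cfg, 1)
  fw1 <- dephos:::tnn_forward(par, tok, cfg, causal = TRUE, keep_cache = TRUE)
  tok2 <- tok; tok2[1, 6] <- (tok2[1, 6] %% 20) + 1L
  fw2 <- dephos:::tnn_forward(par, tok2, cfg, causal = TRUE, keep_cache = TRUE)
  # states at positions before the perturbation are bit-identical
  expect_identical(fw1$states[1:5, ], fw2$states[1:5, ])
  expect_false(isTRUE(all.equal(fw1$states[6:9, ], fw2$states[6:9, ])))

  # encoder: swapping two flank tokens changes the class-token score
  tok_cls <- cbind(22L, tok)
  par10 <- dephos:::tnn_init(10, cfg, 1)
  fe1 <- dephos:::tnn_forward(par10, tok_cls, cfg, causal = FALSE,
                              mask_keys = tok_cls != 21L)
  tok_swap <- tok_cls; tok_swap[, c(3, 7)] <- tok_swap[, c(7, 3)]
  fe2 <- dephos:::tnn_forward(par10, tok_swap, cfg, causal = FALSE,
                              mask_keys = tok_swap != 21L)
  expect_false(isTRUE(all.equal(fe1$prob, fe2$prob)))

  # a masked pad position cannot influence the output
  tok_pad <- tok_cls; tok_pad[, 10] <- 21L
  mk <- tok_pad != 21L
  f1 <- dephos:::tnn_forward(par10, tok_pad, cfg, causal = FALSE, mask_keys = mk)
  # change the embedding the pad token would contribute: score must not move
  par2 <- par10; par2$Emb[21L, ] <- par2$Emb[21L, ] + 5
  f2 <- dephos:::tnn_forward(par2, tok_pad, cfg, causal = FALSE, mask_keys = mk)
  expect_equal(f1$prob, f2$prob, tolerance = 1e-12)
})

test_that("a tiny transformer learns a planted motif", {
  task <- planted_matrix_task()
  tok <- tokenize_windows(task$windows, cls = TRUE)
  cfg <- tnn_config(layers = 2, heads = 2, embed_dim = 32, epochs = 12)
  m <- train_transformer(tok, task$y, "encoder-bidirectional", cfg, seed = 2)
  expect_auc(predict(m, tok), task$y, 0.9)
  m2 <- train_transformer(tok, task$y, "encoder-bidirectional", cfg, seed = 2)
  expect_identical(predict(m2, tok), predict(m, tok))
})

test_that("stacking vectors have the canonical slot layout", {
  sim <- fixture("sim_tiny", function() st_cohort(n_sites = 25L, seed = 9L))
  task <- cohort_task(sim, seed = 2)
  ens <- fixture("ens_tiny", function()
    train_ensemble(task$windows, task$y, "ST",
                   small_config(epochs = 2L, use_tnn = TRUE), seed = 3))
  wins <- task$windows[1:5]
  V <- stack_vector(ens, wins)
  expect_equal(ncol(V), 2 * length(ens$features) + 2)
  expect_equal(colnames(V),
               c(paste0("D", 1:3), paste0("P", 1:3), "B", "G"))
  # mutating one base model changes exactly its own slot
  ens2 <- ens
  ens2$plrs[["onehot"]]$coef <- ens2$plrs[["onehot"]]$coef * 0
  ens2$plrs[["onehot"]]$intercept <- 3
  V2 <- stack_vector(ens2, wins)
  changed <- which(colSums(abs(V - V2)) > 1e-12)
  expect_equal(colnames(V)[changed], "P2")
  # missing slot errors by name
  ens3 <- ens; ens3$dnns[["GPS"]] <- NULL
  expect_error(stack_vector(ens3, wins), "missing DNN base model for slot GPS")
})

test_that("the meta-learner tracks a perfect base model among noise", {
  withr_seed(6, {
    n <- 400
    y <- rbinom(n, 1, 0.5)
    V <- matrix(runif(n * 22), n, 22)
    V[, 7] <- plogis(qlogis(0.02 + 0.96 * y) + rnorm(n, sd = 0.3))
  })
  tr <- 1:300; te <- 301:400
  meta <- train_stacker(V[tr, ], y[tr])
  auc_stack <- auc_score(predict(meta, V[te, ]), y[te])
  auc_base <- auc_score(V[te, 7], y[te])
  expect_gte(auc_stack, auc_base - 0.02)
  # collinear columns do not break the ridge fit
  V_dup <- V[, c(7, 7, 7)]
  expect_silent(meta2 <- train_stacker(V_dup[tr, ], y[tr]))
  expect_length(meta2$coef, 3)
  expect_length(train_stacker(V[tr, ], y[tr])$coef, 22)
})

test_that("alternative integrators emit calibrated probabilities", {
  withr_seed(7, {
    n <- 300
    y <- rbinom(n, 1, 0.5)
    V <- matrix(runif(n * 6), n, 6)
    V[, 2] <- plogis(qlogis(0.02 + 0.96 * y) + rnorm(n, sd = 0.25))
    V[, 5] <- 0.5   # constant feature
  })
  for (method in c("SVM", "RF", "GNB")) {
    m <- alt_integrator(V, y, method, seed = 1)
    p <- predict(m, V)
    expect_true(all(p >= 0 & p <= 1), info = method)
    expect_auc(p, y, 0.95)
  }
  expect_error(alt_integrator(V, y, "nope"))
})

test_that("model bundles round-trip exactly through save/load", {
  sim <- fixture("sim_tiny", function() st_cohort(n_sites = 25L, seed = 9L))
  task <- cohort_task(sim, seed = 2)
  ens <- fixture("ens_tiny", function()
    train_ensemble(task$windows, task$y, "ST",
                   small_config(epochs = 2L, use_tnn = TRUE), seed = 3))
  dir <- tempfile("bundle")
  save_ensemble(ens, dir)
  back <- load_ensemble(dir)
  wins <- task$windows[1:8]
  expect_identical(predict(back, wins), predict(ens, wins))
  expect_true(file.exists(file.path(dir, "manifest.json")))
})
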