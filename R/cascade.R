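# The three-step training cascade: pretrain general phosphorylation models,
# fine-tune them to general dephosphorylation, then derive
# phosphatase-specific predictors per cluster — by transfer learning where a
# cluster has >= 30 distinct sites, by first-order meta-learning (MAML) where
# it has 3..29, skipping clusters below 3.

#' Training plan for the cascade
#'
#' @param neg_ratio negatives sampled per positive (default 10).
#' @param iterations independent negative-resampling iterations per cluster
#'   (default 20).
#' @param folds cross-validation folds for transfer-route clusters (4/6/8/10).
#' @param seed integer seed.
#' @param early_stop stop after this many iterations without improvement of
#'   the validation AUC.
#' @param freeze_mode `"freeze-backbone"` (base models frozen; positive
#'   reference set and meta-learner refit) or `"full-finetune"` (base weights
#'   updated from the pretrained initialization).
#' @return named list.
#' @export
train_plan <- function(neg_ratio = 10L, iterations = 20L, folds = 10L, seed = 1L,
                       early_stop = 3L,
                       freeze_mode = c("freeze-backbone", "full-finetune")) {
  freeze_mode <- match.arg(freeze_mode)
  stopifnot(iterations >= 1L, folds %in% c(4L, 6L, 8L, 10L))
  list(neg_ratio = as.integer(neg_ratio), iterations = as.integer(iterations),
       folds = as.integer(folds), seed = as.integer(seed),
       early_stop = as.integer(early_stop), freeze_mode = freeze_mode)
}

#' Meta-learning configuration
#'
#' @param inner_lr learning rate of the inner (task-adaptation) steps.
#' @param outer_lr learning rate of the meta-update (plain gradient step on
#'   the first-order meta-gradient).
#' @param inner_steps gradient steps per adaptation.
#' @param meta_batch tasks per outer step.
#' @param outer_steps outer-loop iterations.
#' @param first_order drop second-derivative terms (first-order MAML,
#'   default TRUE; the second-order term is not implemented).
#' @return named list.
#' @export
maml_config <- function(inner_lr = 0.05, outer_lr = 0.02, inner_steps = 3L,
                        meta_batch = 4L, outer_steps = 10L, first_order = TRUE) {
  stopifnot(inner_steps >= 0L)
  list(inner_lr = inner_lr, outer_lr = outer_lr,
       inner_steps = as.integer(inner_steps),
       meta_batch = as.integer(meta_batch),
       outer_steps = as.integer(outer_steps), first_order = first_order)
}

# Dataset assembly shared by the cascade entry points: windows + labels from
# positive/negative site-peptide frames after negative resampling.
assemble_training <- function(ds, neg_ratio, seed) {
  neg <- resample_negatives(ds$positives, ds$negatives, neg_ratio, seed)
  list(windows = c(ds$positives$window, neg$window),
       y = c(rep(1, nrow(ds$positives)), rep(0, nrow(neg))),
       positives = ds$positives, negatives = neg)
}

#' Pretrain general phosphorylation ensembles
#'
#' One stacked ensemble per requested residue class, trained on known p-sites
#' versus non-phosphorylated residues of the same class (negatives resampled
#' at the plan's ratio).
#'
#' @param proteins data.frame from [read_fasta()].
#' @param psites data.frame with `accession`, `position` (known p-sites).
#' @param residue_classes classes to train (default both).
#' @param config [ensemble_config()].
#' @param plan [train_plan()].
#' @return named list of `dephos_ensemble` objects.
#' @export
pretrain_general <- function(proteins, psites, residue_classes = c("ST", "Y"),
                             config = ensemble_config(), plan = train_plan()) {
  out <- list()
  for (rc in residue_classes) {
    ds <- build_phospho_datasets(proteins, psites, rc)
    if (nrow(ds$positives) < 2L)
      stop("insufficient phosphorylation data for class ", rc)
    tr <- assemble_training(ds, plan$neg_ratio, seed_offset(plan$seed, 50L))
    out[[rc]] <- train_ensemble(tr$windows, tr$y, rc, config,
                                seed = seed_offset(plan$seed, 60L))
  }
  out
}

# Freeze-backbone fine-tune: keep every base model, swap the positive
# reference set, refit its scaler, retrain the meta-learner, recalibrate.
finetune_freeze <- function(general, windows, y) {
  obj <- general
  obj$gps_reference <- unique(windows[y == 1])
  gtrain <- encode_windows(windows, "GPS", reference = obj$gps_reference)
  obj$scalers[["GPS"]] <- fit_scaler(gtrain, "zscore")
  V <- stack_vector(obj, windows)
  obj$meta <- train_stacker(V, y, obj$config$meta_l2)
  neg <- windows[y == 0]
  if (length(neg) >= 2L)
    obj$cutoffs <- calibrate_cutoffs(predict(obj, neg), obj$config$cutoff_fprs)
  obj
}

# Full fine-tune: continue training every base model from the pretrained
# weights on the new data, then restack.
finetune_full <- function(general, windows, y, seed) {
  obj <- general
  obj$gps_reference <- unique(windows[y == 1])
  for (k in seq_along(obj$features)) {
    f <- obj$features[[k]]
    enc <- encode_scaled(windows, f, obj$gps_reference)
    obj$scalers[[f]] <- enc$scaler
    obj$dnns[[f]] <- train_dnn(enc$X, y, obj$config$dnn,
                               seed = seed_offset(seed, 70L + k),
                               feature_name = f, init = obj$dnns[[f]]$par)
    obj$plrs[[f]] <- train_plr(enc$X, y, obj$config$l2_strength, feature_name = f)
  }
  if (!is.null(obj$tnns)) {
    obj$tnns$encoder <- train_transformer(tokenize_windows(windows, cls = TRUE), y,
                                          "encoder-bidirectional", obj$config$tnn,
                                          seed = seed_offset(seed, 81L),
                                          init = obj$tnns$encoder$par)
    obj$tnns$decoder <- train_transformer(tokenize_windows(windows, cls = FALSE), y,
                                          "decoder-causal", obj$config$tnn,
                                          seed = seed_offset(seed, 82L),
                                          init = obj$tnns$decoder$par)
  }
  V <- stack_vector(obj, windows)
  obj$meta <- train_stacker(V, y, obj$config$meta_l2)
  neg <- windows[y == 0]
  if (length(neg) >= 2L)
    obj$cutoffs <- calibrate_cutoffs(predict(obj, neg), obj$config$cutoff_fprs)
  obj
}

#' Fine-tune a pretrained ensemble to general dephosphorylation
#'
#' In the default freeze-backbone mode the pretrained base-model parameters
#' are left unchanged: only the positive reference set of the similarity
#' feature and the meta-learner are refit on dephosphorylation data. In
#' full-finetune mode the base weights are updated from the pretrained
#' initialization.
#'
#' @param pretrained `dephos_ensemble` from [pretrain_general()].
#' @param proteins substrate proteins.
#' @param dephos_sites data.frame with `accession`, `position`.
#' @param all_psites optional p-site table (see [build_dephos_datasets()]).
#' @param plan [train_plan()].
#' @return fine-tuned `dephos_ensemble`.
#' @export
finetune_general_dephos <- function(pretrained, proteins, dephos_sites,
                                    all_psites = NULL, plan = train_plan()) {
  rc <- pretrained$residue_class
  ds <- build_dephos_datasets(proteins, dephos_sites, all_psites, rc)
  if (nrow(ds$positives) < 2L) stop("insufficient dephosphorylation positives")
  tr <- assemble_training(ds, plan$neg_ratio, seed_offset(plan$seed, 90L))
  if (plan$freeze_mode == "freeze-backbone")
    finetune_freeze(pretrained, tr$windows, tr$y)
  else
    finetune_full(pretrained, tr$windows, tr$y, plan$seed)
}

# ---- phosphatase clustering -------------------------------------------------

route_for <- function(n_sites) {
  if (n_sites < 3L) "excluded" else if (n_sites >= 30L) "transfer" else "maml"
}

#' Hierarchical phosphatase clustering with route assignment
#'
#' Emits clusters at the group, family and individual-phosphatase levels,
#' split by residue class. Distinct sites are counted by (accession,
#' position); the training route follows the site count: fewer than 3 sites
#' excluded, 3-29 meta-learning, 30 or more transfer learning.
#'
#' @param sspsr phosphatase site table (see [read_sspsr_table()]).
#' @param taxonomy data.frame with columns `phosphatase`, `family`, `group`.
#' @return list of `dephos_ppcluster` objects.
#' @export
cluster_pps <- function(sspsr, taxonomy) {
  if (!nrow(sspsr)) stop("empty site table")
  unresolved <- setdiff(unique(sspsr$phosphatase), taxonomy$phosphatase)
  if (length(unresolved)) {
    warning("phosphatase(s) missing from taxonomy, kept as singleton clusters: ",
            paste(unresolved, collapse = ", "))
    taxonomy <- rbind(taxonomy,
                      data.frame(phosphatase = unresolved, family = unresolved,
                                 group = unresolved, stringsAsFactors = FALSE))
  }
  tax <- taxonomy[match(sspsr$phosphatase, taxonomy$phosphatase), ]
  sspsr$residue_class <- residue_class_of(sspsr$residue)
  clusters <- list()
  emit <- function(name, level, members, sites) {
    for (rc in unique(sites$residue_class)) {
      sub <- sites[sites$residue_class == rc, , drop = FALSE]
      n <- length(unique(paste(sub$accession, sub$position)))
      clusters[[length(clusters) + 1L]] <<- structure(
        list(name = name, level = level, members = sort(unique(members)),
             residue_class = rc, sites = sub, n_sites = n,
             route = route_for(n)),
        class = "dephos_ppcluster")
    }
  }
  for (g in unique(tax$group)) {
    sel <- tax$group == g
    emit(g, "group", sspsr$phosphatase[sel], sspsr[sel, , drop = FALSE])
  }
  for (f in unique(tax$family)) {
    sel <- tax$family == f
    emit(f, "family", sspsr$phosphatase[sel], sspsr[sel, , drop = FALSE])
  }
  for (p in unique(sspsr$phosphatase)) {
    sel <- sspsr$phosphatase == p
    emit(p, "single", p, sspsr[sel, , drop = FALSE])
  }
  clusters
}

#' @export
print.dephos_ppcluster <- function(x, ...) {
  cat("PP cluster '", x$name, "' (", x$level, ", ", x$residue_class, "): ",
      x$n_sites, " distinct sites -> ", x$route, "\n", sep = "")
  invisible(x)
}

# Positive/negative site-peptides for a cluster, on its own substrates.
cluster_datasets <- function(cluster, proteins, flank = 30L) {
  build_dephos_datasets(proteins,
                        cluster$sites[, c("accession", "position")],
                        residue_class = cluster$residue_class, flank = flank)
}

# ---- transfer-learning route ------------------------------------------------

# Cross-validated freeze-backbone fine-tune. Scores of the 9 static features
# and the transformers do not depend on the fold (base models are frozen),
# so they are computed once; the similarity feature and the meta-learner are
# refit inside each fold to keep the held-out scores leakage-free.
cv_finetune_freeze <- function(general, windows, y, k, seed) {
  Vs <- static_stack(general, windows)
  gps_cols <- gps_slots(general)
  folds <- integer(length(y))
  withr_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  scores <- numeric(length(y))
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    ref <- unique(windows[tr & y == 1])
    gtr <- encode_windows(windows[tr], "GPS", reference = ref)
    sc <- fit_scaler(gtr, "zscore")
    gte <- encode_windows(windows[!tr], "GPS", reference = ref)
    V_tr <- Vs$V[tr, , drop = FALSE]
    V_te <- Vs$V[!tr, , drop = FALSE]
    if (length(gps_cols)) {
      V_tr[, gps_cols] <- gps_base_scores(general, apply_scaler(gtr, sc))
      V_te[, gps_cols] <- gps_base_scores(general, apply_scaler(gte, sc))
    }
    meta <- train_stacker(V_tr, y[tr], general$config$meta_l2)
    scores[!tr] <- predict(meta, V_te)
    per_fold[f] <- auc_score(scores[!tr], y[!tr])
  }
  structure(list(auc = auc_score(scores, y), per_fold_aucs = per_fold,
                 roc = roc_curve(scores, y), scores = scores, labels = y,
                 folds = folds, n_pos = sum(y == 1), n_neg = sum(y == 0)),
            class = "dephos_eval")
}

# Stack vector with the GPS columns left at zero (filled per fold); also
# reports which columns belong to the similarity feature.
static_stack <- function(ensemble, windows) {
  V <- matrix(0, length(windows),
              2L * length(ensemble$features) + if (is.null(ensemble$tnns)) 0L else 2L)
  for (k in seq_along(ensemble$features)) {
    f <- ensemble$features[[k]]
    if (f == "GPS") next
    enc <- encode_scaled(windows, f, ensemble$gps_reference, ensemble$scalers[[f]])
    V[, k] <- predict(ensemble$dnns[[f]], enc$X)
    V[, length(ensemble$features) + k] <- predict(ensemble$plrs[[f]], enc$X)
  }
  if (!is.null(ensemble$tnns)) {
    V[, 2L * length(ensemble$features) + 1L] <-
      predict(ensemble$tnns$encoder, tokenize_windows(windows, cls = TRUE))
    V[, 2L * length(ensemble$features) + 2L] <-
      predict(ensemble$tnns$decoder, tokenize_windows(windows, cls = FALSE))
  }
  list(V = V)
}

gps_slots <- function(ensemble) {
  k <- match("GPS", ensemble$features)
  if (is.na(k)) integer(0) else c(k, length(ensemble$features) + k)
}

gps_base_scores <- function(ensemble, Xg) {
  cbind(predict(ensemble$dnns[["GPS"]], Xg), predict(ensemble$plrs[["GPS"]], Xg))
}

#' Phosphatase-specific predictor by transfer learning
#'
#' For a data-rich cluster (route `"transfer"`): per iteration, negatives are
#' resampled at the plan's ratio, the general dephosphorylation model is
#' fine-tuned, and k-fold cross-validation measures the validation AUC. The
#' best iterate is kept; iteration stops early when the validation AUC has
#' not improved for `plan$early_stop` consecutive iterations.
#'
#' @param general fine-tuned general dephosphorylation `dephos_ensemble`.
#' @param cluster a `dephos_ppcluster` with route `"transfer"`.
#' @param proteins substrate proteins.
#' @param plan [train_plan()].
#' @return list: `model` (the fine-tuned ensemble), `cv` (its
#'   cross-validation report), `iteration_aucs`.
#' @export
finetune_specific_transfer <- function(general, cluster, proteins,
                                       plan = train_plan()) {
  if (cluster$route != "transfer")
    stop("cluster '", cluster$name, "' routes to ", cluster$route,
         ", not transfer")
  if (general$residue_class != cluster$residue_class)
    stop("residue-class mismatch between model and cluster")
  ds <- cluster_datasets(cluster, proteins)
  best <- NULL; best_auc <- -Inf; aucs <- numeric(0); stall <- 0L
  for (it in seq_len(plan$iterations)) {
    tr <- assemble_training(ds, plan$neg_ratio, seed_offset(plan$seed, 100L + it))
    cv <- cv_finetune_freeze(general, tr$windows, tr$y, plan$folds,
                             seed_offset(plan$seed, 200L + it))
    aucs <- c(aucs, cv$auc)
    if (cv$auc > best_auc + 1e-12) {
      best_auc <- cv$auc
      best <- list(windows = tr$windows, y = tr$y, cv = cv)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= plan$early_stop) break
    }
  }
  model <- if (plan$freeze_mode == "freeze-backbone")
    finetune_freeze(general, best$windows, best$y)
  else
    finetune_full(general, best$windows, best$y, plan$seed)
  list(model = model, cv = best$cv, iteration_aucs = aucs)
}

# ---- meta-learning route ----------------------------------------------------

#' One inner gradient-descent update (meta-learning building block)
#'
#' Plain gradient descent on a flat parameter vector:
#' `theta - lr * grad_fn(theta)` applied `steps` times.
#'
#' @param theta numeric parameter vector.
#' @param grad_fn function returning the gradient at its argument.
#' @param lr step size.
#' @param steps number of steps (0 returns `theta` unchanged).
#' @return updated parameter vector.
#' @export
inner_update <- function(theta, grad_fn, lr, steps = 1L) {
  for (s in seq_len(steps)) theta <- theta - lr * grad_fn(theta)
  theta
}

# Adaptable neural components of an ensemble: every feed-forward model plus
# the two transformers. Each exposes flat get/set and a gradient closure
# over precomputed task encodings.
neural_components <- function(ensemble) {
  comps <- list()
  for (f in ensemble$features) {
    comps[[paste0("dnn_", f)]] <- list(type = "dnn", feature = f)
  }
  if (!is.null(ensemble$tnns)) {
    comps[["tnn_encoder"]] <- list(type = "tnn", feature = "encoder")
    comps[["tnn_decoder"]] <- list(type = "tnn", feature = "decoder")
  }
  comps
}

comp_get <- function(ensemble, comp) {
  if (comp$type == "dnn") mlp_flatten(ensemble$dnns[[comp$feature]]$par)
  else tnn_flatten(ensemble$tnns[[comp$feature]]$par)
}

comp_set <- function(ensemble, comp, flat) {
  if (comp$type == "dnn") {
    ensemble$dnns[[comp$feature]]$par <-
      mlp_unflatten(flat, ensemble$dnns[[comp$feature]]$par)
  } else {
    ensemble$tnns[[comp$feature]]$par <-
      tnn_unflatten(flat, ensemble$tnns[[comp$feature]]$par)
  }
  ensemble
}

# Precompute the encodings a task needs for every component.
task_encodings <- function(ensemble, windows, y) {
  enc <- list()
  for (f in ensemble$features) {
    if (f == "GPS") {
      ref <- unique(windows[y == 1])
      X <- encode_windows(windows, "GPS", reference = ref)
      enc[[f]] <- apply_scaler(X, fit_scaler(X, "zscore"))
    } else {
      enc[[f]] <- apply_scaler(encode_windows(windows, f),
                               ensemble$scalers[[f]])
    }
  }
  list(enc = enc,
       tok_enc = if (!is.null(ensemble$tnns)) tokenize_windows(windows, cls = TRUE),
       tok_dec = if (!is.null(ensemble$tnns)) tokenize_windows(windows, cls = FALSE),
       y = y, windows = windows)
}

comp_grad_fn <- function(ensemble, comp, td) {
  if (comp$type == "dnn") {
    template <- ensemble$dnns[[comp$feature]]$par
    X <- td$enc[[comp$feature]]; y <- td$y
    function(flat) mlp_flat_grad(mlp_unflatten(flat, template), X, y)
  } else {
    model <- ensemble$tnns[[comp$feature]]
    causal <- model$arch == "decoder-causal"
    tokens <- if (causal) td$tok_dec else td$tok_enc
    mask <- if (causal) NULL else tokens != 21L
    y <- td$y
    function(flat) {
      par <- tnn_unflatten(flat, model$par)
      tnn_flatten(tnn_grad(par, tokens, y, model$config, causal, mask)$grad)
    }
  }
}

# Build a fully usable ensemble from adapted neural parameters and a support
# set. The similarity feature is re-referenced on the support positives (its
# own closed refit); every other base model keeps its general-model weights
# or, for the neural components, the meta-adapted ones. The meta-learner is
# then refit on the support stacking vectors. Ridge refits of the
# high-dimensional logistic base models on a few-shot support produce
# stacking columns that are pure in-sample noise, so those stay frozen.
adapted_ensemble <- function(general, theta, comps, support_windows, support_y,
                             seed = 1L) {
  obj <- general
  for (nm in names(comps)) obj <- comp_set(obj, comps[[nm]], theta[[nm]])
  obj$gps_reference <- unique(support_windows[support_y == 1])
  gsup <- encode_windows(support_windows, "GPS", reference = obj$gps_reference)
  obj$scalers[["GPS"]] <- fit_scaler(gsup, "zscore")
  V <- stack_vector(obj, support_windows)
  obj$meta <- train_stacker(V, support_y, obj$config$meta_l2)
  obj
}

#' Phosphatase-specific predictor by first-order meta-learning
#'
#' For a few-shot cluster (route `"maml"`): the neural base models'
#' initialization is meta-trained over sibling tasks (other clusters), each
#' outer step adapting a task's support split for `inner_steps` gradient
#' steps and applying the first-order meta-gradient from its query split.
#' The meta-initialization is then adapted on the target cluster and
#' evaluated by leave-one-out over the target's positive sites, each
#' held-out positive scored against freshly resampled negatives.
#'
#' @param general fine-tuned general dephosphorylation `dephos_ensemble`.
#' @param sibling_clusters list of `dephos_ppcluster` used as the
#'   meta-training task distribution (same residue class).
#' @param target a `dephos_ppcluster` with route `"maml"`.
#' @param proteins substrate proteins.
#' @param cfg [maml_config()].
#' @param plan [train_plan()].
#' @return list: `model` (adapted ensemble), `loo` (leave-one-out report
#'   with `auc`, `scores`, `labels`), `meta_theta` (meta-initialization).
#' @export
maml_adapt <- function(general, sibling_clusters, target, proteins,
                       cfg = maml_config(), plan = train_plan()) {
  if (target$route != "maml")
    stop("cluster '", target$name, "' routes to ", target$route, ", not maml")
  if (general$residue_class != target$residue_class)
    stop("residue-class mismatch between model and cluster")
  sibling_clusters <- Filter(function(cl) cl$residue_class == general$residue_class &&
                               cl$n_sites >= 2L, sibling_clusters)
  comps <- neural_components(general)
  theta <- lapply(comps, function(cp) comp_get(general, cp))

  make_task <- function(cluster, seed) {
    ds <- cluster_datasets(cluster, proteins)
    tr <- assemble_training(ds, plan$neg_ratio, seed)
    npos <- sum(tr$y == 1)
    sup_pos <- withr_seed(seed_offset(seed, 1L),
                          sample(which(tr$y == 1), max(1L, npos %/% 2L)))
    sup_neg <- withr_seed(seed_offset(seed, 2L),
                          sample(which(tr$y == 0), max(1L, sum(tr$y == 0) %/% 2L)))
    sup <- c(sup_pos, sup_neg)
    list(support = task_encodings(general, tr$windows[sup], tr$y[sup]),
         query = task_encodings(general, tr$windows[-sup], tr$y[-sup]))
  }

  if (length(sibling_clusters) && cfg$outer_steps > 0L && cfg$inner_steps > 0L) {
    for (step in seq_len(cfg$outer_steps)) {
      pick <- withr_seed(seed_offset(plan$seed, 300L + step),
                         sample(seq_along(sibling_clusters),
                                min(cfg$meta_batch, length(sibling_clusters))))
      meta_grad <- lapply(theta, function(v) v * 0)
      for (ti in pick) {
        task <- make_task(sibling_clusters[[ti]],
                          seed_offset(plan$seed, 400L + 31L * step + ti))
        for (nm in names(comps)) {
          gf_sup <- comp_grad_fn(general, comps[[nm]], task$support)
          adapted <- inner_update(theta[[nm]], gf_sup, cfg$inner_lr, cfg$inner_steps)
          gf_qry <- comp_grad_fn(general, comps[[nm]], task$query)
          meta_grad[[nm]] <- meta_grad[[nm]] + gf_qry(adapted) / length(pick)
        }
      }
      for (nm in names(comps))
        theta[[nm]] <- theta[[nm]] - cfg$outer_lr * meta_grad[[nm]]
    }
  }

  adapt_on <- function(windows, y) {
    td <- task_encodings(general, windows, y)
    th <- theta
    if (cfg$inner_steps > 0L) {
      for (nm in names(comps)) {
        gf <- comp_grad_fn(general, comps[[nm]], td)
        th[[nm]] <- inner_update(th[[nm]], gf, cfg$inner_lr, cfg$inner_steps)
      }
    } else {
      warning("inner_steps = 0: returning meta-initialization unadapted")
    }
    adapted_ensemble(general, th, comps, windows, y,
                     seed = seed_offset(plan$seed, 800L))
  }

  ds <- cluster_datasets(target, proteins)
  # leave-one-out over the target's positives
  scores <- numeric(0); labels <- numeric(0)
  npos <- nrow(ds$positives)
  for (i in seq_len(npos)) {
    sup_pos <- ds$positives[-i, , drop = FALSE]
    neg <- resample_negatives(sup_pos, ds$negatives, plan$neg_ratio,
                              seed_offset(plan$seed, 500L + i))
    model_i <- adapt_on(c(sup_pos$window, neg$window),
                        c(rep(1, nrow(sup_pos)), rep(0, nrow(neg))))
    remaining <- ds$negatives[!(paste(ds$negatives$accession, ds$negatives$position) %in%
                                  paste(neg$accession, neg$position)), , drop = FALSE]
    if (nrow(remaining) < plan$neg_ratio) remaining <- ds$negatives
    test_neg <- resample_negatives(ds$positives[i, , drop = FALSE], remaining,
                                   plan$neg_ratio, seed_offset(plan$seed, 600L + i))
    sc <- predict(model_i, c(ds$positives$window[i], test_neg$window))
    scores <- c(scores, sc)
    labels <- c(labels, c(1, rep(0, nrow(test_neg))))
  }
  tr <- assemble_training(ds, plan$neg_ratio, seed_offset(plan$seed, 700L))
  final <- adapt_on(tr$windows, tr$y)
  list(model = final,
       loo = list(auc = auc_score(scores, labels), scores = scores, labels = labels),
       meta_theta = theta)
}

#' Build every phosphatase-specific predictor
#'
#' Clusters the site table, then trains one model per non-excluded cluster:
#' transfer learning for clusters with at least 30 distinct sites,
#' meta-learning (with the sibling clusters of the same level and residue
#' class as task distribution) below that. Per-cluster failures are caught
#' and listed; the build continues.
#'
#' @param general_models named list of general dephosphorylation ensembles
#'   (by residue class, from [finetune_general_dephos()]).
#' @param sspsr phosphatase site table.
#' @param taxonomy phosphatase taxonomy.
#' @param proteins substrate proteins.
#' @param plan [train_plan()].
#' @param cfg [maml_config()].
#' @return list of class `dephos_registry`: `models` (named list),
#'   `manifest` (data.frame), `failures` (named character vector).
#' @export
build_all_specific <- function(general_models, sspsr, taxonomy, proteins,
                               plan = train_plan(), cfg = maml_config()) {
  clusters <- cluster_pps(sspsr, taxonomy)
  keep <- Filter(function(cl) cl$route != "excluded", clusters)
  if (!length(keep)) {
    warning("all clusters excluded (fewer than 3 distinct sites each)")
    return(structure(list(models = list(), manifest = data.frame(),
                          failures = character(0)),
                     class = "dephos_registry"))
  }
  models <- list(); rows <- list(); failures <- character(0)
  for (cl in keep) {
    id <- paste(cl$name, cl$level, cl$residue_class, sep = "|")
    rc <- cl$residue_class
    general <- general_models[[rc]]
    if (is.null(general)) { failures[id] <- "no general model for class"; next }
    res <- tryCatch({
      if (cl$route == "transfer") {
        ft <- finetune_specific_transfer(general, cl, proteins, plan)
        list(model = ft$model, metric = ft$cv$auc, metric_name = "cv_auc")
      } else {
        sibs <- Filter(function(o) o$level == cl$level &&
                         o$residue_class == rc &&
                         !identical(o$name, cl$name), clusters)
        ma <- maml_adapt(general, sibs, cl, proteins, cfg, plan)
        list(model = ma$model, metric = ma$loo$auc, metric_name = "loo_auc")
      }
    }, error = function(e) e)
    if (inherits(res, "error")) { failures[id] <- conditionMessage(res); next }
    models[[id]] <- res$model
    rows[[id]] <- data.frame(id = id, name = cl$name, level = cl$level,
                             residue_class = rc, route = cl$route,
                             n_sites = cl$n_sites, metric = res$metric,
                             metric_name = res$metric_name,
                             stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(models = models, manifest = manifest, failures = failures),
            class = "dephos_registry")
}

#' @export
print.dephos_registry <- function(x, ...) {
  cat("Phosphatase-specific model registry: ", length(x$models), " models\n", sep = "")
  if (nrow(x$manifest)) print(x$manifest[, c("id", "route", "n_sites", "metric")])
  if (length(x$failures))
    cat("failures:\n", paste(" ", names(x$failures), ":", x$failures, collapse = "\n"), "\n")
  invisible(x)
}

#' Save / load a model registry
#' @param registry a `dephos_registry`.
#' @param path directory.
#' @return `path` (save) or the registry (load).
#' @export
save_registry <- function(registry, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(registry$manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(registry$models, file.path(path, "models.rds"))
  jsonlite::write_json(as.list(registry$failures), file.path(path, "failures.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_registry
#' @export
load_registry <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  models <- readRDS(file.path(path, "models.rds"))
  failures <- unlist(jsonlite::read_json(file.path(path, "failures.json")))
  if (is.null(failures)) failures <- character(0)
  structure(list(models = models, manifest = as.data.frame(manifest),
                 failures = failures),
            class = "dephos_registry")
}
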