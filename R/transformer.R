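# Compact transformer base learners over tokenized peptide windows.
#
# Two variants are provided: a bidirectional encoder that classifies from the
# state of a prepended class token (pad positions are masked out of the
# attention keys), and a causal decoder that restricts every position to
# attend only to itself and earlier positions and classifies from the final
# position's state. Pre-norm residual blocks with RMS normalization; analytic
# backpropagation; Adam updates. Attention is computed with batched tensor
# contractions (loops run over the small head dimension, never over samples)
# so that CPU training on desk-scale data stays fast.

#' Default transformer configuration
#'
#' @param layers,heads,embed_dim,ff_dim architecture sizes.
#' @param learning_rate,epochs,batch_size optimization settings.
#' @return named list of settings.
#' @export
tnn_config <- function(layers = 2L, heads = 4L, embed_dim = 32L,
                       ff_dim = 4L * embed_dim, learning_rate = 1e-3,
                       epochs = 6L, batch_size = 64L) {
  stopifnot(embed_dim %% heads == 0L)
  list(layers = layers, heads = heads, embed_dim = embed_dim, ff_dim = ff_dim,
       learning_rate = learning_rate, epochs = epochs, batch_size = batch_size)
}

tnn_init <- function(Tlen, cfg, seed) {
  d <- cfg$embed_dim
  rn <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  withr_seed(seed, {
    list(
      Emb = rn(TOKEN_VOCAB, d, 0.02),
      Pos = rn(Tlen, d, 0.02),
      layers = lapply(seq_len(cfg$layers), function(l) list(
        Wq = rn(d, d, 1 / sqrt(d)), Wk = rn(d, d, 1 / sqrt(d)),
        Wv = rn(d, d, 1 / sqrt(d)), Wo = rn(d, d, 1 / sqrt(d)),
        g1 = rep(1, d), g2 = rep(1, d),
        W1 = rn(d, cfg$ff_dim, 1 / sqrt(d)), b1 = numeric(cfg$ff_dim),
        W2 = rn(cfg$ff_dim, d, 1 / sqrt(cfg$ff_dim)), b2 = numeric(d)
      )),
      w_out = rn(d, 1L, 1 / sqrt(d)), b_out = 0
    )
  })
}

rmsnorm_fwd <- function(X, g, eps = 1e-6) {
  r <- sqrt(rowMeans(X^2) + eps)
  list(Y = (X / r) * rep(g, each = nrow(X)), r = r)
}

rmsnorm_bwd <- function(dY, X, g, cache) {
  r <- cache$r
  Gy <- dY * rep(g, each = nrow(dY))
  dX <- Gy / r - X * (rowSums(Gy * X) / (ncol(X) * r^3))
  dg <- colSums(dY * (X / r))
  list(dX = dX, dg = dg)
}

# Batched multi-head attention, forward and backward. The per-sample,
# per-head loops are compiled (src/attention.cpp); these wrappers keep the
# cache plumbing in R.
attn_fwd <- function(Qm, Km, Vm, B, Tlen, H, causal, mask_keys, keep_cache) {
  has_mask <- !causal && !is.null(mask_keys)
  .attn_fwd_cpp(Qm, Km, Vm, B, Tlen, H, causal,
                if (has_mask) mask_keys * 1L else matrix(1L, 1L, 1L),
                has_mask, keep_cache)
}

attn_bwd <- function(dO, cache, Qm, Km, Vm, B, Tlen, H) {
  .attn_bwd_cpp(dO, cache$cache, Qm, Km, Vm, B, Tlen, H)
}

# Forward pass. tokens: B x T integer matrix. mask_keys: B x T logical, TRUE
# where the key position may be attended to (encoder); NULL for the decoder.
tnn_forward <- function(par, tokens, cfg, causal, mask_keys = NULL, keep_cache = FALSE) {
  B <- nrow(tokens); Tlen <- ncol(tokens)
  d <- cfg$embed_dim; H <- cfg$heads
  X <- par$Emb[as.integer(t(tokens)), , drop = FALSE] +
    par$Pos[rep(seq_len(Tlen), B), , drop = FALSE]   # (B*T) x d, sample-major
  caches <- vector("list", length(par$layers))
  for (li in seq_along(par$layers)) {
    lp <- par$layers[[li]]
    n1 <- rmsnorm_fwd(X, lp$g1)
    Q <- n1$Y %*% lp$Wq; K <- n1$Y %*% lp$Wk; V <- n1$Y %*% lp$Wv
    at <- attn_fwd(Q, K, V, B, Tlen, H, causal, mask_keys, keep_cache)
    X1 <- X + at$O %*% lp$Wo
    n2 <- rmsnorm_fwd(X1, lp$g2)
    Z1 <- n2$Y %*% lp$W1
    Z1 <- Z1 + rep(lp$b1, each = nrow(Z1))
    A1 <- pmax(Z1, 0)
    X2 <- X1 + A1 %*% lp$W2 + rep(lp$b2, each = nrow(A1))
    if (keep_cache)
      caches[[li]] <- list(Xin = X, n1 = n1, Q = Q, K = K, V = V,
                           at = at, X1 = X1, n2 = n2, A1 = A1)
    X <- X2
  }
  pos_out <- if (causal) Tlen else 1L
  rows_out <- (seq_len(B) - 1L) * Tlen + pos_out
  logits <- as.numeric(X[rows_out, , drop = FALSE] %*% par$w_out + par$b_out)
  list(prob = stats::plogis(logits), states = if (keep_cache) X else NULL,
       caches = caches, rows_out = rows_out, B = B, Tlen = Tlen)
}

tnn_grad <- function(par, tokens, y, cfg, causal, mask_keys = NULL) {
  fw <- tnn_forward(par, tokens, cfg, causal, mask_keys, keep_cache = TRUE)
  B <- fw$B; Tlen <- fw$Tlen
  d <- cfg$embed_dim; H <- cfg$heads
  gr <- list(Emb = matrix(0, TOKEN_VOCAB, d), Pos = matrix(0, Tlen, d),
             layers = vector("list", length(par$layers)),
             w_out = matrix(0, d, 1L), b_out = 0)
  dlogit <- (fw$prob - y) / B
  states_out <- fw$states[fw$rows_out, , drop = FALSE]
  gr$w_out <- crossprod(states_out, dlogit)
  gr$b_out <- sum(dlogit)
  dX <- matrix(0, B * Tlen, d)
  dX[fw$rows_out, ] <- dlogit %*% t(par$w_out)
  for (li in rev(seq_along(par$layers))) {
    lp <- par$layers[[li]]
    ch <- fw$caches[[li]]
    dA1 <- dX %*% t(lp$W2)
    dZ1 <- dA1 * (ch$A1 > 0)
    gW2 <- crossprod(ch$A1, dX); gb2 <- colSums(dX)
    gW1 <- crossprod(ch$n2$Y, dZ1); gb1 <- colSums(dZ1)
    bn2 <- rmsnorm_bwd(dZ1 %*% t(lp$W1), ch$X1, lp$g2, ch$n2)
    dX1 <- dX + bn2$dX
    gWo <- crossprod(ch$at$O, dX1)
    dO <- dX1 %*% t(lp$Wo)
    ab <- attn_bwd(dO, ch$at, ch$Q, ch$K, ch$V, B, Tlen, H)
    gWq <- crossprod(ch$n1$Y, ab$dQ)
    gWk <- crossprod(ch$n1$Y, ab$dK)
    gWv <- crossprod(ch$n1$Y, ab$dV)
    dn1 <- ab$dQ %*% t(lp$Wq) + ab$dK %*% t(lp$Wk) + ab$dV %*% t(lp$Wv)
    bn1 <- rmsnorm_bwd(dn1, ch$Xin, lp$g1, ch$n1)
    gr$layers[[li]] <- list(Wq = gWq, Wk = gWk, Wv = gWv, Wo = gWo,
                            g1 = bn1$dg, g2 = bn2$dg,
                            W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    dX <- dX1 + bn1$dX
  }
  tok_idx <- as.integer(t(tokens))
  rs <- rowsum(dX, tok_idx)
  gr$Emb[as.integer(rownames(rs)), ] <- rs
  gr$Pos <- rowsum(dX, rep(seq_len(Tlen), B))
  eps <- 1e-12
  loss <- -mean(y * log(fw$prob + eps) + (1 - y) * log(1 - fw$prob + eps))
  list(grad = gr, loss = loss)
}

# Flat parameter views. Leaves are enumerated once per template; flatten and
# unflatten then run over precomputed offsets (no recursive relisting).
tnn_leaves <- function(par) {
  out <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      for (i in seq_along(x)) walk(x[[i]], c(path, i))
    } else {
      out[[length(out) + 1L]] <<- list(path = path, n = length(x),
                                       dim = if (is.matrix(x)) dim(x) else NULL)
    }
  }
  walk(par, integer(0))
  off <- cumsum(c(0L, vapply(out, function(l) l$n, integer(1))))
  for (i in seq_along(out)) out[[i]]$offset <- off[i]
  out
}

tnn_flatten <- function(par) {
  acc <- function(x) if (is.list(x)) unlist(lapply(x, acc), use.names = FALSE) else as.numeric(x)
  acc(par)
}

tnn_unflatten <- function(flat, template, leaves = NULL) {
  if (is.null(leaves)) leaves <- tnn_leaves(template)
  out <- template
  for (lf in leaves) {
    v <- flat[lf$offset + seq_len(lf$n)]
    if (!is.null(lf$dim)) dim(v) <- lf$dim
    out[[lf$path]] <- v
  }
  out
}

tnn_adam_step <- function(flat_par, flat_grad, state, lr,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * flat_grad
  state$v <- beta2 * state$v + (1 - beta2) * flat_grad^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  list(par = flat_par - lr * mh / (sqrt(vh) + eps), state = state)
}

#' Train a compact transformer base learner
#'
#' @param tokens integer token matrix from [tokenize_windows()] (with the
#'   class token for the encoder variant, without it for the decoder).
#' @param y binary labels (0/1).
#' @param arch `"encoder-bidirectional"` or `"decoder-causal"`.
#' @param config list from [tnn_config()].
#' @param seed integer seed.
#' @param init optional parameter list to warm-start from (transfer learning).
#' @return object of class `dephos_tnn`.
#' @export
train_transformer <- function(tokens, y,
                              arch = c("encoder-bidirectional", "decoder-causal"),
                              config = tnn_config(), seed = 1L, init = NULL) {
  arch <- match.arg(arch)
  tokens <- as.matrix(tokens); y <- as.numeric(y)
  if (nrow(tokens) != length(y)) stop("rows of tokens must match length of y")
  if (config$epochs > 0L && length(unique(y)) < 2L)
    stop("both classes must be present in y")
  causal <- arch == "decoder-causal"
  par <- if (is.null(init)) tnn_init(ncol(tokens), config, seed) else init
  leaves <- tnn_leaves(par)
  flat <- tnn_flatten(par)
  st <- list(m = flat * 0, v = flat * 0, t = 0L)
  mask_keys <- if (causal) NULL else tokens != 21L  # pads masked from keys
  losses <- numeric(0)
  if (config$epochs > 0L) withr_seed(seed_offset(seed, 2L), {
    n <- nrow(tokens)
    bs <- min(config$batch_size, n)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        g <- tnn_grad(tnn_unflatten(flat, par, leaves), tokens[idx, , drop = FALSE],
                      y[idx], config, causal,
                      if (is.null(mask_keys)) NULL else mask_keys[idx, , drop = FALSE])
        up <- tnn_adam_step(flat, tnn_flatten(g$grad), st, config$learning_rate)
        flat <- up$par; st <- up$state
        ep_loss <- ep_loss + g$loss; nb <- nb + 1L
      }
      losses <- c(losses, ep_loss / nb)
    }
  })
  structure(list(kind = if (causal) "TNN-decoder" else "TNN-encoder",
                 feature_name = "tokens", arch = arch, par = tnn_unflatten(flat, par),
                 config = config, seed = seed, Tlen = ncol(tokens), losses = losses),
            class = c("dephos_tnn", "dephos_base_model"))
}

#' @export
predict.dephos_tnn <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$Tlen)
    stop("token length mismatch: model expects ", object$Tlen,
         ", got ", ncol(newdata))
  causal <- object$arch == "decoder-causal"
  mask_keys <- if (causal) NULL else newdata != 21L
  out <- numeric(nrow(newdata))
  bs <- 256L
  for (start in seq(1L, nrow(newdata), by = bs)) {
    idx <- start:min(start + bs - 1L, nrow(newdata))
    out[idx] <- tnn_forward(object$par, newdata[idx, , drop = FALSE],
                            object$config, causal,
                            if (is.null(mask_keys)) NULL else mask_keys[idx, , drop = FALSE])$prob
  }
  out
}

#' @export
print.dephos_tnn <- function(x, ...) {
  cat("Transformer base learner (", x$arch, ", ", x$config$layers, " layers, ",
      x$config$heads, " heads, d = ", x$config$embed_dim, ")\n", sep = "")
  invisible(x)
}
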