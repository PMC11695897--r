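# Feed-forward neural network base learner: fully connected ReLU layers with
# inverted dropout, sigmoid output, binary cross-entropy loss, Adam updates.
# Written directly on matrix operations so that weights can be flattened and
# adapted by the first-order meta-learning routine.

mlp_init <- function(d_in, hidden, seed) {
  withr_seed(seed, {
    sizes <- c(d_in, hidden, 1L)
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                    sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
    list(W = W, b = b)
  })
}

mlp_forward <- function(par, X, dropout = 0, training = FALSE) {
  nl <- length(par$W)
  A <- list(X)
  masks <- vector("list", nl)
  H <- X
  for (l in seq_len(nl)) {
    Z <- sweep(H %*% par$W[[l]], 2L, par$b[[l]], "+")
    if (l < nl) {
      H <- pmax(Z, 0)
      if (training && dropout > 0) {
        m <- matrix(stats::runif(length(H)) >= dropout, nrow(H), ncol(H)) / (1 - dropout)
        H <- H * m
        masks[[l]] <- m
      }
      A[[l + 1L]] <- H
    } else {
      H <- stats::plogis(Z)
    }
  }
  list(prob = as.numeric(H), acts = A, masks = masks)
}

mlp_grad <- function(par, X, y, dropout = 0, training = FALSE) {
  n <- nrow(X)
  fw <- mlp_forward(par, X, dropout, training)
  nl <- length(par$W)
  dW <- vector("list", nl); db <- vector("list", nl)
  delta <- matrix(fw$prob - y, n, 1L) / n   # d(BCE)/d(logit)
  for (l in rev(seq_len(nl))) {
    A <- fw$acts[[l]]
    dW[[l]] <- crossprod(A, delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(par$W[[l]])
      if (!is.null(fw$masks[[l - 1L]])) delta <- delta * fw$masks[[l - 1L]]
      delta <- delta * (fw$acts[[l]] > 0)
    }
  }
  eps <- 1e-12
  loss <- -mean(y * log(fw$prob + eps) + (1 - y) * log(1 - fw$prob + eps))
  list(dW = dW, db = db, loss = loss)
}

adam_init <- function(par) {
  z <- rapply(par, function(x) x * 0, how = "replace")
  list(m = z, v = z, t = 0L)
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (l in seq_along(par$W)) {
    for (nm in c("W", "b")) {
      g <- if (nm == "W") grad$dW[[l]] else grad$db[[l]]
      state$m[[nm]][[l]] <- beta1 * state$m[[nm]][[l]] + (1 - beta1) * g
      state$v[[nm]][[l]] <- beta2 * state$v[[nm]][[l]] + (1 - beta2) * g^2
      mh <- state$m[[nm]][[l]] / (1 - beta1^state$t)
      vh <- state$v[[nm]][[l]] / (1 - beta2^state$t)
      par[[nm]][[l]] <- par[[nm]][[l]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(par = par, state = state)
}

#' Default feed-forward architecture
#'
#' Two hidden layers (128, 32), dropout 0.3, learning rate 1e-3, batch 64.
#' Epoch count is a desk-scale default; increase for larger corpora.
#'
#' @param hidden_sizes,dropout,learning_rate,epochs,batch_size overrides.
#' @return named list of architecture settings.
#' @export
dnn_architecture <- function(hidden_sizes = c(128L, 32L), dropout = 0.3,
                             learning_rate = 1e-3, epochs = 10L, batch_size = 64L) {
  list(hidden_sizes = hidden_sizes, dropout = dropout,
       learning_rate = learning_rate, epochs = epochs, batch_size = batch_size)
}

#' Train a feed-forward neural network base learner
#'
#' @param X numeric feature matrix.
#' @param y binary labels (0/1).
#' @param architecture list from [dnn_architecture()].
#' @param seed integer seed (weight init, shuffling, dropout).
#' @param feature_name optional name of the encoder this model consumes.
#' @param init optional parameter list to warm-start from (transfer learning).
#' @return object of class `dephos_dnn`.
#' @export
train_dnn <- function(X, y, architecture = dnn_architecture(), seed = 1L,
                      feature_name = NULL, init = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (!all(is.finite(X))) stop("non-finite values in X")
  if (architecture$epochs > 0L && length(unique(y)) < 2L)
    stop("both classes must be present in y")
  par <- if (is.null(init)) mlp_init(ncol(X), architecture$hidden_sizes, seed) else init
  st <- adam_init(par)
  losses <- numeric(0)
  if (architecture$epochs > 0L) withr_seed(seed_offset(seed, 1L), {
    n <- nrow(X)
    bs <- min(architecture$batch_size, n)
    for (ep in seq_len(architecture$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        g <- mlp_grad(par, X[idx, , drop = FALSE], y[idx],
                      architecture$dropout, training = TRUE)
        up <- adam_step(par, g, st, architecture$learning_rate)
        par <- up$par; st <- up$state
        ep_loss <- ep_loss + g$loss; nb <- nb + 1L
      }
      losses <- c(losses, ep_loss / nb)
    }
  })
  structure(list(kind = "DNN", feature_name = feature_name, par = par,
                 architecture = architecture, seed = seed, losses = losses),
            class = c("dephos_dnn", "dephos_base_model"))
}

#' @export
predict.dephos_dnn <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$par$W[[1L]]))
    stop("feature dimension mismatch: model expects ", nrow(object$par$W[[1L]]),
         ", got ", ncol(newdata))
  mlp_forward(object$par, newdata)$prob
}

#' @export
print.dephos_dnn <- function(x, ...) {
  cat("Feed-forward base learner (", nrow(x$par$W[[1L]]), " -> ",
      paste(x$architecture$hidden_sizes, collapse = " -> "), " -> 1)\n", sep = "")
  invisible(x)
}

# ---- flat parameter view (used by the meta-learning routine) ---------------

mlp_flatten <- function(par) {
  unlist(c(lapply(par$W, as.numeric), lapply(par$b, as.numeric)))
}

mlp_unflatten <- function(flat, template) {
  out <- template
  pos <- 0L
  for (l in seq_along(template$W)) {
    k <- length(template$W[[l]])
    out$W[[l]] <- matrix(flat[pos + seq_len(k)], nrow(template$W[[l]]))
    pos <- pos + k
  }
  for (l in seq_along(template$b)) {
    k <- length(template$b[[l]])
    out$b[[l]] <- flat[pos + seq_len(k)]
    pos <- pos + k
  }
  out
}

mlp_flat_grad <- function(par, X, y) {
  g <- mlp_grad(par, X, y)
  unlist(c(lapply(g$dW, as.numeric), lapply(g$db, as.numeric)))
}
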