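# Multilayer perceptron for binary classification of descriptor pairs.
#
# Architecture: dense ReLU hidden layers (default 64, 32) with inverted
# dropout, a single sigmoid output, binary cross-entropy loss, Adam
# updates in mini-batches, and early stopping on a stratified validation
# split with best-weight restoration. Implemented with base matrix
# algebra; problem sizes here (~10^3 pairs, ~50 features) need nothing
# heavier.

#' Fit a multilayer perceptron classifier
#'
#' @param x Numeric feature matrix (rows = examples).
#' @param y 0/1 numeric vector of labels.
#' @param hidden Integer vector of hidden-layer widths.
#' @param dropout Dropout probability applied after each hidden ReLU
#'   (inverted dropout; 0 disables).
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); the best-validation weights are restored.
#' @param val_fraction Fraction of the training data held out
#'   (stratified) for early stopping.
#' @param seed Integer seed controlling initialization, batching,
#'   dropout and the validation split.
#' @return An object of class `mlp`.
#' @export
mlp_fit <- function(x, y, hidden = c(64L, 32L), dropout = 0.2,
                    learning_rate = 1e-3, batch_size = 32L,
                    max_epochs = 200L, patience = 20L,
                    val_fraction = 0.1, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("training labels are single-class", call. = FALSE)

  with_seed(seed, {
    # stratified validation split for early stopping
    val_idx <- unlist(lapply(c(0, 1), function(cl) {
      idx <- which(y == cl)
      n_val <- max(1L, round(val_fraction * length(idx)))
      sample(idx, n_val)
    }), use.names = FALSE)
    xt <- x[-val_idx, , drop = FALSE]; yt <- y[-val_idx]
    xv <- x[val_idx, , drop = FALSE];  yv <- y[val_idx]

    dims <- c(ncol(x), hidden, 1L)
    n_layers <- length(dims) - 1L
    W <- vector("list", n_layers)
    b <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      # He initialization for the ReLU layers
      W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L], 0,
                                    sqrt(2 / dims[l])),
                       dims[l], dims[l + 1L])
      b[[l]] <- numeric(dims[l + 1L])
    }
    adam <- list(mW = lapply(W, function(w) w * 0),
                 vW = lapply(W, function(w) w * 0),
                 mb = lapply(b, function(v) v * 0),
                 vb = lapply(b, function(v) v * 0),
                 t = 0L)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

    n <- nrow(xt)
    best <- list(loss = Inf, W = W, b = b, epoch = 0L)
    wait <- 0L
    epochs_run <- 0L

    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- xt[idx, , drop = FALSE]; yb <- yt[idx]
        m <- length(idx)

        # forward with dropout
        inputs <- vector("list", n_layers)  # what each layer consumed
        zs <- vector("list", n_layers)
        masks <- vector("list", n_layers)
        a <- xb
        for (l in seq_len(n_layers - 1L)) {
          inputs[[l]] <- a
          z <- sweep(a %*% W[[l]], 2L, b[[l]], "+")
          zs[[l]] <- z
          h <- pmax(z, 0)
          if (dropout > 0) {
            mask <- matrix(stats::rbinom(length(h), 1L, 1 - dropout),
                           nrow(h), ncol(h)) / (1 - dropout)
            masks[[l]] <- mask
            h <- h * mask
          }
          a <- h
        }
        inputs[[n_layers]] <- a
        zout <- drop(a %*% W[[n_layers]]) + b[[n_layers]]
        p <- stats::plogis(zout)

        # backward
        gW <- vector("list", n_layers)
        gb <- vector("list", n_layers)
        delta <- matrix((p - yb) / m, ncol = 1L)
        gW[[n_layers]] <- crossprod(inputs[[n_layers]], delta)
        gb[[n_layers]] <- colSums(delta)
        da <- delta %*% t(W[[n_layers]])
        for (l in rev(seq_len(n_layers - 1L))) {
          if (dropout > 0) da <- da * masks[[l]]
          dz <- da * (zs[[l]] > 0)
          gW[[l]] <- crossprod(inputs[[l]], dz)
          gb[[l]] <- colSums(dz)
          if (l > 1L) da <- dz %*% t(W[[l]])
        }

        # Adam update
        adam$t <- adam$t + 1L
        c1 <- 1 - beta1^adam$t; c2 <- 1 - beta2^adam$t
        for (l in seq_len(n_layers)) {
          adam$mW[[l]] <- beta1 * adam$mW[[l]] + (1 - beta1) * gW[[l]]
          adam$vW[[l]] <- beta2 * adam$vW[[l]] + (1 - beta2) * gW[[l]]^2
          W[[l]] <- W[[l]] - learning_rate * (adam$mW[[l]] / c1) /
            (sqrt(adam$vW[[l]] / c2) + eps)
          adam$mb[[l]] <- beta1 * adam$mb[[l]] + (1 - beta1) * gb[[l]]
          adam$vb[[l]] <- beta2 * adam$vb[[l]] + (1 - beta2) * gb[[l]]^2
          b[[l]] <- b[[l]] - learning_rate * (adam$mb[[l]] / c1) /
            (sqrt(adam$vb[[l]] / c2) + eps)
        }
      }

      epochs_run <- epoch
      pv <- .mlp_forward(xv, W, b)
      val_loss <- .bce(yv, pv)
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, W = W, b = b, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > patience) break
      }
    }

    structure(list(W = best$W, b = best$b, hidden = hidden,
                   dropout = dropout, feature_names = colnames(x),
                   val_loss = best$loss, best_epoch = best$epoch,
                   epochs_run = epochs_run, seed = seed),
              class = "mlp")
  })
}

.mlp_forward <- function(x, W, b) {
  n_layers <- length(W)
  a <- x
  for (l in seq_len(n_layers - 1L)) {
    a <- pmax(sweep(a %*% W[[l]], 2L, b[[l]], "+"), 0)
  }
  stats::plogis(drop(a %*% W[[n_layers]]) + b[[n_layers]])
}

.bce <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Predict probabilities from a fitted MLP
#'
#' @param object An `mlp` fit.
#' @param newdata Feature matrix with the training schema.
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict.mlp <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata))) {
    if (!identical(colnames(newdata), object$feature_names)) {
      stop("feature schema mismatch with fitted MLP", call. = FALSE)
    }
  }
  .mlp_forward(newdata, object$W, object$b)
}
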