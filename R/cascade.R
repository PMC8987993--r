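# Cascade feed-forward network internals.
#
# Architecture: hidden layer k receives [X, A1, ..., A(k-1)]; the linear
# output unit receives [X, A1, ..., AL]. Because the raw inputs reach the
# output directly, the network contains an exact linear regression as a
# special case, which guarantees it can represent a purely linear
# age-feature relationship.

.cascadeInit <- function(d, layers, width) {
  hidden <- vector("list", layers)
  in_dim <- d
  for (k in seq_len(layers)) {
    hidden[[k]] <- list(
      W = matrix(stats::rnorm(in_dim * width, 0, 1 / sqrt(in_dim)),
                 in_dim, width),
      b = rep(0, width))
    in_dim <- in_dim + width
  }
  list(hidden = hidden,
       wo = stats::rnorm(in_dim, 0, 1 / sqrt(in_dim)),
       bo = 0,
       d = d, layers = layers, width = width)
}

.cascadeForward <- function(w, X, keep = FALSE) {
  C <- X
  acts <- if (keep) vector("list", length(w$hidden)) else NULL
  for (k in seq_along(w$hidden)) {
    hk <- w$hidden[[k]]
    A <- tanh(sweep(C %*% hk$W, 2, hk$b, "+"))
    if (keep) acts[[k]] <- A
    C <- cbind(C, A)
  }
  yhat <- drop(C %*% w$wo + w$bo)
  if (keep) list(yhat = yhat, acts = acts, C = C) else yhat
}

# gradient of mean((yhat - y)^2) wrt all weights
.cascadeGrad <- function(w, X, y) {
  n <- nrow(X); d <- w$d; h <- w$width; L <- w$layers
  fw <- .cascadeForward(w, X, keep = TRUE)
  g <- 2 * (fw$yhat - y) / n
  grad <- list(hidden = vector("list", L))
  grad$wo <- drop(crossprod(fw$C, g))
  grad$bo <- sum(g)
  dC <- tcrossprod(g, w$wo)  # n x (d + L*h)
  for (k in L:1) {
    cols <- (d + (k - 1) * h + 1):(d + k * h)
    dZ <- dC[, cols, drop = FALSE] * (1 - fw$acts[[k]]^2)
    Ck <- fw$C[, 1:(d + (k - 1) * h), drop = FALSE]
    grad$hidden[[k]] <- list(W = crossprod(Ck, dZ), b = colSums(dZ))
    dC[, 1:(d + (k - 1) * h)] <- dC[, 1:(d + (k - 1) * h), drop = FALSE] +
      dZ %*% t(w$hidden[[k]]$W)
  }
  list(grad = grad, loss = mean((fw$yhat - y)^2))
}

.flatten <- function(w) {
  c(unlist(lapply(w$hidden, function(l) c(l$W, l$b))), w$wo, w$bo)
}

.unflatten <- function(theta, proto) {
  pos <- 1L
  take <- function(k) {
    out <- theta[pos:(pos + k - 1L)]
    pos <<- pos + k
    out
  }
  for (k in seq_along(proto$hidden)) {
    W <- proto$hidden[[k]]$W
    proto$hidden[[k]]$W <- matrix(take(length(W)), nrow(W), ncol(W))
    proto$hidden[[k]]$b <- take(length(proto$hidden[[k]]$b))
  }
  proto$wo <- take(length(proto$wo))
  proto$bo <- take(1L)
  proto
}

# full-batch Adam with cosine learning-rate decay and early stopping on a
# held-out validation split; returns the best-validation weights
.cascadeTrain <- function(X, y, hyper, seed) {
  n <- nrow(X)
  withr::with_seed(seed, {
    w <- .cascadeInit(ncol(X), hyper$layers, hyper$width)
    n_val <- floor(hyper$val_fraction * n)
    val_idx <- if (n_val >= 1) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]

    theta <- .flatten(w)
    # L2 mask: hidden-layer weights and the hidden part of the output
    # weights; the raw-input skip path, all biases and the output bias
    # stay unpenalized
    mask <- .flatten(local({
      wm <- w
      for (k in seq_along(wm$hidden)) {
        wm$hidden[[k]]$W[] <- 1
        wm$hidden[[k]]$b[] <- 0
      }
      wm$wo[] <- c(rep(0, wm$d), rep(1, length(wm$wo) - wm$d))
      wm$bo <- 0
      wm
    }))
    wd <- if (is.null(hyper$weight_decay)) 0 else hyper$weight_decay
    m <- v <- numeric(length(theta))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    best <- theta; best_val <- Inf; since_best <- 0L
    train_curve <- val_curve <- numeric(0)
    for (t in seq_len(hyper$epochs)) {
      w <- .unflatten(theta, w)
      gr <- .cascadeGrad(w, Xtr, ytr)
      g <- .flatten(gr$grad) + 2 * wd * mask * theta
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      lr <- hyper$lr * (0.005 + 0.995 * 0.5 *
                          (1 + cos(pi * (t - 1) / hyper$epochs)))
      theta <- theta - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
      monitor <- if (length(val_idx)) {
        mean((.cascadeForward(.unflatten(theta, w), Xval) - yval)^2)
      } else gr$loss
      train_curve[t] <- gr$loss
      val_curve[t] <- monitor
      if (monitor < best_val - hyper$tol) {
        best_val <- monitor; best <- theta; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= hyper$patience) break
      }
    }
    list(weights = .unflatten(best, w),
         epochs_run = length(train_curve),
         train_curve = train_curve, val_curve = val_curve,
         best_val = best_val)
  })
}
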