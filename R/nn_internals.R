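# Internal neural-network primitives.
#
# Activations live as (B*T) x C matrices with row index r = (t-1)*B + b, so a
# B x T univariate batch enters the network as matrix(as.vector(X), ncol = 1).
# Convolutions are realized by im2col + one BLAS matmul; "same" zero padding
# with pad_left = floor((k-1)/2), pad_right = k-1-pad_left. All parameters are
# plain numeric matrices/vectors nested in lists; gradients mirror that shape.

conv_forward <- function(X, W, bvec, k, B, T) {
  Cin <- ncol(X)
  pad_l <- (k - 1L) %/% 2L
  Tp <- T + k - 1L
  base <- seq_len(B * T)
  Xp <- matrix(0, B * Tp, Cin)
  Xp[pad_l * B + base, ] <- X
  M <- matrix(0, B * T, k * Cin)
  for (c in seq_len(Cin))
    for (j in seq_len(k))
      M[, (c - 1L) * k + j] <- Xp[(j - 1L) * B + base, c]
  Y <- M %*% W
  Y <- Y + rep(bvec, each = nrow(Y))
  list(out = Y, cache = list(M = M, k = k, B = B, T = T, Cin = Cin,
                             pad_l = pad_l, Tp = Tp))
}

conv_backward <- function(dY, W, cache, need_dx = TRUE) {
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dX <- NULL
  if (need_dx) {
    B <- cache$B; T <- cache$T; k <- cache$k; Cin <- cache$Cin
    base <- seq_len(B * T)
    dM <- tcrossprod(dY, W)
    dXp <- matrix(0, B * cache$Tp, Cin)
    for (c in seq_len(Cin))
      for (j in seq_len(k)) {
        rows <- (j - 1L) * B + base
        dXp[rows, c] <- dXp[rows, c] + dM[, (c - 1L) * k + j]
      }
    dX <- dXp[cache$pad_l * B + base, , drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

bn_forward <- function(X, bn, training, eps, momentum) {
  n <- nrow(X)
  if (training && n > 1L) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = n)
    va <- colMeans(xc * xc)
    invstd <- 1 / sqrt(va + eps)
    xhat <- xc * rep(invstd, each = n)
    bn$rmean <- momentum * bn$rmean + (1 - momentum) * mu
    bn$rvar <- momentum * bn$rvar + (1 - momentum) * va
  } else {
    invstd <- 1 / sqrt(bn$rvar + eps)
    xhat <- (X - rep(bn$rmean, each = n)) * rep(invstd, each = n)
  }
  Y <- xhat * rep(bn$gamma, each = n) + rep(bn$beta, each = n)
  list(out = Y, bn = bn,
       cache = list(xhat = xhat, invstd = invstd, gamma = bn$gamma,
                    training = training && n > 1L))
}

bn_backward <- function(dY, cache) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  if (cache$training) {
    coef <- rep(cache$gamma * cache$invstd / n, each = n)
    dX <- coef * (n * dY - rep(dbeta, each = n) -
                    cache$xhat * rep(dgamma, each = n))
  } else {
    # inference mode: affine map with fixed running statistics
    dX <- dY * rep(cache$gamma * cache$invstd, each = n)
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# one residual block: conv/bn/relu x2 + conv/bn on the main path, identity or
# projected (1x1 conv + bn) shortcut, sum, relu
block_forward <- function(X, blk, kernels, B, T, training, eps, mom) {
  cv1 <- conv_forward(X, blk$conv1$W, blk$conv1$b, kernels[1], B, T)
  n1 <- bn_forward(cv1$out, blk$bn1, training, eps, mom); blk$bn1 <- n1$bn
  r1 <- relu_forward(n1$out)
  cv2 <- conv_forward(r1$out, blk$conv2$W, blk$conv2$b, kernels[2], B, T)
  n2 <- bn_forward(cv2$out, blk$bn2, training, eps, mom); blk$bn2 <- n2$bn
  r2 <- relu_forward(n2$out)
  cv3 <- conv_forward(r2$out, blk$conv3$W, blk$conv3$b, kernels[3], B, T)
  n3 <- bn_forward(cv3$out, blk$bn3, training, eps, mom); blk$bn3 <- n3$bn
  if (!is.null(blk$proj)) {
    pv <- conv_forward(X, blk$proj$conv$W, blk$proj$conv$b, 1L, B, T)
    pn <- bn_forward(pv$out, blk$proj$bn, training, eps, mom)
    blk$proj$bn <- pn$bn
    short <- pn$out
    pcache <- list(conv = pv$cache, bn = pn$cache)
  } else {
    short <- X
    pcache <- NULL
  }
  s <- n3$out + short
  ro <- relu_forward(s)
  list(out = ro$out, blk = blk,
       cache = list(cv1 = cv1$cache, bn1 = n1$cache, r1 = r1$cache,
                    cv2 = cv2$cache, bn2 = n2$cache, r2 = r2$cache,
                    cv3 = cv3$cache, bn3 = n3$cache,
                    proj = pcache, r_out = ro$cache))
}

block_backward <- function(dOut, blk, cache, need_dx = TRUE) {
  d_s <- dOut * cache$r_out
  g <- list()
  b3 <- bn_backward(d_s, cache$bn3)
  g$bn3 <- list(gamma = b3$dgamma, beta = b3$dbeta)
  c3 <- conv_backward(b3$dX, blk$conv3$W, cache$cv3)
  g$conv3 <- list(W = c3$dW, b = c3$db)
  d_r2 <- c3$dX * cache$r2
  b2 <- bn_backward(d_r2, cache$bn2)
  g$bn2 <- list(gamma = b2$dgamma, beta = b2$dbeta)
  c2 <- conv_backward(b2$dX, blk$conv2$W, cache$cv2)
  g$conv2 <- list(W = c2$dW, b = c2$db)
  d_r1 <- c2$dX * cache$r1
  b1 <- bn_backward(d_r1, cache$bn1)
  g$bn1 <- list(gamma = b1$dgamma, beta = b1$dbeta)
  c1 <- conv_backward(b1$dX, blk$conv1$W, cache$cv1,
                      need_dx = need_dx || !is.null(blk$proj))
  g$conv1 <- list(W = c1$dW, b = c1$db)
  dX <- NULL
  if (!is.null(blk$proj)) {
    pb <- bn_backward(d_s, cache$proj$bn)
    g$proj <- list(bn = list(gamma = pb$dgamma, beta = pb$dbeta))
    pc <- conv_backward(pb$dX, blk$proj$conv$W, cache$proj$conv,
                        need_dx = need_dx)
    g$proj$conv <- list(W = pc$dW, b = pc$db)
    if (need_dx) dX <- c1$dX + pc$dX
  } else if (need_dx) {
    dX <- c1$dX + d_s              # identity shortcut passes gradient through
  }
  list(grads = g, dX = dX)
}

nn_forward <- function(net, X, training, with_cache = TRUE) {
  B <- nrow(X); T <- ncol(X)
  A <- matrix(as.vector(X), ncol = 1L)          # (B*T) x 1, r = (t-1)*B + b
  caches <- vector("list", length(net$blocks))
  for (i in seq_along(net$blocks)) {
    bf <- block_forward(A, net$blocks[[i]], net$meta$kernels, B, T,
                        training, net$meta$bn_eps, net$meta$bn_momentum)
    net$blocks[[i]] <- bf$blk
    if (with_cache) caches[[i]] <- bf$cache
    A <- bf$out
  }
  grp <- rep_len(seq_len(B), B * T)
  G <- rowsum(A, grp) / T                        # global average pooling
  dimnames(G) <- NULL
  Z <- G %*% net$head$W + rep(net$head$b, each = B)
  list(logits = Z, net = net,
       cache = if (with_cache) list(caches = caches, G = G, grp = grp,
                                    B = B, T = T, A_rows = B * T) else NULL)
}

nn_backward <- function(net, fwd_cache, dZ, need_input_grad = FALSE) {
  grads <- list(head = list(W = crossprod(fwd_cache$G, dZ), b = colSums(dZ)))
  dG <- tcrossprod(dZ, net$head$W)
  dA <- dG[fwd_cache$grp, , drop = FALSE] / fwd_cache$T
  gblocks <- vector("list", length(net$blocks))
  for (i in rev(seq_along(net$blocks))) {
    need <- need_input_grad || i > 1L
    bb <- block_backward(dA, net$blocks[[i]], fwd_cache$caches[[i]],
                         need_dx = need)
    gblocks[[i]] <- bb$grads
    dA <- bb$dX
  }
  grads$blocks <- gblocks
  dX <- NULL
  if (need_input_grad)
    dX <- matrix(dA[, 1], nrow = fwd_cache$B)    # back to B x T
  list(grads = grads, dX = dX)
}

# ---- Adam over nested parameter lists ------------------------------------
# Trainable leaves are named W, b, gamma, beta; rmean/rvar are skipped.

.trainable <- c("W", "b", "gamma", "beta")

# keep only trainable leaves, preserving (possibly unnamed) list structure
pick_trainable <- function(p, name = "") {
  if (!is.list(p)) {
    if (name %in% .trainable) return(p)
    return(NULL)
  }
  nms <- names(p)
  out <- vector("list", length(p))
  keep <- logical(length(p))
  for (i in seq_along(p)) {
    key <- if (is.null(nms)) "" else nms[i]
    sub <- pick_trainable(p[[i]], key)
    if (!is.null(sub)) { out[[i]] <- sub; keep[i] <- TRUE }
  }
  if (!is.null(nms)) names(out) <- nms
  out <- out[keep]
  if (length(out)) out else NULL
}

adam_init <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  kept <- pick_trainable(params)
  list(m = zero(kept), v = zero(kept))
}

# applies Adam on the parameter list using a gradient list shaped as produced
# by nn_backward; unnamed sub-lists (the block list) are matched by position
adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  step <- function(p, g, m, v) {
    if (is.list(g)) {
      keys <- names(g)
      for (i in seq_along(g)) {
        key <- if (is.null(keys) || !nzchar(keys[i])) i else keys[i]
        res <- step(p[[key]], g[[key]], m[[key]], v[[key]])
        p[[key]] <- res$p; m[[key]] <- res$m; v[[key]] <- res$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  res <- step(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v))
}

n_parameters <- function(params) {
  total <- 0L
  walk <- function(p, name) {
    if (is.list(p)) {
      nms <- names(p)
      for (i in seq_along(p))
        walk(p[[i]], if (is.null(nms)) "" else nms[i])
    } else if (name %in% .trainable) total <<- total + length(p)
    invisible(NULL)
  }
  walk(params, "")
  total
}
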