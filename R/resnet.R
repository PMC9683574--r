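#' Batch size rule for small training sets
#'
#' `min(ceiling(n_train / 10), 16)`, except that very small training sets
#' (`n_train <= 10`) use a batch of 2.
#'
#' @param n_train number of training instances (>= 1).
#' @return A positive integer batch size.
#' @export
compute_batch_size <- function(n_train) {
  if (length(n_train) != 1L || !is.finite(n_train) || n_train < 1 ||
      n_train != round(n_train))
    stop("n_train must be a single integer >= 1", call. = FALSE)
  if (n_train <= 10) return(2L)
  as.integer(min(ceiling(n_train / 10), 16))
}

#' Estimate the residual-block depth from the training set
#'
#' The number of residual blocks is adapted to the training data, shrinking
#' when the (possibly perturbation-induced) data are redundant and growing
#' with dataset complexity, within fixed bounds. The exact distribution-aware
#' depth estimator is external to this package; the documented stand-in maps
#' the complexity score `C * log2(#distinct instances)` linearly from the
#' score range [2, 24] onto the depth bounds, clamped. The heuristic is
#' deterministic, invariant to exact duplication of rows, monotone
#' non-decreasing in the score, and can be overridden by an explicit
#' `n_blocks` in [resnet_config()].
#'
#' @param train a [ts_dataset()].
#' @param bounds integer depth bounds, default `c(2, 10)`.
#' @return An integer depth within `bounds`.
#' @export
estimate_depth <- function(train, bounds = c(2L, 10L)) {
  stopifnot(inherits(train, "shapaal_dataset"))
  lo <- bounds[1]; hi <- bounds[2]
  n_distinct <- nrow(unique(cbind(train$series, train$labels)))
  score <- train$n_classes * log2(max(n_distinct, 1))
  frac <- (score - 2) / (24 - 2)
  as.integer(max(lo, min(hi, lo + round(frac * (hi - lo)))))
}

#' Residual-network configuration
#'
#' @param n_blocks number of residual blocks, in `[2, 10]`; `NULL` defers to
#'   [estimate_depth()] at fit time.
#' @param batch_size mini-batch size; `NULL` (default) applies
#'   [compute_batch_size()] to the training-set size.
#' @param learning_rate fixed learning rate (default `1e-3`).
#' @param epochs number of training epochs (default 500; small training sets
#'   make this cheap).
#' @param filters filters per block, a scalar recycled over blocks or a
#'   vector of length `n_blocks` (default 64, the community time-series
#'   residual-network baseline).
#' @param kernels the three convolution kernel lengths within each block
#'   (default `c(8, 5, 3)`).
#' @param seed integer seed for initialization and batch shuffling.
#' @param restore_best keep the parameters from the epoch with the lowest
#'   training loss (default `TRUE`).
#' @param bn_eps,bn_momentum batch-normalization stabilizer and running-stat
#'   momentum.
#' @return An object of class `shapaal_resnet_config`.
#' @export
resnet_config <- function(n_blocks = NULL, batch_size = NULL,
                          learning_rate = 1e-3, epochs = 500L,
                          filters = 64L, kernels = c(8L, 5L, 3L),
                          seed = 1L, restore_best = TRUE,
                          bn_eps = 1e-3, bn_momentum = 0.9) {
  if (!is.null(n_blocks)) {
    n_blocks <- as.integer(n_blocks)
    if (n_blocks < 2L || n_blocks > 10L)
      stop("n_blocks must lie in [2, 10]", call. = FALSE)
  }
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (length(kernels) != 3L || any(kernels < 1L))
    stop("kernels must be three positive lengths", call. = FALSE)
  structure(list(n_blocks = n_blocks, batch_size = batch_size,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 filters = as.integer(filters), kernels = as.integer(kernels),
                 seed = as.integer(seed), restore_best = isTRUE(restore_best),
                 bn_eps = bn_eps, bn_momentum = bn_momentum),
            class = "shapaal_resnet_config")
}

#' Build an (unfitted) perturbed-identity residual network
#'
#' Architecture: the univariate input of length T is reshaped to a T x 1
#' single-channel plane (so the convolution operators are k x 1 kernels of a
#' 2-D convolution), followed by `n_blocks` residual blocks — each a
#' convolution/batch-norm/ReLU stack of kernel lengths 8/5/3 summed with the
#' shortcut path (1 x 1 projection only where channel counts differ) — then
#' global average pooling and a dense softmax layer over the classes.
#' Parameter initialization is seeded and deterministic.
#'
#' @param config a [resnet_config()] with `n_blocks` set.
#' @param input_length series length T.
#' @param n_classes number of classes C (>= 2).
#' @return An object of class `shapaal_model` (unfitted).
#' @export
build_resnet <- function(config, input_length, n_classes) {
  stopifnot(inherits(config, "shapaal_resnet_config"))
  if (is.null(config$n_blocks))
    stop("n_blocks must be set (or estimated) before building", call. = FALSE)
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  if (input_length < max(config$kernels))
    stop("series length T (", input_length,
         ") is smaller than the largest kernel (", max(config$kernels), ")",
         call. = FALSE)
  chi <- config$n_blocks
  filters <- rep_len(config$filters, chi)
  k <- config$kernels
  net <- local_seed(config$seed, {
    mk_conv <- function(kk, cin, cout)
      list(W = matrix(stats::rnorm(kk * cin * cout, sd = sqrt(2 / (kk * cin))),
                      kk * cin, cout),
           b = numeric(cout))
    mk_bn <- function(cout)
      list(gamma = rep(1, cout), beta = numeric(cout),
           rmean = numeric(cout), rvar = rep(1, cout))
    blocks <- vector("list", chi)
    cin <- 1L
    for (i in seq_len(chi)) {
      f <- filters[i]
      blk <- list(conv1 = mk_conv(k[1], cin, f), bn1 = mk_bn(f),
                  conv2 = mk_conv(k[2], f, f), bn2 = mk_bn(f),
                  conv3 = mk_conv(k[3], f, f), bn3 = mk_bn(f),
                  proj = if (cin != f)
                    list(conv = mk_conv(1L, cin, f), bn = mk_bn(f)) else NULL)
      blocks[[i]] <- blk
      cin <- f
    }
    head <- list(W = matrix(stats::rnorm(cin * n_classes, sd = sqrt(1 / cin)),
                            cin, n_classes),
                 b = numeric(n_classes))
    list(blocks = blocks, head = head,
         meta = list(kernels = k, bn_eps = config$bn_eps,
                     bn_momentum = config$bn_momentum))
  })
  structure(list(net = net, config = config, input_length = input_length,
                 n_classes = n_classes, norm_stats = NULL,
                 label_levels = NULL, history = NULL,
                 variant_tag = NA_character_, fitted = FALSE),
            class = "shapaal_model")
}

#' @export
print.shapaal_model <- function(x, ...) {
  cat(sprintf(paste0("<shapaal_model%s: %d residual blocks, T=%d, C=%d, ",
                     "%d parameters, %s>\n"),
              if (is.na(x$variant_tag)) "" else paste0(" [", x$variant_tag, "]"),
              x$config$n_blocks, x$input_length, x$n_classes,
              n_parameters(x$net), if (x$fitted) "fitted" else "unfitted"))
  invisible(x)
}

#' Fit the residual network by seeded mini-batch training
#'
#' Minimizes cross-entropy at a fixed learning rate (Adam steps, the
#' fixed-rate mini-batch gradient-descent variant used throughout). When a
#' perturbation configuration is supplied the raw series are first perturbed
#' (`x + delta`, the sampled-noise surrogate of the augmented-risk objective)
#' and only then z-normalized with the supplied training statistics — the
#' prescribed order of operations. With `alpha = 0` the run is bit-identical
#' to an unperturbed fit at the same seed. Fully deterministic given seeds.
#'
#' @param model an unfitted [build_resnet()] model.
#' @param train a raw (unnormalized) [ts_dataset()].
#' @param stats [compute_norm_stats()] of the paired (full) training set.
#' @param perturb_cfg optional [perturb_config()]; `NULL` trains unperturbed.
#' @param variant_tag optional tag ("M", "M_Shapley", "M_aug", "M_ShapAAL")
#'   recorded on the model.
#' @return The fitted `shapaal_model`, with `history` holding the per-epoch
#'   training loss and accuracy.
#' @export
fit_resnet <- function(model, train, stats, perturb_cfg = NULL,
                       variant_tag = NA_character_) {
  stopifnot(inherits(model, "shapaal_model"),
            inherits(train, "shapaal_dataset"),
            inherits(stats, "shapaal_norm_stats"))
  if (train$len != model$input_length)
    stop("training length ", train$len, " does not match the model's T = ",
         model$input_length, call. = FALSE)
  if (train$n_classes > model$n_classes)
    stop("training set has more classes than the model head", call. = FALSE)
  cfg <- model$config
  N <- train$n
  bs <- if (is.null(cfg$batch_size)) compute_batch_size(N) else cfg$batch_size
  y <- internal_labels(train)
  X_raw <- train$series

  once_draw <- NULL
  if (!is.null(perturb_cfg)) {
    stopifnot(inherits(perturb_cfg, "shapaal_perturb_config"))
    if (perturb_cfg$resample_policy == "per_instance_once")
      once_draw <- sample_perturbation(perturb_cfg, dim(X_raw))$noise
  }
  normalize <- function(M) (M - stats$mean) / stats$std

  net <- model$net
  adam <- adam_init(net)
  t_step <- 0L
  onehot <- diag(model$n_classes)
  loss_hist <- numeric(cfg$epochs)
  acc_hist <- numeric(cfg$epochs)
  best <- list(loss = Inf, net = NULL)

  for (epoch in seq_len(cfg$epochs)) {
    if (!is.null(perturb_cfg) &&
        perturb_cfg$resample_policy == "per_instance_per_epoch") {
      delta <- sample_perturbation(perturb_cfg, dim(X_raw),
                                   seed = derive_seed(perturb_cfg$seed, epoch))$noise
      X <- normalize(X_raw + delta)
    } else if (!is.null(once_draw)) {
      X <- normalize(X_raw + once_draw)
    } else {
      X <- normalize(X_raw)
    }
    ord <- local_seed(derive_seed(cfg$seed, epoch), sample.int(N))
    splits <- split(ord, ceiling(seq_along(ord) / bs))
    ep_loss <- 0; ep_hit <- 0L
    for (batch in splits) {
      B <- length(batch)
      fw <- nn_forward(net, X[batch, , drop = FALSE], training = TRUE)
      net <- fw$net
      P <- softmax_rows(fw$logits)
      yb <- y[batch]
      loss <- -mean(log(pmax(P[cbind(seq_len(B), yb)], 1e-12)))
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             call. = FALSE)
      ep_loss <- ep_loss + loss * B
      ep_hit <- ep_hit + sum(max.col(P, ties.method = "first") == yb)
      dZ <- (P - onehot[yb, , drop = FALSE]) / B
      bw <- nn_backward(net, fw$cache, dZ)
      t_step <- t_step + 1L
      upd <- adam_update(net, bw$grads, adam, cfg$learning_rate, t_step)
      # adam only touches trainable leaves; re-attach untouched running stats
      net <- upd$params
      adam <- upd$state
    }
    loss_hist[epoch] <- ep_loss / N
    acc_hist[epoch] <- ep_hit / N
    if (cfg$restore_best && loss_hist[epoch] < best$loss)
      best <- list(loss = loss_hist[epoch], net = net)
  }
  if (cfg$restore_best && !is.null(best$net)) net <- best$net

  model$net <- net
  model$norm_stats <- stats
  model$label_levels <- train$label_levels
  model$history <- data.frame(epoch = seq_len(cfg$epochs),
                              loss = loss_hist, accuracy = acc_hist)
  model$variant_tag <- variant_tag
  model$fitted <- TRUE
  model
}

#' Predict class probabilities and labels
#'
#' Raw series are z-normalized with the model's stored training statistics
#' (test data never contributes its own statistics); pass `normalized = TRUE`
#' if the input is already on the training scale. Deterministic.
#'
#' @param object a fitted `shapaal_model`.
#' @param data a [ts_dataset()] or bare numeric matrix whose row length
#'   matches the model's training T.
#' @param normalized set `TRUE` if `data` is already normalized.
#' @param ... unused.
#' @return A list with `prob` (N x C matrix, rows summing to 1) and `labels`
#'   (argmax decoded to the original label values).
#' @export
predict.shapaal_model <- function(object, data, normalized = FALSE, ...) {
  if (!object$fitted) stop("model is not fitted", call. = FALSE)
  X <- if (inherits(data, "shapaal_dataset")) data$series else as.matrix(data)
  if (ncol(X) != object$input_length)
    stop("input length ", ncol(X), " does not match the model's T = ",
         object$input_length, call. = FALSE)
  if (!normalized)
    X <- (X - object$norm_stats$mean) / object$norm_stats$std
  fw <- nn_forward(object$net, X, training = FALSE, with_cache = FALSE)
  P <- softmax_rows(fw$logits)
  idx <- max.col(P, ties.method = "first")
  list(prob = P, labels = object$label_levels[idx])
}

# gradient of the pre-softmax logit of `class_idx` (internal 1..C coding)
# w.r.t. the normalized input, for a batch; inference-mode batch norm
input_gradient <- function(model, X_norm, class_idx) {
  fw <- nn_forward(model$net, X_norm, training = FALSE, with_cache = TRUE)
  B <- nrow(X_norm)
  dZ <- matrix(0, B, model$n_classes)
  dZ[cbind(seq_len(B), class_idx)] <- 1
  bw <- nn_backward(model$net, fw$cache, dZ, need_input_grad = TRUE)
  bw$dX
}
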