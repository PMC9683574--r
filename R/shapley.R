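#' Define a transferable-utility coalition game over training samples
#'
#' Players are the `n_players` training samples; `value_fn` maps a coalition
#' (an integer vector of player indices, possibly empty) to a real payoff.
#' The stored game is normalized so that `v(empty) = 0` exactly by shifting
#' every evaluation by the raw empty-coalition value. Evaluations are
#' memoized, since the exact subset formula revisits coalitions. The value
#' function must be deterministic for a fixed game instance; stochastic
#' trainers have to be seed-frozen inside it.
#'
#' @param n_players number of players N (>= 1).
#' @param value_fn function(integer vector) -> scalar payoff.
#' @return An object of class `shapaal_game`.
#' @export
coalition_game <- function(n_players, value_fn) {
  n_players <- as.integer(n_players)
  if (n_players < 1L) stop("n_players must be >= 1", call. = FALSE)
  stopifnot(is.function(value_fn))
  cache <- new.env(parent = emptyenv())
  v0 <- value_fn(integer(0))
  if (!is.finite(v0)) stop("value_fn(empty) is not finite", call. = FALSE)
  structure(list(n_players = n_players, value_fn = value_fn,
                 v_empty = v0, cache = cache),
            class = "shapaal_game")
}

# normalized coalition value v(S) = v_raw(S) - v_raw(empty), memoized
game_value <- function(game, coalition) {
  if (length(coalition) == 0L) return(0)
  coalition <- sort.int(unique(as.integer(coalition)))
  if (any(coalition < 1L | coalition > game$n_players))
    stop("coalition contains invalid player indices", call. = FALSE)
  key <- paste(coalition, collapse = ",")
  hit <- game$cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- game$value_fn(coalition) - game$v_empty
  game$cache[[key]] <- val
  val
}

#' Marginal contribution of a player to a coalition
#'
#' `v(coalition + player) - v(coalition)`. Both evaluations are memoized on
#' the game.
#'
#' @param game a [coalition_game()].
#' @param player player index, must not already belong to `coalition`.
#' @param coalition integer vector of player indices (may be empty).
#' @return The marginal contribution, a scalar.
#' @export
marginal_contribution <- function(game, player, coalition = integer(0)) {
  stopifnot(inherits(game, "shapaal_game"))
  player <- as.integer(player)
  if (player %in% coalition)
    stop("player ", player, " is already in the coalition", call. = FALSE)
  game_value(game, c(coalition, player)) - game_value(game, coalition)
}

shapley_result <- function(values, estimator, std_errors = NULL,
                           n_evaluations = NA_integer_, seed = NA_integer_) {
  structure(list(values = as.numeric(values), estimator = estimator,
                 std_errors = std_errors,
                 n_evaluations = as.integer(n_evaluations),
                 seed = as.integer(seed)),
            class = "shapaal_shapley")
}

#' @export
print.shapaal_shapley <- function(x, ...) {
  cat(sprintf("<shapley values: N=%d, estimator=%s, sum=%.6g>\n",
              length(x$values), x$estimator, sum(x$values)))
  invisible(x)
}

#' Exact Shapley values by enumeration
#'
#' Two independent exact routes: `subset_formula` enumerates all `2^N`
#' coalitions and applies the weighted-marginal sum
#' `phi(n) = sum over coalitions S not containing n of
#' |S|! (N-|S|-1)! / N! * (v(S+n) - v(S))`; `permutation_enumeration`
#' averages the left-to-right marginal of every one of the `N!` player
#' orders. The two agree to numerical precision and both satisfy the
#' efficiency axiom `sum(phi) = v(grand coalition)`.
#'
#' @param game a [coalition_game()].
#' @param method `"subset_formula"` (default, feasible to `max_players = 12`)
#'   or `"permutation_enumeration"` (default cap 8).
#' @param max_players enumeration cap; above it the call is refused with a
#'   pointer to [monte_carlo_shapley()].
#' @return A `shapaal_shapley` result with `estimator` `"exact_subset"` or
#'   `"exact_permutation"`.
#' @export
exact_shapley <- function(game,
                          method = c("subset_formula", "permutation_enumeration"),
                          max_players = NULL) {
  stopifnot(inherits(game, "shapaal_game"))
  method <- match.arg(method)
  N <- game$n_players
  cap <- if (is.null(max_players)) {
    if (method == "subset_formula") 12L else 8L
  } else as.integer(max_players)
  if (N > cap)
    stop("N = ", N, " exceeds the enumeration cap (", cap,
         ") for ", method, "; use monte_carlo_shapley()", call. = FALSE)

  if (method == "subset_formula") {
    n_sub <- bitwShiftL(1L, N)
    vals <- numeric(n_sub)                       # v by bitmask + 1
    members <- lapply(seq_len(n_sub) - 1L, function(mask)
      which(bitwAnd(mask, bitwShiftL(1L, seq_len(N) - 1L)) != 0L))
    for (i in seq_len(n_sub)) vals[i] <- game_value(game, members[[i]])
    sizes <- vapply(members, length, integer(1))
    lf <- lfactorial(0:N)
    # |S|! (N-|S|-1)! / N!; the grand coalition's entry is never referenced
    # (no player is missing from it), so its index is clamped
    w <- exp(lf[sizes + 1L] + lf[pmax(N - sizes, 1L)] - lf[N + 1L])
    phi <- numeric(N)
    for (n in seq_len(N)) {
      bit <- bitwShiftL(1L, n - 1L)
      without <- which(bitwAnd(seq_len(n_sub) - 1L, bit) == 0L)
      phi[n] <- sum(w[without] *
                      (vals[without + bit] - vals[without]))
    }
    return(shapley_result(phi, "exact_subset",
                          n_evaluations = n_sub))
  }

  # evaluate all coalitions once (memoized), then scan every permutation
  # left-to-right with bitmask prefix lookups
  n_sub <- bitwShiftL(1L, N)
  vals <- numeric(n_sub)
  members <- lapply(seq_len(n_sub) - 1L, function(mask)
    which(bitwAnd(mask, bitwShiftL(1L, seq_len(N) - 1L)) != 0L))
  for (i in seq_len(n_sub)) vals[i] <- game_value(game, members[[i]])
  perms <- all_permutations(N)
  stopifnot(nrow(perms) == factorial(N))
  phi <- numeric(N)
  pow2 <- 2^(seq_len(N) - 1L)
  for (r in seq_len(nrow(perms))) {
    ord <- perms[r, ]
    prefix <- cumsum(pow2[ord])
    phi[ord] <- phi[ord] + (vals[prefix + 1L] - vals[c(0, prefix[-N]) + 1L])
  }
  shapley_result(phi / nrow(perms), "exact_permutation",
                 n_evaluations = n_sub)
}

# all permutations of 1..n as an (n! x n) integer matrix: insert n at every
# position of each permutation of 1..(n-1)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  blocks <- lapply(seq_len(n), function(pos) {
    left <- sub[, seq_len(pos - 1L), drop = FALSE]
    right <- if (pos <= n - 1L) sub[, pos:(n - 1L), drop = FALSE]
             else sub[, integer(0), drop = FALSE]
    cbind(left, n, right)
  })
  out <- do.call(rbind, blocks)
  storage.mode(out) <- "integer"
  out
}

#' Monte-Carlo permutation estimate of Shapley values
#'
#' Samples player orders uniformly and averages, per player, the marginal
#' contribution when it joins its predecessors scanned left to right. Returns
#' per-player standard errors of the mean. Seed-deterministic.
#'
#' @param game a [coalition_game()].
#' @param n_permutations number of sampled orders (>= 2).
#' @param seed integer seed.
#' @return A `shapaal_shapley` result with `estimator = "monte_carlo"` and
#'   `std_errors`.
#' @export
monte_carlo_shapley <- function(game, n_permutations = 200L, seed = 1L) {
  stopifnot(inherits(game, "shapaal_game"))
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 2L) stop("n_permutations must be >= 2", call. = FALSE)
  N <- game$n_players
  sums <- numeric(N)
  sq <- numeric(N)
  orders <- local_seed(seed, {
    matrix(replicate(n_permutations, sample.int(N)), ncol = N, byrow = TRUE)
  })
  # sampled prefixes rarely recur, so the scan calls the value function
  # directly instead of going through the memo
  vfun <- game$value_fn
  v0 <- game$v_empty
  for (r in seq_len(n_permutations)) {
    prev <- 0
    ord <- orders[r, ]
    for (pos in seq_len(N)) {
      cur <- vfun(ord[seq_len(pos)]) - v0
      d <- cur - prev
      p <- ord[pos]
      sums[p] <- sums[p] + d
      sq[p] <- sq[p] + d * d
      prev <- cur
    }
  }
  phi <- sums / n_permutations
  se <- sqrt(pmax(sq / n_permutations - phi^2, 0) / (n_permutations - 1L))
  shapley_result(phi, "monte_carlo", std_errors = se,
                 n_evaluations = n_permutations * N, seed = seed)
}

#' Retraining value function: coalition worth as held-out accuracy
#'
#' Definition-faithful data valuation: the worth of a coalition of training
#' samples is the accuracy on `eval_set` of a surrogate classifier trained on
#' exactly those samples, shifted so the empty coalition — scored as the
#' majority-class baseline — is worth 0.
#'
#' Surrogates: `"1nn"` (default) is the cheap oracle path, a 1-nearest-
#' neighbour on the raw series with Euclidean distance; when `eval_set` is
#' the training set itself (a declared reuse, `reuse_train = TRUE` or
#' detected by identity), matching is leave-one-out so a sample can never
#' validate its own label. `"resnet"` trains the full perturbed residual
#' network per coalition (expensive; only sensible for exact valuation of a
#' handful of players).
#'
#' @param train a [ts_dataset()] whose rows are the players.
#' @param eval_set a [ts_dataset()] scored by the surrogate; either disjoint
#'   from `train` or a declared reuse of it.
#' @param surrogate `"1nn"` or `"resnet"`.
#' @param reuse_train declare that `eval_set` re-uses the training rows
#'   (switches the 1-NN surrogate to leave-one-out matching). Auto-detected
#'   when the two matrices are identical.
#' @param resnet_cfg,stats,perturb_cfg configuration for the `"resnet"`
#'   surrogate (ignored for `"1nn"`).
#' @return A [coalition_game()] with `n_players = train$n`.
#' @export
retrain_value_fn <- function(train, eval_set, surrogate = c("1nn", "resnet"),
                             reuse_train = NULL, resnet_cfg = NULL,
                             stats = NULL, perturb_cfg = NULL) {
  stopifnot(inherits(train, "shapaal_dataset"),
            inherits(eval_set, "shapaal_dataset"))
  surrogate <- match.arg(surrogate)
  if (eval_set$n < 1L) stop("empty eval_set", call. = FALSE)
  if (is.null(reuse_train))
    reuse_train <- identical(train$series, eval_set$series) &&
      identical(train$labels, eval_set$labels)

  # chance/majority baseline for the empty coalition
  majority <- train$label_levels[which.max(tabulate(internal_labels(train),
                                                    train$n_classes))]
  v_base <- mean(eval_set$labels == majority)

  if (surrogate == "1nn") {
    # squared Euclidean distances eval x train, computed once
    D <- outer(rowSums(eval_set$series^2), rowSums(train$series^2), "+") -
      2 * tcrossprod(eval_set$series, train$series)
    if (reuse_train) {
      stopifnot(nrow(D) == train$n)
      D[cbind(seq_len(train$n), seq_len(train$n))] <- Inf   # leave-one-out
    }
    truth <- eval_set$labels
    tr_labels <- train$labels
    value_fn <- function(S) {
      if (length(S) == 0L) return(v_base)
      if (reuse_train && length(S) == 1L) {
        # a lone training sample can classify every eval point except itself
        pred <- rep(tr_labels[S], length(truth))
        pred[S] <- majority                  # no reference left: fall back
        return(mean(pred == truth))
      }
      Dsub <- D[, S, drop = FALSE]
      pred <- tr_labels[S][max.col(-Dsub, ties.method = "first")]
      mean(pred == truth)
    }
  } else {
    if (is.null(resnet_cfg) || is.null(stats))
      stop("the resnet surrogate needs resnet_cfg and stats", call. = FALSE)
    value_fn <- function(S) {
      if (length(S) == 0L) return(v_base)
      sub <- subset_dataset(train, S)
      mdl <- build_resnet(resnet_cfg, train$len, train$n_classes)
      mdl <- fit_resnet(mdl, sub, stats, perturb_cfg = perturb_cfg)
      pr <- predict(mdl, eval_set)
      mean(pr$labels == eval_set$labels)
    }
  }
  coalition_game(train$n, value_fn)
}

#' Per-sample values from gradient attribution on a fitted model
#'
#' The practical shortcut to sample valuation: instead of retraining per
#' coalition, each training sample's value is the signed sum over its T time
#' steps of a gradient-based Shapley-style attribution of the fitted model's
#' true-class logit — the input gradient at the sample multiplied by the
#' sample's displacement from the mean of a background set of training
#' instances (`attribution_t = grad_t * (x_t - mean(background)_t)`), the
#' linearized form of attribution against a background distribution.
#'
#' @param model a fitted `shapaal_model` (typically the augmented model).
#' @param train the training set the model was fitted on.
#' @param background_size number of training instances in the background set
#'   (default `min(N, 50)`); drawn seeded without replacement.
#' @param seed integer seed controlling the background draw.
#' @param aggregation how time-step attributions collapse to one scalar per
#'   sample: `"sum"` (default, sign-preserving), `"mean"`.
#' @return A `shapaal_shapley` result with `estimator = "model_attribution"`.
#' @export
model_attribution_values <- function(model, train,
                                     background_size = NULL, seed = 1L,
                                     aggregation = c("sum", "mean")) {
  stopifnot(inherits(model, "shapaal_model"), inherits(train, "shapaal_dataset"))
  if (!model$fitted) stop("model is not fitted", call. = FALSE)
  aggregation <- match.arg(aggregation)
  N <- train$n
  if (is.null(background_size)) background_size <- min(N, 50L)
  if (background_size > N)
    stop("background_size (", background_size, ") exceeds N (", N, ")",
         call. = FALSE)
  bg_idx <- local_seed(seed, sample.int(N, background_size))
  st <- model$norm_stats
  Xn <- (train$series - st$mean) / st$std
  bg_mean <- colMeans(Xn[bg_idx, , drop = FALSE])
  y_int <- match(train$labels, model$label_levels)
  G <- input_gradient(model, Xn, y_int)
  A <- G * (Xn - rep(bg_mean, each = N))
  vals <- switch(aggregation, sum = rowSums(A), mean = rowMeans(A))
  shapley_result(vals, "model_attribution", n_evaluations = N, seed = seed)
}
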