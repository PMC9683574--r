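#' Configuration of the controlled additive Gaussian perturbation
#'
#' The augmentation noise is drawn as `alpha * Normal(mu, sigma2)`, with `mu`
#' and `sigma2` the pooled mean and variance of the paired training matrix and
#' `alpha` a small scaling factor keeping the signal-to-noise ratio high
#' (default 0.020). `alpha = 0` reduces the perturbation to an exact identity.
#'
#' @param alpha non-negative scaling factor.
#' @param mu mean of the base Gaussian (training-matrix mean).
#' @param sigma2 non-negative variance of the base Gaussian (training-matrix
#'   variance).
#' @param seed integer seed for the draw (R's default Mersenne-Twister).
#' @param resample_policy `"per_instance_once"` (default): one fixed noise
#'   matrix for the whole fit; `"per_instance_per_epoch"`: a fresh draw every
#'   epoch.
#' @return An object of class `shapaal_perturb_config`.
#' @seealso [perturb_config_from_stats()] to derive `mu`/`sigma2` from
#'   normalization statistics.
#' @export
perturb_config <- function(alpha = 0.020, mu = 0, sigma2 = 1, seed = 1L,
                           resample_policy = c("per_instance_once",
                                               "per_instance_per_epoch")) {
  resample_policy <- match.arg(resample_policy)
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be a finite value >= 0", call. = FALSE)
  if (!is.finite(mu) || !is.finite(sigma2)) stop("mu and sigma2 must be finite", call. = FALSE)
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, mu = mu, sigma2 = sigma2,
                 seed = as.integer(seed), resample_policy = resample_policy),
            class = "shapaal_perturb_config")
}

#' Derive a perturbation configuration from training statistics
#'
#' @param stats a [compute_norm_stats()] result of the paired training set.
#' @inheritParams perturb_config
#' @return A [perturb_config()] with `mu = stats$mean`, `sigma2 = stats$std^2`.
#' @export
perturb_config_from_stats <- function(stats, alpha = 0.020, seed = 1L,
                                      resample_policy = "per_instance_once") {
  stopifnot(inherits(stats, "shapaal_norm_stats"))
  perturb_config(alpha = alpha, mu = stats$mean, sigma2 = stats$std^2,
                 seed = seed, resample_policy = resample_policy)
}

#' Sample a concrete perturbation draw
#'
#' Entries are i.i.d. `alpha * Normal(mu, sigma2)`, so the expected entry is
#' `alpha * mu` and the entry standard deviation `alpha * sqrt(sigma2)`.
#' Deterministic given the config seed. With `alpha = 0` an all-zero matrix is
#' returned without consuming random numbers.
#'
#' @param config a [perturb_config()].
#' @param shape integer vector `c(rows, T)` of the target batch.
#' @param seed optional seed overriding `config$seed` (used by the per-epoch
#'   resampling policy).
#' @return An object of class `shapaal_perturb_draw`: list with the `noise`
#'   matrix and a `config_digest` identifier.
#' @export
sample_perturbation <- function(config, shape, seed = NULL) {
  stopifnot(inherits(config, "shapaal_perturb_config"))
  if (length(shape) != 2L || any(shape < 1L))
    stop("shape must be c(rows, T) with positive entries", call. = FALSE)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  n <- as.integer(shape[1]) * as.integer(shape[2])
  if (config$alpha == 0) {
    noise <- matrix(0, shape[1], shape[2])
  } else {
    noise <- local_seed(seed, {
      matrix(config$alpha * stats::rnorm(n, mean = config$mu,
                                         sd = sqrt(config$sigma2)),
             shape[1], shape[2])
    })
  }
  structure(list(noise = noise,
                 config_digest = sprintf("a%.6g_m%.6g_s%.6g_seed%d",
                                         config$alpha, config$mu,
                                         config$sigma2, seed)),
            class = "shapaal_perturb_draw")
}

#' Add a perturbation draw to a batch of series
#'
#' Element-wise sum. Per the training recipe the caller normalizes AFTER
#' perturbing: first `x + delta`, then z-normalization with train statistics.
#'
#' @param series_batch numeric matrix.
#' @param draw a [sample_perturbation()] result (or a bare matrix).
#' @return The perturbed matrix.
#' @export
perturb <- function(series_batch, draw) {
  noise <- if (inherits(draw, "shapaal_perturb_draw")) draw$noise else draw
  if (!identical(dim(series_batch), dim(noise)))
    stop("shape mismatch: batch is ", paste(dim(series_batch), collapse = "x"),
         ", draw is ", paste(dim(noise), collapse = "x"), call. = FALSE)
  series_batch + noise
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic derived seed kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + 7919 * as.double(k)) %% 2147483647)
}
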