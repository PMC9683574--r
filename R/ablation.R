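#' Full pipeline configuration
#'
#' Bundles every tunable of the three-stage pipeline with the defaults used
#' throughout: perturbation scale `alpha = 0.020`, fixed learning rate
#' `1e-3`, depth bounds `[2, 10]` (estimated from the data unless `n_blocks`
#' is given), the batch-size rule, and the sample-valuation estimator.
#'
#' @param alpha perturbation scaling factor (default 0.020).
#' @param n_blocks residual-block count; `NULL` defers to [estimate_depth()].
#' @param filters,kernels,learning_rate,epochs,batch_size see [resnet_config()].
#' @param estimator sample-valuation path: `"model_attribution"` (default,
#'   the fitted-model gradient-attribution shortcut), `"retrain_mc"`
#'   (Monte-Carlo permutation Shapley over the retraining game) or
#'   `"retrain_exact"` (exact enumeration, small N only).
#' @param n_permutations Monte-Carlo permutations for `"retrain_mc"`.
#' @param background_size background set size for `"model_attribution"`
#'   (default `min(N, 50)`).
#' @param surrogate surrogate classifier of the retraining game (`"1nn"` or
#'   `"resnet"`).
#' @param discard_rule `"leq"` (default) discards values `<= 0` as printed in
#'   the selection algorithm; `"lt"` is the strict-inequality variant.
#' @param resample_policy see [perturb_config()].
#' @param seed master integer seed; all stage seeds derive from it.
#' @return An object of class `shapaal_config`.
#' @export
shapaal_config <- function(alpha = 0.020, n_blocks = NULL, filters = 64L,
                           kernels = c(8L, 5L, 3L), learning_rate = 1e-3,
                           epochs = 500L, batch_size = NULL,
                           estimator = c("model_attribution", "retrain_mc",
                                         "retrain_exact"),
                           n_permutations = 200L, background_size = NULL,
                           surrogate = c("1nn", "resnet"),
                           discard_rule = c("leq", "lt"),
                           resample_policy = "per_instance_once",
                           seed = 1L) {
  estimator <- match.arg(estimator)
  surrogate <- match.arg(surrogate)
  discard_rule <- match.arg(discard_rule)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, n_blocks = n_blocks, filters = filters,
                 kernels = kernels, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = batch_size,
                 estimator = estimator,
                 n_permutations = as.integer(n_permutations),
                 background_size = background_size, surrogate = surrogate,
                 discard_rule = discard_rule,
                 resample_policy = resample_policy, seed = as.integer(seed)),
            class = "shapaal_config")
}

resnet_config_of <- function(config, seed) {
  resnet_config(n_blocks = config$n_blocks, batch_size = config$batch_size,
                learning_rate = config$learning_rate, epochs = config$epochs,
                filters = config$filters, kernels = config$kernels,
                seed = seed)
}

#' Partition training samples by the null-player discard rule
#'
#' Samples whose value is `<= 0` (default; `< 0` behind the `"lt"` flag) are
#' discarded, the rest kept. If the rule would discard every sample, a guard
#' engages: the single highest-valued sample of each class is kept and the
#' result is flagged (`fallback = TRUE`) — a trainable dataset must remain.
#'
#' @param values a `shapaal_shapley` result (or bare numeric vector).
#' @param rule `"leq"` (default) or `"lt"`.
#' @param labels class labels, required only for the per-class fallback; with
#'   `NULL` the fallback keeps the single best sample overall.
#' @return An object of class `shapaal_ablation`: `kept_indices`,
#'   `discarded_indices`, `values`, `rule`, `fallback`.
#' @export
select_subset <- function(values, rule = c("leq", "lt"), labels = NULL) {
  rule <- match.arg(rule)
  phi <- if (inherits(values, "shapaal_shapley")) values$values else as.numeric(values)
  if (length(phi) == 0L) stop("empty value vector", call. = FALSE)
  if (any(!is.finite(phi))) stop("values must be finite", call. = FALSE)
  discard <- if (rule == "leq") phi <= 0 else phi < 0
  fallback <- FALSE
  if (all(discard)) {
    fallback <- TRUE
    keep <- if (is.null(labels)) {
      which.max(phi)
    } else {
      vapply(unique(labels), function(cl) {
        idx <- which(labels == cl)
        idx[which.max(phi[idx])]
      }, integer(1))
    }
    discard <- rep(TRUE, length(phi))
    discard[keep] <- FALSE
    warning("all samples had non-positive value; fallback kept the ",
            "highest-valued sample per class", call. = FALSE)
  }
  structure(list(kept_indices = which(!discard),
                 discarded_indices = which(discard),
                 values = values,
                 rule = if (rule == "leq") "discard phi <= 0" else "discard phi < 0",
                 fallback = fallback),
            class = "shapaal_ablation")
}

#' @export
print.shapaal_ablation <- function(x, ...) {
  cat(sprintf("<ablation: kept %d, discarded %d (%s)%s>\n",
              length(x$kept_indices), length(x$discarded_indices), x$rule,
              if (x$fallback) ", FALLBACK ENGAGED" else ""))
  invisible(x)
}

# sample valuation of `train` per the configured estimator; `ref_model` is
# the fitted reference for the attribution path (NULL lets the caller fail
# loudly if that path is requested without one)
valuate_samples <- function(train, config, ref_model = NULL, seed = 1L) {
  switch(config$estimator,
         model_attribution = {
           if (is.null(ref_model))
             stop("model_attribution valuation needs a fitted reference model",
                  call. = FALSE)
           model_attribution_values(ref_model, train,
                                    background_size = config$background_size,
                                    seed = seed)
         },
         retrain_mc = {
           game <- retrain_value_fn(train, train, surrogate = config$surrogate,
                                    reuse_train = TRUE)
           monte_carlo_shapley(game, config$n_permutations, seed = seed)
         },
         retrain_exact = {
           game <- retrain_value_fn(train, train, surrogate = config$surrogate,
                                    reuse_train = TRUE)
           exact_shapley(game)
         })
}

#' Run the full three-stage pipeline (Learn, Unlearn, Re-learn)
#'
#' Learn: fit the augmented model on the perturbed-then-normalized training
#' set. Unlearn: value every training sample (with the augmented model as
#' reference on the attribution path) and discard the non-positive ones by
#' the null-player rule. Re-learn: fit a fresh, re-initialized model on the
#' perturbed retained subset (fresh seeded noise draws). Normalization
#' statistics are computed once from the raw full training matrix and carried
#' to every stage and to the clean test set. Seed-deterministic end to end.
#'
#' @param train,test raw [ts_dataset()] pair (disjoint).
#' @param config a [shapaal_config()].
#' @return A list of class `shapaal_run`: `model` (the re-learned model),
#'   `model_aug` (the stage-1 reference), `ablation`, `values`, `stats`,
#'   `metrics` (test accuracy and MPCE of the final model), `config`.
#' @export
run_shapaal <- function(train, test, config = shapaal_config()) {
  stopifnot(inherits(train, "shapaal_dataset"),
            inherits(test, "shapaal_dataset"),
            inherits(config, "shapaal_config"))
  stats <- compute_norm_stats(train)
  n_blocks <- if (is.null(config$n_blocks)) estimate_depth(train) else config$n_blocks
  rcfg <- resnet_config_of(config, seed = derive_seed(config$seed, 1L))
  rcfg$n_blocks <- as.integer(n_blocks)

  # Learn: augmented model on the full set
  pcfg_learn <- perturb_config_from_stats(stats, alpha = config$alpha,
                                          seed = derive_seed(config$seed, 2L),
                                          resample_policy = config$resample_policy)
  m_aug <- build_resnet(rcfg, train$len, train$n_classes)
  m_aug <- fit_resnet(m_aug, train, stats, perturb_cfg = pcfg_learn,
                      variant_tag = "M_aug")

  # Unlearn: value samples, discard non-contributors
  values <- valuate_samples(train, config, ref_model = m_aug,
                            seed = derive_seed(config$seed, 3L))
  ablation <- select_subset(values, rule = config$discard_rule,
                            labels = train$labels)
  sub <- subset_dataset(train, ablation$kept_indices)

  # Re-learn: fresh (re-initialized) model with the same seeded init, fresh
  # noise draws, retained subset, same statistics
  pcfg_relearn <- perturb_config_from_stats(stats, alpha = config$alpha,
                                            seed = derive_seed(config$seed, 5L),
                                            resample_policy = config$resample_policy)
  m_final <- build_resnet(rcfg, train$len, train$n_classes)
  m_final <- fit_resnet(m_final, sub, stats, perturb_cfg = pcfg_relearn,
                        variant_tag = "M_ShapAAL")

  pr <- predict(m_final, test)
  metrics <- list(
    accuracy = test_accuracy(pr$labels, test$labels),
    mpce = mpce(match(pr$labels, test$label_levels),
                match(test$labels, test$label_levels), test$n_classes))
  structure(list(model = m_final, model_aug = m_aug, ablation = ablation,
                 values = values, stats = stats, metrics = metrics,
                 n_blocks = n_blocks, config = config),
            class = "shapaal_run")
}

#' @export
print.shapaal_run <- function(x, ...) {
  cat(sprintf(paste0("<shapaal run: chi=%d blocks, kept %d/%d samples, ",
                     "test accuracy %.4f, MPCE %.4f>\n"),
              x$n_blocks, length(x$ablation$kept_indices),
              length(x$ablation$kept_indices) + length(x$ablation$discarded_indices),
              x$metrics$accuracy, x$metrics$mpce))
  invisible(x)
}

#' Four-variant ablation study over seeds
#'
#' Evaluates any subset of the variants on the identical test set with
#' identical (raw-full-train) normalization statistics, repeating over seeds
#' and aggregating by the mode of the rounded accuracies (count ties toward
#' the larger value):
#' \describe{
#'   \item{M}{plain fit on all training data, no perturbation.}
#'   \item{M_Shapley}{fit (unperturbed) on the subset selected from an
#'     unperturbed valuation — the attribution path uses the plain base model
#'     M as reference.}
#'   \item{M_aug}{perturbed fit on all training data.}
#'   \item{M_ShapAAL}{the full three-stage pipeline.}
#' }
#' With the retraining-game estimator the valuation does not involve a fitted
#' reference model, so the base fit is only performed when the M or
#' M_Shapley-with-attribution variants require it.
#'
#' @param train,test raw [ts_dataset()] pair.
#' @param config a [shapaal_config()]; its `seed` is overridden per run by
#'   `seeds`.
#' @param variants subset of `c("M", "M_Shapley", "M_aug", "M_ShapAAL")`.
#' @param seeds integer vector of run seeds (>= 1 entries).
#' @return An object of class `shapaal_ablation_report`: `accuracies` and
#'   `mpce` (seed x variant matrices), `mode_accuracy` (per variant),
#'   `ablations` (per-seed selection results of the ShapAAL path), `config`,
#'   `seeds`.
#' @export
run_ablation_study <- function(train, test, config = shapaal_config(),
                               variants = c("M", "M_Shapley", "M_aug",
                                            "M_ShapAAL"),
                               seeds = 1:5) {
  known <- c("M", "M_Shapley", "M_aug", "M_ShapAAL")
  if (length(variants) < 1L || !all(variants %in% known))
    stop("variants must be a non-empty subset of: ",
         paste(known, collapse = ", "), call. = FALSE)
  if (length(seeds) < 1L) stop("need at least one seed", call. = FALSE)
  stats <- compute_norm_stats(train)
  n_blocks <- if (is.null(config$n_blocks)) estimate_depth(train) else config$n_blocks
  acc <- matrix(NA_real_, length(seeds), length(variants),
                dimnames = list(as.character(seeds), variants))
  mpce_m <- acc
  ablations <- vector("list", length(seeds))

  evaluate <- function(model) {
    pr <- predict(model, test)
    c(acc = test_accuracy(pr$labels, test$labels),
      mpce = mpce(match(pr$labels, test$label_levels),
                  match(test$labels, test$label_levels), test$n_classes))
  }

  for (si in seq_along(seeds)) {
    seed <- as.integer(seeds[si])
    rcfg <- resnet_config_of(config, seed = derive_seed(seed, 1L))
    rcfg$n_blocks <- as.integer(n_blocks)
    m_base <- NULL
    fit_base <- function() {
      m <- build_resnet(rcfg, train$len, train$n_classes)
      fit_resnet(m, train, stats, variant_tag = "M")
    }
    need_base <- "M" %in% variants ||
      ("M_Shapley" %in% variants && config$estimator == "model_attribution")
    if (need_base) m_base <- fit_base()

    if ("M" %in% variants) {
      e <- evaluate(m_base)
      acc[si, "M"] <- e["acc"]; mpce_m[si, "M"] <- e["mpce"]
    }
    if ("M_aug" %in% variants || ("M_ShapAAL" %in% variants &&
                                  config$estimator == "model_attribution")) {
      pcfg <- perturb_config_from_stats(stats, alpha = config$alpha,
                                        seed = derive_seed(seed, 2L),
                                        resample_policy = config$resample_policy)
      m_aug <- build_resnet(rcfg, train$len, train$n_classes)
      m_aug <- fit_resnet(m_aug, train, stats, perturb_cfg = pcfg,
                          variant_tag = "M_aug")
    } else m_aug <- NULL
    if ("M_aug" %in% variants) {
      e <- evaluate(m_aug)
      acc[si, "M_aug"] <- e["acc"]; mpce_m[si, "M_aug"] <- e["mpce"]
    }

    if ("M_Shapley" %in% variants) {
      vals <- valuate_samples(train, config, ref_model = m_base,
                              seed = derive_seed(seed, 3L))
      sel <- select_subset(vals, rule = config$discard_rule,
                           labels = train$labels)
      sub <- subset_dataset(train, sel$kept_indices)
      m_shap <- build_resnet(rcfg, train$len, train$n_classes)
      m_shap <- fit_resnet(m_shap, sub, stats, variant_tag = "M_Shapley")
      e <- evaluate(m_shap)
      acc[si, "M_Shapley"] <- e["acc"]; mpce_m[si, "M_Shapley"] <- e["mpce"]
    }

    if ("M_ShapAAL" %in% variants) {
      vals <- valuate_samples(train, config, ref_model = m_aug,
                              seed = derive_seed(seed, 3L))
      sel <- select_subset(vals, rule = config$discard_rule,
                           labels = train$labels)
      ablations[[si]] <- sel
      sub <- subset_dataset(train, sel$kept_indices)
      pcfg2 <- perturb_config_from_stats(stats, alpha = config$alpha,
                                         seed = derive_seed(seed, 5L),
                                         resample_policy = config$resample_policy)
      m_final <- build_resnet(rcfg, train$len, train$n_classes)
      m_final <- fit_resnet(m_final, sub, stats, perturb_cfg = pcfg2,
                            variant_tag = "M_ShapAAL")
      e <- evaluate(m_final)
      acc[si, "M_ShapAAL"] <- e["acc"]; mpce_m[si, "M_ShapAAL"] <- e["mpce"]
    }
  }
  structure(list(accuracies = acc, mpce = mpce_m,
                 mode_accuracy = apply(acc, 2, mode_accuracy),
                 ablations = ablations, config = config, seeds = seeds,
                 n_blocks = n_blocks),
            class = "shapaal_ablation_report")
}

#' @export
print.shapaal_ablation_report <- function(x, ...) {
  cat("<ablation study over", length(x$seeds), "seeds>\n")
  cat("mode test accuracy per variant:\n")
  print(round(x$mode_accuracy, 4))
  invisible(x)
}
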