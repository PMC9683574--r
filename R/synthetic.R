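#' Specification of a synthetic labelled time-series benchmark
#'
#' Emulates the small-training-set regime the classifier targets: N in
#' roughly 20..200 training instances, series length 24..301, 2-3 classes,
#' class-specific waveform templates plus additive Gaussian noise, and a
#' controllable fraction of deliberately mislabeled training instances whose
#' identities are recorded as ground truth (the quantitative stand-in for
#' "negatively contributing" samples).
#'
#' @param n_train,n_test instance counts.
#' @param length_T series length.
#' @param n_classes number of classes (2 or 3).
#' @param template_family `"sinusoid"` (class-specific frequency) or
#'   `"localized_bump"` (class-specific Gaussian bump center).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param mislabel_fraction rho in `[0, 0.5)`: `floor(rho * n_train)` training
#'   labels are flipped to a uniformly chosen wrong class; test labels are
#'   never flipped.
#' @param seed integer seed.
#' @return An object of class `shapaal_synth_spec`.
#' @export
synthetic_spec <- function(n_train = 60L, n_test = 100L, length_T = 48L,
                           n_classes = 2L,
                           template_family = c("sinusoid", "localized_bump"),
                           noise_sd = 0.5, mislabel_fraction = 0,
                           seed = 1L) {
  template_family <- match.arg(template_family)
  if (n_train < 2L || n_test < 1L) stop("need n_train >= 2, n_test >= 1", call. = FALSE)
  if (length_T < 2L) stop("length_T must be >= 2", call. = FALSE)
  if (!n_classes %in% 2:3) stop("n_classes must be 2 or 3", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (mislabel_fraction < 0 || mislabel_fraction >= 0.5)
    stop("mislabel_fraction must lie in [0, 0.5)", call. = FALSE)
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 length_T = as.integer(length_T),
                 n_classes = as.integer(n_classes),
                 template_family = template_family, noise_sd = noise_sd,
                 mislabel_fraction = mislabel_fraction,
                 seed = as.integer(seed)),
            class = "shapaal_synth_spec")
}

# class templates as a C x T matrix
synthetic_templates <- function(spec) {
  T <- spec$length_T
  tt <- seq_len(T) / T
  t(vapply(seq_len(spec$n_classes), function(c) {
    switch(spec$template_family,
           sinusoid = sin(2 * pi * c * tt + (c - 1) * pi / 4),
           localized_bump = exp(-0.5 * ((tt - c / (spec$n_classes + 1)) /
                                          0.08)^2))
  }, numeric(T)))
}

#' Generate a synthetic train/test pair with ground truth
#'
#' Each instance is its class template plus i.i.d. Gaussian noise. Exactly
#' `floor(mislabel_fraction * n_train)` seeded training labels are flipped to
#' a uniformly chosen wrong class; the flipped index set is returned as
#' ground truth. Seed-deterministic; the emitted datasets satisfy all loader
#' invariants and round-trip through [write_ucr()]/[read_ucr()].
#'
#' @param spec a [synthetic_spec()].
#' @param name dataset identifier shared by the train/test pair.
#' @return A list with elements `train`, `test` (both [ts_dataset()]) and
#'   `truth` (class `shapaal_synth_truth`: `clean_labels`, `observed_labels`,
#'   `mislabeled_indices`, `template_parameters`).
#' @export
generate_synthetic <- function(spec, name = "synthetic") {
  stopifnot(inherits(spec, "shapaal_synth_spec"))
  tpl <- synthetic_templates(spec)
  C <- spec$n_classes
  out <- local_seed(spec$seed, {
    lab_train <- rep_len(seq_len(C), spec$n_train)
    lab_test <- rep_len(seq_len(C), spec$n_test)
    draw <- function(labels) {
      t(vapply(labels, function(c)
        tpl[c, ] + stats::rnorm(spec$length_T, sd = spec$noise_sd),
        numeric(spec$length_T)))
    }
    X_train <- draw(lab_train)
    X_test <- draw(lab_test)
    n_flip <- floor(spec$mislabel_fraction * spec$n_train)
    flipped <- if (n_flip > 0) sort(sample.int(spec$n_train, n_flip)) else integer(0)
    observed <- lab_train
    for (i in flipped) {
      wrong <- setdiff(seq_len(C), lab_train[i])
      observed[i] <- if (length(wrong) == 1L) wrong else
        wrong[sample.int(length(wrong), 1L)]
    }
    list(lab_train = lab_train, lab_test = lab_test, X_train = X_train,
         X_test = X_test, flipped = flipped, observed = observed)
  })
  truth <- structure(list(clean_labels = out$lab_train,
                          observed_labels = out$observed,
                          mislabeled_indices = out$flipped,
                          template_parameters = list(
                            family = spec$template_family, templates = tpl)),
                     class = "shapaal_synth_truth")
  train <- ts_dataset(out$X_train, out$observed, name = name, role = "train")
  # a subset can lose a class by chance; pin the declared label set
  train$label_levels <- seq_len(C)
  train$n_classes <- C
  test <- ts_dataset(out$X_test, out$lab_test, name = name, role = "test")
  test$label_levels <- seq_len(C)
  test$n_classes <- C
  list(train = train, test = test, truth = truth)
}

#' Precision of a discarded set against ground-truth mislabels
#'
#' Fraction of discarded training indices that are truly mislabeled. A random
#' discard of any size scores `rho` in expectation, so values above the
#' mislabel fraction demonstrate enrichment. An empty discard set is defined
#' as 0 and flagged.
#'
#' @param ablation a [select_subset()] result.
#' @param truth a `shapaal_synth_truth` from [generate_synthetic()].
#' @return A scalar in `[0, 1]`; attribute `empty_discard` flags the empty
#'   case.
#' @export
enrichment_score <- function(ablation, truth) {
  stopifnot(inherits(ablation, "shapaal_ablation"),
            inherits(truth, "shapaal_synth_truth"))
  n_total <- length(ablation$kept_indices) + length(ablation$discarded_indices)
  if (n_total != length(truth$clean_labels))
    stop("index spaces of ablation result and ground truth differ", call. = FALSE)
  d <- ablation$discarded_indices
  if (length(d) == 0L)
    return(structure(0, empty_discard = TRUE))
  structure(mean(d %in% truth$mislabeled_indices), empty_discard = FALSE)
}
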