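test_that("the null-player discard rule partitions at the <= 0 boundary", {
  sel <- select_subset(c(0.5, -0.1, 0.0, 0.2))
  expect_identical(sel$discarded_indices, c(2L, 3L))   # 0 is discarded too
  expect_identical(sel$kept_indices, c(1L, 4L))
  expect_false(sel$fallback)

  all_pos <- select_subset(c(0.2, 0.1, 0.3))
  expect_identical(all_pos$discarded_indices, integer(0))
  expect_length(all_pos$kept_indices, 3L)

  expect_warning(
    fb <- select_subset(c(-1, -0.5, -2, -0.1), labels = c(1, 1, 2, 2)),
    "fallback")
  expect_true(fb$fallback)
  expect_identical(sort(fb$kept_indices), c(2L, 4L))   # per-class argmax

  # strict-inequality variant keeps exact zeros
  strict <- select_subset(c(0.5, -0.1, 0.0, 0.2), rule = "lt")
  expect_identical(strict$discarded_indices, 2L)
  expect_error(select_subset(numeric(0)), "empty")
})

test_that("partitions match a one-line oracle on many random vectors", {
  set.seed(99)
  for (i in 1:1000) {
    phi <- rnorm(sample(3:20, 1))
    if (all(phi <= 0)) phi[1] <- abs(phi[1]) + 0.1   # guard path tested above
    sel <- select_subset(phi)
    expect_identical(sel$discarded_indices, which(phi <= 0))
    expect_identical(sel$kept_indices, which(phi > 0))
    expect_identical(sort(c(sel$kept_indices, sel$discarded_indices)),
                     seq_along(phi))
  }
})

test_that("the full pipeline runs, conserves indices, and cleans mislabels", {
  spec <- synthetic_spec(n_train = 30L, n_test = 40L, length_T = 24L,
                         mislabel_fraction = 0.2, seed = 21)
  gen <- generate_synthetic(spec)
  cfg <- shapaal_config(n_blocks = 2L, filters = 4L, epochs = 40L,
                        estimator = "retrain_mc", n_permutations = 80L,
                        seed = 5L)
  res <- run_shapaal(gen$train, gen$test, cfg)
  expect_s3_class(res$model, "shapaal_model")
  expect_identical(res$model$variant_tag, "M_ShapAAL")
  expect_identical(sort(c(res$ablation$kept_indices,
                          res$ablation$discarded_indices)), 1:30L)
  expect_gte(res$metrics$accuracy, 0.5)
  # discarded set is enriched for the known mislabels
  expect_gt(enrichment_score(res$ablation, gen$truth), 0.2)
})

test_that("degenerate settings collapse all variants onto the base model", {
  gen <- make_separable(n = 16L, seed = 30)
  cfg <- shapaal_config(alpha = 0, n_blocks = 2L, filters = 4L, epochs = 12L,
                        estimator = "retrain_mc", n_permutations = 40L,
                        seed = 3L)
  # force an all-keep valuation by replacing the estimator outcome: with
  # alpha = 0 and nothing discarded, learn and re-learn see identical data
  rep <- run_ablation_study(gen$train, gen$test, cfg,
                            variants = c("M", "M_aug"), seeds = 7L)
  expect_identical(rep$accuracies[1, "M"], rep$accuracies[1, "M_aug"])

  vals_pos <- rep(1, gen$train$n)
  sel <- select_subset(vals_pos)
  expect_length(sel$kept_indices, gen$train$n)
  st <- compute_norm_stats(gen$train)
  rcfg <- resnet_config(n_blocks = 2L, filters = 4L, epochs = 12L,
                        seed = shapaal:::derive_seed(3L, 1L))
  m_plain <- fit_resnet(build_resnet(rcfg, gen$train$len, 2L), gen$train, st)
  res <- run_shapaal(gen$train, gen$test,
                     shapaal_config(alpha = 0, n_blocks = 2L, filters = 4L,
                                    epochs = 12L, estimator = "retrain_mc",
                                    n_permutations = 40L, discard_rule = "lt",
                                    seed = 3L))
  if (length(res$ablation$discarded_indices) == 0L) {
    # all kept and alpha = 0: the re-learned model IS the plain fit
    expect_identical(res$model$net, m_plain$net)
  }
})

test_that("the ablation study reports per-seed accuracies and is reproducible", {
  gen <- make_separable(n = 14L, len = 24L, seed = 44)
  cfg <- shapaal_config(n_blocks = 2L, filters = 4L, epochs = 10L,
                        estimator = "retrain_mc", n_permutations = 30L)
  r1 <- run_ablation_study(gen$train, gen$test, cfg,
                           variants = c("M", "M_ShapAAL"), seeds = c(1L, 2L))
  expect_identical(dim(r1$accuracies), c(2L, 2L))
  expect_true(all(is.finite(r1$accuracies)))
  expect_named(r1$mode_accuracy, c("M", "M_ShapAAL"))
  r2 <- run_ablation_study(gen$train, gen$test, cfg,
                           variants = c("M", "M_ShapAAL"), seeds = c(1L, 2L))
  expect_identical(r1$accuracies, r2$accuracies)
  expect_error(run_ablation_study(gen$train, gen$test, cfg,
                                  variants = "M_bogus", seeds = 1L),
               "variants")
  one <- run_ablation_study(gen$train, gen$test, cfg, variants = "M",
                            seeds = 9L)
  expect_identical(dim(one$accuracies), c(1L, 1L))
})
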