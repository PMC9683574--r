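test_that("generation is deterministic and honors the spec exactly", {
  spec <- synthetic_spec(n_train = 60L, n_test = 30L, length_T = 32L,
                         mislabel_fraction = 0.2, seed = 12)
  g1 <- generate_synthetic(spec)
  g2 <- generate_synthetic(spec)
  expect_identical(g1$train$series, g2$train$series)
  expect_identical(g1$test$series, g2$test$series)
  expect_identical(g1$truth$mislabeled_indices, g2$truth$mislabeled_indices)

  expect_identical(g1$train$n, 60L)
  expect_identical(g1$test$n, 30L)
  expect_identical(g1$train$len, 32L)
  expect_length(g1$truth$mislabeled_indices, 12L)        # floor(0.2 * 60)

  # observed differs from clean exactly on the recorded indices
  diff_idx <- which(g1$truth$observed_labels != g1$truth$clean_labels)
  expect_identical(diff_idx, g1$truth$mislabeled_indices)
  expect_identical(g1$train$labels, g1$truth$observed_labels)
  # test labels are never flipped
  expect_identical(sort(unique(g1$test$labels)), 1:2L)

  g3 <- generate_synthetic(synthetic_spec(seed = 13))
  expect_false(identical(g1$train$series,
                         g3$train$series[seq_len(60), seq_len(32)]))
})

test_that("noiseless classes are nearest-template separable", {
  spec <- synthetic_spec(n_train = 10L, n_test = 20L, length_T = 40L,
                         noise_sd = 0, seed = 3)
  gen <- generate_synthetic(spec)
  tpl <- gen$truth$template_parameters$templates
  pred <- apply(gen$test$series, 1, function(x)
    which.min(colSums((t(tpl) - x)^2)))
  expect_equal(mean(pred == gen$test$labels), 1.0)
  # per-class mean converges on the template as noise vanishes
  spec2 <- synthetic_spec(n_train = 200L, length_T = 40L, noise_sd = 0.05,
                          seed = 4)
  gen2 <- generate_synthetic(spec2)
  m1 <- colMeans(gen2$train$series[gen2$train$labels == 1, ])
  expect_lt(max(abs(m1 - gen2$truth$template_parameters$templates[1, ])), 0.05)
})

test_that("both template families and three classes are supported", {
  for (fam in c("sinusoid", "localized_bump")) {
    gen <- generate_synthetic(synthetic_spec(n_classes = 3L,
                                             template_family = fam,
                                             noise_sd = 0.1, seed = 6))
    expect_identical(gen$train$n_classes, 3L)
    expect_identical(sort(unique(gen$truth$clean_labels)), 1:3L)
  }
  expect_error(synthetic_spec(n_classes = 5L), "2 or 3")
  expect_error(synthetic_spec(mislabel_fraction = 0.6), "0.5")
})

test_that("generated files round-trip through the UCR dialect unchanged", {
  gen <- generate_synthetic(synthetic_spec(n_train = 12L, length_T = 24L,
                                           seed = 9), name = "roundtrip")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ucr(gen$train, f)
  back <- read_ucr(f, name = "roundtrip", role = "train")
  expect_identical(unname(gen$train$series), back$series)
  expect_identical(gen$train$labels, back$labels)
})

test_that("enrichment scoring is the precision of the discard set", {
  truth <- structure(list(clean_labels = rep(1:2, 5),
                          observed_labels = rep(1:2, 5),
                          mislabeled_indices = c(2L, 5L),
                          template_parameters = list()),
                     class = "shapaal_synth_truth")
  perfect <- structure(list(kept_indices = setdiff(1:10, c(2L, 5L)),
                            discarded_indices = c(2L, 5L)),
                       class = "shapaal_ablation")
  expect_equal(as.numeric(enrichment_score(perfect, truth)), 1.0)
  disjoint <- structure(list(kept_indices = setdiff(1:10, c(1L, 3L)),
                             discarded_indices = c(1L, 3L)),
                        class = "shapaal_ablation")
  expect_equal(as.numeric(enrichment_score(disjoint, truth)), 0.0)
  none <- structure(list(kept_indices = 1:10,
                         discarded_indices = integer(0)),
                    class = "shapaal_ablation")
  sc <- enrichment_score(none, truth)
  expect_equal(as.numeric(sc), 0)
  expect_true(attr(sc, "empty_discard"))

  # random discards of any size score the mislabel fraction in expectation
  set.seed(17)
  rho <- 0.2
  tr2 <- structure(list(clean_labels = rep(1:2, 30),
                        observed_labels = rep(1:2, 30),
                        mislabeled_indices = sort(sample(60L, 12L)),
                        template_parameters = list()),
                   class = "shapaal_synth_truth")
  prec <- replicate(400, {
    d <- sort(sample(60L, 10L))
    abl <- structure(list(kept_indices = setdiff(1:60, d),
                          discarded_indices = d),
                     class = "shapaal_ablation")
    as.numeric(enrichment_score(abl, tr2))
  })
  expect_lt(abs(mean(prec) - rho), 0.05)
})
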